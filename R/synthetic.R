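# Synthetic fixtures: a score-level retention model emulating
# temperature-dependent loss of native interactions, a coordinate-level toy
# dynamics engine, and designed pose panels for parameter-recovery
# experiments. All generators are bit-reproducible for a fixed seed; random
# streams are derived per component from the master seed via a counter-based
# scheme so adding one consumer does not shift the others.

#' Temperature-dependent interaction-retention model
#'
#' Each native fingerprint bit is lost independently with rate
#' `k(T) = k0 * exp(alpha * (T - t_ref))` per ns (loss is absorbing, the
#' score-level analogue of a ligand diffusing out of the binding site);
#' non-native slots flicker on transiently with birth rate `lambda` per ns
#' per slot, emulating spurious contacts.
#'
#' @param k0 loss rate at the reference temperature (per ns, >= 0).
#' @param alpha temperature sensitivity (per K, >= 0).
#' @param t_ref reference temperature (K).
#' @param lambda noise-bit birth rate (per ns per slot, >= 0).
#' @return a `ttmd_retention` model.
#' @export
retention_model <- function(k0, alpha = 0.02, t_ref = 300, lambda = 0) {
  if (k0 < 0 || alpha < 0 || lambda < 0 || !all(is.finite(c(k0, alpha, lambda))))
    abort("rates must be finite and non-negative")
  structure(list(k0 = k0, alpha = alpha, t_ref = t_ref, lambda = lambda),
            class = "ttmd_retention")
}

#' Simulate a score series from a retention model
#'
#' Runs the full TTMD step loop at the score level: per-frame Bernoulli
#' survival of native bits with temperature-dependent rates, transient
#' noise bits, IFP_CS of each simulated fingerprint against the all-native
#' reference, and the early-termination rule after each step.
#'
#' @param native number of native fingerprint bits, or a `ttmd_layout`
#'   (whose slots are then all treated as native).
#' @param ramp a `ttmd_ramp`.
#' @param model a `ttmd_retention`.
#' @param n_slots total layout dimension (native + noise slots); defaults
#'   to twice the native count when `lambda > 0`, else the native count.
#' @param stride saved-frame interval in ns (must divide the step length).
#' @param seed RNG seed.
#' @param fraction,threshold early-termination parameters.
#' @return a `ttmd_scores` tibble.
#' @export
synth_score_series <- function(native, ramp, model, n_slots = NULL,
                               stride = 0.1, seed = 1, fraction = 0.1,
                               threshold = -0.05) {
  n_native <- if (inherits(native, "ttmd_layout")) nrow(native)
              else as.integer(native)
  stopifnot(n_native >= 1, inherits(model, "ttmd_retention"))
  if (any(abs(ramp$duration / stride - round(ramp$duration / stride)) > 1e-9))
    abort("stride must divide the step length")
  n_slots <- n_slots %||% if (model$lambda > 0) 2L * n_native else n_native
  n_noise <- n_slots - n_native
  set.seed(derive_seed(seed, 1L))
  alive <- rep(TRUE, n_native)
  p_noise <- 1 - exp(-model$lambda * stride)
  scores <- numeric(); stepv <- integer(); tempv <- numeric()
  for (i in seq_len(nrow(ramp))) {
    t_i <- ramp$temperature[i]
    k <- model$k0 * exp(model$alpha * (t_i - model$t_ref))
    p_surv <- exp(-k * stride)
    nf <- round(ramp$duration[i] / stride)
    step_scores <- numeric(nf)
    for (f in seq_len(nf)) {
      na_alive <- sum(alive)
      if (na_alive > 0)
        alive[alive] <- stats::runif(na_alive) < p_surv
      n_on_noise <- if (n_noise > 0 && p_noise > 0)
        stats::rbinom(1, n_noise, p_noise) else 0L
      hits <- sum(alive)
      norm <- sqrt((hits + n_on_noise) * n_native)
      step_scores[f] <- if (norm == 0) 0 else -hits / norm
    }
    scores <- c(scores, step_scores)
    stepv <- c(stepv, rep(i, nf)); tempv <- c(tempv, rep(t_i, nf))
    if (should_terminate(step_scores, fraction, threshold)) break
  }
  times <- stride * seq_along(scores)
  score_series(scores, stepv, tempv, times)
}

#' Toy receptor-ligand system
#'
#' A single-particle ligand in a truncated harmonic binding well at the
#' origin (depth `well_depth` kcal/mol, spring constant `spring`
#' kcal/mol/A^2, flat outside the well rim), surrounded by fixed receptor
#' pseudo-atoms on a sphere, inside a cubic box with reflecting walls.
#' All heavy atoms are flagged hydrophobic so native contacts are the
#' hydrophobic/vdW contacts between the bound ligand and the receptor
#' shell; a diffusing ligand loses them.
#'
#' @param n_receptor number of receptor pseudo-atoms.
#' @param shell_radius receptor sphere radius (Angstrom).
#' @param well_depth escape barrier (kcal/mol).
#' @param spring well spring constant (kcal/mol/A^2).
#' @param box cubic box edge (Angstrom).
#' @param gamma friction coefficient (kcal/mol ns/A^2) of the overdamped
#'   Langevin dynamics.
#' @return a `ttmd_toy_system`: a `ttmd_complex` plus dynamics parameters.
#' @export
toy_system <- function(n_receptor = 8, shell_radius = 4.0, well_depth = 3.5,
                       spring = 1.0, box = 30, gamma = 1.0) {
  stopifnot(n_receptor >= 3, well_depth > 0, spring > 0, box > 0)
  # receptor pseudo-atoms: Fibonacci sphere, deterministic
  i <- seq_len(n_receptor)
  phi <- pi * (3 - sqrt(5)) * (i - 1)
  zf <- 1 - 2 * (i - 0.5) / n_receptor
  rf <- sqrt(1 - zf^2)
  rec <- cbind(shell_radius * rf * cos(phi), shell_radius * rf * sin(phi),
               shell_radius * zf)
  atoms <- tibble::tibble(
    name = c(paste0("C", i), "C1"),
    element = "C",
    chain = "A",
    resno = c(i, 999L),
    resname = c(rep("PSD", n_receptor), "LIG"),
    x = c(rec[, 1], 0), y = c(rec[, 2], 0), z = c(rec[, 3], 0),
    is_ligand = c(rep(FALSE, n_receptor), TRUE)
  )
  cx <- suppressWarnings(new_complex(atoms))
  cx$flags$hydrophobe <- TRUE  # pseudo-atoms are apolar by construction
  structure(list(complex = cx, well_depth = well_depth, spring = spring,
                 box = box, gamma = gamma,
                 rim = sqrt(2 * well_depth / spring)),
            class = "ttmd_toy_system")
}

#' Toy Langevin engine
#'
#' A `ttmd_engine` integrating overdamped Langevin dynamics for the ligand
#' particle of a [toy_system()] at the configured temperature (receptor
#' atoms stay fixed). The ligand's escape probability per step increases
#' with temperature through the Boltzmann factor of the well depth; at 0 K
#' it sits at the well minimum. Deterministic for a given `config$seed`.
#'
#' @param system a `ttmd_toy_system`.
#' @param dt integration timestep in ns (saved frames every
#'   `config$stride`).
#' @return a `ttmd_engine`.
#' @export
toy_engine <- function(system, dt = 0.005) {
  stopifnot(inherits(system, "ttmd_toy_system"))
  k <- system$spring; rim <- system$rim
  gamma <- system$gamma; half <- system$box / 2
  lig_row <- which(system$complex$atoms$is_ligand)
  run <- function(config, state) {
    coords <- state$coords
    pos <- coords[lig_row, ]
    set.seed(config$seed)
    sigma <- sqrt(2 * .kB * max(config$temperature, 0) * dt / gamma)
    n_sub <- max(1L, round(config$stride / dt))
    n_frames <- max(1L, round(config$duration / config$stride))
    frames <- vector("list", n_frames)
    for (fr in seq_len(n_frames)) {
      for (s in seq_len(n_sub)) {
        r <- sqrt(sum(pos^2))
        force <- if (r < rim && r > 0) -k * pos else c(0, 0, 0)
        pos <- pos + force * dt / gamma + sigma * stats::rnorm(3)
        # reflecting walls
        over <- abs(pos) > half
        pos[over] <- sign(pos[over]) * (2 * half) - pos[over]
      }
      co <- coords
      co[lig_row, ] <- pos
      frames[[fr]] <- co
    }
    list(frames = frames, state = list(coords = frames[[n_frames]]))
  }
  new_engine(run, description = sprintf(
    "toy overdamped Langevin (well %.1f kcal/mol, spring %.1f)",
    system$well_depth, k))
}

#' Designed pose panel
#'
#' Generates a panel of synthetic "poses" whose retention models are
#' ordered by design: loss rates `k0` are log-spaced across `k0_range`, so
#' pose 1 is the most stable (designed rank 1) and pose `n_poses` the most
#' volatile. Mirrors a crystal-plus-docking-poses panel at desk scale; the
#' ground-truth ranking is recorded for parameter-recovery experiments.
#'
#' @param n_poses number of poses (>= 2).
#' @param k0_range range of loss rates at `t_ref` (per ns); widen for
#'   better-separated stabilities.
#' @param alpha,t_ref,lambda shared [retention_model()] parameters.
#' @return tibble: `pose_id`, `k0`, `designed_rank`, `model` (list-column).
#' @export
make_pose_panel <- function(n_poses = 6, k0_range = c(0.005, 0.5),
                            alpha = 0.02, t_ref = 300, lambda = 0.002) {
  stopifnot(n_poses >= 2)
  k0 <- exp(seq(log(k0_range[1]), log(k0_range[2]), length.out = n_poses))
  tibble::tibble(
    pose_id = sprintf("pose%02d", seq_len(n_poses)),
    k0 = k0,
    designed_rank = seq_len(n_poses),
    model = lapply(k0, retention_model, alpha = alpha, t_ref = t_ref,
                   lambda = lambda)
  )
}

#' Titrate a pose panel
#'
#' Runs `n_replicates` independent synthetic titrations per pose through
#' the full protocol loop (retention-model fingerprints, early
#' termination) and returns the per-replicate MS and IFF coefficients in
#' tidy form, ready for [aggregate_replicates()].
#'
#' @param panel a tibble from [make_pose_panel()].
#' @param ramp a `ttmd_ramp`.
#' @param n_replicates replicates per pose.
#' @param n_native native bits per pose fingerprint.
#' @param stride saved-frame interval (ns).
#' @param seed master seed; per-(pose, replicate) streams are derived.
#' @return tibble: `pose_id`, `replicate`, `ms`, `iff`,
#'   `terminated_early`, `last_temperature`.
#' @export
run_pose_panel <- function(panel, ramp = standard_ramp(), n_replicates = 5,
                           n_native = 20, stride = 0.1, seed = 1) {
  purrr::pmap_dfr(
    list(panel$pose_id, panel$model, seq_len(nrow(panel))),
    function(pid, model, pi_) {
      purrr::map_dfr(seq_len(n_replicates), function(rep_) {
        s <- synth_score_series(n_native, ramp, model, stride = stride,
                                seed = derive_seed(seed, pi_ * 1000L + rep_))
        tibble::tibble(
          pose_id = pid, replicate = rep_,
          ms = ms_coefficient(s), iff = iff_coefficient(s),
          terminated_early = max(s$step) < nrow(ramp),
          last_temperature = max(s$temperature))
      })
    })
}
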