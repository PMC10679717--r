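# Titration orchestration: engine contract, early-termination rule, the
# TTMD step loop, equilibration-stage configs and the receptor-only dry run.

#' Declarative simulation-stage configuration
#'
#' Describes one simulation stage (minimisation, restrained NVT/NPT
#' equilibration, or a constant-temperature production segment) for a
#' pluggable engine. Execution semantics belong to the engine; this object
#' only carries the parameters.
#'
#' @param stage one of `"minimize"`, `"nvt_restrained"`, `"npt_restrained"`,
#'   `"production"`.
#' @param temperature K.
#' @param duration ns (ignored for minimisation).
#' @param steps step count for minimisation stages.
#' @param timestep integration timestep in fs.
#' @param restraint list with `selection` and `force_constant`
#'   (kcal mol^-1 A^-2), or `NULL`.
#' @param pressure atm (NPT stages only).
#' @param cutoff nonbonded cutoff in Angstrom.
#' @param constraints constraint scheme tag for bonds to hydrogen.
#' @param electrostatics electrostatics method tag.
#' @param stride saved-frame interval in ns (production stages).
#' @param seed RNG seed for the engine.
#' @param solvation optional solvation metadata list.
#' @return a `ttmd_engine_config` list.
#' @export
engine_config <- function(stage, temperature = NULL, duration = NULL,
                          steps = NULL, timestep = 2, restraint = NULL,
                          pressure = NULL, cutoff = 9.0,
                          constraints = "m-shake-h", electrostatics = "pme",
                          stride = 0.1, seed = NULL, solvation = NULL) {
  stage <- match.arg(stage, c("minimize", "nvt_restrained",
                              "npt_restrained", "production"))
  if (timestep <= 0) abort("timestep must be positive")
  if (!is.null(restraint) && restraint$force_constant < 0)
    abort("restraint force constant must be >= 0")
  structure(list(stage = stage, temperature = temperature,
                 duration = duration, steps = steps, timestep = timestep,
                 restraint = restraint, pressure = pressure, cutoff = cutoff,
                 constraints = constraints, electrostatics = electrostatics,
                 stride = stride, seed = seed, solvation = solvation),
            class = "ttmd_engine_config")
}

#' Create a simulation engine from a run function
#'
#' Engines are pluggable behind a minimal contract: `run(config, state)`
#' executes one stage and returns `list(frames = <list of n x 3 coordinate
#' matrices>, state = <opaque state for the next stage>)`. Runs must be
#' deterministic given `config$seed`, return at least one frame and
#' preserve the atom count.
#'
#' @param run function of `(config, state)`.
#' @param description short capability descriptor.
#' @return a `ttmd_engine`.
#' @export
new_engine <- function(run, description = "user engine") {
  stopifnot(is.function(run))
  structure(list(run = run, description = description),
            class = "ttmd_engine")
}

#' Early-termination rule
#'
#' After each TTMD step, the mean IFP_CS over the last `fraction` of the
#' step's frames (ceiling of `fraction * n` frames) is compared with the
#' threshold: the titration stops iff that mean is strictly above it,
#' i.e. the ligand has lost its original binding mode. Boundary equality
#' continues the run.
#'
#' @param step_scores per-frame IFP_CS values of one step.
#' @param fraction trailing fraction of the step to average (default 0.1).
#' @param threshold stop threshold (default -0.05).
#' @return logical.
#' @export
should_terminate <- function(step_scores, fraction = 0.1,
                             threshold = -0.05) {
  if (!length(step_scores)) abort("empty step scores")
  k <- ceiling(fraction * length(step_scores))
  mean(tail(step_scores, k)) > threshold
}

# Shared step loop for run_titration / dry_run. Returns frames, per-frame
# scores (unless dry) and RMSD series.
titrate_loop <- function(engine, complex, layout, ramp, rules, seed,
                         stride, fraction, threshold, dry = FALSE,
                         site_radius = 5.0, keep_frames = FALSE) {
  stopifnot(inherits(engine, "ttmd_engine"))
  atoms <- complex$atoms
  ref <- complex$reference_coords
  has_lig <- any(atoms$is_ligand)
  if (!dry) {
    ref_fp <- fingerprint(ref, complex, layout, rules)
    if (sum(ref_fp) == 0)
      abort(paste("reference fingerprint has no interactions;",
                  "check the ligand selector (or use dry_run)"))
  }
  backbone <- which(atoms$is_backbone & atoms$element != "H")
  if (!length(backbone))
    backbone <- which(!atoms$is_ligand & atoms$element != "H")
  lig_heavy <- which(atoms$is_ligand & atoms$element != "H")
  site_keys <- if (has_lig)
    select_binding_site(complex, radius = site_radius)
  else unique(residue_key(atoms$chain, atoms$resno, atoms$resname))
  site_idx <- intersect(residue_atoms(complex, site_keys),
                        which(!atoms$is_ligand & atoms$element != "H"))
  state <- list(coords = ref)
  scores <- numeric(); stepv <- integer(); tempv <- numeric()
  r_lig <- numeric(); r_bb <- numeric(); r_site <- numeric()
  times <- numeric(); t0 <- 0
  frames_kept <- list()
  terminated <- FALSE; completed <- 0L
  for (i in seq_len(nrow(ramp))) {
    cfg <- engine_config("production", temperature = ramp$temperature[i],
                         duration = ramp$duration[i], stride = stride,
                         seed = derive_seed(seed, i))
    out <- engine$run(cfg, state)
    frames <- out$frames
    if (!length(frames)) abort(sprintf("engine returned no frames (step %d)", i))
    if (nrow(frames[[1]]) != nrow(atoms))
      abort(sprintf("engine changed the atom count (step %d)", i))
    state <- out$state
    step_scores <- numeric(length(frames))
    for (f in seq_along(frames)) {
      co <- frames[[f]]
      if (!dry) {
        fp <- fingerprint(co, complex, layout, rules)
        step_scores[f] <- ifp_cs(fp, ref_fp)
      }
      r_bb <- c(r_bb, rmsd(co, ref, backbone, backbone))
      r_site <- c(r_site, rmsd(co, ref, site_idx, site_idx))
      r_lig <- c(r_lig, if (length(lig_heavy))
        rmsd(co, ref, lig_heavy, backbone) else NA_real_)
    }
    scores <- c(scores, step_scores)
    stepv <- c(stepv, rep(i, length(frames)))
    tempv <- c(tempv, rep(ramp$temperature[i], length(frames)))
    times <- c(times, t0 + stride * seq_along(frames))
    t0 <- t0 + ramp$duration[i]
    if (keep_frames) frames_kept <- c(frames_kept, frames)
    completed <- i
    if (!dry && should_terminate(step_scores, fraction, threshold)) {
      terminated <- TRUE
      break
    }
  }
  list(scores = scores, step = stepv, temperature = tempv, times = times,
       rmsd = tibble::tibble(frame = seq_along(times), time = times,
                             step = stepv, rmsd_ligand = r_lig,
                             rmsd_backbone = r_bb, rmsd_site = r_site),
       terminated = terminated, completed = completed,
       frames = frames_kept, site = site_keys)
}

#' Run a thermal titration
#'
#' Executes the TTMD protocol: one engine segment per ramp step at
#' progressively increasing temperature, continuing from the previous
#' state, fingerprinting every saved frame against the reference snapshot
#' and applying the early-termination rule after each step. Also records
#' ligand (fitted on receptor backbone), receptor-backbone and binding-site
#' RMSD per frame.
#'
#' @param engine a `ttmd_engine`.
#' @param complex a `ttmd_complex`; its `reference_coords` define the
#'   native fingerprint.
#' @param layout a `ttmd_layout` built from the same complex.
#' @param ramp a `ttmd_ramp`.
#' @param rules geometric detection rules.
#' @param seed master seed; per-step engine seeds are derived from it.
#' @param stride saved-frame interval (ns).
#' @param fraction,threshold early-termination parameters
#'   (see [should_terminate()]).
#' @param site_radius binding-site RMSD selection radius (Angstrom).
#' @param keep_frames retain the coordinate frames in the result.
#' @return a `ttmd_result`: `scores` (a `ttmd_scores` tibble), `rmsd`
#'   tibble, `ramp`, `terminated_early`, `steps_completed`,
#'   `last_temperature`, `seed` and provenance.
#' @export
run_titration <- function(engine, complex, layout, ramp = standard_ramp(),
                          rules = geometry_rules(), seed = 1, stride = 0.1,
                          fraction = 0.1, threshold = -0.05,
                          site_radius = 5.0, keep_frames = FALSE) {
  lo <- titrate_loop(engine, complex, layout, ramp, rules, seed, stride,
                     fraction, threshold, dry = FALSE,
                     site_radius = site_radius, keep_frames = keep_frames)
  res <- structure(list(
    scores = score_series(lo$scores, lo$step, lo$temperature, lo$times),
    rmsd = lo$rmsd, ramp = ramp,
    terminated_early = lo$terminated,
    steps_completed = lo$completed,
    last_temperature = ramp$temperature[lo$completed],
    seed = seed, dry = FALSE, frames = lo$frames,
    provenance = list(
      geometry = unclass(rules), stride = dplyr::first(stride),
      fraction = fraction, threshold = threshold,
      layout_signature = layout_signature(layout),
      reference_hash = rlang::hash(complex$reference_coords),
      binding_site = as.character(lo$site),
      velocity_handling = "re-thermalized each step")
  ), class = "ttmd_result")
  res
}

#' Receptor-only dry run
#'
#' Runs the temperature ramp on the receptor alone to assess binding-site
#' structural plasticity before titrating the complex. No fingerprints are
#' computed, and the early-termination rule is disabled, so the full ramp
#' always runs; backbone and binding-site RMSD series are populated.
#'
#' @inheritParams run_titration
#' @return a `ttmd_result` with `scores = NULL` and `dry = TRUE`.
#' @export
dry_run <- function(engine, complex, ramp = standard_ramp(), seed = 1,
                    stride = 0.1, site_radius = 5.0) {
  lo <- titrate_loop(engine, complex, layout = NULL, ramp,
                     rules = geometry_rules(), seed, stride,
                     fraction = 0.1, threshold = -0.05, dry = TRUE,
                     site_radius = site_radius)
  structure(list(
    scores = NULL, rmsd = lo$rmsd, ramp = ramp,
    terminated_early = FALSE, steps_completed = lo$completed,
    last_temperature = ramp$temperature[lo$completed],
    seed = seed, dry = TRUE, frames = list(),
    provenance = list(stride = stride,
                      reference_hash = rlang::hash(complex$reference_coords),
                      binding_site = as.character(lo$site))
  ), class = "ttmd_result")
}

#' @export
print.ttmd_result <- function(x, ...) {
  cat("<ttmd_result> ", if (x$dry) "dry run, " else "",
      x$steps_completed, "/", nrow(x$ramp), " steps, last T = ",
      x$last_temperature, " K",
      if (x$terminated_early) " (terminated early)" else "", "\n", sep = "")
  if (!is.null(x$scores))
    cat("  MS = ", format(ms_coefficient(x$scores), digits = 5),
        ", IFF = ", format(iff_coefficient(x$scores), digits = 5), "\n",
        sep = "")
  invisible(x)
}

#' Equilibration-stage configurations
#'
#' The declarative preparation protocol preceding a titration: 500 steps of
#' conjugate-gradient energy minimisation, 0.5 ns restrained NVT
#' equilibration (5 kcal mol^-1 A^-2 harmonic positional restraints on
#' every receptor and ligand atom, water and ions free), then 0.5 ns
#' restrained NPT at 1 atm restraining only the ligand and receptor
#' backbone. All stages carry a 2 fs timestep, 9.0 A nonbonded cutoff,
#' hydrogen-bond constraints and PME electrostatics, plus solvation
#' metadata (TIP3P water, 15 A box padding, 0.154 M NaCl). Execution
#' requires a real engine backend; these objects only describe the stages.
#'
#' @param complex a `ttmd_complex`.
#' @param temperature equilibration temperature (K); by convention the
#'   lowest ramp temperature.
#' @return list of three `ttmd_engine_config` objects.
#' @export
emit_preparation_configs <- function(complex, temperature = 300) {
  solv <- list(water_model = "tip3p", padding = 15, salt = "NaCl",
               salt_concentration = 0.154)
  list(
    engine_config("minimize", steps = 500, solvation = solv),
    engine_config("nvt_restrained", temperature = temperature,
                  duration = 0.5,
                  restraint = list(selection = "receptor+ligand",
                                   force_constant = 5),
                  solvation = solv),
    engine_config("npt_restrained", temperature = temperature,
                  duration = 0.5, pressure = 1,
                  restraint = list(selection = "ligand+backbone",
                                   force_constant = 5),
                  solvation = solv)
  )
}
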