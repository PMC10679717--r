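# RMSD machinery and the titration timeline / profile reports.

#' Optimal rigid superposition
#'
#' Least-squares (Kabsch) fit of the mobile coordinates onto the reference
#' over a selection: returns the rotation and translation minimising the
#' RMSD of the selected atoms. Degenerate selections (< 3 non-collinear
#' atoms) fall back to a translation-only fit with a warning.
#'
#' @param mobile,reference n x 3 coordinate matrices (same atom count).
#' @param selection atom indices used for the fit (default: all).
#' @return list with `rotation` (3 x 3), `translation` (length 3); apply as
#'   `coords %*% rotation + translation` (rows).
#' @export
superpose <- function(mobile, reference, selection = NULL) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  if (!all(dim(mobile) == dim(reference)))
    abort("mobile and reference dimensions differ")
  sel <- selection %||% seq_len(nrow(mobile))
  if (!length(sel)) abort("empty fit selection")
  A <- mobile[sel, , drop = FALSE]
  B <- reference[sel, , drop = FALSE]
  ca <- colMeans(A); cb <- colMeans(B)
  A0 <- sweep(A, 2, ca); B0 <- sweep(B, 2, cb)
  degenerate <- nrow(A0) < 3 ||
    qr(A0, tol = 1e-8)$rank < 2 || qr(B0, tol = 1e-8)$rank < 2
  if (degenerate) {
    warn("degenerate fit selection; translation-only superposition")
    R <- diag(3)
  } else {
    H <- crossprod(A0, B0)
    sv <- svd(H)
    d <- sign(det(tcrossprod(sv$v, sv$u)))
    R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
    R <- t(R)
  }
  list(rotation = R, translation = cb - as.vector(ca %*% R))
}

apply_transform <- function(coords, fit) {
  sweep(as.matrix(coords) %*% fit$rotation, 2, fit$translation, `+`)
}

#' Root-mean-square deviation
#'
#' Superposes the frame onto the reference over `fit_selection` (optimal
#' least-squares rotation), then measures the RMSD over
#' `measure_selection` without re-fitting. With `fit_selection = NULL` no
#' superposition is applied (raw deviation).
#'
#' @param coords,reference n x 3 coordinate matrices.
#' @param measure_selection atom indices to measure over (default: all).
#' @param fit_selection atom indices to fit on, or `NULL` for no fit.
#' @return RMSD in Angstrom.
#' @export
rmsd <- function(coords, reference, measure_selection = NULL,
                 fit_selection = NULL) {
  coords <- as.matrix(coords); reference <- as.matrix(reference)
  msel <- measure_selection %||% seq_len(nrow(coords))
  if (!length(msel)) abort("empty measure selection")
  if (!is.null(fit_selection) && length(fit_selection)) {
    fit <- superpose(coords, reference, fit_selection)
    coords <- apply_transform(coords, fit)
  }
  diff <- coords[msel, , drop = FALSE] - reference[msel, , drop = FALSE]
  sqrt(mean(rowSums(diff^2)))
}

#' Titration timeline
#'
#' The per-frame report of a titration: time, step, temperature, IFP_CS
#' (NA for dry runs) and the ligand / receptor-backbone / binding-site RMSD
#' series.
#'
#' @param result a `ttmd_result`.
#' @return tibble with columns `time`, `step`, `temperature`, `ifp_cs`,
#'   `rmsd_ligand`, `rmsd_backbone`, `rmsd_site`.
#' @export
titration_timeline <- function(result) {
  stopifnot(inherits(result, "ttmd_result"))
  r <- result$rmsd
  if (!is.null(result$scores)) {
    tibble::tibble(time = result$scores$time, step = result$scores$step,
                   temperature = result$scores$temperature,
                   ifp_cs = result$scores$ifp_cs,
                   rmsd_ligand = r$rmsd_ligand,
                   rmsd_backbone = r$rmsd_backbone,
                   rmsd_site = r$rmsd_site)
  } else {
    temps <- result$ramp$temperature[r$step]
    tibble::tibble(time = r$time, step = r$step, temperature = temps,
                   ifp_cs = NA_real_, rmsd_ligand = r$rmsd_ligand,
                   rmsd_backbone = r$rmsd_backbone, rmsd_site = r$rmsd_site)
  }
}

#' Titration profile
#'
#' Per-step mean IFP_CS against step temperature, plus the straight-line
#' segment from `(T_start, -1)` to `(T_end, mean IFP_CS(T_end))` whose
#' slope is the MS coefficient.
#'
#' @param result a `ttmd_result` from [run_titration()].
#' @return tibble of step means, with the MS segment attached as attributes
#'   `endpoints` (two-row tibble) and `ms` (the slope).
#' @export
titration_profile <- function(result) {
  stopifnot(inherits(result, "ttmd_result"), !is.null(result$scores))
  sm <- step_means(result$scores)
  ms <- ms_coefficient(result$scores)
  endpoints <- tibble::tibble(
    temperature = c(sm$temperature[1], sm$temperature[nrow(sm)]),
    mean_ifp_cs = c(-1, sm$mean_ifp_cs[nrow(sm)]))
  attr(sm, "endpoints") <- endpoints
  attr(sm, "ms") <- ms
  sm
}

#' Write the canonical result tables
#'
#' Writes `timeline.csv` and (for non-dry runs) `profile.csv` into `dir`,
#' plus a `provenance.json` sidecar recording the geometry rules, seeds and
#' selections. Output is deterministic: identical seeds and inputs give
#' byte-identical files.
#'
#' @param result a `ttmd_result`.
#' @param dir output directory (created if needed).
#' @return character vector of the files written, invisibly.
#' @export
write_result_csv <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- file.path(dir, "timeline.csv")
  readr::write_csv(titration_timeline(result), files[1])
  if (!is.null(result$scores)) {
    pf <- file.path(dir, "profile.csv")
    readr::write_csv(titration_profile(result), pf)
    files <- c(files, pf)
  }
  pj <- file.path(dir, "provenance.json")
  jsonlite::write_json(c(result$provenance,
                         list(seed = result$seed,
                              terminated_early = result$terminated_early,
                              steps_completed = result$steps_completed)),
                       pj, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(c(files, pj))
}
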