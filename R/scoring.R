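#' Interaction-fingerprint cosine score (IFP_CS)
#'
#' Cosine similarity between a frame fingerprint and the reference
#' fingerprint, multiplied by -1 so the score complies with the usual
#' scoring-function scale: -1 is total congruence with the native binding
#' mode, 0 means every native binding feature is lost. If either vector is
#' all-zero the score is 0.
#'
#' @param fp,ref fingerprints on the same layout (`ttmd_fp` or plain
#'   non-negative numeric vectors of equal length).
#' @return a score in `[-1, 0]`.
#' @export
ifp_cs <- function(fp, ref) {
  if (length(fp) != length(ref))
    abort("fingerprint layout mismatch: lengths differ")
  sa <- attr(fp, "signature"); sb <- attr(ref, "signature")
  if (!is.null(sa) && !is.null(sb) && !identical(sa, sb))
    abort("fingerprint layout mismatch: different layouts")
  a <- as.numeric(fp); b <- as.numeric(ref)
  na2 <- sum(a^2); nb2 <- sum(b^2)
  if (na2 == 0 || nb2 == 0) return(0)
  -sum(a * b) / sqrt(na2 * nb2)
}

#' Per-frame score series
#'
#' Tidy container for the per-frame IFP_CS values of one titration
#' replicate: one row per saved frame with its time (ns), TTMD step index
#' and step temperature (K). Step temperatures must be strictly increasing
#' across steps and every score must lie in `[-1, 0]`.
#'
#' @param ifp_cs per-frame scores.
#' @param step integer step index per frame (1-based, contiguous).
#' @param temperature step temperature (K) per frame.
#' @param time frame times in ns (defaults to frame index / 10).
#' @return a `ttmd_scores` tibble.
#' @export
score_series <- function(ifp_cs, step, temperature, time = NULL) {
  if (!length(ifp_cs)) abort("empty score series")
  if (any(ifp_cs < -1 - 1e-9 | ifp_cs > 1e-9))
    abort("IFP_CS values must lie in [-1, 0]")
  step <- as.integer(step)
  tt <- vapply(split(temperature, step), function(x) x[1], 0)
  if (any(diff(tt[order(as.integer(names(tt)))]) <= 0))
    abort("step temperatures must be strictly increasing")
  out <- tibble::tibble(
    frame = seq_along(ifp_cs),
    time = time %||% (seq_along(ifp_cs) / 10),
    step = step, temperature = temperature,
    ifp_cs = pmin(0, pmax(-1, ifp_cs))
  )
  class(out) <- c("ttmd_scores", class(out))
  out
}

#' Titration profile step means
#'
#' The average IFP_CS score of each completed TTMD step, paired with the
#' temperature at which the step ran (the "titration profile" points).
#'
#' @param series a `ttmd_scores` tibble.
#' @return tibble with columns `step`, `temperature`, `mean_ifp_cs`.
#' @export
step_means <- function(series) {
  if (!nrow(series)) abort("empty score series")
  series |>
    dplyr::group_by(.data$step, .data$temperature) |>
    dplyr::summarise(mean_ifp_cs = mean(.data$ifp_cs), .groups = "drop") |>
    dplyr::arrange(.data$step)
}

#' MS stability coefficient
#'
#' Slope of the straight line linking the first and last points of the
#' titration profile:
#' `MS = (mean_IFP_CS(T_end) - (-1)) / (T_end - T_start)`, where `T_end` is
#' the temperature of the last completed step and the mean is taken over
#' all saved frames of that step. A run that terminates during its first
#' step has `T_end = T_start`, where the slope is undefined; the score is 1
#' by convention (immediate loss of the native pose). Values are clamped to
#' `[0, 1]`: 0 indicates tight, persistent native binding.
#'
#' @param series a `ttmd_scores` tibble.
#' @return MS coefficient in `[0, 1]`.
#' @export
ms_coefficient <- function(series) {
  sm <- step_means(series)
  if (nrow(sm) < 2) return(1)
  t_start <- sm$temperature[1]
  t_end <- sm$temperature[nrow(sm)]
  ms <- (sm$mean_ifp_cs[nrow(sm)] + 1) / (t_end - t_start)
  min(1, max(0, ms))
}

#' IFF stability coefficient
#'
#' Root-mean-square fluctuation of the per-frame IFP_CS values about the
#' whole-run mean, over all frames of the run (steps concatenated):
#' `IFF = sqrt( sum_t (IFP_CS_t - mean)^2 / T )`. Complements MS by
#' penalising runs whose score fluctuates even when the endpoints agree.
#'
#' @param series a `ttmd_scores` tibble (or bare numeric score vector).
#' @return IFF coefficient (>= 0; at most 0.5 for scores bounded in
#'   `[-1, 0]`).
#' @export
iff_coefficient <- function(series) {
  x <- if (is.data.frame(series)) series$ifp_cs else as.numeric(series)
  if (!length(x)) abort("empty score series")
  sqrt(mean((x - mean(x))^2))
}
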