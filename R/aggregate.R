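# Replicate aggregation and pose ranking.

#' Trimmed replicate statistics
#'
#' Core aggregation rule for per-pose replicate coefficients: missing
#' replicates are dropped; one maximum and one minimum (a single instance
#' each, ties broken arbitrarily among tied values) are removed from the
#' remainder and the rest averaged (`trim_mean`). The dispersion
#' (`trim_error`) is the population standard deviation (divisor = n) over
#' all non-missing replicates, before trimming.
#'
#' @param values numeric replicate coefficients, `NA` allowed.
#' @return list with `trim_mean`, `trim_error`, `n_used` (replicates kept
#'   after trimming) and `n_total` (non-missing replicates).
#' @export
trim_stats <- function(values) {
  x <- values[!is.na(values)]
  if (length(x) < 3) abort("need >= 3 non-missing replicate values")
  s <- sort(x)
  kept <- s[-c(1, length(s))]
  list(trim_mean = mean(kept),
       trim_error = sqrt(mean((x - mean(x))^2)),
       n_used = length(kept), n_total = length(x))
}

#' Aggregate replicate coefficients per pose
#'
#' Tidy wrapper over [trim_stats()]: takes a long table of per-replicate
#' coefficient values and returns one summary row per pose.
#'
#' @param data data frame with at least a pose identifier column and a
#'   value column.
#' @param value column holding the coefficient (default `value`).
#' @param pose pose identifier column (default `pose_id`).
#' @return a `ttmd_summary` tibble: `pose_id`, `trim_mean`, `trim_error`,
#'   `n_used`, `n_total`.
#' @export
aggregate_replicates <- function(data, value = "value", pose = "pose_id") {
  out <- data |>
    dplyr::group_by(pose_id = .data[[pose]]) |>
    dplyr::summarise({
      st <- trim_stats(.data[[value]])
      tibble::tibble(trim_mean = st$trim_mean, trim_error = st$trim_error,
                     n_used = st$n_used, n_total = st$n_total)
    }, .groups = "drop")
  class(out) <- c("ttmd_summary", class(out))
  out
}

#' Rank poses by aggregated stability
#'
#' Ascending order of the trimmed-mean coefficient (lower = more stable,
#' i.e. tighter, more persistent native binding); ties broken by pose id so
#' the ranking is stable.
#'
#' @param summaries a `ttmd_summary` tibble (from [aggregate_replicates()]).
#' @return the summaries reordered, with a `rank` column prepended.
#' @export
rank_poses <- function(summaries) {
  if (!nrow(summaries)) abort("no pose summaries to rank")
  out <- dplyr::arrange(summaries, .data$trim_mean, .data$pose_id)
  out <- dplyr::mutate(out, rank = dplyr::row_number(), .before = 1)
  out
}

#' Published benchmark replicate coefficients
#'
#' Per-replicate MS/IFF stability coefficients for six RNA-ligand systems
#' (crystal pose + five docking poses each) under four TTMD protocol
#' presets, as published, together with the published trimmed aggregate
#' columns. Useful for validating the aggregation arithmetic and as example
#' input for [aggregate_replicates()].
#'
#' @return tibble with columns `protocol`, `metric`, `ramp`, `system`,
#'   `pose`, `md1`-`md5` (NA = replicate not available), `trim_mean`,
#'   `trim_error`.
#' @export
benchmark_replicates <- function() {
  path <- system.file("extdata", "benchmark_replicates.csv", package = "ttmd")
  readr::read_csv(path, show_col_types = FALSE,
                  col_types = readr::cols(pose = readr::col_character()))
}

#' Round to fixed decimals, half to even
#'
#' Report rounding used for coefficient tables (5 decimal places,
#' round-half-even, which is R's default rounding mode).
#'
#' @param x numeric vector.
#' @param digits decimal places (default 5).
#' @return rounded numeric vector.
#' @export
report_round <- function(x, digits = 5) round(x, digits)
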