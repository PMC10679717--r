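# broom-style accessors and ggplot2 autoplot methods.

#' Tidy a titration result
#'
#' One row per saved frame: the titration timeline table.
#'
#' @param x a `ttmd_result`.
#' @param ... unused.
#' @return a tibble (see [titration_timeline()]).
#' @method tidy ttmd_result
#' @export
tidy.ttmd_result <- function(x, ...) titration_timeline(x)

#' One-row summary of a titration result
#'
#' @param x a `ttmd_result`.
#' @param ... unused.
#' @return tibble with `steps_completed`, `terminated_early`,
#'   `last_temperature`, `frames`, and (non-dry runs) `ms` and `iff`.
#' @method glance ttmd_result
#' @export
glance.ttmd_result <- function(x, ...) {
  tibble::tibble(
    steps_completed = x$steps_completed,
    terminated_early = x$terminated_early,
    last_temperature = x$last_temperature,
    frames = nrow(x$rmsd),
    ms = if (is.null(x$scores)) NA_real_ else ms_coefficient(x$scores),
    iff = if (is.null(x$scores)) NA_real_ else iff_coefficient(x$scores)
  )
}

#' Titration timeline plot
#'
#' The time-dependent evolution of the IFP_CS score (non-dry runs) and of
#' the ligand, receptor-backbone and binding-site RMSD, faceted by series.
#'
#' @param object a `ttmd_result`.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot ttmd_result
#' @export
autoplot.ttmd_result <- function(object, ...) {
  tl <- titration_timeline(object)
  long <- tl |>
    tidyr::pivot_longer(c("ifp_cs", "rmsd_ligand", "rmsd_backbone",
                          "rmsd_site"),
                        names_to = "series", values_to = "value") |>
    dplyr::filter(!is.na(.data$value))
  ggplot2::ggplot(long, ggplot2::aes(.data$time, .data$value,
                                     colour = factor(.data$step))) +
    ggplot2::geom_line(ggplot2::aes(group = 1), linewidth = 0.3) +
    ggplot2::facet_wrap(~series, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "time (ns)", y = NULL, colour = "TTMD step",
                  title = "Titration timeline") +
    ggplot2::theme_minimal()
}

#' Titration profile plot
#'
#' Per-step mean IFP_CS against step temperature with the MS slope segment
#' from `(T_start, -1)` to the last completed step's mean.
#'
#' @param result a `ttmd_result` from [run_titration()].
#' @return a ggplot.
#' @export
plot_titration_profile <- function(result) {
  pf <- titration_profile(result)
  seg <- attr(pf, "endpoints")
  ggplot2::ggplot(pf, ggplot2::aes(.data$temperature, .data$mean_ifp_cs)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::geom_segment(
      data = tibble::tibble(x = seg$temperature[1], y = seg$mean_ifp_cs[1],
                            xend = seg$temperature[2],
                            yend = seg$mean_ifp_cs[2]),
      ggplot2::aes(x = .data$x, y = .data$y, xend = .data$xend,
                   yend = .data$yend),
      colour = "firebrick", linetype = 2) +
    ggplot2::annotate("text", x = seg$temperature[2],
                      y = seg$mean_ifp_cs[2],
                      label = sprintf("MS = %.5f", attr(pf, "ms")),
                      hjust = 1, vjust = -0.5, size = 3) +
    ggplot2::labs(x = "temperature (K)", y = "mean IFP_CS",
                  title = "Titration profile") +
    ggplot2::theme_minimal()
}

#' Pose-ranking plot
#'
#' Trimmed-mean coefficients per pose with +/- trim_error bars, ordered by
#' rank (most stable first).
#'
#' @param object a `ttmd_summary` from [aggregate_replicates()].
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot ttmd_summary
#' @export
autoplot.ttmd_summary <- function(object, ...) {
  ranked <- rank_poses(object)
  ranked$pose_id <- factor(ranked$pose_id, levels = ranked$pose_id)
  ggplot2::ggplot(ranked, ggplot2::aes(.data$pose_id, .data$trim_mean)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_errorbar(ggplot2::aes(
      ymin = pmax(0, .data$trim_mean - .data$trim_error),
      ymax = .data$trim_mean + .data$trim_error), width = 0.2) +
    ggplot2::labs(x = NULL, y = "trimmed mean coefficient",
                  title = "Pose ranking (lower = more stable)") +
    ggplot2::theme_minimal()
}
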