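# Fingerprint export and YAML run configuration.

#' Fingerprint a whole trajectory
#'
#' @param traj a `ttmd_trajectory`.
#' @param complex,layout,rules as in [fingerprint()].
#' @return integer matrix, frames x slots, with slot labels
#'   `residue|class` as column names.
#' @export
fingerprint_frames <- function(traj, complex, layout,
                               rules = geometry_rules()) {
  m <- t(vapply(traj$coords,
                function(co) as.integer(fingerprint(co, complex, layout,
                                                    rules)),
                integer(nrow(layout))))
  colnames(m) <- paste(layout$residue, layout$class, sep = "|")
  m
}

#' Export per-frame fingerprints
#'
#' Dense CSV (frames x slots) or compact JSON (frame index to set-bit slot
#' indices), chosen by file extension.
#'
#' @param fps matrix from [fingerprint_frames()].
#' @param path output path (`.csv` or `.json`).
#' @return `path`, invisibly.
#' @export
write_fingerprints <- function(fps, path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    bits <- lapply(seq_len(nrow(fps)), function(i) which(fps[i, ] == 1L))
    names(bits) <- as.character(seq_len(nrow(fps)))
    jsonlite::write_json(bits, path)
  } else {
    readr::write_csv(tibble::as_tibble(fps, .name_repair = "minimal"), path)
  }
  invisible(path)
}

#' Read a run configuration
#'
#' YAML configuration with blocks `system`, `ramp`, `fingerprint`,
#' `engine`, `output`. The `ramp` block (`t_start`, `t_end`, `increment`,
#' `step_length`, or `preset: standard|alternative`) is converted to a
#' `ttmd_ramp`; `fingerprint.geometry` overrides [geometry_rules()]
#' defaults.
#'
#' @param path YAML file.
#' @return list with the raw config plus parsed `ramp` and `geometry`.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  ramp <- NULL
  if (!is.null(cfg$ramp)) {
    ramp <- if (!is.null(cfg$ramp$preset)) {
      switch(cfg$ramp$preset, standard = standard_ramp(),
             alternative = alternative_ramp(),
             abort("unknown ramp preset"))
    } else {
      do.call(build_ramp, cfg$ramp)
    }
  }
  geom <- do.call(geometry_rules, cfg$fingerprint$geometry %||% list())
  c(cfg, list(ramp = ramp, geometry = geom))
}
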