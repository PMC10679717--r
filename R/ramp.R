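#' Build a temperature ramp
#'
#' Ordered list of (temperature, duration) TTMD steps. The temperature
#' range must be an exact multiple of the increment; the step count is
#' `(t_end - t_start) / increment + 1`.
#'
#' @param t_start,t_end first and last step temperatures (K).
#' @param increment temperature increase between steps (K).
#' @param step_length duration of each constant-temperature step (ns).
#' @return a `ttmd_ramp` tibble with columns `step`, `temperature`,
#'   `duration`.
#' @export
build_ramp <- function(t_start = 300, t_end = 450, increment = 10,
                       step_length = 10) {
  if (increment <= 0) abort("increment must be positive")
  if (t_end <= t_start) abort("t_end must exceed t_start")
  if (step_length <= 0) abort("step_length must be positive")
  span <- t_end - t_start
  if (abs(span / increment - round(span / increment)) > 1e-9)
    abort("temperature range is not divisible by the increment")
  temps <- seq(t_start, t_end, by = increment)
  out <- tibble::tibble(step = seq_along(temps), temperature = temps,
                        duration = step_length)
  class(out) <- c("ttmd_ramp", class(out))
  out
}

#' Temperature ramp presets
#'
#' `standard_ramp()` is the 300 to 450 K ramp (10 K increments, 10 ns
#' steps; 16 steps, 160 ns total); `alternative_ramp()` is the sub-freezing
#' 73 to 223 K ramp with the same increment and step length, used to reduce
#' receptor flexibility on highly plastic nucleic acids.
#'
#' @return a `ttmd_ramp` tibble.
#' @export
standard_ramp <- function() build_ramp(300, 450, 10, 10)

#' @rdname standard_ramp
#' @export
alternative_ramp <- function() build_ramp(73, 223, 10, 10)

#' Protocol presets
#'
#' Named analysis presets pairing a temperature ramp with the stability
#' metric used for ranking: protocols 1-2 use the standard ramp with the MS
#' coefficient (differing historically in fingerprint backend), protocol 3
#' the alternative ramp with MS, protocol 4 the alternative ramp with IFF.
#'
#' @param protocol integer 1-4.
#' @return list with elements `ramp` (a `ttmd_ramp`) and `metric`
#'   (`"ms"` or `"iff"`).
#' @export
protocol_preset <- function(protocol) {
  switch(as.character(protocol),
    "1" = list(ramp = standard_ramp(), metric = "ms"),
    "2" = list(ramp = standard_ramp(), metric = "ms"),
    "3" = list(ramp = alternative_ramp(), metric = "ms"),
    "4" = list(ramp = alternative_ramp(), metric = "iff"),
    abort("protocol must be 1, 2, 3 or 4")
  )
}
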