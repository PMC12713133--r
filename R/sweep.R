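#' Current-clamp sweep
#'
#' Container for a single current-clamp voltage trace together with its
#' step-current stimulus metadata. All electrophysiology features operate on
#' this object.
#'
#' @param time_ms Numeric vector of sample times in milliseconds, strictly
#'   increasing on a uniform grid (uniform to within 1 part in 1e6).
#' @param voltage_mV Numeric vector of membrane voltage in millivolts, same
#'   length as `time_ms`.
#' @param sampling_khz Sampling rate in kHz. Acquisition systems typically run
#'   at 10 or 20 kHz; any rate of at least 5 kHz is accepted.
#' @param amplitude_pA Step-current amplitude in picoamps.
#' @param onset_ms Stimulus onset time in ms.
#' @param duration_ms Stimulus duration in ms. The window
#'   `[onset, onset + duration]` must lie inside the trace.
#' @param holding_mV Nominal holding potential in mV, or `NA` when the cell was
#'   recorded at its resting potential.
#' @param protocol Optional protocol tag (e.g. `"subthreshold_10pA"`).
#'
#' @return An object of class `ccsweep`: a list with the fields above plus
#'   `dt_ms`, the sample interval.
#' @export
current_clamp_sweep <- function(time_ms, voltage_mV, sampling_khz,
                                amplitude_pA, onset_ms, duration_ms,
                                holding_mV = NA_real_, protocol = NA_character_) {
  stopifnot(is.numeric(time_ms), is.numeric(voltage_mV),
            length(time_ms) == length(voltage_mV), length(time_ms) >= 2)
  if (sampling_khz < 5)
    stop("sampling rate must be at least 5 kHz, got ", sampling_khz)
  dt <- diff(time_ms)
  if (any(dt <= 0)) stop("time must be strictly increasing")
  if (max(abs(dt - dt[1])) > 1e-6 * dt[1])
    stop("time grid not uniform within 1 part in 1e6")
  if (abs(dt[1] - 1 / sampling_khz) > 1e-6 / sampling_khz)
    stop("sample interval inconsistent with sampling_khz")
  if (onset_ms < time_ms[1] || onset_ms + duration_ms > time_ms[length(time_ms)])
    stop("stimulus window [onset, onset+duration] must lie inside the trace")
  structure(list(
    time_ms = time_ms, voltage_mV = voltage_mV,
    sampling_khz = sampling_khz, dt_ms = dt[1],
    amplitude_pA = amplitude_pA, onset_ms = onset_ms,
    duration_ms = duration_ms, holding_mV = holding_mV,
    protocol = protocol
  ), class = "ccsweep")
}

#' @export
print.ccsweep <- function(x, ...) {
  cat(sprintf(
    "<ccsweep> %d samples @ %g kHz | step %+g pA, %g ms at %g ms | protocol %s\n",
    length(x$time_ms), x$sampling_khz, x$amplitude_pA, x$duration_ms,
    x$onset_ms, x$protocol))
  invisible(x)
}

#' Step-protocol specifications
#'
#' The three current-step protocols used throughout: a subthreshold series of
#' six 10-pA increments starting at -30 pA (500 ms) for passive properties, an
#' excitability series of 20-pA increments from 0 to 400 pA (500 ms), and
#' brief 5-ms pulses in 10-pA increments for single evoked APs.
#'
#' @param kind One of `"subthreshold_10pA"`, `"excitability_20pA"`,
#'   `"brief_5ms"`.
#' @param max_brief_pA Upper end of the brief-pulse series (the brief protocol
#'   has no fixed endpoint; pulses are delivered until an AP is evoked).
#'
#' @return A list with `kind`, `amplitudes_pA` and `step_duration_ms`.
#' @export
step_protocol <- function(kind = c("subthreshold_10pA", "excitability_20pA",
                                   "brief_5ms"),
                          max_brief_pA = 400) {
  kind <- match.arg(kind)
  switch(kind,
    subthreshold_10pA = list(kind = kind,
                             amplitudes_pA = seq(-30, 20, by = 10),
                             step_duration_ms = 500),
    excitability_20pA = list(kind = kind,
                             amplitudes_pA = seq(0, 400, by = 20),
                             step_duration_ms = 500),
    brief_5ms = list(kind = kind,
                     amplitudes_pA = seq(10, max_brief_pA, by = 10),
                     step_duration_ms = 5))
}
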