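#' Resting membrane potential
#'
#' Mean voltage over the pre-stimulus baseline window `[0, onset)`. At least
#' 50 ms of baseline must be available.
#'
#' @param sweep A [current_clamp_sweep()].
#' @return RMP in mV.
#' @export
measure_rmp <- function(sweep) {
  stopifnot(inherits(sweep, "ccsweep"))
  baseline_ms <- sweep$onset_ms - sweep$time_ms[1]
  if (baseline_ms < 50)
    stop("pre-stimulus baseline is ", round(baseline_ms, 2),
         " ms; at least 50 ms required to measure RMP")
  mean(sweep$voltage_mV[sweep$time_ms < sweep$onset_ms])
}

#' Input resistance from a subthreshold step series
#'
#' Ordinary least-squares slope of the steady-state voltage deflection versus
#' injected current. The steady-state deflection for each sweep is the mean
#' voltage over the last 100 ms of the step minus the sweep's own pre-stimulus
#' baseline. Sweeps containing action potentials are excluded before the fit.
#'
#' A slope in mV/pA equals GOhm, so the value is multiplied by 1000 to report
#' MOhm.
#'
#' @param sweeps List of [current_clamp_sweep()] from the subthreshold
#'   protocol.
#' @param steady_window_ms Width of the steady-state window at the end of the
#'   step (default 100 ms; the slowest recorded cells have tau well under a
#'   third of this, so the response has settled).
#' @return Input resistance in MOhm.
#' @export
fit_input_resistance <- function(sweeps, steady_window_ms = 100) {
  stopifnot(is.list(sweeps), length(sweeps) >= 1)
  keep <- vapply(sweeps, function(s) length(detect_aps(s)$peak_time_ms) == 0,
                 logical(1))
  sweeps <- sweeps[keep]
  if (length(sweeps) < 3)
    stop("need at least 3 AP-free subthreshold sweeps, have ", length(sweeps))
  amp <- vapply(sweeps, `[[`, numeric(1), "amplitude_pA")
  if (diff(range(amp)) == 0)
    stop("zero spread in injected current; cannot fit a slope")
  dv <- vapply(sweeps, function(s) {
    end <- s$onset_ms + s$duration_ms
    sel <- s$time_ms >= end - steady_window_ms & s$time_ms <= end
    mean(s$voltage_mV[sel]) - measure_rmp(s)
  }, numeric(1))
  slope <- stats::coef(stats::lm(dv ~ amp))[["amp"]]  # mV/pA = GOhm
  slope * 1000
}

#' Membrane time constant from hyperpolarizing steps
#'
#' For each hyperpolarizing (negative-amplitude) sweep, fits the
#' single-exponential relaxation
#' `V(t) = V_ss + (V(onset) - V_ss) * exp(-(t - onset)/tau)` from the start of
#' the decay over at most 200 ms, and returns the mean tau across sweeps.
#' Sweeps whose fit fails to converge, or whose tau falls outside
#' (0.1, 200) ms, are dropped; an error is raised if every sweep is dropped.
#'
#' @param sweeps List of [current_clamp_sweep()]; only negative-amplitude
#'   sweeps are used.
#' @param fit_window_ms Maximum fit-window length after onset (default 200 ms).
#' @return Mean tau in ms.
#' @export
fit_membrane_tau <- function(sweeps, fit_window_ms = 200) {
  stopifnot(is.list(sweeps))
  hyp <- Filter(function(s) s$amplitude_pA < 0, sweeps)
  if (length(hyp) == 0)
    stop("no hyperpolarizing sweeps available for the tau fit")
  taus <- vapply(hyp, function(s) {
    win <- min(fit_window_ms, s$duration_ms)
    sel <- s$time_ms >= s$onset_ms & s$time_ms <= s$onset_ms + win
    t <- s$time_ms[sel] - s$onset_ms
    v <- s$voltage_mV[sel]
    v0 <- v[1]
    vss <- mean(v[t >= 0.8 * win])
    fit <- tryCatch(
      stats::nls(v ~ vss_ + (v0_ - vss_) * exp(-t / tau_),
                 start = list(vss_ = vss, v0_ = v0,
                              tau_ = max(1, win / 10)),
                 # scaleOffset keeps the convergence test meaningful on
                 # noiseless traces where the residual is exactly zero
                 control = stats::nls.control(maxiter = 100,
                                              scaleOffset = 1)),
      error = function(e) NULL)
    if (is.null(fit)) return(NA_real_)
    tau <- stats::coef(fit)[["tau_"]]
    if (tau <= 0.1 || tau >= 200) NA_real_ else tau
  }, numeric(1))
  taus <- taus[!is.na(taus)]
  if (length(taus) == 0)
    stop("tau fit failed on every hyperpolarizing sweep")
  mean(taus)
}

#' Membrane capacitance from input resistance and time constant
#'
#' `Cm = tau / R`; ms / MOhm = nF, reported in pF.
#'
#' @param input_resistance_mohm Input resistance in MOhm (> 0).
#' @param tau_ms Membrane time constant in ms (> 0).
#' @return Capacitance in pF.
#' @export
compute_capacitance <- function(input_resistance_mohm, tau_ms) {
  if (!is.finite(input_resistance_mohm) || input_resistance_mohm <= 0)
    stop("input resistance must be positive")
  if (!is.finite(tau_ms) || tau_ms <= 0)
    stop("tau must be positive")
  tau_ms / input_resistance_mohm * 1000
}
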