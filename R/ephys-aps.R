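#' Detect action potentials in a sweep
#'
#' Local voltage maxima qualify as APs when the peak exceeds -10 mV, or when
#' the peak rises at least 70 mV above the pre-stimulus baseline. Peaks closer
#' than the refractory separation are deduplicated, keeping the taller peak.
#'
#' @param sweep A [current_clamp_sweep()].
#' @param peak_threshold_mV Absolute peak criterion (default -10 mV).
#' @param min_amplitude_mV Amplitude-from-baseline criterion (default 70 mV).
#' @param min_separation_ms Minimum peak separation (default 1 ms; maximal
#'   fast-spiking rates near 160 Hz leave gaps of 6 ms or more).
#' @return A data.frame with columns `peak_time_ms`, `peak_voltage_mV`,
#'   ordered by time. Zero rows when no AP qualifies.
#' @export
detect_aps <- function(sweep, peak_threshold_mV = -10, min_amplitude_mV = 70,
                       min_separation_ms = 1) {
  stopifnot(inherits(sweep, "ccsweep"))
  v <- sweep$voltage_mV
  n <- length(v)
  baseline <- mean(v[sweep$time_ms < sweep$onset_ms])
  # interior local maxima (plateaus count once, at their first sample)
  dv <- diff(v)
  rising <- c(dv > 0, FALSE)
  falling <- c(FALSE, dv < 0)
  # a sample is a peak if the last nonzero slope before it was up and the
  # next nonzero slope after it is down
  up_before <- cummax_last_sign(dv, before = TRUE)
  down_after <- cummax_last_sign(dv, before = FALSE)
  is_peak <- up_before & down_after
  cand <- which(is_peak &
                  (v > peak_threshold_mV | v - baseline >= min_amplitude_mV))
  if (length(cand) == 0)
    return(data.frame(peak_time_ms = numeric(0), peak_voltage_mV = numeric(0)))
  # greedy dedup: keep taller peaks first, drop any later candidate within
  # the refractory separation of a kept peak
  ord <- cand[order(v[cand], decreasing = TRUE)]
  kept <- numeric(0)
  for (i in ord) {
    t_i <- sweep$time_ms[i]
    if (all(abs(t_i - kept) >= min_separation_ms)) kept <- c(kept, t_i)
  }
  kept <- sort(kept)
  idx <- match(kept, sweep$time_ms)
  data.frame(peak_time_ms = kept, peak_voltage_mV = v[idx])
}

# Sign of the nearest nonzero slope before (after) each sample; returns a
# logical marking samples whose preceding slope is positive (following slope
# negative). Internal helper for plateau-safe peak detection.
cummax_last_sign <- function(dv, before) {
  n <- length(dv) + 1
  s <- sign(dv)
  if (before) {
    # carry the last nonzero sign forward; sample i looks at slope i-1
    carried <- s
    nz <- carried != 0
    carried <- carried[nz][cumsum(nz)]
    if (length(carried) < length(s))
      carried <- c(rep(0, length(s) - length(carried)), carried)
    c(FALSE, carried > 0)
  } else {
    # carry the next nonzero sign backward; sample i looks at slope i
    s_rev <- rev(s)
    nz <- s_rev != 0
    carried <- s_rev[nz][cumsum(nz)]
    if (length(carried) < length(s_rev))
      carried <- c(rep(0, length(s_rev) - length(carried)), carried)
    c(rev(carried) < 0, FALSE)
  }
}

#' Per-AP waveform features
#'
#' Computes the full feature set for one action potential located at
#' `peak_time_ms` (an element of [detect_aps()] output):
#'
#' * threshold: the last sample before the peak (searching backward at most
#'   5 ms) at which dV/dt first exceeds 5% of that AP's maximal dV/dt;
#' * fAHP nadir: minimum voltage between the peak and the next AP's threshold
#'   (or peak + 10 ms when the AP is the last one);
#' * amplitude: peak voltage minus nadir voltage;
#' * half-width: time between the two crossings of the level midway between
#'   peak and threshold voltage;
#' * maximum rise slope: max dV/dt between threshold and peak;
#' * maximum decay slope: min dV/dt between peak and nadir.
#'
#' dV/dt is computed by central differences on the raw grid; below 10 kHz a
#' 3-point moving average is applied to the voltage first.
#'
#' @param sweep A [current_clamp_sweep()].
#' @param peak_time_ms Peak time of the AP to characterize.
#' @param next_peak_time_ms Peak time of the following AP, or `NA`.
#' @param back_window_ms Threshold back-search window (default 5 ms).
#' @return A one-row data.frame with columns `peak_time_ms`,
#'   `peak_voltage_mV`, `threshold_time_ms`, `threshold_voltage_mV`,
#'   `fahp_voltage_mV`, `amplitude_mV`, `half_width_ms`,
#'   `max_rise_slope_mV_ms`, `max_decay_slope_mV_ms`, `flagged` (TRUE when no
#'   5% dV/dt crossing was found in the back-window and the threshold is
#'   undefined).
#' @export
ap_features <- function(sweep, peak_time_ms, next_peak_time_ms = NA_real_,
                        back_window_ms = 5) {
  stopifnot(inherits(sweep, "ccsweep"))
  t <- sweep$time_ms
  v <- sweep$voltage_mV
  if (sweep$sampling_khz < 10) v <- stats::filter(v, rep(1 / 3, 3), sides = 2)
  dvdt <- c(NA, (v[-(1:2)] - v[1:(length(v) - 2)]) / (2 * sweep$dt_ms), NA)
  ipk <- which.min(abs(t - peak_time_ms))
  peak_v <- sweep$voltage_mV[ipk]

  na_row <- function() data.frame(
    peak_time_ms = t[ipk], peak_voltage_mV = peak_v,
    threshold_time_ms = NA_real_, threshold_voltage_mV = NA_real_,
    fahp_voltage_mV = NA_real_, amplitude_mV = NA_real_,
    half_width_ms = NA_real_, max_rise_slope_mV_ms = NA_real_,
    max_decay_slope_mV_ms = NA_real_, flagged = TRUE)

  back <- which(t >= t[ipk] - back_window_ms & t < t[ipk])
  back <- back[!is.na(dvdt[back])]
  if (length(back) < 2) return(na_row())
  max_rise_all <- max(dvdt[back])
  if (!is.finite(max_rise_all) || max_rise_all <= 0) return(na_row())
  above <- dvdt[back] > 0.05 * max_rise_all
  if (!any(above)) return(na_row())
  # last sample before the peak at which dV/dt FIRST exceeds the 5% level:
  # the start of the final contiguous supra-5% run leading into the peak
  runs <- rle(above)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  last_true <- max(which(runs$values))
  ithr <- back[starts[last_true]]
  thr_t <- t[ithr]
  thr_v <- sweep$voltage_mV[ithr]

  # fAHP nadir: (peak, next AP threshold or peak + 10 ms]
  nadir_end <- if (is.na(next_peak_time_ms)) t[ipk] + 10 else {
    nxt <- ap_threshold_index(sweep, next_peak_time_ms, dvdt, back_window_ms)
    if (is.na(nxt)) next_peak_time_ms else t[nxt]
  }
  seg <- which(t > t[ipk] & t <= min(nadir_end, t[length(t)]))
  if (length(seg) == 0) return(na_row())
  inad <- seg[which.min(sweep$voltage_mV[seg])]
  nadir_v <- sweep$voltage_mV[inad]

  half_level <- (peak_v + thr_v) / 2
  hw <- half_width_at(t, sweep$voltage_mV, ithr, ipk, inad, half_level)

  rise_idx <- which(t > thr_t & t < t[ipk])
  decay_idx <- which(t > t[ipk] & t < t[inad])
  max_rise <- if (length(rise_idx)) max(dvdt[rise_idx], na.rm = TRUE) else max_rise_all
  max_decay <- if (length(decay_idx)) min(dvdt[decay_idx], na.rm = TRUE) else NA_real_

  data.frame(
    peak_time_ms = t[ipk], peak_voltage_mV = peak_v,
    threshold_time_ms = thr_t, threshold_voltage_mV = thr_v,
    fahp_voltage_mV = nadir_v, amplitude_mV = peak_v - nadir_v,
    half_width_ms = hw, max_rise_slope_mV_ms = max_rise,
    max_decay_slope_mV_ms = max_decay, flagged = FALSE)
}

# threshold sample index for an AP at peak_time, or NA
ap_threshold_index <- function(sweep, peak_time_ms, dvdt, back_window_ms) {
  t <- sweep$time_ms
  ipk <- which.min(abs(t - peak_time_ms))
  back <- which(t >= t[ipk] - back_window_ms & t < t[ipk])
  back <- back[!is.na(dvdt[back])]
  if (length(back) < 2) return(NA_integer_)
  mx <- max(dvdt[back])
  if (!is.finite(mx) || mx <= 0) return(NA_integer_)
  above <- dvdt[back] > 0.05 * mx
  if (!any(above)) return(NA_integer_)
  runs <- rle(above)
  starts <- cumsum(runs$lengths) - runs$lengths + 1
  back[starts[max(which(runs$values))]]
}

# width at `level` between the rising flank (threshold..peak) and the falling
# flank (peak..nadir), with linear interpolation between samples
half_width_at <- function(t, v, ithr, ipk, inad, level) {
  cross_up <- interp_crossing(t, v, ithr:ipk, level, rising = TRUE)
  cross_dn <- interp_crossing(t, v, ipk:inad, level, rising = FALSE)
  if (is.na(cross_up) || is.na(cross_dn)) return(NA_real_)
  cross_dn - cross_up
}

interp_crossing <- function(t, v, idx, level, rising) {
  if (length(idx) < 2) return(NA_real_)
  vv <- v[idx]; tt <- t[idx]
  hit <- if (rising) which(vv[-1] >= level & vv[-length(vv)] < level)
         else        which(vv[-1] <= level & vv[-length(vv)] > level)
  if (length(hit) == 0) return(NA_real_)
  # use the crossing nearest the peak on each flank
  i <- if (rising) hit[length(hit)] else hit[1]
  frac <- (level - vv[i]) / (vv[i + 1] - vv[i])
  tt[i] + frac * (tt[i + 1] - tt[i])
}

#' All AP features for one sweep
#'
#' Runs [detect_aps()] and [ap_features()] for every detected AP, pairing each
#' AP with its successor so the fAHP search window is bounded correctly.
#'
#' @param sweep A [current_clamp_sweep()].
#' @inheritParams detect_aps
#' @return A data.frame with one row per AP (zero rows when none).
#' @export
sweep_ap_table <- function(sweep, peak_threshold_mV = -10,
                           min_amplitude_mV = 70) {
  pk <- detect_aps(sweep, peak_threshold_mV, min_amplitude_mV)
  if (nrow(pk) == 0) return(cbind(pk[0, ], ap_features_empty()))
  nxt <- c(pk$peak_time_ms[-1], NA_real_)
  do.call(rbind, lapply(seq_len(nrow(pk)), function(i)
    ap_features(sweep, pk$peak_time_ms[i], nxt[i])))
}

ap_features_empty <- function() data.frame(
  threshold_time_ms = numeric(0), threshold_voltage_mV = numeric(0),
  fahp_voltage_mV = numeric(0), amplitude_mV = numeric(0),
  half_width_ms = numeric(0), max_rise_slope_mV_ms = numeric(0),
  max_decay_slope_mV_ms = numeric(0), flagged = logical(0))
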