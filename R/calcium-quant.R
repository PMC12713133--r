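#' ROI fluorescence trace
#'
#' @param frame_times_s Frame acquisition times (s), approximately uniform.
#' @param F Raw ROI mean fluorescence (a.u.), background-subtracted.
#' @param roi_id ROI identifier.
#' @param cell_class `"interneuron"`, `"pyramidal"` or `"unknown"`.
#' @return A list of class `fluor_trace`.
#' @export
fluor_trace <- function(frame_times_s, F, roi_id = "roi1",
                        cell_class = c("unknown", "interneuron", "pyramidal")) {
  cell_class <- match.arg(cell_class)
  stopifnot(length(frame_times_s) == length(F), length(F) >= 2)
  structure(list(frame_times_s = frame_times_s, F = F, roi_id = roi_id,
                 cell_class = cell_class), class = "fluor_trace")
}

#' Extract an ROI trace from an image stack
#'
#' Per frame, `F = mean(pixels in roi_mask) - mean(pixels in background_mask)`.
#'
#' @param stack 3-D numeric array `[row, col, frame]`.
#' @param roi_mask,background_mask Logical matrices matching the frame
#'   dimensions; both must be nonempty.
#' @param frame_times_s Frame times; defaults to frames at `1/frame_rate_hz`.
#' @param frame_rate_hz Frame rate used when `frame_times_s` is missing
#'   (default 1.7 Hz).
#' @inheritParams fluor_trace
#' @return A [fluor_trace()].
#' @export
extract_roi_trace <- function(stack, roi_mask, background_mask,
                              frame_times_s = NULL, frame_rate_hz = 1.7,
                              roi_id = "roi1", cell_class = "unknown") {
  stopifnot(length(dim(stack)) == 3)
  if (!any(roi_mask)) stop("ROI mask is empty")
  if (!any(background_mask)) stop("background mask is empty")
  stopifnot(all(dim(roi_mask) == dim(stack)[1:2]),
            all(dim(background_mask) == dim(stack)[1:2]))
  nf <- dim(stack)[3]
  flat <- matrix(stack, ncol = nf)
  Fv <- colMeans(flat[as.vector(roi_mask), , drop = FALSE]) -
    colMeans(flat[as.vector(background_mask), , drop = FALSE])
  if (is.null(frame_times_s))
    frame_times_s <- (seq_len(nf) - 1) / frame_rate_hz
  fluor_trace(frame_times_s, Fv, roi_id, cell_class)
}

#' Compute dF/F0
#'
#' `F0` is the baseline fluorescence: the minimum, over all contiguous
#' windows of `round(baseline_seconds * frame_rate)` frames, of the window
#' mean — the quietest stretch of the recording. Then
#' `dF/F0 = (F - F0)/F0`.
#'
#' The baseline noise level `baseline_sigma` is estimated robustly from the
#' whole dF/F0 trace as `mad(diff(dff)) / sqrt(2)`: first differencing
#' removes the slow transient component and the median absolute deviation is
#' insensitive to the sparse event-related jumps. A handful of frames inside
#' the minimal window is far too few for a stable s.d. (its sampling error
#' spans a factor of three, which turns a 3-sigma event threshold into a
#' 1-sigma one on unlucky traces). The estimate is floored at 1e-4 so
#' noiseless synthetic traces do not produce a zero threshold.
#'
#' @param trace A [fluor_trace()].
#' @param baseline_seconds Baseline window length (default 3.5 s).
#' @param mask Optional logical vector of frames to KEEP (motion-artifact
#'   exclusion); masked-out frames are excised before all computations.
#' @return A list of class `dff_trace` with `frame_times_s`, `dff`, `f0`,
#'   `baseline_window_s`, `baseline_sigma`, `frame_rate_hz`.
#' @export
compute_dff <- function(trace, baseline_seconds = 3.5, mask = NULL) {
  stopifnot(inherits(trace, "fluor_trace"))
  tt <- trace$frame_times_s
  Fv <- trace$F
  if (!is.null(mask)) {
    stopifnot(length(mask) == length(Fv))
    tt <- tt[mask]; Fv <- Fv[mask]
  }
  frame_rate <- 1 / stats::median(diff(tt))
  w <- max(1L, round(baseline_seconds * frame_rate))
  if (length(Fv) <= w)
    stop("trace shorter than the baseline window")
  means <- rolling_mean(Fv, w)
  i0 <- which.min(means)
  f0 <- means[i0]
  if (f0 <= 0)
    stop("baseline F0 is not positive; trace is not background-valid")
  dff <- (Fv - f0) / f0
  win <- i0:(i0 + w - 1L)
  sigma <- max(stats::mad(diff(dff)) / sqrt(2), 1e-4)
  structure(list(frame_times_s = tt, dff = dff, f0 = f0,
                 baseline_window_s = c(tt[win[1]], tt[win[length(win)]]),
                 baseline_sigma = sigma, frame_rate_hz = frame_rate),
            class = "dff_trace")
}

# mean over every contiguous w-frame window, via cumulative sums
rolling_mean <- function(x, w) {
  cs <- c(0, cumsum(x))
  (cs[(w + 1):length(cs)] - cs[1:(length(cs) - w)]) / w
}

#' Detect calcium events
#'
#' Events are maximal contiguous runs of frames with
#' `dff > k * baseline_sigma`, each spanning at least `min_frames` frames
#' (single-frame crossings at slow frame rates are treated as noise). Onset
#' and offset are the first and last supra-threshold frames; the duration is
#' the run width plus one frame interval; the peak is the run maximum.
#'
#' @param dff A [compute_dff()] result.
#' @param k Threshold multiplier (default 3).
#' @param min_frames Minimum event span in frames (default 2).
#' @return A data.frame `onset_s`, `offset_s`, `peak_dff`, `duration_s`
#'   (zero rows when nothing crosses threshold).
#' @export
detect_ca_events <- function(dff, k = 3, min_frames = 2L) {
  stopifnot(inherits(dff, "dff_trace"))
  thr <- k * dff$baseline_sigma
  above <- dff$dff > thr
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_frames
  if (!any(keep))
    return(data.frame(onset_s = numeric(0), offset_s = numeric(0),
                      peak_dff = numeric(0), duration_s = numeric(0)))
  dt <- 1 / dff$frame_rate_hz
  s <- starts[keep]; e <- ends[keep]
  data.frame(
    onset_s = dff$frame_times_s[s],
    offset_s = dff$frame_times_s[e],
    peak_dff = mapply(function(a, b) max(dff$dff[a:b]), s, e),
    duration_s = dff$frame_times_s[e] - dff$frame_times_s[s] + dt)
}

#' Per-cell calcium activity summary
#'
#' Four statistics: AUC (trapezoidal integral of dF/F0 over each complete
#' `auc_window_s` window, averaged across windows; partial tail windows are
#' dropped, and a trace shorter than one window is integrated whole and
#' flagged partial), mean event peak amplitude, mean event duration (full
#' width of the supra-threshold segment), and event frequency in events per
#' minute.
#'
#' @param dff A [compute_dff()] result.
#' @param events Output of [detect_ca_events()].
#' @param auc_window_s AUC window (default 35 s).
#' @return A one-row data.frame: `auc`, `amplitude`, `duration_s`,
#'   `frequency_per_min`, `n_events`, `auc_partial`.
#' @export
summarize_calcium <- function(dff, events, auc_window_s = 35) {
  stopifnot(inherits(dff, "dff_trace"))
  tt <- dff$frame_times_s
  total_s <- tt[length(tt)] - tt[1] + 1 / dff$frame_rate_hz
  wf <- round(auc_window_s * dff$frame_rate_hz)
  n <- length(tt)
  n_win <- (n - 1) %/% wf  # complete windows of wf frame-intervals
  partial <- n_win < 1
  if (partial) {
    auc <- trapz(tt, dff$dff)
  } else {
    aucs <- vapply(seq_len(n_win), function(i) {
      idx <- ((i - 1) * wf + 1):(i * wf + 1)
      trapz(tt[idx], dff$dff[idx])
    }, numeric(1))
    auc <- mean(aucs)
  }
  data.frame(
    auc = auc,
    amplitude = if (nrow(events)) mean(events$peak_dff) else 0,
    duration_s = if (nrow(events)) mean(events$duration_s) else 0,
    frequency_per_min = nrow(events) / total_s * 60,
    n_events = nrow(events),
    auc_partial = partial)
}

# trapezoidal integral
trapz <- function(x, y) sum(diff(x) * (y[-1] + y[-length(y)]) / 2)
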