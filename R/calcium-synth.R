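#' Calcium-trace simulation parameters
#'
#' Emulates a GCaMP6s ROI trace: a homogeneous Poisson train of calcium
#' events, each rendered as a short rise followed by an exponential decay,
#' riding additively on a multiplicative baseline, plus Gaussian sensor
#' noise. Because the events are linear-additive on the baseline, the
#' generator's dF/F0 equals the injected kernel sum exactly, making the
#' amplitude ground truth exact.
#'
#' @param frame_rate_hz Frame rate (default 1.7 Hz, slow two-photon
#'   frame-scan imaging).
#' @param length_s Trace length (s).
#' @param event_rate_per_min Poisson event rate (events/min).
#' @param amplitude_sigma Event peak amplitude in multiples of the noise s.d.
#'   on the dF/F0 scale.
#' @param decay_tau_s Event decay time constant (default 1.5 s, GCaMP6s-like).
#' @param rise_frames Rise time in frames (default 1).
#' @param baseline_f Baseline fluorescence (a.u.).
#' @param noise_sigma Gaussian noise s.d. (a.u., on F).
#' @param amplitude_dff Optional event peak directly on the dF/F0 scale;
#'   overrides `amplitude_sigma` (needed for noise-free traces, where a
#'   sigma-relative amplitude would be zero).
#' @return A list of class `ca_sim_params`.
#' @export
ca_sim_params <- function(frame_rate_hz = 1.7, length_s = 105,
                          event_rate_per_min = 1.0, amplitude_sigma = 8,
                          decay_tau_s = 1.5, rise_frames = 1L,
                          baseline_f = 100, noise_sigma = 1,
                          amplitude_dff = NULL) {
  stopifnot(frame_rate_hz > 0, length_s > 0, event_rate_per_min >= 0,
            amplitude_sigma > 0, decay_tau_s > 0, rise_frames >= 1,
            baseline_f > 0, noise_sigma >= 0,
            is.null(amplitude_dff) || amplitude_dff > 0)
  structure(as.list(environment()), class = "ca_sim_params")
}

#' Simulate one ROI fluorescence trace
#'
#' Event times are a homogeneous Poisson process over the trace; each event
#' contributes, on the relative (dF/F0) scale, a linear rise over
#' `rise_frames` frames to a peak of `amplitude_sigma * noise_sigma /
#' baseline_f`, then an exponential decay with `decay_tau_s`. The raw trace
#' is `F = baseline_f * (1 + sum of event kernels) + N(0, noise_sigma)`.
#'
#' @param params A [ca_sim_params()].
#' @param roi_id,cell_class Passed to [fluor_trace()].
#' @return A list with `trace` (a [fluor_trace()]) and `event_log`
#'   (data.frame `time_s`, `amplitude_dff` of the injected events).
#' @export
simulate_ca_trace <- function(params, roi_id = "roi1",
                              cell_class = "unknown") {
  stopifnot(inherits(params, "ca_sim_params"))
  dt <- 1 / params$frame_rate_hz
  n <- round(params$length_s * params$frame_rate_hz)
  tt <- (seq_len(n) - 1) * dt
  n_ev <- stats::rpois(1, params$event_rate_per_min * params$length_s / 60)
  ev_t <- sort(stats::runif(n_ev, 0, params$length_s))
  amp_dff <- if (!is.null(params$amplitude_dff)) params$amplitude_dff
    else params$amplitude_sigma * params$noise_sigma / params$baseline_f
  s <- numeric(n)
  rise_s <- params$rise_frames * dt
  for (et in ev_t) {
    rel <- tt - et
    ker <- numeric(n)
    rising <- rel >= 0 & rel < rise_s
    decaying <- rel >= rise_s
    ker[rising] <- rel[rising] / rise_s
    ker[decaying] <- exp(-(rel[decaying] - rise_s) / params$decay_tau_s)
    s <- s + amp_dff * ker
  }
  Fv <- params$baseline_f * (1 + s)
  if (params$noise_sigma > 0)
    Fv <- Fv + stats::rnorm(n, 0, params$noise_sigma)
  list(trace = fluor_trace(tt, Fv, roi_id, cell_class),
       event_log = data.frame(time_s = ev_t,
                              amplitude_dff = rep(amp_dff, n_ev)))
}

#' Render an image stack from ROI traces
#'
#' Places non-overlapping disk ROIs in a frame; each ROI's pixels emit its
#' trace value plus per-pixel Gaussian noise, background pixels emit a
#' constant plus noise.
#'
#' @param traces List of [fluor_trace()] of equal length.
#' @param centers Matrix (n x 2) of ROI centers (row, col).
#' @param radius ROI disk radius in pixels.
#' @param dim_px Frame dimensions `c(rows, cols)`.
#' @param background Background constant (a.u.).
#' @param pixel_noise_sigma Per-pixel Gaussian noise s.d.
#' @param tiff_path Optional path; when given and the `tiff` package is
#'   available, the stack is written as a multi-page TIFF (values scaled to
#'   [0,1] by the stack maximum).
#' @return A list with `stack` (array `[row, col, frame]`), `roi_masks`
#'   (list of logical matrices) and `background_mask`.
#' @export
render_ca_stack <- function(traces, centers, radius = 3,
                            dim_px = c(64, 64), background = 10,
                            pixel_noise_sigma = 1, tiff_path = NULL) {
  stopifnot(is.list(traces), nrow(centers) == length(traces))
  nf <- length(traces[[1]]$F)
  rows <- dim_px[1]; cols <- dim_px[2]
  rc <- expand.grid(r = seq_len(rows), c = seq_len(cols))
  masks <- lapply(seq_len(nrow(centers)), function(i) {
    m <- matrix((rc$r - centers[i, 1])^2 + (rc$c - centers[i, 2])^2 <=
                  radius^2, rows, cols)
    if (!any(m)) stop("ROI ", i, " lies outside the frame")
    m
  })
  overlap <- Reduce(`+`, lapply(masks, function(m) m * 1))
  if (any(overlap > 1)) stop("ROIs overlap")
  bg_mask <- overlap == 0
  stack <- array(background, dim = c(rows, cols, nf))
  for (i in seq_along(masks)) {
    idx <- which(masks[[i]])
    for (f in seq_len(nf))
      stack[idx + (f - 1) * rows * cols] <- traces[[i]]$F[f]
  }
  if (pixel_noise_sigma > 0)
    stack <- stack + array(stats::rnorm(length(stack), 0, pixel_noise_sigma),
                           dim = dim(stack))
  if (!is.null(tiff_path)) {
    if (!requireNamespace("tiff", quietly = TRUE))
      stop("the tiff package is required to write a TIFF stack")
    sc <- stack / max(stack)
    tiff::writeTIFF(lapply(seq_len(nf), function(f) sc[, , f]), tiff_path)
  }
  list(stack = stack, roi_masks = masks, background_mask = bg_mask)
}
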