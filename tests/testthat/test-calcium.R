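test_that("ROI extraction is background-subtracted pixel averaging", {
  stack <- array(20, dim = c(8, 8, 5))
  roi <- matrix(FALSE, 8, 8); roi[3:5, 3:5] <- TRUE
  bg <- matrix(FALSE, 8, 8); bg[1, ] <- TRUE
  for (f in 1:5) stack[, , f][roi] <- 100
  tr <- extract_roi_trace(stack, roi, bg)
  expect_equal(tr$F, rep(80, 5))
  # single-pixel ROI with zero background reproduces that pixel's series
  px <- matrix(FALSE, 8, 8); px[2, 2] <- TRUE
  stack2 <- stack; stack2[2, 2, ] <- 1:5
  bg0 <- matrix(FALSE, 8, 8); bg0[8, 8] <- TRUE
  stack2[8, 8, ] <- 0
  expect_equal(extract_roi_trace(stack2, px, bg0)$F, as.numeric(1:5))
  expect_error(extract_roi_trace(stack, matrix(FALSE, 8, 8), bg), "empty")
})

test_that("dF/F0 of a constant trace is zero with F0 equal to the constant", {
  d <- compute_dff(make_const_trace(50))
  expect_equal(d$f0, 50)
  expect_true(all(d$dff == 0))
})

test_that("F0 lands on the quiescent plateau and peak dff is (max-F0)/F0", {
  rate <- 1.7
  n <- 120
  F <- rep(50, n)
  F[60:70] <- 100  # one event
  d <- compute_dff(fluor_trace((seq_len(n) - 1) / rate, F))
  expect_equal(d$f0, 50)
  expect_equal(max(d$dff), 1.0)
})

test_that("F0 equals the brute-force minimal-window oracle on noisy traces", {
  for (seed in 1:5) {
    set.seed(seed)
    tr <- simulate_ca_trace(ca_sim_params(length_s = 60))
    d <- compute_dff(tr$trace)
    w <- round(3.5 * 1.7)
    expect_equal(d$f0, oracle_f0(tr$trace$F, w))
  }
})

test_that("dF/F0 rejects invalid traces", {
  expect_error(compute_dff(make_const_trace(50, n = 4)), "shorter")
  expect_error(compute_dff(make_const_trace(-5)), "not positive")
})

test_that("the exclusion mask excises frames before all computations", {
  rate <- 2
  n <- 100
  F <- rep(50, n); F[40:45] <- 500  # artifact segment
  tr <- fluor_trace((seq_len(n) - 1) / rate, F)
  mask <- rep(TRUE, n); mask[40:45] <- FALSE
  d <- compute_dff(tr, mask = mask)
  expect_equal(d$f0, 50)
  expect_true(all(d$dff == 0))
})

test_that("event detection applies the 3-sigma, two-frame rule", {
  d0 <- compute_dff(make_const_trace(50))
  expect_equal(nrow(detect_ca_events(d0)), 0)
  # rectangular pulse of 10 sigma spanning 6 frames at 1.7 Hz
  rate <- 1.7
  n <- 100
  F <- rep(50, n)
  set.seed(2)
  F <- F + rnorm(n, 0, 0.05)
  sig <- 0.05 / 50
  F[40:45] <- 50 * (1 + 10 * sig)
  d <- compute_dff(fluor_trace((seq_len(n) - 1) / rate, F))
  ev <- detect_ca_events(d)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$duration_s, 6 / rate, tolerance = 0.15)
})

test_that("single-frame crossings are discarded as noise", {
  rate <- 1.7; n <- 80
  F <- rep(50, n); F <- F + rnorm(n, 0, 0.05)
  F[30] <- 60  # one-frame spike
  d <- compute_dff(fluor_trace((seq_len(n) - 1) / rate, F))
  expect_equal(nrow(detect_ca_events(d)), 0)
})

test_that("injected well-separated events are recovered one-to-one", {
  set.seed(4)
  for (rep in 1:5) {
    tr <- simulate_ca_trace(ca_sim_params(event_rate_per_min = 1,
                                          amplitude_sigma = 6))
    d <- compute_dff(tr$trace)
    ev <- detect_ca_events(d)
    gaps <- diff(sort(tr$event_log$time_s))
    if (nrow(tr$event_log) > 0 &&
        (length(gaps) == 0 || min(gaps) > 6 / 1.7)) {
      expect_equal(nrow(ev), nrow(tr$event_log))
      # every true event has a detection within the kernel rise time
      for (et in tr$event_log$time_s)
        expect_true(any(abs(ev$onset_s - et) < 2 / 1.7))
    }
  }
})

test_that("event count is nonincreasing in the threshold multiplier", {
  set.seed(9)
  tr <- simulate_ca_trace(ca_sim_params(event_rate_per_min = 3,
                                        amplitude_sigma = 5))
  d <- compute_dff(tr$trace)
  counts <- vapply(c(1, 2, 3, 4, 6, 10), function(k)
    nrow(detect_ca_events(d, k = k)), integer(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("summary statistics follow their closed forms", {
  # constant dff of 0.2 over exactly 35 s (2 Hz grid) -> AUC 7.0
  rate <- 2
  n <- 71
  tt <- (seq_len(n) - 1) / rate
  d <- structure(list(frame_times_s = tt, dff = rep(0.2, n), f0 = 50,
                      baseline_window_s = c(0, 3.5), baseline_sigma = 0.01,
                      frame_rate_hz = rate), class = "dff_trace")
  s <- summarize_calcium(d, detect_ca_events(d)[0, ])
  expect_equal(s$auc, 7.0)
  # 3 events in a 35-s trace -> 5.14 per minute
  ev3 <- data.frame(onset_s = c(5, 15, 25), offset_s = c(6, 16, 26),
                    peak_dff = c(1, 2, 3), duration_s = rep(1.5, 3))
  s3 <- summarize_calcium(d, ev3)
  expect_equal(s3$frequency_per_min, 3 / 35.5 * 60, tolerance = 0.03)
  expect_equal(s3$amplitude, 2)
  expect_equal(s3$duration_s, 1.5)
})

test_that("AUC equals the independent trapezoid oracle within 1e-9", {
  set.seed(12)
  tr <- simulate_ca_trace(ca_sim_params(length_s = 40, event_rate_per_min = 4))
  d <- compute_dff(tr$trace)
  s <- summarize_calcium(d, detect_ca_events(d))
  wf <- round(35 * d$frame_rate_hz)
  idx <- 1:(wf + 1)
  expect_equal(s$auc, oracle_trapz(d$frame_times_s[idx], d$dff[idx]),
               tolerance = 1e-9)
})

test_that("a trace shorter than the AUC window is integrated whole and flagged", {
  set.seed(13)
  tr <- simulate_ca_trace(ca_sim_params(length_s = 20))
  d <- compute_dff(tr$trace)
  s <- summarize_calcium(d, detect_ca_events(d))
  expect_true(s$auc_partial)
  expect_equal(s$auc, oracle_trapz(d$frame_times_s, d$dff), tolerance = 1e-9)
})

test_that("all calcium statistics are invariant to rescaling raw F", {
  set.seed(21)
  tr <- simulate_ca_trace(ca_sim_params(event_rate_per_min = 2))
  for (c_mult in c(0.5, 3, 100)) {
    tr2 <- fluor_trace(tr$trace$frame_times_s, tr$trace$F * c_mult)
    d1 <- compute_dff(tr$trace); d2 <- compute_dff(tr2)
    expect_equal(d2$dff, d1$dff, tolerance = 1e-12)
    e1 <- detect_ca_events(d1); e2 <- detect_ca_events(d2)
    expect_equal(nrow(e1), nrow(e2))
    expect_equal(summarize_calcium(d2, e2)[, 1:5],
                 summarize_calcium(d1, e1)[, 1:5], tolerance = 1e-12)
  }
})

test_that("adding a constant to F changes dF/F0 (sensitivity, not invariance)", {
  set.seed(22)
  tr <- simulate_ca_trace(ca_sim_params(event_rate_per_min = 2))
  tr2 <- fluor_trace(tr$trace$frame_times_s, tr$trace$F + 100)
  d1 <- compute_dff(tr$trace); d2 <- compute_dff(tr2)
  expect_gt(max(abs(d1$dff - d2$dff)), 1e-3)
})
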