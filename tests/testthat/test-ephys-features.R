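test_that("RMP is the pre-stimulus baseline mean and excludes the step", {
  expect_equal(measure_rmp(make_flat_sweep(-65)), -65)
  # depolarizing step after onset must not contaminate the baseline
  sw <- make_rc_sweep(rmp = -70, amp = 50)
  expect_equal(measure_rmp(sw), -70)
  # simulated cell with measurement noise: SE of the mean is tiny
  set.seed(1)
  p <- lif_params(resting_mV = -62, noise_sigma_mV = 0.2)
  sw2 <- simulate_sweep(p, 0, onset_ms = 200)$sweep
  expect_lt(abs(measure_rmp(sw2) - (-62)), 0.05)
})

test_that("RMP requires at least 50 ms of baseline", {
  n <- 10 * 600 + 1
  t <- (seq_len(n) - 1) / 10
  sw <- current_clamp_sweep(t, rep(-65, n), 10, 0, onset_ms = 30,
                            duration_ms = 500)
  expect_error(measure_rmp(sw), "50 ms")
})

test_that("input resistance is recovered exactly from noiseless RC sweeps", {
  sweeps <- lapply(seq(-30, 20, 10), function(a)
    make_rc_sweep(r_mohm = 150, amp = a))
  expect_equal(fit_input_resistance(sweeps), 150, tolerance = 0.1 / 150)
  # zero deflection at every amplitude -> zero slope
  flat <- lapply(seq(-30, 20, 10), function(a) make_flat_sweep(-70, amp = a))
  expect_equal(fit_input_resistance(flat), 0)
})

test_that("input resistance fit rejects degenerate inputs", {
  sweeps <- lapply(c(-30, -20), function(a) make_rc_sweep(amp = a))
  expect_error(fit_input_resistance(sweeps), "at least 3")
  same_amp <- lapply(1:4, function(i) make_rc_sweep(amp = -20))
  expect_error(fit_input_resistance(same_amp), "spread")
})

test_that("noisy input resistance recovery stays within OLS sampling error", {
  set.seed(7)
  errs <- replicate(10, {
    sweeps <- lapply(seq(-30, 20, 10), function(a)
      make_rc_sweep(r_mohm = 200, tau = 15, amp = a, noise = 0.3))
    fit_input_resistance(sweeps) - 200
  })
  expect_lt(max(abs(errs)), 4)
})

test_that("membrane tau fit recovers the generating exponential", {
  sw <- make_rc_sweep(tau = 12, amp = -30)
  expect_equal(fit_membrane_tau(list(sw)), 12, tolerance = 0.01)
  # two identical sweeps average to the same value
  sws <- list(make_rc_sweep(tau = 8, amp = -30),
              make_rc_sweep(tau = 8, amp = -20))
  expect_equal(fit_membrane_tau(sws), 8, tolerance = 0.01)
  # only hyperpolarizing sweeps are eligible
  expect_error(fit_membrane_tau(list(make_rc_sweep(amp = 10))),
               "hyperpolarizing")
})

test_that("noisy tau recovery is unbiased at the noise level used in vitro", {
  set.seed(3)
  taus <- replicate(10, {
    sws <- lapply(c(-30, -20, -10), function(a)
      make_rc_sweep(tau = 15, amp = a, noise = 0.3))
    fit_membrane_tau(sws)
  })
  expect_lt(max(abs(taus - 15)), 1)
})

test_that("capacitance follows Cm = tau/R with ms/MOhm -> pF units", {
  expect_equal(compute_capacitance(200, 10), 50)
  expect_equal(compute_capacitance(150, 15), 100)
  expect_equal(compute_capacitance(1, 1), 1000)
  expect_error(compute_capacitance(-1, 10), "positive")
  expect_error(compute_capacitance(100, 0), "positive")
})

test_that("capacitance unit round-trip holds to machine precision", {
  for (r in c(50, 150, 1000)) for (tau in c(5, 15, 35)) {
    cm <- compute_capacitance(r, tau)
    expect_equal(cm * r / 1000, tau)
  }
})

test_that("AP detection applies the -10 mV / 70 mV-from-baseline rule", {
  expect_equal(nrow(detect_aps(make_flat_sweep(-65))), 0)
  # one smooth bump peaking at 0 mV
  expect_equal(nrow(detect_aps(make_bump_sweep(peak = 0))), 1)
  # peak below -10 mV but >= 70 mV above baseline still qualifies
  expect_equal(nrow(detect_aps(make_bump_sweep(base = -90, peak = -15))), 1)
  # small bump fails both criteria
  expect_equal(nrow(detect_aps(make_bump_sweep(base = -65, peak = -20))), 0)
})

test_that("AP detection matches the LIF simulator spike log exactly", {
  p <- lif_params(resting_mV = -70, resistance_mohm = 200, tau_ms = 15,
                  threshold_mV = -50)
  for (a in seq(0, 400, 40)) {
    r <- simulate_sweep(p, a)
    expect_equal(nrow(detect_aps(r$sweep)), length(r$spike_times_ms),
                 info = paste("amplitude", a))
  }
})

triangle_spike_sweep <- function(fall_to, khz = 10, tp = 300) {
  n <- 700 * khz + 1
  t <- (seq_len(n) - 1) / khz
  v <- rep(-65, n)
  rise <- t >= tp - 1 & t <= tp
  fall <- t > tp & t <= tp + 1
  v[rise] <- -65 + (20 - (-65)) * (t[rise] - (tp - 1))
  v[fall] <- 20 - (20 - fall_to) * (t[fall] - tp)
  v[t > tp + 1 & t <= tp + 5] <- fall_to
  current_clamp_sweep(t, v, khz, 100, 100, 500)
}

test_that("AP features: symmetric spike has mirror-image slopes", {
  # triangular spike: linear 1 ms rise and fall between the same levels
  f <- ap_features(triangle_spike_sweep(fall_to = -65), 300)
  expect_false(f$flagged)
  expect_equal(abs(f$max_rise_slope_mV_ms), abs(f$max_decay_slope_mV_ms),
               tolerance = 1e-8)
})

test_that("AP amplitude is peak minus the fAHP nadir", {
  f <- ap_features(triangle_spike_sweep(fall_to = -75), 300)
  expect_equal(f$amplitude_mV, 20 - (-75))
})

test_that("AP threshold lands at the 5% dV/dt crossing", {
  # piecewise waveform: slow linear foot then steep linear rise, so the 5%
  # crossing sits exactly at the slope change
  khz <- 10
  n <- 700 * khz + 1
  t <- (seq_len(n) - 1) / khz
  v <- rep(-70, n)
  foot <- t >= 296 & t < 299   # 1 mV/ms foot: 1.25% of max rise
  rise <- t >= 299 & t < 300   # 80 mV/ms
  v[foot] <- -70 + 1 * (t[foot] - 296)
  v[rise] <- -67 + 80 * (t[rise] - 299)
  v[t >= 300 & t < 301] <- 13 - 85 * (t[t >= 300 & t < 301] - 300)
  v[t >= 301 & t <= 310] <- -72
  sw <- current_clamp_sweep(t, v, khz, 100, 100, 500)
  f <- ap_features(sw, 300)
  expect_equal(f$threshold_time_ms, 299, tolerance = 2 / khz)
  expect_equal(f$threshold_voltage_mV, -67, tolerance = 1)
})

test_that("excitability profile: rheobase, latency, first ISI, fAHP", {
  p <- lif_params(resting_mV = -70, resistance_mohm = 200, tau_ms = 10,
                  threshold_mV = -50)
  s <- simulate_protocol_set(p, seed = 2)
  prof <- excitability_profile(s$excitability)
  expect_equal(prof$rheobase_pA, lif_rheobase(p))
  # latency and ISI match the simulator's spike log at rheobase + 100
  log100 <- s$spike_log[[as.character(prof$rheobase_pA + 100)]]
  expect_equal(prof$latency_first_ap_ms, log100[1] - 100, tolerance = 0.2)
  expect_equal(prof$first_isi_ms, log100[2] - log100[1], tolerance = 0.3)
  expect_gt(prof$fahp_mV, 0)  # threshold minus nadir is a positive drop
})

test_that("excitability profile flags degenerate inputs", {
  sweeps <- lapply(seq(0, 400, 20), function(a)
    make_flat_sweep(-70, amp = a))
  prof <- excitability_profile(sweeps)
  expect_true(is.na(prof$rheobase_pA))
  expect_true("no_ap_any_step" %in% prof$flags)
})

test_that("FS classification uses strict tau < 15 ms AND count > 35", {
  expect_equal(classify_fs(10, 50), "FS")
  expect_equal(classify_fs(15, 50), "non_FS")
  expect_equal(classify_fs(10, 35), "non_FS")
  expect_equal(classify_fs(NA, 50), "unclassified")
  # pure function: repeated application gives the same answer
  expect_equal(classify_fs(10, 50), classify_fs(10, 50))
})

test_that("QC applies the stated inclusion criteria with itemized reasons", {
  expect_false(qc_neuron(-54, 150, 40)$included)
  expect_match(qc_neuron(-54, 150, 40)$reasons, "RMP")
  expect_match(qc_neuron(-70, 1200, 40)$reasons, "input resistance")
  expect_match(qc_neuron(-70, 150, 1)$reasons, "APs")
  expect_match(qc_neuron(-70, 150, 40, 30)$reasons, "access resistance")
  expect_match(qc_neuron(-70, 150, 40, 10, 14)$reasons, "variation")
  ok <- qc_neuron(-70, 150, 40, 10)
  expect_true(ok$included)
  expect_length(ok$reasons, 0)
})
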