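#' Leaky integrate-and-fire parameters
#'
#' Ground-truth parameter set for the sweep simulator. Subthreshold dynamics
#' follow `tau dV/dt = -(V - E_L) + R I(t)`; crossing the spike threshold
#' emits a stereotyped rendered spike and resets the membrane.
#'
#' @param resting_mV Resting potential E_L (mV).
#' @param resistance_mohm Input resistance R (MOhm).
#' @param tau_ms Membrane time constant (ms).
#' @param threshold_mV Spike threshold V_th (mV); must exceed `resting_mV`.
#' @param reset_mV Post-spike reset potential (mV); at most `threshold_mV`.
#' @param refractory_ms Absolute refractory period during which the membrane
#'   is clamped at the reset potential.
#' @param spike_peak_mV Rendered spike peak (mV); the stereotyped waveform
#'   rises to this peak over 1 ms and falls to 5 mV below the reset over the
#'   next 1 ms, so both AP detection criteria are met unambiguously.
#' @param noise_sigma_mV S.d. of additive Gaussian measurement noise applied
#'   to the recorded voltage (the dynamics themselves are noiseless, keeping
#'   the spike log exact).
#' @return A list of class `lif_params`.
#' @export
lif_params <- function(resting_mV = -70, resistance_mohm = 200, tau_ms = 15,
                       threshold_mV = -50, reset_mV = -65, refractory_ms = 2,
                       spike_peak_mV = 30, noise_sigma_mV = 0) {
  stopifnot(threshold_mV > resting_mV, reset_mV <= threshold_mV,
            tau_ms > 0, resistance_mohm > 0, refractory_ms >= 0,
            noise_sigma_mV >= 0)
  structure(list(resting_mV = resting_mV, resistance_mohm = resistance_mohm,
                 tau_ms = tau_ms, threshold_mV = threshold_mV,
                 reset_mV = reset_mV, refractory_ms = refractory_ms,
                 spike_peak_mV = spike_peak_mV,
                 noise_sigma_mV = noise_sigma_mV),
            class = "lif_params")
}

# Equality tolerance (mV) for threshold attainment: the exact-exponential
# trajectory approaches its steady state asymptotically, so a step whose
# steady state equals V_th exactly would otherwise never fire in finite time.
LIF_THRESHOLD_TOL <- 1e-6

#' Simulate one current-clamp sweep from a LIF cell
#'
#' Subthreshold dynamics are integrated with the exact exponential update per
#' sample (closed-form relaxation between events), so with zero noise the
#' analytic solution `V(t) = E_L + R I (1 - exp(-t/tau))` holds to machine
#' precision. When V reaches the threshold (within a 1e-6 mV equality
#' tolerance), a stereotyped 2-ms spike waveform is rendered (1 ms linear rise
#' to the spike peak, 1 ms linear fall to 5 mV below the reset), the membrane
#' is clamped to the reset for the refractory period, and the spike time is
#' logged. Gaussian measurement noise is added to the recorded trace.
#'
#' @param params A [lif_params()].
#' @param amplitude_pA Step amplitude (pA).
#' @param onset_ms,duration_ms Step timing (defaults 100 ms onset, 500 ms
#'   duration).
#' @param post_ms Trace tail after the step (default 100 ms).
#' @param sampling_khz Sampling rate (>= 5 kHz).
#' @return A list with `sweep` (a [current_clamp_sweep()]) and
#'   `spike_times_ms` (threshold-crossing times, the ground-truth spike log).
#' @export
simulate_sweep <- function(params, amplitude_pA, onset_ms = 100,
                           duration_ms = 500, post_ms = 100,
                           sampling_khz = 10) {
  stopifnot(inherits(params, "lif_params"))
  if (sampling_khz < 5) stop("sampling rate must be at least 5 kHz")
  dt <- 1 / sampling_khz
  n <- round((onset_ms + duration_ms + post_ms) * sampling_khz) + 1
  t <- (seq_len(n) - 1) * dt
  i_ext <- ifelse(t >= onset_ms & t < onset_ms + duration_ms, amplitude_pA, 0)
  v <- numeric(n)
  v[1] <- params$resting_mV
  spike_times <- numeric(0)
  el <- params$resting_mV; r <- params$resistance_mohm
  tau <- params$tau_ms; vth <- params$threshold_mV
  vre <- params$reset_mV; vpk <- params$spike_peak_mV
  nadir <- vre - 5
  ref_n <- max(1L, round(params$refractory_ms * sampling_khz))
  rise_n <- max(1L, round(1 * sampling_khz))   # 1 ms rise
  fall_n <- max(1L, round(1 * sampling_khz))   # 1 ms fall

  # integrate segment-wise: between spikes the drive is piecewise constant
  # (changes only at step onset/offset), so V relaxes exponentially toward
  # E_L + R I and the whole segment is computed vectorized
  k <- 1L
  while (k < n) {
    # next drive-change boundary after k
    bounds <- sort(unique(c(round(onset_ms * sampling_khz) + 1L,
                            round((onset_ms + duration_ms) * sampling_khz) + 1L,
                            n)))
    nb <- bounds[bounds > k][1]
    vinf <- el + r * i_ext[k] / 1000  # MOhm * pA / 1000 = mV
    seg <- k:nb
    rel <- exp(-(t[seg] - t[k]) / tau)
    vseg <- vinf + (v[k] - vinf) * rel
    hit <- which(vseg >= vth - LIF_THRESHOLD_TOL)
    hit <- hit[hit > 1L]
    if (length(hit) == 0) {
      v[seg] <- vseg
      k <- nb
      if (k == n) break
    } else {
      j <- seg[hit[1]]               # absolute index of threshold crossing
      v[k:(j - 1L)] <- vseg[seq_len(hit[1] - 1L)]
      spike_times <- c(spike_times, t[j])
      # render the stereotyped spike then clamp for the refractory period
      up <- j:min(n, j + rise_n)
      v[up] <- seq(vth, vpk, length.out = length(up))
      dn_start <- min(n, j + rise_n)
      dn <- dn_start:min(n, dn_start + fall_n)
      v[dn] <- seq(vpk, nadir, length.out = length(dn))
      ref_end <- min(n, dn[length(dn)] + ref_n)
      if (ref_end > dn[length(dn)]) v[(dn[length(dn)] + 1L):ref_end] <- vre
      v[ref_end] <- vre
      k <- ref_end
      if (k >= n) break
    }
  }
  if (params$noise_sigma_mV > 0)
    v <- v + stats::rnorm(n, 0, params$noise_sigma_mV)
  sweep <- current_clamp_sweep(t, v, sampling_khz, amplitude_pA,
                               onset_ms, duration_ms)
  list(sweep = sweep, spike_times_ms = spike_times)
}

#' Closed-form LIF rheobase on a step grid
#'
#' Smallest grid amplitude whose steady-state depolarization
#' `E_L + R I` attains the spike threshold (within the simulator's 1e-6 mV
#' equality tolerance) in time, i.e. whose analytic crossing time is within
#' the step duration.
#'
#' @param params A [lif_params()].
#' @param amplitudes_pA Step grid (default 0..400 by 20).
#' @param duration_ms Step duration (default 500 ms).
#' @return Rheobase in pA, or `NA` when no grid step fires.
#' @export
lif_rheobase <- function(params, amplitudes_pA = seq(0, 400, 20),
                         duration_ms = 500) {
  el <- params$resting_mV; r <- params$resistance_mohm
  vth <- params$threshold_mV; tau <- params$tau_ms
  for (a in sort(amplitudes_pA)) {
    vinf <- el + r * a / 1000
    gap <- vinf - (vth - LIF_THRESHOLD_TOL)
    if (gap <= 0) next
    # time for V to come within tol of vth (from rest): analytic crossing
    tcross <- tau * log((vinf - el) / gap)
    if (is.finite(tcross) && tcross <= duration_ms) return(a)
  }
  NA_real_
}

#' Simulate a full protocol set and write it to disk
#'
#' Generates the subthreshold and excitability protocol sweeps for one cell,
#' writes each sweep as a `time_ms,voltage_mV` CSV, a JSON manifest
#' (`cell_id`, `genotype`, `sampling_khz`, per-sweep file/amplitude/onset/
#' duration/protocol), and a ground-truth JSON carrying the generator's R,
#' tau, Cm, closed-form rheobase and the spike count per amplitude.
#'
#' @param params A [lif_params()].
#' @param out_dir Output directory (created if needed); when `NULL`, nothing
#'   is written and the sweeps are only returned.
#' @param cell_id,genotype Manifest identifiers.
#' @param sampling_khz Sampling rate.
#' @param seed Integer seed; the run is bit-reproducible.
#' @return Invisibly, a list with `subthreshold` and `excitability` sweep
#'   lists, `spike_log` (list of spike-time vectors keyed by amplitude), and
#'   `ground_truth`.
#' @export
simulate_protocol_set <- function(params, out_dir = NULL, cell_id = "cell1",
                                  genotype = "WT", sampling_khz = 10,
                                  seed = 1L) {
  set.seed(seed)
  sub_amp <- step_protocol("subthreshold_10pA")$amplitudes_pA
  exc_amp <- step_protocol("excitability_20pA")$amplitudes_pA
  sub <- lapply(sub_amp, function(a)
    simulate_sweep(params, a, sampling_khz = sampling_khz))
  exc <- lapply(exc_amp, function(a)
    simulate_sweep(params, a, sampling_khz = sampling_khz))
  spike_log <- stats::setNames(lapply(exc, `[[`, "spike_times_ms"),
                               as.character(exc_amp))
  gt <- list(
    resistance_mohm = params$resistance_mohm,
    tau_ms = params$tau_ms,
    capacitance_pF = compute_capacitance(params$resistance_mohm,
                                         params$tau_ms),
    rheobase_pA = lif_rheobase(params),
    spike_counts = stats::setNames(vapply(spike_log, length, integer(1)),
                                   names(spike_log)))
  sweeps <- c(lapply(sub, `[[`, "sweep"), lapply(exc, `[[`, "sweep"))
  protos <- c(rep("subthreshold_10pA", length(sub)),
              rep("excitability_20pA", length(exc)))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    entries <- lapply(seq_along(sweeps), function(i) {
      s <- sweeps[[i]]
      f <- sprintf("%s_sweep%02d.csv", cell_id, i)
      utils::write.csv(
        data.frame(time_ms = s$time_ms, voltage_mV = s$voltage_mV),
        file.path(out_dir, f), row.names = FALSE)
      list(file = f, amplitude_pA = s$amplitude_pA, onset_ms = s$onset_ms,
           duration_ms = s$duration_ms, protocol = protos[i],
           holding_mV = NA)
    })
    manifest <- list(cell_id = cell_id, genotype = genotype,
                     sampling_khz = sampling_khz, sweeps = entries)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         na = "null")
    jsonlite::write_json(gt, file.path(out_dir, "ground_truth.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(list(
    subthreshold = lapply(sub, `[[`, "sweep"),
    excitability = lapply(exc, `[[`, "sweep"),
    spike_log = spike_log, ground_truth = gt))
}

#' Read a sweep set written by [simulate_protocol_set()]
#'
#' @param dir Directory containing `manifest.json` and the per-sweep CSVs.
#' @return A list with `cell_id`, `genotype`, `subthreshold` and
#'   `excitability` sweep lists.
#' @export
read_sweep_set <- function(dir) {
  man <- jsonlite::read_json(file.path(dir, "manifest.json"),
                             simplifyVector = FALSE)
  sweeps <- lapply(man$sweeps, function(e) {
    d <- utils::read.csv(file.path(dir, e$file))
    list(sweep = current_clamp_sweep(
      d$time_ms, d$voltage_mV, man$sampling_khz, e$amplitude_pA,
      e$onset_ms, e$duration_ms,
      holding_mV = if (is.null(e$holding_mV)) NA_real_ else e$holding_mV,
      protocol = e$protocol), protocol = e$protocol)
  })
  proto <- vapply(sweeps, `[[`, character(1), "protocol")
  list(cell_id = man$cell_id, genotype = man$genotype,
       subthreshold = lapply(sweeps[proto == "subthreshold_10pA"], `[[`, "sweep"),
       excitability = lapply(sweeps[proto == "excitability_20pA"], `[[`, "sweep"))
}
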