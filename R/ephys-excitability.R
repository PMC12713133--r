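#' Excitability profile from a 20-pA step series
#'
#' Builds the input-output curve (AP count per current step), the rheobase
#' (smallest amplitude eliciting at least one AP, reported on the 20-pA
#' protocol grid without interpolation), and the spike-timing measures taken
#' on the sweep at rheobase + 100 pA: latency to the first AP, first
#' inter-spike interval, and the fast afterhyperpolarization (voltage
#' threshold minus the post-peak minimum), the latter averaged over the first
#' five APs of that sweep. When the sweep carries fewer than five APs the
#' available ones are averaged and the profile is flagged.
#'
#' @param sweeps List of [current_clamp_sweep()] covering 0..400 pA in 20-pA
#'   increments.
#' @param fahp_n_aps Number of leading APs over which the fAHP is averaged
#'   (default 5).
#' @return A list of class `excitability_profile` with `io_curve`
#'   (data.frame `amplitude_pA`, `n_ap`), `rheobase_pA`,
#'   `latency_first_ap_ms`, `first_isi_ms`, `fahp_mV`, and `flags`
#'   (character vector).
#' @export
excitability_profile <- function(sweeps, fahp_n_aps = 5) {
  stopifnot(is.list(sweeps), length(sweeps) >= 1)
  amp <- vapply(sweeps, `[[`, numeric(1), "amplitude_pA")
  ord <- order(amp)
  sweeps <- sweeps[ord]; amp <- amp[ord]
  aps <- lapply(sweeps, detect_aps)
  io <- data.frame(amplitude_pA = amp,
                   n_ap = vapply(aps, nrow, integer(1)))
  flags <- character(0)
  out <- list(io_curve = io, rheobase_pA = NA_real_,
              latency_first_ap_ms = NA_real_, first_isi_ms = NA_real_,
              fahp_mV = NA_real_, flags = flags)
  firing <- which(io$n_ap >= 1)
  if (length(firing) == 0) {
    out$flags <- "no_ap_any_step"
    class(out) <- "excitability_profile"
    return(out)
  }
  out$rheobase_pA <- amp[firing[1]]
  target <- out$rheobase_pA + 100
  it <- which(amp == target)
  if (length(it) == 0) {
    out$flags <- c(out$flags, "rheobase_plus_100_outside_protocol")
  } else {
    sw <- sweeps[[it]]
    tab <- sweep_ap_table(sw)
    if (nrow(tab) >= 1)
      out$latency_first_ap_ms <- tab$peak_time_ms[1] - sw$onset_ms
    if (nrow(tab) >= 2) {
      out$first_isi_ms <- tab$peak_time_ms[2] - tab$peak_time_ms[1]
    } else {
      out$flags <- c(out$flags, "fewer_than_2_aps_at_rheobase_plus_100")
    }
    if (nrow(tab) >= 1) {
      k <- min(fahp_n_aps, nrow(tab))
      f <- tab$threshold_voltage_mV[seq_len(k)] - tab$fahp_voltage_mV[seq_len(k)]
      out$fahp_mV <- mean(f, na.rm = TRUE)
      if (k < fahp_n_aps)
        out$flags <- c(out$flags, sprintf("fahp_averaged_over_%d_aps", k))
    }
  }
  class(out) <- "excitability_profile"
  out
}

#' Fast-spiking classification
#'
#' An interneuron is classified fast-spiking (FS) when its membrane time
#' constant is strictly below 15 ms AND it fires strictly more than 35 APs in
#' the 500-ms step at 400 pA (a firing rate of 70 Hz). Any other cell is
#' non-FS; a missing input yields `"unclassified"`.
#'
#' @param tau_ms Membrane time constant in ms.
#' @param ap_count_400pA AP count at the 400-pA, 500-ms step.
#' @param tau_cutoff_ms,count_cutoff Classifier cutoffs (defaults 15 ms and
#'   35 APs).
#' @return `"FS"`, `"non_FS"` or `"unclassified"`.
#' @export
classify_fs <- function(tau_ms, ap_count_400pA, tau_cutoff_ms = 15,
                        count_cutoff = 35) {
  if (is.na(tau_ms) || is.na(ap_count_400pA)) return("unclassified")
  if (tau_ms < tau_cutoff_ms && ap_count_400pA > count_cutoff) "FS" else "non_FS"
}

#' Neuron inclusion criteria
#'
#' A cell is excluded, with itemized reasons, when any of the following
#' holds: resting membrane potential not more negative than -55 mV; access
#' resistance of 25 MOhm or more (or, when start/end values are both given,
#' a variation of 30% or more across the recording); input resistance of
#' 1000 MOhm or more; or at most one AP evoked over the whole 0..400-pA
#' series at RMP.
#'
#' @param rmp_mV Resting membrane potential.
#' @param input_resistance_mohm Input resistance.
#' @param max_ap_count Maximum AP count over the excitability series.
#' @param access_resistance_mohm Access resistance, or `NA` when not recorded.
#' @param access_resistance_end_mohm Access resistance at the end of the
#'   recording, or `NA`; used only for the 30% variation check.
#' @return A list with `included` (logical) and `reasons` (character vector,
#'   empty iff included).
#' @export
qc_neuron <- function(rmp_mV, input_resistance_mohm, max_ap_count,
                      access_resistance_mohm = NA_real_,
                      access_resistance_end_mohm = NA_real_) {
  reasons <- character(0)
  if (!is.na(rmp_mV) && rmp_mV >= -55)
    reasons <- c(reasons, "RMP not more negative than -55 mV")
  if (!is.na(access_resistance_mohm)) {
    if (access_resistance_mohm >= 25)
      reasons <- c(reasons, "access resistance >= 25 MOhm")
    if (!is.na(access_resistance_end_mohm)) {
      var_frac <- abs(access_resistance_end_mohm - access_resistance_mohm) /
        access_resistance_mohm
      if (var_frac >= 0.30)
        reasons <- c(reasons, "access resistance variation >= 30%")
    }
  }
  if (!is.na(input_resistance_mohm) && input_resistance_mohm >= 1000)
    reasons <- c(reasons, "input resistance >= 1000 MOhm")
  if (!is.na(max_ap_count) && max_ap_count <= 1)
    reasons <- c(reasons, "one or fewer APs evoked over 0-400 pA")
  list(included = length(reasons) == 0, reasons = reasons)
}

#' Summarize one neuron
#'
#' Runs the passive-property fits, the excitability profile, FS
#' classification and QC for one cell's sweep set, returning a one-row
#' summary data.frame.
#'
#' @param cell_id,genotype Identifiers carried through to the output.
#' @param subthreshold_sweeps Sweeps from the subthreshold 10-pA protocol.
#' @param excitability_sweeps Sweeps from the 0..400-pA protocol.
#' @param access_resistance_mohm,access_resistance_end_mohm Optional access
#'   resistance bookkeeping for QC.
#' @return A one-row data.frame (class `neuron_summary` rows) with passive
#'   properties, excitability measures, class label and QC verdict.
#' @export
summarize_neuron <- function(cell_id, genotype, subthreshold_sweeps,
                             excitability_sweeps,
                             access_resistance_mohm = NA_real_,
                             access_resistance_end_mohm = NA_real_) {
  rmp <- mean(vapply(subthreshold_sweeps, measure_rmp, numeric(1)))
  rin <- tryCatch(fit_input_resistance(subthreshold_sweeps),
                  error = function(e) NA_real_)
  tau <- tryCatch(fit_membrane_tau(subthreshold_sweeps),
                  error = function(e) NA_real_)
  cm <- if (!is.na(rin) && !is.na(tau) && rin > 0 && tau > 0)
    compute_capacitance(rin, tau) else NA_real_
  prof <- excitability_profile(excitability_sweeps)
  n400 <- prof$io_curve$n_ap[prof$io_curve$amplitude_pA == 400]
  n400 <- if (length(n400)) n400[1] else NA_integer_
  cls <- classify_fs(tau, n400)
  qc <- qc_neuron(rmp, rin, max(prof$io_curve$n_ap),
                  access_resistance_mohm, access_resistance_end_mohm)
  data.frame(
    cell_id = cell_id, genotype = genotype,
    rmp_mV = rmp, input_resistance_mohm = rin, tau_ms = tau,
    capacitance_pF = cm, rheobase_pA = prof$rheobase_pA,
    latency_first_ap_ms = prof$latency_first_ap_ms,
    first_isi_ms = prof$first_isi_ms, fahp_mV = prof$fahp_mV,
    n_ap_400pA = n400, max_ap_count = max(prof$io_curve$n_ap),
    class_label = cls, qc_included = qc$included,
    qc_reasons = paste(qc$reasons, collapse = "; "),
    stringsAsFactors = FALSE)
}
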