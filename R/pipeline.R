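#' Analysis defaults
#'
#' The fixed constants of the quantification procedures, collected in one
#' place so every stage reads the same values and any of them can be
#' overridden through the run configuration: the AP identification rule
#' (peak above -10 mV or amplitude of at least 70 mV from baseline), the
#' calcium event threshold (3 x baseline s.d.), the 3.5-s baseline and 35-s
#' AUC windows, the 1.7-Hz default frame rate, the FS classifier (tau <
#' 15 ms and > 35 APs at 400 pA), and the neuron inclusion cutoffs (-55 mV
#' RMP, 25 MOhm access resistance, 1000 MOhm input resistance, more than
#' one evoked AP).
#'
#' @return Named list of defaults.
#' @export
nphys_defaults <- function() {
  list(
    ap_peak_threshold_mV = -10,
    ap_min_amplitude_mV = 70,
    ca_event_sigma_k = 3,
    ca_baseline_seconds = 3.5,
    ca_auc_window_s = 35,
    ca_frame_rate_hz = 1.7,
    fs_tau_cutoff_ms = 15,
    fs_ap_count_cutoff = 35,
    qc_rmp_max_mV = -55,
    qc_access_max_mohm = 25,
    qc_rin_max_mohm = 1000,
    qc_min_ap_count = 2)
}

#' Run the electrophysiology pipeline
#'
#' Per cell: extract passive properties and the excitability profile, apply
#' QC, classify FS / non-FS, then compare the two genotype groups per class
#' with Mann-Whitney tests on each scalar metric and a mixed two-way ANOVA
#' on the input-output curves.
#'
#' @param cells A list of cell inputs; each element is a list with
#'   `cell_id`, `genotype`, `subthreshold` (sweep list), `excitability`
#'   (sweep list), and optional `access_resistance_mohm`. Use
#'   [read_sweep_set()] or [simulate_protocol_set()] to build them.
#' @param groups Length-2 character vector of genotype labels to compare.
#' @return A list with `summary` (per-cell NeuronSummary table),
#'   `comparisons` (per-class, per-metric test table) and `skipped`
#'   (character log of comparisons that could not be run).
#' @export
run_ephys <- function(cells, groups = c("WT", "MUT")) {
  if (length(cells) == 0) stop("empty cell manifest")
  summ <- do.call(rbind, lapply(cells, function(cl)
    summarize_neuron(cl$cell_id, cl$genotype, cl$subthreshold,
                     cl$excitability,
                     access_resistance_mohm =
                       cl$access_resistance_mohm %||% NA_real_)))
  inc <- summ[summ$qc_included, ]
  metrics <- c("rmp_mV", "input_resistance_mohm", "capacitance_pF",
               "rheobase_pA", "latency_first_ap_ms", "first_isi_ms",
               "fahp_mV")
  comparisons <- list(); skipped <- character(0)
  for (cls in intersect(c("FS", "non_FS"), unique(inc$class_label))) {
    d <- inc[inc$class_label == cls, ]
    na <- sum(d$genotype == groups[1]); nb <- sum(d$genotype == groups[2])
    if (na < 2 || nb < 2) {
      skipped <- c(skipped, sprintf(
        "%s: fewer than 2 QC-passing cells per group (%d vs %d)",
        cls, na, nb))
      next
    }
    for (m in metrics) {
      x <- d[[m]][d$genotype == groups[1]]
      y <- d[[m]][d$genotype == groups[2]]
      x <- x[!is.na(x)]; y <- y[!is.na(y)]
      if (length(x) < 2 || length(y) < 2) {
        skipped <- c(skipped, sprintf("%s/%s: insufficient data", cls, m))
        next
      }
      mw <- mann_whitney_u(x, y, metric = m)
      comparisons[[length(comparisons) + 1]] <- data.frame(
        class_label = cls, metric = m, test = "mann_whitney_u",
        stat = mw$statistic, p = mw$p_value, n_a = mw$n_a, n_b = mw$n_b)
    }
    # io-curve mixed ANOVA needs the per-cell step counts
    io <- do.call(rbind, lapply(cells, function(cl) {
      row <- summ[summ$cell_id == cl$cell_id, ]
      if (!row$qc_included || row$class_label != cls) return(NULL)
      prof <- excitability_profile(cl$excitability)
      data.frame(cell_id = cl$cell_id, group = cl$genotype,
                 step = prof$io_curve$amplitude_pA,
                 value = prof$io_curve$n_ap)
    }))
    an <- tryCatch(mixed_two_way_anova(io), error = function(e) NULL)
    if (!is.null(an)) {
      comparisons[[length(comparisons) + 1]] <- data.frame(
        class_label = cls, metric = "io_curve", test = "mixed_anova",
        stat = an$f_between, p = an$p_between, n_a = na, n_b = nb)
    } else {
      skipped <- c(skipped, sprintf("%s/io_curve: ANOVA not estimable", cls))
    }
  }
  comp <- if (length(comparisons)) do.call(rbind, comparisons) else
    data.frame(class_label = character(0), metric = character(0),
               test = character(0), stat = numeric(0), p = numeric(0),
               n_a = integer(0), n_b = integer(0))
  list(summary = summ, comparisons = comp, skipped = skipped)
}

#' Run the calcium pipeline
#'
#' Per trace: dF/F0, event detection, and the four summary statistics; then
#' Mann-Whitney comparisons of each statistic between the two groups within
#' each cell class.
#'
#' @param traces List of [fluor_trace()] objects.
#' @param group_labels Character vector, one group label per trace.
#' @param groups Length-2 character vector of group labels to compare.
#' @param defaults Defaults list, see [nphys_defaults()].
#' @return A list with `summary` (per-cell table) and `comparisons`, and
#'   `skipped`.
#' @export
run_calcium <- function(traces, group_labels, groups = c("WT", "MUT"),
                        defaults = nphys_defaults()) {
  stopifnot(length(traces) == length(group_labels))
  summ <- do.call(rbind, lapply(seq_along(traces), function(i) {
    tr <- traces[[i]]
    d <- compute_dff(tr, baseline_seconds = defaults$ca_baseline_seconds)
    ev <- detect_ca_events(d, k = defaults$ca_event_sigma_k)
    cbind(data.frame(roi_id = tr$roi_id, cell_class = tr$cell_class,
                     group = group_labels[i]),
          summarize_calcium(d, ev, auc_window_s = defaults$ca_auc_window_s))
  }))
  metrics <- c("auc", "amplitude", "duration_s", "frequency_per_min")
  comparisons <- list(); skipped <- character(0)
  for (cls in unique(summ$cell_class)) {
    d <- summ[summ$cell_class == cls, ]
    na <- sum(d$group == groups[1]); nb <- sum(d$group == groups[2])
    if (na < 2 || nb < 2) {
      skipped <- c(skipped, sprintf("%s: fewer than 2 cells per group", cls))
      next
    }
    for (m in metrics) {
      mw <- mann_whitney_u(d[[m]][d$group == groups[1]],
                           d[[m]][d$group == groups[2]], metric = m)
      comparisons[[length(comparisons) + 1]] <- data.frame(
        cell_class = cls, metric = m, test = "mann_whitney_u",
        stat = mw$statistic, p = mw$p_value, n_a = mw$n_a, n_b = mw$n_b)
    }
  }
  comp <- if (length(comparisons)) do.call(rbind, comparisons) else
    data.frame(cell_class = character(0), metric = character(0),
               test = character(0), stat = numeric(0), p = numeric(0),
               n_a = integer(0), n_b = integer(0))
  list(summary = summ, comparisons = comp, skipped = skipped)
}

#' Write a run report
#'
#' Serializes the summary and comparison tables as TSV and writes a
#' deterministic markdown report embedding the seed and a hash of the
#' configuration; rerunning with the same inputs yields identical bytes.
#' Missing optional metrics render as `NA`; every QC exclusion is listed
#' with its reasons.
#'
#' @param run Output of [run_ephys()] or [run_calcium()].
#' @param out_dir Output directory.
#' @param seed Seed to embed.
#' @param config Configuration list to hash into the report.
#' @return Invisibly, the markdown path.
#' @export
write_report <- function(run, out_dir, seed = NA_integer_, config = list()) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(run$summary, file.path(out_dir, "summary.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(run$comparisons, file.path(out_dir, "comparisons.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  cfg_json <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA)
  cfg_hash <- substr(digest_hex(cfg_json), 1, 12)
  lines <- c(
    "# Run report", "",
    sprintf("- seed: %s", seed),
    sprintf("- config hash: %s", cfg_hash),
    sprintf("- cells: %d", nrow(run$summary)), "",
    "## Comparisons", "",
    report_table(run$comparisons), "",
    "## QC exclusions", "")
  if ("qc_included" %in% names(run$summary)) {
    exc <- run$summary[!run$summary$qc_included, ]
    lines <- c(lines, if (nrow(exc) == 0) "(none)" else
      sprintf("- %s: %s", exc$cell_id, exc$qc_reasons))
  } else lines <- c(lines, "(not applicable)")
  if (length(run$skipped))
    lines <- c(lines, "", "## Skipped comparisons", "",
               paste0("- ", run$skipped))
  path <- file.path(out_dir, "report.md")
  writeLines(lines, path)
  invisible(path)
}

# fixed-width markdown rendering of a data.frame
report_table <- function(df) {
  if (nrow(df) == 0) return("(no comparisons)")
  fmt <- function(x) if (is.numeric(x)) formatC(x, digits = 6, format = "g")
    else as.character(x)
  cells <- vapply(df, fmt, character(nrow(df)))
  if (is.null(dim(cells))) cells <- matrix(cells, nrow = 1)
  header <- paste(names(df), collapse = " | ")
  sep <- paste(rep("---", ncol(df)), collapse = " | ")
  rows <- apply(cells, 1, paste, collapse = " | ")
  c(header, sep, rows)
}

# tiny stable string hash (djb2), hex-encoded; avoids a digest dependency
digest_hex <- function(s) {
  bytes <- utf8ToInt(as.character(s))
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 2^31
  sprintf("%08x%04x", h, length(bytes) %% 65536)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
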