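#' Percent spliced-in from junction counts
#'
#' Standard junction-ratio estimate: with one or two inclusion junction
#' counts (upstream/downstream of the cassette exon) and one skipping
#' junction count, the effective inclusion count is the mean of the available
#' inclusion junctions and `psi = I_eff / (I_eff + S)`. The estimate is
#' undefined (`NA`) when the effective coverage `I_eff + S` is below
#' `min_coverage`; below that, the ratio is dominated by sampling noise.
#'
#' @param inc1 Upstream inclusion junction count.
#' @param inc2 Downstream inclusion junction count, or `NA` when only one
#'   junction was quantified.
#' @param skip Skipping junction count.
#' @param min_coverage Minimum effective reads (default 10).
#' @return Psi in `[0, 1]`, or `NA` when coverage is insufficient.
#' @export
compute_psi <- function(inc1, inc2 = NA_real_, skip, min_coverage = 10) {
  if (any(c(inc1, inc2, skip) < 0, na.rm = TRUE))
    stop("junction counts must be nonnegative")
  i_eff <- mean(c(inc1, inc2), na.rm = TRUE)
  if (i_eff + skip < min_coverage) return(NA_real_)
  i_eff / (i_eff + skip)
}

#' Differential exon inclusion between two groups
#'
#' Pools inclusion and skipping counts within each group into a 2x2 table
#' and applies the two-sided Fisher exact test (probability-mass rule: the
#' p-value sums all tables with probability not exceeding the observed
#' one). `delta_psi` is the pooled psi of group A minus group B.
#'
#' @param a,b Data frames with columns `inc1`, `inc2` (optional/NA), `skip`;
#'   one row per sample.
#' @param min_coverage Passed to [compute_psi()] for the pooled psi.
#' @return A one-row data.frame: `psi_a`, `psi_b`, `delta_psi`, `p_value`,
#'   `flagged` (TRUE when a table margin is empty, in which case p = 1).
#' @export
diff_splicing <- function(a, b, min_coverage = 10) {
  pool <- function(d) {
    i_eff <- mean(c(sum(d$inc1, na.rm = TRUE),
                    if (!all(is.na(d$inc2))) sum(d$inc2, na.rm = TRUE)),
                  na.rm = TRUE)
    c(inc = i_eff, skip = sum(d$skip, na.rm = TRUE))
  }
  pa <- pool(a); pb <- pool(b)
  psi_a <- compute_psi(pa["inc"], skip = pa["skip"],
                       min_coverage = min_coverage)
  psi_b <- compute_psi(pb["inc"], skip = pb["skip"],
                       min_coverage = min_coverage)
  tab <- round(matrix(c(pa["inc"], pa["skip"], pb["inc"], pb["skip"]), 2))
  flagged <- any(rowSums(tab) == 0) || any(colSums(tab) == 0)
  p <- if (flagged) 1 else stats::fisher.test(tab)$p.value
  data.frame(psi_a = unname(psi_a), psi_b = unname(psi_b),
             delta_psi = unname(psi_a - psi_b), p_value = p,
             flagged = flagged)
}

#' Differential splicing across a count table
#'
#' Applies [diff_splicing()] per exon and adjusts p-values across exons with
#' Benjamini-Hochberg.
#'
#' @param counts Data frame with columns `exon_id`, `sample_id`, `group`,
#'   `inc1`, `inc2`, `skip` (the on-disk TSV layout; `inc2` may be NA).
#' @param groups Length-2 character vector naming groups A and B.
#' @return A data.frame with one row per exon: psi per group, `delta_psi`,
#'   `p_value`, `fdr`.
#' @export
diff_splicing_table <- function(counts, groups) {
  stopifnot(length(groups) == 2,
            all(c("exon_id", "group", "inc1", "skip") %in% names(counts)))
  if (!"inc2" %in% names(counts)) counts$inc2 <- NA_real_
  res <- do.call(rbind, lapply(split(counts, counts$exon_id), function(d) {
    r <- diff_splicing(d[d$group == groups[1], ], d[d$group == groups[2], ])
    cbind(data.frame(exon_id = d$exon_id[1]), r)
  }))
  res$fdr <- bh_fdr(res$p_value)
  rownames(res) <- NULL
  res
}

#' Psi from RT-PCR band intensities
#'
#' Ratio of the inclusion band to the total. With `molar_correct`, the band
#' intensities are first divided by their amplicon lengths so that molarity,
#' not mass, is compared (longer amplicons incorporate more stain per
#' molecule).
#'
#' @param inclusion_band,skipping_band Band intensities (>= 0, not both 0).
#' @param lengths_bp Length-2 vector of amplicon lengths (inclusion,
#'   skipping), required when `molar_correct = TRUE`.
#' @param molar_correct Apply amplicon-length correction (default FALSE).
#' @return Psi in `[0, 1]`.
#' @export
rtpcr_psi <- function(inclusion_band, skipping_band, lengths_bp = NULL,
                      molar_correct = FALSE) {
  stopifnot(inclusion_band >= 0, skipping_band >= 0)
  if (inclusion_band == 0 && skipping_band == 0)
    stop("both band intensities are zero; psi undefined")
  if (molar_correct) {
    stopifnot(length(lengths_bp) == 2, all(lengths_bp > 0))
    inclusion_band <- inclusion_band / lengths_bp[1]
    skipping_band <- skipping_band / lengths_bp[2]
  }
  inclusion_band / (inclusion_band + skipping_band)
}

#' Peptide length encoded by an in-frame cassette exon
#'
#' A microexon of `n` nucleotides with `n` divisible by 3 inserts `n/3`
#' amino acids without shifting the reading frame (e.g. a 27-nt microexon
#' encodes 9 residues; its 33-nt paralog encodes 11).
#'
#' @param n_nt Exon length in nucleotides; must be a multiple of 3.
#' @return Number of encoded residues.
#' @export
exon_peptide_length <- function(n_nt) {
  stopifnot(n_nt > 0)
  if (n_nt %% 3 != 0)
    stop("exon length ", n_nt, " nt is not a multiple of 3; ",
         "inclusion would shift the reading frame")
  n_nt / 3
}

#' Read a junction-count TSV
#'
#' Expected columns: `exon_id`, `sample_id`, `group`, `inc1`, `inc2`,
#' `skip`; `inc2` may be `NA`.
#'
#' @param path TSV path.
#' @return A data.frame.
#' @export
read_junction_counts <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}
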