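#' Y-maze spontaneous alternation
#'
#' A spontaneous alternation is a triad: three consecutive arm entries into
#' three distinct arms. Triads are counted over every sliding window of
#' three entries (overlapping), consistent with the denominator:
#' `alternation% = alternations / (entries - 2) * 100`. The entry sequence
#' is taken verbatim; immediate same-arm re-entries count as entries.
#'
#' @param entries Character vector (or single string) of arm labels, e.g.
#'   `c("A","B","C")` or `"ABCABC"`.
#' @return Alternation percentage, or `NA` with a warning for fewer than 3
#'   entries.
#' @export
alternation_percent <- function(entries) {
  if (length(entries) == 1 && nchar(entries[1]) > 1)
    entries <- strsplit(entries, "")[[1]]
  n <- length(entries)
  if (n < 3) {
    warning("fewer than 3 arm entries; alternation undefined")
    return(NA_real_)
  }
  triads <- vapply(seq_len(n - 2), function(i)
    length(unique(entries[i:(i + 2)])) == 3, logical(1))
  sum(triads) / (n - 2) * 100
}

#' Theoretical chance alternation level
#'
#' Under a memoryless walker that never re-enters the arm it occupies and
#' picks uniformly among the remaining arms, the probability that a triad
#' visits three distinct arms is `((n-1)/n) * ((n-2)/n)` when next-arm
#' choices are uniform over all n arms except under the distinctness
#' requirement; for the standard three-arm maze this is
#' `1 * 2/3 * 1/3 ~ 22%`.
#'
#' @param n_arms Number of maze arms (>= 3; default 3).
#' @return Chance alternation percentage.
#' @export
chance_alternation <- function(n_arms = 3) {
  if (n_arms < 3) stop("need at least 3 arms")
  100 * ((n_arms - 1) / n_arms) * ((n_arms - 2) / n_arms)
}

#' Elevated-plus-maze time percentages
#'
#' Percent of the trial spent in the open and closed arms; the remainder is
#' time in the center.
#'
#' @param open_s,closed_s Dwell times in seconds.
#' @param trial_s Trial duration (default 300 s).
#' @return A list `open_pct`, `closed_pct`, `center_pct`.
#' @export
epm_percentages <- function(open_s, closed_s, trial_s = 300) {
  stopifnot(open_s >= 0, closed_s >= 0, trial_s > 0)
  if (open_s + closed_s > trial_s)
    stop("arm times exceed the trial duration")
  list(open_pct = open_s / trial_s * 100,
       closed_pct = closed_s / trial_s * 100,
       center_pct = (trial_s - open_s - closed_s) / trial_s * 100)
}

#' Gait metrics from labeled footfall distances
#'
#' Paw labels follow the scheme A = left forepaw, B = left hindpaw,
#' C = right forepaw, D = right hindpaw, fixed so that AB and CD are
#' same-side fore-hind pairs and AC and BD span the body. The metrics are
#' literal combinations of the lettered distances, so an alternative
#' mapping only changes their interpretation, not the arithmetic:
#' * forepaw-hindpaw distance = mean(AB, CD);
#' * step length = mean(AA, BB, CC, DD), the consecutive same-paw stride
#'   distances;
#' * stance width = mean(AC, BD);
#' * alternation coefficient = AB / BD (a distance ratio; dimensionless).
#'
#' @param distances Named list or vector with elements `AB`, `CD`, `AC`,
#'   `BD`, `AA`, `BB`, `CC`, `DD` (cm).
#' @return A list `fp_hp_distance`, `step_length`, `stance_width`,
#'   `alternation_coefficient` (the last is `NA` when BD = 0).
#' @export
gait_metrics <- function(distances) {
  d <- as.list(distances)
  need <- c("AB", "CD", "AC", "BD", "AA", "BB", "CC", "DD")
  if (!all(need %in% names(d)))
    stop("missing distances: ", paste(setdiff(need, names(d)), collapse = ", "))
  num <- vapply(d[need], as.numeric, numeric(1))
  if (any(!is.finite(num))) stop("all distances must be finite")
  list(
    fp_hp_distance = mean(num[c("AB", "CD")]),
    step_length = mean(num[c("AA", "BB", "CC", "DD")]),
    stance_width = mean(num[c("AC", "BD")]),
    alternation_coefficient =
      if (num["BD"] == 0) NA_real_ else unname(num["AB"] / num["BD"]))
}

#' Pairwise footfall distances from a coordinate table
#'
#' Computes the mean pairwise distances consumed by [gait_metrics()] from a
#' footfall table. Cross-paw distances (AB, CD, AC, BD) pair placements by
#' step cycle; same-paw distances (AA, ...) are consecutive-placement stride
#' lengths.
#'
#' @param footfalls Data frame with columns `step_index`, `paw_label`
#'   (A/B/C/D), `x_cm`, `y_cm`.
#' @return Named numeric vector of mean distances.
#' @export
footfall_distances <- function(footfalls) {
  stopifnot(all(c("step_index", "paw_label", "x_cm", "y_cm") %in%
                  names(footfalls)))
  get_paw <- function(p) {
    d <- footfalls[footfalls$paw_label == p, ]
    d[order(d$step_index), c("x_cm", "y_cm")]
  }
  paws <- lapply(stats::setNames(nm = c("A", "B", "C", "D")), get_paw)
  cross <- function(p, q) {
    k <- min(nrow(paws[[p]]), nrow(paws[[q]]))
    if (k == 0) return(NA_real_)
    mean(sqrt(rowSums((paws[[p]][1:k, ] - paws[[q]][1:k, ])^2)))
  }
  stride <- function(p) {
    m <- as.matrix(paws[[p]])
    if (nrow(m) < 2) return(NA_real_)
    mean(sqrt(rowSums((m[-1, , drop = FALSE] -
                         m[-nrow(m), , drop = FALSE])^2)))
  }
  c(AB = cross("A", "B"), CD = cross("C", "D"),
    AC = cross("A", "C"), BD = cross("B", "D"),
    AA = stride("A"), BB = stride("B"), CC = stride("C"), DD = stride("D"))
}
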