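#' Mann-Whitney U test
#'
#' U is computed from rank sums with midranks for ties. The two-sided
#' p-value is exact (from the null permutation distribution of U) when the
#' combined sample size is at most `exact_max_n` and there are no ties;
#' otherwise a normal approximation with tie correction and continuity
#' correction is used. The exact/approximate switch at a combined n of 16
#' keeps enumeration cheap while covering typical per-group cell counts.
#'
#' @param a,b Numeric samples (each nonempty).
#' @param exact_max_n Combined-n cutoff for the exact p-value (default 16).
#' @param metric Optional metric name carried into the result.
#' @return A list of class `group_comparison`: `metric`, `test`,
#'   `statistic` (U for sample `a`), `p_value`, `n_a`, `n_b`, `exact`.
#' @export
mann_whitney_u <- function(a, b, exact_max_n = 16, metric = NA_character_) {
  if (length(a) == 0 || length(b) == 0) stop("both samples must be nonempty")
  m <- length(a); n <- length(b)
  r <- rank(c(a, b))
  U <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  ties <- any(duplicated(c(a, b)))
  exact <- (m + n) <= exact_max_n && !ties
  if (exact) {
    mu <- m * n / 2
    p <- if (U > mu) {
      2 * stats::pwilcox(U - 1, m, n, lower.tail = FALSE)
    } else if (U < mu) {
      2 * stats::pwilcox(U, m, n)
    } else 1
    p <- min(1, p)
  } else {
    N <- m + n
    tab <- table(r)
    tie_term <- sum(tab^3 - tab) / (N * (N - 1))
    sigma <- sqrt(m * n / 12 * ((N + 1) - tie_term))
    mu <- m * n / 2
    z <- U - mu
    z <- sign(z) * max(0, abs(z) - 0.5)  # continuity correction
    p <- if (sigma == 0) 1 else 2 * stats::pnorm(-abs(z) / sigma)
    p <- min(1, p)
  }
  structure(list(metric = metric, test = "mann_whitney_u", statistic = U,
                 p_value = p, n_a = m, n_b = n, exact = exact),
            class = "group_comparison")
}

#' Mixed two-way ANOVA for input-output curves
#'
#' Repeated-measures two-way ANOVA with one between-subject factor (group)
#' and one within-subject factor (current step). Cells with missing steps
#' are dropped listwise so the within-factor levels are balanced. The
#' between-subject main effect is tested against the between-cell stratum,
#' giving F on (1, n_a + n_b - 2) degrees of freedom; sphericity is assumed
#' (no Greenhouse-Geisser correction), matching the uncorrected
#' degrees-of-freedom convention in slice-physiology reports. The
#' group-by-step interaction F from the within stratum is reported as well.
#'
#' @param data Data frame with columns `cell_id`, `group`, `step`, `value`
#'   (e.g. AP counts per current step per cell).
#' @return A list of class `mixed_anova`: `f_between`, `df_between`,
#'   `p_between`, `f_interaction`, `p_interaction`, `n_cells`.
#' @export
mixed_two_way_anova <- function(data) {
  stopifnot(all(c("cell_id", "group", "step", "value") %in% names(data)))
  data$cell_id <- factor(data$cell_id)
  data$group <- factor(data$group)
  data$step <- factor(data$step)
  if (nlevels(data$group) != 2) stop("exactly two groups required")
  # listwise drop of cells missing any step
  full <- table(data$cell_id)
  keep <- names(full)[full == nlevels(data$step)]
  data <- data[data$cell_id %in% keep, ]
  data$cell_id <- droplevels(data$cell_id)
  ncell <- tapply(data$cell_id, data$group,
                  function(x) length(unique(x)))
  if (any(is.na(ncell)) || any(ncell < 2))
    stop("each group needs at least 2 complete cells")
  fit <- stats::aov(value ~ group * step + Error(cell_id), data = data)
  s <- summary(fit)
  btw <- s[["Error: cell_id"]][[1]]
  wtn <- s[["Error: Within"]][[1]]
  rn_b <- trimws(rownames(btw)); rn_w <- trimws(rownames(wtn))
  ig <- match("group", rn_b); ii <- match("group:step", rn_w)
  f_b <- btw[ig, "F value"]; p_b <- btw[ig, "Pr(>F)"]
  # zero between-group variance: aov reports NaN; the partition gives F = 0
  if (is.nan(f_b) || (is.finite(btw[ig, "Sum Sq"]) &&
                      btw[ig, "Sum Sq"] < 1e-12)) {
    f_b <- 0; p_b <- 1
  }
  f_i <- wtn[ii, "F value"]; p_i <- wtn[ii, "Pr(>F)"]
  if (is.nan(f_i)) { f_i <- 0; p_i <- 1 }
  structure(list(
    f_between = f_b,
    df_between = c(btw[ig, "Df"], btw[match("Residuals", rn_b), "Df"]),
    p_between = p_b,
    f_interaction = f_i, p_interaction = p_i,
    n_cells = sum(ncell)), class = "mixed_anova")
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up BH with monotonicity enforcement, order-preserving with respect
#' to the input.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted values, same order as the input.
#' @export
bh_fdr <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Descriptive summary: mean, SEM, n
#'
#' SEM uses the n-1 denominator s.d.; it is undefined (`NA`) for n = 1.
#'
#' @param values Nonempty numeric vector.
#' @return A list `mean`, `sem`, `n`.
#' @export
describe_values <- function(values) {
  if (length(values) == 0) stop("empty sample")
  n <- length(values)
  list(mean = mean(values),
       sem = if (n > 1) stats::sd(values) / sqrt(n) else NA_real_,
       n = n)
}
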