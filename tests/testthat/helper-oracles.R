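# Independent oracles and fixture builders shared across the test files.
# Each oracle is a direct, unoptimized transcription of the defining formula,
# kept separate from the implementation paths it checks.

# brute-force F0: minimum over ALL contiguous w-frame window means
oracle_f0 <- function(F, w) {
  min(vapply(seq_len(length(F) - w + 1),
             function(i) mean(F[i:(i + w - 1)]), numeric(1)))
}

# loop transcription of the trapezoid rule
oracle_trapz <- function(x, y) {
  s <- 0
  for (i in seq_len(length(x) - 1))
    s <- s + (x[i + 1] - x[i]) * (y[i] + y[i + 1]) / 2
  s
}

# exact two-sided Mann-Whitney p by enumerating every labeling of the
# combined sample (tie-free data only)
oracle_mw_p <- function(a, b) {
  m <- length(a); n <- length(b)
  pooled <- c(a, b)
  u_of <- function(idx) {
    r <- rank(pooled)
    sum(r[idx]) - m * (m + 1) / 2
  }
  u_obs <- u_of(seq_len(m))
  all_u <- apply(utils::combn(m + n, m), 2, u_of)
  mu <- m * n / 2
  p <- if (u_obs > mu) 2 * mean(all_u >= u_obs)
  else if (u_obs < mu) 2 * mean(all_u <= u_obs)
  else 1
  min(1, p)
}

# two-sided Fisher exact p by hypergeometric enumeration
# (probability-mass rule; tiny relative tolerance for float equality)
oracle_fisher_p <- function(tab) {
  r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); n <- sum(tab)
  ks <- max(0, r1 + c1 - n):min(r1, c1)
  probs <- stats::dhyper(ks, c1, n - c1, r1)
  p_obs <- stats::dhyper(tab[1, 1], c1, n - c1, r1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# direct step-up BH formula
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  sorted <- p[o]
  for (i in seq_len(m))
    adj[i] <- min(1, min(m * sorted[i:m] / (i:m)))
  out <- numeric(m)
  out[o] <- adj
  out
}

# hand partition of sums of squares for the mixed two-way design
# (between: group over cells-within-group; within: step, group:step, error)
oracle_mixed_anova <- function(data) {
  data$cell_id <- as.character(data$cell_id)
  g <- mean(data$value)
  ns <- length(unique(data$step))
  cells <- unique(data[, c("cell_id", "group")])
  m_cell <- tapply(data$value, data$cell_id, mean)
  m_group <- tapply(data$value, data$group, mean)
  n_g <- table(cells$group)
  ss_group <- ns * sum(n_g * (m_group[names(n_g)] - g)^2)
  ss_subj <- ns * sum((m_cell[cells$cell_id] -
                         m_group[as.character(cells$group)])^2)
  df_subj <- nrow(cells) - length(n_g)
  f <- (ss_group / (length(n_g) - 1)) / (ss_subj / df_subj)
  list(f_between = f,
       p_between = stats::pf(f, length(n_g) - 1, df_subj,
                             lower.tail = FALSE))
}

# constant-voltage sweep fixture
make_flat_sweep <- function(v = -65, khz = 10, onset = 100, dur = 500,
                            post = 100, amp = 0) {
  n <- round((onset + dur + post) * khz) + 1
  t <- (seq_len(n) - 1) / khz
  current_clamp_sweep(t, rep(v, n), khz, amp, onset, dur)
}

# passive RC response rendered from its closed form
make_rc_sweep <- function(rmp = -70, r_mohm = 150, tau = 12, amp = -30,
                          khz = 10, onset = 100, dur = 500, post = 100,
                          noise = 0) {
  n <- round((onset + dur + post) * khz) + 1
  t <- (seq_len(n) - 1) / khz
  dv <- r_mohm * amp / 1000
  v <- rep(rmp, n)
  instep <- t >= onset & t < onset + dur
  v[instep] <- rmp + dv * (1 - exp(-(t[instep] - onset) / tau))
  after <- t >= onset + dur
  v_end <- rmp + dv * (1 - exp(-dur / tau))
  v[after] <- rmp + (v_end - rmp) * exp(-(t[after] - onset - dur) / tau)
  if (noise > 0) v <- v + rnorm(n, 0, noise)
  current_clamp_sweep(t, v, khz, amp, onset, dur)
}

# a single smooth spike bump (Gaussian) riding on a flat baseline
make_bump_sweep <- function(base = -65, peak = 0, t_peak = 300,
                            width_ms = 1, khz = 10) {
  n <- round(700 * khz) + 1
  t <- (seq_len(n) - 1) / khz
  v <- base + (peak - base) * exp(-(t - t_peak)^2 / (2 * width_ms^2))
  current_clamp_sweep(t, v, khz, 100, 100, 500)
}

# constant-dff fluorescence fixture at a given frame rate
make_const_trace <- function(F = 50, n = 100, rate = 1.7) {
  fluor_trace((seq_len(n) - 1) / rate, rep(F, n))
}
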