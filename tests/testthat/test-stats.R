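test_that("Mann-Whitney: extreme separation gives U = 0 and exact p = 0.1", {
  r <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 0.1)
  expect_true(r$exact)
})

test_that("complete ties force U to the midpoint n_a*n_b/2", {
  r <- mann_whitney_u(rep(1, 4), rep(1, 5))
  expect_equal(r$statistic, 10)
  expect_equal(r$p_value, 1)
  expect_false(r$exact)
})

test_that("exact p matches full enumeration on random tie-free samples", {
  set.seed(5)
  for (i in 1:10) {
    m <- sample(3:5, 1); n <- sample(3:5, 1)
    a <- sample(1:100, m); b <- sample(setdiff(1:100, a), n)
    r <- mann_whitney_u(a, b)
    expect_equal(r$p_value, oracle_mw_p(a, b), tolerance = 1e-12)
  }
})

test_that("the normal approximation agrees with the reference implementation", {
  set.seed(6)
  for (i in 1:10) {
    a <- rnorm(30); b <- rnorm(30, 0.3)
    r <- mann_whitney_u(a, b)
    ref <- stats::wilcox.test(a, b, exact = FALSE, correct = TRUE)
    expect_equal(r$p_value, ref$p.value, tolerance = 1e-6)
    expect_equal(r$statistic, unname(ref$statistic))
  }
  # with heavy ties the tie-corrected variance is used
  a <- c(1, 1, 2, 2, 3, 3, 4, 4, 5, 5)
  b <- c(2, 2, 3, 3, 4, 4, 5, 5, 6, 6)
  expect_equal(mann_whitney_u(a, b)$p_value,
               stats::wilcox.test(a, b, exact = FALSE, correct = TRUE)$p.value,
               tolerance = 1e-6)
})

test_that("U(a,b) + U(b,a) = n_a * n_b", {
  set.seed(8)
  for (i in 1:10) {
    a <- rnorm(sample(2:12, 1)); b <- rnorm(sample(2:12, 1))
    expect_equal(mann_whitney_u(a, b)$statistic +
                   mann_whitney_u(b, a)$statistic,
                 length(a) * length(b))
  }
  expect_error(mann_whitney_u(numeric(0), 1:3), "nonempty")
})

test_that("mixed ANOVA: identical group profiles give F = 0, p = 1", {
  steps <- seq(0, 400, 20)
  profile1 <- 0:20; profile2 <- seq(0, 40, 2)
  d <- rbind(
    data.frame(cell_id = "a1", group = "A", step = steps, value = profile1),
    data.frame(cell_id = "a2", group = "A", step = steps, value = profile2),
    data.frame(cell_id = "b1", group = "B", step = steps, value = profile1),
    data.frame(cell_id = "b2", group = "B", step = steps, value = profile2))
  r <- mixed_two_way_anova(d)
  expect_equal(r$f_between, 0)
  expect_equal(r$p_between, 1)
})

test_that("mixed ANOVA matches the hand-computed partition of sums of squares", {
  set.seed(11)
  steps <- seq(0, 400, 20)
  d <- do.call(rbind, lapply(1:12, function(i) {
    g <- if (i <= 6) "A" else "B"
    data.frame(cell_id = paste0("c", i), group = g, step = steps,
               value = round(steps / 40 + rnorm(length(steps), 0, 2) +
                               (g == "B") * 3))
  }))
  r <- mixed_two_way_anova(d)
  o <- oracle_mixed_anova(d)
  expect_equal(r$f_between, o$f_between, tolerance = 1e-8)
  expect_equal(r$p_between, o$p_between, tolerance = 1e-8)
  expect_equal(r$df_between, c(1, 10))
})

test_that("mixed ANOVA between-group p-values are uniform under the null", {
  set.seed(13)
  steps <- seq(0, 400, 40)
  ps <- replicate(1000, {
    d <- do.call(rbind, lapply(1:12, function(i)
      data.frame(cell_id = paste0("c", i),
                 group = if (i <= 6) "A" else "B", step = steps,
                 value = steps / 30 + rnorm(1, 0, 2) +
                   rnorm(length(steps), 0, 3))))
    mixed_two_way_anova(d)$p_between
  })
  ks_stat <- stats::ks.test(ps, "punif")$statistic
  expect_lt(unname(ks_stat), 0.05)
})

test_that("mixed ANOVA rejects under-replicated groups", {
  d <- data.frame(cell_id = rep(c("a1", "b1"), each = 3),
                  group = rep(c("A", "B"), each = 3),
                  step = rep(1:3, 2), value = rnorm(6))
  expect_error(mixed_two_way_anova(d), "at least 2")
})

test_that("BH adjustment follows the step-up formula", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.3), 0.3)
  set.seed(14)
  for (i in 1:10) {
    p <- runif(sample(2:50, 1))
    expect_equal(bh_fdr(p), oracle_bh(p), tolerance = 1e-12)
  }
  expect_error(bh_fdr(c(0.1, 1.2)), "0, 1")
})

test_that("BH is permutation-equivariant and monotone in sorted order", {
  set.seed(15)
  p <- runif(20)
  perm <- sample(20)
  expect_equal(bh_fdr(p)[perm], bh_fdr(p[perm]))
  adj <- bh_fdr(p)
  expect_true(all(diff(adj[order(p)]) >= -1e-12))
})

test_that("describe gives mean, n-1 SEM, and flags n = 1", {
  r <- describe_values(c(2, 4, 6))
  expect_equal(r$mean, 4)
  expect_equal(r$sem, 2 / sqrt(3))
  expect_equal(describe_values(rep(5, 4))$sem, 0)
  expect_true(is.na(describe_values(3)$sem))
  expect_error(describe_values(numeric(0)), "empty")
})
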