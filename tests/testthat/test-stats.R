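test_that("pooled t reproduces the worked serum-marker comparison", {
  res <- pooled_t_test(group_summary(86.38, 18.94, 8),
                       group_summary(82.86, 10.03, 7))
  expect_equal(unname(res$statistic), 0.440, tolerance = 0.0015)
  expect_equal(unname(res$parameter), 13)
  expect_equal(res$conf.int[1], -13.79, tolerance = 1e-3)
  expect_equal(res$conf.int[2], 20.83, tolerance = 1e-3)
  expect_equal(res$p.value, 0.67, tolerance = 0.005)
})

test_that("pooled t: antisymmetry, degenerate variance, equal groups", {
  a <- group_summary(5, 2, 10); b <- group_summary(3, 1, 8)
  ab <- pooled_t_test(a, b); ba <- pooled_t_test(b, a)
  expect_equal(unname(ab$statistic), -unname(ba$statistic), tolerance = 1e-12)
  expect_equal(ab$conf.int[1], -ba$conf.int[2], tolerance = 1e-12)
  eq <- pooled_t_test(a, a)
  expect_equal(unname(eq$statistic), 0)
  expect_equal(sum(eq$conf.int), 0, tolerance = 1e-12)
  z <- group_summary(1, 0, 5)
  expect_equal(unname(pooled_t_test(z, z)$statistic), 0)
  expect_error(pooled_t_test(z, group_summary(2, 0, 5)), "zero pooled")
})

test_that("pooled t from summaries agrees with t.test on reconstructed data", {
  for (i in 1:100) {
    m1 <- runif(1, -5, 5); s1 <- runif(1, 0.5, 3); n1 <- sample(3:20, 1)
    m2 <- runif(1, -5, 5); s2 <- runif(1, 0.5, 3); n2 <- sample(3:20, 1)
    x <- raw_with_moments(n1, m1, s1, seed = i)
    y <- raw_with_moments(n2, m2, s2, seed = i + 1000)
    ours <- pooled_t_test(group_summary(m1, s1, n1), group_summary(m2, s2, n2))
    ref <- stats::t.test(x, y, var.equal = TRUE)
    expect_equal(unname(ours$statistic), unname(ref$statistic),
                 tolerance = 1e-10)
    expect_equal(as.numeric(ours$conf.int), as.numeric(ref$conf.int),
                 tolerance = 1e-8)
  }
})

test_that("Mann-Whitney U: separation, symmetry, and pair-count oracle", {
  expect_equal(unname(mann_whitney_u(1:3, 4:6)$statistic), 0)
  x <- c(2, 2, 5, 7)
  expect_equal(unname(mann_whitney_u(x, x)$estimate), length(x)^2 / 2)
  set.seed(3)
  for (i in 1:200) {
    x <- sample(0:8, sample(3:9, 1), replace = TRUE)
    y <- sample(0:8, sample(3:9, 1), replace = TRUE)
    res <- mann_whitney_u(x, y)
    ux <- sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
    expect_equal(unname(res$estimate), ux, tolerance = 1e-9)
    expect_equal(unname(res$statistic),
                 min(ux, length(x) * length(y) - ux), tolerance = 1e-9)
    # reported statistic invariant to swapping groups
    expect_equal(unname(mann_whitney_u(y, x)$statistic),
                 unname(res$statistic), tolerance = 1e-9)
    # orientation statistic matches the standard rank-sum implementation
    expect_equal(unname(res$estimate),
                 unname(suppressWarnings(stats::wilcox.test(x, y)$statistic)),
                 tolerance = 1e-9)
  }
})

test_that("Mann-Whitney exact p matches the reference on tie-free samples", {
  set.seed(9)
  for (i in 1:20) {
    x <- rnorm(5); y <- rnorm(6)
    expect_equal(mann_whitney_u(x, y)$p.value,
                 stats::wilcox.test(x, y, exact = TRUE)$p.value,
                 tolerance = 1e-10)
  }
  # large samples switch to the normal approximation and stay in [0, 1]
  set.seed(10)
  p <- mann_whitney_u(rnorm(20), rnorm(25))$p.value
  expect_gte(p, 0); expect_lte(p, 1)
})

test_that("kappa: perfect agreement, independence, invariances", {
  r <- c(0, 1, 2, 1, 0, 2, 2, 1)
  expect_equal(cohens_kappa(r, r), 1)
  set.seed(7)
  k0 <- cohens_kappa(sample(1:4, 10000, TRUE), sample(1:4, 10000, TRUE))
  expect_lt(abs(k0), 0.03)
  # relabeling categories leaves kappa unchanged
  r1 <- c(0, 1, 2, 2, 1, 0, 1); r2 <- c(0, 1, 1, 2, 1, 0, 2)
  relab <- function(v) c(10, 30, 20)[v + 1]
  expect_equal(cohens_kappa(relab(r1), relab(r2)), cohens_kappa(r1, r2),
               tolerance = 1e-12)
  # kappa <= observed agreement
  expect_lte(cohens_kappa(r1, r2), mean(r1 == r2))
  expect_error(cohens_kappa(rep(1, 5), rep(1, 5)), "undefined")
  expect_error(cohens_kappa(1:3, 1:4), "equal length")
})

test_that("KS normality: statistic oracle and calibration", {
  set.seed(11)
  x <- rnorm(50, 3, 2)
  res <- ks_normality(x, nsim = 200)
  # direct ECDF scan oracle
  z <- sort((x - mean(x)) / sd(x)); n <- length(z)
  D_oracle <- max(pmax(seq_len(n) / n - pnorm(z),
                       pnorm(z) - (seq_len(n) - 1) / n))
  expect_equal(unname(res$statistic), D_oracle, tolerance = 1e-12)
  expect_gte(unname(res$statistic), 0)
  expect_lte(unname(res$statistic), 1)
  # matches the established Lilliefors statistic
  expect_equal(unname(res$statistic),
               unname(nortest::lillie.test(x)$statistic), tolerance = 1e-12)
  # a genuinely normal sample is not rejected
  set.seed(12)
  big <- rnorm(1000)
  expect_gt(ks_normality(big, nsim = 400)$p.value, 0.05)
  expect_error(ks_normality(rep(1, 10)), "constant")
  expect_error(ks_normality(c(1, 2, 3)), "n >= 4")
})

test_that("Cohen's-d sample sizing matches the noncentral-t oracle", {
  # independent power evaluation: P(|T| > t_crit) under noncentrality
  pow <- function(n, d, alpha = 0.05) {
    df <- 2 * n - 2; ncp <- d * sqrt(n / 2)
    tc <- qt(1 - alpha / 2, df)
    pt(-tc, df, ncp) + 1 - pt(tc, df, ncp)
  }
  expect_equal(sample_size_cohens_d(1.2, 0.05, 0.8), 12)
  expect_equal(sample_size_cohens_d(0.5, 0.05, 0.8), 64)
  for (d in c(0.4, 0.8, 1.2)) {
    n <- sample_size_cohens_d(d)
    expect_gte(pow(n, d), 0.8 - 1e-6)
    expect_lt(pow(n - 1, d), 0.8)
  }
  # monotone: larger effects need no more animals
  ns <- sapply(c(0.3, 0.6, 0.9, 1.2, 1.5), sample_size_cohens_d)
  expect_true(all(diff(ns) <= 0))
})

test_that("radiographic scoring enforces ranges and sums to at most 8", {
  expect_equal(score_radiograph(3, 3, 2)$total, 8)
  expect_equal(score_radiograph(0, 0, 0)$total, 0)
  expect_equal(score_radiograph(2, 3, 1)$total, 6)
  v <- score_radiograph(c(1, 3), c(2, 3), c(0, 2))
  expect_equal(v$total, c(3, 8))
  expect_error(score_radiograph(4, 0, 0), "periosteal")
  expect_error(score_radiograph(0, 0, 3), "remodeling")
  expect_error(score_radiograph(1.5, 0, 0), "integer")
})
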