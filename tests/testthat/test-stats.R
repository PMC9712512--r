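# mixed models, exact Wilcoxon signed rank, Bonferroni

# brute-force exact signed-rank p by enumerating all 2^n sign patterns
wilcoxon_oracle <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  vs <- signs %*% r
  p_le <- mean(vs <= v + 1e-12)
  p_ge <- mean(vs >= v - 1e-12)
  min(1, 2 * min(p_le, p_ge))
}

test_that("all-positive n = 7 differences give the exact two-sided 2/2^7", {
  res <- wilcoxon_signed_rank(c(0.5, 1.2, 0.3, 2.2, 0.9, 1.7, 0.1))
  expect_true(res$exact)
  expect_equal(res$statistic, 28)
  expect_equal(res$p, 0.015625)           # 2 / 128 by full sign enumeration
})

test_that("symmetric difference sets give p = 1", {
  res <- wilcoxon_signed_rank(c(-1, 1, -2, 2, -3, 3))
  expect_equal(res$p, 1)
})

test_that("exact p matches the 2^n enumeration oracle, including ties and zeros", {
  set.seed(19)
  for (i in 1:20) {
    n <- sample(6:11, 1)
    d <- sample(c(-3, -2, -1, 1, 2, 3, 4), n, replace = TRUE)  # many ties
    if (sum(d != 0) < 5) next
    expect_equal(wilcoxon_signed_rank(d)$p, wilcoxon_oracle(d),
                 tolerance = 1e-12)
    dc <- rnorm(n)                                              # continuous
    expect_equal(wilcoxon_signed_rank(dc)$p, wilcoxon_oracle(dc),
                 tolerance = 1e-12)
  }
  # zeros are dropped before ranking
  withz <- c(0, 0, 1.5, -0.7, 2.1, 0.9, 1.1, -0.2)
  expect_equal(wilcoxon_signed_rank(withz)$n, 6)
  expect_equal(wilcoxon_signed_rank(withz)$p,
               wilcoxon_oracle(withz[withz != 0]), tolerance = 1e-12)
  # agrees with the reference implementation when no ties are present
  set.seed(23)
  d <- rnorm(12)
  expect_equal(wilcoxon_signed_rank(d)$p,
               wilcox.test(d, exact = TRUE)$p.value, tolerance = 1e-12)
  expect_error(wilcoxon_signed_rank(c(0, 0, 0, 0, 0, 1)), "at least 5")
})

test_that("exact test holds its nominal size under a symmetric null", {
  set.seed(71)
  reject <- 0L
  n_rep <- 2000
  for (i in seq_len(n_rep)) {
    if (wilcoxon_signed_rank(rnorm(7))$p <= 0.05) reject <- reject + 1L
  }
  # achievable size at n = 7 is 6/128 = 0.0469; allow binomial noise
  expect_gt(reject / n_rep, 0.03)
  expect_lt(reject / n_rep, 0.07)
})

test_that("segment-gradient model matches OLS when group variance is zero", {
  set.seed(44)
  seg <- expand.grid(patient = sprintf("P%d", 1:6), muscle = 1:8,
                     segment = 1:5)
  seg$ff <- 40 - 3 * seg$segment + rnorm(nrow(seg), 0, 4)
  fit <- fit_segment_gradient(seg)
  ols <- coef(lm(ff ~ segment, data = seg))[["segment"]]
  expect_true(fit$converged)
  b1 <- fit$fixed$estimate[fit$fixed$term == "segment"]
  expect_lt(abs(b1 - ols), 1e-3)
  expect_equal(fit$n_groups, 6)
  # constant response: slope exactly zero
  seg$ff <- 25
  fit0 <- fit_segment_gradient(seg)
  expect_equal(fit0$fixed$estimate[fit0$fixed$term == "segment"], 0,
               tolerance = 1e-10)
})

test_that("segment-gradient estimates agree with an independent mixed-model backend", {
  skip_if_not_installed("lme4")
  set.seed(55)
  seg <- expand.grid(patient = sprintf("P%d", 1:9), muscle = 1:10,
                     segment = 1:5)
  u <- rnorm(9, 0, 8)
  seg$ff <- pmax(0, 30 + u[as.integer(factor(seg$patient))] -
                   3.4 * seg$segment + rnorm(nrow(seg), 0, 10))
  fit <- fit_segment_gradient(seg)
  ref <- lme4::lmer(ff ~ segment + (1 | patient), data = seg, REML = TRUE)
  b1 <- fit$fixed$estimate[fit$fixed$term == "segment"]
  expect_equal(b1, unname(lme4::fixef(ref)[["segment"]]), tolerance = 1e-5)
})

test_that("bin contrasts use the 0-10 reference and Bonferroni m = 8", {
  set.seed(66)
  bins <- levels(baseline_bin(5))
  d <- data.frame(
    patient = rep(sprintf("P%d", 1:9), times = 40),
    baseline_bin = factor(sample(bins, 360, replace = TRUE), levels = bins),
    change_per_year = rnorm(360, 1, 0.8))
  out <- fit_bin_contrasts(d)
  expect_setequal(out$bin, setdiff(bins, "0-10"))
  expect_equal(out$p_adj, pmin(1, 8 * out$p_raw))
  # identical distributions: no contrast should stand out
  expect_true(all(abs(out$estimate) < 4 * out$se))
  # capping
  expect_true(all(out$p_adj <= 1))
  d0 <- d[d$baseline_bin != "0-10", ]
  expect_error(fit_bin_contrasts(d0), "reference bin")
})

test_that("Bonferroni adjustment is monotone and capped", {
  p <- c(0.001, 0.2, 0.04, 0.9)
  adj <- bonferroni(p, m = 8)
  expect_equal(adj, pmin(1, 8 * p))
  expect_equal(adj, p.adjust(p, method = "bonferroni", n = 8))
  expect_false(is.unsorted(adj[order(p)]))
  expect_equal(bonferroni(0.2, m = 8), 1)
})
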