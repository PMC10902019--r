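test_that("paired_t matches hand arithmetic and flags degenerate input", {
  s <- paired_sample(c(2, 2, 4, 5), c(1, 2, 3, 4))
  tt <- paired_t(s)
  expect_equal(tt$t, 3.0, tolerance = 1e-12)
  expect_equal(tt$df, 3)
  expect_equal(tt$p, 2 * stats::pt(-3, 3), tolerance = 1e-12)
  expect_equal(tt$p, 0.0577, tolerance = 1e-3)
  # independent route: base stats oracle
  expect_equal(tt$p, stats::t.test(c(2, 2, 4, 5), c(1, 2, 3, 4),
                                   paired = TRUE)$p.value, tolerance = 1e-12)
  # symmetric differences: t = 0, p = 1
  a <- c(10, 20, 30, 40); b <- a - c(1, -1, 1, -1)
  tt0 <- paired_t(paired_sample(a, b))
  expect_equal(tt0$t, 0)
  expect_equal(tt0$p, 1)
  expect_error(paired_t(paired_sample(a, a - 1)), "zero variance")
  expect_error(paired_sample(1:2, 2:3), "n >= 3")
})

test_that("pearson_corr matches hand covariance and base oracle", {
  a <- c(1, 2, 3, 4); b <- c(1, 3, 2, 5)
  pc <- pearson_corr(paired_sample(a, b))
  # hand computation: r = S_ab / sqrt(S_aa S_bb)
  r_hand <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  expect_equal(pc$r, r_hand, tolerance = 1e-12)
  expect_equal(pc$r, 0.8315218, tolerance = 1e-6)
  ct <- stats::cor.test(a, b)
  expect_equal(pc$p, ct$p.value, tolerance = 1e-12)
  # exact affine relations
  expect_equal(pearson_corr(paired_sample(2 * a + 1, a))$r, 1)
  expect_equal(pearson_corr(paired_sample(-a, a))$r, -1)
  expect_equal(pearson_corr(paired_sample(2 * a + 1, a))$p, 0)
  expect_error(pearson_corr(paired_sample(c(1, 1, 1), 1:3)), "constant")
})

test_that("pearson_corr is invariant to positive affine transforms", {
  set.seed(8)
  a <- rnorm(10); b <- rnorm(10)
  r0 <- pearson_corr(paired_sample(a, b))$r
  expect_equal(pearson_corr(paired_sample(3.2 * a + 5, b))$r, r0, tolerance = 1e-12)
  expect_equal(pearson_corr(paired_sample(a, 0.4 * b - 2))$r, r0, tolerance = 1e-12)
})

test_that("bland_altman reproduces the hand-computed example", {
  ba0 <- bland_altman(paired_sample(c(5, 7, 9), c(5, 7, 9)))
  expect_equal(ba0$bias, 0)
  expect_equal(ba0$loa_high - ba0$loa_low, 0)
  expect_equal(ba0$proportional_bias_slope, 0)
  ba <- bland_altman(paired_sample(c(12, 18, 22, 28), c(10, 20, 20, 30)))
  expect_equal(ba$bias, 0)
  expect_equal(ba$sd_diff, sqrt(16 / 3), tolerance = 1e-12)
  expect_equal(ba$sd_diff, 2.309, tolerance = 1e-3)
  expect_equal(ba$loa_high, 1.96 * sqrt(16 / 3), tolerance = 1e-12)
  expect_equal(ba$loa_low, -ba$loa_high, tolerance = 1e-12)
  # a = 1.5 b: differences grow with magnitude -> positive proportional bias
  b <- c(10, 20, 30, 40)
  ba2 <- bland_altman(paired_sample(1.5 * b, b))
  expect_gt(ba2$proportional_bias_slope, 0)
  expect_lt(ba2$proportional_bias_p, 0.05)
})

test_that("bias is antisymmetric and LoA cover ~95% of Gaussian differences", {
  set.seed(9)
  a <- rnorm(12, 100, 10); b <- rnorm(12, 90, 10)
  expect_equal(bland_altman(paired_sample(a, b))$bias,
               -bland_altman(paired_sample(b, a))$bias, tolerance = 1e-12)
  n <- 1e4
  x <- rnorm(n, 50, 5); d <- rnorm(n, 2, 3)
  ba <- bland_altman(paired_sample(x + d, x))
  cover <- mean(ba$diffs >= ba$loa_low & ba$diffs <= ba$loa_high)
  expect_equal(cover, 0.95, tolerance = 0.011)
})

test_that("shapiro_wilk delegates correctly and validates n", {
  expect_error(shapiro_wilk(c(1, 2)), "3 <= n")
  expect_error(shapiro_wilk(rnorm(5001)), "3 <= n")
  ref <- c(148, 154, 158, 160, 161, 162, 166, 170, 182, 195, 236)
  sw <- shapiro_wilk(ref)
  expect_equal(sw$W, 0.79, tolerance = 2e-3)
  expect_true(sw$W <= 1)
  expect_lt(sw$p, 0.05)
})

test_that("run_study on an identical-source cohort gives null agreement tables", {
  set.seed(21)
  vals <- array(stats::runif(5 * 3 * 3, 30, 90), c(5, 3, 3))
  conds <- c("rest", "hypercapnia", "exercise")
  coh <- make_metric_cohort(5,
    value_f = function(i, cd, src) vals[i, match(cd, conds), ],
    tcbf_f = function(i, cd) 500 + 10 * i + 50 * match(cd, conds))
  st <- run_study(coh)
  expect_true(all(st$absolute_distributions$degenerate))
  expect_true(all(is.na(st$absolute_distributions$p)))
  expect_equal(st$absolute_correlations$r, rep(1, 9), tolerance = 1e-12)
  expect_equal(st$bland_altman_absolute$bias, rep(0, 9))
  expect_equal(st$bland_altman_absolute$sd_diff, rep(0, 9))
})

test_that("a pure multiplicative bias separates absolute from relative agreement", {
  set.seed(22)
  conds <- c("rest", "hypercapnia", "exercise")
  cfd <- array(stats::runif(6 * 3 * 3, 30, 90), c(6, 3, 3))
  coh <- make_metric_cohort(6,
    value_f = function(i, cd, src) {
      v <- cfd[i, match(cd, conds), ]
      if (src == "tcd") 1.6 * v else v
    },
    tcbf_f = function(i, cd) 600 + 20 * i)
  st <- run_study(coh)
  # absolute: all paired tests significant, TCD above CFD
  expect_true(all(st$absolute_distributions$p < 0.05))
  expect_true(all(st$absolute_distributions$mean_tcd >
                  st$absolute_distributions$mean_cfd))
  # relative: the bias cancels exactly -> identical percent changes
  expect_true(all(st$relative_distributions$degenerate))
  expect_equal(st$relative_correlations$r, rep(1, 6), tolerance = 1e-12)
  expect_equal(st$bland_altman_relative$bias, rep(0, 6), tolerance = 1e-12)
})

test_that("run_study validates cohort completeness and reproduces bit-for-bit", {
  conds <- c("rest", "hypercapnia", "exercise")
  set.seed(23)
  vals <- array(stats::runif(4 * 3 * 3 * 2, 30, 90), c(4, 3, 3, 2))
  vf <- function(i, cd, src)
    vals[i, match(cd, conds), , match(src, c("cfd", "tcd"))]
  coh <- make_metric_cohort(4, vf, function(i, cd) 550 + 15 * i)
  st1 <- run_study(coh)
  st2 <- run_study(coh)
  expect_identical(st1$absolute_distributions, st2$absolute_distributions)
  expect_identical(st1$relative_correlations, st2$relative_correlations)
  broken <- coh
  broken[[2]]$conditions$exercise <- NULL
  expect_error(run_study(broken), "missing condition")
  expect_error(run_study(coh[1:2]), "at least 3")
})

test_that("Holm adjustment is available but off by default", {
  conds <- c("rest", "hypercapnia", "exercise")
  set.seed(24)
  vals <- array(stats::runif(5 * 3 * 3, 30, 90), c(5, 3, 3))
  coh <- make_metric_cohort(5,
    value_f = function(i, cd, src) {
      v <- vals[i, match(cd, conds), ]
      if (src == "tcd") v * 1.6 + stats::rnorm(3, 0, 2) else v
    },
    tcbf_f = function(i, cd) 600 + 20 * i)
  st_raw <- run_study(coh)
  st_holm <- run_study(coh, p_adjust = "holm")
  expect_true(all(st_holm$absolute_distributions$p >=
                  st_raw$absolute_distributions$p - 1e-15))
})
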