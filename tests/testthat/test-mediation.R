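# Product-of-coefficients mediation, bootstrap, EM missing-data handling and
# fit indices.

# noiseless dataset with exact linear path relations:
# M = 0.5 X + 0.3 Mb ; Y = 0.2 X - 0.4 M + 0.1 Yb, with the baseline
# mediator constructed orthogonal (in-sample) to X and Yb so the reduced
# total-effect regression is also exact
exact_paths_data <- function() {
  X <- rep(c(0, 1), 6)
  Mb <- rep(c(1, 1, -1, -1), 3)
  Yb <- rep(c(1, -1, -1, 1), 3)
  M <- 0.5 * X + 0.3 * Mb
  Y <- 0.2 * X - 0.4 * M + 0.1 * Yb
  data.frame(X = X, Mb = Mb, M = M, Yb = Yb, Y = Y)
}

test_that("noiseless linear relations are recovered exactly with additivity", {
  d <- exact_paths_data()
  med <- fit_mediation(d, "X", "M", "Y", "Mb", "Yb", n_boot = 5, seed = 1,
                       standardize = FALSE)
  p <- med$paths
  expect_equal(p[["a"]], 0.5, tolerance = 1e-10)
  expect_equal(p[["b"]], -0.4, tolerance = 1e-10)
  expect_equal(p[["cprime"]], 0.2, tolerance = 1e-10)
  expect_equal(p[["indirect"]], -0.2, tolerance = 1e-10)
  expect_equal(p[["indirect"]] + p[["cprime"]], p[["c"]], tolerance = 1e-10)
})

test_that("a*b + c' = c is an identity under a shared conditioning set", {
  set.seed(123)
  for (r in 1:20) {
    n <- 150
    X <- rbinom(n, 1, 0.5)
    Mb <- rnorm(n)
    Yb <- rnorm(n)
    M <- 0.4 * X + 0.5 * Mb + rnorm(n)
    Y <- -0.2 * X - 0.3 * M + 0.4 * Yb + rnorm(n)
    d <- data.frame(X = X, Mb = Mb, M = M, Yb = Yb, Y = Y)
    med <- fit_mediation(d, "X", "M", "Y", "Mb", "Yb", n_boot = 2, seed = r,
                         covariate_set = "shared")
    p <- med$paths
    expect_equal(p[["indirect"]] + p[["cprime"]], p[["c"]], tolerance = 1e-8)
  }
})

test_that("a null mediator path gives an indirect CI covering zero", {
  set.seed(9)
  n <- 1500
  X <- rbinom(n, 1, 0.5)
  Mb <- rnorm(n)
  Yb <- rnorm(n)
  M <- 0.4 * X + 0.5 * Mb + rnorm(n)
  Y <- -0.2 * X + 0.4 * Yb + rnorm(n) # b = 0
  d <- data.frame(X = X, Mb = Mb, M = M, Yb = Yb, Y = Y)
  med <- fit_mediation(d, "X", "M", "Y", "Mb", "Yb", n_boot = 400, seed = 2)
  expect_lte(med$boot$ci_lo[["indirect"]], 0)
  expect_gte(med$boot$ci_hi[["indirect"]], 0)
  expect_lt(abs(med$paths[["prop_mediated"]]), 25)
})

test_that("inconsistent mediation is flagged, zero-variance exposure errors", {
  set.seed(31)
  n <- 800
  X <- rbinom(n, 1, 0.5)
  Mb <- rnorm(n)
  Yb <- rnorm(n)
  M <- 1.0 * X + 0.3 * Mb + rnorm(n, sd = 0.5)
  Y <- -0.5 * X + 0.6 * M + 0.3 * Yb + rnorm(n, sd = 0.5) # a*b > 0, c' < 0
  d <- data.frame(X = X, Mb = Mb, M = M, Yb = Yb, Y = Y)
  med <- fit_mediation(d, "X", "M", "Y", "Mb", "Yb", n_boot = 10, seed = 3)
  expect_true(med$inconsistent_mediation)
  d$X <- 1
  expect_error(fit_mediation(d, "X", "M", "Y", "Mb", "Yb", n_boot = 2),
               "zero variance")
  expect_error(fit_mediation(d, "M", "M", "Y", "Mb", "Yb", n_boot = 2),
               "distinct")
})

test_that("bootstrap is seed-deterministic with a closed-form SE scale", {
  set.seed(4)
  d <- data.frame(z = rnorm(400))
  stat <- function(dd) c(m = mean(dd$z))
  b1 <- bootstrap_stat(d, stat, n_boot = 600, seed = 11)
  b2 <- bootstrap_stat(d, stat, n_boot = 600, seed = 11)
  expect_identical(b1$dist, b2$dist)
  expect_identical(b1$ci_lo, b2$ci_lo)
  # SE of the mean of n=400 draws from N(0,1) is ~1/20
  expect_lt(abs(b1$se[["m"]] - sd(d$z) / 20) / (sd(d$z) / 20), 0.15)
  b3 <- bootstrap_stat(d, stat, n_boot = 1, seed = 1)
  expect_true(is.na(b3$se[["m"]]))
  expect_true(b3$se_undefined)
  # failing statistic triggers logged redraws rather than NA output
  flaky <- local({
    i <- 0
    function(dd) {
      i <<- i + 1
      if (i %% 7 == 0) stop("boom")
      c(m = mean(dd$z))
    }
  })
  b4 <- bootstrap_stat(d, flaky, n_boot = 50, seed = 5)
  expect_gt(b4$n_failed, 0)
  expect_false(anyNA(b4$dist))
})

test_that("fit indices hit their analytic anchors and an independent oracle", {
  # chi-square equal to df: perfect fit
  fi <- fit_indices(-50, -50 + 0, -80, 0, 10, 500)
  expect_true(fi$saturated)
  expect_equal(fi$rmsea, 0)
  fi2 <- fit_indices(-55, -50, -90, 10, 10, 500)
  expect_lte(fi2$cfi, 1)
  # chisq == baseline chisq with equal df: CFI = 0
  fi3 <- fit_indices(-90, -50, -90, 10, 10, 500)
  expect_equal(fi3$cfi, 0)
  # chisq = 2*df, df = 10, n = 1000: RMSEA = sqrt(10 / 10000)
  fi4 <- fit_indices(-60, -50, -200, 10, 14, 1000)
  expect_equal(fi4$rmsea, sqrt(10 / (10 * 1000)), tolerance = 1e-10)
  # random tuples against an independently coded implementation
  set.seed(8)
  for (r in 1:20) {
    df <- sample(2:20, 1)
    chisq <- runif(1, 0.2 * df, 5 * df)
    df_b <- df + sample(1:10, 1)
    chisq_b <- chisq + runif(1, 0, 400)
    n <- sample(200:3000, 1)
    got <- fit_indices(-chisq / 2, 0, -chisq_b / 2, df, df_b, n)
    want <- oracle_fit_indices(chisq, df, chisq_b, df_b, n)
    expect_equal(got$cfi, want$cfi, tolerance = 1e-8)
    expect_equal(got$rmsea, want$rmsea, tolerance = 1e-8)
    expect_equal(got$rmsea_ci, want$ci, tolerance = 1e-5)
  }
})

test_that("EM equals sample moments with complete data and handles MCAR", {
  set.seed(14)
  n <- 600
  S_true <- matrix(0.4, 4, 4)
  diag(S_true) <- 1
  X <- matrix(rnorm(n * 4), n) %*% chol(S_true)
  colnames(X) <- letters[1:4]
  em <- em_normal_estimates(X)
  expect_equal(em$mu, colMeans(X), tolerance = 1e-8)
  expect_equal(em$sigma, cov(X) * (n - 1) / n, tolerance = 1e-8)
  # a variable with no observed values errors
  Xbad <- X
  Xbad[, 2] <- NA
  expect_error(em_normal_estimates(Xbad), "no observed values")
  # MCAR: estimates stay close to the complete-data moments
  Xm <- X
  Xm[matrix(runif(n * 4) < 0.2, n)] <- NA
  em2 <- em_normal_estimates(Xm)
  expect_lt(max(abs(em2$mu - colMeans(X))), 0.1)
  expect_lt(max(abs(em2$sigma - cov(X))), 0.12)
})

test_that("EM and complete-case mediation agree when nothing is missing", {
  set.seed(18)
  n <- 500
  X <- rbinom(n, 1, 0.5)
  Mb <- rnorm(n)
  Yb <- rnorm(n)
  M <- 0.4 * X + 0.5 * Mb + rnorm(n)
  Y <- -0.2 * X - 0.3 * M + 0.4 * Yb + rnorm(n)
  d <- data.frame(X = X, Mb = Mb, M = M, Yb = Yb, Y = Y)
  cc <- fit_mediation(d, "X", "M", "Y", "Mb", "Yb", n_boot = 2, seed = 1)
  em <- fit_mediation(d, "X", "M", "Y", "Mb", "Yb", n_boot = 2, seed = 1,
                      missing = "em_normal")
  expect_equal(cc$paths, em$paths, tolerance = 1e-6)
  # under MCAR the EM fit recovers the generating paths
  dm <- d
  dm[matrix(runif(n * 5) < 0.15, n, 5) &
       col(matrix(0, n, 5)) != 1] <- NA
  emm <- fit_mediation(dm, "X", "M", "Y", "Mb", "Yb", n_boot = 2, seed = 1,
                       missing = "em_normal", standardize = FALSE)
  expect_equal(emm$paths[["a"]], 0.4, tolerance = 0.35)
  expect_equal(emm$paths[["b"]], -0.3, tolerance = 0.35)
})

test_that("mediation fit indices look like a well-fitting path model", {
  cfg <- sim_config(n_participants = 800L)
  sim <- simulate_cohort(cfg, seed = 40)
  pan <- apply_analysis_filters(derive_exposures(score_waves(sim$waves)))$panel
  md <- mediation_dataset(pan)
  med <- fit_mediation(md, "pdmooc", "m_fu", "y_fu", "m_bl", "y_bl",
                       n_boot = 50, seed = 6)
  fi <- med$fit_indices
  expect_gte(fi$cfi, 0)
  expect_lte(fi$cfi, 1)
  expect_gte(fi$rmsea, 0)
  expect_lte(fi$rmsea_ci[1], fi$rmsea + 1e-9)
  expect_gte(fi$rmsea_ci[2], fi$rmsea - 1e-9)
  expect_equal(fi$df, 2)
})
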