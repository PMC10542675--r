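# Trajectory models, standardized coefficients, marginal means, transitions
# and variance decomposition.

sim_panel <- function(n = 300, seed = 1) {
  cfg <- sim_config(n_participants = as.integer(n))
  sim <- simulate_cohort(cfg, seed = seed)
  apply_analysis_filters(derive_exposures(score_waves(sim$waves)))$model_panel
}

test_that("trajectory fits report coherent coefficient tables and R2", {
  pan <- sim_panel(300, seed = 8)
  fit <- fit_trajectory(pan, pdmooc = TRUE, interaction = TRUE,
                        covariates = c("age", "gender"))
  co <- fit$coefficients
  expect_true(all(c("n_drp_exposures", "log_time", "pdmooc",
                    "n_drp_exposures:pdmooc") %in% co$term))
  expect_true(all(co$ci_lo <= co$estimate & co$estimate <= co$ci_hi))
  expect_true(all(co$b_s_lo <= co$b_s & co$b_s <= co$b_s_hi))
  r2 <- fit$r2
  expect_lte(r2[["marginal"]], r2[["conditional"]])
  expect_lte(r2[["conditional"]], 1)
  expect_gte(r2[["marginal"]], 0)
  expect_identical(marginal_r2(fit), r2)
})

test_that("degenerate designs error instead of fitting silently", {
  pan <- sim_panel(120, seed = 9)
  one_wave <- pan[pan$wave == "BL", ]
  expect_error(fit_trajectory(one_wave), "repeated observations")
  two_ids <- pan[pan$id %in% unique(pan$id)[1], ]
  expect_error(fit_trajectory(two_ids), "2 participants")
  pan$copy_of_exposures <- pan$n_drp_exposures
  expect_error(fit_trajectory(pan, covariates = "copy_of_exposures"),
               "collinear")
  pan$flat <- 1
  expect_error(fit_trajectory(pan, covariates = "flat"), "collinear")
  expect_error(fit_trajectory(pan, outcome = "no_such_column"),
               "missing columns")
})

test_that("standardization matches the closed form and a z-scored refit", {
  set.seed(42)
  n <- 400
  x <- rnorm(n, sd = 2)
  g <- rbinom(n, 1, 0.5)
  y <- 1 - 0.5 * x + 0.8 * g + rnorm(n, sd = 3)
  fit <- lm(y ~ x + g)
  bs <- standardize_coefficients(fit)
  expect_equal(bs[["x"]], coef(fit)[["x"]] * sd(x) / sd(y))
  expect_equal(bs[["g"]], coef(fit)[["g"]] / sd(y))
  # refit on z-scored data reproduces the continuous-term b_s
  zfit <- lm(scale(y) ~ scale(x) + g)
  expect_equal(bs[["x"]], unname(coef(zfit)[2]), tolerance = 1e-6)
  expect_equal(bs[["g"]], unname(coef(zfit)[3]), tolerance = 1e-6)
  # pre-standardized data: b_s equals b
  z <- as.numeric(scale(x))
  w <- as.numeric(scale(y))
  fitz <- lm(w ~ z)
  expect_equal(standardize_coefficients(fitz)[["z"]],
               coef(fitz)[["z"]], tolerance = 1e-12)
  const <- rep(1, n) + c(1e-30, numeric(n - 1))
  expect_error(standardize_coefficients(lm(y ~ x + I(0 * x))),
               "zero-variance")
})

test_that("marginal means reduce to grand and cell means in closed form", {
  set.seed(3)
  y <- rnorm(40)
  fit0 <- lm(y ~ 1)
  mm0 <- marginal_means(fit0, ~1)
  expect_equal(mm0$emmeans$emmean[1], mean(y), tolerance = 1e-10)
  # balanced one-factor data: EMMs equal cell means
  f <- factor(rep(c("a", "b", "c", "d"), each = 10))
  y2 <- rnorm(40) + as.integer(f)
  fit1 <- lm(y2 ~ f)
  mm <- marginal_means(fit1, ~f)
  expect_equal(mm$emmeans$emmean, as.vector(tapply(y2, f, mean)),
               tolerance = 1e-10)
  # 4 levels -> 6 pairwise contrasts; Tukey p >= unadjusted p
  expect_equal(nrow(mm$contrasts), 6)
  expect_true(all(mm$contrasts$p.value >=
                    mm$contrasts_unadjusted$p.value - 1e-12))
  expect_error(marginal_means(fit1, ~no_such_term), "absent from the model")
})

test_that("Tukey adjustment never reduces a contrast p-value on panel fits", {
  pan <- sim_panel(250, seed = 21)
  fit <- fit_trajectory(pan)
  mm <- marginal_means(fit, ~n_drp_exposures,
                       at = list(n_drp_exposures = 0:3))
  expect_equal(nrow(mm$contrasts), 6)
  expect_true(all(mm$contrasts$p.value >=
                    mm$contrasts_unadjusted$p.value - 1e-12))
})

test_that("transition models recover proportions and a hand-computed OR", {
  # intercept-only: fitted category probabilities = observed proportions
  set.seed(10)
  fin <- sample(c("low", "medium", "high"), 300, TRUE, prob = c(.6, .25, .15))
  bl <- rep("low", 300) # single baseline level drops out of the design
  tr <- fit_transitions(bl, fin)
  probs <- predict(tr$model, newdata = tr$data[1, , drop = FALSE],
                   type = "probs")
  obs <- prop.table(table(factor(fin, levels = c("low", "medium", "high"))))
  expect_equal(as.numeric(probs), as.numeric(obs), tolerance = 1e-6)
  # 2x2 contingency table: OR = (40*30)/(10*20) = 6
  bl2 <- c(rep("low", 50), rep("high", 50))
  fin2 <- c(rep("low", 40), rep("high", 10), rep("low", 20), rep("high", 30))
  tr2 <- fit_transitions(bl2, fin2)
  or <- tr2$or_table
  expect_equal(or$or[or$term == "baselinehigh"], 6, tolerance = 1e-4)
  # degenerate: no transitions -> perfect training-set classification
  bl3 <- sample(c("low", "medium", "high"), 200, TRUE)
  tr3 <- fit_transitions(bl3, bl3)
  pred <- predict(tr3$model, newdata = tr3$data, type = "class")
  expect_equal(mean(as.character(pred) == as.character(tr3$data$final)), 1)
  expect_error(fit_transitions("low", c("low", "high")), "paired")
})

test_that("transition ORs with covariates guard sparse categories", {
  set.seed(12)
  n <- 250
  bl <- sample(c("low", "medium", "high"), n, TRUE, prob = c(.5, .3, .2))
  fin <- ifelse(runif(n) < 0.6, bl,
                sample(c("low", "medium", "high"), n, TRUE))
  covs <- data.frame(age = rnorm(n, 64, 7), gender = sample(c("f", "m"), n, TRUE))
  tr <- fit_transitions(bl, fin, covariates = covs)
  expect_true(all(tr$or_table$or > 0))
  expect_true(all(tr$or_table$or_lo <= tr$or_table$or &
                    tr$or_table$or <= tr$or_table$or_hi))
  fin_rare <- c(rep("low", n - 1), "medium")
  expect_error(fit_transitions(bl, fin_rare, covariates = covs),
               "collapsing")
})

test_that("Nakagawa R2 behaves at its analytic limits", {
  pan <- sim_panel(200, seed = 14)
  # zero fixed effects: marginal R2 = 0
  null_fit <- lmerTest::lmer(drp_total ~ 1 + (1 | id), data = pan)
  r2 <- marginal_r2(null_fit)
  expect_equal(r2[["marginal"]], 0, tolerance = 1e-10)
  # vanishing random-intercept variance: marginal ~= conditional
  set.seed(15)
  n <- 400
  dat <- data.frame(id = rep(1:200, each = 2), x = rnorm(n))
  dat$y <- 0.8 * dat$x + rnorm(n) # no true id variance
  fit <- suppressMessages(lmerTest::lmer(y ~ x + (1 | id), data = dat))
  r2b <- marginal_r2(fit)
  expect_lt(r2b[["conditional"]] - r2b[["marginal"]], 0.12)
  # known variance components: analytic marginal R2 within Monte-Carlo range
  set.seed(16)
  id <- rep(1:500, each = 3)
  x <- rnorm(1500)
  b <- rnorm(500, 0, 1)[id]
  y <- 0.5 * x + b + rnorm(1500, 0, 1)
  fit2 <- lmerTest::lmer(y ~ x + (1 | id))
  truth <- 0.25 / (0.25 + 1 + 1)
  expect_equal(marginal_r2(fit2)[["marginal"]], truth, tolerance = 0.25)
})
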