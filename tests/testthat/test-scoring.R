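# Domain scorers against the published cut points and an independent
# rule-table oracle.

test_that("alcohol scoring follows the weekly/occasion cut points", {
  expect_equal(score_alcohol(15, 2, FALSE), "high")
  expect_equal(score_alcohol(0, 0, TRUE), "low")
  expect_equal(score_alcohol(10, 3, FALSE),
               oracle_alcohol(10, 3, FALSE)) # medium
  expect_equal(score_alcohol(10, 3, FALSE), "medium")
  expect_equal(score_alcohol(14, 2, FALSE), "low")
  expect_equal(score_alcohol(14, 2.001, FALSE), "medium")
  expect_equal(score_alcohol(14.001, 0, FALSE), "high")
  expect_equal(score_alcohol(NA, NA, NA), "unknown")
  expect_equal(score_alcohol(NA, NA, TRUE), "low")
  expect_error(score_alcohol(-1, 0, FALSE), "non-negative")
})

test_that("BMI bands are half-open at 18, 25 and 30", {
  expect_equal(score_bmi(1.70, 86.7), "high") # bmi = 30.0
  expect_equal(score_bmi(2.0, 100), "medium") # bmi = 25.0
  expect_equal(score_bmi(1.0, 18.0), "low") # band floor
  expect_equal(score_bmi(1.0, 17.999), "medium")
  expect_equal(score_bmi(1.0, 24.999), "low")
  expect_equal(score_bmi(1.0, 29.999), "medium")
  expect_equal(score_bmi(NA, 70), "unknown")
  expect_error(score_bmi(0, 70), "positive")
  expect_error(score_bmi(1.7, -1), "positive")
})

test_that("cardiometabolic management combinations classify per the table", {
  expect_equal(score_cardiometabolic("yes", TRUE, "medically_managed"), "low")
  expect_equal(score_cardiometabolic("no", FALSE, "n/a"), "high")
  expect_equal(score_cardiometabolic("unsure", TRUE, "n/a"), "medium")
  expect_equal(score_cardiometabolic("no", TRUE, "n/a"), "low")
  expect_equal(score_cardiometabolic("yes", TRUE, "working_toward"), "medium")
  expect_equal(score_cardiometabolic("yes", FALSE, "unmanaged"), "high")
  # medically managed without check-ups is still low risk
  expect_equal(score_cardiometabolic("yes", FALSE, "medically_managed"), "low")
  expect_equal(score_cardiometabolic(NA, TRUE, "n/a"), "unknown")
  expect_error(score_cardiometabolic("maybe", TRUE, "n/a"), "diagnosis")
})

test_that("smoking maps its three categories", {
  expect_equal(score_smoking(c("weekly_or_more", "none", "occasional", NA)),
               c("high", "low", "medium", "unknown"))
  expect_error(score_smoking("pipe"), "smoking")
})

test_that("MET-minutes weighting is 3.3/4/8 and 150 moderate minutes = 600", {
  expect_equal(compute_met_minutes(0, 150, 0), 600)
  expect_equal(compute_met_minutes(0, 0, 0), 0)
  expect_equal(compute_met_minutes(100, 50, 10), oracle_met(100, 50, 10))
  expect_equal(compute_met_minutes(100, 50, 10), 610)
  expect_error(compute_met_minutes(-1, 0, 0), "non-negative")
})

test_that("physical activity is two-level at the 600 MET-minute boundary", {
  expect_equal(score_physical_activity(600), "low")
  expect_equal(score_physical_activity(599.9), "high")
  expect_equal(score_physical_activity(NA_real_), "unknown")
  expect_false("medium" %in% score_physical_activity(runif(200, 0, 1200)))
})

test_that("cognitive activity is two-level at a summed score of 33", {
  expect_equal(score_cognitive_activity(rep(3, 11)), "low")
  expect_equal(score_cognitive_activity(rep(0, 11)), "high")
  expect_equal(score_cognitive_activity(c(rep(3, 10), 2)), "high") # sum 32
  expect_equal(score_cognitive_activity(c(rep(NA, 1), rep(5, 10))), "unknown")
  expect_error(score_cognitive_activity(rep(3, 10)), "11 items")
  expect_error(score_cognitive_activity(c(rep(3, 10), 7)), "integers")
})

test_that("MIND adherence bands split at 7.5 and 12", {
  expect_equal(mind_adherence(rep(1, 14)), 14)
  expect_equal(score_mind_diet(rep(1, 14)), "low")
  expect_equal(score_mind_diet(rep(0, 14)), "high")
  at <- function(a) c(rep(1, floor(a)), a - floor(a), rep(0, 13 - floor(a)))
  expect_equal(score_mind_diet(at(7.5)), "medium")
  expect_equal(score_mind_diet(at(7.0)), "high")
  expect_equal(score_mind_diet(at(11.5)), "medium")
  expect_equal(score_mind_diet(at(12)), "low")
  expect_equal(score_mind_diet(c(NA, rep(1, 13))), "unknown")
  expect_error(score_mind_diet(c(0.3, rep(1, 13))), "0, 0.5 or 1")
})

test_that("DRP totals weight medium 0.5 and high 1 over nine domains", {
  doms <- drp_domains()
  all_low <- setNames(rep("low", 9), doms)
  expect_equal(assemble_drp(all_low)$drp_total, 0)
  all_high <- setNames(rep("high", 9), doms)
  expect_equal(assemble_drp(all_high)$drp_total, 9)
  one_med <- all_low
  one_med["alcohol"] <- "medium"
  expect_equal(assemble_drp(one_med)$drp_total, 0.5)
  unk <- all_low
  unk["diet"] <- "unknown"
  p <- assemble_drp(unk)
  expect_true(is.na(p$drp_total))
  expect_equal(p$n_unknown, 1)
  expect_error(assemble_drp(all_low[-1]), "nine domains")
  bad <- all_low
  bad["physical_activity"] <- "medium"
  expect_error(assemble_drp(bad), "two-level")
})

test_that("scorers agree with the brute-force oracle and totals are additive", {
  set.seed(2024)
  n <- 2000
  r <- random_behaviour_responses(n)
  heights <- ifelse(is.na(r$height), NA, r$height)
  weights <- round(r$bmi * ifelse(is.na(heights), 1.7, heights)^2, 3)
  got <- data.frame(
    alcohol = score_alcohol(r$dpw, r$dpo, r$abst),
    bmi = score_bmi(heights, weights),
    hypertension = score_cardiometabolic(r$diag, r$checkups, r$managed),
    smoking = score_smoking(r$smoking),
    physical_activity = score_physical_activity(
      compute_met_minutes(r$light, r$moderate, r$vigorous)),
    cognitive_activity = score_cognitive_activity(r$cog),
    diet = score_mind_diet(r$mind),
    stringsAsFactors = FALSE
  )
  for (i in seq_len(n)) {
    expect_identical(got$alcohol[i], oracle_alcohol(r$dpw[i], r$dpo[i],
                                                    r$abst[i]))
    expect_identical(got$bmi[i], oracle_bmi(heights[i], weights[i]))
    expect_identical(got$hypertension[i],
                     oracle_cardio(r$diag[i], r$checkups[i], r$managed[i]))
    expect_identical(got$smoking[i], oracle_smoking(r$smoking[i]))
    met <- if (anyNA(c(r$light[i], r$moderate[i], r$vigorous[i]))) NA else
      oracle_met(r$light[i], r$moderate[i], r$vigorous[i])
    expect_identical(got$physical_activity[i], oracle_physical(met))
    expect_identical(got$cognitive_activity[i], oracle_cognitive(r$cog[i, ]))
    expect_identical(got$diet[i], oracle_mind(r$mind[i, ]))
  }
  # additivity of assembled totals on random known profiles
  pool3 <- c("low", "medium", "high")
  for (i in 1:200) {
    lv <- setNames(sample(pool3, 9, TRUE), drp_domains())
    lv[drp_two_level_domains()] <- sample(c("low", "high"), 2, TRUE)
    p <- assemble_drp(lv)
    expect_equal(p$drp_total, 0.5 * sum(lv == "medium") + sum(lv == "high"))
    expect_equal(p$drp_total, oracle_drp_total(lv))
    expect_true(p$drp_total >= 0 && p$drp_total <= 9)
    expect_equal(p$drp_total %% 0.5, 0)
  }
})

test_that("degrading any single domain raises the total by its weight step", {
  set.seed(11)
  pool3 <- c("low", "medium", "high")
  for (i in 1:100) {
    lv <- setNames(sample(pool3, 9, TRUE), drp_domains())
    lv[drp_two_level_domains()] <- sample(c("low", "high"), 2, TRUE)
    base <- assemble_drp(lv)$drp_total
    dom <- sample(drp_domains(), 1)
    cur <- lv[[dom]]
    if (cur == "high") next
    worse <- lv
    if (dom %in% drp_two_level_domains()) {
      worse[dom] <- "high"
      step <- 1
    } else if (cur == "low") {
      worse[dom] <- sample(c("medium", "high"), 1)
      step <- if (worse[dom] == "medium") 0.5 else 1
    } else {
      worse[dom] <- "high"
      step <- 0.5
    }
    expect_equal(assemble_drp(worse)$drp_total, base + step)
  }
})

test_that("score_waves appends risk columns and totals consistently", {
  row <- make_wave_row()
  sc <- score_waves(row)
  expect_equal(sc$risk_alcohol, "low")
  expect_equal(sc$drp_total, 0)
  expect_equal(sc$n_unknown, 0)
  row2 <- row
  row2$drinks_per_week <- NA
  row2$abstains <- NA
  row2$smoking <- "weekly_or_more"
  sc2 <- score_waves(row2)
  expect_equal(sc2$risk_alcohol, "unknown")
  expect_equal(sc2$n_unknown, 1)
  expect_true(is.na(sc2$drp_total))
  expect_error(score_waves(row[, -4]), NA) # dropping a demographic is fine
  expect_error(score_waves(row[, setdiff(names(row), "smoking")]),
               "missing columns")
})
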