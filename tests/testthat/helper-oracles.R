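# Independent brute-force oracles, coded directly from the published
# cut-point table as scalar rule chains, deliberately separate in style from
# the package's vectorised implementations.

oracle_alcohol <- function(dpw, dpo, abst) {
  if (!is.na(dpw) && dpw > 14) return("high")
  if (!is.na(abst) && isTRUE(abst)) return("low")
  if (is.na(dpw) || is.na(dpo)) return("unknown")
  if (dpw <= 14 && dpo > 2) return("medium")
  "low"
}

oracle_bmi <- function(height, weight) {
  if (is.na(height) || is.na(weight)) return("unknown")
  bmi <- weight / (height * height)
  if (bmi >= 30) return("high")
  if (bmi < 18) return("medium")
  if (bmi >= 25) return("medium")
  "low"
}

oracle_cardio <- function(dg, ck, mg) {
  if (!is.na(dg) && dg == "no" && !is.na(ck) && ck) return("low")
  if (!is.na(dg) && dg == "yes" && !is.na(mg) && mg == "medically_managed") {
    return("low")
  }
  if (!is.na(dg) && dg == "unsure" && !is.na(ck) && ck) return("medium")
  if (!is.na(dg) && dg == "yes" && !is.na(ck) && ck &&
      !is.na(mg) && mg == "working_toward") {
    return("medium")
  }
  if (!is.na(dg) && dg == "no" && !is.na(ck) && !ck) return("high")
  if (!is.na(dg) && dg == "yes" && !is.na(ck) && !ck &&
      !is.na(mg) && mg != "medically_managed") {
    return("high")
  }
  "unknown"
}

oracle_smoking <- function(s) {
  if (is.na(s)) return("unknown")
  switch(s, none = "low", occasional = "medium", weekly_or_more = "high")
}

oracle_met <- function(l, m, v) 3.3 * l + 4 * m + 8 * v

oracle_physical <- function(met) {
  if (is.na(met)) return("unknown")
  if (met >= 600) "low" else "high"
}

oracle_cognitive <- function(items) {
  if (any(is.na(items))) return("unknown")
  s <- 0
  for (x in items) s <- s + x
  if (s >= 33) "low" else "high"
}

oracle_mind <- function(comps) {
  if (any(is.na(comps))) return("unknown")
  s <- 0
  for (x in comps) s <- s + x
  if (s >= 12) return("low")
  if (s >= 7.5) return("medium")
  "high"
}

oracle_drp_total <- function(levels) {
  tot <- 0
  for (lv in levels) {
    if (lv == "unknown") return(NA_real_)
    if (lv == "medium") tot <- tot + 0.5
    if (lv == "high") tot <- tot + 1
  }
  tot
}

# random raw behaviour responses spanning the cut-point boundaries, with
# missingness mixed in
random_behaviour_responses <- function(n, na_rate = 0.08) {
  maybe_na <- function(x) {
    x[runif(length(x)) < na_rate] <- NA
    x
  }
  dpw_pool <- c(0:20, 13.5, 14, 14.001, 14.5)
  dpo_pool <- c(0:6, 1.9, 2, 2.001, 2.5)
  bmi_pool <- c(15, 17.9, 17.999, 18, 18.001, 22, 24.9, 24.999, 25, 25.001,
                29.9, 29.999, 30, 30.001, 35, 42)
  list(
    dpw = maybe_na(sample(dpw_pool, n, TRUE)),
    dpo = maybe_na(sample(dpo_pool, n, TRUE)),
    abst = maybe_na(runif(n) < 0.25),
    height = maybe_na(round(runif(n, 1.45, 2.0), 2)),
    bmi = sample(bmi_pool, n, TRUE),
    diag = maybe_na(sample(c("yes", "no", "unsure"), n, TRUE)),
    checkups = maybe_na(runif(n) < 0.5),
    managed = maybe_na(sample(c("medically_managed", "working_toward",
                                "unmanaged", "n/a"), n, TRUE)),
    smoking = maybe_na(sample(c("none", "occasional", "weekly_or_more"),
                              n, TRUE)),
    light = maybe_na(sample(c(0, 30, 60, 100, 150, 181.8, 182, 300), n, TRUE)),
    moderate = maybe_na(sample(c(0, 50, 100, 149, 150, 151, 200), n, TRUE)),
    vigorous = maybe_na(sample(c(0, 10, 74, 75, 76, 120), n, TRUE)),
    cog = matrix(maybe_na(sample(0:5, n * 11, TRUE)), n, 11),
    mind = matrix(maybe_na(sample(c(0, 0.5, 1), n * 14, TRUE)), n, 14)
  )
}

# independent textbook implementation of the chi-square fit indices
oracle_fit_indices <- function(chisq, df, chisq_b, df_b, n) {
  cfi_num <- max(chisq - df, 0)
  cfi_den <- max(chisq_b - df_b, chisq - df, 0)
  cfi <- if (cfi_den == 0) 1 else 1 - cfi_num / cfi_den
  rmsea <- sqrt(max(chisq - df, 0) / (df * n))
  lo_f <- function(ncp) pchisq(chisq, df, ncp) - 0.95
  hi_f <- function(ncp) pchisq(chisq, df, ncp) - 0.05
  find <- function(f) {
    if (f(0) < 0) return(0)
    upper <- 10
    while (f(upper) > 0) upper <- upper * 4
    uniroot(f, c(0, upper), tol = 1e-10)$root
  }
  list(cfi = cfi, rmsea = rmsea,
       ci = c(sqrt(find(lo_f) / (df * n)), sqrt(find(hi_f) / (df * n))))
}

# one complete raw wave row in the score_waves() schema
make_wave_row <- function(id = "P00001", wave = "BL", wave_month = 0) {
  row <- data.frame(
    id = id, wave = wave, wave_month = wave_month,
    age = 65, gender = "female", education = "university",
    marital = "married", employment = "retired", irsad_decile = 7,
    remoteness = "inner_regional", pdmooc = 0, pdmooc_pre = 0,
    drinks_per_week = 2, max_drinks_per_occasion = 1, abstains = FALSE,
    height_m = 1.70, weight_kg = 65, smoking = "none",
    htn_diagnosis = "no", htn_checkups = TRUE, htn_managed = "n/a",
    chol_diagnosis = "no", chol_checkups = TRUE, chol_managed = "n/a",
    diab_diagnosis = "no", diab_checkups = TRUE, diab_managed = "n/a",
    light_min = 0, moderate_min = 200, vigorous_min = 0,
    stringsAsFactors = FALSE
  )
  for (j in 1:11) row[[paste0("cog_", j)]] <- 4
  for (j in 1:14) row[[paste0("mind_", j)]] <- 1
  row$koderr_misconception <- 8
  row$koderr_general <- 15
  row$koderr_strategy <- 12
  row
}
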