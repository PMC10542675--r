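# Seed-reproducible synthetic cohort generator with recorded ground truth.
#
# Generation strategy: each participant-wave gets a latent continuous risk
# total from a linear mixed model (random intercept, exposure/time/course
# effects, covariates, optional knowledge channel). The latent total is
# discretised to the 0.5 grid on [0, 9], nine domain levels are drawn from
# realistic marginal propensities and nudged until their weights sum to that
# total, and raw survey responses are then sampled inside the scoring band
# for each assigned level -- so generator and scorer agree on every cut point
# by construction.

#' Construct a synthetic-cohort configuration
#'
#' Returns the default study-like configuration, optionally overridden by
#' named arguments (unknown names are rejected). Defaults emulate a
#' rolling-baseline cohort aged 50+ (mean 63.7, SD 7.7), ~71.6% female, a
#' 58.8% online-course engagement rate, annual October follow-ups with a
#' five-month invitation lead, a baseline mean risk total of 2.17 (reference
#' SD 1.24), and small beneficial exposure and course effects expressed in
#' outcome SD units.
#'
#' Key fields: `n_participants`; `baseline_window` (month index range for baseline,
#' 0 = October 2019) with `enrolment_decay` (exponential front-loading of
#' enrolment months, in months); `wave_months`; `retention` (completion
#' probability of eligible intermediate/final follow-ups); `pdmooc_rate`;
#' demographic
#' distributions; outcome model (`intercept`, `sd_ref`, `re_sd`, `resid_sd`,
#' `beta_exposure_s`, `beta_pdmooc_s`, `beta_interaction_s`, `beta_time`,
#' covariate effects); mediation truth (`a`, `b_s`, `rho_m`,
#' `g_exp`); per-domain baseline level probabilities; per-domain
#' `unknown_rates` with `followup_unknown_scale`.
#'
#' @param ... Named overrides of default fields.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(...) {
  cfg <- list(
    n_participants = 3038L,
    baseline_window = c(0L, 31L),
    enrolment_decay = 4,
    wave_months = c("Oct-20" = 12L, "Oct-21" = 24L, "Oct-22" = 36L),
    min_lead_months = 5L,
    retention = c(intermediate = 0.70, final = 0.985),
    pdmooc_rate = 0.588,
    pre_enrollee_rate = 0,
    age_mean = 63.7, age_sd = 7.7, age_min = 50,
    gender_probs = c(female = 0.716, male = 0.282, other = 0.002),
    education_probs = c(university = 0.553, post_secondary = 0.279,
                        school_only = 0.130, unknown = 0.038),
    marital_probs = c(married = 0.724, not_married = 0.276),
    employment_probs = c(employed = 0.50, retired = 0.45, other = 0.05),
    irsad_probs = c(rep(0.338 / 4, 4), rep(0.369 / 4, 4), rep(0.293 / 2, 2)),
    remoteness_probs = c(inner_regional = 0.734, outer_regional = 0.255,
                         remote = 0.009, very_remote = 0.002),
    # outcome (latent DRP total) model; *_s effects are in sd_ref units
    intercept = 2.17,
    sd_ref = 1.24,
    re_sd = 0.90,
    resid_sd = 0.75,
    beta_exposure_s = -0.03,
    beta_pdmooc_s = -0.11,
    beta_interaction_s = -0.03,
    beta_time = -0.07,
    beta_male = 0.15,
    beta_school_only = 0.20,
    beta_irsad = -0.02,
    beta_age10 = 0.05,
    # knowledge channel / mediation truth (SD units)
    a = 0.41, b_s = -0.05, rho_m = 0.5, g_exp = 0.11,
    misconception_mean = 7, misconception_sd = 2.2,
    koderr_extra = list(
      general = list(mean = 14, sd = 3.5, range = c(0, 22),
                     exp = 0.13, pd = 0.26, int = 0.07),
      strategy = list(mean = 12, sd = 3.5, range = c(0, 20),
                      exp = 0.15, pd = 0.13, int = 0.07)
    ),
    mchlb = list(
      susceptibility = list(mean = 12, sd = 3, range = c(5, 20),
                            exp = -0.04, pd = 0, int = -0.04),
      severity = list(mean = 15, sd = 3.5, range = c(6, 25),
                      exp = -0.04, pd = 0, int = 0),
      benefits = list(mean = 14, sd = 3, range = c(5, 20),
                      exp = 0.03, pd = 0.11, int = 0),
      barriers = list(mean = 11, sd = 3, range = c(5, 20),
                      exp = 0.03, pd = -0.19, int = -0.04),
      cues_to_action = list(mean = 12, sd = 3, range = c(5, 20),
                            exp = 0.02, pd = 0, int = 0),
      self_efficacy = list(mean = 7, sd = 1.8, range = c(2, 10),
                           exp = 0, pd = 0.15, int = 0.04),
      general_health_motivation = list(mean = 15, sd = 2.5, range = c(5, 20),
                                       exp = -0.02, pd = 0.08, int = 0)
    ),
    # baseline level probabilities per domain (low, medium, high);
    # two-level domains carry (low, 0, high)
    level_probs = list(
      alcohol = c(0.541, 0.321, 0.138),
      bmi = c(0.415, 0.357, 0.228),
      hypertension = c(0.936, 0.023, 0.041),
      cholesterol = c(0.818, 0.036, 0.146),
      diabetes = c(0.826, 0.014, 0.160),
      smoking = c(0.967, 0.014, 0.019),
      cognitive_activity = c(0.587, 0, 0.413),
      physical_activity = c(0.909, 0, 0.091),
      diet = c(0.209, 0.734, 0.057)
    ),
    unknown_rates = c(alcohol = 0.068, bmi = 0.044, hypertension = 0.005,
                      cholesterol = 0.006, diabetes = 0.008, smoking = 0.002,
                      cognitive_activity = 0.011, physical_activity = 0.030,
                      diet = 0.005),
    followup_unknown_scale = 0.4
  )
  over <- list(...)
  if (length(over)) {
    bad <- setdiff(names(over), names(cfg))
    if (length(bad)) stop("unknown sim_config field(s): ", paste(bad, collapse = ", "))
    cfg[names(over)] <- over
  }
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  chk_probs <- function(p, what) {
    if (any(p < 0) || abs(sum(p) - 1) > 1e-6) {
      stop(what, " probabilities must be non-negative and sum to 1")
    }
  }
  chk_probs(cfg$gender_probs, "gender")
  chk_probs(cfg$education_probs, "education")
  chk_probs(cfg$marital_probs, "marital")
  chk_probs(cfg$employment_probs, "employment")
  chk_probs(cfg$irsad_probs, "irsad")
  chk_probs(cfg$remoteness_probs, "remoteness")
  for (d in names(cfg$level_probs)) chk_probs(cfg$level_probs[[d]], d)
  rates <- c(cfg$pdmooc_rate, cfg$pre_enrollee_rate, cfg$retention,
             cfg$unknown_rates, cfg$followup_unknown_scale)
  if (any(rates < 0 | rates > 1)) stop("rates must lie in [0, 1]")
  if (cfg$resid_sd <= 0 || cfg$sd_ref <= 0 || cfg$age_sd <= 0) {
    stop("resid_sd, sd_ref and age_sd must be positive")
  }
  if (cfg$re_sd < 0) stop("re_sd must be non-negative")
  if (cfg$enrolment_decay <= 0) stop("enrolment_decay must be positive")
  if (is.unsorted(cfg$wave_months, strictly = TRUE)) {
    stop("wave schedule must be strictly increasing")
  }
  invisible(cfg)
}

#' Load a simulation configuration from YAML
#'
#' Reads a YAML file of overrides and merges it onto the defaults of
#' [sim_config()]. The configuration shipped with the package
#' (`system.file("extdata", "island-like.yaml", package = "drprofile")`)
#' reproduces the default study-like conditions.
#'
#' @param path Path to a YAML file.
#' @return A `sim_config` object.
#' @export
sim_config_from_yaml <- function(path) {
  raw <- yaml::read_yaml(path)
  for (nm in c("gender_probs", "education_probs", "marital_probs",
               "employment_probs", "remoteness_probs", "retention",
               "unknown_rates", "wave_months", "baseline_window",
               "irsad_probs")) {
    if (!is.null(raw[[nm]])) raw[[nm]] <- unlist(raw[[nm]])
  }
  if (!is.null(raw$level_probs)) {
    raw$level_probs <- lapply(raw$level_probs, unlist)
  }
  do.call(sim_config, raw)
}

.sample_cat <- function(n, probs) {
  names(probs)[1L + findInterval(stats::runif(n), cumsum(probs),
                                 rightmost.closed = TRUE)]
}

.rtruncnorm_left <- function(n, mean, sd, lower) {
  p_lo <- stats::pnorm(lower, mean, sd)
  stats::qnorm(p_lo + stats::runif(n) * (1 - p_lo), mean, sd)
}

#' Simulate a synthetic longitudinal cohort
#'
#' Generates raw survey responses (the schema consumed by [score_waves()])
#' for a rolling-baseline cohort, together with the generating ground truth.
#' Identical `(config, seed)` pairs produce identical output.
#'
#' @param config A [sim_config()] object.
#' @param seed Integer RNG seed.
#' @return List of class `drp_sim`: `waves` (raw long-format table) and
#'   `truth` (generating coefficients on the raw scale, per-participant
#'   random intercepts, latent totals).
#' @export
simulate_cohort <- function(config = sim_config(), seed = 1) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(as.integer(seed))
  cfg <- config
  n <- cfg$n_participants

  # participant-level draws
  age <- .rtruncnorm_left(n, cfg$age_mean, cfg$age_sd, cfg$age_min)
  gender <- .sample_cat(n, cfg$gender_probs)
  education <- .sample_cat(n, cfg$education_probs)
  marital <- .sample_cat(n, cfg$marital_probs)
  employment <- .sample_cat(n, cfg$employment_probs)
  remoteness <- .sample_cat(n, cfg$remoteness_probs)
  irsad <- 1L + findInterval(stats::runif(n), cumsum(cfg$irsad_probs),
                             rightmost.closed = TRUE)
  pdmooc <- stats::rbinom(n, 1, cfg$pdmooc_rate)
  pdmooc_pre <- stats::rbinom(n, 1, cfg$pre_enrollee_rate)
  b_i <- stats::rnorm(n, 0, cfg$re_sd)
  k_bl <- stats::rnorm(n, 0, 1)
  bl_span <- seq(cfg$baseline_window[1], cfg$baseline_window[2])
  bl_probs <- exp(-(bl_span - bl_span[1]) / cfg$enrolment_decay)
  bl_month <- sample(bl_span, n, replace = TRUE, prob = bl_probs / sum(bl_probs))

  # wave completion (baseline always completed)
  wm <- cfg$wave_months
  n_fu <- length(wm)
  eligible <- outer(bl_month, wm, function(b, w) b <= w - cfg$min_lead_months)
  ret <- c(rep(cfg$retention[["intermediate"]], n_fu - 1),
           cfg$retention[["final"]])
  completed <- eligible &
    matrix(stats::runif(n * n_fu), n, n_fu) <
      matrix(ret, n, n_fu, byrow = TRUE)

  # long skeleton: baseline row for everyone + completed follow-ups
  pid <- sprintf("P%05d", seq_len(n))
  idx <- c(seq_len(n), rep(seq_len(n), n_fu)[as.vector(completed)])
  wave <- c(rep("BL", n),
            rep(names(wm), each = n)[as.vector(completed)])
  wave_month <- c(bl_month, rep(unname(wm), each = n)[as.vector(completed)])
  # exposures = completed waves strictly before this one (baseline counts)
  prior_fu <- cbind(0L, t(apply(completed, 1, cumsum))[, -n_fu, drop = FALSE])
  expos <- c(rep(0L, n),
             (1L + prior_fu)[cbind(rep(seq_len(n), n_fu),
                                   rep(seq_len(n_fu), each = n))][as.vector(completed)])
  months <- wave_month - bl_month[idx]
  is_fu <- wave != "BL"
  nrow_all <- length(idx)

  # covariate effects, centred at their configured expectations
  irsad_mean <- sum(seq_along(cfg$irsad_probs) * cfg$irsad_probs)
  cov_eff_p <- cfg$beta_male * ((gender == "male") - cfg$gender_probs[["male"]]) +
    cfg$beta_school_only * ((education == "school_only") -
                              cfg$education_probs[["school_only"]]) +
    cfg$beta_irsad * (irsad - irsad_mean) +
    cfg$beta_age10 * (age - cfg$age_mean) / 10

  # knowledge latent (misconception discernment channel)
  ek_sd <- sqrt(max(0.05, 1 - cfg$rho_m^2 -
                      cfg$a^2 * cfg$pdmooc_rate * (1 - cfg$pdmooc_rate)))
  k <- k_bl[idx]
  k[is_fu] <- cfg$rho_m * k_bl[idx[is_fu]] +
    cfg$g_exp * expos[is_fu] + cfg$a * pdmooc[idx[is_fu]] +
    stats::rnorm(sum(is_fu), 0, ek_sd)

  # latent outcome and discretised target total. The conditional linear
  # predictor is pushed through the inverse of the censored-grid mean
  # function before residual noise is added, so that the *discretised* total
  # has conditional expectation equal to the linear predictor -- i.e. the
  # scored DRP total follows the configured linear mixed model rather than a
  # floor-attenuated version of it.
  beta_exposure <- cfg$beta_exposure_s * cfg$sd_ref
  beta_pdmooc <- cfg$beta_pdmooc_s * cfg$sd_ref
  beta_interaction <- cfg$beta_interaction_s * cfg$sd_ref
  b_raw <- cfg$b_s * cfg$sd_ref
  eta <- cfg$intercept + b_i[idx] +
    beta_exposure * expos +
    cfg$beta_time * log(months + 1) +
    beta_pdmooc * pdmooc[idx] +
    beta_interaction * expos * pdmooc[idx] +
    b_raw * k +
    cov_eff_p[idx]
  mu_star <- .grid_mean_inverse(pmin(pmax(eta, 0.02), 8.98), cfg$resid_sd)
  y <- mu_star + stats::rnorm(nrow_all, 0, cfg$resid_sd)
  t_total <- pmin(9, pmax(0, round(2 * y) / 2))

  levels_mat <- .assign_domain_levels(t_total, cfg$level_probs)
  resp <- .generate_responses(levels_mat)

  waves <- data.frame(
    id = pid[idx], wave = wave, wave_month = wave_month,
    age = round(age[idx], 1), gender = gender[idx],
    education = education[idx], marital = marital[idx],
    employment = employment[idx], irsad_decile = irsad[idx],
    remoteness = remoteness[idx],
    pdmooc = pdmooc[idx], pdmooc_pre = pdmooc_pre[idx],
    resp,
    stringsAsFactors = FALSE
  )

  # instrument subscale scores
  clampr <- function(x, r) pmin(pmax(x, r[1]), r[2])
  waves$koderr_misconception <- clampr(
    round(cfg$misconception_mean + cfg$misconception_sd * k), c(0, 12))
  for (nm in names(cfg$koderr_extra)) {
    sp <- cfg$koderr_extra[[nm]]
    lat <- stats::rnorm(nrow_all, 0, 1) +
      is_fu * (sp$exp * expos + sp$pd * pdmooc[idx] +
                 sp$int * expos * pdmooc[idx])
    waves[[paste0("koderr_", nm)]] <- clampr(round(sp$mean + sp$sd * lat),
                                             sp$range)
  }
  for (nm in names(cfg$mchlb)) {
    sp <- cfg$mchlb[[nm]]
    lat <- stats::rnorm(nrow_all, 0, 1) +
      is_fu * (sp$exp * expos + sp$pd * pdmooc[idx] +
                 sp$int * expos * pdmooc[idx])
    waves[[paste0("mchlb_", nm)]] <- clampr(round(sp$mean + sp$sd * lat),
                                            sp$range)
  }

  truth <- list(
    seed = as.integer(seed),
    coefficients = list(
      intercept = cfg$intercept,
      beta_exposure = beta_exposure, beta_time = cfg$beta_time,
      beta_pdmooc = beta_pdmooc, beta_interaction = beta_interaction,
      b_knowledge = b_raw, a = cfg$a,
      beta_exposure_s = cfg$beta_exposure_s,
      beta_pdmooc_s = cfg$beta_pdmooc_s,
      beta_interaction_s = cfg$beta_interaction_s,
      re_sd = cfg$re_sd, resid_sd = cfg$resid_sd
    ),
    participants = data.frame(id = pid, random_intercept = b_i,
                              knowledge_baseline = k_bl, pdmooc = pdmooc,
                              baseline_month = bl_month),
    latent = data.frame(id = pid[idx], wave = wave, linear_predictor = eta,
                        y_latent = y, t_total = t_total, knowledge = k)
  )
  structure(list(waves = waves, truth = truth, config = cfg), class = "drp_sim")
}

#' @export
print.drp_sim <- function(x, ...) {
  cat("Synthetic cohort:", length(unique(x$waves$id)), "participants,",
      nrow(x$waves), "participant-waves\n")
  invisible(x)
}

# Exact mean of the discretised total min(9, max(0, round(2*N(mu, sd))/2))
# as a function of mu, inverted by monotone interpolation. Rounding to the
# 0.5 grid is unbiased away from the boundaries; the floor/ceiling censoring
# is what this inversion corrects for.
.grid_mean_inverse <- function(target, sd) {
  mugrid <- seq(-4, 13.5, by = 0.01)
  ks <- 0:18
  upper <- ifelse(ks == 18, Inf, ks / 2 + 0.25)
  lower <- ifelse(ks == 0, -Inf, ks / 2 - 0.25)
  pk <- function(mu) {
    stats::pnorm(outer(upper, mu, function(u, m) (u - m) / sd)) -
      stats::pnorm(outer(lower, mu, function(l, m) (l - m) / sd))
  }
  hvals <- colSums((ks / 2) * pk(mugrid))
  stats::approx(hvals, mugrid, xout = target, rule = 2)$y
}

# Draw nine domain levels per row from the marginal propensities, then nudge
# single domains up/down (0.5 steps for three-level domains, 1 for two-level)
# until the weights sum to the target total. Codes: 0 low, 1 medium, 2 high;
# weight = code / 2; two-level domains only use codes 0 and 2.
.assign_domain_levels <- function(t_total, level_probs) {
  doms <- drp_domains()
  two <- doms %in% drp_two_level_domains()
  nr <- length(t_total)
  code <- matrix(0L, nr, length(doms), dimnames = list(NULL, doms))
  for (j in seq_along(doms)) {
    p <- level_probs[[doms[j]]]
    code[, j] <- c(0L, 1L, 2L)[1L + findInterval(stats::runif(nr), cumsum(p),
                                                 rightmost.closed = TRUE)]
  }
  twom <- matrix(two, nr, length(doms), byrow = TRUE)
  for (iter in 1:200) {
    diff <- t_total - rowSums(code) / 2
    act <- which(abs(diff) > 1e-9)
    if (!length(act)) break
    d <- diff[act]
    cd <- code[act, , drop = FALSE]
    tw <- twom[act, , drop = FALSE]
    up <- d > 0
    # eligibility for a single step in the needed direction
    elig <- matrix(FALSE, length(act), length(doms))
    # half-step moves need a three-level domain; full steps prefer any
    half <- abs(d) < 1 - 1e-9
    elig[up & !half, ] <- (cd < 2L)[up & !half, , drop = FALSE]
    elig[up & half, ] <- (cd < 2L & !tw)[up & half, , drop = FALSE]
    elig[!up & !half, ] <- (cd > 0L)[!up & !half, , drop = FALSE]
    elig[!up & half, ] <- (cd > 0L & !tw)[!up & half, , drop = FALSE]
    # fall back to any legal move when no half-step domain is available
    none <- rowSums(elig) == 0
    if (any(none)) {
      elig[none & up, ] <- (cd < 2L)[none & up, , drop = FALSE]
      elig[none & !up, ] <- (cd > 0L)[none & !up, , drop = FALSE]
    }
    pick <- max.col(elig * matrix(stats::runif(length(act) * length(doms)),
                                  length(act)), ties.method = "first")
    sel <- cbind(seq_along(act), pick)
    step <- ifelse(tw[sel], 2L, 1L) * ifelse(up, 1L, -1L)
    cd[sel] <- pmax(0L, pmin(2L, cd[sel] + step))
    code[act, ] <- cd
  }
  if (any(abs(t_total - rowSums(code) / 2) > 1e-9)) {
    stop("domain level assignment failed to match target totals")
  }
  code
}

# allocate integer total s over k items each in 0..cap, near-evenly with
# random remainder placement plus sum-preserving jitter swaps
.alloc_items <- function(s, k, cap, jitter_rounds = 2) {
  nr <- length(s)
  q <- s %/% k
  r <- s %% k
  x <- matrix(q, nr, k)
  if (nr) {
    rk <- t(apply(matrix(stats::runif(nr * k), nr, k), 1, rank,
                  ties.method = "first"))
    x <- x + (rk <= r)
  }
  for (j in seq_len(jitter_rounds)) {
    i1 <- sample.int(k, nr, replace = TRUE)
    i2 <- sample.int(k, nr, replace = TRUE)
    give <- cbind(seq_len(nr), i1)
    take <- cbind(seq_len(nr), i2)
    ok <- i1 != i2 & x[give] < cap & x[take] > 0
    x[give[ok, , drop = FALSE]] <- x[give[ok, , drop = FALSE]] + 1L
    x[take[ok, , drop = FALSE]] <- x[take[ok, , drop = FALSE]] - 1L
  }
  x
}

# Raw responses consistent with assigned levels; vectorised by level group.
.generate_responses <- function(code) {
  nr <- nrow(code)
  out <- data.frame(row = seq_len(nr))

  # alcohol
  lv <- code[, "alcohol"]
  dpw <- integer(nr); dpo <- integer(nr); abst <- logical(nr)
  i <- lv == 0L
  abst[i] <- stats::runif(sum(i)) < 0.4
  dpw[i] <- ifelse(abst[i], 0L, sample(0:14, sum(i), TRUE))
  dpo[i] <- ifelse(abst[i], 0L, sample(0:2, sum(i), TRUE))
  i <- lv == 1L
  dpw[i] <- sample(0:14, sum(i), TRUE)
  dpo[i] <- sample(3:6, sum(i), TRUE)
  i <- lv == 2L
  dpw[i] <- sample(15:40, sum(i), TRUE)
  dpo[i] <- sample(1:8, sum(i), TRUE)
  out$drinks_per_week <- dpw
  out$max_drinks_per_occasion <- dpo
  out$abstains <- abst

  # bmi: sample a BMI inside the band (0.05 off the boundaries so that
  # rounding weight to 0.1 kg cannot cross a cut point), then height/weight
  lv <- code[, "bmi"]
  bmi <- numeric(nr)
  bmi[lv == 0L] <- stats::runif(sum(lv == 0L), 18.05, 24.9)
  i <- lv == 1L
  under <- stats::runif(sum(i)) < 0.12
  bmi[i] <- ifelse(under, stats::runif(sum(i), 16, 17.9),
                   stats::runif(sum(i), 25.05, 29.9))
  bmi[lv == 2L] <- stats::runif(sum(lv == 2L), 30.05, 39)
  h <- round(pmin(pmax(stats::rnorm(nr, 1.68, 0.09), 1.45), 2.05), 2)
  out$height_m <- h
  out$weight_kg <- round(bmi * h^2, 1)

  # cardiometabolic domains
  for (dom in c("hypertension", "cholesterol", "diabetes")) {
    pre <- c(hypertension = "htn", cholesterol = "chol",
             diabetes = "diab")[[dom]]
    lv <- code[, dom]
    dg <- character(nr); ck <- logical(nr); mg <- character(nr)
    i <- lv == 0L
    diagnosed <- stats::runif(sum(i)) < 0.3
    dg[i] <- ifelse(diagnosed, "yes", "no")
    ck[i] <- TRUE
    mg[i] <- ifelse(diagnosed, "medically_managed", "n/a")
    i <- lv == 1L
    unsure <- stats::runif(sum(i)) < 0.5
    dg[i] <- ifelse(unsure, "unsure", "yes")
    ck[i] <- TRUE
    mg[i] <- ifelse(unsure, "n/a", "working_toward")
    i <- lv == 2L
    diagnosed <- stats::runif(sum(i)) < 0.5
    dg[i] <- ifelse(diagnosed, "yes", "no")
    ck[i] <- FALSE
    mg[i] <- ifelse(diagnosed, "unmanaged", "n/a")
    out[[paste0(pre, "_diagnosis")]] <- dg
    out[[paste0(pre, "_checkups")]] <- ck
    out[[paste0(pre, "_managed")]] <- mg
  }

  # smoking
  lv <- code[, "smoking"]
  out$smoking <- c("none", "occasional", "weekly_or_more")[lv + 1L]

  # physical activity (MET-minutes >= 600 vs < 600)
  lv <- code[, "physical_activity"]
  light <- integer(nr); mod <- integer(nr); vig <- integer(nr)
  i <- lv == 0L
  mod[i] <- sample(150:450, sum(i), TRUE)
  light[i] <- sample(0:300, sum(i), TRUE)
  vig[i] <- sample(0:120, sum(i), TRUE)
  i <- lv == 2L
  mod[i] <- sample(0:100, sum(i), TRUE)
  light[i] <- sample(0:60, sum(i), TRUE)
  out$light_min <- light
  out$moderate_min <- mod
  out$vigorous_min <- vig

  # cognitive activity: 11 items 0..5 summing >= 33 (low) or <= 32 (high)
  lv <- code[, "cognitive_activity"]
  s <- integer(nr)
  s[lv == 0L] <- sample(33:48, sum(lv == 0L), TRUE)
  s[lv == 2L] <- sample(8:32, sum(lv == 2L), TRUE)
  cogm <- .alloc_items(s, 11L, 5L)
  for (j in 1:11) out[[paste0("cog_", j)]] <- cogm[, j]

  # MIND diet: 14 components in {0, 0.5, 1}
  lv <- code[, "diet"]
  adh2 <- integer(nr) # adherence on the doubled (integer) scale 0..28
  adh2[lv == 0L] <- sample(24:28, sum(lv == 0L), TRUE)
  adh2[lv == 1L] <- sample(15:23, sum(lv == 1L), TRUE)
  adh2[lv == 2L] <- sample(0:14, sum(lv == 2L), TRUE)
  mindm <- .alloc_items(adh2, 14L, 2L)
  for (j in 1:14) out[[paste0("mind_", j)]] <- mindm[, j] / 2
  out$row <- NULL
  out
}

#' Inject 'unknown'-coded missingness into raw wave tables
#'
#' Blanks the raw inputs of each risk domain at the configured per-domain
#' rates (baseline rates scaled by `followup_unknown_scale` at follow-up
#' waves), so the affected domains score as unknown. Wave-level dropout is
#' governed by the retention probabilities inside [simulate_cohort()].
#'
#' @param waves Raw wave table from [simulate_cohort()].
#' @param config A [sim_config()]; `unknown_rates` of 0 leave the table
#'   unchanged.
#' @param seed Integer RNG seed.
#' @return The wave table with missing raw fields.
#' @export
inject_missingness <- function(waves, config = sim_config(), seed = 1) {
  stopifnot(inherits(config, "sim_config"))
  rates <- config$unknown_rates
  if (any(rates < 0 | rates > 1)) stop("unknown rates must lie in [0, 1]")
  set.seed(as.integer(seed))
  fields <- list(
    alcohol = c("drinks_per_week", "max_drinks_per_occasion", "abstains"),
    bmi = c("height_m", "weight_kg"),
    hypertension = paste0("htn_", c("diagnosis", "checkups", "managed")),
    cholesterol = paste0("chol_", c("diagnosis", "checkups", "managed")),
    diabetes = paste0("diab_", c("diagnosis", "checkups", "managed")),
    smoking = "smoking",
    cognitive_activity = paste0("cog_", 1:11),
    physical_activity = c("light_min", "moderate_min", "vigorous_min"),
    diet = paste0("mind_", 1:14)
  )
  is_fu <- waves$wave != "BL"
  for (dom in names(fields)) {
    r <- rates[[dom]] * ifelse(is_fu, config$followup_unknown_scale, 1)
    hit <- stats::runif(nrow(waves)) < r
    if (any(hit)) for (f in fields[[dom]]) waves[[f]][hit] <- NA
  }
  waves
}
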