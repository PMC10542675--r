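# Nine-domain traffic-light risk scoring and the continuous DRP total.

#' Risk domains of the Dementia Risk Profile
#'
#' The nine modifiable behaviour domains scored by the DRP, in canonical
#' order. `cognitive_activity` and `physical_activity` are two-level domains
#' (low/high only); all others have a medium level.
#'
#' @return Character vector of the nine domain names.
#' @export
drp_domains <- function() {
  c("alcohol", "bmi", "hypertension", "cholesterol", "diabetes",
    "smoking", "cognitive_activity", "physical_activity", "diet")
}

#' @rdname drp_domains
#' @export
drp_two_level_domains <- function() c("cognitive_activity", "physical_activity")

#' Risk levels and their score weights
#'
#' Levels contribute to the DRP total with weights low = 0, medium = 0.5,
#' high = 1. `unknown` has no numeric weight (`NA`).
#'
#' @param level Character vector of levels.
#' @return `risk_levels()`: the four level labels. `risk_weight()`: numeric
#'   weights (`NA` for unknown).
#' @export
risk_levels <- function() c("low", "medium", "high", "unknown")

#' @rdname risk_levels
#' @export
risk_weight <- function(level) {
  w <- c(low = 0, medium = 0.5, high = 1, unknown = NA_real_)
  bad <- !is.na(level) & !level %in% names(w)
  if (any(bad)) {
    stop("unrecognised risk level(s): ", paste(unique(level[bad]), collapse = ", "))
  }
  out <- unname(w[level])
  out[is.na(level)] <- NA_real_
  out
}

.check_nonneg <- function(x, what) {
  if (any(!is.na(x) & x < 0)) stop("`", what, "` must be non-negative")
  invisible(x)
}

#' Score alcohol consumption
#'
#' High risk: more than 14 standard drinks per week. Medium: at most 14 per
#' week but more than 2 standard drinks on an occasion. Low: abstaining, or
#' at most 2 drinks per occasion (and at most 14 per week).
#'
#' @param drinks_per_week Standard drinks per week (non-negative; NA = missing).
#' @param max_per_occasion Most standard drinks on one occasion.
#' @param abstains Logical; does not drink alcohol at all.
#' @return Character vector of risk levels.
#' @export
score_alcohol <- function(drinks_per_week, max_per_occasion, abstains) {
  .check_nonneg(drinks_per_week, "drinks_per_week")
  .check_nonneg(max_per_occasion, "max_per_occasion")
  n <- max(length(drinks_per_week), length(max_per_occasion), length(abstains))
  dpw <- rep_len(drinks_per_week, n)
  dpo <- rep_len(max_per_occasion, n)
  abst <- rep_len(abstains, n)
  out <- rep("unknown", n)
  known <- !is.na(dpw) & !is.na(dpo)
  out[known & dpw <= 14 & dpo <= 2] <- "low"
  out[known & dpw <= 14 & dpo > 2] <- "medium"
  out[!is.na(abst) & abst] <- "low" # abstaining dominates occasion answers
  out[!is.na(dpw) & dpw > 14] <- "high"
  out
}

#' Score body-mass index
#'
#' BMI = weight (kg) / height (m) squared. Low: 18 to under 25. Medium: 25 to
#' under 30, or under 18. High: 30 or over. Bands are half-open so values such
#' as 24.95 have a defined level.
#'
#' @param height Height in metres (> 0; NA = missing).
#' @param weight Weight in kilograms (> 0; NA = missing).
#' @return Character vector of risk levels.
#' @export
score_bmi <- function(height, weight) {
  if (any(!is.na(height) & height <= 0)) stop("`height` must be positive")
  if (any(!is.na(weight) & weight <= 0)) stop("`weight` must be positive")
  n <- max(length(height), length(weight))
  h <- rep_len(height, n)
  w <- rep_len(weight, n)
  bmi <- w / h^2
  out <- rep("unknown", n)
  out[!is.na(bmi) & bmi >= 18 & bmi < 25] <- "low"
  out[!is.na(bmi) & (bmi < 18 | (bmi >= 25 & bmi < 30))] <- "medium"
  out[!is.na(bmi) & bmi >= 30] <- "high"
  out
}

#' Score a cardiometabolic management domain
#'
#' Applied identically to hypertension, cholesterol and diabetes. Low: no
#' diagnosis with regular check-ups, or a diagnosis that is medically managed.
#' Medium: unsure of diagnosis but regular check-ups, or diagnosed with
#' regular check-ups and working toward managing it. High: diagnosed with
#' neither regular check-ups nor medical management, or no diagnosis and no
#' regular check-ups. Other combinations are unknown.
#'
#' @param diagnosis One of `"yes"`, `"no"`, `"unsure"` (NA = missing).
#' @param regular_checkups Logical; has regular check-ups.
#' @param managed One of `"medically_managed"`, `"working_toward"`,
#'   `"unmanaged"`, `"n/a"`.
#' @return Character vector of risk levels.
#' @export
score_cardiometabolic <- function(diagnosis, regular_checkups, managed) {
  diag_ok <- c("yes", "no", "unsure")
  man_ok <- c("medically_managed", "working_toward", "unmanaged", "n/a")
  if (any(!is.na(diagnosis) & !diagnosis %in% diag_ok)) {
    stop("`diagnosis` must be one of ", paste(diag_ok, collapse = ", "))
  }
  if (any(!is.na(managed) & !managed %in% man_ok)) {
    stop("`managed` must be one of ", paste(man_ok, collapse = ", "))
  }
  n <- max(length(diagnosis), length(regular_checkups), length(managed))
  dg <- rep_len(diagnosis, n)
  ck <- rep_len(regular_checkups, n)
  mg <- rep_len(managed, n)
  out <- rep("unknown", n)
  low <- (!is.na(dg) & dg == "no" & !is.na(ck) & ck) |
    (!is.na(dg) & dg == "yes" & !is.na(mg) & mg == "medically_managed")
  med <- (!is.na(dg) & dg == "unsure" & !is.na(ck) & ck) |
    (!is.na(dg) & dg == "yes" & !is.na(ck) & ck & !is.na(mg) & mg == "working_toward")
  high <- (!is.na(dg) & dg == "yes" & !is.na(ck) & !ck &
             !is.na(mg) & mg != "medically_managed") |
    (!is.na(dg) & dg == "no" & !is.na(ck) & !ck)
  out[high] <- "high"
  out[med] <- "medium"
  out[low] <- "low"
  out
}

#' Score smoking
#'
#' Low: not smoking. Medium: occasional smoking. High: smoking once or more
#' a week.
#'
#' @param smoking One of `"none"`, `"occasional"`, `"weekly_or_more"`
#'   (NA = missing).
#' @return Character vector of risk levels.
#' @export
score_smoking <- function(smoking) {
  ok <- c("none", "occasional", "weekly_or_more")
  if (any(!is.na(smoking) & !smoking %in% ok)) {
    stop("`smoking` must be one of ", paste(ok, collapse = ", "))
  }
  out <- rep("unknown", length(smoking))
  out[!is.na(smoking) & smoking == "none"] <- "low"
  out[!is.na(smoking) & smoking == "occasional"] <- "medium"
  out[!is.na(smoking) & smoking == "weekly_or_more"] <- "high"
  out
}

#' Weekly MET-minutes from activity minutes
#'
#' Metabolic-equivalent weighting of weekly activity minutes: light 3.3,
#' moderate 4, vigorous 8. 150 minutes of moderate activity yields the
#' 600 MET-minute sufficiency threshold.
#'
#' @param light_min,moderate_min,vigorous_min Weekly minutes by intensity
#'   (non-negative; NA = missing).
#' @return Numeric vector of weekly MET-minutes.
#' @export
compute_met_minutes <- function(light_min, moderate_min, vigorous_min) {
  .check_nonneg(light_min, "light_min")
  .check_nonneg(moderate_min, "moderate_min")
  .check_nonneg(vigorous_min, "vigorous_min")
  3.3 * light_min + 4 * moderate_min + 8 * vigorous_min
}

#' Score physical activity (two-level domain)
#'
#' Low risk: 600 MET-minutes per week or more; high risk otherwise. There is
#' no medium level.
#'
#' @param met_minutes Weekly MET-minutes (NA = missing).
#' @return Character vector of risk levels (never `"medium"`).
#' @export
score_physical_activity <- function(met_minutes) {
  .check_nonneg(met_minutes, "met_minutes")
  out <- rep("unknown", length(met_minutes))
  out[!is.na(met_minutes) & met_minutes >= 600] <- "low"
  out[!is.na(met_minutes) & met_minutes < 600] <- "high"
  out
}

#' Score cognitive activity (two-level domain)
#'
#' Eleven cultural/cognitive activities rated on an ordinal frequency scale
#' (default 0-5, where 3 = "several times a month"). The summed score is low
#' risk at 33 or higher (all items at least "several times a month" on
#' average), high risk below 33. No medium level.
#'
#' @param freq Numeric vector of 11 frequency codes, or a matrix/data.frame
#'   with 11 columns (one row per observation). NA = missing.
#' @param scale_max Maximum frequency code (default 5).
#' @return Character vector of risk levels (never `"medium"`).
#' @export
score_cognitive_activity <- function(freq, scale_max = 5) {
  m <- .as_item_matrix(freq, 11, "cognitive activity frequencies")
  if (any(!is.na(m) & (m < 0 | m > scale_max | m != floor(m)))) {
    stop("cognitive activity codes must be integers in 0..", scale_max)
  }
  total <- rowSums(m)
  out <- rep("unknown", nrow(m))
  out[!is.na(total) & total >= 33] <- "low"
  out[!is.na(total) & total < 33] <- "high"
  out
}

#' MIND-diet adherence score and risk level
#'
#' Fourteen scoreable diet components (wine excluded), each scored 0, 0.5 or
#' 1; adherence is their sum (range 0-14). Low risk: 12 or higher. Medium:
#' 7.5 to under 12. High: under 7.5. Any missing component makes the level
#' unknown.
#'
#' @param components Numeric vector of 14 component scores, or a
#'   matrix/data.frame with 14 columns.
#' @return `score_mind_diet()`: character vector of risk levels.
#'   `mind_adherence()`: numeric adherence scores (NA when any component is
#'   missing).
#' @export
score_mind_diet <- function(components) {
  adherence <- mind_adherence(components)
  out <- rep("unknown", length(adherence))
  out[!is.na(adherence) & adherence >= 12] <- "low"
  out[!is.na(adherence) & adherence >= 7.5 & adherence < 12] <- "medium"
  out[!is.na(adherence) & adherence < 7.5] <- "high"
  out
}

#' @rdname score_mind_diet
#' @export
mind_adherence <- function(components) {
  m <- .as_item_matrix(components, 14, "MIND components")
  if (any(!is.na(m) & !m %in% c(0, 0.5, 1))) {
    stop("MIND component scores must be 0, 0.5 or 1")
  }
  pmin(pmax(rowSums(m), 0), 14)
}

.as_item_matrix <- function(x, k, what) {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (is.matrix(x)) {
    if (ncol(x) != k) stop(what, ": expected ", k, " items, got ", ncol(x))
    return(x)
  }
  if (length(x) != k) stop(what, ": expected ", k, " items, got ", length(x))
  matrix(x, nrow = 1)
}

#' Assemble a Dementia Risk Profile from domain levels
#'
#' Combines the nine domain risk levels into a profile with the continuous
#' DRP total (0.5 per medium domain, 1 per high domain; range 0-9). The total
#' is undefined (`NA`) whenever any domain is unknown; the number of unknown
#' domains is recorded.
#'
#' @param domain_levels Named character vector or list with exactly the nine
#'   entries of [drp_domains()].
#' @return An object of class `drp_profile`: list with `domain_levels`
#'   (named character), `drp_total` and `n_unknown`.
#' @examples
#' lv <- setNames(rep("low", 9), drp_domains())
#' lv["alcohol"] <- "medium"
#' assemble_drp(lv)$drp_total # 0.5
#' @export
assemble_drp <- function(domain_levels) {
  lv <- unlist(domain_levels)
  doms <- drp_domains()
  if (length(lv) != 9 || is.null(names(lv)) || !setequal(names(lv), doms)) {
    stop("`domain_levels` must be named with exactly the nine domains: ",
         paste(doms, collapse = ", "))
  }
  lv <- lv[doms]
  lv[is.na(lv)] <- "unknown"
  bad <- !lv %in% risk_levels()
  if (any(bad)) stop("unrecognised risk level(s): ", paste(lv[bad], collapse = ", "))
  two <- drp_two_level_domains()
  if (any(lv[two] == "medium")) {
    stop("two-level domains (", paste(two, collapse = ", "),
         ") cannot be medium")
  }
  n_unknown <- sum(lv == "unknown")
  total <- if (n_unknown == 0) sum(risk_weight(lv)) else NA_real_
  structure(list(domain_levels = lv, drp_total = total, n_unknown = n_unknown),
            class = "drp_profile")
}

#' @export
print.drp_profile <- function(x, ...) {
  cat("Dementia Risk Profile\n")
  for (d in names(x$domain_levels)) {
    cat(sprintf("  %-18s %s\n", d, x$domain_levels[[d]]))
  }
  if (is.na(x$drp_total)) {
    cat(sprintf("DRP total: undefined (%d unknown domain%s)\n",
                x$n_unknown, if (x$n_unknown == 1) "" else "s"))
  } else {
    cat(sprintf("DRP total: %.1f / 9\n", x$drp_total))
  }
  invisible(x)
}

#' Score a long-format wave table into risk levels and DRP totals
#'
#' Applies the nine domain scorers to a data frame with one row per
#' participant-wave, appending `risk_<domain>` columns, derived quantities
#' (`met_minutes`, `cognitive_score`, `mind_score`), `drp_total` and
#' `n_unknown`.
#'
#' Expected columns (missing values as `NA`): `drinks_per_week`,
#' `max_drinks_per_occasion`, `abstains`, `height_m`, `weight_kg`,
#' `<dom>_diagnosis`/`<dom>_checkups`/`<dom>_managed` for `dom` in
#' `htn`, `chol`, `diab`, `smoking`, `light_min`, `moderate_min`,
#' `vigorous_min`, `cog_1` .. `cog_11`, `mind_1` .. `mind_14`.
#'
#' @param waves Data frame of raw wave responses.
#' @return The input with scoring columns appended.
#' @export
score_waves <- function(waves) {
  need <- c("drinks_per_week", "max_drinks_per_occasion", "abstains",
            "height_m", "weight_kg", "smoking",
            "light_min", "moderate_min", "vigorous_min",
            paste0("cog_", 1:11), paste0("mind_", 1:14),
            paste0(rep(c("htn", "chol", "diab"), each = 3),
                   c("_diagnosis", "_checkups", "_managed")))
  missing_cols <- setdiff(need, names(waves))
  if (length(missing_cols)) {
    stop("wave table is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  out <- waves
  out$risk_alcohol <- score_alcohol(waves$drinks_per_week,
                                    waves$max_drinks_per_occasion,
                                    waves$abstains)
  out$risk_bmi <- score_bmi(waves$height_m, waves$weight_kg)
  out$risk_hypertension <- score_cardiometabolic(waves$htn_diagnosis,
                                                 waves$htn_checkups,
                                                 waves$htn_managed)
  out$risk_cholesterol <- score_cardiometabolic(waves$chol_diagnosis,
                                                waves$chol_checkups,
                                                waves$chol_managed)
  out$risk_diabetes <- score_cardiometabolic(waves$diab_diagnosis,
                                             waves$diab_checkups,
                                             waves$diab_managed)
  out$risk_smoking <- score_smoking(waves$smoking)
  out$met_minutes <- compute_met_minutes(waves$light_min, waves$moderate_min,
                                         waves$vigorous_min)
  out$risk_physical_activity <- score_physical_activity(out$met_minutes)
  cog <- as.matrix(waves[paste0("cog_", 1:11)])
  out$cognitive_score <- rowSums(cog)
  out$risk_cognitive_activity <- score_cognitive_activity(cog)
  mind <- as.matrix(waves[paste0("mind_", 1:14)])
  out$mind_score <- mind_adherence(mind)
  out$risk_diet <- score_mind_diet(mind)

  lvl <- as.matrix(out[paste0("risk_", drp_domains())])
  out$n_unknown <- rowSums(lvl == "unknown")
  w <- matrix(risk_weight(lvl), nrow = nrow(lvl))
  total <- rowSums(w)
  total[out$n_unknown > 0] <- NA_real_
  out$drp_total <- total
  out
}
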