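# Longitudinal intervention-effect models: REML random-intercept trajectories
# with standardized coefficients, estimated marginal means and Tukey
# contrasts, and multinomial risk-transition models.

#' Fit a random-intercept trajectory model
#'
#' Fits `outcome ~ n_drp_exposures + log_time [+ pdmooc] [+
#' n_drp_exposures:pdmooc] [+ covariates] + (1 | id)` by restricted maximum
#' likelihood. Inference uses Satterthwaite degrees of freedom (normal
#' approximation when unavailable). Standardized coefficients are reported
#' alongside the raw ones: for a continuous predictor `b_s = b * SD(x) /
#' SD(y)`, for a binary predictor `b_s = b / SD(y)`, with SDs taken on the
#' estimation sample.
#'
#' @param panel Analysis panel (e.g. `model_panel` from
#'   [apply_analysis_filters()]): needs `id`, the outcome, and the requested
#'   terms.
#' @param outcome Name of the continuous outcome column (default
#'   `"drp_total"`).
#' @param exposures,time Include the exposure count / log study-time terms.
#' @param pdmooc Include the online-course engagement dummy.
#' @param interaction Include the exposure-by-course interaction (implies
#'   `pdmooc`).
#' @param covariates Character vector of additional covariate columns.
#' @return Object of class `drp_trajectory` with the `lmerMod` fit,
#'   coefficient table (raw and standardized, 95% CIs, p-values), variance
#'   components and Nakagawa marginal/conditional R-squared.
#' @export
fit_trajectory <- function(panel, outcome = "drp_total", exposures = TRUE,
                           time = TRUE, pdmooc = FALSE, interaction = FALSE,
                           covariates = NULL) {
  if (interaction) pdmooc <- TRUE
  terms <- c(if (exposures) "n_drp_exposures", if (time) "log_time",
             if (pdmooc) "pdmooc",
             if (interaction) "n_drp_exposures:pdmooc", covariates)
  if (!length(terms)) terms <- "1"
  need <- unique(c("id", outcome, setdiff(terms, "1"),
                   if (interaction) c("n_drp_exposures", "pdmooc")))
  need <- setdiff(need, grep(":", need, value = TRUE))
  miss <- setdiff(need, names(panel))
  if (length(miss)) stop("panel is missing columns: ", paste(miss, collapse = ", "))

  dat <- panel[stats::complete.cases(panel[need]), need, drop = FALSE]
  if (length(unique(dat$id)) < 2) {
    stop("need at least 2 participants to fit a mixed model")
  }
  multi <- table(dat$id)
  if (!any(multi >= 2)) {
    stop("need repeated observations (>= 2 waves) for at least some participants")
  }
  fixed <- stats::reformulate(terms, response = outcome)
  X <- stats::model.matrix(fixed, dat)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("rank-deficient fixed-effects design; collinear term(s): ",
         paste(dropped, collapse = ", "))
  }
  form <- stats::as.formula(paste(outcome, "~", paste(terms, collapse = " + "),
                                  "+ (1 | id)"))
  fit <- lmerTest::lmer(form, data = dat, REML = TRUE)
  out <- structure(list(fit = fit, formula = form, data = dat,
                        outcome = outcome), class = "drp_trajectory")
  out$coefficients <- .trajectory_coef_table(fit, dat, outcome)
  vc <- as.data.frame(lme4::VarCorr(fit))
  out$varcomp <- c(random_intercept = vc$vcov[vc$grp == "id"],
                   residual = vc$vcov[vc$grp == "Residual"])
  r2 <- marginal_r2(fit)
  out$r2 <- r2
  out
}

.trajectory_coef_table <- function(fit, dat, outcome) {
  sm <- summary(fit)$coefficients
  est <- sm[, "Estimate"]
  se <- sm[, "Std. Error"]
  df <- if ("df" %in% colnames(sm)) sm[, "df"] else rep(Inf, length(est))
  df[!is.finite(df)] <- Inf
  p <- 2 * stats::pt(-abs(est / se), df)
  tq <- stats::qt(0.975, df)
  sdx <- .predictor_sds(fit)
  sdy <- stats::sd(dat[[outcome]])
  scale <- sdx / sdy
  data.frame(
    term = rownames(sm), estimate = est, se = se, df = df,
    ci_lo = est - tq * se, ci_hi = est + tq * se, p = p,
    b_s = est * scale, b_s_lo = (est - tq * se) * scale,
    b_s_hi = (est + tq * se) * scale,
    row.names = NULL
  )
}

# SD multiplier per model-matrix column: sd(x) for continuous columns, 1 for
# binary (0/1) columns, 0 for the intercept (its standardized value is not
# meaningful and is reported as 0).
.predictor_sds <- function(fit) {
  X <- stats::model.matrix(fit)
  vapply(colnames(X), function(cn) {
    x <- X[, cn]
    if (cn == "(Intercept)") return(0)
    ux <- unique(x)
    if (length(ux) == 2 && all(ux %in% c(0, 1))) return(1)
    s <- stats::sd(x)
    if (s == 0) stop("zero-variance predictor: ", cn)
    s
  }, numeric(1))
}

#' Standardized coefficients for a fitted model
#'
#' `b_s = b * SD(x) / SD(y)` for continuous predictors and `b / SD(y)` for
#' binary (0/1) predictors, with SDs computed on the model's estimation
#' sample. Equivalent to refitting on z-scored data.
#'
#' @param model A `drp_trajectory`, `merMod` or `lm` fit.
#' @return Named numeric vector of standardized coefficients (intercept
#'   reported as 0).
#' @export
standardize_coefficients <- function(model) {
  if (inherits(model, "drp_trajectory")) {
    out <- model$coefficients$b_s
    names(out) <- model$coefficients$term
    return(out)
  }
  X <- stats::model.matrix(model)
  y <- if (inherits(model, "merMod")) lme4::getME(model, "y") else
    stats::model.response(stats::model.frame(model))
  b <- if (inherits(model, "merMod")) lme4::fixef(model) else stats::coef(model)
  sdx <- .predictor_sds(model)
  out <- b * sdx / stats::sd(y)
  names(out) <- names(b)
  out
}

#' Estimated marginal means with Tukey-adjusted contrasts
#'
#' Computes model-predicted means over a reference grid (at covariate means)
#' and all pairwise contrasts with studentized-range (Tukey) multiplicity
#' adjustment within the model's contrast family.
#'
#' @param model A `drp_trajectory`, `merMod` or `lm` fit.
#' @param spec One-sided formula naming the grid factor(s), e.g.
#'   `~ n_drp_exposures` or `~ n_drp_exposures * pdmooc`.
#' @param at Optional named list of grid values, e.g.
#'   `list(n_drp_exposures = 0:3)`.
#' @return Object of class `drp_emm`: data frames `emmeans`, `contrasts`
#'   (Tukey-adjusted) and `contrasts_unadjusted`.
#' @export
marginal_means <- function(model, spec, at = NULL) {
  fit <- if (inherits(model, "drp_trajectory")) model$fit else model
  grid_vars <- all.vars(spec)
  known <- all.vars(stats::formula(fit, fixed.only = TRUE)[-2])
  miss <- setdiff(grid_vars, known)
  if (length(miss)) {
    stop("grid term(s) absent from the model: ", paste(miss, collapse = ", "))
  }
  em <- if (is.null(at)) emmeans::emmeans(fit, spec) else
    emmeans::emmeans(fit, spec, at = at)
  structure(list(
    emmeans = as.data.frame(em),
    contrasts = as.data.frame(emmeans::contrast(em, "pairwise",
                                                adjust = "tukey")),
    contrasts_unadjusted = as.data.frame(emmeans::contrast(em, "pairwise",
                                                           adjust = "none"))
  ), class = "drp_emm")
}

#' @export
print.drp_emm <- function(x, ...) {
  cat("Estimated marginal means\n")
  print(x$emmeans, row.names = FALSE)
  cat("\nTukey-adjusted pairwise contrasts\n")
  print(x$contrasts, row.names = FALSE)
  invisible(x)
}

#' Multinomial model of risk-level transitions
#'
#' Models each participant's final-wave risk level (reference category
#' `"low"`) from their baseline level, optionally adjusted for covariates,
#' by multinomial logistic regression. Unknown levels are excluded pairwise.
#'
#' @param baseline_levels,final_levels Character vectors of risk levels, one
#'   entry per participant (paired).
#' @param covariates Optional data frame of participant covariates, same
#'   number of rows.
#' @return Object of class `drp_transitions`: the `nnet::multinom` fit, an
#'   odds-ratio table with 95% Wald CIs, and the analysis sample size.
#' @export
fit_transitions <- function(baseline_levels, final_levels, covariates = NULL) {
  if (length(baseline_levels) != length(final_levels)) {
    stop("baseline and final level vectors must be paired (equal length)")
  }
  keep <- !is.na(baseline_levels) & !is.na(final_levels) &
    baseline_levels != "unknown" & final_levels != "unknown"
  dat <- data.frame(baseline = baseline_levels[keep],
                    final = final_levels[keep], stringsAsFactors = FALSE)
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    if (nrow(covariates) != length(baseline_levels)) {
      stop("covariates must have one row per participant")
    }
    dat <- cbind(dat, covariates[keep, , drop = FALSE])
    empty <- setdiff(c("low", "medium", "high"),
                     unique(c(dat$final, dat$baseline)))
    tabf <- table(dat$final)
    if (any(tabf < 2)) {
      stop("final-level category with < 2 observations while adjusting for ",
           "covariates; consider collapsing risk categories")
    }
  }
  ord <- intersect(c("low", "medium", "high"), unique(dat$final))
  dat$final <- factor(dat$final, levels = ord)
  dat$baseline <- factor(dat$baseline,
                         levels = intersect(c("low", "medium", "high"),
                                            unique(dat$baseline)))
  rhs <- c(if (nlevels(dat$baseline) >= 2) "baseline",
           setdiff(names(dat), c("baseline", "final")))
  if (!length(rhs)) rhs <- "1"
  form <- stats::reformulate(rhs, response = "final")
  fit <- nnet::multinom(form, data = dat, trace = FALSE, maxit = 1000,
                        reltol = 1e-12, abstol = 1e-12)
  cf <- stats::coef(fit)
  if (is.null(dim(cf))) cf <- matrix(cf, nrow = 1,
                                     dimnames = list(levels(dat$final)[-1],
                                                     names(cf)))
  se <- sqrt(diag(stats::vcov(fit)))
  se <- matrix(se, nrow = nrow(cf), byrow = TRUE,
               dimnames = dimnames(cf))
  or <- data.frame(
    outcome_level = rep(rownames(cf), ncol(cf)),
    term = rep(colnames(cf), each = nrow(cf)),
    or = as.vector(exp(cf)),
    or_lo = as.vector(exp(cf - 1.96 * se)),
    or_hi = as.vector(exp(cf + 1.96 * se)),
    row.names = NULL
  )
  structure(list(model = fit, or_table = or, n = nrow(dat),
                 data = dat), class = "drp_transitions")
}

#' @export
print.drp_transitions <- function(x, ...) {
  cat("Risk-level transition model (reference outcome: low), n =", x$n, "\n")
  print(x$or_table, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Marginal and conditional R-squared for a mixed model
#'
#' Nakagawa-style variance decomposition for a random-intercept model:
#' marginal R2 = fixed-effect variance / (fixed + random-intercept +
#' residual variance); conditional R2 adds the random-intercept variance to
#' the numerator.
#'
#' @param model A `drp_trajectory` or `merMod` fit.
#' @return Named numeric vector `c(marginal = , conditional = )`.
#' @export
marginal_r2 <- function(model) {
  fit <- if (inherits(model, "drp_trajectory")) model$fit else model
  X <- stats::model.matrix(fit)
  var_f <- stats::var(as.vector(X %*% lme4::fixef(fit)))
  vc <- as.data.frame(lme4::VarCorr(fit))
  var_r <- sum(vc$vcov[vc$grp != "Residual"])
  var_e <- vc$vcov[vc$grp == "Residual"]
  tot <- var_f + var_r + var_e
  c(marginal = var_f / tot, conditional = (var_f + var_r) / tot)
}

#' @export
print.drp_trajectory <- function(x, ...) {
  cat("Random-intercept trajectory model (REML):",
      deparse(x$formula), "\n")
  cat(sprintf("Observations: %d  Participants: %d\n",
              nrow(x$data), length(unique(x$data$id))))
  print(x$coefficients, row.names = FALSE, digits = 3)
  cat(sprintf("Variance components: id %.4f, residual %.4f\n",
              x$varcomp[["random_intercept"]], x$varcomp[["residual"]]))
  cat(sprintf("Marginal R2 = %.3f, conditional R2 = %.3f\n",
              x$r2[["marginal"]], x$r2[["conditional"]]))
  invisible(x)
}

#' @export
summary.drp_trajectory <- function(object, ...) {
  print(object)
  invisible(object)
}

#' @export
coef.drp_trajectory <- function(object, ...) lme4::fixef(object$fit)

#' @export
predict.drp_trajectory <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) stats::predict(object$fit, ...) else
    stats::predict(object$fit, newdata = newdata, ...)
}
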