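# Baseline-adjusted product-of-coefficients mediation: path regressions
# derived from (possibly EM-estimated) first and second moments, bootstrap
# inference, chi-square fit indices.

#' Fit a baseline-adjusted mediation model
#'
#' Three-variable path model with baseline adjustment: the mediator path
#' regresses follow-up mediator on exposure and baseline mediator (`a` is
#' the exposure coefficient); the outcome path regresses follow-up outcome
#' on exposure, follow-up mediator and baseline outcome (`b` is the mediator
#' coefficient, `c'` the direct effect); the total effect `c` comes from the
#' outcome regressed on exposure and baseline outcome. The indirect effect
#' is the product `a * b`; the proportion mediated is
#' `100 * a*b / (a*b + c')`, flagged as inconsistent mediation when `a*b`
#' and `c'` have opposite signs with `|a*b| > |a*b + c'|`.
#'
#' With `covariate_set = "shared"` all three regressions condition on both
#' baselines, which makes `a*b + c' = c` an exact algebraic identity; under
#' the default `"model_specific"` adjustment (each equation conditions only
#' on its own baseline) the decomposition holds only approximately.
#'
#' Continuous variables are z-scored on the analysis sample before fitting
#' (so effects are in SD units); binary 0/1 variables are left on their
#' original scale.
#'
#' @param data Data frame containing the five analysis variables.
#' @param x,m,y Column names of the exposure, follow-up mediator and
#'   follow-up outcome.
#' @param m_baseline,y_baseline Column names of the baseline mediator and
#'   baseline outcome.
#' @param n_boot Bootstrap replications (default 5000).
#' @param seed RNG seed for the bootstrap.
#' @param missing `"complete_case"` (listwise deletion) or `"em_normal"`
#'   (EM-estimated multivariate-normal moments; the bootstrap re-runs EM on
#'   every resample).
#' @param covariate_set `"model_specific"` or `"shared"` (see above).
#' @param standardize z-score continuous variables before fitting.
#' @return Object of class `drp_mediation`.
#' @export
fit_mediation <- function(data, x, m, y, m_baseline, y_baseline,
                          n_boot = 5000, seed = 1,
                          missing = c("complete_case", "em_normal"),
                          covariate_set = c("model_specific", "shared"),
                          standardize = TRUE) {
  missing <- match.arg(missing)
  covariate_set <- match.arg(covariate_set)
  vars <- c(x, m_baseline, m, y_baseline, y)
  miss_cols <- setdiff(vars, names(data))
  if (length(miss_cols)) {
    stop("data is missing columns: ", paste(miss_cols, collapse = ", "))
  }
  if (anyDuplicated(vars)) {
    stop("follow-up variables must be distinct from baselines")
  }
  if (n_boot < 1) stop("n_boot must be >= 1")
  V <- as.matrix(data[, vars])
  colnames(V) <- c("X", "Mb", "M", "Yb", "Y")
  V <- V[rowSums(!is.na(V)) > 0, , drop = FALSE]
  xv <- V[, "X"][!is.na(V[, "X"])]
  if (length(unique(xv)) < 2) stop("exposure `", x, "` has zero variance")

  est <- .mediation_estimate(V, missing, covariate_set, standardize)
  stat_fun <- function(Vb) {
    .mediation_estimate(Vb, missing, covariate_set, standardize)$stats
  }
  boot <- bootstrap_stat(V, stat_fun, n_boot = n_boot, seed = seed)

  fi <- tryCatch(.mediation_fit_indices(est, covariate_set),
                 error = function(e) {
                   list(chisq = NA_real_, df = NA_integer_, cfi = NA_real_,
                        rmsea = NA_real_, rmsea_ci = c(NA_real_, NA_real_),
                        saturated = FALSE,
                        note = paste("fit indices unavailable:",
                                     conditionMessage(e)))
                 })
  structure(list(
    paths = est$stats, n_used = est$n_used, n_complete = est$n_complete,
    missing = missing, covariate_set = covariate_set,
    inconsistent_mediation = est$inconsistent,
    boot = boot,
    fit_indices = fi,
    moments = est[c("mu", "S")],
    spec = list(x = x, m = m, y = y, m_baseline = m_baseline,
                y_baseline = y_baseline, n_boot = n_boot, seed = seed)
  ), class = "drp_mediation")
}

# point estimation from moments; V has canonical columns X, Mb, M, Yb, Y
.mediation_estimate <- function(V, missing, covariate_set, standardize) {
  if (missing == "em_normal") {
    em <- em_normal_estimates(V)
    mu <- em$mu
    S <- em$sigma
    n_used <- nrow(V)
  } else {
    cc <- stats::complete.cases(V)
    Vc <- V[cc, , drop = FALSE]
    if (nrow(Vc) < 10) stop("fewer than 10 complete cases")
    mu <- colMeans(Vc)
    # ML (n) denominator, matching the EM estimator exactly at 0% missingness
    S <- stats::cov(Vc) * (nrow(Vc) - 1) / nrow(Vc)
    n_used <- nrow(Vc)
  }
  if (standardize) {
    is_bin <- apply(V, 2, function(col) all(stats::na.omit(col) %in% c(0, 1)))
    d <- ifelse(is_bin, 1, sqrt(diag(S)))
    if (any(d == 0)) stop("zero-variance variable in mediation model")
    S <- S / tcrossprod(d)
  }
  reg <- function(dv, ivs) {
    b <- solve(S[ivs, ivs, drop = FALSE], S[ivs, dv])
    names(b) <- ivs
    b
  }
  if (covariate_set == "shared") {
    am <- reg("M", c("X", "Mb", "Yb"))
    ym <- reg("Y", c("X", "M", "Mb", "Yb"))
    tm <- reg("Y", c("X", "Mb", "Yb"))
  } else {
    am <- reg("M", c("X", "Mb"))
    ym <- reg("Y", c("X", "M", "Yb"))
    tm <- reg("Y", c("X", "Yb"))
  }
  a <- am[["X"]]; b <- ym[["M"]]; cprime <- ym[["X"]]; ctot <- tm[["X"]]
  indirect <- a * b
  prop <- 100 * indirect / (indirect + cprime)
  inconsistent <- sign(indirect) != 0 && sign(cprime) != 0 &&
    sign(indirect) != sign(cprime) && abs(indirect) > abs(indirect + cprime)
  list(stats = c(a = a, b = b, cprime = cprime, c = ctot,
                 indirect = indirect, prop_mediated = prop),
       a_model = am, y_model = ym, total_model = tm,
       mu = mu, S = S, n_used = n_used,
       n_complete = sum(stats::complete.cases(V)),
       inconsistent = inconsistent)
}

# chi-square fit of the recursive path model against the saturated and
# independence models, from the fitted moments (RAM formulation)
.mediation_fit_indices <- function(est, covariate_set) {
  S <- est$S
  n <- est$n_used
  p <- 5L
  ord <- c("X", "Mb", "Yb", "M", "Y")
  Ssub <- S[ord, ord]
  A <- matrix(0, p, p, dimnames = list(ord, ord))
  A["M", names(est$a_model)] <- est$a_model
  A["Y", names(est$y_model)] <- est$y_model
  Psi <- matrix(0, p, p, dimnames = list(ord, ord))
  exo <- c("X", "Mb", "Yb")
  Psi[exo, exo] <- Ssub[exo, exo]
  rv <- function(dv, bcoef) {
    ivs <- names(bcoef)
    Ssub[dv, dv] - 2 * sum(bcoef * Ssub[ivs, dv]) +
      drop(t(bcoef) %*% Ssub[ivs, ivs] %*% bcoef)
  }
  Psi["M", "M"] <- rv("M", est$a_model)
  Psi["Y", "Y"] <- rv("Y", est$y_model)
  if (min(Psi["M", "M"], Psi["Y", "Y"]) < 1e-10) {
    stop("zero residual variance (noiseless paths)")
  }
  IA <- solve(diag(p) - A)
  Sigma <- IA %*% Psi %*% t(IA)
  S_ml <- Ssub * (n - 1) / n
  ll <- function(Sig) {
    -n / 2 * (log(det(Sig)) + sum(diag(S_ml %*% solve(Sig))) +
                p * log(2 * pi))
  }
  n_par <- 6L + length(est$a_model) + length(est$y_model) + 2L
  df_model <- p * (p + 1L) / 2L - n_par
  df_base <- p * (p + 1L) / 2L - p
  fit_indices(loglik_model = ll(Sigma), loglik_saturated = ll(S_ml),
              loglik_baseline = ll(diag(diag(S_ml), p)),
              df_model = df_model, df_baseline = df_base, n = n)
}

#' Nonparametric case-resampling bootstrap
#'
#' Resamples rows with replacement and recomputes a statistic; deterministic
#' given the seed. A resample on which the statistic fails is redrawn (the
#' number of redraws is recorded).
#'
#' @param data Matrix or data frame of cases (rows).
#' @param statistic Function of a resampled data object returning a numeric
#'   vector.
#' @param n_boot Number of bootstrap replications.
#' @param seed RNG seed.
#' @return List of class `drp_boot`: `dist` (n_boot x k matrix), `se`
#'   (bootstrap SD per component; `NA` with a flag when `n_boot = 1`),
#'   percentile `ci_lo`/`ci_hi` (2.5/97.5%), and `n_failed`.
#' @export
bootstrap_stat <- function(data, statistic, n_boot = 5000, seed = 1) {
  if (n_boot < 1) stop("n_boot must be >= 1")
  set.seed(as.integer(seed))
  n <- nrow(data)
  first <- statistic(data)
  k <- length(first)
  dist <- matrix(NA_real_, n_boot, k)
  colnames(dist) <- names(first)
  n_failed <- 0L
  for (bindex in seq_len(n_boot)) {
    repeat {
      idx <- sample.int(n, n, replace = TRUE)
      val <- tryCatch(statistic(data[idx, , drop = FALSE]),
                      error = function(e) NULL)
      if (!is.null(val) && all(is.finite(val))) break
      n_failed <- n_failed + 1L
      if (n_failed > 100L + 10L * n_boot) {
        stop("bootstrap statistic failed on too many resamples")
      }
    }
    dist[bindex, ] <- val
  }
  se <- if (n_boot >= 2) apply(dist, 2, stats::sd) else
    stats::setNames(rep(NA_real_, k), colnames(dist))
  structure(list(
    dist = dist, se = se,
    ci_lo = apply(dist, 2, stats::quantile, 0.025, names = FALSE),
    ci_hi = apply(dist, 2, stats::quantile, 0.975, names = FALSE),
    n_failed = n_failed,
    se_undefined = n_boot < 2
  ), class = "drp_boot")
}

#' Chi-square fit indices for a path model
#'
#' Computes the model chi-square `2 * (loglik_saturated - loglik_model)`,
#' the comparative fit index
#' `CFI = 1 - max(chisq_m - df_m, 0) / max(chisq_b - df_b, chisq_m - df_m, 0)`,
#' and `RMSEA = sqrt(max(chisq_m - df_m, 0) / (df_m * n))` with a 90%
#' confidence interval obtained by inverting the noncentral chi-square
#' distribution. A model with `df_model = 0` is reported as saturated with
#' RMSEA 0.
#'
#' @param loglik_model,loglik_saturated,loglik_baseline Log-likelihoods of
#'   the fitted, saturated and independence models on the same data.
#' @param df_model,df_baseline Model degrees of freedom.
#' @param n Sample size.
#' @return Named list: `chisq`, `df`, `cfi`, `rmsea`, `rmsea_ci` (90%),
#'   `saturated` flag.
#' @export
fit_indices <- function(loglik_model, loglik_saturated, loglik_baseline,
                        df_model, df_baseline, n) {
  chisq_m <- 2 * (loglik_saturated - loglik_model)
  chisq_b <- 2 * (loglik_saturated - loglik_baseline)
  num <- max(chisq_m - df_model, 0)
  den <- max(chisq_b - df_baseline, chisq_m - df_model, 0)
  cfi <- if (den <= 0) 1 else 1 - num / den
  if (df_model == 0) {
    return(list(chisq = chisq_m, df = df_model, cfi = cfi, rmsea = 0,
                rmsea_ci = c(0, 0), saturated = TRUE))
  }
  rmsea <- sqrt(num / (df_model * n))
  ncp_bound <- function(target) {
    # largest ncp with P(X2_{df,ncp} <= chisq) >= target (0 when none)
    f <- function(l) stats::pchisq(chisq_m, df_model, ncp = l) - target
    if (f(0) < 0) return(0)
    hi <- 1
    while (f(hi) > 0 && hi < 1e6) hi <- hi * 2
    stats::uniroot(f, c(0, hi))$root
  }
  lam_lo <- ncp_bound(0.95)
  lam_hi <- ncp_bound(0.05)
  list(chisq = chisq_m, df = df_model, cfi = cfi, rmsea = rmsea,
       rmsea_ci = c(sqrt(lam_lo / (df_model * n)),
                    sqrt(lam_hi / (df_model * n))),
       saturated = FALSE)
}

#' EM estimation of multivariate-normal moments with missing data
#'
#' Expectation-maximisation for the mean vector and covariance matrix of a
#' multivariate normal under arbitrary (assumed ignorable) missingness
#' patterns. With no missing data the estimates equal the sample moments
#' (maximum-likelihood denominator `n`). Path/regression coefficients
#' derived from the estimated covariance reproduce complete-case
#' coefficients when nothing is missing.
#'
#' @param data Numeric matrix or data frame (rows = cases). Rows that are
#'   entirely missing are dropped; a column with no observed values is an
#'   error.
#' @param max_iter,tol Convergence controls (max absolute parameter change).
#' @return List: `mu`, `sigma`, `n`, `iterations`, `converged`.
#' @export
em_normal_estimates <- function(data, max_iter = 1000, tol = 1e-7) {
  Y <- as.matrix(data)
  storage.mode(Y) <- "double"
  Y <- Y[rowSums(!is.na(Y)) > 0, , drop = FALSE]
  n <- nrow(Y)
  p <- ncol(Y)
  if (n < p + 1) stop("too few cases for EM estimation")
  all_missing <- colSums(!is.na(Y)) == 0
  if (any(all_missing)) {
    stop("variable(s) with no observed values: ",
         paste(colnames(Y)[all_missing], collapse = ", "))
  }
  mu <- colMeans(Y, na.rm = TRUE)
  Sigma <- stats::cov(Y, use = "pairwise.complete.obs")
  Sigma[is.na(Sigma)] <- 0
  diag(Sigma)[diag(Sigma) <= 0] <- 1
  ev <- eigen(Sigma, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < 1e-8) Sigma <- Sigma + diag(1e-4 - min(ev, 0), p)

  pat_key <- apply(is.na(Y), 1, function(r) paste(as.integer(r), collapse = ""))
  pats <- split(seq_len(n), pat_key)
  trace <- numeric(0)
  for (it in seq_len(max_iter)) {
    T1 <- numeric(p)
    T2 <- matrix(0, p, p)
    for (rows in pats) {
      miss <- is.na(Y[rows[1], ])
      Yo <- Y[rows, !miss, drop = FALSE]
      if (!any(miss)) {
        T1 <- T1 + colSums(Yo)
        T2 <- T2 + crossprod(Yo)
        next
      }
      Soo <- Sigma[!miss, !miss, drop = FALSE]
      Smo <- Sigma[miss, !miss, drop = FALSE]
      B <- Smo %*% solve(Soo)
      cond_cov <- Sigma[miss, miss, drop = FALSE] - B %*% t(Smo)
      Em <- matrix(mu[miss], nrow(Yo), sum(miss), byrow = TRUE) +
        t(B %*% (t(Yo) - mu[!miss]))
      Efull <- matrix(0, nrow(Yo), p)
      Efull[, !miss] <- Yo
      Efull[, miss] <- Em
      T1 <- T1 + colSums(Efull)
      XtX <- crossprod(Efull)
      XtX[miss, miss] <- XtX[miss, miss] + nrow(Yo) * cond_cov
      T2 <- T2 + XtX
    }
    mu_new <- T1 / n
    Sigma_new <- T2 / n - tcrossprod(mu_new)
    delta <- max(abs(c(mu_new - mu, Sigma_new - Sigma)))
    mu <- mu_new
    Sigma <- Sigma_new
    trace <- c(trace, delta)
    if (delta < tol) {
      return(list(mu = mu, sigma = Sigma, n = n, iterations = it,
                  converged = TRUE))
    }
  }
  stop("EM did not converge within ", max_iter,
       " iterations; last parameter changes: ",
       paste(signif(utils::tail(trace, 3), 3), collapse = ", "))
}

#' @export
print.drp_mediation <- function(x, ...) {
  cat("Baseline-adjusted mediation model (", x$missing, ", ",
      x$covariate_set, " covariates)\n", sep = "")
  cat("  n used:", x$n_used, "\n")
  est <- x$paths
  lab <- c(a = "a (X -> M)", b = "b (M -> Y)", cprime = "c' (direct)",
           c = "c (total)", indirect = "indirect (a*b)",
           prop_mediated = "% mediated")
  for (nm in names(est)) {
    cat(sprintf("  %-16s %8.4f  [%.4f, %.4f]  (boot SE %.4f)\n",
                lab[[nm]], est[[nm]], x$boot$ci_lo[[nm]], x$boot$ci_hi[[nm]],
                x$boot$se[[nm]]))
  }
  if (isTRUE(x$inconsistent_mediation)) {
    cat("  note: inconsistent mediation (a*b opposes the direct effect);\n",
        "  the proportion mediated is not interpretable as a share.\n")
  }
  fi <- x$fit_indices
  if (is.na(fi$chisq)) {
    cat("  fit:", if (!is.null(fi$note)) fi$note else "unavailable", "\n")
  } else {
    cat(sprintf("  fit: chisq(%d) = %.3f, CFI = %.3f, RMSEA = %.3f [%.3f, %.3f]\n",
                fi$df, fi$chisq, fi$cfi, fi$rmsea, fi$rmsea_ci[1],
                fi$rmsea_ci[2]))
  }
  invisible(x)
}

#' @export
summary.drp_mediation <- function(object, ...) {
  print(object)
  invisible(object)
}

#' @export
coef.drp_mediation <- function(object, ...) object$paths
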