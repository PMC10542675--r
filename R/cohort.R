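# Panel assembly: exposure counting, study timing, analysis-sample filters.
#
# Calendar convention: `wave_month` is a whole-month index with 0 = the first
# study month (October 2019); the annual follow-up surveys fall at months 12,
# 24 and 36 (each October). Months in study are whole-month differences.

#' Derive exposure counts and study time for a wave table
#'
#' Orders each participant's completed waves, counts Dementia Risk Profile
#' report exposures and computes study time. The personalised report is seen
#' immediately *after* completing each survey, so the exposure count at a row
#' is the number of completed waves strictly before it: a participant with
#' baseline plus only the final annual survey has one exposure at that final
#' row; baseline plus three annual surveys gives three exposures at the last
#' row. The baseline row has zero exposures. `months_in_study` is months
#' since baseline (0 at baseline) and `log_time = log(months_in_study + 1)`
#' (natural log).
#'
#' Participants whose earliest record is not a baseline wave are dropped with
#' a warning (follow-up without baseline).
#'
#' @param waves Data frame with at least `id`, `wave` (label, `"BL"` for
#'   baseline) and `wave_month` columns, one row per completed
#'   participant-wave.
#' @return The input with `months_in_study`, `log_time` and
#'   `n_drp_exposures` appended, ordered by participant and wave month.
#' @export
derive_exposures <- function(waves) {
  need <- c("id", "wave", "wave_month")
  missing_cols <- setdiff(need, names(waves))
  if (length(missing_cols)) {
    stop("wave table is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  waves <- waves[order(waves$id, waves$wave_month), , drop = FALSE]
  first_idx <- !duplicated(waves$id)
  no_bl <- unique(waves$id[first_idx][waves$wave[first_idx] != "BL"])
  if (length(no_bl)) {
    warning(length(no_bl), " participant(s) had follow-up data without a ",
            "baseline wave and were excluded")
    waves <- waves[!waves$id %in% no_bl, , drop = FALSE]
  }
  ord <- stats::ave(seq_along(waves$id), waves$id, FUN = seq_along)
  bl_month <- stats::ave(waves$wave_month, waves$id, FUN = function(m) m[1])
  waves$months_in_study <- waves$wave_month - bl_month
  waves$log_time <- log(waves$months_in_study + 1)
  waves$n_drp_exposures <- ord - 1L
  rownames(waves) <- NULL
  waves
}

#' Apply the analysis-sample filters
#'
#' Retains participants matching the analysis-sample definition: baseline
#' completed inside the enrolment window, at least one follow-up survey, and
#' (by default) no pre-study engagement with the dementia-prevention online
#' course. Pre-study enrollees can instead be retained with `pdmooc = 1`
#' fixed from baseline via `keep_pre_enrollees = TRUE`.
#'
#' Rows whose DRP total is undefined (any unknown domain) are additionally
#' removed from the continuous-outcome model panel; domain-level categorical
#' analyses still use those rows' known domains, so they stay in `panel`.
#'
#' @param panel Panel from [derive_exposures()]; needs `id`, `wave`,
#'   `wave_month` and (for the model panel) `drp_total`. A `pdmooc_pre`
#'   column (0/1, engaged before joining) drives the pre-enrollee filter if
#'   present.
#' @param baseline_window Length-2 numeric: first/last admissible baseline
#'   `wave_month` (default months 0-32, i.e. October 2019 to June 2022).
#' @param keep_pre_enrollees Retain pre-study course enrollees (as exposed
#'   from baseline) instead of excluding them.
#' @return List of class `drp_filter_result`: `panel` (retained rows),
#'   `model_panel` (retained rows with a defined DRP total, if `drp_total`
#'   present), and `exclusions` (data frame of reason x rows excluded;
#'   each excluded row is counted under exactly one reason).
#' @export
apply_analysis_filters <- function(panel, baseline_window = c(0, 32),
                                   keep_pre_enrollees = FALSE) {
  n_in <- nrow(panel)
  excl <- c(pre_study_pdmooc = 0L, baseline_outside_window = 0L,
            no_followup = 0L)
  if (!is.null(panel$pdmooc_pre) && !keep_pre_enrollees) {
    drop <- panel$id %in% unique(panel$id[panel$pdmooc_pre == 1])
    excl["pre_study_pdmooc"] <- sum(drop)
    panel <- panel[!drop, , drop = FALSE]
  } else if (!is.null(panel$pdmooc_pre) && keep_pre_enrollees &&
             !is.null(panel$pdmooc)) {
    pre_ids <- unique(panel$id[panel$pdmooc_pre == 1])
    panel$pdmooc[panel$id %in% pre_ids] <- 1L
  }
  is_bl <- panel$wave == "BL"
  bl_ok <- panel$id %in%
    panel$id[is_bl & panel$wave_month >= baseline_window[1] &
               panel$wave_month <= baseline_window[2]]
  excl["baseline_outside_window"] <- sum(!bl_ok)
  panel <- panel[bl_ok, , drop = FALSE]
  has_fu <- panel$id %in% panel$id[panel$wave != "BL"]
  excl["no_followup"] <- sum(!has_fu)
  panel <- panel[has_fu, , drop = FALSE]

  model_panel <- panel
  if (!is.null(panel$drp_total)) {
    model_panel <- panel[!is.na(panel$drp_total), , drop = FALSE]
  }
  stopifnot(n_in == nrow(panel) + sum(excl))
  structure(list(
    panel = panel,
    model_panel = model_panel,
    exclusions = data.frame(reason = names(excl), n_rows = unname(excl))
  ), class = "drp_filter_result")
}

#' @export
print.drp_filter_result <- function(x, ...) {
  cat("Analysis-sample filter\n")
  cat("  retained rows:       ", nrow(x$panel), "\n")
  cat("  model-input rows:    ", nrow(x$model_panel), "\n")
  for (i in seq_len(nrow(x$exclusions))) {
    cat(sprintf("  excluded (%s): %d\n", x$exclusions$reason[i],
                x$exclusions$n_rows[i]))
  }
  invisible(x)
}
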