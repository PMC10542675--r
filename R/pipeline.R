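# End-to-end deterministic pipeline: simulate -> score -> assemble -> fit ->
# transitions -> mediate -> report, with a JSON manifest of stage outputs.

#' Run the analysis pipeline
#'
#' Chains the package stages over a synthetic cohort and writes each stage's
#' outputs plus a manifest (`manifest.json` with input seed, config hash,
#' package version and an md5 checksum per output file) to `out_dir`. All
#' randomness derives from `seed`, so a rerun with the same configuration
#' and seed is byte-identical.
#'
#' @param stage One of `"simulate"`, `"score"`, `"assemble"`, `"fit"`,
#'   `"transitions"`, `"mediate"`, `"report"`, `"all"`. Stages other than
#'   `"all"` expect the outputs of the preceding stages in `out_dir`.
#' @param config A [sim_config()] object (or path to a YAML config).
#' @param seed Integer seed propagated to every stochastic stage.
#' @param out_dir Output directory (created if needed).
#' @param n_boot Bootstrap replications for the mediation stage.
#' @param n_reports Number of participant reports to render.
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(stage = "all", config = sim_config(), seed = 1,
                         out_dir = "drp-run", n_boot = 5000, n_reports = 3) {
  stages <- c("simulate", "score", "assemble", "fit", "transitions",
              "mediate", "report")
  stage <- match.arg(stage, c(stages, "all"))
  todo <- if (stage == "all") stages else stage
  if (is.character(config)) config <- sim_config_from_yaml(config)
  stopifnot(inherits(config, "sim_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  path <- function(f) file.path(out_dir, f)
  outputs <- character(0)
  emit_csv <- function(df, f) {
    utils::write.csv(df, path(f), row.names = FALSE)
    outputs <<- c(outputs, f)
  }
  emit_json <- function(x, f) {
    jsonlite::write_json(x, path(f), auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    outputs <<- c(outputs, f)
  }

  if ("simulate" %in% todo) {
    sim <- simulate_cohort(config, seed)
    waves <- inject_missingness(sim$waves, config, seed + 1L)
    emit_csv(waves, "waves.csv")
    emit_json(sim$truth$coefficients, "truth-coefficients.json")
  }
  if ("score" %in% todo) {
    waves <- utils::read.csv(path("waves.csv"), stringsAsFactors = FALSE)
    scored <- score_waves(waves)
    emit_csv(scored, "scored.csv")
  }
  if ("assemble" %in% todo) {
    scored <- utils::read.csv(path("scored.csv"), stringsAsFactors = FALSE)
    panel <- derive_exposures(scored)
    filt <- apply_analysis_filters(panel)
    emit_csv(filt$panel, "panel.csv")
    emit_csv(filt$model_panel, "model-panel.csv")
    emit_json(filt$exclusions, "exclusions.json")
  }
  if ("fit" %in% todo) {
    mp <- utils::read.csv(path("model-panel.csv"), stringsAsFactors = FALSE)
    omnibus <- fit_trajectory(mp)
    adjusted <- fit_trajectory(mp, pdmooc = TRUE, interaction = TRUE,
                               covariates = c("age", "gender", "education",
                                              "marital", "irsad_decile"))
    both <- rbind(cbind(model = "omnibus", omnibus$coefficients),
                  cbind(model = "adjusted", adjusted$coefficients))
    emit_csv(both, "trajectory-coefficients.csv")
    emit_json(list(
      omnibus_r2 = as.list(omnibus$r2), adjusted_r2 = as.list(adjusted$r2),
      omnibus_varcomp = as.list(omnibus$varcomp),
      adjusted_varcomp = as.list(adjusted$varcomp)
    ), "trajectory-fit.json")
  }
  if ("transitions" %in% todo) {
    panel <- utils::read.csv(path("panel.csv"), stringsAsFactors = FALSE)
    tr <- transition_table(panel)
    emit_csv(tr, "transitions.csv")
  }
  if ("mediate" %in% todo) {
    panel <- utils::read.csv(path("panel.csv"), stringsAsFactors = FALSE)
    med_dat <- mediation_dataset(panel)
    med <- fit_mediation(med_dat, x = "pdmooc", m = "m_fu", y = "y_fu",
                         m_baseline = "m_bl", y_baseline = "y_bl",
                         n_boot = n_boot, seed = seed)
    emit_json(list(
      n_used = med$n_used, paths = as.list(med$paths),
      boot_se = as.list(med$boot$se),
      ci_lo = as.list(med$boot$ci_lo), ci_hi = as.list(med$boot$ci_hi),
      inconsistent_mediation = med$inconsistent_mediation,
      fit = med$fit_indices[c("chisq", "df", "cfi", "rmsea")],
      rmsea_ci = med$fit_indices$rmsea_ci
    ), "mediation.json")
  }
  if ("report" %in% todo) {
    panel <- utils::read.csv(path("panel.csv"), stringsAsFactors = FALSE)
    ids <- utils::head(unique(panel$id), n_reports)
    tmpl <- report_template()
    for (pid in ids) {
      hist <- panel[panel$id == pid, , drop = FALSE]
      hist <- hist[order(hist$wave_month), , drop = FALSE]
      doc <- render_report(hist, template = tmpl, participant_id = pid)
      f <- paste0("report-", pid, ".md")
      writeLines(unclass(doc), path(f))
      outputs <- c(outputs, f)
    }
  }

  cfg_yaml <- yaml::as.yaml(lapply(unclass(config), function(x)
    if (is.numeric(x)) unclass(x) else x))
  cfg_file <- tempfile(fileext = ".yaml")
  writeLines(cfg_yaml, cfg_file)
  manifest <- list(
    seed = as.integer(seed),
    stage = stage,
    config_md5 = unname(tools::md5sum(cfg_file)),
    package_version = as.character(utils::packageVersion("drprofile")),
    outputs = lapply(stats::setNames(outputs, outputs), function(f)
      unname(tools::md5sum(path(f))))
  )
  unlink(cfg_file)
  jsonlite::write_json(manifest, path("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(manifest)
}

#' Baseline-to-final risk transitions for every domain
#'
#' Pairs each participant's baseline and final-wave (default the last
#' scheduled wave) risk levels per domain and fits [fit_transitions()] for
#' each, adjusted for gender, age, socioeconomic decile and education.
#'
#' @param panel Scored panel with `id`, `wave`, `risk_*` and demographic
#'   columns.
#' @param final_wave Wave label used as "final"; participants without it are
#'   omitted unless `use_last_available = TRUE`.
#' @param use_last_available Use each participant's last completed wave when
#'   the final wave is missing.
#' @param covariates Covariate column names (default gender, age,
#'   irsad_decile, education); `NULL` for unadjusted models.
#' @return Data frame of odds ratios per domain (domains whose model cannot
#'   be fitted are reported with a `note`).
#' @export
transition_table <- function(panel, final_wave = "Oct-22",
                             use_last_available = FALSE,
                             covariates = c("gender", "age", "irsad_decile",
                                            "education")) {
  bl <- panel[panel$wave == "BL", , drop = FALSE]
  if (use_last_available) {
    fu <- panel[panel$wave != "BL", , drop = FALSE]
    fu <- fu[order(fu$id, fu$wave_month), , drop = FALSE]
    fin <- fu[!duplicated(fu$id, fromLast = TRUE), , drop = FALSE]
  } else {
    fin <- panel[panel$wave == final_wave, , drop = FALSE]
  }
  ids <- intersect(bl$id, fin$id)
  bl <- bl[match(ids, bl$id), , drop = FALSE]
  fin <- fin[match(ids, fin$id), , drop = FALSE]
  cov_df <- if (is.null(covariates)) NULL else bl[, covariates, drop = FALSE]
  out <- list()
  for (dom in drp_domains()) {
    col <- paste0("risk_", dom)
    res <- tryCatch({
      tr <- fit_transitions(bl[[col]], fin[[col]], covariates = cov_df)
      cbind(domain = dom, tr$or_table, n = tr$n, note = "")
    }, error = function(e) {
      data.frame(domain = dom, outcome_level = NA, term = NA, or = NA,
                 or_lo = NA, or_hi = NA, n = NA, note = conditionMessage(e))
    })
    out[[dom]] <- res
  }
  do.call(rbind, c(out, make.row.names = FALSE))
}

#' Assemble the mediation analysis dataset from a panel
#'
#' One row per participant: exposure (course engagement), mediator
#' (misconception-discernment knowledge score) at baseline and final wave,
#' outcome (DRP total) at baseline and final wave.
#'
#' @param panel Scored panel with `id`, `wave`, `pdmooc`,
#'   `koderr_misconception` and `drp_total`.
#' @param final_wave Label of the follow-up wave used as the outcome wave.
#' @return Data frame with columns `id`, `pdmooc`, `m_bl`, `m_fu`, `y_bl`,
#'   `y_fu`.
#' @export
mediation_dataset <- function(panel, final_wave = "Oct-22") {
  bl <- panel[panel$wave == "BL", , drop = FALSE]
  fin <- panel[panel$wave == final_wave, , drop = FALSE]
  ids <- intersect(bl$id, fin$id)
  bl <- bl[match(ids, bl$id), , drop = FALSE]
  fin <- fin[match(ids, fin$id), , drop = FALSE]
  data.frame(id = ids, pdmooc = bl$pdmooc,
             m_bl = bl$koderr_misconception, m_fu = fin$koderr_misconception,
             y_bl = bl$drp_total, y_fu = fin$drp_total)
}
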