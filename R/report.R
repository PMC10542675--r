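# Personalised traffic-light risk report rendering.

#' Load a report template
#'
#' Templates are YAML with a `colours` map (risk level -> colour), a
#' `recommendations` map (domain -> level -> text, required for every
#' non-low level a domain can take) and an `unknown_text` entry used when a
#' domain could not be scored. The shipped template seeds recommendations
#' from standard risk-reduction advice (limit drinking to under two standard
#' drinks a day, do not smoke, 150 minutes of moderate activity per week,
#' Mediterranean-style diet, healthy BMI, medical management of
#' cardiometabolic conditions, regular cognitively stimulating activity).
#'
#' @param path YAML file; default is the template shipped with the package.
#' @return Template list.
#' @export
report_template <- function(path = system.file("extdata",
                                               "report-template.yaml",
                                               package = "drprofile")) {
  yaml::read_yaml(path)
}

#' Render a traffic-light risk profile report
#'
#' Produces a deterministic markdown document for one participant: the nine
#' domains with their current level and colour (low = green, medium =
#' orange, high = red, unknown = grey), a recommendation for every non-low
#' domain drawn from the template, and the wave-by-wave trace of the DRP
#' total.
#'
#' @param profile_history Data frame with one row per scored wave for one
#'   participant: `wave`, the nine `risk_*` columns and `drp_total`.
#' @param template Template list from [report_template()].
#' @param participant_id Identifier printed in the heading.
#' @param timestamp Optional timestamp string; omitted from the document
#'   when `NULL` so rendering stays byte-reproducible.
#' @return A single markdown string (class `drp_report`).
#' @export
render_report <- function(profile_history, template = report_template(),
                          participant_id = "participant",
                          timestamp = NULL) {
  if (nrow(profile_history) < 1) stop("need at least one scored wave")
  cols <- paste0("risk_", drp_domains())
  miss <- setdiff(c(cols, "wave", "drp_total"), names(profile_history))
  if (length(miss)) {
    stop("profile history is missing columns: ", paste(miss, collapse = ", "))
  }
  latest <- profile_history[nrow(profile_history), ]
  colour <- template$colours
  lines <- c(
    paste0("# Dementia Risk Profile: ", participant_id),
    if (!is.null(timestamp)) paste0("Generated: ", timestamp),
    "",
    paste0("Current wave: ", latest$wave),
    "",
    "| Domain | Risk level | Colour |",
    "|---|---|---|"
  )
  recs <- character(0)
  for (dom in drp_domains()) {
    lv <- latest[[paste0("risk_", dom)]]
    col <- colour[[lv]]
    if (is.null(col)) stop("template has no colour for level '", lv, "'")
    lines <- c(lines, sprintf("| %s | %s | %s |", gsub("_", " ", dom), lv, col))
    if (lv == "low") next
    txt <- if (lv == "unknown") template$unknown_text else
      template$recommendations[[dom]][[lv]]
    if (is.null(txt)) {
      stop("template has no recommendation for (", dom, ", ", lv, ")")
    }
    recs <- c(recs, paste0("- **", gsub("_", " ", dom), "** (", lv, "): ", txt))
  }
  lines <- c(lines, "", "## Recommendations", "",
             if (length(recs)) recs else "- All domains are low risk. Keep it up!")
  lines <- c(lines, "", "## Your DRP total over time", "")
  for (i in seq_len(nrow(profile_history))) {
    tot <- profile_history$drp_total[i]
    lines <- c(lines, sprintf("- %s: %s", profile_history$wave[i],
                              ifelse(is.na(tot), "not computable (missing data)",
                                     format(tot, nsmall = 1))))
  }
  structure(paste(lines, collapse = "\n"), class = "drp_report")
}

#' @export
print.drp_report <- function(x, ...) {
  cat(unclass(x), "\n")
  invisible(x)
}
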