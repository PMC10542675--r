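# Knowledge (KoDeRR) and motivation (MCHLB-DRR) instrument scoring.
#
# Item structure is configuration, not code: the published material gives
# subscale score ranges but not item lists, so defaults are chosen to attain
# exactly those ranges and can be overridden via a config list (or YAML read
# with yaml::read_yaml()).

#' Default KoDeRR configuration
#'
#' Three knowledge subscales scored as counts of correct responses:
#' general knowledge (22 items, range 0-22), strategy knowledge (20 items,
#' 0-20), misconception discernment (12 items, 0-12).
#'
#' @return Named list: subscale -> number of items.
#' @export
koderr_config <- function() {
  list(general_knowledge = 22L, strategy_knowledge = 20L,
       misconception_discernment = 12L)
}

#' Score the KoDeRR knowledge instrument
#'
#' Each subscale is the count of responses matching the answer key. Missing
#' responses score 0 and set the subscale's missingness flag.
#'
#' @param item_responses Named list: subscale -> vector of responses.
#' @param answer_key Named list: subscale -> vector of correct answers, same
#'   lengths as the responses and as the configured item counts.
#' @param config Subscale item counts, see [koderr_config()].
#' @return List with integer `scores`, logical `incomplete` flags per
#'   subscale, class `koderr_scores`.
#' @examples
#' key <- lapply(koderr_config(), function(k) rep("T", k))
#' score_koderr(key, key)$scores["misconception_discernment"] # 12
#' @export
score_koderr <- function(item_responses, answer_key, config = koderr_config()) {
  scales <- names(config)
  if (!all(scales %in% names(item_responses)) ||
      !all(scales %in% names(answer_key))) {
    stop("responses and key must both contain subscales: ",
         paste(scales, collapse = ", "))
  }
  scores <- integer(0)
  incomplete <- logical(0)
  for (s in scales) {
    resp <- item_responses[[s]]
    key <- answer_key[[s]]
    if (length(key) != config[[s]]) {
      stop("answer key for ", s, " has ", length(key),
           " items; configured for ", config[[s]])
    }
    if (length(resp) != config[[s]]) {
      stop("responses for ", s, " have ", length(resp),
           " items; configured for ", config[[s]])
    }
    scores[s] <- sum(!is.na(resp) & resp == key)
    incomplete[s] <- anyNA(resp)
  }
  structure(list(scores = scores, incomplete = incomplete),
            class = "koderr_scores")
}

#' Default MCHLB-DRR configuration
#'
#' Seven Health-Beliefs-Model dimensions, each summed over Likert items.
#' Defaults honour the published score ranges: susceptibility 5 items on 1-4
#' (5-20); severity 6 items, five on 1-4 and one on 1-5 (6-25); benefits,
#' barriers, cues to action and general health motivation 5 items on 1-4
#' (5-20); self-efficacy 2 items on 1-5 (2-10).
#'
#' @return Named list: dimension -> list(min = per-item minima, max = per-item
#'   maxima).
#' @export
mchlb_config <- function() {
  four <- list(min = rep(1L, 5), max = rep(4L, 5))
  list(
    susceptibility = four,
    severity = list(min = rep(1L, 6), max = c(rep(4L, 5), 5L)),
    benefits = four,
    barriers = four,
    cues_to_action = four,
    self_efficacy = list(min = rep(1L, 2), max = rep(5L, 2)),
    general_health_motivation = four
  )
}

#' Score the MCHLB-DRR motivation instrument
#'
#' Each dimension is the sum of its item responses, clamped to the published
#' range. Higher scores indicate a stronger standing on the construct
#' (barriers are inverted in interpretation only, not in scoring). A
#' dimension with any missing item gets an `NA` score and an incomplete flag
#' rather than a prorated value.
#'
#' @param item_responses Named list: dimension -> numeric responses.
#' @param config Item structure, see [mchlb_config()].
#' @return List with numeric `scores` and logical `incomplete` per dimension,
#'   class `mchlb_scores`.
#' @export
score_mchlb <- function(item_responses, config = mchlb_config()) {
  dims <- names(config)
  if (!all(dims %in% names(item_responses))) {
    stop("responses must contain dimensions: ", paste(dims, collapse = ", "))
  }
  scores <- numeric(0)
  incomplete <- logical(0)
  for (d in dims) {
    resp <- item_responses[[d]]
    lo <- config[[d]]$min
    hi <- config[[d]]$max
    if (length(resp) != length(lo)) {
      stop("responses for ", d, " have ", length(resp),
           " items; configured for ", length(lo))
    }
    out_of_scale <- !is.na(resp) & (resp < lo | resp > hi)
    if (any(out_of_scale)) {
      stop("response outside the configured scale for dimension ", d)
    }
    if (anyNA(resp)) {
      scores[d] <- NA_real_
      incomplete[d] <- TRUE
    } else {
      scores[d] <- min(max(sum(resp), sum(lo)), sum(hi))
      incomplete[d] <- FALSE
    }
  }
  structure(list(scores = scores, incomplete = incomplete),
            class = "mchlb_scores")
}

#' @export
print.koderr_scores <- function(x, ...) {
  cat("KoDeRR knowledge scores\n")
  for (s in names(x$scores)) {
    cat(sprintf("  %-26s %d%s\n", s, x$scores[[s]],
                if (x$incomplete[[s]]) " (incomplete)" else ""))
  }
  invisible(x)
}

#' @export
print.mchlb_scores <- function(x, ...) {
  cat("MCHLB-DRR motivation scores\n")
  for (s in names(x$scores)) {
    cat(sprintf("  %-26s %s%s\n", s,
                ifelse(is.na(x$scores[[s]]), "NA", x$scores[[s]]),
                if (x$incomplete[[s]]) " (incomplete)" else ""))
  }
  invisible(x)
}
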