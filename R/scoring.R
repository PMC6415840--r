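#' Reconcile dual-rater responses to one question
#'
#' Each question is answered twice: from the caregiver interview (parent)
#' and from the investigator's direct observation.  Reconciliation
#' follows the instrument's administration rules:
#'
#' * both raters agree — that response stands (including both "unsure");
#' * exactly one rater is unsure — the definite response stands
#'   (precedence is not invoked);
#' * a definite "yes" vs "no" disagreement — the response of the rater
#'   named by the question's `precedence` stands.
#'
#' "unsure" is therefore recorded only when both raters are unsure.
#'
#' @param parent,investigator character vectors of responses
#'   ("yes", "no" or "unsure"; case-insensitive), recycled to a common
#'   length.
#' @param precedence per-question precedence, "parent" or "investigator".
#' @return character vector of reconciled final responses.
#' @export
#' @examples
#' reconcile_answer("yes", "no", "investigator")  # "no"
#' reconcile_answer("unsure", "no", "parent")     # "no"
reconcile_answer <- function(parent, investigator, precedence) {
  n <- max(length(parent), length(investigator), length(precedence))
  parent <- rep_len(tolower(as.character(parent)), n)
  investigator <- rep_len(tolower(as.character(investigator)), n)
  precedence <- rep_len(tolower(as.character(precedence)), n)

  bad <- !(parent %in% RESPONSE_LEVELS) | !(investigator %in% RESPONSE_LEVELS)
  if (any(bad))
    stop_usage("responses must be one of %s; got: %s",
               paste(RESPONSE_LEVELS, collapse = "/"),
               paste(unique(c(parent[bad], investigator[bad])), collapse = ", "))
  if (!all(precedence %in% c("parent", "investigator")))
    stop_usage("precedence must be 'parent' or 'investigator'")

  final <- parent
  one_unsure_p <- parent == "unsure" & investigator != "unsure"
  final[one_unsure_p] <- investigator[one_unsure_p]
  # investigator unsure, parent definite: parent already in `final`
  conflict <- parent != "unsure" & investigator != "unsure" & parent != investigator
  final[conflict & precedence == "investigator"] <-
    investigator[conflict & precedence == "investigator"]
  # conflict with parent precedence: parent already in `final`
  final
}

#' Flag an answer as abnormal
#'
#' A reconciled response is abnormal when it equals the question's
#' abnormal-response polarity.  "unsure" is never abnormal and
#' contributes nothing to the total score.
#'
#' @param final_response reconciled response(s) ("yes"/"no"/"unsure").
#' @param abnormal_response the question's abnormal polarity ("yes"/"no").
#' @return logical vector.
#' @export
flag_abnormal <- function(final_response, abnormal_response) {
  tolower(as.character(final_response)) == tolower(as.character(abnormal_response))
}

#' Score one subdomain
#'
#' A subdomain is abnormal when at least `abnormal_min_count` of its
#' questions are abnormal (default threshold 1: any abnormal question
#' flags the subdomain).
#'
#' @param abnormal_flags logical vector, one element per question of the
#'   subdomain; must be complete (no `NA`).
#' @param abnormal_min_count threshold in `[1, length(abnormal_flags)]`.
#' @return list with `abnormal_count` and `is_abnormal`.
#' @export
score_subdomain <- function(abnormal_flags, abnormal_min_count = 1L) {
  if (anyNA(abnormal_flags))
    stop_usage("subdomain answers incomplete: missing abnormality flag(s)")
  if (abnormal_min_count < 1L || abnormal_min_count > length(abnormal_flags))
    stop_usage("abnormal_min_count must be in [1, %d]", length(abnormal_flags))
  cnt <- sum(abnormal_flags)
  list(abnormal_count = as.integer(cnt),
       is_abnormal = cnt >= abnormal_min_count)
}

#' Total instrument score
#'
#' The number of abnormal responses over the full 28-question answer set;
#' an integer in `[0, 28]`.
#'
#' @param abnormal_flags complete logical vector of per-question
#'   abnormality flags.
#' @param n_questions expected number of questions (28 for the shipped
#'   instrument).
#' @return integer total score.
#' @export
total_score <- function(abnormal_flags, n_questions = 28L) {
  if (length(abnormal_flags) != n_questions || anyNA(abnormal_flags))
    stop_usage("answer set incomplete: expected %d abnormality flags, got %d (%d missing)",
               n_questions, length(abnormal_flags), sum(is.na(abnormal_flags)))
  as.integer(sum(abnormal_flags))
}

#' Apply the diagnostic decision rule
#'
#' A child is called ASD-positive when all three A1 subdomains (A1a, A1b,
#' A1c) are abnormal, at least 2 of the 4 A2 subdomains (A2a-A2d) are
#' abnormal, and both mandatory Section B items (onset in the early
#' developmental period; impairment of daily functioning) are present.
#' `criteria_met_count` counts the satisfied criteria out of 9 (7
#' subdomains + 2 B items); a positive call always has at least 7.
#'
#' @param subdomain_abnormal named logical vector over the seven
#'   subdomain ids `A1a, A1b, A1c, A2a, A2b, A2c, A2d`.
#' @param onset_early_development,functional_impairment logical scalars,
#'   the Section B mandatory items.
#' @return list with `asd_positive`, `criteria_met_count`,
#'   `a1_abnormal_count`, `a2_abnormal_count`.
#' @export
#' @examples
#' sd <- setNames(rep(TRUE, 7), c("A1a","A1b","A1c","A2a","A2b","A2c","A2d"))
#' diagnose(sd, TRUE, TRUE)$asd_positive  # TRUE
diagnose <- function(subdomain_abnormal, onset_early_development,
                     functional_impairment) {
  missing_sd <- setdiff(SUBDOMAIN_IDS, names(subdomain_abnormal))
  if (length(missing_sd) > 0)
    stop_usage("missing subdomain result(s): %s", paste(missing_sd, collapse = ", "))
  sdv <- subdomain_abnormal[SUBDOMAIN_IDS]
  if (anyNA(sdv) || is.na(onset_early_development) || is.na(functional_impairment))
    stop_usage("diagnose: subdomain flags and both Section B items must be non-missing")

  a1 <- sum(sdv[c("A1a", "A1b", "A1c")])
  a2 <- sum(sdv[c("A2a", "A2b", "A2c", "A2d")])
  b <- sum(onset_early_development, functional_impairment)
  positive <- (a1 == 3L) && (a2 >= 2L) && (b == 2L)
  list(
    asd_positive = positive,
    criteria_met_count = as.integer(a1 + a2 + b),
    a1_abnormal_count = as.integer(a1),
    a2_abnormal_count = as.integer(a2)
  )
}

#' Severity band from the total score
#'
#' The validated score cutoffs are >= 10 for ASD, >= 11 for moderate ASD
#' (corresponding to CARS 34-36.5) and >= 14 for severe ASD (CARS >
#' 36.5).  The non-overlapping band labels layered on these cutoffs are a
#' reporting convention of this package: scores below 10 are
#' `below_threshold`, 10 is `asd_mild`, 11-13 `asd_moderate`, 14 and
#' above `asd_severe`.
#'
#' @param total_score integer score(s) in `[0, 28]`.
#' @param cutoffs strictly increasing integer vector of the three score
#'   cutoffs (ASD, moderate, severe).
#' @return character vector of band labels.
#' @export
#' @examples
#' severity_band(c(9, 10, 12, 14))
severity_band <- function(total_score, cutoffs = c(10L, 11L, 14L)) {
  if (length(cutoffs) != 3L || any(diff(cutoffs) <= 0))
    stop_usage("cutoffs must be three strictly increasing scores")
  if (any(is.na(total_score)) || any(total_score < 0 | total_score > 28))
    stop_usage("total_score must be in [0, 28]")
  bands <- c("below_threshold", "asd_mild", "asd_moderate", "asd_severe")
  bands[findInterval(total_score, cutoffs) + 1L]
}

#' Score a cohort of response records
#'
#' Runs the full scoring pipeline per child: reconciles the dual-rater
#' answers, flags abnormal responses, scores the seven subdomains,
#' applies the diagnostic decision rule with the Section B mandatory
#' items, and assigns the total score and severity band.  Records must be
#' complete: every child must answer every instrument question exactly
#' once and have both Section B items; incomplete children are a hard
#' error (the instrument is administered in full).
#'
#' @param responses data frame with columns `child_id`, `question_id`,
#'   `parent_response`, `investigator_response` (long format, one row per
#'   child x question).
#' @param section_b data frame with columns `child_id`,
#'   `onset_early_development`, `functional_impairment` (logical).
#' @param instrument an [indt_instrument]; default the shipped
#'   definition.
#' @param cutoffs severity cutoffs passed to [severity_band()].
#' @return data frame with one row per child: `child_id`, `total_score`,
#'   one logical flag per subdomain (`A1a` ... `A2d`),
#'   `a2_abnormal_count`, `criteria_met_count`, `asd_positive`,
#'   `severity_band`.
#' @export
score_cohort <- function(responses, section_b, instrument = default_instrument(),
                         cutoffs = c(10L, 11L, 14L)) {
  req <- c("child_id", "question_id", "parent_response", "investigator_response")
  if (!all(req %in% names(responses)))
    stop_usage("responses must have columns: %s", paste(req, collapse = ", "))
  reqb <- c("child_id", B_ITEMS)
  if (!all(reqb %in% names(section_b)))
    stop_usage("section_b must have columns: %s", paste(reqb, collapse = ", "))

  q <- instrument$questions
  unknown <- setdiff(unique(responses$question_id), q$question_id)
  if (length(unknown) > 0)
    stop_usage("responses contain question id(s) not in the instrument: %s",
               paste(unknown, collapse = ", "))

  children <- unique(as.character(responses$child_id))
  b_missing <- setdiff(children, as.character(section_b$child_id))
  if (length(b_missing) > 0)
    stop_usage("Section B record missing for child(ren): %s",
               paste(b_missing, collapse = ", "))

  # completeness: every child answers every question exactly once
  tab <- table(factor(as.character(responses$child_id), levels = children),
               factor(responses$question_id, levels = q$question_id))
  bad <- which(tab != 1L, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    msgs <- apply(bad[seq_len(min(5L, nrow(bad))), , drop = FALSE], 1L, function(ij) {
      sprintf("child %s, question %s (%d answer(s))",
              children[ij[1]], q$question_id[ij[2]], tab[ij[1], ij[2]])
    })
    stop_usage("incomplete or duplicated answers: %s%s",
               paste(msgs, collapse = "; "),
               if (nrow(bad) > 5L) sprintf(" ... and %d more", nrow(bad) - 5L) else "")
  }

  qi <- match(responses$question_id, q$question_id)
  final <- reconcile_answer(responses$parent_response,
                            responses$investigator_response,
                            q$precedence[qi])
  abn <- flag_abnormal(final, q$abnormal_response[qi])

  sd_of_q <- q$subdomain_id[qi]
  child_f <- factor(as.character(responses$child_id), levels = children)
  # abnormal counts per child x subdomain
  cnt <- tapply(abn, list(child_f, factor(sd_of_q, levels = SUBDOMAIN_IDS)), sum)
  cnt[is.na(cnt)] <- 0L
  thr <- setNames(instrument$subdomains$abnormal_min_count,
                  instrument$subdomains$subdomain_id)[SUBDOMAIN_IDS]
  flags <- sweep(cnt, 2L, thr, `>=`)

  total <- as.integer(rowSums(cnt))

  bi <- match(children, as.character(section_b$child_id))
  onset <- as.logical(section_b$onset_early_development[bi])
  impair <- as.logical(section_b$functional_impairment[bi])
  if (anyNA(onset) || anyNA(impair))
    stop_usage("Section B items must be TRUE/FALSE with no missing values")

  a1 <- rowSums(flags[, c("A1a", "A1b", "A1c"), drop = FALSE])
  a2 <- rowSums(flags[, c("A2a", "A2b", "A2c", "A2d"), drop = FALSE])
  positive <- a1 == 3L & a2 >= 2L & onset & impair

  out <- data.frame(
    child_id = children,
    total_score = total,
    stringsAsFactors = FALSE
  )
  for (s in SUBDOMAIN_IDS) out[[s]] <- as.logical(flags[, s])
  out$a2_abnormal_count <- as.integer(a2)
  out$criteria_met_count <- as.integer(a1 + a2 + onset + impair)
  out$asd_positive <- as.logical(positive)
  out$severity_band <- severity_band(total, cutoffs)
  rownames(out) <- NULL
  out
}
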