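#' Instrument structure
#'
#' The AIIMS-Modified INDT-ASD instrument has two sections.  Section A
#' carries 28 yes/no/unsure questions grouped into seven subdomains
#' (criterion clusters): three social interaction/communication clusters
#' (A1a, 8 questions; A1b, 4; A1c, 3) and four restricted/repetitive
#' behaviour clusters including sensory symptoms (A2a, 7; A2b, 1; A2c, 1;
#' A2d, 4).  Section B carries two mandatory items — onset in the early
#' developmental period and impairment of daily functioning — both
#' prerequisites for a positive call.
#'
#' An instrument object holds, per question: its subdomain, a prompt, the
#' abnormal-response polarity (whether "yes" or "no" is the abnormal
#' answer) and which rater's answer takes precedence on a definite
#' yes-vs-no disagreement.  Per subdomain it holds the minimum number of
#' abnormal questions that flags the subdomain abnormal.
#'
#' @name indt_instrument
NULL

RESPONSE_LEVELS <- c("yes", "no", "unsure")
SUBDOMAIN_IDS <- c("A1a", "A1b", "A1c", "A2a", "A2b", "A2c", "A2d")
SUBDOMAIN_SIZES <- c(A1a = 8L, A1b = 4L, A1c = 3L, A2a = 7L, A2b = 1L,
                     A2c = 1L, A2d = 4L)
B_ITEMS <- c("onset_early_development", "functional_impairment")

# YAML 1.1 reads bare yes/no as logicals; map them back to responses.
as_response_token <- function(x) {
  if (is.logical(x)) return(ifelse(x, "yes", "no"))
  tolower(as.character(x))
}

#' Load an instrument definition
#'
#' Parses a hierarchical plain-text (YAML) instrument definition into a
#' validated `indt_instrument` object.  The definition must contain one
#' block per subdomain listing its questions (id, prompt,
#' `abnormal_response` of "yes" or "no", `precedence` of "parent" or
#' "investigator") and an `abnormal_min_count` threshold, plus the two
#' mandatory Section B item names.  The shipped default definition is
#' returned by [default_instrument()].
#'
#' @param path path to a YAML instrument definition.
#' @return an object of class `indt_instrument`: a list with `name`,
#'   `version`, `questions` (data frame with one row per question:
#'   `question_id`, `subdomain_id`, `prompt`, `abnormal_response`,
#'   `precedence`), `subdomains` (data frame `subdomain_id`, `label`,
#'   `n_questions`, `abnormal_min_count`) and `mandatory_b_items`.
#' @export
#' @examples
#' instr <- default_instrument()
#' nrow(instr$questions)  # 28
load_instrument <- function(path) {
  if (!file.exists(path)) stop_usage("instrument definition not found: %s", path)
  raw <- yaml::yaml.load_file(path)
  for (field in c("name", "subdomains", "mandatory_b_items")) {
    if (is.null(raw[[field]]))
      stop_usage("instrument definition: missing field '%s'", field)
  }

  sds <- raw$subdomains
  q_rows <- list()
  sd_rows <- list()
  for (sd in sds) {
    if (is.null(sd$id) || is.null(sd$questions))
      stop_usage("instrument definition: subdomain block missing 'id' or 'questions'")
    qs <- sd$questions
    for (q in qs) {
      if (is.null(q$id) || is.null(q$abnormal_response) || is.null(q$precedence))
        stop_usage("instrument definition: question in subdomain %s missing 'id', 'abnormal_response' or 'precedence'", sd$id)
      q_rows[[length(q_rows) + 1L]] <- data.frame(
        question_id = as.character(q$id),
        subdomain_id = as.character(sd$id),
        prompt = as.character(q$prompt %||% ""),
        abnormal_response = as_response_token(q$abnormal_response),
        precedence = tolower(as.character(q$precedence)),
        stringsAsFactors = FALSE
      )
    }
    sd_rows[[length(sd_rows) + 1L]] <- data.frame(
      subdomain_id = as.character(sd$id),
      label = as.character(sd$label %||% sd$id),
      n_questions = length(qs),
      abnormal_min_count = as.integer(sd$abnormal_min_count %||% 1L),
      stringsAsFactors = FALSE
    )
  }
  instr <- structure(
    list(
      name = as.character(raw$name),
      version = as.character(raw$version %||% ""),
      questions = do.call(rbind, q_rows),
      subdomains = do.call(rbind, sd_rows),
      mandatory_b_items = vapply(raw$mandatory_b_items, as.character, "")
    ),
    class = "indt_instrument"
  )
  validate_instrument(instr)
  instr
}

#' @rdname load_instrument
#' @export
default_instrument <- function() {
  load_instrument(system.file("extdata", "aiims_indt_asd.yaml",
                              package = "indtasd", mustWork = TRUE))
}

validate_instrument <- function(instr) {
  q <- instr$questions
  sd <- instr$subdomains

  dup <- q$question_id[duplicated(q$question_id)]
  if (length(dup) > 0)
    stop_usage("instrument definition: duplicate question id(s): %s",
               paste(unique(dup), collapse = ", "))

  if (!setequal(sd$subdomain_id, SUBDOMAIN_IDS))
    stop_usage("instrument definition: subdomains must be exactly %s; got %s",
               paste(SUBDOMAIN_IDS, collapse = ", "),
               paste(sd$subdomain_id, collapse = ", "))

  counts <- table(factor(q$subdomain_id, levels = SUBDOMAIN_IDS))
  bad <- SUBDOMAIN_IDS[counts != SUBDOMAIN_SIZES[SUBDOMAIN_IDS]]
  if (length(bad) > 0)
    stop_usage(
      "instrument definition: wrong question count in subdomain(s) %s (expected %s, got %s)",
      paste(bad, collapse = ", "),
      paste(SUBDOMAIN_SIZES[bad], collapse = ", "),
      paste(counts[bad], collapse = ", "))

  if (nrow(q) != 28L)
    stop_usage("instrument definition: expected 28 questions in total, got %d", nrow(q))

  if (!all(q$abnormal_response %in% c("yes", "no")))
    stop_usage("instrument definition: abnormal_response must be 'yes' or 'no' (never 'unsure')")
  if (!all(q$precedence %in% c("parent", "investigator")))
    stop_usage("instrument definition: precedence must be 'parent' or 'investigator'")

  sizes <- SUBDOMAIN_SIZES[sd$subdomain_id]
  if (any(sd$abnormal_min_count < 1L | sd$abnormal_min_count > sizes))
    stop_usage("instrument definition: abnormal_min_count out of range for subdomain(s) %s",
               paste(sd$subdomain_id[sd$abnormal_min_count < 1L |
                                       sd$abnormal_min_count > sizes],
                     collapse = ", "))

  if (!setequal(instr$mandatory_b_items, B_ITEMS))
    stop_usage("instrument definition: mandatory_b_items must be exactly: %s",
               paste(B_ITEMS, collapse = ", "))
  invisible(instr)
}

#' @export
print.indt_instrument <- function(x, ...) {
  cat(sprintf("<indt_instrument> %s (version %s)\n", x$name, x$version))
  cat(sprintf("  %d questions in %d subdomains:\n",
              nrow(x$questions), nrow(x$subdomains)))
  for (i in seq_len(nrow(x$subdomains))) {
    s <- x$subdomains[i, ]
    cat(sprintf("    %s  %-50s %d question(s), abnormal if >= %d\n",
                s$subdomain_id, s$label, s$n_questions, s$abnormal_min_count))
  }
  cat("  mandatory Section B items:",
      paste(x$mandatory_b_items, collapse = ", "), "\n")
  invisible(x)
}
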