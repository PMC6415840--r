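# Independent oracles used across the suite.  These deliberately avoid the
# package's own code paths.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Tie-corrected pairwise concordance probability (brute-force AUC oracle).
auc_concordance <- function(scores, labels) {
  pos <- scores[as.logical(labels)]
  neg <- scores[!as.logical(labels)]
  mean(outer(pos, neg, ">") + 0.5 * outer(pos, neg, "=="))
}

SUB_SIZES <- c(A1a = 8, A1b = 4, A1c = 3, A2a = 7, A2b = 1, A2c = 1, A2d = 4)

# Exact probability of a positive decision-rule call for one class of a
# noise-free simulated cohort, by enumeration over subdomain outcomes:
# P(subdomain abnormal) = P(Binom(k, p) >= min_count); all A1 abnormal,
# >= 2 of 4 A2 abnormal, both B items present.
analytic_call_prob <- function(p_sub, b_rates, min_count = 1) {
  p_abn <- pbinom(min_count - 1, SUB_SIZES, p_sub[names(SUB_SIZES)],
                  lower.tail = FALSE)
  p_a1 <- prod(p_abn[c("A1a", "A1b", "A1c")])
  a2 <- p_abn[c("A2a", "A2b", "A2c", "A2d")]
  p_a2_ge2 <- 0
  for (mask in 0:15) {
    bits <- as.logical(bitwAnd(mask, c(1L, 2L, 4L, 8L)))
    if (sum(bits) >= 2)
      p_a2_ge2 <- p_a2_ge2 + prod(ifelse(bits, a2, 1 - a2))
  }
  p_a1 * p_a2_ge2 * prod(b_rates)
}

# Long-format dual-rater responses for one child where exactly the listed
# questions are answered abnormally (both raters agree everywhere).
make_responses <- function(child_id, abnormal_qids,
                           instrument = default_instrument()) {
  q <- instrument$questions
  abn <- q$question_id %in% abnormal_qids
  resp <- ifelse(abn, q$abnormal_response,
                 ifelse(q$abnormal_response == "no", "yes", "no"))
  data.frame(child_id = child_id, question_id = q$question_id,
             parent_response = resp, investigator_response = resp,
             stringsAsFactors = FALSE)
}

make_section_b <- function(child_id, onset = TRUE, impairment = TRUE) {
  data.frame(child_id = child_id, onset_early_development = onset,
             functional_impairment = impairment, stringsAsFactors = FALSE)
}

# Per-child tool/reference label vectors hitting given 2x2 margins.
margins_cohort <- function(tp, fp, fn, tn) {
  list(
    tool = rep(c(TRUE, TRUE, FALSE, FALSE), c(tp, fp, fn, tn)),
    ref = rep(c(TRUE, FALSE, TRUE, FALSE), c(tp, fp, fn, tn))
  )
}
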