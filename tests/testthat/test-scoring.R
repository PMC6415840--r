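test_that("reconciliation follows the administration rules over all rater pairs", {
  states <- c("yes", "no", "unsure")
  # independent restatement of the rule, evaluated pair by pair
  rule <- function(p, i, prec) {
    if (p == i) return(p)
    if (p == "unsure") return(i)
    if (i == "unsure") return(p)
    if (prec == "parent") p else i
  }
  for (prec in c("parent", "investigator")) {
    grid <- expand.grid(p = states, i = states, stringsAsFactors = FALSE)
    got <- reconcile_answer(grid$p, grid$i, prec)
    want <- mapply(rule, grid$p, grid$i, prec)
    expect_equal(got, unname(want), info = paste("precedence", prec))
    # "unsure" arises exactly once: the both-unsure cell
    expect_equal(sum(got == "unsure"), 1L)
    expect_equal(grid[got == "unsure", ], data.frame(p = "unsure", i = "unsure"),
                 ignore_attr = TRUE)
  }
  # spot checks of the stated cases
  expect_equal(reconcile_answer("yes", "no", "investigator"), "no")
  expect_equal(reconcile_answer("yes", "no", "parent"), "yes")
  expect_equal(reconcile_answer("unsure", "no", "investigator"), "no")
  expect_error(reconcile_answer("maybe", "no", "parent"), "yes/no/unsure")
})

test_that("abnormality flags respect polarity and never fire on unsure", {
  expect_true(flag_abnormal("no", "no"))
  expect_false(flag_abnormal("yes", "no"))
  expect_true(flag_abnormal("yes", "yes"))
  expect_false(flag_abnormal("unsure", "no"))
  expect_false(flag_abnormal("unsure", "yes"))
})

test_that("subdomain and total scoring count abnormal answers", {
  r <- score_subdomain(c(TRUE, TRUE, TRUE, rep(FALSE, 5)), 1L)
  expect_equal(r$abnormal_count, 3L)
  expect_true(r$is_abnormal)
  expect_false(score_subdomain(FALSE, 1L)$is_abnormal)         # A2b-style
  expect_equal(score_subdomain(rep(FALSE, 3), 1L)$abnormal_count, 0L)
  expect_false(score_subdomain(c(TRUE, FALSE, FALSE), 2L)$is_abnormal)
  expect_error(score_subdomain(c(TRUE, NA), 1L), "incomplete")
  expect_error(score_subdomain(rep(TRUE, 3), 4L), "abnormal_min_count")

  expect_equal(total_score(rep(TRUE, 28)), 28L)
  expect_equal(total_score(rep(FALSE, 28)), 0L)
  expect_error(total_score(rep(TRUE, 27)), "incomplete")

  # brute-force equivalence on random answer sets
  set.seed(11)
  for (k in 1:20) {
    flags <- runif(28) < runif(1)
    expect_equal(total_score(flags), sum(flags + 0L))
  }
})

test_that("the decision rule needs all of A1, two of A2 and both B items", {
  sd_all <- setNames(rep(TRUE, 7), c("A1a","A1b","A1c","A2a","A2b","A2c","A2d"))

  r <- diagnose(sd_all, TRUE, TRUE)
  expect_true(r$asd_positive)
  expect_equal(r$criteria_met_count, 9L)

  # one A1 subdomain short: never positive (the stringent 3-of-3 rule)
  sd <- sd_all; sd["A1c"] <- FALSE
  expect_false(diagnose(sd, TRUE, TRUE)$asd_positive)

  # only one A2 subdomain abnormal
  sd <- sd_all; sd[c("A2b","A2c","A2d")] <- FALSE
  expect_false(diagnose(sd, TRUE, TRUE)$asd_positive)

  # Section B is a hard prerequisite
  sd <- sd_all; sd[c("A2b","A2c")] <- FALSE
  expect_true(diagnose(sd, TRUE, TRUE)$asd_positive)
  expect_false(diagnose(sd, TRUE, FALSE)$asd_positive)

  expect_error(diagnose(sd_all[-1], TRUE, TRUE), "missing subdomain")
  expect_error(diagnose(sd_all, NA, TRUE), "non-missing")
})

test_that("the decision rule is monotone in its inputs", {
  set.seed(7)
  ids <- c("A1a","A1b","A1c","A2a","A2b","A2c","A2d")
  for (rep_i in 1:100) {
    sd <- setNames(runif(7) < 0.5, ids)
    b <- runif(2) < 0.5
    base <- diagnose(sd, b[1], b[2])$asd_positive
    # flip one normal input to abnormal/true: call may only go up
    off <- c(which(!sd), if (!b[1]) 8L, if (!b[2]) 9L)
    if (length(off) == 0) next
    j <- sample(off, 1)
    sd2 <- sd; b2 <- b
    if (j <= 7) sd2[j] <- TRUE else b2[j - 7L] <- TRUE
    expect_true(diagnose(sd2, b2[1], b2[2])$asd_positive >= base)
  }
})

test_that("severity bands follow the validated score cutoffs", {
  # independent restatement of the banding
  want <- function(s) {
    if (s <= 9) "below_threshold"
    else if (s == 10) "asd_mild"
    else if (s <= 13) "asd_moderate"
    else "asd_severe"
  }
  expect_equal(severity_band(0:28), vapply(0:28, want, ""))
  expect_equal(severity_band(14), "asd_severe")
  expect_equal(severity_band(9), "below_threshold")
  expect_equal(severity_band(28), "asd_severe")
  expect_error(severity_band(29), "0, 28")
  expect_error(severity_band(10, cutoffs = c(10, 10, 14)), "increasing")
  # user-overridden cutoffs shift the bands
  expect_equal(severity_band(12, cutoffs = c(8L, 12L, 20L)), "asd_moderate")
})

test_that("cohort scoring is complete-record and order-invariant", {
  instr <- default_instrument()
  q <- instr$questions

  resp <- rbind(
    make_responses("all_abn", q$question_id),
    make_responses("a1a_only", q$question_id[q$subdomain_id == "A1a"]),
    make_responses("none", character(0))
  )
  b <- make_section_b(c("all_abn", "a1a_only", "none"))
  rep1 <- score_cohort(resp, b)

  expect_equal(rep1$total_score[rep1$child_id == "all_abn"], 28L)
  expect_true(rep1$asd_positive[rep1$child_id == "all_abn"])
  expect_equal(rep1$criteria_met_count[rep1$child_id == "all_abn"], 9L)
  expect_equal(rep1$total_score[rep1$child_id == "a1a_only"], 8L)
  expect_false(rep1$asd_positive[rep1$child_id == "a1a_only"])
  expect_equal(rep1$total_score[rep1$child_id == "none"], 0L)

  # permutation invariance of the row order
  set.seed(5)
  rep2 <- score_cohort(resp[sample(nrow(resp)), ], b)
  rep2 <- rep2[match(rep1$child_id, rep2$child_id), ]
  expect_equal(rep1, rep2, ignore_attr = TRUE)

  # all-unsure answers contribute nothing
  resp_u <- make_responses("u", character(0))
  resp_u$parent_response <- "unsure"
  resp_u$investigator_response <- "unsure"
  rep_u <- score_cohort(resp_u, make_section_b("u"))
  expect_equal(rep_u$total_score, 0L)
  expect_false(rep_u$asd_positive)

  # incompleteness is a hard error naming child and question
  expect_error(score_cohort(resp[-2, ], b), "child all_abn.*A1a\\.2")
  expect_error(score_cohort(resp, b[-1, ]), "Section B record missing")
  bad <- resp; bad$question_id[1] <- "Zzz.9"
  expect_error(score_cohort(bad, b), "not in the instrument")
})
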