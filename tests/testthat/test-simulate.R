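test_that("default parameters encode the validation-study cohort structure", {
  p <- cohort_params()
  expect_equal(p$n, 225L)
  expect_equal(round(p$prevalence, 3), 0.569)
  expect_equal(round(unname(p$band_mix_pos["severe"]), 3), 0.625)
  expect_equal(round(unname(p$band_mix_neg["non_autistic"]), 3), 0.979)
  expect_equal(sum(p$band_mix_pos), 1, tolerance = 1e-12)
  expect_equal(sum(p$band_mix_neg), 1, tolerance = 1e-12)
  expect_equal(sum(p$dq_mix), 1, tolerance = 1e-12)

  expect_error(cohort_params(n = 0), "n must be")
  expect_error(cohort_params(prevalence = 1.2), "\\[0, 1\\]")
  expect_error(cohort_params(band_mix_pos = c(0.5, 0.4, 0.2)), "sum to 1")
  expect_error(cohort_params(p_abnormal_pos = c(A1a = 0.5)), "named over")
})

test_that("the same seed reproduces the identical cohort", {
  a <- simulate_cohort(cohort_params(n = 40, seed = 99))
  b <- simulate_cohort(cohort_params(n = 40, seed = 99))
  expect_identical(a$responses, b$responses)
  expect_identical(a$section_b, b$section_b)
  expect_identical(a$covariates, b$covariates)
  expect_identical(a$truth, b$truth)
  c <- simulate_cohort(cohort_params(n = 40, seed = 100))
  expect_false(identical(a$responses, c$responses))
})

test_that("zero rater noise makes the two raters agree everywhere", {
  co <- simulate_cohort(cohort_params(n = 30, seed = 5,
                                      rater_disagreement = 0, unsure_rate = 0))
  expect_identical(co$responses$parent_response,
                   co$responses$investigator_response)
  expect_false(any(co$responses$parent_response == "unsure"))
})

test_that("CARS scores stay inside their drawn band", {
  co <- simulate_cohort(cohort_params(n = 400, seed = 6))
  band <- cars_band(co$truth$cars_score)
  s <- co$truth$cars_score
  expect_true(all(s[band == "non_autistic"] >= 15 & s[band == "non_autistic"] < 30))
  expect_true(all(s[band == "mild_moderate"] >= 30 & s[band == "mild_moderate"] <= 36.5))
  expect_true(all(s[band == "severe"] > 36.5 & s[band == "severe"] <= 60))
})

test_that("empirical marginals recover the parameters at large n", {
  p <- cohort_params(n = 20000, seed = 7)
  co <- simulate_cohort(p)
  n <- p$n

  prev_hat <- mean(co$truth$latent_class)
  se <- sqrt(p$prevalence * (1 - p$prevalence) / n)
  expect_lt(abs(prev_hat - p$prevalence), 3 * se)

  pos <- co$truth$latent_class
  band <- factor(cars_band(co$truth$cars_score),
                 c("non_autistic", "mild_moderate", "severe"))
  for (cls in c(TRUE, FALSE)) {
    mix <- if (cls) p$band_mix_pos else p$band_mix_neg
    m <- sum(pos == cls)
    hat <- as.numeric(table(band[pos == cls])) / m
    for (j in 1:3) {
      se_j <- sqrt(mix[j] * (1 - mix[j]) / m)
      expect_lt(abs(hat[j] - mix[j]), 3 * se_j + 1e-9)
    }
  }

  dq_hat <- as.numeric(table(factor(co$covariates$dq_band, names(p$dq_mix)))) / n
  expect_lt(max(abs(dq_hat - as.numeric(p$dq_mix))), 0.015)
})

test_that("raising item probabilities never lowers mean pipeline sensitivity", {
  mean_sens <- function(p_pos, seeds) {
    mean(vapply(seeds, function(s) {
      co <- simulate_cohort(cohort_params(n = 120, seed = s,
                                          p_abnormal_pos = p_pos))
      rep <- score_cohort(co$responses, co$section_b)
      ct <- oracle_accuracy(co, rep)
      ct$tp / (ct$tp + ct$fn)
    }, 0))
  }
  seeds <- 1:20
  expect_gte(mean_sens(0.75, seeds), mean_sens(0.55, seeds))
})

test_that("simulated rater agreement matches the analytic kappa expectation", {
  # all children ASD+, one shared item probability, no unsure answers:
  # each rater flips the true yes/no independently with probability d
  d <- 0.10; p_abn <- 0.6
  co <- simulate_cohort(cohort_params(n = 5000, seed = 8, prevalence = 1,
                                      p_abnormal_pos = p_abn,
                                      rater_disagreement = d, unsure_rate = 0))
  one_q <- co$responses[co$responses$question_id == "A1a.1", ]
  k_hat <- cohens_kappa(one_q$parent_response, one_q$investigator_response)$value

  t_yes <- 1 - p_abn                      # polarity "no": abnormal -> "no"
  p_yes <- t_yes * (1 - 2 * d) + d        # each rater's marginal P(yes)
  p_o <- (1 - d)^2 + d^2
  p_e <- p_yes^2 + (1 - p_yes)^2
  k_want <- (p_o - p_e) / (1 - p_e)
  expect_lt(abs(k_hat - k_want), 0.05)
})

test_that("oracle accuracy aligns tool calls with the latent truth", {
  co <- simulate_cohort(cohort_params(n = 60, seed = 9))
  rep <- score_cohort(co$responses, co$section_b)
  ct <- oracle_accuracy(co, rep)
  expect_equal(ct$n, 60L)
  expect_equal(ct$tp + ct$fn, sum(co$truth$latent_class))
  # shuffling the report rows must not change the table
  ct2 <- oracle_accuracy(co, rep[rev(seq_len(nrow(rep))), ])
  expect_equal(unclass(ct), unclass(ct2))
  expect_error(oracle_accuracy(co, rep[0, ]), "non-empty")
})

test_that("cohort files round-trip through the CSV writers and readers", {
  co <- simulate_cohort(cohort_params(n = 12, seed = 10))
  dir <- withr::local_tempdir()
  paths <- write_cohort(co, dir)
  expect_true(all(file.exists(paths)))
  resp <- read_responses(paths["responses"])
  expect_equal(resp, co$responses)
  expect_equal(read_section_b(paths["section_b"]), co$section_b)
  cov <- read_covariates(paths["covariates"])
  expect_equal(cov$expert_dsm5, co$covariates$expert_dsm5)
  expect_equal(cov$cars_score, co$covariates$cars_score, tolerance = 1e-12)
})
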