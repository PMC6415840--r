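#' Parameters of a synthetic validation cohort
#'
#' Defines the generative model for a seeded synthetic validation study:
#' a latent ASD class per child, a class-conditional CARS severity band
#' with a score drawn uniformly within the band, per-subdomain
#' item-abnormality probabilities, dual-rater reporting noise, the two
#' Section B item rates and a developmental-quotient band (generated for
#' report parity; scoring never uses it).
#'
#' The defaults emulate the published validation cohort: n = 225,
#' prevalence 128/225 (56.9%), CARS band mixtures (11, 37, 80)/128 for
#' the ASD-positive class and (95, 2, 0)/97 for the negative class, and
#' the complete-cohort DQ mixture.  Item probabilities and rater-noise
#' rates are not reported for the real cohort; the defaults are fixed
#' package choices whose implied decision-rule operating point lies near
#' the published one (see the methods vignette).
#'
#' @param n cohort size.
#' @param prevalence proportion ASD-positive.
#' @param band_mix_pos,band_mix_neg class-conditional CARS band
#'   distributions over (non_autistic, mild_moderate, severe); each sums
#'   to 1.
#' @param p_abnormal_pos,p_abnormal_neg named per-subdomain probabilities
#'   that a question of that subdomain is latently abnormal, by class.  A
#'   scalar is recycled over the seven subdomains.
#' @param severity_slope logistic slope coupling item abnormality to the
#'   centered CARS score (`cars - 36.5`) within the ASD-positive class;
#'   0 (default) switches the coupling off.
#' @param rater_disagreement probability that a rater independently flips
#'   a definite yes/no response.
#' @param unsure_rate probability that a rater reports "unsure" instead
#'   of their response.
#' @param b_item_rates_pos,b_item_rates_neg class-conditional
#'   probabilities of the two Section B items (onset, impairment).
#' @param dq_mix categorical distribution over DQ bands.
#' @param seed integer root seed; per-child substreams are derived from
#'   it so cohort content is reproducible and independent of iteration
#'   order.
#' @return validated list of class `cohort_params`.
#' @export
#' @examples
#' p <- cohort_params(seed = 1)
#' round(p$prevalence, 3)  # 0.569
cohort_params <- function(
    n = 225L,
    prevalence = 128 / 225,
    band_mix_pos = c(non_autistic = 11, mild_moderate = 37, severe = 80) / 128,
    band_mix_neg = c(non_autistic = 95, mild_moderate = 2, severe = 0) / 97,
    p_abnormal_pos = 0.80,
    p_abnormal_neg = 0.25,
    severity_slope = 0,
    rater_disagreement = 0.05,
    unsure_rate = 0.02,
    b_item_rates_pos = c(onset_early_development = 0.995,
                         functional_impairment = 0.995),
    b_item_rates_neg = c(onset_early_development = 0.70,
                         functional_impairment = 0.50),
    dq_mix = c(dq_le_50 = 115, dq_51_60 = 64, dq_61_70 = 33,
               dq_71_80 = 8, dq_81_90 = 2, dq_gt_90 = 3) / 225,
    seed = 1L) {

  expand_p <- function(p, what) {
    if (length(p) == 1L && is.null(names(p)))
      p <- setNames(rep(p, 7L), SUBDOMAIN_IDS)
    if (!setequal(names(p), SUBDOMAIN_IDS))
      stop_usage("%s must be a scalar or named over %s", what,
                 paste(SUBDOMAIN_IDS, collapse = ", "))
    p[SUBDOMAIN_IDS]
  }
  params <- list(
    n = as.integer(n), prevalence = prevalence,
    band_mix_pos = band_mix_pos, band_mix_neg = band_mix_neg,
    p_abnormal_pos = expand_p(p_abnormal_pos, "p_abnormal_pos"),
    p_abnormal_neg = expand_p(p_abnormal_neg, "p_abnormal_neg"),
    severity_slope = severity_slope,
    rater_disagreement = rater_disagreement, unsure_rate = unsure_rate,
    b_item_rates_pos = b_item_rates_pos, b_item_rates_neg = b_item_rates_neg,
    dq_mix = dq_mix, seed = as.integer(seed)
  )
  validate_cohort_params(params)
  structure(params, class = "cohort_params")
}

validate_cohort_params <- function(p) {
  if (is.na(p$n) || p$n < 1L) stop_usage("cohort_params: n must be >= 1")
  props <- c(p$prevalence, p$band_mix_pos, p$band_mix_neg, p$p_abnormal_pos,
             p$p_abnormal_neg, p$rater_disagreement, p$unsure_rate,
             p$b_item_rates_pos, p$b_item_rates_neg, p$dq_mix)
  if (anyNA(props) || any(props < 0) || any(props > 1))
    stop_usage("cohort_params: every probability must lie in [0, 1]")
  for (nm in c("band_mix_pos", "band_mix_neg", "dq_mix")) {
    if (abs(sum(p[[nm]]) - 1) > 1e-9)
      stop_usage("cohort_params: %s must sum to 1 (got %.12f)", nm, sum(p[[nm]]))
  }
  if (length(p$band_mix_pos) != 3L || length(p$band_mix_neg) != 3L)
    stop_usage("cohort_params: band mixes need the three CARS bands")
  if (length(p$b_item_rates_pos) != 2L || length(p$b_item_rates_neg) != 2L)
    stop_usage("cohort_params: b_item_rates need the two Section B items")
  invisible(p)
}

# CARS support per band: non_autistic [15, 30), mild_moderate [30, 36.5],
# severe (36.5, 60].
draw_cars <- function(band, u) {
  switch(band,
         non_autistic = 15 + u * (30 - 15),
         mild_moderate = 30 + u * (36.5 - 30),
         severe = 36.5 + u * (60 - 36.5))
}

#' Simulate a synthetic validation cohort
#'
#' Generates per child: a latent ASD class (Bernoulli at the prevalence),
#' a class-conditional CARS band and a uniform score within it, a DQ
#' band, the 28 dual-rater question responses and the two Section B
#' items.  A question's latent abnormality is Bernoulli at its
#' subdomain's class-conditional probability, optionally modulated
#' logistically by the centered CARS score within the positive class; the
#' abnormality is mapped through the question's polarity to a true
#' response, and each rater reports that response independently flipped
#' with probability `rater_disagreement` and replaced by "unsure" with
#' probability `unsure_rate`.
#'
#' All randomness flows from `params$seed` through per-child substreams,
#' so the same parameters always reproduce the identical cohort.
#'
#' @param params a [cohort_params()] object.
#' @param instrument the instrument whose structure the responses follow.
#' @return object of class `simulated_cohort`: list with `params` and
#'   four data frames ready for [score_cohort()] and [cmd_validate()]:
#'   `responses` (child_id, question_id, parent_response,
#'   investigator_response), `section_b`, `covariates` (child_id,
#'   cars_score, expert_dsm5, dq_band) and `truth` (child_id,
#'   latent_class, cars_score).
#' @export
#' @examples
#' co <- simulate_cohort(cohort_params(n = 10, seed = 42))
#' nrow(co$responses)  # 10 * 28
simulate_cohort <- function(params, instrument = default_instrument()) {
  stopifnot(inherits(params, "cohort_params"))
  validate_cohort_params(params)
  q <- instrument$questions
  nq <- nrow(q)
  n <- params$n
  ids <- sprintf("child_%04d", seq_len(n))

  old <- globalenv()$.Random.seed
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(params$seed)
  child_seeds <- sample.int(.Machine$integer.max, n, replace = TRUE)

  sd_idx <- match(q$subdomain_id, SUBDOMAIN_IDS)
  normal_of <- ifelse(q$abnormal_response == "no", "yes", "no")

  latent <- logical(n)
  cars <- numeric(n)
  dq <- character(n)
  onset <- logical(n)
  impair <- logical(n)
  parent_m <- matrix("", n, nq)
  invest_m <- matrix("", n, nq)

  clamp <- function(p) pmin(pmax(p, 1e-12), 1 - 1e-12)
  bands <- CARS_BANDS

  for (i in seq_len(n)) {
    set.seed(child_seeds[i])
    pos <- stats::runif(1) < params$prevalence
    mix <- if (pos) params$band_mix_pos else params$band_mix_neg
    band <- sample(bands, 1L, prob = mix)
    ci <- draw_cars(band, stats::runif(1))
    dq[i] <- sample(names(params$dq_mix), 1L, prob = params$dq_mix)

    p_sub <- if (pos) params$p_abnormal_pos else params$p_abnormal_neg
    p_q <- p_sub[sd_idx]
    if (pos && params$severity_slope != 0) {
      p_q <- stats::plogis(stats::qlogis(clamp(p_q)) +
                             params$severity_slope * (ci - 36.5))
    }
    abn <- stats::runif(nq) < p_q
    true_resp <- ifelse(abn, q$abnormal_response, normal_of)

    report <- function() {
      r <- true_resp
      flip <- stats::runif(nq) < params$rater_disagreement
      r[flip] <- ifelse(r[flip] == "yes", "no", "yes")
      r[stats::runif(nq) < params$unsure_rate] <- "unsure"
      r
    }
    parent_m[i, ] <- report()
    invest_m[i, ] <- report()

    b_rates <- if (pos) params$b_item_rates_pos else params$b_item_rates_neg
    onset[i] <- stats::runif(1) < b_rates[[1]]
    impair[i] <- stats::runif(1) < b_rates[[2]]

    latent[i] <- pos
    cars[i] <- ci
  }

  responses <- data.frame(
    child_id = rep(ids, each = nq),
    question_id = rep(q$question_id, times = n),
    parent_response = as.vector(t(parent_m)),
    investigator_response = as.vector(t(invest_m)),
    stringsAsFactors = FALSE
  )
  structure(list(
    params = params,
    responses = responses,
    section_b = data.frame(child_id = ids,
                           onset_early_development = onset,
                           functional_impairment = impair,
                           stringsAsFactors = FALSE),
    covariates = data.frame(child_id = ids,
                            cars_score = cars,
                            expert_dsm5 = ifelse(latent, "positive", "negative"),
                            dq_band = dq,
                            stringsAsFactors = FALSE),
    truth = data.frame(child_id = ids,
                       latent_class = latent,
                       cars_score = cars,
                       stringsAsFactors = FALSE)
  ), class = "simulated_cohort")
}

#' @export
print.simulated_cohort <- function(x, ...) {
  cat(sprintf("<simulated_cohort> n = %d, seed = %d\n",
              x$params$n, x$params$seed))
  cat(sprintf("  latent ASD prevalence: %.3f (target %.3f)\n",
              mean(x$truth$latent_class), x$params$prevalence))
  print(table(cars_band(x$truth$cars_score)))
  invisible(x)
}

#' Confusion of tool calls against the simulation's latent truth
#'
#' @param cohort a [simulate_cohort()] result.
#' @param tool_calls the [score_cohort()] report for that cohort (needs
#'   `child_id` and `asd_positive`).
#' @return a [confusion_table] of tool calls against the latent class.
#' @export
oracle_accuracy <- function(cohort, tool_calls) {
  stopifnot(inherits(cohort, "simulated_cohort"))
  if (is.null(tool_calls$child_id) || nrow(tool_calls) == 0L)
    stop_usage("oracle_accuracy: tool_calls must be a non-empty score report")
  confusion_table(tool_calls$asd_positive, cohort$truth$latent_class,
                  child_id = tool_calls$child_id,
                  reference_child_id = cohort$truth$child_id)
}

#' Write a simulated cohort to CSV files
#'
#' Emits the same CSV formats the scoring pipeline consumes
#' (`responses.csv`, `section_b.csv`, `covariates.csv`) plus the
#' latent-truth table (`truth.csv`) and the generating parameters
#' (`params.yaml`).
#'
#' @param cohort a [simulate_cohort()] result.
#' @param dir output directory, created if needed.
#' @return invisibly, the named vector of file paths written.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "simulated_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    responses = file.path(dir, "responses.csv"),
    section_b = file.path(dir, "section_b.csv"),
    covariates = file.path(dir, "covariates.csv"),
    truth = file.path(dir, "truth.csv")
  )
  for (nm in names(paths))
    utils::write.csv(cohort[[nm]], paths[nm], row.names = FALSE)
  p <- unclass(cohort$params)
  p$p_abnormal_pos <- as.list(p$p_abnormal_pos)
  p$p_abnormal_neg <- as.list(p$p_abnormal_neg)
  p$band_mix_pos <- as.list(p$band_mix_pos)
  p$band_mix_neg <- as.list(p$band_mix_neg)
  p$b_item_rates_pos <- as.list(p$b_item_rates_pos)
  p$b_item_rates_neg <- as.list(p$b_item_rates_neg)
  p$dq_mix <- as.list(p$dq_mix)
  yaml::write_yaml(p, file.path(dir, "params.yaml"))
  invisible(c(paths, params = file.path(dir, "params.yaml")))
}
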