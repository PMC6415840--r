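#' 2x2 confusion table of tool calls against a reference diagnosis
#'
#' @param tool_positive logical vector of instrument calls.
#' @param reference_positive logical vector of reference (gold standard)
#'   diagnoses, same children in the same order; if `child_id` is given
#'   for both sides the records are matched on it instead.
#' @param child_id,reference_child_id optional id vectors used to align
#'   the two inputs.
#' @return object of class `confusion_table`: list with integer cells
#'   `tp`, `fp`, `fn`, `tn` and `n`.
#' @export
#' @examples
#' ct <- confusion_table(c(TRUE, TRUE, FALSE), c(TRUE, FALSE, FALSE))
#' ct$tp; ct$fp
confusion_table <- function(tool_positive, reference_positive,
                            child_id = NULL, reference_child_id = NULL) {
  if (length(tool_positive) == 0L)
    stop_usage("confusion_table: empty input")
  if (!is.null(child_id) || !is.null(reference_child_id)) {
    if (is.null(child_id) || is.null(reference_child_id))
      stop_usage("confusion_table: give child ids for both sides or neither")
    if (!setequal(child_id, reference_child_id) ||
        anyDuplicated(child_id) || anyDuplicated(reference_child_id))
      stop_usage("confusion_table: child ids must match one-to-one between tool and reference")
    reference_positive <- reference_positive[match(child_id, reference_child_id)]
  }
  if (length(tool_positive) != length(reference_positive))
    stop_usage("confusion_table: inputs differ in length (%d vs %d)",
               length(tool_positive), length(reference_positive))
  tool_positive <- as.logical(tool_positive)
  reference_positive <- as.logical(reference_positive)
  if (anyNA(tool_positive) || anyNA(reference_positive))
    stop_usage("confusion_table: missing values are not allowed")
  structure(list(
    tp = sum(tool_positive & reference_positive),
    fp = sum(tool_positive & !reference_positive),
    fn = sum(!tool_positive & reference_positive),
    tn = sum(!tool_positive & !reference_positive),
    n = length(tool_positive)
  ), class = "confusion_table")
}

#' Build a confusion table directly from its four cells
#'
#' Convenience for reconstructing published 2x2 tables.
#'
#' @param tp,fp,fn,tn non-negative integer cell counts (tool x reference).
#' @export
confusion_from_cells <- function(tp, fp, fn, tn) {
  cells <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (any(cells < 0) || any(cells != round(cells)))
    stop_usage("confusion cells must be non-negative integers")
  if (sum(cells) < 1) stop_usage("confusion table must contain at least one subject")
  cells <- as.integer(cells)
  structure(list(tp = cells[1], fp = cells[2], fn = cells[3], tn = cells[4],
                 n = sum(cells)),
            class = "confusion_table")
}

#' @export
print.confusion_table <- function(x, ...) {
  m <- matrix(c(x$tp, x$fp, x$fn, x$tn), 2, byrow = TRUE,
              dimnames = list(c("tool +", "tool -"), c("ref +", "ref -")))
  print(addmargins(as.table(m)))
  invisible(x)
}

#' Clopper-Pearson exact binomial confidence interval
#'
#' The exact (beta-quantile) interval for a binomial proportion:
#' `lower = qbeta(alpha/2, x, n - x + 1)` and
#' `upper = qbeta(1 - alpha/2, x + 1, n - x)`, with `lower = 0` when
#' `x = 0` and `upper = 1` when `x = n`.
#'
#' @param successes,trials integer counts, `0 <= successes <= trials`.
#' @param level confidence level in (0, 1).
#' @return object of class `estimate_ci`: list with `point`, `lower`,
#'   `upper`, `level`, `successes`, `trials`.
#' @export
#' @examples
#' clopper_pearson(126, 128)  # the interval behind "98.44% [94.47, 99.81]"
clopper_pearson <- function(successes, trials, level = 0.95) {
  if (length(successes) != 1L || length(trials) != 1L ||
      is.na(successes) || is.na(trials) ||
      successes != round(successes) || trials != round(trials) ||
      trials < 1 || successes < 0 || successes > trials)
    stop_usage("clopper_pearson: need integer 0 <= successes <= trials, trials >= 1")
  if (length(level) != 1L || is.na(level) || level <= 0 || level >= 1)
    stop_usage("clopper_pearson: level must be in (0, 1)")
  x <- successes; n <- trials; a <- 1 - level
  lower <- if (x == 0) 0 else stats::qbeta(a / 2, x, n - x + 1)
  upper <- if (x == n) 1 else stats::qbeta(1 - a / 2, x + 1, n - x)
  structure(list(point = x / n, lower = lower, upper = upper, level = level,
                 successes = as.integer(x), trials = as.integer(n)),
            class = "estimate_ci")
}

#' @export
print.estimate_ci <- function(x, digits = 2, ...) {
  cat(sprintf("%s [%s to %s] (%d/%d, %g%% exact CI)\n",
              fmt_pct(x$point, digits), fmt_pct(x$lower, digits),
              fmt_pct(x$upper, digits), x$successes, x$trials, 100 * x$level))
  invisible(x)
}

acc_measure <- function(ct, num, den, name, level) {
  if (den == 0)
    stop_usage("%s is undefined: zero denominator", name)
  est <- clopper_pearson(num, den, level)
  est$measure <- name
  est
}

#' Diagnostic accuracy measures with exact confidence intervals
#'
#' Sensitivity `tp/(tp+fn)`, specificity `tn/(tn+fp)`, positive
#' predictive value `tp/(tp+fp)` and negative predictive value
#' `tn/(tn+fn)`, each with a Clopper-Pearson interval on the same
#' numerator/denominator.
#'
#' @param ct a [confusion_table].
#' @param level confidence level.
#' @return an `estimate_ci`.
#' @export
#' @examples
#' ct <- confusion_from_cells(126, 8, 2, 89)
#' sensitivity(ct)
sensitivity <- function(ct, level = 0.95)
  acc_measure(ct, ct$tp, ct$tp + ct$fn, "sensitivity", level)

#' @rdname sensitivity
#' @export
specificity <- function(ct, level = 0.95)
  acc_measure(ct, ct$tn, ct$tn + ct$fp, "specificity", level)

#' @rdname sensitivity
#' @export
ppv <- function(ct, level = 0.95)
  acc_measure(ct, ct$tp, ct$tp + ct$fp, "ppv", level)

#' @rdname sensitivity
#' @export
npv <- function(ct, level = 0.95)
  acc_measure(ct, ct$tn, ct$tn + ct$fn, "npv", level)

#' Full accuracy report for a 2x2 table
#'
#' @param ct a [confusion_table].
#' @param level confidence level.
#' @return data frame: `measure`, `point`, `lower`, `upper` (proportions),
#'   `num`, `den`.
#' @export
accuracy_report <- function(ct, level = 0.95) {
  ests <- list(sensitivity(ct, level), specificity(ct, level),
               ppv(ct, level), npv(ct, level))
  data.frame(
    measure = vapply(ests, `[[`, "", "measure"),
    point = vapply(ests, `[[`, 0, "point"),
    lower = vapply(ests, `[[`, 0, "lower"),
    upper = vapply(ests, `[[`, 0, "upper"),
    num = vapply(ests, `[[`, 0L, "successes"),
    den = vapply(ests, `[[`, 0L, "trials"),
    stringsAsFactors = FALSE
  )
}

#' ROC curve, AUC and Youden-optimal cutoff
#'
#' Builds the ROC of a score against binary labels under the positive
#' rule `score >= cutoff` (the direction in which all the instrument's
#' cutoffs are phrased).  One point is produced per distinct observed
#' score plus a sentinel at `+Inf` (nothing called positive); the lowest
#' observed cutoff calls everything positive, closing the curve at
#' (1, 1).  The AUC is the trapezoidal area over (fpr, tpr), which equals
#' the tie-corrected concordance probability.  The Youden-optimal cutoff
#' maximizes J = tpr - fpr; ties are broken toward the smallest cutoff
#' (favoring sensitivity).
#'
#' @param scores numeric score per subject.
#' @param labels logical (or 0/1) reference label per subject; both
#'   classes must be present.
#' @return object of class `roc_result`: list with `points` (data frame
#'   `cutoff`, `tpr`, `fpr`, sorted by ascending cutoff), `auc`,
#'   `youden_cutoff`, `youden_j`, `n_pos`, `n_neg`.
#' @export
#' @examples
#' r <- roc_curve(c(10, 11, 12, 1, 2, 3), c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE))
#' r$auc  # 1
roc_curve <- function(scores, labels) {
  labels <- as.logical(labels)
  if (length(scores) != length(labels) || anyNA(scores) || anyNA(labels))
    stop_usage("roc_curve: scores and labels must be complete and the same length")
  n_pos <- sum(labels); n_neg <- sum(!labels)
  if (n_pos == 0L || n_neg == 0L)
    stop_usage("roc_curve: AUC undefined, both classes must be present")

  cutoffs <- sort(unique(scores))
  tpr <- vapply(cutoffs, function(c) sum(scores >= c & labels) / n_pos, 0)
  fpr <- vapply(cutoffs, function(c) sum(scores >= c & !labels) / n_neg, 0)
  pts <- data.frame(cutoff = c(cutoffs, Inf), tpr = c(tpr, 0), fpr = c(fpr, 0))

  # descending cutoff -> ascending (fpr, tpr); trapezoid over fpr
  ord <- order(pts$fpr, pts$tpr)
  xf <- pts$fpr[ord]; yt <- pts$tpr[ord]
  auc <- sum(diff(xf) * (utils::head(yt, -1) + utils::tail(yt, -1)) / 2)

  j <- tpr - fpr
  best <- which(j == max(j))
  best <- best[which.min(cutoffs[best])]
  structure(list(points = pts, auc = auc,
                 youden_cutoff = cutoffs[best], youden_j = j[best],
                 n_pos = n_pos, n_neg = n_neg),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> %d positives, %d negatives, %d cutoffs\n",
              x$n_pos, x$n_neg, nrow(x$points) - 1L))
  cat(sprintf("  AUC = %.4f; Youden-optimal cutoff >= %g (J = %.4f)\n",
              x$auc, x$youden_cutoff, x$youden_j))
  invisible(x)
}

#' CARS severity band
#'
#' Bands a Childhood Autism Rating Scale total score: below 30 is
#' non-autistic, 30 to 36.5 mild-to-moderate, above 36.5 severe.  Scores
#' outside the instrument's plausible 15-60 range raise a warning but are
#' still banded.
#'
#' @param cars_score numeric CARS total score(s).
#' @return character vector over
#'   `{"non_autistic", "mild_moderate", "severe"}` (`NA` stays `NA`).
#' @export
#' @examples
#' cars_band(c(29.5, 30, 36.5, 37))
cars_band <- function(cars_score) {
  out_of_range <- !is.na(cars_score) & (cars_score < 15 | cars_score > 60)
  if (any(out_of_range))
    warning(sprintf("%d CARS score(s) outside the plausible 15-60 range",
                    sum(out_of_range)), call. = FALSE)
  ifelse(is.na(cars_score), NA_character_,
         ifelse(cars_score < 30, "non_autistic",
                ifelse(cars_score <= 36.5, "mild_moderate", "severe")))
}

CARS_BANDS <- c("non_autistic", "mild_moderate", "severe")

#' Tool performance across CARS severity bands
#'
#' Cross-tabulates instrument calls against CARS severity bands, with row
#' percentages at one printed decimal (half-up).  Children with a missing
#' CARS score are excluded with a message reporting the count.
#'
#' @param tool_positive logical instrument calls.
#' @param cars_score paired CARS scores (may contain `NA`).
#' @return data frame with one row per band: `band`, `n`,
#'   `tool_positive`, `tool_negative`, `pct_positive`, `pct_negative`
#'   (percentages, 1 decimal; `NA` for empty bands).  The number of
#'   excluded children is attached as attribute `"n_excluded"`.
#' @export
cross_tab_severity <- function(tool_positive, cars_score) {
  if (length(tool_positive) != length(cars_score))
    stop_usage("cross_tab_severity: inputs must be paired per child")
  keep <- !is.na(cars_score)
  n_excl <- sum(!keep)
  if (n_excl > 0)
    message(sprintf("cross_tab_severity: excluded %d child(ren) with missing CARS score", n_excl))
  band <- factor(cars_band(cars_score[keep]), levels = CARS_BANDS)
  pos <- as.logical(tool_positive[keep])
  n <- as.integer(table(band))
  npos <- as.integer(tapply(pos, band, sum, default = 0L))
  out <- data.frame(
    band = CARS_BANDS,
    n = n,
    tool_positive = npos,
    tool_negative = n - npos,
    pct_positive = ifelse(n > 0, round_half_up(100 * npos / n, 1), NA_real_),
    pct_negative = ifelse(n > 0, round_half_up(100 * (n - npos) / n, 1), NA_real_),
    stringsAsFactors = FALSE
  )
  attr(out, "n_excluded") <- n_excl
  out
}

#' Cohen's kappa for two raters
#'
#' Chance-corrected agreement `kappa = (p_o - p_e) / (1 - p_e)` with the
#' expected agreement `p_e` taken from the product of the two raters'
#' marginal distributions.  Unweighted (the instrument's inter-rater
#' pilot uses a binary diagnosis).
#'
#' @param rater_a,rater_b paired categorical label vectors.
#' @return list with `statistic = "kappa"`, `value`, `n`, and `detail`
#'   (observed and expected agreement).
#' @export
#' @examples
#' cohens_kappa(rep(c("pos", "neg"), 10), rep(c("pos", "neg"), 10))$value  # 1
cohens_kappa <- function(rater_a, rater_b) {
  if (length(rater_a) != length(rater_b) || length(rater_a) == 0L)
    stop_usage("cohens_kappa: raters must give paired, non-empty labels")
  if (anyNA(rater_a) || anyNA(rater_b))
    stop_usage("cohens_kappa: missing labels are not allowed")
  a <- as.character(rater_a); b <- as.character(rater_b)
  cats <- sort(unique(c(a, b)))
  pa <- table(factor(a, cats)) / length(a)
  pb <- table(factor(b, cats)) / length(b)
  p_o <- mean(a == b)
  p_e <- sum(as.numeric(pa) * as.numeric(pb))
  if (1 - p_e < .Machine$double.eps)
    stop_usage("cohens_kappa: undefined, both raters are constant (expected agreement 1)")
  list(statistic = "kappa", value = (p_o - p_e) / (1 - p_e), n = length(a),
       detail = list(p_observed = p_o, p_expected = p_e))
}

#' Cronbach's alpha internal-consistency coefficient
#'
#' `alpha = k/(k-1) * (1 - sum(item variances) / variance(row totals))`
#' over a subjects-by-items score matrix, with the per-item
#' alpha-if-deleted values in `detail`.
#'
#' @param item_matrix numeric matrix or data frame, one row per subject,
#'   one column per item; at least 2 items and 2 subjects.
#' @return list with `statistic = "alpha"`, `value`, `n`, and `detail`
#'   (`alpha_if_deleted`, one per item).
#' @export
cronbach_alpha <- function(item_matrix) {
  m <- as.matrix(item_matrix)
  if (nrow(m) < 2L || ncol(m) < 2L)
    stop_usage("cronbach_alpha: need at least 2 subjects and 2 items")
  if (anyNA(m)) stop_usage("cronbach_alpha: missing scores are not allowed")
  alpha_of <- function(x) {
    k <- ncol(x)
    vt <- stats::var(rowSums(x))
    if (vt < .Machine$double.eps)
      stop_usage("cronbach_alpha: undefined, total-score variance is zero")
    k / (k - 1) * (1 - sum(apply(x, 2L, stats::var)) / vt)
  }
  aid <- if (ncol(m) > 2L) {
    vapply(seq_len(ncol(m)), function(j) alpha_of(m[, -j, drop = FALSE]), 0)
  } else rep(NA_real_, 2L)
  names(aid) <- colnames(m) %||% paste0("item", seq_len(ncol(m)))
  list(statistic = "alpha", value = alpha_of(m), n = nrow(m),
       detail = list(alpha_if_deleted = aid))
}

#' Pearson product-moment correlation
#'
#' @param x,y paired numeric vectors, `n >= 3`, both with positive
#'   variance.
#' @return list with `statistic = "pearson_r"`, `value`, `n`.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L || anyNA(x) || anyNA(y))
    stop_usage("pearson_r: need paired complete vectors with n >= 3")
  if (stats::var(x) < .Machine$double.eps || stats::var(y) < .Machine$double.eps)
    stop_usage("pearson_r: undefined, an input has zero variance")
  list(statistic = "pearson_r", value = stats::cor(x, y), n = length(x))
}
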