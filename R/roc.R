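#' Rank a labeled dataset best-first
#'
#' Sorts the records of a `labeled_dataset` so that the best-scoring
#' molecule comes first: descending score for `higher_is_better`, ascending
#' for `lower_is_better`. The sort is stable, so molecules with tied scores
#' keep their input order. Every metric in the package consumes this one
#' shared ranking, which makes all reported numbers mutually consistent.
#'
#' @param dataset a `labeled_dataset` (see [label_by_pattern()]).
#' @return Data frame with columns `name`, `score`, `is_active`, ordered
#'   best-first.
#' @export
rank_dataset <- function(dataset) {
  stopifnot(inherits(dataset, "labeled_dataset"))
  r <- dataset$records
  ord <- if (dataset$sort_direction == "higher_is_better") {
    order(-r$score)             # radix sort: stable
  } else {
    order(r$score)
  }
  r[ord, , drop = FALSE]
}

#' Compute a ROC curve
#'
#' Sweeps the ranked list best-first, maintaining running true-positive and
#' false-positive counts, and emits one vertex per distinct score value
#' (plus the origin and the terminal point), so a block of tied scores
#' produces a single diagonal segment rather than an arbitrary staircase.
#' This is the standard one-pass ROC construction for scored classifiers.
#'
#' @param dataset a `labeled_dataset`.
#' @return A `roc_curve`: a data frame with columns `fpr`, `tpr`, and
#'   `threshold` (the score at which the vertex is reached; `Inf`/`-Inf`
#'   at the origin depending on sort direction). `fpr` and `tpr` are
#'   non-decreasing, the first point is (0, 0) and the last (1, 1).
#' @examples
#' d <- label_by_pattern(data.frame(name = c("ACT1", "ACT2", "DEC1", "DEC2"),
#'                                  score = c(0.9, 0.8, 0.2, 0.1)), "ACT")
#' roc_curve(d)
#' @export
roc_curve <- function(dataset) {
  ranked <- rank_dataset(dataset)
  n_act <- dataset$n_actives
  n_dec <- dataset$n_total - n_act

  act <- ranked$is_active
  score <- ranked$score
  # vertex before each record whose score differs from its predecessor
  new_score <- c(TRUE, score[-1] != score[-length(score)])
  tp_run <- cumsum(act)
  fp_run <- cumsum(!act)
  # counts *before* each record, at positions where a vertex is emitted
  tp_before <- c(0L, tp_run)[which(new_score)]
  fp_before <- c(0L, fp_run)[which(new_score)]

  fpr <- c(fp_before, n_dec) / n_dec
  tpr <- c(tp_before, n_act) / n_act
  origin_thr <- if (dataset$sort_direction == "higher_is_better") Inf else -Inf
  threshold <- c(origin_thr, score[new_score])

  structure(data.frame(fpr = fpr, tpr = tpr, threshold = threshold),
            class = c("roc_curve", "data.frame"),
            sort_direction = dataset$sort_direction)
}

#' Trapezoidal area under a ROC curve
#'
#' @param curve a `roc_curve` as returned by [roc_curve()].
#' @return Area under the curve by the trapezoid rule, in \[0, 1\].
#' @keywords internal
trapezoid_area <- function(curve) {
  x <- curve$fpr
  y <- curve$tpr
  sum(diff(x) * (y[-1] + y[-length(y)]) / 2)
}

#' AUC with Hanley-McNeil standard error
#'
#' Computes the area under the ROC curve by the trapezoid rule over the
#' vertices of [roc_curve()]. Because tied scores are drawn as a single
#' diagonal segment, this area equals the Mann-Whitney statistic: the
#' fraction of (active, decoy) pairs in which the active is ranked better,
#' with tied pairs counting one half. The standard error is the
#' Hanley-McNeil nonparametric estimate (see [hanley_mcneil_se()]).
#'
#' @param dataset a `labeled_dataset`.
#' @return An `auc_result`: list with `auc`, `se`, `n_actives`, `n_decoys`.
#' @examples
#' d <- label_by_pattern(data.frame(name = c("ACT1", "ACT2", "DEC1", "DEC2"),
#'                                  score = c(0.9, 0.8, 0.2, 0.1)), "ACT")
#' roc_auc(d)
#' @export
roc_auc <- function(dataset) {
  stopifnot(inherits(dataset, "labeled_dataset"))
  curve <- roc_curve(dataset)
  auc <- trapezoid_area(curve)
  n_act <- dataset$n_actives
  n_dec <- dataset$n_total - n_act
  structure(list(auc = auc,
                 se = hanley_mcneil_se(auc, n_act, n_dec),
                 n_actives = n_act,
                 n_decoys = n_dec),
            class = "auc_result")
}

#' Hanley-McNeil standard error of an AUC
#'
#' Conservative nonparametric estimate of the sampling standard error of a
#' ROC AUC given the class sizes:
#' \deqn{SE = \sqrt{\frac{A(1-A) + (n_a-1)(Q_1 - A^2) + (n_d-1)(Q_2 - A^2)}
#'                       {n_a n_d}}}
#' with \eqn{Q_1 = A/(2-A)} and \eqn{Q_2 = 2A^2/(1+A)}. A negative rounding
#' residue inside the root is clamped to zero, so perfect (A = 1) and fully
#' inverted (A = 0) classifiers report SE = 0 exactly.
#'
#' @param auc AUC value in \[0, 1\].
#' @param n_actives number of actives (positives), >= 1.
#' @param n_decoys number of decoys (negatives), >= 1.
#' @return Standard error, a non-negative scalar (at most 0.5).
#' @examples
#' hanley_mcneil_se(0.773287667761, 860, 27524)
#' @export
hanley_mcneil_se <- function(auc, n_actives, n_decoys) {
  stopifnot(auc >= 0, auc <= 1, n_actives >= 1, n_decoys >= 1)
  q1 <- auc / (2 - auc)
  q2 <- 2 * auc^2 / (1 + auc)
  num <- auc * (1 - auc) +
    (n_actives - 1) * (q1 - auc^2) +
    (n_decoys - 1) * (q2 - auc^2)
  sqrt(max(num, 0) / (n_actives * n_decoys))
}

#' @export
print.auc_result <- function(x, ...) {
  cat(sprintf("AUC = %s +/- %s (Hanley-McNeil SE; %d actives, %d decoys)\n",
              format(x$auc, digits = 12), format(x$se, digits = 12),
              x$n_actives, x$n_decoys))
  invisible(x)
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("ROC curve with %d vertices (%s)\n", nrow(x),
              gsub("_", " ", attr(x, "sort_direction"))))
  print.data.frame(utils::head(as.data.frame(x), 10))
  if (nrow(x) > 10) cat("...\n")
  invisible(x)
}
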