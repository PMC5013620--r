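# Independent oracles used to cross-check the package's metrics.
# These deliberately share no code with the implementation: the AUC oracle
# counts pairs, the ROC oracle enumerates thresholds, the EFdec oracle
# walks the list with an explicit loop.

# Mann-Whitney pair counting with half credit for tied pairs
pair_count_auc <- function(dataset) {
  r <- dataset$records
  a <- r$score[r$is_active]
  d <- r$score[!r$is_active]
  if (dataset$sort_direction == "lower_is_better") {
    a <- -a
    d <- -d
  }
  mean(outer(a, d, function(x, y) (x > y) + 0.5 * (x == y)))
}

# direct transcription of the Hanley-McNeil SE formula
hm_se_transcription <- function(A, n_pos, n_neg) {
  Q1 <- A / (2 - A)
  Q2 <- 2 * A^2 / (1 + A)
  v <- (A * (1 - A) + (n_pos - 1) * (Q1 - A^2) + (n_neg - 1) * (Q2 - A^2)) /
    (n_pos * n_neg)
  sqrt(max(v, 0))
}

# direct transcription of RIE and BEDROC from 1-based active ranks
bedroc_transcription <- function(active_ranks, n_total, alpha) {
  n <- length(active_ranks)
  N <- n_total
  Ra <- n / N
  rie <- (sum(exp(-alpha * active_ranks / N)) / n) /
    ((1 / N) * (1 - exp(-alpha)) / (exp(alpha / N) - 1))
  rie * (Ra * sinh(alpha / 2) /
           (cosh(alpha / 2) - cosh(alpha / 2 - alpha * Ra))) +
    1 / (1 - exp(alpha * (1 - Ra)))
}

# threshold-enumeration ROC: one point per distinct score, plus the origin
roc_enumeration_oracle <- function(dataset) {
  s <- dataset$records$score
  act <- dataset$records$is_active
  if (dataset$sort_direction == "lower_is_better") s <- -s
  thr <- sort(unique(s), decreasing = TRUE)
  data.frame(
    fpr = c(0, vapply(thr, function(t) mean(s[!act] >= t), numeric(1))),
    tpr = c(0, vapply(thr, function(t) mean(s[act] >= t), numeric(1))))
}

# literal best-first walk for the decoy-fraction enrichment convention
efdec_walk_oracle <- function(dataset, x_percent) {
  s <- dataset$records$score
  act <- dataset$records$is_active
  if (dataset$sort_direction == "lower_is_better") s <- -s
  act <- act[order(-s)]
  n_act <- sum(act)
  target <- max(1, ceiling(x_percent / 100 * sum(!act)))
  seen_dec <- 0
  ligs <- 0
  for (k in seq_along(act)) {
    if (act[k]) {
      ligs <- ligs + 1
    } else {
      seen_dec <- seen_dec + 1
      if (seen_dec >= target) break
    }
  }
  ligs / n_act * 100
}

# --- dataset builders -------------------------------------------------------

make_dataset <- function(active_scores, decoy_scores,
                         direction = "higher_is_better") {
  df <- data.frame(
    name = c(sprintf("ACT%04d", seq_along(active_scores)),
             sprintf("DEC%04d", seq_along(decoy_scores))),
    score = c(active_scores, decoy_scores),
    stringsAsFactors = FALSE)
  label_by_pattern(df, "ACT", direction)
}

# actives placed at the given 1-based ranks of a strictly decreasing score list
dataset_from_ranks <- function(active_ranks, n_total) {
  is_act <- seq_len(n_total) %in% active_ranks
  nm <- ifelse(is_act, sprintf("ACT%05d", seq_len(n_total)),
               sprintf("DEC%05d", seq_len(n_total)))
  label_by_pattern(data.frame(name = nm, score = as.numeric(n_total:1),
                              stringsAsFactors = FALSE), "ACT")
}

random_dataset <- function(n_act, n_dec, ties = FALSE) {
  s <- stats::runif(n_act + n_dec)
  if (ties) s <- round(s, 1)
  make_dataset(s[seq_len(n_act)], s[-seq_len(n_act)])
}
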