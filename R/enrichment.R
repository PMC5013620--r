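round_half_away <- function(x) {
  # round-half-away-from-zero; base round() is round-half-even
  sign(x) * floor(abs(x) + 0.5)
}

#' Enrichment factor over the top X percent of the ranked list
#'
#' The classic docking enrichment factor:
#' \deqn{EF_X = \frac{Ligs_{X\%}/Mols_{X\%}}{Ligs_{all}/Mols_{all}}}
#' where `Mols_X%` is the size of the top slice, `Ligs_X%` the number of
#' actives in it, and the denominator is the active fraction of the whole
#' library. A value of 1 means no enrichment over random selection; the
#' maximum attainable value is `Mols_all / Ligs_all`.
#'
#' The slice size is `round(x_percent/100 * n_total)` with halves rounded
#' away from zero, floored at 1 so the metric is defined for small files.
#'
#' @param dataset a `labeled_dataset`.
#' @param x_percent slice size as a percentage in (0, 100].
#' @return An `enrichment_result`: list with `x_percent`, `value`,
#'   `convention = "top_fraction"`, `ligs_x` (actives in the slice) and
#'   `mols_x` (slice size).
#' @examples
#' d <- label_by_pattern(data.frame(name = c("ACT1", "DEC1", "DEC2", "DEC3"),
#'                                  score = c(4, 3, 2, 1)), "ACT")
#' enrichment_factor(d, 25)$value   # top molecule is active: EF = 4
#' @export
enrichment_factor <- function(dataset, x_percent) {
  stopifnot(inherits(dataset, "labeled_dataset"))
  if (!is.numeric(x_percent) || length(x_percent) != 1L ||
      x_percent <= 0 || x_percent > 100)
    stop("'x_percent' must be in (0, 100]", call. = FALSE)

  ranked <- rank_dataset(dataset)
  mols_x <- max(1L, as.integer(round_half_away(x_percent / 100 * dataset$n_total)))
  ligs_x <- sum(ranked$is_active[seq_len(mols_x)])
  value <- (ligs_x / mols_x) / (dataset$n_actives / dataset$n_total)
  structure(list(x_percent = x_percent, value = value,
                 convention = "top_fraction",
                 ligs_x = ligs_x, mols_x = mols_x),
            class = "enrichment_result")
}

#' Enrichment factor at X percent of decoys found
#'
#' The second convention common in the literature: walk the ranked list
#' best-first until X percent of the decoy molecules have been seen, and
#' report the percentage of all actives recovered by that point:
#' \deqn{EF_{Xdec} = \frac{Ligs_{X\%dec}}{Ligs_{all}} \times 100}
#' The decoy threshold is `ceiling(x_percent/100 * n_decoys)`, so the
#' stated decoy fraction is actually reached; actives are counted strictly
#' before the terminating decoy. The value lies in \[0, 100\]: 100 for
#' perfect separation, 0 when no active precedes any counted decoy.
#'
#' @inheritParams enrichment_factor
#' @return An `enrichment_result` with `convention = "decoy_fraction"`;
#'   `ligs_x` is the number of actives recovered, `mols_x` the number of
#'   molecules walked (terminating decoy included).
#' @export
enrichment_factor_decoys <- function(dataset, x_percent) {
  stopifnot(inherits(dataset, "labeled_dataset"))
  if (!is.numeric(x_percent) || length(x_percent) != 1L ||
      x_percent <= 0 || x_percent > 100)
    stop("'x_percent' must be in (0, 100]", call. = FALSE)

  ranked <- rank_dataset(dataset)
  n_dec <- dataset$n_total - dataset$n_actives
  target <- max(1L, as.integer(ceiling(x_percent / 100 * n_dec)))
  dec_run <- cumsum(!ranked$is_active)
  stop_pos <- match(target, dec_run)      # first position reaching the target
  ligs_x <- sum(ranked$is_active[seq_len(stop_pos)])  # terminating row is a decoy
  value <- ligs_x / dataset$n_actives * 100
  structure(list(x_percent = x_percent, value = value,
                 convention = "decoy_fraction",
                 ligs_x = ligs_x, mols_x = stop_pos),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  if (x$convention == "top_fraction") {
    cat(sprintf("EF_%s = %s  (%d actives among top %d molecules)\n",
                format(x$x_percent), format(x$value, digits = 12),
                x$ligs_x, x$mols_x))
  } else {
    cat(sprintf("EF_%s%%decs = %s  (%d actives recovered at %s%% decoys)\n",
                format(x$x_percent), format(x$value, digits = 12),
                x$ligs_x, format(x$x_percent)))
  }
  invisible(x)
}
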