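#' Simulate a synthetic virtual-screening score set
#'
#' Generates a deterministic synthetic screening result: decoy scores drawn
#' from a baseline Gaussian and active scores from a location-shifted
#' Gaussian. The Gaussian model gives analytic control of the expected
#' AUC via the probit relation
#' `AUC = pnorm((active_location - decoy_location) / (spread * sqrt(2)))`
#' (for `higher_is_better`): the defaults (shift 1, spread 1) emulate a
#' moderately successful screen with expected AUC of about 0.76, a gap of
#' 0 gives a null screen (AUC 0.5), and a very large gap gives perfect
#' separation. A `tie_fraction` share of all scores is rounded to one
#' decimal, mimicking docking output printed with limited score precision
#' and forcing tied ranks.
#'
#' Active names are `ACT00001, ACT00002, ...` and decoys `DEC00001, ...`,
#' so the set can be labeled either with the pattern `"ACT"` or with the
#' returned active-name list; both give the same dataset. The same
#' arguments always produce the same values.
#'
#' @param n_actives,n_decoys class sizes, each at least 1.
#' @param active_location,decoy_location mean score of each population.
#' @param spread common standard deviation, positive.
#' @param tie_fraction fraction in \[0, 1\] of scores snapped to a 0.1 grid.
#' @param seed integer seed; the generator leaves the global RNG state as
#'   it found it.
#' @return List with `records` (data frame of `name`, `score`, actives
#'   first) and `active_names` (character vector).
#' @examples
#' sim <- simulate_screen(10, 90, seed = 7)
#' head(sim$records)
#' @export
simulate_screen <- function(n_actives, n_decoys,
                            active_location = 1, decoy_location = 0,
                            spread = 1, tie_fraction = 0, seed = 1L) {
  stopifnot(n_actives >= 1, n_decoys >= 1, spread > 0,
            tie_fraction >= 0, tie_fraction <= 1)
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old_seed)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old_seed, envir = globalenv())
    }
  })
  set.seed(seed)

  score <- c(stats::rnorm(n_actives, active_location, spread),
             stats::rnorm(n_decoys, decoy_location, spread))
  n <- n_actives + n_decoys
  if (tie_fraction > 0) {
    idx <- sample.int(n, size = round(tie_fraction * n))
    score[idx] <- round(score[idx], 1)
  }
  name <- c(sprintf("ACT%05d", seq_len(n_actives)),
            sprintf("DEC%05d", seq_len(n_decoys)))
  list(records = data.frame(name = name, score = score,
                            stringsAsFactors = FALSE),
       active_names = name[seq_len(n_actives)])
}

#' Write a simulated score set to fixture files
#'
#' Emits the plain-text score table and active-name list in exactly the
#' formats [read_score_table()] and [read_active_list()] consume, so the
#' generated data round-trips with zero skipped rows. The score is placed
#' in `score_column`; intervening columns (if any) are filled with the row
#' index so tables resembling multi-column docking output can be produced.
#' Identical arguments produce byte-identical files.
#'
#' @inheritParams simulate_screen
#' @param table_path path for the score table.
#' @param list_path optional path for the active-name list (skipped if
#'   `NULL`).
#' @param score_column column to hold the score (>= 2).
#' @return Invisibly, the `simulate_screen()` result.
#' @export
write_screen_fixture <- function(table_path, list_path = NULL,
                                 n_actives = 50, n_decoys = 950,
                                 active_location = 1, decoy_location = 0,
                                 spread = 1, tie_fraction = 0, seed = 1L,
                                 score_column = 2L) {
  stopifnot(score_column >= 2L)
  sim <- simulate_screen(n_actives, n_decoys, active_location,
                         decoy_location, spread, tie_fraction, seed)
  rec <- sim$records
  pad <- if (score_column > 2L) {
    apply(vapply(seq_len(score_column - 2L),
                 function(j) as.character(seq_len(nrow(rec))),
                 character(nrow(rec))), 1L, paste, collapse = " ")
  } else NULL
  score_txt <- sprintf("%.12g", rec$score)
  lines <- if (is.null(pad)) paste(rec$name, score_txt)
           else paste(rec$name, pad, score_txt)
  writeLines(lines, table_path)
  if (!is.null(list_path)) writeLines(sim$active_names, list_path)
  invisible(sim)
}
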