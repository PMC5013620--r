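#' Read a whitespace-delimited score table
#'
#' Parses a plain-text score table as produced by docking or other virtual
#' screening programs: one row per molecule, the molecule name in column 1
#' and a numeric score/fitness/energy in a user-selected column. Fields are
#' separated by any run of spaces or tabs; lines beginning with `#` and
#' blank lines are ignored.
#'
#' Rows whose score cell is non-numeric (e.g. a header line, or an `NA`
#' placeholder), and rows with fewer columns than `score_column`, are
#' skipped with a warning giving the running skip count. Non-finite scores
#' (`Inf`, `NaN`) are likewise skipped: only finite scores are admitted.
#'
#' @param source path to a score file, or a connection, or a character
#'   vector of lines (useful for tests).
#' @param score_column 1-based index of the column holding the score.
#'   Must be at least 2 (column 1 is the name).
#' @return A data frame with columns `name` (character) and `score`
#'   (double), one row per parseable input row, in file order. The number
#'   of skipped rows is attached as attribute `skipped`.
#' @seealso [collapse_duplicates()], [label_by_pattern()], [label_by_list()]
#' @examples
#' tbl <- read_score_table(c("CHEMBL25 1.2 3.4 5.6 -7.8",
#'                           "ZINC0001 0.1 0.2 0.3 -1.5"), score_column = 5)
#' tbl$score
#' @export
read_score_table <- function(source, score_column = 2L) {
  score_column <- as.integer(score_column)
  if (is.na(score_column) || score_column < 2L)
    stop("'score_column' must be an integer >= 2 (column 1 holds the name)",
         call. = FALSE)

  lines <- if (is.character(source) && length(source) != 1L) {
    source
  } else if (is.character(source) && !file.exists(source)) {
    if (grepl("[ \t\n]", source)) {
      strsplit(source, "\n", fixed = TRUE)[[1]]   # literal table content
    } else {
      stop("cannot open score table: ", source, call. = FALSE)
    }
  } else {
    readLines(source, warn = FALSE)
  }

  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  if (length(lines) == 0L)
    stop("no records: score table is empty", call. = FALSE)

  fields <- strsplit(trimws(lines), "[ \t]+")
  n_fields <- lengths(fields)
  name <- vapply(fields, `[[`, character(1), 1L)
  cell <- rep(NA_character_, length(fields))
  ok_width <- n_fields >= score_column
  cell[ok_width] <- vapply(fields[ok_width], `[[`, character(1), score_column)
  score <- suppressWarnings(as.numeric(cell))
  keep <- ok_width & !is.na(score) & is.finite(score) & nzchar(name)

  skipped <- sum(!keep)
  if (skipped > 0L)
    warning(sprintf("skipped %d row(s) with missing or non-numeric score in column %d",
                    skipped, score_column), call. = FALSE)
  if (!any(keep))
    stop("no records: zero parseable rows in score table", call. = FALSE)

  out <- data.frame(name = name[keep], score = score[keep],
                    stringsAsFactors = FALSE)
  attr(out, "skipped") <- skipped
  out
}

#' Collapse duplicate molecule entries by score averaging
#'
#' Score files concatenated from several docking runs often list the same
#' molecule more than once. This reduces the table to one record per
#' distinct name, with the score replaced by the arithmetic mean of all
#' scores observed for that name. First-appearance order of names is
#' preserved, so the operation is idempotent.
#'
#' @param records data frame with columns `name` and `score`, as returned
#'   by [read_score_table()].
#' @return Data frame with columns `name` and `score`, one row per distinct
#'   name.
#' @examples
#' collapse_duplicates(data.frame(name = c("a", "a", "b"),
#'                                score = c(1, 3, 5)))
#' @export
collapse_duplicates <- function(records) {
  stopifnot(is.data.frame(records), all(c("name", "score") %in% names(records)))
  f <- factor(records$name, levels = unique(records$name))
  means <- vapply(split(records$score, f), mean, numeric(1))
  data.frame(name = levels(f), score = unname(means), stringsAsFactors = FALSE)
}

new_labeled_dataset <- function(records, is_active, sort_direction) {
  n_actives <- sum(is_active)
  n_total <- nrow(records)
  if (anyDuplicated(records$name))
    stop("record names must be unique; run collapse_duplicates() first",
         call. = FALSE)
  if (n_actives < 1L)
    stop("labeling error: zero actives in dataset", call. = FALSE)
  if (n_total - n_actives < 1L)
    stop("labeling error: zero decoys in dataset", call. = FALSE)
  structure(
    list(records = data.frame(name = records$name, score = records$score,
                              is_active = is_active,
                              stringsAsFactors = FALSE),
         n_actives = n_actives,
         n_total = n_total,
         sort_direction = sort_direction),
    class = "labeled_dataset")
}

check_direction <- function(direction) {
  match.arg(direction, c("higher_is_better", "lower_is_better"))
}

#' Label actives by a name pattern
#'
#' Marks a record as active when the regular expression `pattern` matches
#' at the *start* of its name (the typical benchmark convention: all active
#' ligands share a name prefix such as `"CHEMBL"`, decoys do not). Full
#' regular-expression syntax is available; the match is anchored at the
#' first character.
#'
#' @param records data frame with unique `name`s and finite `score`s
#'   (after [collapse_duplicates()]).
#' @param pattern regular expression matched against the start of each name.
#' @param direction `"higher_is_better"` (default; larger score = better
#'   rank) or `"lower_is_better"` (e.g. docking energies).
#' @return A `labeled_dataset`: a list with elements `records` (data frame
#'   of `name`, `score`, `is_active`), `n_actives`, `n_total`, and
#'   `sort_direction`. This object is the single input to all metric
#'   functions.
#' @examples
#' d <- label_by_pattern(data.frame(name = c("CHEMBL12", "ZINC01"),
#'                                  score = c(2, 1)), "CHEMBL")
#' d$n_actives
#' @export
label_by_pattern <- function(records, pattern,
                             direction = c("higher_is_better",
                                           "lower_is_better")) {
  direction <- match.arg(direction)
  anchored <- paste0("^(?:", pattern, ")")
  is_active <- grepl(anchored, records$name, perl = TRUE)
  new_labeled_dataset(records, is_active, direction)
}

#' Label actives by an explicit name list
#'
#' Marks a record as active when its name appears (exact, case-sensitive
#' match) in `active_names`. Names in `active_names` that match no record
#' are counted and reported as a warning, since they usually indicate a
#' mismatch between the list file and the score table.
#'
#' @inheritParams label_by_pattern
#' @param active_names character vector of active molecule names, e.g. read
#'   with [read_active_list()].
#' @return A `labeled_dataset`; see [label_by_pattern()].
#' @export
label_by_list <- function(records, active_names,
                          direction = c("higher_is_better",
                                        "lower_is_better")) {
  direction <- match.arg(direction)
  if (length(active_names) == 0L)
    stop("'active_names' is empty", call. = FALSE)
  active_names <- unique(active_names)
  is_active <- records$name %in% active_names
  unmatched <- sum(!(active_names %in% records$name))
  if (unmatched > 0L)
    warning(sprintf("%d listed active name(s) not found in the score table",
                    unmatched), call. = FALSE)
  new_labeled_dataset(records, is_active, direction)
}

#' Read an active-name list file
#'
#' One molecule name per line; blank lines and `#` comment lines ignored.
#'
#' @param path path to the list file (or a character vector of lines).
#' @return Character vector of names.
#' @export
read_active_list <- function(path) {
  lines <- if (is.character(path) && length(path) > 1L) path
           else readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines[!grepl("^(#|$)", lines)]
}

#' @export
print.labeled_dataset <- function(x, ...) {
  cat(sprintf("Labeled screening dataset: %d molecules (%d actives, %d decoys), %s\n",
              x$n_total, x$n_actives, x$n_total - x$n_actives,
              gsub("_", " ", x$sort_direction)))
  invisible(x)
}
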