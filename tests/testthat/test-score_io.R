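test_that("score tables parse name and selected score column", {
  tbl <- read_score_table(c("CHEMBL25 1.2 3.4 5.6 -7.8",
                            "ZINC0001 0.1 0.2 0.3 -1.5"), score_column = 5)
  expect_equal(tbl$name, c("CHEMBL25", "ZINC0001"))
  expect_equal(tbl$score, c(-7.8, -1.5))
  expect_identical(attr(tbl, "skipped"), 0L)

  min_tbl <- read_score_table("mol1 0.0", score_column = 2)
  expect_equal(min_tbl$score, 0)

  # tabs and repeated whitespace both separate fields
  expect_equal(read_score_table("m1\t\t3.5   9", score_column = 2)$score, 3.5)
})

test_that("unparseable rows are skipped with a count, not fatal", {
  lines <- c("# a comment", "", "m1 1.5", "m2 NA", "m3 2.5")
  expect_warning(tbl <- read_score_table(lines, 2), "skipped 1")
  expect_equal(tbl$name, c("m1", "m3"))
  expect_identical(attr(tbl, "skipped"), 1L)

  # a row narrower than the score column is skipped too
  expect_warning(tbl2 <- read_score_table(c("m1 1 2 3", "m2 1"), 3),
                 "skipped 1")
  expect_equal(tbl2$name, "m1")

  # non-finite scores are not admitted
  expect_warning(tbl3 <- read_score_table(c("m1 Inf", "m2 2"), 2), "skipped")
  expect_equal(tbl3$name, "m2")
})

test_that("degenerate score tables raise errors", {
  expect_error(read_score_table(character(0)), "no records")
  expect_error(read_score_table(c("# only", "  "), 2), "no records")
  expect_error(suppressWarnings(read_score_table(c("m1 x", "m2 y"), 2)),
               "zero parseable")
  expect_error(read_score_table("m1 1", score_column = 1), "score_column")
})

test_that("duplicate names collapse to the mean score, preserving order", {
  out <- collapse_duplicates(data.frame(name = c("a", "a", "b"),
                                        score = c(1, 3, 5)))
  expect_equal(out, data.frame(name = c("a", "b"), score = c(2, 5)))

  uniq <- data.frame(name = c("x", "y"), score = c(1.5, 2.5))
  expect_equal(collapse_duplicates(uniq), uniq)

  # group-by-then-average oracle on many duplicates
  set.seed(11)
  rec <- data.frame(name = sample(sprintf("m%03d", 1:100), 1000, TRUE),
                    score = rnorm(1000))
  got <- collapse_duplicates(rec)
  oracle <- vapply(got$name, function(nm) mean(rec$score[rec$name == nm]),
                   numeric(1))
  expect_equal(got$score, unname(oracle), tolerance = 1e-12)
  expect_equal(got$name, unique(rec$name))
  # idempotence
  expect_equal(collapse_duplicates(got), got)
})

test_that("pattern labeling is anchored at the start of the name", {
  d <- label_by_pattern(data.frame(name = c("CHEMBL12", "ZINC01"),
                                   score = c(2, 1)), "CHEMBL")
  expect_equal(d$records$is_active, c(TRUE, FALSE))
  expect_equal(d$n_actives, 1L)
  expect_equal(d$n_total, 2L)

  # full regular-expression power, still anchored
  d2 <- label_by_pattern(data.frame(name = c("AX3", "AB", "BX1"),
                                    score = c(3, 2, 1)), "^A.[0-9]+")
  expect_equal(d2$records$name[d2$records$is_active], "AX3")

  # a mid-name match must not label the record active
  d3 <- label_by_pattern(data.frame(name = c("ACT1", "xACT2"),
                                    score = c(2, 1)), "ACT")
  expect_equal(d3$records$is_active, c(TRUE, FALSE))

  tbl <- data.frame(name = c("ACT1", "ACT2"), score = c(1, 2))
  expect_error(label_by_pattern(tbl, "ACT"), "zero decoys")
  expect_error(label_by_pattern(tbl, "ZZZ"), "zero actives")
})

test_that("list labeling matches exactly and warns about unknown names", {
  rec <- data.frame(name = c("a", "b", "c"), score = c(3, 2, 1))
  d <- label_by_list(rec, c("a", "c"))
  expect_equal(d$records$is_active, c(TRUE, FALSE, TRUE))

  expect_warning(d2 <- label_by_list(rec[1:2, ], c("a", "zzz")),
                 "1 listed active")
  expect_equal(d2$n_actives, 1L)

  # case sensitivity
  expect_error(suppressWarnings(label_by_list(rec, "A")), "zero actives")
  expect_error(label_by_list(rec, rec$name), "zero decoys")
  expect_error(label_by_list(rec, character(0)), "empty")

  set.seed(5)
  nm <- sprintf("mol%02d", 1:50)
  rec2 <- data.frame(name = nm, score = runif(50))
  act <- sample(nm, 10)
  d3 <- label_by_list(rec2, act)
  expect_equal(d3$n_actives, 10L)
  expect_equal(d3$n_total, 50L)
  expect_equal(sort(d3$records$name[d3$records$is_active]), sort(act))
})

test_that("pattern and list labeling agree when the list holds the matches", {
  set.seed(7)
  for (rep in 1:5) {
    n <- sample(20:60, 1)
    nm <- ifelse(runif(n) < 0.3, sprintf("ACT%03d", seq_len(n)),
                 sprintf("DEC%03d", seq_len(n)))
    if (!any(startsWith(nm, "ACT")) || all(startsWith(nm, "ACT"))) next
    rec <- data.frame(name = nm, score = rnorm(n))
    by_pat <- label_by_pattern(rec, "ACT")
    by_lst <- label_by_list(rec, nm[startsWith(nm, "ACT")])
    expect_identical(by_pat, by_lst)
    expect_equal(by_pat$n_actives + sum(!by_pat$records$is_active),
                 by_pat$n_total)
  }
})

test_that("active list files ignore blanks and comments", {
  expect_equal(read_active_list(c("a", "", "# note", " b ")), c("a", "b"))
})
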