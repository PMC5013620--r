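test_that("ranking is best-first in either direction and stable on ties", {
  d <- make_dataset(3, c(1, 2))
  expect_equal(rank_dataset(d)$score, c(3, 2, 1))
  d_low <- make_dataset(3, c(1, 2), direction = "lower_is_better")
  expect_equal(rank_dataset(d_low)$score, c(1, 2, 3))

  tied <- make_dataset(c(1, 1), c(1, 1))
  expect_equal(rank_dataset(tied)$name,
               c("ACT0001", "ACT0002", "DEC0001", "DEC0002"))

  set.seed(21)
  d_rand <- random_dataset(40, 160)
  expect_equal(rank_dataset(d_rand)$score,
               sort(d_rand$records$score, decreasing = TRUE))
})

test_that("ROC emits one vertex per distinct score, ties as diagonals", {
  d <- make_dataset(c(0.9, 0.8), c(0.2, 0.1))
  cv <- roc_curve(d)
  expect_equal(cv$fpr, c(0, 0, 0, 0.5, 1))
  expect_equal(cv$tpr, c(0, 0.5, 1, 1, 1))
  expect_equal(cv$threshold, c(Inf, 0.9, 0.8, 0.2, 0.1))

  # one active and one decoy fully tied: a single diagonal segment
  tied <- make_dataset(0.5, 0.5)
  cv2 <- roc_curve(tied)
  expect_equal(cv2$fpr, c(0, 1))
  expect_equal(cv2$tpr, c(0, 1))
})

test_that("ROC vertices match a threshold-enumeration oracle", {
  set.seed(31)
  for (rep in 1:20) {
    d <- random_dataset(sample(3:12, 1), sample(5:18, 1), ties = TRUE)
    cv <- roc_curve(d)
    oracle <- roc_enumeration_oracle(d)
    expect_equal(cv$fpr, oracle$fpr, tolerance = 1e-12)
    expect_equal(cv$tpr, oracle$tpr, tolerance = 1e-12)
    # structural invariants
    expect_equal(cv$fpr[1], 0)
    expect_equal(cv$tpr[1], 0)
    expect_equal(cv$fpr[nrow(cv)], 1)
    expect_equal(cv$tpr[nrow(cv)], 1)
    expect_true(all(diff(cv$fpr) >= 0))
    expect_true(all(diff(cv$tpr) >= 0))
    expect_true(all(diff(cv$threshold) < 0))
    expect_equal(nrow(cv), length(unique(d$records$score)) + 1L)
  }
})

test_that("trapezoidal AUC equals pair counting with half-tie credit", {
  expect_equal(roc_auc(make_dataset(c(0.9, 0.8), c(0.2, 0.1)))$auc, 1)
  expect_equal(roc_auc(make_dataset(c(0.9, 0.8), c(0.2, 0.1)))$se, 0)
  # of 4 pairs, the 0.9 active wins 2, the 0.6 active wins 0
  expect_equal(roc_auc(make_dataset(c(0.9, 0.6), c(0.8, 0.7)))$auc, 0.5)
  # every pair tied counts one half
  expect_equal(roc_auc(make_dataset(rep(1, 3), rep(1, 7)))$auc, 0.5)

  set.seed(41)
  for (rep in 1:20) {
    d <- random_dataset(sample(5:60, 1), sample(5:200, 1),
                        ties = rep %% 2 == 0)
    expect_equal(roc_auc(d)$auc, pair_count_auc(d), tolerance = 1e-12)
  }
})

test_that("reversing the sort direction maps AUC to 1 - AUC", {
  set.seed(51)
  for (rep in 1:10) {
    s_act <- runif(10)
    s_dec <- runif(30)
    if (rep > 5) {
      s_act <- round(s_act, 1)
      s_dec <- round(s_dec, 1)
    }
    a_hi <- roc_auc(make_dataset(s_act, s_dec))$auc
    a_lo <- roc_auc(make_dataset(s_act, s_dec,
                                 direction = "lower_is_better"))$auc
    expect_equal(a_lo, 1 - a_hi, tolerance = 1e-12)
  }
})

test_that("Hanley-McNeil SE matches its closed form and symmetries", {
  expect_equal(hanley_mcneil_se(1, 50, 500), 0)
  expect_equal(hanley_mcneil_se(0, 50, 500), 0)
  # A = 0.5, 10 vs 10: Q1 = Q2 = 1/3
  expect_equal(hanley_mcneil_se(0.5, 10, 10),
               sqrt((0.25 + 18 * (1 / 3 - 0.25)) / 100), tolerance = 1e-12)
  expect_equal(hanley_mcneil_se(0.5, 10, 10), 0.1322875655532295,
               tolerance = 1e-12)

  grid <- expand.grid(A = c(0.05, 0.25, 0.5, 0.7732877, 0.95, 0.999),
                      na = c(1, 5, 86, 860), nd = c(1, 20, 1000, 27524))
  for (k in seq_len(nrow(grid))) {
    se <- hanley_mcneil_se(grid$A[k], grid$na[k], grid$nd[k])
    expect_equal(se, hm_se_transcription(grid$A[k], grid$na[k], grid$nd[k]),
                 tolerance = 1e-12)
    # symmetric under A -> 1 - A with the class counts swapped
    expect_lt(abs(se - hanley_mcneil_se(1 - grid$A[k], grid$nd[k],
                                        grid$na[k])), 1e-12)
    expect_true(se >= 0 && se <= 0.5)
  }
})

test_that("the reported AUC is exactly the trapezoid area of the curve", {
  set.seed(61)
  for (rep in 1:10) {
    d <- random_dataset(8, 40, ties = TRUE)
    cv <- roc_curve(d)
    area <- sum(diff(cv$fpr) * (cv$tpr[-1] + cv$tpr[-nrow(cv)]) / 2)
    expect_equal(roc_auc(d)$auc, area, tolerance = 1e-15)
  }
})
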