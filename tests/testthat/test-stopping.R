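mk_trace <- function(pred = NULL, acc = NULL, ou = NULL, mee = NULL,
                     consistency = NULL) {
  n <- max(lengths(list(pred, acc, ou, mee, consistency)))
  tr <- data.frame(round = seq_len(n),
                   n_observed = seq_len(n) * 10,
                   fraction = seq_len(n) / n,
                   accuracy = acc %||% rep(0.5, n),
                   ou = ou %||% rep(1, n),
                   mee = mee %||% rep(0.5, n),
                   label_consistency = consistency %||% rep(0.5, n))
  if (!is.null(pred)) tr$predicted_accuracy <- pred
  class(tr) <- c("al_trace", "data.frame")
  tr
}

test_that("the predicted-accuracy rule stops at the first crossing", {
  tr <- mk_trace(pred = c(0.5, 0.7, 0.92))
  d <- pa_stop(tr)                      # default threshold 0.9
  expect_equal(d$round, 3)
  expect_equal(d$threshold, 0.9)
  expect_equal(d$reason, "threshold crossed")
  expect_equal(d$fraction, 1)

  d2 <- pa_stop(mk_trace(pred = c(0.5, 0.6, 0.7)), threshold = 0.9)
  expect_equal(d2$round, 3)
  expect_equal(d2$reason, "pool exhausted")
  expect_error(pa_stop(mk_trace(acc = c(0.5, 0.6))), "predicted_accuracy")
})

test_that("overall uncertainty and minimum expected error match closed forms", {
  P <- matrix(c(0.5, 0.5), 1)
  pool <- matrix(TRUE, 1, 2)
  expect_equal(overall_uncertainty(P, pool), log(2))
  expect_equal(minimum_expected_error(P, pool), 0.5)

  Pm <- matrix(c(0.5, 0.9), 1)
  expect_equal(overall_uncertainty(Pm, pool),
               (binary_entropy(0.5) + binary_entropy(0.9)) / 2)
  expect_equal(overall_uncertainty(Pm, pool), 0.5091, tolerance = 1e-4)
  expect_equal(minimum_expected_error(matrix(c(0.5, 0.8), 1), pool), 0.35)
  expect_lt(overall_uncertainty(matrix(c(0.001, 0.999), 1), pool), 0.01)
  expect_equal(minimum_expected_error(matrix(0.99, 1, 2), pool), 0.01)
  expect_error(overall_uncertainty(P, matrix(FALSE, 1, 2)), "empty")
  expect_error(minimum_expected_error(P, matrix(FALSE, 1, 2)), "empty")
})

test_that("entropy and expected error order pool entries identically", {
  set.seed(2)
  P <- stats::runif(200, 0.001, 0.999)
  expect_equal(order(binary_entropy(P)), order(1 - pmax(P, 1 - P)))
})

test_that("OU and MEE rules support fixed and adapted thresholds", {
  tr <- mk_trace(ou = c(0.5, 0.2, 0.1, 0.05), mee = c(0.4, 0.2, 0.11, 0.02),
                 consistency = c(NA, 0.8, 0.995, 0.999))
  expect_equal(ou_stop(tr, 0.12)$round, 3)
  expect_equal(mee_stop(tr, 0.12)$round, 3)
  expect_equal(mee_stop(tr, 0.03)$round, 4)
  expect_equal(ou_stop(tr, 0.01)$reason, "pool exhausted")
  ## adapted: stop at the first label-consistent round
  expect_equal(ou_stop(tr, "adapted")$round, 3)
  expect_equal(mee_stop(tr, "adapted")$round, 3)
  ## stops never exceed the trace length
  for (thr in c(0.03, 0.06, 0.09, 0.12, 1)) {
    expect_lte(ou_stop(tr, thr)$round, nrow(tr))
    expect_lte(mee_stop(tr, thr)$round, nrow(tr))
  }
})

test_that("best stopping time is the first accuracy argmax", {
  expect_equal(best_stopping_time(mk_trace(acc = c(0.6, 0.9, 0.9, 0.85))), 2 / 4)
  expect_equal(best_stopping_time(mk_trace(acc = c(0.5, 0.7, 0.9))), 1)
  expect_equal(best_stopping_time(mk_trace(acc = rep(0.7, 5))), 1 / 5)
})

test_that("delta_ave summarises distances to the best stopping time", {
  expect_equal(delta_ave(c(10, 20, 30), c(10, 20, 30))$mean, 0)
  expect_equal(delta_ave(c(30, 50), c(20, 40))$mean, 10)
  d <- delta_ave(c(10, 60), c(40, 40))
  expect_equal(d$mean, 25)
  expect_equal(d$sd, stats::sd(c(30, 20)))
  expect_error(delta_ave(c(1, 2), 1), "equal length")
})

test_that("rank-based AUC agrees with brute-force pair counting", {
  Y <- matrix(c(1, 1, -1, -1), 1)
  F1 <- matrix(c(0.9, 0.8, 0.2, 0.1), 1)
  expect_equal(interaction_auc(F1, Y, 1:4), 1)
  expect_equal(interaction_auc(matrix(0.5, 1, 4), Y, 1:4), 0.5)
  expect_equal(interaction_auc(matrix(c(0.9, 0.4, 0.6, 0.1), 1), Y, 1:4), 0.75)

  brute_auc <- function(s, l) {
    pos <- s[l == 1]; neg <- s[l == -1]
    cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
    mean(cmp)
  }
  set.seed(6)
  for (i in 1:10) {
    n <- sample(10:100, 1)
    l <- sample(c(-1, 1), n, replace = TRUE)
    if (length(unique(l)) < 2) l[1:2] <- c(-1, 1)
    s <- round(stats::rnorm(n), 1)          # rounding induces ties
    expect_equal(interaction_auc(matrix(s, 1), matrix(l, 1), seq_len(n)),
                 brute_auc(s, l))
  }
  expect_error(interaction_auc(F1, matrix(1, 1, 4), 1:4), "both classes")
})

test_that("rank-based AUC matches an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(9)
  s <- stats::rnorm(80)
  l <- sample(c(-1, 1), 80, replace = TRUE)
  ours <- interaction_auc(matrix(s, 1), matrix(l, 1), 1:80)
  ref <- suppressMessages(as.numeric(pROC::auc(pROC::roc(l, s, quiet = TRUE))))
  expect_equal(ours, ref, tolerance = 1e-12)
})
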