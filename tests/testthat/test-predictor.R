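fake_trace <- function(n, seed, adj_fun) {
  set.seed(seed)
  f <- matrix(stats::runif(n * 13), n, 13,
              dimnames = list(NULL, paste0("f", 1:13)))
  fraction <- seq(0.05, 0.9, length.out = n)
  adj <- adj_fun(f)
  tr <- data.frame(round = seq_len(n), n_observed = round(fraction * 400),
                   fraction = fraction, accuracy = adj + fraction,
                   ou = stats::runif(n), mee = stats::runif(n),
                   label_consistency = stats::runif(n))
  tr <- cbind(tr, as.data.frame(f))
  class(tr) <- c("al_trace", "data.frame")
  tr
}

test_that("a planted linear signal in one feature is recovered by the lasso", {
  traces <- lapply(1:22, function(s)
    fake_trace(15, s, function(f) 0.3 * f[, 1] - 0.1))
  fit <- fit_accuracy_regressor(traces, folds = 11, seed = 1)
  expect_s3_class(fit, "accuracy_predictor")
  expect_lt(min(fit$cv$cvm), 1e-4)

  ## in-sample predictions reproduce the construction
  tr <- traces[[1]]
  pred <- predict(fit, as.matrix(tr[, paste0("f", 1:13)]), tr$fraction)
  expect_lt(mean((pred - tr$accuracy)^2), 1e-4)
})

test_that("constant adjusted accuracy collapses to an intercept-only model", {
  traces <- lapply(1:12, function(s)
    fake_trace(10, s, function(f) 0.2))
  fit <- fit_accuracy_regressor(traces, folds = 11, seed = 1)
  expect_equal(fit$intercept, 0.2, tolerance = 1e-8)
  expect_true(all(fit$beta == 0))
  expect_equal(predict(fit, rep(0.5, 13), 0.4), 0.6, tolerance = 1e-8)
})

test_that("fitting is deterministic and demands enough trajectories", {
  traces <- lapply(1:11, function(s)
    fake_trace(12, s, function(f) 0.2 * f[, 2] + 0.1 * f[, 5] - 0.15))
  f1 <- fit_accuracy_regressor(traces, folds = 11, seed = 3)
  f2 <- fit_accuracy_regressor(traces, folds = 11, seed = 3)
  expect_identical(f1$beta, f2$beta)
  expect_identical(f1$lambda, f2$lambda)
  expect_error(fit_accuracy_regressor(traces[1:5], folds = 11), "at least")
})

test_that("accuracy prediction adds the fraction done and clips to [0, 1]", {
  pr <- structure(list(beta = stats::setNames(numeric(91), paste0("b", 1:91)),
                       intercept = 0.2, lambda = 1,
                       f_min = rep(0, 13), f_range = rep(1, 13)),
                  class = "accuracy_predictor")
  expect_equal(predict_accuracy(pr, numeric(91), 0.5), 0.7)

  pr$intercept <- 0.8
  expect_equal(predict_accuracy(pr, numeric(91), 0.9), 1)   # clipped

  pr$intercept <- 0
  expect_equal(predict_accuracy(pr, numeric(91), 0.37), 0.37)

  ## monotone pass-through in the fraction before clipping
  pr$intercept <- 0.1
  d <- 0.07
  expect_equal(predict_accuracy(pr, numeric(91), 0.3 + d) -
               predict_accuracy(pr, numeric(91), 0.3), d)
  expect_error(predict_accuracy(pr, numeric(13), 0.5), "expected 91")
  expect_error(predict(pr, numeric(91), 0.5), "expected 13")
})

test_that("stored normalization reproduces training-time features exactly", {
  traces <- lapply(1:11, function(s)
    fake_trace(10, s, function(f) 0.25 * f[, 3] - 0.05))
  fit <- fit_accuracy_regressor(traces, folds = 11, seed = 2)
  tr <- add_predicted_accuracy(traces[[4]], fit)
  again <- add_predicted_accuracy(traces[[4]], fit)
  expect_identical(tr$predicted_accuracy, again$predicted_accuracy)
  expect_true(all(tr$predicted_accuracy >= 0 & tr$predicted_accuracy <= 1))
})

test_that("exceedance calibration counts ties as fulfilled and skips empty bins", {
  ## a predictor stuck at zero is always exceeded
  pr <- structure(list(beta = stats::setNames(numeric(91), paste0("b", 1:91)),
                       intercept = -10, lambda = 1,
                       f_min = rep(0, 13), f_range = rep(1, 13)),
                  class = "accuracy_predictor")
  traces <- lapply(1:3, function(s) fake_trace(10, s, function(f) 0.1))
  cal <- calibrate_predictor(pr, traces)
  expect_equal(cal$prob[1], 1)
  expect_true(all(is.na(cal$prob[cal$n == 0])))

  ## a perfect predictor is never strictly exceeded, but ties count
  pred <- stats::runif(500)
  cal2 <- dtal:::calibration_from_pairs(pred, pred)
  expect_true(all(cal2$prob[cal2$n > 0] == 1))

  ## symmetric noise puts mid-range bins near one half
  set.seed(5)
  pred <- stats::runif(20000, 0.3, 0.7)
  truth <- pred + stats::runif(20000, -0.05, 0.05)
  cal3 <- dtal:::calibration_from_pairs(pred, truth)
  mid <- cal3$bin_lo >= 0.35 & cal3$bin_hi <= 0.65
  expect_true(all(abs(cal3$prob[mid & cal3$n > 100] - 0.5) < 0.05))
})

test_that("predictors serialize to JSON and back without loss", {
  traces <- lapply(1:11, function(s)
    fake_trace(10, s, function(f) 0.2 * f[, 1] - 0.1))
  fit <- fit_accuracy_regressor(traces, folds = 11, seed = 9)
  path <- withr::local_tempfile(fileext = ".json")
  write_predictor(fit, path)
  back <- read_predictor(path)
  expect_equal(back$beta, fit$beta)
  expect_equal(back$intercept, fit$intercept)
  expect_equal(back$f_min, unname(fit$f_min))
  f <- rep(0.4, 13)
  expect_equal(predict(back, f, 0.5), predict(fit, f, 0.5))
})
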