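#' Fit the lasso accuracy regressor on simulated traces
#'
#' Learns to predict the active learner's *adjusted accuracy* — the true
#' accuracy on the remaining pool minus the fraction of experiments
#' performed — from the quadratically extended trajectory features.  The
#' model is an L1-penalised linear regression; the penalty is chosen by
#' trajectory-grouped cross-validation under squared loss, i.e. whole
#' traces are held out together so time-points from one run never inform
#' their own fold.  Adding back the fraction of experiments performed turns
#' an adjusted-accuracy prediction into an accuracy prediction (see
#' [predict.accuracy_predictor()]).
#'
#' Raw features are rescaled to `[0, 1]` with min/max constants computed on
#' the training pool; the constants are stored so that prediction-time
#' scaling reproduces training-time values exactly.
#'
#' @param traces a list of [run_trace()] results (or data.frames carrying
#'   `accuracy`, `fraction` and feature columns `f1`..`f13`).
#' @param folds number of cross-validation folds over trajectories
#'   (11 gives each fold slightly more training data than the usual 10).
#' @param seed integer seed for the fold assignment.
#' @return an object of class `"accuracy_predictor"`: coefficients `beta`
#'   (length 91), `intercept`, chosen `lambda`, the normalization
#'   constants, the CV curve and the fold assignment.
#' @export
fit_accuracy_regressor <- function(traces, folds = 11L, seed = 1L) {
  if (inherits(traces, "al_trace")) traces <- list(traces)
  n_tr <- length(traces)
  if (folds < 3L)
    stop("cross-validation needs at least 3 folds", call. = FALSE)
  if (n_tr < folds)
    stop(sprintf("need at least %d trajectories for %d-fold CV, got %d",
                 folds, folds, n_tr), call. = FALSE)

  fcols <- paste0("f", 1:13)
  Xraw <- do.call(rbind, lapply(traces, function(tr) as.matrix(tr[, fcols])))
  y <- unlist(lapply(traces, function(tr) tr$accuracy - tr$fraction),
              use.names = FALSE)
  traj <- rep(seq_len(n_tr), vapply(traces, nrow, integer(1)))

  f_min <- apply(Xraw, 2L, min)
  f_rng <- apply(Xraw, 2L, max) - f_min
  f_rng[f_rng == 0] <- 1
  Xn <- sweep(sweep(Xraw, 2L, f_min), 2L, f_rng, "/")
  Xe <- extend_features(Xn)

  set.seed(seed)
  fold_of_traj <- sample(rep_len(seq_len(folds), n_tr))
  foldid <- fold_of_traj[traj]

  if (stats::var(y) < 1e-12) {
    beta <- stats::setNames(numeric(ncol(Xe)), colnames(Xe))
    out <- list(beta = beta, intercept = mean(y), lambda = Inf,
                f_min = f_min, f_range = f_rng, folds = folds, seed = seed,
                cv = NULL, n_traces = n_tr, n_points = length(y))
    class(out) <- "accuracy_predictor"
    return(out)
  }

  cv <- glmnet::cv.glmnet(Xe, y, alpha = 1, foldid = foldid,
                          family = "gaussian")
  co <- as.matrix(stats::coef(cv, s = "lambda.min"))
  out <- list(beta = stats::setNames(co[-1L, 1L], colnames(Xe)),
              intercept = co[1L, 1L],
              lambda = cv$lambda.min,
              f_min = f_min, f_range = f_rng,
              folds = folds, seed = seed,
              cv = data.frame(lambda = cv$lambda, cvm = cv$cvm, cvsd = cv$cvsd),
              n_traces = n_tr, n_points = length(y))
  class(out) <- "accuracy_predictor"
  out
}

#' Predict accuracy from extended features
#'
#' The low-level prediction contract: given already-normalised, extended
#' features, the accuracy prediction is the adjusted-accuracy regression
#' value plus the fraction of experiments performed, clipped to `[0, 1]`.
#'
#' @param predictor an `"accuracy_predictor"`.
#' @param f_ext extended feature vector (length 91) or matrix (rows =
#'   time-points).
#' @param fraction_done fraction of experiments performed, in `(0, 1]`
#'   (recycled along rows).
#' @return predicted accuracy in `[0, 1]`.
#' @export
predict_accuracy <- function(predictor, f_ext, fraction_done) {
  if (is.matrix(f_ext)) {
    if (ncol(f_ext) != length(predictor$beta))
      stop(sprintf("expected %d extended features, got %d",
                   length(predictor$beta), ncol(f_ext)), call. = FALSE)
    adj <- drop(f_ext %*% predictor$beta) + predictor$intercept
  } else {
    if (length(f_ext) != length(predictor$beta))
      stop(sprintf("expected %d extended features, got %d",
                   length(predictor$beta), length(f_ext)), call. = FALSE)
    adj <- sum(f_ext * predictor$beta) + predictor$intercept
  }
  pmin(pmax(adj + fraction_done, 0), 1)
}

#' @rdname predict_accuracy
#' @param object an `"accuracy_predictor"`.
#' @param features raw 13-feature vector or matrix; the stored training
#'   normalization is applied, then the quadratic extension, then
#'   [predict_accuracy()].
#' @param ... unused.
#' @export
predict.accuracy_predictor <- function(object, features, fraction_done, ...) {
  one <- !is.matrix(features)
  if (one) features <- matrix(features, 1L)
  if (ncol(features) != length(object$f_min))
    stop(sprintf("expected %d raw features, got %d",
                 length(object$f_min), ncol(features)), call. = FALSE)
  Xn <- sweep(sweep(features, 2L, object$f_min), 2L, object$f_range, "/")
  Xn <- pmin(pmax(Xn, 0), 1)
  out <- predict_accuracy(object, extend_features(Xn), fraction_done)
  if (one) out[[1L]] else out
}

#' @rdname predict_accuracy
#' @param trace an `"al_trace"`; a `predicted_accuracy` column is appended.
#' @export
add_predicted_accuracy <- function(trace, predictor) {
  f <- as.matrix(trace[, paste0("f", 1:13)])
  trace$predicted_accuracy <- predict(predictor, f, trace$fraction)
  trace
}

#' @export
coef.accuracy_predictor <- function(object, ...) {
  c("(Intercept)" = object$intercept, object$beta)
}

#' @export
print.accuracy_predictor <- function(x, ...) {
  cat("Lasso accuracy predictor (adjusted accuracy ~ 91 extended features)\n")
  cat(sprintf("  trained on %d time-points from %d trajectories, %d-fold grouped CV\n",
              x$n_points, x$n_traces, x$folds))
  cat(sprintf("  lambda = %.4g, %d nonzero coefficients\n",
              x$lambda, sum(x$beta != 0)))
  invisible(x)
}

#' Exceedance calibration of the accuracy predictor
#'
#' For held-out traces, bins time-points by predicted accuracy and reports
#' per bin the empirical probability that the true accuracy is greater than
#' or equal to the prediction (ties count as fulfilled).  A well-behaved
#' predictor is a lower estimate of the truth in the operating range, so
#' this exceedance probability is what justifies using a predicted-accuracy
#' threshold as a stopping rule.
#'
#' @param predictor an `"accuracy_predictor"`.
#' @param traces held-out traces (list of `"al_trace"`).
#' @param bin_width predicted-accuracy bin width; bins are half-open
#'   `[lo, lo + width)`.
#' @return a `"calibration_table"` data.frame with `bin_lo`, `bin_hi`,
#'   `n` (occurrences) and `prob` (exceedance probability; `NA` for empty
#'   bins, never 0).
#' @export
calibrate_predictor <- function(predictor, traces, bin_width = 0.05) {
  if (inherits(traces, "al_trace")) traces <- list(traces)
  pred <- numeric(0); truth <- numeric(0)
  for (tr in traces) {
    tr <- add_predicted_accuracy(tr, predictor)
    pred <- c(pred, tr$predicted_accuracy)
    truth <- c(truth, tr$accuracy)
  }
  calibration_from_pairs(pred, truth, bin_width)
}

calibration_from_pairs <- function(pred, truth, bin_width = 0.05) {
  lo <- seq(0, 1 - bin_width / 2, by = bin_width)
  bin <- pmin(findInterval(pred, lo), length(lo))
  n <- tabulate(bin, nbins = length(lo))
  prob <- rep(NA_real_, length(lo))
  for (b in which(n > 0))
    prob[b] <- mean(truth[bin == b] >= pred[bin == b])
  structure(data.frame(bin_lo = lo, bin_hi = lo + bin_width, n = n, prob = prob),
            class = c("calibration_table", "data.frame"))
}

#' Cross-validated calibration over trajectories
#'
#' The full calibration protocol: trajectories are split into folds, the
#' accuracy regressor is refit on each training split, predictions are
#' made on the held-out trajectories, and all held-out (predicted, true)
#' pairs are pooled into one exceedance table.
#'
#' @param traces list of `"al_trace"` objects.
#' @param folds number of trajectory folds.
#' @param bin_width calibration bin width.
#' @param seed integer seed (fold assignment and refits).
#' @return a `"calibration_table"` (see [calibrate_predictor()]), with the
#'   pooled held-out pairs in `attr(, "pairs")`.
#' @export
cv_calibrate <- function(traces, folds = 11L, bin_width = 0.05, seed = 1L) {
  n_tr <- length(traces)
  if (n_tr < folds + 3L)
    stop(sprintf("need at least %d trajectories for %d-fold calibration",
                 folds + 3L, folds), call. = FALSE)
  set.seed(seed)
  fold_of <- sample(rep_len(seq_len(folds), n_tr))
  pred <- numeric(0); truth <- numeric(0)
  for (k in seq_len(folds)) {
    fitk <- fit_accuracy_regressor(traces[fold_of != k],
                                   folds = max(3L, min(folds, sum(fold_of != k))),
                                   seed = seed + k)
    for (tr in traces[fold_of == k]) {
      tr <- add_predicted_accuracy(tr, fitk)
      pred <- c(pred, tr$predicted_accuracy)
      truth <- c(truth, tr$accuracy)
    }
  }
  out <- calibration_from_pairs(pred, truth, bin_width)
  attr(out, "pairs") <- data.frame(predicted = pred, true = truth)
  out
}

#' @export
print.calibration_table <- function(x, ...) {
  cat("Exceedance calibration (P[true accuracy >= predicted] per bin)\n")
  occ <- x[x$n > 0, ]
  for (i in seq_len(nrow(occ)))
    cat(sprintf("  [%.2f, %.2f): n = %4d, P = %.3f\n",
                occ$bin_lo[i], occ$bin_hi[i], occ$n[i], occ$prob[i]))
  invisible(x)
}

#' @export
plot.calibration_table <- function(x, ...) {
  mid <- (x$bin_lo + x$bin_hi) / 2
  plot(mid, x$prob, type = "b", pch = 16, ylim = c(0, 1),
       xlab = "predicted accuracy",
       ylab = "P(true accuracy >= predicted)",
       main = "Stopping-rule calibration", ...)
  invisible(x)
}

#' Serialize an accuracy predictor to JSON
#'
#' @param predictor an `"accuracy_predictor"`.
#' @param path output file.
#' @return `path` invisibly; `read_predictor` returns the predictor.
#' @export
write_predictor <- function(predictor, path) {
  obj <- predictor[c("beta", "intercept", "lambda", "f_min", "f_range",
                     "folds", "seed", "n_traces", "n_points")]
  obj$feature_order <- names(predictor$beta)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_predictor
#' @export
read_predictor <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  out <- list(beta = stats::setNames(obj$beta, obj$feature_order),
              intercept = obj$intercept, lambda = obj$lambda,
              f_min = obj$f_min, f_range = obj$f_range,
              folds = obj$folds, seed = obj$seed, cv = NULL,
              n_traces = obj$n_traces, n_points = obj$n_points)
  class(out) <- "accuracy_predictor"
  out
}
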