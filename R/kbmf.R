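#' Kernelized Bayesian matrix factorization for binary interactions
#'
#' Fits the semi-supervised KBMF model to a ternary experimental matrix
#' `X` (+1 interaction, -1 no interaction, 0 not yet measured), using a
#' drug kernel `Kd` and a target kernel `Kt` as side information.  Drugs
#' and targets are projected through transformation matrices `A_d` (N x R)
#' and `A_t` (M x R) into a shared R-dimensional subspace; the prediction
#' matrix is the product of the projected kernels,
#' `F = ((A_d' Kd)') (A_t' Kt)`, and the interaction label is the sign of
#' `F`.  Inference is mean-field variational Bayes: entries of `F` at
#' observed positions follow truncated normal distributions with margin
#' `margin` on the correct side of zero, the projected factors `G = A' K`
#' carry Gaussian noise `sigma_g`, and the entries of the transformation
#' matrices have zero-mean Gaussian priors with entry-wise gamma
#' hyperpriors (`alpha_lambda`, `beta_lambda`).  Only observed entries of
#' `X` enter the likelihood.
#'
#' The updates sweep hyperprior scales, transformation matrices, projected
#' factors (per-entity posterior covariances restricted to that entity's
#' observed entries) and the truncated-normal means of `F`, for
#' `iterations` sweeps or until the relative change of the prediction
#' matrix drops below `tol` (when `tol` is non-NULL).
#'
#' @param X ternary experimental matrix (N x M) with at least one nonzero
#'   entry.
#' @param Kd,Kt drug (N x N) and target (M x M) kernel matrices.
#' @param R subspace dimension; 20 is a good default for drug-target data.
#' @param iterations number of update sweeps (convergence is typically
#'   reached well before 200).
#' @param seed integer seed for the random initialization.
#' @param tol optional relative-change tolerance for early stopping
#'   (e.g. `1e-5`); `NULL` runs exactly `iterations` sweeps.
#' @param sigma_g projection noise standard deviation.
#' @param margin truncation margin separating the two label classes.
#' @param alpha_lambda,beta_lambda gamma hyperprior shape and scale.
#' @param init optional previous `kbmf` fit used as a warm start (same
#'   dimensions and `R`); the random initialization is skipped.
#' @param keep_kernels store the kernels in the fit so `predict()` works
#'   without re-supplying them.
#' @return an object of class `"kbmf"`: a list with transformation matrices
#'   `Ad`, `At`, the subspace dimension `R`, `iterations_run`, a
#'   `convergence` trace (relative change of the prediction matrix per
#'   sweep) and the fit configuration.
#' @seealso [predict.kbmf()], [posterior_prob()]
#' @examples
#' Y <- two_block_matrix(10, 8)
#' ks <- derive_perfect_kernels(Y)
#' fit <- kbmf(Y, ks$Kd, ks$Kt, R = 4, iterations = 50, seed = 1)
#' mean(predict(fit, type = "label") == Y)
#' @export
kbmf <- function(X, Kd, Kt, R = 20L, iterations = 200L, seed = 1L,
                 tol = NULL, sigma_g = 0.1, margin = 1,
                 alpha_lambda = 1, beta_lambda = 1,
                 init = NULL, keep_kernels = TRUE) {
  validate_experimental_matrix(X)
  N <- nrow(X); M <- ncol(X)
  if (nrow(Kd) != N || ncol(Kd) != N)
    stop(sprintf("drug kernel must be %d x %d, got %d x %d",
                 N, N, nrow(Kd), ncol(Kd)), call. = FALSE)
  if (nrow(Kt) != M || ncol(Kt) != M)
    stop(sprintf("target kernel must be %d x %d, got %d x %d",
                 M, M, nrow(Kt), ncol(Kt)), call. = FALSE)
  if (all(X == 0)) stop("no observations: X has no nonzero entries", call. = FALSE)
  stopifnot(R >= 1L, iterations >= 1L, sigma_g > 0)

  obs <- X != 0
  sg2 <- sigma_g^2
  KdKd <- Kd %*% Kd
  KtKt <- Kt %*% Kt
  alpha <- alpha_lambda + 0.5

  if (is.null(init)) {
    set.seed(seed)
    Ad_mu <- matrix(0.01 * stats::rnorm(N * R), N, R)
    At_mu <- matrix(0.01 * stats::rnorm(M * R), M, R)
    Gd_mu <- crossprod(Ad_mu, Kd) + 0.01 * stats::rnorm(R * N)
    Gt_mu <- crossprod(At_mu, Kt) + 0.01 * stats::rnorm(R * M)
    Gd_sig <- array(diag(R), c(R, R, N))
    Gt_sig <- array(diag(R), c(R, R, M))
    Ad_sd <- matrix(1, N, R)   # posterior variances (diagonals), for the hyperprior
    At_sd <- matrix(1, M, R)
    F_mu <- X * (margin + abs(0.5 * stats::rnorm(N * M)))
  } else {
    stopifnot(inherits(init, "kbmf"), init$R == R,
              nrow(init$Ad) == N, nrow(init$At) == M)
    Ad_mu <- init$Ad; At_mu <- init$At
    Gd_mu <- crossprod(Ad_mu, Kd)
    Gt_mu <- crossprod(At_mu, Kt)
    Gd_sig <- array(diag(R), c(R, R, N))
    Gt_sig <- array(diag(R), c(R, R, M))
    Ad_sd <- matrix(1, N, R)
    At_sd <- matrix(1, M, R)
    F_mu <- X * (margin + 0.5)
  }

  ## flatten per-entity factor covariances for fast masked sums
  trace <- numeric(0)
  F_hat_prev <- NULL
  iters_run <- 0L

  for (iter in seq_len(iterations)) {
    ## ---- drug side -----------------------------------------------------
    beta_d <- 1 / (1 / beta_lambda + 0.5 * (Ad_mu^2 + Ad_sd))
    for (s in seq_len(R)) {
      prec <- KdKd / sg2
      diag(prec) <- diag(prec) + alpha * beta_d[, s]
      sig <- chol2inv(chol(prec))
      Ad_mu[, s] <- sig %*% (Kd %*% Gd_mu[s, ]) / sg2
      Ad_sd[, s] <- diag(sig)
    }
    base <- crossprod(Ad_mu, Kd) / sg2              # R x N
    Gt_sig_flat <- matrix(Gt_sig, R * R, M)
    sig_sums <- Gt_sig_flat %*% t(obs)              # R^2 x N
    FX <- F_mu * obs
    for (i in seq_len(N)) {
      oj <- obs[i, ]
      Gt_o <- Gt_mu[, oj, drop = FALSE]
      S <- diag(R) / sg2 + tcrossprod(Gt_o) + matrix(sig_sums[, i], R, R)
      Gd_sig[, , i] <- chol2inv(chol(S))
      Gd_mu[, i] <- Gd_sig[, , i] %*% (base[, i] + Gt_mu %*% FX[i, ])
    }

    ## ---- target side ---------------------------------------------------
    beta_t <- 1 / (1 / beta_lambda + 0.5 * (At_mu^2 + At_sd))
    for (s in seq_len(R)) {
      prec <- KtKt / sg2
      diag(prec) <- diag(prec) + alpha * beta_t[, s]
      sig <- chol2inv(chol(prec))
      At_mu[, s] <- sig %*% (Kt %*% Gt_mu[s, ]) / sg2
      At_sd[, s] <- diag(sig)
    }
    base_t <- crossprod(At_mu, Kt) / sg2            # R x M
    Gd_sig_flat <- matrix(Gd_sig, R * R, N)
    sig_sums_t <- Gd_sig_flat %*% obs               # R^2 x M
    for (j in seq_len(M)) {
      oi <- obs[, j]
      Gd_o <- Gd_mu[, oi, drop = FALSE]
      S <- diag(R) / sg2 + tcrossprod(Gd_o) + matrix(sig_sums_t[, j], R, R)
      Gt_sig[, , j] <- chol2inv(chol(S))
      Gt_mu[, j] <- Gt_sig[, , j] %*% (base_t[, j] + Gd_mu %*% FX[, j])
    }

    ## ---- truncated-normal means of F on observed entries ----------------
    F_hat <- crossprod(Gd_mu, Gt_mu)                # N x M
    z <- X[obs] * F_hat[obs]
    a <- margin - z
    mills <- exp(stats::dnorm(a, log = TRUE) -
                 stats::pnorm(a, lower.tail = FALSE, log.p = TRUE))
    F_mu[obs] <- X[obs] * (z + mills)
    FX <- F_mu * obs

    iters_run <- iter
    if (!is.null(F_hat_prev)) {
      rel <- mean(abs(F_hat - F_hat_prev)) / (mean(abs(F_hat_prev)) + 1e-12)
      trace <- c(trace, rel)
      if (!is.null(tol) && rel < tol) { F_hat_prev <- F_hat; break }
    }
    F_hat_prev <- F_hat
  }

  structure(list(
    Ad = Ad_mu, At = At_mu, R = as.integer(R),
    iterations_run = iters_run, convergence = trace,
    n_observed = sum(obs), dims = c(N = N, M = M),
    sigma_g = sigma_g, margin = margin,
    alpha_lambda = alpha_lambda, beta_lambda = beta_lambda,
    seed = seed,
    Kd = if (keep_kernels) Kd else NULL,
    Kt = if (keep_kernels) Kt else NULL,
    call = match.call()
  ), class = "kbmf")
}

#' Predictions from a fitted KBMF model
#'
#' Computes the prediction matrix `F = ((A_d' Kd)') (A_t' Kt)` and derives
#' posterior probabilities (`P = 1 / (1 + exp(-F))`) or hard labels
#' (`+1` when `F > 0`, `-1` otherwise, including the tie `F = 0`).
#'
#' @param object a fitted `"kbmf"` model.
#' @param Kd,Kt kernels to project through; defaults to the kernels stored
#'   at fit time.
#' @param type `"score"` for `F`, `"prob"` for the sigmoid posterior of
#'   label +1, `"label"` for signs.
#' @param ... unused.
#' @return an N x M matrix of the requested quantity.
#' @export
predict.kbmf <- function(object, Kd = NULL, Kt = NULL,
                         type = c("score", "prob", "label"), ...) {
  type <- match.arg(type)
  Kd <- Kd %||% object$Kd
  Kt <- Kt %||% object$Kt
  if (is.null(Kd) || is.null(Kt))
    stop("kernels were not stored in the fit; supply Kd and Kt", call. = FALSE)
  if (ncol(Kd) != nrow(object$Ad) || ncol(Kt) != nrow(object$At))
    stop("kernel dimensions do not match the fitted transformation matrices",
         call. = FALSE)
  F_hat <- (Kd %*% object$Ad) %*% t(Kt %*% object$At)
  switch(type,
         score = F_hat,
         prob  = posterior_prob(F_hat),
         label = predict_labels(F_hat))
}

#' @rdname predict.kbmf
#' @param F_hat matrix (or vector) of prediction scores.
#' @return `posterior_prob` returns the posterior probability of label +1,
#'   strictly inside (0, 1) even for extreme scores; `predict_labels`
#'   returns the sign thresholding (`F > 0` is +1, else -1).
#' @export
posterior_prob <- function(F_hat) {
  p <- stats::plogis(F_hat)
  pmin(pmax(p, .Machine$double.xmin), 1 - .Machine$double.eps)
}

#' @rdname predict.kbmf
#' @export
predict_labels <- function(F_hat) {
  ifelse(F_hat > 0, 1, -1)
}

#' @export
fitted.kbmf <- function(object, ...) predict.kbmf(object, type = "score")

#' @export
coef.kbmf <- function(object, ...) list(Ad = object$Ad, At = object$At)

#' @export
print.kbmf <- function(x, ...) {
  cat(sprintf("Kernelized Bayesian matrix factorization (R = %d)\n", x$R))
  cat(sprintf("  %d drugs x %d targets, %d observed entries (%.1f%%)\n",
              x$dims["N"], x$dims["M"], x$n_observed,
              100 * x$n_observed / prod(x$dims)))
  cat(sprintf("  %d update sweeps", x$iterations_run))
  if (length(x$convergence) > 0)
    cat(sprintf(", final relative change %.2e", utils::tail(x$convergence, 1)))
  cat("\n")
  invisible(x)
}

#' @export
summary.kbmf <- function(object, ...) {
  F_hat <- try(predict.kbmf(object, type = "score"), silent = TRUE)
  out <- list(fit = object,
              score_range = if (inherits(F_hat, "try-error")) NULL else range(F_hat))
  class(out) <- "summary.kbmf"
  out
}

#' @export
print.summary.kbmf <- function(x, ...) {
  print(x$fit)
  if (!is.null(x$score_range))
    cat(sprintf("  prediction scores in [%.3f, %.3f]\n",
                x$score_range[1], x$score_range[2]))
  invisible(x)
}

#' @export
plot.kbmf <- function(x, ...) {
  if (length(x$convergence) == 0)
    stop("no convergence trace recorded", call. = FALSE)
  plot(seq_along(x$convergence) + 1L, x$convergence, type = "l", log = "y",
       xlab = "update sweep", ylab = "relative change of prediction matrix",
       main = "KBMF convergence", ...)
  invisible(x)
}

#' Serialize a fitted KBMF model to JSON
#'
#' Stores the transformation matrices, subspace dimension, seed and
#' hyperparameters (not the kernels, which travel with the data).  A
#' round-trip reproduces predictions exactly when the same kernels are
#' supplied.
#'
#' @param model a fitted `"kbmf"` object.
#' @param path output file.
#' @return `path` invisibly; `read_kbmf` returns the model.
#' @export
write_kbmf <- function(model, path) {
  obj <- list(Ad = model$Ad, At = model$At, R = model$R,
              iterations_run = model$iterations_run,
              n_observed = model$n_observed, dims = as.list(model$dims),
              sigma_g = model$sigma_g, margin = model$margin,
              alpha_lambda = model$alpha_lambda,
              beta_lambda = model$beta_lambda, seed = model$seed)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_kbmf
#' @export
read_kbmf <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$Ad <- as.matrix(obj$Ad)
  obj$At <- as.matrix(obj$At)
  obj$dims <- c(N = obj$dims$N, M = obj$dims$M)
  obj$convergence <- numeric(0)
  obj$Kd <- NULL; obj$Kt <- NULL
  structure(obj, class = "kbmf")
}

#' Two-block interaction matrix fixture
#'
#' A simple benchmark structure: drugs and targets each split into two
#' coherent groups, with interactions inside matched group pairs and none
#' across.  Its perfect kernels make completion easy, which is what a
#' factorization sanity check needs.
#'
#' @param N,M dimensions; the first `ceiling(N/2)` drugs and
#'   `ceiling(M/2)` targets form the first block.
#' @return an interaction matrix in \{-1, +1\}.
#' @export
two_block_matrix <- function(N, M) {
  gd <- rep(c(1, 2), c(ceiling(N / 2), floor(N / 2)))
  gt <- rep(c(1, 2), c(ceiling(M / 2), floor(M / 2)))
  ifelse(outer(gd, gt, "=="), 1, -1)
}
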