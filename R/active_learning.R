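#' Binary entropy of posterior probabilities
#'
#' The uncertainty of a predicted entry, `U = -(P log P + (1-P) log(1-P))`
#' in nats.  It is maximal (`log 2`) at `P = 0.5` and tends to 0 as the
#' posterior approaches either label.  Uncertainty sampling queries the
#' entries where `U` is largest.
#'
#' @param P probabilities of label +1 (matrix or vector), in `(0, 1)`;
#'   the closed limits are handled by continuity (`0 log 0 = 0`).
#' @return elementwise entropy, same shape as `P`.
#' @export
binary_entropy <- function(P) {
  xlx <- function(p) ifelse(p > 0, p * log(p), 0)
  -(xlx(P) + xlx(1 - P))
}

#' Initialization strategies for the experimental matrix
#'
#' `init_random` selects one full random column plus one uniformly random
#' entry from every row, guaranteeing that every drug and at least one
#' target have observations.  `init_diversity` clusters drugs and targets
#' by k-means on their kernel rows and samples the same number of entries
#' from each drug-cluster x target-cluster combination.
#'
#' @param N,M matrix dimensions.
#' @param seed integer seed.
#' @return a two-column integer matrix of (drug, target) index pairs.
#' @export
init_random <- function(N, M, seed = 1L) {
  stopifnot(N >= 1L, M >= 1L)
  set.seed(seed)
  col <- sample.int(M, 1L)
  ents <- rbind(cbind(seq_len(N), col),
                cbind(seq_len(N), sample.int(M, N, replace = TRUE)))
  unique(ents)
}

#' @rdname init_random
#' @param Kd,Kt drug and target kernels (clustering features are their rows).
#' @param budget total number of initial experiments; must be at least the
#'   number of cluster pairs.
#' @param k_drugs,k_targets cluster counts; default `round(sqrt(N))` and
#'   `round(sqrt(M))`.
#' @export
init_diversity <- function(Kd, Kt, budget, seed = 1L,
                           k_drugs = NULL, k_targets = NULL) {
  N <- nrow(Kd); M <- nrow(Kt)
  k_drugs <- k_drugs %||% max(1L, round(sqrt(N)))
  k_targets <- k_targets %||% max(1L, round(sqrt(M)))
  if (budget < k_drugs * k_targets)
    stop(sprintf("budget %d is below the %d cluster pairs", budget,
                 k_drugs * k_targets), call. = FALSE)
  if (budget > N * M) stop("budget exceeds the matrix size", call. = FALSE)
  set.seed(seed)
  cd <- if (k_drugs == 1L) rep(1L, N) else stats::kmeans(Kd, k_drugs, nstart = 5L)$cluster
  ct <- if (k_targets == 1L) rep(1L, M) else stats::kmeans(Kt, k_targets, nstart = 5L)$cluster

  ## per cluster pair, the available entries in random order
  pools <- vector("list", k_drugs * k_targets)
  for (a in seq_len(k_drugs)) for (b in seq_len(k_targets)) {
    ents <- as.matrix(expand.grid(d = which(cd == a), t = which(ct == b)))
    pools[[(a - 1L) * k_targets + b]] <- ents[sample.int(nrow(ents)), , drop = FALSE]
  }
  ## round-robin over pairs (random pair order) until the budget is met
  order_pairs <- sample.int(length(pools))
  taken <- integer(length(pools))
  out <- matrix(0L, budget, 2L)
  got <- 0L
  while (got < budget) {
    progressed <- FALSE
    for (p in order_pairs) {
      if (got >= budget) break
      if (taken[p] < nrow(pools[[p]])) {
        taken[p] <- taken[p] + 1L
        got <- got + 1L
        out[got, ] <- pools[[p]][taken[p], ]
        progressed <- TRUE
      }
    }
    if (!progressed) break
  }
  dimnames(out) <- NULL
  out[seq_len(got), , drop = FALSE]
}

#' Select a batch of experiments by uncertainty
#'
#' Greedy top-K selection: the K unlabeled entries with the largest
#' uncertainty, ties broken uniformly at random (seeded).
#'
#' @param U matrix of uncertainty values (e.g. [binary_entropy()] of the
#'   posterior grid).
#' @param X experimental matrix; its zero entries form the pool.
#' @param K batch size.
#' @param seed integer seed for tie-breaking.
#' @return a two-column integer matrix of (drug, target) pairs, all from
#'   the pool, no duplicates.
#' @export
select_batch_entries <- function(U, X, K, seed = 1L) {
  pool <- which(X == 0)
  if (K > length(pool))
    stop(sprintf("batch size %d exceeds pool size %d", K, length(pool)),
         call. = FALSE)
  set.seed(seed)
  ord <- order(-U[pool], stats::runif(length(pool)))
  chosen <- pool[ord[seq_len(K)]]
  arrayInd(chosen, dim(X))
}

#' Select a batch of drugs by mean uncertainty
#'
#' Drug-wise querying: drugs are ranked by the mean uncertainty over their
#' unlabeled entries and the top `ceiling(fraction * N)` drugs (among those
#' that still have unlabeled entries) are returned; all their remaining
#' experiments are then performed.
#'
#' @inheritParams select_batch_entries
#' @param fraction fraction of drugs per batch (the field's convention is
#'   1% of drugs).
#' @return an integer vector of drug indices.
#' @export
select_batch_drugs <- function(U, X, fraction = 0.01, seed = 1L) {
  if (fraction <= 0) stop("fraction must be positive", call. = FALSE)
  open <- X == 0
  eligible <- which(rowSums(open) > 0)
  if (length(eligible) == 0L) stop("no drug has unlabeled entries", call. = FALSE)
  meanU <- vapply(eligible, function(i) mean(U[i, open[i, ]]), numeric(1))
  k <- min(length(eligible), ceiling(fraction * nrow(X)))
  set.seed(seed)
  eligible[order(-meanU, stats::runif(length(eligible)))[seq_len(k)]]
}

#' Run one active-learning trace
#'
#' The round-by-round loop: initialize the experimental matrix, then
#' repeatedly (1) fit KBMF on the labels revealed so far, (2) predict the
#' full matrix, (3) record the true accuracy on the remaining pool together
#' with the pool uncertainty statistics and the 13 trajectory features,
#' (4) select the next batch — by uncertainty or uniformly at random — and
#' reveal its ground-truth labels.  The run ends when the observed fraction
#' reaches `stop_fraction` (accuracy is always measured on a non-empty
#' remaining pool) or after `max_rounds` rounds.
#'
#' @param Y ground-truth interaction matrix (labels are read only when an
#'   experiment is performed, and to score pool accuracy).
#' @param Kd,Kt drug and target kernels.
#' @param strategy `"uncertainty"` (entropy-greedy) or `"random"` (the
#'   baseline, which ignores the model's uncertainty entirely).
#' @param init `"random"` or `"diversity"`, or a two-column index matrix of
#'   initial entries (so paired runs can share their starting set).
#' @param batch batch size in entries; default `ceiling(0.01 * N * M)`.
#' @param R,iterations,tol,sigma_g KBMF settings (see [kbmf()]).
#' @param seed integer seed governing initialization, fitting and
#'   tie-breaking.
#' @param stop_fraction stop once this fraction of entries is observed.
#' @param max_rounds cap on the number of rounds.
#' @param warm_start reuse the previous round's transformation matrices as
#'   the next fit's starting point.
#' @param init_budget budget for `init = "diversity"`; defaults to the size
#'   an `init_random` draw would have (`N +` expected extra row picks).
#' @return an object of class `"al_trace"`: a data.frame with one row per
#'   time-point (`round`, `n_observed`, `fraction`, `accuracy`, `ou`,
#'   `mee`, `label_consistency`, features `f1`..`f13`) and the run
#'   configuration in `attr(, "config")`.
#' @export
run_trace <- function(Y, Kd, Kt, strategy = c("uncertainty", "random"),
                      init = "random", batch = NULL,
                      R = 20L, iterations = 200L, tol = NULL, sigma_g = 0.1,
                      seed = 1L, stop_fraction = 0.99, max_rounds = Inf,
                      warm_start = TRUE, init_budget = NULL) {
  strategy <- match.arg(strategy)
  validate_interaction_matrix(Y)
  N <- nrow(Y); M <- ncol(Y)
  batch <- batch %||% ceiling(0.01 * N * M)
  stopifnot(batch >= 1L)

  if (is.matrix(init)) {
    ents <- init
  } else if (identical(init, "random")) {
    ents <- init_random(N, M, seed = seed)
  } else if (identical(init, "diversity")) {
    budget <- init_budget %||% nrow(init_random(N, M, seed = seed))
    ents <- init_diversity(Kd, Kt, budget = budget, seed = seed)
  } else stop("init must be 'random', 'diversity' or an index matrix", call. = FALSE)

  X <- matrix(0, N, M)
  X[ents] <- Y[ents]

  fit <- NULL
  prev_P <- NULL; prev2_P <- NULL; prev_labels <- NULL; new_idx <- NULL
  rows <- list()
  round <- 0L
  repeat {
    round <- round + 1L
    fit <- kbmf(X, Kd, Kt, R = R, iterations = iterations, tol = tol,
                sigma_g = sigma_g, seed = seed + round,
                init = if (warm_start) fit else NULL, keep_kernels = FALSE)
    F_hat <- predict(fit, Kd, Kt, type = "score")
    P <- posterior_prob(F_hat)
    labels <- predict_labels(F_hat)
    pool <- X == 0
    n_pool <- sum(pool)
    U <- binary_entropy(P)

    f <- compute_features(X, labels, P, prev_P = prev_P, prev2_P = prev2_P,
                          prev_labels = prev_labels, new_idx = new_idx)
    rows[[round]] <- c(
      round = round, n_observed = sum(!pool), fraction = mean(!pool),
      accuracy = mean(labels[pool] == Y[pool]),
      ou = mean(U[pool]),
      mee = mean((1 - pmax(P, 1 - P))[pool]),
      label_consistency = if (is.null(prev_labels)) NA_real_
                          else mean(labels[pool] == prev_labels[pool]),
      f)

    done_frac <- mean(!pool)
    if (done_frac >= stop_fraction || round >= max_rounds) break
    ## the last batch never exhausts the reserve pool accuracy is scored on
    reserve <- max(1L, floor((1 - stop_fraction) * N * M))
    K_eff <- min(batch, n_pool - reserve)
    if (K_eff < 1L) break
    sel_seed <- seed + 1000L + round
    if (strategy == "uncertainty") {
      b <- select_batch_entries(U, X, K_eff, seed = sel_seed)
    } else {
      set.seed(sel_seed)
      b <- arrayInd(sample(which(pool), K_eff), dim(X))
    }
    new_idx <- b[, 1L] + (b[, 2L] - 1L) * N
    X[b] <- Y[b]
    prev2_P <- prev_P; prev_P <- P; prev_labels <- labels
  }

  tr <- as.data.frame(do.call(rbind, rows))
  attr(tr, "config") <- list(strategy = strategy, batch = batch, R = R,
                             iterations = iterations, tol = tol,
                             sigma_g = sigma_g, seed = seed,
                             stop_fraction = stop_fraction,
                             N = N, M = M, n_init = nrow(ents))
  class(tr) <- c("al_trace", "data.frame")
  tr
}

#' @export
print.al_trace <- function(x, ...) {
  cfg <- attr(x, "config")
  cat(sprintf("Active-learning trace: %s sampling, %d x %d matrix, %d rounds\n",
              cfg$strategy, cfg$N, cfg$M, nrow(x)))
  cat(sprintf("  observed %.1f%% -> %.1f%%; pool accuracy %.3f -> %.3f\n",
              100 * x$fraction[1], 100 * x$fraction[nrow(x)],
              x$accuracy[1], x$accuracy[nrow(x)]))
  invisible(x)
}

#' @export
plot.al_trace <- function(x, ...) {
  plot(x$fraction, x$accuracy, type = "b", pch = 16, ylim = c(0, 1),
       xlab = "fraction of experiments performed",
       ylab = "accuracy on remaining pool",
       main = "Active-learning trace", ...)
  if ("predicted_accuracy" %in% names(x)) {
    graphics::lines(x$fraction, x$predicted_accuracy, col = 2, type = "b", pch = 1)
    graphics::legend("bottomright", c("true", "predicted"), col = c(1, 2),
                     pch = c(16, 1), bty = "n")
  }
  invisible(x)
}

#' Area under the accuracy-versus-fraction curve
#'
#' Trapezoidal area of pool accuracy against the fraction of experiments
#' performed, normalised by the fraction range covered, so that paired
#' strategies are comparable.  A better query strategy dominates with a
#' larger area.
#'
#' @param trace an `"al_trace"`.
#' @return scalar area (mean accuracy over the covered fraction range).
#' @export
auac <- function(trace) {
  x <- trace$fraction; y <- trace$accuracy
  if (length(x) < 2L) return(y[1L])
  sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2) / (max(x) - min(x))
}
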