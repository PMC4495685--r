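#' Drug-wise cross-validated active learning with the stopping rule
#'
#' The evaluation protocol for new-drug generalisation: drugs are split
#' into `folds` cross-validation folds; in each fold 1/`folds` of the
#' drugs are held out entirely (no experiments are ever performed on
#' them) and active learning runs over the remaining training drugs.
#' Batches are drug-wise: the `batch_fraction` of drugs with the maximal
#' mean uncertainty across targets are selected each round and all their
#' remaining experiments performed.  When the predicted accuracy on the
#' training drugs' pool reaches `threshold`, the run stops and the AUC of
#' the prediction scores on the held-out drugs is reported, together with
#' the fraction of training experiments consumed.  An unreachable
#' threshold (e.g. `Inf`) yields the no-stopping baseline that trains on
#' all training drugs.
#'
#' @param Y interaction matrix.
#' @param Kd,Kt kernels.
#' @param folds number of drug folds (default 5: 80% train / 20% test).
#' @param batch_fraction fraction of drugs queried per round.
#' @param predictor an `"accuracy_predictor"` for the stopping rule, or
#'   `NULL` to disable stopping (baseline).
#' @param threshold predicted-accuracy stopping threshold.
#' @param R,iterations,tol,sigma_g KBMF settings.
#' @param seed integer seed.
#' @return a data.frame with one row per fold: `fold`, `auc`,
#'   `fraction_used` (of training entries), `rounds`, `reason`.
#' @export
run_drugwise_protocol <- function(Y, Kd, Kt, folds = 5L, batch_fraction = 0.01,
                                  predictor = NULL, threshold = 0.9,
                                  R = 20L, iterations = 200L, tol = NULL,
                                  sigma_g = 0.1, seed = 1L) {
  validate_interaction_matrix(Y)
  N <- nrow(Y); M <- ncol(Y)
  if (N < folds) stop("need at least as many drugs as folds", call. = FALSE)
  set.seed(seed)
  fold_of <- sample(rep_len(seq_len(folds), N))

  out <- vector("list", folds)
  for (k in seq_len(folds)) {
    test_drugs <- which(fold_of == k)
    train_drugs <- which(fold_of != k)
    n_train <- length(train_drugs)

    ## initialization restricted to training drugs: one full random column
    ## plus one random entry per training drug
    set.seed(seed + k)
    X <- matrix(0, N, M)
    col <- sample.int(M, 1L)
    X[train_drugs, col] <- Y[train_drugs, col]
    rnd <- cbind(train_drugs, sample.int(M, n_train, replace = TRUE))
    X[rnd] <- Y[rnd]

    fit <- NULL
    round <- 0L
    reason <- "pool exhausted"
    prev_P <- NULL; prev2_P <- NULL; prev_L <- NULL; new_idx <- NULL
    repeat {
      round <- round + 1L
      fit <- kbmf(X, Kd, Kt, R = R, iterations = iterations, tol = tol,
                  sigma_g = sigma_g, seed = seed + 100L * k + round,
                  init = fit, keep_kernels = FALSE)
      F_hat <- predict(fit, Kd, Kt, type = "score")
      P <- posterior_prob(F_hat)
      labels <- predict_labels(F_hat)

      X_tr <- X[train_drugs, , drop = FALSE]
      open_tr <- X_tr == 0
      frac_tr <- mean(!open_tr)
      P_tr <- P[train_drugs, , drop = FALSE]
      L_tr <- labels[train_drugs, , drop = FALSE]

      if (!is.null(predictor)) {
        f <- compute_features(X_tr, L_tr, P_tr, prev_P = prev_P,
                              prev2_P = prev2_P, prev_labels = prev_L,
                              new_idx = new_idx)
        pred_acc <- predict(predictor, f, frac_tr)
        if (pred_acc >= threshold) { reason <- "threshold crossed"; break }
      }
      if (!any(open_tr)) break

      U <- binary_entropy(P)
      sel <- select_batch_drugs(U[train_drugs, , drop = FALSE], X_tr,
                                fraction = batch_fraction,
                                seed = seed + 1000L * k + round)
      new_idx <- which(row(X_tr) %in% sel & open_tr)  # within the training block
      drugs <- train_drugs[sel]
      X[drugs, ] <- Y[drugs, , drop = FALSE]
      prev2_P <- prev_P; prev_P <- P_tr; prev_L <- L_tr
    }

    test_idx <- which(row(Y) %in% test_drugs)
    out[[k]] <- data.frame(
      fold = k,
      auc = interaction_auc(F_hat, Y, test_idx),
      fraction_used = mean(X[train_drugs, ] != 0),
      rounds = round,
      reason = reason)
  }
  do.call(rbind, out)
}

#' Representative drug set by pre-clustering
#'
#' The non-adaptive baseline for choosing which drugs to screen: k-means
#' clusters the drugs on their kernel rows, with the cluster count chosen
#' by the Akaike information criterion (spherical-Gaussian log-likelihood,
#' k scanned over `2..ceiling(sqrt(N))`), and drugs are drawn round-robin
#' across clusters, nearest-to-centroid first, until the budget is met —
#' maximising the representation of the clustering.
#'
#' @param Kd drug kernel.
#' @param budget number of drugs (a count), or a proportion of N.
#' @param seed integer seed.
#' @return integer vector of selected drug indices; cluster representation
#'   counts differ by at most one.
#' @export
precluster_baseline <- function(Kd, budget, seed = 1L) {
  N <- nrow(Kd)
  if (budget <= 1) budget <- round(budget * N)
  budget <- as.integer(budget)
  if (budget > N) stop("budget exceeds the number of drugs", call. = FALSE)
  if (budget == N) return(seq_len(N))

  set.seed(seed)
  n_distinct <- nrow(unique(Kd))
  if (n_distinct < 2L) return(seq_len(budget))
  ks <- 2:max(2L, min(ceiling(sqrt(N)), n_distinct))
  fits <- lapply(ks, function(k) stats::kmeans(Kd, k, nstart = 5L))
  aic <- mapply(function(fit, k) {
    sigma2 <- max(fit$tot.withinss / (N * ncol(Kd)), 1e-12)
    ll <- -N * ncol(Kd) / 2 * (log(2 * pi * sigma2) + 1)
    2 * (k * ncol(Kd) + 1) - 2 * ll
  }, fits, ks)
  km <- fits[[which.min(aic)]]

  ## within each cluster, order members nearest-to-centroid first
  ranked <- lapply(seq_len(max(km$cluster)), function(c) {
    members <- which(km$cluster == c)
    d <- rowSums((Kd[members, , drop = FALSE] -
                  matrix(km$centers[c, ], length(members), ncol(Kd),
                         byrow = TRUE))^2)
    members[order(d)]
  })
  sel <- integer(0)
  i <- 1L
  while (length(sel) < budget) {
    for (c in sample(seq_along(ranked))) {
      if (length(sel) >= budget) break
      if (length(ranked[[c]]) >= i) sel <- c(sel, ranked[[c]][i])
    }
    i <- i + 1L
  }
  sort(sel)
}
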