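#' Trajectory features of an active-learning time-point
#'
#' Thirteen features summarise the state of a run; the accuracy regressor
#' predicts the learner's current accuracy from them.  All are fractions in
#' `[0, 1]`:
#'
#' * `f1`, `f2` — average observed responsiveness across columns
#'   (respectively rows): per column (row), the fraction of +1 among its
#'   *observed* entries, averaged over columns (rows) that have any
#'   observation.
#' * `f3`, `f4` — average predicted responsiveness across columns (rows),
#'   over the predicted labels of *all* entries.
#' * `f5` — mean absolute change of the posterior grid since the previous
#'   time-point; `f6` — the same for the previous pair of time-points.
#'   Posterior probabilities (not labels) are compared, because label flips
#'   are too rare late in a run to carry signal.
#' * `f7` — of the entries newly observed since the previous time-point
#'   that were then predicted interacting, the fraction whose measured
#'   label is +1.
#' * `f8`-`f10` — minimum, maximum and mean number of experiments performed
#'   per drug, divided by M.
#' * `f11`-`f13` — the same per target, divided by N.
#'
#' At the first time-point `f5`-`f7` are defined as 0; `f7` is 0 whenever
#' its denominator is empty.
#'
#' @param X experimental matrix at the current time-point.
#' @param labels current predicted label matrix (+1/-1).
#' @param P current posterior-probability matrix.
#' @param prev_P,prev2_P posterior grids of the one and two previous
#'   time-points, or NULL.
#' @param prev_labels predicted labels at the previous time-point, or NULL.
#' @param new_idx linear indices of entries newly observed since the
#'   previous time-point, or NULL.
#' @return named numeric vector `f1`..`f13`.
#' @export
compute_features <- function(X, labels, P, prev_P = NULL, prev2_P = NULL,
                             prev_labels = NULL, new_idx = NULL) {
  obs <- X != 0
  N <- nrow(X); M <- ncol(X)

  col_obs <- colSums(obs)
  row_obs <- rowSums(obs)
  pos <- X == 1
  f1 <- mean((colSums(pos) / col_obs)[col_obs > 0])
  f2 <- mean((rowSums(pos) / row_obs)[row_obs > 0])

  pred_pos <- labels == 1
  f3 <- mean(colMeans(pred_pos))
  f4 <- mean(rowMeans(pred_pos))

  f5 <- if (is.null(prev_P)) 0 else mean(abs(P - prev_P))
  f6 <- if (is.null(prev_P) || is.null(prev2_P)) 0 else mean(abs(prev_P - prev2_P))

  f7 <- 0
  if (!is.null(new_idx) && !is.null(prev_labels)) {
    hit <- new_idx[prev_labels[new_idx] == 1]
    if (length(hit) > 0L) f7 <- mean(X[hit] == 1)
  }

  c(f1 = f1, f2 = f2, f3 = f3, f4 = f4, f5 = f5, f6 = f6, f7 = f7,
    f8 = min(row_obs) / M, f9 = max(row_obs) / M, f10 = mean(row_obs) / M,
    f11 = min(col_obs) / N, f12 = max(col_obs) / N, f13 = mean(col_obs) / N)
}

#' Quadratic extension of a feature vector
#'
#' Appends `sqrt(f[i] * f[j])` for every unordered pair `i > j` — a simple
#' way to give the linear accuracy regressor quadratic terms while keeping
#' every predictor in `[0, 1]`.  For p = 13 raw features the extended
#' vector has length `0.5 * p * (p + 1) = 91`.  Pairs are enumerated in
#' [utils::combn()] column order: (1,2), (1,3), ..., (1,p), (2,3), ...
#'
#' @param f numeric vector (or matrix, rows = observations) of raw
#'   features, all in `[0, 1]`.
#' @return the extended vector (or matrix) of length `p + choose(p, 2)`.
#' @export
extend_features <- function(f) {
  if (is.matrix(f)) {
    if (any(f < 0)) stop("features must be non-negative", call. = FALSE)
    idx <- utils::combn(ncol(f), 2L)
    ext <- sqrt(f[, idx[1L, ], drop = FALSE] * f[, idx[2L, ], drop = FALSE])
    colnames(ext) <- paste0("x", idx[1L, ], "_", idx[2L, ])
    return(cbind(f, ext))
  }
  if (any(f < 0)) stop("features must be non-negative", call. = FALSE)
  p <- length(f)
  idx <- utils::combn(p, 2L)
  out <- c(f, sqrt(f[idx[1L, ]] * f[idx[2L, ]]))
  names(out) <- c(names(f) %||% paste0("f", seq_len(p)),
                  paste0("x", idx[1L, ], "_", idx[2L, ]))
  out
}
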