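#' Generate an interaction matrix with prescribed uniqueness and responsiveness
#'
#' Interaction matrices are simulated on a grid of uniqueness (`u`) and
#' responsiveness (`r`) values so that active-learning traces can be
#' collected over a wide range of problem difficulties.  The generator is
#' constructive: it builds a core pattern matrix `C` with `k_N` distinct row
#' prototypes and `k_M` distinct column prototypes, where
#' `k_N + k_M = round(u * (N + M))`, tiles it into an `N x M` matrix by
#' assigning every drug (target) to a row (column) prototype, and then runs
#' a greedy local search — flipping core cells or moving a drug/target to a
#' different prototype — until the realised responsiveness is within `tol`
#' of the target.  Distinctness of the prototypes (hence the uniqueness) is
#' preserved by every accepted move.
#'
#' @param u_target,r_target target uniqueness and responsiveness.
#' @param N,M matrix dimensions (drugs x targets).
#' @param tol acceptance tolerance on both achieved statistics.
#' @param seed integer seed; the generator is fully deterministic given it.
#' @param max_attempts independent restarts before declaring infeasibility.
#' @return an interaction matrix whose [responsiveness()] and [uniqueness()]
#'   are within `tol` of the targets; otherwise an error naming the best
#'   achieved `(u, r)`.
#' @export
generate_interaction_matrix <- function(u_target, r_target, N = 50L, M = 50L,
                                        tol = 0.02, seed = 1L,
                                        max_attempts = 25L) {
  stopifnot(N >= 2L, M >= 2L, u_target > 0, u_target <= 1,
            r_target >= 0, r_target <= 1)
  set.seed(seed)

  ## degenerate responsiveness: the matrix is forced
  if (r_target <= tol / 2 || r_target >= 1 - tol / 2) {
    fill <- if (r_target < 0.5) -1 else 1
    Y <- matrix(fill, N, M)
    if (abs(uniqueness(Y) - u_target) > tol)
      stop(sprintf(
        "infeasible (u, r) target: r = %.3f forces a constant matrix with u = %.4f (target u = %.3f)",
        r_target, uniqueness(Y), u_target), call. = FALSE)
    return(Y)
  }

  k_total <- max(2L, round(u_target * (N + M)))
  k_N <- min(N, max(1L, round(k_total * N / (N + M))))
  k_M <- k_total - k_N
  if (k_M < 1L) { k_M <- 1L; k_N <- k_total - 1L }
  if (k_M > M)  { k_M <- M;  k_N <- k_total - M }
  if (k_N < 1L || k_N > N || k_M < 1L || k_M > M ||
      log2(k_N) > k_M || log2(k_M) > k_N)
    stop(sprintf("infeasible uniqueness target u = %.3f for a %d x %d matrix",
                 u_target, N, M), call. = FALSE)

  best <- NULL
  for (attempt in seq_len(max_attempts)) {
    res <- try(build_tiled_matrix(k_N, k_M, N, M, r_target, tol), silent = TRUE)
    if (inherits(res, "try-error")) next
    r_ach <- responsiveness(res)
    u_ach <- uniqueness(res)
    if (is.null(best) || abs(r_ach - r_target) < abs(best$r - r_target))
      best <- list(Y = res, r = r_ach, u = u_ach)
    if (abs(r_ach - r_target) <= tol && abs(u_ach - u_target) <= tol)
      return(res)
  }
  stop(sprintf(
    "could not reach (u = %.3f, r = %.3f) within tol = %.3f; best achieved (u = %.4f, r = %.4f)",
    u_target, r_target, tol,
    if (is.null(best)) NA_real_ else best$u,
    if (is.null(best)) NA_real_ else best$r), call. = FALSE)
}

## one constructive attempt + greedy repair; uses the current RNG stream
build_tiled_matrix <- function(k_N, k_M, N, M, r_target, tol) {
  C <- matrix(ifelse(stats::runif(k_N * k_M) < r_target, 1, -1), k_N, k_M)
  C <- make_patterns_distinct(C)

  ## prototype sizes: as even as possible
  row_sizes <- tabulate(rep_len(seq_len(k_N), N), nbins = k_N)
  col_sizes <- tabulate(rep_len(seq_len(k_M), M), nbins = k_M)

  r_of <- function(C, rs, cs)
    sum((rs %o% cs)[C == 1]) / (N * M)

  r_ach <- r_of(C, row_sizes, col_sizes)
  for (step in seq_len(400L)) {
    delta <- r_target - r_ach
    if (abs(delta) <= tol * 0.75) break
    move <- best_repair_move(C, row_sizes, col_sizes, delta, N, M)
    if (is.null(move)) break
    if (move$type == "flip") {
      C[move$a, move$b] <- -C[move$a, move$b]
    } else if (move$type == "row") {
      row_sizes[move$from] <- row_sizes[move$from] - 1L
      row_sizes[move$to] <- row_sizes[move$to] + 1L
    } else {
      col_sizes[move$from] <- col_sizes[move$from] - 1L
      col_sizes[move$to] <- col_sizes[move$to] + 1L
    }
    r_ach <- r_ach + move$change
  }

  row_assign <- sample(rep(seq_len(k_N), times = row_sizes))
  col_assign <- sample(rep(seq_len(k_M), times = col_sizes))
  C[row_assign, col_assign, drop = FALSE]
}

## pick the move whose responsiveness change best cancels `delta`;
## distinctness is only verified for the top-ranked flip candidates
best_repair_move <- function(C, rs, cs, delta, N, M) {
  k_N <- nrow(C); k_M <- ncol(C)
  pos <- C == 1
  type <- character(0); a <- integer(0); b <- integer(0); change <- numeric(0)

  ## cell flips: change = -C[a,b] * rs[a] * cs[b] / (N*M)
  flip_change <- -C * (rs %o% cs) / (N * M)
  idx <- which(abs(delta - flip_change) < abs(delta) - 1e-12, arr.ind = TRUE)
  if (nrow(idx) > 0L) {
    type <- c(type, rep("flip", nrow(idx)))
    a <- c(a, idx[, 1L]); b <- c(b, idx[, 2L])
    change <- c(change, flip_change[idx])
  }

  ## reassigning one drug from row prototype `from` to `to`:
  ## change = (rowscore[to] - rowscore[from]) / (N*M)
  rowscore <- as.numeric(pos %*% cs)
  colscore <- as.numeric(rs %*% pos)
  movable_r <- which(rs > 1L)
  if (length(movable_r) > 0L) {
    ch <- outer(rowscore, rowscore[movable_r], "-") / (N * M)  # [to, from]
    ok <- which(abs(delta - ch) < abs(delta) - 1e-12, arr.ind = TRUE)
    ok <- ok[ok[, 1L] != movable_r[ok[, 2L]], , drop = FALSE]
    if (nrow(ok) > 0L) {
      type <- c(type, rep("row", nrow(ok)))
      a <- c(a, movable_r[ok[, 2L]]); b <- c(b, ok[, 1L])  # from, to
      change <- c(change, ch[ok])
    }
  }
  movable_c <- which(cs > 1L)
  if (length(movable_c) > 0L) {
    ch <- outer(colscore, colscore[movable_c], "-") / (N * M)
    ok <- which(abs(delta - ch) < abs(delta) - 1e-12, arr.ind = TRUE)
    ok <- ok[ok[, 1L] != movable_c[ok[, 2L]], , drop = FALSE]
    if (nrow(ok) > 0L) {
      type <- c(type, rep("col", nrow(ok)))
      a <- c(a, movable_c[ok[, 2L]]); b <- c(b, ok[, 1L])
      change <- c(change, ch[ok])
    }
  }
  if (length(type) == 0L) return(NULL)

  for (i in order(abs(delta - change))[seq_len(min(25L, length(change)))]) {
    if (type[i] == "flip") {
      C2 <- C; C2[a[i], b[i]] <- -C2[a[i], b[i]]
      if (!patterns_distinct(C2)) next
      return(list(type = "flip", a = a[i], b = b[i], change = change[i]))
    }
    return(list(type = type[i], from = a[i], to = b[i], change = change[i]))
  }
  NULL
}

patterns_distinct <- function(C) {
  n_distinct_rows(C) == nrow(C) && n_distinct_rows(t(C)) == ncol(C)
}

make_patterns_distinct <- function(C) {
  for (i in seq_len(2000L)) {
    if (patterns_distinct(C)) return(C)
    rkey <- apply(C, 1L, paste, collapse = "")
    ckey <- apply(C, 2L, paste, collapse = "")
    dup_r <- which(duplicated(rkey))
    dup_c <- which(duplicated(ckey))
    if (length(dup_r) > 0L) {
      a <- dup_r[1L]; b <- sample.int(ncol(C), 1L)
    } else {
      b <- dup_c[1L]; a <- sample.int(nrow(C), 1L)
    }
    C[a, b] <- -C[a, b]
  }
  stop("could not make prototype patterns distinct", call. = FALSE)
}

#' Derive 'perfect' Gaussian kernels from an interaction matrix
#'
#' Simulated systems come with noiseless similarity information: the drug
#' kernel compares drug interaction profiles (rows of `Y`) and the target
#' kernel compares target profiles (columns) under a Gaussian radial basis,
#' `K(i, j) = exp(-||y_i - y_j||^2 / (2 * sigma^2))`.  The bandwidth is the
#' median of the positive pairwise Euclidean distances (the standard median
#' heuristic).
#'
#' @param Y interaction matrix.
#' @return a list with symmetric unit-diagonal matrices `Kd` (N x N) and
#'   `Kt` (M x M).
#' @export
derive_perfect_kernels <- function(Y) {
  validate_interaction_matrix(Y)
  list(Kd = gaussian_profile_kernel(Y),
       Kt = gaussian_profile_kernel(t(Y)))
}

gaussian_profile_kernel <- function(profiles) {
  d <- as.matrix(stats::dist(profiles))
  pos <- d[upper.tri(d)]
  sigma <- stats::median(pos[pos > 0])
  if (!is.finite(sigma) || sigma <= 0) sigma <- 1
  K <- exp(-d^2 / (2 * sigma^2))
  K <- (K + t(K)) / 2
  dimnames(K) <- NULL
  K
}

#' Corrupt a kernel by forcing entries to one
#'
#' Emulates unreliable similarity information: a fraction of the unordered
#' off-diagonal pairs is forced to the maximal similarity value 1 (both
#' symmetric entries), destroying the information those entries carried.
#' The diagonal is untouched.
#'
#' @param K symmetric kernel matrix.
#' @param fraction proportion of off-diagonal pairs to corrupt, in `[0, 1]`.
#' @param seed integer seed for the pair choice.
#' @return the corrupted kernel, still symmetric.
#' @export
corrupt_kernel <- function(K, fraction, seed = 1L) {
  stopifnot(fraction >= 0, fraction <= 1)
  if (fraction == 0) return(K)
  n <- nrow(K)
  pairs <- which(upper.tri(K), arr.ind = TRUE)
  m <- ceiling(fraction * nrow(pairs))
  set.seed(seed)
  pick <- pairs[sample.int(nrow(pairs), m), , drop = FALSE]
  K[pick] <- 1
  K[pick[, c(2L, 1L), drop = FALSE]] <- 1
  K
}

#' Regularize a kernel to positive semidefiniteness
#'
#' Corruption can make a kernel indefinite, which the factorization's
#' Gaussian projections do not tolerate.  Negative eigenvalues are clipped
#' to zero and the reconstruction is rescaled back to unit diagonal.
#'
#' @param K symmetric kernel matrix.
#' @return a symmetric PSD kernel with unit diagonal (smallest eigenvalue
#'   `>= -1e-8` up to floating point).
#' @export
regularize_psd <- function(K) {
  e <- eigen((K + t(K)) / 2, symmetric = TRUE)
  lam <- pmax(e$values, 0)
  K2 <- e$vectors %*% (lam * t(e$vectors))
  d <- pmax(diag(K2), 1e-12)
  K2 <- K2 / sqrt(d %o% d)
  (K2 + t(K2)) / 2
}

#' Build the simulation scenario grid
#'
#' The calibration grid crosses uniqueness and responsiveness values
#' (default 0.05 to 0.95 in steps of 0.05) with kernel corruption levels
#' (default 0, 0.05, 0.10), replicated `n_seeds` times with distinct seeds.
#'
#' @param u_values,r_values,noise_values grid axes.
#' @param n_seeds replicates per grid cell.
#' @param N,M matrix dimensions for every scenario.
#' @param base_seed offset from which per-scenario seeds are derived.
#' @return a data.frame of scenarios (one row each) with columns `u_target`,
#'   `r_target`, `noise`, `N`, `M`, `rep`, `seed`; seeds are all distinct.
#' @export
build_grid <- function(u_values = seq(0.05, 0.95, by = 0.05),
                       r_values = seq(0.05, 0.95, by = 0.05),
                       noise_values = c(0, 0.05, 0.10),
                       n_seeds = 1L, N = 50L, M = 50L, base_seed = 1L) {
  stopifnot(length(u_values) > 0, length(r_values) > 0, length(noise_values) > 0)
  g <- expand.grid(u_target = u_values, r_target = r_values,
                   noise = noise_values, rep = seq_len(n_seeds),
                   KEEP.OUT.ATTRS = FALSE)
  g$N <- as.integer(N)
  g$M <- as.integer(M)
  g$seed <- as.integer((base_seed + seq_len(nrow(g)) - 1L) %% .Machine$integer.max)
  g
}

#' Realise one simulation scenario
#'
#' Convenience wrapper running the full simulated-data pipeline for one grid
#' row: generate the interaction matrix, derive its perfect kernels, corrupt
#' them, and regularize to PSD.
#'
#' @param u_target,r_target,noise,N,M,seed scenario parameters (see
#'   [build_grid()]).
#' @param tol tolerance passed to [generate_interaction_matrix()].
#' @return a list with `Y`, `Kd`, `Kt` and the achieved `u` and `r`.
#' @export
simulate_scenario <- function(u_target, r_target, noise = 0, N = 50L, M = 50L,
                              seed = 1L, tol = 0.02) {
  Y <- generate_interaction_matrix(u_target, r_target, N = N, M = M,
                                   tol = tol, seed = seed)
  ks <- derive_perfect_kernels(Y)
  if (noise > 0) {
    ks$Kd <- regularize_psd(corrupt_kernel(ks$Kd, noise, seed = seed + 1L))
    ks$Kt <- regularize_psd(corrupt_kernel(ks$Kt, noise, seed = seed + 2L))
  }
  list(Y = Y, Kd = ks$Kd, Kt = ks$Kt,
       u = uniqueness(Y), r = responsiveness(Y))
}
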