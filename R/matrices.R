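#' Validate a binary interaction matrix
#'
#' An interaction matrix records the ground-truth outcome of every
#' drug-target experiment: `+1` for an interaction, `-1` for no interaction.
#' Drugs are rows, targets are columns, throughout the package.
#'
#' @param Y numeric matrix with entries in \{-1, +1\}.
#' @return `Y`, invisibly, after validation.
#' @export
validate_interaction_matrix <- function(Y) {
  if (!is.matrix(Y) || !is.numeric(Y))
    stop("interaction matrix must be a numeric matrix", call. = FALSE)
  if (nrow(Y) < 1L || ncol(Y) < 1L)
    stop("interaction matrix must have at least one row and one column", call. = FALSE)
  bad <- which(!(Y == 1 | Y == -1), arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop(sprintf("non-binary entry %s at row %d, column %d (entries must be -1 or +1)",
                 format(Y[bad[1L, 1L], bad[1L, 2L]]), bad[1L, 1L], bad[1L, 2L]),
         call. = FALSE)
  invisible(Y)
}

#' Validate a ternary experimental matrix against its ground truth
#'
#' The experimental matrix `X` holds the labels revealed so far: `+1`/`-1`
#' where the experiment has been performed, `0` where it has not.  The zero
#' set is the unlabeled pool.
#'
#' @param X numeric matrix with entries in \{-1, 0, +1\}.
#' @param Y optional interaction matrix; when given, every nonzero entry of
#'   `X` must agree with `Y`.
#' @return `X`, invisibly.
#' @export
validate_experimental_matrix <- function(X, Y = NULL) {
  if (!is.matrix(X) || !is.numeric(X))
    stop("experimental matrix must be a numeric matrix", call. = FALSE)
  if (any(!(X == 1 | X == -1 | X == 0)))
    stop("experimental matrix entries must be -1, 0 or +1", call. = FALSE)
  if (!is.null(Y)) {
    if (!identical(dim(X), dim(Y)))
      stop("experimental matrix dimensions do not match the interaction matrix",
           call. = FALSE)
    obs <- X != 0
    if (any(X[obs] != Y[obs]))
      stop("revealed entries disagree with the interaction matrix", call. = FALSE)
  }
  invisible(X)
}

#' @rdname validate_interaction_matrix
#' @param X experimental matrix.
#' @return `unlabeled_pool` returns a two-column integer matrix of (drug,
#'   target) indices whose experiments have not been performed.
#' @export
unlabeled_pool <- function(X) {
  which(X == 0, arr.ind = TRUE, useNames = FALSE)
}

# ---- tab-delimited matrix I/O -------------------------------------------

read_tsv_matrix <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", row.names = 1L,
                          check.names = FALSE, comment.char = "",
                          stringsAsFactors = FALSE)
  as.matrix(df)
}

write_tsv_matrix <- function(M, path) {
  df <- as.data.frame(M, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = TRUE, col.names = NA)
  invisible(path)
}

#' Read and write interaction matrices
#'
#' Tab-delimited files with a header row of target identifiers and a first
#' column of drug identifiers.  Entries are `-1`/`+1`; the `"01"` dialect
#' maps `0` in the file to `-1` (and `1` to `+1`), which is how several
#' public interaction tables are coded.  The dialect is never auto-detected.
#'
#' @param path file path.
#' @param dialect `"pm1"` (default, entries are -1/+1) or `"01"`.
#' @return `read_interaction_matrix` returns a validated interaction matrix
#'   with identifiers preserved in file order as dimnames.
#' @export
read_interaction_matrix <- function(path, dialect = c("pm1", "01")) {
  dialect <- match.arg(dialect)
  M <- read_tsv_matrix(path)
  if (!is.numeric(M))
    stop(sprintf("non-numeric entries in %s", path), call. = FALSE)
  if (dialect == "01") {
    if (any(!(M == 0 | M == 1)))
      stop("entries must be 0 or 1 under the '01' dialect", call. = FALSE)
    M <- 2 * M - 1
  }
  validate_interaction_matrix(M)
  attr(M, "dialect") <- dialect
  M
}

#' @rdname read_interaction_matrix
#' @param Y interaction matrix to write.
#' @return `write_interaction_matrix` returns `path` invisibly.  The writer
#'   emits the same dialect it was asked to read.
#' @export
write_interaction_matrix <- function(Y, path, dialect = NULL) {
  if (is.null(dialect)) dialect <- attr(Y, "dialect") %||% "pm1"
  dialect <- match.arg(dialect, c("pm1", "01"))
  validate_interaction_matrix(Y)
  out <- if (dialect == "01") (Y + 1) / 2 else Y
  if (is.null(rownames(out))) rownames(out) <- paste0("d", seq_len(nrow(out)))
  if (is.null(colnames(out))) colnames(out) <- paste0("t", seq_len(ncol(out)))
  write_tsv_matrix(out, path)
}

#' Read and write similarity kernels
#'
#' A kernel is a square symmetric similarity matrix (drug x drug or target x
#' target).  Values are nominally in `[0, 1]` with unit diagonal, but larger
#' values are accepted with a warning only, since kernel scaling is absorbed
#' by the factorization's transformation matrices.  Mild asymmetry from
#' round-tripping is repaired by averaging the matrix with its transpose.
#'
#' @param path file path (tab-delimited, header row + id column).
#' @return `read_kernel` returns a symmetric numeric matrix.
#' @export
read_kernel <- function(path) {
  K <- read_tsv_matrix(path)
  if (!is.numeric(K)) stop(sprintf("non-numeric entries in %s", path), call. = FALSE)
  if (nrow(K) != ncol(K))
    stop(sprintf("kernel must be square, got %d x %d", nrow(K), ncol(K)), call. = FALSE)
  if (anyNA(K)) stop("kernel contains missing values", call. = FALSE)
  K <- (K + t(K)) / 2
  if (any(abs(diag(K) - 1) > 1e-8))
    warning("kernel diagonal is not 1; proceeding (kernel scale is absorbed by the model)",
            call. = FALSE)
  K
}

#' @rdname read_kernel
#' @param K kernel matrix to write.
#' @export
write_kernel <- function(K, path) {
  if (nrow(K) != ncol(K)) stop("kernel must be square", call. = FALSE)
  if (is.null(rownames(K))) dimnames(K) <- list(paste0("k", seq_len(nrow(K))),
                                                paste0("k", seq_len(ncol(K))))
  write_tsv_matrix(K, path)
}

# ---- matrix statistics ---------------------------------------------------

#' Responsiveness of an interaction matrix
#'
#' The fraction of `+1` entries: the probability that a randomly chosen
#' drug-target pair interacts.
#'
#' @param Y interaction matrix.
#' @return a fraction in `[0, 1]`.
#' @export
responsiveness <- function(Y) {
  validate_interaction_matrix(Y)
  sum(Y == 1) / length(Y)
}

#' Uniqueness of an interaction matrix
#'
#' `(distinct rows + distinct columns) / (N + M)`.  Uniqueness measures how
#' independent the drug and target interaction profiles are; the higher it
#' is, the harder the matrix is to complete from partial observations.
#'
#' @param Y interaction matrix.
#' @return a fraction in `(0, 1]`, at least `2 / (N + M)`.
#' @export
uniqueness <- function(Y) {
  validate_interaction_matrix(Y)
  (n_distinct_rows(Y) + n_distinct_rows(t(Y))) / (nrow(Y) + ncol(Y))
}

n_distinct_rows <- function(M) {
  length(unique(apply(M, 1L, paste, collapse = "")))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
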