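#' Pool-level uncertainty criteria
#'
#' Two classical stopping signals computed over the unlabeled pool:
#' `overall_uncertainty` (OU) is the mean binary entropy of the pool
#' posteriors; `minimum_expected_error` (MEE) is the mean of
#' `1 - max(P, 1 - P)`, the expected error if every pool entry were
#' labelled by its current posterior mode.  Both are non-negative, vanish
#' exactly when every pool posterior is 0 or 1, and are monotone in
#' `min(P, 1 - P)`, so they order pool entries identically.
#'
#' @param P posterior-probability matrix.
#' @param pool logical matrix (TRUE = unlabeled) or indices of pool
#'   entries.
#' @return a scalar criterion value.
#' @export
overall_uncertainty <- function(P, pool) {
  v <- P[pool]
  if (length(v) == 0L) stop("empty unlabeled pool", call. = FALSE)
  mean(binary_entropy(v))
}

#' @rdname overall_uncertainty
#' @export
minimum_expected_error <- function(P, pool) {
  v <- P[pool]
  if (length(v) == 0L) stop("empty unlabeled pool", call. = FALSE)
  mean(1 - pmax(v, 1 - v))
}

stop_decision <- function(rule, threshold, trace, round, reason) {
  structure(list(rule = rule, threshold = threshold,
                 round = round, fraction = trace$fraction[round],
                 reason = reason),
            class = "stop_decision")
}

#' @export
print.stop_decision <- function(x, ...) {
  cat(sprintf("%s(%s): stop at round %d (%.1f%% of experiments) - %s\n",
              x$rule, if (is.numeric(x$threshold)) format(x$threshold) else x$threshold,
              x$round, 100 * x$fraction, x$reason))
  invisible(x)
}

#' Stopping rules on an active-learning trace
#'
#' `pa_stop` stops at the first round whose *predicted* accuracy reaches
#' the threshold (default 0.9, the operating point where the simulation
#' calibration supports trusting the prediction).  `ou_stop` and
#' `mee_stop` stop when the pool criterion falls to its threshold; with
#' `threshold = "adapted"` the threshold is relaxed to the current
#' criterion value once the predicted pool labels become consistent
#' between consecutive rounds (more than 99% unchanged), i.e. the run
#' stops at the first label-consistent round.  If a rule never fires, the
#' decision is the final round with reason `"pool exhausted"`.
#'
#' @param trace an `"al_trace"`; `pa_stop` requires a
#'   `predicted_accuracy` column (see [add_predicted_accuracy()]).
#' @param threshold numeric threshold, or `"adapted"` for OU/MEE.
#' @return a `"stop_decision"`: rule, threshold, stop round, fraction of
#'   experiments at stop, and the reason.
#' @export
pa_stop <- function(trace, threshold = 0.9) {
  if (!"predicted_accuracy" %in% names(trace))
    stop("trace has no predicted_accuracy column; use add_predicted_accuracy()",
         call. = FALSE)
  hit <- which(trace$predicted_accuracy >= threshold)
  if (length(hit) > 0L)
    stop_decision("PA", threshold, trace, hit[1L], "threshold crossed")
  else
    stop_decision("PA", threshold, trace, nrow(trace), "pool exhausted")
}

criterion_stop <- function(rule, values, trace, threshold) {
  if (identical(threshold, "adapted")) {
    hit <- which(!is.na(trace$label_consistency) & trace$label_consistency > 0.99)
  } else {
    hit <- which(values <= threshold)
  }
  if (length(hit) > 0L)
    stop_decision(rule, threshold, trace, hit[1L], "threshold crossed")
  else
    stop_decision(rule, threshold, trace, nrow(trace), "pool exhausted")
}

#' @rdname pa_stop
#' @export
ou_stop <- function(trace, threshold = 0.12) {
  criterion_stop("OU", trace$ou, trace, threshold)
}

#' @rdname pa_stop
#' @export
mee_stop <- function(trace, threshold = 0.12) {
  criterion_stop("MEE", trace$mee, trace, threshold)
}

#' Best stopping time of a trace
#'
#' The fraction of experiments at which the learner *first* attains its
#' maximum true accuracy — the target any stopping rule is evaluated
#' against.
#'
#' @param trace an `"al_trace"` with true accuracies.
#' @return the fraction of experiments at the first accuracy argmax.
#' @export
best_stopping_time <- function(trace) {
  trace$fraction[which.max(trace$accuracy)]
}

#' Average distance of a stopping rule from the best stopping time
#'
#' `delta_ave` summarises a rule over several datasets: the mean (and
#' standard deviation) of the absolute difference between the percentage
#' of experiments completed at the rule's stop and at the best stopping
#' time.
#'
#' @param stop_fractions,bst_fractions equal-length vectors (per dataset),
#'   both on the same scale (fractions or percentage points).
#' @return a list with `mean` and `sd` of the absolute differences.
#' @export
delta_ave <- function(stop_fractions, bst_fractions) {
  if (length(stop_fractions) != length(bst_fractions))
    stop("stop and BST vectors must have equal length", call. = FALSE)
  d <- abs(stop_fractions - bst_fractions)
  list(mean = mean(d), sd = stats::sd(d))
}

#' Rank-based AUC on held-out entries
#'
#' Area under the ROC curve of prediction scores against binary labels,
#' computed from the Mann-Whitney statistic (mid-ranks, so tied scores
#' contribute 1/2).
#'
#' @param F_hat prediction-score matrix.
#' @param Y interaction matrix of true labels.
#' @param heldout indices of the evaluation entries (linear or two-column
#'   array indices); must contain both classes.
#' @return AUC in `[0, 1]`.
#' @export
interaction_auc <- function(F_hat, Y, heldout) {
  s <- F_hat[heldout]
  l <- Y[heldout]
  n_pos <- sum(l == 1); n_neg <- sum(l == -1)
  if (n_pos == 0L || n_neg == 0L)
    stop("held-out set must contain both classes", call. = FALSE)
  r <- rank(s)
  (sum(r[l == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}
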