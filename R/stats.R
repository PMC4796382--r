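# Evaluation statistics: thresholded Kendall's tau with permutation
# significance, r^2, R^2_pred, the PRESS-equivalence transform, MAE,
# enrichment bookkeeping.

# signed pair comparison with a tie threshold
.pair_signs <- function(v, pairs, threshold) {
  d <- v[pairs[, 1L]] - v[pairs[, 2L]]
  s <- sign(d)
  s[abs(d) <= threshold] <- 0
  s
}

#' Kendall's tau with a tie threshold
#'
#' Rank correlation over all pairs, where a pair counts as tied (in x
#' or in y) when the two values differ by no more than
#' `tie_threshold`.  The denominator counts all pairs (tau-a style);
#' `type = "b"` switches to the tau-b denominator that discounts ties.
#'
#' @param x experimental values.
#' @param y predicted values.
#' @param tie_threshold values differing by at most this are tied
#'   (default 0.1).
#' @param type `"a"` (default) or `"b"`.
#' @return tau in [-1, 1].
#' @export
kendall_tau <- function(x, y, tie_threshold = 0.1, type = c("a", "b")) {
  type <- match.arg(type)
  n <- length(x)
  if (n < 2L || length(y) != n) stop("need two equal-length vectors, n >= 2")
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  sx <- .pair_signs(x, pairs, tie_threshold)
  sy <- .pair_signs(y, pairs, tie_threshold)
  num <- sum(sx * sy)
  if (type == "a") return(num / nrow(pairs))
  den <- sqrt(sum(sx != 0) * sum(sy != 0))
  if (den == 0) return(0)
  num / den
}

#' Permutation p value for a positive rank correlation
#'
#' One-sided: the proportion of label permutations of `y` whose
#' thresholded tau meets or exceeds the observed tau, with the +1
#' small-sample correction `p = (1 + #{tau* >= tau}) / (n_perm + 1)`.
#' Deterministic for a fixed seed.
#'
#' @inheritParams kendall_tau
#' @param n_perm number of permutations (default 10000).
#' @param seed RNG seed.
#' @return p value in (0, 1].
#' @export
permutation_pvalue <- function(x, y, tie_threshold = 0.1, n_perm = 10000L,
                               seed = 1L) {
  n <- length(x)
  if (n < 2L || length(y) != n) stop("need two equal-length vectors, n >= 2")
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  sx <- .pair_signs(x, pairs, tie_threshold)
  sy0 <- .pair_signs(y, pairs, tie_threshold)
  obs <- sum(sx * sy0) / nrow(pairs)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))
  hits <- 0L
  for (b in seq_len(n_perm)) {
    yp <- y[sample.int(n)]
    sp <- .pair_signs(yp, pairs, tie_threshold)
    if (sum(sx * sp) / nrow(pairs) >= obs - 1e-12) hits <- hits + 1L
  }
  (1 + hits) / (n_perm + 1)
}

#' Squared Pearson correlation
#'
#' @param x experimental values (variance must be positive).
#' @param y predicted values.
#' @return r^2 in [0, 1].
#' @export
r2 <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3L)
  if (var(x) == 0 || var(y) == 0) stop("zero variance")
  cor(x, y)^2
}

#' PRESS-normalized predictive index
#'
#' `R2_pred = 1 - sum((x - y)^2) / sum((x - mean(x))^2)`: the predicted
#' residual sum of squares normalized by the spread of the data to be
#' predicted.  Equals r^2 only when the predictions are mean-matched
#' with unit slope; otherwise it is smaller, and can be negative.
#'
#' @inheritParams r2
#' @return R2_pred in (-Inf, 1].
#' @export
r2pred <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3L)
  if (var(x) == 0) stop("zero variance in x")
  1 - sum((x - y)^2) / sum((x - mean(x))^2)
}

#' Linear transform making R2_pred equal r^2
#'
#' Regression of x on y: `b = sum((x - xbar)(y - ybar)) / sum((y -
#' ybar)^2)`, `a = xbar - b*ybar`, `yhat = a + b*y`; then
#' `r2pred(x, yhat) == r2(x, y)` to numerical precision.
#'
#' @inheritParams r2
#' @return List with `a`, `b`, `yhat`.
#' @export
press_transform <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (var(y) == 0) stop("zero variance in y")
  b <- sum((x - mean(x)) * (y - mean(y))) / sum((y - mean(y))^2)
  a <- mean(x) - b * mean(y)
  list(a = a, b = b, yhat = a + b * y)
}

#' Leave-one-out cross-validated q^2
#'
#' The PRESS-normalized index applied to caller-supplied leave-one-out
#' predictions.
#'
#' @param x experimental values.
#' @param y_loo leave-one-out predictions, same order.
#' @return q^2 in (-Inf, 1].
#' @export
q2 <- function(x, y_loo) r2pred(x, y_loo)

#' Full evaluation report for a prediction set
#'
#' @param x experimental activities (pKi).
#' @param y predicted activities.
#' @param tie_threshold tau tie threshold.
#' @param n_perm permutations for the tau p value (0 skips it).
#' @param seed permutation seed.
#' @return List of class `pq_evalreport`: `tau`, `tau_pvalue`, `mae`,
#'   `r2`, `r2pred`, `n`, `tie_threshold`.
#' @export
eval_report <- function(x, y, tie_threshold = 0.1, n_perm = 10000L,
                        seed = 1L) {
  structure(list(
    tau = kendall_tau(x, y, tie_threshold),
    tau_pvalue = if (n_perm > 0)
      permutation_pvalue(x, y, tie_threshold, n_perm, seed) else NA_real_,
    mae = mean(abs(x - y)),
    r2 = if (length(x) >= 3L && var(x) > 0 && var(y) > 0) r2(x, y) else NA_real_,
    r2pred = if (length(x) >= 3L && var(x) > 0) r2pred(x, y) else NA_real_,
    n = length(x), tie_threshold = tie_threshold
  ), class = "pq_evalreport")
}

#' @export
print.pq_evalreport <- function(x, ...) {
  cat(sprintf("n = %d  tau = %.3f (p = %s)  MAE = %.3f  r2 = %.3f  R2pred = %.3f\n",
              x$n, x$tau,
              if (is.na(x$tau_pvalue)) "-" else format(x$tau_pvalue, digits = 3),
              x$mae, x$r2, x$r2pred))
  invisible(x)
}

#' Screening enrichment bookkeeping
#'
#' Winners are in-model predictions with predicted activity at or
#' above `activity_cut`.  The true-positive percentage is the share of
#' truly active compounds (experimental activity >= `activity_cut`)
#' flagged as winners; the false-positive percentage is the share of
#' decoys flagged as winners; enrichment is their ratio.  With zero
#' decoy winners and a nonzero TP rate the enrichment is reported as a
#' lower bound (against a one-in-n-decoys rate) and flagged.
#'
#' @param truth named numeric vector of experimental activities for
#'   the active set.
#' @param pred data frame for the active set with columns `id`,
#'   `predicted_activity`, `in_model`.
#' @param activity_cut winner threshold (pKi), default 7.5.
#' @param decoy_pred data frame for the decoys, same columns.
#' @return List of class `pq_enrichment`.
#' @export
enrichment <- function(truth, pred, activity_cut = 7.5, decoy_pred = NULL) {
  pred <- as.data.frame(pred)
  act <- truth[as.character(pred$id)]
  winner <- pred$in_model & pred$predicted_activity >= activity_cut
  positives <- act >= activity_cut
  n_pos <- sum(positives)
  tp <- sum(winner & positives)
  tp_pct <- if (n_pos > 0) 100 * tp / n_pos else 0
  fp_pct <- NA_real_; enr <- NA_real_; lower_bound <- FALSE
  if (!is.null(decoy_pred)) {
    dw <- decoy_pred$in_model & decoy_pred$predicted_activity >= activity_cut
    n_dec <- nrow(decoy_pred)
    fp_pct <- 100 * sum(dw) / n_dec
    if (fp_pct > 0) enr <- tp_pct / fp_pct
    else if (tp_pct > 0) { enr <- tp_pct / (100 / n_dec); lower_bound <- TRUE }
    else enr <- 0
  }
  structure(list(n_total = nrow(pred), n_positives = n_pos,
                 n_winners = sum(winner),
                 winners_mean_activity = if (any(winner))
                   mean(act[winner]) else NA_real_,
                 tp = tp, tp_pct = tp_pct, fp_pct = fp_pct,
                 enrichment = enr, lower_bound = lower_bound),
            class = "pq_enrichment")
}

#' @export
print.pq_enrichment <- function(x, ...) {
  cat(sprintf("winners %d / positives %d: TP%% = %.1f, FP%% = %s, enrichment %s%s\n",
              x$n_winners, x$n_positives, x$tp_pct,
              if (is.na(x$fp_pct)) "-" else sprintf("%.3f", x$fp_pct),
              if (is.na(x$enrichment)) "-" else sprintf("%.1f", x$enrichment),
              if (x$lower_bound) " (lower bound)" else ""))
  invisible(x)
}
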