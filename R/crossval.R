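#' Repeated stratified k-fold cross-validation of the stepwise model
#'
#' For each repeat the subjects are partitioned into `k` stratified random
#' folds (stratification keeps both classes in every training split, which
#' unstratified splitting cannot guarantee at `n = 50` and `k` up to 24);
#' for each fold a [backward_lr()] model is fit on the other `k - 1` folds
#' and predicts the held-out subjects. All `n` out-of-fold probabilities of
#' a repeat are pooled into a single AUC, so each repeat contributes one AUC
#' computed entirely from out-of-sample predictions.
#'
#' @param formula model formula as in [backward_lr()].
#' @param data data frame.
#' @param k number of folds, between 2 and `n`.
#' @param n_repeats number of random re-splits (default 100).
#' @param seed integer seed; every `(k, repeat)` split stream is derived
#'   from it, so results are fully reproducible.
#' @param alpha_remove stepwise retention threshold.
#' @return Numeric vector of per-repeat pooled AUCs, with attributes
#'   `fold_sizes` (size of each fold in the last repeat) and `n`.
#' @export
#' @examples
#' d <- data.frame(y = rep(0:1, each = 10), x = c(rnorm(10), rnorm(10, 2)))
#' repeated_kfold(y ~ x, d, k = 2, n_repeats = 3, seed = 1)
repeated_kfold <- function(formula, data, k, n_repeats = 100, seed = 1,
                           alpha_remove = 0.05) {
  mf <- stats::model.frame(formula, data)
  y <- as_binary(stats::model.response(mf))
  X <- stats::model.matrix(attr(mf, "terms"), mf)
  X <- X[, colnames(X) != "(Intercept)", drop = FALSE]
  n <- length(y)
  if (k < 2 || k > n) stop_("k must lie in [2, n]")
  if (min(table(y)) < k) {
    stop_("each class needs at least k = %d members for stratified folds", k)
  }
  idx1 <- which(y == 1)
  idx0 <- which(y == 0)
  aucs <- numeric(n_repeats)
  n_pooled <- integer(n_repeats)
  fold_sizes <- NULL
  for (r in seq_len(n_repeats)) {
    folds <- with_seed(mix_seed(seed, k, r), {
      f <- integer(n)
      for (attempt in seq_len(10)) {
        # remainder folds are complemented between classes so total fold
        # sizes stay as equal as possible (k = 2, n = 50 -> 25/25)
        f[idx1] <- sample(rep_len(seq_len(k), length(idx1)))
        f[idx0] <- sample(rep_len(rev(seq_len(k)), length(idx0)))
        ok <- all(vapply(seq_len(k), function(j) {
          length(unique(y[f != j])) == 2
        }, logical(1)))
        if (ok) break
        message("degenerate training split; fold assignment redrawn")
        if (attempt == 10) stop_("could not draw folds with both classes in every training split")
      }
      f
    })
    prob <- rep(NA_real_, n)
    for (j in seq_len(k)) {
      tr <- folds != j
      bw <- backward_fit(X[tr, , drop = FALSE], y[tr], alpha_remove)
      prob[!tr] <- if (length(bw$keep)) {
        predict_logit(bw$fit$coef, X[!tr, bw$keep, drop = FALSE])
      } else {
        stats::plogis(bw$fit$coef[1])
      }
    }
    n_pooled[r] <- sum(!is.na(prob))
    stopifnot(n_pooled[r] == n)
    aucs[r] <- auc_rank(prob, y)
    fold_sizes <- tabulate(folds, k)
  }
  structure(aucs, fold_sizes = fold_sizes, n = n, n_pooled = n_pooled)
}

#' Cross-validation AUC curve over a range of fold counts
#'
#' Runs [repeated_kfold()] for every `k` in `k_range` and summarizes each as
#' the mean per-repeat AUC with a normal-approximation 95% interval
#' `mean +/- 1.96 * sd / sqrt(n_repeats)` (an interval for the mean over
#' re-splits; with a single repeat it collapses to the value itself).
#'
#' @param formula,data,n_repeats,seed,alpha_remove as in [repeated_kfold()].
#' @param k_range integer vector of fold counts (default `2:24`).
#' @return An object of class `cv_curve`: list with `k`, `mean_auc`,
#'   `ci_low`, `ci_high`, the per-repeat AUC matrix `repeats`
#'   (`n_repeats` x `length(k_range)`) and `fold_sizes`.
#' @export
cv_curve <- function(formula, data, k_range = 2:24, n_repeats = 100,
                     seed = 1, alpha_remove = 0.05) {
  res <- lapply(k_range, function(k) {
    repeated_kfold(formula, data, k, n_repeats, seed, alpha_remove)
  })
  reps <- vapply(res, as.numeric, numeric(n_repeats))
  if (n_repeats == 1) reps <- matrix(reps, nrow = 1)
  mean_auc <- colMeans(reps)
  sdv <- if (n_repeats > 1) apply(reps, 2, stats::sd) else rep(0, length(k_range))
  half <- 1.96 * sdv / sqrt(n_repeats)
  structure(list(
    k = k_range, mean_auc = mean_auc,
    ci_low = mean_auc - half, ci_high = mean_auc + half,
    repeats = reps,
    fold_sizes = lapply(res, attr, "fold_sizes"),
    n_repeats = n_repeats
  ), class = "cv_curve")
}

#' @export
print.cv_curve <- function(x, ...) {
  cat(sprintf("Cross-validation AUC curve (%d repeats per k)\n", x$n_repeats))
  print(as.data.frame(x), digits = 3, row.names = FALSE)
  invisible(x)
}

#' @export
as.data.frame.cv_curve <- function(x, ...) {
  data.frame(k = x$k, mean_auc = x$mean_auc,
             ci_low = x$ci_low, ci_high = x$ci_high)
}

#' @export
plot.cv_curve <- function(x, ...) {
  graphics::plot(x$k, x$mean_auc, type = "l", lwd = 2,
                 ylim = range(c(x$ci_low, x$ci_high, 0.5)),
                 xlab = "number of folds k", ylab = "mean out-of-fold AUC", ...)
  graphics::lines(x$k, x$ci_low, lty = 2, col = "red")
  graphics::lines(x$k, x$ci_high, lty = 2, col = "red")
  graphics::abline(h = 0.5, col = "grey")
  invisible(x)
}
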