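# Logistic fitting internals --------------------------------------------------

as_binary <- function(labels) {
  if (is.factor(labels)) {
    if (nlevels(labels) != 2) stop_("labels must have exactly 2 levels")
    return(as.integer(labels == levels(labels)[2]))
  }
  u <- sort(unique(labels))
  if (!all(u %in% c(0, 1))) stop_("numeric labels must be 0/1")
  as.integer(labels)
}

# Maximum-likelihood logistic fit through glm.fit, with the covariance
# recovered from the weighted QR exactly as summary.glm does.
logit_mle <- function(X, y) {
  Xd <- cbind(`(Intercept)` = 1, X)
  fit <- suppressWarnings(stats::glm.fit(Xd, y, family = stats::binomial()))
  cf <- fit$coefficients
  se <- rep(NA_real_, length(cf))
  if (fit$rank > 0) {
    p1 <- seq_len(fit$rank)
    Qr <- fit$qr
    cov <- chol2inv(Qr$qr[p1, p1, drop = FALSE])
    se[Qr$pivot[p1]] <- sqrt(diag(cov))
  }
  list(coef = cf, se = se, converged = fit$converged,
       fitted = fit$fitted.values, lambda = 0)
}

# Ridge-penalized logistic IRLS on standardized predictors (intercept
# unpenalized), used to stabilize fits under (quasi-)separation. Returns
# coefficients and Wald SEs on the original scale.
logit_ridge <- function(X, y, lambda) {
  ctr <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  scl[scl == 0] <- 1
  Xs <- sweep(sweep(X, 2, ctr), 2, scl, "/")
  Xd <- cbind(1, Xs)
  q <- ncol(Xd)
  D <- diag(c(0, rep(lambda, q - 1)), q)
  b <- numeric(q)
  converged <- FALSE
  for (it in seq_len(100)) {
    eta <- drop(Xd %*% b)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    H <- crossprod(Xd, Xd * w) + D
    g <- crossprod(Xd, y - mu) - D %*% b
    db <- tryCatch(solve(H, g), error = function(e) NULL)
    if (is.null(db)) break
    b <- b + drop(db)
    if (max(abs(db)) < 1e-9) { converged <- TRUE; break }
  }
  eta <- drop(Xd %*% b)
  mu <- stats::plogis(eta)
  w <- pmax(mu * (1 - mu), 1e-10)
  H <- crossprod(Xd, Xd * w) + D
  V <- tryCatch(solve(H), error = function(e) matrix(NA_real_, q, q))
  # back-transform: beta_raw = T beta_std with T mapping standardized coefs
  Tm <- diag(q)
  Tm[1, -1] <- -ctr / scl
  Tm[cbind(2:q, 2:q)] <- 1 / scl
  b_raw <- drop(Tm %*% b)
  V_raw <- Tm %*% V %*% t(Tm)
  names(b_raw) <- c("(Intercept)", colnames(X))
  list(coef = b_raw, se = sqrt(diag(V_raw)), converged = converged,
       fitted = mu, lambda = lambda, std_coef = b)
}

# One stabilized logistic fit. Plain ML with Wald p-values is the default.
# Under separation symptoms (non-convergence, huge standardized coefficients
# or unusable SEs) Wald statistics degenerate -- the Hauck-Donner effect
# makes exactly the strongest predictors look worthless -- so the
# elimination p-values switch to drop-one likelihood-ratio tests, which
# remain well-behaved, and the reported coefficients come from an
# escalating ridge (capped at 100; hitting the cap flags the data as
# separable).
logit_stable <- function(X, y) {
  scl <- if (ncol(X)) apply(X, 2, stats::sd) else numeric(0)
  scl[scl == 0] <- 1
  degenerate <- function(f) {
    std <- abs(f$coef[-1] * scl)
    se_std <- f$se[-1] * scl
    !f$converged || any(!is.finite(f$coef)) || any(!is.finite(f$se)) ||
      (length(std) && (max(std) > 15 || max(se_std) > 10))
  }
  fit <- logit_mle(X, y)
  separable <- FALSE
  if (!ncol(X) || !degenerate(fit)) {
    z <- fit$coef / fit$se
    fit$p <- (2 * stats::pnorm(-abs(z)))[-1]
    fit$separable <- FALSE
    return(fit)
  }
  dev_full <- deviance_logit(X, y)
  fit$p <- vapply(seq_len(ncol(X)), function(j) {
    dev_red <- deviance_logit(X[, -j, drop = FALSE], y)
    stats::pchisq(max(dev_red - dev_full, 0), df = 1, lower.tail = FALSE)
  }, numeric(1))
  for (lambda in c(1e-6, 1e-4, 1e-2, 1, 100)) {
    rfit <- logit_ridge(X, y, lambda)
    if (!degenerate(rfit)) break
  }
  separable <- degenerate(rfit)
  fit$coef <- rfit$coef
  fit$se <- rfit$se
  fit$fitted <- rfit$fitted
  fit$lambda <- rfit$lambda
  fit$separable <- separable
  fit
}

deviance_logit <- function(X, y) {
  f <- suppressWarnings(stats::glm.fit(cbind(1, X), y, family = stats::binomial()))
  f$deviance
}

# Backward elimination on a numeric feature matrix. Shared by the exported
# model interface and the cross-validation loop (which must avoid formula
# overhead).
backward_fit <- function(X, y, alpha_remove = 0.05) {
  keep <- seq_len(ncol(X))
  trace <- data.frame(step = integer(), removed = character(),
                      p_value = numeric(), stringsAsFactors = FALSE)
  step <- 0L
  repeat {
    fit <- logit_stable(X[, keep, drop = FALSE], y)
    if (!length(keep)) break
    worst <- which.max(fit$p)
    if (!length(worst) || is.na(fit$p[worst]) || fit$p[worst] <= alpha_remove) break
    step <- step + 1L
    trace <- rbind(trace, data.frame(step = step,
                                     removed = colnames(X)[keep[worst]],
                                     p_value = fit$p[worst]))
    keep <- keep[-worst]
  }
  list(keep = keep, fit = fit, trace = trace)
}

predict_logit <- function(coef, X, type = "response") {
  eta <- drop(cbind(1, X) %*% coef)
  if (type == "link") eta else stats::plogis(eta)
}

# Fast tie-aware Mann-Whitney AUC used inside cross-validation loops.
auc_rank <- function(scores, y) {
  n1 <- sum(y == 1)
  n0 <- sum(y == 0)
  r <- rank(scores)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Exported interface ----------------------------------------------------------

#' Backward-elimination logistic regression
#'
#' Fits a logistic regression and repeatedly removes the predictor with the
#' largest Wald p-value until every remaining predictor satisfies
#' `p <= alpha_remove` (one removal per step; no re-entry). The procedure is
#' deterministic given the data. Quasi-separated fits, under which Wald
#' statistics degenerate (the Hauck-Donner effect would otherwise eliminate
#' exactly the strongest predictors), are stabilized by an escalating ridge
#' penalty; if even the strongest penalty leaves the fit degenerate the
#' result is flagged `separable` and returned with a warning.
#'
#' @param formula model formula; the response must be binary (0/1 or a
#'   two-level factor whose second level is the positive class).
#' @param data data frame.
#' @param alpha_remove retention threshold for the Wald p-value.
#' @return An object of class `backward_lr` with the selected features,
#'   coefficients, Wald p-values, elimination trace, in-sample AUC with
#'   DeLong 95% CI, and sensitivity/specificity at the 0.5 cutoff.
#' @seealso [auc_with_ci()], [binary_metrics()], [repeated_kfold()]
#' @export
#' @examples
#' set.seed(1)
#' d <- data.frame(y = rep(0:1, each = 25), x = rnorm(50))
#' d$x <- d$x + d$y * 2
#' fit <- backward_lr(y ~ x, d)
#' fit
backward_lr <- function(formula, data, alpha_remove = 0.05) {
  mf <- stats::model.frame(formula, data)
  y <- as_binary(stats::model.response(mf))
  X <- stats::model.matrix(attr(mf, "terms"), mf)
  X <- X[, colnames(X) != "(Intercept)", drop = FALSE]
  if (length(unique(y)) != 2) stop_("both classes must be present")
  if (min(table(y)) < 2) stop_("need at least 2 subjects per class")
  const <- apply(X, 2, function(v) stats::sd(v) == 0)
  if (any(const)) {
    stop_("constant feature(s): %s", paste(colnames(X)[const], collapse = ", "))
  }
  bw <- backward_fit(X, y, alpha_remove)
  sel <- colnames(X)[bw$keep]
  prob <- predict_logit(bw$fit$coef, X[, bw$keep, drop = FALSE])
  auc <- auc_with_ci(prob, y)
  bm <- binary_metrics(prob, y)
  if (bw$fit$separable) {
    warn_("perfect separation persisted after the ridge fallback; coefficients are unreliable")
  }
  structure(list(
    selected = sel,
    coefficients = bw$fit$coef,
    se = bw$fit$se,
    p_values = stats::setNames(bw$fit$p, sel),
    fitted = unname(prob),
    y = y,
    trace = bw$trace,
    auc = unname(auc["auc"]), auc_ci = unname(auc[c("ci_low", "ci_high")]),
    sensitivity = bm[["sensitivity"]], specificity = bm[["specificity"]],
    separable = bw$fit$separable, lambda = bw$fit$lambda,
    alpha_remove = alpha_remove,
    n = length(y), n_pos = sum(y == 1),
    feature_names = colnames(X),
    call = match.call()
  ), class = "backward_lr")
}

#' @export
print.backward_lr <- function(x, ...) {
  cat("Backward-elimination logistic model\n")
  cat(sprintf("  n = %d (%d positive); %d of %d features retained\n",
              x$n, x$n_pos, length(x$selected), length(x$feature_names)))
  if (length(x$selected)) {
    cat(sprintf("  selected: %s\n", paste(x$selected, collapse = ", ")))
  } else {
    cat("  selected: (none; intercept-only)\n")
  }
  cat(sprintf("  in-sample AUC %.3f [%.3f, %.3f]; sens %.1f%% / spec %.1f%% at 0.5\n",
              x$auc, x$auc_ci[1], x$auc_ci[2],
              100 * x$sensitivity, 100 * x$specificity))
  if (x$separable) cat("  WARNING: data flagged separable\n")
  invisible(x)
}

#' @export
summary.backward_lr <- function(object, ...) {
  print(object)
  cat("\nCoefficients (log-odds):\n")
  tab <- data.frame(estimate = object$coefficients, se = object$se,
                    p_value = c(NA, object$p_values))
  print(tab, digits = 4)
  if (nrow(object$trace)) {
    cat("\nElimination trace:\n")
    print(object$trace, row.names = FALSE)
  }
  invisible(object)
}

#' @export
coef.backward_lr <- function(object, ...) object$coefficients

#' @export
predict.backward_lr <- function(object, newdata,
                                type = c("response", "link"), ...) {
  type <- match.arg(type)
  X <- as.matrix(newdata[, object$selected, drop = FALSE])
  predict_logit(object$coefficients, X, type)
}

#' @export
residuals.backward_lr <- function(object,
                                  type = c("deviance", "pearson", "response"),
                                  ...) {
  type <- match.arg(type)
  y <- object$y
  mu <- object$fitted
  switch(type,
    response = y - mu,
    pearson = (y - mu) / sqrt(mu * (1 - mu)),
    deviance = sign(y - mu) * sqrt(-2 * (y * log(mu) + (1 - y) * log(1 - mu)))
  )
}

#' @export
simulate.backward_lr <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  out <- as.data.frame(replicate(nsim, stats::rbinom(object$n, 1, object$fitted)))
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}

#' @export
plot.backward_lr <- function(x, ...) {
  # empirical ROC curve of the in-sample scores
  thr <- sort(unique(c(-Inf, x$fitted, Inf)), decreasing = TRUE)
  tpr <- vapply(thr, function(t) mean(x$fitted[x$y == 1] >= t), numeric(1))
  fpr <- vapply(thr, function(t) mean(x$fitted[x$y == 0] >= t), numeric(1))
  graphics::plot(fpr, tpr, type = "s", lwd = 2,
                 xlab = "1 - specificity", ylab = "sensitivity",
                 main = sprintf("ROC (AUC %.3f)", x$auc), ...)
  graphics::abline(0, 1, col = "grey")
  invisible(x)
}

#' AUC with a DeLong 95% confidence interval
#'
#' The AUC is the Mann-Whitney concordance probability (ties count one
#' half); the variance is DeLong's placement-based estimator and the
#' interval is normal-approximate, clipped to `[0, 1]`.
#'
#' @param scores numeric scores (higher = more case-like).
#' @param labels binary labels.
#' @param conf_level confidence level (default 0.95).
#' @return Named numeric vector `auc`, `ci_low`, `ci_high`.
#' @export
#' @examples
#' auc_with_ci(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1))
auc_with_ci <- function(scores, labels, conf_level = 0.95) {
  y <- as_binary(labels)
  x1 <- scores[y == 1]
  x0 <- scores[y == 0]
  if (!length(x1) || !length(x0)) stop_("both classes must be present")
  m <- length(x1); n0 <- length(x0)
  v10 <- vapply(x1, function(v) (sum(x0 < v) + 0.5 * sum(x0 == v)) / n0, numeric(1))
  v01 <- vapply(x0, function(v) (sum(x1 > v) + 0.5 * sum(x1 == v)) / m, numeric(1))
  auc <- mean(v10)
  s10 <- if (m > 1) stats::var(v10) else 0
  s01 <- if (n0 > 1) stats::var(v01) else 0
  half <- stats::qnorm(1 - (1 - conf_level) / 2) * sqrt(s10 / m + s01 / n0)
  c(auc = auc, ci_low = max(0, auc - half), ci_high = min(1, auc + half))
}

#' Sensitivity and specificity at a probability cutoff
#'
#' A prediction is positive when the probability is greater than or equal
#' to `cutoff`. Sensitivity is TP/(TP+FN); specificity is TN/(TN+FP).
#'
#' @param probabilities predicted probabilities.
#' @param labels binary labels.
#' @param cutoff decision threshold (default 0.5).
#' @return Named numeric vector `sensitivity`, `specificity`.
#' @export
#' @examples
#' binary_metrics(c(0.9, 0.2, 0.7, 0.4), c(1, 0, 1, 0))
binary_metrics <- function(probabilities, labels, cutoff = 0.5) {
  y <- as_binary(labels)
  if (!any(y == 1) || !any(y == 0)) stop_("both classes must be present")
  pred <- as.integer(probabilities >= cutoff)
  c(sensitivity = sum(pred == 1 & y == 1) / sum(y == 1),
    specificity = sum(pred == 0 & y == 0) / sum(y == 0))
}
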