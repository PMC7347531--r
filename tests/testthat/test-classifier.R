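test_that("the unpenalized path reproduces glm coefficients and Wald p-values", {
  set.seed(3)
  d <- data.frame(y = rep(0:1, each = 20),
                  a = rnorm(40), b = rnorm(40), c = rnorm(40))
  d$a <- d$a + d$y
  fit <- backward_lr(y ~ a + b + c, d, alpha_remove = 1)  # no elimination
  ref <- glm(y ~ a + b + c, d, family = binomial)
  expect_equal(unname(fit$coefficients), unname(coef(ref)), tolerance = 1e-6)
  expect_equal(unname(fit$p_values),
               unname(summary(ref)$coefficients[-1, 4]), tolerance = 1e-6)
})

test_that("backward elimination recovers an informative feature among noise", {
  kept_signal <- logical(50)
  false_kept <- 0
  for (s in 1:50) {
    set.seed(1000 + s)
    n <- 50
    X <- matrix(rnorm(n * 10), n, dimnames = list(NULL, paste0("f", 1:10)))
    y <- rep(0:1, each = 25)
    X[, 1] <- X[, 1] + 2 * y  # ~2 SD effect
    d <- data.frame(y = y, X)
    fit <- backward_lr(y ~ ., d)
    kept_signal[s] <- "f1" %in% fit$selected
    false_kept <- false_kept + sum(fit$selected != "f1")
  }
  expect_gte(mean(kept_signal), 0.9)
  # noise features survive at roughly the per-step error rate
  expect_lt(false_kept / (50 * 9), 0.15)
})

test_that("all-noise tables end in an empty or near-empty selection", {
  n_kept <- vapply(1:30, function(s) {
    set.seed(2000 + s)
    d <- data.frame(y = rep(0:1, each = 25),
                    matrix(rnorm(50 * 8), 50, dimnames = list(NULL, paste0("f", 1:8))))
    length(backward_lr(y ~ ., d)$selected)
  }, numeric(1))
  expect_lt(mean(n_kept), 1.5)
})

test_that("trivial and degenerate elimination cases behave", {
  set.seed(5)
  d <- data.frame(y = rep(0:1, each = 25), x = rnorm(50))
  d$x <- d$x + 1.5 * d$y
  fit <- backward_lr(y ~ x, d)
  expect_identical(fit$selected, "x")
  expect_identical(nrow(fit$trace), 0L)

  d$flat <- 1
  expect_error(backward_lr(y ~ x + flat, d), "constant")

  # perfectly separated single feature: stabilized fit keeps the feature
  dsep <- data.frame(y = rep(0:1, each = 10), x = c(rnorm(10), rnorm(10) + 30))
  fit_sep <- backward_lr(y ~ x, dsep)
  expect_identical(fit_sep$selected, "x")
  expect_equal(fit_sep$auc, 1)
  expect_gt(fit_sep$lambda, 0)

  # elimination is deterministic
  set.seed(6)
  d2 <- data.frame(y = rep(0:1, each = 25),
                   matrix(rnorm(50 * 6), 50, dimnames = list(NULL, paste0("f", 1:6))))
  expect_identical(backward_lr(y ~ ., d2)$trace, backward_lr(y ~ ., d2)$trace)
})

test_that("AUC equals exhaustive concordant-pair counting", {
  expect_equal(unname(auc_with_ci(c(1, 2, 3, 4), c(0, 0, 1, 1))["auc"]), 1)

  set.seed(7)
  for (rep in 1:40) {
    n <- sample(4:20, 1)
    y <- c(0, 1, rbinom(n - 2, 1, 0.5))
    sc <- sample(round(rnorm(n), 1))  # ties likely
    got <- auc_with_ci(sc, y)
    expect_equal(unname(got["auc"]), oracle_auc(sc, y), tolerance = 1e-12)
    expect_lte(got["ci_low"], got["auc"])
    expect_gte(got["ci_high"], got["auc"])
    expect_gte(got["ci_low"], 0)
    expect_lte(got["ci_high"], 1)
  }

  # null scores concentrate near 0.5
  set.seed(8)
  auc_null <- auc_with_ci(rnorm(4000), rbinom(4000, 1, 0.5))
  expect_equal(unname(auc_null["auc"]), 0.5, tolerance = 0.05)

  expect_error(auc_with_ci(1:4, c(1, 1, 1, 1)), "both classes")
})

test_that("AUC is invariant under strictly increasing transforms", {
  set.seed(9)
  sc <- rnorm(60)
  y <- rbinom(60, 1, 0.5); y[1:2] <- 0:1
  a0 <- auc_with_ci(sc, y)["auc"]
  expect_equal(auc_with_ci(exp(sc), y)["auc"], a0, tolerance = 1e-12)
  expect_equal(auc_with_ci(3 * sc - 7, y)["auc"], a0, tolerance = 1e-12)
})

test_that("binary metrics implement the 2x2 arithmetic", {
  expect_equal(unname(binary_metrics(c(0.9, 0.8, 0.1, 0.2), c(1, 1, 0, 0))),
               c(1, 1))
  expect_equal(unname(binary_metrics(rep(1, 4), c(1, 1, 0, 0))), c(1, 0))

  # TP=21 FN=4 TN=20 FP=5 -> sens 0.84, spec 0.80 (the n = 25/25 operating point)
  prob <- c(rep(0.9, 21), rep(0.1, 4), rep(0.1, 20), rep(0.9, 5))
  y <- c(rep(1, 25), rep(0, 25))
  expect_equal(unname(binary_metrics(prob, y)), c(0.84, 0.80))
})

test_that("the DeLong interval matches an independent implementation", {
  set.seed(21)
  for (rep in 1:10) {
    y <- c(rep(0, 15), rep(1, 15))
    sc <- rnorm(30) + y
    got <- auc_with_ci(sc, y)
    ref <- pROC::ci.auc(pROC::roc(y, sc, quiet = TRUE, direction = "<"),
                        method = "delong")
    expect_equal(unname(got["auc"]), as.numeric(ref[2]), tolerance = 1e-9)
    expect_equal(unname(got["ci_low"]), max(0, as.numeric(ref[1])), tolerance = 1e-9)
    expect_equal(unname(got["ci_high"]), min(1, as.numeric(ref[3])), tolerance = 1e-9)
  }
})

test_that("model-object methods are coherent with the fit", {
  set.seed(31)
  d <- data.frame(y = rep(0:1, each = 25), x = rnorm(50))
  d$x <- d$x + 1.5 * d$y
  fit <- backward_lr(y ~ x, d)
  expect_equal(unname(coef(fit)),
               unname(coef(glm(y ~ x, d, family = binomial))), tolerance = 1e-6)
  expect_equal(predict(fit, d), fit$fitted, tolerance = 1e-12)
  expect_equal(residuals(fit, "response"), d$y - fit$fitted, tolerance = 1e-12)
  expect_equal(sum(residuals(fit, "deviance")^2),
               deviance(glm(y ~ x, d, family = binomial)), tolerance = 1e-6)
  sims <- simulate(fit, nsim = 3, seed = 1)
  expect_identical(dim(sims), c(50L, 3L))
  expect_true(all(unlist(sims) %in% 0:1))
})
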