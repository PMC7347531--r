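test_that("symbolization follows right-closed quantile bins", {
  expect_equal(as.integer(symbolize(c(1, 2, 3, 4), pspr_config(n_s = 2, n_p = 1))),
               c(0L, 0L, 1L, 1L))

  # strictly increasing series: non-decreasing symbols, balanced occupancy
  s <- symbolize(seq_len(90), pspr_config(n_s = 9, n_p = 10))
  expect_true(all(diff(s) >= 0))
  expect_equal(as.integer(table(factor(s, levels = 0:8))), rep(10L, 9))

  # constant series degenerates to all-zero symbols
  expect_true(all(symbolize(rep(2, 40), pspr_config()) == 0L))

  # uniform binning option
  su <- symbolize(c(0, 0.9, 1.1, 2), pspr_config(n_s = 2, n_p = 1, binning = "uniform"))
  expect_equal(as.integer(su), c(0L, 0L, 1L, 1L))

  expect_error(symbolize(rnorm(5), pspr_config(n_p = 10)), "too short")
})

test_that("pattern models match the sliding-window enumeration oracle", {
  # worked alternating sequence: contexts 0,1,0,1 with deterministic successors
  m <- build_pattern_model(c(0, 1, 0, 1, 0), pspr_config(n_s = 2, n_p = 2))
  lvl <- model_level_as_named(m, 1)
  expect_equal(lvl$w[["0"]], 0.5)
  expect_equal(lvl$w[["1"]], 0.5)
  expect_equal(lvl$P[["0"]], c(0, 1))
  expect_equal(lvl$P[["1"]], c(1, 0))

  # constant sequence: one context, weight 1, deterministic successor
  mc <- build_pattern_model(rep(0L, 10), pspr_config(n_s = 2, n_p = 8))
  for (p in 1:8) {
    lv <- model_level_as_named(mc, p)
    expect_length(lv$w, 1)
    expect_equal(unname(lv$w[1]), 1)
    expect_equal(lv$P[[1]], c(1, 0))
  }

  # exhaustive small sets + random longer cases
  for (s_len in 3:8) {
    grid <- as.matrix(expand.grid(rep(list(0:1), s_len)))
    for (r in seq_len(nrow(grid))) {
      expect_model_equals_oracle(as.integer(grid[r, ]), 2, min(2, s_len - 1))
    }
  }
  set.seed(7)
  for (rep in 1:60) {
    L <- sample(6:12, 1)
    n_s <- sample(2:3, 1)
    expect_model_equals_oracle(random_symbols(L, n_s), n_s, min(4, L - 1))
  }

  expect_error(build_pattern_model(c(0, 1), pspr_config(n_s = 2, n_p = 5)), "n_p")
})

test_that("model normalization invariants hold on random sequences", {
  set.seed(11)
  for (rep in 1:30) {
    n_s <- sample(2:9, 1)
    L <- sample(20:90, 1)
    n_p <- sample(1:8, 1)
    m <- build_pattern_model(random_symbols(L, n_s), pspr_config(n_s, n_p))
    for (p in seq_len(n_p)) {
      expect_equal(sum(m[[p]]$w), 1, tolerance = 1e-9)
      expect_equal(unname(rowSums(m[[p]]$trans)),
                   rep(1, length(m[[p]]$contexts)), tolerance = 1e-9)
      expect_true(all(m[[p]]$trans >= 0))
    }
  }
})

test_that("the dissimilarity agrees with a from-scratch oracle and behaves like a metric", {
  set.seed(13)
  for (rep in 1:60) {
    n_s <- sample(2:3, 1)
    La <- sample(6:12, 1)
    Lb <- sample(6:12, 1)
    sa <- random_symbols(La, n_s)
    sb <- random_symbols(Lb, n_s)
    p <- sample(seq_len(min(La, Lb) - 1), 1)
    cfg <- pspr_config(n_s, p)
    ma <- build_pattern_model(sa, cfg)
    mb <- build_pattern_model(sb, cfg)
    d <- pspr_distance(ma, mb, p)
    expect_equal(d, oracle_distance(sa, sb, p, n_s), tolerance = 1e-12)
    expect_equal(d, pspr_distance(mb, ma, p), tolerance = 1e-15)
    expect_gte(d, 0)
    expect_lte(d, sqrt(2) + 1e-12)
    expect_equal(pspr_distance(ma, ma, p), 0, tolerance = 1e-15)
  }

  cfg2 <- pspr_config(2, 1)
  cfg3 <- pspr_config(3, 1)
  m2 <- build_pattern_model(c(0, 1, 0, 1), cfg2)
  m3 <- build_pattern_model(c(0, 1, 2, 1), cfg3)
  expect_error(pspr_distance(m2, m3, 1), "different alphabets")
})

test_that("reference features average pairwise dissimilarities", {
  set.seed(17)
  cfg <- pspr_config(n_s = 3, n_p = 4)
  t_seq <- random_symbols(30, 3)
  target <- build_pattern_model(t_seq, cfg)

  expect_equal(unname(pspr_features(target, list(target), cfg)), rep(0, 4))

  r1 <- build_pattern_model(random_symbols(25, 3), cfg)
  r2 <- build_pattern_model(random_symbols(40, 3), cfg)
  got <- pspr_features(target, list(r1, r2), cfg)
  expect_length(got, 4)
  for (p in 1:4) {
    expect_equal(unname(got[p]),
                 (pspr_distance(target, r1, p) + pspr_distance(target, r2, p)) / 2,
                 tolerance = 1e-12)
  }

  big <- pspr_features(build_pattern_model(random_symbols(80, 9), pspr_config()),
                       list(build_pattern_model(random_symbols(80, 9), pspr_config())))
  expect_length(big, 10)
  expect_error(pspr_features(target, list(), cfg), "empty")
})

test_that("grid search scores points independently and breaks ties small-first", {
  set.seed(19)
  # toy cohort: targets near one of two template signals
  tmpl <- sin(seq(0, 6 * pi, length.out = 40))
  mk <- function(shift) tmpl * shift + rnorm(40, sd = 0.3)
  targets <- c(lapply(1:8, function(i) mk(1)), lapply(1:8, function(i) mk(-1)))
  labels <- rep(c(1, 0), each = 8)
  refs <- lapply(1:4, function(i) mk(1))

  score <- function(features, labels) auc_with_ci(rowMeans(features), labels)[["auc"]]

  one <- pspr_grid_search(targets, labels, refs, ns_grid = 3, np_grid = 2,
                          score_fun = score)
  expect_identical(one$best$n_s, 3L)
  expect_identical(one$best$n_p, 2L)

  two <- pspr_grid_search(targets, labels, refs, ns_grid = c(2, 3), np_grid = 2,
                          score_fun = score)
  s22 <- score(pspr_feature_matrix(targets, refs, pspr_config(2, 2)), labels)
  s32 <- score(pspr_feature_matrix(targets, refs, pspr_config(3, 2)), labels)
  want <- if (s32 > s22) c(3L, 2L) else c(2L, 2L)
  expect_identical(c(two$best$n_s, two$best$n_p), want)
  expect_equal(sort(two$table$score), sort(c(s22, s32)))

  # default grid covers the published optimum
  expect_true(9 %in% eval(formals(pspr_grid_search)$ns_grid))
  expect_true(10 %in% eval(formals(pspr_grid_search)$np_grid))

  # infeasible points are skipped with a warning
  expect_warning(
    pspr_grid_search(targets, labels, refs, ns_grid = 3, np_grid = c(2, 50),
                     score_fun = score),
    "skipped")
})
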