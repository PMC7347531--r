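# Independent brute-force oracles, deliberately written as naive loops so
# they share no code with the implementation they check.

# Enumerate every length-p window with a successor and count transitions.
oracle_pattern_model <- function(s, n_s, n_p) {
  L <- length(s)
  lapply(seq_len(n_p), function(p) {
    ctx <- list()
    for (i in seq_len(L - p)) {
      key <- paste(s[i:(i + p - 1)], collapse = ".")
      nxt <- s[i + p]
      if (is.null(ctx[[key]])) ctx[[key]] <- numeric(n_s)
      ctx[[key]][nxt + 1] <- ctx[[key]][nxt + 1] + 1
    }
    w <- vapply(ctx, sum, numeric(1)) / (L - p)
    P <- lapply(ctx, function(cnt) cnt / sum(cnt))
    list(w = w, P = P)
  })
}

# Term-by-term evaluation of the dissimilarity formula from two raw symbol
# sequences.
oracle_distance <- function(sa, sb, p, n_s, n_p = p) {
  ma <- oracle_pattern_model(sa, n_s, n_p)[[p]]
  mb <- oracle_pattern_model(sb, n_s, n_p)[[p]]
  keys <- union(names(ma$w), names(mb$w))
  total <- 0
  for (key in keys) {
    wa <- if (key %in% names(ma$w)) ma$w[[key]] else 0
    wb <- if (key %in% names(mb$w)) mb$w[[key]] else 0
    Pa <- if (key %in% names(ma$P)) ma$P[[key]] else rep(1 / n_s, n_s)
    Pb <- if (key %in% names(mb$P)) mb$P[[key]] else rep(1 / n_s, n_s)
    total <- total + (wa + wb) / 2 * sum((Pa - Pb)^2)
  }
  sqrt(total)
}

# Flatten an implementation pattern_model level for comparison with the
# oracle's named representation.
model_level_as_named <- function(model, p) {
  lev <- model[[p]]
  w <- lev$w
  names(w) <- lev$contexts
  P <- lapply(seq_along(lev$contexts), function(i) as.numeric(lev$trans[i, ]))
  names(P) <- lev$contexts
  list(w = w, P = P)
}

expect_model_equals_oracle <- function(s, n_s, n_p) {
  impl <- build_pattern_model(s, pspr_config(n_s = n_s, n_p = n_p))
  orac <- oracle_pattern_model(s, n_s, n_p)
  for (p in seq_len(n_p)) {
    got <- model_level_as_named(impl, p)
    ref_keys <- sort(names(orac[[p]]$w))
    expect_identical(sort(names(got$w)), ref_keys)
    for (key in ref_keys) {
      expect_equal(got$w[[key]], orac[[p]]$w[[key]], tolerance = 1e-12)
      expect_equal(got$P[[key]], orac[[p]]$P[[key]], tolerance = 1e-12)
    }
  }
}

# All-pairs concordance counting for the AUC.
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (a in pos) for (b in neg) {
    total <- total + if (a > b) 1 else if (a == b) 0.5 else 0
  }
  total / (length(pos) * length(neg))
}

# Direct-formula HR statistics (loop style, n-1 SD, adjusted Fisher-Pearson
# skewness, non-excess kurtosis).
oracle_hr_stats <- function(x) {
  n <- length(x)
  m <- sum(x) / n
  dev <- x - m
  s <- sqrt(sum(dev^2) / (n - 1))
  m2 <- sum(dev^2) / n
  m3 <- sum(dev^3) / n
  m4 <- sum(dev^4) / n
  c(mean = m, median = median(x), sd = s,
    kurtosis = m4 / m2^2,
    skewness = (m3 / m2^1.5) * sqrt(n * (n - 1)) / (n - 2),
    minimum = min(x), maximum = max(x), range = max(x) - min(x),
    cv = 100 * s / m)
}

random_symbols <- function(L, n_s) sample(0:(n_s - 1), L, replace = TRUE)
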