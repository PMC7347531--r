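#' PSPR configuration
#'
#' Parameters of the probabilistic symbolic pattern recognition engine:
#' alphabet size `n_s`, maximum modeled pattern (context) length `n_p`,
#' binning rule and symbol rate. The published optimum for 10 s ECGs is
#' `n_s = 9`, `n_p = 10` at a symbol rate of 8 Hz; those are the defaults.
#'
#' @param n_s alphabet size, at least 2.
#' @param n_p maximum pattern length, at least 1.
#' @param binning `"quantile"` (bin edges at empirical quantiles) or
#'   `"uniform"` (equal-width bins over the value range).
#' @param symbol_rate symbol rate in Hz.
#' @return An object of class `pspr_config`.
#' @export
#' @examples
#' pspr_config()
pspr_config <- function(n_s = 9L, n_p = 10L,
                        binning = c("quantile", "uniform"), symbol_rate = 8) {
  binning <- match.arg(binning)
  if (n_s < 2) stop_("n_s must be at least 2")
  if (n_p < 1) stop_("n_p must be at least 1")
  structure(list(n_s = as.integer(n_s), n_p = as.integer(n_p),
                 binning = binning, symbol_rate = symbol_rate),
            class = "pspr_config")
}

#' @export
print.pspr_config <- function(x, ...) {
  cat(sprintf("PSPR config: n_s = %d, n_p = %d, %s binning, %g Hz symbols\n",
              x$n_s, x$n_p, x$binning, x$symbol_rate))
  invisible(x)
}

#' Bin edges for symbolization
#'
#' Quantile binning places the `n_s - 1` interior edges at the `i/n_s`
#' empirical quantiles (type 7) of `values`; uniform binning spaces them
#' equally over `[min, max]`. Pooling the values of several signals (e.g.
#' the reference set) before calling this function yields one shared edge
#' set under which symbols are comparable across subjects.
#'
#' @param values numeric values the edges are estimated from.
#' @param config a [pspr_config()].
#' @return Numeric vector of `n_s - 1` non-decreasing edges.
#' @export
#' @examples
#' symbol_bin_edges(1:100, pspr_config(n_s = 4))
symbol_bin_edges <- function(values, config = pspr_config()) {
  if (!all(is.finite(values))) stop_("values must be finite")
  probs <- seq_len(config$n_s - 1) / config$n_s
  if (config$binning == "quantile") {
    stats::quantile(values, probs, type = 7, names = FALSE)
  } else {
    min(values) + probs * (max(values) - min(values))
  }
}

#' Symbolize a numeric series
#'
#' Each value is replaced by an integer symbol in `0 .. n_s - 1`: the index
#' of the lowest bin whose right edge is greater than or equal to the value
#' (bins are right-closed). With no `edges` supplied the edges are estimated
#' from the series itself; for reference-based comparisons pass one shared
#' edge set (see [symbol_bin_edges()]). A constant series under quantile
#' binning collapses every edge and maps to all-zero symbols; this is the
#' documented degenerate case, not an error.
#'
#' @param x numeric series (finite, length at least `n_p + 2`).
#' @param config a [pspr_config()].
#' @param edges optional externally estimated bin edges.
#' @return Integer vector of symbols with attribute `n_s`.
#' @export
#' @examples
#' symbolize(c(1, 2, 3, 4), pspr_config(n_s = 2, n_p = 1))
symbolize <- function(x, config = pspr_config(), edges = NULL) {
  if (!all(is.finite(x))) stop_("series must be finite")
  if (length(x) < config$n_p + 2) {
    stop_("series of length %d too short for n_p = %d", length(x), config$n_p)
  }
  if (is.null(edges)) edges <- symbol_bin_edges(x, config)
  sym <- findInterval(x, edges, left.open = TRUE)
  structure(as.integer(sym), n_s = config$n_s)
}

#' Build a pattern-transition probability model
#'
#' For every pattern length `p` in `1 .. n_p`, every length-`p` window with
#' a successor symbol (there are `L - p` of them, sliding with stride 1) is
#' a context. The model stores each distinct context's occurrence weight
#' `w(pi) = count(pi) / (L - p)` and its next-symbol conditional
#' distribution `P(s | pi) = count(pi, s) / count(pi)`.
#'
#' @param symbols integer symbol vector (from [symbolize()]), or a numeric
#'   vector already in `0 .. n_s - 1`.
#' @param config a [pspr_config()]; `n_s` must cover the symbols.
#' @return An object of class `pattern_model`: a list with one element per
#'   pattern length, each holding `contexts` (character keys), `w` and
#'   `trans` (contexts x `n_s` row-stochastic matrix), plus attributes
#'   `n_s`, `n_p`, `L`.
#' @export
#' @examples
#' m <- build_pattern_model(c(0, 1, 0, 1, 0), pspr_config(n_s = 2, n_p = 2))
#' m[[1]]$w
build_pattern_model <- function(symbols, config = pspr_config()) {
  s <- as.integer(symbols)
  L <- length(s)
  n_s <- config$n_s
  if (any(s < 0 | s >= n_s)) stop_("symbols out of range for n_s = %d", n_s)
  if (L <= config$n_p) {
    stop_("sequence length L = %d must exceed the maximum pattern length n_p = %d",
          L, config$n_p)
  }
  schr <- as.character(s)
  model <- vector("list", config$n_p)
  key <- character(L)  # running context keys, extended one symbol per p
  for (p in seq_len(config$n_p)) {
    idx <- seq_len(L - p + 1)
    key[idx] <- if (p == 1) schr[idx] else paste(key[idx], schr[idx + p - 1], sep = ".")
    ctx <- key[seq_len(L - p)]
    nxt <- s[seq_len(L - p) + p]
    tab <- table(factor(ctx), factor(nxt, levels = 0:(n_s - 1)))
    counts <- rowSums(tab)
    model[[p]] <- list(
      contexts = rownames(tab),
      w = as.numeric(counts) / (L - p),
      trans = unname(as.matrix(tab) / counts)
    )
  }
  structure(model, n_s = n_s, n_p = config$n_p, L = L, class = "pattern_model")
}

#' @export
print.pattern_model <- function(x, ...) {
  cat(sprintf("PSPR pattern model: n_s = %d, n_p = %d, L = %d symbols\n",
              attr(x, "n_s"), attr(x, "n_p"), attr(x, "L")))
  cat(sprintf("  distinct contexts per length: %s\n",
              paste(vapply(x, function(e) length(e$contexts), integer(1)),
                    collapse = " ")))
  invisible(x)
}

#' PSPR dissimilarity between two pattern models
#'
#' At pattern length `p`,
#' `D_p(A, B) = sqrt( sum_pi ((w_A + w_B) / 2) * sum_s (P_A(s|pi) - P_B(s|pi))^2 )`
#' over the union of both models' contexts. A model lacking a context
#' contributes weight 0 and the uniform conditional `1/n_s`, which keeps
#' every term a comparison of probability distributions and bounds `D_p` by
#' `sqrt(2)`. The measure is symmetric and zero between identical models.
#'
#' @param a,b `pattern_model` objects built with the same `n_s`.
#' @param p pattern length (at most both models' `n_p`).
#' @return A single non-negative dissimilarity value.
#' @export
#' @examples
#' cfg <- pspr_config(n_s = 2, n_p = 2)
#' m1 <- build_pattern_model(c(0, 1, 0, 1, 0), cfg)
#' pspr_distance(m1, m1, 1)
pspr_distance <- function(a, b, p) {
  n_s <- attr(a, "n_s")
  if (n_s != attr(b, "n_s")) {
    stop_("models were built with different alphabets (n_s %d vs %d)",
          n_s, attr(b, "n_s"))
  }
  if (p < 1 || p > attr(a, "n_p") || p > attr(b, "n_p")) {
    stop_("pattern length p = %d outside both models' range", p)
  }
  A <- a[[p]]; B <- b[[p]]
  u <- union(A$contexts, B$contexts)
  ia <- match(u, A$contexts)
  ib <- match(u, B$contexts)
  wa <- ifelse(is.na(ia), 0, A$w[ia])
  wb <- ifelse(is.na(ib), 0, B$w[ib])
  Pa <- matrix(1 / n_s, length(u), n_s)
  Pb <- matrix(1 / n_s, length(u), n_s)
  if (any(!is.na(ia))) Pa[!is.na(ia), ] <- A$trans[ia[!is.na(ia)], , drop = FALSE]
  if (any(!is.na(ib))) Pb[!is.na(ib), ] <- B$trans[ib[!is.na(ib)], , drop = FALSE]
  sqrt(sum((wa + wb) / 2 * rowSums((Pa - Pb)^2)))
}

#' Reference-based PSPR features
#'
#' Feature `p` is the mean dissimilarity at pattern length `p` between the
#' target and each reference model; with `n_p` modeled lengths the result is
#' a length-`n_p` feature vector. In the study design the references are the
#' prevalent-disease subjects, so small values mean "similar to prevalent
#' disease".
#'
#' @param target a `pattern_model` (or a symbol sequence, which is modeled
#'   with `config`).
#' @param references non-empty list of `pattern_model` references.
#' @param config a [pspr_config()] (used only when `target` is a sequence).
#' @return Named numeric vector `pspr_1 .. pspr_np`.
#' @export
pspr_features <- function(target, references, config = pspr_config()) {
  if (!length(references)) stop_("reference set must not be empty")
  if (!inherits(target, "pattern_model")) {
    target <- build_pattern_model(target, config)
  }
  n_p <- attr(target, "n_p")
  out <- vapply(seq_len(n_p), function(p) {
    mean(vapply(references, function(r) pspr_distance(target, r, p), numeric(1)))
  }, numeric(1))
  stats::setNames(out, paste0("pspr_", seq_len(n_p)))
}

#' PSPR feature matrix for a set of signals
#'
#' Convenience wrapper binding the full reference-based extraction: shared
#' bin edges are estimated from the pooled reference signals, all signals
#' are symbolized under those edges, reference models are built, and each
#' target signal is reduced to its `n_p` reference dissimilarity features.
#'
#' @param targets list of numeric series at the symbol rate.
#' @param references list of numeric reference series.
#' @param config a [pspr_config()].
#' @param edges optional precomputed shared bin edges; the default pools the
#'   reference signals.
#' @return Matrix with one row per target and columns `pspr_1 .. pspr_np`.
#' @export
pspr_feature_matrix <- function(targets, references, config = pspr_config(),
                                edges = NULL) {
  if (is.null(edges)) {
    edges <- symbol_bin_edges(unlist(references, use.names = FALSE), config)
  }
  ref_models <- lapply(references, function(x) {
    build_pattern_model(symbolize(x, config, edges), config)
  })
  feats <- t(vapply(targets, function(x) {
    pspr_features(build_pattern_model(symbolize(x, config, edges), config),
                  ref_models, config)
  }, numeric(config$n_p)))
  rownames(feats) <- names(targets)
  feats
}

#' Grid search over PSPR parameters
#'
#' Evaluates every `(n_s, n_p)` combination: features are extracted for the
#' target signals against the references and scored by the supplied
#' evaluation callback (default: in-sample AUC of a [backward_lr()] fit).
#' Grid points whose `n_p` reaches the symbol sequence length are skipped
#' with a warning. Ties favor the smaller `n_s`, then the smaller `n_p`.
#'
#' @param targets list of numeric series at the symbol rate.
#' @param labels binary labels (0/1) for the targets.
#' @param references list of reference series.
#' @param ns_grid,np_grid integer vectors of candidate values; the defaults
#'   bracket the published optimum (9, 10).
#' @param binning binning rule passed to [pspr_config()].
#' @param score_fun `function(features, labels) -> numeric score`; the
#'   default fits the backward-elimination logistic model on the features
#'   and returns its in-sample AUC.
#' @return List with `best` (a [pspr_config()]), `table` (data frame of
#'   `n_s`, `n_p`, `score`).
#' @export
pspr_grid_search <- function(targets, labels, references,
                             ns_grid = c(5, 7, 9, 11),
                             np_grid = c(4, 6, 8, 10, 12),
                             binning = "quantile",
                             score_fun = NULL) {
  if (length(unique(labels)) != 2) stop_("grid search needs exactly two classes")
  if (is.null(score_fun)) {
    score_fun <- function(features, labels) {
      dat <- data.frame(label = labels, features)
      fit <- backward_lr(label ~ ., dat)
      fit$auc
    }
  }
  Lmin <- min(vapply(c(targets, references), length, integer(1)))
  grid <- expand.grid(n_s = sort(unique(ns_grid)), n_p = sort(unique(np_grid)))
  scores <- rep(NA_real_, nrow(grid))
  for (i in seq_len(nrow(grid))) {
    if (grid$n_p[i] >= Lmin) {
      warn_("grid point (n_s = %d, n_p = %d) skipped: n_p not below symbol length %d",
            grid$n_s[i], grid$n_p[i], Lmin)
      next
    }
    cfg <- pspr_config(grid$n_s[i], grid$n_p[i], binning = binning)
    feats <- pspr_feature_matrix(targets, references, cfg)
    scores[i] <- score_fun(feats, labels)
  }
  if (all(is.na(scores))) stop_("no evaluable grid point")
  tab <- cbind(grid, score = scores)
  ord <- order(-tab$score, tab$n_s, tab$n_p, na.last = TRUE)
  best <- tab[ord[1], ]
  list(best = pspr_config(best$n_s, best$n_p, binning = binning), table = tab)
}
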