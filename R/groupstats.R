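#' Kolmogorov-Smirnov normality screen
#'
#' Tests each group's values against a normal distribution with the sample
#' mean and SD (plain KS, no small-sample correction; with estimated
#' parameters the test is anti-conservative, which is documented rather than
#' corrected). A group is flagged normal when p > 0.05. Groups with fewer
#' than `min_n` values are skipped with a warning; a zero-variance group is
#' reported as non-normal with p = 0.
#'
#' @param values numeric vector.
#' @param group optional grouping factor; without it the whole vector is one
#'   group.
#' @param min_n minimum group size (default 5).
#' @return Data frame with columns `group`, `test`, `statistic`, `p_value`,
#'   `normal`.
#' @export
#' @examples
#' normality_screen(rnorm(50))
normality_screen <- function(values, group = NULL, min_n = 5) {
  if (is.null(group)) group <- rep("all", length(values))
  group <- as.factor(group)
  rows <- lapply(levels(group), function(g) {
    x <- values[group == g]
    if (length(x) < min_n) {
      warn_("group '%s' has fewer than %d values; normality screen skipped", g, min_n)
      return(data.frame(group = g, test = "KS-normality",
                        statistic = NA_real_, p_value = NA_real_, normal = NA))
    }
    if (stats::sd(x) == 0) {
      return(data.frame(group = g, test = "KS-normality",
                        statistic = NA_real_, p_value = 0, normal = FALSE))
    }
    ks <- suppressWarnings(stats::ks.test(x, "pnorm", mean(x), stats::sd(x)))
    data.frame(group = g, test = "KS-normality",
               statistic = unname(ks$statistic), p_value = ks$p.value,
               normal = ks$p.value > 0.05)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Univariate group comparisons
#'
#' For each feature the routing mirrors common epidemiological practice: the
#' feature is screened for normality per group (KS test); if every group
#' passes it is compared by ANOVA, otherwise by the Mann-Whitney U test (two
#' groups) or the Kruskal-Wallis test (three or more). Tests are two-tailed
#' with significance at `alpha`; by design no multiplicity correction is
#' applied (per-test significance is reported as in the source analyses),
#' though `p_adjust` exposes one.
#'
#' @param data data frame holding the features and the grouping column.
#' @param features character vector of feature column names.
#' @param group name of the grouping column.
#' @param alpha significance level (default 0.05).
#' @param p_adjust multiplicity correction passed to [stats::p.adjust()]
#'   (default `"none"`).
#' @return Data frame with columns `feature`, `test`, `statistic`,
#'   `p_value`, `significant`.
#' @export
compare_groups <- function(data, features, group, alpha = 0.05,
                           p_adjust = "none") {
  g <- as.factor(data[[group]])
  if (nlevels(g) < 2) stop_("need at least 2 groups")
  sizes <- table(g)
  if (any(sizes < 2)) {
    stop_("group '%s' has fewer than 2 observations",
          names(sizes)[which(sizes < 2)[1]])
  }
  rows <- lapply(features, function(f) {
    x <- data[[f]]
    scr <- suppressWarnings(normality_screen(x, g))
    normal <- all(scr$normal %in% TRUE)
    if (normal) {
      fit <- stats::aov(x ~ g)
      s <- summary(fit)[[1]]
      data.frame(feature = f, test = "ANOVA",
                 statistic = s$`F value`[1], p_value = s$`Pr(>F)`[1])
    } else if (nlevels(g) == 2) {
      wt <- suppressWarnings(stats::wilcox.test(x ~ g))
      data.frame(feature = f, test = "Mann-Whitney U",
                 statistic = unname(wt$statistic), p_value = wt$p.value)
    } else {
      kt <- stats::kruskal.test(x ~ g)
      data.frame(feature = f, test = "Kruskal-Wallis",
                 statistic = unname(kt$statistic), p_value = kt$p.value)
    }
  })
  out <- do.call(rbind, rows)
  out$p_value <- stats::p.adjust(out$p_value, method = p_adjust)
  out$significant <- out$p_value < alpha
  rownames(out) <- NULL
  out
}
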