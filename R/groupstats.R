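# Normality-gated univariate statistics: Shapiro-Wilk gate, one-way ANOVA
# with Tukey post hoc or Kruskal-Wallis with Dunn post hoc, and
# Pearson/Spearman correlations.

#' Shapiro-Wilk normality gate
#'
#' TRUE iff every group passes the Shapiro-Wilk test at \code{alpha}.
#'
#' @param groups list of numeric vectors (each n >= 3) or a single vector.
#' @param alpha significance level (default 0.05).
#' @return logical.
#' @export
normalityGate <- function(groups, alpha = 0.05) {
  if (!is.list(groups)) groups <- list(groups)
  ns <- lengths(groups)
  if (any(ns < 3))
    stop("Shapiro-Wilk requires n >= 3 in every group")
  all(vapply(groups, function(g) stats::shapiro.test(g)$p.value,
             numeric(1)) > alpha)
}

# Dunn's rank-based post hoc test after Kruskal-Wallis, with tie correction
# and Bonferroni adjustment over all pairs.
.dunnTest <- function(values, g) {
  N <- length(values)
  rk <- rank(values)
  ties <- table(rk)
  tieCorr <- sum(ties^3 - ties) / (12 * (N - 1))
  rbar <- tapply(rk, g, mean)
  ns <- tapply(rk, g, length)
  lv <- levels(g)
  pairs <- utils::combn(lv, 2)
  res <- data.frame(group_a = pairs[1, ], group_b = pairs[2, ],
                    z = NA_real_, p_adjusted = NA_real_)
  m <- ncol(pairs)
  for (k in seq_len(m)) {
    a <- pairs[1, k]; b <- pairs[2, k]
    se <- sqrt((N * (N + 1) / 12 - tieCorr) * (1 / ns[[a]] + 1 / ns[[b]]))
    z <- (rbar[[a]] - rbar[[b]]) / se
    res$z[k] <- z
    res$p_adjusted[k] <- min(1, 2 * stats::pnorm(-abs(z)) * m)
  }
  res
}

#' Normality-gated group comparison
#'
#' If every group passes the Shapiro-Wilk gate: one-way ANOVA with Tukey's
#' post hoc test; otherwise: Kruskal-Wallis with Dunn's post hoc test
#' (Bonferroni-adjusted over pairs). The statistic is reported in the
#' conventional style (\code{F(df1,df2)} or \code{X2(df)}).
#'
#' @param values numeric vector of the feature.
#' @param groups group labels, same length as \code{values} (or \code{values}
#'   may be a named list of group vectors).
#' @param alpha gate level for Shapiro-Wilk (default 0.05).
#' @return list: \code{test_name}, \code{statistic}, \code{df},
#'   \code{statistic_label}, \code{p_value}, \code{posthoc} (data.frame with
#'   group_a, group_b, p_adjusted), \code{normal}.
#' @export
compareGroups <- function(values, groups = NULL, alpha = 0.05) {
  if (is.list(values) && is.null(groups)) {
    groups <- rep(names(values), lengths(values))
    values <- unlist(values, use.names = FALSE)
  }
  g <- droplevels(factor(groups))
  if (nlevels(g) < 2) stop("at least 2 groups are required")
  ns <- table(g)
  if (any(ns < 3)) stop("every group needs n >= 3 (got an empty or tiny group)")
  byGroup <- split(values, g)
  normal <- normalityGate(byGroup, alpha)
  if (normal) {
    fit <- stats::aov(values ~ g)
    an <- stats::anova(fit)
    Fv <- an$`F value`[1]
    df1 <- an$Df[1]; df2 <- an$Df[2]
    tk <- stats::TukeyHSD(fit)$g
    ph <- data.frame(
      group_a = sub("-.*$", "", rownames(tk)),
      group_b = sub("^[^-]*-", "", rownames(tk)),
      p_adjusted = tk[, "p adj"], row.names = NULL)
    list(test_name = "one-way ANOVA + Tukey", statistic = Fv,
         df = c(df1, df2),
         statistic_label = sprintf("F(%d,%d) = %.4g", df1, df2, Fv),
         p_value = an$`Pr(>F)`[1], posthoc = ph, normal = TRUE)
  } else {
    kw <- stats::kruskal.test(values, g)
    dn <- .dunnTest(values, g)
    list(test_name = "Kruskal-Wallis + Dunn",
         statistic = unname(kw$statistic), df = unname(kw$parameter),
         statistic_label = sprintf("X2(%d) = %.4g",
                                   unname(kw$parameter), unname(kw$statistic)),
         p_value = kw$p.value,
         posthoc = dn[c("group_a", "group_b", "p_adjusted")],
         normal = FALSE)
  }
}

#' Normality-gated correlation
#'
#' Pearson when both variables pass Shapiro-Wilk at \code{alpha}, Spearman
#' otherwise; two-sided p-value.
#'
#' @param x,y paired numeric vectors, n >= 4.
#' @param alpha gate level (default 0.05).
#' @return list: \code{method}, \code{r}, \code{p_value}, \code{n}.
#' @export
correlateFeatures <- function(x, y, alpha = 0.05) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 4) stop("correlation requires at least 4 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance in x or y; correlation undefined")
  usePearson <- stats::shapiro.test(x)$p.value > alpha &&
    stats::shapiro.test(y)$p.value > alpha
  method <- if (usePearson) "pearson" else "spearman"
  ct <- suppressWarnings(stats::cor.test(x, y, method = method))
  list(method = method, r = unname(ct$estimate), p_value = ct$p.value, n = n)
}
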