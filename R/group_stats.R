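#' Mann-Whitney (Wilcoxon rank-sum) two-group comparison
#'
#' The two-group workhorse for event power/duration and behavioral
#' endpoints. The p-value is exact (full enumeration of rank assignments)
#' when the combined sample size is at most 20 and there are no ties, and
#' the normal approximation with tie correction and continuity correction
#' otherwise. The reported U statistic counts pairs won by group `a`.
#'
#' @param a,b Numeric vectors, one value per sampling unit (>= 1 each).
#' @param alternative `"two_sided"`, `"greater"` (a tends larger) or
#'   `"less"`.
#' @param alpha_levels Significance tiers for the star annotation.
#' @return A `comparison_result` list: `test`, `statistic` (U for group a),
#'   `p_value`, `n_per_group`, `group_medians`, `significance_tier`,
#'   `exact` flag.
#' @export
mann_whitney <- function(a, b,
                         alternative = c("two_sided", "greater", "less"),
                         alpha_levels = c(0.05, 0.01, 0.001, 0.0001)) {
  alternative <- match.arg(alternative)
  a <- as.numeric(a); b <- as.numeric(b)
  if (!length(a) || !length(b))
    stop("input error: each group needs at least one value")
  ties <- anyDuplicated(c(a, b)) > 0L
  exact <- (length(a) + length(b) <= 20L) && !ties
  wt <- suppressWarnings(stats::wilcox.test(
    a, b,
    alternative = switch(alternative, two_sided = "two.sided",
                         greater = "greater", less = "less"),
    exact = exact, correct = TRUE))
  res <- list(
    test = "mann_whitney",
    statistic = unname(wt$statistic),     # U for group a
    p_value = wt$p.value,
    n_per_group = c(a = length(a), b = length(b)),
    group_medians = c(a = stats::median(a), b = stats::median(b)),
    significance_tier = significance_tier(wt$p.value, alpha_levels),
    exact = exact,
    posthoc = NULL)
  class(res) <- "comparison_result"
  res
}

#' Kruskal-Wallis test with Dunn's post-hoc comparisons
#'
#' The k-group (k >= 3) nonparametric analysis used for multi-arm designs
#' such as genotype x treatment: a tie-corrected Kruskal-Wallis H test
#' followed by Dunn's pairwise z tests on mean ranks, with the selected
#' multiplicity adjustment (Holm by default: it controls the family-wise
#' error rate and is uniformly more powerful than Bonferroni).
#'
#' @param groups Named list mapping group label to numeric values (>= 3
#'   groups, >= 2 values each).
#' @param adjust `"holm"`, `"bonferroni"` or `"none"`.
#' @param alpha_levels Significance tiers for star annotations.
#' @return A `comparison_result` with `test = "kruskal_wallis"`,
#'   `statistic` (H), `p_value`, `group_medians`, and `posthoc`: a data
#'   frame of pairwise Dunn results (`pair`, `z`, `p_raw`, `p_adj`,
#'   `significance_tier`).
#' @export
kruskal_dunn <- function(groups, adjust = c("holm", "bonferroni", "none"),
                         alpha_levels = c(0.05, 0.01, 0.001, 0.0001)) {
  adjust <- match.arg(adjust)
  if (!is.list(groups) || is.null(names(groups)) || any(names(groups) == ""))
    stop("groups must be a named list of numeric vectors")
  if (length(groups) < 3L)
    stop("fewer than 3 groups: use mann_whitney() for a two-group design")
  if (any(vapply(groups, length, 1L) < 2L))
    stop("each group needs at least 2 values")
  kw <- stats::kruskal.test(groups)
  x <- unlist(groups, use.names = FALSE)
  g <- rep(names(groups), vapply(groups, length, 1L))
  n <- length(x)
  rk <- rank(x)
  mean_rank <- tapply(rk, g, mean)
  n_i <- tapply(rk, g, length)
  tie_tab <- table(rk)
  tie_term <- sum(tie_tab^3 - tie_tab) / (12 * (n - 1))
  labs <- names(groups)
  pairs <- utils::combn(labs, 2)
  z <- apply(pairs, 2, function(p) {
    se <- sqrt((n * (n + 1) / 12 - tie_term) *
                 (1 / n_i[[p[1]]] + 1 / n_i[[p[2]]]))
    (mean_rank[[p[1]]] - mean_rank[[p[2]]]) / se
  })
  p_raw <- 2 * stats::pnorm(-abs(z))
  p_adj <- stats::p.adjust(p_raw, method = adjust)
  posthoc <- data.frame(
    pair = paste(pairs[1, ], pairs[2, ], sep = " vs "),
    z = z, p_raw = p_raw, p_adj = p_adj,
    significance_tier = vapply(p_adj, significance_tier, "",
                               alpha_levels = alpha_levels))
  res <- list(
    test = "kruskal_wallis",
    statistic = unname(kw$statistic),
    p_value = kw$p.value,
    n_per_group = vapply(groups, length, 1L),
    group_medians = vapply(groups, stats::median, 1),
    significance_tier = significance_tier(kw$p.value, alpha_levels),
    exact = FALSE,
    posthoc = posthoc)
  class(res) <- "comparison_result"
  res
}

#' Map a p-value to a significance tier
#'
#' Stars follow the conventional tiers: `*` p <= 0.05, `**` p <= 0.01,
#' `***` p <= 0.001, `****` p <= 0.0001, otherwise `ns`.
#'
#' @param p A p-value.
#' @param alpha_levels Descending tier thresholds.
#' @return One of `"ns"`, `"*"`, `"**"`, `"***"`, `"****"`.
#' @export
significance_tier <- function(p, alpha_levels = c(0.05, 0.01, 0.001, 0.0001)) {
  k <- sum(p <= alpha_levels)
  if (k == 0) "ns" else paste(rep("*", k), collapse = "")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("<comparison_result> %s: statistic = %.4g, p = %.4g (%s)\n",
              x$test, x$statistic, x$p_value, x$significance_tier))
  cat("  n per group:", paste(sprintf("%s=%d", names(x$n_per_group),
                                      x$n_per_group), collapse = ", "), "\n")
  cat("  medians:", paste(sprintf("%s=%.4g", names(x$group_medians),
                                  x$group_medians), collapse = ", "), "\n")
  if (!is.null(x$posthoc)) {
    cat("  Dunn post-hoc:\n")
    print(format(x$posthoc, digits = 4))
  }
  invisible(x)
}

#' Violin summary of a metric's distribution
#'
#' The numbers behind a violin plot: median, mean, quartiles, and a kernel
#' density point set normalized to unit area. A single value yields a
#' degenerate summary with a zero-width density flag instead of a density
#' estimate.
#'
#' @param values Numeric vector (>= 1 value).
#' @param n_density Number of density evaluation points.
#' @return List with `n`, `median`, `mean`, `q1`, `q3`, `density` (data
#'   frame `x`, `y` or `NULL`), `degenerate` flag.
#' @export
violin_summary <- function(values, n_density = 256L) {
  values <- as.numeric(values)
  if (!length(values)) stop("input error: no values to summarize")
  degenerate <- length(values) < 2L || stats::sd(values) == 0
  dens <- NULL
  if (!degenerate) {
    d <- stats::density(values, n = n_density)
    area <- sum(diff(d$x) * (d$y[-1] + d$y[-length(d$y)]) / 2)
    dens <- data.frame(x = d$x, y = d$y / area)
  }
  q <- unname(stats::quantile(values, c(0.25, 0.5, 0.75)))
  list(n = length(values), median = q[2], mean = mean(values),
       q1 = q[1], q3 = q[3], density = dens, degenerate = degenerate)
}

#' Export a comparison result as JSON (and post-hoc table as TSV)
#'
#' @param cr A `comparison_result`.
#' @param path JSON output path.
#' @param posthoc_path Optional TSV path for the Dunn table.
#' @return `path`, invisibly.
#' @export
write_comparison_result <- function(cr, path, posthoc_path = NULL) {
  jsonlite::write_json(
    list(test = cr$test, statistic = cr$statistic, p_value = cr$p_value,
         n_per_group = as.list(cr$n_per_group),
         group_medians = as.list(cr$group_medians),
         significance_tier = cr$significance_tier,
         exact = cr$exact,
         posthoc = cr$posthoc),
    path, auto_unbox = TRUE, digits = NA, null = "null")
  if (!is.null(posthoc_path) && !is.null(cr$posthoc))
    utils::write.table(cr$posthoc, posthoc_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  invisible(path)
}
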