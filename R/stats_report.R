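# Nonparametric group comparison of the cytometry and IF read-outs.
# Distributions of S_C%, AAR and fluorescence intensity are skewed and
# bounded, so groups are compared with the Mann-Whitney (Wilcoxon
# rank-sum) test rather than t-tests.

#' Mann-Whitney (Wilcoxon rank-sum) comparison of two samples
#'
#' Two-sided by default. The exact null distribution of U is used when
#' the combined sample size is at most 20 and there are no ties;
#' otherwise a mid-rank normal approximation with tie and continuity
#' correction is used, and the `method` field records which path was
#' taken. Missing values (e.g. undefined AARs of nuclei without
#' condensed chromatin) are dropped with a logged count.
#'
#' @param x,y Numeric samples.
#' @param alpha Significance level, default 0.05.
#' @param alternative `"two.sided"` (default), `"less"` or `"greater"`.
#' @param group_a,group_b Labels carried into the result.
#' @return A `group_comparison` list: `group_a`, `group_b`, `n_a`,
#'   `n_b`, `n_dropped_a`, `n_dropped_b`, `statistic_U` (U of `x`),
#'   `p_value`, `method` (`"exact"` or `"normal_approx"`), `alpha`,
#'   `significant` (`p_value < alpha`).
#' @export
#' @examples
#' mann_whitney(c(1, 2), c(3, 4))  # U = 0, exact two-sided p = 1/3
mann_whitney <- function(x, y, alpha = 0.05,
                         alternative = c("two.sided", "less", "greater"),
                         group_a = "a", group_b = "b") {
  alternative <- match.arg(alternative)
  drop_a <- sum(is.na(x)); drop_b <- sum(is.na(y))
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (drop_a + drop_b > 0) {
    message("mann_whitney: dropped ", drop_a, " missing value(s) from ",
            group_a, " and ", drop_b, " from ", group_b)
  }
  if (!length(x) || !length(y)) stop("empty sample after dropping missing values")
  n_a <- length(x); n_b <- length(y)
  ties <- anyDuplicated(c(x, y)) > 0L
  exact <- (n_a + n_b) <= 20L && !ties
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = alternative,
                       exact = exact, correct = !exact)
  )
  p <- min(1, wt$p.value)
  structure(list(
    group_a = group_a, group_b = group_b,
    n_a = n_a, n_b = n_b,
    n_dropped_a = drop_a, n_dropped_b = drop_b,
    statistic_U = unname(wt$statistic),
    p_value = p,
    method = if (exact) "exact" else "normal_approx",
    alpha = alpha,
    significant = p < alpha
  ), class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> %s (n=%d) vs %s (n=%d): U = %g, p = %.4g (%s)%s\n",
              x$group_a, x$n_a, x$group_b, x$n_b, x$statistic_U, x$p_value,
              x$method, if (x$significant) " *" else ""))
  invisible(x)
}

#' @export
as.data.frame.group_comparison <- function(x, ...) {
  data.frame(group_a = x$group_a, group_b = x$group_b,
             n_a = x$n_a, n_b = x$n_b,
             statistic_U = x$statistic_U, p_value = x$p_value,
             method = x$method, alpha = x$alpha,
             significant = x$significant, stringsAsFactors = FALSE)
}

#' Compare measurement groups pairwise
#'
#' Runs [mann_whitney()] on a value column of a measurement table for
#' each requested pair of groups, and reports the descriptive
#' statistics usually drawn next to such comparisons (per-group median
#' and standard deviation). Undefined values are excluded pairwise with
#' logged counts.
#'
#' @param measurements Data.frame with a group column and the value
#'   column (e.g. output of [batch_measure()] or [if_measure_batch()]).
#' @param value_column Column to compare, e.g. `"Sc_percent"`, `"AAR"`
#'   or `"mean_intensity"`.
#' @param pairs List of length-2 character vectors (or `"a:b"`
#'   strings) naming the groups to compare. An empty list yields an
#'   empty table.
#' @param group_column Name of the group column, default `"group"`.
#' @param alpha Significance level.
#' @param alternative Passed to [mann_whitney()].
#' @param bonferroni Apply a Bonferroni correction across the requested
#'   pairs (off by default, matching per-comparison reporting).
#' @return Data.frame with one row per pair: labels, sample sizes,
#'   medians, SDs, U, p-value, method, significance.
#' @export
compare_conditions <- function(measurements, value_column, pairs,
                               group_column = "group", alpha = 0.05,
                               alternative = "two.sided",
                               bonferroni = FALSE) {
  if (!value_column %in% names(measurements)) {
    stop("unknown value column: ", value_column)
  }
  cols <- c("group_a", "group_b", "value", "n_a", "n_b",
            "median_a", "median_b", "sd_a", "sd_b",
            "statistic_U", "p_value", "method", "significant")
  if (!length(pairs)) {
    out <- as.data.frame(setNames(rep(list(logical(0)), length(cols)), cols))
    return(out)
  }
  groups <- measurements[[group_column]]
  rows <- lapply(pairs, function(pr) {
    if (is.character(pr) && length(pr) == 1L) pr <- strsplit(pr, ":", fixed = TRUE)[[1L]]
    if (length(pr) != 2L) stop("each pair must name exactly two groups")
    for (g in pr) {
      if (!g %in% groups) stop("unknown group label: ", g)
    }
    xa <- measurements[[value_column]][groups == pr[1L]]
    xb <- measurements[[value_column]][groups == pr[2L]]
    if (sum(!is.na(xa)) < 3L || sum(!is.na(xb)) < 3L) {
      stop("group ", pr[which.min(c(sum(!is.na(xa)), sum(!is.na(xb))))],
           " has fewer than 3 usable values for ", value_column)
    }
    cmp <- mann_whitney(xa, xb, alpha = alpha, alternative = alternative,
                        group_a = pr[1L], group_b = pr[2L])
    data.frame(group_a = pr[1L], group_b = pr[2L], value = value_column,
               n_a = cmp$n_a, n_b = cmp$n_b,
               median_a = stats::median(xa, na.rm = TRUE),
               median_b = stats::median(xb, na.rm = TRUE),
               sd_a = stats::sd(xa, na.rm = TRUE),
               sd_b = stats::sd(xb, na.rm = TRUE),
               statistic_U = cmp$statistic_U, p_value = cmp$p_value,
               method = cmp$method, significant = cmp$significant,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (bonferroni) {
    out$p_value <- pmin(1, out$p_value * nrow(out))
    out$significant <- out$p_value < alpha
  }
  rownames(out) <- NULL
  out
}
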