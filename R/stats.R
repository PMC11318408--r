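#' Wilcoxon signed-rank test with an exact small-sample null
#'
#' Paired nonparametric test on a vector of within-slice differences. Zero
#' differences are dropped (Wilcoxon's convention) and tied absolute
#' differences receive average ranks. For `n <= exact_limit` (default 25)
#' the two-sided p-value is exact, computed from the full null distribution
#' of the positive-rank sum over all `2^n` sign assignments (evaluated by
#' convolution over the rank multiset, which is algebraically identical to
#' enumeration); above that a normal approximation with tie-corrected
#' variance and continuity correction is used. The two-sided p doubles the
#' smaller inclusive tail, capped at 1.
#'
#' @param differences Numeric vector of paired differences.
#' @param method `"auto"` (exact up to `exact_limit`), `"exact"`, or
#'   `"normal"`.
#' @param exact_limit Largest n for which the exact null is used under
#'   `"auto"`.
#' @return A `wilcoxon_result`: `statistic` (W, the positive-rank sum),
#'   `p_value`, `method` (`"exact"` or `"normal-approximation"`), `n_used`
#'   (non-zero differences), `n_zeros`.
#' @examples
#' wilcoxon_signed_rank(c(1.2, 0.8, 2.1, 0.4, 1.7))$p_value  # 0.0625
#' @export
wilcoxon_signed_rank <- function(differences,
                                 method = c("auto", "exact", "normal"),
                                 exact_limit = 25L) {
  method <- match.arg(method)
  if (!is.numeric(differences) || length(differences) == 0L ||
      anyNA(differences)) {
    stop("`differences` must be a non-empty numeric vector without NAs",
         call. = FALSE)
  }
  n_zeros <- sum(differences == 0)
  d <- differences[differences != 0]
  n <- length(d)
  if (n == 0L) {
    stop("all differences are zero: the signed-rank statistic is degenerate",
         call. = FALSE)
  }
  r <- rank(abs(d))
  w <- sum(r[d > 0])
  use_exact <- method == "exact" || (method == "auto" && n <= exact_limit)

  if (use_exact) {
    # null distribution of W by convolution; ranks doubled so average ranks
    # (multiples of 1/2) become integers
    r2 <- as.integer(round(2 * r))
    total <- sum(r2)
    f <- numeric(total + 1L)
    f[1] <- 1
    for (rr in r2) {
      shifted <- c(numeric(rr), f[seq_len(total + 1L - rr)])
      f <- f + shifted
    }
    f <- f / sum(f)
    w2 <- as.integer(round(2 * w))
    lower <- sum(f[seq_len(w2 + 1L)])          # P(W <= w)
    upper <- sum(f[seq.int(w2 + 1L, total + 1L)])  # P(W >= w)
    p <- min(1, 2 * min(lower, upper))
    meth <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    cc <- sign(w - mu) * 0.5
    z <- (w - mu - cc) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    meth <- "normal-approximation"
  }
  structure(list(statistic = w, p_value = p, method = meth,
                 n_used = n, n_zeros = n_zeros),
            class = "wilcoxon_result")
}

#' @export
print.wilcoxon_result <- function(x, ...) {
  cat("Wilcoxon signed-rank: W = ", format(x$statistic), ", p = ",
      format(signif(x$p_value, 4)), " (", x$method, ", n = ", x$n_used,
      if (x$n_zeros > 0) paste0(", ", x$n_zeros, " zeros dropped"),
      ")\n", sep = "")
  invisible(x)
}

#' Bonferroni adjustment for a fixed number of planned comparisons
#'
#' `min(1, m * p)`. The multiplier is the number of planned comparisons of
#' the design (e.g. `m = 2` when two treatment levels are each compared with
#' control but not with each other), which need not equal the length of `p`.
#'
#' @param p Raw p-value(s) in `[0, 1]`.
#' @param m Number of comparisons (>= 1).
#' @return Adjusted p-value(s).
#' @examples
#' bonferroni_adjust(0.01, m = 2)  # 0.02
#' @export
bonferroni_adjust <- function(p, m) {
  if (!is.numeric(p) || any(is.na(p)) || any(p < 0 | p > 1)) {
    stop("`p` must be probabilities in [0, 1]", call. = FALSE)
  }
  if (!is.numeric(m) || length(m) != 1L || m < 1) {
    stop("`m` must be a single number >= 1", call. = FALSE)
  }
  pmin(1, m * p)
}

#' Median and interquartile summary
#'
#' Median with 25th and 75th percentiles, quantiles by linear interpolation
#' between order statistics ([stats::quantile()] type 7); the convention is
#' reported in the output so summaries are reproducible across software.
#'
#' @param values Non-empty numeric vector.
#' @return List with `median`, `q25`, `q75`, `n` and `quantile_type`.
#' @examples
#' summarize_median_iqr(c(1, 2, 3, 4))
#' @export
summarize_median_iqr <- function(values) {
  if (!is.numeric(values) || length(values) == 0L || anyNA(values)) {
    stop("`values` must be a non-empty numeric vector without NAs",
         call. = FALSE)
  }
  q <- stats::quantile(values, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  list(median = q[2], q25 = q[1], q75 = q[3], n = length(values),
       quantile_type = 7L)
}

#' Paired comparison of one feature between two conditions
#'
#' Convenience wrapper producing the machine-readable analogue of a Results
#' sentence: condition medians (25th, 75th percentile), the signed-rank
#' statistic on the within-slice differences, and raw and
#' Bonferroni-adjusted p-values.
#'
#' @param control,treated Paired numeric vectors (same slices, same order).
#' @param labels Character vector of length 2 naming the conditions.
#' @param m_comparisons Bonferroni multiplier (see [bonferroni_adjust()]).
#' @param ... Passed to [wilcoxon_signed_rank()].
#' @return A `paired_comparison` object; `as.data.frame()` yields one table
#'   row.
#' @export
paired_comparison <- function(control, treated,
                              labels = c("control", "treated"),
                              m_comparisons = 1, ...) {
  if (length(control) != length(treated)) {
    stop("`control` and `treated` must be paired (equal length)",
         call. = FALSE)
  }
  wt <- wilcoxon_signed_rank(treated - control, ...)
  structure(list(labels = labels,
                 summary_control = summarize_median_iqr(control),
                 summary_treated = summarize_median_iqr(treated),
                 statistic = wt$statistic, p_raw = wt$p_value,
                 p_adjusted = bonferroni_adjust(wt$p_value, m_comparisons),
                 method = wt$method, m_comparisons = m_comparisons,
                 n = length(control)),
            class = "paired_comparison")
}

#' @export
print.paired_comparison <- function(x, ...) {
  fmt <- function(s) paste0(format(signif(s$median, 4)), " (",
                            format(signif(s$q25, 4)), ", ",
                            format(signif(s$q75, 4)), ")")
  cat("Paired comparison (n = ", x$n, "): ", x$labels[1], " ",
      fmt(x$summary_control), " vs ", x$labels[2], " ",
      fmt(x$summary_treated), "\n  W = ", format(x$statistic),
      ", p = ", format(signif(x$p_raw, 4)), ", adjusted p = ",
      format(signif(x$p_adjusted, 4)), " (", x$method, ", m = ",
      x$m_comparisons, ")\n", sep = "")
  invisible(x)
}

#' @export
as.data.frame.paired_comparison <- function(x, ...) {
  data.frame(control = x$labels[1], treated = x$labels[2], n = x$n,
             control_median = x$summary_control$median,
             control_q25 = x$summary_control$q25,
             control_q75 = x$summary_control$q75,
             treated_median = x$summary_treated$median,
             treated_q25 = x$summary_treated$q25,
             treated_q75 = x$summary_treated$q75,
             W = x$statistic, p_raw = x$p_raw, p_adjusted = x$p_adjusted,
             method = x$method, m_comparisons = x$m_comparisons)
}
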