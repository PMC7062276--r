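#' Descriptive box-plot summary of a diameter dataset
#'
#' Sample moments (n-1 SD), Tukey five-number quartiles (hinges, the
#' median-of-halves convention), whiskers at the most extreme observations
#' within 1.5 IQR of the hinges, and the observations outside those fences
#' flagged as outliers.
#'
#' @param dataset A [diameter_dataset()] (or any data frame with a
#'   `diameter_nm` column) with at least 2 records.
#' @return Object of class `"technique_summary"`: list with `technique`,
#'   `n`, `mean_nm`, `sd_nm`, `median_nm`, `q1_nm`, `q3_nm`,
#'   `whisker_low_nm`, `whisker_high_nm`, `outliers`.
#' @export
summarize_diameters <- function(dataset) {
  x <- dataset$diameter_nm
  if (is.null(x)) stop("`dataset` must have a `diameter_nm` column")
  if (length(x) < 2L) stop("insufficient data: need at least 2 records")
  fn <- stats::fivenum(x)  # min, lower hinge, median, upper hinge, max
  q1 <- fn[2]; q3 <- fn[4]
  iqr <- q3 - q1
  lo_fence <- q1 - 1.5 * iqr
  hi_fence <- q3 + 1.5 * iqr
  inside <- x >= lo_fence & x <= hi_fence
  structure(
    list(technique = if (!is.null(dataset$technique))
           as.character(dataset$technique[1]) else NA_character_,
         n = length(x), mean_nm = mean(x), sd_nm = stats::sd(x),
         median_nm = fn[3], q1_nm = q1, q3_nm = q3,
         whisker_low_nm = min(x[inside]), whisker_high_nm = max(x[inside]),
         outliers = sort(x[!inside])),
    class = "technique_summary"
  )
}

#' @export
summary.diameter_dataset <- function(object, ...) summarize_diameters(object)

#' @export
print.technique_summary <- function(x, ...) {
  cat(sprintf("%s: n = %d, %.1f +/- %.1f nm\n",
              x$technique, x$n, x$mean_nm, x$sd_nm))
  cat(sprintf("  median %.1f [Q1 %.1f, Q3 %.1f], whiskers [%.1f, %.1f], %d outlier(s)\n",
              x$median_nm, x$q1_nm, x$q3_nm, x$whisker_low_nm,
              x$whisker_high_nm, length(x$outliers)))
  invisible(x)
}

#' Percent change of a value relative to a baseline
#'
#' `100 * (value - baseline) / baseline`. No rounding is applied here;
#' integer rounding belongs to the reporting layer.
#'
#' @param value,baseline Diameters (nm); `baseline` must be positive.
#'   Vectorised.
#' @return Percent change.
#' @examples
#' percent_change(124, 102)  # 21.57, reported as +22%
#' @export
percent_change <- function(value, baseline) {
  if (any(baseline <= 0)) stop("`baseline` must be positive")
  100 * (value - baseline) / baseline
}

#' One-way fixed-effects ANOVA across technique datasets
#'
#' Classical single-factor ANOVA (equal-variance F test) over two or more
#' diameter datasets, via [stats::oneway.test()] with `var.equal = TRUE`.
#'
#' @param datasets List of [diameter_dataset()]s (>= 2, each n >= 2).
#' @return Object of class `"anova_result"`: `f_stat`, `df_between`,
#'   `df_within`, `p_value`, `degenerate` (TRUE when all groups are constant
#'   with equal means, in which case p = 1 by convention).
#' @export
anova_oneway <- function(datasets) {
  if (!is.list(datasets) || length(datasets) < 2L) {
    stop("need at least 2 datasets")
  }
  if (any(vapply(datasets, nrow, integer(1)) < 2L)) {
    stop("each dataset needs at least 2 records")
  }
  x <- unlist(lapply(datasets, `[[`, "diameter_nm"))
  g <- factor(rep(seq_along(datasets),
                  vapply(datasets, nrow, integer(1))))
  k <- nlevels(g)
  n <- length(x)
  within_var <- vapply(split(x, g), stats::var, numeric(1))
  means <- vapply(split(x, g), mean, numeric(1))
  if (all(within_var == 0) && all(abs(means - means[1]) < 1e-12)) {
    return(structure(list(f_stat = 0, df_between = k - 1L,
                          df_within = n - k, p_value = 1,
                          degenerate = TRUE),
                     class = "anova_result"))
  }
  ft <- stats::oneway.test(x ~ g, var.equal = TRUE)
  structure(list(f_stat = unname(ft$statistic),
                 df_between = unname(ft$parameter[1]),
                 df_within = unname(ft$parameter[2]),
                 p_value = unname(ft$p.value),
                 degenerate = FALSE),
            class = "anova_result")
}

#' @export
print.anova_result <- function(x, ...) {
  cat(sprintf("One-way ANOVA: F(%g, %g) = %.3f, p = %.3g%s\n",
              x$df_between, x$df_within, x$f_stat, x$p_value,
              if (x$degenerate) " (degenerate: constant equal groups)" else ""))
  invisible(x)
}

## Welch / pooled two-sample t from summary statistics; the moment route is
## needed because published tables give only (n, mean, SD).
.t_from_moments <- function(n1, m1, s1, n2, m2, s2, variant) {
  if (variant == "welch") {
    se2 <- s1^2 / n1 + s2^2 / n2
    if (se2 == 0) return(list(t = 0, df = n1 + n2 - 2, p = 1,
                              degenerate = TRUE))
    t <- (m1 - m2) / sqrt(se2)
    df <- se2^2 / ((s1^2 / n1)^2 / (n1 - 1) + (s2^2 / n2)^2 / (n2 - 1))
  } else {
    sp2 <- ((n1 - 1) * s1^2 + (n2 - 1) * s2^2) / (n1 + n2 - 2)
    if (sp2 == 0) return(list(t = 0, df = n1 + n2 - 2, p = 1,
                              degenerate = TRUE))
    t <- (m1 - m2) / sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  }
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df), degenerate = FALSE)
}

#' Two-tailed two-sample t test between technique datasets
#'
#' Welch (default) or pooled-variance two-sample t test, two-sided. Accepts
#' either raw datasets or summary statistics (so published group moments can
#' be tested without raw data). The raw-data route delegates to
#' [stats::t.test()]; both routes agree. When both groups are constant with
#' equal means, t = 0 and p = 1 by convention with `degenerate = TRUE`.
#'
#' @param a,b [diameter_dataset()]s, or lists/named vectors with elements
#'   `n`, `mean_nm`, `sd_nm` (a [summarize_diameters()] result works).
#' @param variant `"welch"` or `"pooled"`.
#' @return Object of class `"comparison_result"`: `pair`, `percent_change`
#'   (of `a`'s mean relative to `b`'s mean as baseline), `t_stat`, `df`,
#'   `p_value`, `variant`, `degenerate`.
#' @examples
#' ttest_two_tailed(list(n = 300, mean_nm = 102, sd_nm = 17),
#'                  list(n = 300, mean_nm = 99, sd_nm = 32))
#' @export
ttest_two_tailed <- function(a, b, variant = c("welch", "pooled")) {
  variant <- match.arg(variant)
  as_summ <- function(d) {
    if (is.data.frame(d)) {
      if (nrow(d) < 2L) stop("each dataset needs at least 2 records")
      list(n = nrow(d), mean_nm = mean(d$diameter_nm),
           sd_nm = stats::sd(d$diameter_nm),
           label = if (!is.null(d$technique)) as.character(d$technique[1])
                   else NA_character_,
           raw = d$diameter_nm)
    } else {
      d <- as.list(d)
      stopifnot(all(c("n", "mean_nm", "sd_nm") %in% names(d)))
      if (d$n < 2L) stop("each dataset needs at least 2 records")
      list(n = d$n, mean_nm = d$mean_nm, sd_nm = d$sd_nm,
           label = if (!is.null(d$technique)) d$technique else NA_character_,
           raw = NULL)
    }
  }
  sa <- as_summ(a); sb <- as_summ(b)
  res <- .t_from_moments(sa$n, sa$mean_nm, sa$sd_nm,
                         sb$n, sb$mean_nm, sb$sd_nm, variant)
  structure(
    list(pair = c(sa$label, sb$label),
         percent_change = percent_change(sa$mean_nm, sb$mean_nm),
         t_stat = res$t, df = res$df, p_value = res$p,
         variant = variant, degenerate = res$degenerate),
    class = "comparison_result"
  )
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("%s vs %s (%s): %+.1f%%, t(%.1f) = %.3f, p = %.3g%s\n",
              x$pair[1], x$pair[2], x$variant, x$percent_change, x$df,
              x$t_stat, x$p_value,
              if (x$degenerate) " (degenerate)" else ""))
  invisible(x)
}

#' Range of SD ratios of one technique against the others
#'
#' Returns the minimum and maximum of `target SD / other SD`; used to state
#' how much more variable one technique's apparent sizes are than every
#' alternative.
#'
#' @param target A `"technique_summary"` (or list with `sd_nm`).
#' @param others Non-empty list of the same.
#' @return Named numeric vector `c(min = ..., max = ...)`.
#' @examples
#' uts <- list(sd_nm = 32)
#' sd_ratio_range(uts, list(list(sd_nm = 17), list(sd_nm = 21)))
#' @export
sd_ratio_range <- function(target, others) {
  if (length(others) == 0L) stop("`others` must be non-empty")
  sds <- vapply(others, function(o) as.numeric(o[["sd_nm"]]), numeric(1))
  tsd <- as.numeric(target[["sd_nm"]])
  if (tsd <= 0 || any(sds <= 0)) stop("all SDs must be positive")
  r <- tsd / sds
  c(min = min(r), max = max(r))
}
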