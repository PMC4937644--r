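#' Paired method comparison container
#'
#' One row per subject (mCBF level) or per subject-by-segment observation
#' (rCBF level), with the two methods' values side by side.
#'
#' @param ids Observation identifiers.
#' @param value_pp,value_ibur Paired values from the two methods.
#' @param level `"mcbf"` or `"rcbf"`.
#' @return An object of class `method_comparison` (a data frame with a
#'   `level` attribute).
#' @export
method_comparison <- function(ids, value_pp, value_ibur,
                              level = c("mcbf", "rcbf")) {
  level <- match.arg(level)
  if (length(ids) != length(value_pp) || length(value_pp) != length(value_ibur))
    stop("ids and value vectors must have equal length")
  if (anyNA(value_pp) || anyNA(value_ibur))
    stop("missing values are not allowed in a method comparison")
  df <- data.frame(id = ids, value_pp = value_pp, value_ibur = value_ibur)
  structure(df, level = level, class = c("method_comparison", "data.frame"))
}

#' Build a cohort comparison from regional CBF results
#'
#' @param pp_results,ibur_results Lists of [regional_cbf()] objects, one per
#'   subject, in matching order.
#' @param level `"mcbf"` (one pair per subject) or `"rcbf"` (one pair per
#'   subject x segment).
#' @return A [method_comparison()].
#' @export
compare_cohort <- function(pp_results, ibur_results,
                           level = c("mcbf", "rcbf")) {
  level <- match.arg(level)
  if (length(pp_results) != length(ibur_results))
    stop("result lists must have equal length")
  if (level == "mcbf") {
    method_comparison(seq_along(pp_results),
                      vapply(pp_results, `[[`, numeric(1), "mcbf"),
                      vapply(ibur_results, `[[`, numeric(1), "mcbf"),
                      level = "mcbf")
  } else {
    ids <- unlist(lapply(seq_along(pp_results), function(i)
      paste0("s", i, ":", names(pp_results[[i]]$per_segment))))
    ibur_aligned <- unlist(lapply(seq_along(pp_results), function(i)
      ibur_results[[i]]$per_segment[names(pp_results[[i]]$per_segment)]))
    method_comparison(
      ids,
      unlist(lapply(pp_results, `[[`, "per_segment")),
      ibur_aligned,
      level = "rcbf")
  }
}

#' Linear regression with Pearson correlation
#'
#' OLS slope and intercept of `y` on `x`, the Pearson correlation, and the
#' two-sided p-value for the correlation under the t distribution with
#' `n - 2` degrees of freedom. A constant `y` is reported as slope 0, r 0.
#'
#' @param x_values,y_values Paired numeric vectors, n >= 3; `x` must vary.
#' @return A list: `slope`, `intercept`, `pearson_r`, `p_value`, `n`.
#' @export
linear_fit <- function(x_values, y_values) {
  n <- length(x_values)
  if (n != length(y_values)) stop("x and y must have equal length")
  if (n < 3) stop("need at least 3 observations")
  if (var(x_values) == 0) stop("degenerate x: zero variance")
  fit <- lm(y_values ~ x_values)
  r <- if (var(y_values) == 0) 0 else cor(x_values, y_values)
  p <- if (abs(r) >= 1) 0 else {
    tt <- r * sqrt((n - 2) / (1 - r^2))
    2 * pt(-abs(tt), df = n - 2)
  }
  if (var(y_values) == 0) p <- 1
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       pearson_r = r, p_value = p, n = n)
}

#' Paired two-tailed test between methods
#'
#' Either the paired t test or the Wilcoxon signed-rank test. Degenerate
#' inputs are handled explicitly: identical pairs give p = 1 with a warning;
#' a constant nonzero difference makes the t statistic unbounded (p reported
#' as 0 with a warning).
#'
#' @param values_a,values_b Paired numeric vectors of equal length, n >= 3.
#' @param kind `"wilcoxon"` (default) or `"t"`.
#' @return Two-sided p-value.
#' @export
paired_test <- function(values_a, values_b, kind = c("wilcoxon", "t")) {
  kind <- match.arg(kind)
  if (length(values_a) != length(values_b))
    stop("paired vectors must have equal length")
  if (length(values_a) < 3) stop("need at least 3 pairs")
  d <- values_b - values_a
  if (all(d == 0)) {
    warning("all paired differences are zero; p = 1")
    return(1)
  }
  if (kind == "t") {
    if (sd(d) == 0) {
      warning("constant nonzero paired difference; t statistic unbounded, p = 0")
      return(0)
    }
    t.test(values_b, values_a, paired = TRUE)$p.value
  } else {
    suppressWarnings(
      wilcox.test(values_b, values_a, paired = TRUE, exact = FALSE)$p.value)
  }
}

#' Summary table comparing the two methods
#'
#' Per-method n, mean, SD, variance (n - 1 denominator), min, max, median,
#' 25th/75th percentiles (linear interpolation, quantile type 7), the PP/IBUR
#' ratios of min, max and variance, and paired two-tailed p-values from both
#' the Wilcoxon signed-rank and the paired t test.
#'
#' @param comparison A [method_comparison()].
#' @return An object of class `summary_table`: `stats` (data frame with rows
#'   PP and IBUR), `ratios`, `p_wilcoxon`, `p_t`, `p_two_tailed` (Wilcoxon).
#' @export
summarize_pair <- function(comparison) {
  if (!inherits(comparison, "method_comparison"))
    stop("`comparison` must be a method_comparison")
  if (nrow(comparison) == 0) stop("empty comparison")
  one <- function(v) {
    q <- quantile(v, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    data.frame(n = length(v), mean = mean(v), sd = sd(v), variance = var(v),
               min = min(v), max = max(v),
               median = q[2], p25 = q[1], p75 = q[3])
  }
  pp <- one(comparison$value_pp)
  ib <- one(comparison$value_ibur)
  stats <- rbind(PP = pp, IBUR = ib)
  ratios <- c(min_ratio = pp$min / ib$min,
              max_ratio = pp$max / ib$max,
              variance_ratio = pp$variance / ib$variance)
  p_w <- suppressWarnings(
    paired_test(comparison$value_ibur, comparison$value_pp, "wilcoxon"))
  p_t <- suppressWarnings(
    paired_test(comparison$value_ibur, comparison$value_pp, "t"))
  structure(list(stats = stats, ratios = ratios,
                 p_wilcoxon = p_w, p_t = p_t, p_two_tailed = p_w,
                 level = attr(comparison, "level")),
            class = "summary_table")
}

#' @export
print.summary_table <- function(x, ...) {
  cat(sprintf("Method comparison (%s level)\n", x$level))
  print(round(x$stats, 2))
  cat(sprintf("PP/IBUR ratios: min %.2f, max %.2f, variance %.2f\n",
              x$ratios["min_ratio"], x$ratios["max_ratio"],
              x$ratios["variance_ratio"]))
  cat(sprintf("Two-tailed p: Wilcoxon %.3g, paired t %.3g\n",
              x$p_wilcoxon, x$p_t))
  invisible(x)
}
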