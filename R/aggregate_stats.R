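# Superplot-style nested aggregation (cells -> experiment means ->
# across-experiment mean with 95% CI) and Holm-Sidak multiple-comparison
# adjustment.

#' Nested (superplot) summary of per-cell values grouped by experiment
#'
#' Each experiment contributes one point — the unweighted mean of its cell
#' values — and the grand mean and t-based 95 percent confidence interval
#' are computed across experiment means ("mean of three experiments,
#' +/- 95 percent C.I."). With a single experiment the CI is undefined and
#' flagged \code{NA}. Set \code{pooled = TRUE} to instead pool all values,
#' ignoring experiment structure (the per-macropinosome convention some
#' quantities use).
#'
#' @param values Numeric vector of per-cell values.
#' @param experiment Vector of experiment identifiers, parallel to
#'   \code{values}.
#' @param metric_name Name stored with the summary.
#' @param pooled Pool all values instead of nesting by experiment.
#' @return Object of class \code{nested_summary}: \code{metric_name,
#'   experiment_means, grand_mean, ci_half_width_95, n_experiments}.
#' @export
nested_summary <- function(values, experiment, metric_name = "metric",
                           pooled = FALSE) {
  if (!length(values)) stop("no values to summarize", call. = FALSE)
  if (length(values) != length(experiment))
    stop("values and experiment lengths differ", call. = FALSE)
  if (any(!is.finite(values)))
    stop("values must be finite", call. = FALSE)
  g <- as.character(experiment)
  if (any(!nzchar(g)) || any(is.na(g)))
    stop("empty experiment identifier", call. = FALSE)
  if (pooled) {
    em <- values
  } else {
    em <- as.numeric(tapply(values, g, mean))
  }
  n <- length(em)
  gm <- mean(em)
  ci <- if (n >= 2) stats::qt(0.975, n - 1) * stats::sd(em) / sqrt(n)
        else NA_real_
  structure(list(metric_name = metric_name, experiment_means = em,
                 grand_mean = gm, ci_half_width_95 = ci,
                 n_experiments = n),
            class = "nested_summary")
}

#' @export
print.nested_summary <- function(x, ...) {
  cat(sprintf("<nested_summary> %s: %.4g +/- %.4g (95%% CI, n = %d)\n",
              x$metric_name, x$grand_mean,
              if (is.na(x$ci_half_width_95)) NA else x$ci_half_width_95,
              x$n_experiments))
  invisible(x)
}

#' Holm-Sidak step-down multiple-comparison adjustment
#'
#' Sorts the m p-values ascending and sets
#' \code{adjusted_(i) = max_(j <= i) (1 - (1 - p_(j))^(m - j + 1))},
#' clamped at 1, then restores the original order. Rejections are
#' \code{adjusted < alpha}.
#'
#' @param p Numeric vector of p-values in [0, 1].
#' @param alpha Significance level (default 0.05).
#' @return List with \code{adjusted} (same order as \code{p}) and
#'   \code{reject} (logical).
#' @export
holm_sidak <- function(p, alpha = 0.05) {
  if (!length(p)) return(list(adjusted = numeric(), reject = logical()))
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  step <- 1 - (1 - ps)^(m - seq_len(m) + 1)
  adj_sorted <- pmin(cummax(step), 1)
  adjusted <- numeric(m)
  adjusted[o] <- adj_sorted
  list(adjusted = adjusted, reject = adjusted < alpha)
}

#' Two-group Welch t-test on experiment means
#'
#' Convenience wrapper: nests each group by experiment (one mean per
#' experiment) and applies \code{stats::t.test} across experiment means.
#'
#' @param values1,values2 Per-cell values of the two groups.
#' @param experiment1,experiment2 Experiment identifiers per group.
#' @return The \code{htest} object from \code{stats::t.test}.
#' @export
nested_t_test <- function(values1, experiment1, values2, experiment2) {
  e1 <- as.numeric(tapply(values1, as.character(experiment1), mean))
  e2 <- as.numeric(tapply(values2, as.character(experiment2), mean))
  stats::t.test(e1, e2)
}
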