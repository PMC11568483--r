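# Evaluation metrics for the Monte Carlo comparison: boxplot-rule outlier
# percentage, per-condition summaries (median/IQR of bias and relative
# bias, outlier rate, and the study's RMSE: the standard deviation of the
# absolute errors), Kruskal-Wallis tests and Dunn post-hoc comparisons.

#' Percentage of boxplot-rule outliers
#'
#' Values strictly outside `[Q1 - 1.5 IQR, Q3 + 1.5 IQR]`, quartiles by
#' linear interpolation (type 7).
#'
#' @param values Numeric vector (at least 4 values).
#' @return Percentage in 0..100.
#' @export
outlier_pct <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) < 4L) abort("Need at least 4 values to assess outliers.")
  q <- quantile(values, c(0.25, 0.75), names = FALSE, type = 7)
  iqr <- q[2] - q[1]
  100 * mean(values < q[1] - 1.5 * iqr | values > q[2] + 1.5 * iqr)
}

#' Summarize replication results per condition and method
#'
#' For each method in one condition: median and IQR of bias and relative
#' bias, percentage of boxplot-rule outliers of bias (identical for
#' relative bias when the true reliability is positive), the study RMSE
#' (standard deviation, divisor n - 1, of the absolute biases) and, for
#' reference, the conventional root-mean-square error.
#'
#' @param results A replication-result tibble from [run_study()].
#' @param condition Condition id to summarize (default: all present, one
#'   block per condition).
#' @return A tibble with one row per condition x method.
#' @export
summarize_condition <- function(results, condition = NULL) {
  if (!is.null(condition)) results <- dplyr::filter(results, .data$condition %in% !!condition)
  ok <- dplyr::filter(results, .data$status == "ok")
  failed <- dplyr::count(dplyr::filter(results, .data$status != "ok"),
                         .data$condition, .data$method, name = "n_failed")
  out <- ok |>
    dplyr::group_by(.data$condition, .data$method) |>
    dplyr::summarise(
      n_reps = dplyr::n(),
      median_bias = median(.data$bias),
      iqr_bias = quantile(.data$bias, 0.75, names = FALSE) -
        quantile(.data$bias, 0.25, names = FALSE),
      median_rel_bias = median(.data$rel_bias),
      iqr_rel_bias = quantile(.data$rel_bias, 0.75, names = FALSE) -
        quantile(.data$rel_bias, 0.25, names = FALSE),
      outlier_pct = outlier_pct(.data$bias),
      rmse = sd(abs(.data$bias)),
      rms_error = sqrt(mean(.data$bias^2)),
      .groups = "drop"
    ) |>
    dplyr::left_join(failed, by = c("condition", "method")) |>
    dplyr::mutate(n_failed = dplyr::coalesce(.data$n_failed, 0L))
  class(out) <- c("sirel_summary", class(out))
  out
}

#' Kruskal-Wallis test across method bias distributions
#'
#' Rank-based H statistic with tie correction, df = groups - 1, p-value
#' from the chi-square distribution.
#'
#' @param groups A named list of numeric vectors (one per method).
#' @return A list with `H`, `df` and `p`.
#' @export
kruskal_wallis <- function(groups) {
  if (length(groups) < 2L) abort("Need at least two groups.")
  if (any(lengths(groups) < 2L)) abort("Each group needs at least two values.")
  values <- unlist(groups, use.names = FALSE)
  if (length(unique(values)) == 1L) {
    return(list(H = 0, df = length(groups) - 1L, p = 1))
  }
  g <- factor(rep(seq_along(groups), lengths(groups)))
  kt <- kruskal.test(values, g)
  list(H = unname(kt$statistic), df = unname(kt$parameter), p = kt$p.value)
}

#' Dunn post-hoc pairwise comparisons after Kruskal-Wallis
#'
#' Pairwise z-tests on pooled mean ranks with tie correction; two-sided
#' p-values, Holm-adjusted across all pairs.
#'
#' @param groups A named list of numeric vectors.
#' @return A tibble with `group1`, `group2`, `z`, `p`, `p_adj`.
#' @export
posthoc_pairwise <- function(groups) {
  k <- length(groups)
  if (k < 2L) abort("Need at least two groups.")
  values <- unlist(groups, use.names = FALSE)
  g <- rep(seq_len(k), lengths(groups))
  N <- length(values)
  rk <- rank(values)
  mean_rank <- tapply(rk, g, mean)
  n_i <- lengths(groups)
  ties <- table(values)
  tie_corr <- sum(ties^3 - ties) / (12 * (N - 1))
  pairs <- utils::combn(k, 2)
  nm <- names(groups) %||% paste0("group", seq_len(k))
  res <- purrr::map_dfr(seq_len(ncol(pairs)), function(j) {
    i1 <- pairs[1, j]; i2 <- pairs[2, j]
    se <- sqrt((N * (N + 1) / 12 - tie_corr) * (1 / n_i[i1] + 1 / n_i[i2]))
    z <- if (se > 0) (mean_rank[i1] - mean_rank[i2]) / se else 0
    tibble::tibble(group1 = nm[i1], group2 = nm[i2], z = unname(z),
                   p = 2 * pnorm(-abs(z)))
  })
  res$p_adj <- p.adjust(res$p, method = "holm")
  res
}
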