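# Classical estimators of single-item reliability: correction for
# attenuation, factor-analysis communality, and Guttman's lambda-6 adapted
# to a single target item.

# CA, FA and lambda-6 are moment-based and accept any numeric item scores;
# only the categorical estimators (DMM, LCM) require integer 0..m scores.
split_single_multi <- function(data, single_col, m = 4L) {
  x <- as.matrix(data)
  if (!is.numeric(x) || nrow(x) < 2L) abort("Need a numeric score matrix with at least 2 rows.")
  if (is.null(colnames(x))) colnames(x) <- paste0("item_", seq_len(ncol(x)))
  si <- resolve_single_col(x, single_col)
  list(single = x[, si], multi = x[, -si, drop = FALSE], m = m)
}

#' Cronbach's alpha of a multi-item scale
#'
#' `alpha = L/(L-1) * (1 - sum(item variances) / var(total score))`, with
#' population (divisor n) variances.
#'
#' @param data Data frame or matrix of the scale's item scores.
#' @return The alpha coefficient.
#' @export
coefficient_alpha <- function(data) {
  x <- as.matrix(data)
  L <- ncol(x)
  if (L < 2L) abort("Alpha needs at least two items.")
  vt <- pop_var(rowSums(x))
  if (vt == 0) abort("Zero total-score variance.")
  L / (L - 1) * (1 - sum(apply(x, 2, pop_var)) / vt)
}

#' Guttman's lambda-2 of a multi-item scale
#'
#' An alternative internal-consistency coefficient usable in place of alpha
#' in the correction-for-attenuation estimator.
#'
#' @inheritParams coefficient_alpha
#' @return The lambda-2 coefficient.
#' @export
coefficient_lambda2 <- function(data) {
  x <- as.matrix(data)
  L <- ncol(x)
  if (L < 2L) abort("Lambda-2 needs at least two items.")
  C <- cov(x) * (nrow(x) - 1) / nrow(x)
  vt <- sum(C)
  off <- C; diag(off) <- 0
  (sum(off) + sqrt(L / (L - 1) * sum(off^2))) / vt
}

#' Correction-for-attenuation estimate of single-item reliability
#'
#' Assuming the single item and the multi-item scale measure the same
#' construct (true correlation 1), the attenuation formula
#' `rho_xy = r_xy / sqrt(r_xx r_yy)` solved for the single item's
#' reliability gives `r_yy = r_xy^2 / r_xx`, where `r_xy` is the Pearson
#' correlation of the single item with the scale's total (sum) score and
#' `r_xx` the scale's internal consistency.
#'
#' @param data Data frame of item scores (single item plus scale).
#' @param single_col Column of the single item (default last).
#' @param coefficient Internal-consistency coefficient for the scale:
#'   Cronbach's `"alpha"` (default) or Guttman's `"lambda2"`.
#' @param m Maximum score level.
#' @return A `sirel_estimate` with method `"CA"`.
#' @export
ca_reliability <- function(data, single_col = NULL, coefficient = c("alpha", "lambda2"),
                           m = 4L) {
  coefficient <- match.arg(coefficient)
  parts <- split_single_multi(data, single_col, m)
  if (pop_var(parts$single) == 0) abort("Degenerate single item: zero variance.")
  total <- rowSums(parts$multi)
  if (pop_var(total) == 0) abort("Zero total-score variance in the multi-item scale.")
  r_xy <- cor(parts$single, total)
  r_xx <- switch(coefficient,
                 alpha = coefficient_alpha(parts$multi),
                 lambda2 = coefficient_lambda2(parts$multi))
  if (r_xx <= 0) abort("Scale reliability coefficient is not positive; CA undefined.")
  new_reliability_estimate("CA", r_xy^2 / r_xx,
                           diagnostics = list(r_xy = r_xy, r_xx = r_xx,
                                              coefficient = coefficient))
}

# One-factor iterated principal-axis factoring of a correlation matrix.
# Start communalities are squared multiple correlations; at each step the
# reduced correlation matrix (communalities on the diagonal) is
# eigendecomposed, the first-factor loadings are lambda = sqrt(e1) v1 and
# the new communalities lambda^2, clamped to [0, 1] (Heywood guard).
paf_one_factor <- function(R, tol = 1e-6, max_iter = 200L) {
  p <- ncol(R)
  Rinv <- tryCatch(solve(R), error = function(e) NULL)
  if (is.null(Rinv)) abort("Correlation matrix is singular; cannot start factoring.")
  h2 <- 1 - 1 / diag(Rinv)   # squared multiple correlations
  h2 <- clamp01(h2)
  converged <- FALSE
  iter <- 0L
  loadings <- rep(0, p)
  for (iter in seq_len(max_iter)) {
    Rr <- R
    diag(Rr) <- h2
    e <- eigen(Rr, symmetric = TRUE)
    lambda <- sqrt(max(e$values[1], 0)) * e$vectors[, 1]
    h2_new <- clamp01(lambda^2)
    delta <- max(abs(h2_new - h2))
    h2 <- h2_new
    loadings <- lambda
    if (delta < tol) { converged <- TRUE; break }
  }
  list(communalities = h2, loadings = loadings, iterations = iter,
       converged = converged)
}

#' Communalities by one-factor iterated principal-axis factoring
#'
#' @param R Correlation matrix.
#' @param tol Convergence tolerance on the maximum communality change.
#' @param max_iter Maximum iterations.
#' @return A list with `communalities`, `loadings`, `iterations`,
#'   `converged`.
#' @export
paf_communalities <- function(R, tol = 1e-6, max_iter = 200L) {
  paf_one_factor(R, tol = tol, max_iter = max_iter)
}

#' Factor-analysis communality estimate of single-item reliability
#'
#' One-factor iterated principal-axis factoring is run on the Pearson
#' correlation matrix of all items (the single item together with the
#' multi-item scale); the single item's communality is taken as a
#' conservative estimate of its reliability (specific variance assumed 0).
#'
#' @inheritParams ca_reliability
#' @param tol Convergence tolerance on the maximum communality change.
#' @param max_iter Maximum number of factoring iterations.
#' @return A `sirel_estimate` with method `"FA"`.
#' @export
fa_reliability <- function(data, single_col = NULL, m = 4L,
                           tol = 1e-6, max_iter = 200L) {
  x <- as.matrix(data)
  if (!is.numeric(x) || nrow(x) < 2L) abort("Need a numeric score matrix with at least 2 rows.")
  if (is.null(colnames(x))) colnames(x) <- paste0("item_", seq_len(ncol(x)))
  si <- resolve_single_col(x, single_col)
  if (any(apply(x, 2, pop_var) == 0)) abort("An item has zero variance; correlation matrix degenerate.")
  R <- cor(x)
  fit <- paf_one_factor(R, tol = tol, max_iter = max_iter)
  if (!fit$converged) {
    abort(sprintf("Principal-axis factoring did not converge in %d iterations (last max change applied).",
                  max_iter))
  }
  new_reliability_estimate("FA", fit$communalities[si],
                           diagnostics = list(iterations = fit$iterations,
                                              loading = fit$loadings[si],
                                              converged = fit$converged))
}

# Pieces of the lambda-6 computation shared by the estimator and the joint
# cumulative decomposition.
lambda6_workspace <- function(data, single_col, m = 4L, ridge = 1e-8) {
  parts <- split_single_multi(data, single_col, m)
  n <- length(parts$single)
  C <- cov(cbind(parts$single, parts$multi)) * (n - 1) / n
  Sigma_ii <- C[-1, -1, drop = FALSE]
  sigma_i <- C[-1, 1]
  s2 <- C[1, 1]
  if (s2 == 0) abort("Degenerate single item: zero variance.")
  sol <- tryCatch(solve(Sigma_ii, sigma_i), error = function(e) NULL)
  regularized <- FALSE
  if (is.null(sol)) {
    Sigma_ii <- Sigma_ii + diag(ridge * sum(diag(Sigma_ii)) / ncol(Sigma_ii),
                                ncol(Sigma_ii))
    sol <- tryCatch(solve(Sigma_ii, sigma_i), error = function(e) NULL)
    regularized <- TRUE
    if (is.null(sol)) abort("Covariance matrix of the remaining items is singular.")
  }
  explained <- sum(sigma_i * sol)
  list(explained = explained, sigma2_xi = s2, eps2 = s2 - explained,
       regularized = regularized, m = parts$m)
}

#' Guttman lambda-6 estimate of single-item reliability
#'
#' The single item is regressed (in population form) on the remaining
#' items: `lambda6_i = sigma_i' Sigma_ii^{-1} sigma_i / sigma^2_xi`, one
#' minus the ratio of the regression's residual variance to the item
#' variance. All covariances use divisor n.
#'
#' @inheritParams ca_reliability
#' @return A `sirel_estimate` with method `"L6"`.
#' @export
lambda6_reliability <- function(data, single_col = NULL, m = 4L) {
  ws <- lambda6_workspace(data, single_col, m)
  new_reliability_estimate("L6", ws$explained / ws$sigma2_xi,
                           diagnostics = list(eps2 = ws$eps2,
                                              sigma2_xi = ws$sigma2_xi,
                                              regularized = ws$regularized))
}

#' Joint cumulative probability table implied by lambda-6
#'
#' Spreads the explained variance `sigma_i' Sigma_ii^{-1} sigma_i` evenly
#' over the m^2 same-item joint cells:
#' `pi_x(i)y(i') = sigma_i' Sigma_ii^{-1} sigma_i / m^2 + pi_x(i) pi_y(i)`.
#' Summing this table through the joint-probability reliability formula
#' returns the lambda-6 value exactly.
#'
#' @inheritParams ca_reliability
#' @return A tibble with columns `x`, `y` and `pi_xy` for x, y in 1..m.
#' @export
lambda6_joint_decomposition <- function(data, single_col = NULL, m = 4L) {
  ws <- lambda6_workspace(data, single_col, m)
  x <- as_score_matrix(data, m)
  si <- resolve_single_col(x, single_col)
  pi_x <- vapply(1:m, function(lv) mean(x[, si] >= lv), numeric(1))
  tidyr::expand_grid(x = 1:m, y = 1:m) |>
    dplyr::mutate(pi_xy = ws$explained / m^2 + pi_x[.data$x] * pi_x[.data$y])
}
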