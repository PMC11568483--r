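# Graded response model simulator.
#
# Scores are generated from a two-dimensional graded response model:
# P(X_i >= x | theta) = logistic(sum_q a_iq theta_q - b_ix), x = 1..m,
# with theta bivariate standard normal with correlation rho. The multi-item
# scale loads dimension 1 only; the single item loads dimension 2 only
# (simple structure), so the correlation between the two constructs is the
# latent correlation rho.

#' Draw graded-response item parameters for a simulation condition
#'
#' Multi-item scale items load latent dimension 1; the single item loads
#' dimension 2. Under the "equal" regime the scale items all have slope
#' a = 1; under "unequal" each slope is uniform on \[0.4, 2.8\]. The single
#' item's slope is always drawn from \[0.4, 2.8\]. Thresholds follow
#' b_1 ~ U\[-4.2, 0\] with a per-item common step b_adv ~ U\[1.4, 2.5\], so
#' b_{x+1} = b_x + b_adv and the four thresholds are strictly increasing.
#'
#' @param condition A condition id (1..36) or one row of [condition_grid()].
#' @param which `"multi"` for the multi-item scale, `"single"` for the
#'   single-item assessment.
#' @param m Number of thresholds (categories are 0..m); default 4.
#' @param a_range,b1_range,badv_range Sampling intervals for the slope, the
#'   first threshold and the common threshold step.
#' @return A tibble with one row per item: `item`, `dim` (loaded latent
#'   dimension), `a`, and `b1`..`b4`.
#' @export
draw_item_params <- function(condition, which = c("multi", "single"), m = 4L,
                             a_range = c(0.4, 2.8), b1_range = c(-4.2, 0),
                             badv_range = c(1.4, 2.5)) {
  which <- match.arg(which)
  cond <- if (is.data.frame(condition)) condition else get_condition(condition)
  n_items <- if (which == "multi") cond$length else 1L
  a <- if (which == "multi" && cond$discrimination == "equal") {
    rep(1, n_items)
  } else {
    runif(n_items, a_range[1], a_range[2])
  }
  b1 <- runif(n_items, b1_range[1], b1_range[2])
  b_adv <- runif(n_items, badv_range[1], badv_range[2])
  b <- sapply(seq_len(m), function(x) b1 + (x - 1) * b_adv)
  b <- matrix(b, nrow = n_items)
  out <- tibble::tibble(
    item = seq_len(n_items),
    dim = if (which == "multi") 1L else 2L,
    a = a
  )
  for (x in seq_len(m)) out[[paste0("b", x)]] <- b[, x]
  out
}

param_b_matrix <- function(params) {
  bcols <- grep("^b[0-9]+$", names(params), value = TRUE)
  as.matrix(params[bcols])
}

#' Cumulative response probability of the graded response model
#'
#' `P(X >= x | theta)`, the probability of scoring at least `x` on the item
#' given latent traits `theta`. By convention `P(X >= 0) = 1`.
#'
#' @param theta Numeric vector of length Q (one person) or an n x Q matrix.
#' @param item One row of an item-parameter tibble (see [draw_item_params()]).
#' @param x Score level, 0..m.
#' @return A probability (vector over persons).
#' @export
cumulative_response_prob <- function(theta, item, x) {
  m <- ncol(param_b_matrix(item))
  if (x < 0 || x > m) abort("`x` must be in 0..m.")
  if (x == 0) {
    n <- if (is.matrix(theta)) nrow(theta) else 1L
    return(rep(1, n))
  }
  if (!is.matrix(theta)) theta <- matrix(theta, nrow = 1)
  eta <- theta[, item$dim] * item$a - param_b_matrix(item)[1, x]
  unname(plogis(eta))
}

#' Category probabilities of the graded response model
#'
#' Successive differences of the cumulative response probabilities:
#' `P(X = x | theta) = P(X >= x) - P(X >= x + 1)` with `P(X >= m + 1) = 0`.
#' Entries are non-negative (thresholds are strictly increasing) and sum to 1.
#'
#' @inheritParams cumulative_response_prob
#' @return An n x (m + 1) matrix of probabilities, columns for scores 0..m.
#' @export
category_probs <- function(theta, item) {
  b <- param_b_matrix(item)[1, ]
  if (any(diff(b) <= 0)) abort("Item thresholds must be strictly increasing.")
  if (!is.matrix(theta)) theta <- matrix(theta, nrow = 1)
  m <- length(b)
  cum <- cbind(1, plogis(outer(theta[, item$dim] * item$a, b, `-`)), 0)
  cum[, seq_len(m + 1), drop = FALSE] - cum[, 1 + seq_len(m + 1), drop = FALSE]
}

#' Draw correlated latent traits
#'
#' @param n Number of persons.
#' @param rho Correlation between the two standard-normal latent dimensions.
#' @return An n x 2 matrix.
#' @export
draw_latent <- function(n, rho) {
  MASS::mvrnorm(n, mu = c(0, 0), Sigma = matrix(c(1, rho, rho, 1), 2))
}

#' Simulate a person x item score matrix for one condition
#'
#' Draws `n` latent trait vectors from the bivariate standard normal with
#' correlation `rho`, then one multinomial score per person-item from the
#' graded-response category probabilities. The single item occupies the
#' last column.
#'
#' @param condition A condition id or one row of [condition_grid()].
#' @param params_multi,params_single Item-parameter tibbles from
#'   [draw_item_params()].
#' @return A tibble with columns `item_1`..`item_L` and `single_item`,
#'   integer scores 0..m.
#' @export
simulate_scores <- function(condition, params_multi, params_single) {
  cond <- if (is.data.frame(condition)) condition else get_condition(condition)
  theta <- draw_latent(cond$n, cond$rho)
  n <- cond$n
  all_params <- rbind(params_multi, params_single)
  L1 <- nrow(all_params)
  b <- param_b_matrix(all_params)
  m <- ncol(b)
  # linear predictor per person-item, then count cumulative probabilities
  # exceeding one uniform draw per cell (a valid multinomial draw since
  # P(X >= x) = pi_x)
  eta <- theta[, all_params$dim, drop = FALSE] *
    matrix(all_params$a, n, L1, byrow = TRUE)
  u <- matrix(runif(n * L1), n, L1)
  scores <- matrix(0L, n, L1)
  for (x in seq_len(m)) {
    scores <- scores + (u < plogis(eta - matrix(b[, x], n, L1, byrow = TRUE)))
  }
  out <- tibble::as_tibble(as.data.frame(scores))
  names(out) <- c(paste0("item_", seq_len(L1 - 1L)), "single_item")
  out
}

#' True reliability of a single item by Monte Carlo
#'
#' Reliability is the ratio of true-score variance to observed-score
#' variance. The true-score variance is the variance over latent-trait draws
#' of the conditional expected score E\[X | theta\] (computed analytically
#' from the category probabilities); the observed-score variance is the
#' variance of scores simulated at the same draws.
#'
#' @param item One row of an item-parameter tibble.
#' @param n_draws Number of latent-trait draws (default one million).
#' @return A list of class `sirel_true_reliability` with `rho_ii`,
#'   `sigma2_T`, `sigma2_X` and `n_draws`.
#' @export
true_reliability <- function(item, n_draws = 1e6) {
  if (n_draws < 1e4) abort("`n_draws` must be at least 10^4.")
  theta <- rnorm(n_draws)
  b <- param_b_matrix(item)[1, ]
  cum <- plogis(outer(theta * item$a, b, `-`))
  # Expected score equals the sum of the cumulative probabilities.
  ex <- rowSums(cum)
  scores <- as.integer(rowSums(cum > runif(n_draws)))
  s2x <- pop_var(scores)
  if (s2x == 0) abort("Degenerate item: simulated scores have zero variance.")
  s2t <- pop_var(ex)
  structure(
    list(rho_ii = clamp01(s2t / s2x), sigma2_T = s2t, sigma2_X = s2x,
         n_draws = n_draws),
    class = "sirel_true_reliability"
  )
}

#' @export
print.sirel_true_reliability <- function(x, ...) {
  cat(sprintf("True single-item reliability: %.4f (sigma2_T = %.4f, sigma2_X = %.4f, %g draws)\n",
              x$rho_ii, x$sigma2_T, x$sigma2_X, x$n_draws))
  invisible(x)
}
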