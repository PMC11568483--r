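# Double monotonicity (DMM) machinery: marginal and joint cumulative
# probabilities over (item, level) pairs, neighbor-based estimation of the
# unobservable same-item joint cumulative probabilities, and the resulting
# single-item reliability
#   rho_ii' = sum_{x,y >= 1} (pi_x(i)y(i') - pi_x(i) pi_y(i)) / sigma^2_xi.

#' Marginal cumulative probabilities per item and level
#'
#' `pi_x(i) = P(X_i >= x)`, the fraction of persons scoring at least `x` on
#' item `i`. Always `pi_0(i) = 1` and `pi_x(i)` is non-increasing in `x`.
#'
#' @param data A data frame of integer item scores (0..m).
#' @param m Maximum score level; default 4.
#' @return A tibble with columns `item` (column name), `level` (0..m) and
#'   `pi` (marginal cumulative probability).
#' @export
cumulative_marginals <- function(data, m = 4L) {
  x <- as_score_matrix(data, m)
  items <- colnames(x) %||% paste0("item_", seq_len(ncol(x)))
  tidyr::expand_grid(item = items, level = 0:m) |>
    dplyr::mutate(pi = purrr::map2_dbl(.data$item, .data$level, function(it, lv) {
      mean(x[, match(it, items)] >= lv)
    }))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Retained (item, level >= 1) pairs, ordered ascending by marginal with
# ties broken by (item name, level), which keeps the grid deterministic and
# invariant to column reordering. Levels whose marginal is 0 or 1 are
# dropped: they contribute exactly 0 to the reliability numerator and make
# the complement-ratio neighbor equations degenerate.
ordered_pairs <- function(marginals, item_order) {
  keep <- marginals$level >= 1 & marginals$pi > 0 & marginals$pi < 1
  pairs <- marginals[keep, , drop = FALSE]
  pairs[order(pairs$pi, pairs$item, pairs$level), , drop = FALSE]
}

#' Ordered grid of joint cumulative probabilities
#'
#' Ranks all retained (item, level) marginal cumulative probabilities from
#' small to large and builds the matrix of joint cumulative probabilities
#' `P(X_i >= x, X_j >= y)` over the ordered pairs. Cells pairing two levels
#' of the same item are unobservable from a single administration and are
#' flagged; they are the quantities the DMM estimator reconstructs.
#'
#' @param data A data frame of integer item scores.
#' @param m Maximum score level.
#' @return An object of class `sirel_joint_matrix`: a list with `values`
#'   (K x K numeric, `NA` where unobservable), `observed` (K x K logical),
#'   `marginals`, `items`, `levels`.
#' @export
build_joint_matrix <- function(data, m = 4L) {
  x <- as_score_matrix(data, m)
  if (ncol(x) < 2L) abort("Need at least two items to build a joint matrix.")
  items <- colnames(x) %||% paste0("item_", seq_len(ncol(x)))
  colnames(x) <- items
  marg <- cumulative_marginals(as.data.frame(x), m)
  pairs <- ordered_pairs(marg, items)
  K <- nrow(pairs)
  if (K == 0L) abort("No non-degenerate (item, level) pairs to retain.")
  G <- vapply(seq_len(K), function(k) {
    as.numeric(x[, pairs$item[k]] >= pairs$level[k])
  }, numeric(nrow(x)))
  values <- crossprod(G) / nrow(x)
  same_item <- outer(pairs$item, pairs$item, `==`)
  values[same_item] <- NA_real_
  new_joint_matrix(values, !same_item, pairs$pi, pairs$item, pairs$level)
}

#' Construct a joint cumulative probability matrix from components
#'
#' Used to load worked-example fixtures where the marginals and observed
#' joint cells are given directly rather than computed from raw scores.
#'
#' @param values K x K numeric matrix (`NA` for unobservable cells).
#' @param observed K x K logical matrix; `FALSE` marks unobservable cells.
#' @param marginals Length-K vector of marginal cumulative probabilities,
#'   ascending.
#' @param items,levels Length-K identifiers of the (item, level) pairs.
#' @return A `sirel_joint_matrix`.
#' @export
new_joint_matrix <- function(values, observed, marginals, items, levels) {
  stopifnot(nrow(values) == ncol(values), all(dim(observed) == dim(values)),
            length(marginals) == nrow(values))
  structure(
    list(values = unname(values), observed = unname(observed),
         marginals = as.numeric(marginals),
         items = items, levels = as.integer(levels)),
    class = "sirel_joint_matrix"
  )
}

#' @export
print.sirel_joint_matrix <- function(x, ...) {
  K <- length(x$marginals)
  cat(sprintf("<ordered joint cumulative probability matrix: %d x %d, %d unobservable cells>\n",
              K, K, sum(!x$observed)))
  lab <- sprintf("%s>=%d", x$items, x$levels)
  v <- round(x$values, 3)
  dimnames(v) <- list(lab, lab)
  print(v)
  invisible(x)
}

#' Tidy a joint cumulative probability matrix
#'
#' @param x A `sirel_joint_matrix`.
#' @param ... Unused.
#' @return A long tibble with one row per cell.
#' @method tidy sirel_joint_matrix
#' @export
tidy.sirel_joint_matrix <- function(x, ...) {
  K <- length(x$marginals)
  tidyr::expand_grid(row = seq_len(K), col = seq_len(K)) |>
    dplyr::mutate(
      row_item = x$items[.data$row], row_level = x$levels[.data$row],
      col_item = x$items[.data$col], col_level = x$levels[.data$col],
      row_marginal = x$marginals[.data$row], col_marginal = x$marginals[.data$col],
      observed = x$observed[cbind(.data$row, .data$col)],
      value = x$values[cbind(.data$row, .data$col)]
    )
}

# Neighbor lookup: value of an originally observed cell, or NA when the
# position is off-grid or itself unobservable. Estimation never chains off
# previously estimated cells.
observed_at <- function(jm, r, c) {
  K <- length(jm$marginals)
  if (r < 1 || r > K || c < 1 || c > K) return(NA_real_)
  if (!jm$observed[r, c]) return(NA_real_)
  jm$values[r, c]
}

#' Neighbor-based estimates of an unobservable joint cumulative probability
#'
#' For an unobservable cell (r, c) with row marginal `P_r` and column
#' marginal `P_c`, up to eight estimates are formed from the four
#' neighboring observed cells (below, right, above, left). Each neighbor
#' yields a direct ratio estimate, e.g. `P_lo * P_r / P_{r+1}` for the lower
#' neighbor, and a complement-ratio estimate obtained by applying the same
#' ratio reasoning to the complementary table (both events failing), e.g.
#' `(P_lo (1 - P_r) - P_c (P_{r+1} - P_r)) / (1 - P_{r+1})`. Estimates whose
#' neighbor is absent (off-grid or itself unobservable) or whose denominator
#' vanishes are skipped.
#'
#' @param jm A `sirel_joint_matrix`.
#' @param r,c Cell indices; the cell must be unobservable.
#' @return A tibble with columns `equation` (1-8), `neighbor`
#'   (lo/ri/up/le), `form` (direct/complement) and `estimate`.
#' @export
neighbor_estimates <- function(jm, r, c) {
  if (jm$observed[r, c]) abort("Cell (r, c) is observed; nothing to estimate.")
  P <- jm$marginals
  Pr <- P[r]; Pc <- P[c]
  K <- length(P)
  P_lo <- observed_at(jm, r + 1, c)
  P_ri <- observed_at(jm, r, c + 1)
  P_up <- observed_at(jm, r - 1, c)
  P_le <- observed_at(jm, r, c - 1)
  Pr1 <- if (r + 1 <= K) P[r + 1] else NA_real_
  Pc1 <- if (c + 1 <= K) P[c + 1] else NA_real_
  Pr0 <- if (r - 1 >= 1) P[r - 1] else NA_real_
  Pc0 <- if (c - 1 >= 1) P[c - 1] else NA_real_
  est <- c(
    P_lo * Pr / Pr1,
    P_ri * Pc / Pc1,
    P_up * Pr / Pr0,
    P_le * Pc / Pc0,
    (P_lo * (1 - Pr) - Pc * (Pr1 - Pr)) / (1 - Pr1),
    (P_ri * (1 - Pc) - Pr * (Pc1 - Pc)) / (1 - Pc1),
    (P_up * (1 - Pr) + Pc * (Pr - Pr0)) / (1 - Pr0),
    (P_le * (1 - Pc) + Pr * (Pc - Pc0)) / (1 - Pc0)
  )
  denom <- c(Pr1, Pc1, Pr0, Pc0, 1 - Pr1, 1 - Pc1, 1 - Pr0, 1 - Pc0)
  out <- tibble::tibble(
    equation = 1:8,
    neighbor = rep(c("lo", "ri", "up", "le"), 2),
    form = rep(c("direct", "complement"), each = 4),
    estimate = est
  )
  ok <- !is.na(est) & !is.na(denom) & abs(denom) > 0
  out[ok, , drop = FALSE]
}

#' Estimate one unobservable joint cumulative probability
#'
#' The mean of the evaluable neighbor estimates, clipped into the admissible
#' interval `[P_r * P_c, min(P_r, P_c)]` implied by the double monotonicity
#' model. When no neighbor estimate is evaluable the interval midpoint is
#' returned.
#'
#' @inheritParams neighbor_estimates
#' @return A list with `estimate` (clipped), `raw_mean`, `n_estimates`,
#'   `lower`, `upper` and `clipped` (logical).
#' @export
estimate_cell <- function(jm, r, c) {
  Pr <- jm$marginals[r]; Pc <- jm$marginals[c]
  lower <- Pr * Pc
  upper <- min(Pr, Pc)
  ests <- neighbor_estimates(jm, r, c)
  if (nrow(ests) == 0L) {
    raw <- (lower + upper) / 2
  } else {
    raw <- mean(ests$estimate)
  }
  val <- min(upper, max(lower, raw))
  list(estimate = val, raw_mean = raw, n_estimates = nrow(ests),
       lower = lower, upper = upper, clipped = !isTRUE(all.equal(val, raw)))
}

#' Fill all unobservable cells of a joint cumulative probability matrix
#'
#' Applies [estimate_cell()] to every unobservable cell using only the
#' originally observed cells as neighbors (no chaining), then symmetrizes
#' the mirror cells (r, c) and (c, r) by averaging.
#'
#' @param jm A `sirel_joint_matrix`.
#' @return The matrix with all cells filled; attribute `n_clipped` counts
#'   the cells whose raw mean fell outside the admissible interval.
#' @export
fill_joint_matrix <- function(jm) {
  todo <- which(!jm$observed, arr.ind = TRUE)
  filled <- jm$values
  K <- length(jm$marginals)
  P <- jm$marginals
  r <- todo[, 1]; c <- todo[, 2]

  # Vectorized evaluation of the eight neighbor estimates for all
  # unobservable cells at once (same arithmetic as neighbor_estimates()).
  val_at <- function(rr, cc) {
    ok <- rr >= 1 & rr <= K & cc >= 1 & cc <= K
    v <- rep(NA_real_, length(rr))
    idx <- cbind(pmin(pmax(rr, 1L), K), pmin(pmax(cc, 1L), K))
    obs <- ok & jm$observed[idx]
    v[obs] <- jm$values[idx[obs, , drop = FALSE]]
    v
  }
  marg_at <- function(i) ifelse(i >= 1 & i <= K, P[pmin(pmax(i, 1L), K)], NA_real_)
  P_lo <- val_at(r + 1L, c); P_ri <- val_at(r, c + 1L)
  P_up <- val_at(r - 1L, c); P_le <- val_at(r, c - 1L)
  Pr <- P[r]; Pc <- P[c]
  Pr1 <- marg_at(r + 1L); Pc1 <- marg_at(c + 1L)
  Pr0 <- marg_at(r - 1L); Pc0 <- marg_at(c - 1L)
  safe_div <- function(num, den) ifelse(!is.na(den) & abs(den) > 0, num / den, NA_real_)
  ests <- cbind(
    safe_div(P_lo * Pr, Pr1),
    safe_div(P_ri * Pc, Pc1),
    safe_div(P_up * Pr, Pr0),
    safe_div(P_le * Pc, Pc0),
    safe_div(P_lo * (1 - Pr) - Pc * (Pr1 - Pr), 1 - Pr1),
    safe_div(P_ri * (1 - Pc) - Pr * (Pc1 - Pc), 1 - Pc1),
    safe_div(P_up * (1 - Pr) + Pc * (Pr - Pr0), 1 - Pr0),
    safe_div(P_le * (1 - Pc) + Pr * (Pc - Pc0), 1 - Pc0)
  )
  n_est <- rowSums(!is.na(ests))
  raw <- rowMeans(ests, na.rm = TRUE)
  lower <- Pr * Pc
  upper <- pmin(Pr, Pc)
  raw[n_est == 0] <- ((lower + upper) / 2)[n_est == 0]
  vals <- pmin(upper, pmax(lower, raw))
  filled[todo] <- vals
  filled <- (filled + t(filled)) / 2
  out <- jm
  out$values <- filled
  attr(out, "n_clipped") <- sum(abs(vals - raw) > 1e-15)
  out
}

#' Single-item reliability via the double monotonicity model
#'
#' Builds the ordered joint cumulative probability matrix over the single
#' item and the multi-item scale, fills the unobservable same-item cells by
#' neighbor estimation, and evaluates
#' `rho_ii' = sum_{x,y} (pi_x(i)y(i') - pi_x(i) pi_y(i)) / sigma^2_xi`
#' over the single item's retained levels, with the population (divisor n)
#' variance of the single item in the denominator.
#'
#' @param data Data frame of item scores; the single item plus the
#'   multi-item scale of the same construct.
#' @param single_col Column of the single item (index, name, or `"last"`;
#'   default the last column).
#' @param m Maximum score level.
#' @return A `sirel_estimate` with method `"DMM"`.
#' @export
dmm_reliability <- function(data, single_col = NULL, m = 4L) {
  x <- as_score_matrix(data, m)
  if (is.null(colnames(x))) colnames(x) <- paste0("item_", seq_len(ncol(x)))
  si <- resolve_single_col(x, single_col)
  s2 <- pop_var(x[, si])
  if (s2 == 0) abort("Degenerate single item: zero variance.")
  jm <- build_joint_matrix(as.data.frame(x), m)
  filled <- fill_joint_matrix(jm)
  single_name <- colnames(x)[si]
  idx <- which(filled$items == single_name)
  num <- 0
  for (rx in idx) for (ry in idx) {
    num <- num + filled$values[rx, ry] - filled$marginals[rx] * filled$marginals[ry]
  }
  new_reliability_estimate("DMM", num / s2, diagnostics = list(
    numerator = num, sigma2_xi = s2,
    retained_levels = length(idx),
    n_clipped = attr(filled, "n_clipped")
  ))
}
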