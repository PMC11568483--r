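# Latent class model for polytomous items, fitted by EM, and the derived
# single-item reliability: within each of Q latent classes the items are
# conditionally independent, so the unobservable joint cumulative
# probability of two independent administrations of the same item is
#   pi_x(i)y(i') = sum_q P(q) P(X_i >= x | q) P(X_i >= y | q).

# Indicator expansion: n x (L * (m + 1)) matrix with one column per
# (item, category); turns both the E-step and the M-step into one
# matrix product each.
score_indicators <- function(x, m) {
  n <- nrow(x); L <- ncol(x)
  Z <- matrix(0, n, L * (m + 1L))
  for (i in seq_len(L)) {
    Z[cbind(seq_len(n), (i - 1L) * (m + 1L) + x[, i] + 1L)] <- 1
  }
  Z
}

em_one_run <- function(Z, n, L, m, Q, tol, max_iter, floor_class = 1e-6) {
  # random responsibility initialization
  post <- matrix(rgamma(n * Q, shape = 1), n, Q)
  post <- post / rowSums(post)
  ll_trace <- numeric(0)
  ll_old <- -Inf
  cp <- NULL; ip <- NULL; ll <- NA_real_
  for (iter in seq_len(max_iter)) {
    # M-step
    nq <- colSums(post)
    cp <- pmax(nq / n, floor_class)
    cp <- cp / sum(cp)
    counts <- crossprod(Z, post)                       # (L(m+1)) x Q
    ip <- sweep(counts, 2, nq, "/")
    if (any(ip <= 0)) {
      ip <- ip + 1e-12
      blocks <- rep(seq_len(L), each = m + 1L)
      for (q in seq_len(Q)) {
        tot <- tapply(ip[, q], blocks, sum)
        ip[, q] <- ip[, q] / tot[blocks]
      }
    }
    # E-step
    lp <- Z %*% log(ip)                                # n x Q
    lp <- sweep(lp, 2, log(cp), "+")
    mx <- apply(lp, 1, max)
    w <- exp(lp - mx)
    sw <- rowSums(w)
    ll <- sum(mx + log(sw))
    post <- w / sw
    ll_trace <- c(ll_trace, ll)
    if (is.finite(ll_old) && (ll - ll_old) <= tol * abs(ll_old)) break
    ll_old <- ll
  }
  list(class_probs = as.numeric(cp), item_counts = ip, loglik = ll,
       trace = ll_trace, iterations = length(ll_trace))
}

#' Fit a latent class model to polytomous item scores
#'
#' EM estimation of a Q-class model with conditionally independent items.
#' The best of `n_starts` random initializations by log-likelihood is
#' returned; within each run the log-likelihood is non-decreasing.
#'
#' @param data Data frame of integer item scores (0..m).
#' @param Q Number of latent classes.
#' @param n_starts Random restarts (Q = 1 has a closed form and needs none).
#' @param tol Relative log-likelihood convergence tolerance.
#' @param max_iter Maximum EM iterations per start.
#' @param m Maximum score level.
#' @return An object of class `sirel_lcm` with `Q`, `class_probs`,
#'   `item_probs` (array item x class x category), `loglik`, `bic`,
#'   `trace` (log-likelihood path of the best start), `n`, `n_starts`.
#' @export
lcm_em_fit <- function(data, Q, n_starts = 10L, tol = 1e-6, max_iter = 1000L,
                       m = 4L) {
  x <- as_score_matrix(data, m)
  n <- nrow(x); L <- ncol(x)
  if (Q < 1L) abort("`Q` must be at least 1.")
  if (n <= Q) abort("Need more persons than classes.")
  Z <- score_indicators(x, m)
  if (Q == 1L) {
    ip <- matrix(colMeans(Z), ncol = 1)
    lp <- Z %*% log(pmax(ip, 1e-300))
    best <- list(class_probs = 1, item_counts = ip, loglik = sum(lp),
                 trace = sum(lp), iterations = 1L)
  } else {
    best <- NULL
    for (s in seq_len(n_starts)) {
      run <- em_one_run(Z, n, L, m, Q, tol, max_iter)
      if (!is.finite(run$loglik)) next
      if (is.null(best) || run$loglik > best$loglik) best <- run
    }
    if (is.null(best)) abort("All EM starts failed (degenerate fits).")
  }
  item_probs <- aperm(array(best$item_counts, dim = c(m + 1L, L, Q)), c(2, 3, 1))
  dimnames(item_probs) <- list(colnames(x), NULL, paste0("cat", 0:m))
  npar <- (Q - 1) + Q * L * m
  structure(
    list(Q = Q, class_probs = best$class_probs, item_probs = item_probs,
         loglik = best$loglik, bic = -2 * best$loglik + npar * log(n),
         npar = npar, trace = best$trace, iterations = best$iterations,
         n = n, L = L, m = m, n_starts = if (Q == 1L) 0L else n_starts),
    class = "sirel_lcm"
  )
}

#' @export
print.sirel_lcm <- function(x, ...) {
  cat(sprintf("<latent class model: Q = %d, n = %d, logLik = %.2f, BIC = %.2f>\n",
              x$Q, x$n, x$loglik, x$bic))
  cat("class probabilities:", paste(sprintf("%.3f", x$class_probs), collapse = " "), "\n")
  invisible(x)
}

#' Glance at a latent class model fit
#'
#' @param x A `sirel_lcm` object.
#' @param ... Unused.
#' @return One-row tibble with `Q`, `loglik`, `bic`, `npar`, `n`,
#'   `iterations`.
#' @method glance sirel_lcm
#' @export
glance.sirel_lcm <- function(x, ...) {
  tibble::tibble(Q = x$Q, loglik = x$loglik, bic = x$bic, npar = x$npar,
                 n = x$n, iterations = x$iterations)
}

#' Tidy a latent class model fit
#'
#' @param x A `sirel_lcm` object.
#' @param ... Unused.
#' @return Long tibble of conditional category probabilities per item and
#'   class.
#' @method tidy sirel_lcm
#' @export
tidy.sirel_lcm <- function(x, ...) {
  items <- dimnames(x$item_probs)[[1]] %||% paste0("item_", seq_len(x$L))
  tidyr::expand_grid(item = items, class = seq_len(x$Q), category = 0:x$m) |>
    dplyr::mutate(prob = x$item_probs[cbind(match(.data$item, items),
                                            .data$class, .data$category + 1L)])
}

#' Select the number of latent classes by BIC
#'
#' @inheritParams lcm_em_fit
#' @param Q_max Largest class count to consider.
#' @return The Q in 1..Q_max minimizing BIC.
#' @export
lcm_select_Q <- function(data, Q_max = 5L, n_starts = 10L, tol = 1e-6,
                         max_iter = 1000L, m = 4L) {
  bics <- vapply(seq_len(Q_max), function(q) {
    lcm_em_fit(data, q, n_starts = n_starts, tol = tol, max_iter = max_iter,
               m = m)$bic
  }, numeric(1))
  which.min(bics)
}

#' Model-implied joint cumulative probabilities of two administrations
#'
#' Given a fitted latent class model, the joint cumulative probability of
#' scoring at least `x` and at least `y` on two conditionally independent
#' administrations of item `item` is
#' `sum_q P(q) P(X >= x | q) P(X >= y | q)`.
#'
#' @param model A `sirel_lcm` fit.
#' @param item Item index or name.
#' @return A tibble with columns `x`, `y`, `pi_xy` for x, y in 1..m.
#' @export
lcm_joint_table <- function(model, item) {
  if (is.character(item)) item <- match(item, dimnames(model$item_probs)[[1]])
  m <- model$m
  p <- model$item_probs[item, , , drop = FALSE]      # 1 x Q x (m+1)
  p <- matrix(p, nrow = model$Q)                     # Q x (m+1)
  # cumulative P(X >= x | q) for x = 1..m
  cum <- t(apply(p, 1, function(v) rev(cumsum(rev(v)))))[, -1, drop = FALSE]
  if (model$Q == 1L) cum <- matrix(cum, nrow = 1)
  w <- model$class_probs
  tidyr::expand_grid(x = 1:m, y = 1:m) |>
    dplyr::mutate(pi_xy = purrr::map2_dbl(.data$x, .data$y, function(xx, yy) {
      sum(w * cum[, xx] * cum[, yy])
    }))
}

#' Latent class estimate of single-item reliability
#'
#' Fits a latent class model to all items (single item plus multi-item
#' scale), computes the model-implied same-item joint cumulative
#' probabilities, and plugs them into the joint-probability reliability
#' formula with the observed marginal cumulative probabilities and the
#' population variance of the single item.
#'
#' @inheritParams ca_reliability
#' @param Q `"auto"` to select by BIC over 1..`Q_max`, or a fixed integer.
#' @param Q_max Largest class count considered when `Q = "auto"`.
#' @inheritParams lcm_em_fit
#' @return A `sirel_estimate` with method `"LCM"`.
#' @export
lcm_reliability <- function(data, single_col = NULL, Q = "auto", Q_max = 5L,
                            n_starts = 10L, tol = 1e-6, max_iter = 1000L,
                            m = 4L) {
  x <- as_score_matrix(data, m)
  if (is.null(colnames(x))) colnames(x) <- paste0("item_", seq_len(ncol(x)))
  si <- resolve_single_col(x, single_col)
  s2 <- pop_var(x[, si])
  if (s2 == 0) abort("Degenerate single item: zero variance.")
  if (identical(Q, "auto")) {
    Q <- lcm_select_Q(as.data.frame(x), Q_max = Q_max, n_starts = n_starts,
                      tol = tol, max_iter = max_iter, m = m)
  }
  fit <- lcm_em_fit(as.data.frame(x), Q, n_starts = n_starts, tol = tol,
                    max_iter = max_iter, m = m)
  joint <- lcm_joint_table(fit, si)
  pi_x <- vapply(1:m, function(lv) mean(x[, si] >= lv), numeric(1))
  num <- sum(joint$pi_xy - pi_x[joint$x] * pi_x[joint$y])
  new_reliability_estimate("LCM", num / s2, diagnostics = list(
    Q = Q, loglik = fit$loglik, bic = fit$bic, n_starts = fit$n_starts,
    iterations = fit$iterations, sigma2_xi = s2
  ))
}
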