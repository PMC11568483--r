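# Internal helpers shared across modules.

#' @importFrom rlang .data abort warn
#' @importFrom stats var cov cor median quantile sd plogis rnorm runif rbinom
#'   rgamma pnorm p.adjust lm coef kruskal.test
NULL

# Population variance (divisor n). The double-monotonicity and latent-class
# estimators express their numerators as probabilities, so the matching
# denominator is the divisor-n variance.
pop_var <- function(x) {
  x <- as.numeric(x)
  mean((x - mean(x))^2)
}

clamp01 <- function(x) pmin(1, pmax(0, x))

# Deterministic child seeds below 2^31 derived from a root seed and integer
# keys, so any (condition, replication) can be regenerated in isolation.
child_seed <- function(root, ...) {
  keys <- c(...)
  s <- as.double(root) %% 2147483647
  for (k in keys) {
    s <- (s * 48271 + as.double(k) + 1) %% 2147483647
  }
  as.integer(s)
}

# Coerce a scores data frame to an integer matrix, validating the 0..m range.
as_score_matrix <- function(data, m = 4L) {
  if (is.matrix(data)) data <- as.data.frame(data)
  if (!is.data.frame(data)) abort("`data` must be a data frame or matrix of item scores.")
  x <- as.matrix(data)
  if (!is.numeric(x)) abort("All score columns must be numeric integer scores.")
  if (nrow(x) < 1L) abort("Score matrix has no rows.")
  bad <- which(x != round(x) | x < 0 | x > m, arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    abort(sprintf(
      "Score at row %d, column %d (value %s) is not an integer in 0..%d.",
      bad[1, 1], bad[1, 2], format(x[bad[1, , drop = FALSE]]), m
    ))
  }
  storage.mode(x) <- "integer"
  x
}

# Resolve the designated single-item column; default is the last column.
resolve_single_col <- function(x, single_col = NULL) {
  if (is.null(single_col)) return(ncol(x))
  if (is.character(single_col)) {
    if (identical(single_col, "last")) return(ncol(x))
    idx <- match(single_col, colnames(x))
    if (is.na(idx)) abort(sprintf("Column '%s' not found in score matrix.", single_col))
    return(idx)
  }
  idx <- as.integer(single_col)
  if (idx < 1L || idx > ncol(x)) abort("`single_col` is out of range.")
  idx
}

new_reliability_estimate <- function(method, value, diagnostics = list()) {
  raw <- value
  structure(
    list(method = method, estimate = clamp01(value), raw = raw,
         diagnostics = diagnostics),
    class = "sirel_estimate"
  )
}

#' @export
print.sirel_estimate <- function(x, ...) {
  cat(sprintf("<single-item reliability estimate [%s]>\n", x$method))
  cat(sprintf("  estimate: %.4f", x$estimate))
  if (!isTRUE(all.equal(x$estimate, x$raw))) cat(sprintf(" (pre-clamp %.4f)", x$raw))
  cat("\n")
  invisible(x)
}

#' Tidy a single-item reliability estimate
#'
#' @param x A `sirel_estimate` object.
#' @param ... Unused.
#' @return A one-row tibble with `method`, `estimate` and the pre-clamp value.
#' @method tidy sirel_estimate
#' @export
tidy.sirel_estimate <- function(x, ...) {
  tibble::tibble(method = x$method, estimate = x$estimate, raw = x$raw)
}

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance
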