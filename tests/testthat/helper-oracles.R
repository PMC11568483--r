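# Independent oracles used across tests. These are deliberately written as
# plain loops / closed forms, separate from the package's vectorized paths.

# Gauss-Hermite quadrature reliability of a graded-response item with slope
# `a` and thresholds `b` under a standard-normal trait.
gh_reliability <- function(a, b, nodes = 61) {
  gh <- pracma::gaussHermite(nodes)
  th <- sqrt(2) * gh$x
  w <- gh$w / sqrt(pi)
  cum <- plogis(outer(th * a, b, `-`))
  ex <- rowSums(cum)                       # E[X | theta]
  m1 <- sum(w * ex)
  vT <- sum(w * ex^2) - m1^2
  ex2 <- as.numeric(cum %*% (2 * seq_along(b) - 1))  # E[X^2 | theta]
  vX <- sum(w * ex2) - m1^2
  list(rel = vT / vX, vT = vT, vX = vX)
}

# Brute-force marginal cumulative probabilities by explicit counting.
brute_marginals <- function(scores, m) {
  out <- NULL
  for (j in seq_len(ncol(scores))) {
    for (lv in 0:m) {
      cnt <- 0
      for (i in seq_len(nrow(scores))) if (scores[i, j] >= lv) cnt <- cnt + 1
      out <- rbind(out, data.frame(item = colnames(scores)[j], level = lv,
                                   pi = cnt / nrow(scores)))
    }
  }
  out
}

# Brute-force outlier percentage via explicit quartile interpolation.
brute_outlier_pct <- function(v) {
  s <- sort(v)
  n <- length(s)
  qt <- function(p) {
    h <- (n - 1) * p + 1
    lo <- floor(h)
    s[lo] + (h - lo) * (s[min(lo + 1, n)] - s[lo])
  }
  q1 <- qt(0.25); q3 <- qt(0.75); iqr <- q3 - q1
  100 * sum(v < q1 - 1.5 * iqr | v > q3 + 1.5 * iqr) / n
}

# Textbook Kruskal-Wallis H with tie correction.
brute_kw <- function(groups) {
  v <- unlist(groups)
  g <- rep(seq_along(groups), lengths(groups))
  N <- length(v)
  r <- rank(v)
  H <- 12 / (N * (N + 1)) * sum(tapply(r, g, sum)^2 / lengths(groups)) - 3 * (N + 1)
  tie <- table(v)
  H / (1 - sum(tie^3 - tie) / (N^3 - N))
}

# Normal-equations least squares.
brute_ols <- function(X, y) {
  qr.solve(crossprod(X), crossprod(X, y))
}

# A fully independent, loop-based implementation of the
# double-monotonicity reliability for small score matrices: brute-force
# marginals, ordering, the eight neighbor equations, clipping and the
# joint-probability reliability sum.
brute_dmm <- function(scores, single_col, m) {
  n <- nrow(scores)
  L1 <- ncol(scores)
  pairs <- list()
  for (j in seq_len(L1)) for (lv in 1:m) {
    p <- sum(scores[, j] >= lv) / n
    if (p > 0 && p < 1) pairs[[length(pairs) + 1]] <- list(item = j, level = lv, pi = p)
  }
  pis <- sapply(pairs, `[[`, "pi")
  its <- sapply(pairs, `[[`, "item")
  lvs <- sapply(pairs, `[[`, "level")
  ord <- order(pis, its, lvs)
  pis <- pis[ord]; its <- its[ord]; lvs <- lvs[ord]
  K <- length(pis)
  J <- matrix(NA_real_, K, K)
  for (r in 1:K) for (cc in 1:K) {
    if (its[r] != its[cc]) {
      J[r, cc] <- sum(scores[, its[r]] >= lvs[r] & scores[, its[cc]] >= lvs[cc]) / n
    }
  }
  get_obs <- function(r, cc) {
    if (r < 1 || r > K || cc < 1 || cc > K) return(NA)
    if (its[r] == its[cc]) return(NA)
    J[r, cc]
  }
  filled <- J
  for (r in 1:K) for (cc in 1:K) {
    if (its[r] != its[cc]) next
    Pr <- pis[r]; Pc <- pis[cc]
    Plo <- get_obs(r + 1, cc); Pri <- get_obs(r, cc + 1)
    Pup <- get_obs(r - 1, cc); Ple <- get_obs(r, cc - 1)
    Pr1 <- if (r < K) pis[r + 1] else NA
    Pc1 <- if (cc < K) pis[cc + 1] else NA
    Pr0 <- if (r > 1) pis[r - 1] else NA
    Pc0 <- if (cc > 1) pis[cc - 1] else NA
    es <- c()
    if (!is.na(Plo)) es <- c(es, Plo * Pr / Pr1,
                             (Plo * (1 - Pr) - Pc * (Pr1 - Pr)) / (1 - Pr1))
    if (!is.na(Pri)) es <- c(es, Pri * Pc / Pc1,
                             (Pri * (1 - Pc) - Pr * (Pc1 - Pc)) / (1 - Pc1))
    if (!is.na(Pup)) es <- c(es, Pup * Pr / Pr0,
                             (Pup * (1 - Pr) + Pc * (Pr - Pr0)) / (1 - Pr0))
    if (!is.na(Ple)) es <- c(es, Ple * Pc / Pc0,
                             (Ple * (1 - Pc) + Pr * (Pc - Pc0)) / (1 - Pc0))
    lo <- Pr * Pc; hi <- min(Pr, Pc)
    raw <- if (length(es) == 0) (lo + hi) / 2 else mean(es)
    filled[r, cc] <- min(hi, max(lo, raw))
  }
  filled <- (filled + t(filled)) / 2
  idx <- which(its == single_col)
  num <- 0
  for (r in idx) for (cc in idx) num <- num + filled[r, cc] - pis[r] * pis[cc]
  x <- scores[, single_col]
  s2 <- mean((x - mean(x))^2)
  min(1, max(0, num / s2))
}

# Small helper: a seeded simulated dataset for a given condition.
sim_condition <- function(condition, seed = 1) {
  set.seed(seed)
  pm <- draw_item_params(condition, "multi")
  ps <- draw_item_params(condition, "single")
  simulate_scores(condition, pm, ps)
}
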