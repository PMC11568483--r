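test_that("marginal cumulative probabilities match brute-force counting", {
  set.seed(21)
  sc <- data.frame(a = sample(0:4, 10, TRUE), b = sample(0:4, 10, TRUE),
                   c = sample(0:4, 10, TRUE))
  got <- cumulative_marginals(sc)
  want <- brute_marginals(as.matrix(sc), 4)
  merged <- merge(got, want, by = c("item", "level"))
  expect_equal(merged$pi.x, merged$pi.y)
  # pi_0 = 1 always
  expect_true(all(got$pi[got$level == 0] == 1))
  # non-increasing in level
  for (it in unique(got$item)) {
    p <- got$pi[got$item == it][order(got$level[got$item == it])]
    expect_true(all(diff(p) <= 0))
  }
  # saturation: everyone at the top category
  sat <- cumulative_marginals(data.frame(z = rep(4L, 8)))
  expect_true(all(sat$pi == 1))
})

test_that("the worked-example grid is ordered and flagged as printed", {
  jm <- load_fixture("mokken_4item")$payload
  expect_s3_class(jm, "sirel_joint_matrix")
  expect_equal(length(jm$marginals), 8L)
  expect_equal(jm$marginals, seq(0.2, 0.9, by = 0.1))
  # ascending rank: items 4,3,2,1 at level 2, then 4,3,2,1 at level 1
  expect_equal(jm$items, paste0("item_", c(4:1, 4:1)))
  expect_equal(jm$levels, rep(2:1, each = 4))
  expect_equal(sum(!jm$observed), 16L)
  # symmetric in value and observability
  expect_identical(jm$observed, t(jm$observed))
  expect_equal(jm$values, t(jm$values))
})

test_that("neighbor estimates at the worked-example cell match hand arithmetic", {
  jm <- load_fixture("mokken_4item")$payload
  ne <- neighbor_estimates(jm, 1, 5)
  # P_up does not exist; P_lo = 0.3, P_le = 0.2, P_ri = 0.2
  expect_false("up" %in% ne$neighbor)
  expect_equal(ne$estimate[ne$neighbor == "lo" & ne$form == "direct"],
               0.3 * (0.2 / 0.3))
  expect_equal(ne$estimate[ne$neighbor == "le" & ne$form == "direct"],
               0.2 * (0.6 / 0.5))
  lo <- ne$estimate[ne$neighbor == "lo" & ne$form == "direct"]
  expect_equal(lo, 0.2, tolerance = 1e-12)
})

test_that("the worked-example cell estimate is clipped into its admissible interval", {
  jm <- load_fixture("mokken_4item")$payload
  est <- estimate_cell(jm, 1, 5)
  expect_equal(est$lower, 0.2 * 0.6)
  expect_equal(est$upper, 0.2)
  # the mean of the six evaluable estimates is ~0.21, above the upper bound
  expect_equal(est$raw_mean, 0.21142857142857, tolerance = 1e-10)
  expect_true(est$clipped)
  expect_equal(est$estimate, 0.2)
})

test_that("clipping floors at the product and is idempotent inside the bounds", {
  # two independent-ish items: synthetic grid where the raw mean lands inside
  jm <- load_fixture("mokken_4item")$payload
  filled <- fill_joint_matrix(jm)
  # every filled cell respects [P_r P_c, min(P_r, P_c)]
  for (r in 1:8) for (cc in 1:8) {
    if (jm$observed[r, cc]) next
    v <- filled$values[r, cc]
    expect_gte(v, jm$marginals[r] * jm$marginals[cc] - 1e-12)
    expect_lte(v, min(jm$marginals[r], jm$marginals[cc]) + 1e-12)
  }
  # fill of an already-complete matrix is a no-op
  expect_equal(fill_joint_matrix(filled)$values, filled$values)
  # symmetric to numerical precision
  expect_lt(max(abs(filled$values - t(filled$values))), 1e-12)
})

test_that("vectorized fill agrees with the per-cell estimator", {
  set.seed(17)
  sc <- sim_condition(4, seed = 17)
  jm <- build_joint_matrix(sc)
  filled <- fill_joint_matrix(jm)
  todo <- which(!jm$observed, arr.ind = TRUE)
  for (k in seq_len(nrow(todo))) {
    r <- todo[k, 1]; cc <- todo[k, 2]
    a <- estimate_cell(jm, r, cc)$estimate
    b <- estimate_cell(jm, cc, r)$estimate
    expect_equal(filled$values[r, cc], (a + b) / 2, tolerance = 1e-12)
  }
})

test_that("joint matrices of independent items approximate the product of marginals", {
  set.seed(33)
  n <- 1e5
  sc <- as.data.frame(matrix(sample(0:2, n * 4, TRUE,
                                    prob = c(0.3, 0.4, 0.3)), n, 4))
  jm <- build_joint_matrix(sc, m = 2L)
  prod_oracle <- outer(jm$marginals, jm$marginals)
  diffs <- abs(jm$values - prod_oracle)[jm$observed]
  expect_lt(max(diffs), 0.01)
  expect_equal(jm$values, t(jm$values))
})

test_that("hide-and-recover estimates land in their admissible interval", {
  set.seed(8)
  sc <- sim_condition(1, seed = 8)
  jm <- build_joint_matrix(sc)
  obs_cells <- which(jm$observed & row(jm$observed) != col(jm$observed), arr.ind = TRUE)
  picks <- obs_cells[sample(nrow(obs_cells), 20), , drop = FALSE]
  for (k in seq_len(nrow(picks))) {
    r <- picks[k, 1]; cc <- picks[k, 2]
    masked <- jm
    masked$observed[r, cc] <- FALSE
    masked$observed[cc, r] <- FALSE
    est <- estimate_cell(masked, r, cc)
    expect_gte(est$estimate, jm$marginals[r] * jm$marginals[cc] - 1e-12)
    expect_lte(est$estimate, min(jm$marginals[r], jm$marginals[cc]) + 1e-12)
  }
})

test_that("DMM reliability matches the loop-based enumeration oracle", {
  # small hand fixture: 5 persons, 3 items, scores 0..2
  sc <- data.frame(i1 = c(0L, 1L, 2L, 2L, 1L),
                   i2 = c(0L, 0L, 1L, 2L, 1L),
                   i3 = c(1L, 0L, 2L, 2L, 0L))
  got <- dmm_reliability(sc, single_col = 3, m = 2L)
  want <- brute_dmm(as.matrix(sc), 3, 2)
  expect_equal(got$estimate, want, tolerance = 1e-12)
  # and on larger simulated data
  for (seed in 1:3) {
    scs <- sim_condition(1, seed = seed)
    got <- dmm_reliability(scs)
    want <- brute_dmm(as.matrix(scs), ncol(scs), 4)
    expect_equal(got$estimate, want, tolerance = 1e-10)
  }
})

test_that("a product-form joint table yields zero reliability", {
  jm <- load_fixture("mokken_4item")$payload
  prod_jm <- new_joint_matrix(outer(jm$marginals, jm$marginals),
                              matrix(TRUE, 8, 8), jm$marginals,
                              jm$items, jm$levels)
  idx <- which(prod_jm$items == "item_4")
  num <- sum(prod_jm$values[idx, idx] -
               outer(prod_jm$marginals[idx], prod_jm$marginals[idx]))
  expect_equal(num, 0)
})

test_that("DMM reliability is invariant to multi-item column order", {
  set.seed(71)
  sc <- sim_condition(2, seed = 71)
  base <- dmm_reliability(sc)$estimate
  perm <- sc[, c(sample(1:12), 13)]
  expect_equal(dmm_reliability(perm)$estimate, base, tolerance = 1e-12)
})

test_that("degenerate single items are rejected", {
  sc <- sim_condition(1, seed = 2)
  sc$single_item <- 0L
  expect_error(dmm_reliability(sc), "zero variance")
})

test_that("population-level fill is near-exact under double monotonicity", {
  # Build the exact joint cumulative probability matrix of an equally
  # discriminating unidimensional scale plus a single item with the same
  # slope, by Gauss-Hermite quadrature, and check that the neighbor-based
  # fill recovers the true same-item joints and hence the true reliability.
  gh <- pracma::gaussHermite(61)
  th <- sqrt(2) * gh$x
  w <- gh$w / sqrt(pi)
  set.seed(90)
  L <- 12
  b1 <- runif(L + 1, -4.2, 0)
  badv <- runif(L + 1, 1.4, 2.5)
  curves <- lapply(seq_len(L + 1), function(i) {
    plogis(outer(th, b1[i] + (0:3) * badv[i], `-`))
  })
  items <- c(paste0("item_", sprintf("%02d", seq_len(L))), "single")
  pairs <- data.frame(item = rep(items, each = 4), i = rep(seq_len(L + 1), each = 4),
                      level = rep(1:4, L + 1))
  pairs$pi <- mapply(function(i, lv) sum(w * curves[[i]][, lv]), pairs$i, pairs$level)
  pairs <- pairs[pairs$pi > 1e-6 & pairs$pi < 1 - 1e-6, ]
  pairs <- pairs[order(pairs$pi, pairs$item, pairs$level), ]
  K <- nrow(pairs)
  C <- vapply(seq_len(K), function(k) curves[[pairs$i[k]]][, pairs$level[k]],
              numeric(61))
  V_true <- crossprod(C, w * C)
  obs <- outer(pairs$i, pairs$i, `!=`)
  V <- V_true; V[!obs] <- NA
  jm <- new_joint_matrix(V, obs, pairs$pi, pairs$item, pairs$level)
  filled <- fill_joint_matrix(jm)
  idx <- which(pairs$item == "single")
  num_true <- sum(V_true[idx, idx] - outer(pairs$pi[idx], pairs$pi[idx]))
  num_fill <- sum(filled$values[idx, idx] - outer(pairs$pi[idx], pairs$pi[idx]))
  cv <- curves[[L + 1]]
  ex <- rowSums(cv); ex2 <- as.numeric(cv %*% c(1, 3, 5, 7))
  vX <- sum(w * ex2) - sum(w * ex)^2
  expect_lt(abs(num_fill / vX - num_true / vX), 0.01)
})
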