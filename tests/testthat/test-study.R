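test_that("outlier percentage follows the boxplot rule", {
  expect_equal(outlier_pct(c(1, 2, 3, 4, 100)), 20)
  expect_equal(outlier_pct(rep(2, 10)), 0)
  expect_error(outlier_pct(c(1, 2, 3)), "at least 4")
  set.seed(40)
  for (i in 1:25) {
    v <- rnorm(50 + i)
    expect_equal(outlier_pct(v), brute_outlier_pct(v))
  }
  # symmetric data flag the same count on each side
  v <- c(-50, seq(-1, 1, length.out = 20), 50)
  q <- quantile(v, c(0.25, 0.75)); iqr <- diff(q)
  expect_equal(sum(v < q[1] - 1.5 * iqr), sum(v > q[2] + 1.5 * iqr))
})

test_that("condition summaries match hand-computed statistics", {
  bias <- c(-0.12, -0.05, 0.01, -0.08, -0.03, -0.15, 0.02, -0.06, -0.09, -0.04)
  rho <- 0.5
  res <- tibble::tibble(condition = 1L, rep = 1:10, method = "CA",
                        estimate = rho + bias, true_rel = rho, bias = bias,
                        rel_bias = bias / rho, status = "ok")
  s <- summarize_condition(res)
  expect_equal(s$median_bias, median(bias))
  expect_equal(s$iqr_bias, unname(diff(quantile(bias, c(0.25, 0.75)))))
  expect_equal(s$median_rel_bias, median(bias) / rho)
  expect_equal(s$rmse, sd(abs(bias)))
  expect_equal(s$rms_error, sqrt(mean(bias^2)))
  # outlier flags agree between bias and relative bias when truth > 0
  expect_equal(outlier_pct(bias), outlier_pct(bias / rho))
  # a perfect estimator zeroes every metric
  perf <- dplyr::mutate(res, bias = 0, rel_bias = 0, estimate = rho)
  sp <- summarize_condition(perf)
  expect_true(all(c(sp$median_bias, sp$iqr_bias, sp$rmse, sp$outlier_pct) == 0))
})

test_that("replication bookkeeping: determinism, pairing, and identities", {
  args <- list(conditions = c(1L, 19L), n_reps = 3L, methods = c("ca", "l6"),
               root_seed = 77L, n_true_draws = 1e4)
  r1 <- do.call(run_study, args)
  r2 <- do.call(run_study, args)
  expect_identical(as.data.frame(r1), as.data.frame(r2))
  expect_equal(nrow(r1), 2L * 3L * 2L)
  # paired conditions share the same true reliability
  expect_equal(unique(r1$true_rel[r1$condition == 1]),
               unique(r1$true_rel[r1$condition == 19]))
  # relative bias times truth is bias
  ok <- r1[r1$status == "ok", ]
  expect_equal(ok$rel_bias * ok$true_rel, ok$bias, tolerance = 1e-12)
})

test_that("Kruskal-Wallis H matches the rank-formula oracle", {
  g0 <- list(a = c(1, 2, 3), b = c(4, 5, 6), c = c(7, 8, 9))
  kw <- kruskal_wallis(g0)
  expect_equal(kw$H, brute_kw(g0), tolerance = 1e-10)
  expect_equal(kw$df, 2L)
  # five identical groups: no rank separation
  same <- replicate(5, rep(1, 10), simplify = FALSE)
  kw0 <- kruskal_wallis(same)
  expect_equal(kw0$H, 0)
  expect_equal(kw0$p, 1)
  expect_equal(kruskal_wallis(replicate(5, rnorm(5), simplify = FALSE))$df, 4L)
  set.seed(41)
  for (i in 1:50) {
    gs <- lapply(1:sample(2:5, 1), function(j) round(rnorm(sample(5:20, 1)), 2))
    expect_equal(kruskal_wallis(gs)$H, brute_kw(gs), tolerance = 1e-10)
  }
})

test_that("Dunn post-hoc comparisons behave as expected", {
  same <- list(a = rep(1, 6), b = rep(1, 6))
  ph0 <- posthoc_pairwise(same)
  expect_true(all(ph0$p_adj == 1))
  set.seed(42)
  gs <- list(a = rnorm(30), b = rnorm(30), c = rnorm(30, 0.2),
             d = rnorm(30, 5), e = rnorm(30, 5.2))
  ph <- posthoc_pairwise(gs)
  expect_true(all(ph$p_adj >= ph$p))
  # the clearly separated pairs get the smallest adjusted p
  worst <- ph[which.min(ph$p_adj), ]
  expect_true(worst$group1 %in% c("a", "b", "c") && worst$group2 %in% c("d", "e"))
})

test_that("method selection applies discard, dominance and tie rules", {
  mk_results <- function(biases) {
    purrr::imap_dfr(biases, function(b, m) {
      tibble::tibble(condition = 1L, rep = seq_along(b), method = m,
                     estimate = 0.5 + b, true_rel = 0.5, bias = b,
                     rel_bias = b / 0.5, status = "ok")
    })
  }
  set.seed(43)
  base <- rnorm(200, 0, 0.02)
  # DMM dominates: smallest |median|, same spread
  res <- mk_results(list(CA = base - 0.10, FA = base - 0.11, DMM = base,
                         L6 = base - 0.12, LCM = base - 0.105))
  s <- summarize_condition(res)
  sel <- select_most_precise(s, res)
  expect_equal(sel$selected, "DMM")
  expect_equal(sel$kw$df, 4L)
  # a method with > 5% outliers is discarded even if unbiased
  spiky <- base
  spiky[1:14] <- spiky[1:14] + 1
  res2 <- mk_results(list(CA = base - 0.05, FA = base - 0.06, DMM = spiky,
                          L6 = base - 0.12, LCM = base - 0.11))
  s2 <- summarize_condition(res2)
  expect_gt(s2$outlier_pct[s2$method == "DMM"], 5)
  sel2 <- select_most_precise(s2, res2)
  expect_false("DMM" %in% sel2$selected)
  expect_true("DMM" %in% sel2$discarded)
  # statistically indistinguishable near-equal medians select both
  res3 <- mk_results(list(CA = base - 0.001, FA = rev(base) + 0.002, DMM = base - 0.2,
                          L6 = base - 0.25, LCM = base - 0.22))
  s3 <- summarize_condition(res3)
  sel3 <- select_most_precise(s3, res3)
  expect_setequal(sel3$selected, c("CA", "FA"))
})

test_that("bias regressions match the normal-equations oracle", {
  set.seed(44)
  grid <- condition_grid()
  res <- tidyr::expand_grid(condition = grid$condition, rep = 1:3,
                            method = c("CA", "FA", "DMM", "L6", "LCM"))
  res$true_rel <- 0.5
  res$bias <- rnorm(nrow(res), -0.05, 0.03)
  res$rel_bias <- res$bias / 0.5
  res$estimate <- 0.5 + res$bias
  res$status <- "ok"
  for (mid in 1:3) {
    tab <- glm_bias_analysis(res, mid)
    des <- sirel:::glm_design(res, mid)
    keep <- setdiff(colnames(des$X), attr(tab, "aliased"))
    oracle <- brute_ols(des$X[, keep], des$y)
    expect_equal(unname(tab$estimate), as.numeric(oracle), tolerance = 1e-8)
  }
  # model 1 includes 8 length-by-correlation interaction columns
  des1 <- sirel:::glm_design(res, 1)
  expect_equal(sum(grepl(":", colnames(des1$X))), 8L)
  expect_equal(sum(grepl(":", colnames(sirel:::glm_design(res, 2)$X))), 5L)
  expect_equal(sum(grepl(":", colnames(sirel:::glm_design(res, 3)$X))), 5L)
  # constant bias: intercept only
  resc <- dplyr::mutate(res, bias = -0.07)
  tabc <- suppressWarnings(glm_bias_analysis(resc, 1))
  expect_equal(tabc$estimate[tabc$term == "(Intercept)"], -0.07, tolerance = 1e-10)
  expect_lt(max(abs(tabc$estimate[tabc$term != "(Intercept)"])), 1e-10)
})

test_that("summaries are deterministic given the results table", {
  res <- run_study(conditions = 1L, n_reps = 5L, methods = c("ca", "dmm"),
                   root_seed = 5L, n_true_draws = 1e4)
  expect_identical(summarize_condition(res), summarize_condition(res))
})
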