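# The Monte Carlo study: for each condition, item parameters are drawn
# once per (length, discrimination, rho) cell and shared by the two sample
# sizes, the single item's true reliability is computed by Monte Carlo,
# datasets are replicated, and every estimator is applied to each dataset.

study_methods <- c("ca", "fa", "dmm", "l6", "lcm")
method_labels <- c(ca = "CA", fa = "FA", dmm = "DMM", l6 = "L6", lcm = "LCM")

# Parameters for one design cell, reproducible from the root seed and the
# cell id alone (shared across the two sample sizes of a pair).
cell_params <- function(cell_id, root_seed, m = 4L) {
  grid <- condition_grid()
  cond <- grid[grid$condition == cell_id, ]
  set.seed(child_seed(root_seed, 1L, cell_id))
  list(
    multi = draw_item_params(cond, "multi", m = m),
    single = draw_item_params(cond, "single", m = m)
  )
}

#' Run the estimator-comparison simulation study
#'
#' For each requested condition: draw item parameters (fixed per
#' (length, discrimination, rho) cell, so paired sample-size conditions
#' share parameters and true reliability), compute the single item's true
#' reliability by Monte Carlo, simulate `n_reps` datasets, and apply each
#' estimation method. Estimator failures are recorded with a status, not
#' dropped.
#'
#' @param conditions Condition ids (default all 36).
#' @param n_reps Replications per condition.
#' @param methods Methods to apply (subset of ca, fa, dmm, l6, lcm).
#' @param root_seed Root seed; independent child seeds are derived per
#'   design cell and per (condition, replication).
#' @param n_true_draws Monte Carlo draws for the true reliability.
#' @param lcm_q `"auto_per_condition"` (select Q by BIC on the first
#'   replication of each condition and reuse it), `"auto"` (select per
#'   dataset) or a fixed integer.
#' @param lcm_n_starts,lcm_max_iter,lcm_tol EM settings used inside the
#'   study.
#' @param m Maximum score level.
#' @param progress Print one line per condition to stderr.
#' @return A tibble of class `sirel_results` with columns `condition`,
#'   `rep`, `method`, `estimate`, `true_rel`, `bias`, `rel_bias`,
#'   `status`; the root seed is kept in attribute `root_seed`.
#' @export
run_study <- function(conditions = 1:36, n_reps = 1000L,
                      methods = study_methods, root_seed = 20240101L,
                      n_true_draws = 1e6, lcm_q = "auto_per_condition",
                      lcm_n_starts = 10L, lcm_max_iter = 1000L,
                      lcm_tol = 1e-6, m = 4L, progress = FALSE) {
  if (n_reps < 2L) abort("`n_reps` must be at least 2.")
  methods <- match.arg(tolower(methods), study_methods, several.ok = TRUE)
  grid <- condition_grid()
  res <- purrr::map_dfr(conditions, function(cid) {
    cond <- get_condition(cid)
    cell <- condition_cell_id(cid)
    params <- cell_params(cell, root_seed, m = m)
    set.seed(child_seed(root_seed, 2L, cell))
    truth <- true_reliability(params$single, n_draws = n_true_draws)
    if (progress) {
      message(sprintf("condition=%d cell=%d true_rel=%.4f seed=%d",
                      cid, cell, truth$rho_ii, root_seed))
    }
    q_cond <- lcm_q
    rows <- purrr::map_dfr(seq_len(n_reps), function(rep_i) {
      set.seed(child_seed(root_seed, 3L, cid, rep_i))
      scores <- simulate_scores(cond, params$multi, params$single)
      if ("lcm" %in% methods && identical(q_cond, "auto_per_condition")) {
        q_cond <<- lcm_select_Q(scores, n_starts = lcm_n_starts,
                                max_iter = lcm_max_iter, tol = lcm_tol, m = m)
      }
      purrr::map_dfr(methods, function(mm) {
        est <- tryCatch(
          switch(mm,
            ca = ca_reliability(scores, m = m),
            fa = fa_reliability(scores, m = m),
            dmm = dmm_reliability(scores, m = m),
            l6 = lambda6_reliability(scores, m = m),
            lcm = lcm_reliability(scores, Q = q_cond, n_starts = lcm_n_starts,
                                  max_iter = lcm_max_iter, tol = lcm_tol, m = m)
          ),
          error = function(e) e
        )
        if (inherits(est, "error")) {
          tibble::tibble(condition = cid, rep = rep_i,
                         method = method_labels[[mm]], estimate = NA_real_,
                         true_rel = truth$rho_ii, bias = NA_real_,
                         rel_bias = NA_real_,
                         status = paste0("error: ", conditionMessage(est)))
        } else {
          b <- est$estimate - truth$rho_ii
          tibble::tibble(condition = cid, rep = rep_i,
                         method = method_labels[[mm]], estimate = est$estimate,
                         true_rel = truth$rho_ii, bias = b,
                         rel_bias = b / truth$rho_ii, status = "ok")
        }
      })
    })
    rows
  })
  attr(res, "root_seed") <- root_seed
  class(res) <- c("sirel_results", class(res))
  res
}

#' Select the most precise estimation method(s) in one condition
#'
#' The selection rule: (1) methods with more than `discard_pct` percent
#' outliers are discarded; (2) among the survivors whose deviation profile
#' (IQR, RMSE, outlier percentage) is comparable to the best observed, the
#' method with the smallest absolute median bias wins; (3) if the runner-up
#' is also deviation-comparable and its median bias is not significantly
#' different by the Dunn post-hoc test, both are selected; (4) exact ties
#' are broken by ease of use (CA easiest, then FA, L6, DMM, LCM).
#' "Comparable deviation" means IQR within `iqr_tol`, RMSE within
#' `rmse_tol`, and outlier percentage within `outlier_tol` points of the
#' best survivor on each metric.
#'
#' @param summary A [summarize_condition()] tibble for one condition.
#' @param results The replication results for the same condition (used for
#'   the Kruskal-Wallis and post-hoc tests).
#' @param discard_pct Outlier-percentage discard threshold.
#' @param iqr_tol,rmse_tol,outlier_tol Comparable-deviation tolerances.
#' @param alpha Significance level for the post-hoc comparison.
#' @return A list with `selected` (character vector), `discarded`,
#'   `kw` (H, df, p) and `posthoc` (pairwise table), `flagged` (TRUE when
#'   every method was discarded and the fallback was used).
#' @export
select_most_precise <- function(summary, results, discard_pct = 5,
                                iqr_tol = 0.01, rmse_tol = 0.005,
                                outlier_tol = 1, alpha = 0.05) {
  stopifnot(length(unique(summary$condition)) == 1L)
  ok <- dplyr::filter(results, .data$status == "ok",
                      .data$condition == summary$condition[1])
  groups <- split(ok$bias, ok$method)[summary$method]
  kw <- kruskal_wallis(groups)
  ph <- posthoc_pairwise(groups)
  discarded <- summary$method[summary$outlier_pct > discard_pct]
  surv <- dplyr::filter(summary, !.data$method %in% discarded)
  flagged <- FALSE
  if (nrow(surv) == 0L) {
    sel <- summary$method[which.min(summary$outlier_pct)]
    return(list(selected = sel, discarded = discarded, kw = kw, posthoc = ph,
                flagged = TRUE))
  }
  comparable <- surv$iqr_bias <= min(surv$iqr_bias) + iqr_tol &
    surv$rmse <= min(surv$rmse) + rmse_tol &
    surv$outlier_pct <= min(surv$outlier_pct) + outlier_tol
  cand <- surv[comparable, , drop = FALSE]
  if (nrow(cand) == 0L) cand <- surv
  ease <- c(CA = 1, FA = 2, L6 = 3, DMM = 4, LCM = 5)
  ord <- order(abs(cand$median_bias), ease[cand$method])
  cand <- cand[ord, , drop = FALSE]
  selected <- cand$method[1]
  if (nrow(cand) >= 2L) {
    top2 <- sort(cand$method[1:2])
    pr <- dplyr::filter(ph, (.data$group1 == top2[1] & .data$group2 == top2[2]) |
                          (.data$group1 == top2[2] & .data$group2 == top2[1]))
    tie_exact <- isTRUE(all.equal(abs(cand$median_bias[1]),
                                  abs(cand$median_bias[2])))
    if (!tie_exact && nrow(pr) == 1L && pr$p_adj[1] > alpha) {
      selected <- cand$method[1:2]
    }
  }
  list(selected = selected, discarded = discarded, kw = kw, posthoc = ph,
       flagged = flagged)
}

#' Run the method selection for every condition in a results table
#'
#' @param results A `sirel_results` tibble.
#' @param ... Passed to [select_most_precise()].
#' @return A tibble with one row per condition: `condition`, `selected`
#'   (list-column), `n_selected`, `discarded` (list-column), `kw_H`,
#'   `kw_p`.
#' @export
select_all_conditions <- function(results, ...) {
  summ <- summarize_condition(results)
  purrr::map_dfr(unique(summ$condition), function(cid) {
    s <- dplyr::filter(summ, .data$condition == cid)
    sel <- select_most_precise(s, results, ...)
    tibble::tibble(condition = cid, selected = list(sel$selected),
                   n_selected = length(sel$selected),
                   discarded = list(sel$discarded),
                   kw_H = sel$kw$H, kw_p = sel$kw$p)
  })
}

# Dummy-coded design matrix for the bias regressions. Main effects use the
# reference levels method CA, short scale, equal discrimination, rho 0.65,
# n 400. The interaction block enumerates level combinations of the two
# interacting factors except the reference-by-reference cell, which makes
# the design rank-deficient together with the main effects; aliased
# columns are dropped from the fit and reported.
glm_design <- function(results, model_id) {
  grid <- condition_grid()
  d <- dplyr::left_join(results, grid, by = "condition")
  X <- tibble::tibble(
    `(Intercept)` = 1,
    method_FA = as.numeric(d$method == "FA"),
    method_DMM = as.numeric(d$method == "DMM"),
    method_L6 = as.numeric(d$method == "L6"),
    method_LCM = as.numeric(d$method == "LCM"),
    medium_length = as.numeric(d$length_label == "medium"),
    long_length = as.numeric(d$length_label == "long"),
    unequal_disc = as.numeric(d$discrimination == "unequal"),
    r_0.75 = as.numeric(d$rho == 0.75),
    r_0.85 = as.numeric(d$rho == 0.85),
    large_n = as.numeric(d$n == 1000)
  )
  combo <- function(f1, l1, f2, l2, name) {
    X[[name]] <<- as.numeric(f1 == l1 & f2 == l2)
  }
  if (model_id == 1) {
    for (r in c(0.65, 0.75, 0.85)) for (len in c("short", "medium", "long")) {
      if (r == 0.65 && len == "short") next
      combo(d$rho, r, d$length_label, len, sprintf("r_%.2f:%s_length", r, len))
    }
  } else if (model_id == 2) {
    for (disc in c("equal", "unequal")) for (r in c(0.65, 0.75, 0.85)) {
      if (disc == "equal" && r == 0.65) next
      combo(d$discrimination, disc, d$rho, r, sprintf("%s_disc:r_%.2f", disc, r))
    }
  } else if (model_id == 3) {
    for (disc in c("equal", "unequal")) for (len in c("short", "medium", "long")) {
      if (disc == "equal" && len == "short") next
      combo(d$discrimination, disc, d$length_label, len,
            sprintf("%s_disc:%s_length", disc, len))
    }
  } else {
    abort("`model_id` must be 1, 2 or 3.")
  }
  list(X = as.matrix(X), y = d$bias)
}

#' Regress replication-level bias on the design factors
#'
#' Gaussian identity-link regression of per-replication bias on dummy-coded
#' method and design factors plus one model-specific interaction block:
#' model 1 crosses correlation with scale length, model 2 discrimination
#' with correlation, model 3 discrimination with scale length. Reference
#' levels: method CA, short scale, equal discrimination, rho 0.65, n 400.
#' Columns aliased by the rank-deficient interaction coding are dropped and
#' reported.
#'
#' @param results A `sirel_results` tibble covering the design.
#' @param model_id 1, 2 or 3 (which interaction block to include).
#' @return A tibble with `term`, `estimate`, `std_error`, `statistic`,
#'   `p_value`; dropped aliased terms are listed in attribute `aliased`.
#' @export
glm_bias_analysis <- function(results, model_id = 1) {
  ok <- dplyr::filter(results, .data$status == "ok")
  des <- glm_design(ok, model_id)
  fit <- lm(des$y ~ des$X - 1)
  cf <- summary(fit)$coefficients
  keep <- !is.na(coef(fit))
  terms_all <- colnames(des$X)
  aliased <- terms_all[!keep]
  out <- tibble::tibble(
    term = terms_all[keep],
    estimate = unname(cf[, 1]), std_error = unname(cf[, 2]),
    statistic = unname(cf[, 3]), p_value = unname(cf[, 4])
  )
  attr(out, "aliased") <- aliased
  out
}
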