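#' Estimate single-item reliability by one or more methods
#'
#' Uniform tidy interface over the five estimators: correction for
#' attenuation (`"ca"`), factor-analysis communality (`"fa"`), the double
#' monotonicity joint-probability estimator (`"dmm"`), Guttman's lambda-6
#' (`"l6"`), and the latent class model (`"lcm"`).
#'
#' @param data Data frame of integer item scores: one designated
#'   single-item column, remaining columns the multi-item scale of the
#'   same construct.
#' @param method Character vector of methods, or `"all"`.
#' @param single_col Single-item column (index, name or `"last"`; default
#'   last).
#' @param m Maximum score level (categories 0..m).
#' @param ca_coefficient Scale reliability coefficient for CA.
#' @param lcm_q `"auto"` or a fixed class count for the LCM method.
#' @param ... Further arguments passed to the LCM fitter
#'   (`n_starts`, `tol`, `max_iter`, `Q_max`).
#' @return A tibble with one row per method: `method`, `estimate`, `raw`
#'   (pre-clamp value) and a `diagnostics` list-column.
#' @examples
#' set.seed(1)
#' pm <- draw_item_params(1, "multi")
#' ps <- draw_item_params(1, "single")
#' scores <- simulate_scores(1, pm, ps)
#' estimate_reliability(scores, method = c("ca", "dmm", "l6"))
#' @export
estimate_reliability <- function(data, method = "all", single_col = NULL,
                                 m = 4L, ca_coefficient = "alpha",
                                 lcm_q = "auto", ...) {
  all_methods <- c("ca", "fa", "dmm", "l6", "lcm")
  if (identical(method, "all")) method <- all_methods
  method <- match.arg(tolower(method), all_methods, several.ok = TRUE)
  fits <- purrr::map(method, function(mm) {
    switch(mm,
      ca = ca_reliability(data, single_col, coefficient = ca_coefficient, m = m),
      fa = fa_reliability(data, single_col, m = m),
      dmm = dmm_reliability(data, single_col, m = m),
      l6 = lambda6_reliability(data, single_col, m = m),
      lcm = lcm_reliability(data, single_col, Q = lcm_q, m = m, ...)
    )
  })
  purrr::map_dfr(fits, function(f) {
    tibble::tibble(method = f$method, estimate = f$estimate, raw = f$raw,
                   diagnostics = list(f$diagnostics))
  })
}
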