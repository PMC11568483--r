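# File formats, configuration and shipped fixtures.

#' Read a person x item score matrix from CSV
#'
#' The file must have a header and integer cells in 0..m. One column is
#' designated as the single-item assessment (by default the last).
#'
#' @param path CSV file path.
#' @param single_col Single-item column (index, name or `"last"`).
#' @param m Maximum score level.
#' @return A tibble of integer scores with attributes `single_col` (index),
#'   `n`, `L` (number of multi-item columns) and `m`.
#' @export
read_scores <- function(path, single_col = "last", m = 4L) {
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  for (j in seq_along(raw)) {
    v <- raw[[j]]
    if (!is.numeric(v)) {
      bad <- which(is.na(suppressWarnings(as.numeric(v))) | is.na(v))[1]
      abort(sprintf("Non-numeric cell at row %d, column '%s'.",
                    ifelse(is.na(bad), 1L, bad), names(raw)[j]))
    }
  }
  x <- as_score_matrix(raw, m)   # validates integer range, names rows/cols
  si <- resolve_single_col(x, single_col)
  out <- tibble::as_tibble(as.data.frame(x))
  attr(out, "single_col") <- si
  attr(out, "n") <- nrow(x)
  attr(out, "L") <- ncol(x) - 1L
  attr(out, "m") <- m
  out
}

#' Write a score matrix to CSV
#'
#' @param data Data frame of integer scores.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_scores <- function(data, path) {
  readr::write_csv(tibble::as_tibble(data), path, progress = FALSE)
  invisible(path)
}

#' Load a shipped fixture
#'
#' Available fixtures:
#' * `"mokken_4item"` — the worked-example 4-item, 3-category assessment:
#'   marginal cumulative probabilities (items 1-4: level 1 = 0.9/0.8/0.7/0.6,
#'   level 2 = 0.5/0.4/0.3/0.2) and the 8 x 8 ordered grid of observed joint
#'   cumulative probabilities with 16 unobservable same-item cells. One cell
#'   printed as -0.2 in the source is corrected to 0.2 (its mirror value).
#'   Payload: a `sirel_joint_matrix`.
#' * `"twoclass_lcm"` — a synthetic well-separated two-class generator for
#'   5-point items; payload: generator parameters plus a `simulate(n)`
#'   function (uses the current RNG state).
#' * `"onefactor_fa"` — a synthetic one-factor population correlation matrix
#'   whose last variable has loading 0.7 (communality 0.49).
#'
#' @param name Fixture name.
#' @return A list of class `sirel_fixture` with `name`, `payload`, `note`.
#' @export
load_fixture <- function(name) {
  fixtures <- c("mokken_4item", "twoclass_lcm", "onefactor_fa")
  if (!name %in% fixtures) {
    abort(sprintf("Unknown fixture '%s'. Available: %s.",
                  name, paste(fixtures, collapse = ", ")))
  }
  payload <- switch(name,
    mokken_4item = {
      path <- system.file("extdata", "mokken_4item.csv", package = "sirel")
      tab <- utils::read.csv(path, comment.char = "#")
      vals <- as.matrix(tab[, paste0("c", 1:8)])
      dimnames(vals) <- NULL
      new_joint_matrix(vals, !is.na(vals), tab$marginal,
                       paste0("item_", tab$item), tab$level)
    },
    twoclass_lcm = twoclass_generator(),
    onefactor_fa = onefactor_population(loading_single = 0.7)
  )
  note <- switch(name,
    mokken_4item = "Worked-example marginals and observed joint cells; the printed -0.2 cell corrected to 0.2.",
    twoclass_lcm = "Synthetic two-class generator (not from any published dataset).",
    onefactor_fa = "Synthetic one-factor population correlation matrix (not from any published dataset)."
  )
  structure(list(name = name, payload = payload, note = note),
            class = "sirel_fixture")
}

# Well-separated two-class generator for 5-point items: class 1 favours low
# categories, class 2 high categories. Used for parameter-recovery tests
# and the analytic mixture reliability check.
twoclass_generator <- function() {
  L <- 5L; m <- 4L
  low <- c(0.45, 0.30, 0.15, 0.07, 0.03)
  high <- rev(low)
  item_probs <- array(NA_real_, dim = c(L, 2L, m + 1L))
  for (i in seq_len(L)) {
    # mild per-item variation, still well separated
    shift <- (i - 3) * 0.02
    p1 <- pmax(low + c(shift, 0, 0, 0, -shift), 0.01); p1 <- p1 / sum(p1)
    p2 <- pmax(high + c(-shift, 0, 0, 0, shift), 0.01); p2 <- p2 / sum(p2)
    item_probs[i, 1, ] <- p1
    item_probs[i, 2, ] <- p2
  }
  class_probs <- c(0.6, 0.4)
  simulate <- function(n) {
    cls <- 1L + rbinom(n, 1L, class_probs[2])
    out <- vapply(seq_len(L), function(i) {
      p <- item_probs[i, , ]
      vapply(cls, function(cl) sample(0:m, 1L, prob = p[cl, ]), integer(1))
    }, integer(n))
    out <- tibble::as_tibble(as.data.frame(out))
    names(out) <- c(paste0("item_", seq_len(L - 1L)), "single_item")
    out
  }
  # analytic reliability of the last item: true score is E[X | class]
  p_last <- item_probs[L, , ]
  mu <- as.numeric(p_last %*% (0:m))
  ex2 <- as.numeric(p_last %*% (0:m)^2)
  sigma2_T <- sum(class_probs * mu^2) - sum(class_probs * mu)^2
  sigma2_X <- sum(class_probs * ex2) - sum(class_probs * mu)^2
  list(L = L, m = m, class_probs = class_probs, item_probs = item_probs,
       simulate = simulate, true_reliability = sigma2_T / sigma2_X)
}

# Population correlation matrix of a one-factor model: first `n_scale`
# variables with loading 0.6, the last variable with the given loading.
onefactor_population <- function(n_scale = 6L, loading_scale = 0.6,
                                 loading_single = 0.7) {
  lambda <- c(rep(loading_scale, n_scale), loading_single)
  R <- tcrossprod(lambda)
  diag(R) <- 1
  list(R = R, loadings = lambda, communalities = lambda^2)
}

#' @export
print.sirel_fixture <- function(x, ...) {
  cat(sprintf("<fixture '%s'>\n%s\n", x$name, x$note))
  invisible(x)
}

#' Read a study configuration file
#'
#' YAML configuration overriding the study defaults: `conditions`,
#' `n_reps`, `root_seed`, `n_true_draws`, sampling intervals (`a_range`,
#' `b1_range`, `badv_range`), `rhos`, `ns`, `lengths`, and LCM settings
#' (`lcm_q`, `lcm_n_starts`, `lcm_max_iter`).
#'
#' @param path YAML file path (or `NULL` for pure defaults).
#' @return A named list of settings.
#' @export
read_study_config <- function(path = NULL) {
  defaults <- list(
    conditions = 1:36, n_reps = 1000L, root_seed = 20240101L,
    n_true_draws = 1e6, a_range = c(0.4, 2.8), b1_range = c(-4.2, 0),
    badv_range = c(1.4, 2.5), rhos = c(0.65, 0.75, 0.85),
    ns = c(400L, 1000L), lengths = c(6L, 12L, 18L),
    lcm_q = "auto_per_condition", lcm_n_starts = 10L, lcm_max_iter = 1000L
  )
  if (is.null(path)) return(defaults)
  cfg <- yaml::read_yaml(path)
  bad_range <- function(v) length(v) != 2 || any(!is.finite(v)) || v[1] > v[2]
  for (k in c("a_range", "b1_range", "badv_range")) {
    if (!is.null(cfg[[k]]) && bad_range(as.numeric(cfg[[k]]))) {
      abort(sprintf("Config '%s' must be a finite non-empty interval.", k))
    }
  }
  if (!is.null(cfg$n_reps) && cfg$n_reps < 2) abort("Config 'n_reps' must be >= 2.")
  if (!is.null(cfg$root_seed) && cfg$root_seed < 0) abort("Config 'root_seed' must be non-negative.")
  utils::modifyList(defaults, cfg)
}
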