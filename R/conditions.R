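#' The 36-condition simulation design
#'
#' Crossing of multi-item scale length (6, 12, 18 items), discrimination
#' regime of the multi-item scale (equal, i.e. all slopes 1, vs. unequal,
#' slopes drawn from \[0.4, 2.8\]), latent correlation between the construct
#' measured by the multi-item scale and the one measured by the single item
#' (0.65, 0.75, 0.85), and sample size (400, 1000). Conditions 1-18 have
#' n = 400 and 19-36 have n = 1000; within each sample size the correlation
#' varies slowest, then discrimination, then length.
#'
#' @return A tibble with 36 rows and columns `condition`, `length`
#'   (number of multi-item scale items), `length_label`
#'   (short/medium/long), `discrimination` ("equal"/"unequal"), `rho`
#'   (latent correlation), and `n` (persons).
#' @examples
#' condition_grid()
#' @export
condition_grid <- function() {
  lengths <- c(6L, 12L, 18L)
  labels <- c(`6` = "short", `12` = "medium", `18` = "long")
  grid <- expand.grid(
    length = lengths,
    discrimination = c("equal", "unequal"),
    rho = c(0.65, 0.75, 0.85),
    n = c(400L, 1000L),
    KEEP.OUT.ATTRS = FALSE,
    stringsAsFactors = FALSE
  )
  tibble::tibble(
    condition = seq_len(nrow(grid)),
    length = grid$length,
    length_label = unname(labels[as.character(grid$length)]),
    discrimination = grid$discrimination,
    rho = grid$rho,
    n = grid$n
  )
}

# Cell index shared by the two sample sizes of the same (length,
# discrimination, rho) triple: item parameters and hence the true
# reliability are identical for such paired conditions.
condition_cell_id <- function(condition) {
  grid <- condition_grid()
  row <- grid[grid$condition == condition, ]
  if (nrow(row) != 1L) abort("Unknown condition id.")
  ((row$condition - 1L) %% 18L) + 1L
}

get_condition <- function(condition) {
  grid <- condition_grid()
  row <- grid[grid$condition == condition, ]
  if (nrow(row) != 1L) abort(sprintf("Condition must be an id in 1..36, got %s.", condition))
  row
}
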