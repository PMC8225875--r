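#' Deterministic gain table over a grid of schemes
#'
#' Evaluates [predict_gain()] for every row of a strategy grid and returns a
#' table in the style of published gain/cost summaries: strategy, selection
#' pressures, prediction accuracy, percent and absolute gain per cycle,
#' program cost, cost per percent gain and parents generated.
#'
#' @param vc a [variance_components()] object.
#' @param design a [trial_design()] object.
#' @param base_mean base population mean (trait units).
#' @param grid a data frame with columns `strategy`, `p_among` and optionally
#'   `p_within`, `r_A` (defaults 0).
#' @param book optional [cost_book()]; when supplied, cost columns are
#'   filled, otherwise they are `NA`.
#' @param n_genotyped_per_family within-family candidates genotyped per
#'   selected family.
#' @return A data frame with one row per grid cell, full precision. Rows
#'   whose scheme is invalid (e.g. a `Wgs` strategy without `p_within`) are
#'   dropped with a warning.
#' @examples
#' vc <- variance_components(14170, 2222, 13406, 38511, 221768)
#' d <- trial_design(2, 3, 2, 3, 200)
#' grid <- data.frame(strategy = c("A_p", "A_Ph"), p_among = 0.20)
#' gain_table(vc, d, 3262, grid)
#' @export
gain_table <- function(vc, design, base_mean, grid, book = NULL,
                       n_genotyped_per_family = 100L) {
  stopifnot(is.data.frame(grid))
  if (nrow(grid) == 0) stop("'grid' is empty")
  if (is.null(grid$p_within)) grid$p_within <- NA_real_
  if (is.null(grid$r_A)) grid$r_A <- 0

  rows <- vector("list", nrow(grid))
  bad <- character()
  for (k in seq_len(nrow(grid))) {
    g <- grid[k, ]
    res <- tryCatch({
      pw <- if (is.na(g$p_within)) NULL else g$p_within
      sc <- selection_scheme(g$strategy, p_among = g$p_among, p_within = pw,
                             r_A = g$r_A,
                             n_genotyped_per_family = n_genotyped_per_family)
      pred <- predict_gain(vc, sc, base_mean, design)
      np <- parents_count(design$n_families, g$p_among,
                          n_genotyped_per_family,
                          if (sc$strategy %in% c("A_pWgs", "A_PhWgs",
                                                 "A_gsWgs")) pw else NULL)
      cost <- if (!is.null(book)) cycle_cost(sc, design, book) else NA_real_
      cpg <- if (!is.null(book) && pred$delta_g_pct > 0)
        cost_per_percent_gain(cost, pred$delta_g_pct) else NA_real_
      data.frame(strategy = sc$strategy, p_among = g$p_among,
                 p_within = ifelse(is.na(g$p_within), NA, g$p_within),
                 r_A = g$r_A,
                 pct_gain = pred$delta_g_pct, abs_gain = pred$delta_g_abs,
                 annual_pct = pred$annual_pct, cost = cost,
                 cost_per_pct = cpg, n_parents = np)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      bad <- c(bad, sprintf("row %d (%s): %s", k, g$strategy,
                            conditionMessage(res)))
    } else rows[[k]] <- res
  }
  if (length(bad))
    warning("dropped invalid grid rows:\n  ", paste(bad, collapse = "\n  "))
  out <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  if (is.null(out) || nrow(out) == 0) stop("no valid grid rows")
  rownames(out) <- NULL
  out
}

#' Write a gain table to CSV, rounded for reporting
#'
#' Percent and absolute gains are rounded to 2 decimals to match standard
#' reporting precision; a companion `*_full.csv` keeps full precision.
#'
#' @param tab a data frame from [gain_table()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_gain_table <- function(tab, path) {
  full <- sub("\\.csv$", "_full.csv", path)
  write.csv(tab, full, row.names = FALSE)
  for (col in c("pct_gain", "abs_gain", "annual_pct", "cost_per_pct"))
    if (col %in% names(tab)) tab[[col]] <- round(tab[[col]], 2)
  write.csv(tab, path, row.names = FALSE)
  invisible(path)
}
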