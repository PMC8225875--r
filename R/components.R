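#' Variance components of a half-sib family trial
#'
#' Container for the among-family and family-by-environment variance
#' components (kg^2 ha^-2 for dry-matter yield) that parameterize the
#' deterministic gain engine. Under random mating with inbreeding coefficient
#' F = 0, the among-HS-family component `fam_var` estimates 1/4 of the
#' additive genetic variance; the engine uses it directly as the
#' "1/4 sigma2_A" numerator of the among-family response, and
#' `2 * sqrt(fam_var)` as the additive standard deviation for within-family
#' genomic selection terms.
#'
#' @param fam_var among-HS-family variance component (>= 0).
#' @param fam_x_year,fam_x_season,fam_x_location family-by-year, -season and
#'   -location interaction components (>= 0).
#' @param residual residual (plot) variance component (>= 0).
#' @return An object of class `variance_components` (named list).
#' @examples
#' vc <- variance_components(14170, 2222, 13406, 38511, 221768)
#' vc
#' @export
variance_components <- function(fam_var, fam_x_year, fam_x_season,
                                fam_x_location, residual) {
  x <- list(fam_var = fam_var, fam_x_year = fam_x_year,
            fam_x_season = fam_x_season, fam_x_location = fam_x_location,
            residual = residual)
  for (nm in names(x)) {
    v <- x[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 0)
      stop("'", nm, "' must be a single finite non-negative number")
  }
  structure(x, class = "variance_components")
}

#' @export
print.variance_components <- function(x, ...) {
  cat("Half-sib family variance components:\n")
  lab <- c(fam_var = "among-family", fam_x_year = "family x year",
           fam_x_season = "family x season", fam_x_location = "family x location",
           residual = "residual")
  for (nm in names(lab))
    cat(sprintf("  %-18s %12.1f\n", lab[[nm]], x[[nm]]))
  invisible(x)
}

#' Evaluation trial design
#'
#' The layout over which HS family means are estimated: locations, seasons,
#' years and replicates, plus the number of families entered.
#'
#' @param n_locations,n_seasons,n_years,n_reps counts (>= 1) of locations,
#'   seasons per year, years, and replicates.
#' @param n_families number of HS families evaluated (>= 1).
#' @return An object of class `trial_design`.
#' @examples
#' trial_design(n_locations = 2, n_seasons = 3, n_years = 2, n_reps = 3,
#'              n_families = 200)
#' @export
trial_design <- function(n_locations, n_seasons, n_years, n_reps,
                         n_families = 1L) {
  x <- list(n_locations = n_locations, n_seasons = n_seasons,
            n_years = n_years, n_reps = n_reps, n_families = n_families)
  for (nm in names(x)) {
    v <- x[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 1)
      stop("'", nm, "' must be a count >= 1")
  }
  structure(lapply(x, as.integer), class = "trial_design")
}

#' @export
print.trial_design <- function(x, ...) {
  cat(sprintf(
    "Trial design: %d families, %d locations x %d seasons x %d years x %d reps\n",
    x$n_families, x$n_locations, x$n_seasons, x$n_years, x$n_reps))
  invisible(x)
}

#' Selection scheme for one breeding cycle
#'
#' Describes one of the five HS family breeding strategies:
#' \describe{
#'   \item{`A_p`}{among-family phenotypic selection (herbage cuts).}
#'   \item{`A_Ph`}{among-family selection on phenomics-derived yield
#'     (LiDAR platform, accuracy `ph_accuracy`).}
#'   \item{`A_pWgs`}{among-family phenotypic selection plus within-family
#'     genomic selection on GEBVs.}
#'   \item{`A_PhWgs`}{as `A_pWgs` with phenomics-based among-family data.}
#'   \item{`A_gsWgs`}{both among- and within-family selection on GEBVs
#'     (no field trial; one-year cycle).}
#' }
#'
#' @param strategy one of `"A_p"`, `"A_Ph"`, `"A_pWgs"`, `"A_PhWgs"`,
#'   `"A_gsWgs"`.
#' @param p_among among-family selected fraction, in (0, 1].
#' @param p_within within-family selected fraction, in (0, 1]; required for
#'   the `Wgs` strategies.
#' @param r_A genomic prediction accuracy (correlation between
#'   phenotype-derived breeding values and GEBVs), in \[0, 1\].
#' @param h_X square root of the heritability of the secondary (selection)
#'   trait; 1 for GEBV-based selection.
#' @param c_f,c_w among- and within-family parental control factors; 0.5 when
#'   selection acts through female gametes only.
#' @param ph_accuracy phenomics accuracy, used by `A_Ph` and `A_PhWgs`.
#' @param cycle_years length of the selection cycle in years (3 for
#'   field-trial strategies, 1 for `A_gsWgs`).
#' @param n_genotyped_per_family individuals genotyped per selected family in
#'   `Wgs` strategies (within-family candidates).
#' @return An object of class `selection_scheme`.
#' @examples
#' selection_scheme("A_pWgs", p_among = 0.02, p_within = 0.01, r_A = 0.46)
#' @export
selection_scheme <- function(strategy = c("A_p", "A_Ph", "A_pWgs", "A_PhWgs",
                                          "A_gsWgs"),
                             p_among, p_within = NULL, r_A = 0,
                             h_X = 1, c_f = 0.5, c_w = 0.5,
                             ph_accuracy = 0.90,
                             cycle_years = NULL,
                             n_genotyped_per_family = 100L) {
  strategy <- match.arg(strategy)
  chk_frac <- function(v, nm, lo0 = FALSE) {
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("'", nm, "' must be a single finite number")
    if (v > 1 || (lo0 && v < 0) || (!lo0 && v <= 0))
      stop("'", nm, "' out of range")
  }
  chk_frac(p_among, "p_among")
  uses_within <- strategy %in% c("A_pWgs", "A_PhWgs", "A_gsWgs")
  if (uses_within) {
    if (is.null(p_within))
      stop("'p_within' is required for strategy ", strategy)
    chk_frac(p_within, "p_within")
  }
  chk_frac(r_A, "r_A", lo0 = TRUE)
  chk_frac(h_X, "h_X", lo0 = TRUE)
  chk_frac(ph_accuracy, "ph_accuracy", lo0 = TRUE)
  if (is.null(cycle_years))
    cycle_years <- if (strategy == "A_gsWgs") 1L else 3L
  if (cycle_years < 1) stop("'cycle_years' must be >= 1")
  structure(list(strategy = strategy, p_among = p_among, p_within = p_within,
                 r_A = r_A, h_X = h_X, c_f = c_f, c_w = c_w,
                 ph_accuracy = ph_accuracy, cycle_years = cycle_years,
                 n_genotyped_per_family = as.integer(n_genotyped_per_family)),
            class = "selection_scheme")
}

#' @export
print.selection_scheme <- function(x, ...) {
  cat(sprintf("Selection scheme %s: among %g%%", x$strategy, 100 * x$p_among))
  if (!is.null(x$p_within)) cat(sprintf(", within %g%%", 100 * x$p_within))
  cat(sprintf(", r_A = %g, cycle = %d yr\n", x$r_A, x$cycle_years))
  invisible(x)
}
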