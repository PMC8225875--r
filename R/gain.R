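#' Standardized selection intensity for truncation selection
#'
#' The mean, in standard-deviation units, of the upper fraction `p` of a
#' standard normal distribution: `i = dnorm(qnorm(1 - p)) / p`. This is the
#' infinite-population form, with no finite-sample (order-statistic)
#' correction.
#'
#' @param p selected fraction, in (0, 1]. Vectorized.
#' @return Selection intensity (dimensionless), 0 when `p = 1`.
#' @examples
#' selection_intensity(c(0.20, 0.10, 0.05, 0.02, 0.01))
#' @export
selection_intensity <- function(p) {
  if (!is.numeric(p) || any(!is.finite(p)) || any(p <= 0) || any(p > 1))
    stop("'p' must be in (0, 1]")
  dnorm(qnorm(1 - p)) / p
}

#' Phenotypic standard deviation among family means
#'
#' The standard deviation of HS family means under the evaluation design:
#' `sqrt(fam + fxl/n_l + fxs/n_s + fxy/n_y + residual/(n_l*n_s*n_y*n_r))`.
#' Interaction components are diluted by the number of levels they are
#' averaged over and the residual by the total number of plots per family.
#'
#' @param vc a [variance_components()] object.
#' @param design a [trial_design()] object.
#' @return Standard deviation among family means (trait units).
#' @export
family_mean_sd <- function(vc, design) {
  stopifnot(inherits(vc, "variance_components"),
            inherits(design, "trial_design"))
  d <- design
  sqrt(vc$fam_var +
         vc$fam_x_location / d$n_locations +
         vc$fam_x_season / d$n_seasons +
         vc$fam_x_year / d$n_years +
         vc$residual / (d$n_locations * d$n_seasons * d$n_years * d$n_reps))
}

#' Narrow-sense heritability on a family-mean basis
#'
#' Ratio of the among-family variance to the variance of family means under
#' the trial design (see [family_mean_sd()]). With the among-HS-family
#' component estimating 1/4 of the additive variance, this is the
#' narrow-sense heritability of family means.
#'
#' @inheritParams family_mean_sd
#' @return Heritability in \[0, 1\].
#' @examples
#' vc <- variance_components(22345, 4102, 12942, 58532, 159453)
#' d <- trial_design(2, 3, 2, 3, 1000)
#' heritability_family_mean(vc, d) # ~0.36
#' @export
heritability_family_mean <- function(vc, design) {
  s2 <- family_mean_sd(vc, design)^2
  if (s2 <= 0) stop("phenotypic variance among family means is zero")
  vc$fam_var / s2
}

#' Predicted response to among-family phenotypic selection
#'
#' Breeder's-equation response for one cycle of among-HS-family truncation
#' selection on family means: `i(p) * c * fam_var / sigma_PF`, where
#' `fam_var` (the among-family component, = 1/4 additive variance) is the
#' heritable numerator and `sigma_PF` the phenotypic SD among family means.
#'
#' @inheritParams family_mean_sd
#' @param p_among among-family selected fraction, in (0, 1].
#' @param c_f parental control factor (0.5 for selection on female gametes
#'   only).
#' @return Absolute gain in trait units per cycle.
#' @export
gain_among_phenotypic <- function(vc, design, p_among, c_f = 0.5) {
  selection_intensity(p_among) * c_f * vc$fam_var / family_mean_sd(vc, design)
}

#' Predicted response to within-family genomic selection
#'
#' The within-HS-family genomic selection term:
#' `i(p_within) * c_w * h_X * r_A * (sqrt(3)/2) * sigma_A`, with
#' `sigma_A = 2 * sqrt(fam_var)` the additive standard deviation and
#' `sqrt(3)/2` the fraction of the additive SD segregating within HS
#' families (3/4 of the additive variance lies within families).
#'
#' @param vc a [variance_components()] object.
#' @param p_within within-family selected fraction, in (0, 1].
#' @param r_A genomic prediction accuracy in \[0, 1\].
#' @param h_X square root of the selection-trait heritability (1 for GEBVs).
#' @param c_w within-family parental control factor.
#' @return Absolute gain in trait units per cycle; 0 when `r_A = 0`.
#' @export
gain_within_gs <- function(vc, p_within, r_A, h_X = 1, c_w = 0.5) {
  sigma_A <- 2 * sqrt(vc$fam_var)
  selection_intensity(p_within) * c_w * h_X * r_A * (sqrt(3) / 2) * sigma_A
}

#' Predict genetic gain for one cycle of an HS breeding strategy
#'
#' Evaluates the deterministic gain prediction for any of the five HS family
#' strategies (see [selection_scheme()]):
#' * `A_p`: among-family phenotypic response only;
#' * `A_Ph`: `A_p` scaled by the phenomics accuracy;
#' * `A_pWgs`: among-family phenotypic response plus within-family GEBV
#'   response;
#' * `A_PhWgs`: `A_pWgs` total scaled by the phenomics accuracy;
#' * `A_gsWgs`: among-family GEBV response
#'   `i(p_among) * c_f * h_X * r_A * sigma_A / 2` plus the same within-family
#'   GEBV term (no field trial; `design` unused).
#'
#' @param vc a [variance_components()] object.
#' @param scheme a [selection_scheme()] object.
#' @param base_mean population mean the gain is expressed against (trait
#'   units; the current cycle's base population mean).
#' @param design a [trial_design()] object; required for strategies with a
#'   phenotypic among-family step.
#' @return An object of class `gain_prediction`: absolute gain, percent gain,
#'   annualized percent gain, base mean and the scheme.
#' @examples
#' vc200 <- variance_components(14170, 2222, 13406, 38511, 221768)
#' d <- trial_design(2, 3, 2, 3, 200)
#' sc <- selection_scheme("A_pWgs", p_among = 0.02, p_within = 0.01, r_A = 0.46)
#' predict_gain(vc200, sc, base_mean = 3262, design = d) # 6.35 % per cycle
#' @export
predict_gain <- function(vc, scheme, base_mean, design = NULL) {
  stopifnot(inherits(vc, "variance_components"),
            inherits(scheme, "selection_scheme"))
  if (!is.numeric(base_mean) || base_mean <= 0)
    stop("'base_mean' must be positive")
  s <- scheme
  needs_design <- s$strategy %in% c("A_p", "A_Ph", "A_pWgs", "A_PhWgs")
  if (needs_design && !inherits(design, "trial_design"))
    stop("'design' is required for strategy ", s$strategy)

  among_ph <- if (needs_design)
    gain_among_phenotypic(vc, design, s$p_among, s$c_f) else 0
  within <- if (s$strategy %in% c("A_pWgs", "A_PhWgs", "A_gsWgs"))
    gain_within_gs(vc, s$p_within, s$r_A, s$h_X, s$c_w) else 0

  abs_gain <- switch(s$strategy,
    A_p = among_ph,
    A_Ph = among_ph,           # phenomics accuracy applied below
    A_pWgs = among_ph + within,
    A_PhWgs = among_ph + within,
    A_gsWgs = {
      sigma_A <- 2 * sqrt(vc$fam_var)
      selection_intensity(s$p_among) * s$c_f * s$h_X * s$r_A * sigma_A / 2 +
        within
    })

  res <- new_gain_prediction(abs_gain, base_mean, s)
  if (s$strategy %in% c("A_Ph", "A_PhWgs"))
    res <- apply_phenomics(res, s$ph_accuracy)
  res
}

new_gain_prediction <- function(abs_gain, base_mean, scheme) {
  structure(list(
    delta_g_abs = abs_gain,
    delta_g_pct = 100 * abs_gain / base_mean,
    base_mean = base_mean,
    annual_pct = 100 * abs_gain / base_mean / scheme$cycle_years,
    cycle_years = scheme$cycle_years,
    scheme = scheme), class = "gain_prediction")
}

#' Scale a gain prediction by phenomics accuracy
#'
#' Multiplies the total predicted gain by the accuracy of the phenomics
#' phenotyping platform (correlation of the phenomics-derived yield with
#' harvested yield). The scaling applies to the whole predicted gain,
#' including any within-family genomic term.
#'
#' @param gain a `gain_prediction` object.
#' @param accuracy phenomics accuracy in \[0, 1\].
#' @return The rescaled `gain_prediction`.
#' @export
apply_phenomics <- function(gain, accuracy) {
  stopifnot(inherits(gain, "gain_prediction"))
  if (!is.numeric(accuracy) || accuracy < 0 || accuracy > 1)
    stop("'accuracy' must be in [0, 1]")
  gain$delta_g_abs <- gain$delta_g_abs * accuracy
  gain$delta_g_pct <- gain$delta_g_pct * accuracy
  gain$annual_pct <- gain$annual_pct * accuracy
  gain
}

#' @export
print.gain_prediction <- function(x, digits = 2, ...) {
  cat(sprintf(
    "Predicted gain (%s): %.*f trait units/cycle = %.*f%% of base %.0f (%.*f%%/yr)\n",
    x$scheme$strategy, digits, x$delta_g_abs, digits, x$delta_g_pct,
    x$base_mean, digits, x$annual_pct))
  invisible(x)
}

#' Chain gain predictions across selection cycles
#'
#' Accumulates per-cycle predictions: each cycle's base mean must equal the
#' previous base mean plus the previous absolute gain (the progeny mean).
#' Total percent gain is the sum of per-cycle percent gains (each relative to
#' its own cycle's base mean); costs, if supplied, sum.
#'
#' @param cycles a list of `gain_prediction` objects in cycle order.
#' @param costs optional numeric vector of per-cycle program costs.
#' @param tol relative tolerance for checking base-mean chaining.
#' @return A list: `total_pct`, `total_abs`, `final_mean`, `total_years`,
#'   `total_cost` (if costs supplied) and a per-cycle data frame.
#' @examples
#' vc <- variance_components(14170, 2222, 13406, 38511, 221768)
#' d <- trial_design(2, 3, 2, 3, 200)
#' c1 <- predict_gain(vc, selection_scheme("A_pWgs", 0.20, 0.10, r_A = 0.26),
#'                    base_mean = 3262, design = d)
#' c2 <- predict_gain(vc, selection_scheme("A_gsWgs", 0.20, 0.10, r_A = 0.26),
#'                    base_mean = 3262 + c1$delta_g_abs)
#' chain_cycles(list(c1, c2))$total_pct # 4.93
#' @export
chain_cycles <- function(cycles, costs = NULL, tol = 1e-6) {
  if (!is.list(cycles) || length(cycles) == 0)
    stop("'cycles' must be a non-empty list of gain predictions")
  stopifnot(all(vapply(cycles, inherits, TRUE, "gain_prediction")))
  if (!is.null(costs) && length(costs) != length(cycles))
    stop("'costs' must have one entry per cycle")
  for (k in seq_along(cycles)[-1]) {
    expected <- cycles[[k - 1]]$base_mean + cycles[[k - 1]]$delta_g_abs
    if (abs(cycles[[k]]$base_mean - expected) > tol * max(1, abs(expected)))
      stop("cycle ", k, " base mean (", cycles[[k]]$base_mean,
           ") does not equal previous mean + gain (", expected, ")")
  }
  tab <- data.frame(
    cycle = seq_along(cycles),
    strategy = vapply(cycles, function(x) x$scheme$strategy, ""),
    base_mean = vapply(cycles, `[[`, 0, "base_mean"),
    delta_g_abs = vapply(cycles, `[[`, 0, "delta_g_abs"),
    delta_g_pct = vapply(cycles, `[[`, 0, "delta_g_pct"),
    cycle_years = vapply(cycles, `[[`, 0, "cycle_years"))
  out <- list(total_pct = sum(tab$delta_g_pct),
              total_abs = sum(tab$delta_g_abs),
              final_mean = tab$base_mean[nrow(tab)] +
                tab$delta_g_abs[nrow(tab)],
              total_years = sum(tab$cycle_years),
              cycles = tab)
  if (!is.null(costs)) {
    out$total_cost <- sum(costs)
    out$cycles$cost <- costs
  }
  out
}

#' Number of parents generated by a selection scheme
#'
#' Families selected = `round(n_families * p_among)` (round half up). For
#' strategies with a within-family genomic step the parent count is
#' `selected families x round(n_genotyped_per_family * p_within)`; for pure
#' among-family selection (`A_p`, `A_Ph`) one parental family is counted per
#' selected family (random remnant-seed sampling does not change the count of
#' selected units).
#'
#' @param n_families families evaluated.
#' @param p_among among-family selected fraction.
#' @param n_genotyped_per_family within-family candidates genotyped per
#'   selected family (`Wgs` strategies).
#' @param p_within within-family selected fraction, or `NULL` for `A_p`-type
#'   random within-family sampling.
#' @return Integer parent count.
#' @examples
#' parents_count(200, 0.20)                     # 40
#' parents_count(200, 0.02, 100, 0.01)          # 4
#' parents_count(1000, 0.20, 100, 0.10)         # 2000
#' @export
parents_count <- function(n_families, p_among, n_genotyped_per_family = NULL,
                          p_within = NULL) {
  round_half_up <- function(x) floor(x + 0.5)
  n_sel <- round_half_up(n_families * p_among)
  if (n_sel < 1) stop("selection pressure leaves zero families selected")
  if (is.null(p_within)) return(as.integer(n_sel))
  k <- round_half_up(n_genotyped_per_family * p_within)
  if (k < 1) stop("within-family pressure leaves zero individuals selected")
  as.integer(n_sel * k)
}
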