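#' Specification of a mock half-sib trial
#'
#' Defines the generating model for a synthetic balanced HS family trial:
#' every plot record is the overall mean, plus fixed location/season/year
#' shifts, plus independent normal draws for each random term at its
#' generating variance (family, family-by-location/season/year, optional
#' replicate/row/column, residual). A row-by-column layout is generated
#' within each replicate; its variances default to 0.
#'
#' @param design a [trial_design()] (counts of locations, seasons, years,
#'   reps and families).
#' @param components a [variance_components()] with the generating values.
#' @param mean overall trait mean.
#' @param loc_effects,season_effects,year_effects optional fixed-effect
#'   shifts (defaults 0).
#' @param rep_var,row_var,col_var blocking variances (defaults 0).
#' @param n_rows rows per replicate for the field layout (columns are
#'   derived from the family count).
#' @param seed RNG seed (required).
#' @return An object of class `mock_trial_spec`.
#' @export
mock_trial_spec <- function(design, components, mean = 3300,
                            loc_effects = NULL, season_effects = NULL,
                            year_effects = NULL,
                            rep_var = 0, row_var = 0, col_var = 0,
                            n_rows = 10L, seed) {
  stopifnot(inherits(design, "trial_design"),
            inherits(components, "variance_components"))
  if (missing(seed)) stop("'seed' is required")
  zero_or <- function(x, n) if (is.null(x)) rep(0, n) else rep_len(x, n)
  structure(list(
    design = design, components = components, mean = mean,
    loc_effects = zero_or(loc_effects, design$n_locations),
    season_effects = zero_or(season_effects, design$n_seasons),
    year_effects = zero_or(year_effects, design$n_years),
    rep_var = rep_var, row_var = row_var, col_var = col_var,
    n_rows = as.integer(n_rows), seed = as.integer(seed)),
    class = "mock_trial_spec")
}

#' Generate a balanced mock half-sib trial
#'
#' Draws a complete balanced data set under the [mock_trial_spec()] model.
#' Identical seeds produce identical output.
#'
#' @param spec a [mock_trial_spec()].
#' @return A data frame of plot records: `family`, `location`, `season`,
#'   `year`, `rep`, `row`, `col`, `value`.
#' @examples
#' spec <- mock_trial_spec(trial_design(2, 3, 2, 3, 50),
#'                         variance_components(14170, 2222, 13406, 38511,
#'                                             221768), seed = 1)
#' head(generate_trial(spec))
#' @export
generate_trial <- function(spec) {
  stopifnot(inherits(spec, "mock_trial_spec"))
  set.seed(spec$seed)
  d <- spec$design
  nf <- d$n_families; nl <- d$n_locations; ns <- d$n_seasons
  ny <- d$n_years; nr <- d$n_reps
  vc <- spec$components

  g <- expand.grid(family = seq_len(nf), location = seq_len(nl),
                   season = seq_len(ns), year = seq_len(ny),
                   rep = seq_len(nr))
  # field layout: families laid out row-major within each replicate
  n_rows <- min(spec$n_rows, nf)
  n_cols <- ceiling(nf / n_rows)
  g$row <- ((g$family - 1) %/% n_cols) + 1L
  g$col <- ((g$family - 1) %% n_cols) + 1L

  rn <- function(n, v) if (v > 0) rnorm(n, 0, sqrt(v)) else numeric(n)
  f <- rn(nf, vc$fam_var)
  fl <- matrix(rn(nf * nl, vc$fam_x_location), nf)
  fs <- matrix(rn(nf * ns, vc$fam_x_season), nf)
  fy <- matrix(rn(nf * ny, vc$fam_x_year), nf)
  b <- array(rn(nl * ns * ny * nr, spec$rep_var), c(nl, ns, ny, nr))
  r_ <- array(rn(nl * ns * ny * nr * n_rows, spec$row_var),
              c(nl, ns, ny, nr, n_rows))
  cc <- array(rn(nl * ns * ny * nr * n_cols, spec$col_var),
              c(nl, ns, ny, nr, n_cols))

  g$value <- spec$mean +
    spec$loc_effects[g$location] + spec$season_effects[g$season] +
    spec$year_effects[g$year] +
    f[g$family] +
    fl[cbind(g$family, g$location)] +
    fs[cbind(g$family, g$season)] +
    fy[cbind(g$family, g$year)] +
    b[cbind(g$location, g$season, g$year, g$rep)] +
    r_[cbind(g$location, g$season, g$year, g$rep, g$row)] +
    cc[cbind(g$location, g$season, g$year, g$rep, g$col)] +
    rn(nrow(g), vc$residual)
  g[c("family", "location", "season", "year", "rep", "row", "col", "value")]
}

#' Generate a synthetic founder population
#'
#' Phased diploid genotypes drawn site-by-site at given allele frequencies,
#' in linkage equilibrium and Hardy-Weinberg proportions at founding. By
#' default allele-1 frequencies are drawn Uniform(0.1, 0.9) per marker.
#'
#' @param spec a [genome_spec()].
#' @param n number of founder individuals (>= 2).
#' @param freq optional numeric vector of allele-1 frequencies per marker;
#'   `NULL` to draw Uniform(0.1, 0.9).
#' @param seed RNG seed (required).
#' @return An `hs_population` of `n` unrelated founders (one family label).
#' @export
generate_founders <- function(spec, n = 98L, freq = NULL, seed) {
  if (missing(seed)) stop("'seed' is required")
  if (n < 2) stop("need at least 2 founders")
  set.seed(seed)
  m <- spec$n_markers
  if (is.null(freq)) freq <- runif(m, 0.1, 0.9)
  freq <- rep_len(freq, m)
  hap1 <- matrix(as.raw(rbinom(m * n, 1L, freq)), m, n)
  hap2 <- matrix(as.raw(rbinom(m * n, 1L, freq)), m, n)
  new_population(hap1, hap2, family = seq_len(n) * 0L + 1L)
}

#' Build a half-sib training population from founders
#'
#' Polycrosses the founders (every founder a mother, pollen pool all
#' founders, no selfing) into one HS family per founder, then draws
#' `family_draws` random individuals per family: 98 founders with 2 draws
#' gives a 196-plant training population, with 10 draws a 980-plant one.
#'
#' @param founders an `hs_population` of founders.
#' @param spec a [genome_spec()].
#' @param family_draws individuals kept per HS family (>= 1).
#' @param family_size progeny generated per family before drawing (must be
#'   >= `family_draws`).
#' @param seed RNG seed (required).
#' @return An `hs_population` with `n_founders * family_draws` individuals,
#'   family labels by maternal parent.
#' @export
build_training_population <- function(founders, spec, family_draws,
                                      family_size = max(10L, family_draws),
                                      seed) {
  if (missing(seed)) stop("'seed' is required")
  if (family_draws < 1) stop("'family_draws' must be >= 1")
  if (family_draws > family_size)
    stop("'family_draws' exceeds the generated family size")
  set.seed(seed)
  n <- n_individuals(founders)
  prog <- polycross(founders, spec, mothers = seq_len(n),
                    progeny_per_mother = family_size)
  keep <- unlist(lapply(split(seq_along(prog$family), prog$family),
                        function(ix) ix[sample.int(length(ix),
                                                   family_draws)]))
  new_population(prog$hap1[, keep, drop = FALSE],
                 prog$hap2[, keep, drop = FALSE],
                 family = prog$family[keep])
}
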