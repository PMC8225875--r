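# Shared fixtures: published-scale variance components and trial design.

vc200 <- function() variance_components(
  fam_var = 14170, fam_x_year = 2222, fam_x_season = 13406,
  fam_x_location = 38511, residual = 221768)

vc1000 <- function() variance_components(
  fam_var = 22345, fam_x_year = 4102, fam_x_season = 12942,
  fam_x_location = 58532, residual = 159453)

design232 <- function(n_families = 200L)
  trial_design(n_locations = 2, n_seasons = 3, n_years = 2, n_reps = 3,
               n_families = n_families)

# Independent oracle for the truncation-selection intensity: numerical
# integration of the upper-tail mean of a standard normal.
intensity_oracle <- function(p) {
  q <- qnorm(1 - p)
  stats::integrate(function(z) z * dnorm(z), q, Inf,
                   rel.tol = 1e-12)$value / p
}

# Small genome + founders for genome-level tests.
tiny_genome <- function(n_markers = 120, n_qtl = 30, seed = 7,
                        positive_effects = FALSE) {
  g <- simulate_genome(n_markers = n_markers, n_qtl = n_qtl, n_chr = 3,
                       chr_len = 80, seed = seed)
  if (positive_effects) g$qtl_eff <- abs(g$qtl_eff)
  g
}

# A uniform population fixed at given alleles on hap1/hap2.
constant_population <- function(n_markers, n_ind, a1 = 1L, a2 = 0L) {
  hs_population(matrix(as.raw(a1), n_markers, n_ind),
                matrix(as.raw(a2), n_markers, n_ind))
}
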