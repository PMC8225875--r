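#' Genome specification: map, markers and QTL effects
#'
#' A multi-chromosome genetic map of biallelic markers, a subset of which
#' are additive QTLs. Effects are expressed for allele 1; the favourable
#' allele at a QTL is allele 1 when its effect is positive, allele 0
#' otherwise.
#'
#' @param chr integer chromosome (linkage group) index per marker.
#' @param pos map position per marker in cM, non-decreasing within a
#'   chromosome.
#' @param qtl_idx indices of the markers that are QTLs.
#' @param qtl_eff additive effect of allele 1 at each QTL (trait units per
#'   allele copy).
#' @return An object of class `genome_spec`.
#' @seealso [simulate_genome()] to draw a random map and effects.
#' @export
genome_spec <- function(chr, pos, qtl_idx, qtl_eff) {
  m <- length(pos)
  if (length(chr) != m) stop("'chr' and 'pos' lengths differ")
  if (any(qtl_idx < 1 | qtl_idx > m)) stop("'qtl_idx' out of range")
  if (length(qtl_eff) != length(qtl_idx))
    stop("'qtl_eff' must match 'qtl_idx'")
  if (any(!is.finite(qtl_eff))) stop("QTL effects must be finite")
  o <- order(chr, pos)
  if (any(o != seq_len(m)))
    stop("markers must be ordered by chromosome then position")
  for (c_ in unique(chr)) {
    p <- pos[chr == c_]
    if (any(diff(p) < 0)) stop("positions must be non-decreasing")
  }
  structure(list(chr = as.integer(chr), pos = as.numeric(pos),
                 qtl_idx = as.integer(qtl_idx),
                 qtl_eff = as.numeric(qtl_eff),
                 n_markers = m, n_chr = length(unique(chr))),
            class = "genome_spec")
}

#' @export
print.genome_spec <- function(x, ...) {
  cat(sprintf(
    "Genome: %d markers on %d linkage groups (%.0f cM total), %d QTLs\n",
    x$n_markers, x$n_chr,
    sum(tapply(x$pos, x$chr, function(p) diff(range(p)))),
    length(x$qtl_idx)))
  invisible(x)
}

#' Draw a random genome specification
#'
#' Markers are placed uniformly on each linkage group; a random subset are
#' QTLs with effects drawn from `N(0, effect_sd^2)`. Defaults emulate a
#' forage-grass genome: 1807 markers on 7 linkage groups of 100 cM, 474 of
#' them additive QTLs.
#'
#' @param n_markers total marker count.
#' @param n_qtl number of QTL markers.
#' @param n_chr number of linkage groups.
#' @param chr_len length of each linkage group in cM (recycled).
#' @param effect_sd SD of QTL effects (trait units).
#' @param seed RNG seed (required: every stochastic entry point is seeded).
#' @return A [genome_spec()] object.
#' @export
simulate_genome <- function(n_markers = 1807L, n_qtl = 474L, n_chr = 7L,
                            chr_len = 100, effect_sd = 1, seed) {
  if (missing(seed)) stop("'seed' is required")
  set.seed(seed)
  chr_len <- rep_len(chr_len, n_chr)
  per <- diff(round(seq(0, n_markers, length.out = n_chr + 1)))
  chr <- rep(seq_len(n_chr), per)
  pos <- unlist(lapply(seq_len(n_chr),
                       function(c_) sort(runif(per[c_], 0, chr_len[c_]))))
  qtl_idx <- sort(sample.int(n_markers, n_qtl))
  genome_spec(chr, pos, qtl_idx, rnorm(n_qtl, 0, effect_sd))
}

#' Rescale QTL effects to a target cycle-0 additive variance
#'
#' Under linkage equilibrium the additive variance is
#' `sum(2 p (1 - p) a^2)` over QTLs, with `p` the allele-1 frequency.
#' Effects are scaled by a common factor so this equals `target_var` at the
#' supplied population's frequencies.
#'
#' @param spec a [genome_spec()].
#' @param pop an `hs_population` whose QTL allele frequencies define `p`.
#' @param target_var target additive variance (trait units^2).
#' @return The rescaled `genome_spec`.
#' @export
scale_qtl_effects <- function(spec, pop, target_var) {
  p <- allele_freq(pop)[spec$qtl_idx]
  v <- sum(2 * p * (1 - p) * spec$qtl_eff^2)
  if (v <= 0) stop("no segregating QTL variance to scale")
  spec$qtl_eff <- spec$qtl_eff * sqrt(target_var / v)
  spec
}

#' Construct a phased half-sib population
#'
#' Bundles phased haplotype matrices (markers in rows, individuals in
#' columns, alleles coded 0/1) with per-individual half-sib family labels.
#' Haplotypes are stored as raw bytes internally.
#'
#' @param hap1,hap2 integer or raw 0/1 matrices of identical dimension.
#' @param family integer family label per individual.
#' @return An object of class `hs_population`.
#' @export
hs_population <- function(hap1, hap2, family = rep(1L, ncol(hap1))) {
  new_population(hap1, hap2, family)
}

new_population <- function(hap1, hap2, family = rep(1L, ncol(hap1))) {
  stopifnot(identical(dim(hap1), dim(hap2)), length(family) == ncol(hap1))
  # haplotypes are stored as raw (one byte per allele) for memory locality
  as_hap <- function(x) {
    if (is.raw(x)) return(x)
    if (any(x != 0L & x != 1L)) stop("allele codes must be 0/1")
    matrix(as.raw(x), nrow(x), ncol(x))
  }
  structure(list(hap1 = as_hap(hap1), hap2 = as_hap(hap2),
                 family = as.integer(family)),
            class = "hs_population")
}

#' @export
print.hs_population <- function(x, ...) {
  cat(sprintf("Population: %d individuals x %d markers, %d families\n",
              ncol(x$hap1), nrow(x$hap1), length(unique(x$family))))
  invisible(x)
}

#' Number of individuals in a population
#' @param pop an `hs_population`.
#' @return Integer count.
#' @export
n_individuals <- function(pop) ncol(pop$hap1)

#' Allele-1 frequency per marker
#' @param pop an `hs_population`.
#' @return Numeric vector of length `n_markers`.
#' @export
allele_freq <- function(pop) {
  .allele_freq_cpp(pop$hap1, pop$hap2)
}

#' Allele-1 dosage matrix
#' @param pop an `hs_population`.
#' @param markers optional marker subset (indices).
#' @return Integer matrix, individuals in rows, markers in columns.
#' @export
dosage <- function(pop, markers = NULL) {
  m <- nrow(pop$hap1)
  d <- matrix(as.integer(pop$hap1), m) + matrix(as.integer(pop$hap2), m)
  if (!is.null(markers)) d <- d[markers, , drop = FALSE]
  t(d)
}

#' True breeding value
#'
#' Sum over QTLs of allele-1 dosage times the additive effect (linear in
#' dosage; no dominance or epistasis).
#'
#' @param pop an `hs_population`.
#' @param spec a [genome_spec()].
#' @return Numeric vector, one TBV per individual (trait units).
#' @export
true_breeding_value <- function(pop, spec) {
  .linear_score_cpp(pop$hap1, pop$hap2, spec$qtl_idx - 1L, spec$qtl_eff,
                    numeric(length(spec$qtl_idx)))
}

#' Simulate gametes by meiosis
#'
#' One recombinant haplotype per requested gamete, under a no-interference
#' (Haldane) crossover model: crossover counts per chromosome are
#' Poisson(map length / 100 Morgan) with uniform positions, chromosomes
#' assort independently.
#'
#' @param pop an `hs_population` of phased parents.
#' @param spec a [genome_spec()].
#' @param parents integer vector of parent indices, one per gamete.
#' @return Integer matrix of haplotypes (markers x gametes).
#' @export
make_gametes <- function(pop, spec, parents) {
  parents <- as.integer(parents)
  if (any(parents < 1 | parents > ncol(pop$hap1)))
    stop("parent index out of range")
  chr_begin <- match(unique(spec$chr), spec$chr) - 1L
  chr_end <- c(chr_begin[-1], spec$n_markers) - 1L
  .gametes_cpp(pop$hap1, pop$hap2, parents - 1L, spec$pos, chr_begin, chr_end)
}

#' Polycross mating into half-sib families
#'
#' Each mother contributes `progeny_per_mother` maternal gametes; each
#' progeny's paternal gamete comes from a pollen parent drawn uniformly from
#' the pollen pool, excluding the mother herself (no selfing). Progeny are
#' grouped by mother into half-sib families (family id = mother's position
#' in `mothers`).
#'
#' @param pop an `hs_population` holding the parents.
#' @param spec a [genome_spec()].
#' @param mothers indices of the maternal parents.
#' @param pollen indices of the pollen pool (defaults to `mothers`).
#' @param progeny_per_mother half-sib family size.
#' @return An `hs_population` of `length(mothers) * progeny_per_mother`
#'   progeny.
#' @export
polycross <- function(pop, spec, mothers, pollen = mothers,
                      progeny_per_mother) {
  mothers <- as.integer(mothers); pollen <- as.integer(pollen)
  if (length(mothers) == 0 || length(pollen) == 0)
    stop("empty parent pools")
  n_prog <- length(mothers) * progeny_per_mother
  mom <- rep(mothers, each = progeny_per_mother)
  # fathers: uniform over pollen pool excluding self
  dad <- pollen[sample.int(length(pollen), n_prog, replace = TRUE)]
  for (it in 1:100) {
    bad <- which(dad == mom)
    if (!length(bad)) break
    if (length(pollen) == 1)
      stop("pollen pool contains only the mother; selfing is excluded")
    dad[bad] <- pollen[sample.int(length(pollen), length(bad),
                                  replace = TRUE)]
  }
  if (any(dad == mom))
    stop("could not draw non-self pollen parents")
  hap_m <- make_gametes(pop, spec, mom)
  hap_p <- make_gametes(pop, spec, dad)
  new_population(hap_m, hap_p,
                 family = rep(seq_along(mothers), each = progeny_per_mother))
}

#' Trait model for phenotype simulation
#'
#' Defines the non-genetic structure of simulated yield phenotypes: a base
#' population mean (trait units), a family-by-environment interaction
#' variance, a single-plant residual variance, and the plot size. When
#' `resid_var` is `NULL` it is calibrated against a population so the
#' single-plant heritability `var(TBV) / (var(TBV) + ge_var + resid_var)`
#' equals `h2_plant` (see [calibrate_trait()]).
#'
#' @param h2_plant target single-plant heritability, in (0, 1].
#' @param plot_size plants per plot.
#' @param ge_var family-by-environment interaction variance (trait units^2).
#' @param resid_var single-plant residual variance, or `NULL` to calibrate.
#' @param base_mean trait mean added to all phenotypes and genetic means.
#' @return An object of class `trait_model`.
#' @export
trait_model <- function(h2_plant, plot_size = 30L, ge_var = 0,
                        resid_var = NULL, base_mean = 3300) {
  if (h2_plant <= 0 || h2_plant > 1) stop("'h2_plant' must be in (0, 1]")
  if (ge_var < 0) stop("'ge_var' must be >= 0")
  structure(list(h2_plant = h2_plant, plot_size = as.integer(plot_size),
                 ge_var = ge_var, resid_var = resid_var,
                 base_mean = base_mean), class = "trait_model")
}

#' Calibrate the residual variance of a trait model
#'
#' Sets `resid_var` so that the single-plant heritability in the supplied
#' population equals the model's `h2_plant`:
#' `resid_var = var(TBV) * (1 - h2) / h2 - ge_var` (floored at 0).
#'
#' @param trait a [trait_model()].
#' @param pop an `hs_population` (typically cycle 0).
#' @param spec a [genome_spec()].
#' @return The calibrated `trait_model`.
#' @export
calibrate_trait <- function(trait, pop, spec) {
  vg <- var(true_breeding_value(pop, spec))
  if (vg <= 0) stop("population has no genetic variance")
  trait$resid_var <- max(0, vg * (1 - trait$h2_plant) / trait$h2_plant -
                           trait$ge_var)
  trait
}

#' Convert family-mean heritability to single-plant heritability
#'
#' For HS families evaluated on `K = plot_size * n_reps * n_env * n_years`
#' plants per family, the family-mean heritability is
#' `(1/4 Va) / (1/4 Va + (3/4 Va + Ve) / K)`. Given the family-mean value and
#' `K`, this solves for `Ve / Va` and returns the single-plant heritability
#' `Va / (Va + Ve)`.
#'
#' @param h2_family family-mean narrow-sense heritability, in (0, 1).
#' @param plants_per_family total plants per family over the whole design.
#' @return Single-plant heritability.
#' @export
h2_single_from_family <- function(h2_family, plants_per_family) {
  if (h2_family <= 0 || h2_family >= 1)
    stop("'h2_family' must be in (0, 1)")
  K <- plants_per_family
  # h2_f = .25 / (.25 + (.75 + ve_over_va) / K)  =>  solve for ve_over_va
  ve_over_va <- 0.25 * K * (1 - h2_family) / h2_family - 0.75
  if (ve_over_va < 0) ve_over_va <- 0
  1 / (1 + ve_over_va)
}

#' Design of the simulated family evaluation trial
#'
#' @param n_env environments (location-like) per year.
#' @param n_years years of evaluation.
#' @param n_reps replicate plots per environment-year.
#' @return A `sim_design` list.
#' @export
sim_design <- function(n_env = 2L, n_years = 2L, n_reps = 3L) {
  structure(list(n_env = as.integer(n_env), n_years = as.integer(n_years),
                 n_reps = as.integer(n_reps)), class = "sim_design")
}

#' Simulate plot phenotypes for a family trial
#'
#' Each half-sib family is evaluated in `n_env x n_years x n_reps` plots of
#' `plot_size` plants. A plot value is the mean over its plants of
#' `base_mean + TBV + GE(family, env, year) + plant residual`; plot plants
#' are drawn from the family's members (with replacement when the family has
#' fewer members than the plot needs).
#'
#' @param pop an `hs_population` grouped into families.
#' @param spec a [genome_spec()].
#' @param trait a [trait_model()] with `resid_var` set (see
#'   [calibrate_trait()]).
#' @param design a [sim_design()].
#' @return A data frame of plot records: `family`, `env`, `year`, `rep`,
#'   `value`.
#' @export
simulate_plot_phenotypes <- function(pop, spec, trait, design) {
  if (is.null(trait$resid_var))
    stop("trait model is not calibrated; call calibrate_trait() first")
  tbv <- true_breeding_value(pop, spec)
  fams <- sort(unique(pop$family))
  nf <- length(fams)
  ne <- design$n_env; ny <- design$n_years; nr <- design$n_reps
  grid <- expand.grid(rep = seq_len(nr), year = seq_len(ny),
                      env = seq_len(ne), family = fams)
  # family-by-environment-year deviations, shared across reps
  ge <- array(rnorm(nf * ne * ny, 0, sqrt(trait$ge_var)), c(nf, ne, ny))
  ps <- trait$plot_size
  idx_by_fam <- split(seq_along(pop$family), pop$family)
  val <- numeric(nrow(grid))
  for (r in seq_len(nrow(grid))) {
    f <- match(grid$family[r], fams)
    members <- idx_by_fam[[f]]
    pick <- members[sample.int(length(members), ps,
                               replace = length(members) < ps)]
    val[r] <- trait$base_mean + mean(tbv[pick]) +
      ge[f, grid$env[r], grid$year[r]] +
      rnorm(1, 0, sqrt(trait$resid_var / ps))
  }
  data.frame(family = grid$family, env = grid$env, year = grid$year,
             rep = grid$rep, value = val)
}

#' Simulate single-plant phenotypes
#'
#' `base_mean + TBV + N(0, ge_var + resid_var)` per individual; with
#' `h2_plant = 1` and no GE the phenotype equals `base_mean + TBV` exactly.
#'
#' @inheritParams simulate_plot_phenotypes
#' @return Numeric vector of phenotypes.
#' @export
simulate_plant_phenotypes <- function(pop, spec, trait) {
  if (is.null(trait$resid_var))
    stop("trait model is not calibrated; call calibrate_trait() first")
  tbv <- true_breeding_value(pop, spec)
  noise_var <- trait$ge_var + trait$resid_var
  trait$base_mean + tbv + rnorm(length(tbv), 0, sqrt(noise_var))
}
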