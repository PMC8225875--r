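#' Unit-cost book for a breeding program cycle
#'
#' Per-sample and per-GEBV unit costs (New Zealand $) plus the fixed
#' operational cost of running one cycle. Defaults are the published unit
#' costs: $7.50 per harvested herbage sample, $0.87 per phenomics (LiDAR)
#' sample, $41 per GEBV. The fixed operational cost depends on program line
#' items and has no reliable default, so it must be supplied.
#'
#' @param per_sample_cut $ per harvested (cut) yield sample.
#' @param per_sample_phenomics $ per phenomics-derived yield sample.
#' @param per_gebv $ per genomic estimated breeding value.
#' @param fixed_operational_per_cycle fixed $ per cycle (trial operations).
#' @return An object of class `cost_book`.
#' @export
cost_book <- function(per_sample_cut = 7.50, per_sample_phenomics = 0.87,
                      per_gebv = 41, fixed_operational_per_cycle) {
  x <- list(per_sample_cut = per_sample_cut,
            per_sample_phenomics = per_sample_phenomics,
            per_gebv = per_gebv,
            fixed_operational_per_cycle = fixed_operational_per_cycle)
  for (nm in names(x))
    if (!is.numeric(x[[nm]]) || length(x[[nm]]) != 1L || x[[nm]] < 0)
      stop("'", nm, "' must be a single non-negative number")
  structure(x, class = "cost_book")
}

#' Phenotyping cost of a family trial
#'
#' One sample per plot: `n_families * n_reps * n_locations * n_seasons *
#' n_years` samples at the given unit cost.
#'
#' @param design a [trial_design()] object.
#' @param per_sample $ per sample.
#' @return Total phenotyping cost ($).
#' @export
phenotyping_cost <- function(design, per_sample) {
  stopifnot(inherits(design, "trial_design"))
  n <- design$n_families * design$n_reps * design$n_locations *
    design$n_seasons * design$n_years
  n * per_sample
}

#' Genotyping cost of within-family genomic selection
#'
#' @param n_families_selected families entering the genomic step.
#' @param n_genotyped_per_family individuals genotyped per family.
#' @param per_gebv $ per GEBV.
#' @return Total genotyping cost ($).
#' @export
genotyping_cost <- function(n_families_selected, n_genotyped_per_family,
                            per_gebv) {
  if (n_families_selected < 0 || n_genotyped_per_family < 0 || per_gebv < 0)
    stop("cost inputs must be non-negative")
  n_families_selected * n_genotyped_per_family * per_gebv
}

#' Cost per percentage point of genetic gain
#'
#' @param total_cost total program cost for the cycle ($).
#' @param pct_gain predicted percent gain for the cycle (> 0).
#' @return $ per percent gain.
#' @export
cost_per_percent_gain <- function(total_cost, pct_gain) {
  if (any(pct_gain <= 0)) stop("'pct_gain' must be positive")
  total_cost / pct_gain
}

#' Total program cost of one selection cycle under a scheme
#'
#' Fixed operational cost, plus phenotyping of the family trial (cut or
#' phenomics sampling depending on the strategy), plus genotyping of
#' within-family candidates for `Wgs` strategies. For `A_gsWgs` (no field
#' trial) only fixed and genotyping costs apply, with all
#' `n_families * n_genotyped_per_family` candidates genotyped.
#'
#' @param scheme a [selection_scheme()] object.
#' @param design a [trial_design()] object (families evaluated; used for
#'   sample counts and the among-family selected count).
#' @param book a [cost_book()] object.
#' @return Total cost ($) of the cycle.
#' @export
cycle_cost <- function(scheme, design, book) {
  stopifnot(inherits(scheme, "selection_scheme"),
            inherits(design, "trial_design"), inherits(book, "cost_book"))
  phenomics <- scheme$strategy %in% c("A_Ph", "A_PhWgs")
  total <- book$fixed_operational_per_cycle
  if (scheme$strategy != "A_gsWgs") {
    per_sample <- if (phenomics) book$per_sample_phenomics else
      book$per_sample_cut
    total <- total + phenotyping_cost(design, per_sample)
  }
  if (scheme$strategy %in% c("A_pWgs", "A_PhWgs")) {
    n_sel <- floor(design$n_families * scheme$p_among + 0.5)
    total <- total + genotyping_cost(n_sel, scheme$n_genotyped_per_family,
                                     book$per_gebv)
  } else if (scheme$strategy == "A_gsWgs") {
    total <- total + genotyping_cost(design$n_families,
                                     scheme$n_genotyped_per_family,
                                     book$per_gebv)
  }
  total
}
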