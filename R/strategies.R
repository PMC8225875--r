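#' Configuration of a stochastic recurrent-selection run
#'
#' Describes one multi-cycle recurrent-selection program:
#' \describe{
#'   \item{`A_p`}{among-family selection on shrunken (BLUP) phenotypic
#'     family means; within-family parents drawn at random.}
#'   \item{`A_pWgs`}{same among-family step; within-family parents are the
#'     top individual GEBVs.}
#'   \item{`A_gsWgs`}{among-family selection on family-mean GEBVs,
#'     within-family on individual GEBVs; no field trial, one-year cycles.}
#' }
#' Each cycle the current parents are polycrossed into one half-sib family
#' per parent with `n_per_family` genotyped candidates; after selection
#' `round(p_among * n_families) * within_k` individuals become the next
#' parents. The defaults (`p_among = 0.20`, `within_k = 5`,
#' `n_per_family = 180`, i.e. a 2.77% within-family pressure) restore a
#' ~196-parent population each cycle.
#'
#' @param strategy `"A_p"`, `"A_pWgs"` or `"A_gsWgs"`.
#' @param p_among among-family selected fraction (0.20 or 0.02 in the
#'   standard scenarios).
#' @param within_k individuals selected per selected family (5 or 50).
#' @param n_per_family genotyped candidates per family.
#' @param n_cycles selection cycles to simulate.
#' @param n_iterations independent replicates to average over.
#' @param design a [sim_design()] for the family evaluation trial
#'   (environments x years x reps).
#' @param train_design a [sim_design()] for the training-population trial.
#' @param h2_family family-mean heritability used to calibrate the trait
#'   model (converted to a single-plant value via
#'   [h2_single_from_family()]).
#' @param ge_var family-by-environment interaction variance (trait units^2).
#' @param plot_size plants per plot.
#' @param base_mean trait base mean (trait units).
#' @param cycle_years years per cycle (3 for field strategies, 1 for
#'   `A_gsWgs`).
#' @param h2_gebv squared correlation of noisy GEBVs with the clean linear
#'   score (genotyping-error model).
#' @param retrain retrain the prediction model each cycle? Default `FALSE`:
#'   the model is trained once on the cycle-0 training population, so
#'   prediction accuracy decays as relatedness to the training set erodes.
#' @param seed master RNG seed (required); per-iteration seeds are derived
#'   from it, so runs with equal seeds are paired across strategies.
#' @return An object of class `strategy_config`.
#' @export
strategy_config <- function(strategy = c("A_p", "A_pWgs", "A_gsWgs"),
                            p_among = 0.20, within_k = 5L,
                            n_per_family = 180L,
                            n_cycles = 10L, n_iterations = 250L,
                            design = sim_design(2L, 2L, 3L),
                            train_design = sim_design(3L, 3L, 3L),
                            h2_family = 0.31, ge_var = 0,
                            plot_size = 30L, base_mean = 3300,
                            cycle_years = NULL, h2_gebv = 0.95,
                            retrain = FALSE, seed) {
  strategy <- match.arg(strategy)
  if (missing(seed)) stop("'seed' is required")
  if (p_among <= 0 || p_among > 1) stop("'p_among' must be in (0, 1]")
  if (within_k < 1 || within_k > n_per_family)
    stop("'within_k' must be in [1, n_per_family]")
  if (is.null(cycle_years))
    cycle_years <- if (strategy == "A_gsWgs") 1L else 3L
  structure(list(strategy = strategy, p_among = p_among,
                 within_k = as.integer(within_k),
                 n_per_family = as.integer(n_per_family),
                 n_cycles = as.integer(n_cycles),
                 n_iterations = as.integer(n_iterations),
                 design = design, train_design = train_design,
                 h2_family = h2_family, ge_var = ge_var,
                 plot_size = as.integer(plot_size), base_mean = base_mean,
                 cycle_years = as.integer(cycle_years), h2_gebv = h2_gebv,
                 retrain = isTRUE(retrain), seed = as.integer(seed)),
            class = "strategy_config")
}

#' Shrunken (BLUP-type) half-sib family means from plot records
#'
#' One-way random-effects shrinkage: with between- and within-family
#' variances estimated by the method of moments from the plot records, each
#' raw family mean is pulled towards the grand mean by its reliability
#' `s2_b / (s2_b + s2_w / n_plots)`.
#'
#' @param plots a data frame with columns `family` and `value` (plot
#'   records, equal replication per family).
#' @return Named vector of shrunken family means, with the reliability in
#'   attribute `"reliability"`.
#' @export
shrunken_family_means <- function(plots) {
  raw <- tapply(plots$value, plots$family, mean)
  n0 <- nrow(plots) / length(raw)
  grand <- mean(plots$value)
  msw <- mean(tapply(plots$value, plots$family, var))
  s2b <- max(0, var(raw) - msw / n0)
  w <- if (s2b > 0) s2b / (s2b + msw / n0) else 0
  out <- grand + w * (raw - grand)
  attr(out, "reliability") <- w
  out
}

subset_population <- function(pop, idx, family = pop$family[idx]) {
  new_population(pop$hap1[, idx, drop = FALSE],
                 pop$hap2[, idx, drop = FALSE], family = family)
}

#' Per-cycle tracker statistics
#'
#' Computes the tracker row comparing a cycle population with the base
#' (cycle-0) population: genetic mean, percent gain per year relative to
#' the previous cycle mean, cumulative gain, percent of cycle-0 genetic
#' variance retained, percent of QTLs fixed for the favourable allele, and
#' prediction accuracy (Pearson correlation of TBVs with GEBVs) when a
#' model is supplied.
#'
#' @param pop current-cycle `hs_population`.
#' @param pop0 cycle-0 `hs_population` (defines the variance baseline).
#' @param spec a [genome_spec()].
#' @param model optional `rrblup_model` for the accuracy tracker.
#' @param prev_mean previous-cycle genetic mean (defaults to the cycle-0
#'   mean), used as the percent-gain denominator.
#' @param cycle_years years per cycle for annualization.
#' @param base_mean trait base mean added to genetic means.
#' @param gebvs optional precomputed GEBVs for `pop` (avoids recomputation).
#' @return A one-row data frame of tracker fields.
#' @export
trackers <- function(pop, pop0, spec, model = NULL, prev_mean = NULL,
                     cycle_years = 1, base_mean = 0, gebvs = NULL) {
  tbv0 <- true_breeding_value(pop0, spec)
  v0 <- var(tbv0)
  if (v0 <= 0) stop("cycle-0 population has zero genetic variance")
  tbv <- true_breeding_value(pop, spec)
  mean0 <- base_mean + mean(tbv0)
  mean_t <- base_mean + mean(tbv)
  if (is.null(prev_mean)) prev_mean <- mean0
  acc <- NA_real_
  if (!is.null(model)) {
    if (is.null(gebvs)) gebvs <- gebv(model, pop, noisy = TRUE)
    acc <- suppressWarnings(cor(tbv, gebvs))
  }
  p <- allele_freq(pop)[spec$qtl_idx]
  fav_fixed <- ifelse(spec$qtl_eff >= 0, p == 1, p == 0)
  data.frame(mean = mean_t,
             pct_gain_per_year =
               100 * (mean_t - prev_mean) / abs(prev_mean) / cycle_years,
             cum_gain = mean_t - mean0,
             pct_genetic_variance = 100 * var(tbv) / v0,
             pct_fixed = 100 * mean(fav_fixed),
             accuracy = acc)
}

#' Run a recurrent-selection breeding strategy
#'
#' Simulates `n_cycles` of half-sib recurrent selection from a training
#' population, averaged over `n_iterations` independent replicates. Each
#' replicate: (1) the training population's own HS families are evaluated in
#' the training trial and an rrBLUP model is trained on member dosages
#' against family means; (2) the training individuals are polycrossed into
#' the cycle-0 candidate population (one HS family per parent,
#' `n_per_family` candidates each); (3) each cycle, families are ranked
#' (phenotypic shrunken means or family-mean GEBVs), the top
#' `round(p_among * n_families)` selected, `within_k` parents taken per
#' family (random for `A_p`, top GEBV otherwise), and the parents
#' polycrossed into the next cycle. Trackers (gain, variance, fixation,
#' accuracy) are recorded per cycle and iteration.
#'
#' @param config a [strategy_config()].
#' @param spec a [genome_spec()].
#' @param parents0 the training population (`hs_population` with family
#'   labels), e.g. from [build_training_population()].
#' @return An object of class `breeding_sim`: `records` (per iteration and
#'   cycle), `summary` (tracker means by cycle) and the config.
#' @examples
#' \donttest{
#' g <- simulate_genome(n_markers = 200, n_qtl = 50, seed = 1)
#' f <- generate_founders(g, n = 30, seed = 2)
#' tp <- build_training_population(f, g, family_draws = 2, seed = 3)
#' cfg <- strategy_config("A_pWgs", n_per_family = 36, within_k = 1,
#'                        n_cycles = 2, n_iterations = 2, seed = 4)
#' run_strategy(cfg, g, tp)
#' }
#' @export
run_strategy <- function(config, spec, parents0) {
  stopifnot(inherits(config, "strategy_config"),
            inherits(spec, "genome_spec"),
            inherits(parents0, "hs_population"))
  set.seed(config$seed)
  iter_seeds <- sample.int(.Machine$integer.max - 1L, config$n_iterations)
  recs <- vector("list", config$n_iterations)
  for (it in seq_len(config$n_iterations)) {
    set.seed(iter_seeds[it])
    r <- run_strategy_once(config, spec, parents0)
    r$iteration <- it
    recs[[it]] <- r
  }
  records <- do.call(rbind, recs)
  num <- c("mean", "pct_gain_per_year", "cum_gain", "pct_genetic_variance",
           "pct_fixed", "accuracy")
  summ <- aggregate(records[num], list(cycle = records$cycle), mean)
  structure(list(records = records, summary = summ, config = config),
            class = "breeding_sim")
}

# One replicate of the recurrent-selection program.
run_strategy_once <- function(config, spec, parents0) {
  cfg <- config
  # trait model calibrated on the training population's genetic variance
  K <- cfg$plot_size * cfg$design$n_reps * cfg$design$n_env *
    cfg$design$n_years
  h2p <- h2_single_from_family(cfg$h2_family, K)
  trait <- trait_model(h2p, plot_size = cfg$plot_size, ge_var = cfg$ge_var,
                       base_mean = cfg$base_mean)
  trait <- calibrate_trait(trait, parents0, spec)

  # train rrBLUP on the training population: member dosage vs the simulated
  # family-trial mean of its HS family
  tr_plots <- simulate_plot_phenotypes(parents0, spec, trait,
                                       cfg$train_design)
  fam_means <- tapply(tr_plots$value, tr_plots$family, mean)
  y_train <- as.numeric(fam_means[as.character(parents0$family)])
  model <- rrblup_train(dosage(parents0), y_train, quiet = TRUE)

  # cycle-0 candidate population: polycross of all training individuals
  n0 <- n_individuals(parents0)
  pop0 <- polycross(parents0, spec, mothers = seq_len(n0),
                    progeny_per_mother = cfg$n_per_family)
  tbv0 <- true_breeding_value(pop0, spec)
  v0 <- var(tbv0)
  if (v0 <= 0) stop("cycle-0 population has zero genetic variance")
  mean0 <- cfg$base_mean + mean(tbv0)

  out <- vector("list", cfg$n_cycles + 1L)
  out[[1]] <- cycle_record(pop0, tbv0, spec, model, cfg,
                           mean0 = mean0, v0 = v0, prev_mean = mean0,
                           cycle = 0L)
  pop <- pop0
  prev_mean <- mean0
  for (t in seq_len(cfg$n_cycles)) {
    sel <- select_parents(pop, spec, model, trait, cfg)
    parents <- subset_population(pop, sel)
    pop <- polycross(parents, spec,
                     mothers = seq_len(n_individuals(parents)),
                     progeny_per_mother = cfg$n_per_family)
    if (cfg$retrain) {
      sub <- subset_population(pop, tracker_subsample(n_individuals(pop),
                                                      500L))
      ph <- simulate_plant_phenotypes(sub, spec, trait)
      model <- rrblup_train(dosage(sub), ph, quiet = TRUE)
    }
    rec <- cycle_record(pop, true_breeding_value(pop, spec), spec, model,
                        cfg, mean0 = mean0, v0 = v0, prev_mean = prev_mean,
                        cycle = t)
    prev_mean <- rec$mean
    out[[t + 1L]] <- rec
  }
  do.call(rbind, out)
}

# one tracker row; accuracy estimated on a capped subsample for speed,
# mean/variance/fixation on the full population
cycle_record <- function(pop, tbv, spec, model, cfg, mean0, v0, prev_mean,
                         cycle) {
  mean_t <- cfg$base_mean + mean(tbv)
  sub <- tracker_subsample(length(tbv))
  g_sub <- gebv(model, subset_population(pop, sub), noisy = TRUE,
                h2_gebv = cfg$h2_gebv)
  acc <- suppressWarnings(cor(tbv[sub], g_sub))
  p <- allele_freq(pop)[spec$qtl_idx]
  data.frame(
    cycle = cycle,
    mean = mean_t,
    pct_gain_per_year =
      100 * (mean_t - prev_mean) / abs(prev_mean) / cfg$cycle_years,
    cum_gain = mean_t - mean0,
    pct_genetic_variance = 100 * var(tbv) / v0,
    pct_fixed = 100 * mean(ifelse(spec$qtl_eff >= 0, p == 1, p == 0)),
    accuracy = acc)
}

tracker_subsample <- function(n, cap = 2000L) {
  if (n <= cap) seq_len(n) else sample.int(n, cap)
}

# strategy-specific among + within selection; returns parent indices
select_parents <- function(pop, spec, model, trait, cfg) {
  fams <- sort(unique(pop$family))
  nf <- length(fams)
  n_sel_f <- max(1L, as.integer(floor(nf * cfg$p_among + 0.5)))
  members <- split(seq_along(pop$family), pop$family)

  need_pheno <- cfg$strategy %in% c("A_p", "A_pWgs")
  if (need_pheno) {
    plots <- simulate_plot_phenotypes(pop, spec, trait, cfg$design)
    fmeans <- shrunken_family_means(plots)
    rank_stat <- as.numeric(fmeans[as.character(fams)])
  }
  if (cfg$strategy == "A_gsWgs") {
    g_hat <- gebv(model, pop, noisy = TRUE, h2_gebv = cfg$h2_gebv)
    rank_stat <- as.numeric(tapply(g_hat, pop$family, mean)[
      as.character(fams)])
  }
  sel_fams <- fams[order(rank_stat, decreasing = TRUE)[seq_len(n_sel_f)]]
  if (cfg$strategy == "A_pWgs") {
    # GEBVs are only needed inside the selected families
    idx_sel <- unlist(members[as.character(sel_fams)], use.names = FALSE)
    g_hat <- rep(NA_real_, length(pop$family))
    g_hat[idx_sel] <- gebv(model, subset_population(pop, idx_sel),
                           noisy = TRUE, h2_gebv = cfg$h2_gebv)
  }

  unlist(lapply(sel_fams, function(f) {
    ix <- members[[as.character(f)]]
    if (length(ix) < cfg$within_k)
      stop("family has fewer candidates than 'within_k'")
    if (cfg$strategy == "A_p") {
      ix[sample.int(length(ix), cfg$within_k)]
    } else {
      ix[order(g_hat[ix], decreasing = TRUE)[seq_len(cfg$within_k)]]
    }
  }), use.names = FALSE)
}

#' @export
print.breeding_sim <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "Recurrent-selection simulation: %s, among %g%%, within %d/%d, %d cycles x %d iterations\n",
    cfg$strategy, 100 * cfg$p_among, cfg$within_k, cfg$n_per_family,
    cfg$n_cycles, cfg$n_iterations))
  print(x$summary, digits = 4)
  invisible(x)
}

#' @export
summary.breeding_sim <- function(object, ...) object$summary

#' Plot simulation trackers across cycles
#'
#' Line charts of the averaged trackers (percent gain per year, percent
#' genetic variance, percent favourable alleles fixed, prediction accuracy)
#' against selection cycle.
#'
#' @param x a `breeding_sim`.
#' @param which tracker columns to draw.
#' @param ... passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.breeding_sim <- function(x, which = c("pct_gain_per_year",
                                           "pct_genetic_variance",
                                           "pct_fixed", "accuracy"), ...) {
  s <- x$summary
  old <- graphics::par(mfrow = c(2, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old))
  labs <- c(pct_gain_per_year = "% gain / year",
            pct_genetic_variance = "% genetic variance",
            pct_fixed = "% favourable alleles fixed",
            accuracy = "prediction accuracy")
  for (w in which) {
    graphics::plot(s$cycle, s[[w]], type = "b", xlab = "cycle",
                   ylab = labs[[w]], ...)
  }
  invisible(x)
}
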