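# Reduced-scale simulations; published-scale property runs live in the
# acceptance suite.

small_setup <- function(seed = 1) {
  g <- simulate_genome(n_markers = 240, n_qtl = 60, n_chr = 3, chr_len = 90,
                       seed = seed)
  f <- generate_founders(g, n = 24, seed = seed + 1)
  tp <- build_training_population(f, g, family_draws = 2, seed = seed + 2)
  list(g = g, tp = tp)
}

test_that("shrunken family means shrink towards the grand mean", {
  set.seed(1)
  fam <- rep(1:20, each = 6)
  y <- rnorm(20, 0, 3)[fam] + rnorm(120)
  plots <- data.frame(family = fam, value = y)
  sh <- shrunken_family_means(plots)
  raw <- tapply(y, fam, mean)
  expect_lt(var(sh), var(raw))
  expect_equal(mean(sh), mean(y), tolerance = 1e-8)
  w <- attr(sh, "reliability")
  expect_true(w > 0 && w < 1)
  # pure noise: heavy shrinkage
  plots0 <- data.frame(family = fam, value = rnorm(120))
  expect_lt(attr(shrunken_family_means(plots0), "reliability"), 0.5)
})

test_that("trackers report baseline and degenerate cases correctly", {
  g <- tiny_genome(positive_effects = TRUE)
  pop <- generate_founders(g, n = 50, seed = 3)
  r0 <- trackers(pop, pop, g, cycle_years = 3)
  expect_equal(r0$pct_genetic_variance, 100)
  expect_equal(r0$cum_gain, 0)
  expect_equal(r0$pct_gain_per_year, 0)
  # all QTLs fixed favourable: fixation 100%, and zero variance is an error
  fixed <- constant_population(g$n_markers, 10, a1 = 1L, a2 = 1L)
  r1 <- trackers(fixed, pop, g)
  expect_equal(r1$pct_fixed, 100)
  expect_equal(r1$pct_genetic_variance, 0)
  expect_error(trackers(pop, fixed, g), "zero genetic variance")
})

test_that("simulation records have coherent tracker invariants", {
  s <- small_setup(31)
  cfg <- strategy_config("A_pWgs", p_among = 0.25, within_k = 2,
                         n_per_family = 24, n_cycles = 3, n_iterations = 4,
                         seed = 42)
  sim <- run_strategy(cfg, s$g, s$tp)
  rec <- sim$records
  expect_equal(nrow(rec), 4 * 4)         # (cycles + baseline) x iterations
  expect_equal(subset(rec, cycle == 0)$pct_genetic_variance, rep(100, 4))
  # fixation is non-decreasing within every iteration
  for (it in unique(rec$iteration)) {
    r <- rec[rec$iteration == it, ]
    expect_true(all(diff(r$pct_fixed[order(r$cycle)]) >= 0))
  }
  expect_true(all(rec$accuracy >= -1 & rec$accuracy <= 1))
  # same seed reproduces the run exactly
  sim2 <- run_strategy(cfg, s$g, s$tp)
  expect_identical(sim$records, sim2$records)
})

test_that("accurate within-family selection beats random within-family choice", {
  s <- small_setup(7)
  wins <- 0L
  for (seed in 1:8) {
    cfgGS <- strategy_config("A_gsWgs", p_among = 0.25, within_k = 4,
                             n_per_family = 24, n_cycles = 1,
                             n_iterations = 2, h2_family = 0.6, seed = seed)
    cfgP <- strategy_config("A_p", p_among = 0.25, within_k = 4,
                            n_per_family = 24, n_cycles = 1,
                            n_iterations = 2, h2_family = 0.6, seed = seed)
    gGS <- run_strategy(cfgGS, s$g, s$tp)$summary
    gP <- run_strategy(cfgP, s$g, s$tp)$summary
    wins <- wins + (gGS$cum_gain[2] >= gP$cum_gain[2])
  }
  expect_gte(wins, 6L)
})

test_that("no selection pressure means no systematic gain", {
  s <- small_setup(17)
  cfg <- strategy_config("A_p", p_among = 1, within_k = 12,
                         n_per_family = 12, n_cycles = 1, n_iterations = 10,
                         seed = 5)
  sim <- run_strategy(cfg, s$g, s$tp)
  gains <- subset(sim$records, cycle == 1)$cum_gain
  # drift only: mean gain indistinguishable from zero
  expect_lt(abs(mean(gains)), 3 * sd(gains) / sqrt(length(gains)) + 1e-9)
})

test_that("invalid selection targets are rejected", {
  s <- small_setup(23)
  expect_error(strategy_config("A_p", within_k = 30, n_per_family = 12,
                               seed = 1), "within_k")
  cfg <- strategy_config("A_pWgs", p_among = 0.25, within_k = 10,
                         n_per_family = 10, n_cycles = 1, n_iterations = 1,
                         seed = 2)
  expect_s3_class(run_strategy(cfg, s$g, s$tp), "breeding_sim")
})
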