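test_that("true breeding values are linear in favourable-allele dosage", {
  g <- tiny_genome(positive_effects = TRUE)
  # all-heterozygous: dosage 1 at every QTL
  het <- constant_population(g$n_markers, 5, a1 = 1L, a2 = 0L)
  expect_equal(true_breeding_value(het, g), rep(sum(g$qtl_eff), 5))
  # fixed favourable: dosage 2 everywhere (the population maximum)
  best <- constant_population(g$n_markers, 3, a1 = 1L, a2 = 1L)
  expect_equal(true_breeding_value(best, g), rep(2 * sum(g$qtl_eff), 3))
})

test_that("cycle-0 additive variance matches the linkage-equilibrium closed form", {
  g <- tiny_genome(n_markers = 400, n_qtl = 120, seed = 2)
  pop <- generate_founders(g, n = 3000, seed = 3)
  p <- allele_freq(pop)[g$qtl_idx]
  expect_equal(var(true_breeding_value(pop, g)),
               sum(2 * p * (1 - p) * g$qtl_eff^2), tolerance = 0.05)
})

test_that("meiosis respects homozygosity and zero map distance", {
  g <- genome_spec(chr = c(1, 1), pos = c(10, 10), qtl_idx = 1,
                   qtl_eff = 1)
  hom <- constant_population(2, 1, a1 = 1L, a2 = 1L)
  set.seed(1)
  gam <- make_gametes(hom, g, rep(1, 200))
  expect_true(all(as.integer(gam) == 1L))
  # heterozygote, loci 0 cM apart: no recombinants
  het <- constant_population(2, 1, a1 = 1L, a2 = 0L)
  set.seed(2)
  gam <- make_gametes(het, g, rep(1, 2000))
  expect_true(all(gam[1, ] == gam[2, ]))
})

test_that("recombinant fractions follow the Haldane map function", {
  for (d_cM in c(1, 10, 50)) {
    g <- genome_spec(chr = c(1, 1), pos = c(0, d_cM), qtl_idx = 1,
                     qtl_eff = 1)
    het <- constant_population(2, 1, a1 = 1L, a2 = 0L)
    set.seed(100 + d_cM)
    gam <- make_gametes(het, g, rep(1, 10000))
    rec <- mean(gam[1, ] != gam[2, ])
    expect_equal(rec, (1 - exp(-2 * d_cM / 100)) / 2, tolerance = 0.011)
  }
})

test_that("polycross builds half-sib families without selfing", {
  g <- tiny_genome()
  founders <- generate_founders(g, n = 20, seed = 4)
  set.seed(5)
  prog <- polycross(founders, g, mothers = 1:20, progeny_per_mother = 7)
  expect_equal(n_individuals(prog), 140L)
  expect_equal(as.integer(table(prog$family)), rep(7L, 20))
  # progeny allele frequency tracks the parental mean
  set.seed(6)
  big <- polycross(founders, g, mothers = 1:20, progeny_per_mother = 100)
  expect_equal(mean(abs(allele_freq(big) - allele_freq(founders))), 0,
               tolerance = 0.03)
  # a pollen pool of one non-self plant makes full sibs; selfing forbidden
  set.seed(7)
  fs <- polycross(founders, g, mothers = 1, pollen = 2,
                  progeny_per_mother = 10)
  expect_equal(n_individuals(fs), 10L)
  expect_error(polycross(founders, g, mothers = 1, pollen = 1,
                         progeny_per_mother = 5), "selfing")
})

test_that("founders are in Hardy-Weinberg proportions at founding", {
  g <- tiny_genome(n_markers = 200, n_qtl = 40, seed = 8)
  pop <- generate_founders(g, n = 1500, freq = 0.5, seed = 9)
  expect_equal(mean(dosage(pop)), 1, tolerance = 0.02)
  m <- nrow(pop$hap1)
  het <- rowMeans(matrix(as.integer(pop$hap1), m) !=
                    matrix(as.integer(pop$hap2), m))
  expect_equal(mean(het), 0.5, tolerance = 0.02)  # 2p(1-p) at p = 0.5
})

test_that("phenotype simulation honours the heritability calibration", {
  g <- tiny_genome(n_markers = 300, n_qtl = 80, seed = 10)
  pop <- generate_founders(g, n = 400, seed = 11)
  # h2 = 1, no GE: phenotype equals base + TBV exactly
  tr1 <- calibrate_trait(trait_model(1, ge_var = 0), pop, g)
  set.seed(12)
  expect_equal(simulate_plant_phenotypes(pop, g, tr1),
               tr1$base_mean + true_breeding_value(pop, g))
  # realized single-plant heritability within 0.05 of target over replicates
  tr <- calibrate_trait(trait_model(0.4), pop, g)
  vg <- var(true_breeding_value(pop, g))
  set.seed(13)
  h2_hat <- replicate(50, vg / var(simulate_plant_phenotypes(pop, g, tr)))
  expect_equal(mean(h2_hat), 0.4, tolerance = 0.05)
})

test_that("plot means regress on family breeding values", {
  g <- tiny_genome(n_markers = 300, n_qtl = 80, seed = 14)
  founders <- generate_founders(g, n = 30, seed = 15)
  set.seed(16)
  pop <- polycross(founders, g, mothers = 1:30, progeny_per_mother = 20)
  tr <- calibrate_trait(trait_model(0.3), pop, g)
  set.seed(17)
  plots <- simulate_plot_phenotypes(pop, g, tr, sim_design(2, 2, 3))
  fam_tbv <- tapply(true_breeding_value(pop, g), pop$family, mean)
  fam_ph <- tapply(plots$value, plots$family, mean)
  expect_gt(cor(fam_tbv, fam_ph), 0.5)
})

test_that("random mating alone does not shift favourable-allele frequencies", {
  g <- tiny_genome(n_markers = 200, n_qtl = 60, seed = 18)
  founders <- generate_founders(g, n = 60, seed = 19)
  fav0 <- ifelse(g$qtl_eff >= 0, allele_freq(founders)[g$qtl_idx],
                 1 - allele_freq(founders)[g$qtl_idx])
  set.seed(20)
  drift <- replicate(30, {
    prog <- polycross(founders, g, mothers = 1:60, progeny_per_mother = 10)
    fav <- ifelse(g$qtl_eff >= 0, allele_freq(prog)[g$qtl_idx],
                  1 - allele_freq(prog)[g$qtl_idx])
    mean(fav - fav0)
  })
  expect_equal(mean(drift), 0, tolerance = 0.005)
})

test_that("genome constructor validates map and QTL assignments", {
  expect_error(genome_spec(1, c(1, 2), 1, 1), "lengths differ")
  expect_error(genome_spec(c(1, 1), c(2, 1), 1, 1), "ordered")
  expect_error(genome_spec(c(1, 1), c(1, 2), 3, 1), "out of range")
  expect_error(genome_spec(c(1, 1), c(1, 2), 1, c(1, 2)), "match")
  g <- simulate_genome(n_markers = 50, n_qtl = 10, n_chr = 2, seed = 1)
  expect_equal(g$n_markers, 50L)
  expect_equal(length(g$qtl_idx), 10L)
  expect_equal(g$n_chr, 2L)
})
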