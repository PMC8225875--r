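test_that("family-mean phenotypic SD matches direct evaluation", {
  d <- design232()
  expect_equal(family_mean_sd(vc1000(), d), 249.81, tolerance = 1e-4)
  expect_equal(family_mean_sd(vc200(), d), 212.52, tolerance = 1e-4)
  vc0 <- variance_components(5000, 0, 0, 0, 0)
  expect_equal(family_mean_sd(vc0, d), sqrt(5000))
  # sigma_PF can never drop below the genetic SD among families
  expect_gte(family_mean_sd(vc200(), d), sqrt(vc200()$fam_var))
})

test_that("family-mean heritability reproduces the published estimates", {
  d <- design232()
  expect_equal(round(heritability_family_mean(vc1000(), d), 2), 0.36)
  expect_equal(heritability_family_mean(vc1000(), d), 0.358,
               tolerance = 0.002)
  expect_equal(round(heritability_family_mean(vc200(), d), 2), 0.31)
  expect_equal(heritability_family_mean(vc200(), d), 0.314,
               tolerance = 0.002)
  vc_pure <- variance_components(5000, 0, 0, 0, 0)
  expect_equal(heritability_family_mean(vc_pure, d), 1.0)
  expect_error(heritability_family_mean(variance_components(0, 0, 0, 0, 0),
                                        d), "zero")
})

test_that("among-family phenotypic response matches worked examples", {
  d <- design232()
  g20 <- gain_among_phenotypic(vc200(), d, p_among = 0.20)
  expect_equal(g20, 46.67, tolerance = 1e-3)
  expect_equal(100 * g20 / 3262, 1.43, tolerance = 0.01)
  g02 <- gain_among_phenotypic(vc200(), d, p_among = 0.02)
  expect_equal(100 * g02 / 3262, 2.47, tolerance = 0.01)
  expect_equal(gain_among_phenotypic(vc200(), d, p_among = 1), 0)
})

test_that("within-family genomic response matches the correlated-response formula", {
  # frozen from direct evaluation of i(p) c r sqrt(3)/2 * 2 sqrt(fam_var)
  expect_equal(gain_within_gs(vc200(), 0.01, r_A = 0.46), 126.4,
               tolerance = 1e-3)
  expect_equal(gain_within_gs(vc200(), 0.10, r_A = 0.26), 47.0,
               tolerance = 1e-2)
  expect_equal(gain_within_gs(vc200(), 0.05, r_A = 0), 0)
  # linearity in accuracy
  expect_equal(gain_within_gs(vc200(), 0.05, r_A = 0.4),
               2 * gain_within_gs(vc200(), 0.05, r_A = 0.2))
})

test_that("combined among-phenotypic + within-GS strategy reproduces headline gains", {
  d200 <- design232(); d1000 <- design232(1000)
  sc <- selection_scheme("A_pWgs", p_among = 0.02, p_within = 0.01,
                         r_A = 0.46)
  expect_equal(predict_gain(vc200(), sc, 3262, d200)$delta_g_pct, 6.35,
               tolerance = 0.005)
  expect_equal(predict_gain(vc1000(), sc, 3301, d1000)$delta_g_pct, 8.10,
               tolerance = 0.02)
  # with zero accuracy the within term vanishes
  sc0 <- selection_scheme("A_pWgs", p_among = 0.02, p_within = 0.01,
                          r_A = 0)
  expect_equal(predict_gain(vc200(), sc0, 3262, d200)$delta_g_abs,
               gain_among_phenotypic(vc200(), d200, 0.02))
  expect_error(selection_scheme("A_pWgs", p_among = 0.02), "p_within")
})

test_that("all-genomic strategy reproduces the cycle-2 worked examples", {
  sc <- function(pa, pw, r) selection_scheme("A_gsWgs", p_among = pa,
                                             p_within = pw, r_A = r)
  expect_equal(predict_gain(vc200(), sc(0.10, 0.05, 0.46), 3419)$delta_g_abs,
               145.9, tolerance = 0.1)
  expect_equal(predict_gain(vc200(), sc(0.10, 0.05, 0.46), 3419)$delta_g_pct,
               4.27, tolerance = 0.01)
  expect_equal(predict_gain(vc1000(), sc(0.10, 0.05, 0.26), 3449)$delta_g_pct,
               3.00, tolerance = 0.01)
  expect_equal(predict_gain(vc200(), sc(0.10, 0.05, 0), 3419)$delta_g_pct, 0)
})

test_that("phenomics accuracy scales the whole prediction", {
  d <- design232()
  ap <- predict_gain(vc200(), selection_scheme("A_p", p_among = 0.20), 3262,
                     d)
  aph <- predict_gain(vc200(), selection_scheme("A_Ph", p_among = 0.20),
                      3262, d)
  expect_equal(aph$delta_g_pct, 1.29, tolerance = 0.005)
  # exact 0.90 ratio at every pressure
  for (p in c(0.20, 0.10, 0.05, 0.02)) {
    a <- predict_gain(vc200(), selection_scheme("A_p", p_among = p), 3262, d)
    b <- predict_gain(vc200(), selection_scheme("A_Ph", p_among = p), 3262,
                      d)
    expect_equal(b$delta_g_pct / a$delta_g_pct, 0.90, tolerance = 1e-10)
  }
  # also applies to the within-GS term of the combined strategy
  sc_p <- selection_scheme("A_pWgs", 0.02, 0.01, r_A = 0.46)
  sc_ph <- selection_scheme("A_PhWgs", 0.02, 0.01, r_A = 0.46)
  gp <- predict_gain(vc200(), sc_p, 3262, d)
  gph <- predict_gain(vc200(), sc_ph, 3262, d)
  expect_equal(gph$delta_g_abs, 0.90 * gp$delta_g_abs, tolerance = 1e-10)
  expect_equal(gph$delta_g_abs, 186.4, tolerance = 0.1)
  # identity accuracy leaves the prediction unchanged
  expect_equal(apply_phenomics(gp, 1)$delta_g_pct, gp$delta_g_pct)
})

test_that("gain is monotone in selection pressure and accuracy", {
  d <- design232()
  ps <- c(0.20, 0.10, 0.05, 0.02)
  among <- vapply(ps, function(p)
    gain_among_phenotypic(vc200(), d, p), 0)
  expect_true(all(diff(among) > 0))
  rs <- c(0.12, 0.26, 0.36, 0.46)
  g <- vapply(rs, function(r)
    predict_gain(vc200(), selection_scheme("A_gsWgs", 0.10, 0.05, r_A = r),
                 3419)$delta_g_pct, 0)
  expect_true(all(diff(g) > 0))
  # combined strategy dominates the pure among-family one at equal pressure
  g1 <- predict_gain(vc200(), selection_scheme("A_p", p_among = 0.10), 3262,
                     d)
  g2 <- predict_gain(vc200(),
                     selection_scheme("A_pWgs", 0.10, 0.05, r_A = 0.26),
                     3262, d)
  expect_gt(g2$delta_g_pct, g1$delta_g_pct)
  # one-year all-GS cycles beat three-year field cycles per year
  for (r in rs) {
    pw <- predict_gain(vc200(), selection_scheme("A_pWgs", 0.10, 0.05,
                                                 r_A = r), 3262, d)
    gs <- predict_gain(vc200(), selection_scheme("A_gsWgs", 0.10, 0.05,
                                                 r_A = r), 3262)
    expect_gt(gs$annual_pct, pw$annual_pct)
  }
})

test_that("cycle chaining accumulates percent gains against rolling means", {
  d <- design232()
  c1 <- predict_gain(vc200(),
                     selection_scheme("A_pWgs", 0.20, 0.10, r_A = 0.26),
                     3262, d)
  # progeny mean = previous mean + absolute gain
  m2 <- 3262 + c1$delta_g_abs
  expect_equal(m2, 3356, tolerance = 1)
  c2 <- predict_gain(vc200(),
                     selection_scheme("A_gsWgs", 0.20, 0.10, r_A = 0.26), m2)
  tot <- chain_cycles(list(c1, c2))
  expect_equal(tot$total_pct, c1$delta_g_pct + c2$delta_g_pct)
  expect_equal(tot$total_pct, 4.93, tolerance = 0.02)
  expect_equal(tot$total_years, 4)
  # single cycle chains to itself
  expect_equal(chain_cycles(list(c1))$total_pct, c1$delta_g_pct)
  # broken chaining is rejected
  c2bad <- predict_gain(vc200(),
                        selection_scheme("A_gsWgs", 0.20, 0.10, r_A = 0.26),
                        3500)
  expect_error(chain_cycles(list(c1, c2bad)), "base mean")
  expect_error(chain_cycles(list()), "non-empty")
  # costs sum when supplied
  expect_equal(chain_cycles(list(c1, c2),
                            costs = c(1e5, 2e5))$total_cost, 3e5)
})

test_that("parent counts follow the rounding rules", {
  expect_identical(parents_count(200, 0.20), 40L)
  expect_identical(parents_count(200, 0.02, 100, 0.01), 4L)
  expect_identical(parents_count(1000, 0.20, 100, 0.10), 2000L)
  expect_error(parents_count(200, 0.001), "zero families")
  expect_error(parents_count(200, 0.20, 100, 0.001), "zero individuals")
})
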