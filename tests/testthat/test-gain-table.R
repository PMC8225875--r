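test_that("gain table reproduces the published 200-family pressure series", {
  grid <- data.frame(strategy = rep(c("A_p", "A_Ph"), each = 4),
                     p_among = rep(c(0.20, 0.10, 0.05, 0.02), 2))
  tab <- gain_table(vc200(), design232(), 3262, grid)
  expect_equal(nrow(tab), 8L)
  expect_equal(round(tab$pct_gain[tab$strategy == "A_p"], 2),
               c(1.43, 1.80, 2.11, 2.47), tolerance = 0.015)
  expect_equal(round(tab$pct_gain[tab$strategy == "A_Ph"], 2),
               c(1.29, 1.62, 1.90, 2.22), tolerance = 0.015)
  expect_equal(tab$n_parents[tab$strategy == "A_p"], c(40L, 20L, 10L, 4L))
})

test_that("invalid grid rows are dropped with a warning, empty grids fail", {
  grid <- data.frame(strategy = c("A_p", "A_pWgs"), p_among = 0.20,
                     r_A = 0.26)   # Wgs row lacks p_within
  expect_warning(tab <- gain_table(vc200(), design232(), 3262, grid),
                 "dropped")
  expect_equal(nrow(tab), 1L)
  expect_error(gain_table(vc200(), design232(), 3262,
                          data.frame(strategy = character(),
                                     p_among = numeric())), "empty")
})

test_that("zero-accuracy all-GS rows show zero gain and no finite cost rate", {
  grid <- data.frame(strategy = "A_gsWgs", p_among = 0.20, p_within = 0.10,
                     r_A = 0)
  book <- cost_book(fixed_operational_per_cycle = 93000)
  tab <- gain_table(vc200(), design232(), 3262, grid, book = book)
  expect_equal(tab$pct_gain, 0)
  expect_true(is.na(tab$cost_per_pct))
  expect_true(tab$cost > 0)
})

test_that("gain tables round-trip through their CSV writers", {
  grid <- data.frame(strategy = "A_p", p_among = c(0.20, 0.10))
  tab <- gain_table(vc200(), design232(), 3262, grid,
                    book = cost_book(fixed_operational_per_cycle = 93000))
  path <- file.path(withr::local_tempdir(), "tab.csv")
  write_gain_table(tab, path)
  expect_true(file.exists(path))
  full <- read.csv(sub("\\.csv$", "_full.csv", path))
  expect_equal(full$pct_gain, tab$pct_gain, tolerance = 1e-12)
  rounded <- read.csv(path)
  expect_equal(rounded$pct_gain, round(tab$pct_gain, 2))
})

test_that("the end-to-end pipeline writes consistent deterministic outputs", {
  out1 <- file.path(withr::local_tempdir(), "run1")
  res <- run_pipeline(out1, seed = 11, n_families = 60,
                      book = cost_book(fixed_operational_per_cycle = 93000),
                      sim_iterations = 2L, sim_cycles = 2L)
  for (f in c("trial_records.csv", "components.csv", "family_blups.csv",
              "gain_table.csv", "gain_table_full.csv", "sim_summary.csv",
              "run_report.json"))
    expect_true(file.exists(file.path(out1, f)), label = f)
  expect_true(res$fit$converged)
  # rerun with the same seed: deterministic stages are byte-identical
  out2 <- file.path(withr::local_tempdir(), "run2")
  run_pipeline(out2, seed = 11, n_families = 60,
               book = cost_book(fixed_operational_per_cycle = 93000),
               sim_iterations = 2L, sim_cycles = 2L)
  expect_identical(readLines(file.path(out1, "gain_table_full.csv")),
                   readLines(file.path(out2, "gain_table_full.csv")))
  expect_identical(readLines(file.path(out1, "sim_summary.csv")),
                   readLines(file.path(out2, "sim_summary.csv")))
  # trial records round-trip through the CSV readers losslessly
  tr <- read_trial_csv(file.path(out1, "trial_records.csv"))
  p2 <- file.path(out1, "roundtrip.csv")
  write_trial_csv(tr, p2)
  expect_identical(readLines(file.path(out1, "trial_records.csv")),
                   readLines(p2))
})
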