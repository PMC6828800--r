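tiny_grid <- function(seeds = 1L) {
  scenario_grid(
    guilds = "forest", thresholds = 0.25, cv_relative = 4,
    methods = c("min_cost", "min_area", "crank"), seeds = seeds,
    config = landscape_config(n_rows_fine = 40, n_cols_fine = 40,
                              aggregation_factor = 10, cost_cv_target = 2,
                              n_species_per_guild = 2, seed = 1),
    targets = seq(0.2, 1, 0.2), gap = 0.01, time_limit = 2)
}

test_that("a sweep produces one row per scenario-target and an efficiency summary", {
  out <- run_experiment(tiny_grid(), quiet = TRUE)
  expect_equal(nrow(out$results), 3 * 5)  # 3 methods x 5 targets
  expect_setequal(unique(out$results$method),
                  c("min_cost", "min_area", "crank"))
  expect_true(all(out$results$status == "ok"))
  expect_equal(nrow(out$efficiency), 1L)
  expect_true(is.finite(out$efficiency$gain_biodiversity_data))
  expect_gte(out$efficiency$auc_min_cost,
             out$efficiency$auc_crank * (1 - 0.02))
})

test_that("sweeps are reproducible and write their tables and provenance", {
  d <- withr::local_tempdir()
  out1 <- run_experiment(tiny_grid(), output_dir = d, quiet = TRUE)
  out2 <- run_experiment(tiny_grid(), quiet = TRUE)
  expect_equal(out1$results$monetary_cost, out2$results$monetary_cost,
               tolerance = 1e-9)
  expect_true(file.exists(file.path(d, "results.csv")))
  expect_true(file.exists(file.path(d, "efficiency.csv")))
  prov <- jsonlite::read_json(file.path(d, "provenance.json"))
  expect_equal(prov$grid$config$n_rows_fine, 40)
  got <- read.csv(file.path(d, "results.csv"))
  expect_equal(nrow(got), nrow(out1$results))
})

test_that("an empty seed list is rejected and failures become failed rows", {
  expect_error(scenario_grid(seeds = integer(0)), "non-empty")
  # an inadmissible relative CV (offset would push costs negative) is
  # recorded, not thrown
  g <- tiny_grid()
  g$cv_relative <- 1e-4
  out <- run_experiment(g, quiet = TRUE)
  expect_true(all(out$results$status == "failed"))
  expect_match(out$results$message[1], "below zero")
})

test_that("the landscape report summarizes every layer and flags guild structure", {
  l <- default_landscape(1)
  rep <- validate_landscape_report(l)
  expect_equal(nrow(rep), 1 + length(l$occupancy))
  expect_identical(rep$layer[1], "cost")
  expect_equal(sum(rep$guild == "forest", na.rm = TRUE), 10)
  gm <- attr(rep, "guild_mean_r_cost")
  expect_gt(gm[["human"]], 0)
  expect_lt(gm[["forest"]], 0)
})

test_that("the command-line wrapper generates and aggregates a landscape", {
  skip_if_not_installed("optparse")
  cli <- system.file("cli", "minset-cli.R", package = "minset")
  cfgp <- withr::local_tempfile(fileext = ".yaml")
  write_landscape_config(small_config(seed = 12), cfgp)
  d <- withr::local_tempdir()
  rscript <- file.path(R.home("bin"), "Rscript")
  out <- system2(rscript, c(cli, "generate", "--config", shQuote(cfgp),
                            "--seed", "12", "--output", shQuote(d)),
                 stdout = TRUE, stderr = TRUE)
  expect_true(file.exists(file.path(d, "cost.tsv")))
  csv <- withr::local_tempfile(fileext = ".csv")
  system2(rscript, c(cli, "aggregate", "--input", shQuote(d),
                     "--output", shQuote(csv)), stdout = TRUE,
          stderr = TRUE)
  u <- read_planning_units(csv)
  expect_equal(nrow(u), 100)
  expect_length(guild_species(u, "forest"), 2)
})

test_that("configurations round-trip through YAML with overrides", {
  cfg <- small_config(seed = 8)
  p <- withr::local_tempfile(fileext = ".yaml")
  write_landscape_config(cfg, p)
  cfg2 <- read_landscape_config(p)
  expect_equal(unclass(cfg2), unclass(cfg), tolerance = 1e-12)
  cfg3 <- read_landscape_config(p, overrides = list(seed = 99L))
  expect_equal(cfg3$seed, 99L)
  writeLines("bogus_key: 1", p)
  expect_error(read_landscape_config(p), "unknown configuration")
})
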