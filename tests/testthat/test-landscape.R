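test_that("random fields are standardized, seed-deterministic, and reject degenerate input", {
  f1 <- generate_field(50, 50, 0, seed = 1)
  f2 <- generate_field(50, 50, 0, seed = 1)
  expect_identical(f1, f2)
  expect_lt(abs(mean(f1)), 1e-9)
  expect_lt(abs(sd(as.vector(f1)) - 1), 1e-9)
  expect_false(identical(f1, generate_field(50, 50, 0, seed = 2)))
  expect_error(generate_field(1, 1, 0, seed = 1), "degenerate")
  expect_error(generate_field(0, 5, 0, seed = 1), "positive")
})

test_that("smoothing induces positive neighbour correlation relative to white noise", {
  lag1 <- function(m) cor(as.vector(m[-1, ]), as.vector(m[-nrow(m), ]))
  white <- generate_field(50, 50, 0, seed = 1)
  smooth <- generate_field(50, 50, 5, seed = 1)
  expect_gt(lag1(smooth), lag1(white))
  expect_gt(lag1(smooth), 0.5)
})

test_that("cost layer hits its CV target, is positive, and spans orders of magnitude", {
  cfg <- landscape_config(seed = 1)
  f <- generate_field(cfg$n_rows_fine, cfg$n_cols_fine,
                      cfg$smoothing_length, cfg$seed)
  cost <- generate_cost_layer(cfg, f)
  v <- as.vector(cost)
  expect_gt(min(v), 0)
  expect_gt(sd(v) / mean(v), 6.5)
  expect_lt(sd(v) / mean(v), 8.0)
  expect_gt(max(v) / min(v), 1e3)
  # degenerate spread collapses to a constant layer
  cfg0 <- landscape_config(cost_log_spread = 0, seed = 1)
  expect_warning(cost0 <- generate_cost_layer(cfg0, f), "clamping")
  expect_lt(sd(as.vector(cost0)) / mean(cost0), 1e-12)
})

test_that("species layers carry the guild's cost-correlation sign and stay in [0,1]", {
  cfg <- small_config(seed = 2)
  f <- generate_field(cfg$n_rows_fine, cfg$n_cols_fine,
                      cfg$smoothing_length, cfg$seed)
  cost <- generate_cost_layer(cfg, f)
  hum <- generate_species_layer(cfg, f, "human", seed = 11)
  fr <- generate_species_layer(cfg, f, "forest", seed = 12)
  expect_true(all(hum >= 0 & hum <= 1))
  expect_gt(cor(as.vector(hum), as.vector(cost)), 0)
  expect_lt(cor(as.vector(fr), as.vector(cost)), 0)
  expect_error(generate_species_layer(cfg, f, "urban", seed = 1),
               "guild")
})

test_that("whole landscapes are deterministic with per-species CVs in the configured range", {
  cfg <- small_config(seed = 3)
  l1 <- generate_landscape(cfg)
  l2 <- generate_landscape(cfg)
  expect_identical(l1$cost, l2$cost)
  expect_identical(l1$occupancy, l2$occupancy)
  expect_length(l1$occupancy, 2 * cfg$n_species_per_guild)
  expect_equal(sum(l1$guild == "forest"), cfg$n_species_per_guild)
  expect_equal(sum(l1$guild == "human"), cfg$n_species_per_guild)
  rng <- cfg$species_cv_range
  for (nm in names(l1$occupancy)) {
    p <- as.vector(l1$occupancy[[nm]])
    expect_true(all(is.finite(p)) && all(p >= 0 & p <= 1))
    cvp <- sd(p) / mean(p)
    expect_gt(cvp, rng[1] * 0.75)
    expect_lt(cvp, rng[2] * 1.25)
  }
})

test_that("single-species-per-guild configuration yields exactly two layers", {
  cfg <- landscape_config(n_rows_fine = 60, n_cols_fine = 60, cost_cv_target = 2,
                          aggregation_factor = 10,
                          n_species_per_guild = 1, seed = 5)
  l <- generate_landscape(cfg)
  expect_length(l$occupancy, 2L)
  expect_setequal(unname(l$guild), c("forest", "human"))
})

test_that("configuration invariants are enforced", {
  expect_error(landscape_config(n_rows_fine = 55, aggregation_factor = 10),
               "divisible")
  expect_error(landscape_config(cost_cv_target = -1), "cost_cv_target")
  expect_error(landscape_config(species_cv_range = c(2, 1)),
               "species_cv_range")
})

test_that("landscapes and grids round-trip losslessly through text IO", {
  cfg <- landscape_config(n_rows_fine = 30, n_cols_fine = 20, cost_cv_target = 1.5,
                          aggregation_factor = 10,
                          n_species_per_guild = 1, seed = 9)
  l <- generate_landscape(cfg)
  d <- withr::local_tempdir()
  write_landscape(l, d)
  l2 <- read_landscape(d)
  expect_identical(l$cost, l2$cost)
  expect_identical(l$occupancy$forest_01, l2$occupancy$forest_01)
  expect_identical(l$guild, l2$guild)
  g <- matrix(c(pi, exp(1), 1 / 3, 1e-300), 2, 2)
  p <- withr::local_tempfile(fileext = ".tsv")
  write_grid(g, p)
  expect_identical(read_grid(p), g)
})
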