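test_that("eligibility is per-species, inclusive, and drives the target denominator", {
  u <- toy_units(c(1, 1, 1), cbind(c(0.2, 0.5, 0.9), c(0.6, 0.1, 0.3)))
  sp <- attr(u, "species")
  pr <- minset_problem(u, target_fraction = 0.5, occupancy_threshold = 0.5)
  expect_equal(eligible_units(pr, sp[1]), c(1L, 2L))  # boundary inclusive
  expect_equal(eligible_units(pr, sp[2]), 0L)
  expect_equal(species_total(pr, sp[1]), 1.4)
  expect_equal(species_total(pr, sp[2]), 0.6)
  pr0 <- minset_problem(u, target_fraction = 0.5, occupancy_threshold = 0)
  expect_equal(eligible_units(pr0, sp[1]), 0:2)
  expect_equal(species_total(pr0, sp[1]), 1.6)
  # pre-threshold denominator option uses the all-units total
  prd <- minset_problem(u, target_fraction = 0.5, occupancy_threshold = 0.5,
                        denominator = "pre_threshold")
  expect_equal(species_total(prd, sp[1]), 1.6)
  expect_error(eligible_units(pr, "sparrow"), "species")
})

test_that("a species with no suitable habitat makes the instance infeasible", {
  u <- toy_units(c(1, 2), cbind(c(0.5, 0.6), c(0.2, 0.3)))
  pr <- minset_problem(u, target_fraction = 0.5, occupancy_threshold = 0.4)
  expect_identical(solve_min_set(pr)$status, "infeasible")
  expect_identical(crank_select(pr)$status, "infeasible")
  expect_identical(brute_force_min_set(pr)$status, "infeasible")
})

test_that("the three-unit instance solves to the enumerated optimum", {
  u <- toy_units(c(1, 2, 10), cbind(c(0.1, 0.9, 0.9)))
  pr <- minset_problem(u, target_fraction = 0.5, occupancy_threshold = 0,
                       gap = 0)
  bf <- brute_force_min_set(pr)
  expect_equal(sort(bf$selected), c(0L, 1L))
  expect_equal(bf$monetary_cost, 3)
  sol <- solve_min_set(pr)
  expect_equal(sol$monetary_cost, 3)
  expect_equal(sort(sol$selected), c(0L, 1L))
  expect_identical(sol$status, "optimal_within_gap")
})

test_that("full targets at zero threshold force selecting every occupied unit", {
  u <- toy_units(c(3, 1, 2), cbind(c(0.2, 0.4, 0.3)))
  pr <- minset_problem(u, target_fraction = 1, occupancy_threshold = 0,
                       gap = 0)
  expect_equal(sort(solve_min_set(pr)$selected), 0:2)
})

test_that("cheapest-first selection follows cost order with unit-id tie-breaks", {
  u <- toy_units(c(5, 1, 3), cbind(c(0.5, 0.5, 0.5)))
  pr <- minset_problem(u, target_fraction = 0.5, occupancy_threshold = 0)
  sol <- crank_select(pr)
  expect_equal(sort(sol$selected), c(1L, 2L))
  expect_equal(sol$monetary_cost, 4)
  # equal costs: selection order is unit-id order
  ue <- toy_units(c(2, 2, 2, 2), cbind(c(0.3, 0.3, 0.3, 0.3)))
  pre <- minset_problem(ue, target_fraction = 0.5, occupancy_threshold = 0)
  expect_equal(sort(crank_select(pre)$selected), c(0L, 1L))
})

test_that("the exhaustive oracle breaks ties lexicographically and respects objectives", {
  # two optimal-cost subsets: {0,1} and {2}; lexicographic tuple wins
  u <- toy_units(c(1, 2, 3), cbind(c(0.5, 0.5, 1.0)))
  pr <- minset_problem(u, target_fraction = 0.5, occupancy_threshold = 0,
                       gap = 0)
  bf <- brute_force_min_set(pr)
  expect_equal(bf$monetary_cost, 3)
  expect_equal(sort(bf$selected), c(0L, 1L))
  # unit-count mode: one expensive unit beats any cheaper pair
  # (total 1.5, target 0.6 -> need 0.9: only unit 2 manages it alone)
  u2 <- toy_units(c(1, 1, 50), cbind(c(0.3, 0.3, 0.9)))
  pr2 <- minset_problem(u2, target_fraction = 0.6, occupancy_threshold = 0,
                        objective = "unit_count", gap = 0)
  bf2 <- brute_force_min_set(pr2)
  expect_equal(bf2$selected, 2L)
  expect_equal(bf2$objective_value, 1)
  expect_error(brute_force_min_set(minset_problem(
    toy_units(rep(1, 21), cbind(runif(21))), target_fraction = 0.1)),
    "guarded")
})

test_that("exact solutions match the oracle at gap zero across random instances", {
  seeds <- 1:50
  problems <- lapply(seeds, random_instance, gap = 0)
  sols <- minset:::solve_min_set_batch(problems)
  for (i in seq_along(seeds)) {
    bf <- brute_force_min_set(problems[[i]])
    expect_equal(sols[[i]]$objective_value, bf$objective_value,
                 tolerance = 1e-9,
                 info = sprintf("instance seed %d", seeds[i]))
  }
})

test_that("cheapest-first never beats the exact optimum and targets stay monotone", {
  for (s in c(3, 17, 29)) {
    pr <- random_instance(s, gap = 0)
    opt <- solve_min_set(pr)$monetary_cost
    expect_gte(crank_select(pr)$monetary_cost, opt * (1 - 1e-9))
    costs <- vapply(c(0.2, 0.5, 0.8), function(tf) {
      p <- pr; p$target_fraction <- tf
      solve_min_set(p)$monetary_cost
    }, 0)
    expect_true(all(diff(costs) >= -1e-9 * costs[-3]))
  }
})

test_that("raising the threshold never increases a species' total occupancy", {
  u <- default_units(1)
  sp <- guild_species(u, "human")[1]
  tots <- vapply(c(0, 0.25, 0.5, 0.75), function(thr)
    species_total(minset_problem(u, target_fraction = 0.5,
                                 occupancy_threshold = thr), sp), 0)
  expect_true(all(diff(tots) <= 1e-12))
})

test_that("unit-count solutions are invariant to an additive cost shift", {
  pr <- random_instance(11, gap = 0)
  pr$objective <- "unit_count"
  base <- solve_min_set(pr)
  shifted <- pr
  shifted$units$cost <- shifted$units$cost + 100
  sol2 <- solve_min_set(shifted)
  expect_equal(sol2$objective_value, base$objective_value)
})

test_that("cost correlation matches its closed forms and guards degeneracy", {
  u <- toy_units(c(1, 2, 3, 4), cbind(c(0.1, 0.2, 0.3, 0.4),
                                      c(0.8, 0.6, 0.4, 0.2)))
  sp <- attr(u, "species")
  expect_equal(cost_correlation(u, sp[1]), 1)
  expect_equal(cost_correlation(u, sp[2]), -1)
  uc <- toy_units(c(1, 2, 3), cbind(c(0.5, 0.5, 0.5)))
  expect_error(cost_correlation(uc, attr(uc, "species")[1]), "variance")
})

test_that("solutions serialize to JSON and membership CSV", {
  u <- toy_units(c(1, 2, 10), cbind(c(0.1, 0.9, 0.9)))
  sol <- solve_min_set(minset_problem(u, target_fraction = 0.5,
                                      occupancy_threshold = 0, gap = 0))
  jp <- withr::local_tempfile(fileext = ".json")
  cp <- withr::local_tempfile(fileext = ".csv")
  write_solution(sol, jp, cp)
  rec <- jsonlite::read_json(jp)
  expect_equal(unlist(rec$selected), c(0, 1))
  expect_equal(rec$monetary_cost, 3)
  mem <- read.csv(cp)
  expect_equal(mem$selected, c(1L, 1L, 0L))
})
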