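manual_curve <- function(targets, cost_fraction,
                         feasible = rep(TRUE, length(targets))) {
  structure(data.frame(target = targets, feasible = feasible,
                       monetary_cost = cost_fraction,
                       cost_fraction = cost_fraction,
                       n_selected = NA_real_),
            class = c("cost_benefit_curve", "data.frame"))
}

test_that("curve AUC recovers closed-form areas and its limiting behaviour", {
  tg <- seq(0.05, 1, 0.05)
  expect_equal(curve_auc(manual_curve(tg, tg)), 0.5)
  # everything achievable at negligible cost: AUC tends to 1
  expect_gt(curve_auc(manual_curve(tg, rep(1e-6, 20))), 0.999)
  # shifting the whole curve right strictly decreases the AUC
  a1 <- curve_auc(manual_curve(tg, tg * 0.5))
  a2 <- curve_auc(manual_curve(tg, pmin(tg * 0.5 + 0.2, 1)))
  expect_lt(a2, a1)
  expect_error(curve_auc(manual_curve(tg, tg, feasible = c(TRUE,
    rep(FALSE, 19)))), "degenerate")
})

test_that("transposed orientation ranks curves the opposite way", {
  tg <- seq(0.05, 1, 0.05)
  cheap <- manual_curve(tg, tg * 0.3)
  dear <- manual_curve(tg, pmin(tg * 0.3 + 0.3, 1))
  expect_gt(curve_auc(cheap), curve_auc(dear))
  expect_lt(curve_auc(cheap, "cost_vs_target"),
            curve_auc(dear, "cost_vs_target"))
})

test_that("fractional gain is the relative AUC improvement", {
  expect_equal(fractional_gain(0.5, 0.5), 0)
  expect_equal(fractional_gain(0.6, 0.4), 0.5)
  expect_false(isTRUE(all.equal(fractional_gain(0.6, 0.4),
                                -fractional_gain(0.4, 0.6))))
  expect_error(fractional_gain(0.5, 0), "positive")
})

test_that("curves report per-target feasibility and a monotone cost profile", {
  u <- toy_units(exp(seq(0, 3, length.out = 8)),
                 cbind(c(0.9, 0.1, 0.6, 0.2, 0.8, 0.1, 0.3, 0.7),
                       c(0.2, 0.8, 0.1, 0.7, 0.3, 0.9, 0.6, 0.1)))
  cur <- build_curve(u, occupancy_threshold = 0, method = "min_cost",
                     gap = 0)
  expect_true(all(cur$feasible))
  expect_true(all(diff(cur$monetary_cost) >= -1e-9))
  expect_true(all(cur$cost_fraction >= 0 & cur$cost_fraction <= 1))
  # single unit holding all occupancy: flat curve at that unit's cost share
  u1 <- toy_units(c(5, 1), cbind(c(0.9, 0)))
  c1 <- build_curve(u1, occupancy_threshold = 0, method = "min_cost",
                    gap = 0)
  expect_true(all(c1$feasible))
  expect_equal(unique(c1$monetary_cost), 5)
})

test_that("the cheapest-first curve never undercuts the exact curve", {
  u <- default_units(1)
  sp <- guild_species(u, "human")
  mc <- build_curve(u, sp, occupancy_threshold = 0.5, method = "min_cost",
                    time_limit = 1)
  cr <- build_curve(u, sp, occupancy_threshold = 0.5, method = "crank")
  both <- mc$feasible & cr$feasible
  expect_true(any(both))
  expect_true(all(cr$monetary_cost[both] >=
                    mc$monetary_cost[both] * (1 - 0.01 - 1e-9)))
  expect_gte(curve_auc(mc), curve_auc(cr) * (1 - 0.02))
})

test_that("infeasible targets are excluded from the AUC support", {
  u <- toy_units(c(1, 2), cbind(c(0.6, 0.7), c(0.9, 0.2)))
  # second species has no habitat above 0.95: every target infeasible
  cur <- build_curve(u, occupancy_threshold = 0.95, method = "min_cost",
                     gap = 0)
  expect_false(any(cur$feasible))
  expect_error(curve_auc(cur), "degenerate")
})
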