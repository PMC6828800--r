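default_targets <- function() seq(0.05, 1, by = 0.05)

#' Build a cost-benefit curve over the target ladder
#'
#' Solves one prioritization per occupancy target (default 5--100% in 5%
#' steps) with the given method and records each solution's monetary cost as
#' a fraction of the total cost of every unit in the table (the scenario's
#' cost layer, offset-adjusted if [apply_relative_cv()] was applied).
#' `min_area` solutions are solved without cost in the objective but costed
#' monetarily afterwards, which is how the value of cost data is measured.
#' Infeasible targets are flagged and excluded from AUC computation.
#'
#' @param units a `planning_units` table.
#' @param species species subset (e.g. one guild).
#' @param occupancy_threshold habitat-suitability threshold in `[0, 1)`.
#' @param method `"min_cost"`, `"min_area"` or `"crank"`.
#' @param gap relative optimality gap for exact methods (default 0.01).
#' @param targets target ladder (default `seq(0.05, 1, 0.05)`).
#' @param denominator target-denominator convention, see [minset_problem()].
#' @param time_limit optional per-solve wall-clock cap in seconds, see
#'   [minset_problem()].
#' @return a `cost_benefit_curve`: a data frame with columns `target`,
#'   `feasible`, `monetary_cost`, `cost_fraction`, `n_selected`, plus
#'   scenario metadata in attributes.
#' @export
build_curve <- function(units, species = species_names(units),
                        occupancy_threshold = 0,
                        method = c("min_cost", "min_area", "crank"),
                        gap = 0.01, targets = default_targets(),
                        denominator = "post_threshold", time_limit = Inf) {
  method <- match.arg(method)
  sols <- curve_solutions(units, species, occupancy_threshold, method, gap,
                          targets, denominator, time_limit)
  curve_from_solutions(sols, targets, total_cost = sum(units$cost),
                       species = species, threshold = occupancy_threshold,
                       method = method)
}

curve_solutions <- function(units, species, occupancy_threshold, method,
                            gap, targets, denominator, time_limit = Inf) {
  problems <- lapply(targets, function(tf)
    minset_problem(units, species, target_fraction = tf,
                   occupancy_threshold = occupancy_threshold,
                   objective = if (method == "min_area") "unit_count" else
                     "monetary_cost",
                   gap = gap, denominator = denominator,
                   time_limit = time_limit))
  if (method == "crank") lapply(problems, crank_select) else
    solve_min_set_batch(problems)
}

curve_from_solutions <- function(sols, targets, total_cost, species,
                                 threshold, method, cv_relative = NA_real_) {
  df <- data.frame(
    target = targets,
    feasible = vapply(sols, function(s) s$status != "infeasible", TRUE),
    monetary_cost = vapply(sols, function(s) s$monetary_cost, 0),
    n_selected = vapply(sols, function(s) as.numeric(s$n_selected), 0))
  df$cost_fraction <- df$monetary_cost / total_cost
  structure(df, species = species, threshold = threshold, method = method,
            cv_relative = cv_relative, total_cost = total_cost,
            class = c("cost_benefit_curve", "data.frame"))
}

#' @export
print.cost_benefit_curve <- function(x, ...) {
  cat(sprintf(
    "Cost-benefit curve (%s, threshold %.0f%%%s): %d/%d targets feasible\n",
    attr(x, "method"), 100 * attr(x, "threshold"),
    if (is.na(attr(x, "cv_relative"))) "" else
      sprintf(", relative CV %.3g", attr(x, "cv_relative")),
    sum(x$feasible), nrow(x)))
  NextMethod()
}

#' Plot a cost-benefit curve
#'
#' Achieved occupancy target against cost fraction; steeper curves are more
#' efficient.
#'
#' @param x a `cost_benefit_curve` (or list of them via `lines`-style
#'   overplotting by the caller).
#' @param add logical, add to an existing plot.
#' @param ... passed to [graphics::lines()].
#' @export
plot.cost_benefit_curve <- function(x, add = FALSE, ...) {
  f <- x[x$feasible, , drop = FALSE]
  xs <- c(0, f$cost_fraction)
  ys <- c(0, f$target)
  if (!add)
    plot(NA, xlim = c(0, 1), ylim = c(0, 1),
         xlab = "cost (fraction of total landscape cost)",
         ylab = "occupancy target achieved",
         main = sprintf("%s, threshold %.0f%%", attr(x, "method"),
                        100 * attr(x, "threshold")))
  lines(xs, ys, ...)
  invisible(x)
}

#' Area under a cost-benefit curve
#'
#' Efficiency metric for a whole target ladder. With the default
#' orientation, the curve is the piecewise-linear path through the origin
#' and the feasible `(cost_fraction, target)` points, extended flat to
#' `cost_fraction = 1`; the AUC is its integral over `[0, 1]`, so a curve
#' reaching the full target at negligible cost has AUC near 1 and the
#' diagonal has AUC 0.5. The transposed orientation
#' (`"cost_vs_target"`, area under cost as a function of target, lower =
#' better) is also available.
#'
#' @param curve a `cost_benefit_curve` with at least 2 feasible points.
#' @param orientation `"target_vs_cost"` (default; higher = more efficient)
#'   or `"cost_vs_target"` (lower = more efficient).
#' @return scalar in `[0, 1]`.
#' @export
curve_auc <- function(curve,
                      orientation = c("target_vs_cost", "cost_vs_target")) {
  orientation <- match.arg(orientation)
  f <- curve[curve$feasible, , drop = FALSE]
  if (nrow(f) < 2L)
    stop("degenerate curve: fewer than 2 feasible points", call. = FALSE)
  if (orientation == "target_vs_cost") {
    xs <- c(0, f$cost_fraction)
    ys <- c(0, f$target)
    o <- order(xs)
    xs <- xs[o]; ys <- ys[o]
    # extend flat at the maximum achieved target out to cost fraction 1
    if (max(xs) < 1) {
      xs <- c(xs, 1)
      ys <- c(ys, ys[length(ys)])
    }
    auc <- sum(diff(xs) * (head(ys, -1) + diff(ys) / 2))
  } else {
    xs <- c(0, f$target)
    ys <- c(0, f$cost_fraction)
    auc <- sum(diff(xs) * (head(ys, -1) + diff(ys) / 2))
  }
  min(max(auc, 0), 1)
}

#' Fractional gain in efficiency between two scenarios
#'
#' `(auc_with - auc_without) / auc_without`: the relative AUC improvement
#' from including a data layer (e.g. exact minimum-cost selection versus the
#' no-cost minimum-area solution, or versus the no-biodiversity C-rank
#' baseline).
#'
#' @param auc_with,auc_without AUC of the richer and poorer scenario;
#'   `auc_without` must be positive.
#' @return scalar (0 when equal; positive when the richer scenario is more
#'   efficient).
#' @export
fractional_gain <- function(auc_with, auc_without) {
  if (auc_without <= 0)
    stop("baseline AUC must be positive", call. = FALSE)
  (auc_with - auc_without) / auc_without
}
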