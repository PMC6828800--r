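#' Define a minimum-set prioritization problem
#'
#' A problem instance fixes the planning-unit table, the species in play
#' (typically one guild), a common representation target, the occupancy
#' threshold defining suitable habitat, the objective (monetary cost or
#' number of units), and the solver's relative optimality gap.
#'
#' Eligibility is per species and inclusive: a unit counts toward species
#' `s` iff its occupancy for `s` is `>= occupancy_threshold`. Ineligible
#' occupancy contributes nothing to a species' constraint, but the unit
#' itself remains selectable (it may serve another species). By default a
#' species' target denominator is its total occupancy over *eligible* units
#' (`denominator = "post_threshold"`), so a 100% target means "capture all
#' suitable habitat"; `"pre_threshold"` instead uses the total over all
#' units.
#'
#' @param units a `planning_units` table.
#' @param species species subset (character vector of occupancy columns);
#'   default all species.
#' @param target_fraction common per-species representation target in
#'   (0, 1].
#' @param occupancy_threshold minimum occupancy probability for a unit to
#'   count as suitable habitat, in `[0, 1)`.
#' @param objective `"monetary_cost"` (minimize summed cost) or
#'   `"unit_count"` (minimize the number of selected units).
#' @param gap relative optimality gap for the integer program (default 0.01,
#'   i.e. within 1\% of the optimum).
#' @param denominator `"post_threshold"` (default) or `"pre_threshold"`.
#' @param time_limit optional wall-clock cap (seconds) on the solver's proof
#'   effort for this instance. When the cap is hit the best feasible
#'   solution found is returned with its actually-achieved gap reported
#'   (status `"feasible_suboptimal"` if that gap exceeds `gap`). Useful in
#'   large sweeps where near-flat cost layers make the last fraction of the
#'   bound expensive to certify; `Inf` (default) means solve to `gap`.
#' @return an object of class `minset_problem`.
#' @export
minset_problem <- function(units, species = species_names(units),
                           target_fraction, occupancy_threshold = 0,
                           objective = c("monetary_cost", "unit_count"),
                           gap = 0.01,
                           denominator = c("post_threshold",
                                           "pre_threshold"),
                           time_limit = Inf) {
  objective <- match.arg(objective)
  denominator <- match.arg(denominator)
  if (length(species) == 0L)
    stop("species subset must be non-empty", call. = FALSE)
  missing_sp <- setdiff(species, names(units))
  if (length(missing_sp) > 0)
    stop("unknown species: ", paste(missing_sp, collapse = ", "),
         call. = FALSE)
  if (!is.numeric(target_fraction) || length(target_fraction) != 1L ||
      target_fraction <= 0 || target_fraction > 1)
    stop("target_fraction must lie in (0, 1]", call. = FALSE)
  if (occupancy_threshold < 0 || occupancy_threshold >= 1)
    stop("occupancy_threshold must lie in [0, 1)", call. = FALSE)
  if (gap < 0) stop("gap must be >= 0", call. = FALSE)
  if (!is.numeric(time_limit) || time_limit <= 0)
    stop("time_limit must be positive (Inf for none)", call. = FALSE)
  structure(list(units = units, species = species,
                 target_fraction = target_fraction,
                 occupancy_threshold = occupancy_threshold,
                 objective = objective, gap = gap,
                 denominator = denominator, time_limit = time_limit),
            class = "minset_problem")
}

#' @export
print.minset_problem <- function(x, ...) {
  cat(sprintf(
    "Minimum-set problem: %d units, %d species, target %.0f%%, threshold %.0f%%\n",
    nrow(x$units), length(x$species), 100 * x$target_fraction,
    100 * x$occupancy_threshold))
  cat(sprintf("  objective: %s, optimality gap %.3g, denominator: %s\n",
              x$objective, x$gap, x$denominator))
  invisible(x)
}

check_species <- function(problem, species) {
  if (!species %in% problem$species)
    stop("species not in problem subset: ", species, call. = FALSE)
}

#' Units eligible for a species
#'
#' Units whose occupancy for `species` meets the problem's threshold
#' (inclusive comparison).
#'
#' @param problem a [minset_problem()].
#' @param species one species id from the problem's subset.
#' @return integer vector of 0-based `unit_id`s.
#' @export
eligible_units <- function(problem, species) {
  check_species(problem, species)
  occ <- problem$units[[species]]
  problem$units$unit_id[occ >= problem$occupancy_threshold]
}

#' Total occupancy backing a species' target
#'
#' Sum of the species' occupancy over its eligible units (the target
#' denominator under the default post-threshold convention), or over all
#' units when the problem uses the pre-threshold denominator.
#'
#' @inheritParams eligible_units
#' @return nonnegative scalar.
#' @export
species_total <- function(problem, species) {
  check_species(problem, species)
  occ <- problem$units[[species]]
  if (problem$denominator == "pre_threshold") return(sum(occ))
  sum(occ[occ >= problem$occupancy_threshold])
}

# constraint system of a problem: eligibility-masked occupancy matrix
# (species x units), target right-hand sides, objective weights
problem_matrices <- function(problem) {
  u <- problem$units
  n <- nrow(u)
  m <- length(problem$species)
  P <- matrix(0, m, n, dimnames = list(problem$species, NULL))
  for (i in seq_len(m)) {
    occ <- u[[problem$species[i]]]
    P[i, ] <- ifelse(occ >= problem$occupancy_threshold, occ, 0)
  }
  totals <- vapply(problem$species, function(s) species_total(problem, s), 0)
  list(P = P, totals = totals,
       rhs = problem$target_fraction * totals,
       weights = if (problem$objective == "monetary_cost") u$cost
                 else rep(1, n))
}

#' Pearson correlation between a species' occupancy and unit cost
#'
#' @param units a `planning_units` table with at least 3 units.
#' @param species one species column name.
#' @return correlation in `[-1, 1]`.
#' @export
cost_correlation <- function(units, species) {
  if (!species %in% species_names(units))
    stop("unknown species: ", species, call. = FALSE)
  if (nrow(units) < 3L) stop("need at least 3 units", call. = FALSE)
  x <- units$cost
  y <- units[[species]]
  if (sd(x) == 0 || sd(y) == 0)
    stop("correlation undefined: zero variance", call. = FALSE)
  cor(x, y)
}
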