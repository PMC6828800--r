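feas_tol <- 1e-9

# assemble a minset_solution from a selection (1-based indices into units)
make_solution <- function(problem, sel_idx, status, method,
                          solver_gap = NA_real_) {
  u <- problem$units
  mats <- problem_matrices(problem)
  sel_idx <- sort(sel_idx)
  captured <- if (length(sel_idx))
    rowSums(mats$P[, sel_idx, drop = FALSE]) else
    rep(0, length(problem$species))
  rep_tab <- data.frame(species = problem$species,
                        captured = as.numeric(captured),
                        total = as.numeric(mats$totals),
                        fraction = ifelse(mats$totals > 0,
                                          captured / mats$totals, NA_real_))
  rownames(rep_tab) <- NULL
  structure(list(
    selected = u$unit_id[sel_idx],
    objective_value = sum(mats$weights[sel_idx]),
    monetary_cost = sum(u$cost[sel_idx]),
    n_selected = length(sel_idx),
    representation = rep_tab,
    status = status,
    solver_gap = solver_gap,
    method = method,
    objective = problem$objective,
    target_fraction = problem$target_fraction,
    occupancy_threshold = problem$occupancy_threshold,
    gap = problem$gap,
    n_units = nrow(u)), class = "minset_solution")
}

infeasible_solution <- function(problem, method) {
  out <- make_solution(problem, integer(0), "infeasible", method)
  out$objective_value <- NA_real_
  out$monetary_cost <- NA_real_
  out
}

# species with an empty eligible set make the instance infeasible outright
# under the post-threshold denominator ("capture x% of nothing" is treated
# as unmeetable, not as trivially met)
empty_eligible <- function(problem) {
  any(vapply(problem$species,
             function(s) length(eligible_units(problem, s)) == 0L, TRUE))
}

#' Solve the minimum-set problem exactly
#'
#' Minimizes `sum(w_i * x_i)` over binary selections `x`, where `w_i` is the
#' unit's cost (`objective = "monetary_cost"`) or 1 (`"unit_count"`),
#' subject to one covering constraint per species: the occupancy captured
#' over that species' eligible units must reach `target_fraction` of the
#' species' total. Solved with the HiGHS branch-and-bound solver to the
#' problem's relative optimality gap.
#'
#' @param problem a [minset_problem()].
#' @return a `minset_solution` with status `"optimal_within_gap"` or
#'   `"infeasible"`. Solver failures raise an error; they are never reported
#'   as infeasibility.
#' @export
solve_min_set <- function(problem) {
  solve_min_set_batch(list(problem))[[1]]
}

# batched variant: one backend invocation for many problems
solve_min_set_batch <- function(problems) {
  method <- vapply(problems, function(p)
    if (p$objective == "monetary_cost") "min_cost" else "min_area", "")
  todo <- !vapply(problems, empty_eligible, TRUE)
  jobs <- lapply(problems[todo], function(p) {
    mats <- problem_matrices(p)
    job <- list(weights = mats$weights, P = mats$P, rhs = mats$rhs,
                gap = p$gap)
    if (is.finite(p$time_limit)) job$time_limit <- p$time_limit
    job
  })
  answers <- milp_batch(jobs)
  out <- vector("list", length(problems))
  j <- 0L
  for (i in seq_along(problems)) {
    if (!todo[i]) {
      out[[i]] <- infeasible_solution(problems[[i]], method[i])
      next
    }
    j <- j + 1L
    ans <- answers[[j]]
    if (ans$status == "infeasible") {
      out[[i]] <- infeasible_solution(problems[[i]], method[i])
    } else {
      status <- if (ans$status == "optimal" ||
                    (!is.na(ans$mip_gap) &&
                     ans$mip_gap <= problems[[i]]$gap + 1e-9))
        "optimal_within_gap" else "feasible_suboptimal"
      sol <- make_solution(problems[[i]], ans$selected, status, method[i],
                           solver_gap = ans$mip_gap)
      # a returned incumbent must actually meet every target
      if (any(sol$representation$fraction <
              problems[[i]]$target_fraction - 1e-6, na.rm = TRUE))
        stop("MILP solver returned an infeasible incumbent", call. = FALSE)
      out[[i]] <- sol
    }
  }
  out
}

#' Cheapest-first (C-rank) selection
#'
#' The cost-data-only baseline: units are bought from cheapest to most
#' expensive (ties broken by ascending `unit_id`) until every species'
#' target is met; biodiversity data are used only to detect when targets are
#' satisfied, with the same eligibility rule as [solve_min_set()].
#'
#' @param problem a [minset_problem()].
#' @return a `minset_solution` (status `"infeasible"` if the targets are
#'   still unmet after buying every unit).
#' @export
crank_select <- function(problem) {
  if (empty_eligible(problem)) return(infeasible_solution(problem, "crank"))
  u <- problem$units
  mats <- problem_matrices(problem)
  ord <- order(u$cost, u$unit_id)
  cums <- apply(mats$P[, ord, drop = FALSE], 1, cumsum)  # n x m
  if (!is.matrix(cums)) cums <- matrix(cums, nrow = 1)
  need <- matrix(mats$rhs - feas_tol, nrow(u), length(problem$species),
                 byrow = TRUE)
  met_all <- rowSums(cums < need) == 0L
  if (!any(met_all)) return(infeasible_solution(problem, "crank"))
  k <- which(met_all)[1]
  make_solution(problem, ord[seq_len(k)], "optimal_within_gap", "crank",
                solver_gap = NA_real_)
}

#' Exhaustive-enumeration oracle for small instances
#'
#' Enumerates every subset of units (guarded to at most 20 units) and
#' returns the feasible subset minimizing the objective, with ties broken by
#' the lexicographically smallest tuple of selected unit ids. Used as an
#' independent check on [solve_min_set()].
#'
#' @param problem a [minset_problem()] with at most 20 units.
#' @return a `minset_solution`.
#' @export
brute_force_min_set <- function(problem) {
  n <- nrow(problem$units)
  if (n > 20L)
    stop("brute force guarded to <= 20 units (got ", n, ")", call. = FALSE)
  if (empty_eligible(problem))
    return(infeasible_solution(problem, "exhaustive"))
  mats <- problem_matrices(problem)
  w <- mats$weights
  P <- mats$P
  rhs <- mats$rhs
  m <- length(rhs)
  best_obj <- Inf
  best_masks <- integer(0)
  chunk <- 2^16
  total <- 2^n
  start <- 0
  while (start < total) {
    msk <- as.integer(start + seq_len(min(chunk, total - start)) - 1)
    obj <- numeric(length(msk))
    feas <- matrix(TRUE, length(msk), 1)
    cap <- matrix(0, length(msk), m)
    for (j in seq_len(n)) {
      has <- bitwAnd(msk, bitwShiftL(1L, j - 1L)) != 0L
      obj <- obj + w[j] * has
      if (m > 0) cap <- cap + tcrossprod(as.numeric(has), P[, j])
    }
    ok <- if (m > 0) rowSums(cap < matrix(rhs - feas_tol, length(msk), m,
                                          byrow = TRUE)) == 0L else
      rep(TRUE, length(msk))
    if (any(ok)) {
      o <- obj[ok]
      mk <- msk[ok]
      cmin <- min(o)
      if (cmin < best_obj - 1e-12 * max(1, abs(cmin))) {
        best_obj <- cmin
        best_masks <- integer(0)
      }
      tol <- 1e-12 * max(1, abs(best_obj))
      best_masks <- c(best_masks, mk[o <= best_obj + tol])
    }
    start <- start + chunk
  }
  if (!length(best_masks)) return(infeasible_solution(problem, "exhaustive"))
  ids_of <- function(mask)
    which(bitwAnd(mask, bitwShiftL(1L, seq_len(n) - 1L)) != 0L)
  tuples <- lapply(best_masks, ids_of)
  best <- tuples[[1]]
  for (t in tuples[-1]) if (lex_less(t, best)) best <- t
  make_solution(problem, best, "optimal_within_gap", "exhaustive",
                solver_gap = 0)
}

# TRUE if tuple a precedes tuple b lexicographically (both ascending)
lex_less <- function(a, b) {
  k <- min(length(a), length(b))
  if (k > 0) for (i in seq_len(k)) {
    if (a[i] < b[i]) return(TRUE)
    if (a[i] > b[i]) return(FALSE)
  }
  length(a) < length(b)
}

#' Run one prioritization
#'
#' The package's central fitting-style entry point: solves one problem
#' instance with the requested method and returns a classed solution.
#'
#' @param problem a [minset_problem()].
#' @param method `"min_cost"` (exact, monetary objective), `"min_area"`
#'   (exact, unit-count objective, i.e. no cost data), `"crank"`
#'   (cheapest-first baseline, i.e. no biodiversity data beyond target
#'   bookkeeping), or `"exhaustive"` (enumeration oracle, small instances
#'   only).
#' @return a `minset_solution`.
#' @export
#' @examples
#' \dontrun{
#' cfg <- landscape_config(n_rows_fine = 60, n_cols_fine = 60, cost_cv_target = 2,
#'                         aggregation_factor = 10, seed = 1)
#' pu <- aggregate(generate_landscape(cfg))
#' pr <- minset_problem(pu, guild_species(pu, "forest"),
#'                      target_fraction = 0.3, occupancy_threshold = 0.25)
#' prioritize(pr, "min_cost")
#' }
prioritize <- function(problem,
                       method = c("min_cost", "min_area", "crank",
                                  "exhaustive")) {
  method <- match.arg(method)
  if (method == "crank") return(crank_select(problem))
  if (method == "exhaustive") return(brute_force_min_set(problem))
  problem$objective <- if (method == "min_cost") "monetary_cost" else
    "unit_count"
  solve_min_set(problem)
}

#' @export
print.minset_solution <- function(x, ...) {
  cat(sprintf("Minimum-set solution (%s): %s\n", x$method, x$status))
  if (x$status != "infeasible") {
    cat(sprintf(
      "  %d of %d units selected; monetary cost %.6g; objective %.6g\n",
      x$n_selected, x$n_units, x$monetary_cost, x$objective_value))
    cat(sprintf("  target %.0f%%, threshold %.0f%%; min representation %.1f%%\n",
                100 * x$target_fraction, 100 * x$occupancy_threshold,
                100 * min(x$representation$fraction)))
  }
  invisible(x)
}

#' @export
summary.minset_solution <- function(object, ...) {
  print(object)
  cat("Per-species representation:\n")
  print(object$representation, digits = 4)
  invisible(object$representation)
}
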