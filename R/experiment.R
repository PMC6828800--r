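#' Define a scenario grid
#'
#' The cross-product of guilds, occupancy thresholds, relative-CV levels and
#' selection methods evaluated by [run_experiment()], together with the
#' landscape configuration and replicate seeds. Defaults mirror the full
#' study grid: both guilds, thresholds 25/50/75%, benefit-to-cost CV ratios
#' 2/4/8/16, and the three methods (exact with cost, exact without cost,
#' cheapest-first).
#'
#' @param guilds subset of `c("forest", "human")`.
#' @param thresholds occupancy thresholds in `[0, 1)`.
#' @param cv_relative relative-CV levels (`NA` entries mean "leave the cost
#'   layer as generated").
#' @param methods subset of `c("min_cost", "min_area", "crank")`.
#' @param seeds non-empty integer vector of replicate landscape seeds.
#' @param config a [landscape_config()] (its own seed is overridden by each
#'   replicate seed).
#' @param targets occupancy-target ladder.
#' @param gap solver relative optimality gap.
#' @param denominator target-denominator convention.
#' @param auc_orientation AUC orientation, see [curve_auc()].
#' @param time_limit optional per-solve wall-clock cap in seconds, see
#'   [minset_problem()].
#' @return an object of class `scenario_grid`.
#' @export
scenario_grid <- function(guilds = c("forest", "human"),
                          thresholds = c(0.25, 0.5, 0.75),
                          cv_relative = c(2, 4, 8, 16),
                          methods = c("min_cost", "min_area", "crank"),
                          seeds = 1L,
                          config = landscape_config(),
                          targets = default_targets(),
                          gap = 0.01,
                          denominator = "post_threshold",
                          auc_orientation = "target_vs_cost",
                          time_limit = Inf) {
  if (length(seeds) == 0L)
    stop("seeds must be a non-empty integer vector", call. = FALSE)
  if (!all(guilds %in% guild_levels)) stop("unknown guild", call. = FALSE)
  if (!all(methods %in% c("min_cost", "min_area", "crank")))
    stop("unknown method", call. = FALSE)
  validate_landscape_config(config)
  structure(list(guilds = guilds, thresholds = thresholds,
                 cv_relative = cv_relative, methods = methods,
                 seeds = as.integer(seeds), config = config,
                 targets = targets, gap = gap, denominator = denominator,
                 auc_orientation = auc_orientation,
                 time_limit = time_limit),
            class = "scenario_grid")
}

#' @export
print.scenario_grid <- function(x, ...) {
  cat(sprintf(
    "Scenario grid: %d guild(s) x %d threshold(s) x %d CV level(s) x %d method(s) x %d seed(s)\n",
    length(x$guilds), length(x$thresholds), length(x$cv_relative),
    length(x$methods), length(x$seeds)))
  cat(sprintf("  = %d curves of %d targets each\n",
              length(x$guilds) * length(x$thresholds) *
                length(x$cv_relative) * length(x$methods) * length(x$seeds),
              length(x$targets)))
  invisible(x)
}

#' Run the full scenario sweep
#'
#' For every replicate seed: generates the landscape, aggregates it to
#' planning units, and for every (guild, threshold, relative CV, method)
#' cell rescales the cost layer, builds the cost-benefit curve, and computes
#' its AUC. Scenario failures (e.g. an inadmissible CV offset) are recorded
#' as failed rows and the sweep continues. Everything is deterministic given
#' the grid, so re-running reproduces the same tables (exact methods up to
#' solver ties within the optimality gap).
#'
#' @param grid a [scenario_grid()].
#' @param output_dir optional directory; when given, writes `results.csv`
#'   (one row per scenario x target), `efficiency.csv` (one row per scenario
#'   with AUC and fractional gains) and `provenance.json`.
#' @param quiet suppress per-scenario progress messages.
#' @return invisibly, a list with `results` (long table), `efficiency`
#'   (AUC/gain summary) and `provenance`.
#' @export
run_experiment <- function(grid, output_dir = NULL, quiet = FALSE) {
  stopifnot(inherits(grid, "scenario_grid"))
  results <- list()
  curves <- list()
  say <- function(...) if (!quiet) message(sprintf(...))
  for (seed in grid$seeds) {
    cfg <- grid$config
    cfg$seed <- as.integer(seed)
    say("landscape seed %d: generating %d x %d fine grid", seed,
        cfg$n_rows_fine, cfg$n_cols_fine)
    units0 <- aggregate.fine_landscape(generate_landscape(cfg))
    for (guild in grid$guilds) {
      sp <- guild_species(units0, guild)
      for (cvr in grid$cv_relative) {
        key <- sprintf("s%d_%s_cv%s", seed, guild,
                       ifelse(is.na(cvr), "raw", format(cvr)))
        units <- tryCatch(
          if (is.na(cvr)) units0 else apply_relative_cv(units0, cvr, sp),
          error = function(e) e)
        for (thr in grid$thresholds) {
          for (method in grid$methods) {
            skey <- sprintf("%s_t%02.0f_%s", key, 100 * thr, method)
            if (inherits(units, "error")) {
              results[[skey]] <- failed_rows(seed, guild, thr, cvr, method,
                                             grid$targets,
                                             conditionMessage(units))
              next
            }
            cur <- tryCatch(
              build_curve(units, sp, occupancy_threshold = thr,
                          method = method, gap = grid$gap,
                          targets = grid$targets,
                          denominator = grid$denominator,
                          time_limit = grid$time_limit),
              error = function(e) e)
            if (inherits(cur, "error")) {
              results[[skey]] <- failed_rows(seed, guild, thr, cvr, method,
                                             grid$targets,
                                             conditionMessage(cur))
              next
            }
            say("  %s: %d/%d targets feasible", skey, sum(cur$feasible),
                nrow(cur))
            curves[[skey]] <- cur
            results[[skey]] <- data.frame(
              seed = seed, guild = guild, threshold = thr,
              cv_relative = cvr, method = method, target = cur$target,
              feasible = cur$feasible, monetary_cost = cur$monetary_cost,
              cost_fraction = cur$cost_fraction,
              n_selected = cur$n_selected, status = "ok", message = "")
          }
        }
      }
    }
  }
  results <- do.call(rbind, c(results, list(make.row.names = FALSE)))
  efficiency <- summarize_efficiency(results, grid$auc_orientation)
  provenance <- list(grid = unclass_grid(grid),
                     r_version = as.character(getRversion()),
                     package_version = as.character(
                       utils::packageVersion("minset")),
                     timestamp = format(Sys.time(), tz = "UTC"))
  if (!is.null(output_dir)) {
    dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
    write.csv(results, file.path(output_dir, "results.csv"),
              row.names = FALSE)
    write.csv(efficiency, file.path(output_dir, "efficiency.csv"),
              row.names = FALSE)
    jsonlite::write_json(provenance,
                         file.path(output_dir, "provenance.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(list(results = results, efficiency = efficiency,
                 provenance = provenance))
}

failed_rows <- function(seed, guild, thr, cvr, method, targets, msg) {
  data.frame(seed = seed, guild = guild, threshold = thr, cv_relative = cvr,
             method = method, target = targets, feasible = FALSE,
             monetary_cost = NA_real_, cost_fraction = NA_real_,
             n_selected = NA_real_, status = "failed", message = msg)
}

unclass_grid <- function(grid) {
  g <- unclass(grid)
  g$config <- unclass(g$config)
  g
}

# AUC per scenario plus fractional gains between method pairs
summarize_efficiency <- function(results, orientation = "target_vs_cost") {
  ok <- results[results$status == "ok", , drop = FALSE]
  keys <- unique(ok[, c("seed", "guild", "threshold", "cv_relative")])
  out <- list()
  for (i in seq_len(nrow(keys))) {
    k <- keys[i, ]
    sub <- merge(ok, k)
    aucs <- c(min_cost = NA_real_, min_area = NA_real_, crank = NA_real_)
    for (method in unique(sub$method)) {
      s <- sub[sub$method == method, , drop = FALSE]
      s <- s[order(s$target), , drop = FALSE]
      curve <- structure(
        data.frame(target = s$target, feasible = s$feasible,
                   monetary_cost = s$monetary_cost,
                   cost_fraction = s$cost_fraction,
                   n_selected = s$n_selected),
        class = c("cost_benefit_curve", "data.frame"))
      aucs[method] <- if (sum(s$feasible) >= 2)
        curve_auc(curve, orientation) else NA_real_
    }
    out[[i]] <- cbind(k, data.frame(
      auc_min_cost = aucs["min_cost"], auc_min_area = aucs["min_area"],
      auc_crank = aucs["crank"],
      gain_cost_data = if (!is.na(aucs["min_cost"]) &&
                           !is.na(aucs["min_area"]) && aucs["min_area"] > 0)
        fractional_gain(aucs["min_cost"], aucs["min_area"]) else NA_real_,
      gain_biodiversity_data = if (!is.na(aucs["min_cost"]) &&
                                   !is.na(aucs["crank"]) &&
                                   aucs["crank"] > 0)
        fractional_gain(aucs["min_cost"], aucs["crank"]) else NA_real_))
  }
  res <- do.call(rbind, c(out, list(make.row.names = FALSE)))
  rownames(res) <- NULL
  res
}

#' Diagnostics table for a generated landscape
#'
#' The synthetic analogue of a study area's descriptive statistics: one row
#' for the cost layer (CV and orders of magnitude spanned) and one per
#' species (occupancy CV and Pearson correlation with cost, at fine
#' resolution), with guild-mean correlations attached as an attribute and
#' shown by `print`.
#'
#' @param landscape a `fine_landscape`.
#' @return a data frame of class `landscape_report`.
#' @export
validate_landscape_report <- function(landscape) {
  stopifnot(inherits(landscape, "fine_landscape"))
  cost <- as.vector(landscape$cost)
  cost_cv <- sd(cost) / mean(cost)
  if (cost_cv == 0) warning("degenerate landscape: constant cost layer")
  rows <- data.frame(layer = "cost", guild = NA_character_,
                     mean = mean(cost), cv = cost_cv,
                     r_cost = NA_real_,
                     log10_range = log10(max(cost) / min(cost)))
  for (nm in names(landscape$occupancy)) {
    occ <- as.vector(landscape$occupancy[[nm]])
    rows <- rbind(rows, data.frame(
      layer = nm, guild = unname(landscape$guild[nm]), mean = mean(occ),
      cv = sd(occ) / mean(occ),
      r_cost = if (sd(occ) > 0 && sd(cost) > 0) cor(occ, cost) else NA_real_,
      log10_range = NA_real_))
  }
  guild_means <- tapply(rows$r_cost[-1], rows$guild[-1], mean)
  structure(rows, guild_mean_r_cost = guild_means,
            class = c("landscape_report", "data.frame"))
}

#' @export
print.landscape_report <- function(x, ...) {
  cat("Landscape diagnostics\n")
  print.data.frame(x, digits = 3, row.names = FALSE)
  gm <- attr(x, "guild_mean_r_cost")
  cat(sprintf("guild mean r_cost: %s\n",
              paste(sprintf("%s %+.3f", names(gm), gm), collapse = ", ")))
  invisible(x)
}
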