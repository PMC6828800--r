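#' Aggregate a fine landscape into planning units
#'
#' Collapses blocks of `factor x factor` fine cells into planning units,
#' taking the sum of the cost layer and the mean of each species occupancy
#' layer -- the standard coarsening used when 1-ha data are planned at the
#' 1-km^2 scale. Blocks are axis-aligned, non-overlapping and anchored at the
#' grid origin; units are indexed 0-based in row-major order.
#'
#' @param x a `fine_landscape` from [generate_landscape()].
#' @param factor fine cells per planning-unit side; must divide both grid
#'   dimensions (no partial edge units). Defaults to the landscape's
#'   configured `aggregation_factor`.
#' @param ... ignored.
#' @return a `planning_units` object: a data frame with columns `unit_id`
#'   (0-based), `row`, `col`, `cost`, then one occupancy column per species
#'   (forest guild first, then human), with the guild lookup kept in
#'   `attr(, "guild")`.
#' @export
#' @examples
#' cfg <- landscape_config(n_rows_fine = 40, n_cols_fine = 40, cost_cv_target = 2,
#'                         aggregation_factor = 10, n_species_per_guild = 2,
#'                         seed = 1)
#' pu <- aggregate(generate_landscape(cfg))
#' head(pu)
aggregate.fine_landscape <- function(x, factor = NULL, ...) {
  if (is.null(factor)) factor <- x$config$aggregation_factor
  factor <- as.integer(factor)
  if (factor < 1L) stop("aggregation factor must be >= 1", call. = FALSE)
  nr <- nrow(x$cost); nc <- ncol(x$cost)
  if (nr %% factor != 0L || nc %% factor != 0L)
    stop(sprintf(
      "fine dimensions %d x %d not divisible by aggregation factor %d",
      nr, nc, factor), call. = FALSE)
  nru <- nr %/% factor
  ncu <- nc %/% factor
  block_apply <- function(m, fun) {
    # sum/mean over factor x factor blocks via two reshapes
    a <- array(m, dim = c(factor, nru, factor, ncu))
    apply(a, c(2, 4), fun)
  }
  cost_u <- block_apply(x$cost, sum)
  # row-major unit ids: unit_id = row * ncu + col, rows/cols 0-based
  grid <- expand.grid(col = 0:(ncu - 1), row = 0:(nru - 1))
  units <- data.frame(unit_id = grid$row * ncu + grid$col,
                      row = grid$row, col = grid$col,
                      cost = as.vector(t(cost_u)))
  for (nm in names(x$occupancy))
    units[[nm]] <- as.vector(t(block_apply(x$occupancy[[nm]], mean)))
  units <- units[order(units$unit_id), , drop = FALSE]
  rownames(units) <- NULL
  planning_units(units, guild = x$guild)
}

#' @rdname aggregate.fine_landscape
#' @export
aggregate.planning_units <- function(x, factor, ...) {
  factor <- as.integer(factor)
  if (factor < 1L) stop("aggregation factor must be >= 1", call. = FALSE)
  nru <- max(x$row) + 1L
  ncu <- max(x$col) + 1L
  if (nru %% factor != 0L || ncu %% factor != 0L)
    stop(sprintf(
      "unit grid %d x %d not divisible by aggregation factor %d",
      nru, ncu, factor), call. = FALSE)
  to_matrix <- function(v) {
    m <- matrix(NA_real_, nru, ncu)
    m[cbind(x$row + 1L, x$col + 1L)] <- v
    m
  }
  ls_like <- list(cost = to_matrix(x$cost),
                  occupancy = lapply(
                    setNames(species_names(x), species_names(x)),
                    function(nm) to_matrix(x[[nm]])),
                  guild = guild_of(x),
                  config = NULL)
  class(ls_like) <- "fine_landscape"
  aggregate.fine_landscape(ls_like, factor)
}

#' Construct or validate a planning-unit table
#'
#' @param units a data frame with columns `unit_id`, `row`, `col`, `cost`
#'   and one column per species.
#' @param guild named character vector mapping species column names to
#'   `"forest"` or `"human"`.
#' @return the validated `planning_units` data frame.
#' @export
planning_units <- function(units, guild) {
  sp <- setdiff(names(units), c("unit_id", "row", "col", "cost"))
  if (!all(sp %in% names(guild)))
    stop("every species column needs a guild label", call. = FALSE)
  guild <- guild[sp]
  n <- nrow(units)
  if (!setequal(units$unit_id, 0:(n - 1)))
    stop("unit_id must be a bijection onto 0..n_units-1", call. = FALSE)
  if (any(!is.finite(units$cost)) || any(units$cost <= 0))
    stop("unit costs must be strictly positive and finite", call. = FALSE)
  occ <- as.matrix(units[, sp, drop = FALSE])
  if (any(!is.finite(occ)) || any(occ < -1e-12) || any(occ > 1 + 1e-12))
    stop("unit occupancies must lie in [0, 1]", call. = FALSE)
  structure(units, guild = guild, species = sp,
            class = c("planning_units", "data.frame"))
}

#' @export
print.planning_units <- function(x, ...) {
  cat(sprintf("Planning units: %d units, %d species; total cost %.6g\n",
              nrow(x), length(attr(x, "species")), sum(x$cost)))
  NextMethod()
}

species_names <- function(units) attr(units, "species")

guild_of <- function(units) attr(units, "guild")

#' Species belonging to one guild of a planning-unit table
#'
#' @param units a `planning_units` table.
#' @param guild `"forest"` or `"human"`, or `NULL` for all species.
#' @return character vector of species column names.
#' @export
guild_species <- function(units, guild = NULL) {
  if (is.null(guild)) return(species_names(units))
  if (!guild %in% guild_levels)
    stop("unknown guild label: ", guild, call. = FALSE)
  names(guild_of(units))[guild_of(units) == guild]
}
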