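# Plain-text readers and writers. Grids go to delimited text at full double
# precision (%.17g), which round-trips losslessly; tables to CSV; solutions
# and provenance to JSON; configurations to YAML.

#' Write / read a numeric grid as delimited text
#'
#' Tab-separated, one grid row per line, `%.17g` formatting so the
#' round-trip is lossless at double precision.
#'
#' @param grid numeric matrix.
#' @param path file path.
#' @return `read_grid` returns the matrix; `write_grid` the path,
#'   invisibly.
#' @export
write_grid <- function(grid, path) {
  stopifnot(is.matrix(grid))
  txt <- apply(grid, 1, function(r) paste(sprintf("%.17g", r),
                                          collapse = "\t"))
  writeLines(txt, path)
  invisible(path)
}

#' @rdname write_grid
#' @export
read_grid <- function(path) {
  rows <- strsplit(readLines(path), "\t", fixed = TRUE)
  m <- t(vapply(rows, as.numeric, numeric(length(rows[[1]]))))
  if (length(rows[[1]]) == 1L) m <- matrix(unlist(lapply(rows, as.numeric)),
                                           ncol = 1)
  m
}

#' Write a fine landscape's layers to a directory
#'
#' One text grid per layer (`cost.tsv`, `<species>.tsv`) plus a
#' `landscape.yaml` with the configuration and guild labels.
#'
#' @param landscape a `fine_landscape`.
#' @param dir output directory (created if needed).
#' @return invisibly, the directory.
#' @export
write_landscape <- function(landscape, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_grid(landscape$cost, file.path(dir, "cost.tsv"))
  for (nm in names(landscape$occupancy))
    write_grid(landscape$occupancy[[nm]], file.path(dir,
                                                    paste0(nm, ".tsv")))
  meta <- list(guild = as.list(landscape$guild),
               config = unclass(landscape$config))
  yaml::write_yaml(meta, file.path(dir, "landscape.yaml"))
  invisible(dir)
}

#' @rdname write_landscape
#' @export
read_landscape <- function(dir) {
  meta <- yaml::read_yaml(file.path(dir, "landscape.yaml"))
  cfg <- do.call(landscape_config, meta$config)
  guild <- unlist(meta$guild)
  occupancy <- lapply(setNames(names(guild), names(guild)), function(nm)
    read_grid(file.path(dir, paste0(nm, ".tsv"))))
  out <- list(cost = read_grid(file.path(dir, "cost.tsv")),
              occupancy = occupancy, guild = guild, config = cfg)
  class(out) <- "fine_landscape"
  validate_fine_landscape(out)
  out
}

#' Write / read a planning-unit table as CSV
#'
#' Columns `unit_id, row, col, cost`, then one occupancy column per species
#' (forest guild first, then human, in generation order). Numeric values are
#' written at full double precision. Guild labels are recovered from the
#' species column-name prefixes on read.
#'
#' @param units a `planning_units` table.
#' @param path CSV path.
#' @return `read_planning_units` returns the table; `write_planning_units`
#'   the path, invisibly.
#' @export
write_planning_units <- function(units, path) {
  df <- as.data.frame(units)
  num <- vapply(df, is.numeric, TRUE) & !(names(df) %in%
                                            c("unit_id", "row", "col"))
  for (nm in names(df)[num]) df[[nm]] <- sprintf("%.17g", df[[nm]])
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_planning_units
#' @export
read_planning_units <- function(path) {
  df <- read.csv(path, check.names = FALSE)
  sp <- setdiff(names(df), c("unit_id", "row", "col", "cost"))
  guild <- setNames(sub("_.*$", "", sp), sp)
  if (!all(guild %in% guild_levels))
    stop("cannot infer guilds from species column names", call. = FALSE)
  planning_units(df, guild)
}

#' Serialize a solution to JSON and selection membership to CSV
#'
#' @param solution a `minset_solution`.
#' @param json_path optional path for the JSON record (selected ids, costs,
#'   per-species representation, status, solver gap).
#' @param csv_path optional path for a `unit_id, selected` 0/1 membership
#'   table.
#' @return invisibly, the JSON-ready list.
#' @export
write_solution <- function(solution, json_path = NULL, csv_path = NULL) {
  stopifnot(inherits(solution, "minset_solution"))
  rec <- list(method = solution$method, status = solution$status,
              objective = solution$objective,
              objective_value = solution$objective_value,
              monetary_cost = solution$monetary_cost,
              target_fraction = solution$target_fraction,
              occupancy_threshold = solution$occupancy_threshold,
              gap = solution$gap, solver_gap = solution$solver_gap,
              selected = solution$selected,
              representation = solution$representation)
  if (!is.null(json_path))
    jsonlite::write_json(rec, json_path, auto_unbox = TRUE, digits = NA,
                         na = "null")
  if (!is.null(csv_path)) {
    sel <- data.frame(unit_id = 0:(solution$n_units - 1))
    sel$selected <- as.integer(sel$unit_id %in% solution$selected)
    write.csv(sel, csv_path, row.names = FALSE)
  }
  invisible(rec)
}

#' Read / write configurations as YAML
#'
#' `read_landscape_config()` builds a [landscape_config()] from a YAML (or
#' JSON) file whose keys mirror the constructor arguments; unknown keys are
#' an error, missing ones take the defaults.
#'
#' @param path YAML file path.
#' @param overrides named list of values taking precedence over the file
#'   (e.g. parsed command-line flags).
#' @return a `landscape_config`.
#' @export
read_landscape_config <- function(path, overrides = list()) {
  vals <- yaml::read_yaml(path)
  vals <- modifyList(vals, overrides)
  bad <- setdiff(names(vals), names(formals(landscape_config)))
  if (length(bad))
    stop("unknown configuration keys: ", paste(bad, collapse = ", "),
         call. = FALSE)
  do.call(landscape_config, vals)
}

#' @rdname read_landscape_config
#' @param config a `landscape_config` to serialize.
#' @export
write_landscape_config <- function(config, path) {
  validate_landscape_config(config)
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}
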