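#' Coefficient of variation
#'
#' Sample standard deviation (n-1 denominator) divided by the sample mean.
#' The same convention is used everywhere in the package, so ratios of CVs
#' are internally consistent.
#'
#' @param values numeric vector with at least two elements and nonzero mean.
#' @return nonnegative scalar.
#' @export
#' @examples
#' cv(c(1, 3))  # sqrt(2)/2
cv <- function(values) {
  if (length(values) < 2L)
    stop("CV needs at least 2 values", call. = FALSE)
  m <- mean(values)
  if (m == 0) stop("CV undefined: zero mean", call. = FALSE)
  sd(values) / m
}

#' Benefit coefficient of variation
#'
#' The benefit CV of a scenario is the arithmetic mean of the per-species
#' occupancy CVs over the species in play (by default, computed at
#' planning-unit resolution, the scale the prioritization operates on).
#'
#' @param units a `planning_units` table.
#' @param species character vector of species columns (e.g. one guild from
#'   [guild_species()]); must be non-empty.
#' @return positive scalar.
#' @export
benefit_cv <- function(units, species = species_names(units)) {
  if (length(species) == 0L)
    stop("species subset must be non-empty", call. = FALSE)
  missing_sp <- setdiff(species, names(units))
  if (length(missing_sp) > 0)
    stop("unknown species: ", paste(missing_sp, collapse = ", "),
         call. = FALSE)
  mean(vapply(species, function(s) cv(units[[s]]), 0))
}

#' Additive cost offset achieving a requested relative CV
#'
#' The relative CV of a scenario is `CV_benefit / CV_cost`. Adding a constant
#' `delta` to every unit cost changes the mean but not the standard
#' deviation, so the offset that makes the post-shift relative CV equal
#' `cv_relative` is
#' `delta = cv_relative * sd_cost / cv_benefit - mu_cost`.
#'
#' @param mu_cost,sd_cost mean and sample standard deviation of unit costs
#'   (`sd_cost > 0`).
#' @param cv_benefit benefit CV (> 0), held constant by the manipulation.
#' @param cv_relative requested ratio `CV_benefit / CV_cost` (> 0).
#' @return the offset (may be negative when the raw ratio already exceeds
#'   the request).
#' @export
#' @examples
#' delta_cost(mu_cost = 10, sd_cost = 5, cv_benefit = 1, cv_relative = 4)
delta_cost <- function(mu_cost, sd_cost, cv_benefit, cv_relative) {
  if (sd_cost <= 0) stop("sd_cost must be > 0", call. = FALSE)
  if (cv_benefit <= 0) stop("cv_benefit must be > 0", call. = FALSE)
  if (cv_relative <= 0) stop("cv_relative must be > 0", call. = FALSE)
  cv_relative * sd_cost / cv_benefit - mu_cost
}

#' Rescale a cost layer to a requested relative CV
#'
#' Shifts every unit cost by the [delta_cost()] offset so that the ratio of
#' the benefit CV (over `species`) to the cost CV equals `cv_relative`
#' exactly. The shift is additive, so the cost standard deviation and the
#' cost ordering of units are unchanged, and occupancy columns are
#' untouched. The applied offset and the CVs involved are recorded in
#' `attr(, "cv_scaling")` for provenance.
#'
#' @param units a `planning_units` table.
#' @param cv_relative requested `CV_benefit / CV_cost` (> 0).
#' @param species species set defining the benefit CV (default: all species
#'   in the table; prioritizations run per guild normally pass one guild).
#' @return the rescaled `planning_units` table.
#' @export
apply_relative_cv <- function(units, cv_relative,
                              species = species_names(units)) {
  mu <- mean(units$cost)
  sdev <- sd(units$cost)
  cvb <- benefit_cv(units, species)
  delta <- delta_cost(mu, sdev, cvb, cv_relative)
  new_cost <- units$cost + delta
  if (any(new_cost <= 0))
    stop(sprintf(
      "relative CV %.4g needs offset %.6g, which drives %d unit cost(s) below zero",
      cv_relative, delta, sum(new_cost <= 0)), call. = FALSE)
  out <- units
  out$cost <- new_cost
  spec <- list(cv_relative = cv_relative, mu_cost = mu, sd_cost = sdev,
               cv_benefit = cvb, delta_cost = delta, species = species)
  class(spec) <- "cv_scaling_spec"
  attr(out, "cv_scaling") <- spec
  out
}

#' @export
print.cv_scaling_spec <- function(x, ...) {
  cat(sprintf(
    "CV rescaling: relative CV %.4g (benefit CV %.4g over %d species)\n",
    x$cv_relative, x$cv_benefit, length(x$species)))
  cat(sprintf("  cost mean %.6g, sd %.6g, additive offset %.6g\n",
              x$mu_cost, x$sd_cost, x$delta_cost))
  invisible(x)
}
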