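# Interface to the HiGHS integer-programming solver, reached through the
# scientific Python stack (scipy.optimize.milp) that ships alongside R in
# this toolchain. Problems are solved in batches so interpreter start-up is
# paid once per batch.

the <- new.env(parent = emptyenv())

find_python <- function() {
  if (!is.null(the$python)) return(the$python)
  cand <- c(getOption("minset.python", ""),
            Sys.getenv("MINSET_PYTHON", ""),
            Sys.which("python3"), Sys.which("python"),
            file.path(dirname(dirname(R.home())), "bin", "python"))
  cand <- cand[nzchar(cand) & file.exists(cand)]
  for (py in cand) {
    ok <- tryCatch(
      system2(py, c("-c", shQuote("import scipy.optimize")),
              stdout = FALSE, stderr = FALSE) == 0L,
      error = function(e) FALSE, warning = function(w) FALSE)
    if (ok) {
      the$python <- py
      return(py)
    }
  }
  stop("no python interpreter with scipy found; point options(minset.python=) ",
       "or MINSET_PYTHON at one", call. = FALSE)
}

#' Is the integer-programming backend available?
#'
#' The minimum-set solver delegates to HiGHS via `scipy.optimize.milp`.
#' This checks that a suitable Python interpreter can be found.
#'
#' @return `TRUE` or `FALSE`.
#' @export
minset_solver_available <- function() {
  ok <- tryCatch({find_python(); TRUE}, error = function(e) FALSE)
  ok
}

# problems: list of list(weights, P (dense species x units matrix), rhs, gap)
# returns: list of list(status, selected (1-based), objective, mip_gap)
milp_batch <- function(problems) {
  if (length(problems) == 0L) return(list())
  py <- find_python()
  script <- system.file("python", "milp_backend.py", package = "minset",
                        mustWork = TRUE)
  payload <- list(problems = lapply(problems, function(p) {
    nz <- which(p$P != 0, arr.ind = TRUE)
    out <- list(n = ncol(p$P),
                weights = as.numeric(p$weights),
                m = nrow(p$P),
                ai = as.integer(nz[, 1] - 1L),
                aj = as.integer(nz[, 2] - 1L),
                ax = as.numeric(p$P[nz]),
                rhs = as.numeric(p$rhs),
                gap = as.numeric(p$gap))
    if (!is.null(p$time_limit)) out$time_limit <- p$time_limit
    out
  }))
  fin <- tempfile(fileext = ".json")
  fout <- tempfile(fileext = ".json")
  on.exit(unlink(c(fin, fout)), add = TRUE)
  jsonlite::write_json(payload, fin, auto_unbox = TRUE, digits = NA)
  code <- system2(py, c(script, fin, fout), stdout = FALSE, stderr = "")
  if (code != 0L || !file.exists(fout))
    stop("MILP backend failed (exit code ", code, ")", call. = FALSE)
  res <- jsonlite::read_json(fout, simplifyVector = FALSE)
  lapply(res, function(r) {
    if (identical(r$status, "error"))
      stop("MILP solver error: ", r$message, call. = FALSE)
    list(status = r$status,
         selected = if (length(r$selected)) unlist(r$selected) + 1L
                    else integer(0),
         objective = r$objective,
         mip_gap = if (is.null(r$mip_gap)) NA_real_ else r$mip_gap)
  })
}
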