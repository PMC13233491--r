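# Internal numeric helpers shared across modules.

# absolute-tolerance equality for doses (mg); fractions use .FRAC_TOL
.DOSE_TOL <- 1e-6
.FRAC_TOL <- 1e-9

near <- function(x, y, tol = .DOSE_TOL) {
  !is.na(x) & !is.na(y) & abs(x - y) <= tol
}

#' Display percentage
#'
#' Formats `count / denom` as a percentage rounded to one decimal place,
#' the convention used throughout the evaluation reports. All stored rates
#' keep the raw count/denominator pair; this rounding is display-only.
#'
#' @param count numerator (a count of cases).
#' @param denom denominator (cases at risk).
#' @return numeric percentage rounded to one decimal.
#' @examples
#' display_pct(210, 288) # 72.9
#' @export
display_pct <- function(count, denom) {
  stopifnot(denom > 0)
  round(100 * count / denom, 1)
}

# Evaluate `expr` under a temporary RNG seed, restoring the caller's RNG
# state afterwards. `seed = NULL` leaves the stream untouched.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Stable short hash of an R object (via its canonical JSON), used to stamp
# pipeline artifacts so a report can be traced to its configuration.
config_hash <- function(x) {
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f))
  writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, force = TRUE), f)
  unname(tools::md5sum(f))
}

# number -> compact string that round-trips through as.numeric
num_chr <- function(x) {
  ifelse(is.na(x), "NA", format(round(x, 6), trim = TRUE, scientific = FALSE))
}
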