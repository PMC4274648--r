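#' Round half away from zero
#'
#' Display rounding used throughout the evaluation tables: ties go up
#' (`85.65` -> `85.7`), unlike [base::round()]'s round-half-even.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return numeric vector rounded half-up.
#' @export
#' @examples
#' roundHalfUp(c(85.645, 0.5, 2.675), 1)
roundHalfUp <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + sqrt(.Machine$double.eps)) / p
}

# run code under a temporary RNG state; seed must be a single finite integer
.withSeed <- function(seed, code) {
  if (length(seed) != 1L || !is.finite(seed)) {
    stop("'seed' must be a single finite integer", call. = FALSE)
  }
  withr::with_seed(as.integer(seed), code)
}

# stable hash of a configuration list, via its canonical JSON serialisation
.configHash <- function(x) {
  json <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, null = "null")
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf), add = TRUE)
  writeLines(as.character(json), tf)
  unname(tools::md5sum(tf))
}

.stopIf <- function(cond, ...) if (isTRUE(cond)) stop(..., call. = FALSE)

# format a proportion as the tables print it: percentage, one decimal half-up
.fmtPct <- function(p) {
  ifelse(is.na(p), "NA", formatC(roundHalfUp(100 * p, 1), format = "f", digits = 1))
}
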