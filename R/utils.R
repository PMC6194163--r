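#' @importFrom rlang %||%
#' @importFrom dplyr %>%
NULL

#' Round a fraction to a whole percentage, half away from zero
#'
#' Cohort yields are displayed as whole percentages with halves rounded up
#' (so 27/40 = 67.5% prints as 68%), the convention used throughout the
#' report tables. The raw numerator and denominator are always kept
#' alongside the rounded value.
#'
#' @param num numerator (count)
#' @param den denominator (count)
#' @return integer percentage, or `NA` when the denominator is zero
#' @export
pct_round <- function(num, den) {
  if (length(den) == 0L || is.na(den) || den == 0) return(NA_integer_)
  as.integer(floor(num / den * 100 + 0.5))
}

# Deterministic 31-bit seed derived from a base seed and a string tag, so
# each family/stage gets its own reproducible RNG stream. Plain polynomial
# string hash; collisions are harmless (streams differ by content anyway).
string_seed <- function(seed, tag) {
  h <- as.double(seed %% 2147483647L)
  for (k in utf8ToInt(tag)) {
    h <- (h * 131 + k) %% 2147483647
  }
  as.integer(h)
}

# Evaluate `code` under a temporary RNG state seeded with `seed`.
with_seed <- function(seed, code) {
  withr::with_seed(seed, code)
}

#' Path to a packaged data file
#'
#' @param file file name under the package's `extdata` directory; when
#'   omitted, lists the available files.
#' @return a file path (or a character vector of file names)
#' @export
mitotriage_example <- function(file = NULL) {
  if (is.null(file)) {
    dir(system.file("extdata", package = "mitotriage"))
  } else {
    p <- system.file("extdata", file, package = "mitotriage")
    if (p == "") stop("no packaged file called ", file, call. = FALSE)
    p
  }
}
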