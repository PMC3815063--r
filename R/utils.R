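#' @importFrom rlang .data abort warn inform %||%
#' @importFrom tibble tibble as_tibble
#' @import dplyr
NULL

#' Round half-up to a fixed number of decimals
#'
#' Table-style rounding: 0.5 always rounds away from zero, unlike base
#' [round()]'s round-half-even. Used when reproducing printed table values;
#' full precision is kept everywhere else.
#'
#' @param x numeric vector.
#' @param digits integer, decimal places.
#' @return numeric vector.
#' @export
#' @examples
#' round_half_up(0.545, 2)  # 0.55, where round() gives 0.54
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' N50 of a set of lengths
#'
#' The length L such that pieces of length >= L together contain at least
#' half the total. Computed by sorting descending and cumulating.
#'
#' @param lengths numeric vector of piece lengths (bp).
#' @return a single length on the same scale as the input; `NA` for empty
#'   input.
#' @export
#' @examples
#' n50(c(10, 9, 8, 7, 6))  # 9: 10+9 = 19 >= 40/2
n50 <- function(lengths) {
  lengths <- lengths[!is.na(lengths) & lengths > 0]
  if (length(lengths) == 0L) return(NA_real_)
  s <- sort(lengths, decreasing = TRUE)
  s[which(cumsum(s) >= sum(s) / 2)[1]]
}

# internal: stop with a classed linkpeak error
lp_abort <- function(msg, class = "linkpeak_error", ...) {
  rlang::abort(msg, class = c(class, "linkpeak_error"), ...)
}

# internal: check required columns in a data frame
check_cols <- function(df, cols, what = "input") {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0L) {
    lp_abort(sprintf("%s is missing required column(s): %s",
                     what, paste(missing, collapse = ", ")))
  }
  invisible(df)
}

# internal: derive a stream-specific 32-bit seed from a base seed so the
# generator modules don't consume each other's random streams
derive_seed <- function(seed, stream) {
  offsets <- c(genome = 101L, scaffolds = 211L, matepairs = 307L,
               markers = 401L, genotypes = 503L, foreign = 601L,
               noise = 701L)
  off <- offsets[[stream]] %||% 997L
  as.integer((as.numeric(seed) * 7919 + off) %% 2147483647)
}
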