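#' Filter a genotype matrix on missing data
#'
#' Removes loci, then individuals, with a missing fraction at or above
#' `max_missing`, then re-checks loci once (individual removal can only
#' lower locus missingness, so one re-check suffices for the individuals
#' that remain).
#'
#' @param geno character matrix (loci x individuals), backcross coding
#'   `A`/`H`, `NA` for missing.
#' @param max_missing removal threshold as a fraction; a row/column is
#'   removed when its missing fraction is `>= max_missing` (default 0.20, so
#'   exactly 20% missing is removed).
#' @return a list with `geno` (the filtered matrix), `removed_loci` and
#'   `removed_individuals` (character vectors of ids).
#' @export
filter_genotype_matrix <- function(geno, max_missing = 0.20) {
  if (is.null(dim(geno)) || nrow(geno) == 0L || ncol(geno) == 0L) {
    lp_abort("genotype matrix is empty")
  }
  if (max_missing <= 0 || max_missing > 1) lp_abort("max_missing must be in (0, 1]")
  miss_frac_rows <- function(m) rowMeans(is.na(m))
  removed_loci <- character()
  removed_ind <- character()

  bad <- miss_frac_rows(geno) >= max_missing
  removed_loci <- rownames(geno)[bad]
  geno <- geno[!bad, , drop = FALSE]

  bad_i <- colMeans(is.na(geno)) >= max_missing
  removed_ind <- colnames(geno)[bad_i]
  geno <- geno[, !bad_i, drop = FALSE]

  bad2 <- miss_frac_rows(geno) >= max_missing
  removed_loci <- c(removed_loci, rownames(geno)[bad2])
  geno <- geno[!bad2, , drop = FALSE]

  list(geno = geno, removed_loci = removed_loci,
       removed_individuals = removed_ind)
}

#' Collapse identically segregating loci
#'
#' Loci with identical call vectors (including the missing pattern) are
#' genetically redundant on a single map; one representative per set is
#' retained — the lexicographically smallest locus id — and the membership
#' is returned so collapsed markers can later inherit their representative's
#' map position during anchoring.
#'
#' @param geno character matrix (loci x individuals).
#' @return list with `geno` (unique loci only) and `groups`, a tibble with
#'   columns `representative` and `member` covering every input locus
#'   (singletons included).
#' @export
collapse_cosegregating <- function(geno) {
  if (nrow(geno) == 0L) {
    return(list(geno = geno,
                groups = tibble(representative = character(), member = character())))
  }
  key <- apply(geno, 1L, function(v) paste(ifelse(is.na(v), ".", v), collapse = ""))
  ids <- rownames(geno)
  groups <- tibble(member = ids, key = key) |>
    group_by(.data$key) |>
    mutate(representative = min(.data$member)) |>
    ungroup() |>
    select("representative", "member") |>
    arrange(.data$representative, .data$member)
  keep <- sort(unique(groups$representative))
  list(geno = geno[keep, , drop = FALSE], groups = groups)
}

#' Segregation-distortion scan
#'
#' Chi-square test of each locus against the 1:1 backcross expectation
#' (df = 1), missing calls excluded per locus. Distorted loci are reported,
#' never removed: distortion is a property to map, not a QC failure.
#'
#' @param geno character matrix (loci x individuals) over `A`/`H`/`NA`.
#' @return tibble with columns `locus_id, n_A, n_H, chi2, p_value, flagged`
#'   (`flagged` marks loci with zero observed calls, for which no test is
#'   computed).
#' @export
segregation_distortion <- function(geno) {
  if (nrow(geno) == 0L) {
    return(tibble(locus_id = character(), n_A = integer(), n_H = integer(),
                  chi2 = numeric(), p_value = numeric(), flagged = logical()))
  }
  n_A <- unname(rowSums(geno == "A", na.rm = TRUE))
  n_H <- unname(rowSums(geno == "H", na.rm = TRUE))
  n <- n_A + n_H
  e <- n / 2
  chi2 <- ifelse(n > 0, (n_A - e)^2 / e + (n_H - e)^2 / e, NA_real_)
  tibble(
    locus_id = rownames(geno),
    n_A = as.integer(n_A), n_H = as.integer(n_H),
    chi2 = chi2,
    p_value = ifelse(n > 0, stats::pchisq(chi2, df = 1, lower.tail = FALSE), NA_real_),
    flagged = n == 0
  )
}

#' Kosambi map function and its inverse
#'
#' `kosambi_cM()` converts a recombination fraction r in `[0, 0.5)` to map
#' distance d = 25 ln((1+2r)/(1-2r)) centimorgans; `kosambi_r()` inverts it,
#' r = tanh(d/50)/2. The pair round-trips to machine precision.
#'
#' @param r recombination fraction(s), `0 <= r < 0.5`.
#' @return map distance in cM.
#' @export
#' @examples
#' kosambi_cM(0.25)       # 25 * log(3) = 27.465...
#' kosambi_r(kosambi_cM(0.1))
kosambi_cM <- function(r) {
  if (any(r < 0 | r >= 0.5)) lp_abort("recombination fraction must be in [0, 0.5)")
  25 * log((1 + 2 * r) / (1 - 2 * r))
}

#' @rdname kosambi_cM
#' @param d map distance(s) in cM, `d >= 0`.
#' @export
kosambi_r <- function(d) {
  if (any(d < 0)) lp_abort("map distance must be >= 0")
  tanh(d / 50) / 2
}

#' Average marker interval spacing of a linkage map
#'
#' Map length divided by the number of marker intervals: `n_mapped - 1` for
#' a single linkage group, `n_mapped - n_groups` for a combined map (each
#' group contributes one fewer interval than markers). Reported rounded
#' half-up to 2 decimals, matching map-summary table conventions.
#'
#' @param map_length_cM total map length in cM.
#' @param n_mapped number of mapped markers.
#' @param n_groups number of linkage groups the length spans (default 1).
#' @return spacing in cM per interval, rounded half-up to 2 decimals.
#' @export
#' @examples
#' map_interval_spacing(936.2, 1751, 12)  # 0.54
map_interval_spacing <- function(map_length_cM, n_mapped, n_groups = 1L) {
  if (n_groups < 1L) lp_abort("n_groups must be >= 1")
  if (n_mapped <= n_groups) lp_abort("need more mapped markers than linkage groups")
  round_half_up(map_length_cM / (n_mapped - n_groups), 2)
}

#' Marey profile: genetic vs. physical position and windowed rate
#'
#' Builds the Marey map of a chromosome from marker anchors — genetic
#' position (cM) against physical position — regularizes the genetic
#' positions to be non-decreasing by isotonic regression (mapping noise
#' produces small local inversions that would otherwise give negative
#' rates), and estimates the local recombination rate (cM/Mb) as the slope
#' of the regularized curve over sliding windows.
#'
#' @param anchors tibble with columns `physical_bp` and `cM`.
#' @param chromosome chromosome label carried into the result.
#' @param window_Mb sliding-window width in Mb (default 5).
#' @param step_Mb window step in Mb (default 1).
#' @return an object of class `marey_profile`: list with `chromosome`,
#'   `points` (tibble `physical_Mb, cM, cM_fit`, sorted by position) and
#'   `window_rates` (tibble `window_start_Mb, window_mid_Mb, window_end_Mb,
#'   rate_cM_per_Mb, n_anchors`).
#' @export
marey_profile <- function(anchors, chromosome = "chr", window_Mb = 5, step_Mb = 1) {
  check_cols(anchors, c("physical_bp", "cM"), "Marey anchors")
  if (nrow(anchors) < 2L) lp_abort("need at least 2 anchors for a Marey profile")
  if (length(unique(anchors$physical_bp)) < 2L) {
    lp_abort("all anchors at a single physical position")
  }
  pts <- anchors |>
    transmute(physical_Mb = .data$physical_bp / 1e6, cM = .data$cM) |>
    arrange(.data$physical_Mb)
  fit <- stats::isoreg(pts$physical_Mb, pts$cM)
  pts$cM_fit <- fit$yf

  # piecewise-linear interpolant of the isotonic fit, for window-edge slopes
  g <- stats::approxfun(pts$physical_Mb, pts$cM_fit, rule = 2, ties = mean)
  lo <- min(pts$physical_Mb)
  hi <- max(pts$physical_Mb)
  starts <- seq(lo, max(lo, hi - window_Mb), by = step_Mb)
  if (length(starts) == 0L) starts <- lo
  ends <- pmin(starts + window_Mb, hi)
  rates <- tibble(
    window_start_Mb = starts,
    window_mid_Mb = (starts + ends) / 2,
    window_end_Mb = ends,
    rate_cM_per_Mb = (g(ends) - g(starts)) / pmax(ends - starts, 1e-9),
    n_anchors = vapply(seq_along(starts), function(i) {
      sum(pts$physical_Mb >= starts[i] & pts$physical_Mb <= ends[i])
    }, integer(1))
  )
  structure(list(chromosome = chromosome, points = pts, window_rates = rates,
                 window_Mb = window_Mb, step_Mb = step_Mb),
            class = "marey_profile")
}

#' @export
print.marey_profile <- function(x, ...) {
  cat(sprintf("<marey_profile> %s: %d anchors, %d windows (%g Mb / step %g Mb)\n",
              x$chromosome, nrow(x$points), nrow(x$window_rates),
              x$window_Mb, x$step_Mb))
  invisible(x)
}

#' Call the pericentromeric (zero-recombination) interval of a chromosome
#'
#' Pericentromeric heterochromatin shows up on a Marey profile as a long run
#' of windows with near-zero recombination rate. This finds the longest
#' maximal run of consecutive windows with rate below `rate_threshold`
#' spanning at least `min_span_Mb`; ties on span go to the more proximal run
#' (smaller start).
#'
#' @param profile a `marey_profile`.
#' @param rate_threshold rate below which a window counts as suppressed
#'   (cM/Mb; default 0.1).
#' @param min_span_Mb minimum physical span of a qualifying run (default 2).
#' @return a one-row tibble `chromosome, start_Mb, end_Mb, span_Mb,
#'   n_windows`, or a zero-row tibble if no run qualifies.
#' @export
call_pericentromere <- function(profile, rate_threshold = 0.1, min_span_Mb = 2.0) {
  stopifnot(inherits(profile, "marey_profile"))
  w <- profile$window_rates
  none <- tibble(chromosome = character(), start_Mb = numeric(),
                 end_Mb = numeric(), span_Mb = numeric(), n_windows = integer())
  if (nrow(w) == 0L) return(none)
  low <- w$rate_cM_per_Mb < rate_threshold
  if (!any(low)) return(none)
  r <- rle(low)
  run_end <- cumsum(r$lengths)
  run_beg <- run_end - r$lengths + 1L
  runs <- tibble(beg = run_beg[r$values], end = run_end[r$values]) |>
    mutate(start_Mb = w$window_start_Mb[.data$beg],
           end_Mb = w$window_end_Mb[.data$end],
           span_Mb = .data$end_Mb - .data$start_Mb,
           n_windows = .data$end - .data$beg + 1L) |>
    filter(.data$span_Mb >= min_span_Mb) |>
    arrange(desc(.data$span_Mb), .data$start_Mb)
  if (nrow(runs) == 0L) return(none)
  tibble(chromosome = profile$chromosome,
         start_Mb = runs$start_Mb[1], end_Mb = runs$end_Mb[1],
         span_Mb = runs$span_Mb[1], n_windows = runs$n_windows[1])
}
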