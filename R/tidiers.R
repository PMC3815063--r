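#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a Marey profile
#'
#' @param x a `marey_profile`.
#' @param what `"rates"` (default; the windowed recombination rates) or
#'   `"points"` (the anchor scatter with the isotonic fit).
#' @param ... unused.
#' @return a tibble.
#' @exportS3Method generics::tidy
tidy.marey_profile <- function(x, what = c("rates", "points"), ...) {
  what <- match.arg(what)
  out <- if (what == "rates") x$window_rates else x$points
  mutate(out, chromosome = x$chromosome, .before = 1)
}

#' @rdname tidy.marey_profile
#' @exportS3Method generics::glance
glance.marey_profile <- function(x, ...) {
  peri <- call_pericentromere(x)
  tibble(chromosome = x$chromosome,
         n_anchors = nrow(x$points),
         map_length_cM = max(x$points$cM_fit) - min(x$points$cM_fit),
         span_Mb = max(x$points$physical_Mb) - min(x$points$physical_Mb),
         mean_rate_cM_per_Mb = mean(x$window_rates$rate_cM_per_Mb),
         pericentromere_start_Mb = if (nrow(peri)) peri$start_Mb else NA_real_,
         pericentromere_end_Mb = if (nrow(peri)) peri$end_Mb else NA_real_)
}

#' Tidy a pseudomolecule assembly
#'
#' @param x a `pm_assembly` from [assemble_pseudomolecules()].
#' @param what `"stats"` (default), `"agp"`, `"ordering"`,
#'   `"orientations"`, `"links"` or `"chimeras"`.
#' @param ... unused.
#' @return a tibble.
#' @exportS3Method generics::tidy
tidy.pm_assembly <- function(x, what = c("stats", "agp", "ordering",
                                         "orientations", "links",
                                         "chimeras"), ...) {
  what <- match.arg(what)
  switch(what,
         stats = x$stats,
         agp = x$agp,
         ordering = x$ordering,
         orientations = x$orientations,
         links = x$links$links,
         chimeras = x$chimeras$breakpoints)
}

#' @rdname tidy.pm_assembly
#' @exportS3Method generics::glance
glance.pm_assembly <- function(x, ...) {
  tot <- x$stats[x$stats$chromosome == "Total", ]
  tibble(n_chromosomes = nrow(x$stats) - 1L,
         anchored_n = tot$anchored_n,
         anchored_Mb = tot$anchored_Mb,
         oriented_pct = tot$oriented_pct,
         mean_N50_Mb = tot$anchored_N50_Mb,
         n_links = nrow(x$links$links),
         n_chimera_breakpoints = nrow(x$chimeras$breakpoints))
}
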