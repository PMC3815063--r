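#' Filter clone-end alignment hits
#'
#' Keeps hits with `match_length >= min_len` and `bit_score > min_bits`.
#' The length bound is inclusive ("minimum"), the bit-score bound strict
#' ("exceeding").
#'
#' @param hits tibble with columns `match_length` and `bit_score` (other
#'   columns pass through).
#' @param min_len minimum match length in bp (default 400, inclusive).
#' @param min_bits bit-score bound (default 700, strict).
#' @return the surviving rows.
#' @export
filter_clone_end_hits <- function(hits, min_len = 400, min_bits = 700) {
  check_cols(hits, c("match_length", "bit_score"), "clone-end hits")
  hits |> filter(.data$match_length >= min_len, .data$bit_score > min_bits)
}

#' Filter synteny matches to a related genome
#'
#' Keeps matches with `length_bp > min_len` and `identity_pct >
#' min_identity`; both bounds strict.
#'
#' @param matches tibble with columns `length_bp` and `identity_pct`.
#' @param min_len length bound in bp (default 1000, strict).
#' @param min_identity percent-identity bound (default 97, strict).
#' @return the surviving rows.
#' @export
filter_synteny_matches <- function(matches, min_len = 1000, min_identity = 97.0) {
  check_cols(matches, c("length_bp", "identity_pct"), "synteny matches")
  matches |> filter(.data$length_bp > min_len, .data$identity_pct > min_identity)
}

#' Place unsequenced clones on scaffolds from their WGP tag hits
#'
#' A clone is placed on the scaffold that carries at least `majority_frac`
#' of its uniquely aligning 25-nt whole-genome-profiling tags, provided that
#' count reaches `min_unique_tags`; its span is the min..max of those tag
#' positions. Non-unique tag hits are discarded up front.
#'
#' @param tag_hits tibble with columns `clone_id, scaffold_id, position_bp,
#'   unique` (logical).
#' @param min_unique_tags minimum supporting unique tags (default 3).
#' @param majority_frac fraction of a clone's unique tags the winning
#'   scaffold must hold (default 0.8).
#' @return tibble `clone_id, scaffold_id, beg, end, n_tags, n_unique_total,
#'   placed`; unplaced clones have `NA` scaffold/span.
#' @export
place_clone_by_wgp_tags <- function(tag_hits, min_unique_tags = 3L,
                                    majority_frac = 0.8) {
  check_cols(tag_hits, c("clone_id", "scaffold_id", "position_bp", "unique"),
             "WGP tag hits")
  uh <- tag_hits |> filter(.data$unique)
  totals <- uh |> count(.data$clone_id, name = "n_unique_total")
  best <- uh |>
    group_by(.data$clone_id, .data$scaffold_id) |>
    summarise(n_tags = dplyr::n(), beg = min(.data$position_bp),
              end = max(.data$position_bp), .groups = "drop") |>
    left_join(totals, by = "clone_id") |>
    group_by(.data$clone_id) |>
    slice_max(.data$n_tags, n = 1L, with_ties = FALSE) |>
    ungroup() |>
    mutate(placed = .data$n_tags >= min_unique_tags &
             .data$n_tags >= majority_frac * .data$n_unique_total)
  best |>
    transmute(.data$clone_id,
              scaffold_id = ifelse(.data$placed, .data$scaffold_id, NA_character_),
              beg = ifelse(.data$placed, .data$beg, NA_real_),
              end = ifelse(.data$placed, .data$end, NA_real_),
              .data$n_tags, .data$n_unique_total, .data$placed)
}

#' Convert placed, mapped clones into proxy anchor points
#'
#' Each placed clone with a genetic-map position yields one anchor at the
#' midpoint of its placement span, class `clone_proxy`. Bin-based map
#' positions (ultra-high-density maps) are converted to pseudo-cM by a
#' configured bin width; a clone whose map interval spans `>= wide_bin_span`
#' bins is an inaccurately mapped clone and is down-weighted.
#'
#' @param placements output of [place_clone_by_wgp_tags()] (or any tibble
#'   with `clone_id, scaffold_id, beg, end`).
#' @param clone_map tibble `clone_id, linkage_group` plus either
#'   `position_cM` or `bin` (optionally `bin_end` for an interval).
#' @param bin_width_cM pseudo-cM per bin (default 0.8).
#' @param source_map map tag for the anchors (default `"RH"`).
#' @param wide_bin_span bin-interval width at or above which a clone is
#'   down-weighted (default 5).
#' @return anchor tibble `marker_id, scaffold_id, position_bp,
#'   linkage_group, position_cM, source_map, marker_class, weight`.
#' @export
clones_to_anchors <- function(placements, clone_map, bin_width_cM = 0.8,
                              source_map = "RH", wide_bin_span = 5L) {
  check_cols(clone_map, c("clone_id", "linkage_group"), "clone map")
  placed <- placements |> filter(!is.na(.data$scaffold_id))
  joined <- placed |> inner_join(clone_map, by = "clone_id")
  skipped <- setdiff(placed$clone_id, clone_map$clone_id)
  if (length(skipped) > 0L) {
    inform(sprintf("%d placed clone(s) have no map position and yield no anchor",
                   length(skipped)))
  }
  if (nrow(joined) == 0L) {
    return(tibble(marker_id = character(), scaffold_id = character(),
                  position_bp = numeric(), linkage_group = character(),
                  position_cM = numeric(), source_map = character(),
                  marker_class = character(), weight = numeric()))
  }
  if (!"position_cM" %in% names(joined)) {
    check_cols(joined, "bin", "clone map (needs position_cM or bin)")
    if (!"bin_end" %in% names(joined)) joined$bin_end <- joined$bin
    joined <- joined |>
      mutate(position_cM = (.data$bin + .data$bin_end) / 2 * bin_width_cM,
             wide = (.data$bin_end - .data$bin + 1) >= wide_bin_span)
  } else {
    joined$wide <- FALSE
  }
  joined |>
    transmute(marker_id = .data$clone_id, .data$scaffold_id,
              position_bp = floor((.data$beg + .data$end) / 2),
              linkage_group = as.character(.data$linkage_group),
              .data$position_cM, source_map = source_map,
              marker_class = "clone_proxy",
              weight = ifelse(.data$wide, 0.5, 1))
}

#' Project foreign-map anchors onto the backbone map
#'
#' Scaffolds anchored in both a foreign map and the backbone map give
#' (foreign cM, backbone cM) reference pairs per linkage group. A monotone
#' piecewise-linear transform is fitted through them (isotonic adjustment
#' of the backbone values, then linear interpolation) and applied to every
#' foreign anchor. Anchors falling inside a declared inversion interval
#' have their local order reversed (reflected within the interval) before
#' transformation. Positions beyond the terminal reference pairs are
#' extrapolated linearly from the terminal segment and flagged.
#'
#' @param anchors foreign anchor tibble with `linkage_group` and
#'   `position_cM` (other columns pass through).
#' @param shared reference pairs: tibble `linkage_group, foreign_cM,
#'   backbone_cM`, at least 2 pairs per group.
#' @param inversions optional inversion catalogue in foreign-map
#'   coordinates: tibble `linkage_group, foreign_beg_cM, foreign_end_cM`.
#' @return the anchors with `position_cM` replaced by the backbone-scale
#'   position, plus columns `foreign_cM` (the input position) and
#'   `extrapolated`; anchors on groups with fewer than 2 reference pairs
#'   are dropped with a warning.
#' @export
project_map <- function(anchors, shared, inversions = NULL) {
  check_cols(anchors, c("linkage_group", "position_cM"), "foreign anchors")
  check_cols(shared, c("linkage_group", "foreign_cM", "backbone_cM"), "shared pairs")
  out <- list()
  for (lg in unique(anchors$linkage_group)) {
    a <- anchors |> filter(.data$linkage_group == lg)
    s <- shared |> filter(.data$linkage_group == lg) |> arrange(.data$foreign_cM)
    if (nrow(s) < 2L) {
      warn(sprintf("linkage group %s has < 2 shared scaffolds; skipped", lg))
      next
    }
    x <- a$position_cM
    if (!is.null(inversions)) {
      inv <- inversions |> filter(.data$linkage_group == lg)
      for (k in seq_len(nrow(inv))) {
        inside <- x >= inv$foreign_beg_cM[k] & x <= inv$foreign_end_cM[k]
        x[inside] <- inv$foreign_beg_cM[k] + inv$foreign_end_cM[k] - x[inside]
      }
    }
    yf <- stats::isoreg(s$foreign_cM, s$backbone_cM)$yf
    fx <- s$foreign_cM
    # linear extrapolation from the terminal segments
    slope_lo <- (yf[2] - yf[1]) / max(fx[2] - fx[1], 1e-9)
    n <- length(fx)
    slope_hi <- (yf[n] - yf[n - 1]) / max(fx[n] - fx[n - 1], 1e-9)
    y <- stats::approx(fx, yf, xout = x, rule = 2, ties = mean)$y
    below <- x < fx[1]; above <- x > fx[n]
    y[below] <- yf[1] + (x[below] - fx[1]) * slope_lo
    y[above] <- yf[n] + (x[above] - fx[n]) * slope_hi
    a$foreign_cM <- a$position_cM
    a$position_cM <- y
    a$extrapolated <- below | above
    out[[lg]] <- a
  }
  bind_rows(out)
}
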