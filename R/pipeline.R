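#' Re-express scaffold coordinates in chimera-split segment coordinates
#'
#' @param segment_table segment table from [apply_splits()].
#' @param scaffold_id,pos parallel vectors of scaffold ids and 0-based
#'   positions.
#' @return tibble `segment_id, pos` in segment-local coordinates.
#' @export
remap_to_segments <- function(segment_table, scaffold_id, pos) {
  out_id <- character(length(pos)); out_pos <- numeric(length(pos))
  for (par in unique(scaffold_id)) {
    s <- segment_table[segment_table$parent_id == par, ]
    s <- s[order(s$parent_beg), ]
    sel <- which(scaffold_id == par)
    if (nrow(s) == 0L) { out_id[sel] <- NA_character_; next }
    idx <- pmax(findInterval(pos[sel], s$parent_beg), 1L)
    out_id[sel] <- s$segment_id[idx]
    out_pos[sel] <- pos[sel] - s$parent_beg[idx]
  }
  tibble(segment_id = out_id, pos = out_pos)
}

#' Build pseudomolecules end to end
#'
#' The full two-stage construction. Stage I: detect and split chimeric
#' scaffolds from conflicting anchor runs, build the backbone ordering from
#' the reference-map anchors, then insert scaffolds carried only by
#' projected foreign maps where the projections agree. Stage II: classify
#' mate pairs against the Stage I layout, compute windowed link-peak
#' profiles, call reciprocal links, use them to insert unanchored segments
#' next to their link partners and to orient segments (map-slope fallback
#' where link evidence is absent), and emit the final AGP with fixed gaps
#' plus assembly statistics.
#'
#' @param anchors_dm reference-map anchor tibble (`marker_id, scaffold_id,
#'   position_bp, linkage_group, position_cM`).
#' @param pairs mate-pair tibble (see [classify_mate_pairs()]).
#' @param libraries library tibble.
#' @param scaffold_lengths tibble `scaffold_id, length`.
#' @param anchors_rh,anchors_tom optional foreign anchors *already
#'   projected* to the backbone cM scale (see [project_map()]).
#' @param gap_bp inter-component gap (default 50,000).
#' @param window_bp,step_bp link-profile windowing.
#' @param min_score,max_noise_ratio link-call thresholds.
#' @param min_support,min_cM_gap chimera-detection parameters.
#' @param slope_floor map-slope orientation floor (cM/Mb).
#' @return object of class `pm_assembly`: list with `agp`, `stats`,
#'   `ordering`, `orientations`, `links`, `profiles`, `chimeras`,
#'   `segment_table`, `classified`.
#' @export
assemble_pseudomolecules <- function(anchors_dm, pairs, libraries,
                                     scaffold_lengths,
                                     anchors_rh = NULL, anchors_tom = NULL,
                                     gap_bp = 50000,
                                     window_bp = 10000, step_bp = 5000,
                                     min_score = 4.0, max_noise_ratio = 0.5,
                                     min_support = 3L, min_cM_gap = 10.0,
                                     slope_floor = 0.1) {
  # chimera screening pools every anchor source: foreign-map proxies locate
  # misjoins in regions the reference map covers thinly (they are already on
  # the backbone cM scale here, so cM-gap checks are comparable)
  as_chr_lg <- function(a) {
    if (!is.null(a)) a$linkage_group <- as.character(a$linkage_group)
    a
  }
  anchors_dm <- as_chr_lg(anchors_dm)
  anchors_rh <- as_chr_lg(anchors_rh)
  anchors_tom <- as_chr_lg(anchors_tom)
  anchor_cols <- c("scaffold_id", "position_bp", "linkage_group", "position_cM")
  all_anchors <- bind_rows(anchors_dm[anchor_cols],
                           if (!is.null(anchors_rh)) anchors_rh[anchor_cols],
                           if (!is.null(anchors_tom)) anchors_tom[anchor_cols])
  chim <- detect_chimeras(all_anchors, min_support = min_support,
                          min_cM_gap = min_cM_gap)
  segment_table <- apply_splits(scaffold_lengths, chim$breakpoints)
  seg_lengths <- segment_table |>
    transmute(scaffold_id = .data$segment_id, length = .data$length)

  remap_anchors <- function(a) {
    if (is.null(a) || nrow(a) == 0L) return(a)
    r <- remap_to_segments(segment_table, a$scaffold_id, a$position_bp)
    a$scaffold_id <- r$segment_id
    a$position_bp <- r$pos
    a |> filter(!is.na(.data$scaffold_id))
  }
  a_dm <- remap_anchors(anchors_dm)
  a_rh <- remap_anchors(anchors_rh)
  a_tom <- remap_anchors(anchors_tom)

  bb <- build_backbone(a_dm)
  ins <- hierarchical_insert(bb$backbone, a_rh, a_tom)
  ordering <- ins$ordering

  r1 <- remap_to_segments(segment_table, pairs$scaffold1, pairs$pos1)
  r2 <- remap_to_segments(segment_table, pairs$scaffold2, pairs$pos2)
  pairs2 <- pairs
  pairs2$scaffold1 <- r1$segment_id; pairs2$pos1 <- r1$pos
  pairs2$scaffold2 <- r2$segment_id; pairs2$pos2 <- r2$pos
  pairs2 <- pairs2 |> filter(!is.na(.data$scaffold1), !is.na(.data$scaffold2))

  layout <- ordering |> select("chromosome", "rank", "scaffold_id")
  cls <- classify_mate_pairs(pairs2, libraries, seg_lengths, layout = layout)
  # link evidence is scored against the pre-scaffolding state: junction
  # evidence between scaffolds the map has already ordered is exactly what
  # orients them, so it must not be discarded as satisfied-adjacent
  cls_denovo <- classify_mate_pairs(pairs2, libraries, seg_lengths,
                                    layout = NULL)
  profiles <- link_score_profiles(cls_denovo$unsatisfied, libraries,
                                  seg_lengths,
                                  window_bp = window_bp, step_bp = step_bp)
  calls <- call_links(profiles, seg_lengths, libraries,
                      min_score = min_score, max_noise_ratio = max_noise_ratio)

  # insert unplaced segments adjacent to their reciprocal link partners
  unplaced <- setdiff(seg_lengths$scaffold_id, layout$scaffold_id)
  if (length(unplaced) > 0L && nrow(calls$links) > 0L) {
    lk <- calls$links
    for (u in unplaced) {
      hit <- lk |> filter(.data$scaffold_a == u | .data$scaffold_b == u)
      if (nrow(hit) == 0L) next
      h <- hit[1, ]
      partner <- if (h$scaffold_a == u) h$scaffold_b else h$scaffold_a
      p_end <- if (h$scaffold_a == u) h$end_b else h$end_a
      at <- layout |> filter(.data$scaffold_id == partner)
      if (nrow(at) == 0L) next
      offset <- if (p_end == "R") 0.5 else -0.5
      layout <- bind_rows(layout,
                          tibble(chromosome = at$chromosome,
                                 rank = at$rank + offset, scaffold_id = u)) |>
        group_by(.data$chromosome) |>
        arrange(.data$rank, .by_group = TRUE) |>
        mutate(rank = dplyr::row_number()) |>
        ungroup()
    }
    ordering <- layout |>
      left_join(ordering |> select("scaffold_id", "cM", "source"),
                by = "scaffold_id") |>
      mutate(source = ifelse(is.na(.data$source), "link", .data$source))
  }

  lo <- infer_orientation(calls$links)
  so <- orient_by_slope(a_dm, slope_floor = slope_floor)
  orientations <- resolve_orientations(lo, so, seg_lengths$scaffold_id)

  agp <- finalize_agp(ordering |> select("chromosome", "rank", "scaffold_id"),
                      orientations, segment_table, gap_bp = gap_bp)
  stats <- assembly_stats(agp)
  structure(list(agp = agp, stats = stats, ordering = ordering,
                 orientations = orientations, links = calls,
                 profiles = profiles, chimeras = chim,
                 segment_table = segment_table, classified = cls,
                 insert_report = ins$report, backbone = bb$backbone),
            class = "pm_assembly")
}

#' @export
print.pm_assembly <- function(x, ...) {
  tot <- x$stats[x$stats$chromosome == "Total", ]
  cat(sprintf(paste0("<pm_assembly> %d chromosome(s), %d segments anchored ",
                     "(%.1f Mb), %.1f%% oriented, %d chimera breakpoint(s)\n"),
              nrow(x$stats) - 1L, tot$anchored_n, tot$anchored_Mb,
              tot$oriented_pct, nrow(x$chimeras$breakpoints)))
  invisible(x)
}
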