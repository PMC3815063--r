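#' Build backbone pseudomolecule bins from reference-map anchors
#'
#' Assigns each scaffold to the chromosome carrying the majority of its
#' anchors (requiring a `supermajority` of them; scaffolds below it are
#' routed to chimera screening rather than placed whole), positions it at
#' the median cM of its anchors on that chromosome, and sorts scaffolds per
#' chromosome. Scaffolds at identical cM share a bin: their relative order
#' is unresolved and flagged.
#'
#' @param anchors anchor tibble (`scaffold_id, linkage_group, position_cM`,
#'   normally `source_map == "DM"`).
#' @param supermajority fraction of a scaffold's anchors that must agree on
#'   one chromosome (default 2/3).
#' @return list with `backbone` (tibble `chromosome, cM, scaffold_id, rank,
#'   bin, cobinned`) and `screen` (scaffold ids failing the supermajority,
#'   to pass to [detect_chimeras()]).
#' @export
build_backbone <- function(anchors, supermajority = 2 / 3) {
  check_cols(anchors, c("scaffold_id", "linkage_group", "position_cM"), "anchors")
  votes <- anchors |>
    count(.data$scaffold_id, .data$linkage_group) |>
    group_by(.data$scaffold_id) |>
    mutate(frac = .data$n / sum(.data$n)) |>
    slice_max(.data$n, n = 1L, with_ties = FALSE) |>
    ungroup()
  screen <- votes$scaffold_id[votes$frac < supermajority]
  placed <- votes |> filter(.data$frac >= supermajority)
  backbone <- anchors |>
    inner_join(placed |> select("scaffold_id", chromosome = "linkage_group"),
               by = "scaffold_id") |>
    filter(.data$linkage_group == .data$chromosome) |>
    group_by(.data$chromosome, .data$scaffold_id) |>
    summarise(cM = stats::median(.data$position_cM), n_anchors = dplyr::n(),
              .groups = "drop") |>
    group_by(.data$chromosome) |>
    arrange(.data$cM, .data$scaffold_id, .by_group = TRUE) |>
    mutate(rank = dplyr::row_number(),
           bin = match(.data$cM, unique(.data$cM)),
           cobinned = duplicated(.data$cM) | duplicated(.data$cM, fromLast = TRUE)) |>
    ungroup()
  list(backbone = backbone, screen = screen)
}

#' Insert foreign-map-only scaffolds into backbone gaps
#'
#' Scaffolds anchored only in the higher-priority foreign map(s) are
#' dropped into the backbone where their projected positions fall, with
#' priority reference > first foreign > second foreign. A scaffold anchored
#' in both foreign maps is inserted only when the two projections agree on
#' the chromosome and on the backbone interval (the same pair of backbone
#' neighbors); disagreements leave it unplaced and counted.
#'
#' @param backbone backbone tibble from [build_backbone()].
#' @param anchors_rh,anchors_tom foreign anchors already projected onto the
#'   backbone cM scale by [project_map()] (`scaffold_id, linkage_group,
#'   position_cM`); either may be `NULL`.
#' @return list with `ordering` (tibble `chromosome, cM, scaffold_id,
#'   source, rank`), `unplaced` (tibble `scaffold_id, reason`) and `report`
#'   (tibble `maps_supporting, n_scaffolds` over the placed set).
#' @export
hierarchical_insert <- function(backbone, anchors_rh = NULL, anchors_tom = NULL) {
  bb <- backbone |>
    transmute(.data$chromosome, .data$cM, .data$scaffold_id, source = "DM")
  foreign <- list(RH = anchors_rh, TOM = anchors_tom)
  foreign <- foreign[!vapply(foreign, is.null, logical(1))]

  # per-scaffold consensus (chromosome, median cM) per foreign map
  summaries <- purrr::imap(foreign, function(a, nm) {
    a |>
      group_by(.data$scaffold_id) |>
      filter(dplyr::n_distinct(.data$linkage_group) == 1L |
               .data$linkage_group == names(sort(table(.data$linkage_group),
                                                 decreasing = TRUE))[1]) |>
      summarise(chromosome = .data$linkage_group[1],
                cM = stats::median(.data$position_cM), .groups = "drop") |>
      mutate(source = nm)
  })
  fsum <- bind_rows(summaries)
  if (nrow(fsum) == 0L) {
    fsum <- tibble(scaffold_id = character(), chromosome = character(),
                   cM = numeric(), source = character())
  }
  new_ids <- setdiff(fsum$scaffold_id, bb$scaffold_id)

  interval_of <- function(chrom, cM) {
    bcm <- sort(bb$cM[bb$chromosome == chrom])
    if (length(bcm) == 0L) return(NA_integer_)
    findInterval(cM, bcm)
  }
  placed <- list(); unplaced <- list()
  for (sc in new_ids) {
    rows <- fsum |> filter(.data$scaffold_id == sc)
    if (nrow(rows) == 1L) {
      placed[[sc]] <- rows |> transmute(.data$chromosome, .data$cM,
                                        .data$scaffold_id, .data$source)
    } else {
      same_chrom <- length(unique(rows$chromosome)) == 1L
      iv <- if (same_chrom) interval_of(rows$chromosome[1], rows$cM) else c(0, 1)
      if (same_chrom && length(unique(iv)) == 1L) {
        placed[[sc]] <- tibble(chromosome = rows$chromosome[1],
                               cM = mean(rows$cM), scaffold_id = sc,
                               source = paste(sort(rows$source), collapse = "+"))
      } else {
        unplaced[[sc]] <- tibble(scaffold_id = sc,
                                 reason = if (same_chrom) "interval_disagreement"
                                          else "chromosome_disagreement")
      }
    }
  }
  ordering <- bind_rows(bb, bind_rows(placed)) |>
    group_by(.data$chromosome) |>
    arrange(.data$cM, .data$scaffold_id, .by_group = TRUE) |>
    mutate(rank = dplyr::row_number()) |>
    ungroup()
  support <- fsum |>
    filter(.data$scaffold_id %in% ordering$scaffold_id) |>
    bind_rows(bb |> select("scaffold_id", "source")) |>
    distinct(.data$scaffold_id, .data$source) |>
    count(.data$scaffold_id, name = "maps")
  report <- support |> count(maps_supporting = .data$maps, name = "n_scaffolds")
  list(ordering = ordering, unplaced = bind_rows(unplaced), report = report)
}

#' Detect chimeric scaffolds from conflicting anchor runs
#'
#' Orders a scaffold's anchors by position and segments them into maximal
#' runs consistent in chromosome and local cM (a jump above `min_cM_gap`
#' starts a new run). Runs with fewer than `min_support` anchors are set
#' aside as candidates; adjacent surviving runs that still disagree —
#' different chromosomes, or a cM gap above `min_cM_gap` — yield a
#' breakpoint at the midpoint between their flanking anchors. At most 3
#' breakpoints are called per scaffold.
#'
#' @param anchors anchor tibble with `scaffold_id, position_bp,
#'   linkage_group, position_cM`.
#' @param min_support minimum anchors per run (default 3).
#' @param min_cM_gap cM discontinuity treated as a conflict (default 10).
#' @return list with `breakpoints` (tibble `scaffold_id, breakpoint_bp,
#'   left_chrom, right_chrom, left_cM, right_cM, support_left,
#'   support_right`) and `candidates` (under-supported runs, logged not
#'   called).
#' @export
detect_chimeras <- function(anchors, min_support = 3L, min_cM_gap = 10.0) {
  check_cols(anchors, c("scaffold_id", "position_bp", "linkage_group",
                        "position_cM"), "anchors")
  bps <- list(); cands <- list()
  for (sc in unique(anchors$scaffold_id)) {
    a <- anchors |> filter(.data$scaffold_id == sc) |> arrange(.data$position_bp)
    if (nrow(a) < 2L) next
    new_run <- c(TRUE, a$linkage_group[-1] != a$linkage_group[-nrow(a)] |
                   abs(diff(a$position_cM)) > min_cM_gap)
    a$run <- cumsum(new_run)
    runs <- a |>
      group_by(.data$run) |>
      summarise(chrom = .data$linkage_group[1], cM = stats::median(.data$position_cM),
                support = dplyr::n(), first_bp = min(.data$position_bp),
                last_bp = max(.data$position_bp),
                first_cM = dplyr::first(.data$position_cM),
                last_cM = dplyr::last(.data$position_cM), .groups = "drop")
    weak <- runs |> filter(.data$support < min_support)
    if (nrow(weak) > 0L) {
      cands[[sc]] <- weak |> mutate(scaffold_id = sc, .before = 1)
    }
    runs <- runs |> filter(.data$support >= min_support)
    if (nrow(runs) < 2L) next
    # merge adjacent surviving runs that agree after weak-run removal
    keep_break <- runs$chrom[-1] != runs$chrom[-nrow(runs)] |
      abs(runs$first_cM[-1] - runs$last_cM[-nrow(runs)]) > min_cM_gap
    grp <- cumsum(c(0L, as.integer(keep_break)))
    merged <- runs |>
      mutate(grp = grp) |>
      group_by(.data$grp) |>
      summarise(chrom = .data$chrom[1], cM = stats::median(.data$cM),
                support = sum(.data$support), first_bp = min(.data$first_bp),
                last_bp = max(.data$last_bp), .groups = "drop")
    if (nrow(merged) < 2L) next
    n_bp <- min(nrow(merged) - 1L, 3L)
    bps[[sc]] <- tibble(
      scaffold_id = sc,
      breakpoint_bp = floor((merged$last_bp[seq_len(n_bp)] +
                               merged$first_bp[seq_len(n_bp) + 1L]) / 2),
      left_chrom = merged$chrom[seq_len(n_bp)],
      right_chrom = merged$chrom[seq_len(n_bp) + 1L],
      left_cM = merged$cM[seq_len(n_bp)],
      right_cM = merged$cM[seq_len(n_bp) + 1L],
      support_left = merged$support[seq_len(n_bp)],
      support_right = merged$support[seq_len(n_bp) + 1L]
    )
  }
  list(breakpoints = bind_rows(bps), candidates = bind_rows(cands))
}

#' Split a scaffold at breakpoints into derived segments
#'
#' `n` breakpoints yield `n + 1` segments named `<parent>_p1 ...`,
#' covering the parent exactly as half-open slices.
#'
#' @param scaffold_id parent id.
#' @param length parent length in bp.
#' @param breakpoints sorted numeric vector of internal breakpoints
#'   (0 < bp < length); may be empty.
#' @return tibble `segment_id, parent_id, parent_beg, parent_end, length`
#'   (0-based half-open parent coordinates).
#' @export
split_scaffold <- function(scaffold_id, length, breakpoints = numeric()) {
  breakpoints <- sort(breakpoints)
  if (anyDuplicated(breakpoints) > 0L) lp_abort("duplicate breakpoints")
  if (any(breakpoints <= 0 | breakpoints >= length)) {
    lp_abort("breakpoints must lie strictly inside the scaffold")
  }
  if (length(breakpoints) == 0L) {
    return(tibble(segment_id = scaffold_id, parent_id = scaffold_id,
                  parent_beg = 0, parent_end = length, length = length))
  }
  edges <- c(0, breakpoints, length)
  n <- length(edges) - 1L
  tibble(segment_id = paste0(scaffold_id, "_p", seq_len(n)),
         parent_id = scaffold_id,
         parent_beg = edges[-length(edges)], parent_end = edges[-1],
         length = diff(edges))
}

#' Apply chimera splits across a scaffold set
#'
#' @param scaffold_lengths tibble `scaffold_id, length`.
#' @param breakpoints breakpoint tibble from [detect_chimeras()] (may have
#'   zero rows).
#' @return a segment table: `segment_id, parent_id, parent_beg, parent_end,
#'   length` with one row per segment; unsplit scaffolds appear as a single
#'   segment keeping their own id.
#' @export
apply_splits <- function(scaffold_lengths, breakpoints) {
  purrr::map_dfr(seq_len(nrow(scaffold_lengths)), function(i) {
    sc <- scaffold_lengths$scaffold_id[i]
    bp <- breakpoints$breakpoint_bp[breakpoints$scaffold_id == sc]
    split_scaffold(sc, scaffold_lengths$length[i], bp)
  })
}

# internal: Theil-Sen median slope of cM against bp for one segment's anchors
theil_sen_slope <- function(bp, cM) {
  n <- length(bp)
  if (n < 2L) return(NA_real_)
  ij <- utils::combn(n, 2L)
  db <- bp[ij[2, ]] - bp[ij[1, ]]
  dc <- cM[ij[2, ]] - cM[ij[1, ]]
  ok <- db != 0
  if (!any(ok)) return(NA_real_)
  stats::median(dc[ok] / db[ok])
}

#' Orient segments by map slope
#'
#' Fallback orientation for segments without link evidence: the sign of
#' the Theil-Sen median slope of anchor cM against bp. A floor on |slope|
#' avoids assigning orientations inside zero-recombination regions, where
#' the map carries no directional information.
#'
#' @param anchors anchor tibble (`scaffold_id, position_bp, position_cM`),
#'   with positions already in segment coordinates.
#' @param slope_floor minimum |slope| in cM/Mb (default 0.1).
#' @return tibble `scaffold_id, slope_cM_per_Mb, orientation` with
#'   orientation `+`, `-` or `?`.
#' @export
orient_by_slope <- function(anchors, slope_floor = 0.1) {
  anchors |>
    group_by(.data$scaffold_id) |>
    summarise(slope_cM_per_Mb = theil_sen_slope(.data$position_bp,
                                                .data$position_cM) * 1e6,
              .groups = "drop") |>
    mutate(orientation = dplyr::case_when(
      is.na(.data$slope_cM_per_Mb) ~ "?",
      abs(.data$slope_cM_per_Mb) < slope_floor ~ "?",
      .data$slope_cM_per_Mb > 0 ~ "+",
      TRUE ~ "-"))
}

#' Combine link-graph and map-slope orientations
#'
#' Link components carry internally consistent relative orientations; the
#' absolute sign of each component is fixed by majority vote of its
#' members' map-slope orientations. Components with no slope-oriented
#' member stay relative and are reported as `?`. Segments outside any link
#' component fall back to their own slope orientation.
#'
#' @param link_orient result of [infer_orientation()].
#' @param slope_orient result of [orient_by_slope()].
#' @param segments character vector of all segment ids to orient.
#' @return tibble `scaffold_id, orientation, method` with method one of
#'   `link`, `slope`, `none`.
#' @export
resolve_orientations <- function(link_orient, slope_orient, segments) {
  lo <- link_orient$orientations
  so <- stats::setNames(slope_orient$orientation, slope_orient$scaffold_id)
  out <- tibble(scaffold_id = segments, orientation = "?", method = "none")
  if (nrow(lo) > 0L) {
    lo$sign <- ifelse(lo$orientation == "+", 1L,
                      ifelse(lo$orientation == "-", -1L, 0L))
    for (cp in unique(lo$component)) {
      members <- lo[lo$component == cp, ]
      if (all(members$sign == 0L)) next  # conflicted component stays '?'
      slopes <- so[members$scaffold_id]
      agree <- sum(members$sign * ifelse(is.na(slopes) | slopes == "?", 0L,
                                         ifelse(slopes == "+", 1L, -1L)))
      if (agree == 0) next  # no absolute anchor: left '?', reported relative
      flip <- sign(agree)
      idx <- match(members$scaffold_id, out$scaffold_id)
      ok <- !is.na(idx)
      out$orientation[idx[ok]] <- ifelse(members$sign[ok] * flip > 0, "+", "-")
      out$method[idx[ok]] <- "link"
    }
  }
  rest <- out$method == "none"
  slope_here <- so[out$scaffold_id[rest]]
  has <- !is.na(slope_here) & slope_here != "?"
  out$orientation[rest][has] <- slope_here[has]
  out$method[rest][has] <- "slope"
  out
}

#' Finalize the AGP from an ordering and orientations
#'
#' Lays ordered segments on each chromosome as alternating component (`W`)
#' and gap (`U`) rows with a fixed gap (no gap-size estimation is
#' attempted), and collects segments absent from the ordering into an
#' unanchored "chromosome 0" object.
#'
#' @param ordering tibble `chromosome, rank, scaffold_id` (segment ids;
#'   each at most once).
#' @param orientations tibble `scaffold_id, orientation` (`+`/`-`/`?`).
#' @param segment_table segment table from [apply_splits()] (supplies
#'   lengths and parent coordinates).
#' @param gap_bp gap length between components (default 50,000).
#' @param gap_type,linkage,linkage_evidence AGP gap vocabulary (defaults
#'   `"contig"`, `"no"`, `"na"`).
#' @param unanchored_object object id for the unanchored bin (default
#'   `"chr0"`).
#' @return an AGP tibble (see [read_agp()]); component ids are the *parent*
#'   scaffold ids with `component_beg/end` the parent slice, so the AGP is
#'   directly renderable against the original scaffold sequences.
#' @export
finalize_agp <- function(ordering, orientations, segment_table,
                         gap_bp = 50000, gap_type = "contig", linkage = "no",
                         linkage_evidence = "na", unanchored_object = "chr0") {
  if (anyDuplicated(ordering$scaffold_id) > 0L) {
    lp_abort("a segment appears more than once in the ordering")
  }
  ordering$chromosome <- as.character(ordering$chromosome)
  seg <- segment_table
  missing <- setdiff(ordering$scaffold_id, seg$segment_id)
  if (length(missing) > 0L) {
    lp_abort(sprintf("ordering references unknown segment(s): %s",
                     paste(missing, collapse = ", ")))
  }
  ori <- stats::setNames(orientations$orientation, orientations$scaffold_id)
  unplaced <- setdiff(seg$segment_id, ordering$scaffold_id)
  plan <- bind_rows(
    ordering |> arrange(.data$chromosome, .data$rank) |>
      transmute(object_id = .data$chromosome, segment_id = .data$scaffold_id),
    tibble(object_id = unanchored_object, segment_id = unplaced)
  )
  rows <- list()
  for (obj in unique(plan$object_id)) {
    segs <- plan$segment_id[plan$object_id == obj]
    pos <- 1
    part <- 1L
    for (k in seq_along(segs)) {
      s <- seg[seg$segment_id == segs[k], ]
      if (k > 1L) {
        rows[[length(rows) + 1L]] <- tibble(
          object_id = obj, object_beg = pos, object_end = pos + gap_bp - 1,
          part_number = part, component_type = "U",
          component_id = NA_character_, component_beg = NA_real_,
          component_end = NA_real_, orientation = NA_character_,
          gap_length = gap_bp, gap_type = gap_type, linkage = linkage,
          linkage_evidence = linkage_evidence)
        pos <- pos + gap_bp; part <- part + 1L
      }
      o <- ori[segs[k]]
      rows[[length(rows) + 1L]] <- tibble(
        object_id = obj, object_beg = pos, object_end = pos + s$length - 1,
        part_number = part, component_type = "W",
        component_id = s$parent_id, component_beg = s$parent_beg + 1,
        component_end = s$parent_end, orientation = ifelse(is.na(o), "?", o),
        gap_length = NA_real_, gap_type = NA_character_,
        linkage = NA_character_, linkage_evidence = NA_character_)
      pos <- pos + s$length; part <- part + 1L
    }
  }
  agp <- bind_rows(rows)
  validate_agp(agp)
  agp
}

#' Per-chromosome assembly statistics from an AGP
#'
#' Anchored = components placed on real chromosomes (everything except the
#' unanchored bin); oriented = anchored components with orientation other
#' than `?`. The oriented percentage is size-based, 100 * oriented Mb /
#' anchored Mb, rounded half-up to 1 decimal. The `Total` row sums counts
#' and sizes but averages N50 and the oriented percentage across
#' chromosomes, following assembly-table convention.
#'
#' @param agp AGP tibble.
#' @param unanchored_object id of the unanchored bin (default `"chr0"`).
#' @return tibble `chromosome, anchored_n, anchored_Mb, anchored_N50_Mb,
#'   oriented_n, oriented_Mb, oriented_pct`, with a final `Total` row.
#' @export
assembly_stats <- function(agp, unanchored_object = "chr0") {
  w <- agp |> filter(.data$component_type == "W",
                     .data$object_id != unanchored_object) |>
    mutate(len = .data$component_end - .data$component_beg + 1)
  per <- w |>
    group_by(chromosome = .data$object_id) |>
    summarise(anchored_n = dplyr::n(),
              anchored_Mb = sum(.data$len) / 1e6,
              anchored_N50_Mb = n50(.data$len) / 1e6,
              oriented_n = sum(.data$orientation != "?"),
              oriented_Mb = sum(.data$len[.data$orientation != "?"]) / 1e6,
              .groups = "drop") |>
    mutate(oriented_pct = oriented_percentage(.data$oriented_Mb, .data$anchored_Mb))
  total <- tibble(chromosome = "Total",
                  anchored_n = sum(per$anchored_n),
                  anchored_Mb = sum(per$anchored_Mb),
                  anchored_N50_Mb = mean(per$anchored_N50_Mb),
                  oriented_n = sum(per$oriented_n),
                  oriented_Mb = sum(per$oriented_Mb),
                  oriented_pct = round_half_up(mean(per$oriented_pct), 1))
  bind_rows(per, total)
}

#' Size-based oriented percentage
#'
#' @param oriented_Mb,anchored_Mb sizes in Mb.
#' @return 100 * oriented / anchored, rounded half-up to 1 decimal.
#' @export
#' @examples
#' oriented_percentage(40.4, 49.5)  # 81.6
oriented_percentage <- function(oriented_Mb, anchored_Mb) {
  round_half_up(100 * oriented_Mb / anchored_Mb, 1)
}

#' Validate AGP joins against independent clone assemblies
#'
#' A scaffolding join between two segments adjacent in the AGP is
#' *validated* when some clone forms a cycle through its label: the
#' clone's assembled contigs match both flanking segments. A clone whose
#' contigs connect two segments that are not adjacent in the AGP is a
#' *contradiction*; joins touched by no multi-segment clone are
#' *untested*.
#'
#' @param contig_matches tibble `contig_id, segment_id` of filtered
#'   contig-to-segment matches (pre-filter with
#'   [filter_synteny_matches()]).
#' @param clone_contigs tibble `clone_id, contig_id` membership.
#' @param agp AGP tibble.
#' @param unanchored_object unanchored bin id excluded from joins.
#' @return list with `joins` (tibble `chromosome, segment_a, segment_b,
#'   status, clones`), `contradictions` (tibble `clone_id, segment_a,
#'   segment_b`).
#' @export
validate_with_clone_assemblies <- function(contig_matches, clone_contigs, agp,
                                           unanchored_object = "chr0") {
  w <- agp |> filter(.data$component_type == "W",
                     .data$object_id != unanchored_object) |>
    arrange(.data$object_id, .data$part_number)
  joins <- w |>
    group_by(.data$object_id) |>
    reframe(segment_a = .data$component_id[-dplyr::n()],
            segment_b = .data$component_id[-1]) |>
    rename(chromosome = "object_id")
  clone_segments <- clone_contigs |>
    inner_join(contig_matches, by = "contig_id",
               relationship = "many-to-many") |>
    distinct(.data$clone_id, .data$segment_id)
  pairs <- clone_segments |>
    inner_join(clone_segments, by = "clone_id",
               relationship = "many-to-many") |>
    filter(.data$segment_id.x < .data$segment_id.y) |>
    distinct(.data$clone_id, segment_a = .data$segment_id.x,
             segment_b = .data$segment_id.y)
  jkey <- function(a, b) paste(pmin(a, b), pmax(a, b))
  joins$key <- jkey(joins$segment_a, joins$segment_b)
  pairs$key <- jkey(pairs$segment_a, pairs$segment_b)
  support <- pairs |>
    group_by(.data$key) |>
    summarise(clones = paste(sort(unique(.data$clone_id)), collapse = ","),
              .groups = "drop")
  joins <- joins |>
    left_join(support, by = "key") |>
    mutate(status = ifelse(is.na(.data$clones), "untested", "validated")) |>
    select("chromosome", "segment_a", "segment_b", "status", "clones")
  contradictions <- pairs |>
    filter(!.data$key %in% jkey(joins$segment_a, joins$segment_b)) |>
    select("clone_id", "segment_a", "segment_b")
  list(joins = joins, contradictions = contradictions)
}
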