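#' Remove alignments dominated by repeat-depth competition
#'
#' An alignment is removed when at least `frac` of its length is covered by
#' positions where `max_competitors` or more *other* competing alignments
#' overlap it. Competition is evaluated in query space by default (other
#' alignments of the same query sequence, compared on query coordinates) or
#' in target space (other alignments overlapping the same target region).
#' Alignments that merely span a short repeat are kept: removal always
#' requires the fractional condition, never overlap alone.
#'
#' @param alignments alignment tibble in the internal convention (see
#'   [read_alignment_table()]).
#' @param max_competitors depth threshold: number of competing alignments
#'   that must co-overlap a base for it to count (default 5).
#' @param frac fraction of the alignment's length that must be at or above
#'   that depth for removal (default 0.20; exactly 20% is removed).
#' @param mode `"query"` (default) or `"target"` competition space.
#' @return the surviving alignments, same columns, original order.
#' @export
depth_filter <- function(alignments, max_competitors = 5L, frac = 0.20,
                         mode = c("query", "target")) {
  mode <- match.arg(mode)
  if (nrow(alignments) == 0L) return(alignments)
  if (mode == "query") {
    grp <- alignments$query_id
    beg <- alignments$q_beg; end <- alignments$q_end
  } else {
    grp <- alignments$target_id
    beg <- alignments$t_beg; end <- alignments$t_end
  }
  removed <- logical(nrow(alignments))
  for (idx in split(seq_len(nrow(alignments)), grp)) {
    if (length(idx) <= max_competitors) next  # can't reach the depth
    b <- beg[idx]; e <- end[idx]
    for (j in seq_along(idx)) {
      ob <- b[-j]; oe <- e[-j]
      # clip competitors to this alignment's interval, then sweep depth
      cb <- pmax(ob, b[j]); ce <- pmin(oe, e[j])
      keep <- cb < ce
      if (sum(keep) < max_competitors) next
      ev <- sort(unique(c(cb[keep], ce[keep])))
      depth_len <- 0
      for (k in seq_len(length(ev) - 1L)) {
        mid <- (ev[k] + ev[k + 1L]) / 2
        d <- sum(cb[keep] <= mid & ce[keep] > mid)
        if (d >= max_competitors) depth_len <- depth_len + (ev[k + 1L] - ev[k])
      }
      if (depth_len / (e[j] - b[j]) >= frac) removed[idx[j]] <- TRUE
    }
  }
  alignments[!removed, , drop = FALSE]
}

#' Group alignments into indel-tolerant hits
#'
#' Short alignment blocks of one query on the same scaffold and strand,
#' whose target-coordinate gaps do not exceed `max_gap_bp`, are chained into
#' a single "hit": span is the union of blocks, score the sum of block
#' scores. This tolerates indels that split an alignment into blocks.
#'
#' @param alignments alignment tibble (typically already depth-filtered).
#' @param max_gap_bp largest target gap bridged within one hit (default
#'   1000).
#' @return a tibble of hits: `marker_id, scaffold_id, beg, end, strand,
#'   score, n_blocks` (0-based half-open span).
#' @export
group_into_hits <- function(alignments, max_gap_bp = 1000) {
  if (nrow(alignments) == 0L) {
    return(tibble(marker_id = character(), scaffold_id = character(),
                  beg = numeric(), end = numeric(), strand = character(),
                  score = numeric(), n_blocks = integer()))
  }
  alignments |>
    arrange(.data$query_id, .data$target_id, .data$strand, .data$t_beg) |>
    group_by(.data$query_id, .data$target_id, .data$strand) |>
    mutate(chain = cumsum(c(0, pmax(.data$t_beg[-1] - cummax(.data$t_end)[-dplyr::n()], 0)) > max_gap_bp)) |>
    group_by(.data$query_id, .data$target_id, .data$strand, .data$chain) |>
    summarise(beg = min(.data$t_beg), end = max(.data$t_end),
              score = sum(.data$score), n_blocks = dplyr::n(),
              .groups = "drop") |>
    transmute(marker_id = .data$query_id, scaffold_id = .data$target_id,
              beg = .data$beg, end = .data$end, strand = .data$strand,
              score = .data$score, n_blocks = as.integer(.data$n_blocks))
}

#' Filter forward/reverse read hit pairs on orientation and separation
#'
#' For a marker assayed with a forward and a reverse read, a hit pair is
#' consistent only when both hits lie on one scaffold, point toward each
#' other (the `+` hit upstream of the `-` hit, in either read role), and
#' their midpoint separation falls inside the expected bounds for the
#' marker class.
#'
#' @param hits_f,hits_r hit tibbles (from [group_into_hits()]) for the
#'   forward and reverse read of one marker.
#' @param expected numeric length-2 vector `c(min_sep, max_sep)` in bp
#'   (default `c(50, 5000)`, the PCR-amplicon scale).
#' @return a tibble of consistent pairs: `marker_id, scaffold_id, beg, end,
#'   separation, score, n_blocks` with span the union of the two hits and
#'   score their sum.
#' @export
pair_filter <- function(hits_f, hits_r, expected = c(50, 5000)) {
  empty <- tibble(marker_id = character(), scaffold_id = character(),
                  beg = numeric(), end = numeric(), separation = numeric(),
                  score = numeric(), n_blocks = integer())
  if (nrow(hits_f) == 0L || nrow(hits_r) == 0L) return(empty)
  pairs <- inner_join(
    hits_f |> rename_with(~ paste0(.x, "_f"), -"scaffold_id"),
    hits_r |> rename_with(~ paste0(.x, "_r"), -"scaffold_id"),
    by = "scaffold_id", relationship = "many-to-many")
  if (nrow(pairs) == 0L) return(empty)
  pairs |>
    mutate(mid_f = (.data$beg_f + .data$end_f) / 2,
           mid_r = (.data$beg_r + .data$end_r) / 2,
           separation = abs(.data$mid_r - .data$mid_f),
           convergent =
             (.data$strand_f == "+" & .data$strand_r == "-" & .data$mid_f <= .data$mid_r) |
             (.data$strand_f == "-" & .data$strand_r == "+" & .data$mid_r <= .data$mid_f)) |>
    filter(.data$convergent,
           .data$separation >= expected[1], .data$separation <= expected[2]) |>
    transmute(marker_id = sub("/[FR]$", "", .data$marker_id_f),
              scaffold_id = .data$scaffold_id,
              beg = pmin(.data$beg_f, .data$beg_r),
              end = pmax(.data$end_f, .data$end_r),
              separation = .data$separation,
              score = .data$score_f + .data$score_r,
              n_blocks = .data$n_blocks_f + .data$n_blocks_r)
}

#' Select a unique high-scoring placement among a marker's hits
#'
#' A marker is placed only when its best hit is unambiguous: a single hit,
#' or a best score at least `min_ratio` times the runner-up. Otherwise the
#' marker is classified ambiguous and yields nothing.
#'
#' @param hits hit tibble for one marker (non-empty).
#' @param min_ratio best/second-best score margin (default 1.2).
#' @return list with `status` (`"placed"` or `"ambiguous"`) and `hit` (a
#'   one-row tibble when placed, else `NULL`).
#' @export
unique_placement <- function(hits, min_ratio = 1.2) {
  if (nrow(hits) == 0L) lp_abort("unique_placement needs at least one hit")
  ord <- order(hits$score, decreasing = TRUE)
  if (nrow(hits) > 1L && hits$score[ord[1]] < min_ratio * hits$score[ord[2]]) {
    return(list(status = "ambiguous", hit = NULL))
  }
  list(status = "placed", hit = hits[ord[1], , drop = FALSE])
}

#' Anchor mapped markers to scaffolds through the full filter cascade
#'
#' Runs the marker-placement pipeline — repeat-depth filtering, indel-
#' tolerant hit grouping, forward/reverse pair consistency (for two-read
#' markers, recognized by `/F` and `/R` query-id suffixes), unique
#' placement — and joins the survivors to the genetic map to produce anchor
#' points. Markers designed a priori against the assembly (non-missing
#' `a_priori_scaffold`/`a_priori_pos` in `metadata`) are anchored directly,
#' skipping the alignment stages. Co-segregating markers absent from the
#' map inherit the map position of their group representative.
#'
#' @param alignments alignment tibble in the internal convention.
#' @param map genetic-map tibble (`marker_id, linkage_group, position_cM`).
#' @param metadata marker metadata tibble: `marker_id, marker_class`, and
#'   optionally `a_priori_scaffold`, `a_priori_pos`.
#' @param coseg_groups optional co-segregation tibble
#'   (`representative, member`) from [collapse_cosegregating()].
#' @param source_map map tag stamped on the anchors (default `"DM"`).
#' @param params list of stage parameters: `max_competitors`, `frac`,
#'   `max_gap_bp`, `pair_bounds` (length-2 bp vector), `min_ratio`.
#' @return list with `anchors` (tibble `marker_id, scaffold_id, position_bp,
#'   linkage_group, position_cM, source_map, marker_class`; position is the
#'   hit-span midpoint), `report` (per-stage marker counts) and `dropped`
#'   (tibble `marker_id, reason`).
#' @export
anchor_markers <- function(alignments, map, metadata,
                           coseg_groups = NULL, source_map = "DM",
                           params = list()) {
  p <- utils::modifyList(list(max_competitors = 5L, frac = 0.20,
                              max_gap_bp = 1000, pair_bounds = c(50, 5000),
                              min_ratio = 1.2), params)
  check_cols(metadata, c("marker_id", "marker_class"), "marker metadata")
  check_cols(map, c("marker_id", "linkage_group", "position_cM"), "map")

  # resolve each marker's map position, via its co-segregation
  # representative when the marker itself was collapsed out of the map
  map_lookup <- map |> select("marker_id", "linkage_group", "position_cM")
  if (!is.null(coseg_groups) && nrow(coseg_groups) > 0L) {
    inherited <- coseg_groups |>
      inner_join(map_lookup, by = c(representative = "marker_id")) |>
      filter(!.data$member %in% map_lookup$marker_id) |>
      transmute(marker_id = .data$member, .data$linkage_group, .data$position_cM)
    map_lookup <- bind_rows(map_lookup, inherited)
  }

  meta <- as_tibble(metadata)
  if (!"a_priori_scaffold" %in% names(meta)) meta$a_priori_scaffold <- NA_character_
  if (!"a_priori_pos" %in% names(meta)) meta$a_priori_pos <- NA_real_
  apriori <- meta |> filter(!is.na(.data$a_priori_scaffold))
  aligned_meta <- meta |> filter(is.na(.data$a_priori_scaffold))

  aln <- alignments |>
    mutate(base_marker = sub("/[FR]$", "", .data$query_id)) |>
    filter(.data$base_marker %in% aligned_meta$marker_id)
  n_in <- length(unique(aln$base_marker))

  surv <- depth_filter(aln, p$max_competitors, p$frac)
  n_depth <- length(unique(surv$base_marker))

  hits <- group_into_hits(surv, p$max_gap_bp) |>
    mutate(base_marker = sub("/[FR]$", "", .data$marker_id),
           read = ifelse(grepl("/F$", .data$marker_id), "F",
                         ifelse(grepl("/R$", .data$marker_id), "R", "S")))
  placed <- list(); ambiguous <- character(); pair_failed <- character()
  for (mk in unique(hits$base_marker)) {
    h <- hits[hits$base_marker == mk, ]
    if (all(c("F", "R") %in% h$read)) {
      h2 <- pair_filter(h[h$read == "F", 1:7], h[h$read == "R", 1:7],
                        expected = p$pair_bounds)
      if (nrow(h2) == 0L) { pair_failed <- c(pair_failed, mk); next }
    } else {
      h2 <- h |> transmute(marker_id = .data$base_marker, .data$scaffold_id,
                           .data$beg, .data$end, separation = NA_real_,
                           .data$score, .data$n_blocks)
    }
    u <- unique_placement(h2, p$min_ratio)
    if (u$status == "placed") placed[[mk]] <- u$hit else ambiguous <- c(ambiguous, mk)
  }
  n_hits <- length(unique(hits$base_marker))
  n_pair <- n_hits - length(pair_failed)
  n_unique <- length(placed)

  cand <- if (length(placed) > 0L) {
    bind_rows(placed) |>
      mutate(marker_id = sub("/[FR]$", "", .data$marker_id),
             position_bp = floor((.data$beg + .data$end) / 2)) |>
      select("marker_id", "scaffold_id", "position_bp")
  } else {
    tibble(marker_id = character(), scaffold_id = character(), position_bp = numeric())
  }
  cand <- bind_rows(cand,
                    apriori |> transmute(.data$marker_id,
                                         scaffold_id = .data$a_priori_scaffold,
                                         position_bp = .data$a_priori_pos))
  anchors <- cand |>
    inner_join(map_lookup, by = "marker_id") |>
    left_join(meta |> select("marker_id", "marker_class"), by = "marker_id") |>
    mutate(source_map = source_map) |>
    select("marker_id", "scaffold_id", "position_bp", "linkage_group",
           "position_cM", "source_map", "marker_class") |>
    distinct(.data$marker_id, .keep_all = TRUE)

  unmapped <- setdiff(cand$marker_id, map_lookup$marker_id)
  dropped <- bind_rows(
    tibble(marker_id = setdiff(unique(aligned_meta$marker_id), unique(aln$base_marker)),
           reason = "no_alignment"),
    tibble(marker_id = setdiff(unique(aln$base_marker), unique(surv$base_marker)),
           reason = "repeat_depth"),
    tibble(marker_id = pair_failed, reason = "pair_inconsistent"),
    tibble(marker_id = ambiguous, reason = "ambiguous_placement"),
    tibble(marker_id = unmapped, reason = "not_in_map")
  )
  report <- tibble(
    stage = c("input", "depth_filter", "hit_grouping", "pair_filter",
              "unique_placement", "map_join", "a_priori", "anchored"),
    markers = c(n_in + nrow(apriori), n_depth, n_hits, n_pair, n_unique,
                n_unique - length(unmapped), nrow(apriori), nrow(anchors))
  )
  list(anchors = anchors, report = report, dropped = dropped)
}
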