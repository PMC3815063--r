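#' Classify mate pairs as satisfied or unsatisfied against a layout
#'
#' A mate pair is *satisfied* when both ends map to one scaffold, or to
#' scaffolds adjacent (rank distance 1) in the current per-chromosome
#' layout with a plausible implied insert; every other reliably mapped pair
#' is *unsatisfied* and becomes link evidence. With no layout, only
#' same-scaffold pairs are satisfied. Because inter-scaffold gaps are a
#' fixed convention rather than an estimate, the plausibility check for
#' adjacent scaffolds discounts the gap entirely: the summed distance of
#' the two ends to their scaffold edges must be within `insert_mean + 3 *
#' insert_sd` of the pair's library.
#'
#' @param pairs tibble `pair_id, lib_id, scaffold1, pos1, strand1,
#'   scaffold2, pos2, strand2` and optional logical `mapq_ok` (rows with
#'   `FALSE` are dropped first).
#' @param libraries library tibble (see [read_library_specs()]).
#' @param scaffold_lengths tibble `scaffold_id, length`.
#' @param layout optional tibble `chromosome, rank, scaffold_id` describing
#'   the current ordering.
#' @return list with tibbles `satisfied` and `unsatisfied`.
#' @export
classify_mate_pairs <- function(pairs, libraries, scaffold_lengths,
                                layout = NULL) {
  check_cols(pairs, c("pair_id", "lib_id", "scaffold1", "pos1", "strand1",
                      "scaffold2", "pos2", "strand2"), "mate pairs")
  unknown <- setdiff(unique(pairs$lib_id), libraries$lib_id)
  if (length(unknown) > 0L) {
    lp_abort(sprintf("unknown lib_id(s): %s", paste(unknown, collapse = ", ")))
  }
  if ("mapq_ok" %in% names(pairs)) pairs <- pairs |> filter(.data$mapq_ok)
  same <- pairs$scaffold1 == pairs$scaffold2
  adj <- rep(FALSE, nrow(pairs))
  if (!is.null(layout) && nrow(layout) > 0L && any(!same)) {
    key <- paste(layout$chromosome, layout$rank)
    pos1 <- match(pairs$scaffold1, layout$scaffold_id)
    pos2 <- match(pairs$scaffold2, layout$scaffold_id)
    ok <- !is.na(pos1) & !is.na(pos2) &
      layout$chromosome[pos1] == layout$chromosome[pos2] &
      abs(layout$rank[pos1] - layout$rank[pos2]) == 1L
    ok[is.na(ok)] <- FALSE
    if (any(ok & !same)) {
      len1 <- scaffold_lengths$length[match(pairs$scaffold1, scaffold_lengths$scaffold_id)]
      len2 <- scaffold_lengths$length[match(pairs$scaffold2, scaffold_lengths$scaffold_id)]
      d1 <- pmin(pairs$pos1, len1 - pairs$pos1)
      d2 <- pmin(pairs$pos2, len2 - pairs$pos2)
      reach <- libraries$insert_mean[match(pairs$lib_id, libraries$lib_id)] +
        3 * libraries$insert_sd[match(pairs$lib_id, libraries$lib_id)]
      adj <- ok & !same & (d1 + d2 <= reach)
    }
  }
  list(satisfied = pairs[same | adj, , drop = FALSE],
       unsatisfied = pairs[!(same | adj), , drop = FALSE])
}

# internal: unsatisfied pairs in long form, one row per end, with the mate's
# scaffold as target and the library weight attached
pairs_to_ends <- function(unsatisfied, libraries) {
  w <- libraries$value_weight[match(unsatisfied$lib_id, libraries$lib_id)]
  bind_rows(
    unsatisfied |> transmute(pair_id = .data$pair_id,
                             source = .data$scaffold1, pos = .data$pos1,
                             strand = .data$strand1, target = .data$scaffold2,
                             target_pos = .data$pos2, weight = w),
    unsatisfied |> transmute(pair_id = .data$pair_id,
                             source = .data$scaffold2, pos = .data$pos2,
                             strand = .data$strand2, target = .data$scaffold1,
                             target_pos = .data$pos1, weight = w)
  )
}

#' Windowed directional link-score profile of one scaffold
#'
#' Slides a window along the source scaffold; in each window, unsatisfied
#' mate-pair ends are grouped by the scaffold their mates reach (the
#' target), each group scored as the sum of its pairs' library weights. The
#' *link-peak score* of the window is the greatest group score; the *noise
#' score* is the sum of all the other groups — high noise relative to peak
#' marks repeat-driven spurious links. The peak's direction is the side the
#' evidence points to: the majority strand of the peak group's source ends
#' (`+` reads point right, `-` reads left). The implied end of the target
#' scaffold (`L`/`R`) is taken from the median position of the mates on
#' the target.
#'
#' @param source_scaffold scaffold id to profile.
#' @param unsatisfied unsatisfied-pair tibble from [classify_mate_pairs()].
#' @param libraries library tibble with `lib_id` and `value_weight`.
#' @param scaffold_lengths tibble `scaffold_id, length`.
#' @param window_bp,step_bp window size and step (defaults 10,000 / 5,000;
#'   `window_bp >= step_bp`).
#' @return a tibble of class `link_profile`: one row per window with
#'   `source_scaffold, start, end, peak_target, peak_score, direction,
#'   peak_target_end, noise_score, total_score, n_pairs, tie` (0-based
#'   half-open windows).
#' @export
link_score_profile <- function(source_scaffold, unsatisfied, libraries,
                               scaffold_lengths, window_bp = 10000,
                               step_bp = 5000) {
  if (window_bp < step_bp) lp_abort("window_bp must be >= step_bp")
  len <- scaffold_lengths$length[match(source_scaffold, scaffold_lengths$scaffold_id)]
  if (is.na(len)) lp_abort(sprintf("unknown scaffold: %s", source_scaffold))
  unknown <- setdiff(unique(unsatisfied$lib_id), libraries$lib_id)
  if (length(unknown) > 0L) {
    lp_abort(sprintf("unknown lib_id(s): %s", paste(unknown, collapse = ", ")))
  }
  ends <- pairs_to_ends(unsatisfied, libraries) |>
    filter(.data$source == source_scaffold)
  tlen <- scaffold_lengths$length[match(ends$target, scaffold_lengths$scaffold_id)]
  ends$target_end <- ifelse(ends$target_pos < tlen / 2, "L", "R")
  starts <- seq(0, max(0, len - 1), by = step_bp)
  rows <- purrr::map_dfr(starts, function(s) {
    e <- min(s + window_bp, len)
    inw <- ends |> filter(.data$pos >= s, .data$pos < s + window_bp)
    if (nrow(inw) == 0L) {
      return(tibble(start = s, end = e, peak_target = NA_character_,
                    peak_score = 0, direction = "none",
                    peak_target_end = NA_character_, noise_score = 0,
                    total_score = 0, n_pairs = 0L, tie = FALSE,
                    right_target = NA_character_, right_score = 0,
                    right_noise = 0, right_target_end = NA_character_,
                    left_target = NA_character_, left_score = 0,
                    left_noise = 0, left_target_end = NA_character_))
    }
    groups <- inw |>
      group_by(.data$target) |>
      summarise(score = sum(.data$weight), n = dplyr::n(),
                right_w = sum(.data$weight[.data$strand == "+"]),
                left_w = sum(.data$weight[.data$strand == "-"]),
                end_L = sum(.data$target_end == "L"),
                end_R = sum(.data$target_end == "R"), .groups = "drop") |>
      arrange(desc(.data$score), .data$target)
    top <- groups[1, ]
    tie <- nrow(groups) > 1L && isTRUE(all.equal(groups$score[2], top$score))
    # per-direction top groups: a scaffold shorter than the insert reach has
    # both ends' evidence in the same windows, so the overall peak alone
    # would mask the weaker end's partner
    dir_top <- function(strand_sym) {
      g <- inw |> filter(.data$strand == strand_sym) |>
        group_by(.data$target) |>
        summarise(score = sum(.data$weight), end_L = sum(.data$target_end == "L"),
                  end_R = sum(.data$target_end == "R"), .groups = "drop") |>
        arrange(desc(.data$score), .data$target)
      if (nrow(g) == 0L) {
        list(target = NA_character_, score = 0, noise = 0,
             tend = NA_character_)
      } else {
        list(target = g$target[1], score = g$score[1],
             noise = sum(g$score) - g$score[1],
             tend = if (g$end_L[1] >= g$end_R[1]) "L" else "R")
      }
    }
    rt <- dir_top("+"); lt <- dir_top("-")
    tibble(start = s, end = e, peak_target = top$target,
           peak_score = top$score,
           direction = if (top$right_w >= top$left_w) "right" else "left",
           peak_target_end = if (top$end_L >= top$end_R) "L" else "R",
           noise_score = sum(groups$score) - top$score,
           total_score = sum(groups$score),
           n_pairs = as.integer(sum(groups$n)), tie = tie,
           right_target = rt$target, right_score = rt$score,
           right_noise = rt$noise, right_target_end = rt$tend,
           left_target = lt$target, left_score = lt$score,
           left_noise = lt$noise, left_target_end = lt$tend)
  })
  out <- bind_cols(tibble(source_scaffold = source_scaffold), rows)
  class(out) <- c("link_profile", class(out))
  out
}

#' Link-score profiles for every scaffold touched by unsatisfied pairs
#'
#' @inheritParams link_score_profile
#' @param scaffolds optional character vector restricting which scaffolds
#'   to profile (default: all in `scaffold_lengths`).
#' @return a single `link_profile` tibble covering all profiled scaffolds.
#' @export
link_score_profiles <- function(unsatisfied, libraries, scaffold_lengths,
                                window_bp = 10000, step_bp = 5000,
                                scaffolds = NULL) {
  scaffolds <- scaffolds %||% scaffold_lengths$scaffold_id
  touched <- unique(c(unsatisfied$scaffold1, unsatisfied$scaffold2))
  scaffolds <- intersect(scaffolds, touched)
  out <- purrr::map_dfr(scaffolds, link_score_profile,
                        unsatisfied = unsatisfied, libraries = libraries,
                        scaffold_lengths = scaffold_lengths,
                        window_bp = window_bp, step_bp = step_bp)
  class(out) <- c("link_profile", class(out))
  out
}

#' Call reciprocal scaffolding links from link-score profiles
#'
#' For each scaffold end, only windows within reach of the largest library
#' insert are examined (evidence farther from an end than any insert can
#' span is ignored). The end's dominant target is the scaffold with the
#' greatest summed peak score over those terminal windows whose peak
#' direction points off that end; it becomes a candidate when its best
#' window peak reaches `min_score` and the noise/peak ratio at that window
#' stays at or below `max_noise_ratio`. A link is emitted only when the
#' target end's own dominant candidate points back (reciprocity);
#' non-reciprocal candidates are returned as suggestions.
#'
#' @param profiles `link_profile` tibble from [link_score_profiles()].
#' @param scaffold_lengths tibble `scaffold_id, length`.
#' @param libraries library tibble (largest `insert_mean` sets the
#'   terminal-window reach).
#' @param min_score minimum window peak score (default 4).
#' @param max_noise_ratio maximum noise/peak ratio (default 0.5).
#' @return list with `links` (tibble `scaffold_a, end_a, scaffold_b, end_b,
#'   score_ab, score_ba, reciprocal, relative_orientation`; `R`-`L` or
#'   `L`-`R` end pairing implies the same strand, `R`-`R` / `L`-`L`
#'   opposite) and `suggestions` (non-reciprocal candidates).
#' @export
call_links <- function(profiles, scaffold_lengths, libraries,
                       min_score = 4.0, max_noise_ratio = 0.5) {
  step_bp <- if (nrow(profiles) > 1L) {
    d <- diff(profiles$start[profiles$source_scaffold == profiles$source_scaffold[1]])
    min(d[d > 0])
  } else max(1, profiles$end[1] - profiles$start[1])
  reach_windows <- ceiling(max(libraries$insert_mean) / step_bp)

  candidates <- purrr::map_dfr(unique(profiles$source_scaffold), function(sc) {
    p <- profiles |> filter(.data$source_scaffold == sc) |> arrange(.data$start)
    len <- scaffold_lengths$length[match(sc, scaffold_lengths$scaffold_id)]
    n <- nrow(p)
    k <- min(reach_windows, n)
    purrr::map_dfr(c("L", "R"), function(side) {
      term <- if (side == "L") p[seq_len(k), ] else p[seq(n - k + 1L, n), ]
      if (side == "L") {
        term <- term |>
          transmute(target = .data$left_target, score = .data$left_score,
                    noise = .data$left_noise, tend = .data$left_target_end)
      } else {
        term <- term |>
          transmute(target = .data$right_target, score = .data$right_score,
                    noise = .data$right_noise, tend = .data$right_target_end)
      }
      term <- term |> filter(!is.na(.data$target), .data$target != sc)
      if (nrow(term) == 0L) return(NULL)
      dom <- term |>
        group_by(.data$target) |>
        summarise(total = sum(.data$score),
                  best_peak = max(.data$score),
                  best_noise = .data$noise[which.max(.data$score)],
                  target_end = .data$tend[which.max(.data$score)],
                  .groups = "drop") |>
        arrange(desc(.data$total), .data$target) |>
        slice(1L)
      if (dom$best_peak < min_score ||
          dom$best_noise / dom$best_peak > max_noise_ratio) return(NULL)
      tibble(scaffold = sc, end = side, target = dom$target,
             target_end = dom$target_end, score = dom$best_peak)
    })
  })
  empty <- tibble(scaffold_a = character(), end_a = character(),
                  scaffold_b = character(), end_b = character(),
                  score_ab = numeric(), score_ba = numeric(),
                  reciprocal = logical(), relative_orientation = character())
  if (nrow(candidates) == 0L) return(list(links = empty, suggestions = empty))

  key <- paste(candidates$scaffold, candidates$end)
  back <- match(paste(candidates$target, candidates$target_end), key)
  reciprocal <- !is.na(back) &
    candidates$target[back] == candidates$scaffold &
    candidates$target_end[back] == candidates$end
  calls <- candidates |>
    mutate(score_back = ifelse(reciprocal, candidates$score[back], NA_real_),
           reciprocal = reciprocal) |>
    transmute(scaffold_a = .data$scaffold, end_a = .data$end,
              scaffold_b = .data$target, end_b = .data$target_end,
              score_ab = .data$score, score_ba = .data$score_back,
              reciprocal = .data$reciprocal,
              relative_orientation = ifelse(.data$end_a != .data$end_b,
                                            "same", "opposite"))
  links <- calls |>
    filter(.data$reciprocal, .data$scaffold_a < .data$scaffold_b)
  list(links = links, suggestions = calls |> filter(!.data$reciprocal))
}

#' Infer relative scaffold orientations from reciprocal links
#'
#' Treats reciprocal links as edges of a graph with a parity: an `R`-`L`
#' (or `L`-`R`) end pairing means the two scaffolds lie on the same strand,
#' `R`-`R` / `L`-`L` on opposite strands. Orientations are propagated by
#' breadth-first traversal from an arbitrary root per connected component;
#' a component containing a parity-conflicting cycle has all its members
#' flagged unoriented (`?`) and the conflicts counted.
#'
#' @param links reciprocal-link tibble from [call_links()].
#' @return list with `orientations` (tibble `scaffold_id, orientation,
#'   component` where orientation is relative: `+` for the component root's
#'   strand, `-` for the opposite, `?` in conflicted components) and
#'   `n_conflicts`.
#' @export
infer_orientation <- function(links) {
  if (nrow(links) > 0L && !all(links$reciprocal)) {
    lp_abort("infer_orientation expects reciprocal links only")
  }
  nodes <- unique(c(links$scaffold_a, links$scaffold_b))
  if (length(nodes) == 0L) {
    return(list(orientations = tibble(scaffold_id = character(),
                                      orientation = character(),
                                      component = integer()),
                n_conflicts = 0L))
  }
  # adjacency with edge parity: +1 same strand, -1 opposite
  adj <- stats::setNames(vector("list", length(nodes)), nodes)
  for (i in seq_len(nrow(links))) {
    s <- if (links$relative_orientation[i] == "same") 1L else -1L
    a <- links$scaffold_a[i]; b <- links$scaffold_b[i]
    adj[[a]] <- c(adj[[a]], stats::setNames(s, b))
    adj[[b]] <- c(adj[[b]], stats::setNames(s, a))
  }
  sign <- stats::setNames(rep(NA_integer_, length(nodes)), nodes)
  comp <- stats::setNames(rep(NA_integer_, length(nodes)), nodes)
  conflicts <- 0L
  comp_id <- 0L
  bad_comps <- integer()
  for (root in nodes) {
    if (!is.na(sign[root])) next
    comp_id <- comp_id + 1L
    sign[root] <- 1L; comp[root] <- comp_id
    queue <- root
    while (length(queue) > 0L) {
      u <- queue[1]; queue <- queue[-1]
      nb <- adj[[u]]
      for (j in seq_along(nb)) {
        v <- names(nb)[j]
        want <- sign[u] * nb[[j]]
        if (is.na(sign[v])) {
          sign[v] <- want; comp[v] <- comp_id; queue <- c(queue, v)
        } else if (sign[v] != want) {
          conflicts <- conflicts + 1L
          bad_comps <- union(bad_comps, comp_id)
        }
      }
    }
  }
  # each conflicting edge is visited from both endpoints during traversal
  conflicts <- conflicts %/% 2L
  orient <- ifelse(unname(comp) %in% bad_comps, "?",
                   ifelse(unname(sign) > 0, "+", "-"))
  list(orientations = tibble(scaffold_id = nodes,
                             orientation = orient,
                             component = unname(comp)),
       n_conflicts = conflicts)
}

#' Convert link-score profiles to wiggle tracks
#'
#' Produces two tracks per scaffold: the peak score signed by direction
#' (right-pointing peaks positive — the suggested downstream path — and
#' left-pointing negative) and the unsigned noise score.
#'
#' @param profiles `link_profile` tibble.
#' @return list of two wiggle-track tibbles, `peak` and `noise`, ready for
#'   [write_wiggle()] (1-based `start`).
#' @export
profiles_to_wiggle <- function(profiles) {
  step <- if (nrow(profiles) > 1L) {
    d <- diff(profiles$start)
    max(1, min(d[d > 0], na.rm = TRUE))
  } else 1
  base <- profiles |>
    group_by(.data$source_scaffold) |>
    mutate(first_start = min(.data$start)) |>
    ungroup()
  mk <- function(value) {
    tibble(target_id = base$source_scaffold,
           start = base$first_start + 1,
           step = step, span = step, value = value)
  }
  signed <- ifelse(base$direction == "left", -base$peak_score, base$peak_score)
  list(peak = mk(signed), noise = mk(base$noise_score))
}
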