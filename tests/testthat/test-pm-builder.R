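mk_anchor <- function(scaffold, lg, cM, bp = seq_along(cM) * 1e5,
                      id = NULL) {
  tibble::tibble(marker_id = id %||% sprintf("%s_m%d", scaffold, seq_along(cM)),
                 scaffold_id = scaffold, position_bp = bp,
                 linkage_group = as.character(lg), position_cM = cM,
                 source_map = "DM", marker_class = "DArT")
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("backbone ordering sorts scaffolds by median anchor cM", {
  anchors <- dplyr::bind_rows(
    mk_anchor("A", 1, c(4, 5, 6)),
    mk_anchor("B", 1, c(9, 10, 11)),
    mk_anchor("C", 1, c(19, 20, 21)))
  bb <- build_backbone(anchors)$backbone
  expect_equal(bb$scaffold_id, c("A", "B", "C"))
  expect_equal(bb$cM, c(5, 10, 20))
  expect_false(any(bb$cobinned))

  # identical cM: shared bin, flagged
  anchors2 <- dplyr::bind_rows(mk_anchor("A", 1, 10), mk_anchor("B", 1, 10))
  bb2 <- build_backbone(anchors2)$backbone
  expect_equal(unique(bb2$bin), 1L)
  expect_true(all(bb2$cobinned))

  # anchors split across chromosomes below supermajority: screened out
  split <- dplyr::bind_rows(mk_anchor("X", 1, c(5, 6)), mk_anchor("X", 2, c(50, 51)))
  res <- build_backbone(split)
  expect_equal(res$screen, "X")
  expect_false("X" %in% res$backbone$scaffold_id)
})

test_that("backbone order matches simulated truth", {
  sim <- nochimera_sim()
  bb <- build_backbone(truth_anchors(sim))$backbone
  joined <- dplyr::inner_join(bb, sim$truth$order,
                              by = c(scaffold_id = "segment_id"))
  for (ch in unique(joined$chromosome.y)) {
    m <- joined[joined$chromosome.y == ch & joined$chromosome.x == ch, ]
    expect_gte(cor(m$rank.x, m$rank.y, method = "spearman"), 0.95)
  }
})

test_that("foreign-only scaffolds insert where projections agree", {
  backbone <- build_backbone(dplyr::bind_rows(
    mk_anchor("A", 1, c(9, 10, 11)), mk_anchor("B", 1, c(14, 15, 16))))$backbone
  rh_only <- mk_anchor("N", 1, c(11.5, 12, 12.5))
  ins <- hierarchical_insert(backbone, anchors_rh = rh_only)
  ord <- ins$ordering[ins$ordering$chromosome == "1", ]
  expect_equal(ord$scaffold_id[order(ord$rank)], c("A", "N", "B"))
  expect_equal(ord$source[ord$scaffold_id == "N"], "RH")

  # RH and tomato disagreeing on position: unplaced, conflict logged
  tom_far <- mk_anchor("N", 1, c(79, 80, 81))
  ins2 <- hierarchical_insert(backbone, anchors_rh = rh_only,
                              anchors_tom = tom_far)
  expect_false("N" %in% ins2$ordering$scaffold_id)
  expect_equal(ins2$unplaced$reason, "interval_disagreement")

  # agreement across both maps places once, tagged with both sources
  tom_near <- mk_anchor("N", 1, c(12, 12.2, 12.4))
  ins3 <- hierarchical_insert(backbone, anchors_rh = rh_only,
                              anchors_tom = tom_near)
  expect_equal(sum(ins3$ordering$scaffold_id == "N"), 1L)
  expect_equal(ins3$ordering$source[ins3$ordering$scaffold_id == "N"],
               "RH+TOM")
})

test_that("scaffolds dropped from the reference map are recovered via foreign maps", {
  sim <- nochimera_sim()
  dm <- truth_anchors(sim)
  segs <- unique(dm$scaffold_id)
  set.seed(77)
  dropped <- sample(segs, round(0.3 * length(segs)))
  dm_thin <- dm[!dm$scaffold_id %in% dropped, ]

  rh <- simulate_foreign_anchors(sim$genome, sim$truth, "RH", dropout = 0)
  tom <- simulate_foreign_anchors(sim$genome, sim$truth, "TOM", dropout = 0)
  rh_p <- project_map(rh$anchors, shared_pairs(dm_thin, rh$anchors))
  tom_p <- project_map(tom$anchors, shared_pairs(dm_thin, tom$anchors))

  bb <- build_backbone(dm_thin)$backbone
  ins <- hierarchical_insert(bb, rh_p, tom_p)
  recovered <- mean(dropped %in% ins$ordering$scaffold_id)
  expect_gte(recovered, 0.9)
})

test_that("chimera detection calls breakpoints between conflicting runs", {
  anchors <- dplyr::bind_rows(
    mk_anchor("chim", 4, c(10, 11, 12), bp = c(0.2e6, 0.5e6, 0.9e6)),
    mk_anchor("chim", 5, c(50, 52, 55), bp = c(1.3e6, 3e6, 6e6),
              id = paste0("b", 1:3)))
  res <- detect_chimeras(anchors)
  expect_equal(nrow(res$breakpoints), 1L)
  expect_equal(res$breakpoints$breakpoint_bp, 1.1e6)
  expect_equal(res$breakpoints$left_chrom, "4")
  expect_equal(res$breakpoints$right_chrom, "5")
  expect_equal(res$breakpoints$support_left, 3L)

  # one chromosome, monotone cM: nothing to call
  mono <- mk_anchor("ok", 1, c(5, 6, 7, 8), bp = (1:4) * 1e6)
  expect_equal(nrow(detect_chimeras(mono)$breakpoints), 0L)

  # under-supported runs are candidates, not calls
  weak <- dplyr::bind_rows(
    mk_anchor("w", 4, c(10, 11), bp = c(0.2e6, 0.5e6)),
    mk_anchor("w", 5, c(50, 52, 55), bp = c(1.3e6, 3e6, 6e6),
              id = paste0("b", 1:3)))
  resw <- detect_chimeras(weak)
  expect_equal(nrow(resw$breakpoints), 0L)
  expect_true("w" %in% resw$candidates$scaffold_id)

  # a large within-chromosome cM jump also breaks
  jump <- dplyr::bind_rows(
    mk_anchor("j", 1, c(5, 6, 7), bp = c(1e6, 2e6, 3e6)),
    mk_anchor("j", 1, c(60, 61, 62), bp = c(4e6, 5e6, 6e6),
              id = paste0("b", 1:3)))
  expect_equal(nrow(detect_chimeras(jump)$breakpoints), 1L)
})

test_that("splitting covers the parent exactly", {
  segs <- split_scaffold("DMB2", 6562806, 1117982)
  expect_equal(segs$length, c(1117982, 5444824))
  expect_equal(segs$segment_id, c("DMB2_p1", "DMB2_p2"))
  expect_equal(segs$parent_beg, c(0, 1117982))
  expect_equal(segs$parent_end, c(1117982, 6562806))

  # no breakpoints: identity
  one <- split_scaffold("X", 1000)
  expect_equal(one$segment_id, "X")
  expect_equal(one$length, 1000)

  # conservation with two breakpoints
  three <- split_scaffold("X", 10000, c(2500, 7000))
  expect_equal(nrow(three), 3L)
  expect_equal(sum(three$length), 10000)

  expect_error(split_scaffold("X", 1000, c(500, 500)), "duplicate")
  expect_error(split_scaffold("X", 1000, 1000), "strictly inside")

  # conservation through detect + split on random scaffolds
  sl <- tibble::tibble(scaffold_id = c("a", "b", "chim"),
                       length = c(5e5, 7e5, 2e6))
  bp <- tibble::tibble(scaffold_id = "chim", breakpoint_bp = 1.2e6)
  st <- apply_splits(sl, bp)
  expect_equal(sum(st$length), sum(sl$length))
  expect_equal(nrow(st), 4L)
})

test_that("AGP finalization alternates components with fixed gaps", {
  st <- tibble::tibble(segment_id = c("a", "b", "c"),
                       parent_id = c("a", "b", "c"), parent_beg = 0,
                       parent_end = c(1e6, 2e6, 3e6),
                       length = c(1e6, 2e6, 3e6))
  ordering <- tibble::tibble(chromosome = "1", rank = 1:3,
                             scaffold_id = c("a", "b", "c"))
  ori <- tibble::tibble(scaffold_id = c("a", "b", "c"),
                        orientation = c("+", "-", "?"))
  agp <- finalize_agp(ordering, ori, st)
  expect_equal(max(agp$object_end), 6e6 + 2 * 50000)
  expect_equal(agp$component_type, c("W", "U", "W", "U", "W"))
  expect_equal(agp$gap_length[agp$component_type == "U"], c(50000, 50000))
  validate_agp(agp)

  expect_error(finalize_agp(dplyr::bind_rows(ordering, ordering[1, ]),
                            ori, st), "more than once")

  # unplaced segments land in the chromosome-0 bin
  agp2 <- finalize_agp(ordering[1:2, ], ori, st)
  expect_true("chr0" %in% agp2$object_id)
  expect_equal(agp2$component_id[agp2$object_id == "chr0"], "c")
})

test_that("map-slope orientation respects the rate floor", {
  a <- tibble::tibble(scaffold_id = "s", position_bp = c(1e5, 9e5),
                      position_cM = c(5, 9))
  expect_equal(orient_by_slope(a)$orientation, "+")
  expect_equal(orient_by_slope(dplyr::mutate(a, position_cM = c(9, 5)))$orientation, "-")
  # |slope| below 0.1 cM/Mb: unoriented (zero-recombination region)
  flat <- dplyr::mutate(a, position_cM = c(5, 5.00001))
  expect_equal(orient_by_slope(flat)$orientation, "?")
  single <- tibble::tibble(scaffold_id = "s", position_bp = 1e5,
                           position_cM = 5)
  expect_equal(orient_by_slope(single)$orientation, "?")
})

test_that("assembly statistics reproduce size-based oriented percentages", {
  expect_equal(oriented_percentage(40.4, 49.5), 81.6)
  expect_equal(oriented_percentage(79.8, 82.6), 96.6)
  expect_equal(oriented_percentage(0, 50), 0.0)

  # N50 equals brute force on random length sets
  set.seed(31)
  for (i in 1:20) {
    lens <- sample(1e4:5e6, sample(3:40, 1))
    expect_equal(n50(lens), brute_n50(lens))
  }

  # stats from a constructed AGP: counts, sizes, totals
  st <- tibble::tibble(segment_id = c("a", "b", "c", "d"),
                       parent_id = c("a", "b", "c", "d"), parent_beg = 0,
                       parent_end = c(4e6, 2e6, 3e6, 1e6),
                       length = c(4e6, 2e6, 3e6, 1e6))
  ordering <- tibble::tibble(chromosome = c("1", "1", "2", "2"), rank = c(1, 2, 1, 2),
                             scaffold_id = c("a", "b", "c", "d"))
  ori <- tibble::tibble(scaffold_id = c("a", "b", "c", "d"),
                        orientation = c("+", "?", "-", "-"))
  stats <- assembly_stats(finalize_agp(ordering, ori, st))
  c1 <- stats[stats$chromosome == "1", ]
  expect_equal(c1$anchored_Mb, 6)
  expect_equal(c1$oriented_Mb, 4)
  expect_equal(c1$oriented_pct, round(100 * 4 / 6, 1))
  expect_equal(c1$anchored_N50_Mb, 4)
  tot <- stats[stats$chromosome == "Total", ]
  expect_equal(tot$anchored_n, 4L)
  # total percentage is the average of per-chromosome percentages
  expect_equal(tot$oriented_pct,
               round_half_up(mean(stats$oriented_pct[stats$chromosome != "Total"]), 1))
})

test_that("clone assemblies validate AGP joins through label cycles", {
  st <- tibble::tibble(segment_id = c("a", "b", "c"),
                       parent_id = c("a", "b", "c"), parent_beg = 0,
                       parent_end = 1e6, length = 1e6)
  agp <- finalize_agp(tibble::tibble(chromosome = "1", rank = 1:3,
                                     scaffold_id = c("a", "b", "c")),
                      tibble::tibble(scaffold_id = c("a", "b", "c"),
                                     orientation = "+"), st)
  contig_matches <- tibble::tibble(
    contig_id = c("t1", "t1", "t2", "t3", "t4"),
    segment_id = c("a", "b", "b", "a", "c"))
  clone_contigs <- tibble::tibble(
    clone_id = c("BAC1", "BAC2", "BAC3", "BAC3"),
    contig_id = c("t1", "t2", "t3", "t4"))
  res <- validate_with_clone_assemblies(contig_matches, clone_contigs, agp)
  # BAC1 spans the a-b join: validated
  ab <- res$joins[res$joins$segment_a == "a" & res$joins$segment_b == "b", ]
  expect_equal(ab$status, "validated")
  expect_equal(ab$clones, "BAC1")
  # BAC2 touches one segment only: b-c join untested
  bc <- res$joins[res$joins$segment_a == "b" & res$joins$segment_b == "c", ]
  expect_equal(bc$status, "untested")
  # BAC3 connects non-adjacent a and c: contradiction
  expect_equal(res$contradictions$clone_id, "BAC3")
})
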