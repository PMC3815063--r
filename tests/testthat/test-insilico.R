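test_that("clone-end and synteny filters apply the stated strictness", {
  hits <- tibble::tibble(match_length = c(450, 399, 450),
                         bit_score = c(720, 900, 700))
  kept <- filter_clone_end_hits(hits)
  expect_equal(nrow(kept), 1L)
  expect_equal(kept$match_length, 450)
  expect_equal(kept$bit_score, 720)
  # length bound is inclusive ("minimum 400")
  expect_equal(nrow(filter_clone_end_hits(
    tibble::tibble(match_length = 400, bit_score = 701))), 1L)

  m <- tibble::tibble(length_bp = c(1500, 1000, 5000),
                      identity_pct = c(98, 99, 97.0))
  kept2 <- filter_synteny_matches(m)
  expect_equal(nrow(kept2), 1L)
  expect_equal(kept2$length_bp, 1500)

  # filters are pure and order-independent (set semantics)
  set.seed(2)
  big <- tibble::tibble(match_length = sample(300:500, 50, TRUE),
                        bit_score = runif(50, 600, 800), id = 1:50)
  shuf <- big[sample(50), ]
  expect_setequal(filter_clone_end_hits(big)$id,
                  filter_clone_end_hits(shuf)$id)
})

test_that("WGP tag placement needs a unique-tag majority", {
  mk <- function(clone, scafs, pos = seq_along(scafs) * 1000, uniq = TRUE) {
    tibble::tibble(clone_id = clone, scaffold_id = scafs, position_bp = pos,
                   unique = uniq)
  }
  # 9 of 10 unique tags on scaffold X: placed, span min..max
  t1 <- mk("c1", c(rep("X", 9), "Y"))
  p1 <- place_clone_by_wgp_tags(t1)
  expect_true(p1$placed)
  expect_equal(p1$scaffold_id, "X")
  expect_equal(p1$beg, 1000)
  expect_equal(p1$end, 9000)

  # 2 unique tags: below the minimum
  expect_false(place_clone_by_wgp_tags(mk("c2", c("X", "X")))$placed)
  # 5/5 split: no majority
  expect_false(place_clone_by_wgp_tags(mk("c3", rep(c("X", "Y"), 5)))$placed)
  # non-unique tags are discarded before counting
  t4 <- dplyr::bind_rows(mk("c4", rep("X", 4)),
                         mk("c4", rep("Y", 20), uniq = FALSE))
  p4 <- place_clone_by_wgp_tags(t4)
  expect_true(p4$placed)
  expect_equal(p4$scaffold_id, "X")
})

test_that("placed mapped clones become bin-converted proxy anchors", {
  placements <- tibble::tibble(
    clone_id = c("c1", "c2", "c3"),
    scaffold_id = c("S1", "S1", NA), beg = c(1000, 51000, NA),
    end = c(3000, 53000, NA), n_tags = 5L, n_unique_total = 5L,
    placed = c(TRUE, TRUE, FALSE))
  clone_map <- tibble::tibble(clone_id = c("c1", "c2"),
                              linkage_group = "1", bin = c(12, 13))
  a <- clones_to_anchors(placements, clone_map, bin_width_cM = 0.8)
  expect_equal(nrow(a), 2L)
  expect_equal(a$position_cM, c(12, 13) * 0.8)
  expect_equal(a$position_bp, c(2000, 52000))
  expect_equal(a$marker_class, rep("clone_proxy", 2))
  # adjacent bins preserve order
  expect_lt(a$position_cM[1], a$position_cM[2])
  expect_true(all(a$weight == 1))

  # placed clone without a map position yields no anchor (and a message)
  placements2 <- placements[1, ]
  expect_message(
    a2 <- clones_to_anchors(placements2,
                            tibble::tibble(clone_id = "cX",
                                           linkage_group = "1", bin = 1)),
    "no map position")
  expect_equal(nrow(a2), 0L)

  # clones spanning >= 5 bins are down-weighted
  wide <- clones_to_anchors(
    placements[1, ],
    tibble::tibble(clone_id = "c1", linkage_group = "1",
                   bin = 10, bin_end = 14))
  expect_equal(wide$weight, 0.5)
  expect_equal(wide$position_cM, 12 * 0.8)
})

test_that("map projection interpolates through shared reference pairs", {
  shared <- tibble::tibble(linkage_group = "1",
                           foreign_cM = c(0, 50, 100),
                           backbone_cM = c(0, 60, 100))
  a <- tibble::tibble(marker_id = "x", scaffold_id = "s",
                      linkage_group = "1", position_cM = 25)
  out <- project_map(a, shared)
  expect_equal(out$position_cM, 30)
  expect_false(out$extrapolated)

  # identical maps: identity transform
  ident <- dplyr::mutate(shared, backbone_cM = foreign_cM)
  grid <- tibble::tibble(marker_id = letters[1:5], scaffold_id = "s",
                         linkage_group = "1", position_cM = c(5, 20, 50, 77, 99))
  expect_equal(project_map(grid, ident)$position_cM, grid$position_cM)

  # extrapolation beyond terminal pairs is linear and flagged
  out2 <- project_map(dplyr::mutate(a, position_cM = 110), shared)
  expect_true(out2$extrapolated)
  expect_equal(out2$position_cM, 100 + 10 * (100 - 60) / 50)

  # a group with < 2 shared scaffolds is skipped with a warning
  expect_warning(
    none <- project_map(dplyr::mutate(a, linkage_group = "9"),
                        shared[1, ] |> dplyr::mutate(linkage_group = "9")),
    "skipped")
  expect_equal(nrow(none), 0L)
})

test_that("declared inversions reverse local order before projection", {
  shared <- tibble::tibble(linkage_group = "1", foreign_cM = c(0, 100),
                           backbone_cM = c(0, 100))
  a <- tibble::tibble(marker_id = c("a", "b", "c"), scaffold_id = "s",
                      linkage_group = "1", position_cM = c(40, 50, 60))
  inv <- tibble::tibble(linkage_group = "1", foreign_beg_cM = 35,
                        foreign_end_cM = 65)
  out <- project_map(a, shared, inversions = inv)
  expect_equal(out$position_cM, c(60, 50, 40))  # order reversed

  # monotone outside declared inversions
  set.seed(4)
  many <- tibble::tibble(marker_id = sprintf("m%02d", 1:20), scaffold_id = "s",
                         linkage_group = "1",
                         position_cM = sort(runif(20, 0, 100)))
  outm <- project_map(many, shared)
  expect_true(all(diff(outm$position_cM) >= 0))
})

test_that("projection recovers true order across a planted inversion", {
  sim <- nochimera_sim()
  dm <- truth_anchors(sim)
  inv_true <- tibble::tibble(chromosome = "2", beg_cM = 10, end_cM = 30)
  f <- simulate_foreign_anchors(sim$genome, sim$truth, "TOM",
                                anchors_per_segment = 6L, dropout = 0,
                                inversion = inv_true)
  scl <- f$scale[f$scale$chromosome == "2", ]
  inv_foreign <- tibble::tibble(
    linkage_group = "2",
    foreign_beg_cM = inv_true$beg_cM * scl$mult + scl$offset,
    foreign_end_cM = inv_true$end_cM * scl$mult + scl$offset)
  # reference pairs are taken outside the rearranged block, as a curator
  # aligning maps would do
  outside <- f$anchors[!(f$anchors$linkage_group == "2" &
                           f$anchors$true_cM >= inv_true$beg_cM &
                           f$anchors$true_cM <= inv_true$end_cM), ]
  sp <- shared_pairs(dm, outside)

  inside <- f$anchors$linkage_group == "2" &
    f$anchors$true_cM >= inv_true$beg_cM & f$anchors$true_cM <= inv_true$end_cM
  stopifnot(sum(inside) >= 5)

  # with the inversion declared, projected positions restore true order
  with_inv <- project_map(f$anchors, sp, inversions = inv_foreign)
  ins <- with_inv[with_inv$linkage_group == "2" &
                    with_inv$true_cM >= inv_true$beg_cM &
                    with_inv$true_cM <= inv_true$end_cM, ]
  expect_gte(cor(ins$position_cM, ins$true_cM, method = "spearman"), 0.9)

  # without it, the inverted block's rank correlation is negative
  without <- project_map(f$anchors, sp)
  ins0 <- without[without$linkage_group == "2" &
                    without$true_cM >= inv_true$beg_cM &
                    without$true_cM <= inv_true$end_cM, ]
  expect_lt(cor(ins0$position_cM, ins0$true_cM, method = "spearman"), 0)
})
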