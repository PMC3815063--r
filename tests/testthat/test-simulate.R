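test_that("the generator is fully deterministic under a seed", {
  cfg <- sim_config(seed = 42L)
  g1 <- simulate_genome(cfg)
  t1 <- fragment_into_scaffolds(g1)
  t2 <- fragment_into_scaffolds(simulate_genome(sim_config(seed = 42L)))
  expect_identical(t1, t2)
  p1 <- simulate_matepairs(g1, t1)
  p2 <- simulate_matepairs(g1, t1)
  expect_identical(p1, p2)
  m1 <- simulate_markers_and_genotypes(g1, t1)
  m2 <- simulate_markers_and_genotypes(g1, t1)
  expect_identical(m1, m2)

  # a different seed changes the draw
  t3 <- fragment_into_scaffolds(simulate_genome(sim_config(seed = 7L)))
  expect_false(identical(t1$scaffolds, t3$scaffolds))
})

test_that("the recombination landscape integrates to the map length", {
  cfg <- sim_config(pericentromere_frac = 0.3)
  g <- simulate_genome(cfg)
  land <- g$landscape
  for (ch in g$chromosomes$chromosome) {
    l <- land[land$chromosome == ch, ]
    integral <- sum(l$rate_cM_per_Mb * (l$end_bp - l$beg_bp) / 1e6)
    expect_equal(g$chromosomes$map_length_cM[g$chromosomes$chromosome == ch],
                 integral, tolerance = 1e-9)
  }
  # central 30% has map slope 0
  L <- g$chromosomes$length_bp[1]
  mid <- genetic_position(g, "1", c(0.36 * L, 0.64 * L))
  expect_equal(mid[1], mid[2])
  # and positive slope outside
  eu <- genetic_position(g, "1", c(0, 0.2 * L))
  expect_gt(eu[2], eu[1])
  # physical/genetic inverses agree in euchromatin
  cM <- genetic_position(g, "1", 0.1 * L)
  expect_equal(physical_position(g, "1", cM), 0.1 * L, tolerance = 1e-6)

  expect_error(sim_config(marker_density_eu = 0, marker_density_peri = 0),
               "density")
})

test_that("fragmentation conserves length and plants the chimeras", {
  sim <- default_sim()
  truth <- sim$truth
  g <- sim$genome
  expect_equal(sum(truth$scaffolds$length), sum(g$chromosomes$length_bp))
  expect_equal(sum(truth$scaffolds$is_chimera), 2L)
  expect_equal(nrow(truth$breakpoints), 2L)

  # every non-chimeric scaffold maps to one contiguous chromosome interval
  normal <- truth$segments |>
    dplyr::filter(!truth$scaffolds$is_chimera[
      match(scaffold_id, truth$scaffolds$scaffold_id)])
  expect_true(all(table(normal$scaffold_id) == 1))
  expect_equal(normal$chrom_end - normal$chrom_beg,
               normal$scaf_end - normal$scaf_beg)
  # segments tile each chromosome exactly
  for (ch in g$chromosomes$chromosome) {
    s <- truth$segments[truth$segments$chromosome == ch, ]
    s <- s[order(s$chrom_beg), ]
    expect_equal(s$chrom_beg[1], 0)
    expect_equal(max(s$chrom_end),
                 g$chromosomes$length_bp[g$chromosomes$chromosome == ch])
    if (nrow(s) > 1) expect_equal(s$chrom_beg[-1], s$chrom_end[-nrow(s)])
  }
  # chimera parts come from different chromosomes
  for (sc in truth$breakpoints$scaffold_id) {
    parts <- truth$segments[truth$segments$scaffold_id == sc, ]
    expect_equal(nrow(parts), 2L)
    expect_false(parts$chromosome[1] == parts$chromosome[2])
  }
})

test_that("mate-pair counts across well-separated junctions match the binomial model", {
  sim <- nochimera_sim()
  g <- sim$genome
  lib <- sim$libraries[sim$libraries$lib_id == "dm_clone", ]
  genome_bp <- sum(g$chromosomes$length_bp)
  lens <- sim$scaffold_lengths

  adj <- sim$truth$adjacencies
  flank_len <- function(id) lens$length[lens$scaffold_id == id]
  wide <- adj[vapply(adj$seg_a, flank_len, 1) >= 2 * lib$insert_mean &
                vapply(adj$seg_b, flank_len, 1) >= 2 * lib$insert_mean, ]
  stopifnot(nrow(wide) >= 10)

  pr <- sim$pairs[sim$pairs$lib_id == "dm_clone", ]
  key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  crossing <- key(pr$scaffold1, pr$scaffold2)
  observed <- sum(crossing %in% key(wide$seg_a, wide$seg_b))
  p_cross <- nrow(wide) * lib$insert_mean / genome_bp
  expected <- lib$n_pairs * p_cross
  sd3 <- 3 * sqrt(lib$n_pairs * p_cross * (1 - p_cross))
  expect_lt(abs(observed - expected), sd3)
})

test_that("noise-free pairs are all consistent with the true genome", {
  cfg <- sim_config(noise_pair_frac = 0, chimera_count = 0L)
  g <- simulate_genome(cfg)
  tr <- fragment_into_scaffolds(g)
  pr <- simulate_matepairs(g, tr)
  # reconstruct chromosome positions of both ends; separation must be a
  # plausible insert for the library and both ends on one chromosome
  seg <- tr$segments
  back <- function(sc, pos) {
    s <- seg[match(sc, seg$scaffold_id), ]
    ifelse(s$orientation == "+", s$chrom_beg + (pos - s$scaf_beg),
           s$chrom_end - 1 - (pos - s$scaf_beg))
  }
  ch1 <- seg$chromosome[match(pr$scaffold1, seg$scaffold_id)]
  ch2 <- seg$chromosome[match(pr$scaffold2, seg$scaffold_id)]
  expect_true(all(ch1 == ch2))
  sep <- abs(back(pr$scaffold2, pr$pos2) - back(pr$scaffold1, pr$pos1))
  reach <- cfg$libraries$insert_mean[match(pr$lib_id, cfg$libraries$lib_id)] +
    6 * cfg$libraries$insert_sd[match(pr$lib_id, cfg$libraries$lib_id)]
  expect_true(all(sep <= reach))
})

test_that("planted distortion is detectable at the stated power", {
  hits <- 0L
  for (s in 1:20) {
    cfg <- sim_config(n_chromosomes = 1L, chromosome_Mb = 5,
                      chimera_count = 0L,
                      distortion_loci = tibble::tibble(chromosome = "1",
                                                       position_Mb = 1,
                                                       ratio = 2),
                      missing_rate = 0, seed = 1000L + s)
    g <- simulate_genome(cfg)
    tr <- fragment_into_scaffolds(g)
    mk <- simulate_markers_and_genotypes(g, tr)
    target_cM <- genetic_position(g, "1", 1e6)
    near <- which.min(abs(mk$map$position_cM - target_cM))
    d <- segregation_distortion(mk$genotypes[near, , drop = FALSE])
    if (d$p_value < 0.001) hits <- hits + 1L
  }
  expect_gte(hits / 20, 0.95)
})

test_that("realized recombination matches the map scale", {
  sim <- default_sim()
  map <- sim$markers$map
  geno <- sim$markers$genotypes
  # two markers ~10 cM apart on chromosome 1
  m1 <- map[map$linkage_group == "1", ]
  i <- 1L
  j <- which.min(abs(m1$position_cM - (m1$position_cM[1] + 10)))
  d_cM <- abs(m1$position_cM[j] - m1$position_cM[i])
  g1 <- geno[m1$marker_id[i], ]
  g2 <- geno[m1$marker_id[j], ]
  ok <- !is.na(g1) & !is.na(g2)
  r_obs <- mean(g1[ok] != g2[ok])
  r_exp <- kosambi_r(d_cM)
  sd3 <- 3 * sqrt(r_exp * (1 - r_exp) / sum(ok))
  expect_lt(abs(r_obs - r_exp), sd3)
})

test_that("a simulation writes and reloads as standard files", {
  dir <- withr::local_tempdir()
  cfg <- sim_config(n_chromosomes = 1L, chromosome_Mb = 3,
                    chimera_count = 0L,
                    libraries = dplyr::mutate(default_sim_libraries(),
                                              n_pairs = c(200L, 200L, 200L)))
  sim <- simulate_assembly(cfg)
  write_simulation(sim, dir)
  expect_true(all(file.exists(file.path(dir,
    c("scaffolds.tsv", "pairs.tsv", "libraries.yaml", "markers.tsv",
      "alignments.tsv", "genotypes.tsv", "map.tsv")))))
  libs <- read_library_specs(file.path(dir, "libraries.yaml"))
  expect_equal(libs$value_weight, c(3, 2, 1.5))
  geno <- read_genotype_matrix(file.path(dir, "genotypes.tsv"))
  expect_identical(geno, sim$markers$genotypes)
  aln <- read_alignment_table(file.path(dir, "alignments.tsv"), "internal")
  expect_equal(nrow(aln), nrow(sim$markers$alignments))
  map <- read_map_table(file.path(dir, "map.tsv"))
  expect_equal(nrow(map), nrow(sim$markers$map))
})
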