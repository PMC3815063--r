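# Shared simulated fixtures, computed once per test run.

.sim_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .sim_cache)) {
    assign(key, force(expr), envir = .sim_cache)
  }
  get(key, envir = .sim_cache)
}

# the default study conditions: 3 chromosomes, ~60 scaffolds, 2 chimeras,
# 3 libraries, seed 42
default_sim <- function() cached("default", simulate_assembly(sim_config()))

# chimera-free variant for focused link-calling and backbone tests
nochimera_sim <- function() {
  cached("nochimera",
         simulate_assembly(sim_config(chimera_count = 0L,
                                      noise_pair_frac = 0)))
}

# anchors recovered by the full marker cascade on the default simulation
default_anchor_run <- function() {
  cached("anchors", {
    sim <- default_sim()
    qc <- filter_genotype_matrix(sim$markers$genotypes)
    cs <- collapse_cosegregating(qc$geno)
    anchor_markers(sim$markers$alignments, sim$markers$map,
                   sim$markers$metadata, cs$groups)
  })
}

# truth-derived anchors (oracle parameters), for isolating downstream ops
truth_anchors <- function(sim) {
  pos <- sim$markers$positions
  tibble::tibble(marker_id = pos$marker_id, scaffold_id = pos$scaffold_id,
                 position_bp = pos$scaffold_bp,
                 linkage_group = pos$chromosome, position_cM = pos$cM,
                 source_map = "DM", marker_class = pos$marker_class)
}

# foreign-anchor reference pairs shared with a backbone anchor set
shared_pairs <- function(dm_anchors, foreign_anchors) {
  dmm <- dm_anchors |>
    dplyr::group_by(scaffold_id, linkage_group) |>
    dplyr::summarise(backbone_cM = stats::median(position_cM), .groups = "drop")
  fm <- foreign_anchors |>
    dplyr::group_by(scaffold_id, linkage_group) |>
    dplyr::summarise(foreign_cM = stats::median(position_cM), .groups = "drop")
  dplyr::inner_join(dmm, fm, by = c("scaffold_id", "linkage_group")) |>
    dplyr::select(linkage_group, foreign_cM, backbone_cM)
}

# full pipeline run on the default simulation, reused by several files
default_assembly <- function() {
  cached("assembly", {
    sim <- default_sim()
    res <- default_anchor_run()
    rh <- simulate_foreign_anchors(sim$genome, sim$truth, "RH")
    tom <- simulate_foreign_anchors(sim$genome, sim$truth, "TOM")
    rh_p <- project_map(rh$anchors, shared_pairs(res$anchors, rh$anchors))
    tom_p <- project_map(tom$anchors, shared_pairs(res$anchors, tom$anchors))
    assemble_pseudomolecules(res$anchors, sim$pairs, sim$libraries,
                             sim$scaffold_lengths,
                             anchors_rh = rh_p, anchors_tom = tom_p)
  })
}

# brute-force per-base depth filter, the independent oracle for depth_filter
brute_depth_filter <- function(alignments, max_competitors = 5L, frac = 0.20) {
  keep <- logical(nrow(alignments))
  for (i in seq_len(nrow(alignments))) {
    same <- which(alignments$query_id == alignments$query_id[i])
    same <- setdiff(same, i)
    b <- alignments$q_beg[i]; e <- alignments$q_end[i]
    bases <- seq(b, e - 1)  # integer coordinates
    depth <- vapply(bases, function(x) {
      sum(alignments$q_beg[same] <= x & alignments$q_end[same] > x)
    }, numeric(1))
    keep[i] <- mean(depth >= max_competitors) < frac
  }
  alignments[keep, , drop = FALSE]
}

# brute-force N50: cumulate sorted lengths to half the total
brute_n50 <- function(lengths) {
  s <- sort(lengths, decreasing = TRUE)
  tot <- sum(s)
  run <- 0
  for (x in s) {
    run <- run + x
    if (run >= tot / 2) return(x)
  }
  NA_real_
}

random_alignments <- function(n, n_queries = 3, span = 1000) {
  b <- floor(runif(n, 0, span))
  len <- floor(runif(n, 10, 200))
  tibble::tibble(
    query_id = sample(paste0("q", seq_len(n_queries)), n, replace = TRUE),
    q_beg = b, q_end = b + len,
    target_id = sample(c("t1", "t2"), n, replace = TRUE),
    t_beg = b, t_end = b + len,
    strand = sample(c("+", "-"), n, replace = TRUE),
    score = runif(n, 50, 500), identity_pct = runif(n, 90, 100),
    match_length = len)
}
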