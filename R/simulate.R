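#' Simulation configuration
#'
#' Bundles every tunable of the synthetic-data generator into one list. The
#' defaults describe a desk-scale diploid plant genome: 3 chromosomes of
#' 10 Mb cut into ~60 scaffolds (lognormal lengths, mean ~0.5 Mb), 2
#' planted chimeric misjoins, a central pericentromeric block covering 25%
#' of each chromosome with recombination fully suppressed, euchromatic
#' recombination of 10 cM/Mb (~75 cM per chromosome), marker densities of
#' 10/Mb in euchromatin and 1.5/Mb in the pericentromere, a 180-individual
#' backcross, and three mate-pair libraries: clone ends (100 kb inserts,
#' weight 3, 20x physical coverage), 20-kb and 8-kb long-insert reads
#' (weights 2 and 1.5).
#'
#' @param n_chromosomes number of chromosomes.
#' @param chromosome_Mb length of each chromosome (Mb).
#' @param scaffold_len_meanlog,scaffold_len_sdlog lognormal scaffold-length
#'   parameters (bp scale).
#' @param min_scaffold_bp floor on scaffold length.
#' @param chimera_count number of planted false joins.
#' @param pericentromere_frac central fraction of each chromosome with
#'   suppressed recombination.
#' @param recomb_rate_eu euchromatic recombination rate (cM/Mb).
#' @param marker_density_eu,marker_density_peri markers per Mb.
#' @param distortion_loci tibble `chromosome, position_Mb, ratio` of
#'   transmission-distorted loci.
#' @param missing_rate fraction of genotype calls masked missing.
#' @param n_individuals backcross population size.
#' @param libraries library tibble with an extra `n_pairs` column.
#' @param noise_pair_frac fraction of chimeric/noise mate pairs.
#' @param repeat_marker_frac fraction of aligned markers given a stack of
#'   repeat-like competing alignments.
#' @param ambiguous_marker_frac fraction given one near-score decoy hit.
#' @param foreign_map_dropout fraction of segments absent from each
#'   foreign map.
#' @param inversion_intervals optional tibble of planted inversions.
#' @param seed integer master seed; every generator draw derives from it.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(n_chromosomes = 3L,
                       chromosome_Mb = 10,
                       scaffold_len_meanlog = log(4.2e5),
                       scaffold_len_sdlog = 0.6,
                       min_scaffold_bp = 2e4,
                       chimera_count = 2L,
                       pericentromere_frac = 0.25,
                       recomb_rate_eu = 10,
                       marker_density_eu = 10,
                       marker_density_peri = 1.5,
                       distortion_loci = tibble(chromosome = "1",
                                                position_Mb = 2,
                                                ratio = 2),
                       missing_rate = 0.03,
                       n_individuals = 180L,
                       libraries = default_sim_libraries(),
                       noise_pair_frac = 0.02,
                       repeat_marker_frac = 0.05,
                       ambiguous_marker_frac = 0.03,
                       foreign_map_dropout = 0.10,
                       inversion_intervals = NULL,
                       seed = 42L) {
  cfg <- as.list(environment())
  fracs <- c(cfg$pericentromere_frac, cfg$missing_rate, cfg$noise_pair_frac,
             cfg$repeat_marker_frac, cfg$ambiguous_marker_frac,
             cfg$foreign_map_dropout)
  if (any(fracs < 0 | fracs > 1)) lp_abort("all fractions must be in [0, 1]")
  if (cfg$marker_density_eu <= 0 && cfg$marker_density_peri <= 0) {
    lp_abort("marker density must be positive somewhere")
  }
  structure(cfg, class = "sim_config")
}

#' @rdname sim_config
#' @export
default_sim_libraries <- function() {
  tibble(
    lib_id = c("dm_clone", "dm_454_20k", "dm_454_8k"),
    origin = "DM",
    kind = c("clone_end", "long_insert_454", "long_insert_454"),
    insert_mean = c(1e5, 2e4, 8e3),
    insert_sd = c(1e4, 2e3, 8e2),
    value_weight = c(3, 2, 1.5),
    n_pairs = c(6000L, 12000L, 20000L)
  )
}

#' Simulate chromosome coordinate systems and recombination landscape
#'
#' Deterministic given the configuration: each chromosome gets a
#' three-piece recombination landscape — euchromatic rate on both arms, a
#' central pericentromeric block at rate 0 — from which genetic positions
#' are the running integral.
#'
#' @param config a [sim_config()].
#' @return object of class `sim_genome`: list with `chromosomes` (tibble
#'   `chromosome, length_bp, map_length_cM`) and `landscape` (tibble
#'   `chromosome, beg_bp, end_bp, rate_cM_per_Mb, cM_beg`).
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  L <- round(config$chromosome_Mb * 1e6)
  chroms <- as.character(seq_len(config$n_chromosomes))
  peri <- config$pericentromere_frac
  c1 <- round(L * (0.5 - peri / 2)); c2 <- round(L * (0.5 + peri / 2))
  landscape <- purrr::map_dfr(chroms, function(ch) {
    tibble(chromosome = ch,
           beg_bp = c(0, c1, c2), end_bp = c(c1, c2, L),
           rate_cM_per_Mb = c(config$recomb_rate_eu, 0, config$recomb_rate_eu))
  }) |>
    group_by(.data$chromosome) |>
    mutate(cM_beg = cumsum(dplyr::lag(.data$rate_cM_per_Mb *
                                        (.data$end_bp - .data$beg_bp) / 1e6,
                                      default = 0))) |>
    ungroup()
  chromosomes <- landscape |>
    group_by(chromosome = .data$chromosome) |>
    summarise(length_bp = max(.data$end_bp),
              map_length_cM = sum(.data$rate_cM_per_Mb *
                                    (.data$end_bp - .data$beg_bp) / 1e6),
              .groups = "drop")
  structure(list(chromosomes = chromosomes, landscape = landscape,
                 config = config), class = "sim_genome")
}

#' Genetic position of physical coordinates (and back)
#'
#' @param genome a `sim_genome`.
#' @param chromosome chromosome id(s).
#' @param bp physical position(s), 0-based.
#' @return `genetic_position()`: cM; `physical_position()`: bp.
#' @export
genetic_position <- function(genome, chromosome, bp) {
  purrr::map2_dbl(as.character(chromosome), bp, function(ch, p) {
    l <- genome$landscape[genome$landscape$chromosome == ch, ]
    i <- max(findInterval(p, l$beg_bp), 1L)
    l$cM_beg[i] + (p - l$beg_bp[i]) * l$rate_cM_per_Mb[i] / 1e6
  })
}

#' @rdname genetic_position
#' @param cM genetic position(s).
#' @export
physical_position <- function(genome, chromosome, cM) {
  purrr::map2_dbl(as.character(chromosome), cM, function(ch, g) {
    l <- genome$landscape[genome$landscape$chromosome == ch, ]
    ends_cM <- l$cM_beg + l$rate_cM_per_Mb * (l$end_bp - l$beg_bp) / 1e6
    i <- which(g <= ends_cM + 1e-12)[1]
    if (is.na(i)) i <- nrow(l)
    if (l$rate_cM_per_Mb[i] == 0) return(l$beg_bp[i])
    l$beg_bp[i] + (g - l$cM_beg[i]) * 1e6 / l$rate_cM_per_Mb[i]
  })
}

#' Fragment chromosomes into scaffolds and plant chimeric joins
#'
#' Cuts each chromosome into scaffolds with lognormal lengths, assigns each
#' scaffold a random orientation and a shuffled id (so id order carries no
#' positional information), then fuses `chimera_count` pairs of scaffolds
#' from different chromosomes into chimeric scaffolds, recording the join
#' coordinate. Fusion partners are drawn from scaffolds of at least 300 kb
#' lying mostly (>= 60%) in euchromatin, where anchor support makes a
#' misjoin detectable — mirroring where curated assemblies actually catch
#' them.
#'
#' @param genome a `sim_genome`.
#' @param config the [sim_config()] (defaults to the one inside `genome`).
#' @return list of class `sim_truth`:
#'   `scaffolds` (tibble `scaffold_id, length, is_chimera`),
#'   `segments` (tibble `scaffold_id, segment_id, part, chromosome,
#'   chrom_beg, chrom_end, scaf_beg, scaf_end, orientation` — the full
#'   coordinate map between chromosomes and scaffolds),
#'   `order` (tibble `chromosome, rank, segment_id, orientation`),
#'   `adjacencies` (tibble `chromosome, seg_a, seg_b`),
#'   `breakpoints` (tibble `scaffold_id, breakpoint_bp`).
#' @export
fragment_into_scaffolds <- function(genome, config = genome$config) {
  set.seed(derive_seed(config$seed, "scaffolds"))
  pieces <- purrr::map_dfr(seq_len(nrow(genome$chromosomes)), function(i) {
    ch <- genome$chromosomes$chromosome[i]
    L <- genome$chromosomes$length_bp[i]
    lens <- numeric(); tot <- 0
    while (tot < L) {
      l <- max(round(stats::rlnorm(1, config$scaffold_len_meanlog,
                                   config$scaffold_len_sdlog)),
               config$min_scaffold_bp)
      l <- min(l, L - tot)
      lens <- c(lens, l); tot <- tot + l
    }
    # avoid a dangling sliver at the chromosome end
    if (length(lens) > 1L && lens[length(lens)] < config$min_scaffold_bp) {
      lens[length(lens) - 1L] <- lens[length(lens) - 1L] + lens[length(lens)]
      lens <- lens[-length(lens)]
    }
    tibble(chromosome = ch, chrom_beg = cumsum(c(0, lens[-length(lens)])),
           chrom_end = cumsum(lens), length = lens)
  })
  n <- nrow(pieces)
  if (config$chimera_count * 2L > n) lp_abort("chimera_count too large for scaffold count")
  pieces$orientation <- sample(c("+", "-"), n, replace = TRUE)
  pieces$piece_id <- sprintf("P%03d", seq_len(n))

  # choose chimera partners: large, mostly euchromatic, different chromosomes
  peri <- genome$landscape |> filter(.data$rate_cM_per_Mb == 0)
  eu_frac <- purrr::map_dbl(seq_len(n), function(i) {
    p <- peri[peri$chromosome == pieces$chromosome[i], ]
    ov <- sum(pmax(0, pmin(pieces$chrom_end[i], p$end_bp) -
                     pmax(pieces$chrom_beg[i], p$beg_bp)))
    1 - ov / pieces$length[i]
  })
  eligible <- which(pieces$length >= 3e5 & eu_frac >= 0.6)
  fused <- integer(0)
  chim <- list()
  for (k in seq_len(config$chimera_count)) {
    pool <- setdiff(eligible, fused)
    a <- sample(pool, 1L)
    pool_b <- pool[pieces$chromosome[pool] != pieces$chromosome[a] & pool != a]
    if (length(pool_b) == 0L) lp_abort("cannot place chimera across chromosomes")
    b <- if (length(pool_b) == 1L) pool_b else sample(pool_b, 1L)
    fused <- c(fused, a, b)
    chim[[k]] <- c(a, b)
  }

  # scaffold ids shuffled over all final scaffolds
  n_scaf <- n - config$chimera_count
  ids <- sprintf("S%03d", sample(n_scaf))
  segs <- list(); scaf_rows <- list(); bp_rows <- list()
  id_i <- 0L
  in_chimera <- unlist(chim)
  for (i in setdiff(seq_len(n), in_chimera)) {
    id_i <- id_i + 1L
    segs[[length(segs) + 1L]] <- tibble(
      scaffold_id = ids[id_i], segment_id = ids[id_i], part = 1L,
      chromosome = pieces$chromosome[i],
      chrom_beg = pieces$chrom_beg[i], chrom_end = pieces$chrom_end[i],
      scaf_beg = 0, scaf_end = pieces$length[i],
      orientation = pieces$orientation[i])
    scaf_rows[[length(scaf_rows) + 1L]] <- tibble(
      scaffold_id = ids[id_i], length = pieces$length[i], is_chimera = FALSE)
  }
  for (pair in chim) {
    id_i <- id_i + 1L
    l1 <- pieces$length[pair[1]]; l2 <- pieces$length[pair[2]]
    segs[[length(segs) + 1L]] <- tibble(
      scaffold_id = ids[id_i],
      segment_id = paste0(ids[id_i], "_p", 1:2), part = 1:2,
      chromosome = pieces$chromosome[pair],
      chrom_beg = pieces$chrom_beg[pair], chrom_end = pieces$chrom_end[pair],
      scaf_beg = c(0, l1), scaf_end = c(l1, l1 + l2),
      orientation = pieces$orientation[pair])
    scaf_rows[[length(scaf_rows) + 1L]] <- tibble(
      scaffold_id = ids[id_i], length = l1 + l2, is_chimera = TRUE)
    bp_rows[[length(bp_rows) + 1L]] <- tibble(
      scaffold_id = ids[id_i], breakpoint_bp = l1)
  }
  segments <- bind_rows(segs)
  ord <- segments |>
    arrange(.data$chromosome, .data$chrom_beg) |>
    group_by(.data$chromosome) |>
    mutate(rank = dplyr::row_number()) |>
    ungroup() |>
    select("chromosome", "rank", "segment_id", "orientation")
  adjac <- ord |>
    group_by(.data$chromosome) |>
    reframe(seg_a = .data$segment_id[-dplyr::n()], seg_b = .data$segment_id[-1])
  structure(list(scaffolds = bind_rows(scaf_rows), segments = segments,
                 order = ord, adjacencies = adjac,
                 breakpoints = if (length(bp_rows) > 0L) bind_rows(bp_rows)
                               else tibble(scaffold_id = character(),
                                           breakpoint_bp = numeric())),
            class = "sim_truth")
}

# internal: map chromosome coordinates/strands into scaffold coordinates
map_to_scaffold <- function(segments, chromosome, pos, strand = NULL) {
  chromosome <- as.character(chromosome)
  out_sc <- character(length(pos)); out_pos <- numeric(length(pos))
  out_str <- if (is.null(strand)) NULL else character(length(pos))
  for (ch in unique(chromosome)) {
    s <- segments[segments$chromosome == ch, ]
    s <- s[order(s$chrom_beg), ]
    sel <- which(chromosome == ch)
    idx <- findInterval(pos[sel], s$chrom_beg)
    idx[idx < 1L] <- 1L
    flip <- s$orientation[idx] == "-"
    out_sc[sel] <- s$scaffold_id[idx]
    p <- pos[sel]
    out_pos[sel] <- ifelse(flip,
                           s$scaf_beg[idx] + (s$chrom_end[idx] - 1 - p),
                           s$scaf_beg[idx] + (p - s$chrom_beg[idx]))
    if (!is.null(strand)) {
      out_str[sel] <- ifelse(flip,
                             ifelse(strand[sel] == "+", "-", "+"),
                             strand[sel])
    }
  }
  tibble(scaffold_id = out_sc, pos = out_pos,
         strand = out_str %||% NA_character_)
}

#' Simulate mate-pair libraries over the true genome
#'
#' Fragments are placed uniformly on the concatenated chromosomes, insert
#' sizes drawn truncated-normal per library, and the two ends transformed
#' into scaffold coordinates (an innie configuration: the left end on
#' `+`, the right end on `-`, before the scaffold-orientation transform).
#' A configurable fraction of noise pairs gets fully random ends.
#'
#' @param genome a `sim_genome`.
#' @param truth a `sim_truth`.
#' @param libraries library tibble with `n_pairs` (default: the config's).
#' @param config the [sim_config()].
#' @return a pairs tibble: `pair_id, lib_id, scaffold1, pos1, strand1,
#'   scaffold2, pos2, strand2, mapq_ok`.
#' @export
simulate_matepairs <- function(genome, truth, libraries = NULL,
                               config = genome$config) {
  set.seed(derive_seed(config$seed, "matepairs"))
  libraries <- libraries %||% config$libraries
  chroms <- genome$chromosomes
  out <- purrr::map_dfr(seq_len(nrow(libraries)), function(li) {
    lb <- libraries[li, ]
    n <- lb$n_pairs
    ch <- sample(chroms$chromosome, n, replace = TRUE,
                 prob = chroms$length_bp)
    L <- chroms$length_bp[match(ch, chroms$chromosome)]
    ins <- abs(stats::rnorm(n, lb$insert_mean, lb$insert_sd))
    ins <- pmin(ins, L - 1)
    start <- floor(stats::runif(n, 0, L - ins))
    e1 <- map_to_scaffold(truth$segments, ch, start, rep("+", n))
    e2 <- map_to_scaffold(truth$segments, ch, floor(start + ins), rep("-", n))
    tibble(pair_id = sprintf("%s_%06d", lb$lib_id, seq_len(n)),
           lib_id = lb$lib_id,
           scaffold1 = e1$scaffold_id, pos1 = e1$pos, strand1 = e1$strand,
           scaffold2 = e2$scaffold_id, pos2 = e2$pos, strand2 = e2$strand,
           mapq_ok = TRUE)
  })
  n_noise <- round(config$noise_pair_frac * nrow(out))
  if (n_noise > 0L) {
    set.seed(derive_seed(config$seed, "noise"))
    idx <- sample(nrow(out), n_noise)
    sc <- truth$scaffolds
    r1 <- sample(nrow(sc), n_noise, replace = TRUE)
    r2 <- sample(nrow(sc), n_noise, replace = TRUE)
    out$scaffold1[idx] <- sc$scaffold_id[r1]
    out$pos1[idx] <- floor(stats::runif(n_noise, 0, sc$length[r1]))
    out$strand1[idx] <- sample(c("+", "-"), n_noise, replace = TRUE)
    out$scaffold2[idx] <- sc$scaffold_id[r2]
    out$pos2[idx] <- floor(stats::runif(n_noise, 0, sc$length[r2]))
    out$strand2[idx] <- sample(c("+", "-"), n_noise, replace = TRUE)
  }
  out
}

#' Simulate markers, their alignments, the genetic map and genotypes
#'
#' Markers are laid down by the density landscape (dense in euchromatin,
#' sparse in the pericentromere). SNP-class markers are "designed against
#' the assembly" and carry a priori scaffold positions; SSR-class markers
#' align as convergent forward/reverse read pairs; DArT-class markers as
#' single reads. A fraction of aligned markers receives a stack of
#' competing decoy alignments (repeat mimics, removed by the depth filter)
#' and another fraction a single near-score decoy (ambiguous placements).
#' Backcross genotypes are simulated by meiosis along the true map
#' (crossover count Poisson in map length, positions uniform in cM);
#' distortion loci bias transmission by rejection sampling; calls are
#' masked missing at the configured rate.
#'
#' @param genome a `sim_genome`.
#' @param truth a `sim_truth`.
#' @param config the [sim_config()].
#' @return list: `metadata` (tibble `marker_id, marker_class,
#'   a_priori_scaffold, a_priori_pos`), `map` (`marker_id, linkage_group,
#'   position_cM`), `alignments` (internal-dialect tibble), `genotypes`
#'   (character matrix), `positions` (truth: `marker_id, chromosome,
#'   chrom_bp, scaffold_id, scaffold_bp, decoy_class`).
#' @export
simulate_markers_and_genotypes <- function(genome, truth,
                                           config = genome$config) {
  set.seed(derive_seed(config$seed, "markers"))
  land <- genome$landscape |>
    mutate(density = ifelse(.data$rate_cM_per_Mb == 0,
                            config$marker_density_peri,
                            config$marker_density_eu))
  pos_rows <- purrr::map_dfr(seq_len(nrow(land)), function(i) {
    span_Mb <- (land$end_bp[i] - land$beg_bp[i]) / 1e6
    k <- stats::rpois(1, land$density[i] * span_Mb)
    if (k == 0L) return(NULL)
    tibble(chromosome = land$chromosome[i],
           chrom_bp = sort(floor(stats::runif(k, land$beg_bp[i], land$end_bp[i]))))
  })
  m <- nrow(pos_rows)
  if (m < 2L) lp_abort("marker landscape produced too few markers")
  pos_rows$marker_id <- sprintf("M%04d", seq_len(m))
  pos_rows$marker_class <- sample(c("SNP", "DArT", "SSR"), m, replace = TRUE,
                                  prob = c(0.2, 0.6, 0.2))
  sc <- map_to_scaffold(truth$segments, pos_rows$chromosome, pos_rows$chrom_bp,
                        rep("+", m))
  pos_rows$scaffold_id <- sc$scaffold_id
  pos_rows$scaffold_bp <- sc$pos
  pos_rows$scaffold_strand <- sc$strand
  pos_rows$cM <- genetic_position(genome, pos_rows$chromosome, pos_rows$chrom_bp)

  map <- pos_rows |>
    transmute(.data$marker_id, linkage_group = .data$chromosome,
              position_cM = .data$cM)
  metadata <- pos_rows |>
    transmute(.data$marker_id, .data$marker_class,
              a_priori_scaffold = ifelse(.data$marker_class == "SNP",
                                         .data$scaffold_id, NA_character_),
              a_priori_pos = ifelse(.data$marker_class == "SNP",
                                    .data$scaffold_bp, NA_real_))

  # --- alignments for DArT (single read) and SSR (read pair) markers
  read_len <- 150
  aligned <- pos_rows |> filter(.data$marker_class != "SNP")
  aln <- purrr::map_dfr(seq_len(nrow(aligned)), function(i) {
    r <- aligned[i, ]
    if (r$marker_class == "DArT") {
      tibble(query_id = r$marker_id, q_beg = 0, q_end = read_len,
             target_id = r$scaffold_id,
             t_beg = max(0, r$scaffold_bp - read_len / 2),
             t_end = max(0, r$scaffold_bp - read_len / 2) + read_len,
             strand = r$scaffold_strand, score = 2 * read_len,
             identity_pct = 99.5, match_length = read_len)
    } else {
      sep <- round(stats::runif(1, 200, 400))
      f_chrom <- r$chrom_bp - sep / 2; r_chrom <- r$chrom_bp + sep / 2
      ef <- map_to_scaffold(truth$segments, r$chromosome, max(0, f_chrom), "+")
      er <- map_to_scaffold(truth$segments, r$chromosome, r_chrom, "-")
      tibble(query_id = paste0(r$marker_id, c("/F", "/R")),
             q_beg = 0, q_end = read_len,
             target_id = c(ef$scaffold_id, er$scaffold_id),
             t_beg = pmax(0, c(ef$pos, er$pos) - read_len / 2),
             t_end = pmax(0, c(ef$pos, er$pos) - read_len / 2) + read_len,
             strand = c(ef$strand, er$strand), score = 2 * read_len,
             identity_pct = 99.5, match_length = read_len)
    }
  })
  # decoys: repeat stacks and near-score ambiguity
  n_a <- nrow(aligned)
  n_rep <- round(config$repeat_marker_frac * n_a)
  n_amb <- round(config$ambiguous_marker_frac * n_a)
  decoy_pick <- sample(seq_len(n_a), n_rep + n_amb)
  rep_ids <- aligned$marker_id[decoy_pick[seq_len(n_rep)]]
  amb_ids <- aligned$marker_id[decoy_pick[seq(n_rep + 1, length.out = n_amb)]]
  other_scaffold <- function(k, avoid) {
    pool <- setdiff(truth$scaffolds$scaffold_id, avoid)
    sample(pool, k, replace = TRUE)
  }
  decoys <- list()
  for (mk in rep_ids) {
    # every read of a repeat-derived marker aligns all over the assembly
    for (q in aln$query_id[sub("/[FR]$", "", aln$query_id) == mk]) {
      tr <- aln[aln$query_id == q, ][1, ]
      tgt <- other_scaffold(6L, tr$target_id)
      decoys[[length(decoys) + 1L]] <- tibble(
        query_id = q, q_beg = tr$q_beg, q_end = tr$q_end, target_id = tgt,
        t_beg = floor(stats::runif(6, 0,
          pmax(1, truth$scaffolds$length[match(tgt, truth$scaffolds$scaffold_id)] - read_len))),
        strand = sample(c("+", "-"), 6, replace = TRUE),
        score = tr$score * stats::runif(6, 0.85, 1),
        identity_pct = 95, match_length = read_len) |>
        mutate(t_end = .data$t_beg + read_len)
    }
  }
  for (mk in amb_ids) {
    # a paralogous second locus: a near-score decoy placement for every
    # read, mutually consistent so it survives the pair stage
    qs <- aln$query_id[sub("/[FR]$", "", aln$query_id) == mk]
    tgt <- other_scaffold(1L, aln$target_id[aln$query_id == qs[1]][1])
    tlen <- truth$scaffolds$length[match(tgt, truth$scaffolds$scaffold_id)]
    tb <- floor(stats::runif(1, read_len, max(2 * read_len, tlen - 1000)))
    for (k in seq_along(qs)) {
      is_r <- grepl("/R$", qs[k])
      tr <- aln[aln$query_id == qs[k], ][1, ]
      decoys[[length(decoys) + 1L]] <- tibble(
        query_id = qs[k], q_beg = tr$q_beg, q_end = tr$q_end,
        target_id = tgt,
        t_beg = if (is_r) tb + 300 else tb,
        t_end = (if (is_r) tb + 300 else tb) + read_len,
        strand = if (is_r) "-" else "+",
        score = tr$score * 0.9, identity_pct = 97, match_length = read_len)
    }
  }
  alignments <- bind_rows(aln, bind_rows(decoys)) |>
    select("query_id", "q_beg", "q_end", "target_id", "t_beg", "t_end",
           "strand", "score", "identity_pct", "match_length")
  pos_rows$decoy_class <- ifelse(pos_rows$marker_id %in% rep_ids, "repeat",
                                 ifelse(pos_rows$marker_id %in% amb_ids,
                                        "ambiguous", "clean"))

  # --- backcross genotypes by meiosis along the true map
  set.seed(derive_seed(config$seed, "genotypes"))
  n_ind <- config$n_individuals
  geno <- matrix(NA_character_, nrow = m, ncol = n_ind,
                 dimnames = list(pos_rows$marker_id,
                                 sprintf("I%03d", seq_len(n_ind))))
  dist_loci <- config$distortion_loci
  for (ci in seq_len(nrow(genome$chromosomes))) {
    ch <- genome$chromosomes$chromosome[ci]
    Lc <- genome$chromosomes$map_length_cM[ci]
    rows <- which(pos_rows$chromosome == ch)
    mcm <- pos_rows$cM[rows]
    dl <- if (!is.null(dist_loci)) {
      dist_loci |> filter(as.character(.data$chromosome) == ch)
    } else tibble()
    dl_cM <- if (nrow(dl) > 0L) {
      genetic_position(genome, rep(ch, nrow(dl)), dl$position_Mb * 1e6)
    } else numeric()
    for (ind in seq_len(n_ind)) {
      repeat {
        n_xo <- stats::rpois(1, Lc / 100)
        xo <- sort(stats::runif(n_xo, 0, Lc))
        start <- sample(c("A", "H"), 1L)
        allele_at <- function(g) {
          par <- vapply(g, function(x) sum(xo <= x) %% 2L, integer(1))
          ifelse((start == "A") == (par == 0L), "A", "H")
        }
        if (nrow(dl) > 0L) {
          al <- allele_at(dl_cM)
          p_keep <- prod(ifelse(al == "H", 1, 1 / dl$ratio))
          if (stats::runif(1) > p_keep) next
        }
        geno[rows, ind] <- allele_at(mcm)
        break
      }
    }
  }
  miss <- matrix(stats::runif(length(geno)) < config$missing_rate,
                 nrow = nrow(geno))
  geno[miss] <- NA_character_

  list(metadata = metadata, map = map, alignments = alignments,
       genotypes = geno,
       positions = pos_rows |>
         select("marker_id", "chromosome", "chrom_bp", "scaffold_id",
                "scaffold_bp", "cM", "marker_class", "decoy_class"))
}

#' Simulate foreign-map proxy anchors with a distorted cM scale
#'
#' Emulates anchoring evidence from another genotype's or species' map:
#' each chromosome's foreign cM axis is an affine distortion of the true
#' one, a fraction of segments is dropped (markers of that map simply miss
#' them), and each covered segment receives a few proxy anchors. An
#' optional planted inversion reverses the foreign order inside an
#' interval.
#'
#' @param genome a `sim_genome`.
#' @param truth a `sim_truth`.
#' @param source_map `"RH"` or `"TOM"`.
#' @param anchors_per_segment anchors drawn per covered segment (default 3).
#' @param dropout fraction of segments not covered (default: config's
#'   `foreign_map_dropout`).
#' @param inversion optional tibble `chromosome, beg_cM, end_cM` (true-map
#'   scale) whose content is order-reversed on the foreign axis.
#' @param config the [sim_config()].
#' @return list with `anchors` (anchor tibble, `position_cM` on the foreign
#'   scale) and `scale` (tibble `chromosome, mult, offset` of the affine
#'   distortion, for constructing reference pairs in tests).
#' @export
simulate_foreign_anchors <- function(genome, truth, source_map = "RH",
                                     anchors_per_segment = 3L,
                                     dropout = NULL,
                                     inversion = NULL,
                                     config = genome$config) {
  set.seed(derive_seed(config$seed, "foreign") +
             sum(utf8ToInt(source_map)))
  dropout <- dropout %||% config$foreign_map_dropout
  segs <- truth$segments
  keep <- stats::runif(nrow(segs)) >= dropout
  segs <- segs[keep, , drop = FALSE]
  scale <- genome$chromosomes |>
    transmute(chromosome = .data$chromosome,
              mult = stats::runif(dplyr::n(), 0.8, 1.2),
              offset = stats::runif(dplyr::n(), 0, 5))
  anchors <- purrr::map_dfr(seq_len(nrow(segs)), function(i) {
    s <- segs[i, ]
    k <- anchors_per_segment
    cpos <- floor(stats::runif(k, s$chrom_beg, s$chrom_end))
    true_cM <- genetic_position(genome, rep(s$chromosome, k), cpos)
    sc <- map_to_scaffold(truth$segments, rep(s$chromosome, k), cpos)
    scl <- scale[scale$chromosome == s$chromosome, ]
    f_cM <- true_cM * scl$mult + scl$offset + stats::rnorm(k, 0, 0.2)
    tibble(marker_id = sprintf("%s_%s_%d", source_map, s$segment_id, seq_len(k)),
           scaffold_id = sc$scaffold_id, position_bp = sc$pos,
           linkage_group = s$chromosome, position_cM = f_cM,
           true_cM = true_cM, source_map = source_map,
           marker_class = ifelse(source_map == "RH", "clone_proxy",
                                 "synteny_proxy"))
  })
  if (!is.null(inversion)) {
    for (k in seq_len(nrow(inversion))) {
      scl <- scale[scale$chromosome == as.character(inversion$chromosome[k]), ]
      lo <- inversion$beg_cM[k] * scl$mult + scl$offset
      hi <- inversion$end_cM[k] * scl$mult + scl$offset
      inside <- anchors$linkage_group == as.character(inversion$chromosome[k]) &
        anchors$position_cM >= lo & anchors$position_cM <= hi
      anchors$position_cM[inside] <- lo + hi - anchors$position_cM[inside]
    }
  }
  list(anchors = anchors, scale = scale)
}

#' Run the whole generator under one configuration
#'
#' Convenience wrapper producing every synthetic input with shared truth.
#'
#' @param config a [sim_config()].
#' @return list: `genome`, `truth`, `pairs`, `libraries`, `markers` (the
#'   list from [simulate_markers_and_genotypes()]), `scaffold_lengths`
#'   (tibble `scaffold_id, length`).
#' @export
simulate_assembly <- function(config = sim_config()) {
  genome <- simulate_genome(config)
  truth <- fragment_into_scaffolds(genome, config)
  pairs <- simulate_matepairs(genome, truth, config = config)
  markers <- simulate_markers_and_genotypes(genome, truth, config)
  list(genome = genome, truth = truth, pairs = pairs,
       libraries = config$libraries, markers = markers,
       scaffold_lengths = truth$scaffolds |>
         select(scaffold_id = "scaffold_id", length = "length"))
}

#' Write a simulated data set to a directory of standard files
#'
#' Emits `scaffolds.tsv`, `pairs.tsv`, `libraries.yaml`, `markers.tsv`,
#' `alignments.tsv`, `genotypes.tsv`, `map.tsv` and `truth.json` (plus
#' `scaffolds.fa` with random nucleotide content when `fasta = TRUE`).
#'
#' @param sim result of [simulate_assembly()].
#' @param dir output directory (created if absent).
#' @param fasta also emit random sequences for each scaffold.
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir, fasta = FALSE) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  readr::write_tsv(sim$scaffold_lengths, p("scaffolds.tsv"), progress = FALSE)
  readr::write_tsv(sim$pairs, p("pairs.tsv"), progress = FALSE)
  write_library_specs(sim$libraries, p("libraries.yaml"))
  readr::write_tsv(sim$markers$metadata, p("markers.tsv"), progress = FALSE)
  write_alignment_table(sim$markers$alignments, p("alignments.tsv"))
  write_genotype_matrix(sim$markers$genotypes, p("genotypes.tsv"))
  readr::write_tsv(sim$markers$map, p("map.tsv"), progress = FALSE)
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    jsonlite::write_json(
      list(order = sim$truth$order, breakpoints = sim$truth$breakpoints,
           segments = sim$truth$segments, adjacencies = sim$truth$adjacencies),
      p("truth.json"), auto_unbox = TRUE, digits = NA)
  }
  if (fasta) {
    set.seed(derive_seed(sim$genome$config$seed, "fasta"))
    seqs <- vapply(sim$scaffold_lengths$length, function(l) {
      paste(sample(c("A", "C", "G", "T"), l, replace = TRUE), collapse = "")
    }, character(1))
    names(seqs) <- sim$scaffold_lengths$scaffold_id
    write_fasta(seqs, p("scaffolds.fa"))
  }
  invisible(dir)
}
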