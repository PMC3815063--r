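#' Write fixedStep wiggle tracks
#'
#' Emits one `fixedStep` declaration block per run of rows sharing a
#' `target_id`, with one value per line, for display of link-peak and noise
#' scores (or any per-window quantity) as genome-browser tracks.
#'
#' @param track a tibble with columns `target_id`, `start` (1-based position
#'   of the first window), `step`, `span` (bp) and `value`; rows within a
#'   target must be in window order.
#' @param path output path.
#' @param name optional track name, written as a `track` line.
#' @return `path`, invisibly.
#' @export
write_wiggle <- function(track, path, name = NULL) {
  check_cols(track, c("target_id", "start", "step", "span", "value"), "wiggle track")
  if (nrow(track) == 0L) lp_abort("wiggle track is empty")
  if (any(track$step < 1)) lp_abort("wiggle step must be >= 1")
  if (any(track$span > track$step)) lp_abort("wiggle span must be <= step")
  if (any(!is.finite(track$value))) {
    lp_abort("wiggle values must be finite (no NaN/Inf)")
  }
  run <- cumsum(c(TRUE, track$target_id[-1] != track$target_id[-nrow(track)]))
  blocks <- split(seq_len(nrow(track)), run)
  lines <- character()
  if (!is.null(name)) {
    lines <- sprintf("track type=wiggle_0 name=\"%s\"", name)
  }
  for (idx in blocks) {
    first <- track[idx[1], ]
    lines <- c(lines,
               sprintf("fixedStep chrom=%s start=%d step=%d span=%d",
                       first$target_id, as.integer(first$start),
                       as.integer(first$step), as.integer(first$span)),
               format(track$value[idx], trim = TRUE, scientific = FALSE))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a tabular alignment file into the internal convention
#'
#' Supports three dialects and normalizes them all to 0-based half-open
#' coordinates with an explicit strand: `blast6` (BLAST `-outfmt 6`, 1-based
#' inclusive, strand encoded by a descending subject interval), `psl` (BLAT
#' PSL, already 0-based half-open) and `internal` (this package's own TSV,
#' written by [write_alignment_table()]).
#'
#' @param path path to the alignment file (no header for `blast6`/`psl`;
#'   header for `internal`).
#' @param dialect one of `"blast6"`, `"psl"`, `"internal"`.
#' @return a tibble with columns `query_id, q_beg, q_end, target_id, t_beg,
#'   t_end, strand, score, identity_pct, match_length` (0-based half-open;
#'   `q_end > q_beg`, `t_end > t_beg`).
#' @export
read_alignment_table <- function(path, dialect = c("blast6", "psl", "internal")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) lp_abort(sprintf("alignment file not found: %s", path))
  empty <- tibble(query_id = character(), q_beg = numeric(), q_end = numeric(),
                  target_id = character(), t_beg = numeric(), t_end = numeric(),
                  strand = character(), score = numeric(),
                  identity_pct = numeric(), match_length = numeric())
  if (dialect == "internal") {
    raw <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
    if (nrow(raw) == 0L) return(empty)
    check_cols(raw, names(empty), "internal alignment table")
    return(as_tibble(raw)[names(empty)])
  }
  raw <- tryCatch(
    readr::read_tsv(path, col_names = FALSE, show_col_types = FALSE, progress = FALSE),
    error = function(e) lp_abort(sprintf("failed to parse %s: %s", path, conditionMessage(e)),
                                 class = "linkpeak_parse_error"))
  if (nrow(raw) == 0L) return(empty)
  if (dialect == "blast6") {
    if (ncol(raw) < 12L) {
      lp_abort("blast6 dialect requires 12 columns", class = "linkpeak_parse_error")
    }
    minus <- raw[[9]] > raw[[10]]
    tibble(
      query_id = as.character(raw[[1]]),
      q_beg = as.numeric(raw[[7]]) - 1, q_end = as.numeric(raw[[8]]),
      target_id = as.character(raw[[2]]),
      t_beg = ifelse(minus, as.numeric(raw[[10]]), as.numeric(raw[[9]])) - 1,
      t_end = ifelse(minus, as.numeric(raw[[9]]), as.numeric(raw[[10]])),
      strand = ifelse(minus, "-", "+"),
      score = as.numeric(raw[[12]]),
      identity_pct = as.numeric(raw[[3]]),
      match_length = as.numeric(raw[[4]])
    )
  } else { # psl
    if (ncol(raw) < 17L) {
      lp_abort("psl dialect requires >= 17 columns", class = "linkpeak_parse_error")
    }
    matches <- as.numeric(raw[[1]])
    mism <- as.numeric(raw[[2]]) + as.numeric(raw[[3]])
    tibble(
      query_id = as.character(raw[[10]]),
      q_beg = as.numeric(raw[[12]]), q_end = as.numeric(raw[[13]]),
      target_id = as.character(raw[[14]]),
      t_beg = as.numeric(raw[[16]]), t_end = as.numeric(raw[[17]]),
      strand = substr(as.character(raw[[9]]), 1, 1),
      score = matches,
      identity_pct = 100 * matches / pmax(matches + mism, 1),
      match_length = matches + mism
    )
  }
}

#' Write an alignment table in the internal dialect
#'
#' @param alignments tibble in the internal convention (see
#'   [read_alignment_table()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_alignment_table <- function(alignments, path) {
  readr::write_tsv(alignments, path, progress = FALSE)
  invisible(path)
}

#' Read / write FASTA
#'
#' Thin wrappers around Biostrings for the package's sequence ends.
#'
#' @param path file path.
#' @return `read_fasta()`: a [Biostrings::DNAStringSet].
#' @export
read_fasta <- function(path) Biostrings::readDNAStringSet(path)

#' @rdname read_fasta
#' @param seqs a [Biostrings::DNAStringSet] or named character vector.
#' @export
write_fasta <- function(seqs, path) {
  if (is.character(seqs)) seqs <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Read a genetic map table
#'
#' @param path TSV with columns `marker_id`, `linkage_group`, `position_cM`
#'   (header required).
#' @return tibble with those columns.
#' @export
read_map_table <- function(path) {
  m <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  check_cols(m, c("marker_id", "linkage_group", "position_cM"), "map table")
  mutate(as_tibble(m), linkage_group = as.character(.data$linkage_group))
}

#' Read a genotype matrix
#'
#' Loci as rows, individuals as columns, backcross coding `A`/`H` with `-`
#' for missing; first column holds locus ids.
#'
#' @param path TSV path.
#' @param missing_char character used for missing calls (default `-`).
#' @return a character matrix (loci x individuals) with `NA` for missing,
#'   locus ids as rownames.
#' @export
read_genotype_matrix <- function(path, missing_char = "-") {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (ncol(df) < 2L) lp_abort("genotype matrix needs an id column plus individuals")
  m <- as.matrix(df[, -1, drop = FALSE])
  mode(m) <- "character"
  m[m == missing_char] <- NA_character_
  rownames(m) <- as.character(df[[1]])
  m
}

#' @rdname read_genotype_matrix
#' @param geno character matrix with `NA` for missing.
#' @export
write_genotype_matrix <- function(geno, path, missing_char = "-") {
  out <- geno
  out[is.na(out)] <- missing_char
  df <- tibble(locus_id = rownames(out))
  df <- dplyr::bind_cols(df, as_tibble(out))
  readr::write_tsv(df, path, progress = FALSE)
  invisible(path)
}

#' Read / write mate-pair library specifications (YAML)
#'
#' Each library has an id, an origin (`DM`, `RH`, `TOM`), a kind
#' (`clone_end` or `long_insert_454`), an insert-size mean and sd (bp), and
#' the positive weight its pairs contribute to link scores.
#'
#' @param path YAML path.
#' @return a tibble with columns `lib_id, origin, kind, insert_mean,
#'   insert_sd, value_weight`.
#' @export
read_library_specs <- function(path) {
  y <- yaml::read_yaml(path)
  libs <- purrr::map_dfr(y, as_tibble)
  check_cols(libs, c("lib_id", "origin", "kind", "insert_mean", "insert_sd",
                     "value_weight"), "library spec")
  if (any(libs$value_weight <= 0)) lp_abort("value_weight must be > 0")
  libs
}

#' @rdname read_library_specs
#' @param libraries library tibble.
#' @export
write_library_specs <- function(libraries, path) {
  yaml::write_yaml(purrr::transpose(as.list(libraries)), path)
  invisible(path)
}

#' Write a minimal GFF3 track
#'
#' @param features tibble with columns `seqid, start, end` (1-based
#'   inclusive) and optionally `source, type, score, strand, attributes`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(features, path) {
  check_cols(features, c("seqid", "start", "end"), "GFF3 features")
  n <- nrow(features)
  get <- function(col, default) {
    if (col %in% names(features)) as.character(features[[col]]) else rep(default, n)
  }
  lines <- paste(features$seqid, get("source", "linkpeak"),
                 get("type", "region"),
                 format(features$start, scientific = FALSE, trim = TRUE),
                 format(features$end, scientific = FALSE, trim = TRUE),
                 get("score", "."), get("strand", "."), rep(".", n),
                 get("attributes", "."), sep = "\t")
  writeLines(c("##gff-version 3", lines), path)
  invisible(path)
}
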