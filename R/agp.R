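#' Read an AGP 2.0 file
#'
#' Parses a tab-delimited AGP (accessioned golden path) file describing how
#' sequence components and gaps tile one or more objects (pseudomolecules).
#' Lines starting with `#` are comments. Component (`W`) rows carry
#' `component_id`, `component_beg`, `component_end` and `orientation`; gap
#' (`U`/`N`) rows carry `gap_length`, `gap_type`, `linkage` and
#' `linkage_evidence`.
#'
#' Coordinates are kept in the AGP's native 1-based inclusive convention in
#' the returned tibble; the rest of the package converts at this boundary.
#'
#' @param path path to an AGP file.
#' @param validate validate tiling/span invariants with [validate_agp()]
#'   (default `TRUE`).
#' @return a tibble with columns `object_id, object_beg, object_end,
#'   part_number, component_type, component_id, component_beg,
#'   component_end, orientation, gap_length, gap_type, linkage,
#'   linkage_evidence`; `NA` where a field does not apply to the row type.
#' @seealso [write_agp()], [validate_agp()], [build_pm_sequence()]
#' @export
read_agp <- function(path, validate = TRUE) {
  if (!file.exists(path)) lp_abort(sprintf("AGP file not found: %s", path))
  lines <- readLines(path)
  keep <- !startsWith(lines, "#") & nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) return(empty_agp())

  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) != 9L)
  if (length(bad) > 0L) {
    lp_abort(sprintf("malformed AGP row at line %d: expected 9 tab-separated fields, got %d",
                     lineno[bad[1]], length(fields[[bad[1]]])),
             class = "linkpeak_parse_error")
  }
  m <- do.call(rbind, fields)
  type <- m[, 5]
  is_gap <- type %in% c("U", "N")

  num_or_na <- function(x, ok) ifelse(ok, suppressWarnings(as.numeric(x)), NA_real_)
  agp <- tibble(
    object_id        = m[, 1],
    object_beg       = as.numeric(m[, 2]),
    object_end       = as.numeric(m[, 3]),
    part_number      = as.integer(m[, 4]),
    component_type   = type,
    component_id     = ifelse(is_gap, NA_character_, m[, 6]),
    component_beg    = num_or_na(m[, 7], !is_gap),
    component_end    = num_or_na(m[, 8], !is_gap),
    orientation      = ifelse(is_gap, NA_character_, m[, 9]),
    gap_length       = num_or_na(m[, 6], is_gap),
    gap_type         = ifelse(is_gap, m[, 7], NA_character_),
    linkage          = ifelse(is_gap, m[, 8], NA_character_),
    linkage_evidence = ifelse(is_gap, m[, 9], NA_character_)
  )
  nn <- is.na(agp$object_beg) | is.na(agp$object_end) |
    (!is_gap & (is.na(agp$component_beg) | is.na(agp$component_end))) |
    (is_gap & is.na(agp$gap_length))
  if (any(nn)) {
    lp_abort(sprintf("malformed AGP row at line %d: non-numeric coordinate",
                     lineno[which(nn)[1]]),
             class = "linkpeak_parse_error")
  }
  if (validate) validate_agp(agp)
  agp
}

empty_agp <- function() {
  tibble(
    object_id = character(), object_beg = numeric(), object_end = numeric(),
    part_number = integer(), component_type = character(),
    component_id = character(), component_beg = numeric(),
    component_end = numeric(), orientation = character(),
    gap_length = numeric(), gap_type = character(), linkage = character(),
    linkage_evidence = character()
  )
}

#' Validate an AGP tibble
#'
#' Checks, per object: rows tile `1..L` contiguously with no overlap or
#' uncovered base, part numbers strictly increase, and every component row's
#' span on the object equals its span on the component.
#'
#' @param agp a tibble as returned by [read_agp()] or [finalize_agp()].
#' @return the input, invisibly; aborts with a validation error otherwise.
#' @export
validate_agp <- function(agp) {
  check_cols(agp, c("object_id", "object_beg", "object_end", "part_number",
                    "component_type"), "AGP")
  if (nrow(agp) == 0L) return(invisible(agp))
  if (any(agp$object_end < agp$object_beg)) {
    lp_abort("AGP validation: object_end < object_beg",
             class = "linkpeak_validation_error")
  }
  w <- agp$component_type == "W"
  span_obj <- agp$object_end - agp$object_beg
  span_cmp <- agp$component_end - agp$component_beg
  bad <- which(w & span_obj != span_cmp)
  if (length(bad) > 0L) {
    lp_abort(sprintf(
      "AGP validation: component span differs from object span for %s part %d",
      agp$object_id[bad[1]], agp$part_number[bad[1]]),
      class = "linkpeak_validation_error")
  }
  bad_gap <- which(!w & (agp$object_end - agp$object_beg + 1) != agp$gap_length)
  if (length(bad_gap) > 0L) {
    lp_abort(sprintf(
      "AGP validation: gap span differs from gap_length for %s part %d",
      agp$object_id[bad_gap[1]], agp$part_number[bad_gap[1]]),
      class = "linkpeak_validation_error")
  }
  for (obj in unique(agp$object_id)) {
    rows <- agp[agp$object_id == obj, ]
    rows <- rows[order(rows$part_number), ]
    if (any(diff(rows$part_number) <= 0)) {
      lp_abort(sprintf("AGP validation: part_number not strictly increasing in %s", obj),
               class = "linkpeak_validation_error")
    }
    if (rows$object_beg[1] != 1) {
      lp_abort(sprintf("AGP validation: %s does not start at base 1", obj),
               class = "linkpeak_validation_error")
    }
    if (nrow(rows) > 1L &&
        any(rows$object_beg[-1] != rows$object_end[-nrow(rows)] + 1)) {
      lp_abort(sprintf("AGP validation: coordinate discontinuity in %s", obj),
               class = "linkpeak_validation_error")
    }
  }
  invisible(agp)
}

#' Write an AGP 2.0 file
#'
#' Inverse of [read_agp()]: a read/write/read cycle is a fixpoint for any
#' valid file (comments excepted).
#'
#' @param agp AGP tibble.
#' @param path output path.
#' @param comment optional character vector of header comment lines (written
#'   with a leading `#`).
#' @return `path`, invisibly.
#' @export
write_agp <- function(agp, path, comment = NULL) {
  validate_agp(agp)
  fmt_n <- function(x) format(x, scientific = FALSE, trim = TRUE)
  is_gap <- agp$component_type %in% c("U", "N")
  f6 <- ifelse(is_gap, fmt_n(agp$gap_length), agp$component_id)
  f7 <- ifelse(is_gap, agp$gap_type, fmt_n(agp$component_beg))
  f8 <- ifelse(is_gap, agp$linkage, fmt_n(agp$component_end))
  f9 <- ifelse(is_gap, agp$linkage_evidence, agp$orientation)
  lines <- paste(agp$object_id, fmt_n(agp$object_beg), fmt_n(agp$object_end),
                 fmt_n(agp$part_number), agp$component_type,
                 f6, f7, f8, f9, sep = "\t")
  if (!is.null(comment)) lines <- c(paste0("#", comment), lines)
  writeLines(lines, path)
  invisible(path)
}

#' Assemble pseudomolecule sequences from an AGP layout
#'
#' Renders each AGP object as a nucleotide sequence: `W` rows contribute the
#' referenced scaffold slice (reverse-complemented for `-` orientation), gap
#' rows contribute runs of `N`. Scaffolds with unknown orientation (`?`) are
#' written in `+` orientation and reported in the `unknown_orientation`
#' attribute of the result.
#'
#' @param agp AGP tibble (validated).
#' @param scaffolds scaffold sequences: a [Biostrings::DNAStringSet], a named
#'   character vector, or a tibble with columns `id` and `sequence`.
#' @return a [Biostrings::DNAStringSet], one entry per AGP object, with an
#'   attribute `unknown_orientation` listing component ids rendered as `+`
#'   despite a `?` orientation.
#' @export
build_pm_sequence <- function(agp, scaffolds) {
  validate_agp(agp)
  if (is.data.frame(scaffolds)) {
    check_cols(scaffolds, c("id", "sequence"), "scaffolds")
    seqs <- Biostrings::DNAStringSet(stats::setNames(scaffolds$sequence, scaffolds$id))
  } else if (is.character(scaffolds)) {
    seqs <- Biostrings::DNAStringSet(scaffolds)
  } else {
    seqs <- scaffolds
  }
  w <- agp[agp$component_type == "W", ]
  missing <- setdiff(w$component_id, names(seqs))
  if (length(missing) > 0L) {
    lp_abort(sprintf("components missing from scaffold set: %s",
                     paste(missing, collapse = ", ")))
  }
  too_short <- w$component_end > Biostrings::width(seqs)[match(w$component_id, names(seqs))]
  if (any(too_short)) {
    lp_abort(sprintf("component_end beyond scaffold length for: %s",
                     paste(unique(w$component_id[too_short]), collapse = ", ")))
  }
  unknown <- character()
  objects <- unique(agp$object_id)
  out <- vector("list", length(objects))
  names(out) <- objects
  for (obj in objects) {
    rows <- agp[agp$object_id == obj, ]
    rows <- rows[order(rows$part_number), ]
    parts <- purrr::pmap(rows, function(component_type, component_id,
                                        component_beg, component_end,
                                        orientation, gap_length, ...) {
      if (component_type %in% c("U", "N")) {
        Biostrings::DNAString(strrep("N", gap_length))
      } else {
        s <- Biostrings::subseq(seqs[[component_id]], component_beg, component_end)
        if (identical(orientation, "-")) {
          s <- Biostrings::reverseComplement(s)
        } else if (identical(orientation, "?")) {
          unknown <<- c(unknown, component_id)
        }
        s
      }
    })
    out[[obj]] <- do.call(Biostrings::xscat, parts)
  }
  res <- Biostrings::DNAStringSet(out)
  expected <- vapply(objects, function(obj) max(agp$object_end[agp$object_id == obj]),
                     numeric(1))
  stopifnot(all(Biostrings::width(res) == expected))
  if (length(unknown) > 0L) {
    inform(sprintf("%d component(s) with '?' orientation rendered as '+': %s",
                   length(unknown), paste(unknown, collapse = ", ")))
  }
  attr(res, "unknown_orientation") <- unique(unknown)
  res
}
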