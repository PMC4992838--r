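#' Read a FASTA file into a sequence table
#'
#' Parses with [Biostrings::readDNAStringSet()] and enforces the contracts the
#' pipeline relies on: ids (first whitespace-delimited header token) unique,
#' sequences non-empty, alphabet restricted to IUPAC DNA codes. Sequences are
#' stored uppercase.
#'
#' @param path path to a FASTA file.
#' @return a tibble with columns `id` and `seq`, in file order.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stopf("no such file: '%s'", path)
  lines <- readLines(path)
  is_seq <- !startsWith(lines, ">")
  bad <- which(is_seq & grepl("[^ACGTMRWSYKVHDBNacgtmrwsykvhdbn]", lines))
  if (length(bad)) {
    ch <- sub(".*?([^ACGTMRWSYKVHDBNacgtmrwsykvhdbn]).*", "\\1", lines[bad[1]])
    stopf("non-IUPAC character '%s' in '%s' at line %d", ch, path, bad[1])
  }
  set <- Biostrings::readDNAStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids)) {
    stopf("duplicate sequence id '%s' in '%s'", ids[duplicated(ids)][1], path)
  }
  if (any(Biostrings::width(set) == 0)) {
    stopf("empty sequence for id '%s' in '%s'",
          ids[Biostrings::width(set) == 0][1], path)
  }
  tibble::tibble(id = ids, seq = toupper(as.character(set, use.names = FALSE)))
}

#' Write a sequence table to FASTA
#'
#' @param seqs tibble with columns `id` and `seq`.
#' @param path output path.
#' @param line_width sequence characters per line.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, line_width = 60) {
  if (line_width < 1) stopf("line_width must be >= 1")
  if (nrow(seqs) == 0) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  validate_seqs(seqs)
  chunks <- purrr::map2(toupper(seqs$seq), seqs$id, function(s, id) {
    starts <- seq(1, nchar(s), by = line_width)
    c(paste0(">", id), substring(s, starts, pmin(starts + line_width - 1, nchar(s))))
  })
  writeLines(unlist(chunks), path)
  invisible(path)
}

read_checked_tsv <- function(path, cols, what) {
  if (!file.exists(path)) stopf("no such file: '%s'", path)
  x <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                       progress = FALSE)
  missing <- setdiff(names(cols), names(x))
  if (length(missing)) {
    stopf("%s '%s' is missing column(s): %s", what, path,
          paste(missing, collapse = ", "))
  }
  for (nm in names(cols)) {
    if (cols[[nm]] == "numeric") {
      v <- suppressWarnings(as.numeric(x[[nm]]))
      if (anyNA(v)) {
        stopf("%s '%s': non-numeric '%s' in column '%s' at data row %d", what,
              path, x[[nm]][which(is.na(v))[1]], nm, which(is.na(v))[1])
      }
      x[[nm]] <- v
    }
  }
  x[names(cols)]
}

#' Read a marker map TSV (marker_id, lg, cm)
#'
#' @param path path to a tab-separated file with a header line.
#' @return a tibble with columns `marker_id`, `lg`, `cm`.
#' @export
read_marker_map <- function(path) {
  x <- read_checked_tsv(path, c(marker_id = "character", lg = "character",
                                cm = "numeric"), "marker map")
  if (anyDuplicated(x$marker_id)) {
    stopf("marker map '%s': duplicate marker_id '%s'", path,
          x$marker_id[duplicated(x$marker_id)][1])
  }
  if (any(!is.finite(x$cm) | x$cm < 0)) {
    stopf("marker map '%s': negative or non-finite cM at data row %d", path,
          which(!is.finite(x$cm) | x$cm < 0)[1])
  }
  x
}

#' Read marker-to-scaffold placements (marker_id, scaffold_id, pos_bp; 1-based)
#'
#' @param path path to a tab-separated file with a header line.
#' @return a tibble with columns `marker_id`, `scaffold_id`, `pos_bp`.
#' @export
read_placements <- function(path) {
  x <- read_checked_tsv(path, c(marker_id = "character",
                                scaffold_id = "character",
                                pos_bp = "numeric"), "placement table")
  if (any(x$pos_bp < 1 | x$pos_bp != floor(x$pos_bp))) {
    stopf("placement table '%s': pos_bp must be a positive integer (data row %d)",
          path, which(x$pos_bp < 1 | x$pos_bp != floor(x$pos_bp))[1])
  }
  x$pos_bp <- as.integer(x$pos_bp)
  x
}

#' Cross-check placements against sequences and a marker map
#'
#' @param placements tibble from [read_placements()].
#' @param seqs optional sequence table; positions must not exceed lengths.
#' @param marker_map optional marker map; all placed markers must be mapped.
#' @return the placements, invisibly.
#' @export
validate_placements <- function(placements, seqs = NULL, marker_map = NULL) {
  if (!is.null(seqs)) {
    len <- seq_lengths(seqs)
    unknown <- setdiff(placements$scaffold_id, names(len))
    if (length(unknown)) stopf("placement names unknown scaffold '%s'", unknown[1])
    over <- placements$pos_bp > len[placements$scaffold_id]
    if (any(over)) {
      stopf("placement position %d exceeds length of scaffold '%s'",
            placements$pos_bp[which(over)[1]],
            placements$scaffold_id[which(over)[1]])
    }
  }
  if (!is.null(marker_map)) {
    unknown <- setdiff(placements$marker_id, marker_map$marker_id)
    if (length(unknown)) stopf("placement references unknown marker '%s'", unknown[1])
  }
  invisible(placements)
}

#' Read a k-mer depth histogram (depth, count)
#'
#' @param path path to a tab-separated file with a header line.
#' @return a tibble with integer columns `depth` and `count`.
#' @export
read_kmer_histogram <- function(path) {
  x <- read_checked_tsv(path, c(depth = "numeric", count = "numeric"),
                        "k-mer histogram")
  if (any(x$depth < 1)) stopf("k-mer histogram '%s': depth must be >= 1", path)
  if (any(x$count < 0)) stopf("k-mer histogram '%s': negative count", path)
  if (any(diff(x$depth) <= 0)) {
    stopf("k-mer histogram '%s': depths must be strictly increasing", path)
  }
  x$depth <- as.integer(x$depth)
  x
}

hit_cols <- c("query_id", "subject_id", "percent_identity", "alignment_length",
              "mismatches", "gap_opens", "q_start", "q_end", "s_start", "s_end",
              "e_value", "bit_score")

#' Read a 12-column tabular hit table (BLAST outfmt-6 dialect, no header)
#'
#' Extra trailing columns are dropped with a warning; fewer than 12 columns is
#' an error.
#'
#' @param path path to a tab-separated hit table.
#' @return a tibble with the 12 standard columns.
#' @export
read_hit_table <- function(path) {
  if (!file.exists(path)) stopf("no such file: '%s'", path)
  x <- readr::read_tsv(path, col_names = FALSE, progress = FALSE,
                       col_types = readr::cols(.default = readr::col_character()))
  if (nrow(x) == 0) {
    return(tibble::as_tibble(stats::setNames(
      c(rep(list(character(0)), 2), rep(list(numeric(0)), 10)), hit_cols)))
  }
  if (ncol(x) < 12) stopf("hit table '%s' has %d columns; 12 required", path, ncol(x))
  if (ncol(x) > 12) {
    warnf("hit table '%s': ignoring %d extra column(s)", path, ncol(x) - 12)
    x <- x[, 1:12]
  }
  names(x) <- hit_cols
  for (nm in hit_cols[-(1:2)]) {
    v <- suppressWarnings(as.numeric(x[[nm]]))
    if (anyNA(v)) stopf("hit table '%s': non-numeric value in column %s", path, nm)
    x[[nm]] <- v
  }
  if (any(x$e_value < 0)) stopf("hit table '%s': negative e-value", path)
  if (any(!is.finite(x$bit_score))) stopf("hit table '%s': non-finite bit score", path)
  x
}

#' Read a single rooted Newick tree
#'
#' @param path path to a Newick file containing one tree.
#' @return an [ape] `phylo` object with branch lengths.
#' @export
read_newick <- function(path) {
  if (!file.exists(path)) stopf("no such file: '%s'", path)
  tr <- tryCatch(ape::read.tree(path),
                 error = function(e) stopf("unparseable Newick in '%s': %s",
                                           path, conditionMessage(e)))
  if (is.null(tr)) stopf("unparseable Newick in '%s'", path)
  if (inherits(tr, "multiPhylo")) stopf("'%s' contains %d trees; expected one",
                                        path, length(tr))
  if (is.null(tr$edge.length)) stopf("tree in '%s' lacks branch lengths", path)
  tr
}

# ---- AGP ----

validate_agp <- function(agp) {
  need <- c("object_id", "object_beg", "object_end", "part_number",
            "component_type")
  if (!all(need %in% names(agp))) stopf("not an AGP table")
  for (obj in unique(agp$object_id)) {
    rows <- agp[agp$object_id == obj, ]
    if (rows$object_beg[1] != 1) stopf("AGP object '%s' does not start at 1", obj)
    if (nrow(rows) > 1 && any(rows$object_beg[-1] != rows$object_end[-nrow(rows)] + 1)) {
      stopf("AGP object '%s': discontinuous object coordinates", obj)
    }
    if (any(rows$part_number != seq_len(nrow(rows)))) {
      stopf("AGP object '%s': part numbers not consecutive", obj)
    }
    span <- rows$object_end - rows$object_beg + 1
    expect <- ifelse(rows$component_type == "N", rows$gap_length,
                     rows$component_end - rows$component_beg + 1)
    if (any(span != expect)) stopf("AGP object '%s': row span mismatch", obj)
  }
  invisible(agp)
}

#' Write pseudomolecules (or an AGP row table) as AGP v2.1
#'
#' Gap rows are written as `component_type` N with `gap_type` "map" and
#' `linkage` "no", matching map-derived joins. Coordinates are 1-based
#' inclusive.
#'
#' @param x a pseudomolecule, a list of pseudomolecules, or an AGP tibble as
#'   produced by [build_pseudomolecule()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_agp <- function(x, path) {
  agp <- as_agp_table(x)
  validate_agp(agp)
  body <- vapply(seq_len(nrow(agp)), function(i) {
    r <- agp[i, ]
    if (r$component_type == "N") {
      paste(r$object_id, r$object_beg, r$object_end, r$part_number, "N",
            r$gap_length, r$gap_type, r$linkage, "na", sep = "\t")
    } else {
      paste(r$object_id, r$object_beg, r$object_end, r$part_number, "W",
            r$component_id, r$component_beg, r$component_end, r$orientation,
            sep = "\t")
    }
  }, character(1))
  writeLines(c("##agp-version\t2.1", body), path)
  invisible(path)
}

as_agp_table <- function(x) {
  if (inherits(x, "pseudomolecule")) return(x$agp)
  if (is.data.frame(x)) return(x)
  if (is.list(x)) return(dplyr::bind_rows(purrr::map(x, as_agp_table)))
  stopf("cannot interpret object of class '%s' as AGP", class(x)[1])
}

#' Read an AGP v2.1 file
#'
#' @param path path to an AGP file; comment lines (`#`) are skipped.
#' @return an AGP tibble (one row per component or gap).
#' @export
read_agp <- function(path) {
  if (!file.exists(path)) stopf("no such file: '%s'", path)
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) != 9)) {
    stopf("AGP '%s': line %d does not have 9 columns", path,
          which(lengths(parts) != 9)[1])
  }
  m <- do.call(rbind, parts)
  is_gap <- m[, 5] == "N" | m[, 5] == "U"
  int_col <- function(x, sel) {
    out <- rep(NA_integer_, length(x))
    out[sel] <- as.integer(x[sel])
    out
  }
  agp <- tibble::tibble(
    object_id = m[, 1],
    object_beg = as.integer(m[, 2]),
    object_end = as.integer(m[, 3]),
    part_number = as.integer(m[, 4]),
    component_type = m[, 5],
    component_id = ifelse(is_gap, NA_character_, m[, 6]),
    component_beg = int_col(m[, 7], !is_gap),
    component_end = int_col(m[, 8], !is_gap),
    orientation = ifelse(is_gap, NA_character_, m[, 9]),
    gap_length = int_col(m[, 6], is_gap),
    gap_type = ifelse(is_gap, m[, 7], NA_character_),
    linkage = ifelse(is_gap, m[, 8], NA_character_)
  )
  validate_agp(agp)
  agp
}
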