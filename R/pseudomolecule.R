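#' Build one pseudomolecule from ordered, oriented scaffolds
#'
#' Components are concatenated in anchor order, a `-` component contributing
#' its reverse complement, with a fixed run of `gap_length` N characters
#' between adjacent components. AGP rows (1-based inclusive coordinates) are
#' generated in lockstep with the sequence.
#'
#' @param name pseudomolecule name (e.g. `"chr1"`).
#' @param ordered_anchors anchor rows for one linkage group, already ordered
#'   (see [order_scaffolds()]); needs columns `scaffold_id` and `orientation`.
#' @param seqs sequence table holding every component.
#' @param gap_length N bases inserted between adjacent components.
#' @return an object of class `pseudomolecule`: a list with `name`,
#'   `components` (tibble: `scaffold_id`, `orientation`, `length_bp`),
#'   `sequence`, and `agp` (AGP tibble).
#' @export
build_pseudomolecule <- function(name, ordered_anchors, seqs, gap_length = 10000) {
  if (gap_length < 0) stopf("gap_length must be >= 0")
  validate_seqs(seqs)
  ids <- ordered_anchors$scaffold_id
  if (length(ids) == 0) stopf("cannot build '%s' from zero scaffolds", name)
  missing <- setdiff(ids, seqs$id)
  if (length(missing)) stopf("missing sequence for scaffold '%s'", missing[1])
  ori <- ordered_anchors$orientation
  if (!all(ori %in% c("+", "-"))) stopf("orientation must be '+' or '-'")

  s <- seqs$seq[match(ids, seqs$id)]
  lens <- nchar(s)
  oriented <- ifelse(ori == "-", revcomp(s), s)
  gap_run <- strrep("N", gap_length)
  sequence <- paste(oriented, collapse = gap_run)

  n <- length(ids)
  spans <- integer(2 * n - 1)
  spans[seq(1, 2 * n - 1, by = 2)] <- lens
  if (n > 1) spans[seq(2, 2 * n - 2, by = 2)] <- gap_length
  ends <- cumsum(spans)
  begs <- ends - spans + 1L
  is_w <- seq_along(spans) %% 2 == 1
  comp_idx <- cumsum(is_w)
  agp <- tibble::tibble(
    object_id = name,
    object_beg = as.integer(begs),
    object_end = as.integer(ends),
    part_number = seq_along(spans),
    component_type = ifelse(is_w, "W", "N"),
    component_id = ifelse(is_w, ids[comp_idx], NA_character_),
    component_beg = ifelse(is_w, 1L, NA_integer_),
    component_end = ifelse(is_w, lens[comp_idx], NA_integer_),
    orientation = ifelse(is_w, ori[comp_idx], NA_character_),
    gap_length = ifelse(is_w, NA_integer_, as.integer(gap_length)),
    gap_type = ifelse(is_w, NA_character_, "map"),
    linkage = ifelse(is_w, NA_character_, "no")
  )
  structure(list(name = name,
                 components = tibble::tibble(scaffold_id = ids,
                                             orientation = ori,
                                             length_bp = lens),
                 sequence = sequence,
                 agp = agp),
            class = "pseudomolecule")
}

#' @export
print.pseudomolecule <- function(x, ...) {
  cat(sprintf("<pseudomolecule %s: %d components, %s bp (%s bp gaps)>\n",
              x$name, nrow(x$components),
              format(nchar(x$sequence), big.mark = ","),
              format(nchar(x$sequence) - sum(x$components$length_bp),
                     big.mark = ",")))
  invisible(x)
}

#' Build pseudomolecules for every linkage group
#'
#' Linkage groups become `chr1..chrK` in map order; scaffolds without anchors
#' form the unplaced (`chr0`) pool and are reported but not concatenated.
#'
#' @param ordered_anchors output of [order_scaffolds()] over all groups.
#' @param seqs sequence table for all scaffolds.
#' @param gap_length N bases between adjacent components.
#' @return a list with `molecules` (named list of `pseudomolecule`), `table`
#'   (per-molecule tibble: `name`, `lg`, `length_bp`, `n_components`,
#'   `n_gap_bases`) and `unplaced` (character vector of scaffold ids).
#' @export
build_pseudomolecules <- function(ordered_anchors, seqs, gap_length = 10000) {
  lgs <- unique(ordered_anchors$lg)
  molecules <- purrr::imap(stats::setNames(lgs, paste0("chr", seq_along(lgs))),
    function(lg, nm) {
      build_pseudomolecule(nm, ordered_anchors[ordered_anchors$lg == lg, ],
                           seqs, gap_length)
    })
  tab <- purrr::imap_dfr(molecules, function(p, nm) {
    tibble::tibble(name = nm,
                   lg = ordered_anchors$lg[match(p$components$scaffold_id[1],
                                                 ordered_anchors$scaffold_id)],
                   length_bp = nchar(p$sequence),
                   n_components = nrow(p$components),
                   n_gap_bases = nchar(p$sequence) - sum(p$components$length_bp))
  })
  list(molecules = molecules, table = tab,
       unplaced = setdiff(seqs$id, ordered_anchors$scaffold_id))
}

#' Rebuild an object sequence from AGP rows and component sequences
#'
#' The inverse of [build_pseudomolecule()]'s AGP emission; used to verify that
#' FASTA and AGP outputs stay mutually consistent.
#'
#' @param agp AGP tibble (one object).
#' @param seqs sequence table with every component.
#' @return a tibble with columns `id` (object id) and `seq`, one row per
#'   object in the AGP.
#' @export
reconstruct_from_agp <- function(agp, seqs) {
  validate_agp(agp)
  validate_seqs(seqs)
  len <- seq_lengths(seqs)
  purrr::map_dfr(unique(agp$object_id), function(obj) {
    rows <- agp[agp$object_id == obj, ]
    parts <- vapply(seq_len(nrow(rows)), function(i) {
      r <- rows[i, ]
      if (r$component_type == "N") return(strrep("N", r$gap_length))
      if (!r$component_id %in% names(len)) {
        stopf("AGP component '%s' has no sequence", r$component_id)
      }
      if (r$component_end > len[r$component_id]) {
        stopf("AGP span %d-%d exceeds length of '%s'", r$component_beg,
              r$component_end, r$component_id)
      }
      frag <- substr(seqs$seq[seqs$id == r$component_id],
                     r$component_beg, r$component_end)
      if (identical(r$orientation, "-")) revcomp(frag) else frag
    }, character(1))
    tibble::tibble(id = obj, seq = paste(parts, collapse = ""))
  })
}

#' Anchored fraction of an assembly
#'
#' @param anchored_bp bases in anchored scaffolds.
#' @param assembly_bp total assembly bases.
#' @return percentage, rounded half-up to one decimal.
#' @export
#' @examples
#' anchored_fraction(384208136, 471834188) # 81.4
anchored_fraction <- function(anchored_bp, assembly_bp) {
  assert_scalar_number(anchored_bp, "anchored_bp")
  assert_scalar_number(assembly_bp, "assembly_bp")
  if (assembly_bp <= 0) stopf("assembly_bp must be positive")
  if (anchored_bp < 0 || anchored_bp > assembly_bp) {
    stopf("anchored_bp must lie in [0, assembly_bp]")
  }
  round_half_up(100 * anchored_bp / assembly_bp, 1)
}
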