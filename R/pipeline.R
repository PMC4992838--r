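#' Run the full anchoring pipeline
#'
#' Stages, in order: bin the map, anchor scaffolds through their markers,
#' detect chimeric scaffolds, split them and remap placements, re-anchor,
#' orient and order within each linkage group, concatenate into
#' pseudomolecules with fixed N gaps, and summarise. Every number in the
#' resulting report is recomputable from the returned tables.
#'
#' @param scaffolds sequence table (`id`, `seq`).
#' @param marker_map marker map tibble (`marker_id`, `lg`, `cm`).
#' @param placements placement tibble (`marker_id`, `scaffold_id`, `pos_bp`).
#' @param cm_precision decimals for map binning.
#' @param min_markers minimum mapped markers to anchor a scaffold.
#' @param max_intra_lg_gap_cm within-group cM jump that triggers a split.
#' @param gap_length N bases between adjacent pseudomolecule components.
#' @return an object of class `anchor_run`: list with `bins`,
#'   `anchors_before`, `chimeras`, `scaffolds` (post-split), `placements`
#'   (post-split), `anchors`, `ordered`, `pseudomolecules` (see
#'   [build_pseudomolecules()]), `stats` (assembly summaries of the input
#'   scaffolds and of the pseudomolecules), `tallies`, and `params`.
#' @export
run_pipeline <- function(scaffolds, marker_map, placements, cm_precision = 2,
                         min_markers = 1, max_intra_lg_gap_cm = 20,
                         gap_length = 10000) {
  validate_seqs(scaffolds)
  validate_marker_map(marker_map)
  validate_placements(placements, seqs = scaffolds, marker_map = marker_map)

  bins <- build_bins(marker_map, cm_precision)
  anchors_before <- assign_scaffolds(placements, bins, marker_map, min_markers)
  chimeras <- detect_chimeras(anchors_before, max_intra_lg_gap_cm)
  split <- split_scaffolds(scaffolds, chimeras, placements)
  anchors <- assign_scaffolds(split$placements, bins, marker_map, min_markers)
  ordered <- order_scaffolds(anchors, split$seqs)
  pseudo <- build_pseudomolecules(ordered, split$seqs, gap_length)

  assembly_bp <- sum(nchar(scaffolds$seq))
  anchored_bp <- sum(ordered$length_bp)
  n_pieces <- if (nrow(chimeras)) sum(chimeras$n_pieces) else 0L
  tallies <- list(
    n_scaffolds = nrow(scaffolds),
    assembly_bp = assembly_bp,
    n_anchored_before = nrow(anchors_before),
    n_split = nrow(chimeras),
    n_pieces = n_pieces,
    n_anchored_after = anchoring_accounting(nrow(anchors_before),
                                            nrow(chimeras), n_pieces),
    anchored_bp = anchored_bp,
    anchored_percent = anchored_fraction(anchored_bp, assembly_bp)
  )
  pseudo_seqs <- tibble::tibble(
    id = names(pseudo$molecules),
    seq = unname(vapply(pseudo$molecules, function(p) p$sequence, character(1))))
  structure(list(
    bins = bins, anchors_before = anchors_before, chimeras = chimeras,
    scaffolds = split$seqs, placements = split$placements, anchors = anchors,
    ordered = ordered, pseudomolecules = pseudo,
    pseudo_seqs = pseudo_seqs,
    stats = list(scaffolds = assembly_summary(scaffolds),
                 pseudomolecules = assembly_summary(pseudo_seqs)),
    tallies = tallies,
    params = list(cm_precision = cm_precision, min_markers = min_markers,
                  max_intra_lg_gap_cm = max_intra_lg_gap_cm,
                  gap_length = gap_length)
  ), class = "anchor_run")
}

#' @export
print.anchor_run <- function(x, ...) {
  t <- x$tallies
  cat(sprintf(paste0(
    "<anchor_run: %d scaffolds, %s bp>\n",
    "  anchored before splitting: %d\n",
    "  chimeras split: %d (-> %d pieces); anchored after: %d\n",
    "  anchored bases: %s bp (%.1f%% of assembly)\n",
    "  pseudomolecules: %d\n"),
    t$n_scaffolds, format(t$assembly_bp, big.mark = ","),
    t$n_anchored_before, t$n_split, t$n_pieces, t$n_anchored_after,
    format(t$anchored_bp, big.mark = ","), t$anchored_percent,
    nrow(x$pseudomolecules$table)))
  invisible(x)
}

#' @export
tidy.anchor_run <- function(x, ...) x$pseudomolecules$table

#' @export
glance.anchor_run <- function(x, ...) tibble::as_tibble(x$tallies)

#' Write the outputs of an anchoring run to disk
#'
#' Emits the pseudomolecule FASTA and AGP, the anchor and chimera tables, and
#' a JSON run report whose percentages and accounting are recomputed from its
#' own integer fields at write time.
#'
#' @param run an `anchor_run` from [run_pipeline()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_run <- function(run, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_fasta(run$pseudo_seqs, file.path(dir, "pseudomolecules.fa"))
  write_agp(run$pseudomolecules$molecules, file.path(dir, "pseudomolecules.agp"))
  readr::write_tsv(dplyr::select(run$ordered, -"markers"),
                   file.path(dir, "anchors.tsv"))
  readr::write_tsv(
    dplyr::mutate(run$chimeras,
                  breakpoints_bp = purrr::map_chr(.data$breakpoints_bp,
                                                  paste, collapse = ","),
                  piece_ids = purrr::map_chr(.data$piece_ids,
                                             paste, collapse = ",")),
    file.path(dir, "chimeras.tsv"))
  t <- run$tallies
  stopifnot(t$n_anchored_after ==
              anchoring_accounting(t$n_anchored_before, t$n_split, t$n_pieces),
            t$anchored_percent ==
              anchored_fraction(t$anchored_bp, t$assembly_bp))
  report <- list(parameters = run$params, tallies = t,
                 pseudomolecules = run$pseudomolecules$table,
                 n_unplaced = length(run$pseudomolecules$unplaced))
  jsonlite::write_json(report, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
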