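#' Infer scaffold orientation from marker positions
#'
#' The sign of the Kendall rank correlation between physical position on the
#' scaffold and genetic position on the map gives the strand: increasing cM
#' along the scaffold is `+`, decreasing is `-`. With fewer than two distinct
#' physical or genetic positions, or an exactly zero correlation, the
#' orientation is undetermined (`?`); downstream the scaffold is then placed
#' on its original strand and flagged.
#'
#' @param pos_bp physical marker positions on the scaffold (1-based bp).
#' @param cm genetic positions (cM) of the same markers.
#' @return one of `"+"`, `"-"`, `"?"`.
#' @export
orient_scaffold <- function(pos_bp, cm) {
  if (length(pos_bp) == 0) stopf("cannot orient a scaffold with no markers")
  if (length(pos_bp) != length(cm)) stopf("pos_bp and cm lengths differ")
  if (length(unique(pos_bp)) < 2 || length(unique(cm)) < 2) return("?")
  tau <- suppressWarnings(stats::cor(pos_bp, cm, method = "kendall"))
  if (is.na(tau) || tau == 0) return("?")
  if (tau > 0) "+" else "-"
}

#' Anchor scaffolds to the linkage map through their mapped markers
#'
#' Each scaffold carrying at least `min_markers` mapped markers receives a
#' linkage group (the one carrying most of its markers; ties go to the first
#' encountered), a map position (mean of its markers' bin cM on that group, so
#' bins with more markers weigh more), and an orientation from
#' [orient_scaffold()]. Scaffolds whose markers span several linkage groups
#' are candidate chimeras; see [detect_chimeras()].
#'
#' @param placements tibble with `marker_id`, `scaffold_id`, `pos_bp`.
#' @param bins bin table from [build_bins()].
#' @param marker_map the marker map the bins were built from.
#' @param min_markers minimum mapped markers required to anchor a scaffold.
#' @return a tibble with one row per anchored scaffold: `scaffold_id`, `lg`,
#'   `position_cm`, `n_markers`, `n_lgs`, `orientation`,
#'   `ambiguous_orientation`, and a `markers` list-column (per-marker
#'   `marker_id`, `pos_bp`, `lg`, `cm`, `bin_cm`, sorted by `pos_bp`).
#' @export
assign_scaffolds <- function(placements, bins, marker_map, min_markers = 1) {
  validate_placements(placements, marker_map = marker_map)
  if (min_markers < 1) stopf("min_markers must be >= 1")
  bin_of <- bins |>
    dplyr::select("lg", bin_cm = "cm", "marker_ids") |>
    tidyr::unnest(marker_ids) |>
    dplyr::rename(marker_id = "marker_ids")
  lg_order <- unique(bins$lg)
  marked <- placements |>
    dplyr::inner_join(dplyr::select(marker_map, "marker_id", "cm"),
                      by = "marker_id") |>
    dplyr::inner_join(bin_of, by = "marker_id") |>
    dplyr::arrange(.data$scaffold_id, .data$pos_bp, .data$marker_id)

  marked |>
    dplyr::group_by(.data$scaffold_id) |>
    dplyr::filter(dplyr::n() >= min_markers) |>
    dplyr::summarise(markers = list(dplyr::pick("marker_id", "pos_bp", "lg",
                                                "cm", "bin_cm")),
                     .groups = "drop") |>
    dplyr::mutate(purrr::map_dfr(.data$markers, summarise_anchor,
                                 lg_order = lg_order)) |>
    dplyr::arrange(factor(.data$lg, levels = lg_order), .data$position_cm,
                   .data$scaffold_id) |>
    dplyr::select("scaffold_id", "lg", "position_cm", "n_markers", "n_lgs",
                  "orientation", "ambiguous_orientation", "markers")
}

summarise_anchor <- function(mk, lg_order) {
  tab <- table(factor(mk$lg, levels = lg_order))
  lg <- names(tab)[which.max(tab)]
  own <- mk[mk$lg == lg, ]
  ori <- orient_scaffold(own$pos_bp, own$bin_cm)
  tibble::tibble(
    lg = lg,
    position_cm = mean(own$bin_cm),
    n_markers = nrow(mk),
    n_lgs = length(unique(mk$lg)),
    orientation = if (ori == "?") "+" else ori,
    ambiguous_orientation = ori == "?"
  )
}

#' Detect chimeric (multi-position) scaffolds
#'
#' A scaffold is flagged as a putative mis-assembly when, walking its markers
#' in physical order, adjacent markers either map to different linkage groups
#' (`multi_lg`) or to bin positions further apart than `max_intra_lg_gap_cm`
#' on the same group (`intra_lg_gap`). A split breakpoint is placed at the
#' floor midpoint between the two flanking markers' bp positions (0-based
#' split coordinate); contiguous marker runs on the same side form one piece.
#'
#' @param anchors anchor table from [assign_scaffolds()].
#' @param max_intra_lg_gap_cm largest within-group bin-cM jump between
#'   physically adjacent markers tolerated before splitting (cM).
#' @return a tibble with one row per chimeric scaffold: `scaffold_id`,
#'   `reason`, `n_pieces`, `breakpoints_bp` (list-column of 0-based split
#'   coordinates) and `piece_ids` (list-column, `<scaffold_id>.1`, `.2`, ...).
#' @export
detect_chimeras <- function(anchors, max_intra_lg_gap_cm = 20) {
  if (max_intra_lg_gap_cm < 0) stopf("max_intra_lg_gap_cm must be >= 0")
  reports <- purrr::map2(anchors$scaffold_id, anchors$markers, function(id, mk) {
    if (nrow(mk) < 2) return(NULL)
    mk <- mk[order(mk$pos_bp, mk$marker_id), ]
    lg_change <- mk$lg[-nrow(mk)] != mk$lg[-1]
    cm_jump <- !lg_change &
      abs(mk$bin_cm[-nrow(mk)] - mk$bin_cm[-1]) > max_intra_lg_gap_cm
    cut <- lg_change | cm_jump
    if (!any(cut)) return(NULL)
    idx <- which(cut)
    bp <- floor((mk$pos_bp[idx] + mk$pos_bp[idx + 1]) / 2)
    bp <- unique(bp)
    tibble::tibble(
      scaffold_id = id,
      reason = if (any(lg_change)) "multi_lg" else "intra_lg_gap",
      n_pieces = length(bp) + 1L,
      breakpoints_bp = list(bp),
      piece_ids = list(paste0(id, ".", seq_len(length(bp) + 1L)))
    )
  })
  out <- dplyr::bind_rows(reports)
  if (nrow(out) == 0) {
    out <- tibble::tibble(scaffold_id = character(0), reason = character(0),
                          n_pieces = integer(0), breakpoints_bp = list(),
                          piece_ids = list())
  }
  out
}

#' Split chimeric scaffolds and remap marker placements
#'
#' Pieces tile each split scaffold exactly: their concatenation (in order)
#' reproduces the original sequence. Placements on split scaffolds are
#' re-addressed to the containing piece with positions shifted accordingly;
#' intact scaffolds pass through unchanged.
#'
#' @param seqs sequence table (`id`, `seq`).
#' @param chimeras report from [detect_chimeras()].
#' @param placements optional placement table to remap alongside.
#' @return a list with elements `seqs` (split sequence table) and
#'   `placements` (remapped, or `NULL` when not supplied).
#' @export
split_scaffolds <- function(seqs, chimeras, placements = NULL) {
  validate_seqs(seqs)
  if (nrow(chimeras) == 0) {
    return(list(seqs = seqs, placements = placements))
  }
  missing <- setdiff(chimeras$scaffold_id, seqs$id)
  if (length(missing)) stopf("no sequence for chimeric scaffold '%s'", missing[1])

  bounds <- stats::setNames(vector("list", nrow(chimeras)), chimeras$scaffold_id)
  new_seqs <- vector("list", nrow(chimeras))
  for (i in seq_len(nrow(chimeras))) {
    id <- chimeras$scaffold_id[i]
    s <- seqs$seq[seqs$id == id]
    len <- nchar(s)
    bp <- sort(chimeras$breakpoints_bp[[i]])
    if (any(bp <= 0 | bp >= len)) {
      stopf("breakpoint outside scaffold '%s' (length %d)", id, len)
    }
    b <- c(0L, bp, len)
    bounds[[id]] <- b
    new_seqs[[i]] <- tibble::tibble(
      id = chimeras$piece_ids[[i]],
      seq = substring(s, b[-length(b)] + 1, b[-1])
    )
  }
  keep <- !(seqs$id %in% chimeras$scaffold_id)
  pos <- match(seqs$id, chimeras$scaffold_id)
  out_seqs <- dplyr::bind_rows(purrr::map(seq_len(nrow(seqs)), function(j) {
    if (keep[j]) seqs[j, c("id", "seq")] else new_seqs[[pos[j]]]
  }))

  out_pl <- placements
  if (!is.null(placements)) {
    split_idx <- match(placements$scaffold_id, chimeras$scaffold_id)
    hit <- !is.na(split_idx)
    if (any(hit)) {
      new_id <- placements$scaffold_id
      new_pos <- placements$pos_bp
      for (j in which(hit)) {
        b <- bounds[[placements$scaffold_id[j]]]
        piece <- findInterval(placements$pos_bp[j] - 1L, b,
                              rightmost.closed = FALSE)
        new_id[j] <- chimeras$piece_ids[[split_idx[j]]][piece]
        new_pos[j] <- placements$pos_bp[j] - b[piece]
      }
      out_pl <- placements
      out_pl$scaffold_id <- new_id
      out_pl$pos_bp <- as.integer(new_pos)
    }
  }
  list(seqs = out_seqs, placements = out_pl)
}

#' Order anchored scaffolds along each linkage group
#'
#' Scaffolds sort by ascending map position; ties break by descending scaffold
#' length then lexicographic id, so the order is a deterministic function of
#' the anchor set.
#'
#' @param anchors anchor table from [assign_scaffolds()].
#' @param seqs optional sequence table supplying lengths for tie-breaking.
#' @return the anchors, arranged, with an added per-group rank `lg_rank` and a
#'   `length_bp` column.
#' @export
order_scaffolds <- function(anchors, seqs = NULL) {
  len <- if (is.null(seqs)) integer(0) else seq_lengths(seqs)
  lg_order <- unique(anchors$lg)
  anchors |>
    dplyr::mutate(length_bp = dplyr::coalesce(
      unname(len[.data$scaffold_id]), 0L)) |>
    dplyr::arrange(factor(.data$lg, levels = lg_order), .data$position_cm,
                   dplyr::desc(.data$length_bp), .data$scaffold_id) |>
    dplyr::group_by(.data$lg) |>
    dplyr::mutate(lg_rank = dplyr::row_number()) |>
    dplyr::ungroup()
}

#' Anchored-scaffold accounting after chimera splitting
#'
#' Splitting removes each chimera from the anchored set and adds its pieces,
#' so the anchored count after revision is
#' `n_anchored_before - n_split + n_pieces`.
#'
#' @param n_anchored_before scaffolds anchored before splitting.
#' @param n_split scaffolds found at multiple map positions and split.
#' @param n_pieces total pieces those splits produced.
#' @return the anchored count after splitting.
#' @export
#' @examples
#' anchoring_accounting(1505, 158, 355) # 1702
anchoring_accounting <- function(n_anchored_before, n_split, n_pieces) {
  for (v in list(n_anchored_before, n_split, n_pieces)) {
    assert_scalar_number(v, "accounting input")
  }
  if (n_split > n_anchored_before) stopf("n_split exceeds n_anchored_before")
  if (n_split > 0 && n_pieces < 2 * n_split) {
    stopf("each split scaffold must yield at least 2 pieces")
  }
  if (n_split == 0 && n_pieces != 0) stopf("pieces without splits")
  n_anchored_before - n_split + n_pieces
}
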