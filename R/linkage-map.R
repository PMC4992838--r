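#' Group mapped markers into bins of identical genetic position
#'
#' Markers sharing a linkage group and a rounded cM position co-segregate (no
#' recombination observed among them) and form one bin. The rounding precision
#' stands in for the map software's co-segregation grouping, which typical
#' outputs encode as identical printed cM values.
#'
#' @param marker_map tibble with columns `marker_id`, `lg`, `cm`.
#' @param cm_precision decimals to which cM is rounded before grouping.
#' @param lg_order optional character vector fixing linkage-group order;
#'   defaults to first appearance in `marker_map`.
#' @return a tibble with one row per bin: `lg`, `cm` (rounded), `n_markers`,
#'   `marker_ids` (list-column), sorted by LG order then cM.
#' @export
build_bins <- function(marker_map, cm_precision = 2, lg_order = NULL) {
  if (cm_precision < 0) stopf("cm_precision must be >= 0")
  validate_marker_map(marker_map)
  if (is.null(lg_order)) lg_order <- unique(marker_map$lg)
  if (!all(marker_map$lg %in% lg_order)) {
    stopf("lg_order does not cover linkage group '%s'",
          setdiff(marker_map$lg, lg_order)[1])
  }
  marker_map |>
    dplyr::mutate(cm = round(.data$cm, cm_precision),
                  lg = factor(.data$lg, levels = lg_order)) |>
    dplyr::group_by(.data$lg, .data$cm) |>
    dplyr::summarise(n_markers = dplyr::n(),
                     marker_ids = list(sort(.data$marker_id)),
                     .groups = "drop") |>
    dplyr::arrange(.data$lg, .data$cm) |>
    dplyr::mutate(lg = as.character(.data$lg))
}

validate_marker_map <- function(marker_map) {
  if (!all(c("marker_id", "lg", "cm") %in% names(marker_map))) {
    stopf("marker map needs columns marker_id, lg, cm")
  }
  if (nrow(marker_map) == 0) stopf("marker map is empty")
  if (anyDuplicated(marker_map$marker_id)) {
    stopf("duplicate marker_id '%s'",
          marker_map$marker_id[duplicated(marker_map$marker_id)][1])
  }
  if (any(!is.finite(marker_map$cm) | marker_map$cm < 0)) {
    stopf("cM values must be finite and non-negative")
  }
  invisible(marker_map)
}

#' Per-linkage-group map summary
#'
#' Marker and bin counts and map length (max cM minus min cM) per linkage
#' group, with a final `Total` row summing counts and lengths.
#'
#' @param marker_map tibble with columns `marker_id`, `lg`, `cm`.
#' @param bins bins built from the same map by [build_bins()]; built with
#'   defaults when omitted.
#' @return a tibble with columns `lg`, `n_markers`, `n_bins`, `length_cm`.
#' @export
map_summary <- function(marker_map, bins = NULL) {
  validate_marker_map(marker_map)
  if (is.null(bins)) bins <- build_bins(marker_map)
  lg_order <- unique(bins$lg)
  per_lg <- marker_map |>
    dplyr::mutate(lg = factor(.data$lg, levels = lg_order)) |>
    dplyr::group_by(.data$lg) |>
    dplyr::summarise(n_markers = dplyr::n(),
                     length_cm = max(.data$cm) - min(.data$cm),
                     .groups = "drop") |>
    dplyr::left_join(dplyr::count(bins, lg = factor(.data$lg, levels = lg_order),
                                  name = "n_bins"),
                     by = "lg") |>
    dplyr::arrange(.data$lg) |>
    dplyr::mutate(lg = as.character(.data$lg)) |>
    dplyr::select("lg", "n_markers", "n_bins", "length_cm")
  dplyr::bind_rows(per_lg,
                   tibble::tibble(lg = "Total",
                                  n_markers = sum(per_lg$n_markers),
                                  n_bins = sum(per_lg$n_bins),
                                  length_cm = sum(per_lg$length_cm)))
}
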