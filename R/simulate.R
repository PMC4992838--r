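#' Configuration for the synthetic fragmented-genome simulator
#'
#' Defaults describe a desk-scale diploid-plant-like genome: eight chromosomes
#' of 2 Mb, GC content 0.33, 100 markers per Mb on a linear genetic map of
#' 3.8 cM per Mb, scaffolds of 50 kb on average, 10% of scaffolds inverted
#' and 5% fused into cross-chromosome chimeras. `cm_jitter_sd` adds Gaussian
#' noise (cM) to observed marker positions; `p_chimera_intra` optionally
#' fuses scaffolds from the same chromosome to exercise the within-group gap
#' rule.
#'
#' @param seed integer RNG seed; all randomness flows from it.
#' @param n_chromosomes,chromosome_length_bp genome shape.
#' @param gc_content proportion of G+C bases.
#' @param markers_per_mb marker density.
#' @param cm_per_mb linear genetic-map rate (cM per Mb).
#' @param mean_scaffold_bp mean fragment size.
#' @param p_invert,p_chimera,p_chimera_intra perturbation rates.
#' @param cm_jitter_sd SD of Gaussian noise added to observed cM.
#' @return a `sim_config` list.
#' @export
sim_config <- function(seed, n_chromosomes = 8, chromosome_length_bp = 2e6,
                       gc_content = 0.33, markers_per_mb = 100,
                       cm_per_mb = 3.8, mean_scaffold_bp = 5e4,
                       p_invert = 0.10, p_chimera = 0.05,
                       p_chimera_intra = 0, cm_jitter_sd = 0) {
  cfg <- list(seed = as.integer(seed), n_chromosomes = n_chromosomes,
              chromosome_length_bp = chromosome_length_bp,
              gc_content = gc_content, markers_per_mb = markers_per_mb,
              cm_per_mb = cm_per_mb, mean_scaffold_bp = mean_scaffold_bp,
              p_invert = p_invert, p_chimera = p_chimera,
              p_chimera_intra = p_chimera_intra, cm_jitter_sd = cm_jitter_sd)
  probs <- c(cfg$gc_content, cfg$p_invert, cfg$p_chimera, cfg$p_chimera_intra)
  if (any(probs < 0 | probs > 1)) stopf("probabilities must lie in [0, 1]")
  if (cfg$n_chromosomes < 1 || cfg$chromosome_length_bp < 1000 ||
      cfg$mean_scaffold_bp < 100) stopf("genome dimensions too small")
  if (cfg$markers_per_mb <= 0 || cfg$cm_per_mb <= 0) stopf("rates must be positive")
  if (cfg$cm_jitter_sd < 0) stopf("cm_jitter_sd must be >= 0")
  if (is.na(cfg$seed)) stopf("seed is mandatory")
  structure(cfg, class = "sim_config")
}

random_dna <- function(n, gc) {
  paste(sample(c("A", "T", "G", "C"), n, replace = TRUE,
               prob = c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2)),
        collapse = "")
}

#' Simulate a fragmented genome with a linkage map and truth tables
#'
#' Chromosomes are drawn base-by-base at the configured GC content and carry a
#' strictly monotone linear genetic map, `cM(bp) = cm_per_mb * bp / 1e6`.
#' Each chromosome is fragmented at uniform random breakpoints into scaffolds
#' of the configured mean size; scaffolds are independently inverted with
#' `p_invert`, and with `p_chimera` fused end-to-end with a scaffold from a
#' different chromosome (mis-assembly). Markers are placed uniformly and
#' their physical positions recomputed through inversions and fusions;
#' observed cM optionally receives Gaussian jitter. Scaffold ids are assigned
#' in shuffled order so they carry no positional information. Everything is a
#' deterministic function of the seed.
#'
#' @param config a [sim_config()].
#' @return a `sim_dataset` list: `scaffolds` (tibble `id`, `seq`),
#'   `marker_map`, `placements`, `truth` (list of `scaffolds` part table and
#'   `markers` table), and `config`.
#' @export
simulate_genome <- function(config) {
  if (!inherits(config, "sim_config")) stopf("config must come from sim_config()")
  set.seed(config$seed)
  K <- config$n_chromosomes
  len <- config$chromosome_length_bp

  chrom_seq <- character(K)
  parts <- vector("list", K)
  marker_rows <- vector("list", K)
  for (k in seq_len(K)) {
    chrom <- paste0("chr", k)
    chrom_seq[k] <- random_dna(len, config$gc_content)
    n_pieces <- max(1, round(len / config$mean_scaffold_bp))
    cuts <- if (n_pieces > 1) sort(sample.int(len - 1, n_pieces - 1)) else integer(0)
    b <- c(0L, cuts, len)
    parts[[k]] <- tibble::tibble(chromosome = chrom,
                                 start = b[-length(b)] + 1L, end = b[-1])
    n_mark <- round(config$markers_per_mb * len / 1e6)
    pos <- sort(sample.int(len, n_mark))
    cm_true <- config$cm_per_mb * pos / 1e6
    marker_rows[[k]] <- tibble::tibble(chromosome = chrom,
                                       lg = paste0("LG", k),
                                       bp = pos, cm_true = cm_true)
  }
  parts <- dplyr::bind_rows(parts)
  markers <- dplyr::bind_rows(marker_rows)
  markers$marker_id <- sprintf("M%05d", seq_len(nrow(markers)))
  cm_obs <- markers$cm_true
  if (config$cm_jitter_sd > 0) {
    cm_obs <- pmax(0, cm_obs + stats::rnorm(length(cm_obs), 0, config$cm_jitter_sd))
  }
  markers$cm <- cm_obs

  np <- nrow(parts)
  parts$strand <- ifelse(stats::runif(np) < config$p_invert, "-", "+")

  # pair flagged parts into chimeric fusions
  partner <- rep(NA_integer_, np)
  pair_up <- function(flagged, cross_chromosome) {
    flagged <- sample(flagged)           # random pairing order
    while (length(flagged) >= 2) {
      i <- flagged[1]
      ok <- if (cross_chromosome) {
        flagged[-1][parts$chromosome[flagged[-1]] != parts$chromosome[i]]
      } else {
        flagged[-1][parts$chromosome[flagged[-1]] == parts$chromosome[i]]
      }
      if (length(ok) == 0) { flagged <- flagged[-1]; next }
      j <- ok[1]
      partner[i] <<- j; partner[j] <<- i
      flagged <- setdiff(flagged, c(i, j))
    }
  }
  if (config$p_chimera > 0) {
    pair_up(which(stats::runif(np) < config$p_chimera & is.na(partner)), TRUE)
  }
  if (config$p_chimera_intra > 0) {
    pair_up(which(stats::runif(np) < config$p_chimera_intra & is.na(partner)), FALSE)
  }

  # assemble scaffolds: singletons plus fused pairs, then shuffle ids
  first_of_pair <- which(!is.na(partner) & seq_len(np) < partner)
  singletons <- which(is.na(partner))
  units <- c(as.list(singletons), purrr::map(first_of_pair, ~c(.x, partner[.x])))
  units <- sample(units)
  ids <- sprintf("scf%05d", seq_along(units))

  part_seq <- function(i) {
    s <- substr(chrom_seq[match(parts$chromosome[i], paste0("chr", seq_len(K)))],
                parts$start[i], parts$end[i])
    if (parts$strand[i] == "-") revcomp(s) else s
  }
  scaffold_rows <- vector("list", length(units))
  truth_rows <- vector("list", length(units))
  for (u in seq_along(units)) {
    idx <- units[[u]]
    pieces <- vapply(idx, part_seq, character(1))
    plen <- nchar(pieces)
    offset <- cumsum(c(0L, plen[-length(plen)]))
    scaffold_rows[[u]] <- tibble::tibble(id = ids[u],
                                         seq = paste(pieces, collapse = ""))
    truth_rows[[u]] <- tibble::tibble(
      scaffold_id = ids[u], part_index = seq_along(idx),
      chromosome = parts$chromosome[idx],
      start = parts$start[idx], end = parts$end[idx],
      strand = parts$strand[idx],
      is_chimera = length(idx) > 1,
      fused_from = if (length(idx) > 1)
        paste(parts$chromosome[idx], collapse = "+") else NA_character_,
      scaffold_offset = offset, part_length = plen
    )
  }
  scaffolds <- dplyr::bind_rows(scaffold_rows)
  truth_parts <- dplyr::bind_rows(truth_rows)

  # marker placements through inversion and fusion
  pl <- markers |>
    dplyr::inner_join(truth_parts,
                      by = dplyr::join_by(chromosome, bp >= start, bp <= end)) |>
    dplyr::mutate(
      within = ifelse(.data$strand == "-",
                      .data$end - .data$bp + 1L, .data$bp - .data$start + 1L),
      pos_bp = as.integer(.data$scaffold_offset + .data$within))
  placements <- dplyr::select(pl, "marker_id", "scaffold_id", "pos_bp") |>
    dplyr::arrange(.data$marker_id)

  structure(list(
    scaffolds = scaffolds,
    marker_map = dplyr::select(markers, "marker_id", "lg", "cm"),
    placements = placements,
    truth = list(scaffolds = truth_parts,
                 markers = dplyr::select(markers, "marker_id", "chromosome",
                                         "bp", "cm_true")),
    config = config
  ), class = "sim_dataset")
}

#' Write a simulated dataset to disk
#'
#' Emits `scaffolds.fa`, `map.tsv`, `placements.tsv`, `truth_scaffolds.tsv`,
#' `truth_markers.tsv` and `provenance.json` (the full configuration,
#' including the seed).
#'
#' @param dataset a `sim_dataset` from [simulate_genome()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_sim_dataset <- function(dataset, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_fasta(dataset$scaffolds, file.path(dir, "scaffolds.fa"))
  readr::write_tsv(dataset$marker_map, file.path(dir, "map.tsv"))
  readr::write_tsv(dataset$placements, file.path(dir, "placements.tsv"))
  readr::write_tsv(dataset$truth$scaffolds, file.path(dir, "truth_scaffolds.tsv"))
  readr::write_tsv(dataset$truth$markers, file.path(dir, "truth_markers.tsv"))
  jsonlite::write_json(unclass(dataset$config),
                       file.path(dir, "provenance.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' Simulate a k-mer depth histogram for a genome of known size
#'
#' Per-position depths are Poisson(`mean_depth`); sequencing errors add a
#' singleton spike at depth 1 of `round(error_rate * genome_size_bp *
#' mean_depth)` k-mers.
#'
#' @param genome_size_bp true genome size.
#' @param mean_depth mean k-mer coverage.
#' @param error_rate per-base error rate feeding the depth-1 spike.
#' @param seed RNG seed.
#' @return a histogram tibble (`depth`, `count`).
#' @export
simulate_kmer_histogram <- function(genome_size_bp, mean_depth, error_rate = 0,
                                    seed = 1) {
  if (genome_size_bp <= 0) stopf("genome_size_bp must be positive")
  if (mean_depth <= 0) stopf("mean_depth must be positive")
  set.seed(seed)
  depths <- stats::rpois(genome_size_bp, mean_depth)
  depths <- depths[depths >= 1]
  tab <- table(depths)
  out <- tibble::tibble(depth = as.integer(names(tab)),
                        count = as.integer(tab))
  n_err <- round(error_rate * genome_size_bp * mean_depth)
  if (n_err > 0) {
    if (1 %in% out$depth) {
      out$count[out$depth == 1] <- out$count[out$depth == 1] + n_err
    } else {
      out <- dplyr::bind_rows(tibble::tibble(depth = 1L,
                                             count = as.integer(n_err)), out)
    }
  }
  dplyr::arrange(out, .data$depth)
}

#' Score pipeline recovery against simulation truth
#'
#' Orientation accuracy is scored over post-split anchor units carrying at
#' least two distinct genetic positions, each matched to its truth part
#' (piece *k* of a split chimera to part *k* when counts agree). Chimera
#' sensitivity is scored against the map-visible planted fusions — those whose
#' scaffold carries mapped markers on two or more of its source parts; a
#' fusion with all its markers on one side is indistinguishable from an intact
#' scaffold for any map-based detector, so the all-planted recall is reported
#' separately as `chimera_sensitivity_all`. Precision compares called splits
#' with planted fusions; order
#' recovery is the per-linkage-group Spearman correlation between the
#' pipeline's scaffold order and the true positions on the corresponding
#' chromosome.
#'
#' @param run an `anchor_run` from [run_pipeline()].
#' @param truth the `truth` element of a `sim_dataset`.
#' @return a one-row tibble: `orientation_accuracy`, `n_orientation_eval`,
#'   `chimera_sensitivity` (over visible fusions), `chimera_sensitivity_all`,
#'   `n_visible_chimeras`, `chimera_precision`, `order_spearman_min`,
#'   `order_spearman_mean`, `anchored_percent`, plus `per_lg` (list-column of
#'   per-group Spearman rho).
#' @export
evaluate_recovery <- function(run, truth) {
  if (!inherits(run, "anchor_run")) stopf("run must come from run_pipeline()")
  tp <- truth$scaffolds
  truth_chim <- unique(tp$scaffold_id[tp$is_chimera])
  called_chim <- run$chimeras$scaffold_id
  if (!all(called_chim %in% tp$scaffold_id)) {
    stopf("chimera call references unknown scaffold '%s'",
          setdiff(called_chim, tp$scaffold_id)[1])
  }
  visible_chim <- truth_chim[vapply(truth_chim, function(id) {
    i <- match(id, run$anchors_before$scaffold_id)
    if (is.na(i)) return(FALSE)
    parts <- tp[tp$scaffold_id == id, ]
    mk <- run$anchors_before$markers[[i]]
    part_of <- findInterval(mk$pos_bp - 1L,
                            c(0L, cumsum(parts$part_length)))
    length(unique(part_of)) >= 2
  }, logical(1))]
  sens <- if (length(visible_chim) == 0) NA_real_ else
    length(intersect(called_chim, visible_chim)) / length(visible_chim)
  sens_all <- if (length(truth_chim) == 0) NA_real_ else
    length(intersect(called_chim, truth_chim)) / length(truth_chim)
  prec <- if (length(called_chim) == 0) NA_real_ else
    length(intersect(called_chim, truth_chim)) / length(called_chim)

  anchors <- run$ordered
  parent_id <- sub("\\.\\d+$", "", anchors$scaffold_id)
  piece_no <- rep(1L, nrow(anchors))
  has_piece <- grepl("\\.\\d+$", anchors$scaffold_id)
  piece_no[has_piece] <- as.integer(sub("^.*\\.", "",
                                        anchors$scaffold_id[has_piece]))
  n_parts <- table(tp$scaffold_id)
  n_pieces_called <- table(parent_id)
  matched <- purrr::map2_dfr(parent_id, piece_no, function(pid, k) {
    if (!pid %in% tp$scaffold_id) {
      stopf("anchor references unknown scaffold '%s'", pid)
    }
    if (n_parts[[pid]] != n_pieces_called[[pid]]) {
      return(tibble::tibble(strand = NA_character_, chromosome = NA_character_,
                            start = NA_integer_))
    }
    row <- tp[tp$scaffold_id == pid & tp$part_index == k, ]
    tibble::tibble(strand = row$strand, chromosome = row$chromosome,
                   start = row$start)
  })

  eligible <- purrr::map2_lgl(anchors$markers, anchors$lg, function(mk, lg) {
    length(unique(mk$bin_cm[mk$lg == lg])) >= 2
  }) & !is.na(matched$strand)
  orientation_accuracy <- if (!any(eligible)) NA_real_ else
    mean(anchors$orientation[eligible] == matched$strand[eligible])

  lgs <- unique(anchors$lg)
  rho <- vapply(lgs, function(lg) {
    sel <- anchors$lg == lg & !is.na(matched$start) &
      matched$chromosome == sub("^LG", "chr", lg)
    sel[is.na(sel)] <- FALSE
    if (sum(sel) < 3) return(NA_real_)
    stats::cor(anchors$lg_rank[sel], matched$start[sel], method = "spearman")
  }, numeric(1))

  tibble::tibble(
    orientation_accuracy = orientation_accuracy,
    n_orientation_eval = sum(eligible),
    chimera_sensitivity = sens,
    chimera_sensitivity_all = sens_all,
    n_visible_chimeras = length(visible_chim),
    chimera_precision = prec,
    order_spearman_min = if (all(is.na(rho))) NA_real_ else min(rho, na.rm = TRUE),
    order_spearman_mean = if (all(is.na(rho))) NA_real_ else mean(rho, na.rm = TRUE),
    anchored_percent = run$tallies$anchored_percent,
    per_lg = list(tibble::tibble(lg = lgs, spearman = unname(rho)))
  )
}
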