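#' Reciprocal-best-hit gene pairs from two hit tables
#'
#' After discarding hits above the E-value cutoff, each query's best hit is
#' chosen by bit score (ties: lower E-value, then higher percent identity,
#' then lexicographic subject id). A pair is kept iff the two directions agree:
#' best(a) = b and best(b) = a.
#'
#' @param hits_ab hit table of set A queried against set B (see
#'   [read_hit_table()]).
#' @param hits_ba hit table of set B queried against set A.
#' @param evalue_cutoff maximum E-value for a hit to be considered.
#' @return a tibble with columns `gene_a`, `gene_b`, sorted by `gene_a`.
#' @export
reciprocal_best_hits <- function(hits_ab, hits_ba, evalue_cutoff = 1e-10) {
  best <- function(hits) {
    hits |>
      dplyr::filter(.data$e_value <= evalue_cutoff) |>
      dplyr::arrange(.data$query_id, dplyr::desc(.data$bit_score),
                     .data$e_value, dplyr::desc(.data$percent_identity),
                     .data$subject_id) |>
      dplyr::distinct(.data$query_id, .keep_all = TRUE) |>
      dplyr::select("query_id", "subject_id")
  }
  ab <- best(hits_ab)
  ba <- best(hits_ba)
  ab |>
    dplyr::inner_join(ba, by = c(subject_id = "query_id"),
                      suffix = c("", "_back")) |>
    dplyr::filter(.data$query_id == .data$subject_id_back) |>
    dplyr::transmute(gene_a = .data$query_id, gene_b = .data$subject_id) |>
    dplyr::arrange(.data$gene_a)
}

#' Synteny dot-plot coordinates for gene pairs
#'
#' One point per pair at the two genes' midpoints; pairs lacking coordinates
#' on either side are skipped with a warning giving the count.
#'
#' @param pairs tibble with `gene_a`, `gene_b` (e.g. from
#'   [reciprocal_best_hits()]).
#' @param coords_a,coords_b coordinate tables with columns `gene_id`,
#'   `molecule`, `start`, `end` and optionally `strand` (`+`/`-`).
#' @return a tibble sorted by (`x_mol`, `x_pos`): `gene_a`, `gene_b`, `x_mol`,
#'   `x_pos`, `y_mol`, `y_pos`, `strand_concordance` (logical; `NA` without
#'   strand columns).
#' @export
dotplot_pairs <- function(pairs, coords_a, coords_b) {
  mid <- function(coords, who) {
    need <- c("gene_id", "molecule", "start", "end")
    if (!all(need %in% names(coords))) {
      stopf("%s needs columns %s", who, paste(need, collapse = ", "))
    }
    tibble::tibble(gene_id = coords$gene_id, mol = coords$molecule,
                   pos = (coords$start + coords$end) / 2,
                   strand = if ("strand" %in% names(coords)) coords$strand
                            else NA_character_)
  }
  a <- mid(coords_a, "coords_a")
  b <- mid(coords_b, "coords_b")
  out <- pairs |>
    dplyr::left_join(a, by = c(gene_a = "gene_id")) |>
    dplyr::left_join(b, by = c(gene_b = "gene_id"), suffix = c("_a", "_b"))
  dropped <- sum(is.na(out$mol_a) | is.na(out$mol_b))
  if (dropped > 0) warnf("dotplot_pairs: skipping %d pair(s) without coordinates",
                         dropped)
  out |>
    dplyr::filter(!is.na(.data$mol_a), !is.na(.data$mol_b)) |>
    dplyr::transmute(gene_a = .data$gene_a, gene_b = .data$gene_b,
                     x_mol = .data$mol_a, x_pos = .data$pos_a,
                     y_mol = .data$mol_b, y_pos = .data$pos_b,
                     strand_concordance = .data$strand_a == .data$strand_b) |>
    dplyr::arrange(.data$x_mol, .data$x_pos, .data$gene_a)
}

# ---- Nei-Gojobori (1986) ----

ng86_env <- new.env(parent = emptyenv())

genetic_code <- function() Biostrings::GENETIC_CODE

# Fraction of synonymous sites per sense codon: at each of the three
# positions, the share of the three single-nucleotide changes that preserve
# the amino acid. Changes creating stop codons count as nonsynonymous, so
# synonymous + nonsynonymous sites always total 3 per codon.
syn_sites_per_codon <- function() {
  if (!is.null(ng86_env$syn_sites)) return(ng86_env$syn_sites)
  gc <- genetic_code()
  bases <- c("A", "C", "G", "T")
  out <- stats::setNames(numeric(length(gc)), names(gc))
  for (codon in names(gc)) {
    if (gc[[codon]] == "*") { out[codon] <- NA_real_; next }
    s <- 0
    cs <- strsplit(codon, "")[[1]]
    for (p in 1:3) {
      for (b in setdiff(bases, cs[p])) {
        alt <- cs; alt[p] <- b
        alt <- paste(alt, collapse = "")
        if (gc[[alt]] == gc[[codon]]) s <- s + 1 / 3
      }
    }
    out[codon] <- s
  }
  ng86_env$syn_sites <- out
  out
}

# Average synonymous/nonsynonymous difference counts between two sense
# codons, averaged over all orderings of single-step mutational pathways;
# pathways passing through a stop codon are excluded (unless all are, in
# which case every pathway counts).
codon_diffs <- function(codon_a, codon_b) {
  if (codon_a == codon_b) return(c(sd = 0, nd = 0))
  key <- paste0(codon_a, codon_b)
  cached <- ng86_env$diffs[[key]]
  if (!is.null(cached)) return(cached)
  gc <- genetic_code()
  a <- strsplit(codon_a, "")[[1]]
  b <- strsplit(codon_b, "")[[1]]
  pos <- which(a != b)
  paths <- if (length(pos) == 1) list(pos) else
    apply(permute_all(pos), 1, identity, simplify = FALSE)
  tally <- function(order_pos) {
    cur <- a
    sd <- nd <- 0
    for (p in order_pos) {
      nxt <- cur; nxt[p] <- b[p]
      aa_from <- gc[[paste(cur, collapse = "")]]
      aa_to <- gc[[paste(nxt, collapse = "")]]
      if (aa_to == "*" || aa_from == "*") return(NULL)
      if (aa_from == aa_to) sd <- sd + 1 else nd <- nd + 1
      cur <- nxt
    }
    c(sd = sd, nd = nd)
  }
  counted <- purrr::compact(purrr::map(paths, tally))
  if (length(counted) == 0) {  # every route crosses a stop; count them anyway
    counted <- purrr::map(paths, function(order_pos) {
      cur <- a; sd <- nd <- 0
      for (p in order_pos) {
        nxt <- cur; nxt[p] <- b[p]
        same <- gc[[paste(cur, collapse = "")]] == gc[[paste(nxt, collapse = "")]]
        if (same) sd <- sd + 1 else nd <- nd + 1
        cur <- nxt
      }
      c(sd = sd, nd = nd)
    })
  }
  res <- colMeans(do.call(rbind, counted))
  if (is.null(ng86_env$diffs)) ng86_env$diffs <- new.env(parent = emptyenv())
  assign(key, res, envir = ng86_env$diffs)
  res
}

permute_all <- function(x) {
  if (length(x) == 1) return(matrix(x, 1, 1))
  do.call(rbind, lapply(seq_along(x), function(i) {
    cbind(x[i], permute_all(x[-i]))
  }))
}

#' Jukes-Cantor multiple-hit correction
#'
#' `d = -(3/4) * log(1 - (4/3) * p)`; undefined (NA) when `p >= 3/4`.
#'
#' @param p observed proportion of differing sites.
#' @return corrected distance, or `NA` outside the domain.
#' @export
jukes_cantor <- function(p) {
  ifelse(4 / 3 * p >= 1, NA_real_, -3 / 4 * log(1 - 4 / 3 * p))
}

#' Nei-Gojobori (1986) synonymous and nonsynonymous rates for a codon
#' alignment
#'
#' Counts synonymous and nonsynonymous sites per codon from the standard
#' genetic code (changes to stop codons count as nonsynonymous so sites total
#' three per codon), averages difference counts over all orderings of
#' single-step mutational pathways for multi-difference codons (pathways
#' through stop codons excluded), and applies the Jukes-Cantor correction to
#' the proportions pS and pN. Codon columns containing gaps or ambiguity
#' codes, and columns where either codon is a stop, are excluded pairwise
#' (stops with a warning).
#'
#' @param seq_a,seq_b aligned coding sequences of equal length (multiple of
#'   3), gaps as `-`.
#' @return a one-row tibble: `n_codons` (compared), `S_sites`, `N_sites`,
#'   `S_diffs`, `N_diffs`, `pS`, `pN`, `Ks`, `Ka` (`NA` when the correction is
#'   undefined), `ks_defined`, `ka_defined`, `n_excluded_codons`.
#' @export
ng86_ks <- function(seq_a, seq_b) {
  seq_a <- toupper(seq_a); seq_b <- toupper(seq_b)
  if (nchar(seq_a) != nchar(seq_b)) stopf("aligned sequences differ in length")
  if (nchar(seq_a) %% 3 != 0) stopf("alignment length is not a multiple of 3")
  n <- nchar(seq_a) / 3
  starts <- 3 * seq_len(n) - 2
  ca <- substring(seq_a, starts, starts + 2)
  cb <- substring(seq_b, starts, starts + 2)
  clean <- grepl("^[ACGT]{3}$", ca) & grepl("^[ACGT]{3}$", cb)
  gc <- genetic_code()
  is_stop <- clean & (gc[ca] == "*" | gc[cb] == "*")
  if (any(is_stop, na.rm = TRUE)) {
    warnf("ng86_ks: excluding %d codon column(s) containing a stop codon",
          sum(is_stop, na.rm = TRUE))
  }
  use <- clean & !is_stop
  if (!any(use)) stopf("no comparable codon columns")
  ca <- ca[use]; cb <- cb[use]
  ssites <- syn_sites_per_codon()
  S_sites <- sum((ssites[ca] + ssites[cb]) / 2)
  N_sites <- 3 * length(ca) - S_sites
  dmat <- t(mapply(codon_diffs, ca, cb))
  S_diffs <- sum(dmat[, "sd"])
  N_diffs <- sum(dmat[, "nd"])
  pS <- if (S_sites > 0) S_diffs / S_sites else 0
  pN <- if (N_sites > 0) N_diffs / N_sites else 0
  tibble::tibble(
    n_codons = length(ca),
    S_sites = S_sites, N_sites = N_sites,
    S_diffs = S_diffs, N_diffs = N_diffs,
    pS = pS, pN = pN,
    Ks = jukes_cantor(pS), Ka = jukes_cantor(pN),
    ks_defined = 4 / 3 * pS < 1,
    ka_defined = 4 / 3 * pN < 1,
    n_excluded_codons = n - length(ca)
  )
}

#' Bin Ks values into a histogram
#'
#' Half-open bins `[i*w, (i+1)*w)` up to `max_ks`; non-finite (undefined) and
#' out-of-range values are excluded and reported via attributes
#' `n_undefined` and `n_out_of_range`. Proportions sum to one over retained
#' values.
#'
#' @param ks_values numeric vector of Ks estimates (NA = undefined).
#' @param bin_width bin width.
#' @param max_ks upper bound of the histogram.
#' @return a tibble: `bin_start`, `bin_end`, `count`, `proportion`.
#' @export
ks_histogram <- function(ks_values, bin_width = 0.1, max_ks = 3.0) {
  if (bin_width <= 0) stopf("bin_width must be positive")
  if (max_ks <= 0) stopf("max_ks must be positive")
  finite <- ks_values[is.finite(ks_values)]
  n_undef <- length(ks_values) - length(finite)
  keep <- finite[finite >= 0 & finite < max_ks]
  n_oor <- length(finite) - length(keep)
  if (length(keep) == 0) stopf("no finite Ks values within [0, max_ks)")
  n_bins <- ceiling(max_ks / bin_width)
  idx <- floor(keep / bin_width) + 1
  counts <- tabulate(idx, nbins = n_bins)
  out <- tibble::tibble(
    bin_start = (seq_len(n_bins) - 1) * bin_width,
    bin_end = seq_len(n_bins) * bin_width,
    count = counts,
    proportion = counts / length(keep)
  )
  attr(out, "n_retained") <- length(keep)
  attr(out, "n_undefined") <- n_undef
  attr(out, "n_out_of_range") <- n_oor
  out
}

# ---- divergence-time calibration ----

descendant_tips <- function(tree) {
  nt <- length(tree$tip.label)
  nn <- nt + tree$Nnode
  desc <- vector("list", nn)
  for (i in seq_len(nt)) desc[[i]] <- i
  ord <- ape::postorder(tree)
  for (e in ord) {
    parent <- tree$edge[e, 1]; child <- tree$edge[e, 2]
    desc[[parent]] <- c(desc[[parent]], desc[[child]])
  }
  desc
}

#' Convert tree branch lengths to node ages with a single calibration
#'
#' Each node's height is its mean path length to the tips below it (a
#' uniform-rates operationalization); every height is then scaled so that the
#' most recent common ancestor of the two calibration taxa sits at
#' `age_mya`. Ages are finally clipped child-to-parent so they decrease
#' toward the tips even on non-ultrametric inputs.
#'
#' @param tree an [ape] `phylo` object with branch lengths (see
#'   [read_newick()]).
#' @param taxon_a,taxon_b tip labels whose MRCA is calibrated.
#' @param age_mya age assigned to that MRCA, million years.
#' @return an object of class `calibrated_tree`: list with `tree`,
#'   `calibration`, and `node_ages` (tibble: `node`, `label`, `is_tip`,
#'   `age_mya`).
#' @export
calibrate_times <- function(tree, taxon_a, taxon_b, age_mya = 114.0) {
  if (!inherits(tree, "phylo")) stopf("'tree' must be a phylo object")
  if (is.null(tree$edge.length)) stopf("tree lacks branch lengths")
  if (any(tree$edge.length < 0)) stopf("negative branch lengths")
  tips <- tree$tip.label
  for (tx in c(taxon_a, taxon_b)) {
    if (!tx %in% tips) stopf("calibration taxon '%s' not in tree", tx)
  }
  if (taxon_a == taxon_b) stopf("calibration taxa must differ")
  nt <- length(tips)
  nn <- nt + tree$Nnode
  dm <- ape::dist.nodes(tree)
  desc <- descendant_tips(tree)
  height <- vapply(seq_len(nn), function(i) mean(dm[i, desc[[i]]]), numeric(1))
  cal_node <- ape::getMRCA(tree, c(taxon_a, taxon_b))
  if (height[cal_node] <= 0) stopf("calibration node has zero height")
  age <- age_mya * height / height[cal_node]

  # preorder clip: child age never exceeds parent age
  pre <- rev(ape::postorder(tree))
  for (e in pre) {
    parent <- tree$edge[e, 1]; child <- tree$edge[e, 2]
    age[child] <- min(age[child], age[parent])
  }
  labels <- c(tips, if (!is.null(tree$node.label) &&
                        length(tree$node.label) == tree$Nnode) tree$node.label
                    else paste0("node", (nt + 1):nn))
  structure(list(
    tree = tree,
    calibration = list(taxon_a = taxon_a, taxon_b = taxon_b,
                       age_mya = age_mya, node = cal_node),
    node_ages = tibble::tibble(node = seq_len(nn), label = labels,
                               is_tip = seq_len(nn) <= nt, age_mya = age)
  ), class = "calibrated_tree")
}

#' @export
print.calibrated_tree <- function(x, ...) {
  cat(sprintf("<calibrated_tree: %d tips; MRCA(%s, %s) fixed at %.1f MYA>\n",
              length(x$tree$tip.label), x$calibration$taxon_a,
              x$calibration$taxon_b, x$calibration$age_mya))
  invisible(x)
}

#' @export
tidy.calibrated_tree <- function(x, ...) x$node_ages

#' @export
glance.calibrated_tree <- function(x, ...) {
  nt <- length(x$tree$tip.label)
  tibble::tibble(
    n_tips = nt,
    root_age_mya = x$node_ages$age_mya[nt + 1],
    calibration_age_mya = x$calibration$age_mya,
    calibration_node_age_mya = x$node_ages$age_mya[x$calibration$node]
  )
}
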