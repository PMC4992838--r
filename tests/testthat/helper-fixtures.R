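# Shared toy fixtures and independent oracles, built in code.

toy_map <- function() {
  tibble::tibble(
    marker_id = c("m1", "m2", "m3", "m4", "m5", "m6"),
    lg = c("LG1", "LG1", "LG1", "LG2", "LG2", "LG2"),
    cm = c(1.0, 3.0, 5.0, 0.0, 2.0, 2.0)
  )
}

toy_scaffolds <- function() {
  tibble::tibble(
    id = c("sA", "sB", "sC"),
    seq = c(strrep("ACGT", 25),           # 100 bp
            strrep("GGCC", 50),           # 200 bp
            paste0(strrep("AT", 30), strrep("GC", 20)))  # 100 bp
  )
}

toy_placements <- function() {
  tibble::tibble(
    marker_id = c("m1", "m2", "m3", "m4", "m5"),
    scaffold_id = c("sA", "sA", "sA", "sB", "sB"),
    pos_bp = c(10L, 50L, 90L, 20L, 180L)
  )
}

small_sim <- function(seed = 11, ...) {
  simulate_genome(sim_config(seed = seed, n_chromosomes = 3,
                             chromosome_length_bp = 4e5,
                             mean_scaffold_bp = 2e4, markers_per_mb = 150, ...))
}

# --- independent oracles ---

# N50 by explicit cumulative walk over the descending-sorted lengths.
oracle_n50 <- function(lengths) {
  s <- sort(lengths, decreasing = TRUE)
  half <- sum(s) / 2
  acc <- 0
  for (l in s) {
    acc <- acc + l
    if (acc >= half) return(l)
  }
}

# Synonymous-site fraction of one codon by enumeration of its nine single
# mutations, translated independently with seqinr.
oracle_syn_sites <- function(codon) {
  aa <- function(x) seqinr::translate(strsplit(tolower(x), "")[[1]])
  ref <- aa(codon)
  s <- 0
  cs <- strsplit(codon, "")[[1]]
  for (p in 1:3) {
    for (b in setdiff(c("A", "C", "G", "T"), cs[p])) {
      alt <- cs
      alt[p] <- b
      if (identical(aa(paste(alt, collapse = "")), ref)) s <- s + 1 / 3
    }
  }
  s
}

# Reciprocal best hits by exhaustive double loop over the raw hit rows.
oracle_rbh <- function(hits_ab, hits_ba, cutoff = 1e-10) {
  best_of <- function(hits, q) {
    h <- hits[hits$query_id == q & hits$e_value <= cutoff, ]
    if (nrow(h) == 0) return(NA_character_)
    h <- h[order(-h$bit_score, h$e_value, -h$percent_identity, h$subject_id), ]
    h$subject_id[1]
  }
  out <- list()
  for (q in unique(hits_ab$query_id)) {
    b <- best_of(hits_ab, q)
    if (!is.na(b) && identical(best_of(hits_ba, b), q)) {
      out[[length(out) + 1]] <- c(q, b)
    }
  }
  if (length(out) == 0) {
    return(tibble::tibble(gene_a = character(0), gene_b = character(0)))
  }
  m <- do.call(rbind, out)
  tibble::tibble(gene_a = m[, 1], gene_b = m[, 2])[order(m[, 1]), ]
}

sense_codons <- function() {
  gc <- Biostrings::GENETIC_CODE
  names(gc)[gc != "*"]
}

hit_row <- function(q, s, bits, evalue = 1e-30, pid = 90) {
  tibble::tibble(query_id = q, subject_id = s, percent_identity = pid,
                 alignment_length = 100, mismatches = 5, gap_opens = 0,
                 q_start = 1, q_end = 100, s_start = 1, s_end = 100,
                 e_value = evalue, bit_score = bits)
}

random_hit_table <- function(n_q, n_s, n_hits, prefix_q, prefix_s) {
  tibble::tibble(
    query_id = paste0(prefix_q, sample.int(n_q, n_hits, replace = TRUE)),
    subject_id = paste0(prefix_s, sample.int(n_s, n_hits, replace = TRUE)),
    percent_identity = round(stats::runif(n_hits, 60, 100), 2),
    alignment_length = sample(50:500, n_hits, replace = TRUE),
    mismatches = sample(0:40, n_hits, replace = TRUE),
    gap_opens = sample(0:5, n_hits, replace = TRUE),
    q_start = 1, q_end = 100, s_start = 1, s_end = 100,
    e_value = 10^stats::runif(n_hits, -50, -5),
    bit_score = round(stats::runif(n_hits, 50, 400), 1)
  )
}
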