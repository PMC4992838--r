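test_that("reciprocal best hits require agreement in both directions", {
  ab <- hit_row("a1", "b1", bits = 200)
  ba <- hit_row("b1", "a1", bits = 190, evalue = 1e-28)
  expect_equal(reciprocal_best_hits(ab, ba),
               tibble::tibble(gene_a = "a1", gene_b = "b1"))

  # reciprocity fails when b1's best is a2
  ba2 <- dplyr::bind_rows(ba, hit_row("b1", "a2", bits = 250, evalue = 1e-40))
  expect_equal(nrow(reciprocal_best_hits(ab, ba2)), 0)

  # E-value cutoff removes hits entirely
  weak <- ab
  weak$e_value <- 1e-5
  expect_equal(nrow(reciprocal_best_hits(weak, ba)), 0)
})

test_that("RBH agrees with the brute-force oracle and ignores row order", {
  set.seed(8)
  for (i in 1:10) {
    ab <- random_hit_table(6, 6, 25, "a", "b")
    ba <- random_hit_table(6, 6, 25, "b", "a")
    got <- reciprocal_best_hits(ab, ba)
    want <- oracle_rbh(ab, ba)
    expect_equal(got$gene_a, want$gene_a)
    expect_equal(got$gene_b, want$gene_b)
    shuffled <- reciprocal_best_hits(ab[sample.int(nrow(ab)), ],
                                     ba[sample.int(nrow(ba)), ])
    expect_equal(shuffled, got)
  }
})

test_that("dot-plot points sit at gene midpoints and skip missing coordinates", {
  pairs <- tibble::tibble(gene_a = c("g1", "g2"), gene_b = c("t1", "t2"))
  ca <- tibble::tibble(gene_id = "g1", molecule = "chr1", start = 100,
                       end = 200, strand = "+")
  cb <- tibble::tibble(gene_id = c("t1", "t2"), molecule = "mt1",
                       start = c(1000, 5000), end = c(1100, 5100),
                       strand = c("+", "-"))
  expect_warning(pts <- dotplot_pairs(pairs, ca, cb), "1 pair")
  expect_equal(nrow(pts), 1)
  expect_equal(pts$x_pos, 150)
  expect_equal(pts$y_pos, 1050)
  expect_true(pts$strand_concordance)

  expect_equal(nrow(dotplot_pairs(pairs[0, ], ca, cb)), 0)

  # colinear gene sets give monotone diagonals
  n <- 30
  pairs2 <- tibble::tibble(gene_a = paste0("g", 1:n), gene_b = paste0("t", 1:n))
  ca2 <- tibble::tibble(gene_id = paste0("g", 1:n), molecule = "chr1",
                        start = (1:n) * 1000, end = (1:n) * 1000 + 500)
  cb2 <- tibble::tibble(gene_id = paste0("t", 1:n), molecule = "mt1",
                        start = (1:n) * 2000, end = (1:n) * 2000 + 500)
  pts2 <- dotplot_pairs(pairs2, ca2, cb2)
  expect_true(all(diff(pts2$y_pos[order(pts2$x_pos)]) > 0))
})

test_that("NG86 site counts match hand enumeration and stay conserved", {
  r <- ng86_ks("TTT", "TTA")
  expect_equal(r$S_sites, 0.5)
  expect_equal(r$N_sites, 2.5)
  expect_equal(r$S_diffs, 0)
  expect_equal(r$N_diffs, 1)
  expect_equal(r$Ks, 0)

  ident <- ng86_ks("ATGGCTAAA", "ATGGCTAAA")
  expect_equal(ident$S_diffs + ident$N_diffs, 0)
  expect_equal(ident$Ks, 0)
  expect_equal(ident$Ka, 0)

  set.seed(9)
  codons <- sense_codons()
  for (i in 1:40) {
    a <- paste(sample(codons, 5, TRUE), collapse = "")
    b <- paste(sample(codons, 5, TRUE), collapse = "")
    r <- ng86_ks(a, b)
    expect_equal(r$S_sites + r$N_sites, 3 * r$n_codons)
    r_sym <- ng86_ks(b, a)
    expect_equal(r_sym$S_diffs, r$S_diffs)
    expect_equal(r_sym$Ks, r$Ks)
  }
})

test_that("saturated synonymous divergence flags Ks undefined without error", {
  r <- ng86_ks("GCT", "GCA")  # 4-fold site, pS = 1
  expect_equal(r$pS, 1)
  expect_false(r$ks_defined)
  expect_true(is.na(r$Ks))
  expect_equal(r$Ka, 0)
  expect_true(is.na(jukes_cantor(0.75)))
  expect_equal(jukes_cantor(0), 0)
})

test_that("mutations at 4-fold degenerate third positions are purely synonymous", {
  set.seed(10)
  fourfold <- c("GC", "GG", "CC", "CT", "GT", "TC", "AC", "CG")
  stems <- sample(fourfold, 20, TRUE)
  third_a <- sample(c("A", "C", "G", "T"), 20, TRUE)
  third_b <- sample(c("A", "C", "G", "T"), 20, TRUE)
  a <- paste0(stems, third_a, collapse = "")
  b <- paste0(stems, third_b, collapse = "")
  r <- ng86_ks(a, b)
  expect_equal(r$N_diffs, 0)
  expect_equal(r$Ka, 0)
  expect_equal(r$S_diffs, sum(third_a != third_b))
})

test_that("gap and stop codon columns are excluded pairwise", {
  expect_warning(r <- ng86_ks("ATGTAAGCT", "ATGTACGCT"), "stop codon")
  expect_equal(r$n_codons, 2)
  r2 <- ng86_ks("ATG---GCT", "ATGCCAGCT")
  expect_equal(r2$n_codons, 2)
  expect_error(ng86_ks("ATGC", "ATGC"), "multiple of 3")
  expect_error(ng86_ks("ATG", "ATGGCT"), "length")
  expect_error(ng86_ks("---", "---"), "no comparable")
})

test_that("Ks histograms bin half-open and report proportions over retained values", {
  h <- ks_histogram(c(0.05, 0.05, 0.15), bin_width = 0.1)
  expect_equal(h$count[1:2], c(2, 1))
  expect_equal(h$proportion[1], 2 / 3)
  expect_equal(sum(h$proportion), 1)

  h2 <- ks_histogram(c(0.1, NA, 5), bin_width = 0.1, max_ks = 3)
  expect_equal(attr(h2, "n_undefined"), 1)
  expect_equal(attr(h2, "n_out_of_range"), 1)
  expect_equal(h2$count[2], 1)  # 0.1 falls in [0.1, 0.2)

  expect_error(ks_histogram(c(NA_real_, NA_real_)), "no finite")
  expect_error(ks_histogram(0.5, bin_width = 0), "positive")

  set.seed(12)
  u <- stats::runif(1e4)
  hu <- ks_histogram(u, bin_width = 0.1, max_ks = 1)
  expect_true(all(abs(hu$proportion - 0.1) < 0.02))
})

test_that("calibrated node ages scale linearly from one calibration point", {
  tr <- ape::read.tree(text = "((A:1,B:1):3,Out:4);")
  ct <- calibrate_times(tr, "A", "Out", 114.0)
  ages <- ct$node_ages
  root <- length(tr$tip.label) + 1
  expect_equal(ages$age_mya[root], 114.0)
  expect_equal(ages$age_mya[ape::getMRCA(tr, c("A", "B"))], 28.5)
  expect_equal(glance(ct)$calibration_node_age_mya, 114.0)

  # doubling all branch lengths leaves ages unchanged
  tr2 <- tr
  tr2$edge.length <- tr2$edge.length * 2
  ct2 <- calibrate_times(tr2, "A", "Out", 114.0)
  expect_equal(ct2$node_ages$age_mya, ages$age_mya)

  # child ages never exceed the parent's
  internal <- dplyr::filter(tidy(ct), !is_tip)
  expect_true(all(internal$age_mya <= ages$age_mya[root] + 1e-12))

  star <- ape::read.tree(text = "(A:2,B:2,C:2);")
  cs <- calibrate_times(star, "A", "C", 50)
  expect_equal(dplyr::filter(tidy(cs), !is_tip)$age_mya, 50)

  expect_error(calibrate_times(tr, "A", "Z", 114), "not in tree")
  zero <- ape::read.tree(text = "((A:0,B:0):0,Out:0);")
  expect_error(calibrate_times(zero, "A", "Out", 114), "zero height")
})
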