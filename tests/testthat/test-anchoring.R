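test_that("scaffolds anchor at the mean bin cM of their markers", {
  m <- toy_map()
  b <- build_bins(m)
  a <- assign_scaffolds(toy_placements(), b, m)
  expect_equal(a$scaffold_id, c("sA", "sB"))
  expect_equal(a$position_cm[a$scaffold_id == "sA"], mean(c(1, 3, 5)))
  expect_equal(a$lg, c("LG1", "LG2"))
  expect_false("sC" %in% a$scaffold_id)  # no markers -> unanchored

  bad <- toy_placements()
  bad$marker_id[1] <- "nope"
  expect_error(assign_scaffolds(bad, b, m), "unknown marker")
})

test_that("orientation follows the sign of the bp-cM rank correlation", {
  expect_equal(orient_scaffold(c(1e4, 5e4, 9e4), c(1, 3, 5)), "+")
  expect_equal(orient_scaffold(c(1e4, 5e4, 9e4), c(5, 3, 1)), "-")
  expect_equal(orient_scaffold(1e4, 5), "?")
  expect_equal(orient_scaffold(c(1e4, 2e4), c(3, 3)), "?")
  expect_error(orient_scaffold(numeric(0), numeric(0)), "no markers")

  # antisymmetry: reversing physical coordinates flips the call
  set.seed(4)
  for (i in 1:20) {
    bp <- sort(sample.int(1e5, 6))
    cm <- sort(round(stats::runif(6, 0, 10), 2))
    fwd <- orient_scaffold(bp, cm)
    rev <- orient_scaffold(max(bp) - bp + 1, cm)
    expect_equal(rev, switch(fwd, "+" = "-", "-" = "+", "?" = "?"))
  }
})

test_that("multi-LG scaffolds are chimeric with a midpoint breakpoint", {
  m <- tibble::tibble(marker_id = c("x1", "x2"), lg = c("LG1", "LG5"),
                      cm = c(2, 30))
  pl <- tibble::tibble(marker_id = c("x1", "x2"), scaffold_id = "s",
                       pos_bp = c(10000L, 90000L))
  a <- assign_scaffolds(pl, build_bins(m), m)
  ch <- detect_chimeras(a)
  expect_equal(ch$reason, "multi_lg")
  expect_equal(ch$breakpoints_bp[[1]], 50000)
  expect_equal(ch$piece_ids[[1]], c("s.1", "s.2"))
})

test_that("large within-group cM jumps split a scaffold (derived case)", {
  m <- tibble::tibble(marker_id = paste0("y", 1:4), lg = "LG1",
                      cm = c(3, 4, 60, 60))
  pl <- tibble::tibble(marker_id = paste0("y", 1:4), scaffold_id = "s",
                       pos_bp = c(10000L, 20000L, 80000L, 90000L))
  a <- assign_scaffolds(pl, build_bins(m), m)
  ch <- detect_chimeras(a, max_intra_lg_gap_cm = 20)
  expect_equal(ch$reason, "intra_lg_gap")
  expect_equal(ch$breakpoints_bp[[1]], 50000)
  expect_equal(ch$n_pieces, 2L)

  # all markers in one bin: not chimeric
  m1 <- tibble::tibble(marker_id = c("z1", "z2"), lg = "LG1", cm = c(5, 5))
  pl1 <- tibble::tibble(marker_id = c("z1", "z2"), scaffold_id = "s",
                        pos_bp = c(100L, 900L))
  expect_equal(nrow(detect_chimeras(assign_scaffolds(pl1, build_bins(m1), m1))), 0)
})

test_that("splitting tiles the sequence and remaps placements", {
  seqs <- tibble::tibble(id = "s", seq = paste(rep("ACGTTGCA", 25), collapse = ""))
  ch <- tibble::tibble(scaffold_id = "s", reason = "multi_lg", n_pieces = 2L,
                       breakpoints_bp = list(40), piece_ids = list(c("s.1", "s.2")))
  pl <- tibble::tibble(marker_id = c("m1", "m2"), scaffold_id = "s",
                       pos_bp = c(40L, 41L))
  out <- split_scaffolds(seqs, ch, pl)
  expect_equal(nchar(out$seqs$seq), c(40, 160))
  expect_equal(paste(out$seqs$seq, collapse = ""), seqs$seq)
  expect_equal(out$placements$scaffold_id, c("s.1", "s.2"))
  expect_equal(out$placements$pos_bp, c(40L, 1L))

  # two breakpoints -> three pieces conserving length
  ch3 <- tibble::tibble(scaffold_id = "s", reason = "multi_lg", n_pieces = 3L,
                        breakpoints_bp = list(c(50, 120)),
                        piece_ids = list(paste0("s.", 1:3)))
  out3 <- split_scaffolds(seqs, ch3)
  expect_equal(sum(nchar(out3$seqs$seq)), 200)

  # no chimeras: identity
  none <- detect_chimeras(tibble::tibble(scaffold_id = character(0),
                                         markers = list())[0, ])
  expect_identical(split_scaffolds(seqs, none)$seqs, seqs)

  # breakpoint at/past the end is a hard error
  bad <- ch
  bad$breakpoints_bp <- list(200)
  expect_error(split_scaffolds(seqs, bad), "breakpoint outside")
})

test_that("ordering sorts by cM then descending length then id, deterministically", {
  anchors <- tibble::tibble(
    scaffold_id = c("b", "a", "c"), lg = "LG1",
    position_cm = c(2, 5, 5), orientation = "+")
  seqs <- tibble::tibble(id = c("a", "b", "c"),
                         seq = c(strrep("A", 10), strrep("A", 5), strrep("A", 50)))
  o <- order_scaffolds(anchors, seqs)
  expect_equal(o$scaffold_id, c("b", "c", "a"))
  expect_equal(o$lg_rank, 1:3)
  o2 <- order_scaffolds(anchors[c(3, 1, 2), ], seqs)
  expect_equal(o2$scaffold_id, o$scaffold_id)
})

test_that("anchoring accounting matches the split arithmetic", {
  expect_equal(anchoring_accounting(1505, 158, 355), 1702)
  expect_equal(anchoring_accounting(10, 0, 0), 10)
  expect_equal(anchoring_accounting(10, 2, 5), 13)
  expect_error(anchoring_accounting(5, 6, 12), "exceeds")
  expect_error(anchoring_accounting(10, 2, 3), "at least 2 pieces")
  expect_error(anchoring_accounting(10, 0, 3), "pieces without splits")
})

test_that("anchored base count is conserved through splitting", {
  ds <- small_sim(seed = 21)
  run <- run_pipeline(ds$scaffolds, ds$marker_map, ds$placements)
  before <- sum(nchar(ds$scaffolds$seq))
  after <- sum(nchar(run$scaffolds$seq))
  expect_equal(after, before)
  expect_equal(run$tallies$n_anchored_after, nrow(run$anchors))
})
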