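test_that("simulation is a deterministic function of the seed", {
  a <- small_sim(seed = 31)
  b <- small_sim(seed = 31)
  expect_identical(a$scaffolds, b$scaffolds)
  expect_identical(a$marker_map, b$marker_map)
  expect_identical(a$placements, b$placements)
  expect_identical(a$truth, b$truth)
  c <- small_sim(seed = 32)
  expect_false(identical(a$scaffolds$seq, c$scaffolds$seq))
})

test_that("truth intervals tile each chromosome and rebuild it exactly", {
  ds <- small_sim(seed = 33)
  tp <- ds$truth$scaffolds
  for (chrom in unique(tp$chromosome)) {
    iv <- tp[tp$chromosome == chrom, ]
    iv <- iv[order(iv$start), ]
    expect_equal(iv$start[1], 1)
    expect_equal(iv$start[-1], iv$end[-nrow(iv)] + 1)
  }
  # reconstructing one chromosome from scaffold pieces matches base counts
  chrom1 <- tp[tp$chromosome == "chr1", ]
  expect_equal(sum(chrom1$end - chrom1$start + 1),
               ds$config$chromosome_length_bp)
})

test_that("placements point at real scaffold positions carrying the marker map", {
  ds <- small_sim(seed = 34)
  expect_silent(validate_placements(ds$placements, ds$scaffolds, ds$marker_map))
  expect_setequal(ds$placements$marker_id, ds$marker_map$marker_id)
})

test_that("inversion and chimera rates land near their configured values", {
  ds <- simulate_genome(sim_config(seed = 35, n_chromosomes = 4,
                                   chromosome_length_bp = 1e6,
                                   mean_scaffold_bp = 2e4))
  tp <- ds$truth$scaffolds
  expect_gt(mean(tp$strand == "-"), 0.05)
  expect_lt(mean(tp$strand == "-"), 0.17)
  n_chim <- length(unique(tp$scaffold_id[tp$is_chimera]))
  expect_gt(n_chim, 0)
  chim_parts <- tp[tp$is_chimera, ]
  by_scaffold <- split(chim_parts$chromosome, chim_parts$scaffold_id)
  expect_true(all(vapply(by_scaffold, function(x) length(unique(x)) == 2,
                         logical(1))))
})

test_that("the noiseless pipeline recovers truth exactly", {
  ds <- small_sim(seed = 36)
  run <- run_pipeline(ds$scaffolds, ds$marker_map, ds$placements)
  m <- evaluate_recovery(run, ds$truth)
  expect_equal(m$orientation_accuracy, 1.0)
  expect_equal(m$chimera_sensitivity, 1.0)
  expect_equal(m$chimera_precision, 1.0)
  expect_equal(m$order_spearman_min, 1.0)
  expect_true(all(run$chimeras$reason == "multi_lg"))
})

test_that("recovery metrics flag empty denominators as undefined", {
  ds <- simulate_genome(sim_config(seed = 37, n_chromosomes = 2,
                                   chromosome_length_bp = 3e5,
                                   mean_scaffold_bp = 3e4,
                                   p_chimera = 0, p_invert = 0))
  run <- run_pipeline(ds$scaffolds, ds$marker_map, ds$placements)
  m <- evaluate_recovery(run, ds$truth)
  expect_true(is.na(m$chimera_sensitivity))
  expect_true(is.na(m$chimera_precision))
})

test_that("a shuffled scaffold order scores near-zero Spearman", {
  ds <- simulate_genome(sim_config(seed = 38, n_chromosomes = 1,
                                   chromosome_length_bp = 3e6,
                                   mean_scaffold_bp = 4e4,
                                   p_chimera = 0, p_invert = 0))
  run <- run_pipeline(ds$scaffolds, ds$marker_map, ds$placements)
  expect_gte(nrow(run$ordered), 50)
  set.seed(39)
  run$ordered$lg_rank <- sample(run$ordered$lg_rank)
  m <- evaluate_recovery(run, ds$truth)
  expect_lt(abs(m$order_spearman_min), 0.2)
})

test_that("simulated k-mer histograms peak at the modal Poisson depth", {
  h <- simulate_kmer_histogram(2e5, 20.5, error_rate = 0, seed = 40)
  expect_equal(h$depth[which.max(h$count)], 20)
  h_err <- simulate_kmer_histogram(2e5, 20.5, error_rate = 0.05, seed = 40)
  expect_gt(h_err$count[h_err$depth == 1], max(h_err$count[h_err$depth > 5]))
  expect_error(simulate_kmer_histogram(2e5, 0), "positive")
})

test_that("datasets round trip through their on-disk representation", {
  ds <- simulate_genome(sim_config(seed = 41, n_chromosomes = 2,
                                   chromosome_length_bp = 2e5,
                                   mean_scaffold_bp = 2e4))
  dir <- withr::local_tempdir()
  write_sim_dataset(ds, dir)
  expect_equal(read_fasta(file.path(dir, "scaffolds.fa")), ds$scaffolds)
  expect_equal(read_marker_map(file.path(dir, "map.tsv")), ds$marker_map)
  expect_equal(read_placements(file.path(dir, "placements.tsv")), ds$placements)
  prov <- jsonlite::read_json(file.path(dir, "provenance.json"))
  expect_equal(prov$seed, 41)
})
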