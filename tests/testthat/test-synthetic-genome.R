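test_that("generate_genome plants retrievable, TSD-flanked elements", {
  cfg <- generator_config(genome_length = 60000, families = list(
    family_spec(clade_label = "A", copy_count = 3,
                divergence_waves = list(c(0, 1)), truncation_prob = 0)),
    seed = 3, min_spacing = 3000)
  sim <- generate_genome(cfg)
  expect_equal(nrow(sim$truth), 3)
  expect_false(any(sim$truth$truncated))
  g <- as.character(sim$genome[[1]])
  for (i in seq_len(3)) {
    tr <- sim$truth[i, ]
    expect_equal(tr$end - tr$start, 2500)
    el <- substr(g, tr$start + 1, tr$end)
    expect_equal(nchar(el), 2500)
    # TTAA immediately outside both ends
    expect_equal(substr(g, tr$start - 3, tr$start), "TTAA")
    expect_equal(substr(g, tr$end + 1, tr$end + 4), "TTAA")
    # master copies: perfect TIRs at the ends (on the genome strand the
    # element's outer edges are reverse complements regardless of strand)
    expect_equal(substr(el, 1, tr$tir_length),
                 revcomp_chr(substr(el, 2500 - tr$tir_length + 1, 2500)))
  }
})

test_that("element interiors carry a single long ORF with the clade triad", {
  cfg <- generator_config(genome_length = 30000, families = list(
    family_spec(clade_label = "B", copy_count = 1)), seed = 5)
  sim <- generate_genome(cfg)
  tr <- sim$truth[1, ]
  el <- as.character(Biostrings::subseq(sim$genome[[tr$contig]],
                                        tr$start + 1, tr$end))
  if (tr$strand == "-") el <- revcomp_chr(el)
  orf <- find_longest_orf(el)
  expect_equal(orf$length_aa, 580)
  expect_equal(orf$strand, "+")
  scan <- scan_domains(orf$protein, clade = "B")
  expect_true(scan$triad_intact)
  expect_true(scan$crd_regular)
})

test_that("truncation removes one TIR and its TSD", {
  cfg <- generator_config(genome_length = 60000, families = list(
    family_spec(clade_label = "A", copy_count = 4, truncation_prob = 1)),
    seed = 11, min_spacing = 3000)
  sim <- generate_genome(cfg)
  expect_true(all(sim$truth$truncated))
  g <- as.character(sim$genome[[1]])
  for (i in seq_len(nrow(sim$truth))) {
    tr <- sim$truth[i, ]
    expect_lt(tr$end - tr$start, 2500)           # at least 20% lost
    expect_lte(tr$end - tr$start, ceiling(0.8 * 2500))
    lf <- substr(g, tr$start - 3, tr$start)
    rf <- substr(g, tr$end + 1, tr$end + 4)
    # exactly one surviving TSD (the lost end lost its TSD too)
    expect_equal(sum(c(lf, rf) == "TTAA"), 1)
  }
})

test_that("fixed seed reproduces the genome byte-for-byte", {
  cfg <- generator_config(genome_length = 20000, families = list(
    family_spec(copy_count = 2)), seed = 42)
  s1 <- generate_genome(cfg)
  s2 <- generate_genome(cfg)
  expect_identical(as.character(s1$genome), as.character(s2$genome))
  expect_identical(s1$truth, s2$truth)
  cfg2 <- generator_config(genome_length = 20000, families = list(
    family_spec(copy_count = 2)), seed = 43)
  s3 <- generate_genome(cfg2)
  expect_false(identical(as.character(s1$genome), as.character(s3$genome)))
  expect_identical(names(s1$truth), names(s3$truth))
})

test_that("generator validates its configuration", {
  expect_error(family_spec(divergence_waves = list(c(0, 0.5))), "sum to 1")
  expect_error(family_spec(element_length = 1000), "too small")
  expect_error(generator_config(genome_length = 5000), "genome_length")
  # genome too small to place copies at spacing
  cfg <- generator_config(genome_length = 12000, families = list(
    family_spec(copy_count = 5)), seed = 1, min_spacing = 5000)
  expect_error(generate_genome(cfg), "too small")
})

test_that("mutate_copy honours target divergence and limits", {
  seq <- random_dna(2500, 0.4)
  expect_identical(mutate_copy(seq, 0), seq)
  # pure-transition limit: no transversions
  m <- mutate_copy(seq, 30, ts_tv_ratio = Inf, seed = 1)
  sc <- count_substitutions(m, seq)
  expect_gt(sc$transitions, 0)
  expect_equal(sc$transversions, 0)
  expect_error(mutate_copy(seq, 200), "saturation")
})

test_that("measured K2P of mutated copies is unbiased for target_K", {
  set.seed(101)
  master <- random_dna(2500, 0.4)
  for (target in c(5, 10)) {
    K <- replicate(25, {
      m <- mutate_copy(master, target)
      sc <- count_substitutions(m, master)
      kimura_distance(sc$P, sc$Q)
    })
    expect_lt(abs(mean(K) - target), 1.5)
  }
})

test_that("write_simulation emits the documented text artifacts", {
  cfg <- generator_config(genome_length = 20000, families = list(
    family_spec(copy_count = 1)), seed = 2)
  sim <- generate_genome(cfg)
  d <- withr::local_tempdir()
  write_simulation(sim, d)
  expect_true(all(file.exists(file.path(d,
    c("genome.fa", "truth.tsv", "truth.bed", "config.json")))))
  tr <- read.delim(file.path(d, "truth.tsv"))
  expect_equal(tr$start1, tr$start + 1)
  bed <- read.delim(file.path(d, "truth.bed"), header = FALSE)
  expect_equal(bed$V2, sim$truth$start)   # BED stays 0-based
})
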