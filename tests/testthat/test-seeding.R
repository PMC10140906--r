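test_that("six_frame_translate produces correct frames and coordinates", {
  fr <- six_frame_translate("ATGAAA")
  expect_equal(fr$peptide[fr$frame == "+0"], "MK")
  fr2 <- six_frame_translate("TTTCAT")
  expect_equal(fr2$peptide[fr2$frame == "-0"], "MK")
  # peptide lengths are floor((L - f)/3) in every frame
  set.seed(1)
  s <- random_dna(3001, 0.5)
  fr3 <- six_frame_translate(s)
  expect_equal(nchar(fr3$peptide), (3001 - fr3$offset) %/% 3)
  # coordinate maps invert exactly: translating the mapped interval
  # reproduces the peptide slice
  for (fi in seq_len(nrow(fr3))) {
    gi <- frame_to_genome(11, 20, fr3$strand[fi], fr3$offset[fi], 3001)
    sub <- substr(s, gi[1] + 1, gi[2])
    if (fr3$strand[fi] == "-") sub <- revcomp_chr(sub)
    expect_equal(
      as.character(suppressWarnings(Biostrings::translate(
        Biostrings::DNAString(sub), if.fuzzy.codon = "solve"))),
      substr(fr3$peptide[fi], 11, 20))
  }
  # N translates to X
  expect_match(six_frame_translate("ATGNNNAAA")$peptide[1], "^MXK$")
})

test_that("protein_search finds planted transposases on either strand", {
  cfg <- generator_config(genome_length = 50000, families = list(
    family_spec(clade_label = "C", copy_count = 2)), seed = 21)
  sim <- generate_genome(cfg)
  hits <- protein_search(sim$genome)
  expect_gt(nrow(hits), 0)
  for (i in seq_len(nrow(sim$truth))) {
    tr <- sim$truth[i, ]
    ov <- hits$contig == tr$contig & hits$start < tr$end & hits$end > tr$start
    expect_true(any(ov))
    expect_equal(hits$ref_clade[ov][which.max(hits$score[ov])], "C")
  }
})

test_that("protein_search scores agree with the Smith-Waterman oracle", {
  set.seed(7)
  B62 <- get_blosum62()
  refs <- pb_reference_proteins("refs")[1:2]
  ref1 <- as.character(refs[[1]])
  # coding region for a diverged variant of ref1 inside a short contig
  variant <- mutate_protein(ref1, 0.2)
  cds <- pbmine:::reverse_translate(variant)
  genome <- c(ctg = paste0(random_dna(300, 0.4), cds, random_dna(300, 0.4)))
  hits <- protein_search(genome, refs, min_score = 100)
  expect_gt(nrow(hits), 0)
  best <- hits[which.max(hits$score), ]
  # oracle: full SW of the reference against the whole translated frame
  fr <- six_frame_translate(genome[[1]])
  pep <- fr$peptide[fr$frame == best$frame]
  expect_equal(best$score,
               oracle_sw_score(as.character(refs[[best$ref_id]]), pep, B62))
})

test_that("no hits on dinucleotide-shuffled sequence at the default score", {
  set.seed(33)
  cfg <- generator_config(genome_length = 100000, families = list(
    family_spec(copy_count = 2)), seed = 5)
  sim <- generate_genome(cfg)
  v <- strsplit(as.character(sim$genome[[1]]), "")[[1]]
  n2 <- length(v) %/% 2
  di <- paste0(v[seq(1, 2 * n2, 2)], v[seq(2, 2 * n2, 2)])
  for (r in 1:2) {
    shuf <- c(shuf = paste(sample(di), collapse = ""))
    expect_equal(nrow(protein_search(shuf)), 0)
  }
})

test_that("lowering min_score never removes a hit; shuffled strand symmetry", {
  cfg <- generator_config(genome_length = 40000, families = list(
    family_spec(copy_count = 1)), seed = 9)
  sim <- generate_genome(cfg)
  h_hi <- protein_search(sim$genome, min_score = 400)
  h_lo <- protein_search(sim$genome, min_score = 150)
  key <- function(h) paste(h$contig, h$start, h$end, h$ref_id)
  expect_true(all(key(h_hi) %in% key(h_lo)))
  # reverse-complementing the genome mirrors every hit with equal score
  L <- Biostrings::width(sim$genome)[1]
  rc <- setNames(as.character(Biostrings::reverseComplement(sim$genome[[1]])),
                 names(sim$genome)[1])
  h_rc <- protein_search(rc, min_score = 150)
  expect_equal(nrow(h_rc), nrow(h_lo))
  mirrored <- data.frame(start = L - h_rc$end, end = L - h_rc$start,
                         score = h_rc$score)
  mirrored <- mirrored[order(mirrored$start, mirrored$end, mirrored$score), ]
  orig <- h_lo[order(h_lo$start, h_lo$end, h_lo$score), c("start", "end", "score")]
  expect_equal(mirrored$start, orig$start)
  expect_equal(mirrored$end, orig$end)
  expect_equal(mirrored$score, orig$score)
})

test_that("build_loci extends, clips and merges per the published flank", {
  cl <- c(ctgA = 100000L)
  h <- data.frame(contig = "ctgA", start = 5000L, end = 6000L, strand = "+",
                  frame = "+0", score = 500, ref_id = "r", ref_clade = "A",
                  ref_cov = 1, stringsAsFactors = FALSE)
  lc <- build_loci(h, cl, flank = 2000)
  expect_equal(c(lc$start, lc$end), c(3000L, 8000L))
  # clipped at the contig start
  h2 <- h; h2$start <- 500L; h2$end <- 900L
  lc2 <- build_loci(h2, cl, flank = 2000)
  expect_equal(c(lc2$start, lc2$end), c(0L, 2900L))
  # two hits 3500 bp apart merge under a 2000 bp flank
  h3 <- rbind(h, within(h, { start <- 9500L; end <- 10500L }))
  lc3 <- build_loci(h3, cl, flank = 2000)
  expect_equal(nrow(lc3), 1)
  expect_equal(c(lc3$start, lc3$end), c(3000L, 12500L))
  expect_equal(lc3$n_hits, 2)
  # empty input
  expect_equal(nrow(build_loci(h[0, ], cl)), 0)
})
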