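test_that("find_tir_pairs recovers a planted perfect pair", {
  set.seed(2)
  arm <- "CACTATTGACGTGCA"                    # 15 bp
  core <- random_dna(200, 0.5)
  locus <- paste0(strrep("N", 20), arm, core, revcomp_chr(arm), strrep("N", 20))
  p <- find_tir_pairs(locus, min_len = 10, max_mismatch = 0)
  expect_equal(nrow(p), 1)
  expect_equal(p$arm_length, 15)
  expect_equal(p$mismatches, 0)
  expect_equal(p$left_start, 20)
  expect_equal(p$right_end, 20 + 15 + 200 + 15)
})

test_that("homopolymer loci yield no pairs", {
  p <- find_tir_pairs(strrep("A", 300), min_len = 10, max_mismatch = 2)
  expect_equal(nrow(p), 0)
})

test_that("find_tir_pairs equals the exhaustive enumeration oracle", {
  set.seed(17)
  for (r in 1:25) {
    n <- sample(60:220, 1)
    seq <- random_dna(n, runif(1, 0.3, 0.6))
    # occasionally plant a pair so non-trivial cases are covered
    if (r %% 3 == 0) {
      arm <- random_dna(sample(10:14, 1), 0.5)
      seq <- paste0(substr(seq, 1, 5), arm,
                    substr(seq, 6 + nchar(arm), n - nchar(arm) - 5),
                    revcomp_chr(arm), substr(seq, n - 4, n))
    }
    mm <- sample(0:2, 1)
    got <- find_tir_pairs(seq, min_len = 8, max_len = 500, max_mismatch = mm)
    want <- oracle_tir_pairs(seq, min_len = 8, max_len = 500, max_mismatch = mm)
    expect_equal(nrow(got), nrow(want), info = sprintf("rep %d", r))
    if (nrow(got)) {
      expect_equal(got$left_start, want$left_start, info = sprintf("rep %d", r))
      expect_equal(got$right_start, want$right_start, info = sprintf("rep %d", r))
      expect_equal(got$arm_length, want$arm_length, info = sprintf("rep %d", r))
      expect_equal(got$mismatches, want$mismatches, info = sprintf("rep %d", r))
    }
  }
})

test_that("reverse-complement symmetry of pair finding", {
  set.seed(5)
  arm <- "GCACTATTGACGT"
  locus <- paste0(random_dna(30, 0.5), arm, random_dna(150, 0.5),
                  revcomp_chr(arm), random_dna(30, 0.5))
  n <- nchar(locus)
  p1 <- find_tir_pairs(locus, min_len = 10, max_mismatch = 1)
  p2 <- find_tir_pairs(revcomp_chr(locus), min_len = 10, max_mismatch = 1)
  expect_equal(nrow(p1), nrow(p2))
  # mirrored coordinates: left arm of the mirror is the mirrored right arm
  m_left <- sort(n - p2$right_end)
  expect_equal(sort(p1$left_start), m_left)
  expect_equal(sort(p1$arm_length), sort(p2$arm_length))
})

test_that("select_element prefers canonical TSDs, then equal flanks", {
  px <- make_planted_locus()
  pairs <- find_tir_pairs(px$locus, min_len = 10, max_mismatch = 2)
  bnd <- select_element(pairs, px$locus)
  expect_equal(bnd$start, px$el_start)
  expect_equal(bnd$end, px$el_end)
  expect_true(bnd$tsd_canonical)
  expect_equal(bnd$tsd_left, "TTAA")
  expect_equal(bnd$tir_length, nchar(px$tir))

  # two candidate pairs, only the shorter flanked by TTAA -> TTAA wins
  set.seed(31)
  armA <- "CCGGATCCGGTAGCATT"                 # 17 bp, flanked by GGGG
  armB <- "CACTATACCG"                        # 10 bp, flanked by TTAA
  locus <- paste0(random_dna(40, 0.5),
                  "GGGG", armA, random_dna(60, 0.5), revcomp_chr(armA), "GGGG",
                  random_dna(40, 0.5),
                  "TTAA", armB, random_dna(60, 0.5), revcomp_chr(armB), "TTAA",
                  random_dna(40, 0.5))
  pairs <- find_tir_pairs(locus, min_len = 8, max_mismatch = 0,
                          search_window = nchar(locus))
  bnd <- select_element(pairs, locus)
  expect_true(bnd$tsd_canonical)
  expect_equal(bnd$tir_length, 10)

  # equal non-canonical flanks are accepted and flagged
  locus2 <- paste0(random_dna(40, 0.5),
                   "TTGA", armA, random_dna(60, 0.5), revcomp_chr(armA), "TTGA",
                   random_dna(40, 0.5))
  pairs2 <- find_tir_pairs(locus2, min_len = 8, max_mismatch = 0,
                           search_window = nchar(locus2))
  bnd2 <- select_element(pairs2, locus2)
  expect_false(is.null(bnd2))
  expect_false(bnd2$tsd_canonical)
  expect_equal(bnd2$tsd_left, "TTGA")
  expect_equal(bnd2$tsd_right, "TTGA")
})

test_that("select_element returns NULL without matching flanks", {
  set.seed(8)
  arm <- "CCGGATCCGGTAGCATT"
  locus <- paste0(random_dna(40, 0.5), "ACGT", arm, random_dna(60, 0.5),
                  revcomp_chr(arm), "TGCA", random_dna(40, 0.5))
  pairs <- find_tir_pairs(locus, min_len = 8, max_mismatch = 0,
                          search_window = nchar(locus))
  # flanks unequal and non-canonical everywhere with overwhelming likelihood
  bnd <- select_element(pairs, locus)
  if (!is.null(bnd)) expect_true(bnd$tsd_canonical || bnd$tsd_left == bnd$tsd_right)
})
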