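test_that("pairwise_identity matches arithmetic and the DP oracle", {
  set.seed(14)
  p <- random_protein(100)
  expect_equal(pairwise_identity(p, p), 100)
  q <- p; substr(q, 50, 50) <- if (substr(p, 50, 50) == "A") "C" else "A"
  expect_equal(pairwise_identity(p, q), 99)
  # substitution-only pairs align gaplessly: identity equals the direct
  # per-position count, and the NW score equals the DP oracle
  B62 <- get_blosum62()
  for (r in 1:5) {
    a <- random_protein(60)
    b <- mutate_protein(a, 0.25)
    expect_equal(pairwise_identity(a, b),
                 100 * mean(strsplit(a, "")[[1]] == strsplit(b, "")[[1]]))
  }
  # indel pairs: compare the alignment *score* against the oracle (identity
  # can differ between co-optimal alignments; the score cannot)
  for (r in 1:4) {
    a <- random_protein(50)
    b <- paste0(substr(a, 1, 20), substr(a, 26, 50))  # 5-aa deletion
    pa <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(a), Biostrings::AAString(b),
      substitutionMatrix = B62, gapOpening = 11, gapExtension = 1,
      type = "global")
    expect_equal(Biostrings::score(pa), oracle_nw_score(a, b, B62))
  }
})

test_that("identity_matrix is symmetric with a 100 diagonal", {
  set.seed(15)
  seqs <- setNames(replicate(4, random_protein(60)), paste0("s", 1:4))
  im <- identity_matrix(seqs, clades = c("A", "A", "B", "B"))
  expect_equal(diag(im$matrix), setNames(rep(100, 4), names(seqs)))
  expect_lt(max(abs(im$matrix - t(im$matrix))), 1e-9)
  # consistent with the scalar implementation
  expect_equal(im$matrix["s1", "s2"], pairwise_identity(seqs[1], seqs[2]))
})

test_that("identity_summary separates within and between clades", {
  seqs <- c(a1 = "AAAAAAAAAAAAAAAAAAAAWWWWW", a2 = "AAAAAAAAAAAAAAAAAAAAWWWWW",
            b1 = "CCCCCCCCCCCCCCCCCCCCWWWWW", b2 = "CCCCCCCCCCCCCCCCCCCCWWWWW")
  im <- identity_matrix(seqs, clades = c("A", "A", "B", "B"))
  s <- identity_summary(im)
  expect_equal(unname(s$within), c(100, 100))
  expect_equal(s$between_mean, im$matrix["a1", "b1"])
  # clade-structured random proteins: within mean exceeds between mean
  set.seed(16)
  base <- list(A = random_protein(80), B = random_protein(80))
  seqs2 <- c(lapply(1:3, function(i) mutate_protein(base$A, 0.1)),
             lapply(1:3, function(i) mutate_protein(base$B, 0.1)))
  names(seqs2) <- paste0("t", 1:6)
  im2 <- identity_matrix(unlist(seqs2), clades = rep(c("A", "B"), each = 3))
  s2 <- identity_summary(im2)
  expect_gt(s2$within_mean, s2$between_mean)
  # singleton clade: within mean absent
  im3 <- identity_matrix(unlist(seqs2)[1:4], clades = c("A", "A", "A", "B"))
  s3 <- identity_summary(im3)
  expect_true(is.na(s3$within["B"]))
})

random_additive_tree <- function(n) {
  tr <- ape::rtree(n, rooted = FALSE)
  tr$edge.length <- runif(nrow(tr$edge), 0.05, 1)
  tr
}

test_that("nj_tree recovers additive trees exactly", {
  # 3 taxa: closed-form branch lengths
  d <- matrix(c(0, 5, 9, 5, 0, 10, 9, 10, 0), 3,
              dimnames = list(c("x", "y", "z"), c("x", "y", "z")))
  tr <- nj_tree(d)
  expect_s3_class(tr, "phylo")
  bl <- setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(bl[["x"]], (5 + 9 - 10) / 2)
  expect_equal(bl[["y"]], (5 + 10 - 9) / 2)
  expect_equal(bl[["z"]], (9 + 10 - 5) / 2)
  # 4-taxon additive matrix from a known tree topology
  true4 <- ape::read.tree(text = "((a:1,b:2):1,(c:1.5,d:1):1);")
  d4 <- cophenetic(true4)
  tr4 <- nj_tree(d4)
  expect_equal(as.numeric(ape::dist.topo(ape::unroot(true4), tr4)), 0)
  # property: random additive trees up to 12 leaves are recovered, and the
  # topology agrees with an established NJ implementation
  set.seed(18)
  for (r in 1:10) {
    tt <- random_additive_tree(sample(5:12, 1))
    dd <- cophenetic(tt)
    got <- nj_tree(dd)
    expect_equal(as.numeric(ape::dist.topo(ape::unroot(tt), got)), 0)
    ref <- ape::nj(dd)
    expect_equal(as.numeric(ape::dist.topo(ref, got)), 0)
  }
})

test_that("nj_tree handles duplicates and rejects bad input", {
  d <- matrix(c(0, 0, 4, 0, 0, 4, 4, 4, 0), 3,
              dimnames = list(c("p", "q", "r"), c("p", "q", "r")))
  tr <- nj_tree(d)
  bl <- setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(bl[["p"]], 0)
  expect_equal(bl[["q"]], 0)
  bad <- matrix(c(0, 1, 2, 0), 2, 2)
  expect_error(nj_tree(rbind(cbind(bad, 1), c(1, 4, 0))), "symmetric")
})

test_that("assign_clades recovers generator clades and flags ambiguity", {
  set.seed(20)
  base <- list(A = random_protein(90), B = random_protein(90), C = random_protein(90))
  refs <- list(); queries <- list()
  for (cl in names(base)) {
    for (k in 1:2) refs[[paste0("ref", cl, k)]] <- mutate_protein(base[[cl]], 0.1)
    for (k in 1:3) queries[[paste0("q", cl, k)]] <- mutate_protein(base[[cl]], 0.1)
  }
  og_base <- random_protein(90)
  og <- setNames(lapply(1:3, function(i) mutate_protein(og_base, 0.1)), paste0("og", 1:3))
  allp <- c(unlist(refs), unlist(queries), unlist(og))
  im <- identity_matrix(allp, clades = rep("x", length(allp)))
  d <- (100 - im$matrix) / 100
  tr <- nj_tree(d)
  ref_clades <- setNames(rep(c("A", "B", "C"), each = 2), names(refs))
  got <- assign_clades(tr, ref_clades, outgroup = names(og))
  want <- setNames(rep(c("A", "B", "C"), each = 3), names(queries))
  expect_equal(got[names(want)], want)
  # a query identical to a reference inherits its clade
  expect_error(assign_clades(tr, ref_clades, outgroup = "nope"), "outgroup")
})

test_that("tir_logo frequencies, information content and padding", {
  tirs <- rep("CACTATACCG", 5)
  lg <- tir_logo(tirs)
  expect_equal(lg$consensus, "CACTATACCG")
  expect_equal(lg$ic, rep(2, 10))
  expect_equal(colSums(lg$freq), rep(1, 10))
  # a uniform column has IC 0
  lg2 <- tir_logo(c("A", "C", "G", "T"))
  expect_equal(lg2$ic, 0)
  # right-padding is flagged and excluded from frequencies
  lg3 <- tir_logo(c("CACTA", "CAC"))
  expect_equal(lg3$n_padded, 1)
  expect_equal(colSums(lg3$freq), rep(1, 5))
  expect_error(tir_logo("CACTA"), "at least 2")
  # CACTA-prefixed TIRs with 10% noise: first five consensus calls read CACTA
  set.seed(22)
  cons <- paste0("CACTA", random_dna(9, 0.5))
  noisy <- vapply(1:40, function(i) mutate_dna_subs(cons, 0.1), "")
  lg4 <- tir_logo(noisy)
  expect_equal(substr(lg4$consensus, 1, 5), "CACTA")
  expect_true(all(lg4$ic >= 0 & lg4$ic <= 2))
})
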