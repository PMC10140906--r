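# Independent oracle implementations used to cross-check the package's
# alignment and TIR-search machinery.  These are deliberately written from
# the textbook definitions, not shared with the package code paths.

.AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

random_protein <- function(n) paste(sample(.AA20, n, replace = TRUE), collapse = "")

mutate_protein <- function(p, rate) {
  v <- strsplit(p, "")[[1]]
  hit <- which(runif(length(v)) < rate)
  for (i in hit) v[i] <- sample(setdiff(.AA20, v[i]), 1)
  paste(v, collapse = "")
}

mutate_dna_subs <- function(s, rate) {
  v <- strsplit(s, "")[[1]]
  hit <- which(runif(length(v)) < rate)
  for (i in hit) v[i] <- sample(setdiff(c("A", "C", "G", "T"), v[i]), 1)
  paste(v, collapse = "")
}

get_blosum62 <- function() {
  e <- new.env(); utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
}

# ---- affine-gap dynamic programming oracles -------------------------------
# Gap of length L costs go + L*ge (the Biostrings convention).
# Row-wise DP; the E (horizontal) recursion uses the running-max identity
# E[i,j] = max_{k<j} H[i,k] - go - (j-k)*ge = cummax(H[i,k] + k*ge) - go - j*ge.

oracle_sw_score <- function(a, b, mat, go = 11, ge = 1) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  H <- matrix(0, n + 1, m + 1)
  E <- matrix(-Inf, n + 1, m + 1)   # gap in pattern a (horizontal)
  F <- matrix(-Inf, n + 1, m + 1)   # gap in subject b (vertical)
  for (i in 2:(n + 1)) {
    srow <- mat[av[i - 1], bv]
    for (j in 2:(m + 1)) {
      E[i, j] <- max(E[i, j - 1] - ge, H[i, j - 1] - go - ge)
      F[i, j] <- max(F[i - 1, j] - ge, H[i - 1, j] - go - ge)
      H[i, j] <- max(0, H[i - 1, j - 1] + srow[j - 1], E[i, j], F[i, j])
    }
  }
  max(H)
}

oracle_nw_score <- function(a, b, mat, go = 11, ge = 1) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  NEG <- -1e18
  H <- matrix(NEG, n + 1, m + 1)
  E <- matrix(NEG, n + 1, m + 1)
  F <- matrix(NEG, n + 1, m + 1)
  H[1, 1] <- 0
  for (j in 2:(m + 1)) { E[1, j] <- -go - (j - 1) * ge; H[1, j] <- E[1, j] }
  for (i in 2:(n + 1)) { F[i, 1] <- -go - (i - 1) * ge; H[i, 1] <- F[i, 1] }
  for (i in 2:(n + 1)) {
    srow <- mat[av[i - 1], bv]
    for (j in 2:(m + 1)) {
      E[i, j] <- max(E[i, j - 1] - ge, H[i, j - 1] - go - ge)
      F[i, j] <- max(F[i - 1, j] - ge, H[i - 1, j] - go - ge)
      H[i, j] <- max(H[i - 1, j - 1] + srow[j - 1], E[i, j], F[i, j])
    }
  }
  H[n + 1, m + 1]
}

# ---- TIR maximal-pair enumeration oracle ----------------------------------
# Enumerates maximal inverted-repeat arm pairs by scanning anti-diagonals:
# positions a (left arm) pair with D - a (right arm).  For each candidate
# left-start the inner extent is grown greedily under the mismatch budget;
# the window is kept only if it cannot be extended outward either.
oracle_tir_pairs <- function(seq, min_len = 10, max_len = 500,
                             max_mismatch = 2, search_window = NULL) {
  s <- strsplit(toupper(seq), "")[[1]]
  n <- length(s)
  W <- if (is.null(search_window)) max(round(0.45 * n), min_len) else search_window
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  is_match <- function(a, b)   # 0-based positions
    !is.na(comp[s[a + 1]]) && !is.na(s[b + 1]) && comp[[s[a + 1]]] == s[b + 1]
  res <- list()
  for (D in 1:(2 * n - 3)) {            # D = a + b, 0-based positions
    lo <- max(0, D - (n - 1))
    hi <- (D - 1) %/% 2                 # a < b strictly
    if (hi < lo) next
    a0 <- lo
    while (a0 <= hi) {
      # greedy inner extension from a0
      mm <- 0L; a1 <- a0 - 1L
      while (a1 + 1 <= hi && a1 - a0 + 1 < max_len) {
        add <- !is_match(a1 + 1, D - (a1 + 1))
        if (add && mm + 1 > max_mismatch) break
        a1 <- a1 + 1L; mm <- mm + add
      }
      L <- a1 - a0 + 1
      if (L >= 1) {
        # outward extension: position a0-1 paired with D-(a0-1)
        ext_out <- a0 - 1 >= lo && L + 1 <= max_len &&
          (is_match(a0 - 1, D - (a0 - 1)) || mm + 1 <= max_mismatch)
        i <- a0; j <- D - a1
        if (!ext_out && L >= min_len &&
            i <= W - 1 && j >= n - W && j <= n - 1)
          res[[length(res) + 1L]] <- c(i = i, j = j, L = L, mm = mm)
      }
      a0 <- a0 + 1L
    }
  }
  if (!length(res))
    return(data.frame(left_start = integer(), right_start = integer(),
                      arm_length = integer(), mismatches = integer()))
  m <- do.call(rbind, res)
  out <- data.frame(left_start = m[, "i"], right_start = m[, "j"],
                    arm_length = m[, "L"], mismatches = m[, "mm"])
  out[order(out$left_start, out$right_start), ]
}

# canonical element fixture: TIR + spacer + CDS + spacer + revcomp TIR,
# flanked by TSDs inside a random locus
make_planted_locus <- function(tir = "CACTATACCGGTAC", core_len = 800,
                               flank = 300, tsd = "TTAA", seed = 99) {
  set.seed(seed)
  core <- pbmine::random_dna(core_len, 0.4)
  # break complementarity just inside the TIRs so the planted arm length
  # is exact (mirrors the generator's behaviour)
  comp1 <- pbmine::revcomp_chr(substr(core, core_len, core_len))
  if (substr(core, 1, 1) == comp1)
    substr(core, 1, 1) <- setdiff(c("A", "C", "G", "T"), comp1)[1]
  el <- paste0(tir, core, pbmine::revcomp_chr(tir))
  lf <- pbmine::random_dna(flank, 0.4)
  rf <- pbmine::random_dna(flank, 0.4)
  list(locus = paste0(lf, tsd, el, tsd, rf),
       el_start = flank + 4, el_end = flank + 4 + nchar(el),
       element = el, tir = tir)
}
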