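#' Global percent identity between two proteins
#'
#' Needleman-Wunsch global alignment with BLOSUM62 and affine gaps;
#' identity is matches divided by all alignment columns (gap columns
#' included) times 100 -- the stricter of the common conventions.
#'
#' @param a,b aa character scalars (>= 20 aa)
#' @return percent identity in `[0, 100]`
#' @export
pairwise_identity <- function(a, b) {
  a <- toupper(as.character(a)); b <- toupper(as.character(b))
  stopifnot(nchar(a) >= 20, nchar(b) >= 20)
  pa <- Biostrings::pairwiseAlignment(Biostrings::AAString(a),
                                      Biostrings::AAString(b),
                                      substitutionMatrix = blosum62(),
                                      gapOpening = 11, gapExtension = 1,
                                      type = "global")
  x <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
  y <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
  100 * sum(x == y & x != "-") / length(x)
}

#' Pairwise identity matrix for a labeled protein set
#'
#' @param seqs named character vector (or AAStringSet) of proteins
#' @param clades clade label per sequence (same order)
#' @return list of class `pb_identity_matrix`: labels, matrix (symmetric,
#'   diagonal 100), clades
#' @export
identity_matrix <- function(seqs, clades) {
  seqs <- vapply(as.list(seqs), function(x) toupper(as.character(x)), "")
  n <- length(seqs)
  stopifnot(length(clades) == n, n >= 2)
  labels <- names(seqs) %||% paste0("seq", seq_len(n))
  m <- matrix(100, n, n, dimnames = list(labels, labels))
  # one vectorised alignment call per column; identity = matches over all
  # alignment columns, identical to pairwise_identity()
  aset <- Biostrings::AAStringSet(seqs)
  for (j in 2:n) {
    pa <- Biostrings::pairwiseAlignment(aset[1:(j - 1)], aset[[j]],
                                        substitutionMatrix = blosum62(),
                                        gapOpening = 11, gapExtension = 1,
                                        type = "global")
    v <- 100 * Biostrings::nmatch(pa) /
      Biostrings::width(Biostrings::alignedPattern(pa))
    m[1:(j - 1), j] <- v
    m[j, 1:(j - 1)] <- v
  }
  structure(list(labels = labels, matrix = m, clades = clades),
            class = "pb_identity_matrix")
}

#' Within- and between-clade mean identities
#'
#' Within-clade means exclude the diagonal; the between-clade mean is over
#' all cross-clade pairs.  Singleton clades have no within mean and are
#' reported as NA.
#'
#' @param im a `pb_identity_matrix`
#' @return list of class `pb_identity_summary`: within (named per clade),
#'   within_mean, between_mean, pair_means (clade x clade matrix of mean
#'   identities, the Fig-6-style heat map values)
#' @export
identity_summary <- function(im) {
  stopifnot(inherits(im, "pb_identity_matrix"))
  cl <- im$clades
  u <- sort(unique(cl))
  m <- im$matrix
  pair_means <- matrix(NA_real_, length(u), length(u), dimnames = list(u, u))
  within <- setNames(rep(NA_real_, length(u)), u)
  for (a in u) for (b in u) {
    ia <- which(cl == a); ib <- which(cl == b)
    if (a == b) {
      if (length(ia) >= 2) {
        v <- m[ia, ia][upper.tri(m[ia, ia])]
        pair_means[a, a] <- mean(v)
        within[a] <- mean(v)
      }
    } else {
      pair_means[a, b] <- mean(m[ia, ib])
    }
  }
  cross <- pair_means[upper.tri(pair_means)]
  structure(list(within = within,
                 within_mean = if (all(is.na(within))) NA_real_
                               else mean(within, na.rm = TRUE),
                 between_mean = if (length(u) < 2) NA_real_ else mean(cross),
                 pair_means = pair_means),
            class = "pb_identity_summary")
}

#' Neighbor-joining tree from a distance matrix
#'
#' A from-scratch implementation of the Saitou-Nei neighbor-joining
#' agglomeration.  For an additive distance matrix the generating tree is
#' recovered exactly.  Negative branch lengths (possible on non-additive
#' input) are clamped to zero and counted in the `clamped` attribute.
#'
#' @param d symmetric numeric matrix with zero diagonal and row/col names
#' @return an [ape::phylo] unrooted tree
#' @export
nj_tree <- function(d) {
  if (!is.matrix(d) || nrow(d) != ncol(d)) stop("d must be a square matrix")
  if (max(abs(d - t(d))) > 1e-8) stop("distance matrix must be symmetric")
  if (any(diag(d) != 0)) stop("distance matrix must have a zero diagonal")
  n <- nrow(d)
  labels <- rownames(d) %||% paste0("t", seq_len(n))
  if (n < 3) stop("need at least 3 taxa")
  clamped <- 0L
  clamp <- function(x) {
    if (x < -1e-12) clamped <<- clamped + 1L
    max(x, 0)
  }
  D <- d
  sub <- labels                    # newick fragment per active node
  while (length(sub) > 3) {
    m <- nrow(D)
    r <- rowSums(D)
    Q <- (m - 2) * D - outer(r, r, "+")
    diag(Q) <- Inf
    ij <- which(Q == min(Q), arr.ind = TRUE)[1, ]
    i <- min(ij); j <- max(ij)
    dij <- D[i, j]
    li <- clamp(0.5 * dij + (r[i] - r[j]) / (2 * (m - 2)))
    lj <- clamp(dij - (0.5 * dij + (r[i] - r[j]) / (2 * (m - 2))))
    newsub <- sprintf("(%s:%.10g,%s:%.10g)", sub[i], li, sub[j], lj)
    others <- setdiff(seq_len(m), c(i, j))
    newd <- 0.5 * (D[i, others] + D[j, others] - dij)
    D <- rbind(cbind(D[others, others, drop = FALSE], newd),
               c(newd, 0))
    sub <- c(sub[others], newsub)
  }
  # final three nodes: exact three-point formulas around the central node
  dxy <- D[1, 2]; dxz <- D[1, 3]; dyz <- D[2, 3]
  lx <- clamp((dxy + dxz - dyz) / 2)
  ly <- clamp((dxy + dyz - dxz) / 2)
  lz <- clamp((dxz + dyz - dxy) / 2)
  nwk <- sprintf("(%s:%.10g,%s:%.10g,%s:%.10g);", sub[1], lx, sub[2], ly, sub[3], lz)
  tr <- ape::read.tree(text = nwk)
  attr(tr, "clamped") <- clamped
  tr
}

#' Assign query leaves to reference-defined clades
#'
#' The tree is rooted on the outgroup leaves; each query leaf inherits the
#' clade of the smallest rooted cluster that contains it together with at
#' least one reference, provided all references in that cluster share one
#' clade; otherwise the query is "unassigned".
#'
#' @param tree an [ape::phylo] tree
#' @param reference_clades named character vector: clade per reference
#'   leaf label (outgroup leaves excluded)
#' @param outgroup character vector of outgroup leaf labels present in the
#'   tree
#' @return named character vector: clade (or "unassigned") per query leaf
#' @export
assign_clades <- function(tree, reference_clades, outgroup) {
  stopifnot(inherits(tree, "phylo"))
  if (!length(reference_clades)) stop("no reference labels supplied")
  og <- intersect(outgroup, tree$tip.label)
  if (!length(og)) stop("no outgroup leaves present for rooting")
  rt <- tryCatch(ape::root(tree, outgroup = og, resolve.root = TRUE),
                 error = function(e)   # non-monophyletic outgroup: root on one leaf
                   ape::root(tree, outgroup = og[1], resolve.root = TRUE))
  tips <- rt$tip.label
  n <- length(tips)
  refs <- intersect(names(reference_clades), tips)
  queries <- setdiff(tips, c(refs, og))
  if (!length(queries)) return(setNames(character(0), character(0)))
  # leaves under each node, built bottom-up over the postorder edge list
  parent <- integer(n + rt$Nnode)
  for (k in seq_len(nrow(rt$edge))) parent[rt$edge[k, 2]] <- rt$edge[k, 1]
  desc <- vector("list", n + rt$Nnode)
  for (tip in seq_len(n)) desc[[tip]] <- tip
  ed <- ape::reorder.phylo(rt, "postorder")$edge
  for (k in seq_len(nrow(ed)))
    desc[[ed[k, 1]]] <- c(desc[[ed[k, 1]]], desc[[ed[k, 2]]])
  out <- setNames(rep("unassigned", length(queries)), queries)
  ref_idx <- match(refs, tips)
  for (q in queries) {
    nd <- match(q, tips)
    repeat {
      nd <- parent[nd]
      if (nd == 0) break
      here_refs <- intersect(desc[[nd]], ref_idx)
      if (length(here_refs)) {
        cl <- unique(reference_clades[tips[here_refs]])
        if (length(cl) == 1) out[q] <- unname(cl)
        break
      }
    }
  }
  out
}

#' Position frequency matrix and information content of aligned TIRs
#'
#' TIRs are left-anchored (the TIR start is the element edge); shorter
#' TIRs are right-padded and the padding is excluded from the column
#' frequencies.  Information content per column is 2 + sum f log2 f bits,
#' in `[0, 2]`.
#'
#' @param tirs character vector of TIR sequences (n >= 2)
#' @return list of class `pb_tir_logo`: freq (4 x width), ic, consensus,
#'   n, n_padded
#' @export
tir_logo <- function(tirs) {
  tirs <- toupper(vapply(as.list(tirs), as.character, ""))
  if (length(tirs) < 2) stop("need at least 2 TIRs")
  w <- max(nchar(tirs))
  n_padded <- sum(nchar(tirs) < w)
  mat <- matrix(NA_character_, length(tirs), w)
  for (i in seq_along(tirs)) {
    s <- strsplit(tirs[i], "")[[1]]
    mat[i, seq_along(s)] <- s
  }
  freq <- matrix(0, 4, w, dimnames = list(BASES, NULL))
  ic <- numeric(w)
  cons <- character(w)
  for (j in seq_len(w)) {
    col <- mat[, j]
    col <- col[!is.na(col) & col %in% BASES]
    f <- table(factor(col, levels = BASES)) / length(col)
    freq[, j] <- as.numeric(f)
    nz <- freq[, j][freq[, j] > 0]
    ic[j] <- 2 + sum(nz * log2(nz))
    cons[j] <- BASES[which.max(freq[, j])]
  }
  structure(list(freq = freq, ic = ic, consensus = paste(cons, collapse = ""),
                 n = length(tirs), n_padded = n_padded),
            class = "pb_tir_logo")
}
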