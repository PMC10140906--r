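#' Six-frame translation with exact coordinate maps
#'
#' Translates the three forward and three reverse-complement frames of a
#' DNA sequence.  Stop codons are rendered as `*`; codons containing N
#' translate to `X`.  Frame labels are `+0,+1,+2,-0,-1,-2`, where the
#' offset is counted from the 5' end of the translated strand.
#'
#' @param dna character scalar or [Biostrings::DNAString]
#' @return a data.frame with columns `frame`, `strand`, `offset`, `peptide`
#'   (one row per frame).  Use [frame_to_genome()] to map peptide positions
#'   back to genomic intervals.
#' @export
six_frame_translate <- function(dna) {
  d <- if (is(dna, "DNAString")) dna else Biostrings::DNAString(as.character(dna))
  L <- length(d)
  rc <- Biostrings::reverseComplement(d)
  rows <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") d else rc
    for (f in 0:2) {
      n_codon <- max((L - f) %/% 3, 0)
      pep <- if (n_codon == 0) "" else
        as.character(suppressWarnings(Biostrings::translate(
          Biostrings::subseq(s, f + 1, f + 3 * n_codon),
          if.fuzzy.codon = "solve")))
      rows[[length(rows) + 1L]] <- data.frame(
        frame = paste0(strand, f), strand = strand, offset = f,
        peptide = pep, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Map peptide positions of a translation frame to a genomic interval
#'
#' @param aa_start,aa_end 1-based closed peptide positions
#' @param strand "+" or "-"
#' @param offset frame offset 0..2 on the translated strand
#' @param L length of the source DNA
#' @return integer c(start, end), 0-based half-open genomic coordinates
#' @export
frame_to_genome <- function(aa_start, aa_end, strand, offset, L) {
  if (strand == "+") {
    c(offset + 3 * (aa_start - 1), offset + 3 * aa_end)
  } else {
    c(L - offset - 3 * aa_end, L - offset - 3 * (aa_start - 1))
  }
}

# all k-mers of a protein set -> data.frame(kmer, ref, rpos)
ref_kmer_index <- function(refs, k) {
  out <- lapply(seq_along(refs), function(i) {
    s <- as.character(refs[[i]])
    n <- nchar(s)
    if (n < k) return(NULL)
    data.frame(kmer = substring(s, 1:(n - k + 1), k:n),
               ref = names(refs)[i], rpos = 1:(n - k + 1),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

# greedy clustering of seeds on nearby diagonals; returns a list of index
# vectors into the input order
cluster_seeds <- function(ppos, diag, band = 16, gap = 400) {
  o <- order(diag, ppos)
  d <- diag[o]; p <- ppos[o]
  cur <- 0L
  cl <- integer(length(o))
  for (i in seq_along(o)) {
    if (i == 1 || d[i] - d[i - 1] > band || abs(p[i] - p[i - 1]) > gap)
      cur <- cur + 1L
    cl[i] <- cur
  }
  split(o, cl)
}

#' Translated homology search for transposase-coding regions
#'
#' A seed-and-extend re-implementation of a translated (TBLASTN-style)
#' search: each of the six translation frames is scanned for exact
#' `seed_k`-mer matches to the reference proteins; seeds clustered on a
#' diagonal band are extended by a Smith-Waterman local alignment
#' (BLOSUM62, affine gaps) of the reference against the surrounding
#' peptide window, and alignments scoring at least `min_score` are
#' reported as hits.  The default `min_score` was calibrated once on
#' dinucleotide-shuffled sequence so that the empirical false-positive
#' rate on shuffles is zero (see the methods vignette); it plays the role
#' of the tool-specific e-value cutoff used in the original protocol.
#'
#' @param genome DNAStringSet, FASTA path, or named character vector
#' @param refs AAStringSet of reference proteins (default: the bundled
#'   clade references)
#' @param min_score minimum local-alignment raw score
#' @param seed_k protein seed word size
#' @param min_seeds minimum seeds per diagonal cluster before extension
#' @param gap_opening,gap_extension affine gap penalties
#' @return data.frame of class `pb_seed_hits`: one row per hit with
#'   contig, start, end (0-based half-open), strand, frame, score, ref_id,
#'   ref_clade, ref_cov (fraction of the reference covered)
#' @export
protein_search <- function(genome, refs = pb_reference_proteins("refs"),
                           min_score = 150, seed_k = 5, min_seeds = 2,
                           gap_opening = 11, gap_extension = 1) {
  genome <- as_dnastringset(genome)
  if (length(refs) == 0) stop("refs must be non-empty")
  clades <- S4Vectors::mcols(refs)$clade %||% rep("reference", length(refs))
  names(clades) <- names(refs)
  B62 <- blosum62()
  kidx <- ref_kmer_index(refs, seed_k)
  hits <- list()
  for (ci in seq_along(genome)) {
    contig <- names(genome)[ci]
    L <- Biostrings::width(genome)[ci]
    frames <- six_frame_translate(genome[[ci]])
    for (fi in seq_len(nrow(frames))) {
      pep <- frames$peptide[fi]
      np <- nchar(pep)
      if (np < seed_k) next
      pk <- substring(pep, 1:(np - seed_k + 1), seed_k:np)
      m <- which(pk %in% kidx$kmer)
      if (!length(m)) next
      seed_df <- merge(data.frame(kmer = pk[m], ppos = m, stringsAsFactors = FALSE),
                       kidx, by = "kmer")
      for (rid in unique(seed_df$ref)) {
        sd <- seed_df[seed_df$ref == rid, ]
        rlen <- nchar(as.character(refs[[rid]]))
        cls <- cluster_seeds(sd$ppos, sd$ppos - sd$rpos,
                             band = 16, gap = max(400, rlen))
        for (ii in cls) {
          if (length(ii) < min_seeds) next
          cl <- sd[ii, , drop = FALSE]
          dg <- cl$ppos - cl$rpos            # projected ref start per seed
          w0 <- max(1, min(dg) + 1 - 30)
          w1 <- min(np, max(dg) + rlen + 30)
          sub <- substr(pep, w0, w1)
          pa <- Biostrings::pairwiseAlignment(
            Biostrings::AAString(as.character(refs[[rid]])),
            Biostrings::AAString(sub),
            substitutionMatrix = B62, gapOpening = gap_opening,
            gapExtension = gap_extension, type = "local")
          sc <- Biostrings::score(pa)
          if (sc < min_score) next
          s_aa <- w0 + Biostrings::start(Biostrings::subject(pa)) - 1
          e_aa <- w0 + Biostrings::end(Biostrings::subject(pa)) - 1
          gi <- frame_to_genome(s_aa, e_aa, frames$strand[fi], frames$offset[fi], L)
          rcov <- (Biostrings::end(Biostrings::pattern(pa)) -
                   Biostrings::start(Biostrings::pattern(pa)) + 1) / rlen
          hits[[length(hits) + 1L]] <- data.frame(
            contig = contig, start = gi[1], end = gi[2],
            strand = frames$strand[fi], frame = frames$frame[fi],
            score = sc, ref_id = rid,
            ref_clade = unname(clades[rid]), ref_cov = rcov,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (!length(hits)) {
    out <- data.frame(contig = character(), start = integer(), end = integer(),
                      strand = character(), frame = character(),
                      score = numeric(), ref_id = character(),
                      ref_clade = character(), ref_cov = numeric(),
                      stringsAsFactors = FALSE)
  } else {
    out <- do.call(rbind, hits)
    # deduplicate identical genomic intervals, keeping the best score
    out <- out[order(out$contig, out$start, out$end, -out$score), , drop = FALSE]
    key <- paste(out$contig, out$start, out$end)
    out <- out[!duplicated(key), , drop = FALSE]
    out <- out[order(out$contig, out$start), , drop = FALSE]
    rownames(out) <- NULL
  }
  class(out) <- c("pb_seed_hits", "data.frame")
  out
}

#' Merge flank-extended hits into candidate loci
#'
#' Each hit interval is extended by `flank` bp on both sides (clipped at
#' contig bounds); extended intervals that overlap on the same contig are
#' merged into one candidate locus.
#'
#' @param hits a `pb_seed_hits` data.frame from [protein_search()]
#' @param contig_lengths named integer vector of contig lengths
#' @param flank extension in bp (default 2000, the published value)
#' @return data.frame of class `pb_loci`: contig, start, end, n_hits,
#'   best_ref, best_clade, best_score
#' @export
build_loci <- function(hits, contig_lengths, flank = 2000) {
  if (nrow(hits) == 0)
    return(structure(data.frame(contig = character(), start = integer(),
                                end = integer(), n_hits = integer(),
                                best_ref = character(), best_clade = character(),
                                best_score = numeric(), stringsAsFactors = FALSE),
                     class = c("pb_loci", "data.frame")))
  out <- list()
  for (ctg in unique(hits$contig)) {
    h <- hits[hits$contig == ctg, , drop = FALSE]
    L <- contig_lengths[[ctg]]
    if (is.null(L)) stop("no length for contig ", ctg)
    ext <- IRanges::IRanges(pmax(h$start - flank, 0) + 1,
                            pmin(h$end + flank, L))   # 1-based closed for IRanges
    red <- IRanges::reduce(ext)
    ov <- IRanges::findOverlaps(ext, red)
    grp <- S4Vectors::subjectHits(ov)[order(S4Vectors::queryHits(ov))]
    for (g in seq_along(red)) {
      hh <- h[grp == g, , drop = FALSE]
      b <- which.max(hh$score)
      out[[length(out) + 1L]] <- data.frame(
        contig = ctg, start = IRanges::start(red)[g] - 1L,
        end = IRanges::end(red)[g], n_hits = nrow(hh),
        best_ref = hh$ref_id[b], best_clade = hh$ref_clade[b],
        best_score = hh$score[b], stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, out)
  out <- out[order(out$contig, out$start), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("pb_loci", "data.frame")
  out
}
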