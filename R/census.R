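#' Seed-and-extend nucleotide search for genomic copies of a query
#'
#' Re-implements the BLASTN step used to census transposon copies: exact
#' `word`-size matches between the query and the genome (both strands) are
#' clustered on diagonal bands and extended with a local alignment; each
#' hit carries percent identity (matches / alignment columns, gap columns
#' included) and query coverage (aligned query bases / query length).
#' Hits overlapping a higher-scoring hit by more than half their length
#' are suppressed so each genomic copy is counted once.
#'
#' @param query DNA character scalar (>= 100 bp)
#' @param genome DNAStringSet / FASTA path / character vector
#' @param word nucleotide seed size
#' @param min_cluster minimum seeds per diagonal cluster before extension
#' @param min_seed_bp minimum distinct query bp covered by a cluster's
#'   seeds before extension; scattered chance seeds rarely exceed a few
#'   words, while genuine copies (even 25\% diverged or truncated) seed
#'   hundreds of bp
#' @param min_score minimum local alignment score (match +1, mismatch -2,
#'   gap open 5, gap extend 2)
#' @param query_id label stored with each hit
#' @return data.frame of class `pb_copy_hits`: contig, start, end
#'   (0-based half-open), strand, percent_identity, query_coverage, score,
#'   query_id
#' @export
search_copies <- function(query, genome, word = 11, min_cluster = 3,
                          min_seed_bp = 60, min_score = 50,
                          query_id = "query") {
  query <- toupper(as.character(query))
  qlen <- nchar(query)
  stopifnot(qlen >= 100)
  genome <- as_dnastringset(genome)
  submat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -2,
                                                     baseOnly = FALSE)
  qd <- Biostrings::DNAString(query)
  pd <- Biostrings::PDict(Biostrings::DNAStringSet(
    substring(query, 1:(qlen - word + 1), word:qlen)))
  hits <- list()
  for (ci in seq_along(genome)) {
    contig <- names(genome)[ci]
    L <- Biostrings::width(genome)[ci]
    for (strand in c("+", "-")) {
      subject <- if (strand == "+") genome[[ci]] else
        Biostrings::reverseComplement(genome[[ci]])
      mt <- Biostrings::matchPDict(pd, subject)
      st <- Biostrings::startIndex(mt)
      qpos <- rep(seq_along(st), lengths(st))
      gpos <- unlist(st)
      if (!length(gpos)) next
      cls <- cluster_seeds(gpos, gpos - qpos, band = 2 * word, gap = qlen)
      for (ii in cls) {
        if (length(ii) < min_cluster) next
        cov_bp <- sum(IRanges::width(IRanges::reduce(
          IRanges::IRanges(qpos[ii], width = word))))
        if (cov_bp < min_seed_bp) next
        dg <- gpos[ii] - qpos[ii]            # projected copy start per seed
        w0 <- max(1, min(dg) + 1 - 100)
        w1 <- min(L, max(dg) + qlen + 100)
        pa <- Biostrings::pairwiseAlignment(
          qd, Biostrings::subseq(subject, w0, w1),
          substitutionMatrix = submat, gapOpening = 5, gapExtension = 2,
          type = "local")
        sc <- Biostrings::score(pa)
        if (sc < min_score) next
        ap <- as.character(Biostrings::alignedPattern(pa))
        as_ <- as.character(Biostrings::alignedSubject(pa))
        cols <- nchar(ap)
        matches <- sum(strsplit(ap, "")[[1]] == strsplit(as_, "")[[1]] &
                       strsplit(ap, "")[[1]] != "-")
        pident <- 100 * matches / cols
        qcov <- 100 * (Biostrings::end(Biostrings::pattern(pa)) -
                       Biostrings::start(Biostrings::pattern(pa)) + 1) / qlen
        s0 <- w0 + Biostrings::start(Biostrings::subject(pa)) - 1  # 1-based on strand
        e0 <- w0 + Biostrings::end(Biostrings::subject(pa))        # half-open
        if (strand == "+") {
          gs <- s0 - 1L; ge <- e0 - 1L
        } else {
          gs <- L - (e0 - 1L); ge <- L - (s0 - 1L)
        }
        hits[[length(hits) + 1L]] <- data.frame(
          contig = contig, start = gs, end = ge, strand = strand,
          percent_identity = pident, query_coverage = qcov, score = sc,
          query_id = query_id, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(hits)) {
    out <- data.frame(contig = character(), start = integer(), end = integer(),
                      strand = character(), percent_identity = numeric(),
                      query_coverage = numeric(), score = numeric(),
                      query_id = character(), stringsAsFactors = FALSE)
    class(out) <- c("pb_copy_hits", "data.frame")
    return(out)
  }
  out <- do.call(rbind, hits)
  # one copy, one count: suppress hits overlapping a better hit by > 50%
  out <- out[order(-out$score), , drop = FALSE]
  keep <- rep(TRUE, nrow(out))
  for (i in seq_len(nrow(out))) {
    if (!keep[i]) next
    if (i == 1) next
    prev <- which(keep[seq_len(i - 1)])
    same <- prev[out$contig[prev] == out$contig[i]]
    if (!length(same)) next
    ov <- pmax(0, pmin(out$end[same], out$end[i]) - pmax(out$start[same], out$start[i]))
    if (any(ov > 0.5 * (out$end[i] - out$start[i]))) keep[i] <- FALSE
  }
  out <- out[keep, , drop = FALSE]
  out <- out[order(out$contig, out$start), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("pb_copy_hits", "data.frame")
  out
}

#' Census family copies at the published thresholds
#'
#' A hit is counted iff query coverage exceeds `min_cov` AND percent
#' identity exceeds `min_ident` (both strictly, per the published "> 40%"
#' and "> 80%").  Counted hits with a detectable TIR+TSD boundary are
#' *full*; full hits whose transposase ORF is at least 500 aa are
#' *intact*.
#'
#' @param hits a `pb_copy_hits` data.frame
#' @param boundaries logical vector per hit: TIR+TSD detectable (or a list
#'   of `pb_element_boundary`/NULL); NULL means none detectable
#' @param orfs numeric vector per hit: transposase aa (NA/0 = none), or a
#'   list of `pb_orf`/NULL
#' @param min_cov,min_ident strict thresholds in percent
#' @param min_intact_aa intact transposase floor in aa
#' @param family family label for the report
#' @return list of class `pb_family_census`: family, total_hits, counted,
#'   full_copies, intact_copies, counted_idx
#' @export
census <- function(hits, boundaries = NULL, orfs = NULL,
                   min_cov = 40, min_ident = 80, min_intact_aa = 500,
                   family = "family") {
  n <- nrow(hits)
  det <- if (is.null(boundaries)) rep(FALSE, n)
         else if (is.list(boundaries)) !vapply(boundaries, is.null, TRUE)
         else as.logical(boundaries)
  aa <- if (is.null(orfs)) rep(0, n)
        else if (is.list(orfs)) vapply(orfs, function(o) if (is.null(o)) 0 else o$length_aa, 0)
        else { x <- as.numeric(orfs); x[is.na(x)] <- 0; x }
  counted <- hits$query_coverage > min_cov & hits$percent_identity > min_ident
  full <- counted & det
  intact <- full & aa >= min_intact_aa
  structure(list(family = family, total_hits = n, counted = sum(counted),
                 full_copies = sum(full), intact_copies = sum(intact),
                 counted_idx = which(counted)),
            class = "pb_family_census")
}

#' @export
print.pb_family_census <- function(x, ...) {
  cat(sprintf("pb_family_census [%s]: %d hits, %d counted, %d full, %d intact\n",
              x$family, x$total_hits, x$counted, x$full_copies, x$intact_copies))
  invisible(x)
}

#' Majority-rule consensus over a star alignment of copies
#'
#' Each copy is globally aligned to the representative; per representative
#' column, the majority symbol over all copies (including gaps) is taken,
#' ties resolved toward the representative's base, and gap-majority
#' columns dropped.  Insertions relative to the representative are
#' ignored, which is adequate at the substitution-dominated divergences
#' (<= 20%) this pipeline targets.
#'
#' @param copies character vector / DNAStringSet of copy sequences (>= 2)
#' @param representative the star centre (defaults to the longest copy)
#' @return consensus DNA character scalar
#' @export
build_consensus <- function(copies, representative = NULL) {
  copies <- vapply(as.list(copies), function(x) toupper(as.character(x)), "")
  stopifnot(length(copies) >= 2)
  if (is.null(representative)) representative <- copies[which.max(nchar(copies))]
  representative <- toupper(as.character(representative))
  rl <- nchar(representative)
  submat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -2,
                                                     baseOnly = FALSE)
  counts <- matrix(0L, nrow = 5, ncol = rl,
                   dimnames = list(c("A", "C", "G", "T", "-"), NULL))
  rs <- Biostrings::DNAString(representative)
  for (cp in copies) {
    pa <- Biostrings::pairwiseAlignment(Biostrings::DNAString(cp), rs,
                                        substitutionMatrix = submat,
                                        gapOpening = 5, gapExtension = 2,
                                        type = "global")
    ap <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
    as_ <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
    si <- 0L
    for (col in seq_along(as_)) {
      if (as_[col] == "-") next
      si <- si + 1L
      b <- ap[col]
      if (!b %in% rownames(counts)) next
      counts[b, si] <- counts[b, si] + 1L
    }
  }
  rep_base <- strsplit(representative, "")[[1]]
  out <- character(rl)
  for (j in seq_len(rl)) {
    mx <- max(counts[, j])
    top <- rownames(counts)[counts[, j] == mx]
    pick <- if (rep_base[j] %in% top) rep_base[j] else top[1]
    out[j] <- pick
  }
  paste(out[out != "-"], collapse = "")
}
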