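dna_codes <- function(seq) {
  v <- utf8ToInt(toupper(seq))
  code <- rep(-1L, 128)
  code[utf8ToInt("A")] <- 0L; code[utf8ToInt("C")] <- 1L
  code[utf8ToInt("G")] <- 2L; code[utf8ToInt("T")] <- 3L
  code[v]
}

#' Find maximal TIR arm pairs in a candidate locus
#'
#' Scans a locus for pairs of intervals whose sequences are reverse
#' complements of each other up to a mismatch budget: the signature of a
#' terminal-inverted-repeat pair.  Only maximal pairs are reported: a pair
#' extendable by one base (inward or outward) within the budget and the
#' `max_len` cap is reported only at its extended length.  Arm starts must
#' fall within `search_window` bp of the respective locus edge, reflecting
#' that candidate loci carry ~2 kb flanks around a seeded transposase, so
#' true TIRs lie near the ends.
#'
#' @param locus_seq DNA character scalar (or DNAString)
#' @param min_len,max_len arm length bounds in bp; the 10/500 defaults
#'   cover the short (~14 bp) and long (200-500 bp) TIR regimes
#' @param max_mismatch allowed mismatches between the left arm and the
#'   reverse complement of the right arm
#' @param search_window bp from each locus end within which an arm must
#'   start; default 45\% of the locus length (see the methods vignette for
#'   why this is wider than a bare flank)
#' @return data.frame of class `pb_tir_pairs` with 0-based half-open arm
#'   intervals: left_start, left_end, right_start, right_end, arm_length,
#'   mismatches, arm_identity
#' @export
find_tir_pairs <- function(locus_seq, min_len = 10, max_len = 500,
                           max_mismatch = 2, search_window = NULL) {
  seq <- toupper(as.character(locus_seq))
  n <- nchar(seq)
  if (n < 2 * min_len) stop("locus shorter than twice min_len")
  W <- as.integer(search_window %||% max(round(0.45 * n), min_len))
  codes <- dna_codes(seq)
  m <- .tir_scan_cpp(codes,
                     0L, W - 1L,
                     max(n - W, 0L), n - 1L,
                     as.integer(min_len), as.integer(max_len),
                     as.integer(max_mismatch))
  out <- data.frame(left_start = m[, "i"], left_end = m[, "i"] + m[, "L"],
                    right_start = m[, "j"], right_end = m[, "j"] + m[, "L"],
                    arm_length = m[, "L"], mismatches = m[, "mm"],
                    stringsAsFactors = FALSE)
  out$arm_identity <- 100 * (out$arm_length - out$mismatches) / out$arm_length
  out <- out[order(out$left_start, out$right_start), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("pb_tir_pairs", "data.frame")
  out
}

#' Select the element boundary among candidate TIR pairs
#'
#' Ranks TIR pairs by their flanking 4-mers (putative TSDs) and arm
#' quality:
#' 1. both flanks equal to the canonical motif (TTAA for piggyBac);
#' 2. both flanks equal to each other (a mutated, non-canonical TSD);
#' 3. longer arm; 4. fewer mismatches; 5. leftmost start.
#'
#' Because TTAA is its own reverse complement, the true inverted repeat of
#' a canonical piggyBac insertion extends through the TSDs (and sometimes
#' into the flank), so a maximal pair typically overshoots the element
#' edge by a few bases.  Each pair is therefore also considered at outer
#' trims of 1..`trim_max` bp (both arms shortened at their outer ends,
#' mismatches recounted), and all trimmed variants compete under the same
#' ranking; ties between variants prefer the longer (less-trimmed) arm.
#' Pairs whose flanking 4-mers are unreadable (too close to the locus
#' edge) are skipped.  Returns `NULL` when no variant has matching flanks.
#'
#' @param pairs result of [find_tir_pairs()] on the same locus
#' @param locus_seq the locus sequence
#' @param tsd_motif canonical TSD 4-mer
#' @param trim_max maximum outer trim in bp
#' @param min_arm minimum arm length a trimmed variant may have
#' @return one-row data.frame of class `pb_element_boundary` with the
#'   element interval (outer TIR edges, 0-based half-open, locus
#'   coordinates), TIR geometry, TSDs and a `tsd_canonical` flag, or NULL
#' @export
select_element <- function(pairs, locus_seq, tsd_motif = "TTAA",
                           trim_max = 10, min_arm = 5) {
  seq <- toupper(as.character(locus_seq))
  n <- nchar(seq)
  if (nrow(pairs) == 0) return(NULL)
  # expand pairs x trims
  reps <- pmin(trim_max, pmax(pairs$arm_length - min_arm, 0)) + 1L
  pidx <- rep(seq_len(nrow(pairs)), reps)
  trim <- unlist(lapply(reps, function(r) 0:(r - 1L)))
  ls <- pairs$left_start[pidx] + trim            # trimmed left arm start
  re <- pairs$right_end[pidx] - trim             # trimmed right arm end
  len <- pairs$arm_length[pidx] - trim
  ok <- ls >= 4 & re + 4 <= n
  if (!any(ok)) return(NULL)
  lf <- rep(NA_character_, length(ls)); rf <- lf
  lf[ok] <- substring(seq, ls[ok] - 3, ls[ok])
  rf[ok] <- substring(seq, re[ok] + 1, re[ok] + 4)
  canonical <- ok & lf == tsd_motif & rf == tsd_motif
  equal <- ok & !is.na(lf) & !is.na(rf) & lf == rf
  eligible <- canonical | equal
  if (!any(eligible)) return(NULL)
  idx <- which(eligible)
  # recount mismatches on the trimmed arms (candidates are few)
  sv <- strsplit(seq, "")[[1]]
  cv <- comp_chr(sv)
  mism <- vapply(idx, function(k) {
    p <- pidx[k]; s <- trim[k]; L <- len[k]
    i <- pairs$left_start[p]; jL <- pairs$right_end[p]   # 0-based; right outer edge
    kk <- s:(s + L - 1L)
    sum(sv[i + kk + 1L] != cv[jL - kk])                  # jL - kk is 1-based mirror
  }, 0L)
  o <- order(-canonical[idx], -len[idx], mism, ls[idx])
  b <- idx[o[1]]
  bm <- mism[match(b, idx)]
  # measured TIR: the perfect inverted-repeat arm anchored at the element
  # edges (the tabulated "TIR length"); the budgeted pair stats are kept
  # alongside as pair_arm_length / pair_mismatches
  i0 <- ls[b]; e0 <- re[b]
  cap <- (e0 - i0) %/% 2
  k <- 0L
  while (k < cap && sv[i0 + k + 1L] == cv[e0 - k]) k <- k + 1L
  out <- data.frame(
    start = i0, end = e0,
    tir_length = k,
    pair_arm_length = len[b], pair_mismatches = bm,
    arm_identity = 100 * (len[b] - bm) / len[b],
    left_tir_start = i0, left_tir_end = i0 + k,
    right_tir_start = e0 - k, right_tir_end = e0,
    tsd_left = lf[b], tsd_right = rf[b],
    tsd_canonical = canonical[b], trim = trim[b],
    score = len[b] - bm + 4 * canonical[b] + 2 * equal[b],
    stringsAsFactors = FALSE)
  class(out) <- c("pb_element_boundary", "data.frame")
  out
}
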