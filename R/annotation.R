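#' Find the longest ORF of an element
#'
#' piggyBac transposases are encoded by a single ORF in the middle of the
#' element, so gene prediction reduces to longest-ORF finding: the longest
#' ATG-initiated, stop-terminated reading frame on either strand.  Ties are
#' broken toward the forward strand, then the 5'-most start.
#'
#' @param element_seq DNA character scalar (or DNAString)
#' @param min_aa minimum ORF length in aa (default 100, the floor used for
#'   tree building)
#' @return list of class `pb_orf` with `start`, `end` (0-based half-open
#'   nucleotide span on the input orientation, stop codon included),
#'   `strand`, `protein` (no stop), `length_aa`; or NULL if no ORF reaches
#'   `min_aa`
#' @export
find_longest_orf <- function(element_seq, min_aa = 100) {
  seq <- toupper(as.character(element_seq))
  L <- nchar(seq)
  if (L < 300) return(NULL)
  frames <- six_frame_translate(seq)
  best <- NULL
  for (fi in seq_len(nrow(frames))) {
    pep <- frames$peptide[fi]
    m <- gregexpr("M[^*]*\\*", pep)[[1]]
    if (m[1] == -1) next
    len <- attr(m, "match.length")
    for (k in seq_along(m)) {
      aa_len <- len[k] - 1L            # protein length excluding the stop
      if (aa_len < min_aa) next
      if (!is.null(best)) {
        better <- aa_len > best$length_aa ||
          (aa_len == best$length_aa && frames$strand[fi] == "+" && best$strand == "-")
        if (!better) next
      }
      gi <- frame_to_genome(m[k], m[k] + len[k] - 1L,
                            frames$strand[fi], frames$offset[fi], L)
      prot <- substr(pep, m[k], m[k] + aa_len - 1L)
      best <- list(start = gi[1], end = gi[2], strand = frames$strand[fi],
                   protein = prot, length_aa = aa_len)
    }
  }
  if (!is.null(best)) class(best) <- "pb_orf"
  best
}

#' Scan a transposase for diagnostic piggyBac domains
#'
#' Globally aligns the protein to a bundled clade consensus and maps the
#' consensus catalytic triad (three aspartates), the insertion-motif span
#' and the CRD cysteine positions through the alignment.  Triad residues
#' are reported verbatim so that inactivating substitutions (D to N, D to
#' H) stay visible.  The CRD is called regular when at least seven
#' cysteines in the C-terminal 60 aa have consecutive gaps within +/-2 of
#' the consensus spacing.
#'
#' @param protein aa character scalar (>= 100 aa)
#' @param clade which clade consensus to align against ("A","B","C")
#' @param min_align_score alignment score floor below which the triad is
#'   reported unmapped
#' @return list of class `pb_domain_scan`: triad_positions,
#'   triad_residues, triad_intact, insertion_motif_span, crd_cysteine_positions,
#'   crd_cysteine_count, crd_regular, alignment_score, note
#' @export
scan_domains <- function(protein, clade = "A", min_align_score = 100) {
  protein <- toupper(as.character(protein))
  if (nchar(protein) < 100) stop("protein shorter than 100 aa")
  ann <- pb_domain_annotation()
  cons_set <- pb_reference_proteins("consensus")
  cons <- as.character(cons_set)[match(clade, S4Vectors::mcols(cons_set)$clade)]
  if (is.na(cons)) stop("unknown clade ", clade)
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(protein), Biostrings::AAString(cons),
    substitutionMatrix = blosum62(),
    gapOpening = 11, gapExtension = 1, type = "global")
  sc <- Biostrings::score(pa)
  note <- ""
  if (sc < min_align_score) {
    triad_pos <- rep(NA_integer_, 3)
    triad_res <- rep(NA_character_, 3)
    ins_span <- c(NA_integer_, NA_integer_)
    note <- "alignment below score floor; positions unmapped"
  } else {
    ap <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
    as_ <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
    # map consensus (subject) position -> protein (pattern) position
    map <- rep(NA_integer_, nchar(cons))
    pi_ <- 0L; si <- 0L
    for (col in seq_along(ap)) {
      if (ap[col] != "-") pi_ <- pi_ + 1L
      if (as_[col] != "-") {
        si <- si + 1L
        if (ap[col] != "-") map[si] <- pi_
      }
    }
    triad_pos <- map[unlist(ann$triad_positions)]
    triad_res <- ifelse(is.na(triad_pos), NA_character_,
                        substring(protein, triad_pos, triad_pos))
    ins_span <- c(map[ann$insertion_motif$start], map[ann$insertion_motif$end])
  }
  triad_intact <- !any(is.na(triad_res)) && all(triad_res == "D")
  # CRD: cysteines in the C-terminal 60 aa, spacing within +/-2 of consensus
  np <- nchar(protein)
  tail_start <- max(np - 60 + 1, 1)
  tail_seq <- substr(protein, tail_start, np)
  cpos <- tail_start - 1L + which(strsplit(tail_seq, "")[[1]] == "C")
  gaps_cons <- unlist(ann$crd_cysteine_gaps)
  # ladder walk: from each candidate first cysteine, require a cysteine
  # within +/-2 of each successive consensus offset (tolerates extra Cs)
  crd_regular <- FALSE
  if (length(cpos) >= 7) {
    offs_cons <- cumsum(c(0, gaps_cons))
    for (s in seq_along(cpos)) {
      targets <- cpos[s] + offs_cons
      if (all(vapply(targets, function(t) any(abs(cpos - t) <= 2), TRUE))) {
        crd_regular <- TRUE; break
      }
    }
  }
  structure(list(triad_positions = triad_pos, triad_residues = triad_res,
                 triad_intact = triad_intact,
                 insertion_motif_span = ins_span,
                 crd_cysteine_positions = cpos,
                 crd_cysteine_count = length(cpos),
                 crd_regular = crd_regular,
                 alignment_score = sc, note = note),
            class = "pb_domain_scan")
}

#' Classify an element as intact, full or truncated
#'
#' Published criteria: a *full* copy is flanked by detectable TSDs and
#' TIRs; an *intact* copy additionally encodes a transposase of at least
#' 500 aa; anything else is *truncated*.
#'
#' @param boundary a `pb_element_boundary` (or NULL if no TIR/TSD pair was
#'   detectable)
#' @param orf a `pb_orf` (or NULL)
#' @param min_intact_aa intact threshold in aa (default 500)
#' @return list of class `pb_element_class`: label, tir_tsd_detectable,
#'   transposase_aa
#' @export
classify_element <- function(boundary, orf, min_intact_aa = 500) {
  detectable <- !is.null(boundary)
  aa <- if (is.null(orf)) 0L else orf$length_aa
  label <- if (detectable && aa >= min_intact_aa) "intact"
           else if (detectable) "full" else "truncated"
  structure(list(label = label, tir_tsd_detectable = detectable,
                 transposase_aa = aa),
            class = "pb_element_class")
}
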