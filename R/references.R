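#' Bundled piggyBac transposase reference proteins
#'
#' The package ships three clade-consensus proteins (clades A, B, C), 13
#' clade-labeled reference transposases and 10 IS1380-like outgroup
#' proteins.  All are synthetic stand-ins: clade-structured proteins that
#' carry the canonical piggyBac landmarks (catalytic DDD triad, conserved
#' DDBD2 tryptophan, seven regularly spaced CRD cysteines) at fixed
#' consensus coordinates, with the catalytic domain the most conserved
#' between clades and the NTD the least, mirroring the conservation ranking
#' reported for real PB transposases.  Clade labels are parsed from the
#' `clade=` tag in each FASTA header.
#'
#' @param set one of "refs" (13 clade references), "consensus" (3 clade
#'   consensuses), "outgroup" (10 IS1380-like stand-ins)
#' @return an [Biostrings::AAStringSet] with a `clade` metadata column
#' @export
pb_reference_proteins <- function(set = c("refs", "consensus", "outgroup")) {
  set <- match.arg(set)
  fn <- switch(set,
    refs      = "pb_transposase_refs_synthetic.faa",
    consensus = "pb_clade_consensus_synthetic.faa",
    outgroup  = "is1380_outgroup_synthetic.faa")
  path <- system.file("extdata", fn, package = "pbmine", mustWork = TRUE)
  aa <- Biostrings::readAAStringSet(path)
  hdr <- names(aa)
  clade <- sub(".*clade=(\\S+).*", "\\1", hdr)
  names(aa) <- sub("\\s.*", "", hdr)
  S4Vectors::mcols(aa)$clade <- clade
  aa
}

#' Domain annotation of the bundled clade consensuses
#'
#' Returns the 1-based closed domain spans (NTD, DDBD1, DDD, DDBD2, CRD),
#' the three catalytic triad positions, the insertion-motif span and the
#' CRD cysteine positions, all in consensus coordinates.  The three clade
#' consensuses are substitution-only derivatives of one scaffold, so the
#' same coordinates apply to each.
#'
#' @return a list as stored in `inst/extdata/pb_domain_annotation.json`
#' @export
pb_domain_annotation <- function() {
  path <- system.file("extdata", "pb_domain_annotation.json",
                      package = "pbmine", mustWork = TRUE)
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' @importFrom S4Vectors mcols
NULL
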