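BASES <- c("A", "C", "G", "T")

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Reverse complement of a DNA string
#' @param x character scalar over the DNA alphabet
#' @return character scalar
#' @export
revcomp_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

comp_chr <- function(x) chartr("ACGTNacgtn", "TGCANtgcan", x)

# run code with a private RNG stream, restoring the caller's state
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(code)
}

#' Sample an i.i.d. DNA sequence at a given GC content
#' @param n length in bp
#' @param gc GC fraction in (0,1)
#' @return character scalar of length n
#' @export
random_dna <- function(n, gc = 0.5) {
  stopifnot(n >= 0, gc > 0, gc < 1)
  if (n == 0) return("")
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(BASES, n, replace = TRUE, prob = p), collapse = "")
}

#' Write intervals as BED6
#'
#' Coordinates are 0-based half-open, as in the BED standard and in all
#' internal interval representations of this package.
#'
#' @param df data.frame with columns contig, start, end, name, score, strand
#' @param path output file
#' @export
write_bed6 <- function(df, path) {
  stopifnot(all(c("contig", "start", "end", "name", "score", "strand") %in% names(df)))
  out <- df[, c("contig", "start", "end", "name", "score", "strand")]
  write.table(out, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

seq_lengths <- function(genome) setNames(Biostrings::width(genome), names(genome))

as_dnastringset <- function(genome) {
  if (is(genome, "DNAStringSet")) return(genome)
  if (is.character(genome) && length(genome) == 1 && file.exists(genome))
    return(Biostrings::readDNAStringSet(genome))
  if (is.character(genome)) {
    nm <- names(genome) %||% paste0("contig", seq_along(genome))
    return(setNames(Biostrings::DNAStringSet(genome), nm))
  }
  stop("cannot interpret 'genome' as a DNAStringSet, file path or character vector")
}

.pb_cache <- new.env(parent = emptyenv())

blosum62 <- function() {
  if (is.null(.pb_cache$B62)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    .pb_cache$B62 <- e$BLOSUM62
  }
  .pb_cache$B62
}

#' @importFrom methods is
NULL
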