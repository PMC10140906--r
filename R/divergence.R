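#' Count transitions and transversions between a copy and its consensus
#'
#' The two sequences are globally aligned (match +1 / mismatch -2, affine
#' gaps); columns containing a gap or an ambiguous base are excluded.
#' Transitions are A<->G and C<->T; every other mismatch is a
#' transversion.
#'
#' @param copy,consensus DNA character scalars (both >= 50 bp)
#' @return list of class `pb_subst_counts`: aligned_sites, transitions,
#'   transversions, P, Q
#' @export
count_substitutions <- function(copy, consensus) {
  copy <- toupper(as.character(copy)); consensus <- toupper(as.character(consensus))
  stopifnot(nchar(copy) >= 50, nchar(consensus) >= 50)
  submat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -2,
                                                     baseOnly = FALSE)
  pa <- Biostrings::pairwiseAlignment(Biostrings::DNAString(copy),
                                      Biostrings::DNAString(consensus),
                                      substitutionMatrix = submat,
                                      gapOpening = 5, gapExtension = 2,
                                      type = "global")
  a <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
  b <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
  ok <- a %in% BASES & b %in% BASES
  a <- a[ok]; b <- b[ok]
  n <- length(a)
  if (n == 0) stop("no gap-free aligned columns")
  mm <- a != b
  ts <- mm & ((a == "A" & b == "G") | (a == "G" & b == "A") |
              (a == "C" & b == "T") | (a == "T" & b == "C"))
  tv <- mm & !ts
  structure(list(aligned_sites = n, transitions = sum(ts),
                 transversions = sum(tv), P = sum(ts) / n, Q = sum(tv) / n),
            class = "pb_subst_counts")
}

#' Kimura 2-parameter distance
#'
#' K = -1/2 ln[(1 - 2P - Q) sqrt(1 - 2Q)] x 100, with P and Q the
#' transition and transversion fractions.  Requires 1 - 2P - Q > 0 and
#' 1 - 2Q > 0; outside that domain the estimator is saturated and an
#' error of class `pb_saturation_error` is raised.
#'
#' @param P,Q transition / transversion fractions (vectorised)
#' @return K2P distance in percent
#' @export
kimura_distance <- function(P, Q) {
  stopifnot(length(P) == length(Q), all(P >= 0), all(Q >= 0))
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  if (any(w1 <= 0) || any(w2 <= 0))
    stop(structure(class = c("pb_saturation_error", "error", "condition"),
                   list(message = "K2P saturated: 1-2P-Q and 1-2Q must be > 0",
                        call = sys.call())))
  -50 * log(w1 * sqrt(w2))
}

#' Divergence landscape of a family
#'
#' Each copy is compared to the family consensus; its gap-free aligned bp
#' are assigned to the Kimura-divergence bin containing its K estimate.
#' Bin coverage is summed copy bp divided by genome size, in percent, so a
#' landscape is the histogram of genome coverage across divergence bins
#' that is commonly plotted for repeat families.  Saturated copies are
#' excluded and counted in `n_saturated`.
#'
#' @param copies character vector / DNAStringSet of copy sequences
#' @param consensus family consensus (or representative)
#' @param genome_bp genome size in bp (the coverage denominator)
#' @param bin_width bin width in percent K
#' @return list of class `pb_landscape`: family, bin_width, bins
#'   (data.frame bin_start, coverage_percent, copy_bp, n_copies),
#'   total_copy_bp, genome_bp, n_saturated, copy_K
#' @export
divergence_landscape <- function(copies, consensus, genome_bp,
                                 bin_width = 1, family = "family") {
  copies <- vapply(as.list(copies), function(x) toupper(as.character(x)), "")
  if (length(copies) == 0) stop("empty copy list")
  K <- numeric(0); bp <- numeric(0)
  n_sat <- 0L
  for (cp in copies) {
    sc <- count_substitutions(cp, consensus)
    k <- tryCatch(kimura_distance(sc$P, sc$Q),
                  pb_saturation_error = function(e) NA_real_)
    if (is.na(k)) { n_sat <- n_sat + 1L; next }
    K <- c(K, k); bp <- c(bp, sc$aligned_sites)
  }
  if (!length(K)) stop("all copies saturated; no landscape")
  bin <- floor(K / bin_width) * bin_width
  starts <- seq(0, max(bin), by = bin_width)
  copy_bp <- vapply(starts, function(s) sum(bp[bin == s]), 0)
  n_cp <- vapply(starts, function(s) sum(bin == s), 0)
  bins <- data.frame(bin_start = starts,
                     coverage_percent = 100 * copy_bp / genome_bp,
                     copy_bp = copy_bp, n_copies = n_cp)
  structure(list(family = family, bin_width = bin_width, bins = bins,
                 total_copy_bp = sum(bp), genome_bp = genome_bp,
                 n_saturated = n_sat, copy_K = K),
            class = "pb_landscape")
}

#' @export
print.pb_landscape <- function(x, ...) {
  cat(sprintf("pb_landscape [%s]: %d bins, %.0f copy bp, %d saturated\n",
              x$family, nrow(x$bins), x$total_copy_bp, x$n_saturated))
  invisible(x)
}

#' Call invasion age and wave structure from a landscape
#'
#' Formalises the narrative reading of repeat landscapes: a family is
#' *recent* when the majority of its copy bp falls in bins entirely below
#' `recent_max` percent K, *old* when the majority falls in bins entirely
#' above `old_min`, and *intermediate* otherwise.  Multiple amplification
#' waves are flagged when at least two local maxima, separated by at least
#' `min_mode_sep` bins and each holding at least `min_mode_frac` of the
#' copy bp, are present.
#'
#' @param landscape a `pb_landscape`
#' @param recent_max recent cutoff in percent K (published: K < 2)
#' @param old_min old cutoff in percent K (published: K > 15)
#' @param min_mode_sep minimum separation between modes in bins
#' @param min_mode_frac minimum copy-bp fraction per mode
#' @return list of class `pb_age_call`: family, label, multi_wave,
#'   wave_modes (K percents), recent_fraction, old_fraction
#' @export
call_age <- function(landscape, recent_max = 2, old_min = 15,
                     min_mode_sep = 3, min_mode_frac = 0.10) {
  b <- landscape$bins
  bw <- landscape$bin_width
  tot <- sum(b$copy_bp)
  recent_mass <- sum(b$copy_bp[b$bin_start + bw <= recent_max + 1e-9])
  # a bin counts as old only when it lies entirely above old_min (a bin
  # whose lower edge equals the cutoff still contains K values == cutoff)
  old_mass <- sum(b$copy_bp[b$bin_start > old_min + 1e-9])
  label <- if (recent_mass > 0.5 * tot) "recent"
           else if (old_mass > 0.5 * tot) "old" else "intermediate"
  # local maxima over the binned mass (zero-padded)
  v <- b$copy_bp
  pad <- c(0, v, 0)
  is_max <- vapply(seq_along(v), function(i)
    pad[i + 1] > pad[i] && pad[i + 1] >= pad[i + 2] && v[i] >= min_mode_frac * tot,
    TRUE)
  modes <- which(is_max)
  if (length(modes) > 1) {
    # enforce pairwise separation greedily by mass
    ord <- modes[order(-v[modes])]
    sel <- integer(0)
    for (m in ord) if (!length(sel) || all(abs(sel - m) >= min_mode_sep)) sel <- c(sel, m)
    modes <- sort(sel)
  }
  multi_wave <- length(modes) >= 2
  structure(list(family = landscape$family, label = label,
                 multi_wave = multi_wave,
                 wave_modes = b$bin_start[modes] + bw / 2,
                 recent_fraction = recent_mass / tot,
                 old_fraction = old_mass / tot),
            class = "pb_age_call")
}
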