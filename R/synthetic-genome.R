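#' Specify a synthetic piggyBac family
#'
#' Describes one transposon family to be planted by [generate_genome()].
#' Defaults follow the structural statistics reported for complete PB
#' elements in bees: elements ~2.2-3.5 kb, transposases ~580 aa, TIRs ~14 bp
#' (long-TIR families of 200-500 bp are allowed), TTAA TSDs.
#'
#' @param clade_label one of "A","B","C": which bundled clade consensus the
#'   planted transposase is derived from
#' @param element_length total element length in bp (outer TIR edge to outer
#'   TIR edge)
#' @param tir_length TIR arm length in bp (>= 5)
#' @param tsd 4-mer target-site duplication (canonical "TTAA")
#' @param transposase_length transposase length in aa
#' @param copy_count number of copies to plant
#' @param divergence_waves list of c(mean_K_percent, copy_fraction) pairs;
#'   fractions must sum to 1.  Each copy is assigned to a wave and mutated
#'   to that expected Kimura 2-parameter divergence from the master.
#' @param truncation_prob probability that a copy is planted truncated
#'   (missing a uniform-random terminal 20-50\% of its length, including one
#'   TIR and the adjacent TSD)
#' @param ts_tv_ratio ratio of the transition rate to each transversion
#'   rate (kappa) used when mutating copies; 2 is a typical genomic value
#' @param arm_mismatch number of extra mismatches planted into the right
#'   TIR arm of the master (0 = perfect inverted repeat, the common case)
#' @return an object of class `pb_family_spec`
#' @export
family_spec <- function(clade_label = "A", element_length = 2500,
                        tir_length = 14, tsd = "TTAA",
                        transposase_length = 580, copy_count = 5,
                        divergence_waves = list(c(0, 1)),
                        truncation_prob = 0, ts_tv_ratio = 2,
                        arm_mismatch = 0) {
  stopifnot(clade_label %in% c("A", "B", "C"),
            tir_length >= 5, nchar(tsd) == 4,
            copy_count >= 1, truncation_prob >= 0, truncation_prob <= 1,
            transposase_length >= 150, ts_tv_ratio > 0)
  fr <- vapply(divergence_waves, function(w) w[2], 0)
  if (abs(sum(fr) - 1) > 1e-8)
    stop("divergence_waves copy fractions must sum to 1")
  if (element_length < 2 * tir_length + 3 * transposase_length + 3 + 20)
    stop("element_length too small for TIRs plus transposase CDS")
  structure(list(clade_label = clade_label, element_length = element_length,
                 tir_length = tir_length, tsd = toupper(tsd),
                 transposase_length = transposase_length,
                 copy_count = copy_count, divergence_waves = divergence_waves,
                 truncation_prob = truncation_prob, ts_tv_ratio = ts_tv_ratio,
                 arm_mismatch = arm_mismatch),
            class = "pb_family_spec")
}

#' Configure the synthetic genome generator
#'
#' @param genome_length total genome size in bp (>= 10 kb)
#' @param gc_content background GC fraction in (0,1); 0.38 approximates a
#'   bee genome
#' @param contig_count number of contigs (genome split evenly)
#' @param families list of [family_spec()] objects
#' @param seed integer RNG seed; a fixed seed makes outputs byte-identical
#' @param min_spacing minimum distance in bp between planted elements (kept
#'   above twice the default locus flank so that candidate loci of distinct
#'   elements do not merge)
#' @return an object of class `pb_generator_config`
#' @export
generator_config <- function(genome_length = 2e6, gc_content = 0.38,
                             contig_count = 1, families = list(family_spec()),
                             seed = 1, min_spacing = 5000) {
  stopifnot(genome_length >= 1e4, gc_content > 0, gc_content < 1,
            contig_count >= 1, length(families) >= 1)
  lapply(families, function(f) stopifnot(inherits(f, "pb_family_spec")))
  structure(list(genome_length = genome_length, gc_content = gc_content,
                 contig_count = contig_count, families = families,
                 seed = as.integer(seed), min_spacing = min_spacing),
            class = "pb_generator_config")
}

# reverse-translate a protein, sampling synonymous codons uniformly;
# returns the CDS without the stop codon
reverse_translate <- function(protein) {
  gc <- Biostrings::GENETIC_CODE
  by_aa <- split(names(gc), gc)
  aa <- strsplit(protein, "")[[1]]
  codons <- vapply(aa, function(a) {
    cs <- by_aa[[a]]
    if (is.null(cs)) stop("no codon for residue ", a)
    if (length(cs) == 1) cs else sample(cs, 1)
  }, "")
  paste(codons, collapse = "")
}

# remove every ATG from a spacer so it cannot start a competing ORF
scrub_atg <- function(seq) {
  while (grepl("ATG", seq, fixed = TRUE)) {
    i <- regexpr("ATG", seq, fixed = TRUE)
    substr(seq, i + 1, i + 1) <- "C"
  }
  seq
}

# the planted transposase protein for a family: the clade consensus,
# trimmed or padded (random residues inserted before the CRD) to the
# requested length, always starting with M
family_protein <- function(spec, consensus) {
  p <- strsplit(consensus, "")[[1]]
  L <- spec$transposase_length
  ann <- pb_domain_annotation()
  if (L <= length(p)) {
    p <- p[seq_len(L)]
  } else {
    AA <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
    ins <- sample(AA, L - length(p), replace = TRUE)
    at <- ann$domains$DDBD2$end            # pad between DDBD2 and CRD
    p <- c(p[1:at], ins, p[(at + 1):length(p)])
  }
  p[1] <- "M"
  paste(p, collapse = "")
}

# master (undiverged) element for one family: TIR + spacer + CDS + spacer + TIR
build_master_element <- function(spec, consensus, gc = 0.38) {
  tir <- spec$tir_length
  core <- "CACTATACCG"                      # terminal motifs seen in PB TIR logos
  left <- if (tir <= nchar(core)) substr(core, 1, tir) else
    paste0(core, random_dna(tir - nchar(core), gc))
  right <- revcomp_chr(left)
  if (spec$arm_mismatch > 0) {
    r <- strsplit(right, "")[[1]]
    at <- sample(seq_along(r), min(spec$arm_mismatch, length(r)))
    for (i in at) r[i] <- sample(setdiff(BASES, r[i]), 1)
    right <- paste(r, collapse = "")
  }
  prot <- family_protein(spec, consensus)
  cds <- paste0(scrub_atg_after_start(reverse_translate(prot)), "TAA")
  rem <- spec$element_length - 2 * tir - nchar(cds)
  if (rem < 2) stop("element_length too small for the transposase CDS")
  sp5 <- scrub_atg(random_dna(floor(rem * 0.45), gc))
  sp3 <- scrub_atg(random_dna(rem - nchar(sp5), gc))
  seq <- paste0(left, sp5, cds, sp3, right)
  stopifnot(nchar(seq) == spec$element_length)
  # break complementarity just inside the TIRs so the planted TIR length
  # is exactly recoverable (no chance inward extension of the repeat)
  n <- nchar(seq)
  inner_l <- substr(seq, tir + 1, tir + 1)
  inner_r <- substr(seq, n - tir, n - tir)
  if (inner_l == comp_chr(inner_r)) {
    if (nchar(sp5) >= 1) {
      avoid <- unique(c(comp_chr(inner_r), "A"))  # "A" also avoids new ATGs
      substr(seq, tir + 1, tir + 1) <- sample(setdiff(BASES, avoid), 1)
    } else if (nchar(sp3) >= 1) {
      avoid <- unique(c(comp_chr(inner_l), "T"))  # "T" avoids reverse-strand ATGs
      substr(seq, n - tir, n - tir) <- sample(setdiff(BASES, avoid), 1)
    }
  }
  list(seq = seq, tir_left = left, tir_right = right, protein = prot,
       cds_start = tir + nchar(sp5), cds_end = tir + nchar(sp5) + nchar(cds))
}

# keep the initial ATG, remove any further ATG on the forward frame-agnostic
# string is unnecessary (internal ATGs are harmless); only guard spacers.
scrub_atg_after_start <- function(cds) cds

#' Mutate a sequence to a target Kimura 2-parameter divergence
#'
#' Substitutions are drawn per site from the exact K2P transition
#' probabilities at divergence time t chosen so that the expected K2P
#' distance between input and output equals `target_K`.  With transition
#' rate alpha and transversion rate beta per target (kappa = alpha/beta),
#' the expected fractions are
#' P(t) = 1/4 + 1/4 exp(-4 beta t) - 1/2 exp(-2 (alpha+beta) t) and
#' Q(t) = 1/2 - 1/2 exp(-4 beta t), and the K2P estimator applied to
#' (P, Q) returns exactly (alpha + 2 beta) t, the planted divergence.
#' No indels are introduced.
#'
#' @param seq DNA character scalar
#' @param target_K expected K2P divergence in percent (0 to 150; beyond
#'   that the finite-sequence estimator saturates and an error is raised)
#' @param ts_tv_ratio kappa, the transition/transversion rate ratio; `Inf`
#'   gives pure transitions (Q = 0)
#' @param seed optional integer; if given, mutation uses a private RNG
#'   stream and the caller's RNG state is untouched
#' @return mutated DNA character scalar of the same length
#' @export
mutate_copy <- function(seq, target_K, ts_tv_ratio = 2, seed = NULL) {
  stopifnot(nchar(seq) > 0, target_K >= 0)
  if (target_K > 150)
    stop("target_K = ", target_K, "% is beyond K2P saturation for finite sequences")
  with_seed(seed, {
    k <- target_K / 100
    if (is.infinite(ts_tv_ratio)) {
      P <- 0.5 - 0.5 * exp(-2 * k); Q <- 0
    } else {
      bt <- k / (ts_tv_ratio + 2)          # beta * t
      at <- ts_tv_ratio * bt               # alpha * t
      P <- 0.25 + 0.25 * exp(-4 * bt) - 0.5 * exp(-2 * (at + bt))
      Q <- 0.5 - 0.5 * exp(-4 * bt)
    }
    s <- strsplit(seq, "")[[1]]
    n <- length(s)
    r <- runif(n)
    ts_partner <- c(A = "G", G = "A", C = "T", T = "C")
    tv_partner <- list(A = c("C", "T"), G = c("C", "T"),
                       C = c("A", "G"), T = c("A", "G"))
    idx_ts <- which(r < P & s %in% BASES)
    idx_tv <- which(r >= P & r < P + Q & s %in% BASES)
    if (length(idx_ts)) s[idx_ts] <- ts_partner[s[idx_ts]]
    if (length(idx_tv)) {
      pick <- runif(length(idx_tv)) < 0.5
      s[idx_tv] <- mapply(function(b, p) tv_partner[[b]][1 + p],
                          s[idx_tv], pick, USE.NAMES = FALSE)
    }
    paste(s, collapse = "")
  })
}

# truncate a copy: drop a uniform-random 20-50% prefix or suffix
# (always removes one TIR); returns list(seq, lost_side)
truncate_copy <- function(seq) {
  n <- nchar(seq)
  frac <- runif(1, 0.2, 0.5)
  cut <- max(ceiling(n * frac), 1)
  if (runif(1) < 0.5)
    list(seq = substr(seq, cut + 1, n), lost = "left")
  else
    list(seq = substr(seq, 1, n - cut), lost = "right")
}

#' Generate a synthetic genome with planted piggyBac elements
#'
#' Builds i.i.d. background contigs at the configured GC content and plants
#' each family's copies at uniform-random non-overlapping positions (with a
#' minimum spacing), on random strands, each copy mutated to its assigned
#' divergence wave and optionally truncated.  Non-truncated copies are
#' flanked by the family TSD on both sides; truncated copies keep the TSD
#' only on their surviving end.  Because TTAA is its own reverse
#' complement, TSDs read the same on either strand.
#'
#' @param config a [generator_config()]
#' @return a list of class `pb_simulation` with elements `genome`
#'   (DNAStringSet), `truth` (data.frame of truth records, 0-based
#'   half-open coordinates), `config`
#' @export
generate_genome <- function(config) {
  stopifnot(inherits(config, "pb_generator_config"))
  with_seed(config$seed, {
    n_contig <- config$contig_count
    clen <- rep(floor(config$genome_length / n_contig), n_contig)
    clen[n_contig] <- config$genome_length - sum(clen[-n_contig])
    contigs <- vapply(clen, random_dna, "", gc = config$gc_content)
    names(contigs) <- sprintf("contig%02d", seq_len(n_contig))

    cons_set <- pb_reference_proteins("consensus")
    cons_by_clade <- setNames(as.character(cons_set), S4Vectors::mcols(cons_set)$clade)

    # build all inserts first
    inserts <- list()
    eid <- 0L
    for (fi in seq_along(config$families)) {
      spec <- config$families[[fi]]
      fam_id <- sprintf("fam%d_%s", fi, spec$clade_label)
      master <- build_master_element(spec, cons_by_clade[[spec$clade_label]],
                                     gc = config$gc_content)
      waves <- config$families[[fi]]$divergence_waves
      wave_of <- sample(seq_along(waves), spec$copy_count, replace = TRUE,
                        prob = vapply(waves, function(w) w[2], 0))
      for (ci in seq_len(spec$copy_count)) {
        eid <- eid + 1L
        K <- waves[[wave_of[ci]]][1]
        seq <- if (K > 0)
          mutate_copy(master$seq, K, ts_tv_ratio = spec$ts_tv_ratio) else master$seq
        truncated <- runif(1) < spec$truncation_prob
        lost <- NA_character_
        if (truncated) {
          tr <- truncate_copy(seq); seq <- tr$seq; lost <- tr$lost
        }
        strand <- if (runif(1) < 0.5) "+" else "-"
        if (strand == "-") seq <- revcomp_chr(seq)
        inserts[[eid]] <- list(
          element_id = sprintf("el%03d", eid), family = fam_id,
          clade_label = spec$clade_label, seq = seq, strand = strand,
          tsd = spec$tsd, tir_length = spec$tir_length, target_K = K,
          truncated = truncated, lost = lost,
          transposase_length = spec$transposase_length)
      }
    }

    # assign contigs and insertion points with spacing, re-drawing clashes
    n_ins <- length(inserts)
    placed <- FALSE
    for (attempt in 1:200) {
      ctg <- sample(seq_len(n_contig), n_ins, replace = TRUE,
                    prob = clen / sum(clen))
      pos <- integer(n_ins)
      ok <- TRUE
      for (i in seq_len(n_ins)) {
        lo <- 100; hi <- clen[ctg[i]] - 100
        if (hi <= lo) { ok <- FALSE; break }
        pos[i] <- sample(lo:hi, 1)
      }
      if (ok) {
        for (ci in unique(ctg)) {
          p <- sort(pos[ctg == ci])
          if (length(p) > 1 && any(diff(p) < config$min_spacing)) { ok <- FALSE; break }
        }
      }
      if (ok) { placed <- TRUE; break }
    }
    if (!placed)
      stop("genome too small to place ", n_ins,
           " elements at min_spacing = ", config$min_spacing)

    # splice inserts into contigs, computing final coordinates
    truth <- list()
    for (ci in seq_len(n_contig)) {
      idx <- which(ctg == ci)
      idx <- idx[order(pos[idx])]
      if (!length(idx)) next
      parts <- character(0)
      cursor <- 0L        # consumed host bp (0-based)
      offset <- 0L        # bp already emitted
      for (i in idx) {
        ins <- inserts[[i]]
        host <- substr(contigs[ci], cursor + 1, pos[i])
        parts <- c(parts, host)
        offset <- offset + nchar(host)
        # a TSD is kept only on a surviving end (on the genome strand)
        lost_genome_left <- ins$truncated &&
          ((ins$strand == "+" && ins$lost == "left") ||
           (ins$strand == "-" && ins$lost == "right"))
        lost_genome_right <- ins$truncated &&
          ((ins$strand == "+" && ins$lost == "right") ||
           (ins$strand == "-" && ins$lost == "left"))
        tsd_l <- if (lost_genome_left) "" else ins$tsd
        tsd_r <- if (lost_genome_right) "" else ins$tsd
        parts <- c(parts, tsd_l, ins$seq, tsd_r)
        start <- offset + nchar(tsd_l)
        end <- start + nchar(ins$seq)
        offset <- offset + nchar(tsd_l) + nchar(ins$seq) + nchar(tsd_r)
        cursor <- pos[i]
        truth[[length(truth) + 1L]] <- data.frame(
          element_id = ins$element_id, contig = names(contigs)[ci],
          start = start, end = end, strand = ins$strand,
          family = ins$family, clade_label = ins$clade_label,
          tir_length = ins$tir_length, tsd = ins$tsd,
          target_K = ins$target_K, truncated = ins$truncated,
          transposase_length = ins$transposase_length,
          stringsAsFactors = FALSE)
      }
      parts <- c(parts, substr(contigs[ci], cursor + 1, clen[ci]))
      contigs[ci] <- paste(parts, collapse = "")
    }
    truth <- do.call(rbind, truth)
    truth <- truth[order(truth$contig, truth$start), , drop = FALSE]
    rownames(truth) <- NULL
    structure(list(genome = Biostrings::DNAStringSet(contigs),
                   truth = truth, config = config),
              class = "pb_simulation")
  })
}

#' @export
print.pb_simulation <- function(x, ...) {
  cat("pb_simulation:", sum(Biostrings::width(x$genome)), "bp in",
      length(x$genome), "contig(s);", nrow(x$truth), "planted element(s)\n")
  invisible(x)
}

#' Write a simulation to disk
#'
#' Emits `genome.fa`, `truth.tsv` (1-based closed `start1`/`end` columns are
#' added beside the 0-based ones), `truth.bed` (BED6) and `config.json`.
#'
#' @param sim a `pb_simulation`
#' @param dir output directory (created if needed)
#' @return `dir`, invisibly
#' @export
write_simulation <- function(sim, dir) {
  stopifnot(inherits(sim, "pb_simulation"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Biostrings::writeXStringSet(sim$genome, file.path(dir, "genome.fa"))
  tr <- sim$truth
  tr$start1 <- tr$start + 1L
  write_tsv(tr, file.path(dir, "truth.tsv"))
  write_bed6(data.frame(contig = tr$contig, start = tr$start, end = tr$end,
                        name = tr$element_id, score = 0, strand = tr$strand),
             file.path(dir, "truth.bed"))
  cfg <- sim$config
  cfg$families <- lapply(cfg$families, unclass)
  jsonlite::write_json(unclass(cfg), file.path(dir, "config.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}
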