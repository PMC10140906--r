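#' Pipeline configuration with the published defaults
#'
#' Collects every stage threshold in one serialisable object.  Defaults
#' are the values printed in the source protocol: 2000 bp flanks, census
#' coverage > 40 and identity > 80 (strict), consensus building for
#' families with > 10 counted copies, intact transposase >= 500 aa,
#' landscape bin width 1\% K, recent < 2\% K, old > 15\% K.
#'
#' @param seed integer seed used for any stochastic step
#' @param flank locus extension in bp
#' @param min_seed_score translated-search score threshold
#' @param tir_min_len,tir_max_len,tir_max_mismatch TIR search parameters
#' @param tir_search_window bp from each locus edge within which TIR arms
#'   must start (NULL = 45\% of locus length)
#' @param tsd_motif canonical TSD
#' @param min_intact_aa intact transposase floor (aa)
#' @param census_min_cov,census_min_ident strict census thresholds (%)
#' @param consensus_min_copies consensus trigger (copies, strict >)
#' @param landscape_bin bin width (% K)
#' @param recent_max,old_min age-call cutoffs (% K)
#' @return list of class `pb_run_config`
#' @export
run_config <- function(seed = 1, flank = 2000, min_seed_score = 150,
                       tir_min_len = 10, tir_max_len = 500,
                       tir_max_mismatch = 2, tir_search_window = NULL,
                       tsd_motif = "TTAA", min_intact_aa = 500,
                       census_min_cov = 40, census_min_ident = 80,
                       consensus_min_copies = 10, landscape_bin = 1,
                       recent_max = 2, old_min = 15) {
  structure(as.list(environment()), class = "pb_run_config")
}

reciprocal_overlap <- function(s1, e1, s2, e2) {
  ov <- pmax(0, pmin(e1, e2) - pmax(s1, s2))
  pmin(ov / pmax(e1 - s1, 1), ov / pmax(e2 - s2, 1))
}

#' Run the full mining pipeline
#'
#' Executes seeding, boundary resolution, annotation, census, divergence
#' and comparative stages on a genome, optionally scoring against a truth
#' table and writing all artifacts to a run directory.
#'
#' @param genome DNAStringSet / FASTA path / named character vector
#' @param config a [run_config()]
#' @param refs reference proteins (default: bundled clade references)
#' @param truth optional truth table (as from [generate_genome()])
#' @param out_dir optional output directory
#' @param verbose log per-stage counts
#' @return list of class `pb_run`: elements (detail data.frame), hits,
#'   loci, census (per family), landscapes, age_calls, tree, clades,
#'   logo, evaluation, config
#' @export
run_pipeline <- function(genome, config = run_config(),
                         refs = pb_reference_proteins("refs"),
                         truth = NULL, out_dir = NULL, verbose = TRUE) {
  stopifnot(inherits(config, "pb_run_config"))
  say <- function(...) if (verbose) message(sprintf(...))
  genome <- as_dnastringset(genome)
  clens <- seq_lengths(genome)
  genome_bp <- sum(clens)
  with_seed(config$seed, {

  t0 <- Sys.time()
  hits <- protein_search(genome, refs, min_score = config$min_seed_score)
  say("seeding: %d hits", nrow(hits))
  loci <- build_loci(hits, clens, flank = config$flank)
  say("loci: %d candidate loci", nrow(loci))

  # --- boundary resolution + annotation per locus ---
  el_rows <- list()
  el_seqs <- character(0)
  el_prot <- character(0)
  for (li in seq_len(nrow(loci))) {
    lc <- loci[li, ]
    lseq <- as.character(Biostrings::subseq(genome[[lc$contig]],
                                            lc$start + 1, lc$end))
    pairs <- find_tir_pairs(lseq, min_len = config$tir_min_len,
                            max_len = config$tir_max_len,
                            max_mismatch = config$tir_max_mismatch,
                            search_window = config$tir_search_window)
    bnd <- select_element(pairs, lseq, tsd_motif = config$tsd_motif)
    if (is.null(bnd)) next
    e_start <- lc$start + bnd$start
    e_end <- lc$start + bnd$end
    eseq <- substr(lseq, bnd$start + 1, bnd$end)
    orf <- find_longest_orf(eseq)
    strand <- if (is.null(orf)) "+" else orf$strand
    scan <- NULL
    if (!is.null(orf) && nchar(orf$protein) >= 100)
      scan <- scan_domains(orf$protein, clade = lc$best_clade)
    cls <- classify_element(bnd, orf, min_intact_aa = config$min_intact_aa)
    id <- sprintf("PB_%s_%d", lc$contig, e_start)
    el_rows[[length(el_rows) + 1L]] <- data.frame(
      element_id = id, contig = lc$contig, start = e_start, end = e_end,
      strand = strand, clade = lc$best_clade, best_ref = lc$best_ref,
      tir_length = bnd$tir_length, tir_mismatches = bnd$pair_mismatches,
      arm_identity = bnd$arm_identity,
      tsd_left = bnd$tsd_left, tsd_right = bnd$tsd_right,
      tsd_canonical = bnd$tsd_canonical,
      orf_aa = if (is.null(orf)) 0L else orf$length_aa,
      triad_intact = if (is.null(scan)) NA else scan$triad_intact,
      crd_regular = if (is.null(scan)) NA else scan$crd_regular,
      class = cls$label, stringsAsFactors = FALSE)
    el_seqs <- c(el_seqs, setNames(eseq, id))
    if (!is.null(orf)) el_prot <- c(el_prot, setNames(orf$protein, id))
  }
  elements <- if (length(el_rows)) do.call(rbind, el_rows) else
    data.frame(element_id = character(), contig = character(),
               start = integer(), end = integer(), strand = character(),
               clade = character(), best_ref = character(),
               tir_length = integer(), tir_mismatches = integer(),
               arm_identity = numeric(), tsd_left = character(),
               tsd_right = character(), tsd_canonical = logical(),
               orf_aa = integer(), triad_intact = logical(),
               crd_regular = logical(), class = character(),
               stringsAsFactors = FALSE)
  say("boundaries: %d elements resolved (%d intact, %d full)",
      nrow(elements), sum(elements$class == "intact"),
      sum(elements$class == "full"))

  # --- per-family census, consensus, divergence ---
  censuses <- list(); landscapes <- list(); age_calls <- list()
  consensi <- character(0)
  for (fam in sort(unique(elements$clade))) {
    mem <- elements[elements$clade == fam, , drop = FALSE]
    pick <- mem[order(mem$class != "intact", -(mem$end - mem$start)), ][1, ]
    rep_seq <- el_seqs[[pick$element_id]]
    chits <- search_copies(rep_seq, genome, query_id = fam)
    consensus_used <- FALSE
    fam_query <- rep_seq
    counted0 <- sum(chits$query_coverage > config$census_min_cov &
                    chits$percent_identity > config$census_min_ident)
    if (counted0 > config$consensus_min_copies) {
      idx <- which(chits$query_coverage > config$census_min_cov &
                   chits$percent_identity > config$census_min_ident)
      copies <- vapply(idx, function(i) {
        s <- as.character(Biostrings::subseq(genome[[chits$contig[i]]],
                                             chits$start[i] + 1, chits$end[i]))
        if (chits$strand[i] == "-") revcomp_chr(s) else s
      }, "")
      fam_query <- build_consensus(copies, rep_seq)
      consensus_used <- TRUE
      chits <- search_copies(fam_query, genome, query_id = fam)
    }
    # full/intact status of each copy hit, inherited from overlapping elements
    det <- logical(nrow(chits)); aa <- numeric(nrow(chits))
    for (i in seq_len(nrow(chits))) {
      same <- which(elements$contig == chits$contig[i])
      if (!length(same)) next
      ro <- reciprocal_overlap(chits$start[i], chits$end[i],
                               elements$start[same], elements$end[same])
      j <- same[which.max(ro)]
      if (max(ro) >= 0.5) { det[i] <- TRUE; aa[i] <- elements$orf_aa[j] }
    }
    cen <- census(chits, det, aa, min_cov = config$census_min_cov,
                  min_ident = config$census_min_ident,
                  min_intact_aa = config$min_intact_aa, family = fam)
    cen$representative <- pick$element_id
    cen$consensus_used <- consensus_used
    censuses[[fam]] <- cen
    consensi[fam] <- fam_query
    if (cen$counted > 0) {
      idx <- cen$counted_idx
      copies <- vapply(idx, function(i) {
        s <- as.character(Biostrings::subseq(genome[[chits$contig[i]]],
                                             chits$start[i] + 1, chits$end[i]))
        if (chits$strand[i] == "-") revcomp_chr(s) else s
      }, "")
      ls <- tryCatch(
        divergence_landscape(copies, fam_query, genome_bp,
                             bin_width = config$landscape_bin, family = fam),
        error = function(e) NULL)
      if (!is.null(ls)) {
        landscapes[[fam]] <- ls
        age_calls[[fam]] <- call_age(ls, recent_max = config$recent_max,
                                     old_min = config$old_min)
      }
    }
    say("census [%s]: %d hits, %d full, %d intact (consensus: %s)",
        fam, cen$total_hits, cen$full_copies, cen$intact_copies,
        consensus_used)
  }

  # --- comparative: tree, clade assignment, TIR logo ---
  tree <- NULL; clades <- NULL; logo <- NULL; idsum <- NULL
  qprot <- el_prot[nchar(el_prot) >= 100]
  refs_chr <- setNames(as.character(refs), names(refs))
  ref_clades <- setNames(S4Vectors::mcols(refs)$clade, names(refs))
  og <- pb_reference_proteins("outgroup")
  og_chr <- setNames(as.character(og), names(og))
  if (length(qprot) >= 1) {
    allp <- c(qprot, refs_chr, og_chr)
    allcl <- c(elements$clade[match(names(qprot), elements$element_id)],
               unname(ref_clades), rep("outgroup", length(og_chr)))
    im <- identity_matrix(allp, allcl)
    dmat <- (100 - im$matrix) / 100
    tree <- nj_tree(dmat)
    clades <- assign_clades(tree, ref_clades, outgroup = names(og_chr))
    qim <- identity_matrix(c(qprot, refs_chr),
                           c(elements$clade[match(names(qprot), elements$element_id)],
                             unname(ref_clades)))
    idsum <- identity_summary(qim)
    say("comparative: %d proteins in tree, %d queries assigned",
        length(allp), sum(names(clades) %in% names(qprot)))
  }
  if (nrow(elements) >= 2) {
    tirs <- c(
      vapply(seq_len(nrow(elements)), function(i)
        substr(el_seqs[[elements$element_id[i]]], 1, elements$tir_length[i]), ""),
      vapply(seq_len(nrow(elements)), function(i) {
        s <- el_seqs[[elements$element_id[i]]]
        revcomp_chr(substr(s, nchar(s) - elements$tir_length[i] + 1, nchar(s)))
      }, ""))
    logo <- tir_logo(tirs)
  }

  evaluation <- if (!is.null(truth))
    evaluate_predictions(elements, truth) else NULL

  run <- structure(list(
    elements = elements, element_seqs = el_seqs, element_proteins = el_prot,
    hits = hits, loci = loci, census = censuses, consensus = consensi,
    landscapes = landscapes, age_calls = age_calls,
    tree = tree, clades = clades, identity_summary = idsum, logo = logo,
    evaluation = evaluation, config = config,
    genome_bp = genome_bp,
    elapsed_sec = as.numeric(difftime(Sys.time(), t0, units = "secs"))),
    class = "pb_run")
  if (!is.null(out_dir)) write_run(run, out_dir)
  run
  })
}

#' @export
print.pb_run <- function(x, ...) {
  cat(sprintf("pb_run: %d elements (%d intact / %d full / %d truncated-class), %d families, %.1f s\n",
              nrow(x$elements), sum(x$elements$class == "intact"),
              sum(x$elements$class == "full"),
              sum(x$elements$class == "truncated"),
              length(x$census), x$elapsed_sec))
  if (!is.null(x$evaluation))
    cat(sprintf("  evaluation: precision %.3f recall %.3f boundary-exact %.3f\n",
                x$evaluation$precision, x$evaluation$recall,
                x$evaluation$boundary_exact_fraction))
  invisible(x)
}

#' Write all pipeline artifacts to a directory
#'
#' Emits elements as BED6 (0-based half-open) and a detail TSV (1-based
#' closed `start1` column added), census/landscape/age TSVs, consensus
#' FASTA, the tree in newick, logo TSV and the resolved configuration as
#' JSON.
#'
#' @param run a `pb_run`
#' @param dir output directory
#' @return `dir`, invisibly
#' @export
write_run <- function(run, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  el <- run$elements
  if (nrow(el)) {
    write_bed6(data.frame(contig = el$contig, start = el$start, end = el$end,
                          name = el$element_id, score = 0, strand = el$strand),
               file.path(dir, "elements.bed"))
    det <- el; det$start1 <- det$start + 1L
    write_tsv(det, file.path(dir, "elements.tsv"))
  }
  if (length(run$census)) {
    cen <- do.call(rbind, lapply(run$census, function(x)
      data.frame(family = x$family, total_hits = x$total_hits,
                 counted = x$counted, full_copies = x$full_copies,
                 intact_copies = x$intact_copies,
                 representative = x$representative,
                 consensus_used = x$consensus_used)))
    write_tsv(cen, file.path(dir, "census.tsv"))
    Biostrings::writeXStringSet(
      Biostrings::DNAStringSet(run$consensus),
      file.path(dir, "family_query.fa"))
  }
  if (length(run$landscapes)) {
    ld <- do.call(rbind, lapply(run$landscapes, function(l)
      cbind(family = l$family, l$bins)))
    write_tsv(ld, file.path(dir, "landscape.tsv"))
  }
  if (length(run$age_calls)) {
    ac <- do.call(rbind, lapply(run$age_calls, function(a)
      data.frame(family = a$family, label = a$label, multi_wave = a$multi_wave,
                 modes = paste(a$wave_modes, collapse = ","))))
    write_tsv(ac, file.path(dir, "age_calls.tsv"))
  }
  if (!is.null(run$tree))
    ape::write.tree(run$tree, file.path(dir, "tree.nwk"))
  if (!is.null(run$logo)) {
    lg <- as.data.frame(t(run$logo$freq))
    lg$ic <- run$logo$ic
    lg$position <- seq_len(nrow(lg))
    write_tsv(lg, file.path(dir, "tir_logo.tsv"))
  }
  if (!is.null(run$evaluation)) {
    jsonlite::write_json(run$evaluation[c("precision", "recall",
                                          "boundary_exact_fraction",
                                          "n_truth", "n_pred", "n_matched")],
                         file.path(dir, "evaluation.json"), auto_unbox = TRUE)
  }
  jsonlite::write_json(unclass(run$config), file.path(dir, "config.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null")
  invisible(dir)
}

#' Score predicted elements against a truth table
#'
#' A prediction matches a truth record when their reciprocal overlap is at
#' least `overlap_frac`; matching is greedy by decreasing overlap, one
#' prediction per truth record.  A match is boundary-exact when both
#' coordinates agree exactly.  When both sides carry `tir_length`/TSD
#' columns, per-match structure agreement is reported too.
#'
#' @param predictions data.frame with contig/start/end (0-based half-open;
#'   optionally element_id, tir_length, tsd_left)
#' @param truth truth data.frame from [generate_genome()]
#' @param overlap_frac reciprocal overlap threshold
#' @return list of class `pb_evaluation`: precision, recall,
#'   boundary_exact_fraction, n_truth, n_pred, n_matched, matches
#'   (per-truth data.frame), spurious (unmatched prediction ids)
#' @export
evaluate_predictions <- function(predictions, truth, overlap_frac = 0.5) {
  if (anyDuplicated(truth$element_id)) stop("duplicate truth ids")
  np <- nrow(predictions); nt <- nrow(truth)
  cand <- list()
  for (ti in seq_len(nt)) {
    same <- which(predictions$contig == truth$contig[ti])
    if (!length(same)) next
    ro <- reciprocal_overlap(truth$start[ti], truth$end[ti],
                             predictions$start[same], predictions$end[same])
    ok <- ro >= overlap_frac
    if (any(ok))
      cand[[length(cand) + 1L]] <- data.frame(ti = ti, pi = same[ok],
                                              ro = ro[ok])
  }
  cand <- if (length(cand)) do.call(rbind, cand) else
    data.frame(ti = integer(), pi = integer(), ro = numeric())
  cand <- cand[order(-cand$ro), , drop = FALSE]
  t_used <- logical(nt); p_used <- logical(np)
  pairs <- list()
  for (k in seq_len(nrow(cand))) {
    ti <- cand$ti[k]; pi <- cand$pi[k]
    if (t_used[ti] || p_used[pi]) next
    t_used[ti] <- TRUE; p_used[pi] <- TRUE
    exact <- predictions$start[pi] == truth$start[ti] &&
             predictions$end[pi] == truth$end[ti]
    row <- data.frame(
      element_id = truth$element_id[ti],
      pred_id = if ("element_id" %in% names(predictions))
        predictions$element_id[pi] else as.character(pi),
      overlap = cand$ro[k], boundary_exact = exact,
      stringsAsFactors = FALSE)
    if ("tir_length" %in% names(predictions) && "tir_length" %in% names(truth))
      row$tir_length_match <- predictions$tir_length[pi] == truth$tir_length[ti]
    if ("tsd_left" %in% names(predictions) && "tsd" %in% names(truth))
      row$tsd_match <- predictions$tsd_left[pi] == truth$tsd[ti] &
                       predictions$tsd_right[pi] == truth$tsd[ti]
    row$truncated <- truth$truncated[ti]
    pairs[[length(pairs) + 1L]] <- row
  }
  matches <- if (length(pairs)) do.call(rbind, pairs) else NULL
  n_matched <- sum(t_used)
  structure(list(
    precision = if (np) sum(p_used) / np else NA_real_,
    recall = if (nt) n_matched / nt else NA_real_,
    boundary_exact_fraction = if (n_matched) mean(matches$boundary_exact) else NA_real_,
    n_truth = nt, n_pred = np, n_matched = n_matched,
    matches = matches,
    missed = truth$element_id[!t_used],
    spurious = which(!p_used)),
    class = "pb_evaluation")
}
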