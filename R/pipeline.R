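# end-to-end discovery: tags -> mapped loci -> hairpins -> catalogue

#' Discover miRNA loci from collapsed tags
#'
#' Runs the full discovery chain: perfect genome mapping, annotation-priority
#' categorisation, pileup locus calling, excision and folding of the two
#' candidate precursors per locus, duplex metrics and the structural filter,
#' folding p-values for exon-sense candidates, known/novel calling, overlap
#' deduplication, and catalogue annotation (isoforms, clusters, paralogs,
#' conservation tiers, sense/antisense pairs, genomic context).
#'
#' @param tags tag table from [collapse_tags()] / [preprocess_reads()].
#' @param genome named character vector, `DNAStringSet` or FASTA path.
#' @param annotations an `annotation_set`.
#' @param ref_matures named character vector of reference matures
#'   (miRBase-style `species-miR-name` names); may be empty.
#' @param taxon_map species prefix -> taxon group map for conservation calls.
#' @param libraries library ids (count columns of `tags`).
#' @param max_hits multi-mapper cap (default 20).
#' @param max_locus_span pileup split span (default 200).
#' @param min_reads_known,min_reads_novel read-support thresholds
#'   (defaults 2 and 5, within a single library).
#' @param pooled_novel pool reads across libraries for the novel threshold
#'   (default FALSE).
#' @param n_shuffles shuffles for the exon-sense folding p-value
#'   (default 100).
#' @param max_pvalue exon-sense rescue threshold, exclusive (default 0.01).
#' @param seed seed for the folding p-value shuffles.
#' @param engine folding engine forwarded to [fold_rna()].
#' @return list with `catalogue` (one row per accepted locus), `candidates`
#'   (every evaluated pileup locus with filter outcome and reasons),
#'   `assignments`, `category_tbl`, `clusters`, `paralogs`, `pairs`,
#'   `alignments`, `unmapped` and `report`.
#' @export
discover_mirnas <- function(tags, genome, annotations,
                            ref_matures = character(0),
                            taxon_map = DEFAULT_TAXON_MAP,
                            libraries = NULL,
                            max_hits = 20L, max_locus_span = 200L,
                            min_reads_known = 2L, min_reads_novel = 5L,
                            pooled_novel = FALSE,
                            n_shuffles = 100L, max_pvalue = 0.01,
                            seed = 1L, engine = NULL) {
  if (is.character(genome) && length(genome) == 1L && file.exists(genome)) {
    genome <- Biostrings::readDNAStringSet(genome)
    names(genome) <- sub("\\s.*$", "", names(genome))
  }
  if (methods::is(genome, "DNAStringSet")) {
    genome <- stats::setNames(as.character(genome), names(genome))
  }
  libraries <- libraries %||%
    setdiff(names(tags), c("tag_id", "sequence", "length", "total"))

  index <- build_index(genome, seed_width = min(18L, min(tags$length %||% 18L)))
  mp <- map_tags(tags, index, max_hits = max_hits)
  assignments <- categorize_tags(mp$alignments, annotations)
  category_tbl <- category_table(assignments, tags, libraries)

  eligible_tags <- assignments$tag_id[assignments$eligible_for_discovery]
  aln <- mp$alignments
  aln <- aln[!aln$hyper_repetitive & aln$tag_id %in% eligible_tags, ,
             drop = FALSE]
  pileups <- call_pileups(aln, tags, max_locus_span = max_locus_span)

  ## excise both windows for every locus, fold everything in one batch
  shells <- lapply(pileups, excise_precursors, genome = genome)
  seqs <- unlist(lapply(shells, function(s) {
    vapply(s, function(c) c$precursor_seq, character(1))
  }))
  folded <- if (length(seqs)) fold_rna(seqs, engine = engine) else NULL
  k <- 0L
  cand_rows <- list()
  loci_eval <- list()
  for (li in seq_along(pileups)) {
    locus <- pileups[[li]]
    cands <- shells[[li]]
    for (w in seq_along(cands)) {
      k <- k + 1L
      cands[[w]]$structure <- folded$structure[k]
      cands[[w]]$mfe <- folded$mfe[k]
      if (nchar(cands[[w]]$precursor_seq) >= 40L &&
          diff(cands[[w]]$mature_span) >= 2L) {
        cands[[w]] <- duplex_metrics(cands[[w]])
      } else {
        cands[[w]]$reject_reason <- "short-precursor"
      }
      cands[[w]]$star_genomic <- star_genomic_span(cands[[w]])
    }
    ## star-arm read support (over all alignments, not just locus members)
    star_counts <- lapply(cands, function(cc) {
      if (is.null(cc$star_genomic)) return(NULL)
      counts_in_span(mp$alignments, tags, libraries, locus$chrom,
                     locus$strand, cc$star_genomic,
                     exclude_tags = locus$members$tag_id)
    })
    for (w in seq_along(cands)) {
      reads_on_star <- !is.null(star_counts[[w]]) &&
        sum(star_counts[[w]]) > 0
      cands[[w]]$filter <- structural_filter(cands[[w]],
                                             reads_on_star = reads_on_star)
      cands[[w]]$reads_on_star <- reads_on_star
    }
    best <- select_precursor(cands[[1L]], cands[[2L]])
    mature_tag <- locus$mature_guess
    category <- assignments$category[match(mature_tag$tag_id,
                                           assignments$tag_id)]
    ## locus read support: members plus star-arm reads
    member_counts <- colSums(as.matrix(
      tags[match(unique(locus$members$tag_id), tags$tag_id), libraries,
           drop = FALSE]))
    wsel <- if (!is.null(best)) which(vapply(cands, function(cc)
      identical(cc$window, best$window), logical(1)))[1L] else NA_integer_
    star_cnt <- if (!is.na(wsel) && !is.null(star_counts[[wsel]])) {
      star_counts[[wsel]]
    } else stats::setNames(rep(0, length(libraries)), libraries)
    lib_counts <- member_counts + star_cnt
    loci_eval[[li]] <- list(locus = locus, best = best, cands = cands,
                            category = category, lib_counts = lib_counts,
                            member_reads = sum(member_counts),
                            star_counts = star_cnt)
    for (w in seq_along(cands)) {
      cc <- cands[[w]]
      cand_rows[[length(cand_rows) + 1L]] <- data.frame(
        locus_index = li, chrom = locus$chrom, strand = locus$strand,
        start = cc$start, end = cc$end, window = cc$window,
        mfe = cc$mfe,
        pass = cc$filter$pass,
        reasons = paste(cc$filter$reasons, collapse = ";"),
        category = category,
        selected = !is.null(best) && identical(best$window, cc$window),
        stringsAsFactors = FALSE)
    }
  }
  candidates <- if (length(cand_rows)) do.call(rbind, cand_rows) else
    data.frame()

  ## exon-sense rescue p-values (only for loci that need and may pass)
  pseed <- seed
  for (li in seq_along(loci_eval)) {
    le <- loci_eval[[li]]
    if (is.null(le$best)) next
    if (identical(le$category, "exon_sense")) {
      pseed <- pseed + 1L
      loci_eval[[li]]$fold_p <- fold_pvalue(le$best$precursor_seq,
                                            n_shuffles = n_shuffles,
                                            seed = pseed, engine = engine)
    } else {
      loci_eval[[li]]$fold_p <- NA_real_
    }
  }

  ## known/novel calls
  mature_seqs <- vapply(loci_eval, function(le)
    rna_to_dna(le$locus$mature_guess$sequence), character(1))
  km <- match_known(mature_seqs, ref_matures)
  accepted <- list()
  for (li in seq_along(loci_eval)) {
    le <- loci_eval[[li]]
    if (is.null(le$best)) next
    mature_lib <- mature_arm_counts(le$locus, tags, libraries)
    known <- (km$known[li] || identical(le$category, "known_mirna")) &&
      any(mature_lib >= min_reads_known)
    novel <- call_novel(known, le$category, le$lib_counts,
                        filter_pass = TRUE, fold_p = le$fold_p,
                        min_reads = min_reads_novel,
                        max_pvalue = max_pvalue, pooled = pooled_novel)
    if (!known && !novel) next
    accepted[[length(accepted) + 1L]] <- c(
      le, list(known = known, ref_name = km$ref_name[li],
               mature_lib = mature_lib))
  }

  ## deduplicate same-strand overlapping precursors (keep deepest locus)
  accepted <- dedup_loci(accepted)

  catalogue <- finalize_catalogue(accepted, tags, libraries, annotations,
                                  ref_matures, taxon_map)
  clusters <- detect_clusters(catalogue)
  paralogs <- group_paralogs(catalogue)
  pairs <- detect_sense_antisense(catalogue)
  report <- build_report(catalogue, category_tbl = category_tbl,
                         clusters = clusters, paralogs = paralogs,
                         pairs = pairs)
  list(catalogue = catalogue, candidates = candidates,
       assignments = assignments, category_tbl = category_tbl,
       clusters = clusters, paralogs = paralogs, pairs = pairs,
       alignments = mp$alignments, unmapped = mp$unmapped,
       report = report)
}

# genomic 0-based half-open interval of a candidate's star span
#' @keywords internal
star_genomic_span <- function(cand) {
  if (is.null(cand$star_span)) return(NULL)
  s <- cand$star_span
  if (cand$strand == "+") {
    c(cand$start + s[1L] - 1L, cand$start + s[2L])
  } else {
    c(cand$end - s[2L], cand$end - s[1L] + 1L)
  }
}

# per-library read counts of tags lying mostly inside a genomic span
#' @keywords internal
counts_in_span <- function(alignments, tags, libraries, chrom, strand, span,
                           min_frac = 0.6, exclude_tags = character(0)) {
  sel <- alignments$chrom == chrom & alignments$strand == strand &
    alignments$start < span[2L] & alignments$end > span[1L] &
    !(alignments$tag_id %in% exclude_tags)
  out <- stats::setNames(rep(0, length(libraries)), libraries)
  if (!any(sel)) return(out)
  sub <- alignments[sel, , drop = FALSE]
  ov <- pmin(sub$end, span[2L]) - pmax(sub$start, span[1L])
  sub <- sub[ov / (sub$end - sub$start) >= min_frac, , drop = FALSE]
  if (nrow(sub) == 0L) return(out)
  idx <- match(unique(sub$tag_id), tags$tag_id)
  for (lib in libraries) out[lib] <- sum(tags[[lib]][idx])
  out
}

# per-library counts of members overlapping the mature guess span
#' @keywords internal
mature_arm_counts <- function(locus, tags, libraries) {
  mg <- locus$mature_guess
  mem <- locus$members
  ov <- pmin(mem$end, mg$end) - pmax(mem$start, mg$start)
  sel <- ov / (mem$end - mem$start) >= 0.6
  idx <- match(unique(mem$tag_id[sel]), tags$tag_id)
  out <- stats::setNames(rep(0, length(libraries)), libraries)
  for (lib in libraries) out[lib] <- sum(tags[[lib]][idx])
  out
}

# among accepted loci, collapse same-strand overlapping precursors onto the
# locus whose own pileup carries the most reads (the mature arm; a star-arm
# pileup of the same hairpin carries far fewer reads of its own)
#' @keywords internal
dedup_loci <- function(accepted) {
  if (length(accepted) < 2L) return(accepted)
  info <- data.frame(
    i = seq_along(accepted),
    chrom = vapply(accepted, function(a) a$locus$chrom, character(1)),
    strand = vapply(accepted, function(a) a$locus$strand, character(1)),
    start = vapply(accepted, function(a) a$best$start, numeric(1)),
    end = vapply(accepted, function(a) a$best$end, numeric(1)),
    reads = vapply(accepted, function(a)
      a$member_reads %||% sum(a$lib_counts), numeric(1))
  )
  drop <- logical(nrow(info))
  ord <- order(-info$reads, info$start)
  for (a in ord) {
    if (drop[a]) next
    for (b in ord) {
      if (a == b || drop[a] || drop[b]) next
      if (info$chrom[a] == info$chrom[b] &&
          info$strand[a] == info$strand[b] &&
          info$start[a] < info$end[b] && info$end[a] > info$start[b]) {
        drop[b] <- TRUE
      }
    }
  }
  accepted[!drop]
}

# assemble the final catalogue data.frame
#' @keywords internal
finalize_catalogue <- function(accepted, tags, libraries, annotations,
                               ref_matures, taxon_map) {
  cols <- c("name", "chrom", "start", "end", "strand", "status", "context",
            "tier", "mature_seq", "star_seq", "window", "mfe", "fold_p",
            "arm_dominance", "arm_switch", "ref_name",
            paste0("reads_", libraries), paste0("star_reads_", libraries))
  if (length(accepted) == 0L) {
    out <- as.data.frame(stats::setNames(
      replicate(length(cols), character(0), simplify = FALSE), cols))
    return(out)
  }
  ord <- order(vapply(accepted, function(a) a$locus$chrom, character(1)),
               vapply(accepted, function(a) a$best$start, numeric(1)))
  accepted <- accepted[ord]
  rows <- list()
  nov_n <- 0L
  used_names <- character(0)
  for (a in accepted) {
    best <- a$best
    star_seq <- if (!is.null(best$star_span)) {
      substr(best$precursor_seq, best$star_span[1L], best$star_span[2L])
    } else NA_character_
    known <- isTRUE(a$known)
    if (known) {
      base <- a$ref_name %||% "known-mir"
      if (is.na(base)) base <- "known-mir"
    } else {
      nov_n <- nov_n + 1L
      base <- sprintf("nov-mir-%d", nov_n)
    }
    name <- base
    sfx <- 0L
    while (name %in% used_names) { sfx <- sfx + 1L; name <- paste0(base, "-", sfx) }
    used_names <- c(used_names, name)
    cons <- classify_conservation(rna_to_dna(a$locus$mature_guess$sequence),
                                  ref_matures, taxon_map)
    ## for knowns: the annotated arm is the arm whose dominant isoform best
    ## matches the reference mature; a mismatch with the max-read arm flags
    ## arm switching
    known_arm <- NA_character_
    iso0 <- refine_isoforms(
      a$locus$members,
      precursor = list(start = best$start, end = best$end,
                       strand = best$strand))
    if (known && !is.na(a$ref_name %||% NA) &&
        (a$ref_name %in% names(ref_matures))) {
      refseq <- ref_matures[[a$ref_name]]
      dists <- vapply(c("5p", "3p"), function(arm) {
        dom <- iso0$dominant[[arm]]
        if (is.null(dom)) return(Inf)
        seq_match_dist(rna_to_dna(dom$sequence), refseq)$mismatches
      }, numeric(1))
      if (any(is.finite(dists))) known_arm <- names(which.min(dists))
    }
    iso <- refine_isoforms(
      a$locus$members,
      precursor = list(start = best$start, end = best$end,
                       strand = best$strand),
      known_arm = known_arm)
    row <- data.frame(
      name = name, chrom = a$locus$chrom, start = best$start,
      end = best$end, strand = best$strand,
      status = if (known) "known" else "novel",
      context = NA_character_, tier = cons$tier,
      mature_seq = dna_to_rna(a$locus$mature_guess$sequence),
      star_seq = star_seq,
      window = best$window, mfe = best$mfe,
      fold_p = a$fold_p %||% NA_real_,
      arm_dominance = iso$arm_dominance,
      arm_switch = iso$arm_switch,
      ref_name = a$ref_name %||% NA_character_,
      stringsAsFactors = FALSE
    )
    for (lib in libraries) {
      row[[paste0("reads_", lib)]] <- unname(a$lib_counts[lib])
      row[[paste0("star_reads_", lib)]] <- unname(a$star_counts[lib])
    }
    rows[[length(rows) + 1L]] <- row
  }
  out <- do.call(rbind, rows)
  out$context <- genomic_context(out, annotations)
  rownames(out) <- NULL
  out
}
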