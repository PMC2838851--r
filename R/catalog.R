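# catalogue layer: known/novel calls, isoforms, clusters, paralogs,
# conservation, sense/antisense pairs, genomic context, summary report

#' Match candidate matures against the native reference database
#'
#' A candidate corresponds to a known miRNA when its mature sequence matches
#' a native-species reference mature with at most `max_mismatch` mismatches
#' and at most `max_shift` nt end shift, or when its precursor locus overlaps
#' a supplied reference hairpin interval. The call additionally requires at
#' least `min_reads` mature-arm reads in some library.
#'
#' @param mature_seqs character vector of candidate mature sequences.
#' @param ref_matures named character vector of reference matures
#'   (names like `bmo-miR-x`; only entries of `native_prefix` species count
#'   as known).
#' @param max_mismatch,max_shift matching tolerance (defaults 2 and 3;
#'   dominant sequenced isoforms frequently differ from database annotations
#'   by a shifted end or a substitution).
#' @param native_prefix species tag of the study organism (default `bmo`).
#' @return data.frame with `known` (logical) and `ref_name` (best native
#'   match or `NA`).
#' @export
match_known <- function(mature_seqs, ref_matures, max_mismatch = 2L,
                        max_shift = 3L, native_prefix = "bmo") {
  native <- ref_matures[grepl(paste0("^", native_prefix, "-"),
                              names(ref_matures))]
  out <- data.frame(known = logical(length(mature_seqs)),
                    ref_name = NA_character_,
                    stringsAsFactors = FALSE)
  if (length(native) == 0L || length(mature_seqs) == 0L) return(out)
  for (i in seq_along(mature_seqs)) {
    best <- Inf; best_name <- NA_character_
    for (j in seq_along(native)) {
      d <- seq_match_dist(mature_seqs[i], native[[j]], max_shift = max_shift)
      if (d$mismatches < best) { best <- d$mismatches; best_name <- names(native)[j] }
    }
    if (best <= max_mismatch) {
      out$known[i] <- TRUE; out$ref_name[i] <- best_name
    }
  }
  out
}

#' Single-linkage clustering of miRNA loci along the genome
#'
#' Consecutive loci on the same chromosome and strand whose inter-precursor
#' gap is strictly below `max_gap` join one cluster (polycistronic
#' transcription of closely spaced miRNA genes). Singletons are not reported.
#'
#' @param loci data.frame with `name`, `chrom`, `start`, `end`, `strand`.
#' @param max_gap maximum gap in nt, exclusive (default 2500).
#' @param same_strand require cluster members on one strand (default TRUE;
#'   polycistronic transcription implies a shared strand).
#' @return data.frame: `cluster_id`, `member` (locus name), `chrom`,
#'   `strand`; empty when no clusters exist.
#' @export
detect_clusters <- function(loci, max_gap = 2500L, same_strand = TRUE) {
  empty <- data.frame(cluster_id = character(0), member = character(0),
                      chrom = character(0), strand = character(0),
                      stringsAsFactors = FALSE)
  if (nrow(loci) < 2L) return(empty)
  key <- if (same_strand) paste(loci$chrom, loci$strand) else loci$chrom
  rows <- list()
  cl_n <- 0L
  for (grp in split(seq_len(nrow(loci)), key)) {
    sub <- loci[grp, , drop = FALSE]
    sub <- sub[order(sub$start, sub$end), , drop = FALSE]
    if (nrow(sub) < 2L) next
    gap <- sub$start[-1L] - sub$end[-nrow(sub)]
    brk <- c(0L, cumsum(gap >= max_gap))
    for (members in split(seq_len(nrow(sub)), brk)) {
      if (length(members) < 2L) next
      cl_n <- cl_n + 1L
      rows[[length(rows) + 1L]] <- data.frame(
        cluster_id = sprintf("cluster%02d", cl_n),
        member = sub$name[members],
        chrom = sub$chrom[members[1L]],
        strand = if (same_strand) sub$strand[members[1L]] else "*",
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L) return(empty)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Group miRNA loci into paralog families by mature/star similarity
#'
#' Two loci are linked when the ungapped best-overlap distance between their
#' matures, or between one's mature and the other's star, is at most
#' `max_mismatch`; groups are the transitive closure (union-find) and only
#' groups of two or more loci are reported.
#'
#' @param loci data.frame with `name`, `mature_seq` and optionally
#'   `star_seq` (NA when absent).
#' @param max_mismatch similarity threshold (default 2).
#' @param max_shift maximum end shift in the overlap alignment (default 3).
#' @return data.frame: `group_id`, `member`, `representative_mature`.
#' @export
group_paralogs <- function(loci, max_mismatch = 2L, max_shift = 3L) {
  n <- nrow(loci)
  empty <- data.frame(group_id = character(0), member = character(0),
                      representative_mature = character(0),
                      stringsAsFactors = FALSE)
  if (n < 2L) return(empty)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  union_ <- function(i, j) {
    ri <- find(i); rj <- find(j)
    if (ri != rj) parent[rj] <<- ri
  }
  linked <- function(i, j) {
    m <- function(a, b) {
      if (is.na(a) || is.na(b)) return(FALSE)
      seq_match_dist(a, b, max_shift = max_shift)$mismatches <= max_mismatch
    }
    m(loci$mature_seq[i], loci$mature_seq[j]) ||
      m(loci$mature_seq[i], loci$star_seq[j] %||% NA) ||
      m(loci$star_seq[i] %||% NA, loci$mature_seq[j])
  }
  for (i in seq_len(n - 1L)) for (j in seq.int(i + 1L, n)) {
    if (linked(i, j)) union_(i, j)
  }
  roots <- vapply(seq_len(n), find, integer(1))
  rows <- list()
  g <- 0L
  for (r in unique(roots)) {
    members <- which(roots == r)
    if (length(members) < 2L) next
    g <- g + 1L
    rows[[length(rows) + 1L]] <- data.frame(
      group_id = sprintf("paralog%02d", g),
      member = loci$name[members],
      representative_mature = loci$mature_seq[members[1L]],
      stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L) return(empty)
  do.call(rbind, rows)
}

#' Classify the evolutionary conservation tier of a mature sequence
#'
#' Collects reference matures within the matching tolerance across all
#' species and assigns one of four tiers: `inv-ver` (matched in both an
#' invertebrate and a vertebrate), `inv` (a non-insect invertebrate match),
#' `ins` (a non-native insect match), or `sw` (native species only).
#'
#' @param mature_seq candidate mature sequence.
#' @param ref_matures named character vector (`species-miR-...` names).
#' @param taxon_map named character vector mapping species prefixes to
#'   `silkworm` (native), `insect`, `invertebrate` or `vertebrate`.
#' @param max_mismatch,max_shift matching tolerance (defaults 2 and 3).
#' @return list with `tier` and `matched_refs` (character vector).
#' @export
classify_conservation <- function(mature_seq, ref_matures,
                                  taxon_map = DEFAULT_TAXON_MAP,
                                  max_mismatch = 2L, max_shift = 3L) {
  if (length(ref_matures) == 0L) {
    return(list(tier = "sw", matched_refs = character(0)))
  }
  sp <- sub("-.*$", "", names(ref_matures))
  unknown <- setdiff(unique(sp), names(taxon_map))
  if (length(unknown) > 0) {
    stop("species tag(s) missing from taxon map: ",
         paste(unknown, collapse = ", "))
  }
  hit <- vapply(ref_matures, function(r) {
    seq_match_dist(mature_seq, r, max_shift = max_shift)$mismatches <=
      max_mismatch
  }, logical(1))
  matched <- names(ref_matures)[hit]
  groups <- unname(taxon_map[sp[hit]])
  has_vert <- "vertebrate" %in% groups
  has_invert_any <- any(groups %in% c("silkworm", "insect", "invertebrate"))
  tier <- if (has_vert && has_invert_any) {
    "inv-ver"
  } else if ("invertebrate" %in% groups) {
    "inv"
  } else if ("insect" %in% groups) {
    "ins"
  } else {
    "sw"
  }
  list(tier = tier, matched_refs = matched)
}

#' Detect sense/antisense miRNA pairs
#'
#' Pairs of precursor loci on opposite strands whose genomic intervals
#' overlap reciprocally by at least `min_reciprocal` of each locus' length.
#'
#' @param loci data.frame with `name`, `chrom`, `start`, `end`, `strand`.
#' @param min_reciprocal reciprocal overlap fraction (default 0.5).
#' @return data.frame: `locus_a`, `locus_b` (one row per unordered pair).
#' @export
detect_sense_antisense <- function(loci, min_reciprocal = 0.5) {
  rows <- list()
  n <- nrow(loci)
  if (n >= 2L) for (i in seq_len(n - 1L)) for (j in seq.int(i + 1L, n)) {
    if (loci$chrom[i] != loci$chrom[j]) next
    if (loci$strand[i] == loci$strand[j]) next
    ov <- min(loci$end[i], loci$end[j]) - max(loci$start[i], loci$start[j])
    if (ov <= 0) next
    if (ov / (loci$end[i] - loci$start[i]) >= min_reciprocal &&
        ov / (loci$end[j] - loci$start[j]) >= min_reciprocal) {
      rows[[length(rows) + 1L]] <- data.frame(
        locus_a = loci$name[i], locus_b = loci$name[j],
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(locus_a = character(0), locus_b = character(0),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

#' Genomic context of precursor loci
#'
#' Assigns each precursor interval one context by overlap priority:
#' `te` (transposable element / repeat) > `exonic` > `intronic` >
#' `intergenic`.
#'
#' @param loci data.frame with `chrom`, `start`, `end` (0-based half-open).
#' @param ann an `annotation_set` carrying `repeat`, `exon` and `intron`
#'   intervals.
#' @return character vector of context labels, one per locus.
#' @export
genomic_context <- function(loci, ann) {
  stopifnot(inherits(ann, "annotation_set"))
  if (nrow(loci) == 0L) return(character(0))
  qry <- GenomicRanges::GRanges(
    seqnames = loci$chrom,
    ranges = IRanges::IRanges(start = loci$start + 1L, end = loci$end))
  ov <- GenomicRanges::findOverlaps(qry, ann$gr, minoverlap = 1L,
                                    ignore.strand = TRUE)
  cls <- S4Vectors::mcols(ann$gr)$feature_class[S4Vectors::subjectHits(ov)]
  ctx_prio <- c("te" = 1L, "exonic" = 2L, "intronic" = 3L)
  ctx <- ifelse(cls == "repeat", "te",
         ifelse(cls == "exon", "exonic",
         ifelse(cls == "intron", "intronic", NA_character_)))
  out <- rep("intergenic", nrow(loci))
  keep <- !is.na(ctx)
  if (any(keep)) {
    dt <- data.table::data.table(i = S4Vectors::queryHits(ov)[keep],
                                 p = ctx_prio[ctx[keep]])
    best <- dt[, list(p = min(p)), by = "i"]
    out[best$i] <- names(ctx_prio)[best$p]
  }
  out
}

#' Refine the isoform structure of a called locus
#'
#' Per arm, the dominant isoform is the member tag with the highest total
#' read count (ties: longest, then 5'-most); 5' and 3' end-offset histograms
#' are tallied relative to the dominant isoform; arm dominance is the 5p/3p
#' read ratio; `arm_switch` flags loci whose annotated reference arm is not
#' the arm with the most reads.
#'
#' @param members data.frame of member alignments with `tag_id`, `start`,
#'   `end`, `strand`, `sequence`, `total`.
#' @param precursor list with `start`, `end`, `strand` delimiting the
#'   precursor, and optionally `loop_mid` (genomic midpoint separating the
#'   arms; defaults to the precursor midpoint).
#' @param known_arm annotated arm of a known reference (`"5p"`, `"3p"` or
#'   `NA`).
#' @return list: `dominant` (per-arm dominant tag rows), `offsets` (per-arm
#'   5'/3' offset histograms), `arm_counts`, `arm_dominance`, `arm_switch`.
#' @export
refine_isoforms <- function(members, precursor, known_arm = NA_character_) {
  stopifnot(nrow(members) >= 1L)
  mid <- precursor$loop_mid %||% ((precursor$start + precursor$end) / 2)
  centre <- (members$start + members$end) / 2
  # 5p arm = transcript-upstream arm: low genomic coords on '+', high on '-'
  arm <- if (precursor$strand == "+") {
    ifelse(centre < mid, "5p", "3p")
  } else {
    ifelse(centre >= mid, "5p", "3p")
  }
  members$arm <- arm
  dominant <- list(); offsets <- list(); arm_counts <- c(`5p` = 0L, `3p` = 0L)
  for (a in c("5p", "3p")) {
    sub <- members[members$arm == a, , drop = FALSE]
    if (nrow(sub) == 0L) next
    arm_counts[a] <- sum(sub$total)
    five_pos <- if (precursor$strand == "+") sub$start else -sub$end
    ord <- order(-sub$total, -(sub$end - sub$start), five_pos)
    dom <- sub[ord[1L], , drop = FALSE]
    dominant[[a]] <- dom
    if (precursor$strand == "+") {
      off5 <- sub$start - dom$start
      off3 <- sub$end - dom$end
    } else {
      off5 <- dom$end - sub$end
      off3 <- dom$start - sub$start
    }
    offsets[[a]] <- list(
      off5 = c(tapply(sub$total, off5, sum)),
      off3 = c(tapply(sub$total, off3, sum)))
  }
  max_arm <- names(arm_counts)[which.max(arm_counts)]
  list(dominant = dominant,
       offsets = offsets,
       arm_counts = arm_counts,
       arm_dominance = unname(arm_counts["5p"] / max(arm_counts["3p"], 1L)),
       arm_switch = !is.na(known_arm) && known_arm != max_arm)
}

#' Decide novel-miRNA status for a candidate locus
#'
#' A candidate is novel when it is not known, not discarded by annotation
#' (rRNA/tRNA/snRNA/snoRNA), supported by at least `min_reads` reads in a
#' single library (or pooled across libraries when `pooled = TRUE`), its
#' selected precursor passed the structural filter, and - for exon-sense
#' candidates - its precursor folding p-value is below `max_pvalue`.
#'
#' @param known logical, already called known.
#' @param category the tag category of the locus' mature tag.
#' @param lib_counts numeric vector of per-library locus read counts.
#' @param filter_pass logical, structural filter outcome.
#' @param fold_p folding p-value (NA when not required).
#' @param min_reads novel read threshold (default 5).
#' @param max_pvalue exon-sense rescue threshold, exclusive (default 0.01).
#' @param pooled pool reads across libraries (default FALSE: the threshold
#'   must be met within one library).
#' @return logical.
#' @export
call_novel <- function(known, category, lib_counts, filter_pass,
                       fold_p = NA_real_, min_reads = 5L,
                       max_pvalue = 0.01, pooled = FALSE) {
  if (known) return(FALSE)
  if (category == "ncrna_discard" || category == "known_mirna") return(FALSE)
  enough <- if (pooled) sum(lib_counts) >= min_reads
            else any(lib_counts >= min_reads)
  if (!enough) return(FALSE)
  if (!isTRUE(filter_pass)) return(FALSE)
  if (category == "exon_sense" && !(is.finite(fold_p) && fold_p < max_pvalue)) {
    return(FALSE)
  }
  TRUE
}

#' Summary report over a miRNA catalogue
#'
#' @param catalogue locus catalogue data.frame (see [discover_mirnas()]).
#' @param category_tbl optional per-library category table
#'   ([category_table()]).
#' @param clusters,paralogs,pairs optional outputs of [detect_clusters()],
#'   [group_paralogs()], [detect_sense_antisense()].
#' @return list of summary data.frames: `totals` (known/novel/total gene and
#'   locus counts), `tiers`, `contexts`, plus any supplied tables.
#' @export
build_report <- function(catalogue, category_tbl = NULL, clusters = NULL,
                         paralogs = NULL, pairs = NULL) {
  n_known <- sum(catalogue$status == "known")
  n_novel <- sum(catalogue$status == "novel")
  totals <- data.frame(
    n_known = n_known, n_novel = n_novel, n_total = n_known + n_novel,
    n_loci = nrow(catalogue))
  tiers <- as.data.frame(table(tier = factor(
    catalogue$tier, levels = c("inv-ver", "inv", "ins", "sw"))),
    responseName = "n")
  contexts <- as.data.frame(table(context = factor(
    catalogue$context, levels = c("te", "exonic", "intronic", "intergenic"))),
    responseName = "n")
  out <- list(totals = totals, tiers = tiers, contexts = contexts)
  if (!is.null(category_tbl)) out$categories <- category_tbl
  if (!is.null(clusters)) {
    out$clusters <- clusters
    out$totals$n_clusters <- if (nrow(clusters)) length(unique(clusters$cluster_id)) else 0L
  }
  if (!is.null(paralogs)) {
    out$paralogs <- paralogs
    out$totals$n_paralog_groups <- if (nrow(paralogs)) length(unique(paralogs$group_id)) else 0L
  }
  if (!is.null(pairs)) {
    out$sense_antisense <- pairs
    out$totals$n_sense_antisense_pairs <- nrow(pairs)
  }
  out
}
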