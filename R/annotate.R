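# annotation-priority categorisation of mapped tags

ANNOTATION_CLASSES <- c("known_mirna", "rrna", "trna", "snrna", "snorna",
                        "repeat", "exon", "intron")

# category priority, highest first; exon splits into sense/antisense later
CATEGORY_PRIORITY <- c("known_mirna", "ncrna_discard", "repeat_associated",
                       "exon_sense", "exon_antisense", "intron", "intergenic")

#' Construct a strand-aware annotation set
#'
#' @param df data.frame with columns `chrom`, `start`, `end` (0-based
#'   half-open), `strand`, `feature_class` (one of `known_mirna`, `rrna`,
#'   `trna`, `snrna`, `snorna`, `repeat`, `exon`, `intron`) and `feature_id`;
#'   or a `GRanges` with `feature_class`/`feature_id` metadata columns
#'   (1-based closed, as usual for `GRanges`).
#' @param source free-text provenance label.
#' @return an `annotation_set` object wrapping a `GRanges`.
#' @export
annotation_set <- function(df, source = "user") {
  if (methods::is(df, "GRanges")) {
    gr <- df
  } else {
    stopifnot(all(c("chrom", "start", "end", "strand", "feature_class",
                    "feature_id") %in% names(df)))
    if (nrow(df) > 0 && any(df$start >= df$end)) {
      stop("annotation intervals must satisfy start < end")
    }
    gr <- GenomicRanges::GRanges(
      seqnames = df$chrom,
      ranges = IRanges::IRanges(start = df$start + 1L, end = df$end),
      strand = df$strand
    )
    S4Vectors::mcols(gr)$feature_class <- df$feature_class
    S4Vectors::mcols(gr)$feature_id <- df$feature_id
  }
  bad <- setdiff(unique(S4Vectors::mcols(gr)$feature_class),
                 ANNOTATION_CLASSES)
  if (length(bad) > 0) {
    stop("unknown feature_class value(s): ", paste(bad, collapse = ", "))
  }
  structure(list(gr = gr, source = source), class = "annotation_set")
}

#' Read annotations from a GFF3 file
#'
#' The GFF3 `type` column is mapped to the annotation vocabulary through
#' `class_map`; unmapped types are dropped.
#'
#' @param path GFF3 file.
#' @param class_map named character vector, GFF3 type -> feature class.
#' @return an `annotation_set`.
#' @export
read_annotations <- function(path,
                             class_map = c(known_mirna = "known_mirna",
                                           rRNA = "rrna", tRNA = "trna",
                                           snRNA = "snrna", snoRNA = "snorna",
                                           repeat_region = "repeat",
                                           exon = "exon", intron = "intron",
                                           rrna = "rrna", trna = "trna",
                                           snrna = "snrna", snorna = "snorna",
                                           "repeat" = "repeat")) {
  if (!requireNamespace("rtracklayer", quietly = TRUE)) {
    stop("reading GFF3 requires the rtracklayer package")
  }
  gr <- rtracklayer::import(path, format = "gff3")
  keep <- as.character(gr$type) %in% names(class_map)
  gr <- gr[keep]
  S4Vectors::mcols(gr)$feature_class <-
    unname(class_map[as.character(gr$type)])
  id <- gr$ID
  if (is.null(id)) id <- paste0("feat", seq_along(gr))
  S4Vectors::mcols(gr)$feature_id <- id
  S4Vectors::mcols(gr) <-
    S4Vectors::mcols(gr)[, c("feature_class", "feature_id")]
  annotation_set(gr, source = path)
}

#' Assign each mapped tag to one small-RNA category
#'
#' Overlaps (>= 1 bp, at any of the tag's loci, either strand) are collected
#' against the annotation set and resolved by fixed priority:
#' `known_mirna` > rRNA/tRNA/snRNA/snoRNA (`ncrna_discard`) >
#' `repeat_associated` > `exon_sense` > `exon_antisense` > `intron` >
#' `intergenic`. Tags in the `ncrna_discard` category are ineligible for
#' hairpin discovery; exon-sense tags stay eligible but must later be rescued
#' by a folding p-value below 0.01.
#'
#' @param alignments alignment data.frame from [map_tags()].
#' @param ann an `annotation_set`.
#' @return data.frame: `tag_id`, `category`, `eligible_for_discovery`,
#'   `needs_fold_pvalue`.
#' @export
categorize_tags <- function(alignments, ann) {
  stopifnot(inherits(ann, "annotation_set"))
  tag_ids <- unique(alignments$tag_id)
  if (length(tag_ids) == 0L) {
    return(data.frame(tag_id = character(0), category = character(0),
                      eligible_for_discovery = logical(0),
                      needs_fold_pvalue = logical(0)))
  }
  qry <- GenomicRanges::GRanges(
    seqnames = alignments$chrom,
    ranges = IRanges::IRanges(start = alignments$start + 1L,
                              end = alignments$end),
    strand = alignments$strand
  )
  ov <- GenomicRanges::findOverlaps(qry, ann$gr, minoverlap = 1L,
                                    ignore.strand = TRUE)
  cls <- S4Vectors::mcols(ann$gr)$feature_class[S4Vectors::subjectHits(ov)]
  same_strand <- as.character(GenomicRanges::strand(qry))[S4Vectors::queryHits(ov)] ==
    as.character(GenomicRanges::strand(ann$gr))[S4Vectors::subjectHits(ov)]
  cat_of_overlap <- ifelse(
    cls == "known_mirna", "known_mirna",
    ifelse(cls %in% c("rrna", "trna", "snrna", "snorna"), "ncrna_discard",
    ifelse(cls == "repeat", "repeat_associated",
    ifelse(cls == "exon", ifelse(same_strand, "exon_sense", "exon_antisense"),
           "intron"))))
  prio <- match(cat_of_overlap, CATEGORY_PRIORITY)
  category <- stats::setNames(rep("intergenic", length(tag_ids)), tag_ids)
  if (length(prio) > 0L) {
    dt <- data.table::data.table(
      tag_id = alignments$tag_id[S4Vectors::queryHits(ov)], prio = prio)
    best <- dt[, list(prio = min(prio)), by = tag_id]
    category[best$tag_id] <- CATEGORY_PRIORITY[best$prio]
  }
  data.frame(
    tag_id = tag_ids,
    category = unname(category[tag_ids]),
    eligible_for_discovery = unname(category[tag_ids] != "ncrna_discard"),
    needs_fold_pvalue = unname(category[tag_ids] == "exon_sense"),
    stringsAsFactors = FALSE
  )
}

#' Per-library small-RNA category table
#'
#' Summarises, per library, total and unique read counts per category, with
#' percentages of the library total rounded half-up to two decimals.
#'
#' @param assignments output of [categorize_tags()].
#' @param tags tag table from [collapse_tags()] (must cover every assigned
#'   tag; unmapped tags are ignored).
#' @param libraries library ids (defaults to count columns present).
#' @return data.frame: `library_id`, `category`, `n_reads`, `n_unique`,
#'   `pct_reads`, `pct_unique`.
#' @export
category_table <- function(assignments, tags, libraries = NULL) {
  stopifnot(all(assignments$tag_id %in% tags$tag_id))
  libraries <- libraries %||%
    setdiff(names(tags), c("tag_id", "sequence", "length", "total"))
  rows <- list()
  idx <- match(assignments$tag_id, tags$tag_id)
  cats <- unique(assignments$category)
  for (lib in libraries) {
    cnt <- tags[[lib]][idx]
    tot_reads <- sum(cnt)
    tot_unique <- sum(cnt > 0)
    for (cat in cats) {
      sel <- assignments$category == cat
      rows[[length(rows) + 1L]] <- data.frame(
        library_id = lib, category = cat,
        n_reads = sum(cnt[sel]),
        n_unique = sum(cnt[sel] > 0),
        pct_reads = round_half_up(100 * sum(cnt[sel]) / max(tot_reads, 1L), 2),
        pct_unique = round_half_up(100 * sum(cnt[sel] > 0) /
                                     max(tot_unique, 1L), 2),
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, rows)
}
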