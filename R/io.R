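# writers for the pipeline's tabular and FASTA outputs

#' Write collapsed tags as a count-annotated FASTA plus a count matrix
#'
#' FASTA headers follow the `>tag<N>_x<total>` convention of collapsed
#' small-RNA pipelines; the TSV carries the per-library count matrix.
#'
#' @param tags tag table from [collapse_tags()].
#' @param fasta,tsv output paths (either may be `NULL` to skip).
#' @return invisibly, the tag table.
#' @export
write_tags <- function(tags, fasta = NULL, tsv = NULL) {
  if (!is.null(fasta)) {
    writeLines(paste0(">", tags$tag_id, "_x", tags$total, "\n",
                      tags$sequence), fasta)
  }
  if (!is.null(tsv)) {
    utils::write.table(tags, tsv, sep = "\t", row.names = FALSE,
                       quote = FALSE)
  }
  invisible(tags)
}

#' Write discovery results to a directory
#'
#' Emits the catalogue TSV, the candidate table TSV, a precursor FASTA with
#' dot-bracket structures, mature/star FASTA, a BED6 of accepted loci and
#' the cluster/paralog/pair tables.
#'
#' @param res result list from [discover_mirnas()].
#' @param dir output directory (created if missing).
#' @return invisibly, the vector of written paths.
#' @export
write_discovery <- function(res, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(df, name) {
    p <- file.path(dir, name)
    utils::write.table(df, p, sep = "\t", row.names = FALSE, quote = FALSE)
    p
  }
  paths <- c(
    catalogue = wt(res$catalogue, "catalogue.tsv"),
    candidates = wt(res$candidates, "candidates.tsv"),
    clusters = wt(res$clusters, "clusters.tsv"),
    paralogs = wt(res$paralogs, "paralogs.tsv"),
    pairs = wt(res$pairs, "sense_antisense.tsv"),
    categories = wt(res$category_tbl, "categories.tsv")
  )
  cat_ <- res$catalogue
  if (nrow(cat_) > 0) {
    bed <- data.frame(cat_$chrom, cat_$start, cat_$end, cat_$name, 0,
                      cat_$strand)
    p <- file.path(dir, "loci.bed")
    utils::write.table(bed, p, sep = "\t", row.names = FALSE,
                       col.names = FALSE, quote = FALSE)
    paths["bed"] <- p
    p <- file.path(dir, "mature.fa")
    writeLines(paste0(">", cat_$name, "\n", cat_$mature_seq), p)
    paths["mature"] <- p
    has_star <- !is.na(cat_$star_seq)
    if (any(has_star)) {
      p <- file.path(dir, "star.fa")
      writeLines(paste0(">", cat_$name[has_star], "*\n",
                        cat_$star_seq[has_star]), p)
      paths["star"] <- p
    }
  }
  invisible(paths)
}
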