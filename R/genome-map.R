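# perfect full-length mapping of tags to both genome strands

#' Build an exact-match genome index
#'
#' Prepares a genome for exact full-length substring queries on both strands.
#' Matching is performed with preprocessed dictionaries over the forward
#' strand; minus-strand hits are found by querying reverse complements, and
#' are reported as plus-strand intervals with strand `-`. Non-ACGT characters
#' in the genome are unmatchable.
#'
#' @param genome a named character vector, `DNAStringSet`, or path to a
#'   genome FASTA file.
#' @param seed_width minimum query width supported by the index (default 18,
#'   the shortest tag considered downstream); querying shorter tags errors.
#' @return a `genome_index` object.
#' @export
build_index <- function(genome, seed_width = 18L) {
  if (is.character(genome) && length(genome) == 1L && file.exists(genome)) {
    genome <- Biostrings::readDNAStringSet(genome)
    names(genome) <- sub("\\s.*$", "", names(genome))
  }
  if (is.character(genome)) genome <- Biostrings::DNAStringSet(genome)
  stopifnot(methods::is(genome, "DNAStringSet"))
  if (is.null(names(genome)) || anyNA(names(genome)) ||
      any(!nzchar(names(genome)))) {
    stop("genome sequences must be named")
  }
  if (anyDuplicated(names(genome))) {
    stop("duplicate chromosome names in genome FASTA")
  }
  structure(list(genome = genome, seed_width = as.integer(seed_width)),
            class = "genome_index")
}

#' Map tags to the genome by perfect full-length match
#'
#' Every tag is located at every genomic position (either strand) where its
#' sequence occurs exactly along its entire length. Tags with no hit are
#' reported unmapped; tags with more than `max_hits` loci are flagged
#' hyper-repetitive (excluded from hairpin discovery, retained for the
#' repeat-category tally).
#'
#' @param tags data.frame with `tag_id` and `sequence` columns (ACGT only),
#'   e.g. from [collapse_tags()].
#' @param index a `genome_index` from [build_index()].
#' @param max_hits maximum genomic loci per retained tag (default 20).
#' @return list with `alignments` (data.frame: `tag_id`, `chrom`, `start`,
#'   `end` 0-based half-open, `strand`, `n_genomic_hits`, `hyper_repetitive`;
#'   sorted by chrom, start), and `unmapped` (tag ids with zero hits).
#' @export
map_tags <- function(tags, index, max_hits = 20L) {
  stopifnot(inherits(index, "genome_index"),
            all(c("tag_id", "sequence") %in% names(tags)))
  if (nrow(tags) == 0L) {
    return(list(alignments = empty_alignments(), unmapped = character(0)))
  }
  if (any(nchar(tags$sequence) < index$seed_width)) {
    stop("tag(s) shorter than the index seed width (", index$seed_width, ")")
  }
  genome <- index$genome
  hits <- list()
  for (w in unique(nchar(tags$sequence))) {
    sel <- which(nchar(tags$sequence) == w)
    fwd <- Biostrings::DNAStringSet(tags$sequence[sel])
    rev <- Biostrings::reverseComplement(fwd)
    for (strand_ in c("+", "-")) {
      pd <- Biostrings::PDict(if (strand_ == "+") fwd else rev)
      for (ci in seq_along(genome)) {
        m <- Biostrings::matchPDict(pd, genome[[ci]])
        cnt <- S4Vectors::elementNROWS(m)
        if (sum(cnt) == 0L) next
        st <- unlist(lapply(m, IRanges::start), use.names = FALSE)
        hits[[length(hits) + 1L]] <- data.frame(
          tag_id = rep(tags$tag_id[sel], cnt),
          chrom = names(genome)[ci],
          start = st - 1L,
          end = st - 1L + w,
          strand = strand_,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  if (length(hits) == 0L) {
    return(list(alignments = empty_alignments(),
                unmapped = tags$tag_id))
  }
  aln <- do.call(rbind, hits)
  nh <- table(aln$tag_id)
  aln$n_genomic_hits <- as.integer(nh[aln$tag_id])
  aln$hyper_repetitive <- aln$n_genomic_hits > max_hits
  aln <- aln[order(aln$chrom, aln$start, aln$strand, aln$tag_id), ,
             drop = FALSE]
  rownames(aln) <- NULL
  list(alignments = aln,
       unmapped = setdiff(tags$tag_id, unique(aln$tag_id)))
}

#' @keywords internal
empty_alignments <- function() {
  data.frame(tag_id = character(0), chrom = character(0),
             start = integer(0), end = integer(0), strand = character(0),
             n_genomic_hits = integer(0), hyper_repetitive = logical(0),
             stringsAsFactors = FALSE)
}
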