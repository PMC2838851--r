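# raw FASTQ -> unique, length-filtered, counted tags

#' Filter reads on mean base quality and N content
#'
#' A read passes when its mean Phred quality is at least `min_mean_q` and it
#' contains at most `max_n` ambiguous bases. Whole reads are accepted or
#' rejected; no end trimming is performed.
#'
#' @param reads data.frame with columns `read_id`, `sequence`, `quality`
#'   (quality string, same length as the sequence).
#' @param min_mean_q minimum mean Phred score (default 20).
#' @param max_n maximum number of N bases (default 0).
#' @param offset quality encoding offset (33 for Phred+33, 64 for Phred+64).
#' @return list with `pass` (the surviving rows), `n_low_quality` and
#'   `n_input`.
#' @export
quality_filter <- function(reads, min_mean_q = 20, max_n = 0L, offset = 33L) {
  stopifnot(is.data.frame(reads),
            all(c("read_id", "sequence", "quality") %in% names(reads)))
  bad_len <- nchar(reads$sequence) != nchar(reads$quality)
  if (any(bad_len)) {
    stop("sequence/quality length mismatch for read(s): ",
         paste(utils::head(reads$read_id[bad_len], 3), collapse = ", "))
  }
  if (nrow(reads) == 0L) {
    return(list(pass = reads, n_low_quality = 0L, n_input = 0L))
  }
  qmean <- vapply(reads$quality,
                  function(q) mean(utf8ToInt(q)) - offset, numeric(1),
                  USE.NAMES = FALSE)
  nN <- nchar(reads$sequence) - nchar(gsub("N", "", reads$sequence, fixed = TRUE))
  keep <- qmean >= min_mean_q & nN <= max_n
  list(pass = reads[keep, , drop = FALSE],
       n_low_quality = sum(!keep),
       n_input = nrow(reads))
}

#' Clip the 3' adapter from reads
#'
#' Finds, for each read, the leftmost ungapped semi-global alignment of the
#' adapter prefix to a read suffix with overlap of at least `min_overlap`
#' bases and a mismatch rate of at most `max_error_rate`, and returns the 5'
#' insert. Reads in which no adapter is detected return `NA` (un-ligated
#' molecules of indeterminate insert length).
#'
#' @param sequences character vector of read sequences.
#' @param adapter 3' adapter sequence (DNA).
#' @param min_overlap minimum adapter overlap (default 6).
#' @param max_error_rate maximum mismatches/overlap (default 0.1).
#' @return character vector of inserts (possibly empty strings for
#'   adapter-dimers), `NA` where no adapter was found.
#' @export
clip_adapter3 <- function(sequences, adapter, min_overlap = 6L,
                          max_error_rate = 0.1) {
  stopifnot(nchar(adapter) >= 1L)
  adapter <- toupper(adapter)
  if (length(sequences) == 0L) return(character(0))
  av <- strsplit(adapter, "", fixed = TRUE)[[1]]
  alen <- length(av)
  out <- rep(NA_character_, length(sequences))
  for (grp in split(seq_along(sequences), nchar(sequences))) {
    L <- nchar(sequences[grp[1L]])
    if (L < min_overlap) next
    M <- matrix(unlist(strsplit(toupper(sequences[grp]), "", fixed = TRUE)),
                nrow = length(grp), ncol = L, byrow = TRUE)
    cut <- rep(NA_integer_, length(grp))
    for (j in 0:(L - min_overlap)) {       # j = candidate insert length
      w <- min(L - j, alen)
      if (w < min_overlap) break
      mism <- rowSums(M[, (j + 1):(j + w), drop = FALSE] !=
                        matrix(av[seq_len(w)], nrow = length(grp), ncol = w,
                               byrow = TRUE))
      hit <- is.na(cut) & (mism / w) <= max_error_rate
      cut[hit] <- j
    }
    found <- !is.na(cut)
    out[grp[found]] <- substr(sequences[grp[found]], 1L, cut[found])
  }
  out
}

#' Flag 5' adapter contaminants
#'
#' An insert is a ligation contaminant when its 5' end reproduces a suffix of
#' the 5' adapter over at least `min_prefix` bases with at most one mismatch.
#'
#' @param inserts character vector of clipped inserts.
#' @param adapter5 the 5' adapter sequence (DNA).
#' @param min_prefix minimum matched prefix length (default 8).
#' @return logical vector, `TRUE` = keep (not a contaminant).
#' @export
drop_5p_contaminants <- function(inserts, adapter5, min_prefix = 8L) {
  adapter5 <- toupper(adapter5)
  alen <- nchar(adapter5)
  keep <- rep(TRUE, length(inserts))
  up <- toupper(inserts)
  for (L in seq.int(min_prefix, alen)) {
    suf <- substr(adapter5, alen - L + 1L, alen)
    cand <- which(keep & nchar(up) >= L)
    if (length(cand) == 0L) next
    pre <- substr(up[cand], 1L, L)
    sv <- strsplit(suf, "", fixed = TRUE)[[1]]
    mism <- vapply(strsplit(pre, "", fixed = TRUE),
                   function(p) sum(p != sv), integer(1))
    keep[cand[mism <= 1L]] <- FALSE
  }
  keep
}

#' Collapse inserts into unique counted tags
#'
#' Identical insert sequences are merged within and across libraries into
#' tags carrying per-library read counts. Inserts shorter than `min_len`,
#' longer than `max_len`, or containing N are excluded and tallied.
#'
#' @param inserts data.frame with columns `library_id` and `sequence`.
#' @param min_len minimum insert length retained (default 18).
#' @param max_len maximum insert length retained (default 30, matching a
#'   16-30 nt size selection with the lower bound superseded by `min_len`).
#' @return list with `tags` (data.frame: `tag_id`, `sequence`, `length`, one
#'   count column per library, `total`; sorted by total count descending then
#'   sequence), `libraries`, and `n_excluded` (short/long/N tally).
#' @export
collapse_tags <- function(inserts, min_len = 18L, max_len = 30L) {
  stopifnot(min_len >= 1L,
            all(c("library_id", "sequence") %in% names(inserts)))
  libs <- unique(as.character(inserts$library_id))
  len <- nchar(inserts$sequence)
  ok <- len >= min_len & len <= max_len &
    !grepl("N", inserts$sequence, fixed = TRUE)
  n_excluded <- sum(!ok)
  dt <- data.table::data.table(
    library_id = as.character(inserts$library_id)[ok],
    sequence = toupper(inserts$sequence[ok])
  )
  if (nrow(dt) == 0L) {
    tags <- data.frame(tag_id = character(0), sequence = character(0),
                       length = integer(0), total = integer(0))
    for (l in libs) tags[[l]] <- integer(0)
    return(list(tags = tags, libraries = libs, n_excluded = n_excluded))
  }
  counts <- dt[, list(n = .N), by = list(sequence, library_id)]
  wide <- data.table::dcast(counts, sequence ~ library_id,
                            value.var = "n", fill = 0L)
  for (l in setdiff(libs, names(wide))) wide[[l]] <- 0L
  data.table::setcolorder(wide, c("sequence", libs))
  wide$total <- as.integer(rowSums(wide[, libs, with = FALSE]))
  data.table::setorderv(wide, c("total", "sequence"), order = c(-1L, 1L))
  tags <- as.data.frame(wide)
  tags <- cbind(
    data.frame(tag_id = sprintf("tag%06d", seq_len(nrow(tags))),
               sequence = tags$sequence,
               length = nchar(tags$sequence),
               stringsAsFactors = FALSE),
    tags[, c(libs, "total"), drop = FALSE]
  )
  list(tags = tags, libraries = libs, n_excluded = n_excluded)
}

#' Run the full preprocessing stage on FASTQ files
#'
#' Quality filter, 3' adapter clipping, 5' contaminant removal, length filter
#' and collapsing, with a stage-by-stage summary suitable for reporting.
#'
#' @param fastq_files character vector of FASTQ paths (Phred+33 by default).
#' @param library_ids one id per file.
#' @param adapter3,adapter5 adapter sequences (DNA).
#' @param min_mean_q,max_n quality-filter settings (see [quality_filter()]).
#' @param min_overlap,max_error_rate adapter-clip settings.
#' @param min_prefix 5'-contaminant setting.
#' @param min_len,max_len collapse length window.
#' @param offset quality encoding offset.
#' @return list with `tags`, `libraries`, and `summary` (per-library counts
#'   for every stage, with percentages of raw reads).
#' @export
preprocess_reads <- function(fastq_files, library_ids,
                             adapter3, adapter5,
                             min_mean_q = 20, max_n = 0L,
                             min_overlap = 6L, max_error_rate = 0.1,
                             min_prefix = 8L,
                             min_len = 18L, max_len = 30L,
                             offset = 33L) {
  stopifnot(length(fastq_files) == length(library_ids))
  all_inserts <- list()
  summaries <- list()
  for (i in seq_along(fastq_files)) {
    fq <- ShortRead::readFastq(fastq_files[i])
    reads <- data.frame(
      read_id = as.character(ShortRead::id(fq)),
      sequence = as.character(ShortRead::sread(fq)),
      quality = as.character(Biostrings::quality(Biostrings::quality(fq))),
      stringsAsFactors = FALSE
    )
    summaries[[i]] <- preprocess_library(
      reads, library_ids[i], adapter3, adapter5, min_mean_q, max_n,
      min_overlap, max_error_rate, min_prefix, offset)
    all_inserts[[i]] <- summaries[[i]]$inserts
  }
  inserts <- do.call(rbind, all_inserts)
  col <- collapse_tags(inserts, min_len = min_len, max_len = max_len)
  summary <- do.call(rbind, lapply(summaries, function(s) s$summary))
  list(tags = col$tags, libraries = as.character(library_ids),
       summary = summary, n_excluded_collapse = col$n_excluded)
}

# one library worth of reads -> clean inserts + stage summary
#' @keywords internal
preprocess_library <- function(reads, library_id, adapter3, adapter5,
                               min_mean_q, max_n, min_overlap, max_error_rate,
                               min_prefix, offset) {
  qf <- quality_filter(reads, min_mean_q = min_mean_q, max_n = max_n,
                       offset = offset)
  ins <- clip_adapter3(qf$pass$sequence, adapter3,
                       min_overlap = min_overlap,
                       max_error_rate = max_error_rate)
  n_no_adapter <- sum(is.na(ins))
  ins <- ins[!is.na(ins)]
  keep <- drop_5p_contaminants(ins, adapter5, min_prefix = min_prefix)
  n_contam <- sum(!keep)
  ins <- ins[keep]
  summary <- preprocess_summary_row(
    library_id,
    n_raw = qf$n_input, n_low_quality = qf$n_low_quality,
    n_no_adapter = n_no_adapter, n_contaminant_5p = n_contam,
    n_clean = length(ins))
  list(inserts = data.frame(library_id = library_id, sequence = ins,
                            stringsAsFactors = FALSE),
       summary = summary)
}

#' Preprocessing summary row with printed-style percentages
#'
#' Turns raw stage counts into the per-library filtration table: low and high
#' quality reads and downstream losses, each with its percentage of the raw
#' total (rounded half-up to two decimals, the convention of printed
#' filtration tables).
#'
#' @param library_id library label.
#' @param n_raw total raw reads.
#' @param n_low_quality reads failing the quality filter.
#' @param n_no_adapter reads without a detectable 3' adapter.
#' @param n_contaminant_5p 5' adapter-ligation contaminants.
#' @param n_clean clean inserts entering the collapse.
#' @return one-row data.frame with counts and `pct_*` columns.
#' @export
preprocess_summary_row <- function(library_id, n_raw, n_low_quality,
                                   n_no_adapter = 0L, n_contaminant_5p = 0L,
                                   n_clean = NA_integer_) {
  n_high_quality <- n_raw - n_low_quality
  pct <- function(x) round_half_up(100 * x / n_raw, 2)
  data.frame(
    library_id = library_id,
    n_raw = n_raw,
    n_low_quality = n_low_quality,
    n_high_quality = n_high_quality,
    n_no_adapter = n_no_adapter,
    n_contaminant_5p = n_contaminant_5p,
    n_clean = n_clean,
    pct_low_quality = pct(n_low_quality),
    pct_high_quality = pct(n_high_quality),
    stringsAsFactors = FALSE
  )
}
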