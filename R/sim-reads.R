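# simulate raw 35-nt small RNA-seq reads from a synthetic reference

#' Simulate small RNA-seq libraries from a synthetic reference
#'
#' Each expressed hairpin locus receives a negative-binomial total read count
#' per library, split into mature isoforms (5'/3' end offsets drawn from the
#' configured shift distributions), star reads and loop reads. Decoy
#' rRNA/tRNA loci emit uniformly positioned degradation fragments, exonic
#' fragment loci emit an mRNA-degradation hotspot, and intergenic noise loci
#' emit a handful of reads. Every insert is 3'-extended with the 3' adapter
#' and truncated/padded to the raw read length; a configured fraction of
#' reads receive failing qualities, 5'-adapter contaminant inserts, and
#' per-base substitution errors.
#'
#' Read ids carry the ground truth
#' (`locus|arm|offset5|offset3|clean|contaminant|serial`) so downstream
#' results can be checked against the manifest.
#'
#' @param ref a `sim_reference` from [build_reference()].
#' @param n_libraries number of libraries to simulate (default 3).
#' @param config simulation configuration (defaults to `ref$config`).
#' @return list with `reads` (named list of per-library data.frames:
#'   `read_id`, `sequence`, `quality`), `counts` (per-locus per-library
#'   planted counts, including error-free "clean" tallies), `truth` (the
#'   manifest with `expected_call` finalised against the planted counts) and
#'   `libraries`.
#' @export
simulate_reads <- function(ref, n_libraries = 3L, config = ref$config) {
  stopifnot(inherits(ref, "sim_reference"))
  if (n_libraries < 1L) stop("n_libraries must be >= 1")
  withr::with_seed(config$seed + 104729L,
                   simulate_reads_impl(ref, n_libraries, config))
}

#' @keywords internal
simulate_reads_impl <- function(ref, n_libraries, cfg) {
  libs <- sprintf("lib%d", seq_len(n_libraries))
  genome <- ref$genome
  truth <- ref$truth
  offsets <- -2:2
  nb_size <- 1 / cfg$count_dispersion

  draw_span_reads <- function(row, span_start, span_end, n, shift = TRUE) {
    if (n == 0L) return(character(0))
    if (shift) {
      o5 <- sample(offsets, n, replace = TRUE, prob = cfg$end_shift_probs$p5)
      o3 <- sample(offsets, n, replace = TRUE, prob = cfg$end_shift_probs$p3)
    } else {
      o5 <- o3 <- rep(0L, n)
    }
    if (row$strand == "+") {
      s <- span_start + o5; e <- span_end + o3
    } else {
      s <- span_start - o3; e <- span_end - o5
    }
    clen <- nchar(genome[[row$chrom]])
    s <- pmax(0L, s); e <- pmin(clen, e)
    ins <- vapply(seq_len(n), function(i) {
      genome_seq_chr(genome, row$chrom, s[i], e[i], row$strand)
    }, character(1))
    attr(ins, "o5") <- o5; attr(ins, "o3") <- o3
    ins
  }

  all_reads <- stats::setNames(vector("list", n_libraries), libs)
  count_rows <- list()
  for (lib in libs) {
    inserts <- character(0); meta <- list()
    add <- function(ins, locus, arm, o5 = NULL, o3 = NULL) {
      if (length(ins) == 0L) return(invisible())
      o5 <- o5 %||% attr(ins, "o5") %||% rep(NA_integer_, length(ins))
      o3 <- o3 %||% attr(ins, "o3") %||% rep(NA_integer_, length(ins))
      inserts <<- c(inserts, as.character(ins))
      meta[[length(meta) + 1L]] <<- data.frame(
        locus_id = locus, arm = arm, o5 = o5, o3 = o3,
        stringsAsFactors = FALSE)
    }
    for (r in seq_len(nrow(truth))) {
      row <- truth[r, ]
      cls <- row$feature_class
      if (cls %in% c("true_mirna", "te_mirna")) {
        total <- stats::rnbinom(1L, mu = cfg$count_mean, size = nb_size)
        n_loop <- stats::rbinom(1L, total, cfg$loop_read_rate)
        n_star <- stats::rbinom(1L, total - n_loop, cfg$star_fraction)
        n_mat <- total - n_loop - n_star
        add(draw_span_reads(row, row$mature_start, row$mature_end, n_mat),
            row$locus_id, "mature")
        add(draw_span_reads(row, row$star_start, row$star_end, n_star),
            row$locus_id, "star")
        if (n_loop > 0L) {
          lens <- sample(18:22, n_loop, replace = TRUE)
          anchor <- if (row$strand == "+") row$loop_start else row$loop_end
          starts <- if (row$strand == "+") {
            pmax(0L, anchor - sample(2:8, n_loop, replace = TRUE))
          } else {
            anchor + sample(2:8, n_loop, replace = TRUE) - lens
          }
          ins <- vapply(seq_len(n_loop), function(i) {
            genome_seq_chr(genome, row$chrom, starts[i], starts[i] + lens[i],
                           row$strand)
          }, character(1))
          add(ins, row$locus_id, "loop")
        }
      } else if (cls %in% c("rrna_decoy", "trna_decoy")) {
        total <- stats::rnbinom(1L, mu = 30, size = 1)
        if (total > 0L) {
          lens <- sample(18:28, total, replace = TRUE)
          starts <- row$start +
            vapply(lens, function(l) {
              sample.int(max(row$end - row$start - l, 1L), 1L) - 1L
            }, integer(1))
          ins <- vapply(seq_len(total), function(i) {
            genome_seq_chr(genome, row$chrom, starts[i], starts[i] + lens[i],
                           row$strand)
          }, character(1))
          add(ins, row$locus_id, "frag")
        }
      } else if (cls == "exon_fragment") {
        total <- stats::rnbinom(1L, mu = 15, size = 1)
        add(draw_span_reads(row, row$start, row$end, total),
            row$locus_id, "frag")
      } else if (cls == "intergenic_noise") {
        total <- sample(0:4, 1L)
        add(draw_span_reads(row, row$start, row$end, total),
            row$locus_id, "frag")
      }
    }
    meta <- data.table::rbindlist(meta)
    meta <- as.data.frame(meta)
    n <- nrow(meta)
    if (n == 0L) {
      all_reads[[lib]] <- data.frame(read_id = character(0),
                                     sequence = character(0),
                                     quality = character(0))
      next
    }

    ## library construction artefacts
    contam <- stats::runif(n) < cfg$adapter5_contam_rate
    if (any(contam)) {
      a5 <- cfg$adapter5
      pre_len <- sample(10:16, sum(contam), replace = TRUE)
      keep_len <- sample(4:8, sum(contam), replace = TRUE)
      inserts[contam] <- paste0(
        substr(rep(a5, sum(contam)), nchar(a5) - pre_len + 1L, nchar(a5)),
        substr(inserts[contam], 1L, keep_len))
    }
    raw <- substr(paste0(inserts, cfg$adapter3,
                         strrep("A", cfg$raw_read_len)),
                  1L, cfg$raw_read_len)
    ## per-base substitution errors
    has_err <- logical(n)
    if (cfg$error_rate > 0) {
      errmat <- matrix(stats::runif(n * cfg$raw_read_len) < cfg$error_rate,
                       nrow = n)
      has_err <- rowSums(errmat) > 0L
      for (i in which(has_err)) {
        v <- strsplit(raw[i], "", fixed = TRUE)[[1]]
        for (p in which(errmat[i, ])) {
          v[p] <- sample(setdiff(c("A", "C", "G", "T"), v[p]), 1L)
        }
        raw[i] <- paste(v, collapse = "")
      }
    }
    lowq <- stats::runif(n) < cfg$lowq_fraction
    qual <- vapply(seq_len(n), function(i) {
      q <- if (lowq[i]) sample(6:14, cfg$raw_read_len, replace = TRUE)
      else sample(34:40, cfg$raw_read_len, replace = TRUE)
      intToUtf8(q + 33L)
    }, character(1))
    clean <- !contam & !lowq & !has_err
    read_id <- sprintf("%s|%s|%s|%s|%d|%d|%s_%06d",
                       meta$locus_id, meta$arm,
                       ifelse(is.na(meta$o5), ".", meta$o5),
                       ifelse(is.na(meta$o3), ".", meta$o3),
                       as.integer(clean), as.integer(contam),
                       lib, seq_len(n))
    all_reads[[lib]] <- data.frame(read_id = read_id, sequence = raw,
                                   quality = qual, stringsAsFactors = FALSE)
    cr <- data.table::data.table(
      locus_id = meta$locus_id, arm = meta$arm, clean = clean)
    agg <- cr[, list(
      n_total = .N,
      n_mature = sum(arm == "mature"),
      n_star = sum(arm == "star"),
      n_loop = sum(arm == "loop"),
      n_clean = sum(clean),
      n_clean_mature = sum(clean & arm == "mature")
    ), by = "locus_id"]
    agg$library_id <- lib
    count_rows[[lib]] <- agg
  }
  counts <- as.data.frame(data.table::rbindlist(count_rows))
  ## ensure every locus x library combination is present (zero-filled)
  full <- expand.grid(locus_id = truth$locus_id, library_id = libs,
                      stringsAsFactors = FALSE)
  counts <- merge(full, counts, by = c("locus_id", "library_id"),
                  all.x = TRUE)
  num <- setdiff(names(counts), c("locus_id", "library_id", "arm"))
  for (cn in num) counts[[cn]][is.na(counts[[cn]])] <- 0L
  counts$arm <- NULL

  ## finalise expected calls against the planted clean counts
  truth$expected_call <- finalize_expected_calls(truth, counts)
  list(reads = all_reads, counts = counts, truth = truth, libraries = libs)
}

#' @keywords internal
finalize_expected_calls <- function(truth, counts) {
  mx <- function(col) {
    dt <- data.table::as.data.table(counts)
    m <- dt[, list(v = max(get(col))), by = "locus_id"]
    stats::setNames(m$v, m$locus_id)
  }
  max_clean <- mx("n_clean")
  max_clean_mat <- mx("n_clean_mature")
  vapply(seq_len(nrow(truth)), function(i) {
    row <- truth[i, ]
    if (!row$feature_class %in% c("true_mirna", "te_mirna")) return("rejected")
    has_native_ref <- grepl("(^|,)bmo(,|$)", row$ref_species)
    if (has_native_ref) {
      if (max_clean_mat[[row$locus_id]] >= 2L) "known" else "rejected"
    } else {
      if (max_clean[[row$locus_id]] >= 5L) "novel" else "rejected"
    }
  }, character(1))
}

# character-genome variant of genome_seq (transcript orientation)
#' @keywords internal
genome_seq_chr <- function(genome, chrom, start, end, strand = "+") {
  s <- substr(genome[[chrom]], start + 1L, end)
  if (strand == "-") s <- revcomp(s)
  s
}

#' Write a simulated data set to disk
#'
#' Writes the genome FASTA, reference mature FASTA (DNA form), annotation
#' GFF3, ground-truth manifest TSV, per-locus count table TSV and one
#' Phred+33 FASTQ per library.
#'
#' @param ref a `sim_reference`.
#' @param sim output of [simulate_reads()].
#' @param dir output directory (created if missing).
#' @return invisibly, the named vector of written paths.
#' @export
write_simulation <- function(ref, sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(genome = file.path(dir, "genome.fa"),
             matures = file.path(dir, "reference_matures.fa"),
             annotations = file.path(dir, "annotations.gff3"),
             truth = file.path(dir, "truth.tsv"),
             counts = file.path(dir, "counts.tsv"))
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(ref$genome),
                              paths["genome"])
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(ref$ref_matures),
                              paths["matures"])
  write_gff3(ref$annotations, paths["annotations"])
  utils::write.table(sim$truth, paths["truth"], sep = "\t", row.names = FALSE,
                     quote = FALSE)
  utils::write.table(sim$counts, paths["counts"], sep = "\t",
                     row.names = FALSE, quote = FALSE)
  for (lib in sim$libraries) {
    fq <- file.path(dir, paste0(lib, ".fastq"))
    paths[lib] <- fq
    rd <- sim$reads[[lib]]
    sr <- ShortRead::ShortReadQ(
      sread = Biostrings::DNAStringSet(rd$sequence),
      quality = Biostrings::BStringSet(rd$quality),
      id = Biostrings::BStringSet(rd$read_id))
    ShortRead::writeFastq(sr, fq, mode = "w", compress = FALSE)
  }
  invisible(paths)
}

# minimal GFF3 writer for an annotation_set (type column = feature class)
#' @keywords internal
write_gff3 <- function(ann, path) {
  gr <- ann$gr
  df <- data.frame(
    seqid = as.character(GenomicRanges::seqnames(gr)),
    source = "mirforge_sim",
    type = S4Vectors::mcols(gr)$feature_class,
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    score = ".",
    strand = as.character(GenomicRanges::strand(gr)),
    phase = ".",
    attributes = paste0("ID=", S4Vectors::mcols(gr)$feature_id),
    stringsAsFactors = FALSE
  )
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  utils::write.table(df, con, sep = "\t", row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
}
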