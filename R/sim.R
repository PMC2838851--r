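# synthetic reference and read simulation with a ground-truth manifest

DEFAULT_TAXON_MAP <- c(
  bmo = "silkworm",
  dme = "insect", aga = "insect", tca = "insect",
  cel = "invertebrate", lgi = "invertebrate",
  hsa = "vertebrate", mmu = "vertebrate", gga = "vertebrate"
)

#' Build a synthetic genome, annotations, reference matures and ground truth
#'
#' Plants miRNA hairpins (mature + 8-15 nt loop + near-reverse-complement
#' star with up to 2 engineered mismatches), repeat-embedded hairpins, decoy
#' rRNA/tRNA loci, gene models with exon/intron structure, intergenic noise
#' loci and optional sense/antisense hairpin pairs into a random genome.
#' Every planted hairpin is folded with the pipeline's folding engine and
#' redesigned until its MFE is at most -25 kcal/mol. A configurable subset of
#' planted matures is copied (with up to 2 substitutions) into the reference
#' mature database under species tags spanning the four conservation tiers.
#'
#' @param config a [sim_config()] object.
#' @param engine folding engine forwarded to [fold_rna()].
#' @return a `sim_reference` list: `genome` (named character), `annotations`
#'   (an `annotation_set`), `ref_matures` (named character vector, names are
#'   `species-miR-simNNN` identifiers), `taxon_map`, `truth` (the
#'   ground-truth manifest data.frame) and `config`.
#' @export
build_reference <- function(config = sim_config(), engine = NULL) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed, build_reference_impl(config, engine))
}

#' @keywords internal
build_reference_impl <- function(cfg, engine) {
  chroms <- sprintf("chr%d", seq_len(cfg$n_chromosomes))
  genome <- stats::setNames(
    random_dna(cfg$n_chromosomes, cfg$chrom_length, gc = 0.5), chroms)

  occupied <- stats::setNames(
    rep(list(data.frame(start = integer(0), end = integer(0))), length(chroms)),
    chroms)
  place <- function(len, gap = 40L) {
    for (try in seq_len(4000L)) {
      chrom <- sample(chroms, 1L)
      if (cfg$chrom_length - len < 1L) break
      pos <- sample.int(cfg$chrom_length - len, 1L) - 1L
      occ <- occupied[[chrom]]
      if (nrow(occ) == 0L ||
          all(pos + len + gap <= occ$start | pos >= occ$end + gap)) {
        occupied[[chrom]] <<- rbind(occ,
                                    data.frame(start = pos, end = pos + len))
        return(list(chrom = chrom, start = pos, end = pos + len))
      }
    }
    stop("chromosome too short to host requested features: no free slot of ",
         len, " nt (+", gap, " nt gap) after 4000 placement attempts")
  }

  ## gene models: 3 exons (~150 nt) separated by 2 introns (~200 nt)
  ann_rows <- list()
  gene_models <- list()
  if (cfg$n_gene_models > 0) for (g in seq_len(cfg$n_gene_models)) {
    ex_len <- sample(120:180, 3L, replace = TRUE)
    in_len <- sample(150:250, 2L, replace = TRUE)
    total <- sum(ex_len) + sum(in_len)
    slot <- place(total, gap = 60L)
    strand <- sample(c("+", "-"), 1L)
    off <- slot$start
    parts <- list()
    for (k in 1:3) {
      parts[[length(parts) + 1L]] <- data.frame(
        chrom = slot$chrom, start = off, end = off + ex_len[k],
        strand = strand, feature_class = "exon",
        feature_id = sprintf("gene%02d.exon%d", g, k))
      off <- off + ex_len[k]
      if (k < 3) {
        parts[[length(parts) + 1L]] <- data.frame(
          chrom = slot$chrom, start = off, end = off + in_len[k],
          strand = strand, feature_class = "intron",
          feature_id = sprintf("gene%02d.intron%d", g, k))
        off <- off + in_len[k]
      }
    }
    ann_rows <- c(ann_rows, parts)
    gene_models[[g]] <- do.call(rbind, parts)
  }

  ## decoy rRNA/tRNA loci (annotation intervals over random sequence)
  truth_rows <- list()
  decoy_classes <- rep_len(c("rrna", "trna"), cfg$n_decoy_ncrna)
  if (cfg$n_decoy_ncrna > 0) for (d in seq_len(cfg$n_decoy_ncrna)) {
    cls <- decoy_classes[d]
    len <- if (cls == "rrna") sample(120:180, 1L) else sample(70:90, 1L)
    slot <- place(len)
    strand <- sample(c("+", "-"), 1L)
    id <- sprintf("%s%02d", cls, d)
    ann_rows[[length(ann_rows) + 1L]] <- data.frame(
      chrom = slot$chrom, start = slot$start, end = slot$end,
      strand = strand, feature_class = cls, feature_id = id)
    truth_rows[[length(truth_rows) + 1L]] <- truth_row(
      id, slot$chrom, slot$start, slot$end, strand,
      feature_class = paste0(cls, "_decoy"), expected_call = "rejected")
  }

  ## hairpin designs: true miRNAs, TE miRNAs and antisense-pair bases
  n_hp <- cfg$n_true_mirnas + cfg$n_te_mirnas + cfg$n_antisense_pairs
  designs <- lapply(seq_len(n_hp), function(i) design_hairpin(cfg))
  is_as_base <- seq_len(n_hp) > cfg$n_true_mirnas + cfg$n_te_mirnas
  designs <- validate_hairpins(designs, cfg, engine, with_antisense = is_as_base)

  ## conservation tier plan for the reference database
  n_true <- cfg$n_true_mirnas
  known_idx <- if (n_true > 0) {
    utils::head(seq_len(n_true), round(cfg$known_fraction * n_true))
  } else integer(0)
  tier_cycle <- rep_len(c("inv-ver", "inv", "ins", "sw"),
                        max(length(known_idx), 1L))
  ref_seqs <- character(0)

  plant <- function(design, id, strand, slot) {
    hp <- design$hairpin
    sub <- if (strand == "+") hp else revcomp(hp)
    substr(genome[[slot$chrom]], slot$start + 1L, slot$end) <<- sub
    g <- function(i1, i2) {      # hairpin 1-based span -> genomic 0-based
      L <- nchar(hp)
      if (strand == "+") c(slot$start + i1 - 1L, slot$start + i2)
      else c(slot$start + L - i2, slot$start + L - i1 + 1L)
    }
    list(mature = g(design$m_span[1L], design$m_span[2L]),
         star = g(design$s_span[1L], design$s_span[2L]),
         loop = g(design$l_span[1L], design$l_span[2L]))
  }

  mk_refs <- function(mature, base, species) {
    for (sp in species) {
      seq <- mutate_seq(mature, sample(0:2, 1L))
      ref_seqs[[sprintf("%s-miR-sim%03d", sp, base)]] <<- seq
    }
  }

  for (i in seq_len(n_true)) {
    d <- designs[[i]]
    slot <- place(nchar(d$hairpin))
    strand <- sample(c("+", "-"), 1L)
    id <- sprintf("mir%03d", i)
    spans <- plant(d, id, strand, slot)
    is_known <- i %in% known_idx
    tier <- "sw"; species <- character(0)
    if (is_known) {
      tier <- tier_cycle[match(i, known_idx)]
      species <- switch(tier,
                        "inv-ver" = c("bmo", "dme", "hsa"),
                        "inv" = c("bmo", "cel"),
                        "ins" = c("bmo", "tca"),
                        "sw" = "bmo")
    } else if (i %% 5L == 0L) {
      # some novel loci have non-native orthologs (insect tier)
      tier <- "ins"; species <- "dme"
    }
    if (length(species) > 0) mk_refs(d$mature, i, species)
    if (is_known) {
      ann_rows[[length(ann_rows) + 1L]] <- data.frame(
        chrom = slot$chrom, start = slot$start, end = slot$end,
        strand = strand, feature_class = "known_mirna",
        feature_id = sprintf("bmo-mir-sim%03d", i))
    }
    truth_rows[[length(truth_rows) + 1L]] <- truth_row(
      id, slot$chrom, slot$start, slot$end, strand,
      feature_class = "true_mirna",
      mature_seq = d$mature, star_seq = d$star,
      expected_call = if (is_known) "known" else "novel",
      mature_start = spans$mature[1L], mature_end = spans$mature[2L],
      star_start = spans$star[1L], star_end = spans$star[2L],
      loop_start = spans$loop[1L], loop_end = spans$loop[2L],
      arm = d$arm, tier = tier,
      ref_species = paste(species, collapse = ","))
  }

  for (j in seq_len(cfg$n_te_mirnas)) {
    d <- designs[[n_true + j]]
    slot <- place(nchar(d$hairpin) + 40L)
    strand <- sample(c("+", "-"), 1L)
    hp_slot <- list(chrom = slot$chrom, start = slot$start + 20L,
                    end = slot$end - 20L)
    id <- sprintf("temir%03d", j)
    spans <- plant(d, id, strand, hp_slot)
    ann_rows[[length(ann_rows) + 1L]] <- data.frame(
      chrom = slot$chrom, start = slot$start, end = slot$end,
      strand = "+", feature_class = "repeat",
      feature_id = sprintf("TE%03d", j))
    truth_rows[[length(truth_rows) + 1L]] <- truth_row(
      id, hp_slot$chrom, hp_slot$start, hp_slot$end, strand,
      feature_class = "te_mirna",
      mature_seq = d$mature, star_seq = d$star,
      expected_call = "novel",
      mature_start = spans$mature[1L], mature_end = spans$mature[2L],
      star_start = spans$star[1L], star_end = spans$star[2L],
      loop_start = spans$loop[1L], loop_end = spans$loop[2L],
      arm = d$arm, tier = "sw", ref_species = "")
  }

  if (cfg$n_antisense_pairs > 0) for (a in seq_len(cfg$n_antisense_pairs)) {
    d <- designs[[n_true + cfg$n_te_mirnas + a]]
    slot <- place(nchar(d$hairpin))
    id_s <- sprintf("asmir%03d_s", a)
    id_as <- sprintf("asmir%03d_as", a)
    spans <- plant(d, id_s, "+", slot)
    truth_rows[[length(truth_rows) + 1L]] <- truth_row(
      id_s, slot$chrom, slot$start, slot$end, "+",
      feature_class = "true_mirna",
      mature_seq = d$mature, star_seq = d$star, expected_call = "novel",
      mature_start = spans$mature[1L], mature_end = spans$mature[2L],
      star_start = spans$star[1L], star_end = spans$star[2L],
      loop_start = spans$loop[1L], loop_end = spans$loop[2L],
      arm = d$arm, tier = "sw", ref_species = "", antisense_of = "")
    # the opposite strand of a hairpin is itself a hairpin; its mature is the
    # reverse complement of the planted star (and vice versa)
    truth_rows[[length(truth_rows) + 1L]] <- truth_row(
      id_as, slot$chrom, slot$start, slot$end, "-",
      feature_class = "true_mirna",
      mature_seq = revcomp(d$star), star_seq = revcomp(d$mature),
      expected_call = "novel",
      mature_start = spans$star[1L], mature_end = spans$star[2L],
      star_start = spans$mature[1L], star_end = spans$mature[2L],
      loop_start = spans$loop[1L], loop_end = spans$loop[2L],
      arm = d$arm, tier = "sw", ref_species = "", antisense_of = id_s)
  }

  ## exonic mRNA-degradation fragment loci and intergenic noise loci
  for (g in seq_along(gene_models)) {
    ex <- gene_models[[g]]
    ex <- ex[ex$feature_class == "exon", , drop = FALSE]
    row <- ex[sample.int(nrow(ex), 1L), , drop = FALSE]
    fstart <- row$start + sample.int(row$end - row$start - 22L, 1L)
    truth_rows[[length(truth_rows) + 1L]] <- truth_row(
      sprintf("exfrag%02d", g), row$chrom, fstart, fstart + 22L, row$strand,
      feature_class = "exon_fragment", expected_call = "rejected")
  }
  if (cfg$n_intergenic_noise > 0) for (z in seq_len(cfg$n_intergenic_noise)) {
    len <- sample(20:26, 1L)
    slot <- place(len)
    truth_rows[[length(truth_rows) + 1L]] <- truth_row(
      sprintf("noise%02d", z), slot$chrom, slot$start, slot$end,
      sample(c("+", "-"), 1L),
      feature_class = "intergenic_noise", expected_call = "rejected")
  }

  truth <- data.table::rbindlist(truth_rows, fill = TRUE)
  truth <- as.data.frame(truth)
  ann_df <- as.data.frame(data.table::rbindlist(ann_rows))
  structure(list(
    genome = genome,
    annotations = annotation_set(ann_df, source = "simulated"),
    ref_matures = unlist(ref_seqs) %||% character(0),
    taxon_map = DEFAULT_TAXON_MAP,
    truth = truth,
    config = cfg
  ), class = "sim_reference")
}

#' @keywords internal
truth_row <- function(locus_id, chrom, start, end, strand, feature_class,
                      expected_call,
                      mature_seq = NA_character_, star_seq = NA_character_,
                      mature_start = NA_integer_, mature_end = NA_integer_,
                      star_start = NA_integer_, star_end = NA_integer_,
                      loop_start = NA_integer_, loop_end = NA_integer_,
                      arm = NA_character_, tier = NA_character_,
                      ref_species = NA_character_,
                      antisense_of = NA_character_) {
  data.frame(locus_id = locus_id, chrom = chrom, start = start, end = end,
             strand = strand, feature_class = feature_class,
             mature_seq = mature_seq, star_seq = star_seq,
             expected_call = expected_call,
             mature_start = mature_start, mature_end = mature_end,
             star_start = star_start, star_end = star_end,
             loop_start = loop_start, loop_end = loop_end,
             arm = arm, tier = tier, ref_species = ref_species,
             antisense_of = antisense_of,
             stringsAsFactors = FALSE)
}

# one hairpin design: mature + AT-rich loop + near-revcomp star
#' @keywords internal
design_hairpin <- function(cfg) {
  mlen <- sample(seq.int(cfg$mature_len_range[1L], cfg$mature_len_range[2L]), 1L)
  mature <- random_dna(1L, mlen, gc = 0.6)
  # 1-2 engineered mismatches: realistic imperfect duplexes, and the
  # precursor is never a perfect palindrome (which would also occur on the
  # opposite strand and create a spurious antisense twin)
  star <- mutate_seq(revcomp(mature), sample(1:2, 1L), interior = TRUE)
  loop <- random_dna(1L, sample(8:15, 1L), gc = 0.25)
  arm <- sample(c("5p", "3p"), 1L)
  if (arm == "5p") {
    hairpin <- paste0(mature, loop, star)
    m_span <- c(1L, mlen)
    s_span <- c(mlen + nchar(loop) + 1L, nchar(hairpin))
  } else {
    hairpin <- paste0(star, loop, mature)
    s_span <- c(1L, nchar(star))
    m_span <- c(nchar(star) + nchar(loop) + 1L, nchar(hairpin))
  }
  l_span <- c(min(m_span[2L], s_span[2L]) + 1L,
              max(m_span[1L], s_span[1L]) - 1L)
  list(mature = mature, star = star, loop = loop, arm = arm,
       hairpin = hairpin, m_span = m_span, s_span = s_span, l_span = l_span)
}

# fold every design (and, for antisense bases, also the reverse complement)
# with the pipeline's engine; redesign until MFE <= -25 kcal/mol
#' @keywords internal
validate_hairpins <- function(designs, cfg, engine, with_antisense,
                              max_rounds = 25L) {
  if (length(designs) == 0L) return(designs)
  for (round in seq_len(max_rounds)) {
    seqs <- vapply(designs, function(d) d$hairpin, character(1))
    mfe <- fold_rna(seqs, engine = engine)$mfe
    ok <- mfe <= -25
    if (any(with_antisense)) {
      rc <- revcomp(seqs[with_antisense])
      mfe_rc <- fold_rna(rc, engine = engine)$mfe
      ok[with_antisense] <- ok[with_antisense] & (mfe_rc <= -25)
    }
    if (all(ok)) return(designs)
    for (i in which(!ok)) designs[[i]] <- design_hairpin(cfg)
  }
  stop("failed to design hairpins with MFE <= -25 kcal/mol after ",
       max_rounds, " rounds")
}

# substitute n interior (or arbitrary) positions with a different base
#' @keywords internal
mutate_seq <- function(seq, n, interior = FALSE) {
  if (n == 0L) return(seq)
  v <- strsplit(seq, "", fixed = TRUE)[[1]]
  cand <- if (interior && length(v) > 8L) 4:(length(v) - 3L) else seq_along(v)
  pos <- sample(cand, min(n, length(cand)))
  for (p in pos) v[p] <- sample(setdiff(c("A", "C", "G", "T"), v[p]), 1L)
  paste(v, collapse = "")
}
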