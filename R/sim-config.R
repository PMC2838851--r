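# simulation configuration

#' Configuration for the synthetic small RNA-seq data generator
#'
#' Defines the study conditions the simulator emulates: a toy genome with
#' planted miRNA hairpins (including repeat-embedded ones), decoy rRNA/tRNA
#' loci and gene models, plus library construction artefacts (3' adapter,
#' 5'-adapter ligation contaminants, low-quality reads) on 35-nt raw reads.
#'
#' @param seed integer RNG seed; all simulator output is deterministic in it.
#' @param n_chromosomes,chrom_length toy genome dimensions (default 2 x
#'   100 kb).
#' @param n_true_mirnas planted canonical miRNA hairpins (default 30).
#' @param n_te_mirnas hairpins planted inside repeat-annotated intervals
#'   (default 10).
#' @param n_decoy_ncrna decoy rRNA/tRNA loci emitting degradation fragments
#'   (default 20, alternating rRNA and tRNA).
#' @param n_gene_models protein-coding gene models with exon/intron structure
#'   (default 8); each contributes one exonic mRNA-degradation fragment locus.
#' @param n_intergenic_noise low-count random intergenic fragment loci
#'   (default 10).
#' @param n_antisense_pairs hairpins additionally expressed from the opposite
#'   strand of the same interval, yielding sense/antisense locus pairs
#'   (default 1; the pair counts on top of `n_true_mirnas`).
#' @param mature_len_range mature length range in nt (default 20-23; must
#'   lie within 18-30).
#' @param count_mean,count_dispersion negative-binomial total read count per
#'   expressed locus per library (default mean 40, dispersion 0.5, i.e. NB
#'   size 1/0.5) - a heavily skewed abundance distribution.
#' @param end_shift_probs list with elements `p5` and `p3`: probability
#'   vectors over end offsets -2..+2 for the 5' and 3' read ends. The default
#'   puts more mass away from 0 at the 3' end (0.60 at offset 0) than at the
#'   5' end (0.90), encoding the stronger 3' isomiR heterogeneity of real
#'   libraries.
#' @param star_fraction proportion of a locus' reads from the star arm
#'   (default 0.05; star recovery is far below mature recovery in tissues).
#' @param loop_read_rate proportion of reads from the hairpin loop region
#'   (default 0.01).
#' @param error_rate per-base substitution probability (default 0.005).
#' @param adapter3 3' adapter, DNA form (default the standard small-RNA
#'   cloning 3' adapter).
#' @param adapter5 5' adapter, DNA form.
#' @param adapter5_contam_rate fraction of reads whose insert is a 5'-adapter
#'   ligation artefact (default 0.02).
#' @param raw_read_len raw read length in nt (default 35; must be at least
#'   the maximum insert + 4 so the 3' adapter is always visible).
#' @param max_insert_len upper bound of the size-selected insert (default 30).
#' @param lowq_fraction fraction of reads emitted with failing base
#'   qualities (default 0.1).
#' @param quality_threshold mean Phred score separating passing from failing
#'   reads; shared with the preprocessing filter (default 20).
#' @param known_fraction fraction of true miRNAs copied into the reference
#'   mature database under the native species tag, i.e. expected to be
#'   called *known* (default 0.4).
#' @return a validated `sim_config` object (list).
#' @export
sim_config <- function(seed = 1L,
                       n_chromosomes = 2L,
                       chrom_length = 100000L,
                       n_true_mirnas = 30L,
                       n_te_mirnas = 10L,
                       n_decoy_ncrna = 20L,
                       n_gene_models = 8L,
                       n_intergenic_noise = 10L,
                       n_antisense_pairs = 1L,
                       mature_len_range = c(20L, 23L),
                       count_mean = 40,
                       count_dispersion = 0.5,
                       end_shift_probs = list(
                         p5 = c(`-2` = 0.01, `-1` = 0.04, `0` = 0.90,
                                `1` = 0.04, `2` = 0.01),
                         p3 = c(`-2` = 0.02, `-1` = 0.10, `0` = 0.60,
                                `1` = 0.20, `2` = 0.08)),
                       star_fraction = 0.05,
                       loop_read_rate = 0.01,
                       error_rate = 0.005,
                       adapter3 = "TCGTATGCCGTCTTCTGCTTG",
                       adapter5 = "GTTCAGAGTTCTACAGTCCGACGATC",
                       adapter5_contam_rate = 0.02,
                       raw_read_len = 35L,
                       max_insert_len = 30L,
                       lowq_fraction = 0.10,
                       quality_threshold = 20,
                       known_fraction = 0.4) {
  cfg <- as.list(environment())
  probs <- c(cfg$star_fraction, cfg$loop_read_rate, cfg$error_rate,
             cfg$lowq_fraction, cfg$adapter5_contam_rate, cfg$known_fraction)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  for (nm in c("p5", "p3")) {
    p <- cfg$end_shift_probs[[nm]]
    if (length(p) != 5L || any(p < 0) || abs(sum(p) - 1) > 1e-8) {
      stop("end_shift_probs$", nm,
           " must be 5 non-negative values over offsets -2..2 summing to 1")
    }
  }
  if (cfg$mature_len_range[1L] < 18L || cfg$mature_len_range[2L] > 30L ||
      cfg$mature_len_range[1L] > cfg$mature_len_range[2L]) {
    stop("mature_len_range must be an increasing pair within [18, 30]")
  }
  if (cfg$raw_read_len < cfg$max_insert_len + 4L) {
    stop("raw_read_len must be at least max_insert_len + 4")
  }
  if (cfg$count_dispersion <= 0) stop("count_dispersion must be positive")
  structure(cfg, class = "sim_config")
}
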