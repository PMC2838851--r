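# shared fixtures: cached small simulation and hand-built objects

.fixture_env <- new.env(parent = emptyenv())

# small simulated data set reused across test files (built once per run)
small_sim <- function() {
  if (!is.null(.fixture_env$small)) return(.fixture_env$small)
  cfg <- sim_config(seed = 42L, n_chromosomes = 1L, chrom_length = 30000L,
                    n_true_mirnas = 8L, n_te_mirnas = 2L,
                    n_decoy_ncrna = 6L, n_gene_models = 2L,
                    n_intergenic_noise = 4L, n_antisense_pairs = 1L)
  ref <- build_reference(cfg)
  sim <- simulate_reads(ref, n_libraries = 2L)
  dir <- file.path(tempdir(), "mirforge-small-sim")
  paths <- write_simulation(ref, sim, dir)
  pp <- preprocess_reads(paths[sim$libraries], sim$libraries,
                         adapter3 = cfg$adapter3, adapter5 = cfg$adapter5)
  .fixture_env$small <- list(cfg = cfg, ref = ref, sim = sim,
                             paths = paths, pp = pp)
  .fixture_env$small
}

# full discovery result on the small simulation, cached
small_discovery <- function() {
  if (!is.null(.fixture_env$small_res)) return(.fixture_env$small_res)
  fx <- small_sim()
  .fixture_env$small_res <- discover_mirnas(
    fx$pp$tags, fx$ref$genome, fx$ref$annotations, fx$ref$ref_matures,
    seed = 11L)
  .fixture_env$small_res
}

# parse the truth-tagged read ids written by the simulator
parse_read_ids <- function(ids) {
  parts <- strsplit(ids, "|", fixed = TRUE)
  data.frame(
    locus_id = vapply(parts, `[`, "", 1L),
    arm = vapply(parts, `[`, "", 2L),
    o5 = suppressWarnings(as.integer(vapply(parts, `[`, "", 3L))),
    o3 = suppressWarnings(as.integer(vapply(parts, `[`, "", 4L))),
    clean = vapply(parts, `[`, "", 5L) == "1",
    contam = vapply(parts, `[`, "", 6L) == "1",
    stringsAsFactors = FALSE
  )
}

# build a hairpin-candidate list directly from a dot-bracket structure
make_candidate <- function(structure, mature_span, mfe = -30,
                           window = "up10_down70", strand = "+",
                           start = 0L) {
  n <- nchar(structure)
  list(precursor_seq = strrep("A", n), structure = structure, mfe = mfe,
       mature_span = mature_span, window = window, strand = strand,
       start = start, end = start + n)
}

# random phred+33 quality string with the given mean score
qual_string <- function(len, q) intToUtf8(rep(q + 33L, len))

# independent rule-table oracle for the structural filter
filter_oracle <- function(mfe, um, us, bulge, asym, overhang, reads_on_star) {
  mfe <= -25 & um <= 6 & us <= 6 & bulge <= 4 & asym <= 3 &
    (overhang | !reads_on_star)
}
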