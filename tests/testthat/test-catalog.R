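# known/novel calling, clusters, paralogs, conservation, pairs, context

test_that("known matching tolerates 2 mismatches and 3 nt shifts", {
  set.seed(9)
  base <- paste(sample(c("A", "C", "G", "T"), 22, replace = TRUE),
                collapse = "")
  refs <- c("bmo-miR-sim001" = base)
  mut <- function(n) mirforge:::mutate_seq(base, n)
  for (n in 0:3) {
    got <- match_known(mut(n), refs)
    expect_identical(got$known, n <= 2, label = paste(n, "mismatches"))
  }
  # shifted by 3 nt still matches; non-native species never counts as known
  shifted <- paste0("ACG", substr(base, 1, 19))
  expect_true(match_known(shifted, refs)$known)
  expect_false(match_known(base, c("dme-miR-sim001" = base))$known)
  # a 5-nt shift breaks the end-shift tolerance even with zero mismatches
  far <- paste0("ACGTA", substr(base, 1, 17))
  d <- seq_match_dist(far, base, max_shift = 3)
  expect_true(!is.finite(d$mismatches) || d$mismatches > 2 ||
                !match_known(far, refs)$known)
})

test_that("novel calls enforce the per-library read threshold and rescue", {
  ok <- function(...) call_novel(...)
  expect_true(ok(FALSE, "intergenic", c(5, 0, 0), TRUE))
  # four reads in each of three libraries: no single library reaches five
  expect_false(ok(FALSE, "intergenic", c(4, 4, 4), TRUE))
  expect_true(ok(FALSE, "intergenic", c(4, 4, 4), TRUE, pooled = TRUE))
  expect_false(ok(FALSE, "ncrna_discard", c(50, 0, 0), TRUE))
  expect_false(ok(TRUE, "intergenic", c(50, 0, 0), TRUE))
  expect_false(ok(FALSE, "intergenic", c(9, 0, 0), FALSE))
  # exon-sense candidates need a folding p-value strictly below 0.01
  expect_false(ok(FALSE, "exon_sense", c(9, 0, 0), TRUE, fold_p = 0.02))
  expect_true(ok(FALSE, "exon_sense", c(9, 0, 0), TRUE, fold_p = 0.009))
  expect_false(ok(FALSE, "exon_sense", c(9, 0, 0), TRUE, fold_p = NA))
})

loci_df <- function(starts, ends, strand = "+", chrom = "chr1",
                    names = NULL) {
  data.frame(name = names %||% sprintf("L%02d", seq_along(starts)),
             chrom = chrom, start = starts, end = ends, strand = strand,
             stringsAsFactors = FALSE)
}
`%||%` <- function(x, y) if (is.null(x)) y else x

test_that("cluster gaps respect the strict 2.5 kb boundary", {
  # gap of 2400 joins, exactly 2500 separates
  cl <- detect_clusters(loci_df(c(0, 2500), c(100, 2600)))
  expect_identical(length(unique(cl$cluster_id)), 1L)
  cl2 <- detect_clusters(loci_df(c(0, 2600), c(100, 2700)))
  expect_identical(nrow(cl2), 0L)
  # chain of three with 2 kb gaps forms one cluster of three
  cl3 <- detect_clusters(loci_df(c(0, 2100, 4200), c(100, 2200, 4300)))
  expect_identical(nrow(cl3), 3L)
  expect_identical(length(unique(cl3$cluster_id)), 1L)
  # opposite strands never cluster by default
  cl4 <- detect_clusters(loci_df(c(0, 500), c(100, 600),
                                 strand = c("+", "-")))
  expect_identical(nrow(cl4), 0L)
  cl5 <- detect_clusters(loci_df(c(0, 500), c(100, 600),
                                 strand = c("+", "-")), same_strand = FALSE)
  expect_identical(length(unique(cl5$cluster_id)), 1L)
})

test_that("clustering equals the all-pairs transitive-closure oracle", {
  skip_if_not_installed("igraph")
  set.seed(13)
  for (rep in 1:5) {
    n <- sample(20:50, 1)
    st <- sort(sample.int(60000, n))
    loci <- loci_df(st, st + 90,
                    strand = sample(c("+", "-"), n, replace = TRUE),
                    chrom = sample(c("chr1", "chr2"), n, replace = TRUE))
    got <- detect_clusters(loci)
    # oracle: graph over all pairs with gap < 2500, same chrom & strand
    edges <- matrix(integer(0), ncol = 2)
    for (i in seq_len(n - 1)) for (j in seq.int(i + 1, n)) {
      if (loci$chrom[i] != loci$chrom[j]) next
      if (loci$strand[i] != loci$strand[j]) next
      gap <- max(loci$start[i], loci$start[j]) -
        min(loci$end[i], loci$end[j])
      if (gap < 2500) edges <- rbind(edges, c(i, j))
    }
    g <- igraph::graph_from_edgelist(edges, directed = FALSE)
    g <- igraph::add_vertices(g, n - igraph::vcount(g))
    comp <- igraph::components(g)$membership
    want <- sort(unname(unlist(
      lapply(split(loci$name, comp), function(m) if (length(m) > 1) m))))
    expect_identical(sort(got$member), want)
    # memberships agree group-wise, not just as a pooled set
    if (nrow(got) > 0) {
      got_groups <- lapply(split(got$member, got$cluster_id), sort)
      want_groups <- Filter(function(m) length(m) > 1,
                            lapply(split(loci$name, comp), sort))
      expect_setequal(lapply(got_groups, paste, collapse = ","),
                      lapply(unname(want_groups), paste, collapse = ","))
    }
  }
})

test_that("paralog grouping is the union-find closure of similarity links", {
  set.seed(19)
  A <- paste(sample(c("A", "C", "G", "T"), 22, replace = TRUE), collapse = "")
  B <- mirforge:::mutate_seq(A, 2)             # A ~ B
  C <- mirforge:::mutate_seq(B, 2)             # B ~ C, likely A !~ C
  D <- paste(sample(c("A", "C", "G", "T"), 22, replace = TRUE), collapse = "")
  loci <- data.frame(name = c("a", "b", "c", "d"),
                     mature_seq = c(A, B, C, D),
                     star_seq = NA_character_, stringsAsFactors = FALSE)
  got <- group_paralogs(loci)
  expect_setequal(got$member[got$group_id == got$group_id[1]],
                  c("a", "b", "c"))
  expect_false("d" %in% got$member)
  # identical matures at two loci form a group
  two <- data.frame(name = c("x", "y"), mature_seq = c(A, A),
                    star_seq = NA_character_)
  expect_identical(sort(group_paralogs(two)$member), c("x", "y"))
  # three substitutions exceed the default threshold
  E <- mirforge:::mutate_seq(A, 3)
  far <- data.frame(name = c("x", "y"), mature_seq = c(A, E),
                    star_seq = NA_character_)
  d <- seq_match_dist(A, E)$mismatches
  expect_identical(nrow(group_paralogs(far)) > 0, d <= 2)
})

test_that("paralog partition matches the connected-components oracle", {
  skip_if_not_installed("igraph")
  set.seed(29)
  seqs <- character(12)
  seqs[1] <- paste(sample(c("A", "C", "G", "T"), 21, replace = TRUE),
                   collapse = "")
  for (i in 2:12) {
    seqs[i] <- if (i %% 3 == 0) {
      mirforge:::mutate_seq(seqs[i - 1], sample(1:2, 1))
    } else {
      paste(sample(c("A", "C", "G", "T"), 21, replace = TRUE), collapse = "")
    }
  }
  loci <- data.frame(name = sprintf("p%02d", 1:12), mature_seq = seqs,
                     star_seq = NA_character_, stringsAsFactors = FALSE)
  got <- group_paralogs(loci)
  adj <- outer(1:12, 1:12, Vectorize(function(i, j) {
    i != j && seq_match_dist(seqs[i], seqs[j])$mismatches <= 2
  }))
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "max")
  comp <- igraph::components(g)$membership
  want <- sort(unlist(lapply(split(loci$name, comp),
                             function(m) if (length(m) > 1) m)))
  expect_identical(sort(got$member), unname(want))
})

test_that("conservation tiers follow the taxon evidence", {
  set.seed(37)
  m <- paste(sample(c("A", "C", "G", "T"), 22, replace = TRUE), collapse = "")
  tm <- mirforge:::DEFAULT_TAXON_MAP
  tier <- function(refs) classify_conservation(m, refs, tm)$tier
  expect_identical(tier(c("dme-miR-1" = m, "hsa-miR-1" = m)), "inv-ver")
  expect_identical(tier(c("aga-miR-1" = m, "tca-miR-1" = m)), "ins")
  expect_identical(tier(c("cel-miR-1" = m)), "inv")
  expect_identical(tier(c("bmo-miR-1" = m)), "sw")
  expect_identical(tier(c("bmo-miR-1" = revcomp(m))), "sw")   # no match
  expect_identical(tier(character(0)), "sw")
  expect_error(classify_conservation(m, c("zzz-miR-1" = m), tm),
               "missing from taxon map")
})

test_that("sense/antisense pairing needs reciprocal overlap on both strands", {
  same <- loci_df(c(100, 100), c(200, 200), strand = c("+", "-"))
  expect_identical(nrow(detect_sense_antisense(same)), 1L)
  adjacent <- loci_df(c(100, 200), c(200, 300), strand = c("+", "-"))
  expect_identical(nrow(detect_sense_antisense(adjacent)), 0L)
  partial <- loci_df(c(100, 160), c(200, 260), strand = c("+", "-"))
  expect_identical(nrow(detect_sense_antisense(partial)), 0L)   # 40% < 50%
  samestrand <- loci_df(c(100, 100), c(200, 200), strand = c("+", "+"))
  expect_identical(nrow(detect_sense_antisense(samestrand)), 0L)
})

test_that("genomic context follows the te > exon > intron priority", {
  ann <- annotation_set(data.frame(
    chrom = "chr1",
    start = c(1000L, 1000L, 1150L, 3000L),
    end = c(1400L, 1150L, 1300L, 3100L),
    strand = "+",
    feature_class = c("repeat", "exon", "intron", "exon"),
    feature_id = c("te1", "e1", "i1", "e2"), stringsAsFactors = FALSE))
  loci <- loci_df(c(1180, 1100, 5000), c(1220, 1200, 5100))
  expect_identical(genomic_context(loci, ann),
                   c("te", "te", "intergenic"))
  ann2 <- annotation_set(data.frame(
    chrom = "chr1", start = c(1000L, 1150L), end = c(1150L, 1300L),
    strand = "+", feature_class = c("exon", "intron"),
    feature_id = c("e1", "i1"), stringsAsFactors = FALSE))
  # overlapping exon and intron of one gene resolves to exonic
  expect_identical(genomic_context(loci_df(1100, 1200), ann2), "exonic")
  expect_identical(genomic_context(loci_df(1160, 1290), ann2), "intronic")
})

test_that("isoform refinement finds dominants, offsets and arm switches", {
  members <- data.frame(
    tag_id = c("m1", "m2", "s1"),
    start = c(1000L, 1001L, 1040L), end = c(1022L, 1023L, 1062L),
    strand = "+", sequence = c(strrep("A", 22), strrep("C", 22),
                               strrep("G", 22)),
    total = c(120L, 30L, 500L), stringsAsFactors = FALSE)
  prec <- list(start = 990L, end = 1092L, strand = "+")
  iso <- refine_isoforms(members, prec)
  expect_identical(iso$dominant[["5p"]]$tag_id, "m1")     # 120 > 30
  expect_identical(iso$dominant[["3p"]]$tag_id, "s1")
  expect_equal(unname(iso$offsets[["5p"]]$off5[c("0", "1")]), c(120, 30))
  expect_equal(unname(iso$arm_counts), c(150, 500))
  expect_false(iso$arm_switch)
  # annotated arm 5p but 3p reads dominate: arm switching
  iso2 <- refine_isoforms(members, prec, known_arm = "5p")
  expect_true(iso2$arm_switch)
  iso3 <- refine_isoforms(members, prec, known_arm = "3p")
  expect_false(iso3$arm_switch)
})

test_that("report totals add up and tiers partition the catalogue", {
  fake <- data.frame(
    name = sprintf("m%03d", 1:257),
    status = c(rep("known", 55), rep("novel", 202)),
    tier = rep(c("inv-ver", "inv", "ins", "sw"), length.out = 257),
    context = rep(c("te", "exonic", "intronic", "intergenic"),
                  length.out = 257),
    stringsAsFactors = FALSE)
  rep_ <- build_report(fake)
  expect_identical(rep_$totals$n_known, 55L)
  expect_identical(rep_$totals$n_novel, 202L)
  expect_identical(rep_$totals$n_total, 257L)
  expect_identical(sum(rep_$tiers$n), nrow(fake))
  expect_identical(sum(rep_$contexts$n), nrow(fake))
  # empty catalogue: zero tables, no crash
  empty <- fake[0, ]
  rep0 <- build_report(empty)
  expect_identical(rep0$totals$n_total, 0L)
  expect_identical(sum(rep0$tiers$n), 0L)
})
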