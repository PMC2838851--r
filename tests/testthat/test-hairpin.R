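# pileups, excision, duplex metrics, structural filter, precursor selection

aln_row <- function(tag_id, start, end, strand = "+", chrom = "chr1") {
  data.frame(tag_id = tag_id, chrom = chrom, start = as.integer(start),
             end = as.integer(end), strand = strand, n_genomic_hits = 1L,
             hyper_repetitive = FALSE, stringsAsFactors = FALSE)
}

tag_row <- function(tag_id, seq, total) {
  data.frame(tag_id = tag_id, sequence = seq, length = nchar(seq),
             lib1 = as.integer(total), total = as.integer(total),
             stringsAsFactors = FALSE)
}

test_that("pileups merge overlapping same-strand alignments only", {
  aln <- rbind(aln_row("a", 100, 122), aln_row("b", 112, 134),
               aln_row("c", 100, 122, strand = "-"),
               aln_row("d", 500, 522))
  tags <- rbind(tag_row("a", strrep("A", 22), 50),
                tag_row("b", strrep("C", 22), 7),
                tag_row("c", strrep("G", 22), 3),
                tag_row("d", strrep("T", 22), 9))
  loci <- call_pileups(aln, tags)
  expect_length(loci, 3L)
  spans <- vapply(loci, function(l) paste(l$chrom, l$strand, l$start, l$end),
                  character(1))
  expect_setequal(spans, c("chr1 + 100 134", "chr1 - 100 122",
                           "chr1 + 500 522"))
  plus <- loci[[which(spans == "chr1 + 100 134")]]
  expect_identical(plus$mature_guess$tag_id, "a")   # 50 reads beat 7
})

test_that("mature guess is invariant to input order and ties break 5'-most", {
  base <- rbind(aln_row("a", 100, 122), aln_row("b", 110, 132),
                aln_row("c", 105, 127))
  tags <- rbind(tag_row("a", strrep("A", 22), 7),
                tag_row("b", strrep("C", 22), 50),
                tag_row("c", strrep("G", 22), 7))
  set.seed(2)
  for (i in 1:10) {
    perm <- sample(nrow(base))
    loci <- call_pileups(base[perm, ], tags[sample(nrow(tags)), ])
    expect_identical(loci[[1]]$mature_guess$tag_id, "b")
  }
  # tie on counts: the 5'-most alignment wins on the plus strand
  tags2 <- rbind(tag_row("a", strrep("A", 22), 50),
                 tag_row("b", strrep("C", 22), 50),
                 tag_row("c", strrep("G", 22), 7))
  loci2 <- call_pileups(base, tags2)
  expect_identical(loci2[[1]]$mature_guess$tag_id, "a")
  # on the minus strand the 5'-most is the highest end coordinate
  basem <- rbind(aln_row("a", 100, 122, "-"), aln_row("b", 110, 132, "-"))
  tagsm <- rbind(tag_row("a", strrep("A", 22), 10),
                 tag_row("b", strrep("C", 22), 10))
  locim <- call_pileups(basem, tagsm)
  expect_identical(locim[[1]]$mature_guess$tag_id, "b")
})

test_that("over-long loci are split at the deepest coverage minimum", {
  # two dense blocks bridged by a weak tag: span 400 forces a split
  aln <- rbind(aln_row("a", 100, 122), aln_row("b", 104, 126),
               aln_row("link", 240, 262),
               aln_row("c", 380, 402), aln_row("d", 384, 406))
  aln2 <- rbind(aln, aln_row("bridge1", 118, 244), aln_row("bridge2", 258, 384))
  tags <- rbind(tag_row("a", strrep("A", 22), 40), tag_row("b", strrep("C", 22), 30),
                tag_row("link", strrep("G", 22), 1),
                tag_row("c", strrep("T", 22), 35), tag_row("d", strrep("AC", 11), 25),
                tag_row("bridge1", strrep("AG", 63), 1),
                tag_row("bridge2", strrep("CT", 63), 1))
  loci <- call_pileups(aln2, tags, max_locus_span = 200L)
  expect_gte(length(loci), 2L)
  expect_true(all(vapply(loci, function(l) l$end - l$start, numeric(1)) <= 310))
  # the two dense blocks end up in different loci
  where <- vapply(loci, function(l) "a" %in% l$members$tag_id &&
                    "c" %in% l$members$tag_id, logical(1))
  expect_false(any(where))
})

test_that("excision windows follow the 10/70 rule in transcript orientation", {
  set.seed(12)
  genome <- c(chr1 = paste(sample(c("A", "C", "G", "T"), 2000,
                                  replace = TRUE), collapse = ""))
  mk_locus <- function(strand) {
    mg <- aln_row("m", 1000, 1022, strand)
    mg$total <- 10L; mg$sequence <- strrep("A", 22)
    list(chrom = "chr1", strand = strand, start = 1000L, end = 1022L,
         members = mg, mature_guess = mg)
  }
  sh <- excise_precursors(mk_locus("+"), genome)
  expect_identical(c(sh$up10_down70$start, sh$up10_down70$end),
                   c(990L, 1092L))
  expect_identical(c(sh$up70_down10$start, sh$up70_down10$end),
                   c(930L, 1032L))
  expect_identical(sh$up10_down70$precursor_seq,
                   chartr("T", "U", substr(genome[["chr1"]], 991, 1092)))
  expect_identical(sh$up10_down70$mature_span, c(11L, 32L))
  # minus strand: windows mirror genomically, sequence reverse-complemented
  shm <- excise_precursors(mk_locus("-"), genome)
  expect_identical(c(shm$up10_down70$start, shm$up10_down70$end),
                   c(930L, 1032L))
  oracle <- chartr("T", "U", revcomp(substr(genome[["chr1"]], 931, 1032)))
  expect_identical(shm$up10_down70$precursor_seq, oracle)
  expect_identical(shm$up10_down70$mature_span, c(11L, 32L))
  # clipping near the chromosome start sets the flag
  mg <- aln_row("m", 5, 27); mg$total <- 10L; mg$sequence <- strrep("A", 22)
  near <- list(chrom = "chr1", strand = "+", start = 5L, end = 27L,
               members = mg, mature_guess = mg)
  shc <- excise_precursors(near, genome)
  expect_true(shc$up70_down10$clipped)
  expect_identical(shc$up70_down10$start, 0L)
})

test_that("duplex metrics on a perfect duplex hairpin are all zero", {
  st <- paste0(strrep("(", 26), "....", strrep(")", 26))
  cand <- duplex_metrics(make_candidate(st, c(3L, 24L)))
  expect_identical(cand$duplex$unpaired_mature, 0L)
  expect_identical(cand$duplex$unpaired_star, 0L)
  expect_identical(cand$duplex$max_bulge, 0L)
  expect_identical(cand$duplex$asymmetry, 0L)
  expect_true(cand$duplex$overhang_3p_both)
  expect_identical(cand$star_span, c(35L, 56L))
})

test_that("an engineered 3-nt bulge yields bulge 3 and asymmetry 3", {
  st <- paste0(strrep("(", 10), "...", strrep("(", 12), "....",
               strrep(")", 22), "..")
  cand <- duplex_metrics(make_candidate(st, c(3L, 25L)))
  expect_identical(cand$duplex$unpaired_mature, 3L)
  expect_identical(cand$duplex$unpaired_star, 0L)
  expect_identical(cand$duplex$max_bulge, 3L)
  expect_identical(cand$duplex$asymmetry, 3L)
  expect_true(cand$duplex$overhang_3p_both)
})

test_that("metrics are symmetric when the mature sits on the 3' arm", {
  st5 <- paste0(strrep("(", 26), "....", strrep(")", 26))
  m5 <- duplex_metrics(make_candidate(st5, c(3L, 24L)))
  # mirrored: mature occupies the corresponding 3'-arm span
  m3 <- duplex_metrics(make_candidate(st5, c(33L, 54L)))
  expect_identical(m3$duplex$unpaired_mature, m5$duplex$unpaired_mature)
  expect_identical(m3$duplex$max_bulge, m5$duplex$max_bulge)
  expect_identical(m3$duplex$asymmetry, m5$duplex$asymmetry)
  # star of the 3'-arm mature lies on the 5' arm
  expect_lt(m3$star_span[2L], 27L)
})

test_that("a loop-spanning mature is rejected with its reason", {
  st <- paste0(strrep("(", 20), "........", strrep(")", 20))
  cand <- duplex_metrics(make_candidate(st, c(15L, 34L)))
  expect_identical(cand$reject_reason, "loop-spanning")
  filt <- structural_filter(cand)
  expect_false(filt$pass)
  expect_true("loop-spanning" %in% filt$reasons)
})

test_that("duplex metrics agree with an independent dot-bracket scan", {
  set.seed(77)
  for (i in 1:30) {
    S <- paste(sample(c("A", "C", "G", "T"), 26, replace = TRUE),
               collapse = "")
    hp <- paste0(S, paste(sample(c("A", "T"), 9, replace = TRUE),
                          collapse = ""),
                 mirforge:::mutate_seq(revcomp(S), sample(0:2, 1)))
    f <- fold_rna(hp)
    cand <- make_candidate(f$structure, c(3L, 24L), mfe = f$mfe)
    cand$precursor_seq <- chartr("T", "U", hp)
    cand <- duplex_metrics(cand)
    if (!is.null(cand$reject_reason)) next
    # independent scan: recount from the structure string and the spans
    pt2 <- {
      ch <- strsplit(f$structure, "")[[1]]
      stack <- integer(0); p <- integer(length(ch))
      for (k in seq_along(ch)) {
        if (ch[k] == "(") stack <- c(stack, k)
        else if (ch[k] == ")") { p[k] <- stack[length(stack)]
          p[stack[length(stack)]] <- k
          stack <- stack[-length(stack)] }
      }
      p
    }
    dots <- function(span) {
      sum(strsplit(substr(f$structure, span[1], span[2]), "")[[1]] == ".")
    }
    runmax <- function(span) {
      r <- rle(strsplit(substr(f$structure, span[1], span[2]), "")[[1]] == ".")
      if (!any(r$values)) 0L else max(r$lengths[r$values])
    }
    m <- cand$mature_span; s <- cand$star_span
    expect_identical(cand$duplex$unpaired_mature, dots(m))
    expect_identical(cand$duplex$unpaired_star, dots(s))
    expect_identical(cand$duplex$max_bulge, max(runmax(m), runmax(s)))
    expect_identical(cand$duplex$asymmetry, abs(dots(m) - dots(s)))
    # star really lies on the opposite arm: every paired mature base has its
    # partner beyond the mature span, on the star side
    partners <- pt2[m[1]:m[2]]; partners <- partners[partners > 0]
    expect_true(all(partners > m[2]) || all(partners < m[1]))
  }
})

test_that("the structural filter enforces each boundary exactly", {
  mk <- function(mfe, um, us, bulge, asym, overhang) {
    list(mfe = mfe, duplex = list(
      unpaired_mature = um, unpaired_star = us, max_bulge = bulge,
      asymmetry = asym, overhang_3p_both = overhang))
  }
  # energy boundary is inclusive at -25.0, exclusive above
  expect_false(structural_filter(mk(-24.9, 0, 0, 0, 0, TRUE))$pass)
  expect_identical(structural_filter(mk(-24.9, 0, 0, 0, 0, TRUE))$reasons,
                   "energy")
  expect_true(structural_filter(mk(-25.0, 6, 6, 4, 3, TRUE))$pass)
  # each metric boundary, one past the limit
  expect_identical(structural_filter(mk(-30, 7, 0, 0, 0, TRUE))$reasons,
                   "unpaired_mature")
  expect_identical(structural_filter(mk(-30, 0, 7, 0, 0, TRUE))$reasons,
                   "unpaired_star")
  expect_identical(structural_filter(mk(-30, 0, 0, 5, 0, TRUE))$reasons,
                   "bulge")
  expect_identical(structural_filter(mk(-30, 0, 4, 0, 4, TRUE))$reasons,
                   "asymmetry")
  # the overhang requirement binds only when star reads were sequenced
  noov <- mk(-30, 0, 0, 0, 0, FALSE)
  expect_true(structural_filter(noov, reads_on_star = FALSE)$pass)
  expect_false(structural_filter(noov, reads_on_star = TRUE)$pass)
})

test_that("precursor selection prefers passing, then lower energy", {
  a <- list(window = "up10_down70", mfe = -30,
            filter = list(pass = TRUE, reasons = character(0)))
  b <- list(window = "up70_down10", mfe = -42,
            filter = list(pass = TRUE, reasons = character(0)))
  expect_identical(select_precursor(a, b)$mfe, -42)
  bfail <- modifyList(b, list(filter = list(pass = FALSE, reasons = "energy")))
  expect_identical(select_precursor(a, bfail)$window, "up10_down70")
  afail <- modifyList(a, list(filter = list(pass = FALSE, reasons = "bulge")))
  expect_null(select_precursor(afail, bfail))
  # tie on energy prefers the up10_down70 window regardless of order
  tie_a <- modifyList(a, list(mfe = -33))
  tie_b <- modifyList(b, list(mfe = -33))
  expect_identical(select_precursor(tie_b, tie_a)$window, "up10_down70")
})
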