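# hairpin discovery core: read pileups, precursor excision, duplex metrics,
# structural filter, precursor selection

#' Merge tag alignments into candidate expression loci
#'
#' Overlapping same-strand alignments are merged by a linear sweep into
#' pileup loci; loci longer than `max_locus_span` are split at their deepest
#' coverage minimum. The locus' mature guess is the member tag with the
#' highest total read count (ties resolved 5'-most on the locus strand, then
#' lexicographically by sequence) - a stand-in for scoring read starts as
#' Drosha/Dicer processing sites.
#'
#' @param alignments alignment data.frame (see [map_tags()]); rows flagged
#'   `hyper_repetitive` should be removed by the caller beforehand.
#' @param tags tag table with per-library counts and `total`.
#' @param max_locus_span split loci longer than this many nt (default 200).
#' @return list of pileup loci; each is a list with `chrom`, `strand`,
#'   `start`, `end` (0-based half-open), `members` (alignment rows joined
#'   with counts) and `mature_guess` (one member row).
#' @export
call_pileups <- function(alignments, tags, max_locus_span = 200L) {
  if (nrow(alignments) == 0L) return(list())
  m <- match(alignments$tag_id, tags$tag_id)
  stopifnot(!anyNA(m))
  aln <- alignments
  aln$total <- tags$total[m]
  aln$sequence <- tags$sequence[m]
  loci <- list()
  for (key in split(seq_len(nrow(aln)),
                    paste(aln$chrom, aln$strand, sep = "\r"))) {
    sub <- aln[key, , drop = FALSE]
    sub <- sub[order(sub$start, sub$end), , drop = FALSE]
    # sweep: merge transitively overlapping intervals
    grp <- integer(nrow(sub))
    g <- 0L; cur_end <- -1L
    for (i in seq_len(nrow(sub))) {
      if (sub$start[i] >= cur_end) { g <- g + 1L; cur_end <- sub$end[i] }
      else cur_end <- max(cur_end, sub$end[i])
      grp[i] <- g
    }
    for (gi in split(seq_len(nrow(sub)), grp)) {
      loci <- c(loci, split_locus(sub[gi, , drop = FALSE], max_locus_span))
    }
  }
  lapply(loci, finalize_locus)
}

# recursively split an over-long locus at its deepest coverage minimum
#' @keywords internal
split_locus <- function(members, max_locus_span) {
  span <- max(members$end) - min(members$start)
  if (span <= max_locus_span || nrow(members) < 2L) return(list(members))
  lo <- min(members$start); hi <- max(members$end)
  cov <- numeric(hi - lo)
  for (i in seq_len(nrow(members))) {
    idx <- (members$start[i] - lo + 1L):(members$end[i] - lo)
    cov[idx] <- cov[idx] + members$total[i]
  }
  inner <- seq.int(2L, length(cov) - 1L)
  cut <- inner[which.min(cov[inner])] + lo - 1L   # genomic split coordinate
  left <- members[members$start < cut & members$end <= cut + 1L |
                    (members$start + members$end) / 2 <= cut, , drop = FALSE]
  right <- members[!(rownames(members) %in% rownames(left)), , drop = FALSE]
  if (nrow(left) == 0L || nrow(right) == 0L) return(list(members))
  c(split_locus(left, max_locus_span), split_locus(right, max_locus_span))
}

#' @keywords internal
finalize_locus <- function(members) {
  strand <- members$strand[1L]
  # argmax count; tie -> 5'-most on the locus strand, then lexicographic
  five_pos <- if (strand == "+") members$start else -members$end
  ord <- order(-members$total, five_pos, members$sequence)
  list(chrom = members$chrom[1L], strand = strand,
       start = min(members$start), end = max(members$end),
       members = members, mature_guess = members[ord[1L], , drop = FALSE])
}

#' Excise the two candidate precursors around a locus' mature guess
#'
#' Extends the mature span in transcript orientation by 10 nt upstream plus
#' 70 nt downstream (`up10_down70`) and by 70 nt upstream plus 10 nt
#' downstream (`up70_down10`), clips at chromosome ends, and emits the
#' precursor sequence as RNA 5'->3' on the locus strand.
#'
#' @param locus a pileup locus from [call_pileups()].
#' @param genome named character vector or `DNAStringSet`.
#' @return list of two hairpin-candidate shells, each a list with `window`,
#'   `chrom`, `strand`, `start`, `end` (genomic, 0-based half-open),
#'   `precursor_seq` (RNA), `mature_span` (1-based inclusive positions of the
#'   mature guess within the precursor) and `clipped` flag.
#' @export
excise_precursors <- function(locus, genome) {
  if (methods::is(genome, "DNAStringSet")) {
    genome <- stats::setNames(as.character(genome), names(genome))
  }
  mg <- locus$mature_guess
  chrom_len <- nchar(genome[[locus$chrom]])
  shells <- list()
  for (win in c("up10_down70", "up70_down10")) {
    up <- if (win == "up10_down70") 10L else 70L
    dn <- if (win == "up10_down70") 70L else 10L
    if (locus$strand == "+") {
      s <- mg$start - up; e <- mg$end + dn
    } else {
      s <- mg$start - dn; e <- mg$end + up
    }
    clipped <- s < 0L || e > chrom_len
    s <- max(0L, s); e <- min(chrom_len, e)
    seq <- dna_to_rna(genome_seq_chr(genome, locus$chrom, s, e, locus$strand))
    # mature position within the precursor, transcript orientation, 1-based
    m1 <- if (locus$strand == "+") mg$start - s + 1L else e - mg$end + 1L
    m2 <- m1 + (mg$end - mg$start) - 1L
    shells[[win]] <- list(
      window = win, chrom = locus$chrom, strand = locus$strand,
      start = s, end = e, precursor_seq = seq,
      mature_span = c(m1, m2), clipped = clipped
    )
  }
  shells
}

#' miRNA/miRNA* duplex metrics of a folded hairpin candidate
#'
#' Given the candidate's dot-bracket structure and the mature span, infers
#' the star span on the opposite arm under the Dicer 2-nt 3' overhang
#' convention and computes the duplex statistics used by the structural
#' filter: unpaired bases within each of mature and star, the longest
#' unpaired run (bulge) on either strand, duplex asymmetry
#' (|unpaired mature - unpaired star|), and whether both duplex 3' ends
#' protrude.
#'
#' @param candidate hairpin-candidate list with `precursor_seq`,
#'   `structure` (dot-bracket) and `mature_span` set.
#' @return the candidate with `star_span`, `loop_span` and `duplex` (list:
#'   `unpaired_mature`, `unpaired_star`, `max_bulge`, `asymmetry`,
#'   `overhang_3p_both`) filled in, or with `reject_reason` set
#'   (`"unpaired-mature"`, `"loop-spanning"`, `"star-out-of-range"`) when no
#'   valid duplex exists.
#' @export
duplex_metrics <- function(candidate) {
  pt <- pair_table(candidate$structure)
  n <- length(pt)
  m1 <- candidate$mature_span[1L]; m2 <- candidate$mature_span[2L]
  stopifnot(m1 >= 1L, m2 <= n, m1 < m2)
  mat <- m1:m2
  paired <- mat[pt[mat] > 0L]
  if (length(paired) == 0L) {
    candidate$reject_reason <- "unpaired-mature"
    return(candidate)
  }
  partners <- pt[paired]
  if (any(partners %in% mat) ||
      (any(partners > m2) && any(partners < m1))) {
    candidate$reject_reason <- "loop-spanning"
    return(candidate)
  }
  # extrapolated partner of an arbitrary mature position: partner coordinates
  # decrease by one per +1 step along the mature in a perfect helix
  f <- function(t) {
    q <- paired[which.min(abs(paired - t))]
    pt[q] - (t - q)
  }
  # star span under the 2-nt 3' overhang convention (antiparallel duplex:
  # star 3' end lies opposite the mature 5' end)
  s_hi <- f(m1) + 2L
  s_lo <- f(m2) + 2L
  if (s_lo > s_hi) { tmp <- s_lo; s_lo <- s_hi; s_hi <- tmp }
  if (s_lo < 1L || s_hi > n || (s_lo <= m2 && s_hi >= m1)) {
    candidate$reject_reason <- "star-out-of-range"
    return(candidate)
  }
  star <- s_lo:s_hi
  longest_run <- function(unp) {
    if (!any(unp)) return(0L)
    r <- rle(unp)
    max(r$lengths[r$values])
  }
  unp_m <- pt[mat] == 0L
  unp_s <- pt[star] == 0L
  # 3' protrusion: each strand's 3' end must extend past the partner of the
  # other strand's 5'-most duplex-paired base
  star_paired <- star[pt[star] > 0L & pt[star] %in% mat]
  mat_paired_in_duplex <- mat[pt[mat] > 0L & pt[mat] %in% star]
  if (length(star_paired) == 0L || length(mat_paired_in_duplex) == 0L) {
    overhang <- FALSE
  } else {
    prot_m <- m2 - pt[min(star_paired)]
    prot_s <- s_hi - pt[min(mat_paired_in_duplex)]
    overhang <- prot_m >= 1L && prot_s >= 1L
  }
  loop <- if (s_lo > m2) c(m2 + 1L, s_lo - 1L) else c(s_hi + 1L, m1 - 1L)
  candidate$star_span <- c(s_lo, s_hi)
  candidate$loop_span <- if (loop[1L] <= loop[2L]) loop else NULL
  candidate$duplex <- list(
    unpaired_mature = sum(unp_m),
    unpaired_star = sum(unp_s),
    max_bulge = max(longest_run(unp_m), longest_run(unp_s)),
    asymmetry = abs(sum(unp_m) - sum(unp_s)),
    overhang_3p_both = overhang
  )
  candidate
}

#' Structural filter on a folded hairpin candidate
#'
#' A candidate passes when all of the following hold: folding energy
#' <= -25 kcal/mol; mature and star reside on different arms of the hairpin
#' (a valid duplex was found); at most 6 unpaired bases within each of mature
#' and star; maximum bulge in the duplex at most 4 nt; duplex asymmetry at
#' most 3; and, only when star reads were actually sequenced, the duplex
#' shows 3' overhangs at both ends. All boundaries are inclusive.
#'
#' @param candidate candidate with `mfe` and [duplex_metrics()] applied.
#' @param reads_on_star were reads sequenced from the star arm?
#' @param max_mfe,max_unpaired,max_bulge,max_asymmetry filter thresholds
#'   (defaults -25 kcal/mol, 6, 4, 3).
#' @return list with `pass` (logical) and `reasons` (character vector of
#'   failed criteria, empty when passing).
#' @export
structural_filter <- function(candidate, reads_on_star = FALSE,
                              max_mfe = -25.0, max_unpaired = 6L,
                              max_bulge = 4L, max_asymmetry = 3L) {
  reasons <- character(0)
  if (!is.null(candidate$reject_reason)) {
    reasons <- c(reasons, candidate$reject_reason)
  }
  if (is.null(candidate$mfe) || candidate$mfe > max_mfe) {
    reasons <- c(reasons, "energy")
  }
  d <- candidate$duplex
  if (is.null(d)) {
    if (is.null(candidate$reject_reason)) reasons <- c(reasons, "arms")
  } else {
    if (d$unpaired_mature > max_unpaired) reasons <- c(reasons, "unpaired_mature")
    if (d$unpaired_star > max_unpaired) reasons <- c(reasons, "unpaired_star")
    if (d$max_bulge > max_bulge) reasons <- c(reasons, "bulge")
    if (d$asymmetry > max_asymmetry) reasons <- c(reasons, "asymmetry")
    if (reads_on_star && !d$overhang_3p_both) reasons <- c(reasons, "overhang")
  }
  list(pass = length(reasons) == 0L, reasons = reasons)
}

#' Select the better of the two candidate precursors
#'
#' Returns the passing candidate; when both pass, the one with the lower
#' folding energy (tie broken in favour of the `up10_down70` window); `NULL`
#' when both fail (with merged failure reasons in the `"reasons"` attribute).
#'
#' @param cand_a,cand_b evaluated candidates, each carrying a `filter`
#'   element as returned by [structural_filter()].
#' @return the selected candidate, or `NULL` when both fail (the failure
#'   reasons remain available on each candidate's `filter` element).
#' @export
select_precursor <- function(cand_a, cand_b) {
  pa <- isTRUE(cand_a$filter$pass); pb <- isTRUE(cand_b$filter$pass)
  if (pa && pb) {
    if (cand_a$mfe < cand_b$mfe) return(cand_a)
    if (cand_b$mfe < cand_a$mfe) return(cand_b)
    if (identical(cand_b$window, "up10_down70")) return(cand_b)
    return(cand_a)        # tie -> up10_down70 window
  }
  if (pa) return(cand_a)
  if (pb) return(cand_b)
  NULL
}
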