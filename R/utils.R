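# small shared helpers

#' Reverse complement of DNA/RNA character vectors
#'
#' @param x character vector of sequences (DNA letters; T or U accepted).
#' @return character vector of reverse complements, in the same alphabet
#'   (U in, U out).
#' @keywords internal
revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  has_u <- grepl("U", x, fixed = TRUE)
  dna <- chartr("Uu", "Tt", x)
  out <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(dna)))
  out[has_u] <- chartr("Tt", "Uu", out[has_u])
  unname(out)
}

#' @keywords internal
dna_to_rna <- function(x) chartr("Tt", "Uu", x)

#' @keywords internal
rna_to_dna <- function(x) chartr("Uu", "Tt", x)

#' Round half away from zero (printed-table style)
#'
#' Base R rounds half to even; summary tables here use the conventional
#' "round half up" so that printed percentages match hand arithmetic.
#'
#' @param x numeric vector.
#' @param digits decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 2) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5 + 1e-9) / m
}

#' Best ungapped overlap distance between two short sequences
#'
#' Slides one sequence against the other by at most `max_shift` positions at
#' the 5' end while requiring the 3' end shift (implied by the length
#' difference) to stay within `max_shift` as well, and counts mismatches over
#' the overlapping window. Used for known-miRNA matching, paralog grouping
#' and conservation classification.
#'
#' @param a,b sequences (character scalars, same alphabet).
#' @param max_shift maximum permitted shift of either end (nt).
#' @return list with `mismatches` (minimum over admissible shifts; `Inf` when
#'   no admissible shift exists) and `shift` (the 5' shift achieving it).
#' @export
seq_match_dist <- function(a, b, max_shift = 3L) {
  a <- toupper(rna_to_dna(a)); b <- toupper(rna_to_dna(b))
  na <- nchar(a); nb <- nchar(b)
  best <- Inf; best_shift <- NA_integer_
  av <- strsplit(a, "", fixed = TRUE)[[1]]
  bv <- strsplit(b, "", fixed = TRUE)[[1]]
  for (s in seq.int(-max_shift, max_shift)) {
    # s: position of b's first base relative to a's first base
    shift3 <- s + nb - na           # displacement of b's 3' end vs a's
    if (abs(shift3) > max_shift) next
    lo <- max(1L, 1L + s); hi <- min(na, nb + s)
    if (hi < lo) next
    mism <- sum(av[lo:hi] != bv[(lo - s):(hi - s)])
    if (mism < best) { best <- mism; best_shift <- s }
  }
  list(mismatches = best, shift = best_shift)
}

#' @keywords internal
`%||%` <- function(x, y) if (is.null(x)) y else x

# fast random DNA string(s)
#' @keywords internal
random_dna <- function(n, len, gc = 0.5) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  vapply(seq_len(n), function(i) {
    paste(sample(names(p), len, replace = TRUE, prob = p), collapse = "")
  }, character(1))
}
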