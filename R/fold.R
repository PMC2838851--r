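# RNA secondary-structure folding and the dinucleotide-shuffle folding p-value

#' Fold RNA sequences into minimum-free-energy secondary structures
#'
#' Computes, for each input sequence, the deterministic MFE structure in
#' dot-bracket notation and its free energy in kcal/mol at 37 degrees C.
#' The engine is pluggable: the default runs ViennaRNA's `RNAfold` binary in
#' a single batch call; any function with the same contract can be supplied
#' via `engine` or globally via `options(mirforge.fold_engine = fun)`.
#'
#' @param seqs character vector of RNA sequences (T is converted to U;
#'   only A, C, G, U are accepted).
#' @param engine `NULL` for the default engine, or a function
#'   `function(seqs) data.frame(structure, mfe)` returning one row per input.
#' @return data.frame with columns `sequence` (RNA, uppercase), `structure`
#'   (dot-bracket, same length) and `mfe` (kcal/mol).
#' @examples
#' \dontrun{
#' fold_rna(c("GGGGAAAACCCC", "ACGUACGUACGU"))
#' }
#' @export
fold_rna <- function(seqs, engine = NULL) {
  seqs <- toupper(dna_to_rna(seqs))
  if (length(seqs) == 0L) {
    return(data.frame(sequence = character(0), structure = character(0),
                      mfe = numeric(0), stringsAsFactors = FALSE))
  }
  bad <- grepl("[^ACGU]", seqs)
  if (any(bad)) {
    stop("non-ACGU characters in sequence(s): ",
         paste(utils::head(which(bad), 5), collapse = ", "))
  }
  engine <- engine %||% getOption("mirforge.fold_engine") %||% rnafold_engine
  out <- engine(seqs)
  stopifnot(nrow(out) == length(seqs),
            all(nchar(out$structure) == nchar(seqs)))
  data.frame(sequence = seqs, structure = out$structure, mfe = out$mfe,
             stringsAsFactors = FALSE)
}

# default engine: one batched call to ViennaRNA's RNAfold
#' @keywords internal
rnafold_engine <- function(seqs) {
  exe <- Sys.which("RNAfold")
  if (!nzchar(exe)) {
    stop("RNAfold binary not found on PATH; supply a custom folding engine ",
         "via options(mirforge.fold_engine = ...)")
  }
  fin <- tempfile(fileext = ".fa")
  on.exit(unlink(fin), add = TRUE)
  writeLines(paste0(">s", seq_along(seqs), "\n", seqs), fin)
  out <- suppressWarnings(
    system2(exe, c("--noPS", "--noconv", "--infile", fin), stdout = TRUE)
  )
  out <- out[nzchar(out)]
  hdr <- grep("^>", out)
  if (length(hdr) != length(seqs)) stop("RNAfold output could not be parsed")
  struct_lines <- out[hdr + 2L]
  m <- regmatches(struct_lines,
                  regexpr("^[.()]+ +\\( *(-?[0-9.]+)\\)$", struct_lines))
  if (length(m) != length(seqs)) stop("RNAfold structure lines malformed")
  structure <- sub(" .*$", "", struct_lines)
  mfe <- as.numeric(sub("^.*\\( *(-?[0-9.]+)\\)$", "\\1", struct_lines))
  data.frame(structure = structure, mfe = mfe, stringsAsFactors = FALSE)
}

#' Pairing table of a dot-bracket structure
#'
#' @param structure dot-bracket string (balanced round brackets).
#' @return integer vector `p` with `p[i]` = 1-based partner of position `i`,
#'   or 0 when unpaired.
#' @export
pair_table <- function(structure) {
  ch <- strsplit(structure, "", fixed = TRUE)[[1]]
  n <- length(ch)
  p <- integer(n)
  stack <- integer(0)
  for (i in seq_len(n)) {
    if (ch[i] == "(") {
      stack <- c(stack, i)
    } else if (ch[i] == ")") {
      if (length(stack) == 0L) stop("unbalanced dot-bracket structure")
      j <- stack[length(stack)]
      stack <- stack[-length(stack)]
      p[i] <- j; p[j] <- i
    } else if (ch[i] != ".") {
      stop("invalid character in dot-bracket structure: ", ch[i])
    }
  }
  if (length(stack) > 0L) stop("unbalanced dot-bracket structure")
  p
}

#' Dinucleotide-preserving sequence shuffle
#'
#' Altschul-Erickson doublet-preserving shuffle: the returned sequence has
#' exactly the dinucleotide composition (and hence first/last letters) of the
#' input. Used to build the null distribution of folding energies.
#'
#' @param seq a single sequence (character scalar, any alphabet).
#' @return shuffled sequence (character scalar).
#' @export
dinuc_shuffle <- function(seq) {
  s <- strsplit(seq, "", fixed = TRUE)[[1]]
  n <- length(s)
  if (n < 4L) stop("sequence too short to shuffle (< 4 nt)")
  letters_ <- unique(s)
  code <- match(s, letters_)
  k <- length(letters_)
  last <- code[n]
  # multigraph of doublet edges: from[i] -> to[i]
  from <- code[-n]; to <- code[-1L]
  out_edges <- split(seq_along(to), from)      # indices into `to` per vertex
  # pick, for every vertex except the last, a terminal edge such that each
  # chosen edge leads (transitively) to the last vertex
  verts <- sort(unique(from))
  repeat {
    term <- rep(NA_integer_, k)                # chosen terminal target vertex
    for (v in verts) {
      if (v == last) next
      idx <- out_edges[[as.character(v)]]
      term[v] <- to[idx[sample.int(length(idx), 1L)]]
    }
    ok <- TRUE
    for (v in verts) {
      if (v == last) next
      cur <- v; steps <- 0L
      while (cur != last && steps <= k) {
        cur <- term[cur]
        if (is.na(cur)) break
        steps <- steps + 1L
      }
      if (is.na(cur) || cur != last) { ok <- FALSE; break }
    }
    if (ok) break
  }
  # order each vertex's out-edge targets: random permutation, terminal last
  succ <- vector("list", k)
  for (v in verts) {
    idx <- out_edges[[as.character(v)]]
    targets <- to[idx]
    if (v != last) {
      ti <- which(targets == term[v])[1L]
      rest <- targets[-ti]
      if (length(rest) > 1L) rest <- rest[sample.int(length(rest))]
      succ[[v]] <- c(rest, targets[ti])
    } else {
      if (length(targets) > 1L) targets <- targets[sample.int(length(targets))]
      succ[[v]] <- targets
    }
  }
  # Eulerian walk from the first vertex consuming edges in order
  ptr <- integer(k)
  res <- integer(n)
  res[1L] <- code[1L]
  cur <- code[1L]
  for (i in 2:n) {
    ptr[cur] <- ptr[cur] + 1L
    nxt <- succ[[cur]][ptr[cur]]
    res[i] <- nxt
    cur <- nxt
  }
  paste(letters_[res], collapse = "")
}

#' Folding p-value by dinucleotide shuffling
#'
#' Estimates how unusually stable a sequence's MFE structure is relative to
#' dinucleotide-preserving shuffles of itself:
#' `p = (1 + #\{shuffles with MFE <= observed\}) / (n_shuffles + 1)`.
#'
#' @param seq RNA sequence (character scalar).
#' @param n_shuffles number of shuffles (>= 99 so that a 0.01 threshold is
#'   resolvable; default 100).
#' @param seed optional integer seed; the global RNG state is restored.
#' @param engine folding engine passed to [fold_rna()].
#' @return p-value in (0, 1].
#' @export
fold_pvalue <- function(seq, n_shuffles = 100L, seed = NULL, engine = NULL) {
  if (nchar(seq) < 4L) stop("sequence too short to shuffle (< 4 nt)")
  if (n_shuffles < 99L) stop("n_shuffles must be >= 99 to resolve p < 0.01")
  run <- function() {
    shuf <- vapply(seq_len(n_shuffles), function(i) dinuc_shuffle(seq),
                   character(1))
    fr <- fold_rna(c(seq, shuf), engine = engine)
    obs <- fr$mfe[1L]
    (1 + sum(fr$mfe[-1L] <= obs)) / (n_shuffles + 1)
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}
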