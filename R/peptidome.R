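#' A fixed-length peptidome
#'
#' The set of unique k-length peptides (default 15mers) derivable from a
#' pool of MHC protein sequences by a step-1 sliding window, with
#' bookkeeping of which alleles contribute each peptide. Windows
#' containing the unknown residue \code{'X'} are skipped: they can be
#' neither matched nor bound meaningfully.
#'
#' @slot k peptide length.
#' @slot peptides character vector of unique k-mers (first-seen order).
#' @slot sources named list mapping each peptide to the character vector
#'   of contributing allele names.
#' @export
setClass("Peptidome",
  representation(k = "integer", peptides = "character", sources = "list"))

setValidity("Peptidome", function(object) {
  if (length(object@k) != 1L || object@k < 1L)
    return("k must be a single positive integer")
  if (length(object@peptides) &&
      any(nchar(object@peptides) != object@k))
    return("every peptide must have length k")
  if (anyDuplicated(object@peptides))
    return("peptides must be unique")
  if (any(grepl("X", object@peptides, fixed = TRUE)))
    return("peptides must not contain 'X'")
  if (!identical(sort(names(object@sources)), sort(object@peptides)))
    return("sources' key set must equal the peptide set")
  TRUE
})

#' @describeIn Peptidome summary display
#' @param object a \code{Peptidome}
#' @export
setMethod("show", "Peptidome", function(object) {
  cat("Peptidome of", length(object@peptides), "unique", object@k,
      "mers\n")
  nsrc <- length(unique(unlist(object@sources, use.names = FALSE)))
  cat("  from", nsrc, "source allele(s)\n")
})

#' @describeIn Peptidome number of unique peptides
#' @param x a \code{Peptidome}
#' @export
setMethod("length", "Peptidome", function(x) length(x@peptides))

#' Peptides of a peptidome
#' @param p a \code{Peptidome}.
#' @return character vector of unique k-mers.
#' @export
peptides <- function(p) {
  stopifnot(is(p, "Peptidome"))
  p@peptides
}

#' Enumerate sliding-window k-mers of a protein sequence
#'
#' All \code{max(0, L - k + 1)} windows at step 1, in start-position
#' order, minus any window containing \code{'X'}. Duplicates are kept
#' (this is the raw window list, not a set).
#'
#' @param seq protein string.
#' @param k window length (positive integer, default 15).
#' @return character vector of k-mers (possibly empty).
#' @examples
#' enumerateKmers("ACDEFGHIKLMNPQRST", 15)  # 3 windows
#' @export
enumerateKmers <- function(seq, k = 15L) {
  stopifnot(is.character(seq), length(seq) == 1L)
  k <- as.integer(k)
  if (is.na(k) || k < 1L) stop("k must be a positive integer")
  L <- nchar(seq)
  if (L < k) return(character(0))
  starts <- seq_len(L - k + 1L)
  kmers <- substring(seq, starts, starts + k - 1L)
  kmers[!grepl("X", kmers, fixed = TRUE)]
}

#' Build a peptidome from allele sequences
#'
#' Union of unique k-mers across all sequences, recording per peptide the
#' set of contributing alleles. Duplicate input sequences collapse to the
#' same peptides (set semantics), so the operation is idempotent under
#' repeated concatenation of the same input.
#'
#' @param x an \code{\linkS4class{AlleleDb}} or a named character vector
#'   of protein sequences.
#' @param k peptide length (default 15).
#' @return a \code{\linkS4class{Peptidome}}.
#' @export
buildPeptidome <- function(x, k = 15L) {
  seqs <- if (is(x, "AlleleDb")) as.character(x@seqs) else toupper(x)
  stopifnot(is.character(seqs), length(seqs) >= 1L)
  if (is.null(names(seqs)) || any(!nzchar(names(seqs))))
    stop("every sequence must be named by its allele")
  k <- as.integer(k)
  pepList <- lapply(seqs, enumerateKmers, k = k)
  allPep <- unlist(pepList, use.names = FALSE)
  allSrc <- rep(names(seqs), lengths(pepList))
  uniq <- unique(allPep)
  srcByPep <- lapply(split(allSrc, factor(allPep, levels = uniq)), unique)
  new("Peptidome", k = k, peptides = uniq, sources = srcByPep[uniq])
}

#' Peptidome overlap statistics
#'
#' Overlap summary of two peptidomes: set sizes, exact intersection size
#' and the shared percentage. The default denominator is the combined
#' (summed) pool size \code{nA + nB}; \code{"union"} uses the
#' deduplicated union. The percentage is rounded to one decimal, the
#' precision at which such overlaps are conventionally reported.
#'
#' @param a,b \code{\linkS4class{Peptidome}} objects with equal \code{k}.
#' @param denominator \code{"combined"} (default) or \code{"union"}.
#' @return an \code{\linkS4class{OverlapStats}}.
#' @export
overlapStats <- function(a, b, denominator = c("combined", "union")) {
  denominator <- match.arg(denominator)
  stopifnot(is(a, "Peptidome"), is(b, "Peptidome"))
  if (a@k != b@k)
    stop("peptide length mismatch: ", a@k, " vs ", b@k)
  nShared <- length(intersect(a@peptides, b@peptides))
  overlapStatsCounts(length(a@peptides), length(b@peptides), nShared,
                     denominator = denominator)
}

#' Overlap summary of two peptide pools
#'
#' @slot nA,nB,nShared pool sizes and exact intersection size.
#' @slot sharedPct shared percentage (one decimal).
#' @slot denominator \code{"combined"} (\code{nA + nB}) or \code{"union"}.
#' @export
setClass("OverlapStats",
  representation(nA = "integer", nB = "integer", nShared = "integer",
                 sharedPct = "numeric", denominator = "character"))

setValidity("OverlapStats", function(object) {
  if (object@nShared > min(object@nA, object@nB))
    return("nShared cannot exceed the smaller pool")
  TRUE
})

#' @describeIn OverlapStats compact display
#' @param object an \code{OverlapStats}
#' @export
setMethod("show", "OverlapStats", function(object) {
  cat("OverlapStats: |A| =", object@nA, " |B| =", object@nB,
      " shared =", object@nShared,
      sprintf(" (%.1f%% of %s)\n", object@sharedPct, object@denominator))
})

#' Shared-percentage arithmetic from pool counts
#'
#' Computes the shared percentage directly from counts, without the
#' peptide sets themselves — useful for checking published pool sizes.
#'
#' @param nA,nB,nShared pool sizes and intersection size.
#' @param denominator \code{"combined"} (\code{nA + nB}, default) or
#'   \code{"union"} (\code{nA + nB - nShared}).
#' @return an \code{\linkS4class{OverlapStats}}.
#' @examples
#' overlapStatsCounts(158083, 13969, 894)  # shared 0.5% of combined pools
#' @export
overlapStatsCounts <- function(nA, nB, nShared,
                               denominator = c("combined", "union")) {
  denominator <- match.arg(denominator)
  nA <- as.integer(nA); nB <- as.integer(nB); nShared <- as.integer(nShared)
  den <- if (denominator == "combined") nA + nB else nA + nB - nShared
  pct <- if (den > 0) round(100 * nShared / den, 1L) else 0
  new("OverlapStats", nA = nA, nB = nB, nShared = nShared,
      sharedPct = pct, denominator = denominator)
}

#' Export a peptidome as TSV
#'
#' One row per peptide: the peptide, its source count and a
#' comma-separated source allele list.
#'
#' @param p a \code{Peptidome}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writePeptidomeTsv <- function(p, path) {
  stopifnot(is(p, "Peptidome"))
  df <- data.frame(
    peptide = p@peptides,
    n_sources = lengths(p@sources[p@peptides]),
    sources = vapply(p@sources[p@peptides], paste, character(1L),
                     collapse = ","),
    stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
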