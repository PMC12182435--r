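#' A pairwise global protein alignment
#'
#' Result of \code{\link{globalAlign}}: the two input sequences with
#' \code{'-'} gap characters inserted, plus the alignment score. Removing
#' the gaps recovers the original sequences.
#'
#' @slot aAligned,bAligned aligned strings of equal length.
#' @slot score alignment score under the chosen scheme.
#' @export
setClass("AlignedPair",
  representation(aAligned = "character", bAligned = "character",
                 score = "numeric"))

setValidity("AlignedPair", function(object) {
  if (nchar(object@aAligned) != nchar(object@bAligned))
    return("aligned strings must have equal length")
  TRUE
})

#' @describeIn AlignedPair compact display
#' @param object an \code{AlignedPair}
#' @export
setMethod("show", "AlignedPair", function(object) {
  cat("AlignedPair (score ", object@score, ", length ",
      nchar(object@aAligned), ")\n", sep = "")
  cat(" ", object@aAligned, "\n ", object@bAligned, "\n", sep = "")
})

.identityMatrix <- function(match = 1, mismatch = 0) {
  m <- matrix(mismatch, length(AA_ALPHABET_X), length(AA_ALPHABET_X),
              dimnames = list(AA_ALPHABET_X, AA_ALPHABET_X))
  diag(m) <- match
  m["X", "X"] <- mismatch  # unknown residues never count as a match
  m
}

#' Global pairwise protein alignment
#'
#' Needleman-Wunsch global alignment with affine gap penalties, computed
#' by \code{\link[Biostrings]{pairwiseAlignment}}. The default scheme is
#' an identity matrix (match +1, mismatch 0) with a per-position gap cost
#' of 1, appropriate when the target quantity is a count of differing
#' positions rather than a similarity score; \code{"BLOSUM62"} is
#' available for conventional similarity alignment. Traceback is
#' deterministic, so identical inputs always give the identical
#' alignment.
#'
#' @param a,b protein sequences (non-empty strings).
#' @param substitution \code{"identity"} (default) or \code{"BLOSUM62"}.
#' @param match,mismatch scores used by the identity scheme.
#' @param gapOpen,gapExtend non-negative gap penalties (costs).
#' @return an \code{\linkS4class{AlignedPair}}.
#' @examples
#' globalAlign("ACDE", "ACE")
#' @export
globalAlign <- function(a, b, substitution = c("identity", "BLOSUM62"),
                        match = 1, mismatch = 0,
                        gapOpen = 0, gapExtend = 1) {
  substitution <- match.arg(substitution)
  stopifnot(is.character(a), is.character(b),
            length(a) == 1L, length(b) == 1L)
  if (!nzchar(a) || !nzchar(b)) stop("cannot align an empty sequence")
  a <- toupper(a); b <- toupper(b)
  mat <- if (substitution == "identity") .identityMatrix(match, mismatch)
         else {
           e <- new.env()
           utils::data("BLOSUM62", package = "Biostrings", envir = e)
           e$BLOSUM62
         }
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b),
    substitutionMatrix = mat, gapOpening = gapOpen,
    gapExtension = gapExtend, type = "global")
  new("AlignedPair",
      aAligned = as.character(Biostrings::alignedPattern(pa)),
      bAligned = as.character(Biostrings::alignedSubject(pa)),
      score = Biostrings::score(pa))
}

#' Hamming distance between aligned sequences
#'
#' Count of alignment columns at which the two symbols differ. By default
#' a gap opposite a residue counts as a difference (length differences
#' contribute to distance); set \code{countGaps = FALSE} to ignore
#' gap-containing columns.
#'
#' @param x an \code{\linkS4class{AlignedPair}}, or an aligned string.
#' @param y when \code{x} is a string: the second aligned string (equal
#'   length required).
#' @param countGaps count gap-vs-residue columns as differing (default
#'   \code{TRUE}).
#' @return integer distance.
#' @examples
#' hammingDistance("ABCD", "ABCE")            # 1
#' hammingDistance(globalAlign("ACDE", "ACE")) # 1 (one gap column)
#' @export
hammingDistance <- function(x, y = NULL, countGaps = TRUE) {
  if (is(x, "AlignedPair")) {
    a <- x@aAligned; b <- x@bAligned
  } else {
    stopifnot(is.character(x), is.character(y),
              length(x) == 1L, length(y) == 1L)
    if (nchar(x) != nchar(y))
      stop("aligned sequences must have equal length (", nchar(x),
           " vs ", nchar(y), ")")
    a <- x; b <- y
  }
  ca <- strsplit(a, "", fixed = TRUE)[[1L]]
  cb <- strsplit(b, "", fixed = TRUE)[[1L]]
  diff <- ca != cb
  if (!countGaps) diff <- diff & ca != "-" & cb != "-"
  as.integer(sum(diff))
}

#' All-pairs Hamming distance matrix
#'
#' Aligns every pair of sequences with \code{\link{globalAlign}} and
#' records the Hamming distance of the alignment. The result is a square
#' symmetric matrix with zero diagonal, labelled by allele name.
#'
#' @param x an \code{\linkS4class{AlleleDb}} or a named character vector
#'   of sequences (at least two; duplicate labels are an error).
#' @param countGaps passed to \code{\link{hammingDistance}}.
#' @param ... passed to \code{\link{globalAlign}}.
#' @return a symmetric numeric matrix of differing-position counts.
#' @export
distanceMatrix <- function(x, countGaps = TRUE, ...) {
  seqs <- if (is(x, "AlleleDb")) as.character(x@seqs) else x
  stopifnot(is.character(seqs))
  if (length(seqs) < 2L) stop("need at least two sequences")
  labels <- names(seqs)
  if (is.null(labels) || any(!nzchar(labels)))
    stop("every sequence must be labelled")
  if (anyDuplicated(labels))
    stop("duplicate labels: ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "))
  n <- length(seqs)
  d <- matrix(0, n, n, dimnames = list(labels, labels))
  for (i in seq_len(n - 1L)) {
    for (j in seq((i + 1L), n)) {
      h <- hammingDistance(globalAlign(seqs[[i]], seqs[[j]], ...),
                           countGaps = countGaps)
      d[i, j] <- h
      d[j, i] <- h
    }
  }
  d
}

#' Write / read a labelled distance matrix as TSV
#'
#' Labels occupy the first row and first column.
#'
#' @param d square labelled matrix.
#' @param path file path.
#' @return \code{path} (write) or the matrix (read).
#' @export
writeDistanceTsv <- function(d, path) {
  utils::write.table(d, path, sep = "\t", quote = FALSE,
                     row.names = TRUE, col.names = NA)
  invisible(path)
}

#' @rdname writeDistanceTsv
#' @export
readDistanceTsv <- function(path) {
  df <- utils::read.delim(path, row.names = 1L, check.names = FALSE)
  as.matrix(df)
}

.checkDistanceMatrix <- function(d) {
  if (!is.matrix(d) || nrow(d) != ncol(d))
    stop("distance matrix must be square")
  if (is.null(rownames(d)) || !identical(rownames(d), colnames(d)))
    stop("distance matrix must carry identical row and column labels")
  if (any(d < 0)) stop("distance matrix has negative entries")
  if (max(abs(d - t(d))) > 1e-8) stop("distance matrix is not symmetric")
  if (any(abs(diag(d)) > 1e-8)) stop("distance matrix diagonal must be zero")
  invisible(TRUE)
}

#' Neighbor-joining tree from a distance matrix
#'
#' Builds an unrooted neighbor-joining tree (\code{\link[ape]{nj}}) from a
#' symmetric non-negative distance matrix. Additive matrices are recovered
#' exactly (their path-length metric is reproduced). Negative branch
#' lengths that NJ can produce on non-additive input are clamped to zero.
#'
#' @param d square symmetric matrix with zero diagonal and at least three
#'   labels.
#' @return an \code{ape} \code{phylo} object (serializable to Newick via
#'   \code{\link[ape]{write.tree}}).
#' @export
njTree <- function(d) {
  .checkDistanceMatrix(d)
  if (nrow(d) < 3L) stop("need at least three labels for a tree")
  tree <- ape::nj(stats::as.dist(d))
  tree$edge.length[tree$edge.length < 0] <- 0
  tree
}

#' Do groups form separate clades?
#'
#' Tests whether some edge of the (unrooted) tree bipartitions the leaves
#' exactly into the two given groups, i.e. whether each group is
#' monophyletic. Delegates to \code{\link[ape]{is.monophyletic}} after
#' validating that the groups partition the leaf set.
#'
#' @param tree a \code{phylo} object.
#' @param groups list of two character vectors of leaf labels, or a named
#'   vector/factor mapping leaf label to group.
#' @return \code{TRUE} iff the two groups are separated by a single edge.
#' @export
speciesMonophyly <- function(tree, groups) {
  stopifnot(inherits(tree, "phylo"))
  if (!is.list(groups)) {
    if (is.null(names(groups))) stop("groups vector must be named by leaf")
    groups <- split(names(groups), as.character(groups))
  }
  if (length(groups) != 2L) stop("exactly two groups required")
  g1 <- as.character(groups[[1L]]); g2 <- as.character(groups[[2L]])
  tips <- tree$tip.label
  unknown <- setdiff(c(g1, g2), tips)
  if (length(unknown))
    stop("unknown leaf label(s): ", paste(unknown, collapse = ", "))
  if (length(intersect(g1, g2)) || !setequal(c(g1, g2), tips))
    stop("groups must partition the leaf set (every leaf in exactly one group)")
  if (length(g1) <= 1L || length(g2) <= 1L) return(TRUE)
  ape::is.monophyletic(tree, g1) && ape::is.monophyletic(tree, g2)
}
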