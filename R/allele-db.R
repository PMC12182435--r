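#' Allele sequence database
#'
#' A set of named MHC protein sequences (one per allele) with parsed
#' nomenclature metadata. Wraps a \code{\link[Biostrings]{AAStringSet}};
#' lookups resolve on the two-field allele key so e.g. a genotype naming
#' \code{"HLA-A*01:01"} finds a database entry \code{"HLA-A*01:01:01"}.
#'
#' @slot seqs \code{AAStringSet} named by the raw allele name.
#' @slot meta \code{data.frame} with columns \code{raw}, \code{species},
#'   \code{gene}, \code{key} (two-field name), parallel to \code{seqs}.
#' @export
setClass("AlleleDb",
  representation(seqs = "AAStringSet", meta = "data.frame"))

setValidity("AlleleDb", function(object) {
  n <- length(object@seqs)
  if (nrow(object@meta) != n)
    return("meta must have one row per sequence")
  if (n && !identical(names(object@seqs), object@meta$raw))
    return("sequence names and meta$raw out of step")
  if (anyDuplicated(object@meta$raw))
    return("duplicate allele names")
  widths <- Biostrings::width(object@seqs)
  if (n && any(widths == 0L))
    return("empty sequence in database")
  TRUE
})

#' Construct an allele database from named sequences
#'
#' @param seqs named character vector (or \code{AAStringSet}) of protein
#'   sequences; names are allele designations. Sequences are uppercased
#'   and must use the 20 amino-acid letters plus \code{'X'}.
#' @return an \code{\linkS4class{AlleleDb}}.
#' @examples
#' db <- alleleDb(c("HLA-A*01:01" = "MAVMAPRTLLL", "SLA-1*07:02" = "MGPRTLILL"))
#' db
#' @export
alleleDb <- function(seqs) {
  if (is(seqs, "AAStringSet")) seqs <- as.character(seqs)
  if (length(seqs) == 0L) stop("no sequences given")
  if (is.null(names(seqs)) || any(!nzchar(names(seqs))))
    stop("every sequence must be named by its allele")
  seqs <- toupper(seqs)
  .checkResidues(seqs)
  parsed <- lapply(names(seqs), parseAlleleName)
  meta <- data.frame(
    raw = vapply(parsed, function(p) p@raw, character(1L)),
    species = vapply(parsed, function(p) p@species, character(1L)),
    gene = vapply(parsed, function(p) p@gene, character(1L)),
    key = vapply(parsed, formatAlleleName, character(1L), nFields = 2L),
    stringsAsFactors = FALSE)
  if (anyDuplicated(meta$raw))
    stop("duplicate allele names: ",
         paste(unique(meta$raw[duplicated(meta$raw)]), collapse = ", "))
  aset <- Biostrings::AAStringSet(seqs)
  names(aset) <- meta$raw
  new("AlleleDb", seqs = aset, meta = meta)
}

.checkResidues <- function(seqs) {
  for (i in seq_along(seqs)) {
    ch <- strsplit(seqs[[i]], "", fixed = TRUE)[[1L]]
    bad <- which(!ch %in% AA_ALPHABET_X)
    if (length(bad))
      stop("non-amino-acid character ", sQuote(ch[bad[1L]]),
           " in record ", sQuote(names(seqs)[i]), " at position ", bad[1L])
  }
  invisible(TRUE)
}

#' @describeIn AlleleDb number of alleles
#' @param x an \code{AlleleDb}
#' @export
setMethod("length", "AlleleDb", function(x) length(x@seqs))

#' @describeIn AlleleDb raw allele names
#' @export
setMethod("names", "AlleleDb", function(x) x@meta$raw)

#' @describeIn AlleleDb summary display
#' @param object an \code{AlleleDb}
#' @export
setMethod("show", "AlleleDb", function(object) {
  cat("AlleleDb with", length(object), "allele sequences\n")
  sp <- table(ifelse(nzchar(object@meta$species), object@meta$species, "<none>"))
  cat("  species:", paste(names(sp), sp, sep = "=", collapse = ", "), "\n")
  if (length(object)) {
    w <- Biostrings::width(object@seqs)
    cat("  lengths:", min(w), "-", max(w), "residues\n")
    cat("  e.g.", paste(utils::head(names(object), 3L), collapse = ", "), "\n")
  }
})

#' Combine allele databases
#' @param x,... \code{AlleleDb} objects.
#' @return a merged \code{AlleleDb}; duplicate raw names are an error.
#' @export
setMethod("c", "AlleleDb", function(x, ...) {
  dbs <- c(list(x), list(...))
  seqs <- unlist(lapply(dbs, function(d) as.character(d@seqs)))
  alleleDb(seqs)
})

#' Subset an allele database
#' @param x an \code{AlleleDb}.
#' @param i numeric, logical or character (raw name) index.
#' @param j,...,drop ignored.
#' @return an \code{AlleleDb} with the selected alleles.
#' @export
setMethod("[", "AlleleDb", function(x, i, j, ..., drop = TRUE) {
  if (is.character(i)) i <- match(i, x@meta$raw)
  if (anyNA(i)) stop("unknown allele name in subset")
  sel <- as.character(x@seqs)[i]
  names(sel) <- x@meta$raw[i]
  alleleDb(sel)
})

#' Allele metadata table
#' @param db an \code{AlleleDb}.
#' @return the metadata \code{data.frame} (raw, species, gene, key).
#' @export
alleleMeta <- function(db) {
  stopifnot(is(db, "AlleleDb"))
  db@meta
}

#' Resolve allele names to sequences
#'
#' Looks up sequences by two-field allele key. When several database
#' entries share a key (higher-field variants of one allele) the first is
#' used.
#'
#' @param db an \code{AlleleDb}.
#' @param alleles character vector of allele names.
#' @return named character vector of sequences (names = input alleles).
#' @export
dbSequences <- function(db, alleles) {
  stopifnot(is(db, "AlleleDb"))
  keys <- alleleKey(alleles)
  idx <- match(keys, db@meta$key)
  if (anyNA(idx))
    stop("allele(s) not in sequence database: ",
         paste(unique(alleles[is.na(idx)]), collapse = ", "))
  out <- as.character(db@seqs)[idx]
  names(out) <- alleles
  out
}
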