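#' Parsed MHC allele name
#'
#' Represents one HLA/SLA-style allele designation such as
#' \code{"HLA-A*01:01"} or \code{"SLA-DQA*02:04"}, split into a species
#' prefix, a gene (locus) symbol and an ordered vector of numeric-string
#' fields. Allele identity throughout the package is the two-field name;
#' deeper fields are preserved but ignored in comparisons (see
#' \code{\link{alleleKey}}).
#'
#' @slot raw normalized input string (unicode hyphens mapped to ASCII).
#' @slot species species prefix, e.g. \code{"HLA"} or \code{"SLA"}; may be
#'   \code{""} for bare locus names.
#' @slot gene gene/locus symbol, e.g. \code{"A"}, \code{"DRB1"}, \code{"1"}.
#' @slot fields character vector of allele fields, e.g. \code{c("07","02")}.
#' @export
setClass("AlleleName",
  representation(raw = "character", species = "character",
                 gene = "character", fields = "character"))

setValidity("AlleleName", function(object) {
  if (length(object@gene) != 1L || !nzchar(object@gene))
    return("gene must be a non-empty string")
  if (length(object@fields) && any(!nzchar(object@fields)))
    return("allele fields must be non-empty")
  TRUE
})

#' @describeIn AlleleName compact display
#' @param object an \code{AlleleName}
#' @export
setMethod("show", "AlleleName", function(object) {
  cat("AlleleName:", formatAlleleName(object), "\n")
  cat("  species:", if (nzchar(object@species)) object@species else "<none>",
      " gene:", object@gene,
      " fields:", paste(object@fields, collapse = ":"), "\n")
})

# map unicode hyphen variants (U+2010/2011/2212, as printed in journal text)
# to ASCII and strip whitespace
.normalizeAlleleString <- function(x) {
  x <- gsub("[‐‑−–—]", "-", x)
  gsub("[[:space:]]+", "", x)
}

#' Parse an HLA/SLA allele name
#'
#' Splits a nomenclature string of the form
#' \code{"<SPECIES>-<GENE>*<F1>:<F2>[:...]"} into its components. The
#' species prefix is optional (\code{"DRB1*04:03"} parses with an empty
#' species); a bare gene symbol without \code{"*"} is accepted and yields
#' zero fields. Unicode hyphens are normalized to ASCII so strings copied
#' from typeset text parse identically.
#'
#' @param raw a single allele name string.
#' @return an \code{\linkS4class{AlleleName}}.
#' @examples
#' parseAlleleName("SLA-DQA*02:04")
#' parseAlleleName("HLA-A*01:01:01")
#' @export
parseAlleleName <- function(raw) {
  if (!is.character(raw) || length(raw) != 1L || is.na(raw) || !nzchar(raw))
    stop("allele name must be a single non-empty string")
  norm <- .normalizeAlleleString(raw)
  if (!nzchar(norm)) stop("allele name is blank: ", sQuote(raw))
  parts <- strsplit(norm, "*", fixed = TRUE)[[1L]]
  if (length(parts) > 2L)
    stop("malformed allele name (multiple '*'): ", sQuote(raw))
  if (length(parts) == 1L && grepl("*", norm, fixed = TRUE))
    stop("malformed allele name (empty field list): ", sQuote(raw))
  locusPart <- parts[1L]
  if (!nzchar(locusPart))
    stop("malformed allele name (no gene before '*'): ", sQuote(raw))
  # species prefix = leading alphabetic token before the first hyphen,
  # provided a hyphen is present ("HLA-A" -> HLA/A; bare "DRB1" -> ""/DRB1)
  if (grepl("-", locusPart, fixed = TRUE)) {
    hy <- regexpr("-", locusPart, fixed = TRUE)
    species <- substr(locusPart, 1L, hy - 1L)
    gene <- substr(locusPart, hy + 1L, nchar(locusPart))
    if (!grepl("^[A-Za-z]+$", species))
      stop("malformed species prefix in allele name: ", sQuote(raw))
  } else {
    species <- ""
    gene <- locusPart
  }
  if (!nzchar(gene))
    stop("malformed allele name (empty gene): ", sQuote(raw))
  if (length(parts) == 2L) {
    if (!nzchar(parts[2L]))
      stop("malformed allele name (empty field list): ", sQuote(raw))
    fields <- strsplit(parts[2L], ":", fixed = TRUE)[[1L]]
    if (length(fields) == 0L || any(!nzchar(fields)))
      stop("malformed allele name (empty field): ", sQuote(raw))
    if (any(!grepl("^[0-9]+[A-Za-z]?$", fields)))
      stop("malformed allele field in ", sQuote(raw), ": ",
           sQuote(fields[which(!grepl("^[0-9]+[A-Za-z]?$", fields))[1L]]))
  } else {
    fields <- character(0)
  }
  new("AlleleName", raw = norm, species = species, gene = gene,
      fields = fields)
}

#' Format an allele name
#'
#' Inverse of \code{\link{parseAlleleName}}: reassembles the nomenclature
#' string, optionally truncated to a fixed number of fields (two-field
#' truncation keeps exactly the first two fields).
#'
#' @param x an \code{AlleleName} or a string (parsed first).
#' @param nFields maximum number of fields to keep (default all).
#' @return a single string.
#' @examples
#' formatAlleleName("HLA-A*01:01:01", nFields = 2)  # "HLA-A*01:01"
#' @export
formatAlleleName <- function(x, nFields = Inf) {
  if (is.character(x)) x <- parseAlleleName(x)
  stopifnot(is(x, "AlleleName"))
  fields <- x@fields
  if (is.finite(nFields) && length(fields) > nFields)
    fields <- fields[seq_len(nFields)]
  locus <- if (nzchar(x@species)) paste0(x@species, "-", x@gene) else x@gene
  if (length(fields) == 0L) locus
  else paste0(locus, "*", paste(fields, collapse = ":"))
}

#' Two-field allele identity key
#'
#' Canonical identity used for every set operation in the package: the
#' allele name truncated to its first two fields. Vectorized.
#'
#' @param x character vector of allele names (or a single
#'   \code{AlleleName}).
#' @return character vector of two-field names.
#' @examples
#' alleleKey(c("HLA-A*01:01:01", "SLA-1*07:02"))
#' @export
alleleKey <- function(x) {
  if (is(x, "AlleleName")) return(formatAlleleName(x, nFields = 2L))
  vapply(x, function(a) formatAlleleName(parseAlleleName(a), nFields = 2L),
         character(1L), USE.NAMES = FALSE)
}

# locus key used for grouping: "<SPECIES>-<GENE>" or bare gene
.locusKey <- function(an) {
  if (nzchar(an@species)) paste0(an@species, "-", an@gene) else an@gene
}
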