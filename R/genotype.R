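#' An individual's MHC genotype
#'
#' Alleles grouped by locus for one individual, with a subset of loci
#' designated as class-II presenter loci (the loci whose products present
#' peptides to CD4+ T cells when this individual is the recipient;
#' HLA-DRB1-like by default). Loci may carry one to three alleles: the
#' reference SLA xenodonor genotype in common use lists three SLA-1
#' alleles, so diploidy is not enforced. Duplicate alleles (homozygosity)
#' are retained; they are deduplicated wherever sets are formed.
#'
#' @slot id individual identifier.
#' @slot species species label, e.g. \code{"human"} or \code{"swine"}.
#' @slot loci named list; each element a character vector of allele names
#'   at that locus.
#' @slot presenterLoci character vector of locus names whose alleles act
#'   as class-II presenters when this genotype is a recipient.
#' @export
setClass("Genotype",
  representation(id = "character", species = "character",
                 loci = "list", presenterLoci = "character"))

setValidity("Genotype", function(object) {
  if (length(object@loci) == 0L)
    return("genotype must contain at least one locus")
  if (is.null(names(object@loci)) || any(!nzchar(names(object@loci))))
    return("every locus must be named")
  if (anyDuplicated(names(object@loci)))
    return("duplicate locus names")
  for (l in names(object@loci)) {
    a <- object@loci[[l]]
    if (!is.character(a) || length(a) == 0L || any(!nzchar(a)))
      return(paste0("locus ", l, " must hold at least one allele name"))
    if (length(a) > 3L)
      return(paste0("locus ", l, " holds more than three alleles"))
  }
  TRUE
})

#' Construct a genotype
#'
#' @param id individual identifier.
#' @param species species label.
#' @param loci named list of character vectors of allele names per locus.
#' @param presenterLoci loci acting as class-II presenters (default
#'   \code{"DRB1"}-suffixed loci present in \code{loci}).
#' @return a \code{\linkS4class{Genotype}}.
#' @examples
#' g <- genotype("R1", "human",
#'               list(A = c("HLA-A*01:01", "HLA-A*02:01"),
#'                    DRB1 = c("HLA-DRB1*04:01", "HLA-DRB1*07:01")))
#' presenterAlleles(g)
#' @export
genotype <- function(id, species, loci, presenterLoci = NULL) {
  if (is.null(presenterLoci))
    presenterLoci <- grep("DRB1$", names(loci), value = TRUE)
  new("Genotype", id = as.character(id), species = as.character(species),
      loci = loci, presenterLoci = as.character(presenterLoci))
}

#' @describeIn Genotype summary display
#' @param object a \code{Genotype}
#' @export
setMethod("show", "Genotype", function(object) {
  cat("Genotype", sQuote(object@id), "(", object@species, ")\n")
  for (l in names(object@loci))
    cat("  ", format(l, width = 6), paste(object@loci[[l]], collapse = " + "),
        if (l %in% object@presenterLoci) " [presenter]" else "", "\n", sep = "")
})

#' All allele names of a genotype
#' @param g a \code{Genotype}.
#' @param unique drop duplicate two-field keys (default \code{FALSE}:
#'   homozygous duplicates retained).
#' @return character vector of allele names.
#' @export
genotypeAlleles <- function(g, unique = FALSE) {
  stopifnot(is(g, "Genotype"))
  a <- unlist(g@loci, use.names = FALSE)
  if (unique) a <- a[!duplicated(alleleKey(a))]
  a
}

#' Presenter alleles of a recipient genotype
#'
#' Alleles at the presenter loci, deduplicated on the two-field key (a
#' homozygous presenter contributes once).
#'
#' @param g a \code{Genotype}.
#' @return character vector (possibly empty) of presenter allele names.
#' @export
presenterAlleles <- function(g) {
  stopifnot(is(g, "Genotype"))
  keep <- intersect(g@presenterLoci, names(g@loci))
  a <- unlist(g@loci[keep], use.names = FALSE)
  if (is.null(a)) a <- character(0)
  a[!duplicated(alleleKey(a))]
}

#' Parse a caret/plus genotype string
#'
#' Parses the compact genotype notation in which \code{"^"} separates
#' loci and \code{"+"} separates alleles within a locus, e.g.
#' \code{"SLA-1*07:02 + SLA-1*13:01^SLA-2*10:01 + SLA-2*02:02"}. Loci are
#' labelled by each allele's gene symbol; alleles are grouped by gene, so
#' a gene split across \code{"^"} groups still forms one locus.
#'
#' @param x the genotype string.
#' @param id,species identifier and species label for the genotype.
#' @param presenterLoci presenter loci (default: DRB1-like loci present).
#' @return a \code{\linkS4class{Genotype}}.
#' @export
parseGenotypeString <- function(x, id = "genotype", species = "unknown",
                                presenterLoci = NULL) {
  stopifnot(is.character(x), length(x) == 1L)
  norm <- gsub("[‐‑−–—]", "-", x)
  tokens <- unlist(strsplit(norm, "[\\^+]"))
  tokens <- trimws(tokens)
  tokens <- tokens[nzchar(tokens)]
  if (length(tokens) == 0L) stop("empty genotype string")
  parsed <- lapply(tokens, parseAlleleName)
  lociKeys <- vapply(parsed, function(p) p@gene, character(1L))
  names(tokens) <- NULL
  loci <- split(vapply(parsed, function(p) p@raw, character(1L)), lociKeys)
  # keep first-appearance locus order rather than alphabetical
  loci <- loci[unique(lociKeys)]
  genotype(id, species, loci, presenterLoci)
}
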