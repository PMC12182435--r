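#' Indirect T-cell epitope (T2) score of a donor-recipient pair
#'
#' Result of \code{\link{pircheT2}}. An epitope is a pair of a recipient
#' class-II presenter allele (two-field identity) and the specific 9mer
#' core peptide it presents; the score counts unique epitopes.
#'
#' @slot recipientId,donorId individual identifiers.
#' @slot epitopes \code{data.frame} with columns \code{presenter}
#'   (two-field allele) and \code{core} (9mer), one row per unique
#'   epitope.
#' @slot score integer, \code{nrow(epitopes)}.
#' @slot provenance \code{data.frame} mapping epitopes to the donor
#'   15mers (and their source alleles) they derive from; every listed
#'   peptide passed the self-filter and the presentation threshold.
#' @export
setClass("T2Result",
  representation(recipientId = "character", donorId = "character",
                 epitopes = "data.frame", score = "integer",
                 provenance = "data.frame"))

setValidity("T2Result", function(object) {
  if (object@score != nrow(object@epitopes))
    return("score must equal the number of unique epitopes")
  if (nrow(object@epitopes) &&
      anyDuplicated(paste(object@epitopes$presenter, object@epitopes$core)))
    return("epitopes must be unique")
  TRUE
})

#' @describeIn T2Result compact display
#' @param object a \code{T2Result}
#' @export
setMethod("show", "T2Result", function(object) {
  cat("T2Result: recipient", sQuote(object@recipientId), "vs donor",
      sQuote(object@donorId), "\n  score =", object@score,
      "unique (presenter, core) epitopes\n")
})

#' Shared T-cell epitope (STEP) score between sequential grafts
#'
#' Result of \code{\link{stepScore}}: the epitopes a recipient is
#' predicted to see from both of two grafts, a proxy for memory T-cell
#' risk on re-exposure.
#'
#' @slot recipientId,graft1Id,graft2Id identifiers.
#' @slot sharedEpitopes \code{data.frame} (presenter, core) of epitopes
#'   in both grafts' epitope sets.
#' @slot score integer, \code{nrow(sharedEpitopes)}.
#' @export
setClass("StepResult",
  representation(recipientId = "character", graft1Id = "character",
                 graft2Id = "character", sharedEpitopes = "data.frame",
                 score = "integer"))

#' @describeIn StepResult compact display
#' @param object a \code{StepResult}
#' @export
setMethod("show", "StepResult", function(object) {
  cat("StepResult: recipient", sQuote(object@recipientId), ", grafts",
      sQuote(object@graft1Id), "&", sQuote(object@graft2Id),
      "\n  score =", object@score, "shared epitopes\n")
})

#' Self peptidome of a recipient
#'
#' Union peptidome over every allele of the recipient at every locus
#' (class I and II); homozygous duplicates contribute once. Donor
#' peptides found in this set are regarded as self and removed before
#' epitope scoring.
#'
#' @param recipient a \code{\linkS4class{Genotype}}.
#' @param db an \code{\linkS4class{AlleleDb}} resolving every recipient
#'   allele.
#' @param k peptide length (default 15).
#' @return a \code{\linkS4class{Peptidome}}.
#' @export
selfPeptidome <- function(recipient, db, k = 15L) {
  stopifnot(is(recipient, "Genotype"))
  alleles <- genotypeAlleles(recipient, unique = TRUE)
  seqs <- dbSequences(db, alleles)
  buildPeptidome(seqs, k = k)
}

# unique donor peptides with source bookkeeping
.donorPeptidome <- function(donor, db, k) {
  alleles <- genotypeAlleles(donor, unique = TRUE)
  seqs <- dbSequences(db, alleles)
  buildPeptidome(seqs, k = k)
}

# presenters resolved to sequences; error if none
.resolvePresenters <- function(recipient, db) {
  pres <- presenterAlleles(recipient)
  if (length(pres) == 0L)
    stop("recipient ", sQuote(recipient@id),
         " has no presenter alleles (presenter loci: ",
         paste(recipient@presenterLoci, collapse = ", "), ")")
  seqs <- dbSequences(db, pres)
  list(alleles = pres, keys = alleleKey(pres), seqs = seqs)
}

# Epitope calls for a set of candidate (already self-filtered) peptides:
# one row per (peptide, presenter) with rank/core; `presented` applied.
.epitopeCalls <- function(presenters, peptideSet, predictor, threshold,
                          epitopeIdentity) {
  rows <- vector("list", length(presenters$alleles))
  for (i in seq_along(presenters$alleles)) {
    calls <- predictBinding(predictor, presenters$alleles[i],
                            presenters$seqs[[i]], peptideSet)
    keep <- isPresented(calls, threshold)
    calls <- calls[keep, , drop = FALSE]
    if (nrow(calls)) {
      calls$presenter <- presenters$keys[i]
      calls$epitope <- if (epitopeIdentity == "core") calls$core
                       else calls$peptide
    }
    rows[[i]] <- calls
  }
  out <- do.call(rbind, rows[vapply(rows, nrow, integer(1L)) > 0])
  if (is.null(out))
    out <- data.frame(peptide = character(0), rank_pct = numeric(0),
                      core = character(0), core_offset = integer(0),
                      presenter = character(0), epitope = character(0),
                      stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

# self set used by the filter, at peptide or core granularity
.selfSet <- function(recipient, db, k, selfFilter) {
  if (selfFilter == "peptide")
    peptides(selfPeptidome(recipient, db, k = k))
  else
    peptides(selfPeptidome(recipient, db, k = .CORE_LEN))
}

#' PIRCHE-T2 style epitope score
#'
#' Counts the unique donor-MHC-derived T-helper epitopes a recipient is
#' predicted to see from a graft: all donor 15mers (every donor locus,
#' class I and II) are pooled, peptides present in the recipient's own
#' MHC-derived peptidome are removed (self-filter), the remainder are
#' scored against each recipient class-II presenter allele, and calls at
#' or below the rank threshold contribute their (presenter two-field
#' allele, 9mer core) pair to the epitope set. The score is the size of
#' that set; an epitope reachable from several donor peptides counts
#' once.
#'
#' @param recipient,donor \code{\linkS4class{Genotype}} objects; the
#'   recipient must have at least one presenter allele.
#' @param db an \code{\linkS4class{AlleleDb}} resolving all alleles.
#' @param predictor a binding predictor (default
#'   \code{\link{mockPredictor}()}).
#' @param threshold presentation rank threshold in (0, 100], default 10.
#' @param k donor/self peptide length (default 15).
#' @param epitopeIdentity \code{"core"} (default; epitope = presenter +
#'   9mer core) or \code{"peptide"} (presenter + full 15mer), the latter
#'   for sensitivity analysis.
#' @param selfFilter \code{"peptide"} (default; donor 15mers found among
#'   recipient 15mers are removed) or \code{"core"} (calls whose 9mer
#'   core occurs among the recipient's 9mer windows are removed).
#' @return a \code{\linkS4class{T2Result}}.
#' @export
pircheT2 <- function(recipient, donor, db, predictor = mockPredictor(),
                     threshold = 10, k = 15L,
                     epitopeIdentity = c("core", "peptide"),
                     selfFilter = c("peptide", "core")) {
  epitopeIdentity <- match.arg(epitopeIdentity)
  selfFilter <- match.arg(selfFilter)
  stopifnot(is(recipient, "Genotype"), is(donor, "Genotype"))
  presenters <- .resolvePresenters(recipient, db)
  donorPome <- .donorPeptidome(donor, db, k)
  selfSet <- .selfSet(recipient, db, k, selfFilter)
  candidates <- if (selfFilter == "peptide")
    setdiff(peptides(donorPome), selfSet) else peptides(donorPome)
  calls <- .epitopeCalls(presenters, candidates, predictor, threshold,
                         epitopeIdentity)
  if (selfFilter == "core" && nrow(calls))
    calls <- calls[!(calls$core %in% selfSet), , drop = FALSE]
  .t2FromCalls(recipient@id, donor@id, calls, donorPome)
}

.t2FromCalls <- function(recipientId, donorId, calls, donorPome) {
  if (nrow(calls)) {
    key <- paste(calls$presenter, calls$epitope, sep = "|")
    epitopes <- unique(data.frame(presenter = calls$presenter,
                                  core = calls$epitope,
                                  stringsAsFactors = FALSE))
    rownames(epitopes) <- NULL
    provenance <- data.frame(
      presenter = calls$presenter, core = calls$epitope,
      peptide = calls$peptide, rank_pct = calls$rank_pct,
      alleles = vapply(donorPome@sources[calls$peptide], paste,
                       character(1L), collapse = ","),
      stringsAsFactors = FALSE)
    rownames(provenance) <- NULL
  } else {
    epitopes <- data.frame(presenter = character(0), core = character(0),
                           stringsAsFactors = FALSE)
    provenance <- data.frame(presenter = character(0), core = character(0),
                             peptide = character(0), rank_pct = numeric(0),
                             alleles = character(0), stringsAsFactors = FALSE)
  }
  new("T2Result", recipientId = recipientId, donorId = donorId,
      epitopes = epitopes, score = nrow(epitopes), provenance = provenance)
}

.epitopeKeys <- function(t2) {
  if (nrow(t2@epitopes) == 0L) return(character(0))
  paste(t2@epitopes$presenter, t2@epitopes$core, sep = "|")
}

#' STEP / Tmem shared-epitope score for sequential grafts
#'
#' Epitopes derived from one graft that are also derived from the other
#' graft, for the same recipient: the intersection of the two grafts'
#' \code{\link{pircheT2}} epitope sets. The count is symmetric in graft
#' order (swapping "first" and "second" graft leaves it unchanged).
#'
#' @param recipient,graft1,graft2 \code{\linkS4class{Genotype}} objects.
#' @inheritParams pircheT2
#' @return a \code{\linkS4class{StepResult}}.
#' @export
stepScore <- function(recipient, graft1, graft2, db,
                      predictor = mockPredictor(), threshold = 10,
                      k = 15L, epitopeIdentity = c("core", "peptide"),
                      selfFilter = c("peptide", "core")) {
  epitopeIdentity <- match.arg(epitopeIdentity)
  selfFilter <- match.arg(selfFilter)
  t1 <- pircheT2(recipient, graft1, db, predictor, threshold, k,
                 epitopeIdentity, selfFilter)
  t2 <- pircheT2(recipient, graft2, db, predictor, threshold, k,
                 epitopeIdentity, selfFilter)
  k1 <- .epitopeKeys(t1)
  k2 <- .epitopeKeys(t2)
  sharedKeys <- intersect(k2, k1)
  shared <- t2@epitopes[match(sharedKeys, k2), , drop = FALSE]
  rownames(shared) <- NULL
  new("StepResult", recipientId = recipient@id, graft1Id = graft1@id,
      graft2Id = graft2@id, sharedEpitopes = shared,
      score = nrow(shared))
}

#' Export T2/STEP epitopes as TSV
#'
#' One epitope per row. For a \code{T2Result} the provenance rows
#' (presenter, core, source peptide, source alleles, rank) are written;
#' for a \code{StepResult} the shared epitope pairs.
#'
#' @param x a \code{T2Result} or \code{StepResult}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeEpitopesTsv <- function(x, path) {
  df <- if (is(x, "T2Result")) x@provenance
        else if (is(x, "StepResult")) x@sharedEpitopes
        else stop("x must be a T2Result or StepResult")
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
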