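#' Weighted haplotype frequency table
#'
#' Population haplotypes over a fixed locus set with positive sampling
#' weights, the input for virtual genotype generation. Weights are
#' normalized to sum to one at construction.
#'
#' @slot haplotypes \code{data.frame}, one column per locus, one row per
#'   haplotype; entries are allele names.
#' @slot weights normalized positive sampling weights.
#' @slot species species label for sampled genotypes.
#' @export
setClass("HaplotypeTable",
  representation(haplotypes = "data.frame", weights = "numeric",
                 species = "character"))

setValidity("HaplotypeTable", function(object) {
  if (nrow(object@haplotypes) == 0L)
    return("haplotype table is empty")
  if (length(object@weights) != nrow(object@haplotypes))
    return("one weight per haplotype required")
  if (any(object@weights <= 0))
    return("all weights must be positive")
  if (abs(sum(object@weights) - 1) > 1e-8)
    return("weights must be normalized")
  TRUE
})

#' Construct a haplotype table
#'
#' @param haplotypes \code{data.frame} of allele names, one column per
#'   locus.
#' @param weights positive weights (normalized internally).
#' @param species species label (default \code{"human"}).
#' @return a \code{\linkS4class{HaplotypeTable}}.
#' @export
haplotypeTable <- function(haplotypes, weights, species = "human") {
  haplotypes <- as.data.frame(haplotypes, stringsAsFactors = FALSE)
  if (nrow(haplotypes) == 0L) stop("haplotype table is empty")
  w <- as.numeric(weights)
  if (length(w) != nrow(haplotypes))
    stop("need one weight per haplotype")
  if (any(!is.finite(w)) || any(w <= 0))
    stop("all haplotype weights must be positive")
  new("HaplotypeTable", haplotypes = haplotypes, weights = w / sum(w),
      species = species)
}

#' @describeIn HaplotypeTable summary display
#' @param object a \code{HaplotypeTable}
#' @export
setMethod("show", "HaplotypeTable", function(object) {
  cat("HaplotypeTable:", nrow(object@haplotypes), "haplotypes over loci",
      paste(names(object@haplotypes), collapse = ", "),
      "(", object@species, ")\n")
  cat("  weight range:", signif(min(object@weights), 3), "-",
      signif(max(object@weights), 3), "\n")
})

#' @describeIn HaplotypeTable number of haplotypes
#' @param x a \code{HaplotypeTable}
#' @export
setMethod("length", "HaplotypeTable", function(x) nrow(x@haplotypes))

#' Sample a virtual genotype from haplotype frequencies
#'
#' Draws two haplotypes independently, with replacement, with probability
#' proportional to weight, and unions them per locus (both alleles kept,
#' so a twice-drawn haplotype yields a fully homozygous genotype). The
#' draw is a pure function of \code{(seed, id)}: the RNG substream is
#' keyed by both, so genotypes of other individuals never shift when a
#' cohort grows.
#'
#' @param table a \code{\linkS4class{HaplotypeTable}}.
#' @param seed integer master seed.
#' @param id individual identifier (also keys the substream).
#' @param presenterLoci presenter loci for the genotype (default
#'   DRB1-like loci present in the table).
#' @return a \code{\linkS4class{Genotype}} with two alleles per locus.
#' @export
sampleGenotype <- function(table, seed, id, presenterLoci = NULL) {
  stopifnot(is(table, "HaplotypeTable"))
  rng <- .lcgNew(.lcgMix("genotype", seed, id))
  draws <- .lcgSampleProb(rng, 2L, table@weights)
  loci <- lapply(names(table@haplotypes), function(l)
    as.character(table@haplotypes[[l]][draws]))
  names(loci) <- names(table@haplotypes)
  genotype(id, table@species, loci, presenterLoci)
}

#' Pair enumeration schemes
#'
#' Closed-form pair counts and a streaming iterator over pairings used in
#' cohort and all-vs-all comparison designs. \code{"cross"} pairs every
#' element of \code{a} with every element of \code{b} (\code{|a| * |b|}
#' pairs); \code{"all_vs_all_self"} forms every ordered pair within
#' \code{a}, including self-pairs (\code{n^2} pairs).
#'
#' @param nA,nB list sizes (\code{nB} ignored for
#'   \code{"all_vs_all_self"}).
#' @param mode pairing scheme.
#' @return \code{pairCount}: the exact number of pairs (numeric, exact
#'   for sizes beyond integer range).
#' @examples
#' pairCount(4000, 1000, "cross")        # 4,000,000
#' pairCount(138, mode = "all_vs_all_self")  # 19,044
#' @export
pairCount <- function(nA, nB = NULL, mode = c("cross", "all_vs_all_self")) {
  mode <- match.arg(mode)
  nA <- as.double(nA)
  if (mode == "cross") {
    if (is.null(nB)) stop("cross pairing needs two list sizes")
    nA * as.double(nB)
  } else {
    nA * nA
  }
}

#' @rdname pairCount
#' @param a,b vectors (or lists) to pair; \code{b} only for
#'   \code{"cross"}.
#' @return \code{enumeratePairs}: a \code{\linkS4class{PairIterator}}.
#' @export
enumeratePairs <- function(a, b = NULL, mode = c("cross", "all_vs_all_self")) {
  mode <- match.arg(mode)
  if (length(a) == 0L) stop("empty first list")
  if (mode == "cross") {
    if (is.null(b) || length(b) == 0L) stop("cross pairing needs two non-empty lists")
  } else {
    b <- a
  }
  state <- new.env(parent = emptyenv())
  state$i <- 1L
  state$j <- 0L
  new("PairIterator", count = pairCount(length(a), length(b), mode),
      mode = mode, a = as.list(a), b = as.list(b), state = state)
}

#' Streaming pair iterator
#'
#' Iterates over a pairing scheme without materializing all pairs; see
#' \code{\link{enumeratePairs}}. Advance with \code{\link{nextPair}},
#' test with \code{\link{hasNext}}.
#'
#' @slot count exact number of pairs.
#' @slot mode pairing scheme.
#' @slot a,b the two lists.
#' @slot state iteration cursor.
#' @export
setClass("PairIterator",
  representation(count = "numeric", mode = "character",
                 a = "list", b = "list", state = "environment"))

#' @describeIn PairIterator compact display
#' @param object a \code{PairIterator}
#' @export
setMethod("show", "PairIterator", function(object) {
  cat("PairIterator (", object@mode, "): ", format(object@count, big.mark = ","),
      " pairs over ", length(object@a), " x ", length(object@b),
      " elements\n", sep = "")
})

#' @rdname PairIterator
#' @param it a \code{PairIterator}.
#' @return \code{hasNext}: logical; \code{nextPair}: list of the two
#'   elements (\code{first}, \code{second}).
#' @export
hasNext <- function(it) {
  stopifnot(is(it, "PairIterator"))
  it@state$i < length(it@a) || it@state$j < length(it@b)
}

#' @rdname PairIterator
#' @export
nextPair <- function(it) {
  stopifnot(is(it, "PairIterator"))
  if (!hasNext(it)) stop("iterator exhausted")
  if (it@state$j < length(it@b)) {
    it@state$j <- it@state$j + 1L
  } else {
    it@state$i <- it@state$i + 1L
    it@state$j <- 1L
  }
  list(first = it@a[[it@state$i]], second = it@b[[it@state$j]])
}

#' Virtual cohort T2 score summary
#'
#' Result of \code{\link{simulateCohort}}: the full patient x donor score
#' table (human donors plus the reference xenodonor), per-patient medians
#' over the human donor pool, and the optimum (best/worst median)
#' patients with ties retained.
#'
#' @slot scores \code{data.frame}: \code{patient_id}, \code{donor_id},
#'   \code{donor_source} (\code{"human"}/\code{"xeno"}), \code{t2}.
#' @slot patientMedians \code{data.frame}: \code{patient_id},
#'   \code{median_human_t2} (median over all human donors),
#'   \code{xeno_t2}, \code{max_human_t2}.
#' @slot bestPatients,worstPatients patient ids attaining the lowest /
#'   highest median (all ties).
#' @slot nPatients,nDonors cohort dimensions.
#' @slot seed master seed.
#' @slot threshold presentation threshold used.
#' @export
setClass("CohortSummary",
  representation(scores = "data.frame", patientMedians = "data.frame",
                 bestPatients = "character", worstPatients = "character",
                 nPatients = "integer", nDonors = "integer",
                 seed = "numeric", threshold = "numeric"))

#' @describeIn CohortSummary summary display
#' @param object a \code{CohortSummary}
#' @export
setMethod("show", "CohortSummary", function(object) {
  cat("CohortSummary:", object@nPatients, "patients x", object@nDonors,
      "human donors + 1 xenodonor (seed", object@seed, ")\n")
  hm <- object@patientMedians$median_human_t2
  cat("  median human-donor T2 per patient:", min(hm), "-", max(hm), "\n")
  cat("  xenodonor T2 per patient:",
      min(object@patientMedians$xeno_t2), "-",
      max(object@patientMedians$xeno_t2), "\n")
  cat("  best patient(s):", paste(object@bestPatients, collapse = ", "),
      " worst:", paste(object@worstPatients, collapse = ", "), "\n")
})

#' Cohort score table
#' @param x a \code{CohortSummary}.
#' @return the \code{scores} \code{data.frame}.
#' @export
cohortScores <- function(x) {
  stopifnot(is(x, "CohortSummary"))
  x@scores
}

#' Per-patient cohort medians
#' @param x a \code{CohortSummary}.
#' @return the \code{patientMedians} \code{data.frame}.
#' @export
patientMedians <- function(x) {
  stopifnot(is(x, "CohortSummary"))
  x@patientMedians
}

# ---- internal fast epitope-set machinery ---------------------------------

# per-allele peptide cache (keyed by 2-field allele key)
.allelePeptides <- function(db, allele, k, cache) {
  key <- paste0(alleleKey(allele), "#", k)
  hit <- cache[[key]]
  if (!is.null(hit)) return(hit)
  peps <- enumerateKmers(dbSequences(db, allele)[[1L]], k)
  cache[[key]] <- peps
  peps
}

.genotypePeptides <- function(g, db, k, cache) {
  alleles <- genotypeAlleles(g, unique = TRUE)
  unique(unlist(lapply(alleles, .allelePeptides, db = db, k = k,
                       cache = cache), use.names = FALSE))
}

# Epitope key sets ("presenterKey|core") of one recipient against a list
# of donor peptide vectors, sharing one predictBinding pass over the
# union of surviving peptides. Matches pircheT2 with the default
# core-identity / peptide-level self-filter exactly.
.epitopeSetsForRecipient <- function(recipient, donorPeps, db, predictor,
                                     threshold, k, cache) {
  presenters <- .resolvePresenters(recipient, db)
  self <- .genotypePeptides(recipient, db, k, cache)
  unionPeps <- unique(unlist(donorPeps, use.names = FALSE))
  candidates <- setdiff(unionPeps, self)
  calls <- .epitopeCalls(presenters, candidates, predictor, threshold,
                         "core")
  keysByPep <- split(paste(calls$presenter, calls$epitope, sep = "|"),
                     calls$peptide)
  lapply(donorPeps, function(peps) {
    surv <- intersect(setdiff(peps, self), names(keysByPep))
    unique(unlist(keysByPep[surv], use.names = FALSE))
  })
}

# ---- cohort simulation ----------------------------------------------------

#' Simulate a virtual transplant cohort
#'
#' Generates \code{nPatients} virtual patients and \code{nDonors} virtual
#' human donors from the haplotype table (independent seeded substreams
#' per individual), computes the PIRCHE-T2 score of every patient x
#' human-donor pair and of every patient against the reference
#' xenodonor, and summarizes per-patient score distributions. The result
#' is a pure function of the inputs and seed.
#'
#' @param table a \code{\linkS4class{HaplotypeTable}} for both patients
#'   and donors.
#' @param xenodonor the reference xenodonor
#'   \code{\linkS4class{Genotype}}.
#' @param db an \code{\linkS4class{AlleleDb}} resolving all alleles.
#' @param nPatients,nDonors cohort dimensions (both >= 1).
#' @param predictor binding predictor (default \code{mockPredictor()}).
#' @param threshold presentation rank threshold, default 10.
#' @param seed integer master seed.
#' @param k peptide length (default 15).
#' @return a \code{\linkS4class{CohortSummary}}.
#' @export
simulateCohort <- function(table, xenodonor, db, nPatients, nDonors,
                           predictor = mockPredictor(), threshold = 10,
                           seed = 1L, k = 15L) {
  stopifnot(is(table, "HaplotypeTable"), is(xenodonor, "Genotype"),
            nPatients >= 1L, nDonors >= 1L)
  patients <- lapply(seq_len(nPatients), function(i)
    sampleGenotype(table, seed, sprintf("P%04d", i)))
  donors <- lapply(seq_len(nDonors), function(i)
    sampleGenotype(table, seed, sprintf("D%04d", i)))
  cache <- new.env(parent = emptyenv())
  donorPeps <- lapply(donors, .genotypePeptides, db = db, k = k,
                      cache = cache)
  names(donorPeps) <- vapply(donors, function(d) d@id, character(1L))
  donorPeps$XENO <- .genotypePeptides(xenodonor, db, k, cache)

  rows <- vector("list", nPatients)
  med <- vector("list", nPatients)
  for (i in seq_len(nPatients)) {
    sets <- .epitopeSetsForRecipient(patients[[i]], donorPeps, db,
                                     predictor, threshold, k, cache)
    t2 <- vapply(sets, length, integer(1L))
    human <- t2[names(t2) != "XENO"]
    rows[[i]] <- data.frame(
      patient_id = patients[[i]]@id,
      donor_id = c(names(human), xenodonor@id),
      donor_source = c(rep("human", length(human)), "xeno"),
      t2 = as.integer(c(human, t2[["XENO"]])),
      stringsAsFactors = FALSE)
    med[[i]] <- data.frame(
      patient_id = patients[[i]]@id,
      median_human_t2 = stats::median(as.numeric(human)),
      xeno_t2 = as.integer(t2[["XENO"]]),
      max_human_t2 = as.integer(max(human)),
      stringsAsFactors = FALSE)
  }
  scores <- do.call(rbind, rows)
  medians <- do.call(rbind, med)
  rownames(scores) <- rownames(medians) <- NULL
  best <- medians$patient_id[medians$median_human_t2 ==
                               min(medians$median_human_t2)]
  worst <- medians$patient_id[medians$median_human_t2 ==
                                max(medians$median_human_t2)]
  new("CohortSummary", scores = scores, patientMedians = medians,
      bestPatients = best, worstPatients = worst,
      nPatients = as.integer(nPatients), nDonors = as.integer(nDonors),
      seed = as.numeric(seed), threshold = as.numeric(threshold))
}

#' Repeat-transplant (Tmem/STEP) analysis over a virtual cohort
#'
#' For each virtual patient, draws a human donor (and a second,
#' independent human donor) from the simulated donor pool and computes
#' shared-epitope STEP scores for the three repeat-transplant
#' directions: swine-after-human (\code{SAH}: first graft human, second
#' the xenodonor), human-after-swine (\code{HAS}: order reversed) and
#' human-after-human (\code{HAH}: the two independently drawn human
#' donors). SAH and HAS are computed independently in both orders; the
#' shared-epitope count is order-symmetric, so the two vectors are
#' expected to be identical element-wise. Patients and donors reuse the
#' same seeded substreams as \code{\link{simulateCohort}}, so the two
#' analyses describe the same virtual cohort.
#'
#' @inheritParams simulateCohort
#' @param directions subset of \code{c("SAH", "HAS", "HAH")}.
#' @return a list with \code{steps} (\code{data.frame}:
#'   \code{patient_id}, \code{direction}, \code{step}, plus the donor ids
#'   used) and \code{summary} (\code{data.frame}: per direction the
#'   median STEP and the fraction of patients with zero shared
#'   epitopes).
#' @export
repeatTransplantAnalysis <- function(table, xenodonor, db, nPatients,
                                     nDonors,
                                     predictor = mockPredictor(),
                                     threshold = 10, seed = 1L, k = 15L,
                                     directions = c("SAH", "HAS", "HAH")) {
  directions <- match.arg(directions, several.ok = TRUE)
  stopifnot(is(table, "HaplotypeTable"), is(xenodonor, "Genotype"))
  patients <- lapply(seq_len(nPatients), function(i)
    sampleGenotype(table, seed, sprintf("P%04d", i)))
  donors <- lapply(seq_len(nDonors), function(i)
    sampleGenotype(table, seed, sprintf("D%04d", i)))
  cache <- new.env(parent = emptyenv())
  xenoPeps <- .genotypePeptides(xenodonor, db, k, cache)

  rows <- vector("list", nPatients)
  for (i in seq_len(nPatients)) {
    rngPair <- .lcgNew(.lcgMix("tmem", seed, i))
    d1 <- .lcgInt(rngPair, 1L, nDonors)
    d2 <- .lcgInt(rngPair, 1L, nDonors)
    donorPeps <- list(
      h1 = .genotypePeptides(donors[[d1]], db, k, cache),
      h2 = .genotypePeptides(donors[[d2]], db, k, cache),
      xeno = xenoPeps)
    sets <- .epitopeSetsForRecipient(patients[[i]], donorPeps, db,
                                     predictor, threshold, k, cache)
    step <- c(
      SAH = length(intersect(sets$xeno, sets$h1)),  # second graft: swine
      HAS = length(intersect(sets$h1, sets$xeno)),  # second graft: human
      HAH = length(intersect(sets$h2, sets$h1)))
    rows[[i]] <- data.frame(
      patient_id = patients[[i]]@id,
      direction = directions,
      step = as.integer(step[directions]),
      first_graft = c(SAH = donors[[d1]]@id, HAS = xenodonor@id,
                      HAH = donors[[d1]]@id)[directions],
      second_graft = c(SAH = xenodonor@id, HAS = donors[[d1]]@id,
                       HAH = donors[[d2]]@id)[directions],
      stringsAsFactors = FALSE)
  }
  steps <- do.call(rbind, rows)
  rownames(steps) <- NULL
  summary <- do.call(rbind, lapply(directions, function(dir) {
    s <- steps$step[steps$direction == dir]
    data.frame(direction = dir, median_step = stats::median(as.numeric(s)),
               zero_fraction = mean(s == 0), stringsAsFactors = FALSE)
  }))
  list(steps = steps, summary = summary)
}
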