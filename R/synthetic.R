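#' Specification of a synthetic two-species MHC world
#'
#' Parameters for \code{\link{generateWorld}}. The two species draw their
#' residues from disjoint 10-letter vocabularies, so every position of a
#' cross-species sequence pair differs by construction and the baseline
#' cross-species peptidome sharing is provably zero; the only shared
#' peptides are the \code{nSharedKmers} k-mers injected verbatim into one
#' carrier allele per species. Within a species, each allele is its locus
#' base sequence with exactly \code{withinDivergence} substituted
#' positions, so within-species distances are small and known while
#' cross-species distances equal the sequence length.
#'
#' @slot seed integer seed; the whole world is a pure function of the
#'   spec including this seed.
#' @slot nAllelesHuman,nAllelesSwine alleles per locus per species.
#' @slot lociHuman,lociSwine locus names per species. The swine default
#'   covers class I and II (7 loci) so the generated xenodonor can mirror
#'   the reference SLA genotype structure, including its three SLA-1
#'   alleles.
#' @slot sequenceLength protein length (no indels are simulated).
#' @slot withinDivergence substituted positions per allele relative to
#'   its locus base (within-locus pairwise divergence is up to twice
#'   this).
#' @slot locusDivergence substituted positions of each locus base
#'   relative to the single species base, mimicking paralog divergence:
#'   within a species, loci are much closer to each other than either is
#'   to the other species.
#' @slot betweenDivergence expected differing positions between
#'   cross-species pairs; realized structurally as the full sequence
#'   length by the disjoint vocabularies (validated: greater than
#'   \code{withinDivergence}, at most \code{sequenceLength}).
#' @slot nSharedKmers number of distinct shared k-mers injected into both
#'   species (ground truth for overlap recovery).
#' @slot k shared k-mer length (default 15).
#' @slot vocabHuman,vocabSwine disjoint residue vocabularies.
#' @slot nHaplotypes number of haplotypes in the generated human
#'   frequency table.
#' @export
setClass("WorldSpec",
  representation(seed = "numeric",
                 nAllelesHuman = "integer", nAllelesSwine = "integer",
                 lociHuman = "character", lociSwine = "character",
                 sequenceLength = "integer",
                 withinDivergence = "integer",
                 locusDivergence = "integer",
                 betweenDivergence = "integer",
                 nSharedKmers = "integer", k = "integer",
                 vocabHuman = "character", vocabSwine = "character",
                 nHaplotypes = "integer"))

setValidity("WorldSpec", function(object) {
  L <- object@sequenceLength
  if (L < object@k)
    return("sequence length must be at least k")
  if (object@withinDivergence < 0L || object@withinDivergence > L)
    return("withinDivergence must lie in [0, sequenceLength]")
  if (object@locusDivergence < 0L || object@locusDivergence > L)
    return("locusDivergence must lie in [0, sequenceLength]")
  if (object@betweenDivergence <= object@withinDivergence)
    return("betweenDivergence must exceed withinDivergence")
  if (object@betweenDivergence > L)
    return("betweenDivergence cannot exceed the sequence length")
  if (length(intersect(object@vocabHuman, object@vocabSwine)))
    return("species vocabularies must be disjoint")
  if (any(!c(object@vocabHuman, object@vocabSwine) %in% AA20))
    return("vocabularies must use the 20 amino-acid letters")
  if (length(object@vocabHuman) < 2L || length(object@vocabSwine) < 2L)
    return("each vocabulary needs at least two letters")
  if (object@nSharedKmers < 0L)
    return("nSharedKmers must be non-negative")
  # capacity: non-overlapping injection slots, >=1 native residue between
  slotsPerAllele <- (L - object@k) %/% (object@k + 1L) + 1L
  capH <- length(object@lociHuman) * object@nAllelesHuman * slotsPerAllele
  capS <- length(object@lociSwine) * object@nAllelesSwine * slotsPerAllele
  if (object@nSharedKmers > min(capH, capS))
    return(paste0("nSharedKmers = ", object@nSharedKmers,
                  " exceeds injection capacity (", min(capH, capS), ")"))
  TRUE
})

#' Create a synthetic world specification
#'
#' Defaults describe the study conditions used throughout the package's
#' tests: two divergent allele universes (4 human class I/II loci, 7
#' swine loci), 180-residue proteins, 5 substitutions per allele
#' relative to its locus base and 15 per locus base relative to the
#' species base (so allelic divergence is small compared to paralog
#' divergence, mirroring the observed hierarchy of within-locus,
#' cross-locus and cross-species mean Hamming distances), disjoint
#' half-alphabet vocabularies and an 8-haplotype weighted frequency
#' table.
#'
#' @param seed integer seed.
#' @param nAllelesHuman,nAllelesSwine alleles per locus (defaults 4, 3).
#' @param lociHuman,lociSwine locus names.
#' @param sequenceLength protein length (default 180).
#' @param withinDivergence substitutions per allele (default 5).
#' @param locusDivergence substitutions per locus base relative to the
#'   species base (default 15).
#' @param betweenDivergence expected cross-species differing positions
#'   (default: the sequence length, which the disjoint vocabularies
#'   realize exactly).
#' @param nSharedKmers injected shared k-mers (default 0).
#' @param k shared k-mer length (default 15).
#' @param vocabHuman,vocabSwine disjoint residue sets (defaults: first vs
#'   last 10 letters of the fixed amino-acid order).
#' @param nHaplotypes haplotypes in the generated table (default 8).
#' @return a \code{\linkS4class{WorldSpec}}.
#' @export
worldSpec <- function(seed = 1L, nAllelesHuman = 4L, nAllelesSwine = 3L,
                      lociHuman = c("A", "B", "C", "DRB1"),
                      lociSwine = c("1", "2", "3", "DRB1", "DQB1",
                                    "DQA", "DRA"),
                      sequenceLength = 180L, withinDivergence = 5L,
                      locusDivergence = 15L,
                      betweenDivergence = sequenceLength,
                      nSharedKmers = 0L, k = 15L,
                      vocabHuman = AA20[1:10], vocabSwine = AA20[11:20],
                      nHaplotypes = 8L) {
  new("WorldSpec", seed = as.numeric(seed),
      nAllelesHuman = as.integer(nAllelesHuman),
      nAllelesSwine = as.integer(nAllelesSwine),
      lociHuman = lociHuman, lociSwine = lociSwine,
      sequenceLength = as.integer(sequenceLength),
      withinDivergence = as.integer(withinDivergence),
      locusDivergence = as.integer(locusDivergence),
      betweenDivergence = as.integer(betweenDivergence),
      nSharedKmers = as.integer(nSharedKmers), k = as.integer(k),
      vocabHuman = vocabHuman, vocabSwine = vocabSwine,
      nHaplotypes = as.integer(nHaplotypes))
}

#' @describeIn WorldSpec summary display
#' @param object a \code{WorldSpec}
#' @export
setMethod("show", "WorldSpec", function(object) {
  cat("WorldSpec (seed ", object@seed, "): L = ", object@sequenceLength,
      ", within-divergence ", object@withinDivergence,
      ", shared k-mers ", object@nSharedKmers, "\n", sep = "")
  cat("  human loci:", paste(object@lociHuman, collapse = ", "),
      "x", object@nAllelesHuman, "alleles\n")
  cat("  swine loci:", paste(object@lociSwine, collapse = ", "),
      "x", object@nAllelesSwine, "alleles\n")
})

# exactly n positions substituted to a *different* letter of vocab
.substitutePositions <- function(seq, positions, rng, vocab) {
  ch <- strsplit(seq, "", fixed = TRUE)[[1L]]
  for (p in positions) {
    repl <- vocab[.lcgInt(rng, 1L, length(vocab))]
    while (repl == ch[p]) repl <- vocab[.lcgInt(rng, 1L, length(vocab))]
    ch[p] <- repl
  }
  paste(ch, collapse = "")
}

#' Substitute a fixed number of allele positions
#'
#' Changes exactly \code{nSubstitutions} distinct positions of the
#' sequence to a different residue drawn from the vocabulary
#' (substitution-only: Hamming ground truth stays exact, no indels).
#' Deterministic given the seed.
#'
#' @param seq protein string.
#' @param nSubstitutions number of positions to change (at most the
#'   sequence length).
#' @param seed integer seed.
#' @param vocab residue vocabulary to draw replacements from.
#' @return the perturbed sequence.
#' @export
perturbAllele <- function(seq, nSubstitutions, seed, vocab = AA20) {
  stopifnot(is.character(seq), length(seq) == 1L)
  n <- as.integer(nSubstitutions)
  L <- nchar(seq)
  if (n > L) stop("cannot substitute ", n, " positions in a length-", L,
                  " sequence")
  if (length(vocab) < 2L) stop("vocabulary needs at least two letters")
  if (n == 0L) return(seq)
  rng <- .lcgNew(.lcgMix("perturb", seed))
  positions <- .lcgSampleNoReplace(rng, n, L)
  .substitutePositions(seq, positions, rng, vocab)
}

.randomSeq <- function(rng, L, vocab) {
  paste(vocab[.lcgInt(rng, L, length(vocab))], collapse = "")
}

# allele naming: "<PREFIX>-<LOCUS>*<NN>:01"
.alleleNameFor <- function(prefix, locus, i) {
  sprintf("%s-%s*%02d:01", prefix, locus, i)
}

# One species' universe: a single species base sequence; each locus base
# is the species base with `locusDiv` substitutions (paralog
# divergence); each allele is its locus base with `within` substitutions
# (allelic polymorphism). Within-species distances therefore stay small
# relative to cross-species ones, which the disjoint vocabularies pin at
# the full sequence length.
.generateUniverse <- function(rng, prefix, loci, nAlleles, L, within,
                              locusDiv, vocab) {
  speciesBase <- .randomSeq(rng, L, vocab)
  seqs <- character(0)
  for (locus in loci) {
    base <- if (locusDiv > 0L)
      .substitutePositions(speciesBase,
                           .lcgSampleNoReplace(rng, locusDiv, L), rng, vocab)
    else speciesBase
    for (i in seq_len(nAlleles)) {
      s <- if (within > 0L)
        .substitutePositions(base, .lcgSampleNoReplace(rng, within, L),
                             rng, vocab)
      else base
      seqs[[.alleleNameFor(prefix, locus, i)]] <- s
    }
  }
  seqs
}

#' Generate a synthetic two-species MHC world
#'
#' Builds, deterministically from the spec: a human-like and a
#' swine-like allele universe (disjoint residue vocabularies; per-locus
#' base sequences with per-allele substitutions), \code{nSharedKmers}
#' distinct k-mers injected verbatim into carrier alleles of both
#' species at non-overlapping offsets (with a native residue between
#' adjacent injections, so the cross-species peptidome intersection
#' equals the injected set exactly), a weighted human haplotype table, a
#' reference xenodonor genotype (three alleles at the first swine locus,
#' two elsewhere, mirroring the reference SLA genotype structure) and a
#' ground-truth record backing every recovery test.
#'
#' @param spec a \code{\linkS4class{WorldSpec}}.
#' @return a list of class \code{"XenoWorld"}:
#'   \describe{
#'     \item{humanDb, swineDb, db}{\code{\linkS4class{AlleleDb}} per
#'       species and combined.}
#'     \item{haplotypes}{\code{\linkS4class{HaplotypeTable}} (human).}
#'     \item{xenodonor}{\code{\linkS4class{Genotype}}.}
#'     \item{truth}{ground truth: injected k-mers with carrier alleles
#'       and offsets, realized within/between-species mean Hamming
#'       distances, haplotype weights.}
#'     \item{spec}{the input spec.}
#'   }
#' @examples
#' world <- generateWorld(worldSpec(seed = 7, nSharedKmers = 2))
#' overlapStats(buildPeptidome(world$humanDb), buildPeptidome(world$swineDb))
#' @export
generateWorld <- function(spec) {
  stopifnot(is(spec, "WorldSpec"))
  validObject(spec)
  rng <- .lcgNew(.lcgMix("world", spec@seed))
  L <- spec@sequenceLength
  k <- spec@k

  humanSeqs <- .generateUniverse(rng, "HLA", spec@lociHuman,
                                 spec@nAllelesHuman, L,
                                 spec@withinDivergence,
                                 spec@locusDivergence, spec@vocabHuman)
  swineSeqs <- .generateUniverse(rng, "SLA", spec@lociSwine,
                                 spec@nAllelesSwine, L,
                                 spec@withinDivergence,
                                 spec@locusDivergence, spec@vocabSwine)

  # --- inject shared k-mers -----------------------------------------------
  # Injected k-mers use human-vocabulary letters only. Every all-human-
  # letter window of a swine allele must then lie inside one injected
  # segment (native swine residues separate adjacent segments), so the
  # cross-species shared peptide set is exactly the injected k-mers.
  G <- spec@nSharedKmers
  injections <- data.frame(kmer = character(0),
                           human_allele = character(0),
                           human_start = integer(0),
                           swine_allele = character(0),
                           swine_start = integer(0),
                           stringsAsFactors = FALSE)
  if (G > 0L) {
    kmers <- character(0)
    while (length(kmers) < G) {
      cand <- .randomSeq(rng, k, spec@vocabHuman)
      if (!cand %in% kmers) kmers <- c(kmers, cand)
    }
    # round-robin over alleles so injected content is spread thinly:
    # the j-th k-mer goes into allele ((j-1) mod nAlleles) at the next
    # free slot; slots are k+1 apart, leaving a native residue between
    # adjacent injections
    inject <- function(seqs, j, kmer) {
      nA <- length(seqs)
      allele <- (j - 1L) %% nA + 1L
      slot <- (j - 1L) %/% nA
      start <- slot * (k + 1L) + 1L
      nm <- names(seqs)[allele]
      s <- seqs[[nm]]
      substr(s, start, start + k - 1L) <- kmer
      seqs[[nm]] <- s
      list(seqs = seqs, allele = nm, start = start)
    }
    for (j in seq_len(G)) {
      hi <- inject(humanSeqs, j, kmers[j]); humanSeqs <- hi$seqs
      si <- inject(swineSeqs, j, kmers[j]); swineSeqs <- si$seqs
      injections[j, ] <- list(kmers[j], hi$allele, hi$start,
                              si$allele, si$start)
    }
  }

  humanDb <- alleleDb(humanSeqs)
  swineDb <- alleleDb(swineSeqs)

  # --- haplotype table ----------------------------------------------------
  # weights decay geometrically with jitter, mimicking the skew of
  # population haplotype frequency tables
  hap <- as.data.frame(lapply(spec@lociHuman, function(locus) {
    idx <- .lcgInt(rng, spec@nHaplotypes, spec@nAllelesHuman)
    vapply(idx, function(i) .alleleNameFor("HLA", locus, i), character(1L))
  }), stringsAsFactors = FALSE)
  names(hap) <- spec@lociHuman
  w <- exp(-0.15 * (seq_len(spec@nHaplotypes) - 1L)) *
    (0.5 + .lcgUnif(rng, spec@nHaplotypes))
  haplotypes <- haplotypeTable(hap, w, species = "human")

  # --- xenodonor: 3 alleles at the first swine locus, 2 elsewhere ---------
  xloci <- lapply(seq_along(spec@lociSwine), function(li) {
    nTake <- min(if (li == 1L) 3L else 2L, spec@nAllelesSwine)
    vapply(seq_len(nTake), function(i)
      .alleleNameFor("SLA", spec@lociSwine[li], i), character(1L))
  })
  names(xloci) <- spec@lociSwine
  xenodonor <- genotype("XENO-REF", "swine", xloci,
                        presenterLoci = intersect("DRB1", spec@lociSwine))

  locusOf <- function(seqs) sub("\\*.*$", "", names(seqs))
  truth <- list(
    injections = injections,
    withinLocusMeanHamming = list(
      human = .meanPositionalHamming(humanSeqs, locusOf(humanSeqs)),
      swine = .meanPositionalHamming(swineSeqs, locusOf(swineSeqs))),
    withinSpeciesMeanHamming = list(
      human = .meanPositionalHamming(humanSeqs),
      swine = .meanPositionalHamming(swineSeqs)),
    betweenMeanHamming = .meanCrossHamming(humanSeqs, swineSeqs),
    haplotypeWeights = haplotypes@weights)

  structure(list(humanDb = humanDb, swineDb = swineDb,
                 db = c(humanDb, swineDb), haplotypes = haplotypes,
                 xenodonor = xenodonor, truth = truth, spec = spec),
            class = "XenoWorld")
}

#' @export
print.XenoWorld <- function(x, ...) {
  cat("XenoWorld (seed ", x$spec@seed, "): ",
      length(x$humanDb), " human + ", length(x$swineDb),
      " swine alleles, ", nrow(x$truth$injections),
      " injected shared ", x$spec@k, "mers\n", sep = "")
  cat("  realized mean Hamming: within-species human ",
      round(x$truth$withinSpeciesMeanHamming$human, 1), ", swine ",
      round(x$truth$withinSpeciesMeanHamming$swine, 1), ", between ",
      round(x$truth$betweenMeanHamming, 1), "\n", sep = "")
  invisible(x)
}

# positional Hamming over equal-length unaligned sequences
.pairHamming <- function(a, b) {
  sum(strsplit(a, "", fixed = TRUE)[[1L]] !=
        strsplit(b, "", fixed = TRUE)[[1L]])
}

# mean over all unordered pairs; with `group` given, only same-group pairs
.meanPositionalHamming <- function(seqs, group = NULL) {
  n <- length(seqs)
  if (n < 2L) return(NA_real_)
  tot <- 0; m <- 0L
  for (i in seq_len(n - 1L)) for (j in seq(i + 1L, n)) {
    if (!is.null(group) && group[i] != group[j]) next
    tot <- tot + .pairHamming(seqs[[i]], seqs[[j]]); m <- m + 1L
  }
  if (m == 0L) NA_real_ else tot / m
}

.meanCrossHamming <- function(a, b) {
  tot <- 0; m <- 0L
  for (i in seq_along(a)) for (j in seq_along(b)) {
    tot <- tot + .pairHamming(a[[i]], b[[j]]); m <- m + 1L
  }
  tot / m
}

#' Write a synthetic world to disk
#'
#' Emits \code{human.fasta}, \code{swine.fasta}, \code{haplotypes.tsv},
#' \code{xenodonor.json} and \code{truth.json} into a directory.
#'
#' @param world a \code{"XenoWorld"} from \code{\link{generateWorld}}.
#' @param dir output directory (created if absent).
#' @return the directory path, invisibly.
#' @export
writeWorld <- function(world, dir) {
  stopifnot(inherits(world, "XenoWorld"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  writeAlleleFasta(world$humanDb, file.path(dir, "human.fasta"))
  writeAlleleFasta(world$swineDb, file.path(dir, "swine.fasta"))
  writeHaplotypeTable(world$haplotypes, file.path(dir, "haplotypes.tsv"))
  writeGenotype(world$xenodonor, file.path(dir, "xenodonor.json"))
  jsonlite::write_json(world$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}
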