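#' Deterministic mock class-II binding predictor
#'
#' The epitope pipeline treats peptide-MHC class-II binding prediction as
#' a pluggable contract: any object with a \code{\link{predictBinding}}
#' method that maps (presenter allele, presenter sequence, 15mer peptide)
#' to a percentile binding rank and a 9mer core can drive the scorer.
#' \code{MockPredictor} is the bundled implementation, a pure function of
#' its inputs: every (presenter sequence, 9mer window) pair maps through
#' a deterministic hash to a score in (0, 1); each 15mer is scored by
#' its best 9mer window; and the reported rank is the percentile of that
#' score against a fixed background set of 15mers drawn once from a
#' vertebrate residue-frequency model with a constant internal seed.
#' Scores are presenter-specific (different presenters present different
#' cores) but exchangeable across peptide pools: the fraction of any
#' peptide set called presented is composition-independent, mirroring
#' the absence of systematic species-level binding-rate bias when real
#' HLA- and SLA-derived peptides, which share one amino-acid alphabet,
#' are ranked by a trained predictor. Identical inputs always give
#' identical calls, on any platform, regardless of R's RNG state. The
#' mock carries no trained binding knowledge; it exists so the pipeline
#' is fully testable without an external model.
#'
#' @slot backgroundSize number of background peptides (default 10000).
#' @slot background the background 15mers.
#' @slot cache per-presenter memo of weight matrices and sorted
#'   background score distributions.
#' @export
setClass("MockPredictor",
  representation(backgroundSize = "integer", background = "character",
                 cache = "environment"))

# residue frequencies of a typical vertebrate proteome (approximate
# database-wide amino-acid composition), order = AA20
.AA_FREQ <- c(A = 0.074, C = 0.025, D = 0.054, E = 0.068, F = 0.047,
              G = 0.074, H = 0.026, I = 0.068, K = 0.058, L = 0.099,
              M = 0.025, N = 0.045, P = 0.039, Q = 0.034, R = 0.052,
              S = 0.057, T = 0.051, V = 0.073, W = 0.013, Y = 0.032)

.BG_SEED <- 70291       # constant: background set is part of the predictor
.PEPTIDE_LEN <- 15L
.CORE_LEN <- 9L

.makeBackground <- function(n) {
  rng <- .lcgNew(.BG_SEED)
  cw <- cumsum(.AA_FREQ) / sum(.AA_FREQ)
  idx <- findInterval(.lcgUnif(rng, n * .PEPTIDE_LEN), cw,
                      left.open = TRUE) + 1L
  m <- matrix(AA20[idx], nrow = n, ncol = .PEPTIDE_LEN)
  apply(m, 1L, paste, collapse = "")
}

#' Create the bundled mock binding predictor
#'
#' @param backgroundSize size of the fixed background peptide set used
#'   for percentile ranks (default 10000).
#' @return a \code{\linkS4class{MockPredictor}}.
#' @examples
#' pred <- mockPredictor()
#' predictBinding(pred, "HLA-DRB1*04:01", strrep("ACDEFGHIKL", 9),
#'                "ACDEFGHIKLMNPQR")
#' @export
mockPredictor <- function(backgroundSize = 10000L) {
  backgroundSize <- as.integer(backgroundSize)
  stopifnot(backgroundSize >= 10L)
  new("MockPredictor", backgroundSize = backgroundSize,
      background = .makeBackground(backgroundSize),
      cache = new.env(parent = emptyenv()))
}

#' @describeIn MockPredictor summary display
#' @param object a \code{MockPredictor}
#' @export
setMethod("show", "MockPredictor", function(object) {
  cat("MockPredictor: deterministic position-weight scorer,",
      object@backgroundSize, "background 15mers\n")
})

# Vectorized deterministic score in (0, 1) per (presenter, 9mer window):
# a polynomial rolling hash of the window's residues seeded by the
# presenter hash, scrambled through two LCG steps. Pure and
# platform-independent (all arithmetic exact in doubles below 2^53).
.windowScores <- function(presenterHash, peptides, offset) {
  h <- rep(presenterHash %% .LCG_M, length(peptides))
  for (pos in seq_len(.CORE_LEN)) {
    code <- match(substr(peptides, offset + pos, offset + pos), LETTERS)
    code[is.na(code)] <- 27
    h <- (h * 131 + code * 7919) %% .LCG_M
  }
  h <- (.LCG_A * ((h + 12345) %% .LCG_M)) %% .LCG_M
  h <- (.LCG_A * h) %% .LCG_M
  h / .LCG_M
}

# best 9mer-window score and (0-based) offset for each 15mer; ties keep
# the smallest offset
.coreScoreBest <- function(presenterHash, peptides) {
  n <- length(peptides)
  best <- rep(-Inf, n)
  bestOff <- integer(n)
  for (off in 0:(.PEPTIDE_LEN - .CORE_LEN)) {
    s <- .windowScores(presenterHash, peptides, off)
    better <- s > best
    best[better] <- s[better]
    bestOff[better] <- off
  }
  list(score = best, offset = bestOff)
}

.presenterModel <- function(predictor, presenterSeq) {
  key <- paste0("k", .lcgMix(presenterSeq))
  hit <- predictor@cache[[key]]
  if (!is.null(hit) && identical(hit$seq, presenterSeq)) return(hit)
  presenterHash <- .lcgMix("binder", presenterSeq)
  bg <- sort(.coreScoreBest(presenterHash, predictor@background)$score)
  model <- list(seq = presenterSeq, hash = presenterHash, bgSorted = bg)
  predictor@cache[[key]] <- model
  model
}

#' Predict class-II binding of 15mer peptides to a presenter
#'
#' Generic entry point of the predictor contract. For each 15mer the
#' predictor chooses the best-scoring 9mer core window (smallest offset
#' on ties) and reports a percentile rank in \code{[0, 100]}: the
#' percentage of background peptides scoring at least as well (lower =
#' stronger predicted binder).
#'
#' @param predictor a predictor object (e.g.
#'   \code{\linkS4class{MockPredictor}}).
#' @param presenter presenter allele name (string or
#'   \code{AlleleName}); recorded in the output.
#' @param presenterSeq the presenter's protein sequence.
#' @param peptides character vector of 15mer peptides.
#' @param ... further arguments for methods.
#' @return \code{data.frame} with columns \code{peptide},
#'   \code{rank_pct}, \code{core} (9mer), \code{core_offset} (0-based,
#'   in 0..6).
#' @export
setGeneric("predictBinding",
  function(predictor, presenter, presenterSeq, peptides, ...)
    standardGeneric("predictBinding"))

#' @rdname predictBinding
#' @export
setMethod("predictBinding", "MockPredictor",
  function(predictor, presenter, presenterSeq, peptides, ...) {
    if (is(presenter, "AlleleName")) presenter <- formatAlleleName(presenter)
    stopifnot(is.character(presenterSeq), length(presenterSeq) == 1L)
    if (!nzchar(presenterSeq)) stop("unknown presenter: no sequence given")
    if (length(peptides) == 0L)
      return(data.frame(peptide = character(0), rank_pct = numeric(0),
                        core = character(0), core_offset = integer(0),
                        stringsAsFactors = FALSE))
    bad <- which(nchar(peptides) != .PEPTIDE_LEN)
    if (length(bad))
      stop("peptide of length ", nchar(peptides[bad[1L]]),
           " (need ", .PEPTIDE_LEN, "): ", peptides[bad[1L]])
    model <- .presenterModel(predictor, toupper(presenterSeq))
    sc <- .coreScoreBest(model$hash, toupper(peptides))
    n <- length(model$bgSorted)
    # count of background scores >= s, as a percentage of the background
    rank <- 100 * (n - findInterval(sc$score, model$bgSorted,
                                    left.open = TRUE)) / n
    data.frame(peptide = peptides, rank_pct = rank,
               core = substr(peptides, sc$offset + 1L,
                             sc$offset + .CORE_LEN),
               core_offset = sc$offset, stringsAsFactors = FALSE)
  })

#' Is a binding call presented?
#'
#' Threshold rule on the percentile rank: presented iff
#' \code{rank_pct <= threshold} (inclusive). The default threshold of 10
#' is the conventional weak-binder percentile cutoff for class-II
#' presentation.
#'
#' @param x a \code{data.frame} from \code{\link{predictBinding}} or a
#'   numeric vector of ranks.
#' @param threshold presentation threshold in (0, 100].
#' @return logical vector.
#' @export
isPresented <- function(x, threshold = 10) {
  stopifnot(is.numeric(threshold), length(threshold) == 1L,
            threshold > 0, threshold <= 100)
  rank <- if (is.data.frame(x)) x$rank_pct else x
  stopifnot(is.numeric(rank))
  rank <= threshold
}
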