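# Shared fixtures and independent brute-force oracles.
#
# The oracles deliberately use naive loops / exhaustive enumeration and
# never call the package's pipeline internals, so agreement is a real
# cross-check. The predictor is shared across tests: it is a pure
# function of its inputs, and reusing one instance just reuses its
# per-presenter cache.

PRED <- mockPredictor()

AA20_TEST <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
               "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

randomProtein <- function(n, alphabet = AA20_TEST) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# --- alignment / distance oracles -----------------------------------------

# independent Needleman-Wunsch score, linear gap cost (gapOpen = 0)
dpAlignScore <- function(a, b, match = 1, mismatch = 0, gap = 1) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  n <- length(ca); m <- length(cb)
  S <- matrix(0, n + 1, m + 1)
  S[, 1] <- -gap * (0:n)
  S[1, ] <- -gap * (0:m)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      sub <- if (ca[i] == cb[j]) match else mismatch
      S[i + 1, j + 1] <- max(S[i, j] + sub, S[i, j + 1] - gap,
                             S[i + 1, j] - gap)
    }
  }
  S[n + 1, m + 1]
}

loopHamming <- function(a, b, countGaps = TRUE) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  stopifnot(length(ca) == length(cb))
  d <- 0L
  for (i in seq_along(ca)) {
    if (!countGaps && (ca[i] == "-" || cb[i] == "-")) next
    if (ca[i] != cb[i]) d <- d + 1L
  }
  d
}

loopSharedCount <- function(pepsA, pepsB) {
  n <- 0L
  for (p in pepsA) {
    for (q in pepsB) {
      if (p == q) { n <- n + 1L; break }
    }
  }
  n
}

# all leaf bipartitions induced by internal edges (edge-cut enumeration)
edgeCutMonophyly <- function(tree, group1, group2) {
  ntip <- length(tree$tip.label)
  tipsUnder <- function(node) {
    if (node <= ntip) return(tree$tip.label[node])
    kids <- tree$edge[tree$edge[, 1] == node, 2]
    unlist(lapply(kids, tipsUnder))
  }
  for (e in seq_len(nrow(tree$edge))) {
    below <- tipsUnder(tree$edge[e, 2])
    if (setequal(below, group1) || setequal(below, group2)) return(TRUE)
  }
  FALSE
}

# --- brute-force epitope oracles ------------------------------------------

bruteWindows <- function(seq, k = 15L) {
  out <- character(0)
  if (nchar(seq) < k) return(out)
  for (i in 1:(nchar(seq) - k + 1)) {
    w <- substr(seq, i, i + k - 1)
    if (!grepl("X", w, fixed = TRUE)) out <- c(out, w)
  }
  out
}

# epitope keys "presenter|core" by exhaustive per-peptide enumeration
bruteT2Keys <- function(recipient, donor, db, predictor = PRED,
                        threshold = 10, k = 15L) {
  selfPeps <- character(0)
  for (a in genotypeAlleles(recipient)) {
    s <- dbSequences(db, a)[[1]]
    selfPeps <- union(selfPeps, bruteWindows(s, k))
  }
  donorPeps <- character(0)
  for (a in genotypeAlleles(donor)) {
    s <- dbSequences(db, a)[[1]]
    donorPeps <- union(donorPeps, bruteWindows(s, k))
  }
  surviving <- donorPeps[!donorPeps %in% selfPeps]
  pres <- presenterAlleles(recipient)
  pres <- pres[!duplicated(alleleKey(pres))]
  keys <- character(0)
  for (p in pres) {
    pseq <- dbSequences(db, p)[[1]]
    for (pep in surviving) {
      call <- predictBinding(predictor, p, pseq, pep)
      if (call$rank_pct <= threshold)
        keys <- union(keys, paste(alleleKey(p), call$core, sep = "|"))
    }
  }
  keys
}

bruteStepCount <- function(recipient, graft1, graft2, db,
                           predictor = PRED, threshold = 10, k = 15L) {
  k1 <- bruteT2Keys(recipient, graft1, db, predictor, threshold, k)
  k2 <- bruteT2Keys(recipient, graft2, db, predictor, threshold, k)
  length(intersect(k2, k1))
}

# --- tiny random worlds for oracle-equivalence sweeps ---------------------

# a self-contained world: <=5 alleles of length <= 40 across two loci,
# with related sequences so the self-filter actually bites
tinyWorld <- function(maxLen = 40L) {
  L <- sample(24:maxLen, 1)
  base1 <- randomProtein(L)
  base2 <- randomProtein(L)
  mut <- function(s, n) {
    ch <- strsplit(s, "")[[1]]
    pos <- sample(seq_along(ch), n)
    for (p in pos) ch[p] <- sample(setdiff(AA20_TEST, ch[p]), 1)
    paste(ch, collapse = "")
  }
  seqs <- c(
    "HLA-A*01:01" = base1,
    "HLA-A*02:01" = mut(base1, 3),
    "HLA-A*03:01" = mut(base1, 5),
    "HLA-DRB1*01:01" = base2,
    "HLA-DRB1*02:01" = mut(base2, 4))
  db <- alleleDb(seqs)
  pick <- function(id) genotype(id, "human", list(
    A = sample(c("HLA-A*01:01", "HLA-A*02:01", "HLA-A*03:01"), 2,
               replace = TRUE),
    DRB1 = sample(c("HLA-DRB1*01:01", "HLA-DRB1*02:01"), 2,
                  replace = TRUE)))
  list(db = db, recipient = pick("R"), donor = pick("D1"),
       graft2 = pick("D2"))
}
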