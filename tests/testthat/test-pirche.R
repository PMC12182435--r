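test_that("self peptidome is the union over all recipient alleles", {
  set.seed(701)
  seqs <- c("HLA-A*01:01" = randomProtein(30),
            "HLA-A*02:01" = randomProtein(30),
            "HLA-DRB1*01:01" = randomProtein(30))
  db <- alleleDb(seqs)
  one <- genotype("r", "human", list(A = "HLA-A*01:01"),
                  presenterLoci = character(0))
  expect_setequal(peptides(selfPeptidome(one, db)),
                  bruteWindows(seqs[[1]]))

  # homozygous duplicates contribute once; union equals a brute union
  g <- genotype("r", "human",
                list(A = c("HLA-A*01:01", "HLA-A*01:01"),
                     DRB1 = "HLA-DRB1*01:01"))
  expect_setequal(peptides(selfPeptidome(g, db)),
                  union(bruteWindows(seqs[[1]]), bruteWindows(seqs[[3]])))
})

test_that("a donor identical to the recipient scores zero", {
  set.seed(702)
  w <- tinyWorld()
  res <- pircheT2(w$recipient, w$recipient, w$db, PRED)
  expect_equal(res@score, 0L)
  expect_equal(nrow(res@epitopes), 0L)
})

test_that("a threshold no peptide reaches gives an empty epitope set", {
  set.seed(703)
  w <- tinyWorld()
  res <- pircheT2(w$recipient, w$donor, w$db, PRED, threshold = 1e-9)
  expect_equal(res@score, 0L)
})

test_that("recipients without presenter alleles are rejected", {
  set.seed(704)
  w <- tinyWorld()
  r <- genotype("r", "human", list(A = "HLA-A*01:01"),
                presenterLoci = character(0))
  expect_error(pircheT2(r, w$donor, w$db, PRED), "presenter")
})

test_that("T2 epitope sets equal exhaustive enumeration on tiny worlds", {
  set.seed(705)
  for (i in 1:20) {
    w <- tinyWorld()
    res <- pircheT2(w$recipient, w$donor, w$db, PRED)
    keys <- sort(paste(res@epitopes$presenter, res@epitopes$core,
                       sep = "|"))
    expect_identical(keys, sort(bruteT2Keys(w$recipient, w$donor, w$db)))
  }
})

test_that("STEP is the intersection of the grafts' epitope sets", {
  set.seed(706)
  for (i in 1:10) {
    w <- tinyWorld()
    st <- stepScore(w$recipient, w$donor, w$graft2, w$db, PRED)
    expect_equal(st@score,
                 bruteStepCount(w$recipient, w$donor, w$graft2, w$db))
    # symmetric in graft order
    st2 <- stepScore(w$recipient, w$graft2, w$donor, w$db, PRED)
    expect_equal(st@score, st2@score)
    # bounded by both T2 scores
    t2a <- pircheT2(w$recipient, w$donor, w$db, PRED)@score
    t2b <- pircheT2(w$recipient, w$graft2, w$db, PRED)@score
    expect_lte(st@score, min(t2a, t2b))
  }
})

test_that("a graft repeated twice shares its full epitope set", {
  set.seed(707)
  w <- tinyWorld()
  st <- stepScore(w$recipient, w$donor, w$donor, w$db, PRED)
  t2 <- pircheT2(w$recipient, w$donor, w$db, PRED)
  expect_equal(st@score, t2@score)
})

test_that("grafts with disjoint non-self peptidomes share nothing", {
  world <- generateWorld(worldSpec(seed = 21, sequenceLength = 45L,
                                   nSharedKmers = 0L))
  pat <- sampleGenotype(world$haplotypes, 1, "P0001")
  don <- sampleGenotype(world$haplotypes, 1, "D0001")
  st <- stepScore(pat, don, world$xenodonor, world$db, PRED)
  expect_equal(st@score, 0L)
})

test_that("raising the threshold never lowers T2 or STEP", {
  set.seed(708)
  w <- tinyWorld()
  t2s <- vapply(c(1, 5, 10, 30, 60, 100), function(th)
    pircheT2(w$recipient, w$donor, w$db, PRED, threshold = th)@score,
    integer(1))
  expect_true(all(diff(t2s) >= 0L))
  steps <- vapply(c(5, 20, 80), function(th)
    stepScore(w$recipient, w$donor, w$graft2, w$db, PRED,
              threshold = th)@score, integer(1))
  expect_true(all(diff(steps) >= 0L))
})

test_that("adding a recipient allele never enlarges the surviving donor pool", {
  set.seed(709)
  for (i in 1:5) {
    w <- tinyWorld()
    donorPeps <- peptides(xenostep:::.donorPeptidome(w$donor, w$db, 15L))
    before <- setdiff(donorPeps, peptides(selfPeptidome(w$recipient, w$db)))
    bigger <- w$recipient
    extra <- setdiff(c("HLA-A*01:01", "HLA-A*02:01", "HLA-A*03:01"),
                     bigger@loci$A)[1]
    if (is.na(extra)) next
    bigger@loci$A <- c(bigger@loci$A[1], extra, bigger@loci$A[2])[1:3]
    after <- setdiff(donorPeps, peptides(selfPeptidome(bigger, w$db)))
    expect_true(all(after %in% before))
  }
})

test_that("epitope identity and self-filter alternatives behave sensibly", {
  set.seed(710)
  w <- tinyWorld()
  core <- pircheT2(w$recipient, w$donor, w$db, PRED)
  full <- pircheT2(w$recipient, w$donor, w$db, PRED,
                   epitopeIdentity = "peptide")
  # distinct 15mers can collapse onto one core, never the reverse
  expect_gte(full@score, core@score)
  expect_true(all(nchar(core@epitopes$core) == 9L))
  if (nrow(full@epitopes)) {
    expect_true(all(nchar(full@epitopes$core) == 15L))
  }

  # core-level self-filtering is at least as strict as peptide-level
  strict <- pircheT2(w$recipient, w$donor, w$db, PRED,
                     selfFilter = "core")
  expect_lte(strict@score, core@score)
})

test_that("epitope provenance records only presented, filtered peptides", {
  set.seed(711)
  w <- tinyWorld()
  res <- pircheT2(w$recipient, w$donor, w$db, PRED, threshold = 25)
  if (nrow(res@provenance)) {
    expect_true(all(res@provenance$rank_pct <= 25))
    self <- peptides(selfPeptidome(w$recipient, w$db))
    expect_false(any(res@provenance$peptide %in% self))
    expect_setequal(paste(res@provenance$presenter, res@provenance$core),
                    paste(res@epitopes$presenter, res@epitopes$core))
  }
})
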