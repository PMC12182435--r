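test_that("haplotype tables normalize weights and validate", {
  hl <- data.frame(A = c("HLA-A*01:01", "HLA-A*02:01"),
                   DRB1 = c("HLA-DRB1*01:01", "HLA-DRB1*02:01"))
  tab <- haplotypeTable(hl, c(3, 1))
  expect_equal(tab@weights, c(0.75, 0.25))
  expect_error(haplotypeTable(hl, c(1, 0)), "positive")
  expect_error(haplotypeTable(hl[0, ], numeric(0)), "empty")

  path <- withr::local_tempfile(fileext = ".tsv")
  writeHaplotypeTable(tab, path)
  tab2 <- readHaplotypeTable(path)
  expect_equal(tab2@haplotypes, tab@haplotypes)
  expect_equal(tab2@weights, tab@weights)
})

test_that("a single-haplotype table always yields homozygous genotypes", {
  tab <- haplotypeTable(data.frame(A = "HLA-A*01:01",
                                   DRB1 = "HLA-DRB1*01:01"), 1)
  for (i in 1:5) {
    g <- sampleGenotype(tab, seed = i, id = "x")
    expect_equal(g@loci$A, rep("HLA-A*01:01", 2))
    expect_equal(g@loci$DRB1, rep("HLA-DRB1*01:01", 2))
  }
})

test_that("two equal-weight haplotypes give one-half homozygosity", {
  tab <- haplotypeTable(data.frame(A = c("HLA-A*01:01", "HLA-A*02:01")),
                        c(1, 1))
  n <- 10000
  hom <- vapply(seq_len(n), function(i) {
    g <- sampleGenotype(tab, seed = 99, id = paste0("i", i))
    g@loci$A[1] == g@loci$A[2]
  }, logical(1))
  # binomial expectation 1/2, 3 sigma tolerance
  expect_lt(abs(mean(hom) - 0.5), 3 * sqrt(0.25 / n))
})

test_that("haplotype draw frequencies track the weights", {
  w <- c(0.5, 0.3, 0.15, 0.05)
  tab <- haplotypeTable(
    data.frame(A = sprintf("HLA-A*%02d:01", 1:4)), w)
  n <- 25000
  draws <- unlist(lapply(seq_len(n), function(i)
    sampleGenotype(tab, seed = 7, id = paste0("i", i))@loci$A))
  freq <- table(factor(draws, levels = sprintf("HLA-A*%02d:01", 1:4)))
  freq <- as.numeric(freq) / (2 * n)
  for (j in 1:4) {
    expect_lt(abs(freq[j] - w[j]), 3 * sqrt(w[j] * (1 - w[j]) / (2 * n)))
  }
})

test_that("genotype sampling is a pure function of (seed, id)", {
  tab <- haplotypeTable(data.frame(A = c("HLA-A*01:01", "HLA-A*02:01"),
                                   DRB1 = c("HLA-DRB1*01:01",
                                            "HLA-DRB1*02:01")),
                        c(2, 1))
  g1 <- sampleGenotype(tab, 42, "P0001")
  g2 <- sampleGenotype(tab, 42, "P0001")
  expect_identical(g1@loci, g2@loci)
  g3 <- sampleGenotype(tab, 43, "P0001")
  g4 <- sampleGenotype(tab, 42, "P0002")
  # different seed or id gives an independent substream (same table, so
  # draws may coincide; across many ids they must not all coincide)
  many42 <- lapply(1:20, function(i) sampleGenotype(tab, 42, paste0("x", i))@loci)
  many43 <- lapply(1:20, function(i) sampleGenotype(tab, 43, paste0("x", i))@loci)
  expect_false(identical(many42, many43))
})

test_that("pair counts match the closed forms", {
  expect_equal(pairCount(4000, 1000, "cross"), 4e6)
  expect_equal(pairCount(138, mode = "all_vs_all_self"), 19044)
  expect_equal(pairCount(1, 1, "cross"), 1)

  it <- enumeratePairs(letters[1:3], LETTERS[1:4], "cross")
  expect_equal(it@count, 12)
  seen <- 0L
  while (hasNext(it)) { nextPair(it); seen <- seen + 1L }
  expect_equal(seen, 12L)
  expect_error(nextPair(it), "exhausted")

  it1 <- enumeratePairs("a", "b", "cross")
  expect_equal(it1@count, 1)
  expect_equal(nextPair(it1), list(first = "a", second = "b"))

  itS <- enumeratePairs(1:5, mode = "all_vs_all_self")
  expect_equal(itS@count, 25)
  first <- nextPair(itS)
  expect_equal(first, list(first = 1L, second = 1L))  # self-pairs included
})

test_that("a 1x1 cohort yields exactly one human and one xeno score", {
  world <- generateWorld(worldSpec(seed = 31, sequenceLength = 45L))
  cs <- simulateCohort(world$haplotypes, world$xenodonor, world$db,
                       nPatients = 1, nDonors = 1, predictor = PRED,
                       seed = 5)
  expect_equal(nrow(cohortScores(cs)), 2L)
  expect_setequal(cohortScores(cs)$donor_source, c("human", "xeno"))
  expect_equal(nrow(patientMedians(cs)), 1L)
})

test_that("an all-identical-haplotype world gives zero human-donor T2", {
  world <- generateWorld(worldSpec(seed = 33, sequenceLength = 45L))
  tab <- world$haplotypes
  one <- haplotypeTable(tab@haplotypes[1, , drop = FALSE], 1)
  cs <- simulateCohort(one, world$xenodonor, world$db,
                       nPatients = 3, nDonors = 3, predictor = PRED,
                       seed = 2)
  human <- cohortScores(cs)
  expect_true(all(human$t2[human$donor_source == "human"] == 0L))
  expect_true(all(human$t2[human$donor_source == "xeno"] > 0L))
})

test_that("cohort summaries are reproducible and internally consistent", {
  world <- generateWorld(worldSpec(seed = 35, sequenceLength = 45L,
                                   nSharedKmers = 2L))
  run <- function() simulateCohort(world$haplotypes, world$xenodonor,
                                   world$db, nPatients = 4, nDonors = 6,
                                   predictor = PRED, seed = 11)
  cs1 <- run(); cs2 <- run()
  expect_identical(cohortScores(cs1), cohortScores(cs2))
  expect_identical(patientMedians(cs1), patientMedians(cs2))

  # a different seed changes only the stochastic fields
  cs3 <- simulateCohort(world$haplotypes, world$xenodonor, world$db,
                        nPatients = 4, nDonors = 6, predictor = PRED,
                        seed = 12)
  expect_equal(cs3@nPatients, cs1@nPatients)
  expect_false(identical(cohortScores(cs1), cohortScores(cs3)))

  # medians and optimum patients recompute from the raw score table
  sc <- cohortScores(cs1)
  pm <- patientMedians(cs1)
  for (p in pm$patient_id) {
    v <- sc$t2[sc$patient_id == p & sc$donor_source == "human"]
    expect_length(v, 6L)
    expect_equal(median(v), pm$median_human_t2[pm$patient_id == p])
  }
  expect_setequal(cs1@bestPatients,
                  pm$patient_id[pm$median_human_t2 ==
                                  min(pm$median_human_t2)])
  expect_setequal(cs1@worstPatients,
                  pm$patient_id[pm$median_human_t2 ==
                                  max(pm$median_human_t2)])

  # per-pair scores agree with the public single-pair scorer
  pat <- sampleGenotype(world$haplotypes, 11, "P0002")
  don <- sampleGenotype(world$haplotypes, 11, "D0003")
  direct <- pircheT2(pat, don, world$db, PRED)@score
  expect_equal(sc$t2[sc$patient_id == "P0002" & sc$donor_id == "D0003"],
               direct)
  xeno <- pircheT2(pat, world$xenodonor, world$db, PRED)@score
  expect_equal(sc$t2[sc$patient_id == "P0002" &
                       sc$donor_source == "xeno"], xeno)
})

test_that("repeat-transplant vectors are consistent and order-free", {
  world <- generateWorld(worldSpec(seed = 37, sequenceLength = 45L,
                                   nSharedKmers = 3L))
  rt <- repeatTransplantAnalysis(world$haplotypes, world$xenodonor,
                                 world$db, nPatients = 6, nDonors = 5,
                                 predictor = PRED, seed = 3)
  steps <- rt$steps
  sah <- steps[steps$direction == "SAH", ]
  has <- steps[steps$direction == "HAS", ]
  expect_equal(sah$step, has$step)
  # the two directions really are the same pair in swapped order
  expect_equal(sah$first_graft, has$second_graft)
  expect_equal(sah$second_graft, has$first_graft)

  # summary medians / zero fractions recompute from the step table
  for (d in c("SAH", "HAS", "HAH")) {
    v <- steps$step[steps$direction == d]
    expect_equal(rt$summary$median_step[rt$summary$direction == d],
                 median(as.numeric(v)))
    expect_equal(rt$summary$zero_fraction[rt$summary$direction == d],
                 mean(v == 0))
  }

  # per-patient STEP agrees with the public scorer
  p1 <- sampleGenotype(world$haplotypes, 3, "P0001")
  g1 <- steps$first_graft[steps$direction == "SAH" &
                            steps$patient_id == "P0001"]
  don <- sampleGenotype(world$haplotypes, 3, g1)
  direct <- stepScore(p1, don, world$xenodonor, world$db, PRED)@score
  expect_equal(steps$step[steps$direction == "SAH" &
                            steps$patient_id == "P0001"], direct)
})
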