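test_that("allele names parse into species/gene/fields and round-trip", {
  an <- parseAlleleName("SLA-DQA*02:04")
  expect_equal(an@species, "SLA")
  expect_equal(an@gene, "DQA")
  expect_equal(an@fields, c("02", "04"))
  expect_equal(formatAlleleName(an), "SLA-DQA*02:04")

  an2 <- parseAlleleName("SLA-1*07:02")
  expect_equal(an2@gene, "1")
  expect_equal(an2@fields, c("07", "02"))

  # two-field truncation keeps exactly the first two fields
  expect_equal(formatAlleleName("HLA-A*01:01:01", nFields = 2),
               "HLA-A*01:01")
  expect_equal(alleleKey(c("HLA-A*01:01:01", "HLA-DRB1*04:03")),
               c("HLA-A*01:01", "HLA-DRB1*04:03"))

  # unicode hyphens from typeset text normalize to ASCII
  expect_equal(formatAlleleName(parseAlleleName("SLA‐1*07:02")),
               "SLA-1*07:02")

  # bare gene and species-free forms
  expect_equal(parseAlleleName("DRB1*04:01")@species, "")
  expect_equal(formatAlleleName(parseAlleleName("HLA-A")), "HLA-A")
})

test_that("malformed allele names raise parse errors naming the token", {
  expect_error(parseAlleleName("HLA-A*"), "empty field")
  expect_error(parseAlleleName("HLA-A*01::01"), "empty field")
  expect_error(parseAlleleName("-A*01:01"), "species")
  expect_error(parseAlleleName(""), "non-empty")
  expect_error(parseAlleleName("HLA-A*xx:01"), "malformed")
})

test_that("every allele in the reference SLA genotype string round-trips", {
  g <- slaReferenceGenotype()
  for (a in genotypeAlleles(g)) {
    expect_equal(formatAlleleName(parseAlleleName(a)), a)
  }
})

test_that("the bundled reference SLA genotype has 15 slots over 7 loci", {
  g <- slaReferenceGenotype()
  expect_length(g@loci, 7L)
  expect_length(genotypeAlleles(g), 15L)
  expect_equal(sort(names(g@loci)),
               sort(c("1", "2", "3", "DRB1", "DQB1", "DQA", "DRA")))
  # the triple SLA-1 is preserved: loci allow up to three alleles
  expect_length(g@loci[["1"]], 3L)
  expect_equal(g@presenterLoci, "DRB1")
  expect_true("SLA-DQA*02:04" %in% g@loci[["DQA"]])
})

test_that("FASTA read/write/read is the identity on names and sequences", {
  world <- generateWorld(worldSpec(seed = 11, sequenceLength = 60L))
  path <- withr::local_tempfile(fileext = ".fasta")
  writeAlleleFasta(world$humanDb, path)
  db2 <- readAlleleFasta(path)
  expect_identical(names(db2), names(world$humanDb))
  expect_identical(as.character(db2@seqs), as.character(world$humanDb@seqs))

  # a second write of the re-read database is byte-identical
  path2 <- withr::local_tempfile(fileext = ".fasta")
  writeAlleleFasta(db2, path2)
  expect_identical(readLines(path), readLines(path2))
})

test_that("FASTA reader normalizes case, finds names after accessions, and validates", {
  path <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">IPD00001 HLA-A*01:01 some description",
               "mavmapr", ">HLA-B*07:02", "ACDEFGHIKL"), path)
  db <- readAlleleFasta(path)
  expect_equal(names(db), c("HLA-A*01:01", "HLA-B*07:02"))
  expect_equal(as.character(db@seqs)[[1]], "MAVMAPR")

  bad <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">HLA-A*01:01", "ACDEFZ"), bad)
  expect_error(readAlleleFasta(bad), "position 6")

  dup <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">HLA-A*01:01", "ACDEF", ">HLA-A*01:01", "ACDEF"), dup)
  expect_error(readAlleleFasta(dup), "duplicate")
  expect_length(readAlleleFasta(dup, duplicates = "dedup"), 1L)

  empty <- withr::local_tempfile(fileext = ".fasta")
  writeLines(character(0), empty)
  expect_error(readAlleleFasta(empty), "empty")
})

test_that("genotypes read from JSON and TSV, keeping homozygous duplicates", {
  g <- genotype("R1", "human",
                list(A = c("HLA-A*01:01", "HLA-A*01:01"),
                     DRB1 = c("HLA-DRB1*04:01", "HLA-DRB1*07:01")))
  jpath <- withr::local_tempfile(fileext = ".json")
  writeGenotype(g, jpath)
  g2 <- readGenotype(jpath)
  expect_equal(g2@loci, g@loci)
  expect_equal(g2@presenterLoci, "DRB1")
  # homozygosity retained in the slots, deduplicated in presenter sets
  expect_length(g2@loci$A, 2L)
  expect_length(presenterAlleles(g2), 2L)

  tpath <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("locus\tallele\tpresenter",
               "A\tHLA-A*01:01\tFALSE",
               "A\tHLA-A*02:01\tFALSE",
               "DRB1\tHLA-DRB1*04:01\tTRUE"), tpath)
  g3 <- readGenotype(tpath)
  expect_equal(names(g3@loci), c("A", "DRB1"))
  expect_equal(g3@presenterLoci, "DRB1")

  empty <- withr::local_tempfile(fileext = ".json")
  writeLines('{"id": "x", "loci": {}}', empty)
  expect_error(readGenotype(empty), "no loci")
})

test_that("genotype validity enforces locus structure", {
  expect_error(genotype("x", "human", list()), "at least one locus")
  expect_error(genotype("x", "human",
                        list(A = c("a*01", "a*02", "a*03", "a*04"))),
               "more than three")
  # unresolvable alleles are fine at parse time, fatal at scoring time
  g <- genotype("x", "human", list(DRB1 = "HLA-DRB1*99:99"))
  db <- alleleDb(c("HLA-A*01:01" = "ACDEFGHIKLMNPQRSTVWY"))
  expect_error(selfPeptidome(g, db), "HLA-DRB1\\*99:99")
})
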