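test_that("global alignment handles identity, gaps and empty input", {
  ap <- globalAlign("ACDE", "ACDE")
  expect_equal(ap@aAligned, "ACDE")
  expect_equal(ap@bAligned, "ACDE")
  expect_equal(hammingDistance(ap), 0L)

  ap2 <- globalAlign("ACDE", "ACE")
  expect_equal(nchar(ap2@aAligned), 4L)
  expect_equal(sum(strsplit(ap2@bAligned, "")[[1]] == "-"), 1L)

  expect_error(globalAlign("", "ACDE"), "empty")
})

test_that("alignment scores equal an independent DP oracle on random 30mers", {
  set.seed(401)
  for (i in 1:25) {
    a <- randomProtein(30)
    b <- randomProtein(sample(20:30, 1))
    ap <- globalAlign(a, b, gapOpen = 0, gapExtend = 1)
    expect_equal(ap@score, dpAlignScore(a, b), tolerance = 1e-9)
    # removing gaps recovers the originals
    expect_equal(gsub("-", "", ap@aAligned), a)
    expect_equal(gsub("-", "", ap@bAligned), b)
  }
})

test_that("hamming distance counts differing columns, gaps per flag", {
  expect_equal(hammingDistance("ABCD", "ABCE"), 1L)
  expect_equal(hammingDistance("AB-D", "ABCD"), 1L)
  expect_equal(hammingDistance("AB-D", "ABCD", countGaps = FALSE), 0L)
  expect_error(hammingDistance("AB", "ABC"), "equal length")

  set.seed(402)
  for (i in 1:20) {
    n <- sample(10:40, 1)
    a <- randomProtein(n, c("A", "C", "D", "-"))
    b <- randomProtein(n, c("A", "C", "D", "-"))
    expect_equal(hammingDistance(a, b), loopHamming(a, b))
    expect_equal(hammingDistance(a, b, countGaps = FALSE),
                 loopHamming(a, b, countGaps = FALSE))
    expect_equal(hammingDistance(a, b), hammingDistance(b, a))
  }
})

test_that("distance matrices are symmetric with zero diagonal", {
  seqs <- c(x = "ACDEF", y = "ACDEF")
  d <- distanceMatrix(seqs)
  expect_equal(unname(d), matrix(0, 2, 2))

  set.seed(403)
  seqs <- vapply(1:5, function(i) randomProtein(25), character(1))
  names(seqs) <- paste0("s", 1:5)
  d <- distanceMatrix(seqs)
  expect_identical(d, t(d))
  expect_equal(unname(diag(d)), rep(0, 5))
  expect_true(all(d >= 0))

  expect_error(distanceMatrix(c(a = "ACD", a = "ACE")), "duplicate")
  expect_error(distanceMatrix(c(a = "ACD")), "at least two")
})

test_that("realized distances match the generator's recorded divergence", {
  world <- generateWorld(worldSpec(seed = 5,
                                   nAllelesHuman = 2L, nAllelesSwine = 2L,
                                   lociSwine = c("1", "2")))
  sel <- c(names(world$humanDb)[1:4], names(world$swineDb)[1:4])
  d <- distanceMatrix(world$db[sel])
  grp <- rep(c("human", "swine"), each = 4)
  cross <- d[grp == "human", grp == "swine"]
  # disjoint vocabularies force cross-species distances near the length
  expect_equal(mean(cross), world$truth$betweenMeanHamming,
               tolerance = 0.05)
  within <- d[grp == "human", grp == "human"]
  expect_lt(mean(within[upper.tri(within)]), mean(cross) / 3)
})

test_that("neighbor joining recovers additive matrices exactly", {
  # 4-leaf additive matrix: the correct split minimizes the pair-sum,
  # checked against enumeration of the three possible topologies
  set.seed(404)
  for (i in 1:10) {
    tr <- ape::rtree(4, br = function(n) runif(n, 0.5, 2))
    d <- ape::cophenetic.phylo(tr)
    labs <- rownames(d)
    est <- njTree(d)
    expect_equal(ape::cophenetic.phylo(est)[labs, labs], d,
                 tolerance = 1e-9)
    sums <- c(d[1, 2] + d[3, 4], d[1, 3] + d[2, 4], d[1, 4] + d[2, 3])
    bestSplit <- switch(which.min(sums),
                        list(labs[c(1, 2)], labs[c(3, 4)]),
                        list(labs[c(1, 3)], labs[c(2, 4)]),
                        list(labs[c(1, 4)], labs[c(2, 3)]))
    expect_true(speciesMonophyly(est, bestSplit))
  }

  # larger additive matrices: path metric reproduced within 1e-9
  for (n in c(6, 10)) {
    tr <- ape::rtree(n, br = function(x) runif(x, 0.5, 2))
    d <- ape::cophenetic.phylo(tr)
    est <- njTree(d)
    expect_equal(ape::cophenetic.phylo(est)[rownames(d), colnames(d)], d,
                 tolerance = 1e-9)
  }
})

test_that("three leaves give the closed-form star branch lengths", {
  d <- matrix(c(0, 3, 5, 3, 0, 6, 5, 6, 0), 3, 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- njTree(d)
  expect_equal(ape::Ntip(tr), 3L)
  # a = (dab + dac - dbc)/2 = 1, b = 2, c = 4
  lens <- tr$edge.length[match(1:3, tr$edge[, 2])]
  expect_equal(lens[match(c("a", "b", "c"), tr$tip.label)], c(1, 2, 4))
})

test_that("njTree rejects malformed matrices", {
  d <- matrix(c(0, 1, 2, 0), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_error(njTree(d), "symmetric|three")
  d3 <- matrix(0, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  d3[1, 2] <- d3[2, 1] <- -1
  expect_error(njTree(d3), "negative")
})

test_that("species monophyly agrees with edge-cut bipartition enumeration", {
  tr <- ape::read.tree(text = "((a:1,b:1):2,(c:1,d:1):2,(e:1,f:1):2);")
  expect_true(speciesMonophyly(tr, list(c("a", "b"), c("c", "d", "e", "f"))))
  expect_false(speciesMonophyly(tr, list(c("a", "c"), c("b", "d", "e", "f"))))
  expect_error(speciesMonophyly(tr, list(c("a", "z"), c("b", "c", "d", "e", "f"))),
               "unknown leaf")
  expect_error(speciesMonophyly(tr, list(c("a"), c("b", "c"))), "partition")

  set.seed(405)
  for (i in 1:20) {
    n <- sample(5:8, 1)
    tr <- ape::unroot(ape::rtree(n))
    g1 <- sample(tr$tip.label, sample(2:(n - 2), 1))
    g2 <- setdiff(tr$tip.label, g1)
    expect_equal(speciesMonophyly(tr, list(g1, g2)),
                 edgeCutMonophyly(tr, g1, g2))
  }
})

test_that("high-divergence synthetic worlds split into two species clades", {
  world <- generateWorld(worldSpec(seed = 17, sequenceLength = 60L,
                                   nAllelesHuman = 2L, nAllelesSwine = 2L))
  d <- distanceMatrix(world$db)
  tr <- njTree(d)
  groups <- split(rownames(d), ifelse(grepl("^HLA", rownames(d)),
                                      "human", "swine"))
  expect_true(speciesMonophyly(tr, groups))
})
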