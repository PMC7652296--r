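test_that("AMOVA F_ST hits its fixed points", {
  # identical allele frequencies, large n: no differentiation
  set.seed(31)
  n <- 200
  gam <- function() sample(1:4, n, TRUE, prob = c(0.4, 0.3, 0.2, 0.1))
  g0 <- genotypeMatrix(matrix(c(gam(), gam()), 2 * n, 1),
                       matrix(c(gam(), gam()), 2 * n, 1),
                       populations = rep(c("a", "b"), each = n))
  expect_lte(amovaFst(g0)$fst, 0.01)

  # complete fixation for different alleles
  expect_equal(amovaFst(fixedDifferentGenotypes())$fst, 1)

  expect_error(amovaFst(fixedDifferentGenotypes()[1:5, ]), "two populations")
})

test_that("AMOVA F_ST recovers the Balding-Nichols divergence parameter", {
  set.seed(77)
  est <- replicate(8, {
    sim <- simulateGenotypes(nPops = 8, nPerPop = 50, nLoci = 10, F = 0.10,
                             nWest = 0, missingRate = 0,
                             seed = sample.int(1e6, 1))
    amovaFst(sim$genotypes)$fst
  })
  expect_lt(abs(mean(est) - 0.10), 0.02)
})

test_that("maximal-differentiation recoding preserves within-population spectra", {
  sim <- simulateGenotypes(nPops = 3, nPerPop = 20, nLoci = 4, nAlleles = 5,
                           F = 0.1, nWest = 0, missingRate = 0.05, seed = 13)
  g <- sim$genotypes
  rec <- maxFstRecode(g)

  # single population: allele counts unchanged
  g1 <- subsetPopulations(g, "pop01")
  rec1 <- maxFstRecode(g1)
  for (l in lociNames(g1)) {
    expect_equal(
      length(unique(stats::na.omit(c(rec1@alleleA[, l], rec1@alleleB[, l])))),
      length(unique(stats::na.omit(c(g1@alleleA[, l], g1@alleleB[, l]))))
    )
  }

  # populations share no alleles after recoding
  af <- alleleFrequencies(rec)
  for (l in names(af)) {
    pres <- unlist(lapply(af[[l]], names))
    expect_equal(anyDuplicated(pres), 0)
  }

  # per-population he identical before and after
  expect_equal(diversitySummary(rec)$he, diversitySummary(g)$he)

  # two pops sharing an allele label get distinct labels
  gshare <- genotypeMatrix(matrix(120L, 4, 1), matrix(120L, 4, 1),
                           populations = c("a", "a", "b", "b"))
  recs <- maxFstRecode(gshare)
  expect_equal(length(unique(c(recs@alleleA))), 2)
})

test_that("pairwise differentiation: F'ST bounds, fixed points and relabeling invariance", {
  set.seed(5)
  sim <- simulateGenotypes(nPops = 3, nPerPop = 25, nLoci = 5, F = 0.08,
                           nWest = 0, missingRate = 0, seed = 21)
  g <- sim$genotypes
  pd <- pairwiseDifferentiation(g, nPerm = 49, seed = 3)
  fst <- as.matrix(pd$fst)
  fp <- as.matrix(pd$fstPrime)
  off <- upper.tri(fst)
  expect_true(all(fp[off] >= fst[off] - 1e-9))
  expect_true(all(fp[off] >= 0 & fp[off] <= 1))

  # invariant under a global relabeling of alleles
  g2 <- genotypeMatrix(g@alleleA + 1000L, g@alleleB + 1000L,
                       populations = as.character(populations(g)))
  pd2 <- pairwiseDifferentiation(g2, nPerm = 49, seed = 3)
  expect_equal(as.matrix(pd2$fstPrime), fp, tolerance = 1e-12)

  # zero within-population diversity: F'ST = F_ST = 1
  pdf <- pairwiseDifferentiation(fixedDifferentGenotypes(), nPerm = 19, seed = 1)
  expect_equal(as.matrix(pdf$fst)[1, 2], 1)
  expect_equal(as.matrix(pdf$fstPrime)[1, 2], 1)
})

test_that("cross-block permutation p-values are extreme under a deep split", {
  sim <- simulateGenotypes(nPops = 4, nPerPop = 20, nLoci = 6, F = 0.02,
                           nWest = 2, missingRate = 0, seed = 8)
  pd <- pairwiseDifferentiation(sim$genotypes, nPerm = 999, seed = 2)
  pv <- pvalues(pd$fst)
  cross <- pv[c("pop01", "pop02"), c("pop03", "pop04")]
  expect_true(all(cross <= 0.001))
})

test_that("permutation p-values are calibrated under exchangeable null", {
  # multi-locus, multi-allele data so the F_ST permutation distribution is
  # effectively continuous (a single near-monomorphic locus would give a
  # legitimately conservative, tie-heavy p)
  set.seed(303)
  ps <- replicate(100, {
    n <- 20
    a <- sapply(1:5, function(k) sample(1:6, 2 * n, TRUE))
    b <- sapply(1:5, function(k) sample(1:6, 2 * n, TRUE))
    g <- genotypeMatrix(a, b, populations = rep(c("a", "b"), each = n))
    as.vector(pvalues(pairwiseDifferentiation(
      g, nPerm = 99, seed = sample.int(1e6, 1))$fst)[1, 2])
  })
  # approximately uniform: moments and tail coverage (p is discrete on
  # {1/100, ..., 1}, so KS is inappropriate); per-replicate Monte-Carlo
  # noise from 99 permutations adds to the partition-level spread
  expect_lt(abs(mean(ps) - 0.505), 0.1)
  expect_lt(abs(mean(ps <= 0.25) - 0.25), 0.15)
  expect_gt(mean(ps > 0.05), 0.8)
  expect_lte(mean(ps <= 0.05), 0.12)
})

test_that("modified FDR threshold equals alpha over the harmonic sum", {
  expect_equal(narumFdr(0.04, 0.05)$alphaCrit, 0.05)
  f5 <- narumFdr(rep(0.01, 5), alpha = 0.05)
  expect_equal(f5$alphaCrit, 0.05 / sum(1 / (1:5)))
  expect_true(all(f5$decisions))
  f136 <- narumFdr(runif(136), alpha = 0.05)
  expect_equal(f136$alphaCrit, 0.05 / sum(1 / (1:136)))
  expect_error(narumFdr(numeric(0)), "empty")
  expect_error(narumFdr(c(0.5, 1.2)), "0, 1")
})

test_that("PCoA reproduces known geometry and agrees with classical scaling", {
  # four points on a line: one axis carries all variation
  x <- c(0, 1, 3, 7)
  d <- as.matrix(dist(x))
  m <- labeledMatrix(d, statName = "distance_km",
                     labels = paste0("p", 1:4))
  pc <- pcoa(m, assumeSquared = FALSE)
  expect_equal(pc$percent[1], 100, tolerance = 1e-8)

  # random planar points: coordinates reproduce pairwise distances
  set.seed(17)
  pts <- cbind(runif(6), runif(6))
  dm <- as.matrix(dist(pts))
  m2 <- labeledMatrix(dm, statName = "distance_km", labels = paste0("q", 1:6))
  pc2 <- pcoa(m2, assumeSquared = FALSE)
  rec <- as.matrix(dist(pc2$coordinates))
  expect_lt(max(abs(rec - dm)), 1e-6)

  # independent cross-check: base R classical MDS eigenvalues
  cmd <- stats::cmdscale(dm, k = 2, eig = TRUE)
  pos <- cmd$eig[cmd$eig > 1e-12]
  expect_equal(pc2$percent[1], 100 * pos[1] / sum(pos), tolerance = 1e-8)

  expect_error(pcoa(labeledMatrix(matrix(c(NA, NA, NA, NA), 2, 2,
    dimnames = list(c("a", "b"), c("a", "b"))), "x")), "NA")
})
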