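test_that("pair vectors enumerate shared labels deterministically", {
  lab <- paste0("c", sprintf("%02d", 1:11))
  mk <- function(labels, seed) {
    set.seed(seed)
    k <- length(labels)
    v <- matrix(0, k, k, dimnames = list(labels, labels))
    v[upper.tri(v)] <- runif(sum(upper.tri(v)))
    v[lower.tri(v)] <- t(v)[lower.tri(v)]
    labeledMatrix(v, "x")
  }
  a <- mk(lab, 1)
  b <- mk(lab, 2)
  pv <- pairVectors(a, b)
  expect_equal(nrow(pv), choose(11, 2)) # 55
  expect_true(all(pv$label1 < pv$label2))

  # disjoint label sets
  expect_error(pairVectors(a, mk(paste0("z", 1:4), 3)), "shared labels")

  # study fixtures: 11 colonies in both Table 3 and Table 6 -> 55 pairs
  tabs <- loadStudyTables()
  pvF <- pairVectors(tabs$fstPrime, tabs$udoi)
  expect_equal(nrow(pvF), 55)
  expect_false("MO" %in% c(pvF$label1, pvF$label2)) # no tags retrieved
  expect_false("SEF" %in% c(pvF$label1, pvF$label2)) # dropped from genetics
})

test_that("Spearman r is the Pearson correlation of mid-ranks", {
  expect_equal(spearmanR(1:8, (1:8)^3), 1)
  expect_equal(spearmanR(1:8, -(1:8)), -1)

  # tie-heavy vectors against an explicit mid-rank oracle
  x <- c(1, 2, 2, 2, 5, 5, 7, 8)
  y <- c(3, 3, 1, 4, 4, 4, 2, 2)
  midrank <- function(v) {
    vapply(v, function(vi) sum(v < vi) + (1 + sum(v == vi)) / 2, numeric(1))
  }
  rx <- midrank(x)
  ry <- midrank(y)
  oracle <- sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  expect_equal(spearmanR(x, y), oracle, tolerance = 1e-12)
  expect_equal(spearmanR(x, y), cor(x, y, method = "spearman"),
               tolerance = 1e-12)

  expect_error(spearmanR(1:3, rep(1, 3)), "zero rank variance")
  expect_error(spearmanR(1:3, 1:4), "equal length")
})

test_that("randomization p matches exhaustive enumeration for five pairs", {
  x <- c(0.1, 0.4, 0.2, 0.9, 0.5)
  y <- c(2.0, 1.1, 3.2, 0.4, 1.9)
  rObs <- spearmanR(x, y)
  perms <- as.matrix(expand.grid(rep(list(1:5), 5)))
  perms <- perms[apply(perms, 1, function(p) !any(duplicated(p))), ]
  rAll <- apply(perms, 1, function(p) spearmanR(x, y[p]))
  pExact <- mean(rAll >= rObs - 1e-12)
  res <- randomizationPvalue(x, y, nPerm = 4000, alternative = "greater",
                             seed = 9)
  se <- sqrt(pExact * (1 - pExact) / 4000)
  expect_lt(abs(res$p - pExact), 2 * se + 1 / 4001)

  # strictly increasing: no permutation beats the observed r
  inc <- randomizationPvalue(1:10, (1:10)^2, nPerm = 5000,
                             alternative = "greater", seed = 2)
  expect_equal(inc$p, 1 / 5001)

  # bit-reproducible given the seed, order-invariant in the pairs
  res2 <- randomizationPvalue(x, y, nPerm = 4000, alternative = "greater",
                              seed = 9)
  expect_identical(res$p, res2$p)
})

test_that("randomization null is calibrated and has the Spearman permutation spread", {
  set.seed(404)
  ps <- replicate(200, {
    x <- rnorm(15)
    y <- rnorm(15)
    randomizationPvalue(x, y, nPerm = 199, alternative = "greater",
                        seed = sample.int(1e6, 1))$p
  })
  # discrete-uniform calibration: moments and tail coverage
  expect_lt(abs(mean(ps) - 0.5025), 3 * sqrt(1 / 12 / 200))
  expect_lt(abs(mean(ps <= 0.25) - 0.25), 0.1)

  # null sd of Spearman r ~ 1/sqrt(n-1) for n = 55 pairs
  x <- rnorm(55)
  y <- rnorm(55)
  res <- randomizationPvalue(x, y, nPerm = 3000, seed = 11)
  expect_lt(abs(stats::sd(res$replicates) - 1 / sqrt(54)) * sqrt(54), 0.1)
})

test_that("great-circle distances follow spherical geometry", {
  col <- data.frame(abbrev = c("o", "e", "n"),
                    lon = c(0, 90, 0), lat = c(0, 0, 90))
  d <- as.matrix(greatCircleMatrix(col))
  quarter <- 2 * pi * 6371 / 4
  expect_lt(abs(d["o", "e"] - quarter) / quarter, 0.001)
  expect_lt(abs(d["o", "n"] - quarter) / quarter, 0.001)
  expect_equal(d["o", "e"], d["e", "o"])

  set.seed(21)
  pts <- data.frame(abbrev = paste0("p", 1:9),
                    lon = runif(9, -180, 180), lat = runif(9, -80, 80))
  dm <- as.matrix(greatCircleMatrix(pts))
  diag(dm) <- 0
  for (k in 1:20) {
    tri <- sample(9, 3)
    expect_lte(dm[tri[1], tri[2]],
               dm[tri[1], tri[3]] + dm[tri[3], tri[2]] + 1e-9)
  }
})

test_that("association tests run both hypotheses over the fixture tables", {
  tabs <- loadStudyTables()
  res <- associationTests(tabs$fstPrime, tabs$udoi, tabs$colonies,
                          nPerm = 500, seed = 5)
  expect_equal(res$ibd$nPairs, 55)
  expect_equal(res$overlap$nPairs, 55)
  expect_equal(res$ibd$alternative, "greater")
  expect_equal(res$overlap$alternative, "less")
  expect_gt(res$ibd$r, 0)
  expect_lt(res$overlap$r, 0)

  # the 12-colony variant of the distance test is selectable
  east12 <- tabs$colonies$abbrev[tabs$colonies$region == "east" &
                                   tabs$colonies$abbrev != "SEF"]
  res12 <- associationTests(tabs$fstPrime, tabs$udoi, tabs$colonies,
                            nPerm = 200, seed = 5, ibdLabels = east12)
  expect_equal(res12$ibd$nPairs, 66)

  # signal check: a label shuffle rarely reaches a correlation as
  # negative as the observed overlap r
  pv <- pairVectors(tabs$fstPrime, tabs$udoi)
  set.seed(33)
  beats <- replicate(100, {
    spearmanR(pv$x, sample(pv$y)) <= res$overlap$r
  })
  expect_gte(mean(!beats), 0.9)
})
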