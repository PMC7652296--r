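test_that("season filter keeps the closed Nov-Feb window across the year boundary", {
  days <- seq(as.Date("2014-10-01"), as.Date("2015-03-31"), by = 1)
  tr <- dailyTrack(data.frame(date = days, lon = -140, lat = 45,
                              status = "present"))
  out <- seasonFilter(tr)
  expect_equal(min(out$date), as.Date("2014-11-01"))
  expect_equal(max(out$date), as.Date("2015-02-28"))
  expect_equal(nrow(out), 30 + 31 + 31 + 28)

  # leap year keeps Feb 29
  days2 <- seq(as.Date("2015-11-01"), as.Date("2016-03-05"), by = 1)
  tr2 <- dailyTrack(data.frame(date = days2, lon = -140, lat = 45,
                               status = "present"))
  out2 <- seasonFilter(tr2)
  expect_true(as.Date("2016-02-29") %in% out2$date)

  # a fully-in-window simulated track is retained in full
  grid <- smallOceanGrid()
  tr3 <- simulateTrack(grid, oceanOrigin(grid),
                       seq(as.Date("2014-11-01"), by = 1, length.out = 120),
                       stepScale = 1, seed = 3)
  expect_equal(nrow(seasonFilter(tr3)), 120)

  # non-present days are dropped, empty result warns
  tr4 <- dailyTrack(data.frame(date = as.Date("2014-06-15"), lon = -140,
                               lat = 45, status = "present"))
  expect_warning(out4 <- seasonFilter(tr4), "no positions")
  expect_equal(nrow(out4), 0)
})

test_that("ad hoc bandwidth follows its formula and scale equivariance", {
  set.seed(61)
  n <- 1000
  sigma <- 2.5
  pts <- data.frame(lon = rnorm(n, -140, sigma), lat = rnorm(n, 45, sigma))
  h <- hrefBandwidth(pts)
  expect_lt(abs(h - sigma * n^(-1 / 6)) / (sigma * n^(-1 / 6)), 0.1)

  pts2 <- data.frame(lon = -140 + 2 * (pts$lon + 140),
                     lat = 45 + 2 * (pts$lat - 45))
  expect_equal(hrefBandwidth(pts2), 2 * h, tolerance = 1e-12)

  expect_error(hrefBandwidth(pts[1:4, ]), "5 points")
  same <- data.frame(lon = rep(-140, 6), lat = rep(45, 6))
  expect_error(hrefBandwidth(same), "zero spread")
})

test_that("kernel UD normalizes, localizes and splits mass between clusters", {
  grid <- gridSpec(c(-150, -125), c(35, 55), 1)
  one <- kernelUD(data.frame(lon = -140.5, lat = 45.5), grid, h = 0.1)
  expect_equal(sum(one@density), 1, tolerance = 1e-12)
  expect_gt(max(one@density), 0.99)
  cc <- cellCenters(grid)
  top <- which.max(as.vector(one@density))
  expect_equal(c(cc$lon[top], cc$lat[top]), c(-140.5, 45.5))

  set.seed(62)
  for (k in 1:5) {
    pts <- data.frame(lon = runif(50, -149, -126), lat = runif(50, 36, 54))
    expect_equal(sum(kernelUD(pts, grid, h = runif(1, 0.3, 2))@density), 1,
                 tolerance = 1e-9)
  }

  two <- kernelUD(
    data.frame(lon = c(rnorm(100, -145, 0.5), rnorm(100, -130, 0.5)),
               lat = c(rnorm(100, 40, 0.5), rnorm(100, 50, 0.5))),
    grid, h = 0.7
  )
  west <- as.vector(outer(seq(35.5, 54.5), seq(-149.5, -125.5),
                          function(la, lo) lo < -137.5))
  expect_lt(abs(sum(two@density[matrix(west, nrow(two@density))]) - 0.5), 0.01)
})

test_that("isopleths select highest-mass cells with documented tie-breaks and spherical areas", {
  grid <- gridSpec(c(0, 3), c(-1.5, 1.5), 1) # 3x3 at the equator
  mass <- rep(0, 9)
  mass[c(1, 2, 4, 5)] <- 0.25
  ud <- udFromMass(grid, mass)
  hr <- udIsopleth(ud, 50)
  expect_equal(length(hr$cells), 2)
  expect_equal(hr$cells, c(1, 2)) # ties broken by linear cell index

  # one 1x1 degree cell at the equator: ~12,364 km2
  single <- rep(0, 9)
  single[5] <- 1 # middle cell straddles the equator
  hr1 <- udIsopleth(udFromMass(grid, single), 50)
  expect_equal(length(hr1$cells), 1)
  expect_lt(abs(hr1$areaKm2 - 12364) / 12364, 0.01)

  # nesting and boundary-vertex alignment on random surfaces
  set.seed(63)
  g2 <- gridSpec(c(-150, -140), c(40, 50), 1)
  for (k in 1:20) {
    ud2 <- udFromMass(g2, rexp(100))
    a50 <- udIsopleth(ud2, 50)
    a90 <- udIsopleth(ud2, 90)
    expect_lte(a50$areaKm2, a90$areaKm2)
  }
  ud3 <- udFromMass(g2, rexp(100))
  hr3 <- udIsopleth(ud3, 50)
  for (ring in hr3$rings) {
    expect_true(all(abs(ring[, "lon"] - round(ring[, "lon"])) < 1e-9))
    expect_true(all(abs(ring[, "lat"] - round(ring[, "lat"])) < 1e-9))
  }
  expect_error(udIsopleth(ud3, 0), "level")
})

test_that("UDOI satisfies its defining cases, symmetry and refinement convergence", {
  grid <- gridSpec(c(0, 10), c(-5, 5), 1)
  unif <- udFromMass(grid, ifelse(seq_len(100) <= 50, 1, 0))

  # identical uniform surfaces over the same region (tolerance covers the
  # cos-latitude variation of cell areas across the band)
  expect_equal(udoi(unif, unif), 1, tolerance = 1e-5)

  # disjoint supports
  other <- udFromMass(grid, ifelse(seq_len(100) > 50, 1, 0))
  expect_equal(udoi(unif, other), 0)

  # identical concentrated surfaces exceed 1; symmetric
  gA <- gaussianUD(grid, c(4, 0), 1)
  gB <- gaussianUD(grid, c(6, 0), 1.5)
  expect_gt(udoi(gA, gA), 1)
  expect_equal(udoi(gA, gB), udoi(gB, gA))

  # refinement towards an independent fine-grid numerical integration of
  # the same two Gaussian surfaces (0.05 degree quadrature with
  # cos-latitude cell areas)
  fineOracle <- function(mu1, mu2, s1, s2, lonR, latR, step = 0.05) {
    lon <- seq(lonR[1] + step / 2, lonR[2], by = step)
    lat <- seq(latR[1] + step / 2, latR[2], by = step)
    pts <- expand.grid(lon = lon, lat = lat)
    f <- function(mu, s) {
      exp(-((pts$lon - mu[1])^2 + (pts$lat - mu[2])^2) / (2 * s^2))
    }
    fa <- f(mu1, s1)
    fb <- f(mu2, s2)
    # cell masses ~ kernel value; per-km2 densities = mass / cell area
    areas <- (111.195 * step)^2 * cos(pts$lat * pi / 180)
    sum(areas) * sum((fa / sum(fa)) * (fb / sum(fb)) / areas)
  }
  vals <- vapply(c(2, 1, 0.5), function(cs) {
    g <- gridSpec(c(0, 20), c(-10, 10), cs)
    udoi(gaussianUD(g, c(8, 0), 2), gaussianUD(g, c(12, 0), 2))
  }, numeric(1))
  target <- fineOracle(c(8, 0), c(12, 0), 2, 2, c(0, 20), c(-10, 10))
  expect_lt(abs(vals[3] - target) / target, 0.01)
  expect_lt(abs(vals[3] - target), abs(vals[1] - target))

  expect_error(udoi(unif, gaussianUD(gridSpec(c(0, 10), c(-5, 5), 0.5),
                                     c(4, 0), 1)), "different grids")
})

test_that("colony aggregates pool tracks and behave under duplication", {
  grid <- smallOceanGrid()
  dates <- seq(as.Date("2014-11-10"), by = 1, length.out = 60)
  t1 <- simulateTrack(grid, oceanOrigin(grid, 80), dates, 1, seed = 71,
                      tagId = "t1")
  ud1 <- kernelUD(seasonFilter(t1), grid, source = "t1")
  agg1 <- colonyAggregateUD(list(t1), grid)
  expect_equal(agg1@density, ud1@density, tolerance = 1e-12)

  # duplicated identical tracks leave the normalized density unchanged
  # (bandwidth matched; the default ad hoc rule depends on pooled n)
  agg2 <- colonyAggregateUD(list(t1, t1), grid, h = ud1@smoothingH)
  expect_equal(agg2@density, ud1@density, tolerance = 1e-12)

  # aggregate 90% area at least the median individual 90% area
  t2 <- simulateTrack(grid, oceanOrigin(grid, 140), dates, 1, seed = 72,
                      tagId = "t2")
  t3 <- simulateTrack(grid, oceanOrigin(grid, 200), dates, 1, seed = 73,
                      tagId = "t3")
  tracks <- list(t1, t2, t3)
  indAreas <- vapply(tracks, function(t) {
    udIsopleth(kernelUD(seasonFilter(t), grid), 90)$areaKm2
  }, numeric(1))
  aggArea <- udIsopleth(colonyAggregateUD(tracks, grid), 90)$areaKm2
  expect_gte(aggArea, stats::median(indAreas))
})
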