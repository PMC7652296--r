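# Shared in-code fixtures and independent oracles.

# Two-population toy: pop a fixed for allele 1, pop b fixed for allele 2.
fixedDifferentGenotypes <- function(nPerPop = 5) {
  n <- 2 * nPerPop
  a <- matrix(rep(c(1L, 2L), each = nPerPop), n, 2)
  genotypeMatrix(a, a, populations = rep(c("a", "b"), each = nPerPop))
}

# Locus with gene-copy multiset {A:3, B:2, C:1} over three individuals.
toyRarefactionGenotypes <- function() {
  genotypeMatrix(
    alleleA = matrix(c(101L, 101L, 102L), 3, 1),
    alleleB = matrix(c(101L, 102L, 103L), 3, 1),
    populations = rep("p", 3), loci = "L1"
  )
}

# Small coastal test grid with a procedural sea mask.
smallOceanGrid <- function(cellSize = 1, seed = 2) {
  syntheticSeaMask(gridSpec(c(-150, -125), c(35, 55), cellSize), seed = seed)
}

# An ocean cell center well inside the small grid.
oceanOrigin <- function(grid, k = 100) {
  cc <- cellCenters(grid)[as.vector(seaMask(grid)), ]
  c(cc$lon[k], cc$lat[k])
}

# Independent solar ephemeris: Astronomical Almanac low-precision formula
# (different derivation from the package's NOAA polynomial algorithm).
almanacElevation <- function(lat, lon, time) {
  n <- as.numeric(time) / 86400 + 2440587.5 - 2451545
  L <- (280.460 + 0.9856474 * n) %% 360
  g <- ((357.528 + 0.9856003 * n) %% 360) * pi / 180
  lam <- (L + 1.915 * sin(g) + 0.020 * sin(2 * g)) * pi / 180
  eps <- (23.439 - 0.0000004 * n) * pi / 180
  ra <- atan2(cos(eps) * sin(lam), cos(lam)) # radians
  dec <- asin(sin(eps) * sin(lam))
  gmst <- (18.697374558 + 24.06570982441908 * n) %% 24 # hours
  ha <- (gmst * 15 + lon) * pi / 180 - ra
  el <- asin(sin(lat * pi / 180) * sin(dec) +
               cos(lat * pi / 180) * cos(dec) * cos(ha))
  el * 180 / pi
}

# Exhaustive rarefaction oracle: mean distinct alleles over all
# choose(N, g) gene-copy subsamples.
enumRarefaction <- function(copies, g) {
  idx <- utils::combn(length(copies), g)
  mean(apply(idx, 2, function(s) length(unique(copies[s]))))
}

# Build a UDSurface directly from a per-cell mass vector.
udFromMass <- function(grid, mass, source = "manual") {
  mass <- mass / sum(mass)
  new("UDSurface",
    grid = grid,
    density = matrix(mass, nrow(seaMask(grid)), ncol(seaMask(grid))),
    smoothingH = 1, source = source
  )
}

# Discretize an isotropic bivariate normal onto a grid (cell-center
# evaluation, mass-normalized) -- used for UDOI refinement oracles.
gaussianUD <- function(grid, mu, sigma) {
  cc <- cellCenters(grid)
  m <- exp(-((cc$lon - mu[1])^2 + (cc$lat - mu[2])^2) / (2 * sigma^2))
  udFromMass(grid, m)
}

# Mid-winter date sequence (well away from the equinoxes).
winterDates <- function(n = 40, start = "2014-12-01") {
  seq(as.Date(start), by = 1, length.out = n)
}

# Build a masked 5x5-grid decoding problem, fit it, and score both the
# decoded path and ALL nOcean^nDays paths by independent enumeration.
# Returns the decoded path score, the enumeration maximum, and the true
# simulated path's score.
viterbiEnumProblem <- function(nOcean, nDays, maskSeed = 99, simSeed = 12) {
  set.seed(maskSeed)
  mask <- matrix(FALSE, 5, 5)
  mask[sample.int(25, nOcean)] <- TRUE
  grid <- gridSpec(c(-140, -135), c(40, 45), 1, seaMask = mask)
  params <- hmmParams(movementBeta = 2, grid = grid)
  dates <- winterDates(nDays + 1)
  cc0 <- cellCenters(grid)[as.vector(mask), ]
  tr <- simulateTrack(grid, c(cc0$lon[1], cc0$lat[1]), dates,
                      stepScale = 1, seed = simSeed)
  lr0 <- simulateLight(tr, qShade = 0.1, sampleIntervalMin = 30,
                       groundtruthDays = 0, seed = simSeed + 1)
  lo <- as.POSIXct(paste(dates[1], "12:00:00"), tz = "UTC")
  hi <- as.POSIXct(paste(dates[nDays + 1], "12:00:00"), tz = "UTC")
  keep <- lr0@time >= lo & lr0@time < hi
  lr <- lightRecord(lr0@time[keep], lr0@lux[keep], tagId = "toy")
  segs <- daySegments(lr, params$lightThreshold)
  stopifnot(length(segs) == nDays,
            !any(vapply(segs, `[[`, logical(1), "missing")))
  fit <- fitTrack(lr, params)

  nS <- nrow(cc0)
  em <- lapply(segs, function(sg) {
    winterlink:::.emissionForCells(sg$light, sg$time, cc0$lat, cc0$lon,
                                   params)
  })
  logA <- winterlink:::.logTransition(grid, params$movementBeta)
  paths <- as.matrix(expand.grid(rep(list(seq_len(nS)), nDays)))
  score <- -log(nS) + em[[1]][paths[, 1]]
  for (d in 2:nDays) {
    score <- score + logA[cbind(paths[, d - 1], paths[, d])] +
      em[[d]][paths[, d]]
  }
  pathScore <- function(idx) {
    s <- -log(nS) + em[[1]][idx[1]]
    for (d in 2:nDays) s <- s + logA[idx[d - 1], idx[d]] + em[[d]][idx[d]]
    s
  }
  toIdx <- function(df) {
    vapply(seq_len(nrow(df)), function(i) {
      which(abs(cc0$lon - df$lon[i]) < 1e-9 & abs(cc0$lat - df$lat[i]) < 1e-9)
    }, integer(1))
  }
  segDates <- as.Date(vapply(segs, function(s) as.character(s$date), ""))
  td <- as.data.frame(tr)
  list(
    fitScore = pathScore(toIdx(as.data.frame(fit))),
    bestEnum = max(score),
    trueScore = pathScore(toIdx(td[match(segDates, td$date), ]))
  )
}

# Great-circle error between fitted and true track, in degrees of the
# grid (Euclidean in lon/lat cell units is adequate at test scale).
trackErrors <- function(fit, truth) {
  fd <- as.data.frame(fit)
  td <- as.data.frame(truth)
  m <- merge(fd[fd$status == "present", c("date", "lon", "lat")],
             td[, c("date", "lon", "lat")], by = "date")
  sqrt((m$lon.x - m$lon.y)^2 + (m$lat.x - m$lat.y)^2)
}
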