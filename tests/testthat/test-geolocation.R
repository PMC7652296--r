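test_that("solar elevation matches an independent ephemeris and basic geometry", {
  # equator, lon 0, equinox noon: sun near zenith
  eq <- solarElevation(0, 0, as.POSIXct("2015-03-20 12:00:00", tz = "UTC"))
  expect_lt(abs(eq - 90), 2)

  # spot checks against the Almanac low-precision formula
  set.seed(71)
  for (k in 1:10) {
    lat <- runif(1, -60, 60)
    lon <- runif(1, -180, 180)
    t <- as.POSIXct("2015-01-01", tz = "UTC") + runif(1, 0, 300 * 86400)
    expect_lt(abs(solarElevation(lat, lon, t) - almanacElevation(lat, lon, t)),
              0.3)
  }

  # local solar midnight below local solar noon
  for (lat in c(-50, -10, 20, 60)) {
    lon <- -140
    noon <- as.POSIXct("2014-12-21 00:00:00", tz = "UTC") +
      (12 - lon / 15) * 3600
    midnight <- noon + 12 * 3600
    expect_lt(solarElevation(lat, lon, midnight),
              solarElevation(lat, lon, noon))
  }
})

test_that("calibration recovers the simulated zenith and threshold", {
  grid <- smallOceanGrid()
  origin <- oceanOrigin(grid)
  tr <- simulateTrack(grid, origin, winterDates(8), stepScale = 0, seed = 1)

  lr <- simulateLight(tr, zenith = 96, threshold = 10, qShade = 0,
                      sampleIntervalMin = 5, seed = 2)
  cal <- calibrateLight(lr)
  expect_lt(abs(cal$zenith - 96), 0.5)
  expect_lte(cal$lightThreshold, 10)

  # moderate shading still recovers the zenith within a degree
  lrS <- simulateLight(tr, zenith = 96, threshold = 10, qShade = 0.15,
                       sampleIntervalMin = 5, seed = 3)
  expect_lt(abs(calibrateLight(lrS)$zenith - 96), 1)

  # an entirely dark record cannot be calibrated
  dark <- lightRecord(lr@time, rep(0, length(lr@lux)),
                      groundtruth = lr@groundtruth)
  expect_error(calibrateLight(dark), "calibration failed")
  # and a record with no groundtruth at all
  expect_error(calibrateLight(lightRecord(lr@time, lr@lux)), "groundtruth")
})

test_that("day segmentation applies the gap and no-information rules", {
  grid <- smallOceanGrid()
  tr <- simulateTrack(grid, oceanOrigin(grid), winterDates(4), 0, seed = 5)
  lr <- simulateLight(tr, qShade = 0, sampleIntervalMin = 10,
                      groundtruthDays = 0, seed = 1)
  segs <- daySegments(lr, 10)
  complete <- Filter(function(s) !s$missing, segs)
  expect_equal(length(complete), 3) # interior days; edge days are partial
  expect_equal(length(segs),
               length(unique(as.Date(lr@time + 12 * 3600, tz = "UTC"))))

  # a 3-h gap flags the day missing
  d2 <- as.Date(complete[[2]]$date)
  gapStart <- as.POSIXct(paste(d2, "18:00:00"), tz = "UTC")
  keep <- !(lr@time >= gapStart & lr@time < gapStart + 3 * 3600)
  segs2 <- daySegments(lightRecord(lr@time[keep], lr@lux[keep]), 10)
  flag <- vapply(segs2, function(s) identical(s$date, d2), logical(1))
  expect_true(segs2[[which(flag)]]$missing)

  # polar night: all-dark days carry no information -> missing
  allDark <- lightRecord(lr@time, rep(0, length(lr@lux)))
  expect_true(all(vapply(daySegments(allDark, 10), `[[`, logical(1),
                         "missing")))
})

test_that("emission log-likelihood has the stated closed form", {
  params <- hmmParams(grid = smallOceanGrid())
  qShade <- 1 / (1 + params$shadingAlpha)
  lat <- 45; lon <- -140
  times <- seq(as.POSIXct("2014-12-20 12:00:00", tz = "UTC"),
               by = 600, length.out = 144)
  expected <- solarElevation(lat, lon, times) > (90 - params$zenith)
  day <- list(time = times, light = expected)
  nDay <- sum(expected); nNight <- sum(!expected)
  ll <- emissionLoglik(day, lon, lat, params)
  expect_equal(ll, nDay * log(1 - qShade) + nNight * log(1 - 1e-6),
               tolerance = 1e-9)

  # one light sample during predicted night
  flip <- which(!expected)[1]
  day2 <- day
  day2$light[flip] <- TRUE
  expect_equal(emissionLoglik(day2, lon, lat, params) - ll,
               log(1e-6) - log(1 - 1e-6), tolerance = 1e-6)

  # the true cell dominates distant cells on clean mid-winter days
  far <- emissionLoglik(day, lon - 20, lat, params)
  expect_gt(ll, far)
})

test_that("transition kernel rows are normalized over ocean cells", {
  grid <- smallOceanGrid(cellSize = 2)
  logA <- winterlink:::.logTransition(grid, beta = 2)
  expect_equal(unname(rowSums(exp(logA))), rep(1, nrow(logA)),
               tolerance = 1e-9)
})

test_that("Viterbi decoding equals brute-force path enumeration on a masked toy", {
  # small instance: 9 ocean cells x 4 days (9^4 paths, exhaustive)
  pr <- viterbiEnumProblem(nOcean = 9, nDays = 4, maskSeed = 98,
                           simSeed = 12)
  expect_equal(pr$fitScore, pr$bestEnum, tolerance = 1e-9)
  # Viterbi optimality: decoded score >= the true simulated path's score
  expect_gte(pr$fitScore, pr$trueScore - 1e-9)
})

test_that("decoded tracks respect the sea mask and grid bounds", {
  grid <- smallOceanGrid()
  tr <- simulateTrack(grid, oceanOrigin(grid), winterDates(15), 1, seed = 31)
  lr <- simulateLight(tr, qShade = 0.1, seed = 32)
  params <- hmmParams(movementBeta = 2, grid = grid)
  fit <- fitTrack(lr, params)
  fd <- as.data.frame(fit)
  fd <- fd[!is.na(fd$lon), ]
  mask <- seaMask(grid)
  j <- floor((fd$lon - grid@lonRange[1]) / grid@cellSize) + 1
  i <- floor((fd$lat - grid@latRange[1]) / grid@cellSize) + 1
  expect_true(all(i >= 1 & i <= nrow(mask) & j >= 1 & j <= ncol(mask)))
  expect_true(all(mask[cbind(i, j)]))
})

test_that("two-pass fit excludes corrupted days and matches the direct fit when clean", {
  grid <- smallOceanGrid()
  dates <- winterDates(25)
  tr <- simulateTrack(grid, oceanOrigin(grid), dates, 0, seed = 41)
  lr0 <- simulateLight(tr, qShade = 0, groundtruthDays = 0, seed = 42)
  # trim to complete day-split segments so no edge day is partial
  lo <- as.POSIXct(paste(dates[1], "12:00:00"), tz = "UTC")
  hi <- as.POSIXct(paste(dates[25], "12:00:00"), tz = "UTC")
  keep <- lr0@time >= lo & lr0@time < hi
  lr <- lightRecord(lr0@time[keep], lr0@lux[keep], tagId = "clean")
  params <- hmmParams(movementBeta = 2, grid = grid)

  # clean record: pass-2 equals the direct fine fit, nothing excluded
  direct <- fitTrack(lr, params)
  two <- twoPassFit(lr, params)
  expect_equal(as.data.frame(two), as.data.frame(direct))
  expect_length(attr(two, "excludedDays"), 0)

  # corrupt 3 interior days with random light
  set.seed(43)
  corruptDates <- as.Date(c("2014-12-08", "2014-12-13", "2014-12-18"))
  lux <- lr@lux
  segLab <- as.Date(lr@time + 12 * 3600, tz = "UTC") - 1
  bad <- segLab %in% corruptDates
  lux[bad] <- sample(c(0, 80), sum(bad), TRUE)
  lrBad <- lightRecord(lr@time, lux, tagId = "bad")
  twoBad <- twoPassFit(lrBad, params)
  excl <- attr(twoBad, "excludedDays")
  expect_gte(length(excl), 2) # injected count +- 1
  expect_lte(length(excl), 4)
  expect_true(all(corruptDates %in% excl))
  fd <- as.data.frame(twoBad)
  expect_true(all(fd$status[fd$date %in% excl] == "excluded"))
  err <- trackErrors(twoBad, tr)
  expect_lte(stats::median(err), 2)
})
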