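# Threshold-free HMM geolocation: hidden states are daily grid cells
# restricted to ocean, the observation is each day's pattern of light and
# dark, decoding is Viterbi over a Gaussian movement kernel.

#' HMM geolocation parameters
#'
#' @param zenith solar zenith angle (degrees) defining the light/dark
#'   boundary; the sun is "up" for the light model when its elevation
#'   exceeds `90 - zenith`. Default 96 (civil-to-nautical twilight).
#' @param lightThreshold lux level separating light from dark (default 10).
#' @param shadingAlpha shading concentration; the probability that a
#'   daylight sample reads dark (sensor shaded) is `1 / (1 +
#'   shadingAlpha)`, so the default 5 gives moderate shading (~0.17).
#' @param movementBeta Gaussian daily step scale in grid cells; the
#'   transition kernel is truncated at `3 * movementBeta` cells.
#' @param grid a [GridSpec-class].
#' @return list of class `HMMParams`.
#' @export
hmmParams <- function(zenith = 96, lightThreshold = 10, shadingAlpha = 5,
                      movementBeta = 5, grid = gridSpec()) {
  stopifnot(zenith > 90, zenith < 108, lightThreshold > 0,
            shadingAlpha > 0, movementBeta > 0)
  structure(
    list(zenith = zenith, lightThreshold = lightThreshold,
         shadingAlpha = shadingAlpha, movementBeta = movementBeta,
         grid = grid),
    class = "HMMParams"
  )
}

#' Apparent solar elevation
#'
#' Geometric solar elevation angle from the NOAA solar position algorithm
#' (polynomial ephemeris in Julian centuries; equation of time and
#' declination from the geometric mean longitude, anomaly and obliquity).
#' Accuracy is a few hundredths of a degree over this century, well within
#' the tolerance the light model needs; atmospheric refraction is not
#' added (the calibrated zenith absorbs it).
#'
#' @param lat,lon position in degrees (vectors recycle against `time`).
#' @param time POSIXct (UTC).
#' @return elevation in degrees.
#' @export
solarElevation <- function(lat, lon, time) {
  stopifnot(all(abs(lat) <= 90))
  t <- as.numeric(as.POSIXct(time, tz = "UTC"))
  jd <- t / 86400 + 2440587.5
  jc <- (jd - 2451545) / 36525
  deg2rad <- pi / 180
  gmls <- (280.46646 + jc * (36000.76983 + jc * 0.0003032)) %% 360
  gmas <- 357.52911 + jc * (35999.05029 - 0.0001537 * jc)
  eccent <- 0.016708634 - jc * (0.000042037 + 0.0000001267 * jc)
  ctr <- sin(gmas * deg2rad) * (1.914602 - jc * (0.004817 + 0.000014 * jc)) +
    sin(2 * gmas * deg2rad) * (0.019993 - 0.000101 * jc) +
    sin(3 * gmas * deg2rad) * 0.000289
  truelong <- gmls + ctr
  app <- truelong - 0.00569 - 0.00478 * sin((125.04 - 1934.136 * jc) * deg2rad)
  mob <- 23 + (26 + (21.448 - jc * (46.815 + jc * (0.00059 - jc * 0.001813))) / 60) / 60
  obcorr <- mob + 0.00256 * cos((125.04 - 1934.136 * jc) * deg2rad)
  decl <- asin(sin(obcorr * deg2rad) * sin(app * deg2rad)) / deg2rad
  vary <- tan(obcorr / 2 * deg2rad)^2
  eqtime <- 4 / deg2rad * (
    vary * sin(2 * gmls * deg2rad) -
      2 * eccent * sin(gmas * deg2rad) +
      4 * eccent * vary * sin(gmas * deg2rad) * cos(2 * gmls * deg2rad) -
      0.5 * vary^2 * sin(4 * gmls * deg2rad) -
      1.25 * eccent^2 * sin(2 * gmas * deg2rad)
  )
  minsUTC <- (t %% 86400) / 60
  trueSolarTime <- (minsUTC + eqtime + 4 * lon) %% 1440
  ha <- trueSolarTime / 4 - 180
  ha <- ifelse(ha < -180, ha + 360, ha)
  cosz <- sin(lat * deg2rad) * sin(decl * deg2rad) +
    cos(lat * deg2rad) * cos(decl * deg2rad) * cos(ha * deg2rad)
  cosz <- pmin(1, pmax(-1, cosz))
  90 - acos(cosz) / deg2rad
}

#' Read a .lux light record
#'
#' Text dialect: header lines (any line not starting with a digit) are
#' ignored; data lines are `DD/MM/YYYY HH:MM:SS<TAB>lux`.
#'
#' @param file path to the .lux file.
#' @param tagId label (defaults to the file name).
#' @return a [LightRecord-class] (no groundtruth segments; attach those
#'   separately).
#' @export
readLux <- function(file, tagId = basename(file)) {
  lines <- readLines(file)
  dataLines <- grepl("^[0-9]", lines)
  parts <- strsplit(lines[dataLines], "\t", fixed = TRUE)
  stamp <- vapply(parts, `[`, "", 1)
  lux <- as.numeric(vapply(parts, `[`, "", 2))
  time <- as.POSIXct(stamp, format = "%d/%m/%Y %H:%M:%S", tz = "UTC")
  if (anyNA(time)) stop("unparseable timestamp in ", file)
  lightRecord(time, lux, tagId = tagId)
}

#' Write a LightRecord in the .lux text dialect
#'
#' @param record a [LightRecord-class].
#' @param file destination path.
#' @export
writeLux <- function(record, file) {
  stopifnot(is(record, "LightRecord"))
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(c("lux record", paste0("tag: ", record@tagId)), con)
  writeLines(paste0(format(record@time, "%d/%m/%Y %H:%M:%S", tz = "UTC"),
                    "\t", format(record@lux, trim = TRUE)), con)
}

#' Calibrate light threshold and zenith from a groundtruth segment
#'
#' Uses the record's groundtruth interval(s) (tag run at a known location
#' for at least three days). The threshold is the smallest level cleanly
#' separating night from day: the maximum lux observed during astronomical
#' night (solar elevation below -18 deg) at the known location, plus a
#' small margin. The zenith is estimated from the observed dawn and dusk
#' transitions — per day, the first and last light samples bounded by a
#' dark neighbour (interior light/dark flips are shading, not twilight) —
#' by mapping each transition midpoint to the sun's elevation at the known
#' location; the zenith is 90 minus the mean transition elevation.
#'
#' @param record a [LightRecord-class] with at least one groundtruth
#'   segment.
#' @return list with `zenith` and `lightThreshold`.
#' @export
calibrateLight <- function(record) {
  stopifnot(is(record, "LightRecord"))
  gt <- record@groundtruth
  if (!nrow(gt)) stop("no groundtruth segment present")
  elevAll <- numeric(0)
  luxAll <- numeric(0)
  timeAll <- as.POSIXct(character(), tz = "UTC")
  lonAll <- latAll <- numeric(0)
  for (s in seq_len(nrow(gt))) {
    sel <- record@time >= gt$start[s] & record@time <= gt$end[s]
    if (!any(sel)) next
    e <- solarElevation(gt$lat[s], gt$lon[s], record@time[sel])
    elevAll <- c(elevAll, e)
    luxAll <- c(luxAll, record@lux[sel])
    timeAll <- c(timeAll, record@time[sel])
    lonAll <- c(lonAll, rep(gt$lon[s], sum(sel)))
    latAll <- c(latAll, rep(gt$lat[s], sum(sel)))
  }
  if (!length(luxAll)) stop("groundtruth segments contain no samples")
  night <- elevAll < -18
  day <- elevAll > 0
  if (!any(day) || all(luxAll[day] <= max(luxAll[night], 0)))
    stop("calibration failed: record has no usable daylight samples")
  darkCeiling <- if (any(night)) max(luxAll[night]) else 0
  threshold <- darkCeiling + 1e-6
  light <- luxAll > threshold
  # dawn/dusk edges per day: the first and last light samples adjacent to
  # a dark sample; interior flips (sensor shading) carry no twilight
  # information and are ignored
  dayLab <- as.Date(timeAll + 12 * 3600, tz = "UTC")
  edges <- integer(0)
  for (d in split(seq_along(light), dayLab)) {
    lit <- d[light[d]]
    if (!length(lit)) next
    first <- min(lit)
    last <- max(lit)
    if (first > d[1] && !light[first - 1]) edges <- c(edges, first - 1L)
    if (last < d[length(d)] && !light[last + 1]) edges <- c(edges, last)
  }
  if (!length(edges)) stop("calibration failed: no light/dark transitions")
  transElev <- vapply(edges, function(i) {
    tm <- timeAll[i] + (as.numeric(timeAll[i + 1]) - as.numeric(timeAll[i])) / 2
    solarElevation(latAll[i], lonAll[i], tm)
  }, numeric(1))
  list(zenith = 90 - mean(transElev), lightThreshold = threshold)
}

#' Split a light record into per-day light/dark sequences
#'
#' Samples are binarized at the threshold and grouped into calendar days
#' relative to a day-split meridian (default 180 deg: the day boundary
#' falls at that meridian's local midnight, keeping the study window's
#' daylight period inside one segment). Each segment is labelled with the
#' UTC date its daylight period falls on (for the study's west-of-dateline
#' longitudes, the boundary date minus one), so decoded days line up with
#' UTC-dated truth. A day is flagged missing when more than one hour of
#' its expected samples (at the record's median sampling interval) is
#' absent, or when it carries no light information at all (entirely dark,
#' as in polar night, or entirely light).
#'
#' @param record a [LightRecord-class].
#' @param lightThreshold lux threshold (calibrated value).
#' @param splitMeridian day-split meridian in degrees east.
#' @return data.frame-backed list: one element per day with `date`,
#'   `time` (POSIXct), `light` (logical), `missing` (flag).
#' @export
daySegments <- function(record, lightThreshold = 10, splitMeridian = 180) {
  stopifnot(is(record, "LightRecord"))
  shift <- splitMeridian / 15 * 3600
  day <- as.Date(record@time + shift, tz = "UTC") - 1
  interval <- stats::median(diff(as.numeric(record@time)))
  expectedN <- floor(86400 / interval)
  idxByDay <- split(seq_along(day), day)
  lapply(names(idxByDay), function(d) {
    idx <- idxByDay[[d]]
    light <- record@lux[idx] > lightThreshold
    list(
      date = as.Date(d),
      time = record@time[idx],
      light = light,
      missing = (expectedN - length(idx)) * interval > 3600 ||
        !any(light) || all(light)
    )
  })
}

# Emission log-likelihood of one day's light/dark sequence for a set of
# candidate positions. lat/lon vectors define the cells; returns a vector.
.emissionForCells <- function(light, time, lat, lon, params) {
  qShade <- 1 / (1 + params$shadingAlpha)
  epsNight <- 1e-6
  nC <- length(lat)
  nS <- length(time)
  tnum <- rep(time, each = nC)
  elev <- solarElevation(rep(lat, nS), rep(lon, nS), tnum)
  expLight <- matrix(elev, nC, nS) > (90 - params$zenith)
  obsL <- matrix(rep(light, each = nC), nC, nS)
  ll <- ifelse(expLight,
    ifelse(obsL, log(1 - qShade), log(qShade)),
    ifelse(obsL, log(epsNight), log1p(-epsNight))
  )
  rowSums(ll)
}

#' Emission log-likelihood of a day's light pattern at one grid cell
#'
#' The observation model: at a sample time the sun is expected "up" at the
#' cell when its elevation exceeds `90 - zenith`. A daylight sample reads
#' dark with the shading probability `1/(1 + shadingAlpha)`; a night
#' sample reads light with probability 1e-6 (sensor noise floor). The
#' day's log-likelihood is the sum over samples.
#'
#' @param day one element of [daySegments()] output (`time`, `light`).
#' @param cellLon,cellLat cell center coordinates (degrees).
#' @param params [hmmParams()].
#' @return log-likelihood (scalar).
#' @export
emissionLoglik <- function(day, cellLon, cellLat, params) {
  .emissionForCells(day$light, day$time, cellLat, cellLon, params)
}

# Log transition matrix over ocean cells: Gaussian in cell distance,
# truncated at 3*beta cells, renormalized over ocean cells (rows sum to 1).
.logTransition <- function(grid, beta) {
  mask <- seaMask(grid)
  cc <- cellCenters(grid)[as.vector(mask), ]
  li <- round((cc$lon - grid@lonRange[1]) / grid@cellSize + 0.5)
  la <- round((cc$lat - grid@latRange[1]) / grid@cellSize + 0.5)
  d2 <- outer(li, li, "-")^2 + outer(la, la, "-")^2
  logk <- -d2 / (2 * beta^2)
  logk[d2 > (3 * beta)^2] <- -Inf
  # renormalize rows over ocean states
  lse <- apply(logk, 1, function(r) {
    m <- max(r)
    m + log(sum(exp(r - m)))
  })
  logk - lse
}

#' Fit the most likely daily track by Viterbi decoding
#'
#' Hidden states are the ocean cells of the grid; the per-day emission is
#' [emissionLoglik()] and transitions follow a truncated Gaussian movement
#' kernel with daily step scale `movementBeta` (in cells). Days flagged
#' missing (and any dates listed in `exclude`) contribute no emission term
#' and are bridged by the movement model alone.
#'
#' @param record a [LightRecord-class].
#' @param params [hmmParams()] carrying the grid and sea mask.
#' @param exclude optional Date vector of days to decode without emission
#'   and flag `excluded` in the output.
#' @return a [DailyTrack-class].
#' @export
fitTrack <- function(record, params, exclude = as.Date(character())) {
  stopifnot(inherits(params, "HMMParams"))
  grid <- params$grid
  segs <- daySegments(record, params$lightThreshold)
  mask <- seaMask(grid)
  cc <- cellCenters(grid)[as.vector(mask), ]
  nS <- nrow(cc)
  logA <- .logTransition(grid, params$movementBeta)
  nD <- length(segs)
  status <- character(nD)
  emit <- vector("list", nD)
  for (d in seq_len(nD)) {
    sg <- segs[[d]]
    if (sg$date %in% exclude) {
      status[d] <- "excluded"
    } else if (sg$missing) {
      status[d] <- "missing"
    } else {
      status[d] <- "present"
      emit[[d]] <- .emissionForCells(sg$light, sg$time, cc$lat, cc$lon, params)
    }
  }
  # Viterbi
  delta <- rep(-log(nS), nS)
  if (!is.null(emit[[1]])) delta <- delta + emit[[1]]
  back <- matrix(NA_integer_, nD, nS)
  for (d in seq_len(nD)[-1]) {
    m <- delta + logA # column j: delta_i + logA[i, j]
    arg <- max.col(t(m), ties.method = "first")
    delta <- m[cbind(arg, seq_len(nS))]
    if (all(!is.finite(delta)))
      stop("no feasible path at day ", as.character(segs[[d]]$date))
    if (!is.null(emit[[d]])) delta <- delta + emit[[d]]
    back[d, ] <- arg
  }
  path <- integer(nD)
  path[nD] <- which.max(delta)
  for (d in rev(seq_len(nD - 1))) path[d] <- back[d + 1, path[d + 1]]
  days <- data.frame(
    date = as.Date(vapply(segs, function(s) as.character(s$date), "")),
    lon = cc$lon[path], lat = cc$lat[path], status = status,
    stringsAsFactors = FALSE
  )
  days$lon[days$status == "excluded"] <- NA_real_
  days$lat[days$status == "excluded"] <- NA_real_
  dailyTrack(days, tagId = record@tagId)
}

#' Two-pass track fit: coarse screening, then fine decoding
#'
#' Pass one fits the record on a coarse (default 4 deg) version of the
#' grid and marks days to exclude: days flagged missing, days whose best
#' per-sample emission log-likelihood falls strictly below the 1st
#' percentile of the record's per-day best values, and days implausibly
#' far below the record median (more than 1 nat per sample — light
#' patterns no cell can reconcile, e.g. light readings in the middle of
#' the night). Pass two refits on the fine grid with those days excluded;
#' the pass-two track is returned.
#'
#' @param record a [LightRecord-class].
#' @param params [hmmParams()] with the fine grid (e.g. 1 deg).
#' @param coarseCellSize pass-one cell size in degrees (default 4).
#' @return a [DailyTrack-class]; the excluded dates are attached as
#'   attribute `"excludedDays"`.
#' @export
twoPassFit <- function(record, params, coarseCellSize = 4) {
  stopifnot(inherits(params, "HMMParams"))
  fine <- params$grid
  coarse <- .coarsenGrid(fine, coarseCellSize)
  segs <- daySegments(record, params$lightThreshold)
  cc <- cellCenters(coarse)[as.vector(seaMask(coarse)), ]
  best <- rep(NA_real_, length(segs))
  missing <- logical(length(segs))
  for (d in seq_along(segs)) {
    sg <- segs[[d]]
    missing[d] <- sg$missing
    if (!sg$missing) {
      perSample <- .emissionForCells(sg$light, sg$time, cc$lat, cc$lon, params)
      best[d] <- max(perSample) / length(sg$light)
    }
  }
  q01 <- stats::quantile(best, 0.01, na.rm = TRUE, names = FALSE, type = 1)
  med <- stats::median(best, na.rm = TRUE)
  bad <- !is.na(best) & (best < q01 - 1e-12 | best < med - 1)
  excl <- as.Date(vapply(segs, function(s) as.character(s$date),
                         ""))[missing | bad]
  if (length(excl) == length(segs)) stop("all days excluded")
  out <- fitTrack(record, params, exclude = as.Date(excl))
  attr(out, "excludedDays") <- as.Date(excl)
  out
}

# Coarse version of a grid: cell is ocean if any covered fine cell is.
.coarsenGrid <- function(grid, cellSize) {
  f <- cellSize / grid@cellSize
  stopifnot(abs(f - round(f)) < 1e-9)
  f <- round(f)
  mask <- seaMask(grid)
  nlat <- floor(nrow(mask) / f)
  nlon <- floor(ncol(mask) / f)
  cm <- matrix(FALSE, nlat, nlon)
  for (i in seq_len(nlat)) {
    for (j in seq_len(nlon)) {
      cm[i, j] <- any(mask[((i - 1) * f + 1):(i * f), ((j - 1) * f + 1):(j * f)])
    }
  }
  gridSpec(
    lonRange = c(grid@lonRange[1], grid@lonRange[1] + nlon * cellSize),
    latRange = c(grid@latRange[1], grid@latRange[1] + nlat * cellSize),
    cellSize = cellSize, seaMask = cm
  )
}

#' Write a DailyTrack as CSV
#'
#' @param track a [DailyTrack-class].
#' @param file destination path.
#' @export
writeTrack <- function(track, file) {
  stopifnot(is(track, "DailyTrack"))
  utils::write.csv(as.data.frame(track), file, row.names = FALSE, na = "")
}
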