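# Seed-deterministic generators for every input the pipeline consumes —
# genotypes with known differentiation, ocean random-walk tracks, light
# records, a procedural sea mask — plus the packaged transcriptions of the
# published study-system summary tables.

#' Simulate multi-population microsatellite genotypes (Balding-Nichols)
#'
#' Island-model genotypes with a known differentiation target: per
#' population and locus, allele frequencies are drawn from a Dirichlet
#' with mean equal to the ancestral frequencies and concentration
#' `(1 - F)/F`, so the expected F_ST against the ancestral pool is `F`
#' (`F = 0` uses the ancestral frequencies exactly). Individuals are two
#' independent gamete draws; genotypes are masked missing at `missingRate`.
#' The defaults emulate the study's sampling design: 18 colonies with the
#' published per-colony sample sizes, 10 loci, modest within-region
#' differentiation (F = 0.04) and a deep east-west split produced by
#' giving the first `nWest` populations their own ancestral frequency
#' spectrum.
#'
#' @param nPops number of populations.
#' @param nPerPop individuals per population (scalar or vector; default:
#'   the study's per-colony sample sizes when `nPops = 18`, else 20).
#' @param nLoci,nAlleles loci count and alleles per locus.
#' @param F divergence from the ancestral pool (scalar or per-population).
#' @param nWest first `nWest` populations form a diverged "west" block
#'   with independent ancestral frequencies (0 disables the split).
#' @param missingRate per-genotype missing probability.
#' @param seed integer seed; output is byte-identical given `cfg` + seed.
#' @return list with `genotypes` ([GenotypeMatrix-class]), `F`,
#'   `ancestral` (per-locus frequency list), `popFreqs`.
#' @export
simulateGenotypes <- function(nPops = 18, nPerPop = NULL, nLoci = 10,
                              nAlleles = 8, F = 0.04, nWest = 5,
                              missingRate = 0.02, seed = 1) {
  set.seed(seed)
  if (is.null(nPerPop)) {
    nPerPop <- if (nPops == 18) {
      c(20, 10, 25, 21, 12, 18, 50, 22, 26, 53, 18, 26, 27, 30, 18, 19, 7, 22)
    } else rep(20, nPops)
  }
  nPerPop <- rep_len(nPerPop, nPops)
  F <- rep_len(F, nPops)
  rdirichlet <- function(alpha) {
    x <- stats::rgamma(length(alpha), shape = alpha)
    if (sum(x) <= 0) x <- alpha # degenerate draw guard
    x / sum(x)
  }
  ancestral <- lapply(seq_len(nLoci), function(l) {
    p <- rdirichlet(rep(1.5, nAlleles))
    names(p) <- as.character(100 + 2 * seq_len(nAlleles)) # repeat sizes
    p
  })
  ancestralWest <- lapply(seq_len(nLoci), function(l) {
    p <- rdirichlet(rep(1.5, nAlleles))
    names(p) <- names(ancestral[[l]])
    p
  })
  pops <- sprintf("pop%02d", seq_len(nPops))
  popFreqs <- lapply(seq_len(nPops), function(k) {
    anc <- if (nWest > 0 && k <= nWest) ancestralWest else ancestral
    lapply(seq_len(nLoci), function(l) {
      if (F[k] <= 0) return(anc[[l]])
      conc <- (1 - F[k]) / F[k]
      p <- rdirichlet(anc[[l]] * conc)
      names(p) <- names(anc[[l]])
      p
    })
  })
  nTot <- sum(nPerPop)
  a <- b <- matrix(NA_integer_, nTot, nLoci)
  popLab <- rep(pops, nPerPop)
  sizes <- as.integer(names(ancestral[[1]]))
  rowEnd <- cumsum(nPerPop)
  rowStart <- rowEnd - nPerPop + 1L
  for (k in seq_len(nPops)) {
    rows <- rowStart[k]:rowEnd[k]
    for (l in seq_len(nLoci)) {
      p <- popFreqs[[k]][[l]]
      a[rows, l] <- sample(sizes, length(rows), replace = TRUE, prob = p)
      b[rows, l] <- sample(sizes, length(rows), replace = TRUE, prob = p)
    }
  }
  if (missingRate > 0) {
    miss <- matrix(stats::runif(nTot * nLoci) < missingRate, nTot, nLoci)
    a[miss] <- NA_integer_
    b[miss] <- NA_integer_
  }
  g <- genotypeMatrix(a, b, populations = popLab,
                      individuals = sprintf("ind%04d", seq_len(nTot)),
                      loci = sprintf("L%02d", seq_len(nLoci)))
  list(genotypes = g, F = F, ancestral = ancestral, popFreqs = popFreqs)
}

#' Procedural land/sea mask
#'
#' Fabricates a coastline so tests need no geographic download: land lies
#' east of a wiggly meridian (a half-plane plus smooth sinusoidal noise),
#' emulating the eastern Pacific margin. Deterministic given the seed.
#'
#' @param grid a [GridSpec-class] (mask slot ignored).
#' @param coastLon mean coastline longitude (default 15 degrees in from
#'   the eastern edge).
#' @param amplitude coastline wiggle amplitude in degrees.
#' @param seed integer seed for the wiggle phases.
#' @return the grid with its `seaMask` replaced.
#' @export
syntheticSeaMask <- function(grid, coastLon = NULL, amplitude = 4, seed = 1) {
  set.seed(seed)
  if (is.null(coastLon)) coastLon <- grid@lonRange[2] - 15
  nlat <- nrow(seaMask(grid))
  nlon <- ncol(seaMask(grid))
  lat <- grid@latRange[1] + (seq_len(nlat) - 0.5) * grid@cellSize
  lon <- grid@lonRange[1] + (seq_len(nlon) - 0.5) * grid@cellSize
  ph <- stats::runif(3, 0, 2 * pi)
  coast <- coastLon + amplitude * (sin(lat / 7 + ph[1]) +
                                     0.5 * sin(lat / 3 + ph[2]) +
                                     0.25 * sin(lat / 1.5 + ph[3]))
  mask <- outer(coast, lon, function(cst, ln) ln < cst)
  gridSpec(grid@lonRange, grid@latRange, grid@cellSize, seaMask = mask)
}

#' Simulate a daily movement track on ocean cells
#'
#' Biased random walk over the grid's ocean cells: each day the bird moves
#' to an ocean cell within `stepScale` cells of its position, weighted by
#' a Gaussian step kernel and, when `attraction` is given, by proximity to
#' an attraction center (wintering ground).
#'
#' @param grid a [GridSpec-class] with a sea mask.
#' @param origin `c(lon, lat)` start position (must fall in an ocean
#'   cell).
#' @param dates Date vector of track days.
#' @param stepScale daily step scale in cells (0 = stationary).
#' @param attraction optional `c(lon, lat)` attraction center.
#' @param attractionStrength bias weight (degrees^-1 scale, default 0.15).
#' @param seed integer seed.
#' @param tagId label.
#' @return a [DailyTrack-class] with all days `present`.
#' @export
simulateTrack <- function(grid, origin, dates, stepScale = 2,
                          attraction = NULL, attractionStrength = 0.15,
                          seed = 1, tagId = "sim") {
  set.seed(seed)
  mask <- seaMask(grid)
  cc <- cellCenters(grid)
  nlat <- nrow(mask)
  toIdx <- function(lon, lat) {
    j <- floor((lon - grid@lonRange[1]) / grid@cellSize) + 1
    i <- floor((lat - grid@latRange[1]) / grid@cellSize) + 1
    c(i, j)
  }
  pos <- toIdx(origin[1], origin[2])
  if (!mask[pos[1], pos[2]]) stop("origin is not an ocean cell")
  lin <- function(i, j) (j - 1L) * nlat + i
  out <- matrix(NA_real_, length(dates), 2)
  r <- max(1, ceiling(3 * max(stepScale, 1e-9)))
  for (d in seq_along(dates)) {
    out[d, ] <- c(cc$lon[lin(pos[1], pos[2])], cc$lat[lin(pos[1], pos[2])])
    if (d == length(dates)) break
    if (stepScale <= 0) next
    di <- rep(-r:r, times = 2 * r + 1)
    dj <- rep(-r:r, each = 2 * r + 1)
    ii <- pos[1] + di
    jj <- pos[2] + dj
    ok <- ii >= 1 & ii <= nlat & jj >= 1 & jj <= ncol(mask)
    ok[ok] <- mask[cbind(ii[ok], jj[ok])]
    ok <- ok & (di^2 + dj^2) <= r^2
    if (!any(ok)) stop("trapped walker: no ocean cell in reach at day ", d)
    w <- exp(-(di[ok]^2 + dj[ok]^2) / (2 * max(stepScale, 1e-9)^2))
    if (!is.null(attraction)) {
      latC <- grid@latRange[1] + (ii[ok] - 0.5) * grid@cellSize
      lonC <- grid@lonRange[1] + (jj[ok] - 0.5) * grid@cellSize
      distA <- sqrt((lonC - attraction[1])^2 + (latC - attraction[2])^2)
      w <- w * exp(-attractionStrength * distA)
    }
    pick <- sample.int(length(w), 1, prob = w)
    pos <- c(ii[ok][pick], jj[ok][pick])
  }
  dailyTrack(
    data.frame(date = dates, lon = out[, 1], lat = out[, 2],
               status = "present", stringsAsFactors = FALSE),
    tagId = tagId
  )
}

#' Simulate a light record from a daily track
#'
#' Inverse of the geolocation emission model: at each sample time the tag
#' reads a bright constant when the sun at the day's true position is
#' above the twilight elevation (`90 - zenith`) and the sensor is not
#' shaded (Bernoulli `qShade`), else a dark constant. A groundtruth
#' segment of `groundtruthDays` days at the track's first position is
#' prepended, emulating the pre-deployment calibration run.
#'
#' @param track a [DailyTrack-class] (true positions).
#' @param zenith,threshold emission geometry and the lux level the bright
#'   constant must exceed (bright = `8 * threshold`, dark = 0).
#' @param qShade per-sample shading probability.
#' @param sampleIntervalMin sampling interval in minutes.
#' @param groundtruthDays length of the prepended calibration segment.
#' @param seed integer seed.
#' @return a [LightRecord-class] with the groundtruth segment attached.
#' @export
simulateLight <- function(track, zenith = 96, threshold = 10, qShade = 0,
                          sampleIntervalMin = 10, groundtruthDays = 3,
                          seed = 1) {
  stopifnot(is(track, "DailyTrack"))
  set.seed(seed)
  days <- as.data.frame(track)
  days <- days[!is.na(days$lon), ]
  bright <- 8 * threshold
  gtStart <- min(days$date) - groundtruthDays
  t0 <- as.POSIXct(paste(gtStart, "00:00:00"), tz = "UTC")
  t1 <- as.POSIXct(paste(max(days$date) + 1, "00:00:00"), tz = "UTC")
  times <- seq(t0, t1 - 1, by = sampleIntervalMin * 60)
  # position at each sample: groundtruth location before deployment,
  # else the day's true cell
  sampleDate <- as.Date(times, tz = "UTC")
  idx <- match(sampleDate, days$date)
  lon <- ifelse(is.na(idx), days$lon[1], days$lon[idx])
  lat <- ifelse(is.na(idx), days$lat[1], days$lat[idx])
  elev <- solarElevation(lat, lon, times)
  up <- elev > (90 - zenith)
  shaded <- stats::runif(length(times)) < qShade
  lux <- ifelse(up & !shaded, bright, 0)
  lightRecord(
    times, lux, tagId = track@tagId,
    groundtruth = data.frame(
      start = t0,
      end = as.POSIXct(paste(min(days$date), "00:00:00"), tz = "UTC") - 1,
      lon = days$lon[1], lat = days$lat[1]
    )
  )
}

#' Transcribed published summary tables for the study system
#'
#' Loads the packaged transcriptions of the rhinoceros auklet study
#' tables: the colony table (18 colonies with coordinates and breeding
#' population sizes), the 17-colony pairwise F_ST (lower triangle) /
#' F'ST (upper triangle) matrix, the colony and individual home-range
#' areas, the 12-colony pairwise UDOI matrix, and the geolocator
#' deployment/retrieval counts. Matrix labels are colony abbreviations;
#' the UDOI table's colony names (including the "Farallones" alias for
#' Southeast Farallon) are resolved through the colony table.
#'
#' @return list with `colonies`, `fst`, `fstPrime`, `udoi`
#'   ([LabeledMatrix-class]), `homeRanges`, `deployments` (data.frames).
#' @export
loadStudyTables <- function() {
  ext <- function(f) system.file("extdata", f, package = "winterlink",
                                 mustWork = TRUE)
  colonies <- utils::read.csv(ext("colonies.csv"), check.names = FALSE,
                              fileEncoding = "UTF-8")
  fst <- readLabeledMatrix(ext("pairwise_fst.csv"), triangle = "lower",
                           statName = "fst")
  fstPrime <- readLabeledMatrix(ext("pairwise_fst.csv"), triangle = "upper",
                                statName = "fst_prime")
  udoiRaw <- readLabeledMatrix(ext("udoi.csv"), triangle = "upper",
                               statName = "udoi")
  alias <- c(Farallones = "Southeast Farallon", Matsumae = "Matsumae-Kojima")
  nm <- labels(udoiRaw)
  nm <- ifelse(nm %in% names(alias), alias[nm], nm)
  ab <- colonies$abbrev[match(nm, colonies$name)]
  if (anyNA(ab)) stop("unresolved colony name in UDOI table")
  udoiM <- labeledMatrix(as.matrix(udoiRaw), statName = "udoi", labels = ab)
  homeRanges <- utils::read.csv(ext("homerange_areas.csv"),
                                fileEncoding = "UTF-8")
  deployments <- utils::read.csv(ext("deployments.csv"),
                                 fileEncoding = "UTF-8")
  list(colonies = colonies, fst = fst, fstPrime = fstPrime, udoi = udoiM,
       homeRanges = homeRanges, deployments = deployments)
}
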