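# Constructors, accessors and show methods for the core containers.

#' Construct a GenotypeMatrix
#'
#' @param alleleA,alleleB integer matrices (individuals x loci) of allele
#'   labels; use `NA` for missing genotypes (both matrices).
#' @param populations population label per individual (character or factor).
#' @param individuals,loci optional dimnames; taken from `alleleA` otherwise.
#' @return a [GenotypeMatrix-class] object.
#' @examples
#' g <- genotypeMatrix(
#'   alleleA = matrix(c(120L, 120L), 2, 1),
#'   alleleB = matrix(c(124L, 120L), 2, 1),
#'   populations = c("A", "A"),
#'   individuals = c("i1", "i2"), loci = "L1"
#' )
#' nInd(g)
#' @export
genotypeMatrix <- function(alleleA, alleleB, populations,
                           individuals = rownames(alleleA),
                           loci = colnames(alleleA)) {
  alleleA <- as.matrix(alleleA)
  alleleB <- as.matrix(alleleB)
  storage.mode(alleleA) <- "integer"
  storage.mode(alleleB) <- "integer"
  if (is.null(individuals)) individuals <- paste0("ind", seq_len(nrow(alleleA)))
  if (is.null(loci)) loci <- paste0("locus", seq_len(ncol(alleleA)))
  dimnames(alleleA) <- dimnames(alleleB) <- list(individuals, loci)
  # a factor input keeps its declared levels (a population may be empty)
  pops <- if (is.factor(populations)) populations else factor(populations)
  new("GenotypeMatrix", alleleA = alleleA, alleleB = alleleB,
      populations = pops)
}

#' @rdname GenotypeMatrix-class
#' @export
setMethod("nInd", "GenotypeMatrix", function(x) nrow(x@alleleA))

#' @rdname GenotypeMatrix-class
#' @export
setMethod("nLoci", "GenotypeMatrix", function(x) ncol(x@alleleA))

#' @rdname GenotypeMatrix-class
#' @export
setMethod("lociNames", "GenotypeMatrix", function(x) colnames(x@alleleA))

#' @rdname GenotypeMatrix-class
#' @export
setMethod("indNames", "GenotypeMatrix", function(x) rownames(x@alleleA))

#' @rdname GenotypeMatrix-class
#' @export
setMethod("populations", "GenotypeMatrix", function(x) x@populations)

#' @rdname GenotypeMatrix-class
#' @export
setMethod("popNames", "GenotypeMatrix", function(x) levels(x@populations))

#' Subset a GenotypeMatrix by individuals (i) and loci (j)
#'
#' @param x a `GenotypeMatrix`
#' @param i,j index vectors over individuals and loci
#' @param ... ignored
#' @param drop ignored (always `FALSE` semantics)
#' @export
setMethod("[", "GenotypeMatrix", function(x, i, j, ..., drop = FALSE) {
  if (missing(i)) i <- seq_len(nInd(x))
  if (missing(j)) j <- seq_len(nLoci(x))
  genotypeMatrix(
    x@alleleA[i, j, drop = FALSE], x@alleleB[i, j, drop = FALSE],
    populations = as.character(x@populations)[i]
  )
})

setMethod("show", "GenotypeMatrix", function(object) {
  cat(sprintf(
    "GenotypeMatrix: %d individuals x %d loci, %d populations\n",
    nInd(object), nLoci(object), nlevels(object@populations)
  ))
  miss <- mean(is.na(object@alleleA))
  cat(sprintf("  missing genotypes: %.1f%%\n", 100 * miss))
  cat("  populations:", paste(utils::head(popNames(object), 8), collapse = ", "),
      if (nlevels(object@populations) > 8) "..." else "", "\n")
})

#' Subset a GenotypeMatrix to whole populations
#'
#' @param x a `GenotypeMatrix`
#' @param pops character vector of population labels to keep
#' @return a `GenotypeMatrix` restricted to those populations.
#' @export
subsetPopulations <- function(x, pops) {
  stopifnot(is(x, "GenotypeMatrix"))
  bad <- setdiff(pops, popNames(x))
  if (length(bad)) stop("unknown population(s): ", paste(bad, collapse = ", "))
  x[as.character(x@populations) %in% pops, ]
}

#' Construct a LabeledMatrix
#'
#' @param values square numeric matrix (symmetric off-diagonal); dimnames
#'   supply the labels unless `labels` is given.
#' @param statName statistic tag, e.g. `"fst"`, `"fst_prime"`, `"udoi"`,
#'   `"distance_km"`.
#' @param labels optional label vector.
#' @param pvalues optional symmetric p-value matrix.
#' @return a [LabeledMatrix-class] object.
#' @export
labeledMatrix <- function(values, statName, labels = rownames(values),
                          pvalues = NULL) {
  values <- as.matrix(values)
  if (!is.null(labels)) dimnames(values) <- list(labels, labels)
  diag(values) <- NA_real_
  if (is.null(pvalues)) {
    pvalues <- matrix(numeric(), 0, 0)
  } else {
    pvalues <- as.matrix(pvalues)
    dimnames(pvalues) <- dimnames(values)
  }
  new("LabeledMatrix", values = values, statName = statName, pvalues = pvalues)
}

#' @rdname LabeledMatrix-class
#' @export
setMethod("statName", "LabeledMatrix", function(x) x@statName)

#' @rdname LabeledMatrix-class
#' @export
setMethod("pvalues", "LabeledMatrix", function(x) x@pvalues)

#' @rdname LabeledMatrix-class
#' @export
setMethod("labels", "LabeledMatrix", function(object, ...) rownames(object@values))

#' Coerce a LabeledMatrix to a plain matrix
#' @param x a `LabeledMatrix`
#' @param ... ignored
#' @export
setMethod("as.matrix", "LabeledMatrix", function(x, ...) x@values)

#' Subset a LabeledMatrix to a label set
#' @param x a `LabeledMatrix`
#' @param i label or index vector (applied to rows and columns jointly)
#' @param j,...,drop ignored
#' @export
setMethod("[", "LabeledMatrix", function(x, i, j, ..., drop = FALSE) {
  v <- x@values[i, i, drop = FALSE]
  p <- if (length(x@pvalues)) x@pvalues[i, i, drop = FALSE] else NULL
  labeledMatrix(v, statName = x@statName, pvalues = p)
})

setMethod("show", "LabeledMatrix", function(object) {
  cat(sprintf(
    "LabeledMatrix '%s': %d labels%s\n", object@statName,
    nrow(object@values), if (length(object@pvalues)) " (with p-values)" else ""
  ))
  off <- object@values[upper.tri(object@values)]
  off <- off[!is.na(off)]
  if (length(off))
    cat(sprintf("  off-diagonal range: [%.4g, %.4g]\n", min(off), max(off)))
})

#' Paired off-diagonal values of a LabeledMatrix
#'
#' Returns one row per unordered label pair (sorted labels, deterministic
#' order), with the pair's value; `NA` entries are kept so callers can
#' decide how to treat missing pairs.
#'
#' @param m a `LabeledMatrix`
#' @return data.frame with columns `label1`, `label2`, `value`.
#' @export
pairValues <- function(m) {
  stopifnot(is(m, "LabeledMatrix"))
  lab <- sort(labels(m))
  pr <- t(utils::combn(lab, 2))
  data.frame(
    label1 = pr[, 1], label2 = pr[, 2],
    value = m@values[pr], stringsAsFactors = FALSE
  )
}

#' Construct a GridSpec
#'
#' @param lonRange,latRange grid extent in degrees (defaults cover the
#'   eastern North Pacific study window).
#' @param cellSize cell edge in degrees.
#' @param seaMask logical `[nLat, nLon]` matrix, `TRUE` = ocean; default all
#'   ocean.
#' @return a [GridSpec-class] object.
#' @export
gridSpec <- function(lonRange = c(-180, -100), latRange = c(10, 65),
                     cellSize = 1, seaMask = NULL) {
  nlon <- round(diff(lonRange) / cellSize)
  nlat <- round(diff(latRange) / cellSize)
  if (is.null(seaMask)) seaMask <- matrix(TRUE, nlat, nlon)
  new("GridSpec",
    lonRange = as.numeric(lonRange), latRange = as.numeric(latRange),
    cellSize = as.numeric(cellSize), seaMask = seaMask
  )
}

#' @rdname GridSpec-class
#' @export
setMethod("seaMask", "GridSpec", function(x) x@seaMask)

#' @rdname GridSpec-class
#' @export
setMethod("dim", "GridSpec", function(x) dim(x@seaMask))

#' @rdname GridSpec-class
#' @export
setMethod("cellCenters", "GridSpec", function(x) {
  nlat <- nrow(x@seaMask); nlon <- ncol(x@seaMask)
  lon <- x@lonRange[1] + (seq_len(nlon) - 0.5) * x@cellSize
  lat <- x@latRange[1] + (seq_len(nlat) - 0.5) * x@cellSize
  # linear cell index = column-major order of the [nLat, nLon] matrices
  # (latitude varying fastest); this is the documented tie-break order.
  data.frame(lon = rep(lon, each = nlat), lat = rep(lat, nlon))
})

setMethod("cellAreasKm2", "GridSpec", function(x) {
  cc <- cellCenters(x)
  kmPerDeg <- 111.195
  (kmPerDeg * x@cellSize)^2 * cos(cc$lat * pi / 180)
})

setMethod("show", "GridSpec", function(object) {
  d <- dim(object@seaMask)
  cat(sprintf(
    "GridSpec: %g deg cells, lon [%g, %g], lat [%g, %g] (%d x %d; %d ocean)\n",
    object@cellSize, object@lonRange[1], object@lonRange[2],
    object@latRange[1], object@latRange[2], d[1], d[2], sum(object@seaMask)
  ))
})

#' Construct a LightRecord
#'
#' @param time POSIXct sample times (UTC), strictly increasing.
#' @param lux light levels (>= 0).
#' @param tagId tag label.
#' @param groundtruth optional data.frame (`start`, `end`, `lon`, `lat`).
#' @return a [LightRecord-class] object.
#' @export
lightRecord <- function(time, lux, tagId = "tag",
                        groundtruth = data.frame(
                          start = as.POSIXct(character(), tz = "UTC"),
                          end = as.POSIXct(character(), tz = "UTC"),
                          lon = numeric(), lat = numeric()
                        )) {
  new("LightRecord",
    time = as.POSIXct(time, tz = "UTC"), lux = as.numeric(lux),
    tagId = tagId, groundtruth = groundtruth
  )
}

setMethod("show", "LightRecord", function(object) {
  cat(sprintf(
    "LightRecord '%s': %d samples, %s to %s UTC, %d groundtruth segment(s)\n",
    object@tagId, length(object@lux),
    format(min(object@time)), format(max(object@time)),
    nrow(object@groundtruth)
  ))
})

#' Construct a DailyTrack
#'
#' @param days data.frame with columns `date`, `lon`, `lat`, `status`.
#' @param tagId tag label.
#' @return a [DailyTrack-class] object.
#' @export
dailyTrack <- function(days, tagId = "tag") {
  days$date <- as.Date(days$date)
  new("DailyTrack", days = days, tagId = tagId)
}

#' @rdname DailyTrack-class
#' @param x a `DailyTrack`
#' @param ... ignored
#' @export
setMethod("as.data.frame", "DailyTrack", function(x, ...) x@days)

setMethod("show", "DailyTrack", function(object) {
  tab <- table(factor(object@days$status,
                      levels = c("present", "missing", "excluded")))
  cat(sprintf(
    "DailyTrack '%s': %d days (%d present, %d missing, %d excluded)\n",
    object@tagId, nrow(object@days), tab["present"], tab["missing"],
    tab["excluded"]
  ))
})

setMethod("show", "UDSurface", function(object) {
  cat(sprintf(
    "UDSurface '%s': %g deg grid, h = %.3f deg, peak cell mass %.3g\n",
    object@source, object@grid@cellSize, object@smoothingH,
    max(object@density)
  ))
})
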