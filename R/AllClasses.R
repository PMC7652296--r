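#' @import methods
NULL

#' Diploid multi-locus genotypes with population labels
#'
#' Container for codominant microsatellite genotypes: two integer allele
#' labels (repeat sizes) per individual and locus, stored as a pair of
#' parallel matrices. A genotype is either fully present (both alleles
#' non-`NA`) or fully missing (both `NA`); half-missing calls are not
#' representable, matching the GenAlEx convention in which they are coerced
#' to missing on read.
#'
#' @slot alleleA,alleleB integer matrices, individuals x loci; `NA` = missing.
#' @slot populations factor of length `nInd(x)` giving each individual's
#'   breeding population (colony).
#' @export
setClass("GenotypeMatrix",
  representation(
    alleleA = "matrix",
    alleleB = "matrix",
    populations = "factor"
  )
)

setValidity("GenotypeMatrix", function(object) {
  a <- object@alleleA
  b <- object@alleleB
  msg <- character()
  if (!identical(dim(a), dim(b)))
    msg <- c(msg, "alleleA and alleleB must have identical dimensions")
  if (!identical(dimnames(a), dimnames(b)))
    msg <- c(msg, "alleleA and alleleB must have identical dimnames")
  if (is.null(rownames(a)) || is.null(colnames(a)))
    msg <- c(msg, "individual and locus names are required")
  if (length(object@populations) != nrow(a))
    msg <- c(msg, "one population label per individual is required")
  if (any(xor(is.na(a), is.na(b))))
    msg <- c(msg, "genotypes must be fully present or fully missing, never one allele")
  ok <- !is.na(a)
  if (any(a[ok] <= 0) || any(b[!is.na(b)] <= 0))
    msg <- c(msg, "allele labels must be positive integers")
  if (length(msg)) msg else TRUE
})

#' Symmetric pairwise statistic matrix keyed by population name
#'
#' Holds one pairwise statistic (F_ST, F'ST, UDOI, great-circle distance)
#' for a set of labelled populations, with an optional matrix of p-values.
#' The diagonal is ignored by all consumers and stored as `NA`.
#'
#' @slot values symmetric numeric matrix with labels as dimnames.
#' @slot statName one of `"fst"`, `"fst_prime"`, `"udoi"`, `"distance_km"`
#'   (free text permitted for derived statistics).
#' @slot pvalues optional symmetric matrix of p-values (0 x 0 when absent).
#' @export
setClass("LabeledMatrix",
  representation(
    values = "matrix",
    statName = "character",
    pvalues = "matrix"
  ),
  prototype(pvalues = matrix(numeric(), 0, 0))
)

setValidity("LabeledMatrix", function(object) {
  v <- object@values
  msg <- character()
  if (nrow(v) != ncol(v)) msg <- c(msg, "values must be square")
  if (is.null(rownames(v)) || !identical(rownames(v), colnames(v)))
    msg <- c(msg, "row and column labels must be present and identical")
  off <- v
  diag(off) <- 0
  off[is.na(off)] <- 0
  if (max(abs(off - t(off))) > 1e-9)
    msg <- c(msg, "off-diagonal values must be symmetric (tolerance 1e-9)")
  if (length(object@pvalues) && !identical(dim(object@pvalues), dim(v)))
    msg <- c(msg, "pvalues must match the dimensions of values")
  if (length(object@statName) != 1L)
    msg <- c(msg, "statName must be a single string")
  if (length(msg)) msg else TRUE
})

#' Lon/lat analysis grid with a land/sea mask
#'
#' Regular longitude/latitude grid whose cell centers are the discrete
#' states of the geolocation model and the support of utilization
#' distributions. The sea mask flags ocean cells (`TRUE`); geolocation
#' restricts tracks to them. Cells carry a linear index in column-major
#' order of the `[nLat, nLon]` mask (latitude varying fastest); that index
#' is the documented tie-break order for isopleth construction.
#'
#' @slot lonRange,latRange numeric length-2, grid extent in degrees.
#' @slot cellSize cell edge in degrees.
#' @slot seaMask logical matrix `[nLat, nLon]`, `TRUE` = ocean.
#' @export
setClass("GridSpec",
  representation(
    lonRange = "numeric",
    latRange = "numeric",
    cellSize = "numeric",
    seaMask = "matrix"
  )
)

setValidity("GridSpec", function(object) {
  msg <- character()
  nlon <- round(diff(object@lonRange) / object@cellSize)
  nlat <- round(diff(object@latRange) / object@cellSize)
  if (nlon < 1 || nlat < 1) msg <- c(msg, "grid must contain at least one cell")
  if (!is.logical(object@seaMask)) msg <- c(msg, "seaMask must be logical")
  if (!all(dim(object@seaMask) == c(nlat, nlon)))
    msg <- c(msg, sprintf("seaMask must be a %d x %d matrix", nlat, nlon))
  if (!any(object@seaMask)) msg <- c(msg, "at least one ocean cell is required")
  if (length(msg)) msg else TRUE
})

#' Timestamped ambient light record from a geolocator tag
#'
#' @slot time POSIXct (UTC), strictly increasing.
#' @slot lux non-negative light levels.
#' @slot tagId tag label.
#' @slot groundtruth data.frame with columns `start`, `end` (POSIXct),
#'   `lon`, `lat`: intervals during which the tag ran at a known location
#'   (pre-deployment calibration); may have zero rows.
#' @export
setClass("LightRecord",
  representation(
    time = "POSIXct",
    lux = "numeric",
    tagId = "character",
    groundtruth = "data.frame"
  )
)

setValidity("LightRecord", function(object) {
  msg <- character()
  if (length(object@time) != length(object@lux))
    msg <- c(msg, "time and lux must have equal length")
  if (length(object@time) > 1 && any(diff(as.numeric(object@time)) <= 0))
    msg <- c(msg, "timestamps must be strictly increasing")
  if (any(object@lux < 0)) msg <- c(msg, "lux must be non-negative")
  if (length(msg)) msg else TRUE
})

#' Fitted daily positions for one tag
#'
#' One row per calendar day: the decoded grid-cell center and a status flag
#' (`present`, `missing` = no usable light but bridged by the movement
#' model, `excluded` = dropped by the coarse first pass).
#'
#' @slot days data.frame with columns `date` (Date), `lon`, `lat`, `status`.
#' @slot tagId tag label.
#' @export
setClass("DailyTrack",
  representation(days = "data.frame", tagId = "character")
)

setValidity("DailyTrack", function(object) {
  d <- object@days
  msg <- character()
  need <- c("date", "lon", "lat", "status")
  if (!all(need %in% names(d)))
    msg <- c(msg, "days must have columns date, lon, lat, status")
  else if (!all(d$status %in% c("present", "missing", "excluded")))
    msg <- c(msg, "status must be present, missing or excluded")
  if (length(msg)) msg else TRUE
})

#' Gridded utilization distribution
#'
#' Per-cell probability mass of a kernel utilization distribution over a
#' [GridSpec]; masses sum to one over the grid.
#'
#' @slot grid the [GridSpec] the density lives on.
#' @slot density numeric matrix `[nLat, nLon]` of cell probability masses.
#' @slot smoothingH kernel bandwidth in degrees.
#' @slot source tag id or colony label the surface describes.
#' @export
setClass("UDSurface",
  representation(
    grid = "GridSpec",
    density = "matrix",
    smoothingH = "numeric",
    source = "character"
  )
)

setValidity("UDSurface", function(object) {
  msg <- character()
  if (!identical(dim(object@density), dim(object@grid@seaMask)))
    msg <- c(msg, "density must match the grid dimensions")
  if (any(object@density < 0)) msg <- c(msg, "density must be non-negative")
  if (abs(sum(object@density) - 1) > 1e-9)
    msg <- c(msg, "density must sum to 1 over the grid (tolerance 1e-9)")
  if (length(msg)) msg else TRUE
})
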