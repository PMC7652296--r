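# Kernel utilization distributions, home-range isopleths and areas, and
# the UDOI pairwise overlap index.

.kmPerDeg <- 111.195 # mean spherical degree of latitude, R = 6371 km

#' Restrict a track to the non-breeding season
#'
#' Keeps present-status daily positions whose dates fall inside a closed
#' month-day window that spans the year boundary; the default (1 November
#' to end of February) is the study's wintering period, which also keeps
#' clear of the equinoxes where light-level positions degrade. Feb 29 is
#' included in leap years.
#'
#' @param track a [DailyTrack-class].
#' @param window character length-2 `"MM-DD"` start and end (end `"02-29"`
#'   means end of February in any year).
#' @return data.frame with `date`, `lon`, `lat` of retained days (may be
#'   empty, with a warning).
#' @export
seasonFilter <- function(track, window = c("11-01", "02-29")) {
  stopifnot(is(track, "DailyTrack"))
  d <- as.data.frame(track)
  d <- d[d$status == "present" & !is.na(d$lon), ]
  md <- as.integer(format(d$date, "%m")) * 100 + as.integer(format(d$date, "%d"))
  bound <- function(s) {
    p <- as.integer(strsplit(s, "-")[[1]])
    p[1] * 100 + p[2]
  }
  lo <- bound(window[1])
  hi <- bound(window[2])
  keep <- if (lo > hi) md >= lo | md <= hi else md >= lo & md <= hi
  out <- d[keep, c("date", "lon", "lat")]
  if (!nrow(out)) warning("season filter retained no positions")
  rownames(out) <- NULL
  out
}

#' Ad hoc kernel bandwidth
#'
#' The reference-style ad hoc smoothing parameter used for the
#' utilization distributions, in degrees:
#' \eqn{h = \tfrac{1}{2}(sd_{lon} + sd_{lat}) \cdot n^{-1/6}}.
#'
#' @param points data.frame with `lon`, `lat`.
#' @return bandwidth in degrees.
#' @export
hrefBandwidth <- function(points) {
  n <- nrow(points)
  if (is.null(n) || n < 5) stop("at least 5 points are required")
  sdl <- stats::sd(points$lon)
  sdt <- stats::sd(points$lat)
  if (sdl + sdt <= 0) stop("zero spread in both axes")
  0.5 * (sdl + sdt) * n^(-1 / 6)
}

#' Kernel utilization distribution on a grid
#'
#' Bivariate normal kernel with bandwidth `h` (degrees, both axes)
#' evaluated at the grid cell centers and normalized to unit mass over the
#' grid.
#'
#' @param points data.frame with `lon`, `lat` daily positions.
#' @param grid a [GridSpec-class].
#' @param h bandwidth in degrees; default [hrefBandwidth()] of the points.
#' @param source label stored on the surface.
#' @return a [UDSurface-class].
#' @export
kernelUD <- function(points, grid, h = hrefBandwidth(points),
                     source = "points") {
  stopifnot(is(grid, "GridSpec"), h > 0, nrow(points) >= 1)
  cc <- cellCenters(grid)
  dens <- numeric(nrow(cc))
  for (i in seq_len(nrow(points))) {
    dens <- dens + exp(-((cc$lon - points$lon[i])^2 +
                           (cc$lat - points$lat[i])^2) / (2 * h^2))
  }
  tot <- sum(dens)
  if (tot < 1e-12) stop("all kernel mass falls outside the grid")
  new("UDSurface",
    grid = grid,
    density = matrix(dens / tot, nrow(seaMask(grid)), ncol(seaMask(grid))),
    smoothingH = h, source = source
  )
}

#' Aggregate colony utilization distribution
#'
#' Pools the season-filtered positions of all tags from a colony (years
#' pooled) into a single UD with one bandwidth derived from the pooled
#' points.
#'
#' @param tracks list of [DailyTrack-class] (or of point data.frames
#'   already filtered).
#' @param grid a [GridSpec-class].
#' @param window season window passed to [seasonFilter()].
#' @param h bandwidth in degrees; defaults to [hrefBandwidth()] of the
#'   pooled points (so the default bandwidth depends on the pooled sample
#'   size; pass `h` explicitly for bandwidth-matched comparisons).
#' @param source label for the surface.
#' @return a [UDSurface-class].
#' @export
colonyAggregateUD <- function(tracks, grid, window = c("11-01", "02-29"),
                              h = NULL, source = "colony") {
  stopifnot(length(tracks) >= 1)
  pts <- do.call(rbind, lapply(tracks, function(t) {
    if (is(t, "DailyTrack")) seasonFilter(t, window) else t
  }))
  if (is.null(h)) h <- hrefBandwidth(pts)
  kernelUD(pts, grid, h = h, source = source)
}

#' Lambert azimuthal equal-area projection (spherical)
#'
#' @param lon,lat coordinates in degrees.
#' @param lon0,lat0 projection center in degrees.
#' @return data.frame `x`, `y` in km.
#' @export
lambertAzimuthal <- function(lon, lat, lon0, lat0) {
  r <- 6371
  p <- pi / 180
  dl <- (lon - lon0) * p
  k <- sqrt(2 / (1 + sin(lat0 * p) * sin(lat * p) +
                   cos(lat0 * p) * cos(lat * p) * cos(dl)))
  data.frame(
    x = r * k * cos(lat * p) * sin(dl),
    y = r * k * (cos(lat0 * p) * sin(lat * p) -
                   sin(lat0 * p) * cos(lat * p) * cos(dl))
  )
}

# Trace outer boundaries of a set of grid cells. Cells given as (latIdx,
# lonIdx). Returns a list of closed rings of (lon, lat) vertices lying on
# cell boundaries.
.cellBoundary <- function(cells, grid) {
  cs <- grid@cellSize
  lon0 <- grid@lonRange[1]
  lat0 <- grid@latRange[1]
  inSet <- new.env(hash = TRUE)
  for (r in seq_len(nrow(cells))) {
    assign(paste(cells[r, 1], cells[r, 2]), TRUE, envir = inSet)
  }
  has <- function(i, j) exists(paste(i, j), envir = inSet)
  # boundary edges as directed segments keyed by start vertex, oriented so
  # the cell interior lies on the left (counter-clockwise outer rings)
  edges <- list()
  for (r in seq_len(nrow(cells))) {
    i <- cells[r, 1] # lat index
    j <- cells[r, 2] # lon index
    x1 <- lon0 + (j - 1) * cs; x2 <- x1 + cs
    y1 <- lat0 + (i - 1) * cs; y2 <- y1 + cs
    if (!has(i - 1, j)) edges[[length(edges) + 1]] <- c(x1, y1, x2, y1) # south
    if (!has(i, j + 1)) edges[[length(edges) + 1]] <- c(x2, y1, x2, y2) # east
    if (!has(i + 1, j)) edges[[length(edges) + 1]] <- c(x2, y2, x1, y2) # north
    if (!has(i, j - 1)) edges[[length(edges) + 1]] <- c(x1, y2, x1, y1) # west
  }
  if (!length(edges)) return(list())
  em <- do.call(rbind, edges)
  key <- function(x, y) sprintf("%.9g_%.9g", x, y)
  byStart <- split(seq_len(nrow(em)), key(em[, 1], em[, 2]))
  used <- logical(nrow(em))
  rings <- list()
  for (e0 in seq_len(nrow(em))) {
    if (used[e0]) next
    ring <- list(em[e0, 1:2])
    cur <- e0
    repeat {
      used[cur] <- TRUE
      nxt <- em[cur, 3:4]
      ring[[length(ring) + 1]] <- nxt
      cand <- byStart[[key(nxt[1], nxt[2])]]
      cand <- cand[!used[cand]]
      if (!length(cand)) break
      cur <- cand[1]
    }
    rings[[length(rings) + 1]] <- do.call(rbind, ring)
  }
  lapply(rings, function(m) {
    colnames(m) <- c("lon", "lat")
    m
  })
}

#' Home-range isopleth of a utilization distribution
#'
#' Selects the smallest set of highest-mass cells whose cumulative
#' probability reaches `level`/100 (ties broken by the grid's linear cell
#' index, for bit-reproducibility), reports the summed spherical cell
#' areas in km2, and traces the selected cells' outer boundaries both in
#' lon/lat and in a Lambert azimuthal equal-area projection centered on
#' the mean of the selected cell centers.
#'
#' @param ud a [UDSurface-class].
#' @param level isopleth level in percent, in (0, 100); 50 = core range,
#'   90 = home range.
#' @return object of class `HomeRange`: list with `level`, `areaKm2`,
#'   `cells` (linear indices), `rings` (lon/lat matrices), `ringsXY`
#'   (projected, km), `center` (projection center).
#' @export
udIsopleth <- function(ud, level) {
  stopifnot(is(ud, "UDSurface"), level > 0, level < 100)
  dens <- as.vector(ud@density)
  ord <- order(-dens, seq_along(dens)) # ties: lower linear index first
  cum <- cumsum(dens[ord])
  nSel <- which(cum >= level / 100 - 1e-12)[1]
  sel <- ord[seq_len(nSel)]
  grid <- ud@grid
  areas <- cellAreasKm2(grid)
  cc <- cellCenters(grid)
  nlat <- nrow(ud@density)
  cells <- cbind(
    lat = (sel - 1) %% nlat + 1,
    lon = (sel - 1) %/% nlat + 1
  )
  rings <- .cellBoundary(cells, grid)
  center <- c(lon = mean(cc$lon[sel]), lat = mean(cc$lat[sel]))
  ringsXY <- lapply(rings, function(m) {
    as.matrix(lambertAzimuthal(m[, "lon"], m[, "lat"], center["lon"],
                               center["lat"]))
  })
  structure(
    list(level = level, areaKm2 = sum(areas[sel]), cells = sel,
         rings = rings, ringsXY = ringsXY, center = center),
    class = "HomeRange"
  )
}

#' @export
print.HomeRange <- function(x, ...) {
  cat(sprintf("HomeRange %g%%: %.0f km2, %d cell(s), %d ring(s)\n",
              x$level, x$areaKm2, length(x$cells), length(x$rings)))
  invisible(x)
}

#' Utilization distribution overlap index (UDOI)
#'
#' \deqn{UDOI = A_{overlap} \int\int UD_a(x) UD_b(x) dx}
#' computed on the shared grid as `A_overlap * sum(massA * massB /
#' cellArea)`, where `A_overlap` is the total area of cells where both
#' densities are positive. 1 for identical uniform distributions with full
#' overlap, 0 for disjoint ranges, above 1 for concentrated distributions
#' sharing their high-use areas. By default the product is taken over the
#' full shared support; `restrictLevel` restricts both surfaces to an
#' isopleth (e.g. 95) first, the convention of some home-range software.
#'
#' @param a,b [UDSurface-class] objects on the same grid.
#' @param restrictLevel optional isopleth percent applied to both
#'   surfaces before the overlap computation.
#' @return UDOI (non-negative scalar).
#' @export
udoi <- function(a, b, restrictLevel = NULL) {
  stopifnot(is(a, "UDSurface"), is(b, "UDSurface"))
  ga <- a@grid
  gb <- b@grid
  if (!isTRUE(all.equal(ga@lonRange, gb@lonRange)) ||
      !isTRUE(all.equal(ga@latRange, gb@latRange)) ||
      !isTRUE(all.equal(ga@cellSize, gb@cellSize)))
    stop("surfaces live on different grids")
  da <- as.vector(a@density)
  db <- as.vector(b@density)
  if (!is.null(restrictLevel)) {
    keepA <- keepB <- rep(FALSE, length(da))
    keepA[udIsopleth(a, restrictLevel)$cells] <- TRUE
    keepB[udIsopleth(b, restrictLevel)$cells] <- TRUE
    da[!keepA] <- 0
    db[!keepB] <- 0
  }
  areas <- cellAreasKm2(ga)
  both <- da > 0 & db > 0
  if (!any(both)) return(0)
  sum(areas[both]) * sum(da[both] * db[both] / areas[both])
}

#' Pairwise UDOI matrix over a set of surfaces
#'
#' @param surfaces named list of [UDSurface-class] objects (names become
#'   the matrix labels).
#' @param restrictLevel see [udoi()].
#' @return a [LabeledMatrix-class] with `statName = "udoi"`.
#' @export
udoiMatrix <- function(surfaces, restrictLevel = NULL) {
  k <- length(surfaces)
  lab <- names(surfaces)
  v <- matrix(NA_real_, k, k, dimnames = list(lab, lab))
  for (i in seq_len(k - 1)) {
    for (j in seq(i + 1, k)) {
      v[i, j] <- v[j, i] <- udoi(surfaces[[i]], surfaces[[j]], restrictLevel)
    }
  }
  labeledMatrix(v, statName = "udoi")
}

#' Write home-range polygons as GeoJSON
#'
#' One Feature per isopleth with the rings as (multi)polygon coordinates
#' in lon/lat and the area in km2 as a property.
#'
#' @param homeRanges list of `HomeRange` objects.
#' @param file destination path.
#' @export
writeGeoJSON <- function(homeRanges, file) {
  feats <- lapply(homeRanges, function(hr) {
    coords <- lapply(hr$rings, function(m) {
      lapply(seq_len(nrow(m)), function(i) c(m[i, "lon"], m[i, "lat"]))
    })
    list(
      type = "Feature",
      properties = list(level = hr$level, area_km2 = hr$areaKm2),
      geometry = list(type = "MultiPolygon",
                      coordinates = lapply(coords, list))
    )
  })
  jsonlite::write_json(
    list(type = "FeatureCollection", features = feats),
    file, auto_unbox = TRUE, digits = 8
  )
}

#' Write a UD surface as lon/lat/density CSV
#'
#' @param ud a [UDSurface-class].
#' @param file destination path.
#' @export
writeUDSurface <- function(ud, file) {
  cc <- cellCenters(ud@grid)
  utils::write.csv(
    data.frame(lon = cc$lon, lat = cc$lat, density = as.vector(ud@density)),
    file, row.names = FALSE
  )
}
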