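# Orchestration: run configuration with the study defaults, the three
# pipeline stages (genetics, tracking, association), and report writers.

#' Run configuration with the study's default parameters
#'
#' Every parameter defaults to the value used in the study: zenith 96
#' degrees, light threshold 10 lux, shading alpha 5, movement beta 5 cells
#' per day, analysis grid -180..-100 longitude by 10..65 latitude at 1
#' degree (4 degree screening pass), 50/90 percent isopleths, 999
#' permutations for genetic significance at alpha 0.05, 5000
#' randomizations for the association tests at alpha 0.10, non-breeding
#' season 1 November to end of February, rarefaction at 20 gene copies.
#' The resolved configuration is serialized into every output directory
#' for provenance.
#'
#' @param ... overrides of the defaults (unknown names are an error).
#' @return list of class `RunConfig`.
#' @export
runConfig <- function(...) {
  cfg <- list(
    genotypes = NULL,          # path to GenAlEx-style CSV, or a GenotypeMatrix
    luxFiles = NULL,           # character vector of .lux paths, or LightRecords
    colonies = NULL,           # colony table path or data.frame
    fixtures = FALSE,          # use the packaged study tables
    zenith = 96, lightThreshold = 10,
    shadingAlpha = 5, movementBeta = 5,
    lonRange = c(-180, -100), latRange = c(10, 65),
    cellSizeFine = 1, cellSizeCoarse = 4,
    seaMask = NULL,            # GridSpec with mask; synthetic mask if NULL
    isopleths = c(50, 90),
    gCopies = 20,
    nPermGenetic = 999, alphaGenetic = 0.05,
    nPermAssociation = 5000, alphaAssociation = 0.10,
    season = c("11-01", "02-29"),
    tagColonies = NULL,        # named vector tagId -> colony
    seed = 1
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown))
    stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  structure(cfg, class = "RunConfig")
}

# serializable view of a config (drops in-memory objects)
.configRecord <- function(config) {
  keep <- vapply(config, function(x) {
    is.numeric(x) || is.character(x) || is.logical(x) || is.null(x)
  }, logical(1))
  c(unclass(config)[keep], list(package_version = "1.0.0"))
}

.writeConfig <- function(config, outDir) {
  if (is.null(outDir)) return(invisible())
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(.configRecord(config),
                       file.path(outDir, "run_config.json"),
                       auto_unbox = TRUE, null = "null", digits = NA)
}

#' Genetics stage: diversity, differentiation, FDR, PCoA
#'
#' Reads (or accepts) a genotype table, computes the per-colony diversity
#' summary, pairwise F_ST / F'ST with permutation significance, the
#' modified-FDR decisions, and the PCoA of the F'ST matrix. When `outDir`
#' is given, writes `diversity.csv` (columns population, n, Na, He, Ho,
#' PA, AR), `differentiation.csv` (lower triangle F_ST, upper triangle
#' F'ST), `differentiation_pvalues.csv`, `pcoa.csv` and the resolved
#' config.
#'
#' @param config a [runConfig()].
#' @param outDir optional output directory.
#' @return (invisibly) list with `diversity`, `differentiation`, `fdr`,
#'   `pcoa`, `config`.
#' @export
runGenetics <- function(config = runConfig(), outDir = NULL) {
  g <- config$genotypes
  if (is.null(g)) stop("config$genotypes is required (path or GenotypeMatrix)")
  if (is.character(g)) g <- readGenotypeTable(g)
  message("genetics: ", nInd(g), " individuals, ", nLoci(g), " loci, ",
          length(popNames(g)), " populations")
  div <- diversitySummary(g, gCopies = config$gCopies)
  diff <- pairwiseDifferentiation(g, nPerm = config$nPermGenetic,
                                  seed = config$seed)
  pv <- pvalues(diff$fst)
  fdr <- narumFdr(pv[upper.tri(pv)], alpha = config$alphaGenetic)
  pc <- pcoa(diff$fstPrime)
  if (!is.null(outDir)) {
    .writeConfig(config, outDir)
    divOut <- div
    names(divOut) <- c("population", "n", "Na", "He", "Ho", "PA", "AR")[
      seq_along(divOut)]
    utils::write.csv(divOut, file.path(outDir, "diversity.csv"),
                     row.names = FALSE)
    comb <- as.matrix(diff$fst)
    comb[upper.tri(comb)] <- as.matrix(diff$fstPrime)[upper.tri(comb)]
    utils::write.csv(as.data.frame(comb),
                     file.path(outDir, "differentiation.csv"))
    utils::write.csv(as.data.frame(pv),
                     file.path(outDir, "differentiation_pvalues.csv"))
    utils::write.csv(
      data.frame(population = rownames(pc$coordinates), pc$coordinates,
                 check.names = FALSE),
      file.path(outDir, "pcoa.csv"), row.names = FALSE
    )
  }
  invisible(list(diversity = div, differentiation = diff, fdr = fdr,
                 pcoa = pc, config = config))
}

#' Tracking stage: geolocation, home ranges, overlap
#'
#' Calibrates and fits every light record with the two-pass HMM, builds
#' individual and colony-aggregate utilization distributions over the
#' season-filtered positions, extracts the configured isopleths with
#' areas, and computes the pairwise colony UDOI matrix. Per-tag failures
#' (corrupt records, failed calibration) are logged and skipped, not
#' fatal.
#'
#' @param config a [runConfig()]; `luxFiles` may be paths or
#'   [LightRecord-class] objects, `tagColonies` maps tag ids to colonies
#'   (single colony assumed when `NULL`).
#' @param outDir optional output directory (`tracks/*.csv`, `areas.csv`,
#'   `udoi.csv`, `homeranges.geojson`, config).
#' @return (invisibly) list with `tracks`, `areas`, `udoi`, `colonyUDs`,
#'   `skipped`, `config`.
#' @export
runTracking <- function(config = runConfig(), outDir = NULL) {
  recs <- config$luxFiles
  if (is.null(recs)) stop("config$luxFiles is required")
  if (is.character(recs)) recs <- lapply(recs, readLux)
  if (is(recs, "LightRecord")) recs <- list(recs)
  grid <- config$seaMask
  if (is.null(grid)) {
    grid <- syntheticSeaMask(gridSpec(config$lonRange, config$latRange,
                                      config$cellSizeFine),
                             seed = config$seed)
  }
  tracks <- list()
  skipped <- character()
  for (rec in recs) {
    res <- tryCatch({
      cal <- calibrateLight(rec)
      params <- hmmParams(
        zenith = cal$zenith, lightThreshold = max(cal$lightThreshold, 1e-6),
        shadingAlpha = config$shadingAlpha,
        movementBeta = config$movementBeta, grid = grid
      )
      twoPassFit(rec, params, coarseCellSize = config$cellSizeCoarse)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      message("tracking: skipping tag '", rec@tagId, "': ",
              conditionMessage(res))
      skipped <- c(skipped, rec@tagId)
    } else {
      tracks[[rec@tagId]] <- res
    }
  }
  if (!length(tracks)) stop("no track could be fitted")
  colonyOf <- config$tagColonies
  if (is.null(colonyOf)) {
    colonyOf <- stats::setNames(rep("colony", length(tracks)), names(tracks))
  }
  byColony <- split(tracks, colonyOf[names(tracks)])
  colonyUDs <- lapply(names(byColony), function(cn) {
    colonyAggregateUD(byColony[[cn]], grid, window = config$season,
                      source = cn)
  })
  names(colonyUDs) <- names(byColony)
  areas <- do.call(rbind, lapply(names(colonyUDs), function(cn) {
    do.call(rbind, lapply(config$isopleths, function(lv) {
      hr <- udIsopleth(colonyUDs[[cn]], lv)
      data.frame(colony = cn, level = lv, area_km2 = hr$areaKm2)
    }))
  }))
  udoiM <- if (length(colonyUDs) >= 2) udoiMatrix(colonyUDs) else NULL
  if (!is.null(outDir)) {
    .writeConfig(config, outDir)
    dir.create(file.path(outDir, "tracks"), showWarnings = FALSE)
    for (tn in names(tracks)) {
      writeTrack(tracks[[tn]],
                 file.path(outDir, "tracks", paste0(tn, ".csv")))
    }
    utils::write.csv(areas, file.path(outDir, "areas.csv"),
                     row.names = FALSE)
    if (!is.null(udoiM))
      writeLabeledMatrix(udoiM, file.path(outDir, "udoi.csv"))
    hrs <- unlist(lapply(colonyUDs, function(ud) {
      lapply(config$isopleths, function(lv) udIsopleth(ud, lv))
    }), recursive = FALSE)
    writeGeoJSON(hrs, file.path(outDir, "homeranges.geojson"))
  }
  message("tracking: fitted ", length(tracks), " tag(s), skipped ",
          length(skipped))
  invisible(list(tracks = tracks, areas = areas, udoi = udoiM,
                 colonyUDs = colonyUDs, skipped = skipped, config = config))
}

#' Association stage: F'ST vs distance and vs winter overlap
#'
#' Runs the two randomization tests of [associationTests()] either on the
#' packaged study tables (`fixtures = TRUE`) or on matrices supplied by
#' the caller (`fstPrime`, `udoi` and a colony table from upstream
#' stages).
#'
#' @param config a [runConfig()].
#' @param fstPrime,udoi optional [LabeledMatrix-class] inputs when not in
#'   fixture mode.
#' @param outDir optional output directory (`association.csv`, config).
#' @return (invisibly) list with `report` (data.frame), `tests`, `config`.
#' @export
runAssociation <- function(config = runConfig(fixtures = TRUE),
                           fstPrime = NULL, udoi = NULL, outDir = NULL) {
  if (config$fixtures) {
    tabs <- loadStudyTables()
    fstPrime <- tabs$fstPrime
    udoi <- tabs$udoi
    colonies <- tabs$colonies
  } else {
    colonies <- config$colonies
    if (is.character(colonies)) {
      colonies <- utils::read.csv(colonies, fileEncoding = "UTF-8")
    }
    if (is.null(fstPrime) || is.null(udoi) || is.null(colonies))
      stop("fstPrime, udoi and config$colonies are required without fixtures")
  }
  tests <- associationTests(fstPrime, udoi, colonies,
                            nPerm = config$nPermAssociation,
                            alpha = config$alphaAssociation,
                            seed = config$seed)
  report <- do.call(rbind, lapply(c("ibd", "overlap"), function(nm) {
    tt <- tests[[nm]]
    data.frame(
      test = nm, n_pairs = tt$nPairs, r = tt$r, p = tt$p,
      alternative = tt$alternative, significant = tt$significant,
      n_perm = tt$nPerm, seed = tt$seed, stringsAsFactors = FALSE
    )
  }))
  if (!is.null(outDir)) {
    .writeConfig(config, outDir)
    utils::write.csv(report, file.path(outDir, "association.csv"),
                     row.names = FALSE)
    reps <- data.frame(ibd = tests$ibd$replicates,
                       overlap = tests$overlap$replicates)
    utils::write.csv(reps, file.path(outDir, "association_replicates.csv"),
                     row.names = FALSE)
  }
  invisible(list(report = report, tests = tests, config = config))
}
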