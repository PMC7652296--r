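# AMOVA-framework F_ST, standardized F'ST via maximal-differentiation
# recoding, permutation significance, modified-FDR correction, and PCoA.

# Per-locus data in a compact form for fast repeated F_ST evaluation:
# integer allele codes of all gene copies plus the population index of each
# copy (missing genotypes dropped per locus: pairwise deletion).
.lociCopies <- function(g) {
  popAll <- as.integer(g@populations)
  lapply(seq_len(nLoci(g)), function(l) {
    a <- g@alleleA[, l]
    b <- g@alleleB[, l]
    ok <- !is.na(a)
    allele <- c(a[ok], b[ok])
    lev <- sort(unique(allele))
    list(
      allele = allele,
      code = match(allele, lev), # dense 1..m codes for tabulate()
      m = length(lev),
      ind = c(which(ok), which(ok)), # individual carrying each copy
      pop = c(popAll[ok], popAll[ok])
    )
  })
}

# Variance components for one locus given copy alleles and pop index.
# Allele-level sums of squares; returns c(sigmaAmong, sigmaWithin) or NULL
# when fewer than 2 populations have data.
.amovaComponentsLocus <- function(allele, popIdx) {
  pops <- unique(popIdx)
  k <- length(pops)
  if (k < 2) return(NULL)
  N <- length(allele)
  nI <- tabulate(match(popIdx, pops))
  # SS_total = N (1 - sum P^2); SS_within = sum_i n_i (1 - sum p_i^2)
  totTab <- table(allele)
  ssTot <- N * (1 - sum((totTab / N)^2))
  ssW <- 0
  for (i in seq_len(k)) {
    cnt <- table(allele[popIdx == pops[i]])
    ssW <- ssW + nI[i] * (1 - sum((cnt / nI[i])^2))
  }
  ssA <- ssTot - ssW
  dfA <- k - 1
  dfW <- N - k
  if (dfW <= 0) return(NULL)
  msA <- ssA / dfA
  msW <- ssW / dfW
  n0 <- (N - sum(nI^2) / N) / dfA
  c(among = (msA - msW) / n0, within = msW)
}

#' AMOVA-framework F_ST over two or more populations
#'
#' Allele-level analysis of molecular variance with among- and
#' within-population components only (the GenAlEx framework): per locus,
#' sums of squares over gene copies are partitioned among and within
#' populations, variance components are summed over loci, and
#' \eqn{F_{ST} = \sigma^2_{AP} / (\sigma^2_{AP} + \sigma^2_{WP})}. A
#' negative summed among-population component is truncated to zero.
#' Missing genotypes are dropped per locus (pairwise deletion).
#'
#' @param g a [GenotypeMatrix-class].
#' @param subset optional character vector of two (or more) population
#'   labels to restrict the analysis to.
#' @return list with `fst`, `varAmong`, `varWithin`.
#' @export
amovaFst <- function(g, subset = NULL) {
  stopifnot(is(g, "GenotypeMatrix"))
  if (!is.null(subset)) g <- subsetPopulations(g, subset)
  if (nlevels(droplevels(g@populations)) < 2)
    stop("at least two populations are required")
  dataByPop <- tapply(rowSums(!is.na(g@alleleA)) > 0, g@populations, any)
  dataByPop <- dataByPop[!is.na(dataByPop)]
  if (!all(dataByPop))
    stop("population(s) with zero data at every locus: ",
         paste(names(dataByPop)[!dataByPop], collapse = ", "))
  comp <- vapply(.lociCopies(g), function(lc) {
    v <- .amovaComponentsLocus(lc$allele, lc$pop)
    if (is.null(v)) c(NA_real_, NA_real_) else v
  }, numeric(2))
  among <- sum(comp[1, ], na.rm = TRUE)
  within <- sum(comp[2, ], na.rm = TRUE)
  among <- max(among, 0)
  fst <- if (among + within <= 0) 0 else among / (among + within)
  list(fst = fst, varAmong = among, varWithin = within)
}

#' Recode alleles for maximal differentiation
#'
#' Maps every allele label so that it becomes unique to its (population,
#' allele) combination: populations then share no alleles while every
#' within-population frequency spectrum is unchanged. Running [amovaFst()]
#' on the recoded data gives the maximum F_ST attainable given the
#' within-population diversity, the denominator of the standardized F'ST.
#'
#' @param g a [GenotypeMatrix-class].
#' @return a recoded [GenotypeMatrix-class].
#' @export
maxFstRecode <- function(g) {
  stopifnot(is(g, "GenotypeMatrix"))
  popIdx <- as.integer(g@populations)
  a <- g@alleleA
  b <- g@alleleB
  for (l in seq_len(ncol(a))) {
    key <- function(m) ifelse(is.na(m[, l]), NA, popIdx * 10000L + m[, l])
    ka <- key(a)
    kb <- key(b)
    lev <- sort(unique(c(ka, kb)))
    a[, l] <- match(ka, lev)
    b[, l] <- match(kb, lev)
  }
  genotypeMatrix(a, b, populations = as.character(g@populations))
}

# Fast per-pair F_ST from precomputed per-locus copies (used by the
# permutation loop). popOf: individual index -> 1/2 group assignment.
# Returns the UNtruncated ratio: the permutation comparison needs the raw
# estimator (truncating negative estimates at zero would pile ties at 0
# and distort the null), truncation to [0, 1] happens at reporting.
.pairFst <- function(lociCopies, popOf) {
  among <- within <- 0
  for (lc in lociCopies) {
    grp <- popOf[lc$ind]
    code <- lc$code
    nTot <- length(code)
    n1 <- sum(grp == 1L)
    n2 <- nTot - n1
    if (n1 == 0 || n2 == 0 || nTot <= 2) next
    cTot <- tabulate(code, lc$m)
    c1 <- tabulate(code[grp == 1L], lc$m)
    c2 <- cTot - c1
    ssTot <- nTot - sum(cTot^2) / nTot
    ssW <- (n1 - sum(c1^2) / n1) + (n2 - sum(c2^2) / n2)
    msW <- ssW / (nTot - 2)
    n0 <- nTot - (n1^2 + n2^2) / nTot
    among <- among + ((ssTot - ssW) - msW) / n0
    within <- within + msW
  }
  if (among + within == 0) 0 else among / (among + within)
}

#' Pairwise F_ST and F'ST with permutation significance
#'
#' For every pair of populations: F_ST via [amovaFst()]; F'ST as the ratio
#' of the pair's F_ST to the F_ST of the same pair after
#' [maxFstRecode()]; and a permutation p-value obtained by shuffling
#' individuals between the two populations (sizes preserved), with the
#' never-zero estimator \eqn{p = (1 + \#\{F_{ST}^{perm} \ge F_{ST}\}) /
#' (1 + n_{perm})}. Global statistics over all populations are included.
#'
#' @param g a [GenotypeMatrix-class].
#' @param nPerm permutations per pair (default 999).
#' @param seed integer seed.
#' @return list with `fst` and `fstPrime` ([LabeledMatrix-class], the
#'   former carrying the p-value matrix), `global` (list with `fst`,
#'   `fstPrime`), and `nPerm`.
#' @export
pairwiseDifferentiation <- function(g, nPerm = 999, seed = 1) {
  stopifnot(is(g, "GenotypeMatrix"))
  if (nPerm < 1) stop("nPerm must be >= 1")
  pops <- popNames(g)
  if (length(pops) < 2) stop("at least two populations are required")
  set.seed(seed)
  k <- length(pops)
  fstM <- fpM <- pM <- matrix(NA_real_, k, k, dimnames = list(pops, pops))
  for (i in seq_len(k - 1)) {
    for (j in seq((i + 1), k)) {
      pair <- c(pops[i], pops[j])
      sub <- subsetPopulations(g, pair)
      lc <- .lociCopies(sub)
      popOf <- as.integer(droplevels(sub@populations))
      obsRaw <- .pairFst(lc, popOf)
      obs <- min(max(obsRaw, 0), 1)
      fmax <- amovaFst(maxFstRecode(sub))$fst
      fp <- if (fmax <= 0) 0 else obs / fmax
      ge <- 0L
      nind <- nInd(sub)
      for (r in seq_len(nPerm)) {
        if (.pairFst(lc, popOf[sample.int(nind)]) >= obsRaw - 1e-12)
          ge <- ge + 1L
      }
      fstM[i, j] <- fstM[j, i] <- obs
      fpM[i, j] <- fpM[j, i] <- min(fp, 1)
      pM[i, j] <- pM[j, i] <- (1 + ge) / (1 + nPerm)
    }
  }
  globalFst <- amovaFst(g)
  globalMax <- amovaFst(maxFstRecode(g))$fst
  list(
    fst = labeledMatrix(fstM, statName = "fst", pvalues = pM),
    fstPrime = labeledMatrix(fpM, statName = "fst_prime"),
    global = list(
      fst = globalFst$fst,
      fstPrime = if (globalMax <= 0) 0 else globalFst$fst / globalMax
    ),
    nPerm = nPerm
  )
}

#' Modified false discovery rate correction
#'
#' Benjamini-Yekutieli-style adjusted threshold as used for microsatellite
#' multiple testing: \eqn{\alpha_{crit} = \alpha / \sum_{i=1}^{k} 1/i}. A
#' test is significant when its p-value does not exceed the adjusted
#' threshold.
#'
#' @param pvalues vector of p-values in `[0, 1]`.
#' @param alpha nominal level (default 0.05).
#' @return list with `k`, `alpha`, `alphaCrit`, `decisions` (logical).
#' @export
narumFdr <- function(pvalues, alpha = 0.05) {
  if (!length(pvalues)) stop("empty p-value list")
  if (any(pvalues < 0 | pvalues > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  k <- length(pvalues)
  alphaCrit <- alpha / sum(1 / seq_len(k))
  list(
    k = k, alpha = alpha, alphaCrit = alphaCrit,
    decisions = !is.na(pvalues) & pvalues <= alphaCrit
  )
}

#' Principal coordinates analysis of a pairwise matrix
#'
#' Gower double-centering followed by eigendecomposition. GenAlEx-style
#' pairwise genetic distance matrices (F'ST) are treated as *squared*
#' distances, i.e. the centered matrix is \eqn{-d/2} (`assumeSquared =
#' TRUE`, the default, which reproduces GenAlEx's "standardized
#' covariance" PCoA); set `assumeSquared = FALSE` for a matrix of plain
#' distances, centering \eqn{-d^2/2}. Percent variation is computed over
#' positive eigenvalues only.
#'
#' @param m a [LabeledMatrix-class] of symmetric non-negative values.
#' @param assumeSquared treat matrix entries as squared distances?
#' @return list with `coordinates` (populations x axes, scaled by
#'   \eqn{\sqrt\lambda}), `eigenvalues`, and `percent` (per positive axis,
#'   sums to 100).
#' @export
pcoa <- function(m, assumeSquared = TRUE) {
  stopifnot(is(m, "LabeledMatrix"))
  d <- m@values
  diag(d) <- 0
  if (anyNA(d)) stop("matrix has NA entries after symmetrization")
  a <- if (assumeSquared) -0.5 * d else -0.5 * d^2
  n <- nrow(a)
  ctr <- diag(n) - matrix(1 / n, n, n)
  bmat <- ctr %*% a %*% ctr
  e <- eigen((bmat + t(bmat)) / 2, symmetric = TRUE)
  pos <- which(e$values > 1e-12)
  coords <- e$vectors[, pos, drop = FALSE] %*%
    diag(sqrt(e$values[pos]), length(pos))
  # a fully undifferentiated matrix yields no positive axes (0 columns)
  dimnames(coords) <- list(
    rownames(d),
    if (length(pos)) paste0("Axis", seq_along(pos)) else NULL
  )
  list(
    coordinates = coords,
    eigenvalues = e$values,
    percent = 100 * e$values[pos] / sum(e$values[pos])
  )
}
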