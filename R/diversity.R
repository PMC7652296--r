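# Per-population diversity statistics, rarefied allelic richness, and the
# Guo-Thompson Markov-chain exact test of Hardy-Weinberg proportions.

# Allele counts per population for one locus: list of named count vectors.
.alleleCounts <- function(g, locus) {
  a <- g@alleleA[, locus]
  b <- g@alleleB[, locus]
  pop <- g@populations
  ok <- !is.na(a)
  copies <- c(a[ok], b[ok])
  popc <- factor(c(as.character(pop[ok]), as.character(pop[ok])),
                 levels = levels(pop))
  tab <- table(popc, factor(copies))
  lapply(stats::setNames(seq_len(nrow(tab)), rownames(tab)), function(i) {
    x <- tab[i, ]
    x[x > 0]
  })
}

#' Per-locus allele frequencies by population
#'
#' @param g a [GenotypeMatrix-class].
#' @return nested list `[[locus]][[population]]` of named frequency vectors
#'   over non-missing gene copies (each sums to 1; empty when the
#'   population has no data at the locus).
#' @export
alleleFrequencies <- function(g) {
  stopifnot(is(g, "GenotypeMatrix"))
  out <- lapply(lociNames(g), function(l) {
    lapply(.alleleCounts(g, l), function(x) {
      if (sum(x) == 0) return(numeric(0))
      x / sum(x)
    })
  })
  stats::setNames(out, lociNames(g))
}

#' Per-population genetic diversity summary
#'
#' Computes, for every population, the sample size `n`, mean number of
#' alleles per locus `na`, expected heterozygosity `he` (Nei's
#' \eqn{1 - \sum p_i^2}, per-locus then averaged; the small-sample unbiased
#' variant \eqn{2N/(2N-1)} is available via `unbiased = TRUE`), observed
#' heterozygosity `ho`, private allele count `pa` (alleles found in no
#' other population, summed over loci), and, when `gCopies` is given, the
#' mean rarefied allelic richness `ar` (see [rarefiedAllelicRichness()]).
#' Loci with no data in a population are excluded from that population's
#' per-locus means.
#'
#' @param g a [GenotypeMatrix-class].
#' @param unbiased apply the \eqn{2N/(2N-1)} correction to `he`?
#' @param gCopies optional rarefaction size in gene copies for the `ar`
#'   column.
#' @return data.frame with one row per population, columns
#'   `population, n, na, he, ho, pa` (and `ar` when requested).
#' @export
diversitySummary <- function(g, unbiased = FALSE, gCopies = NULL) {
  stopifnot(is(g, "GenotypeMatrix"))
  pops <- popNames(g)
  loci <- lociNames(g)
  nByPop <- table(g@populations)
  if (any(nByPop == 0))
    stop("empty population(s): ",
         paste(names(nByPop)[nByPop == 0], collapse = ", "))
  countsByLocus <- lapply(loci, function(l) .alleleCounts(g, l))
  names(countsByLocus) <- loci

  # private alleles: per locus, alleles observed in exactly one population
  pa <- stats::setNames(numeric(length(pops)), pops)
  for (l in loci) {
    cl <- countsByLocus[[l]]
    presence <- table(unlist(lapply(cl, names)))
    priv <- names(presence)[presence == 1]
    for (p in pops) {
      pa[p] <- pa[p] + sum(names(cl[[p]]) %in% priv)
    }
  }

  rows <- lapply(pops, function(p) {
    heL <- hoL <- naL <- rep(NA_real_, length(loci))
    for (k in seq_along(loci)) {
      cnt <- countsByLocus[[loci[k]]][[p]]
      if (sum(cnt) == 0) next # locus with zero data in this population
      freq <- cnt / sum(cnt)
      he <- 1 - sum(freq^2)
      if (unbiased) he <- he * sum(cnt) / (sum(cnt) - 1)
      heL[k] <- he
      naL[k] <- length(cnt)
      inPop <- g@populations == p
      a <- g@alleleA[inPop, loci[k]]
      b <- g@alleleB[inPop, loci[k]]
      ok <- !is.na(a)
      hoL[k] <- if (any(ok)) mean(a[ok] != b[ok]) else NA_real_
    }
    data.frame(
      population = p, n = as.integer(nByPop[p]),
      na = mean(naL, na.rm = TRUE), he = mean(heL, na.rm = TRUE),
      ho = mean(hoL, na.rm = TRUE), pa = as.integer(pa[p]),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  if (!is.null(gCopies)) {
    ar <- rarefiedAllelicRichness(g, gCopies)
    out$ar <- ar$mean[out$population]
  }
  out
}

#' Rarefied allelic richness
#'
#' Expected number of distinct alleles in a random draw of `gCopies` gene
#' copies, the standard rarefaction correction for unequal sample sizes:
#' \deqn{AR = \sum_i \left[1 - \binom{N - N_i}{g} / \binom{N}{g}\right]}
#' where \eqn{N_i} is the count of allele *i* and \eqn{N} the total copies
#' in the population x locus cell. Cells with fewer than `gCopies` copies
#' are excluded (returned as `NA`) and reported via a message.
#'
#' The published standardization "to a sample size of 10" is ambiguous
#' between 10 individuals (20 gene copies, the default here, matching how
#' HP-Rare counts genes) and 10 copies; pass `gCopies = 10` for the
#' alternative reading.
#'
#' @param g a [GenotypeMatrix-class].
#' @param gCopies rarefaction draw size in gene copies (default 20 = 10
#'   diploid individuals).
#' @return list with `richness` (population x locus matrix) and `mean`
#'   (named per-population mean over loci).
#' @export
rarefiedAllelicRichness <- function(g, gCopies = 20) {
  stopifnot(is(g, "GenotypeMatrix"))
  if (gCopies < 1) stop("gCopies must be >= 1")
  pops <- popNames(g)
  loci <- lociNames(g)
  rich <- matrix(NA_real_, length(pops), length(loci),
                 dimnames = list(pops, loci))
  excluded <- 0L
  for (l in loci) {
    cl <- .alleleCounts(g, l)
    for (p in pops) {
      cnt <- cl[[p]]
      N <- sum(cnt)
      if (N < gCopies) {
        excluded <- excluded + 1L
        next
      }
      # 1 - C(N - Ni, g)/C(N, g), via log binomials for stability
      term <- 1 - exp(lchoose(N - cnt, gCopies) - lchoose(N, gCopies))
      rich[p, l] <- sum(term)
    }
  }
  if (excluded > 0)
    message(excluded, " population x locus cell(s) with fewer than ",
            gCopies, " gene copies excluded from rarefaction")
  list(richness = rich, mean = rowMeans(rich, na.rm = TRUE))
}

# log conditional probability terms of a genotype table that change under
# allele swaps: 2^H / prod(n_ij!) (Levene's conditional distribution, up to
# the constant n! prod(n_a!)/(2n)!).
.hweLogW <- function(het, tab) {
  het * log(2) - sum(lfactorial(tab))
}

#' Monte-Carlo exact test of Hardy-Weinberg proportions
#'
#' Guo-Thompson-style Markov chain over genotype configurations with the
#' observed allele counts held fixed. Each step picks two random
#' individuals and one random allele from each and swaps them. On the
#' labeled-individual state space the stationary distribution under
#' random union of gametes is proportional to \eqn{2^H} (H = heterozygote
#' count), and the two-per-heterozygote proposal asymmetry cancels it
#' exactly, so every swap is accepted; the chain nonetheless mixes over
#' genotype tables according to Levene's conditional distribution. The
#' p-value is the proportion of visited tables whose conditional
#' probability does not exceed that of the observed table; it is estimated
#' per batch after a dememorization burn-in, with the Monte-Carlo standard
#' error taken across batches (GENEPOP's batching semantics: `iterations`
#' is per batch).
#'
#' @param g a [GenotypeMatrix-class].
#' @param population,locus labels selecting the sample to test.
#' @param dememorization burn-in steps (default 2000).
#' @param batches number of batches (default 300).
#' @param iterations chain steps per batch (default 1000).
#' @param seed integer seed; results are bit-reproducible given the seed.
#' @return list with `p_value`, `se`, `degenerate` (TRUE when fewer than
#'   two alleles segregate, in which case `p_value = 1`), and
#'   `chain_params`.
#' @export
hweExactMC <- function(g, population, locus, dememorization = 2000,
                       batches = 300, iterations = 1000, seed = 1) {
  stopifnot(is(g, "GenotypeMatrix"))
  if (!population %in% popNames(g)) stop("unknown population: ", population)
  if (!locus %in% lociNames(g)) stop("unknown locus: ", locus)
  sel <- g@populations == population
  a <- g@alleleA[sel, locus]
  b <- g@alleleB[sel, locus]
  ok <- !is.na(a)
  a <- a[ok]
  b <- b[ok]
  n <- length(a)
  chain <- list(dememorization = dememorization, batches = batches,
                iterations = iterations)
  alleles <- sort(unique(c(a, b)))
  if (length(alleles) < 2 || n < 3) {
    return(list(p_value = 1, se = 0, degenerate = TRUE, chain_params = chain))
  }
  k <- length(alleles)
  ai <- match(a, alleles)
  bi <- match(b, alleles)
  # genotype table as k x k counts with i <= j in (row, col)
  lo <- pmin(ai, bi)
  hi <- pmax(ai, bi)
  tab <- matrix(0L, k, k)
  for (i in seq_len(n)) tab[lo[i], hi[i]] <- tab[lo[i], hi[i]] + 1L
  het <- sum(lo != hi)
  logWobs <- .hweLogW(het, tab)

  set.seed(seed)
  # individual-level allele lists for the swap proposal
  A1 <- lo
  A2 <- hi
  logW <- logWobs
  pBatch <- numeric(batches)
  runStep <- function(nSteps, record) {
    hits <- 0L
    for (s in seq_len(nSteps)) {
      ij <- sample.int(n, 2L)
      i <- ij[1]; j <- ij[2]
      # swap a random allele of i with a random allele of j
      si <- if (stats::runif(1) < 0.5) 1L else 2L
      sj <- if (stats::runif(1) < 0.5) 1L else 2L
      gi <- c(A1[i], A2[i])
      gj <- c(A1[j], A2[j])
      xi <- gi[si]
      xj <- gj[sj]
      if (xi != xj) {
        ni <- sort(c(gi[-si], xj))
        nj <- sort(c(gj[-sj], xi))
        dHet <- sum(ni[1] != ni[2], nj[1] != nj[2]) -
          sum(gi[1] != gi[2], gj[1] != gj[2])
        # every swap is accepted (see Details); the genotype table is
        # maintained only for the recorded probability statistic
        tab[gi[1], gi[2]] <<- tab[gi[1], gi[2]] - 1L
        tab[gj[1], gj[2]] <<- tab[gj[1], gj[2]] - 1L
        tab[ni[1], ni[2]] <<- tab[ni[1], ni[2]] + 1L
        tab[nj[1], nj[2]] <<- tab[nj[1], nj[2]] + 1L
        het <<- het + dHet
        logW <<- .hweLogW(het, tab)
        A1[i] <<- ni[1]; A2[i] <<- ni[2]
        A1[j] <<- nj[1]; A2[j] <<- nj[2]
      }
      if (record && logW <= logWobs + 1e-12) hits <- hits + 1L
    }
    hits
  }
  runStep(dememorization, record = FALSE)
  for (bb in seq_len(batches)) {
    pBatch[bb] <- runStep(iterations, record = TRUE) / iterations
  }
  list(
    p_value = mean(pBatch),
    se = stats::sd(pBatch) / sqrt(batches),
    degenerate = FALSE,
    chain_params = chain
  )
}

#' Exhaustive exact Hardy-Weinberg p-value for a biallelic sample
#'
#' Full enumeration over heterozygote counts under Levene's conditional
#' distribution; practical only for small biallelic samples and intended
#' as the reference for the Monte-Carlo chain.
#'
#' @param nAA,nAB,nBB observed genotype counts.
#' @return exact p-value (sum of probabilities of tables no more probable
#'   than the observed one).
#' @export
hweExactBiallelic <- function(nAA, nAB, nBB) {
  n <- nAA + nAB + nBB
  nA <- 2 * nAA + nAB
  hVals <- seq(nA %% 2, min(nA, 2 * n - nA), by = 2)
  logP <- vapply(hVals, function(h) {
    aa <- (nA - h) / 2
    bb <- n - aa - h
    lfactorial(n) - lfactorial(aa) - lfactorial(h) - lfactorial(bb) +
      h * log(2) + lfactorial(nA) + lfactorial(2 * n - nA) - lfactorial(2 * n)
  }, numeric(1))
  p <- exp(logP - max(logP))
  p <- p / sum(p)
  obs <- p[match(nAB, hVals)]
  sum(p[p <= obs + 1e-12])
}
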