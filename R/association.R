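# Spearman correlation between pairwise genetic differentiation and (a)
# geographic distance, (b) winter overlap, with the pair-shuffling
# randomization p-value (Mantel-style).

#' Paired off-diagonal values of two LabeledMatrix objects
#'
#' For each unordered pair of labels present in both matrices and
#' non-missing in both, returns one `(x, y)` row. Pair order is
#' deterministic (sorted labels).
#'
#' @param a,b [LabeledMatrix-class] objects.
#' @return data.frame with `label1`, `label2`, `x` (from `a`), `y` (from
#'   `b`).
#' @export
pairVectors <- function(a, b) {
  stopifnot(is(a, "LabeledMatrix"), is(b, "LabeledMatrix"))
  shared <- sort(intersect(labels(a), labels(b)))
  if (length(shared) < 2) stop("fewer than 2 shared labels")
  pr <- t(utils::combn(shared, 2))
  x <- as.matrix(a)[pr]
  y <- as.matrix(b)[pr]
  ok <- !is.na(x) & !is.na(y)
  data.frame(label1 = pr[ok, 1], label2 = pr[ok, 2], x = x[ok], y = y[ok],
             stringsAsFactors = FALSE)
}

#' Spearman rank correlation
#'
#' Pearson correlation of mid-ranks (ties receive average ranks).
#'
#' @param x,y numeric vectors of equal length (>= 3).
#' @return correlation coefficient in `[-1, 1]`.
#' @export
spearmanR <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3)
    stop("x and y must have equal length >= 3")
  rx <- rank(x)
  ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0)
    stop("zero rank variance")
  stats::cor(rx, ry)
}

#' Randomization test for a Spearman correlation of paired values
#'
#' Holds the x-values fixed and randomly re-assigns the y-values to pairs
#' (a permutation of the pair matching, not of matrix rows and columns),
#' recomputing Spearman's r each time. The p-value is the proportion of
#' randomized r at least as extreme as the observed value in the stated
#' direction, with the add-one correction so p is never zero:
#' \eqn{p = (1 + \#extreme) / (1 + n_{perm})}.
#'
#' @param x,y paired numeric vectors.
#' @param nPerm number of randomizations (default 5000).
#' @param alternative `"greater"` (randomized r >= observed counts as
#'   extreme) or `"less"`; `"two.sided"` uses `|r|`.
#' @param seed integer seed; p-values are bit-reproducible given the seed.
#' @return object of class `AssociationResult`: list with `r`, `p`,
#'   `nPairs`, `nPerm`, `alternative`, `seed`, and `replicates` (the full
#'   null distribution, for audit).
#' @export
randomizationPvalue <- function(x, y, nPerm = 5000,
                                alternative = c("greater", "less",
                                                "two.sided"),
                                seed = 1) {
  alternative <- match.arg(alternative)
  if (nPerm < 1) stop("nPerm must be >= 1")
  rObs <- spearmanR(x, y)
  set.seed(seed)
  n <- length(y)
  reps <- vapply(seq_len(nPerm), function(i) {
    spearmanR(x, y[sample.int(n)])
  }, numeric(1))
  extreme <- switch(alternative,
    greater = sum(reps >= rObs - 1e-12),
    less = sum(reps <= rObs + 1e-12),
    two.sided = sum(abs(reps) >= abs(rObs) - 1e-12)
  )
  structure(
    list(r = rObs, p = (1 + extreme) / (1 + nPerm), nPairs = length(x),
         nPerm = nPerm, alternative = alternative, seed = seed,
         replicates = reps),
    class = "AssociationResult"
  )
}

#' @export
print.AssociationResult <- function(x, ...) {
  cat(sprintf(
    "AssociationResult: Spearman r = %.3f over %d pairs, p = %.4f (%s, %d randomizations, seed %d)\n",
    x$r, x$nPairs, x$p, x$alternative, x$nPerm, x$seed
  ))
  invisible(x)
}

#' Great-circle distance matrix between colonies
#'
#' Haversine distances on a sphere of radius 6371 km.
#'
#' @param colonies data.frame with `lat`, `lon` and a label column (first
#'   of `abbrev`/`name` found).
#' @return a [LabeledMatrix-class] with `statName = "distance_km"`.
#' @export
greatCircleMatrix <- function(colonies) {
  labCol <- intersect(c("abbrev", "name"), names(colonies))[1]
  if (is.na(labCol)) stop("colonies need an 'abbrev' or 'name' column")
  d <- geosphere::distm(
    as.matrix(colonies[, c("lon", "lat")]),
    fun = function(p1, p2) geosphere::distHaversine(p1, p2, r = 6371000)
  ) / 1000
  dimnames(d) <- list(colonies[[labCol]], colonies[[labCol]])
  labeledMatrix(d, statName = "distance_km")
}

#' Genetic differentiation vs geographic distance and winter overlap
#'
#' The two headline tests: Spearman correlation of pairwise F'ST with (i)
#' great-circle distance between breeding colonies (isolation by
#' distance; alternative `greater`, the direction of the IBD hypothesis)
#' and (ii) the UDOI winter-overlap index (alternative `less`: more
#' shared wintering area, less differentiation), each with the
#' pair-shuffling randomization p-value. Pairs enter a test when both of
#' its matrices carry the pair; by default both tests therefore run over
#' the colonies present in both the genetic and the overlap matrix. Pass
#' `ibdLabels` to widen (or narrow) the distance test to another colony
#' set.
#'
#' @param fstPrime [LabeledMatrix-class] of pairwise F'ST.
#' @param overlap [LabeledMatrix-class] of pairwise UDOI.
#' @param colonies colony table with `lat`, `lon` and labels matching the
#'   matrices.
#' @param nPerm randomizations per test (default 5000).
#' @param alpha decision level (default 0.10).
#' @param seed integer seed.
#' @param ibdLabels optional label set for the distance test.
#' @return list with `ibd` and `overlap` (`AssociationResult`s, each with
#'   a `significant` flag at `alpha`), and `alpha`.
#' @export
associationTests <- function(fstPrime, overlap, colonies, nPerm = 5000,
                             alpha = 0.10, seed = 1, ibdLabels = NULL) {
  stopifnot(is(fstPrime, "LabeledMatrix"), is(overlap, "LabeledMatrix"))
  dist <- greatCircleMatrix(colonies)
  if (is.null(ibdLabels)) {
    ibdLabels <- intersect(labels(fstPrime), labels(overlap))
  }
  pvIbd <- pairVectors(fstPrime[intersect(ibdLabels, labels(fstPrime))], dist)
  pvOv <- pairVectors(fstPrime, overlap)
  ibd <- randomizationPvalue(pvIbd$x, pvIbd$y, nPerm = nPerm,
                             alternative = "greater", seed = seed)
  ov <- randomizationPvalue(pvOv$x, pvOv$y, nPerm = nPerm,
                            alternative = "less", seed = seed + 1)
  ibd$significant <- ibd$p <= alpha
  ov$significant <- ov$p <= alpha
  list(ibd = ibd, overlap = ov, alpha = alpha)
}
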