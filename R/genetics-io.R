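# Readers and writers for genotype tables and labeled pairwise matrices.

#' Read a GenAlEx-style two-columns-per-locus genotype CSV
#'
#' The dialect is a plain CSV whose header row declares `ind`, `pop` and the
#' locus names, each locus name heading the first of two adjacent allele
#' columns (the second may repeat the name or carry a suffix). `0` is the
#' missing-data code. Half-missing genotypes (exactly one allele 0) are
#' coerced to fully missing with a warning, following the GenAlEx
#' convention. Allele labels are kept as the integer repeat sizes read from
#' the file; no binning or re-coding is applied.
#'
#' @param file path or connection to the CSV.
#' @param dialect currently only `"genalex_csv"`.
#' @return a [GenotypeMatrix-class].
#' @seealso [writeGenotypeTable()], [writeStructureFormat()]
#' @export
readGenotypeTable <- function(file, dialect = c("genalex_csv")) {
  dialect <- match.arg(dialect)
  lines <- readLines(file)
  if (!length(lines)) stop("empty genotype table")
  header <- strsplit(lines[1], ",", fixed = TRUE)[[1]]
  header <- trimws(header)
  if (length(header) < 4)
    stop("malformed header (line 1): need ind, pop and at least one locus pair")
  nAllele <- length(header) - 2L
  if (nAllele %% 2L != 0L)
    stop("malformed header (line 1): odd number of allele columns (", nAllele, ")")
  loci <- header[seq(3, length(header), by = 2)]
  if (any(loci == "")) stop("malformed header (line 1): empty locus name")
  body <- lines[-1]
  body <- body[nzchar(trimws(body))]
  n <- length(body)
  if (!n) stop("genotype table has no data rows")
  a <- b <- matrix(NA_integer_, n, length(loci))
  ind <- pop <- character(n)
  halfMissing <- 0L
  for (r in seq_len(n)) {
    f <- trimws(strsplit(body[r], ",", fixed = TRUE)[[1]])
    if (length(f) != length(header))
      stop("parse error at line ", r + 1L, ": expected ", length(header),
           " fields, found ", length(f))
    ind[r] <- f[1]
    pop[r] <- f[2]
    if (pop[r] == "")
      stop("parse error at line ", r + 1L, ": missing population label")
    al <- suppressWarnings(as.integer(f[-(1:2)]))
    if (anyNA(al))
      stop("parse error at line ", r + 1L, ": non-integer allele call")
    a1 <- al[seq(1, length(al), by = 2)]
    a2 <- al[seq(2, length(al), by = 2)]
    half <- xor(a1 == 0L, a2 == 0L)
    if (any(half)) {
      halfMissing <- halfMissing + sum(half)
      a1[half] <- 0L
      a2[half] <- 0L
    }
    a1[a1 == 0L] <- NA_integer_
    a2[a2 == 0L] <- NA_integer_
    a[r, ] <- a1
    b[r, ] <- a2
  }
  if (halfMissing > 0)
    warning(halfMissing, " half-missing genotype(s) coerced to missing")
  genotypeMatrix(a, b, populations = pop, individuals = ind, loci = loci)
}

#' Write a GenotypeMatrix in the GenAlEx-style CSV dialect
#'
#' Inverse of [readGenotypeTable()]: missing genotypes are written as `0,0`.
#'
#' @param g a [GenotypeMatrix-class].
#' @param file path or connection.
#' @export
writeGenotypeTable <- function(g, file) {
  stopifnot(is(g, "GenotypeMatrix"))
  loci <- lociNames(g)
  header <- c("ind", "pop", as.vector(rbind(loci, paste0(loci, "_2"))))
  a <- g@alleleA
  b <- g@alleleB
  a[is.na(a)] <- 0L
  b[is.na(b)] <- 0L
  inter <- matrix(NA_integer_, nInd(g), 2L * nLoci(g))
  inter[, seq(1, ncol(inter), by = 2)] <- a
  inter[, seq(2, ncol(inter), by = 2)] <- b
  rows <- apply(inter, 1, paste, collapse = ",")
  out <- paste(indNames(g), as.character(populations(g)), rows, sep = ",")
  writeLines(c(paste(header, collapse = ","), out), file)
}

#' Export a GenotypeMatrix as STRUCTURE two-row-per-individual text
#'
#' One header row of locus names, then two whitespace-separated rows per
#' individual (`label popIndex allele...`), missing alleles encoded as -9.
#' Provided so genotypes can be handed to external Bayesian clustering
#' tools; running those tools is outside this package's scope.
#'
#' @param g a [GenotypeMatrix-class].
#' @param file path or connection.
#' @export
writeStructureFormat <- function(g, file) {
  stopifnot(is(g, "GenotypeMatrix"))
  popIdx <- as.integer(populations(g))
  fmt <- function(m) {
    m[is.na(m)] <- -9L
    m
  }
  a <- fmt(g@alleleA)
  b <- fmt(g@alleleB)
  out <- character(2L * nInd(g))
  for (i in seq_len(nInd(g))) {
    pre <- paste(indNames(g)[i], popIdx[i])
    out[2 * i - 1] <- paste(pre, paste(a[i, ], collapse = " "))
    out[2 * i] <- paste(pre, paste(b[i, ], collapse = " "))
  }
  writeLines(c(paste(lociNames(g), collapse = " "), out), file)
}

#' Read a labeled square CSV as a LabeledMatrix
#'
#' The CSV carries row and column labels (first column = row labels). For
#' tables that print two statistics in the two triangles (as pairwise
#' F_ST / F'ST tables do), read each triangle as its own matrix.
#'
#' @param file path or connection.
#' @param triangle which entries carry the statistic: `"lower"`, `"upper"`
#'   or `"full"`. Triangle input is mirrored; full input must be symmetric
#'   to 1e-9.
#' @param statName statistic tag stored on the result.
#' @return a [LabeledMatrix-class].
#' @export
readLabeledMatrix <- function(file, triangle = c("lower", "upper", "full"),
                              statName = "stat") {
  triangle <- match.arg(triangle)
  raw <- utils::read.csv(file, row.names = 1, check.names = FALSE,
                         fileEncoding = "UTF-8")
  m <- as.matrix(raw)
  storage.mode(m) <- "double"
  if (nrow(m) != ncol(m))
    stop("non-square input: ", nrow(m), " rows vs ", ncol(m), " columns")
  if (!identical(trimws(rownames(m)), trimws(colnames(m))))
    stop("row and column labels differ")
  rownames(m) <- colnames(m) <- trimws(rownames(m))
  if (triangle == "lower") {
    m[upper.tri(m)] <- t(m)[upper.tri(m)]
  } else if (triangle == "upper") {
    m[lower.tri(m)] <- t(m)[lower.tri(m)]
  } else {
    off <- m
    diag(off) <- 0
    off[is.na(off)] <- 0
    if (max(abs(off - t(off))) > 1e-9)
      stop("full matrix is asymmetric beyond tolerance 1e-9")
  }
  labeledMatrix(m, statName = statName)
}

#' Write a LabeledMatrix as a labeled square CSV
#'
#' @param m a [LabeledMatrix-class].
#' @param file path or connection.
#' @param diagonal value to print on the diagonal (default empty).
#' @export
writeLabeledMatrix <- function(m, file, diagonal = NA) {
  stopifnot(is(m, "LabeledMatrix"))
  v <- m@values
  diag(v) <- diagonal
  df <- as.data.frame(v, check.names = FALSE)
  utils::write.csv(df, file, row.names = TRUE, na = "")
}
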