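# Genotype matrix helpers. Convention: integer matrix with two columns per
# locus named <locus>_a1 / <locus>_a2; allele pairs unordered, stored sorted;
# a missing locus has both entries NA.

genoColNames <- function(loci) {
  as.vector(rbind(paste0(loci, "_a1"), paste0(loci, "_a2")))
}

emptyGenoMatrix <- function(n, loci) {
  matrix(NA_integer_, nrow = n, ncol = 2L * length(loci),
         dimnames = list(NULL, genoColNames(loci)))
}

locusCols <- function(l) c(2L * l - 1L, 2L * l)

#' Normalize a genotype matrix
#'
#' Sorts each allele pair (pairs are unordered) and turns half-missing pairs
#' into fully missing loci.
#'
#' @param geno Genotype matrix, two columns per locus.
#' @return Normalized integer matrix of the same shape.
#' @export
normalizeGenotypes <- function(geno) {
  if (!is.matrix(geno)) geno <- as.matrix(geno)
  storage.mode(geno) <- "integer"
  nl <- ncol(geno) %/% 2L
  for (l in seq_len(nl)) {
    cc <- locusCols(l)
    a <- geno[, cc[1]]
    b <- geno[, cc[2]]
    half <- xor(is.na(a), is.na(b))
    a[half] <- NA_integer_
    b[half] <- NA_integer_
    lo <- pmin(a, b)
    hi <- pmax(a, b)
    geno[, cc[1]] <- lo
    geno[, cc[2]] <- hi
  }
  geno
}

typedLociCount <- function(geno) {
  nl <- ncol(geno) %/% 2L
  if (nrow(geno) == 0L) return(integer(0))
  rowSums(vapply(seq_len(nl),
                 function(l) !is.na(geno[, 2L * l - 1L]),
                 logical(nrow(geno))))
}

# Per-locus genotype strings ("a/b", NA if missing); used for fast pairwise
# comparison during consolidation.
genoStrings <- function(geno) {
  nl <- ncol(geno) %/% 2L
  out <- matrix(NA_character_, nrow(geno), nl,
                dimnames = list(rownames(geno), lociFromGeno(geno)))
  for (l in seq_len(nl)) {
    cc <- locusCols(l)
    ok <- !is.na(geno[, cc[1]])
    out[ok, l] <- paste0(geno[ok, cc[1]], "/", geno[ok, cc[2]])
  }
  out
}

# Hardy-Weinberg probability of an unordered genotype {a, b} given allele
# frequencies f (named by allele code).
hweProb <- function(a, b, f) {
  fa <- unname(f[as.character(a)])
  fb <- unname(f[as.character(b)])
  if (is.na(fa) || is.na(fb)) return(0)
  if (a == b) fa * fb else 2 * fa * fb
}

# Mendelian transmission probability of unordered offspring genotype
# {o1, o2} given parent genotypes {d1, d2} and {s1, s2}: each parent
# transmits one of its two alleles with probability 1/2.
transmissionProb <- function(o1, o2, d1, d2, s1, s2) {
  p <- 0
  for (u in c(d1, d2)) for (v in c(s1, s2)) {
    if ((u == o1 && v == o2) || (u == o2 && v == o1)) p <- p + 0.25
  }
  p
}

# All unordered genotypes over the alleles of frequency vector f, with their
# HWE probabilities. Returns a data.frame (a1, a2, p).
enumerateGenotypes <- function(f) {
  al <- as.integer(names(f))
  n <- length(al)
  a1 <- a2 <- integer(0)
  for (i in seq_len(n)) for (j in i:n) {
    a1 <- c(a1, al[i]); a2 <- c(a2, al[j])
  }
  p <- mapply(function(x, y) hweProb(x, y, f), a1, a2)
  data.frame(a1 = a1, a2 = a2, p = p)
}

roundHalfUp <- function(x, digits = 0) {
  # Percentages in reports are rounded half-up (so 95.15 -> 95.2), matching
  # how printed summary tables are typically rounded.
  m <- 10^digits
  floor(x * m + 0.5) / m
}

`%||%` <- function(a, b) if (is.null(a)) b else a
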