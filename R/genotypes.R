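#' Coerce to a haplotype allele vector
#'
#' A haplotype is a vector of allele codes over L markers, with 0 the major
#' and 1 the minor allele.  Accepts an integer/numeric vector of 0/1 or a
#' single compact string such as \code{"10110"}.
#'
#' @param x integer vector of 0/1, or a single character string of 0/1 digits.
#' @return An integer vector of 0s and 1s.
#' @export
as_haplotype <- function(x) {
  if (is.character(x)) {
    if (length(x) != 1L) stop("a haplotype string must be a single string")
    x <- as.integer(strsplit(x, "")[[1L]])
  }
  x <- as.integer(x)
  if (anyNA(x) || !all(x %in% c(0L, 1L)))
    stop("haplotype alleles must be 0 (major) or 1 (minor)")
  x
}

#' Coerce to a genotype code vector
#'
#' Genotypes are coded per marker as 0 = homozygous major, 1 = homozygous
#' minor, 2 = heterozygous; missing entries are \code{NA} (the character
#' \code{"?"} in compact strings).
#'
#' @param x integer vector over \{0,1,2,NA\}, or a single string over
#'   \code{0}, \code{1}, \code{2}, \code{?}.
#' @return An integer vector over \{0,1,2,NA\}.
#' @export
as_genotype <- function(x) {
  if (is.character(x)) {
    if (length(x) != 1L) stop("a genotype string must be a single string")
    ch <- strsplit(x, "")[[1L]]
    x <- suppressWarnings(as.integer(ch))
    if (any(is.na(x) & ch != "?")) stop("genotype strings may only contain 0, 1, 2, ?")
  }
  x <- as.integer(x)
  bad <- !is.na(x) & !(x %in% 0:2)
  if (any(bad)) stop("genotype codes must be 0, 1, 2 or NA")
  x
}

#' Bundle the three genotype vectors of a trio
#'
#' @param father,mother,child genotype vectors (see [as_genotype()]) of equal
#'   length.
#' @return An object of class \code{"trio_genotypes"}: a list with elements
#'   \code{father}, \code{mother}, \code{child}.
#' @examples
#' trio_genotypes("2012", "2010", "2011")
#' @export
trio_genotypes <- function(father, mother, child) {
  f <- as_genotype(father); m <- as_genotype(mother); k <- as_genotype(child)
  if (length(f) != length(m) || length(f) != length(k))
    stop("father, mother and child genotype vectors must have equal length")
  structure(list(father = f, mother = m, child = k), class = "trio_genotypes")
}

#' @export
print.trio_genotypes <- function(x, ...) {
  fmt <- function(g) paste(ifelse(is.na(g), "?", g), collapse = "")
  cat("trio genotypes over", length(x$father), "markers\n")
  cat("  father:", fmt(x$father), "\n  mother:", fmt(x$mother),
      "\n  child: ", fmt(x$child), "\n")
  invisible(x)
}

#' @export
length.trio_genotypes <- function(x) length(x$father)

# Restrict a trio to a marker interval (1-based, inclusive).
#' Subset a trio to a marker window
#' @param trio a [trio_genotypes()] object.
#' @param cols integer vector of marker indices to keep.
#' @export
trio_slice <- function(trio, cols) {
  structure(list(father = trio$father[cols], mother = trio$mother[cols],
                 child = trio$child[cols]), class = "trio_genotypes")
}

#' Genotype implied by a pair of haplotypes
#'
#' Site-wise: two major alleles give 0, two minor alleles give 1, and a
#' mixed pair gives 2 (heterozygous).  For example the haplotype pair
#' \code{"10110"} / \code{"00100"} produces the genotype \code{"20120"}.
#'
#' @param h_a,h_b haplotypes (see [as_haplotype()]) of equal length.
#' @return An integer genotype vector.
#' @examples
#' genotype_from_haplotypes("10110", "00100")  # 2 0 1 2 0
#' @export
genotype_from_haplotypes <- function(h_a, h_b) {
  a <- as_haplotype(h_a); b <- as_haplotype(h_b)
  if (length(a) != length(b)) stop("haplotype lengths differ")
  s <- a + b
  g <- integer(length(s))
  g[s == 1L] <- 2L
  g[s == 2L] <- 1L
  g
}

# Compact string key for a haplotype; used for catalog lookups.
hap_key <- function(h) paste(h, collapse = "")

# Stack trio members into a genotype matrix (rows father, mother, child per
# trio, in input order) -- the matrix the block partitioner works on.
#' Genotype matrix of a trio cohort
#'
#' Stacks all trio members (father, mother, child per trio, in order) into a
#' single matrix with one row per individual and one column per marker.
#'
#' @param trios list of [trio_genotypes()] objects over the same markers.
#' @return Integer matrix with \code{3 * length(trios)} rows.
#' @export
genotype_matrix <- function(trios) {
  if (!length(trios)) stop("empty trio list")
  L <- length(trios[[1L]]$father)
  G <- matrix(NA_integer_, nrow = 3L * length(trios), ncol = L)
  for (i in seq_along(trios)) {
    t <- trios[[i]]
    if (length(t$father) != L) stop("trios differ in marker count")
    G[3L * i - 2L, ] <- t$father
    G[3L * i - 1L, ] <- t$mother
    G[3L * i, ] <- t$child
  }
  G
}
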