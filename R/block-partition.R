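# Entropy-based partition of the marker axis into haplotype blocks.
#
# Haplotypes show block structure: within a block only a handful of distinct
# haplotypes circulate.  Working directly from genotypes (no phasing
# required), a segment's entropy is computed from the frequencies of the
# distinct genotype segments it contains, and a dynamic program finds the
# width-capped partition minimizing total block entropy.

# Row keys of G over columns i..j, missing as "?".
segment_keys <- function(G, i, j) {
  sub <- G[, i:j, drop = FALSE]
  sub[is.na(sub)] <- -1L
  do.call(paste, c(as.data.frame(sub), sep = ","))
}

#' Genotype entropy of a marker segment
#'
#' For the segment spanning markers \code{i..j} (inclusive), counts the
#' occurrences a_k of each distinct genotype segment across rows and returns
#' the Shannon entropy \eqn{-\sum_k p_k \ln p_k} with \eqn{p_k = a_k / \sum_l
#' a_l} (natural log).  Missing entries act as a distinct symbol.
#'
#' @param G genotype matrix (rows = individuals, entries in \{0,1,2,NA\}).
#' @param i,j segment bounds, 1-based inclusive, \code{i <= j}.
#' @return Non-negative entropy in nats; 0 when all rows agree.
#' @export
segment_entropy <- function(G, i, j) {
  G <- as.matrix(G)
  if (nrow(G) == 0L) stop("empty genotype matrix")
  if (i < 1L || j > ncol(G) || i > j) stop("invalid segment bounds")
  cnt <- table(segment_keys(G, i, j))
  p <- as.numeric(cnt) / sum(cnt)
  -sum(p * log(p))
}

#' Minimum-entropy haplotype block partition
#'
#' Dynamic program over split points: \code{C(j) = min_i \{C(i-1) + E(i,j)\}}
#' subject to the width cap of at most \code{W} markers per block, where
#' \code{E(i,j)} is [segment_entropy()].  Ties are broken toward fewer
#' blocks, then toward later split points.
#'
#' @param G genotype matrix.
#' @param W maximum block width in markers (default 12).
#' @return An object of class \code{"block_partition"}: list with
#'   \code{blocks} (n x 2 matrix of 1-based inclusive \code{start},
#'   \code{end}), \code{total_entropy} and \code{W}.
#' @export
optimal_partition <- function(G, W = 12L) {
  G <- as.matrix(G)
  W <- as.integer(W)
  if (W < 1L) stop("W must be >= 1")
  L <- ncol(G)
  if (L == 0L) stop("no markers")
  eps <- 1e-12
  # E[i, j] for j - i < W
  E <- matrix(NA_real_, L, L)
  for (j in seq_len(L))
    for (i in seq.int(max(1L, j - W + 1L), j))
      E[i, j] <- segment_entropy(G, i, j)
  C <- c(0, rep(Inf, L))       # C[j + 1] = best entropy up to marker j
  nb <- c(0L, rep(NA_integer_, L))
  back <- integer(L)
  for (j in seq_len(L)) {
    for (i in seq.int(max(1L, j - W + 1L), j)) {
      cand <- C[i] + E[i, j]
      cand_nb <- nb[i] + 1L
      cur <- C[j + 1L]
      better <- cand < cur - eps ||
        (abs(cand - cur) <= eps &&
           (cand_nb < nb[j + 1L] ||
              (cand_nb == nb[j + 1L] && i > back[j])))
      if (better) {
        C[j + 1L] <- cand
        nb[j + 1L] <- cand_nb
        back[j] <- i
      }
    }
  }
  blocks <- matrix(0L, nrow = nb[L + 1L], ncol = 2L,
                   dimnames = list(NULL, c("start", "end")))
  j <- L
  for (b in seq.int(nb[L + 1L], 1L)) {
    blocks[b, ] <- c(back[j], j)
    j <- back[j] - 1L
  }
  structure(list(blocks = blocks, total_entropy = C[L + 1L], W = W),
            class = "block_partition")
}

#' @export
print.block_partition <- function(x, ...) {
  cat(sprintf("block partition: %d block(s) over %d markers (W = %d), total entropy %.4f\n",
              nrow(x$blocks), x$blocks[nrow(x$blocks), 2L], x$W, x$total_entropy))
  invisible(x)
}
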