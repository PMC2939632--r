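# End-to-end phasing driver: block partition -> per-block deterministic
# sampling -> minimum-entropy ligation -> finalized haplotypes.

# Combine two phased blocks covering the SAME marker interval but disjoint
# consecutive trio subsets (cohort slices): solution sets are concatenated
# trio-wise, weights multiply, and the top K combinations survive.
cross_trio_sets <- function(a, b, K) {
  na <- length(a$solutions); nb <- length(b$solutions)
  ia <- rep(seq_len(na), each = nb)
  ib <- rep(seq_len(nb), times = na)
  w <- a$weights[ia] * b$weights[ib]
  ord <- order(-w, ia, ib)
  keep <- ord[seq_len(min(K, length(ord)))]
  sols <- lapply(keep, function(k)
    c(a$solutions[[ia[k]]], b$solutions[[ib[k]]]))
  new_phased_block(a$start, a$end, sols, w[keep] / sum(w[keep]), a$entropy)
}

# Phase one block's trios in consecutive slices, each slice seeded with the
# haplotypes assigned by the previous slices' top stream as extra prior
# pseudocounts (large cohorts only).
run_block_sliced <- function(btrios, interval, G, K, epsilon, prior_slice,
                             max_solutions, slice_size) {
  n <- length(btrios)
  starts <- seq.int(1L, n, by = slice_size)
  carry <- prior_slice
  pbs <- vector("list", length(starts))
  for (s in seq_along(starts)) {
    idx <- starts[s]:min(n, starts[s] + slice_size - 1L)
    fit <- run_block(btrios[idx], K, epsilon, carry, max_solutions)
    pb <- phased_block(fit, interval, G)
    pbs[[s]] <- pb
    top <- pb$solutions[[which.max(pb$weights)]]
    carry <- rbind(carry, do.call(rbind, top))
  }
  comb <- pbs[[1L]]
  for (s in seq_along(pbs)[-1L]) comb <- cross_trio_sets(comb, pbs[[s]], K)
  comb
}

#' Phase a trio cohort by tree-based deterministic sampling
#'
#' The full pipeline: (1) screen Mendelian inconsistencies; (2) partition
#' the markers into low-entropy haplotype blocks (dynamic program, width cap
#' \code{W}); (3) phase each block by deterministic sampling over weighted
#' solution streams (capacity \code{K}, Dirichlet pseudocounts
#' \code{epsilon}); (4) ligate adjacent blocks in minimum-entropy order;
#' (5) extract the top-weight solution, imputing originally missing
#' genotypes from the chosen haplotypes.  Deterministic: identical inputs
#' and settings give identical output.
#'
#' @param trios list of [trio_genotypes()] over the same markers.
#' @param K stream capacity per block, or \code{"auto"} (default) for
#'   \code{min(5000, max(64, 4 n))}.
#' @param W maximum block width in markers (default 12).
#' @param epsilon prior Dirichlet pseudocount per catalog haplotype
#'   (default 0.1).
#' @param max_solutions per-trio, per-block enumeration cap (default 4096).
#' @param slice_size cohorts larger than this are phased in consecutive
#'   slices, later slices seeded with earlier top-stream haplotype counts
#'   (default 100 trios).
#' @param prior_haplotypes optional matrix of full-length phased reference
#'   haplotypes (rows) that seed prior pseudocounts in every block.
#' @param mendel_policy \code{"mask"} (default) or \code{"error"}; see
#'   [apply_mendel_policy()].
#' @param verbose log the partition, K and ligation schedule via
#'   \code{message()}.
#' @return A \code{"phased_dataset"} (see [finalize_phasing()]) with
#'   attributes \code{partition} (the [optimal_partition()] result),
#'   \code{schedule} (ligation steps) and \code{K}.
#' @export
tds_phase <- function(trios, K = "auto", W = 12L, epsilon = 0.1,
                      max_solutions = 4096, slice_size = 100L,
                      prior_haplotypes = NULL,
                      mendel_policy = c("mask", "error"), verbose = FALSE) {
  if (inherits(trios, "trio_genotypes")) trios <- list(trios)
  n <- length(trios)
  if (!n) stop("no trios")
  trios <- apply_mendel_policy(trios, match.arg(mendel_policy))
  if (identical(K, "auto")) K <- auto_K(n)
  K <- as.integer(K)
  G <- genotype_matrix(trios)
  part <- optimal_partition(G, W)
  if (verbose)
    message(sprintf("partition: %d block(s), total entropy %.4f; K = %d",
                    nrow(part$blocks), part$total_entropy, K))
  if (!is.null(prior_haplotypes)) {
    prior_haplotypes <- hap_rows(prior_haplotypes)
    if (ncol(prior_haplotypes) != ncol(G))
      stop("prior haplotypes must span all markers")
    if (verbose)
      message(sprintf("prior panel: %d haplotype(s) added as pseudocounts",
                      nrow(prior_haplotypes)))
  }
  blocks <- vector("list", nrow(part$blocks))
  for (b in seq_len(nrow(part$blocks))) {
    iv <- part$blocks[b, ]
    cols <- iv[1L]:iv[2L]
    btrios <- lapply(trios, trio_slice, cols = cols)
    pslice <- if (is.null(prior_haplotypes)) NULL
      else prior_haplotypes[, cols, drop = FALSE]
    blocks[[b]] <- if (n > slice_size)
      run_block_sliced(btrios, iv, G, K, epsilon, pslice, max_solutions,
                       slice_size)
    else
      phased_block(run_block(btrios, K, epsilon, pslice, max_solutions),
                   iv, G)
  }
  lig <- ligate_blocks(blocks, G, K, epsilon, prior_haplotypes)
  if (verbose && nrow(lig$schedule))
    message(sprintf("ligation: %d step(s), first merged interval [%d, %d]",
                    nrow(lig$schedule), lig$schedule$start[1L],
                    lig$schedule$end[1L]))
  out <- finalize_phasing(lig$block, trios)
  attr(out, "partition") <- part
  attr(out, "schedule") <- lig$schedule
  attr(out, "K") <- K
  out
}
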