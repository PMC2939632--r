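# Partition-ligation: merge phased blocks into chromosome-scale solutions.
#
# Each phased block carries up to K weighted solution sets (one phase
# solution per trio).  Two adjacent blocks are merged by forming candidate
# pairs of their solution sets, each with a ligation weight equal to the
# product of the two source weights; the candidates are then re-scored by
# the deterministic-sampling factor over the merged interval (counts rebuilt
# from scratch on the merged catalog) with the score scaled by the ligation
# weight.  Blocks are merged greedily in order of minimum merged-interval
# genotype entropy, the most homogeneous intervals first.

#' Construct a phased block from a block fit
#'
#' Converts the stream set of [run_block()] into the per-trio solution sets
#' (in original trio order) that the ligation stage consumes.
#'
#' @param fit a \code{"tds_block_fit"}.
#' @param interval length-2 integer vector, 1-based inclusive marker range
#'   of the block within the full dataset.
#' @param G full genotype matrix (for the block's genotype entropy).
#' @return Object of class \code{"phased_block"}: list with \code{start},
#'   \code{end}, \code{solutions} (list per stream; each a list per trio of
#'   4 x width matrices, original trio order), \code{weights} and
#'   \code{entropy}.
#' @export
phased_block <- function(fit, interval, G) {
  st <- fit$streams
  n <- length(fit$order)
  inv <- integer(n); inv[fit$order] <- seq_len(n)   # original -> processed pos
  sets <- lapply(seq_len(nrow(st$paths)), function(k) {
    lapply(seq_len(n), function(orig) {
      p <- inv[orig]
      fit$solutions[[p]][[st$paths[k, p]]]
    })
  })
  structure(list(start = interval[1L], end = interval[2L],
                 solutions = sets, weights = exp(st$logw),
                 entropy = segment_entropy(G, interval[1L], interval[2L])),
            class = "phased_block")
}

#' @export
print.phased_block <- function(x, ...) {
  cat(sprintf("phased block [%d, %d]: %d weighted solution set(s), entropy %.4f\n",
              x$start, x$end, length(x$solutions), x$entropy))
  invisible(x)
}

# Build a degenerate phased block directly from solution sets (tests,
# slicing).
new_phased_block <- function(start, end, solutions, weights, entropy = NA_real_) {
  structure(list(start = start, end = end, solutions = solutions,
                 weights = weights, entropy = entropy), class = "phased_block")
}

#' Ligate two adjacent phased blocks
#'
#' Forms all pairs of solution sets from the two blocks, each with ligation
#' weight = product of the source weights; prunes to the top K pairs by
#' ligation weight; re-scores the surviving candidates with the sequential
#' stream factor over the merged interval (Dirichlet counts rebuilt on the
#' merged catalog), scaling each score by its ligation weight; returns the
#' merged block with at most K solution sets, weights normalized.  Trios are
#' scored in ascending order of their number of distinct merged solutions
#' among the candidates.
#'
#' @param a,b phased blocks with \code{a$end + 1 == b$start}.
#' @param K capacity of the merged block.
#' @param G full genotype matrix (merged-interval entropy).
#' @param epsilon prior pseudocount per merged-catalog haplotype.
#' @param prior_haplotypes optional full-length haplotype matrix; the merged
#'   interval's columns seed extra pseudocounts.
#' @return The merged \code{"phased_block"}.
#' @export
merge_blocks <- function(a, b, K, G, epsilon = 0.1, prior_haplotypes = NULL) {
  if (a$end + 1L != b$start) stop("blocks are not adjacent in marker order")
  na <- length(a$solutions); nb <- length(b$solutions)
  n_trios <- length(a$solutions[[1L]])
  ia <- rep(seq_len(na), each = nb)
  ib <- rep(seq_len(nb), times = na)
  ligw <- a$weights[ia] * b$weights[ib]
  if (length(ligw) > K) {
    ord <- order(-ligw, ia, ib)
    keep <- ord[seq_len(K)]
    ia <- ia[keep]; ib <- ib[keep]; ligw <- ligw[keep]
  }
  C <- length(ligw)
  merged <- lapply(seq_len(C), function(c)
    lapply(seq_len(n_trios), function(t)
      cbind(a$solutions[[ia[c]]][[t]], b$solutions[[ib[c]]][[t]])))
  # catalog over the merged interval from candidate haplotypes (+ priors)
  hap_pool <- unlist(lapply(merged, function(set)
    unlist(lapply(set, function(m) lapply(1:4, function(r) m[r, ])),
           recursive = FALSE)), recursive = FALSE)
  catalog <- haplotype_catalog(hap_pool)
  prior_slice <- if (is.null(prior_haplotypes)) NULL
    else prior_haplotypes[, a$start:b$end, drop = FALSE]
  pr <- prior_counts(catalog, prior_slice, epsilon)
  catalog <- pr$catalog
  # candidate-by-trio index array, then score trios in ascending diversity
  idx_by_trio <- lapply(seq_len(n_trios), function(t) {
    m <- t(vapply(seq_len(C), function(c)
      catalog_index(catalog, merged[[c]][[t]]), integer(4L)))
    matrix(m, ncol = 4L)
  })
  div <- vapply(idx_by_trio, function(m) nrow(unique(m)), 1L)
  t_ord <- order(div)
  sc <- score_paths(idx_by_trio[t_ord], pr$rho)
  logw <- base::log(ligw) + sc$logw
  ord <- order(-logw, ia, ib)
  logw <- logw[ord] - log_sum_exp(logw)
  new_phased_block(a$start, b$end, merged[ord], exp(logw),
                   entropy = segment_entropy(G, a$start, b$end))
}

#' Minimum-entropy ligation schedule
#'
#' Greedy schedule: at each step the adjacent block pair whose merged
#' interval has the lowest genotype entropy is merged (ties to the leftmost
#' pair), until one block remains.
#'
#' @param blocks list of phased blocks (or any objects with \code{start} /
#'   \code{end}), adjacent and in marker order.
#' @param G full genotype matrix.
#' @return Data frame with one row per merge step: \code{left} (index of the
#'   left block of the pair at that step, among the blocks remaining),
#'   \code{start}, \code{end}, \code{entropy} of the merged interval.
#' @export
ligation_order <- function(blocks, G) {
  iv <- lapply(blocks, function(b) c(b$start, b$end))
  steps <- list()
  while (length(iv) > 1L) {
    ent <- vapply(seq_len(length(iv) - 1L), function(i)
      segment_entropy(G, iv[[i]][1L], iv[[i + 1L]][2L]), 1.0)
    i <- which.min(ent)      # ties: leftmost
    steps[[length(steps) + 1L]] <-
      data.frame(left = i, start = iv[[i]][1L], end = iv[[i + 1L]][2L],
                 entropy = ent[i])
    iv[[i]] <- c(iv[[i]][1L], iv[[i + 1L]][2L])
    iv[[i + 1L]] <- NULL
  }
  if (!length(steps))
    return(data.frame(left = integer(), start = integer(), end = integer(),
                      entropy = numeric()))
  do.call(rbind, steps)
}

#' Ligate all blocks into one
#'
#' Runs [ligation_order()]'s greedy minimum-entropy schedule, applying
#' [merge_blocks()] at each step.
#'
#' @inheritParams merge_blocks
#' @param blocks list of adjacent phased blocks in marker order.
#' @return List with the final \code{block} and the \code{schedule} data
#'   frame.
#' @export
ligate_blocks <- function(blocks, G, K, epsilon = 0.1, prior_haplotypes = NULL) {
  schedule <- list()
  while (length(blocks) > 1L) {
    ent <- vapply(seq_len(length(blocks) - 1L), function(i)
      segment_entropy(G, blocks[[i]]$start, blocks[[i + 1L]]$end), 1.0)
    i <- which.min(ent)
    schedule[[length(schedule) + 1L]] <-
      data.frame(left = i, start = blocks[[i]]$start,
                 end = blocks[[i + 1L]]$end, entropy = ent[i])
    blocks[[i]] <- merge_blocks(blocks[[i]], blocks[[i + 1L]], K, G,
                                epsilon, prior_haplotypes)
    blocks[[i + 1L]] <- NULL
  }
  list(block = blocks[[1L]],
       schedule = if (length(schedule)) do.call(rbind, schedule)
         else data.frame(left = integer(), start = integer(),
                         end = integer(), entropy = numeric()))
}

#' Finalize a fully ligated block into a phased dataset
#'
#' Extracts the top-weight solution set, checks that it reconstructs every
#' non-missing input genotype, and records which entries were imputed.
#'
#' @param block a single phased block spanning all markers.
#' @param trios the original cohort (original order, full markers).
#' @return Object of class \code{"phased_dataset"}: list with
#'   \code{haplotypes} (per trio a 4 x L matrix, rows \code{f.t, f.u, m.t,
#'   m.u}), \code{weights} (final top-K stream weights), \code{imputed}
#'   (per trio a 3 x L logical matrix, rows father/mother/child).
#' @export
finalize_phasing <- function(block, trios) {
  L <- length(trios[[1L]]$father)
  if (block$start != 1L || block$end != L)
    stop("block does not span all markers; ligate first")
  top <- block$solutions[[which.max(block$weights)]]
  haps <- vector("list", length(trios))
  imputed <- vector("list", length(trios))
  for (i in seq_along(trios)) {
    sol <- top[[i]]
    tr <- trios[[i]]
    gf <- genotype_from_haplotypes(sol["f.t", ], sol["f.u", ])
    gm <- genotype_from_haplotypes(sol["m.t", ], sol["m.u", ])
    gc <- genotype_from_haplotypes(sol["f.t", ], sol["m.t", ])
    obs <- rbind(tr$father, tr$mother, tr$child)
    rec <- rbind(gf, gm, gc)
    miss <- is.na(obs)
    if (any(rec[!miss] != obs[!miss]))
      stop(sprintf("internal error: trio %d solution does not reconstruct its genotypes", i))
    haps[[i]] <- sol
    imputed[[i]] <- miss
    dimnames(imputed[[i]]) <- list(c("father", "mother", "child"), NULL)
  }
  structure(list(haplotypes = haps, weights = block$weights,
                 imputed = imputed), class = "phased_dataset")
}

#' @export
print.phased_dataset <- function(x, ...) {
  L <- ncol(x$haplotypes[[1L]])
  n_imp <- sum(vapply(x$imputed, sum, 1L))
  cat(sprintf("phased dataset: %d trio(s), %d marker(s), %d imputed genotype entrie(s)\n",
              length(x$haplotypes), L, n_imp))
  cat(sprintf("  top stream weight %.4f of %d retained stream(s)\n",
              max(x$weights), length(x$weights)))
  invisible(x)
}
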