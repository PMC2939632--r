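# Core deterministic-sampling recursion over solution streams.
#
# A stream holds one phase solution per already-processed trio, a weight,
# and its own Dirichlet pseudocounts rho over the block's haplotype catalog
# (the sufficient statistics of the haplotype-frequency posterior).  When a
# trio with K_ext candidate solutions is processed, every stream is extended
# by every candidate, each candidate's weight is the parent weight times
#
#     rho_h1 * rho_h2 * rho_h3 * rho_h4 / (sum_m rho_m)^4
#
# evaluated under the parent stream's counts (the posterior-predictive
# factor of drawing the solution's four haplotypes), and only the K
# highest-weight streams survive.  Everything is deterministic; weights are
# kept in log space.

#' Build a haplotype catalog
#'
#' The catalog Z is the ordered set of distinct haplotypes over the current
#' block that appear in any enumerated trio solution (plus any prior
#' haplotypes); Dirichlet counts are vectors aligned to it.
#'
#' @param haps matrix with one haplotype per row (0/1), or a list of
#'   haplotype vectors/solution matrices.
#' @return Object of class \code{"haplotype_catalog"}: list with \code{haps}
#'   (M x L matrix, first-seen order) and \code{keys}.
#' @export
haplotype_catalog <- function(haps) {
  m <- hap_rows(haps)
  keys <- apply(m, 1L, paste, collapse = "")
  keep <- !duplicated(keys)
  structure(list(haps = m[keep, , drop = FALSE], keys = keys[keep]),
            class = "haplotype_catalog")
}

# Normalize haplotype input to a matrix of rows.
hap_rows <- function(haps) {
  if (is.matrix(haps)) return(haps)
  if (is.list(haps)) {
    rows <- lapply(haps, function(h) if (is.matrix(h)) h else matrix(h, nrow = 1L))
    return(do.call(rbind, rows))
  }
  matrix(as_haplotype(haps), nrow = 1L)
}

#' @export
print.haplotype_catalog <- function(x, ...) {
  cat(sprintf("haplotype catalog: %d haplotype(s) over %d marker(s)\n",
              length(x$keys), ncol(x$haps)))
  invisible(x)
}

# Indices of haplotype rows in the catalog (NA when absent).
catalog_index <- function(catalog, haps) {
  m <- hap_rows(haps)
  match(apply(m, 1L, paste, collapse = ""), catalog$keys)
}

catalog_add <- function(catalog, haps) {
  m <- hap_rows(haps)
  keys <- apply(m, 1L, paste, collapse = "")
  new <- !(keys %in% catalog$keys) & !duplicated(keys)
  if (any(new)) {
    catalog$haps <- rbind(catalog$haps, m[new, , drop = FALSE])
    catalog$keys <- c(catalog$keys, keys[new])
  }
  catalog
}

#' Prior Dirichlet pseudocounts over a catalog
#'
#' Every catalog haplotype receives \code{epsilon}; each occurrence of a
#' haplotype in \code{prior_haplotypes} (e.g. a phased reference panel) adds
#' one further pseudocount, which is how external phase knowledge enters the
#' model.  The prior mean frequency of haplotype i is
#' \code{rho_i / sum(rho)}.  Prior haplotypes absent from the catalog are
#' appended to it.
#'
#' @param catalog a [haplotype_catalog()].
#' @param prior_haplotypes optional matrix/list of haplotypes over the same
#'   markers.
#' @param epsilon baseline pseudocount per catalog haplotype (> 0,
#'   default 0.1).
#' @return List with the (possibly extended) \code{catalog} and the count
#'   vector \code{rho}.
#' @export
prior_counts <- function(catalog, prior_haplotypes = NULL, epsilon = 0.1) {
  if (epsilon <= 0) stop("epsilon must be positive")
  if (!is.null(prior_haplotypes) && length(prior_haplotypes))
    catalog <- catalog_add(catalog, prior_haplotypes)
  rho <- rep(epsilon, length(catalog$keys))
  if (!is.null(prior_haplotypes) && length(prior_haplotypes)) {
    idx <- catalog_index(catalog, prior_haplotypes)
    rho <- rho + tabulate(idx, nbins = length(rho))
  }
  list(catalog = catalog, rho = rho)
}

#' Stream-extension factor of one solution
#'
#' The posterior-predictive probability factor of a trio solution's four
#' haplotypes under Dirichlet counts rho:
#' \code{rho_h1 rho_h2 rho_h3 rho_h4 / (sum rho)^4}, the closed form of the
#' marginal over haplotype frequencies.  Scale-invariant in rho.  With
#' \code{exact = TRUE} the exact fourth-order Dirichlet moment
#' \eqn{E[\theta_{h1}\theta_{h2}\theta_{h3}\theta_{h4}]} is used instead
#' (rising factorials for repeated haplotypes); the product-of-means form is
#' the published default.
#'
#' @param sol integer vector of 4 catalog indices (a solution's haplotypes),
#'   or a 4 x L solution matrix together with \code{catalog}.
#' @param counts numeric vector of Dirichlet counts rho.
#' @param log return the log factor.
#' @param exact use the exact joint moment instead of the product of means.
#' @param catalog needed only when \code{sol} is a solution matrix.
#' @return Positive scalar (or its log).
#' @export
solution_factor <- function(sol, counts, log = FALSE, exact = FALSE,
                            catalog = NULL) {
  if (is.matrix(sol)) {
    if (is.null(catalog)) stop("catalog required for a solution matrix")
    sol <- catalog_index(catalog, sol)
  }
  if (length(sol) != 4L || anyNA(sol)) stop("sol must give 4 catalog indices")
  tot <- sum(counts)
  lf <- if (!exact) {
    sum(base::log(counts[sol])) - 4 * base::log(tot)
  } else {
    cnt <- tabulate(sol, nbins = length(counts))
    used <- which(cnt > 0L)
    num <- sum(unlist(lapply(used, function(m)
      base::log(counts[m] + seq_len(cnt[m]) - 1))))
    num - sum(base::log(tot + 0:3))
  }
  if (log) lf else exp(lf)
}

#' Posterior count update for one solution
#'
#' Each of the solution's four haplotypes gains one count (a haplotype used
#' twice gains two); the total increases by exactly 4.
#'
#' @inheritParams solution_factor
#' @return Updated count vector.
#' @export
update_counts <- function(counts, sol, catalog = NULL) {
  if (is.matrix(sol)) {
    if (is.null(catalog)) stop("catalog required for a solution matrix")
    sol <- catalog_index(catalog, sol)
  }
  if (length(sol) != 4L || anyNA(sol)) stop("sol must give 4 catalog indices")
  counts + tabulate(sol, nbins = length(counts))
}

#' Order trios by phase ambiguity
#'
#' Stable ascending sort by the exact number of compatible phase solutions,
#' so that the least ambiguous trios seed the stream set.
#'
#' @param trios list of [trio_genotypes()].
#' @return List with \code{trios} (reordered), \code{order} (original
#'   indices) and \code{counts} (solution counts, reordered).
#' @export
sort_trios <- function(trios) {
  counts <- vapply(trios, function(t) count_ambiguity(t)$n_solutions_bound, 1)
  ord <- order(counts)     # radix: stable, ties keep input order
  list(trios = trios[ord], order = ord, counts = counts[ord])
}

# ---- internal stream-set machinery ----------------------------------------
# A stream set is a list:
#   paths  K x t matrix of chosen solution indices (processed-trio order)
#   logw   normalized log weights (logsumexp = 0)
#   rho    K x M matrix of Dirichlet counts
#   total  K vector of rowSums(rho), maintained incrementally
#   catalog

log_sum_exp <- function(x) {
  m <- max(x)
  m + base::log(sum(exp(x - m)))
}

# Lexicographic ranks of path rows (for deterministic tie-breaking).
path_lex_rank <- function(paths) {
  if (ncol(paths) == 0L) return(rep(1L, nrow(paths)))
  o <- do.call(order, lapply(seq_len(ncol(paths)), function(j) paths[, j]))
  r <- integer(nrow(paths)); r[o] <- seq_len(nrow(paths)); r
}

# Score fixed solution paths: path_sols is a list (one per trio, in
# processing order) of C x 4 index matrices, row c being candidate c's
# solution for that trio.  Returns unnormalized log scores and final counts.
score_paths <- function(path_sols, prior_rho) {
  C <- if (length(path_sols)) nrow(path_sols[[1L]]) else 1L
  M <- length(prior_rho)
  rho <- matrix(prior_rho, nrow = C, ncol = M, byrow = TRUE)
  total <- rep(sum(prior_rho), C)
  lw <- numeric(C)
  rows <- seq_len(C)
  for (t in seq_along(path_sols)) {
    idx <- path_sols[[t]]
    lw <- lw + base::log(rho[cbind(rows, idx[, 1L])]) +
      base::log(rho[cbind(rows, idx[, 2L])]) +
      base::log(rho[cbind(rows, idx[, 3L])]) +
      base::log(rho[cbind(rows, idx[, 4L])]) - 4 * base::log(total)
    for (k in 1:4) {          # sequential so duplicate haplotypes accumulate
      at <- cbind(rows, idx[, k])
      rho[at] <- rho[at] + 1
    }
    total <- total + 4
  }
  list(logw = lw, rho = rho, total = total)
}

#' Initialize the stream set from the least ambiguous trios
#'
#' Uses the longest prefix of the (ascending-sorted) trios whose product of
#' solution counts does not exceed K, enumerating every combination of their
#' solutions as one stream.  Initial weights are proportional to the product
#' of stream-extension factors evaluated sequentially from the prior counts.
#' If even the first trio exceeds K, its solutions are scored under the
#' prior and truncated to the top K.
#'
#' @param sols list (per trio, ascending solution count) of n x 4 catalog
#'   index matrices, one row per candidate solution.
#' @param K stream capacity.
#' @param prior_rho prior Dirichlet counts over the catalog.
#' @param catalog the block's [haplotype_catalog()].
#' @return List with the stream set (\code{streams}) and \code{n_consumed},
#'   the number of trios absorbed at initialization.
#' @export
init_streams <- function(sols, K, prior_rho, catalog) {
  counts <- vapply(sols, nrow, 1L)
  if (is.unsorted(counts)) stop("sols must be sorted ascending by solution count")
  cum <- cumprod(as.numeric(counts))
  n <- if (cum[1L] > K) 1L else max(which(cum <= K))
  if (counts[1L] > K)
    message(sprintf("first trio has %d solutions > K = %d; truncating to top K",
                    counts[1L], K))
  prefix <- seq_len(n)
  grid <- as.matrix(expand.grid(rev(lapply(counts[prefix], seq_len)),
                                KEEP.OUT.ATTRS = FALSE))[, n:1, drop = FALSE]
  colnames(grid) <- NULL
  path_sols <- lapply(prefix, function(t) sols[[t]][grid[, t], , drop = FALSE])
  sc <- score_paths(path_sols, prior_rho)
  ord <- do.call(order, c(list(-sc$logw), lapply(seq_len(n), function(j) grid[, j])))
  keep <- ord[seq_len(min(K, nrow(grid)))]
  logw <- sc$logw[keep]
  st <- list(paths = grid[keep, , drop = FALSE],
             logw = logw - log_sum_exp(logw),
             rho = sc$rho[keep, , drop = FALSE],
             total = sc$total[keep],
             catalog = catalog)
  class(st) <- "stream_set"
  list(streams = st, n_consumed = n)
}

#' Extend all streams by a trio's solutions and prune to capacity
#'
#' Forms every stream-by-solution candidate, weights each by the parent
#' weight times the extension factor under the parent's counts, keeps the K
#' highest-weight candidates (ties broken by lexicographic solution path),
#' updates the survivors' counts and renormalizes the weights.
#'
#' @param streams a stream set (from [init_streams()]).
#' @param sol_idx n x 4 matrix of catalog indices, one row per candidate
#'   solution of the incoming trio.
#' @param K capacity.
#' @return The pruned, updated stream set.
#' @export
extend_and_prune <- function(streams, sol_idx, K) {
  st <- streams
  S <- nrow(sol_idx)
  K0 <- nrow(st$paths)
  lfac <- matrix(0, K0, S)
  log_tot4 <- 4 * base::log(st$total)
  for (s in seq_len(S))
    lfac[, s] <- base::log(st$rho[, sol_idx[s, 1L]]) +
      base::log(st$rho[, sol_idx[s, 2L]]) +
      base::log(st$rho[, sol_idx[s, 3L]]) +
      base::log(st$rho[, sol_idx[s, 4L]]) - log_tot4
  lw <- as.vector(st$logw + lfac)          # column-major: parent fastest
  parent <- rep(seq_len(K0), times = S)
  schoice <- rep(seq_len(S), each = K0)
  if (!any(is.finite(lw))) stop("all candidate stream weights underflowed")
  prank <- path_lex_rank(st$paths)
  ord <- order(-lw, prank[parent], schoice)
  keep <- ord[seq_len(min(K, length(ord)))]
  kp <- parent[keep]; ks <- schoice[keep]
  rho <- st$rho[kp, , drop = FALSE]
  rows <- seq_along(keep)
  for (k in 1:4) {
    at <- cbind(rows, sol_idx[cbind(ks, k)])
    rho[at] <- rho[at] + 1
  }
  logw <- lw[keep]
  st$paths <- cbind(st$paths[kp, , drop = FALSE], ks, deparse.level = 0)
  st$logw <- logw - log_sum_exp(logw)
  st$rho <- rho
  st$total <- st$total[kp] + 4
  st
}

#' @export
print.stream_set <- function(x, ...) {
  cat(sprintf("stream set: %d stream(s) over %d trio(s), catalog of %d haplotype(s)\n",
              nrow(x$paths), ncol(x$paths), length(x$catalog$keys)))
  invisible(x)
}

# Default stream capacity: generous relative to cohort size, capped.
auto_K <- function(n_trios) min(5000L, max(64L, 4L * n_trios))

#' Phase one haplotype block by deterministic sampling
#'
#' Enumerates every trio's phase solutions over the block, orders trios by
#' ascending ambiguity, builds the haplotype catalog from the enumerated
#' solutions (plus any prior haplotypes), seeds the stream set from the
#' least ambiguous trios and processes the rest with [extend_and_prune()].
#'
#' @param trios list of [trio_genotypes()] restricted to the block's
#'   markers.
#' @param K stream capacity, or \code{"auto"} for
#'   \code{min(5000, max(64, 4 n))}.
#' @param epsilon prior pseudocount per catalog haplotype.
#' @param prior_haplotypes optional haplotype matrix over the block's
#'   markers seeding extra pseudocounts.
#' @param max_solutions per-trio enumeration cap; trios exceeding it fall
#'   back to catalog-restricted enumeration of missing completions.
#' @return Object of class \code{"tds_block_fit"}: the final stream set plus
#'   the processing order, per-trio solution lists and the catalog.
#' @export
run_block <- function(trios, K = "auto", epsilon = 0.1,
                      prior_haplotypes = NULL, max_solutions = 4096) {
  n <- length(trios)
  if (!n) stop("no trios")
  if (identical(K, "auto")) K <- auto_K(n)
  K <- as.integer(K)
  # pass 1: unrestricted enumeration where the bound allows it
  sols <- vector("list", n)
  over <- logical(n)
  for (i in seq_len(n)) {
    b <- count_ambiguity(trios[[i]])$n_solutions_bound
    if (b > max_solutions) over[i] <- TRUE
    else sols[[i]] <- enumerate_trio_solutions(trios[[i]], max_solutions)
  }
  hap_pool <- unlist(lapply(sols[!over], function(sl)
    lapply(sl, function(m) lapply(1:4, function(r) m[r, ]))),
    recursive = FALSE)
  hap_pool <- unlist(hap_pool, recursive = FALSE)
  if (any(over)) {
    if (!length(hap_pool)) stop("every trio exceeds max_solutions; shrink blocks")
    restrict <- haplotype_catalog(hap_pool)$haps
    for (i in which(over))
      sols[[i]] <- enumerate_trio_solutions(trios[[i]], max_solutions, restrict)
    hap_pool <- c(hap_pool, unlist(lapply(sols[over], function(sl)
      unlist(lapply(sl, function(m) lapply(1:4, function(r) m[r, ])),
             recursive = FALSE)), recursive = FALSE))
  }
  catalog <- haplotype_catalog(hap_pool)
  pr <- prior_counts(catalog, prior_haplotypes, epsilon)
  catalog <- pr$catalog
  counts <- vapply(sols, length, 1L)
  ord <- order(counts)
  sols_sorted <- sols[ord]
  sol_idx <- lapply(sols_sorted, function(sl) {
    m <- t(vapply(sl, function(s) catalog_index(catalog, s), integer(4L)))
    if (ncol(m) != 4L) m <- matrix(m, ncol = 4L)   # single-solution trios
    m
  })
  ini <- init_streams(sol_idx, K, pr$rho, catalog)
  st <- ini$streams
  t0 <- ini$n_consumed
  if (t0 < n)
    for (t in seq.int(t0 + 1L, n))
      st <- extend_and_prune(st, sol_idx[[t]], K)
  structure(list(streams = st, order = ord, solutions = sols_sorted,
                 sol_idx = sol_idx, catalog = catalog, K = K,
                 counts = counts[ord], prior_rho = pr$rho),
            class = "tds_block_fit")
}

#' @export
print.tds_block_fit <- function(x, ...) {
  cat(sprintf("TDS block fit: %d trio(s), %d surviving stream(s) (K = %d), %d catalog haplotype(s)\n",
              length(x$order), nrow(x$streams$paths), x$K, length(x$catalog$keys)))
  invisible(x)
}
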