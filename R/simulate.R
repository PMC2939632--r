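# Synthetic trio cohorts from a block-mosaic haplotype pool.
#
# The pool emulates the features real trio panels present to a phaser:
# limited haplotype diversity inside blocks (a few skewed-frequency founder
# segments per block), recombination concentrated at block boundaries
# (hotspots), a minor-allele-frequency floor, and configurable marker count
# and genotype missingness.  It deliberately does not model demography,
# genotyping error or fine-scale recombination variation.

#' Simulation configuration
#'
#' Defaults mirror a standard trio phasing study design: 30 trios typed at
#' 200 markers (a 1 Mb region at 1 SNP per 5 kb), minor allele frequency
#' floor 0.05, every parental haplotype distinct (pool of 4 per trio), and
#' no missing genotypes unless requested.
#'
#' @param n_haplotypes_pool pool size; must be >= 4 * n_trios so every
#'   individual carries distinct haplotypes.
#' @param n_markers markers after MAF filtering.
#' @param n_trios cohort size.
#' @param block_diversity founder haplotype segments per block (<= 8 keeps
#'   diversity in the range block-based phasers exploit).
#' @param block_len markers per founder block (expected block scale).
#' @param recomb_hotspot_rate probability of switching founder lineage at
#'   each block boundary (hotspot crossover rate).
#' @param maf_min minimum pooled minor allele frequency, in (0, 0.5).
#' @param missing_rate per-genotype-entry missingness probability in [0, 1).
#' @param seed master seed; expands to independent per-stage seeds.
#' @return A list of class \code{"sim_config"}.
#' @export
sim_config <- function(n_haplotypes_pool = 120L, n_markers = 200L,
                       n_trios = 30L, block_diversity = 8L, block_len = 10L,
                       recomb_hotspot_rate = 0.1, maf_min = 0.05,
                       missing_rate = 0, seed = 1L) {
  cfg <- list(n_haplotypes_pool = as.integer(n_haplotypes_pool),
              n_markers = as.integer(n_markers), n_trios = as.integer(n_trios),
              block_diversity = as.integer(block_diversity),
              block_len = as.integer(block_len),
              recomb_hotspot_rate = recomb_hotspot_rate, maf_min = maf_min,
              missing_rate = missing_rate, seed = as.integer(seed))
  stopifnot(cfg$n_haplotypes_pool >= 4L * cfg$n_trios,
            cfg$maf_min > 0, cfg$maf_min < 0.5,
            cfg$missing_rate >= 0, cfg$missing_rate < 1,
            cfg$block_diversity >= 1L, cfg$block_len >= 1L,
            cfg$recomb_hotspot_rate >= 0, cfg$recomb_hotspot_rate <= 1)
  class(cfg) <- "sim_config"
  cfg
}

# One master seed -> independent child seeds per stage, so pool, haplotype
# assignment, transmission and masking are separately reproducible.
derive_seeds <- function(seed) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  s <- sample.int(.Machine$integer.max - 1L, 4L)
  names(s) <- c("pool", "assign", "transmit", "mask")
  s
}

#' Simulate a block-mosaic haplotype pool
#'
#' Per founder block, \code{block_diversity} founder segments are drawn with
#' Zipf-skewed lineage frequencies; each pool haplotype follows one founder
#' lineage, switching lineage with probability \code{recomb_hotspot_rate} at
#' each block boundary.  Columns are recoded so 0 is the pooled major
#' allele, markers below \code{maf_min} are dropped, and generation repeats
#' until \code{n_markers} passing markers exist.
#'
#' @param cfg a [sim_config()].
#' @return Integer matrix, \code{n_haplotypes_pool} x \code{n_markers}.
#' @export
simulate_pool <- function(cfg) {
  seeds <- derive_seeds(cfg$seed)
  set.seed(seeds[["pool"]])
  H <- cfg$n_haplotypes_pool
  d <- cfg$block_diversity
  lineage_w <- (1 / seq_len(d)); lineage_w <- lineage_w / sum(lineage_w)
  lineage <- sample.int(d, H, replace = TRUE, prob = lineage_w)
  kept <- matrix(integer(0), nrow = H, ncol = 0L)
  for (round in seq_len(60L)) {
    if (ncol(kept) >= cfg$n_markers) break
    # one founder block
    p <- runif(cfg$block_len, min = cfg$maf_min, max = 0.5)
    founders <- matrix(rbinom(d * cfg$block_len, 1L, rep(p, each = d)),
                       nrow = d)
    block <- founders[lineage, , drop = FALSE]
    # hotspot at the block boundary: lineage may switch before next block
    switchers <- runif(H) < cfg$recomb_hotspot_rate
    lineage[switchers] <- sample.int(d, sum(switchers), replace = TRUE,
                                     prob = lineage_w)
    freq1 <- colMeans(block)
    flip <- freq1 > 0.5
    block[, flip] <- 1L - block[, flip]
    maf <- colMeans(block)
    kept <- cbind(kept, block[, maf >= cfg$maf_min, drop = FALSE])
  }
  if (ncol(kept) < cfg$n_markers)
    stop("could not reach n_markers under the MAF floor; relax maf_min or block_diversity")
  kept[, seq_len(cfg$n_markers), drop = FALSE]
}

#' Simulate trio genotypes with known truth
#'
#' Assigns each parent two pool haplotypes, drawing without replacement
#' across the whole cohort so no two individuals share a haplotype; one
#' haplotype per parent is chosen (uniformly) as transmitted, the child's
#' genotype is built from the two transmitted haplotypes, and genotype
#' entries are masked to missing independently at \code{missing_rate}.
#'
#' @param pool haplotype pool matrix from [simulate_pool()].
#' @param cfg the same [sim_config()].
#' @return List with \code{trios} (list of [trio_genotypes()], masked) and
#'   \code{truth}, a \code{"trio_truth"} object holding per-trio true
#'   solution matrices (rows \code{f.t, f.u, m.t, m.u}), the pre-masking
#'   genotypes and the missingness masks.
#' @export
simulate_trios <- function(pool, cfg) {
  seeds <- derive_seeds(cfg$seed)
  n <- cfg$n_trios
  if (nrow(pool) < 4L * n) stop("pool too small for distinct assignment")
  set.seed(seeds[["assign"]])
  pick <- sample.int(nrow(pool), 4L * n)
  set.seed(seeds[["transmit"]])
  tf <- sample.int(2L, n, replace = TRUE)   # which father haplotype transmits
  tm <- sample.int(2L, n, replace = TRUE)
  set.seed(seeds[["mask"]])
  trios <- vector("list", n)
  sols <- vector("list", n)
  genos <- vector("list", n)
  masks <- vector("list", n)
  for (i in seq_len(n)) {
    fh <- pool[pick[c(4L * i - 3L, 4L * i - 2L)], , drop = FALSE]
    mh <- pool[pick[c(4L * i - 1L, 4L * i)], , drop = FALSE]
    sol <- rbind(f.t = fh[tf[i], ], f.u = fh[3L - tf[i], ],
                 m.t = mh[tm[i], ], m.u = mh[3L - tm[i], ])
    g <- rbind(father = genotype_from_haplotypes(sol["f.t", ], sol["f.u", ]),
               mother = genotype_from_haplotypes(sol["m.t", ], sol["m.u", ]),
               child = genotype_from_haplotypes(sol["f.t", ], sol["m.t", ]))
    mask <- matrix(runif(length(g)) < cfg$missing_rate, nrow = 3L,
                   dimnames = dimnames(g))
    gm <- g
    gm[mask] <- NA_integer_
    trios[[i]] <- trio_genotypes(gm["father", ], gm["mother", ], gm["child", ])
    sols[[i]] <- sol
    genos[[i]] <- g
    masks[[i]] <- mask
  }
  truth <- structure(list(solutions = sols, genotypes = genos, masks = masks),
                     class = "trio_truth")
  list(trios = trios, truth = truth)
}

#' Simulate a full trio dataset
#'
#' Convenience wrapper: [simulate_pool()] then [simulate_trios()].
#'
#' @param cfg a [sim_config()].
#' @return List with \code{pool}, \code{trios}, \code{truth}.
#' @export
simulate_dataset <- function(cfg = sim_config()) {
  pool <- simulate_pool(cfg)
  sim <- simulate_trios(pool, cfg)
  c(list(pool = pool), sim)
}

#' @export
print.trio_truth <- function(x, ...) {
  cat(sprintf("trio truth: %d trio(s), %d marker(s), %d masked entrie(s)\n",
              length(x$solutions), ncol(x$solutions[[1L]]),
              sum(vapply(x$masks, sum, 1L))))
  invisible(x)
}
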