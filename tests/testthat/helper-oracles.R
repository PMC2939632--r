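# Independent brute-force oracles and random-instance generators used
# across the suite.  The oracles deliberately avoid the package's internal
# recursions: enumeration filters all haplotype pairs, the partition oracle
# tries every width-capped boundary set, and the path scorer re-derives the
# sequential stream weights with plain loops.

# A Mendelian-consistent random trio built from four random haplotypes,
# optionally with missing entries.
random_trio <- function(L, missing_rate = 0) {
  h <- matrix(sample(0:1, 4L * L, replace = TRUE), nrow = 4L)
  g <- rbind(genotype_from_haplotypes(h[1L, ], h[2L, ]),
             genotype_from_haplotypes(h[3L, ], h[4L, ]),
             genotype_from_haplotypes(h[1L, ], h[3L, ]))
  if (missing_rate > 0)
    g[matrix(runif(3L * L) < missing_rate, nrow = 3L)] <- NA_integer_
  trio_genotypes(g[1L, ], g[2L, ], g[3L, ])
}

# Trio genotypes implied by a 4 x L solution matrix.
trio_from_solution <- function(sol) {
  trio_genotypes(genotype_from_haplotypes(sol["f.t", ], sol["f.u", ]),
                 genotype_from_haplotypes(sol["m.t", ], sol["m.u", ]),
                 genotype_from_haplotypes(sol["f.t", ], sol["m.t", ]))
}

sol_key <- function(m) paste(apply(m, 1L, paste, collapse = ""), collapse = "|")

# Exhaustive enumeration oracle: all ordered parental haplotype pairs,
# filtered by genotype compatibility and child transmission.
oracle_enumerate <- function(trio) {
  L <- length(trio$father)
  haps <- as.matrix(expand.grid(rep(list(0:1), L), KEEP.OUT.ATTRS = FALSE))
  pair_ok <- function(g) {
    n <- nrow(haps)
    ok <- matrix(TRUE, n, n)
    for (s in seq_len(L)) {
      if (is.na(g[s])) next
      a <- haps[, s]
      ok <- ok & if (g[s] == 0L) outer(a == 0L, a == 0L, "&")
        else if (g[s] == 1L) outer(a == 1L, a == 1L, "&")
        else outer(a, a, "!=")
    }
    ok
  }
  Fp <- which(pair_ok(trio$father), arr.ind = TRUE)  # rows (transmitted, untransmitted)
  Mp <- which(pair_ok(trio$mother), arr.ind = TRUE)
  okc <- pair_ok(trio$child)
  combo <- expand.grid(f = seq_len(nrow(Fp)), m = seq_len(nrow(Mp)))
  keep <- okc[cbind(Fp[combo$f, 1L], Mp[combo$m, 1L])]
  combo <- combo[keep, , drop = FALSE]
  lapply(seq_len(nrow(combo)), function(r) {
    m <- rbind(haps[Fp[combo$f[r], 1L], ], haps[Fp[combo$f[r], 2L], ],
               haps[Mp[combo$m[r], 1L], ], haps[Mp[combo$m[r], 2L], ])
    rownames(m) <- c("f.t", "f.u", "m.t", "m.u")
    m
  })
}

# Exhaustive partition oracle: minimum total entropy over every boundary
# set obeying the width cap.
oracle_partition_entropy <- function(G, W) {
  L <- ncol(G)
  best <- Inf
  n_cutpoints <- L - 1L
  for (mask in 0:(2^n_cutpoints - 1L)) {
    cuts <- if (n_cutpoints) which(bitwAnd(mask, 2^(seq_len(n_cutpoints) - 1L)) > 0L)
      else integer(0)
    bounds <- c(0L, cuts, L)
    widths <- diff(bounds)
    if (any(widths > W)) next
    tot <- sum(vapply(seq_along(widths), function(b)
      segment_entropy(G, bounds[b] + 1L, bounds[b + 1L]), 1.0))
    best <- min(best, tot)
  }
  best
}

# Naive sequential path scorer: enumerates every solution combination and
# accumulates the stream factor rho_h1..rho_h4 / (sum rho)^4 with plain
# loops and count updates.
naive_path_weights <- function(sol_idx, prior_rho) {
  counts <- vapply(sol_idx, nrow, 1L)
  n <- length(counts)
  grid <- as.matrix(expand.grid(rev(lapply(counts, seq_len)),
                                KEEP.OUT.ATTRS = FALSE))[, n:1, drop = FALSE]
  colnames(grid) <- NULL
  w <- numeric(nrow(grid))
  for (r in seq_len(nrow(grid))) {
    rho <- prior_rho
    wt <- 1
    for (t in seq_len(n)) {
      idx <- sol_idx[[t]][grid[r, t], ]
      wt <- wt * prod(rho[idx]) / sum(rho)^4
      for (k in idx) rho[k] <- rho[k] + 1
    }
    w[r] <- wt
  }
  list(paths = grid, w = w)
}
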