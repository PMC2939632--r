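# Accuracy metric definitions on constructed fixtures with hand-computed
# values, plus their invariances and the random baseline.

# Build a trio_truth object from true solution matrices and missingness
# masks (genotypes derived from the solutions).
make_truth <- function(sols, masks = NULL) {
  genos <- lapply(sols, function(sol)
    rbind(father = genotype_from_haplotypes(sol["f.t", ], sol["f.u", ]),
          mother = genotype_from_haplotypes(sol["m.t", ], sol["m.u", ]),
          child = genotype_from_haplotypes(sol["f.t", ], sol["m.t", ])))
  if (is.null(masks))
    masks <- lapply(genos, function(g) {
      m <- g == 99L
      m[] <- FALSE
      m
    })
  structure(list(solutions = sols, genotypes = genos, masks = masks),
            class = "trio_truth")
}

sol_mat <- function(...) {
  m <- rbind(...)
  rownames(m) <- c("f.t", "f.u", "m.t", "m.u")
  m
}

# Fixture: 3 trios over 4 markers.  Site tuple (1,0,0,1) or (0,1,1,0) is a
# triple-heterozygous (ambiguous) site; (0,0,0,0) is resolved.
fixture <- local({
  amb1 <- c(1L, 0L, 0L, 1L)    # column tuples (f.t,f.u,m.t,m.u)
  amb2 <- c(0L, 1L, 1L, 0L)
  hom <- c(0L, 0L, 0L, 0L)
  s1 <- sol_mat(c(1, 0, 0, 0), c(0, 0, 1, 0), c(0, 0, 1, 0), c(1, 0, 0, 0))
  # build columns explicitly instead: sites trio1 = A,B,A,B
  t1 <- cbind(amb1, hom, amb2, hom); rownames(t1) <- c("f.t", "f.u", "m.t", "m.u")
  t2 <- cbind(amb1, hom, hom, hom); rownames(t2) <- rownames(t1)
  t3 <- cbind(hom, hom, hom, amb2); rownames(t3) <- rownames(t1)
  masks <- lapply(1:3, function(i) matrix(FALSE, 3, 4,
    dimnames = list(c("father", "mother", "child"), NULL)))
  masks[[1]]["father", 2] <- TRUE   # resolved site, imputed correctly
  masks[[2]]["mother", 1] <- TRUE   # ambiguous site: excluded from TER denom
  masks[[3]]["child", 2] <- TRUE    # will be mis-imputed
  truth <- make_truth(list(t1, t2, t3), masks)
  # inferred: flip trio 2's ambiguous site and mis-impute trio 3's child
  inf <- list(t1, t2, t3)
  inf[[2]][, 1] <- amb2             # father+mother phase flipped at site 1
  inf[[3]]["f.t", 2] <- 1L          # child allele wrong at the masked entry
  list(truth = truth, inferred = inf)
})

test_that("transmission error rate matches the hand-computed fixture", {
  # denominator: trio1 2 amb sites x 2 parents = 4; trio2 father only
  # (mother masked) = 1; trio3 1 amb site x 2 = 2 -> 7.  numerator: trio2
  # father's flipped transmission -> 1.
  expect_equal(transmission_error_rate(fixture$truth, fixture$inferred), 1 / 7)
  expect_equal(transmission_error_rate(fixture$truth, fixture$truth$solutions), 0)
})

test_that("incorrect trios counts phase and imputation failures once per trio", {
  # trio2 mis-phased, trio3 mis-imputed, trio1 clean -> 2
  expect_identical(incorrect_trios(fixture$truth, fixture$inferred), 2L)
  expect_identical(incorrect_trios(fixture$truth, fixture$truth$solutions), 0L)
})

test_that("allelic imputation error rate counts mismatched alleles over masked alleles", {
  # 3 masked entries = 6 alleles; trio1's is correct; trio2's mother pair is
  # the same unordered pair after the flip (no allele error); trio3's child
  # pair (1,0) vs truth (0,0) -> 1 mismatch -> 1/6
  expect_equal(allelic_imputation_error_rate(fixture$truth, fixture$inferred),
               1 / 6)
  expect_equal(allelic_imputation_error_rate(fixture$truth,
                                             fixture$truth$solutions), 0)
})

test_that("degenerate denominators return zero with a note", {
  hom <- sol_mat(c(0, 0), c(0, 0), c(0, 0), c(0, 0))
  truth <- make_truth(list(hom))
  expect_message(ter <- transmission_error_rate(truth, list(hom)),
                 "no ambiguous")
  expect_identical(ter, 0)
  expect_message(aier <- allelic_imputation_error_rate(truth, list(hom)),
                 "no masked")
  expect_identical(aier, 0)
})

test_that("metrics are invariant to trio order and parent relabeling", {
  perm <- c(3, 1, 2)
  permute <- function(x, p) {
    if (inherits(x, "trio_truth"))
      structure(list(solutions = x$solutions[p], genotypes = x$genotypes[p],
                     masks = x$masks[p]), class = "trio_truth")
    else x[p]
  }
  expect_equal(transmission_error_rate(permute(fixture$truth, perm),
                                       permute(fixture$inferred, perm)),
               transmission_error_rate(fixture$truth, fixture$inferred))
  swap_parents <- function(sol) sol[c("m.t", "m.u", "f.t", "f.u"), , drop = FALSE]
  swap_truth <- function(x) {
    structure(list(
      solutions = lapply(x$solutions, function(s) {
        m <- swap_parents(s); rownames(m) <- c("f.t", "f.u", "m.t", "m.u"); m
      }),
      genotypes = lapply(x$genotypes, function(g) {
        m <- g[c("mother", "father", "child"), , drop = FALSE]
        rownames(m) <- c("father", "mother", "child"); m
      }),
      masks = lapply(x$masks, function(mk) {
        m <- mk[c("mother", "father", "child"), , drop = FALSE]
        rownames(m) <- c("father", "mother", "child"); m
      })), class = "trio_truth")
  }
  swapped_inf <- lapply(fixture$inferred, function(s) {
    m <- swap_parents(s); rownames(m) <- c("f.t", "f.u", "m.t", "m.u"); m
  })
  expect_equal(transmission_error_rate(swap_truth(fixture$truth), swapped_inf),
               transmission_error_rate(fixture$truth, fixture$inferred))
  expect_identical(incorrect_trios(swap_truth(fixture$truth), swapped_inf),
                   incorrect_trios(fixture$truth, fixture$inferred))
  expect_equal(allelic_imputation_error_rate(swap_truth(fixture$truth),
                                             swapped_inf),
               allelic_imputation_error_rate(fixture$truth, fixture$inferred))
})

test_that("random phasing errs on about half of the ambiguous genotypes", {
  set.seed(77)
  amb <- sol_mat(rep(1, 10), rep(0, 10), rep(0, 10), rep(1, 10))
  truth <- make_truth(rep(list(amb), 8))
  trios <- lapply(truth$genotypes, function(g)
    trio_genotypes(g["father", ], g["mother", ], g["child", ]))
  rates <- vapply(1:20, function(s)
    transmission_error_rate(truth, phase_random(trios, seed = s)), 1.0)
  expect_gt(mean(rates), 0.4)
  expect_lt(mean(rates), 0.6)
})
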