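# Accuracy metrics for trio phasing against a known truth, plus the
# random-phase baseline.

# Accept either a phased_dataset or a bare list of 4 x L solution matrices.
get_haps <- function(x) {
  if (inherits(x, "phased_dataset")) x$haplotypes
  else if (inherits(x, "trio_truth")) x$solutions
  else x
}

# Ambiguous (triple-heterozygous) sites per trio, from the PRE-MASKING
# genotypes, so missingness does not silently shrink the denominator.
ambiguous_sites <- function(truth, i) {
  g <- truth$genotypes[[i]]
  which(g["father", ] == 2L & g["mother", ] == 2L & g["child", ] == 2L)
}

#' Transmission error rate
#'
#' The proportion of non-missing parental genotypes with ambiguous phase
#' (the triple-heterozygous sites) whose inferred transmitted/untransmitted
#' assignment differs from the truth.  Ambiguity is judged on the original
#' complete genotypes; an observed-missing parental entry at an ambiguous
#' site is excluded from the denominator.  A cohort with no ambiguous
#' parental genotypes returns 0 (with a note).
#'
#' @param truth a \code{"trio_truth"} from [simulate_trios()].
#' @param inferred a \code{"phased_dataset"} (or list of 4 x L solution
#'   matrices in the same trio order).
#' @return Error rate in [0, 1].
#' @export
transmission_error_rate <- function(truth, inferred) {
  haps <- get_haps(inferred)
  if (length(haps) != length(truth$solutions)) stop("cohort size mismatch")
  num <- 0L; den <- 0L
  for (i in seq_along(haps)) {
    amb <- ambiguous_sites(truth, i)
    if (!length(amb)) next
    if (ncol(haps[[i]]) != ncol(truth$solutions[[i]])) stop("marker count mismatch")
    for (s in amb) {
      for (par in c("f", "m")) {
        row_obs <- if (par == "f") "father" else "mother"
        if (truth$masks[[i]][row_obs, s]) next   # observed missing: excluded
        den <- den + 1L
        tkey <- paste0(par, ".t")
        if (haps[[i]][tkey, s] != truth$solutions[[i]][tkey, s])
          num <- num + 1L
      }
    }
  }
  if (den == 0L) {
    message("no ambiguous non-missing parental genotypes; transmission error rate defined as 0")
    return(0)
  }
  num / den
}

# Allele mismatches between two unordered allele pairs (0, 1 or 2).
pair_mismatches <- function(a, b) {
  sum(sort(a) != sort(b))
}

# Per-trio error flags: any mis-phased ambiguous parental entry, or any
# mis-imputed allele at a masked entry.
trio_error_flags <- function(truth, inferred) {
  haps <- get_haps(inferred)
  vapply(seq_along(haps), function(i) {
    sol <- haps[[i]]; tru <- truth$solutions[[i]]
    for (s in ambiguous_sites(truth, i)) {
      if (sol["f.t", s] != tru["f.t", s] || sol["m.t", s] != tru["m.t", s])
        return(TRUE)
    }
    mk <- truth$masks[[i]]
    pairs <- list(father = c("f.t", "f.u"), mother = c("m.t", "m.u"),
                  child = c("f.t", "m.t"))
    for (member in rownames(mk)) {
      for (s in which(mk[member, ])) {
        rw <- pairs[[member]]
        if (pair_mismatches(sol[rw, s], tru[rw, s]) > 0L) return(TRUE)
      }
    }
    FALSE
  }, TRUE)
}

#' Number of incorrectly phased trios
#'
#' Counts trios with at least one mis-phased ambiguous parental genotype or
#' one mis-imputed allele at a masked entry.
#'
#' @inheritParams transmission_error_rate
#' @return Integer count, at most the number of trios.
#' @export
incorrect_trios <- function(truth, inferred) {
  sum(trio_error_flags(truth, inferred))
}

#' Allelic imputation error rate
#'
#' The proportion of mistakenly inferred alleles among all masked (missing)
#' alleles: each masked genotype entry contributes its two alleles, compared
#' to the truth as an unordered pair within that individual and site.  No
#' masked entries returns 0 (with a note).
#'
#' @inheritParams transmission_error_rate
#' @return Error rate in [0, 1].
#' @export
allelic_imputation_error_rate <- function(truth, inferred) {
  haps <- get_haps(inferred)
  if (length(haps) != length(truth$solutions)) stop("cohort size mismatch")
  pairs <- list(father = c("f.t", "f.u"), mother = c("m.t", "m.u"),
                child = c("f.t", "m.t"))
  num <- 0L; den <- 0L
  for (i in seq_along(haps)) {
    mk <- truth$masks[[i]]
    for (member in rownames(mk)) {
      for (s in which(mk[member, ])) {
        rw <- pairs[[member]]
        den <- den + 2L
        num <- num + pair_mismatches(haps[[i]][rw, s],
                                     truth$solutions[[i]][rw, s])
      }
    }
  }
  if (den == 0L) {
    message("no masked alleles; allelic imputation error rate defined as 0")
    return(0)
  }
  num / den
}

#' Random-phase baseline
#'
#' Phases each trio site-by-site using only Mendelian logic: resolved sites
#' take their forced assignment; ambiguous or missing-data sites take a
#' uniformly random consistent assignment.  The expected transmission error
#' rate of this baseline is 0.5 per ambiguous parental genotype, the
#' reference point an informative phaser must beat.
#'
#' @param trios list of [trio_genotypes()].
#' @param seed RNG seed for the random choices.
#' @return List of 4 x L solution matrices (same layout as the truth),
#'   usable directly in the metric functions.
#' @export
phase_random <- function(trios, seed = 1L) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  lapply(trios, function(tr) {
    L <- length(tr$father)
    sol <- matrix(0L, 4L, L, dimnames = list(c("f.t", "f.u", "m.t", "m.u"), NULL))
    for (s in seq_len(L)) {
      rows <- site_tuple_rows(tr$father[s], tr$mother[s], tr$child[s])
      if (!length(rows)) stop(sprintf("Mendelian inconsistency at site %d", s))
      pick <- if (length(rows) == 1L) rows else rows[sample.int(length(rows), 1L)]
      sol[, s] <- .tuples16[pick, ]
    }
    sol
  })
}
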