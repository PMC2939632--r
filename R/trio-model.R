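# Per-site phase logic and exhaustive enumeration of trio phase solutions.
#
# A solution assigns four haplotypes to a trio: the transmitted and
# untransmitted haplotype of the father (rows "f.t", "f.u") and of the
# mother ("m.t", "m.u").  The child's two haplotypes are the transmitted
# pair (f.t, m.t).  Site by site, the allele assignment is a 4-tuple
# (f.t, f.u, m.t, m.u); Mendelian logic fixes it everywhere except where
# all three genotypes are heterozygous, so a trio with L' triple-het sites
# and no missing data has exactly 2^L' solutions.

# All 16 allele 4-tuples in descending lexicographic order over
# (f.t, f.u, m.t, m.u).  This fixed order makes enumeration deterministic,
# with the father-transmits-minor branch first at ambiguous sites.
.tuples16 <- local({
  g <- expand.grid(m.u = c(1L, 0L), m.t = c(1L, 0L),
                   f.u = c(1L, 0L), f.t = c(1L, 0L))
  m <- as.matrix(g[, c("f.t", "f.u", "m.t", "m.u")])
  dimnames(m) <- list(NULL, c("f.t", "f.u", "m.t", "m.u"))
  m
})

# Rows of .tuples16 consistent with one site's three genotype codes.
# A missing code constrains nothing.
site_tuple_rows <- function(f, m, c) {
  ok_geno <- function(code, a1, a2) {
    if (is.na(code)) return(rep(TRUE, length(a1)))
    if (code == 0L) a1 == 0L & a2 == 0L
    else if (code == 1L) a1 == 1L & a2 == 1L
    else a1 != a2
  }
  t <- .tuples16
  which(ok_geno(f, t[, 1L], t[, 2L]) &
        ok_geno(m, t[, 3L], t[, 4L]) &
        ok_geno(c, t[, 1L], t[, 3L]))
}

#' Phase status of a single trio site
#'
#' Applies Mendelian transmission logic to one marker.  The assignment of
#' alleles to (father transmitted, father untransmitted, mother transmitted,
#' mother untransmitted) is unique unless all three members are heterozygous
#' (the only truly ambiguous configuration) or a genotype is missing; an
#' impossible configuration (e.g. father 0, child 1) is a Mendelian error.
#'
#' @param father_code,mother_code,child_code genotype codes in \{0,1,2,NA\}.
#' @return A list of class \code{"site_phase"} with \code{status} (one of
#'   \code{"RESOLVED"}, \code{"AMBIGUOUS"}, \code{"HAS_MISSING"},
#'   \code{"MENDEL_ERROR"}) and, when resolved, \code{resolved_alleles}, the
#'   named allele 4-tuple.
#' @examples
#' infer_site_phase(2, 0, 2)  # father must transmit the minor allele
#' infer_site_phase(2, 2, 2)  # ambiguous
#' @export
infer_site_phase <- function(father_code, mother_code, child_code) {
  codes <- c(father_code, mother_code, child_code)
  codes <- suppressWarnings(as.integer(codes))
  rows <- site_tuple_rows(codes[1L], codes[2L], codes[3L])
  status <- if (length(rows) == 0L) "MENDEL_ERROR"
    else if (!anyNA(codes) && all(codes == 2L)) "AMBIGUOUS"
    else if (length(rows) == 1L) "RESOLVED"
    else "HAS_MISSING"
  res <- structure(list(status = status, resolved_alleles = NULL),
                   class = "site_phase")
  if (status == "RESOLVED") res$resolved_alleles <- .tuples16[rows, ]
  res
}

# Per-site lists of admissible tuple rows for a whole trio; the basic object
# both the enumerator and the ambiguity counter work from.
trio_site_rows <- function(trio) {
  L <- length(trio$father)
  lapply(seq_len(L), function(s)
    site_tuple_rows(trio$father[s], trio$mother[s], trio$child[s]))
}

#' Count phase ambiguity of a trio
#'
#' Reports the number of triple-heterozygous (phase-ambiguous) sites, the
#' number of missing genotype entries, and the exact number of compatible
#' phase solutions (the product over sites of admissible allele
#' assignments; sites are independent, so the product is exact).  A
#' Mendelian-inconsistent trio has a solution bound of 0.
#'
#' @param trio a [trio_genotypes()] object.
#' @return List with \code{n_ambiguous_sites}, \code{n_missing_entries},
#'   \code{n_solutions_bound} (a double; may be large).
#' @export
count_ambiguity <- function(trio) {
  rows <- trio_site_rows(trio)
  amb <- !is.na(trio$father) & !is.na(trio$mother) & !is.na(trio$child) &
    trio$father == 2L & trio$mother == 2L & trio$child == 2L
  list(n_ambiguous_sites = sum(amb),
       n_missing_entries = sum(is.na(trio$father)) + sum(is.na(trio$mother)) +
         sum(is.na(trio$child)),
       n_solutions_bound = prod(vapply(rows, length, 1L)))
}

# Build the 4 x L solution matrix from one tuple-row choice per site.
solution_from_choice <- function(rows_per_site, choice) {
  L <- length(rows_per_site)
  sol <- matrix(0L, nrow = 4L, ncol = L,
                dimnames = list(c("f.t", "f.u", "m.t", "m.u"), NULL))
  for (s in seq_len(L)) sol[, s] <- .tuples16[rows_per_site[[s]][choice[s]], ]
  sol
}

#' Enumerate every phase solution of a trio
#'
#' Returns all assignments of four haplotypes (father transmitted /
#' untransmitted, mother transmitted / untransmitted) consistent with the
#' three genotypes.  With no missing data the list has exactly 2^L' entries
#' for L' triple-heterozygous sites; missing entries are enumerated over all
#' allele completions consistent with the non-missing members.  The order is
#' deterministic: lexicographic over site-wise choices, earlier sites most
#' significant, with the father-transmits-minor branch first at ambiguous
#' sites.
#'
#' @param trio a [trio_genotypes()] object.
#' @param max_solutions cap on the enumeration size (default 4096).  When the
#'   completion bound exceeds the cap and \code{restrict} is supplied,
#'   missing-site completions are restricted to haplotypes present in
#'   \code{restrict}; otherwise an error asks the caller to shrink the block.
#' @param restrict optional haplotype matrix (rows = haplotypes over the same
#'   markers) used to prune missing-data completions under the cap.
#' @return List of 4 x L integer matrices with rows
#'   \code{f.t, f.u, m.t, m.u}.
#' @examples
#' trio <- trio_genotypes("22", "22", "22")
#' length(enumerate_trio_solutions(trio))  # 4 = 2^2
#' @export
enumerate_trio_solutions <- function(trio, max_solutions = 4096, restrict = NULL) {
  rows <- trio_site_rows(trio)
  n_per_site <- vapply(rows, length, 1L)
  if (any(n_per_site == 0L)) {
    site <- which(n_per_site == 0L)[1L]
    stop(structure(class = c("mendel_error", "error", "condition"),
                   list(message = sprintf(
                     "Mendelian inconsistency at site %d (father=%s, mother=%s, child=%s)",
                     site, trio$father[site], trio$mother[site], trio$child[site]),
                     call = sys.call(-1L), site = site)))
  }
  bound <- prod(n_per_site)
  if (bound > max_solutions) {
    if (is.null(restrict))
      stop(sprintf(paste0("trio has %.0f candidate solutions (> max_solutions = %d); ",
                          "shrink the block or supply a restriction catalog"),
                   bound, max_solutions))
    return(enumerate_restricted(rows, restrict, max_solutions))
  }
  L <- length(rows)
  # earlier sites most significant: site 1 varies slowest
  grid <- as.matrix(expand.grid(rev(lapply(n_per_site, seq_len)),
                                KEEP.OUT.ATTRS = FALSE))[, L:1, drop = FALSE]
  lapply(seq_len(nrow(grid)), function(r)
    solution_from_choice(rows, grid[r, ]))
}

# Depth-first enumeration with every partial haplotype constrained to be a
# prefix of some row of `restrict`; used only when the unrestricted bound
# exceeds the cap (heavily missing trios).
enumerate_restricted <- function(rows, restrict, max_solutions) {
  restrict <- as.matrix(restrict)
  L <- length(rows)
  if (ncol(restrict) != L) stop("restriction catalog has wrong marker count")
  out <- list()
  cand0 <- replicate(4L, seq_len(nrow(restrict)), simplify = FALSE)
  recurse <- function(s, choice, cand) {
    if (s > L) {
      if (length(out) >= max_solutions)
        stop("restricted enumeration still exceeds max_solutions")
      out[[length(out) + 1L]] <<- solution_from_choice(rows, choice)
      return(invisible())
    }
    for (k in seq_along(rows[[s]])) {
      tup <- .tuples16[rows[[s]][k], ]
      cand2 <- lapply(1:4, function(i) cand[[i]][restrict[cand[[i]], s] == tup[i]])
      if (any(vapply(cand2, length, 1L) == 0L)) next
      recurse(s + 1L, c(choice, k), cand2)
    }
  }
  recurse(1L, integer(0), cand0)
  out
}

# Apply the Mendelian-inconsistency policy across a cohort: sites where a
# trio admits no allele assignment are set to missing in all three members
# (policy "mask", with a warning) or raise an error (policy "error").
#' Screen a cohort for Mendelian inconsistencies
#' @param trios list of [trio_genotypes()].
#' @param policy \code{"mask"} (default) sets inconsistent sites to missing
#'   in all three members and warns; \code{"error"} stops at the first one.
#' @return The (possibly modified) trio list.
#' @export
apply_mendel_policy <- function(trios, policy = c("mask", "error")) {
  policy <- match.arg(policy)
  n_masked <- 0L
  for (i in seq_along(trios)) {
    rows <- trio_site_rows(trios[[i]])
    bad <- which(vapply(rows, length, 1L) == 0L)
    if (length(bad)) {
      if (policy == "error")
        stop(sprintf("Mendelian inconsistency in trio %d at site(s) %s",
                     i, paste(bad, collapse = ", ")))
      trios[[i]]$father[bad] <- NA_integer_
      trios[[i]]$mother[bad] <- NA_integer_
      trios[[i]]$child[bad] <- NA_integer_
      n_masked <- n_masked + length(bad)
    }
  }
  if (n_masked > 0L)
    warning(sprintf("%d Mendelian-inconsistent site(s) set to missing", n_masked))
  trios
}
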