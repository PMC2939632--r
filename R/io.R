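# File formats: PLINK PED/MAP ingestion, a minimal trio genotype matrix
# format for tests and simulation output, haplotype panel files, and the
# phased-output writer/reader.

#' Read trio genotypes from PLINK PED/MAP files
#'
#' Whitespace-delimited PED (family, individual, father, mother, sex,
#' phenotype, then two allele columns per marker; allele \code{0} =
#' missing) and MAP (chromosome, marker id, genetic distance, position).
#' Every family must contain exactly a father, a mother and a child.  Per
#' marker, alleles are recoded by frequency among the parents: the more
#' frequent symbol becomes 0 (major), the other 1 (minor); ties go to the
#' ASCII-smaller symbol.  Genotypes with one missing allele are treated as
#' missing.
#'
#' @param ped_path,map_path file paths.
#' @return List with \code{trios} (list of [trio_genotypes()]),
#'   \code{pedigree} (data frame: family, father/mother/child ids),
#'   \code{markers} (the MAP table) and \code{alleles} (2 x L character
#'   matrix, rows \code{major}, \code{minor}).
#' @export
read_ped_map <- function(ped_path, map_path) {
  map <- utils::read.table(map_path, header = FALSE,
                           col.names = c("chrom", "id", "cm", "pos"),
                           colClasses = c("character", "character",
                                          "numeric", "integer"))
  for (ch in unique(map$chrom)) {
    p <- map$pos[map$chrom == ch]
    if (any(diff(p) <= 0))
      stop(sprintf("marker positions not strictly increasing on chromosome %s", ch))
  }
  L <- nrow(map)
  ped <- utils::read.table(ped_path, header = FALSE, colClasses = "character")
  if (ncol(ped) != 6L + 2L * L)
    stop(sprintf("PED has %d columns; expected %d for %d markers",
                 ncol(ped), 6L + 2L * L, L))
  fam <- ped[[1L]]; ind <- ped[[2L]]; fa <- ped[[3L]]; mo <- ped[[4L]]
  al <- as.matrix(ped[, -(1:6), drop = FALSE])
  a1 <- al[, seq(1L, 2L * L, by = 2L), drop = FALSE]
  a2 <- al[, seq(2L, 2L * L, by = 2L), drop = FALSE]
  fams <- unique(fam)
  ped_tab <- data.frame(family = character(0), father = character(0),
                        mother = character(0), child = character(0))
  trio_rows <- list()
  for (f in fams) {
    rows <- which(fam == f)
    if (length(rows) != 3L)
      stop(sprintf("family %s has %d members; trios require exactly 3", f, length(rows)))
    child <- rows[fa[rows] != "0" & mo[rows] != "0"]
    if (length(child) != 1L)
      stop(sprintf("family %s does not contain exactly one child", f))
    fr <- rows[ind[rows] == fa[child]]
    mr <- rows[ind[rows] == mo[child]]
    if (length(fr) != 1L || length(mr) != 1L)
      stop(sprintf("family %s: child's parents not resolvable", f))
    ped_tab <- rbind(ped_tab, data.frame(family = f, father = ind[fr],
                                         mother = ind[mr], child = ind[child]))
    trio_rows[[length(trio_rows) + 1L]] <- c(fr, mr, child)
  }
  parent_rows <- unlist(lapply(trio_rows, function(r) r[1:2]))
  alleles <- matrix("", 2L, L, dimnames = list(c("major", "minor"), map$id))
  half_missing <- 0L
  code_mat <- matrix(NA_integer_, nrow(ped), L)
  for (j in seq_len(L)) {
    sym <- c(a1[parent_rows, j], a2[parent_rows, j])
    sym <- sym[sym != "0"]
    us <- sort(unique(sym))
    if (length(us) > 2L)
      stop(sprintf("marker %s has more than 2 alleles (%s)",
                   map$id[j], paste(us, collapse = ", ")))
    if (length(us) == 0L) us <- c("A", "A")  # fully missing marker: arbitrary
    cnt <- vapply(us, function(u) sum(sym == u), 1L)
    major <- us[order(-cnt, us)][1L]         # ties: ASCII-smaller is major
    minor <- if (length(us) == 2L) setdiff(us, major) else major
    alleles[, j] <- c(major, minor)
    x1 <- a1[, j]; x2 <- a2[, j]
    miss <- x1 == "0" | x2 == "0"
    half_missing <- half_missing + sum(xor(x1 == "0", x2 == "0"))
    code <- ifelse(x1 == x2, ifelse(x1 == major, 0L, 1L), 2L)
    code[miss] <- NA_integer_
    code_mat[, j] <- code
  }
  if (half_missing > 0L)
    message(sprintf("%d half-missing genotype(s) treated as missing", half_missing))
  trios <- lapply(trio_rows, function(r)
    trio_genotypes(code_mat[r[1L], ], code_mat[r[2L], ], code_mat[r[3L], ]))
  list(trios = trios, pedigree = ped_tab, markers = map, alleles = alleles)
}

#' Write / read the minimal trio genotype matrix format
#'
#' One whitespace-separated row per individual in father, mother, child
#' order per trio; symbols \code{0 1 2 ?}.
#'
#' @param trios list of [trio_genotypes()].
#' @param path file path.
#' @export
write_trio_matrix <- function(trios, path) {
  G <- genotype_matrix(trios)
  lines <- apply(G, 1L, function(r)
    paste(ifelse(is.na(r), "?", r), collapse = " "))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_trio_matrix
#' @export
read_trio_matrix <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) %% 3L != 0L)
    stop("row count is not a multiple of 3 (father, mother, child per trio)")
  rows <- lapply(strsplit(trimws(lines), "[[:space:]]+"), function(x) {
    x[x == "?"] <- NA
    as.integer(x)
  })
  lapply(seq_len(length(rows) / 3L), function(i)
    trio_genotypes(rows[[3L * i - 2L]], rows[[3L * i - 1L]], rows[[3L * i]]))
}

#' Read a haplotype panel file
#'
#' One haplotype per line as a compact 0/1 string (whitespace ignored);
#' suitable for reference panels supplied as prior pseudocounts.
#'
#' @param path file path.
#' @return Integer matrix, one haplotype per row.
#' @export
read_hap_file <- function(path) {
  lines <- readLines(path)
  lines <- gsub("[[:space:]]", "", lines)
  lines <- lines[nzchar(lines)]
  do.call(rbind, lapply(lines, function(l) as_haplotype(l)))
}

#' @rdname read_hap_file
#' @param haps haplotype matrix (rows) to write.
#' @export
write_hap_file <- function(haps, path) {
  haps <- hap_rows(haps)
  writeLines(apply(haps, 1L, paste, collapse = ""), path)
  invisible(path)
}

#' Write / read a phased dataset
#'
#' Writes three plain-text files under \code{dir}: \code{haplotypes.txt}
#' (per trio four lines -- father transmitted/untransmitted, mother
#' transmitted/untransmitted -- as tab-separated trio index, role, 0/1
#' haplotype string; the child's two haplotypes are the two transmitted
#' lines), \code{weights.txt} (final top-K stream weights) and
#' \code{mask.txt} (trio, member, site of every imputed entry).
#' \code{read_phased()} round-trips the haplotypes and weights.
#'
#' @param phased a \code{"phased_dataset"}.
#' @param dir output directory (created if needed).
#' @export
write_phased <- function(phased, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  roles <- c("father_transmitted", "father_untransmitted",
             "mother_transmitted", "mother_untransmitted")
  lines <- unlist(lapply(seq_along(phased$haplotypes), function(i) {
    m <- phased$haplotypes[[i]]
    vapply(1:4, function(r)
      paste(i, roles[r], paste(m[r, ], collapse = ""), sep = "\t"), "")
  }))
  writeLines(lines, file.path(dir, "haplotypes.txt"))
  writeLines(format(phased$weights, digits = 15L),
             file.path(dir, "weights.txt"))
  mask_lines <- unlist(lapply(seq_along(phased$imputed), function(i) {
    mk <- phased$imputed[[i]]
    idx <- which(mk, arr.ind = TRUE)
    if (!nrow(idx)) return(character(0))
    paste(i, rownames(mk)[idx[, 1L]], idx[, 2L], sep = "\t")
  }))
  writeLines(mask_lines, file.path(dir, "mask.txt"))
  invisible(dir)
}

#' @rdname write_phased
#' @export
read_phased <- function(dir) {
  tab <- utils::read.table(file.path(dir, "haplotypes.txt"), sep = "\t",
                           colClasses = c("integer", "character", "character"))
  n <- max(tab[[1L]])
  haps <- lapply(seq_len(n), function(i) {
    rows <- tab[tab[[1L]] == i, ]
    m <- do.call(rbind, lapply(rows[[3L]], as_haplotype))
    rownames(m) <- c("f.t", "f.u", "m.t", "m.u")
    m
  })
  weights <- as.numeric(readLines(file.path(dir, "weights.txt")))
  list(haplotypes = haps, weights = weights)
}
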