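#' Diploid genotype matrix
#'
#' Container for diploid biallelic genotypes at polymorphic sites: per
#' sample and site, the count of derived (or alternate) alleles in
#' \{0, 1, 2, NA\}. Sites are ordered with strictly increasing positions
#' within each chromosome; when `polarized` is `TRUE`, allele 0 is the
#' ancestral state so derived-allele counts are meaningful for unfolded
#' site-frequency spectra.
#'
#' @param geno integer matrix, sites in rows and samples in columns;
#'   values 0, 1, 2 or `NA`.
#' @param chrom character vector of sequence names, one per site.
#' @param pos integer vector of 1-based positions, one per site; strictly
#'   increasing within each chromosome.
#' @param sample_ids character vector of unique sample identifiers.
#' @param pop optional character vector assigning each sample to a
#'   population (or super-population) label.
#' @param polarized logical; is allele 0 known to be ancestral?
#'
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(geno, chrom, pos, sample_ids, pop = NULL,
                            polarized = FALSE) {
  geno <- as.matrix(geno)
  storage.mode(geno) <- "integer"
  n_sites <- nrow(geno)
  n_samples <- ncol(geno)
  if (n_samples < 1L) stop("at least one sample is required")
  if (length(sample_ids) != n_samples || anyDuplicated(sample_ids))
    stop("sample_ids must be unique and match the genotype columns")
  if (length(chrom) != n_sites || length(pos) != n_sites)
    stop("chrom and pos must have one entry per site")
  bad <- geno[!is.na(geno)]
  if (length(bad) && (any(bad < 0L) || any(bad > 2L)))
    stop("genotypes must be 0, 1, 2 or NA")
  pos <- as.integer(pos)
  if (n_sites > 1L) {
    same <- chrom[-1L] == chrom[-n_sites]
    if (any(same & diff(pos) <= 0L))
      stop("positions must be strictly increasing within each chromosome")
  }
  if (!is.null(pop) && length(pop) != n_samples)
    stop("pop must have one label per sample")
  colnames(geno) <- sample_ids
  structure(
    list(geno = geno, chrom = as.character(chrom), pos = pos,
         sample_ids = as.character(sample_ids),
         pop = if (is.null(pop)) NULL else as.character(pop),
         polarized = isTRUE(polarized)),
    class = "genotype_matrix"
  )
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", nrow(x$geno), "sites x", length(x$sample_ids),
      "samples;", length(unique(x$chrom)), "sequences;",
      if (x$polarized) "polarized" else "unpolarized", "\n")
  if (!is.null(x$pop)) {
    tab <- table(x$pop)
    cat("  populations:",
        paste(names(tab), tab, sep = ":", collapse = " "), "\n")
  }
  invisible(x)
}

#' Number of sites in a genotype matrix
#' @param g a [genotype_matrix()].
#' @return Integer site count.
#' @export
n_sites <- function(g) {
  stopifnot(inherits(g, "genotype_matrix"))
  nrow(g$geno)
}

# subset sites, preserving order
subset_sites <- function(g, keep) {
  genotype_matrix(g$geno[keep, , drop = FALSE], g$chrom[keep], g$pos[keep],
                  g$sample_ids, pop = g$pop, polarized = g$polarized)
}
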