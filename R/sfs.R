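#' Filter to biallelic sites by minor allele count
#'
#' Keeps sites at which both alleles are observed among non-missing
#' genotypes and the minor allele count is strictly greater than
#' `mac_min` (the conventional filter for structure/tree site sets uses
#' `mac_min = 3`, i.e. MAC > 3, which excludes autapomorphy-dominated
#' sites). Missing genotypes are excluded from the counts.
#'
#' @param g a [genotype_matrix()].
#' @param mac_min minor-allele-count threshold; sites with MAC
#'   `<= mac_min` are removed.
#' @return The filtered [genotype_matrix()]; the number of removed sites
#'   is attached as attribute `n_removed` and logged.
#' @export
filter_biallelic_mac <- function(g, mac_min = 3) {
  stopifnot(inherits(g, "genotype_matrix"))
  alt <- rowSums(g$geno, na.rm = TRUE)
  tot <- 2L * rowSums(!is.na(g$geno))
  mac <- pmin(alt, tot - alt)
  keep <- alt > 0 & alt < tot & mac > mac_min
  message("filter_biallelic_mac: kept ", sum(keep), " of ", length(keep),
          " site(s)")
  out <- subset_sites(g, keep)
  attr(out, "n_removed") <- sum(!keep)
  out
}

#' Thin sites to a minimum pairwise distance
#'
#' Greedy left-to-right scan per chromosome: the first site of each
#' chromosome is kept, and a subsequent site is kept if and only if its
#' position is at least `min_bp` after the last kept site. Used to avoid
#' sites in linkage (the conventional spacing is 20 kb).
#'
#' @param g a [genotype_matrix()] with positions sorted within
#'   chromosome.
#' @param min_bp minimum distance between kept sites, in bp (inclusive:
#'   sites spaced exactly `min_bp` apart are both kept).
#' @return The thinned [genotype_matrix()].
#' @export
thin_by_distance <- function(g, min_bp = 20000) {
  stopifnot(inherits(g, "genotype_matrix"))
  n <- n_sites(g)
  keep <- logical(n)
  last_chrom <- NA_character_
  last_pos <- -Inf
  for (i in seq_len(n)) {
    if (!identical(g$chrom[i], last_chrom)) {
      last_chrom <- g$chrom[i]
      last_pos <- -Inf
    }
    if (g$pos[i] - last_pos >= min_bp || !is.finite(last_pos)) {
      keep[i] <- TRUE
      last_pos <- g$pos[i]
    }
  }
  message("thin_by_distance: kept ", sum(keep), " of ", n, " site(s)")
  subset_sites(g, keep)
}

#' Pool populations into super-populations
#'
#' Relabels each sample's population according to a population-to-
#' super-population mapping; genotypes are untouched. The pooled haploid
#' sample size of a super-population is twice its diploid sample count
#' (e.g. one fully re-sequenced individual from each of three nearby
#' populations pools to a haploid size of 6).
#'
#' @param g a [genotype_matrix()].
#' @param mapping named character vector: population label ->
#'   super-population label.
#' @param metadata optional data frame from [read_metadata()] providing
#'   each sample's population; if omitted, `g$pop` is used.
#' @return The relabeled [genotype_matrix()].
#' @export
pool_superpopulations <- function(g, mapping, metadata = NULL) {
  stopifnot(inherits(g, "genotype_matrix"))
  if (!length(mapping) || is.null(names(mapping)))
    stop("mapping must be a non-empty named vector")
  pops <- if (!is.null(metadata)) {
    i <- match(g$sample_ids, metadata$sample_id)
    if (anyNA(i)) stop("sample(s) absent from metadata: ",
                       paste(g$sample_ids[is.na(i)], collapse = ", "))
    metadata$population[i]
  } else {
    if (is.null(g$pop)) stop("no population labels available")
    g$pop
  }
  unmapped <- setdiff(unique(pops), names(mapping))
  if (length(unmapped))
    stop("population(s) not in mapping: ", paste(unmapped, collapse = ", "))
  g$pop <- unname(mapping[pops])
  g
}

#' Compute the joint unfolded site-frequency spectrum
#'
#' Tallies, for each site, the tuple of derived-allele counts per
#' (super-)population into a multidimensional array of dimension
#' `prod(haploid size + 1)`. Requires polarized genotypes (allele 0
#' ancestral). Sites with any missing genotype among the pooled samples
#' are dropped and counted. The fixed-ancestral cell `(0, ..., 0)` and
#' fixed-derived cell `(n1, ..., nk)` are populated but flagged
#' monomorphic; composite-likelihood fitting conditions on the
#' polymorphic cells.
#'
#' @param g a polarized [genotype_matrix()].
#' @param pops per-sample super-population labels; defaults to `g$pop`.
#' @return An object of class `joint_sfs` with fields `pop_labels`,
#'   `sample_sizes` (haploid), `counts` (array), `polarized`,
#'   `n_dropped` and `monomorphic_cells` (linear indices).
#' @export
compute_joint_sfs <- function(g, pops = NULL) {
  stopifnot(inherits(g, "genotype_matrix"))
  if (!g$polarized)
    stop("compute_joint_sfs requires polarized genotypes")
  if (is.null(pops)) pops <- g$pop
  if (is.null(pops)) stop("no population labels available")
  labels <- unique(pops)
  sizes <- 2L * as.integer(table(factor(pops, levels = labels)))
  complete <- rowSums(is.na(g$geno)) == 0L
  n_dropped <- sum(!complete)
  if (n_dropped > 0)
    message("compute_joint_sfs: dropped ", n_dropped,
            " site(s) with missing genotypes")
  gg <- g$geno[complete, , drop = FALSE]
  counts_per_pop <- vapply(labels, function(lab)
    rowSums(gg[, pops == lab, drop = FALSE]), numeric(nrow(gg)))
  if (nrow(gg) == 1L) counts_per_pop <- matrix(counts_per_pop, nrow = 1L)
  dims <- sizes + 1L
  stride <- cumprod(c(1L, dims[-length(dims)]))
  idx <- 1L + as.vector(counts_per_pop %*% stride)
  counts <- array(tabulate(idx, nbins = prod(dims)), dim = dims)
  new_joint_sfs(labels, sizes, counts, n_dropped)
}

new_joint_sfs <- function(labels, sizes, counts, n_dropped = 0L) {
  structure(list(pop_labels = labels, sample_sizes = sizes,
                 counts = counts, polarized = TRUE,
                 n_dropped = as.integer(n_dropped),
                 monomorphic_cells = c(1L, prod(sizes + 1L))),
            class = "joint_sfs")
}

#' @export
print.joint_sfs <- function(x, ...) {
  poly <- sum(x$counts) - sum(x$counts[x$monomorphic_cells])
  cat("joint_sfs over", paste(x$pop_labels, collapse = ", "),
      "(haploid sizes", paste(x$sample_sizes, collapse = ", "), ")\n")
  cat("  ", poly, "polymorphic site(s),",
      sum(x$counts[x$monomorphic_cells]), "monomorphic,",
      x$n_dropped, "dropped\n")
  invisible(x)
}

# polymorphic-cell counts as a flat vector
sfs_poly_counts <- function(sfs) {
  as.vector(sfs$counts)[-sfs$monomorphic_cells]
}

#' Write / read a joint SFS in a plain-text layout
#'
#' The layout is a small header (`labels`, `sizes`, `dropped`) followed
#' by one line per nonzero cell: the derived-allele count in each
#' population and the cell count, whitespace-separated.
#'
#' @param sfs a `joint_sfs`.
#' @param path output (or input) file path.
#' @return `write_sfs` returns the path invisibly; `read_sfs` returns a
#'   `joint_sfs`.
#' @export
write_sfs <- function(sfs, path) {
  stopifnot(inherits(sfs, "joint_sfs"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# splitself joint unfolded SFS",
               paste("labels:", paste(sfs$pop_labels, collapse = " ")),
               paste("sizes:", paste(sfs$sample_sizes, collapse = " ")),
               paste("dropped:", sfs$n_dropped)), con)
  nz <- which(sfs$counts != 0)
  if (length(nz)) {
    coords <- arrayInd(nz, dim(sfs$counts)) - 1L
    writeLines(paste(apply(coords, 1, paste, collapse = " "),
                     sfs$counts[nz]), con)
  }
  invisible(path)
}

#' @rdname write_sfs
#' @export
read_sfs <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  labels <- strsplit(sub("^labels: *", "", lines[1]), " ")[[1]]
  sizes <- as.integer(strsplit(sub("^sizes: *", "", lines[2]), " ")[[1]])
  dropped <- as.integer(sub("^dropped: *", "", lines[3]))
  counts <- array(0L, dim = sizes + 1L)
  body <- lines[-(1:3)]
  body <- body[nzchar(body)]
  for (ln in body) {
    v <- as.integer(strsplit(trimws(ln), " +")[[1]])
    k <- length(v)
    counts[matrix(v[-k] + 1L, 1L)] <- v[k]
  }
  new_joint_sfs(labels, sizes, counts, dropped)
}
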