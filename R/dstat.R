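#' Patterson's D statistic (ABBA-BABA) with block jackknife
#'
#' Allele-frequency form of the four-taxon introgression test. For each
#' site with derived-allele frequencies p1, p2, p3, p4 in the quartet
#' (P1, P2, P3, outgroup),
#' `ABBA = (1 - p1) p2 p3 (1 - p4)` and `BABA = p1 (1 - p2) p3 (1 - p4)`;
#' `D = sum(ABBA - BABA) / sum(ABBA + BABA)`. Under the species topology
#' ((P1, P2), P3) and no gene flow, E\[D\] = 0; an excess of ABBA
#' (D > 0) indicates gene flow between P2 and P3. The standard error
#' comes from a delete-one block jackknife over contiguous genomic
#' blocks of `block_size_bp` and Z = D / SE; by the field's convention
#' |Z| >= 3 is taken as evidence of introgression.
#'
#' @param g a [genotype_matrix()]. If unpolarized, sites are polarized
#'   by the outgroup major allele (sites with outgroup frequency exactly
#'   0.5 are dropped).
#' @param quartet list with elements `P1`, `P2`, `P3`, `O`, each a
#'   vector of sample ids; the four sets must be disjoint.
#' @param block_size_bp jackknife block size in bp (blocks are
#'   `[1, b], (b, 2b], ...` per chromosome).
#' @return An object of class `dstat_result`: `D`, `abba`, `baba`, `se`,
#'   `z`, `n_blocks`, `n_sites`, and flags `undefined` (zero
#'   denominator) and `jackknife_refused` (fewer than 3 non-empty
#'   blocks).
#' @export
patterson_d <- function(g, quartet, block_size_bp = 1e6) {
  stopifnot(inherits(g, "genotype_matrix"))
  sets <- quartet[c("P1", "P2", "P3", "O")]
  if (any(vapply(sets, is.null, logical(1))))
    stop("quartet must have elements P1, P2, P3 and O")
  all_ids <- unlist(sets)
  if (anyDuplicated(all_ids)) stop("quartet sample sets must be disjoint")
  missing_ids <- setdiff(all_ids, g$sample_ids)
  if (length(missing_ids))
    stop("unknown sample(s): ", paste(missing_ids, collapse = ", "))
  freqs <- vapply(sets, function(ids) {
    sub <- g$geno[, ids, drop = FALSE]
    rowSums(sub, na.rm = TRUE) / (2 * rowSums(!is.na(sub)))
  }, numeric(n_sites(g)))
  if (n_sites(g) == 1L) freqs <- matrix(freqs, nrow = 1L)
  ok <- rowSums(is.na(freqs)) == 0L
  if (!g$polarized) {
    flip <- freqs[, 4] > 0.5
    amb <- freqs[, 4] == 0.5
    freqs[flip & ok, ] <- 1 - freqs[flip & ok, ]
    ok <- ok & !amb
  }
  freqs <- freqs[ok, , drop = FALSE]
  p1 <- freqs[, 1]; p2 <- freqs[, 2]; p3 <- freqs[, 3]; p4 <- freqs[, 4]
  abba <- (1 - p1) * p2 * p3 * (1 - p4)
  baba <- p1 * (1 - p2) * p3 * (1 - p4)
  num <- sum(abba - baba)
  den <- sum(abba + baba)
  res <- list(D = NA_real_, abba = sum(abba), baba = sum(baba),
              se = NA_real_, z = NA_real_, n_blocks = 0L,
              n_sites = sum(ok), undefined = FALSE,
              jackknife_refused = FALSE)
  if (den == 0) {
    res$undefined <- TRUE
    return(structure(res, class = "dstat_result"))
  }
  res$D <- num / den
  block <- paste(g$chrom[ok], (g$pos[ok] - 1L) %/% block_size_bp)
  contrib_num <- tapply(abba - baba, block, sum)
  contrib_den <- tapply(abba + baba, block, sum)
  B <- length(contrib_num)
  res$n_blocks <- B
  if (B < 3L) {
    res$jackknife_refused <- TRUE
    return(structure(res, class = "dstat_result"))
  }
  d_jack <- (num - contrib_num) / (den - contrib_den)
  d_jack <- d_jack[is.finite(d_jack)]
  B <- length(d_jack)
  res$se <- sqrt((B - 1) / B * sum((d_jack - mean(d_jack))^2))
  res$z <- if (res$se > 0) res$D / res$se else NA_real_
  structure(res, class = "dstat_result")
}

#' @export
print.dstat_result <- function(x, ...) {
  if (x$undefined) {
    cat("dstat_result: D undefined (zero denominator)\n")
    return(invisible(x))
  }
  cat(sprintf("dstat_result: D = %.4f (ABBA %.2f, BABA %.2f), %d site(s)\n",
              x$D, x$abba, x$baba, x$n_sites))
  if (x$jackknife_refused)
    cat("  jackknife refused: fewer than 3 non-empty blocks\n")
  else
    cat(sprintf("  block jackknife: SE = %.4f, Z = %.2f (%d blocks)\n",
                x$se, x$z, x$n_blocks))
  invisible(x)
}
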