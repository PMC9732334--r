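#' Multilocus inbreeding coefficient F_IS
#'
#' Per polymorphic locus, `H_obs` is the fraction of heterozygous
#' individuals and `H_exp = 2 p q * n / (n - 1)` the sample-size
#' corrected expected heterozygosity (n = diploid count with data at the
#' locus). The multilocus estimator is
#' `F_IS = 1 - sum(H_obs) / sum(H_exp)` over polymorphic loci — the
#' heterozygote deficit relative to Hardy-Weinberg, which at
#' mixed-mating equilibrium equals F = s / (2 - s).
#'
#' @param g a [genotype_matrix()] restricted to one population (>= 2
#'   samples).
#' @return An object of class `mating_system_estimate` with fields
#'   `fis`, `fis_per_locus`, `n_loci_used`, `method =
#'   "fis_equilibrium"`, and `undefined = TRUE` when every locus is
#'   monomorphic (F_IS cannot be determined under very low
#'   polymorphism).
#' @export
fis_multilocus <- function(g) {
  stopifnot(inherits(g, "genotype_matrix"))
  if (length(g$sample_ids) < 2L) stop("at least 2 samples are required")
  n <- rowSums(!is.na(g$geno))
  alt <- rowSums(g$geno, na.rm = TRUE)
  p <- alt / (2 * n)
  poly <- n >= 2L & p > 0 & p < 1
  if (!any(poly)) {
    return(structure(list(fis = NA_real_, fis_per_locus = numeric(0),
                          n_loci_used = 0L, t_m = NA_real_,
                          t_sd = NA_real_, method = "fis_equilibrium",
                          undefined = TRUE),
                     class = "mating_system_estimate"))
  }
  h_obs <- rowSums(g$geno == 1L, na.rm = TRUE)[poly] / n[poly]
  pq <- p[poly] * (1 - p[poly])
  h_exp <- 2 * pq * n[poly] / (n[poly] - 1)
  structure(list(fis = 1 - sum(h_obs) / sum(h_exp),
                 fis_per_locus = 1 - h_obs / h_exp,
                 n_loci_used = sum(poly), t_m = NA_real_, t_sd = NA_real_,
                 method = "fis_equilibrium", undefined = FALSE),
            class = "mating_system_estimate")
}

#' @export
print.mating_system_estimate <- function(x, ...) {
  cat("mating_system_estimate (", x$method, ")\n", sep = "")
  if (isTRUE(x$undefined)) {
    cat("  undefined (insufficient polymorphism or detection power)\n")
    return(invisible(x))
  }
  if (!is.na(x$fis))
    cat(sprintf("  multilocus F_IS = %.4f over %d locus/loci\n", x$fis,
                x$n_loci_used))
  if (!is.na(x$t_m))
    cat(sprintf("  multilocus outcrossing rate t_m = %.4f (SD %.4f)\n",
                x$t_m, x$t_sd))
  invisible(x)
}

#' Convert between F, selfing rate and outcrossing rate
#'
#' Applies the mixed-mating equilibrium identities
#' `F = s / (2 - s)`, `s = 2 F / (1 + F)`, `t = 1 - s =
#' (1 - F) / (1 + F)`. Supply exactly one of `F`, `s` or `t`.
#'
#' @param F inbreeding coefficient in \[0, 1\].
#' @param s selfing rate in \[0, 1\].
#' @param t outcrossing rate in \[0, 1\].
#' @return List with all three quantities.
#' @export
mating_system_conversions <- function(F = NULL, s = NULL, t = NULL) {
  given <- !c(is.null(F), is.null(s), is.null(t))
  if (sum(given) != 1L) stop("supply exactly one of F, s or t")
  chk <- function(x, nm) {
    if (x < 0 || x > 1) stop(nm, " must lie in [0, 1]")
    x
  }
  if (!is.null(F)) {
    F <- chk(F, "F"); s <- 2 * F / (1 + F)
  } else if (!is.null(s)) {
    s <- chk(s, "s"); F <- s / (2 - s)
  } else {
    t <- chk(t, "t"); s <- 1 - t; F <- s / (2 - s)
  }
  list(F = F, s = s, t = 1 - s)
}

#' Map F_IS to an outcrossing rate
#'
#' By default uses the equilibrium identity `t = (1 - F) / (1 + F)`. An
#' empirical calibration table (columns `F` and `t`, e.g. from an
#' extensive progeny-array study relating the two in a related species)
#' can be supplied instead and is applied by linear interpolation; note
#' that empirical curves typically give lower t than the equilibrium
#' identity at intermediate F.
#'
#' @param F inbreeding coefficient(s) in \[0, 1\].
#' @param calibration optional data frame with columns `F` and `t`.
#' @return Outcrossing rate(s).
#' @export
fis_to_outcrossing <- function(F, calibration = NULL) {
  if (any(F < 0 | F > 1)) stop("F must lie in [0, 1]")
  if (is.null(calibration)) return((1 - F) / (1 + F))
  stopifnot(all(c("F", "t") %in% names(calibration)))
  approx(calibration$F, calibration$t, xout = F, rule = 2)$y
}

#' Multilocus outcrossing rate from progeny arrays
#'
#' Detection-corrected progeny-array estimator. An offspring is
#' detected-outcrossed iff at some locus it carries an allele absent
#' from its mother. Given outcrossing, the per-offspring detection
#' probability is `P_det = 1 - prod_loci P(pollen allele among maternal
#' alleles)` (heterozygous mothers detect nothing at that locus; a
#' homozygous mother detects the opposite allele at the pollen-pool
#' frequency). The estimate is `t_m = detected fraction / mean(P_det)`,
#' truncated to \[0, 1\]; its standard deviation comes from a bootstrap
#' over families. Offspring compatible with neither selfing nor
#' outcrossing via a maternal gamete (no maternal allele at some locus)
#' are flagged as genotyping errors, excluded and logged.
#'
#' @param arrays list of `progeny_array` objects (see
#'   [simulate_progeny_arrays()]).
#' @param pollen_freqs optional per-locus pollen-pool frequencies of
#'   allele 1; defaults to each array's stored frequencies, or, absent
#'   those, to allele frequencies among the maternal plants.
#' @param n_boot bootstrap replicates over families for the SD.
#' @param seed integer seed for the bootstrap.
#' @return A `mating_system_estimate` with `t_m`, `t_sd`,
#'   `n_offspring`, `n_detected`, `n_excluded` and `method =
#'   "progeny_array"`.
#' @export
outcrossing_progeny_array <- function(arrays, pollen_freqs = NULL,
                                      n_boot = 200, seed = 1) {
  stopifnot(length(arrays) >= 1,
            all(vapply(arrays, inherits, logical(1), "progeny_array")))
  n_loci <- arrays[[1]]$n_loci
  if (is.null(pollen_freqs)) {
    if (!is.null(arrays[[1]]$pollen_freqs)) {
      pollen_freqs <- arrays[[1]]$pollen_freqs
    } else {
      mat <- vapply(arrays, `[[`, numeric(n_loci), "maternal")
      pollen_freqs <- rowMeans(mat) / 2
    }
  }
  fam <- lapply(arrays, function(a) {
    mg <- a$maternal
    og <- a$offspring
    # allele absent from mother: mother hom 0 sees allele 1, hom 2 sees 0
    det_mat <- sweep(og, 2, mg, function(o, m)
      (m == 0L & o >= 1L) | (m == 2L & o <= 1L))
    err_mat <- sweep(og, 2, mg, function(o, m)
      (m == 0L & o == 2L) | (m == 2L & o == 0L))
    err <- rowSums(err_mat) > 0
    detected <- rowSums(det_mat) > 0 & !err
    p_in <- ifelse(mg == 1L, 1,
                   ifelse(mg == 2L, pollen_freqs, 1 - pollen_freqs))
    p_det <- 1 - prod(p_in)
    list(detected = detected[!err], p_det = p_det,
         n_err = sum(err))
  })
  n_excluded <- sum(vapply(fam, `[[`, numeric(1), "n_err"))
  if (n_excluded > 0)
    message("outcrossing_progeny_array: excluded ", n_excluded,
            " offspring incompatible with the mother (genotyping error)")
  est <- function(families) {
    det <- unlist(lapply(families, `[[`, "detected"))
    pd <- unlist(lapply(families, function(f)
      rep(f$p_det, length(f$detected))))
    if (!length(det) || mean(pd) == 0) return(NA_real_)
    min(max(mean(det) / mean(pd), 0), 1)
  }
  t_m <- est(fam)
  set.seed(seed)
  boots <- vapply(seq_len(n_boot), function(b)
    est(fam[sample.int(length(fam), replace = TRUE)]), numeric(1))
  t_sd <- sd(boots[!is.na(boots)])
  if (!length(boots[!is.na(boots)])) t_sd <- NA_real_
  structure(list(fis = NA_real_, fis_per_locus = numeric(0),
                 n_loci_used = n_loci, t_m = t_m, t_sd = t_sd,
                 n_offspring = sum(lengths(lapply(fam, `[[`, "detected"))),
                 n_detected = sum(unlist(lapply(fam, `[[`, "detected"))),
                 n_excluded = n_excluded,
                 method = "progeny_array", undefined = is.na(t_m)),
            class = "mating_system_estimate")
}
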