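#' Simulate genotypes at independent loci under the structured coalescent
#'
#' For each locus a genealogy is drawn under the structured coalescent of
#' the model (pairwise coalescence at rate k(k-1)/2 / (2 N_e) per
#' population, migration as lineage movement, splits as backward lineage
#' pooling); mutations are placed as a Poisson process on branches at
#' rate `mutation_rate * locus_length` per generation under the
#' infinite-sites model, and diploid genotypes are formed by pairing
#' haploids within individuals. Partial selfing uses the equilibrium
#' identity-by-descent shortcut: an individual's two haploid lineages
#' coalesce at sampling with probability F = s / (2 - s).
#'
#' Loci are independent and non-recombining; each locus becomes its own
#' sequence (`locus_1`, `locus_2`, ...) with mutation positions uniform
#' over the locus. Output genotypes are polarized (allele 0 ancestral).
#'
#' @param model a [demographic_model()].
#' @param n_loci number of independent loci.
#' @param seed integer seed; the same seed reproduces the output exactly.
#' @return A polarized [genotype_matrix()] with per-sample population
#'   labels; loci without mutations contribute no sites.
#' @export
simulate_coalescent_sfs_data <- function(model, n_loci, seed) {
  stopifnot(inherits(model, "demographic_model"), n_loci >= 1)
  set.seed(seed)
  lg <- leaf_groups(model)
  loci <- .sim_genotype_loci(demography_payload(model), as.integer(n_loci),
                             model$mutation_rate * model$locus_length)
  L <- model$locus_length
  chrom <- character(0); pos <- integer(0)
  keep <- vapply(loci, nrow, integer(1)) > 0L
  mats <- vector("list", sum(keep))
  j <- 0L
  for (i in which(keep)) {
    m <- loci[[i]]
    if (nrow(m) > L)
      stop("more mutations than positions on a locus; ",
           "increase locus_length or lower the mutation rate")
    j <- j + 1L
    mats[[j]] <- m
    chrom <- c(chrom, rep(sprintf("locus_%d", i), nrow(m)))
    pos <- c(pos, sort(sample.int(L, nrow(m))))
  }
  geno <- if (j > 0L) do.call(rbind, mats) else
    matrix(integer(0), 0L, sum(lg$n_dip))
  ids <- unlist(lapply(seq_along(lg$labels), function(p)
    sprintf("%s_%d", lg$labels[p], seq_len(lg$n_dip[p]))))
  pop <- rep(lg$labels, times = lg$n_dip)
  genotype_matrix(geno, chrom, pos, ids, pop = pop, polarized = TRUE)
}

#' Simulate a stationary heterozygosity-tract sequence
#'
#' Generates a binary heterozygosity indicator along a chromosome as a
#' stationary two-state Markov chain over \{hom, het\} with stationary
#' het probability `theta` (the genome-wide heterozygosity) and lag-1
#' autocorrelation `rho` (per-bp tract persistence); the lag-d
#' autocorrelation is `rho^d`. This is the generative counterpart of the
#' correlation-of-zygosity analysis: long `rho` near 1 produces the long
#' homozygosity/heterozygosity tracts characteristic of selfing genomes.
#'
#' @param theta stationary heterozygosity, in (0, 1).
#' @param rho per-bp persistence (lag-1 autocorrelation), in \[0, 1).
#' @param length_bp sequence length (>= 2).
#' @param seed integer seed.
#' @return Integer vector of 0/1 heterozygosity indicators.
#' @export
simulate_zygosity_tracts <- function(theta, rho, length_bp, seed) {
  if (theta <= 0 || theta >= 1) stop("theta must lie in (0, 1)")
  if (rho < 0 || rho >= 1) stop("rho must lie in [0, 1)")
  if (length_bp < 2) stop("length_bp must be at least 2")
  set.seed(seed)
  .sim_zygosity_chain(theta, rho, as.integer(length_bp))
}

#' Simulate progeny arrays under mixed mating
#'
#' Maternal genotypes are drawn at inbreeding equilibrium
#' (F = s / (2 - s)); each offspring is a selfed gamete pair from its
#' mother with probability `s`, otherwise one maternal gamete plus one
#' pollen-pool gamete. Genotypes are counts of allele 1, whose per-locus
#' pollen-pool frequency is `pollen_pool_freqs`.
#'
#' @param n_mothers,n_offspring,n_loci array dimensions.
#' @param selfing_rate selfing rate s in \[0, 1\].
#' @param pollen_pool_freqs per-locus frequencies of allele 1; a single
#'   value is recycled; `NULL` draws frequencies uniformly in
#'   \[0.2, 0.8\].
#' @param seed integer seed.
#' @return A list of `progeny_array` objects, each with elements
#'   `maternal` (length `n_loci`), `offspring` (`n_offspring` x `n_loci`
#'   matrix), `pollen_freqs`, `n_loci` and `n_offspring`.
#' @export
simulate_progeny_arrays <- function(n_mothers, n_offspring, n_loci,
                                    selfing_rate, pollen_pool_freqs = NULL,
                                    seed = 1) {
  s <- selfing_rate
  if (s < 0 || s > 1) stop("selfing_rate must lie in [0, 1]")
  set.seed(seed)
  p <- if (is.null(pollen_pool_freqs)) runif(n_loci, 0.2, 0.8) else
    rep_len(pollen_pool_freqs, n_loci)
  if (any(p < 0 | p > 1)) stop("pollen-pool frequencies must lie in [0, 1]")
  Fibd <- s / (2 - s)
  lapply(seq_len(n_mothers), function(m) {
    ibd <- runif(n_loci) < Fibd
    maternal <- ifelse(ibd, 2L * rbinom(n_loci, 1L, p), rbinom(n_loci, 2L, p))
    offspring <- matrix(0L, n_offspring, n_loci)
    for (o in seq_len(n_offspring)) {
      g1 <- rbinom(n_loci, 1L, maternal / 2)
      g2 <- if (runif(1) < s) rbinom(n_loci, 1L, maternal / 2) else
        rbinom(n_loci, 1L, p)
      offspring[o, ] <- g1 + g2
    }
    structure(list(maternal = maternal, offspring = offspring,
                   pollen_freqs = p, n_loci = n_loci,
                   n_offspring = n_offspring),
              class = "progeny_array")
  })
}

#' Simulate genotypes at inbreeding equilibrium under partial selfing
#'
#' Draws unlinked biallelic genotypes for one population at mixed-mating
#' equilibrium: per individual and locus, the two alleles are identical
#' by descent with probability F = s / (2 - s) (a single allele drawn at
#' the locus frequency, doubled), otherwise in Hardy-Weinberg
#' proportions.
#'
#' @param n_ind diploid individuals.
#' @param n_loci loci; allele frequencies drawn uniformly over
#'   `freq_range`.
#' @param selfing_rate selfing rate s in \[0, 1\].
#' @param freq_range range for the per-locus allele-1 frequency.
#' @param seed integer seed.
#' @return An unpolarized [genotype_matrix()] (one `chr1` sequence, loci
#'   1 kb apart).
#' @export
simulate_equilibrium_genotypes <- function(n_ind, n_loci, selfing_rate,
                                           freq_range = c(0.2, 0.8),
                                           seed = 1) {
  s <- selfing_rate
  if (s < 0 || s > 1) stop("selfing_rate must lie in [0, 1]")
  set.seed(seed)
  p <- runif(n_loci, freq_range[1], freq_range[2])
  Fibd <- s / (2 - s)
  n <- n_loci * n_ind
  pmat <- rep(p, times = n_ind)
  ibd <- runif(n) < Fibd
  g <- integer(n)
  g[ibd] <- 2L * rbinom(sum(ibd), 1L, pmat[ibd])
  g[!ibd] <- rbinom(sum(!ibd), 2L, pmat[!ibd])
  geno <- matrix(g, n_loci, n_ind)
  genotype_matrix(geno, rep("chr1", n_loci), seq_len(n_loci) * 1000L,
                  sprintf("ind_%d", seq_len(n_ind)),
                  pop = rep("pop1", n_ind), polarized = FALSE)
}

#' Simulate an impact-annotated VCF with known per-sample load
#'
#' Writes a toy VCF whose variants carry SnpEff-style ANN impact levels
#' drawn from `impact_probs` and i.i.d. genotypes (homozygous alternate
#' with probability `hom_alt_prob`, the remainder split equally between
#' heterozygous and homozygous reference). The ground-truth mutational
#' load — the per-sample count of homozygous-alternate MODERATE and HIGH
#' variants — is returned and written to `<path>.truth.tsv`.
#'
#' @param n_samples,n_variants dimensions.
#' @param impact_probs named probabilities over LOW, MODERATE, HIGH,
#'   MODIFIER (normalized internally).
#' @param hom_alt_prob probability a genotype is homozygous alternate.
#' @param seed integer seed.
#' @param path output VCF path.
#' @return Invisibly, a list with `path` and `truth` (data frame of
#'   sample_id and load).
#' @export
simulate_annotated_vcf <- function(n_samples, n_variants,
                                   impact_probs = c(LOW = 0.25,
                                                    MODERATE = 0.25,
                                                    HIGH = 0.25,
                                                    MODIFIER = 0.25),
                                   hom_alt_prob = 0.2, seed = 1, path) {
  lev <- c("LOW", "MODERATE", "HIGH", "MODIFIER")
  if (is.null(names(impact_probs)) || !all(names(impact_probs) %in% lev))
    stop("impact_probs must be named with SnpEff impact levels")
  if (any(impact_probs < 0) || sum(impact_probs) <= 0)
    stop("impact_probs must be non-negative and not all zero")
  if (hom_alt_prob < 0 || hom_alt_prob > 1)
    stop("hom_alt_prob must lie in [0, 1]")
  set.seed(seed)
  impact <- sample(names(impact_probs), n_variants, replace = TRUE,
                   prob = impact_probs / sum(impact_probs))
  h <- hom_alt_prob
  geno <- matrix(sample(0:2, n_samples * n_variants, replace = TRUE,
                        prob = c((1 - h) / 2, (1 - h) / 2, h)),
                 n_variants, n_samples)
  ids <- sprintf("S%02d", seq_len(n_samples))
  g <- genotype_matrix(geno, rep("chr1", n_variants),
                       seq_len(n_variants) * 100L, ids)
  write_vcf(g, path, impact = impact)
  deleterious <- impact %in% c("MODERATE", "HIGH")
  truth <- data.frame(sample_id = ids,
                      load = colSums(geno == 2L & deleterious))
  write.table(truth, paste0(path, ".truth.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  invisible(list(path = path, truth = truth))
}

#' Simulate mutational load along a serial-founder expansion route
#'
#' Emulates a range expansion by serial founder events: deleterious
#' allele frequencies drift by binomial resampling of `2 * n_founders`
#' gametes at each colonization step, which inflates homozygosity for
#' deleterious alleles with distance from the origin. Sampled individuals
#' at each step carry Hardy-Weinberg genotypes at the local frequencies;
#' their load is the count of homozygous deleterious genotypes.
#'
#' @param n_steps colonization steps along the route.
#' @param n_variants deleterious variants tracked.
#' @param n_founders founding individuals per step.
#' @param n_samples_per_step individuals sampled per step.
#' @param step_km geodesic distance between consecutive steps.
#' @param init_freq_range initial deleterious-allele frequency range.
#' @param seed integer seed.
#' @return Data frame with sample_id, population, load and
#'   expansion_distance_km.
#' @export
simulate_expansion_load <- function(n_steps = 8, n_variants = 400,
                                    n_founders = 10,
                                    n_samples_per_step = 4,
                                    step_km = 300,
                                    init_freq_range = c(0.05, 0.2),
                                    seed = 1) {
  set.seed(seed)
  q <- runif(n_variants, init_freq_range[1], init_freq_range[2])
  out <- vector("list", n_steps)
  for (s in seq_len(n_steps)) {
    if (s > 1) q <- rbinom(n_variants, 2L * n_founders, q) / (2 * n_founders)
    load <- vapply(seq_len(n_samples_per_step), function(i)
      sum(rbinom(n_variants, 2L, q) == 2L), numeric(1))
    out[[s]] <- data.frame(
      sample_id = sprintf("step%d_ind%d", s, seq_len(n_samples_per_step)),
      population = sprintf("step%d", s), load = load,
      expansion_distance_km = s * step_km)
  }
  do.call(rbind, out)
}
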