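# Coalescent and mating-system generators checked against closed-form
# neutral-theory oracles.

test_that("zero mutation rate yields zero segregating sites", {
  m <- demographic_model(
    populations = data.frame(label = "A", N = 1000, selfing = 0),
    mutation_rate = 0, locus_length = 1000L, sample_config = c(A = 3))
  g <- simulate_coalescent_sfs_data(m, 50, seed = 1)
  expect_equal(n_sites(g), 0L)
})

test_that("neutral single-population SFS matches Watterson and xi_i = theta/i", {
  # theta_locus = 4 N mu L = 1, n = 6 haploids, 2000 loci
  g <- simulate_coalescent_sfs_data(watterson_model(), 2000, seed = 42)
  # E[S] per locus = theta * sum(1/i, i = 1..5) = 2.2833; MC SE ~ 0.043
  expect_equal(n_sites(g) / 2000, sum(1 / (1:5)), tolerance = 0.07)
  sfs <- compute_joint_sfs(g)
  xi <- as.vector(sfs$counts)[2:6] / 2000
  # E[xi_i] = theta / i
  for (i in 1:5)
    expect_equal(xi[i], 1 / i, tolerance = 0.35 / i + 0.05)
  # singleton class: E[xi_1] = theta = 1
  expect_equal(xi[1], 1, tolerance = 0.1)
})

test_that("selfing produces the equilibrium heterozygote deficit F = s/(2-s)", {
  m <- demographic_model(
    populations = data.frame(label = "A", N = 10000, selfing = 0.6486),
    mutation_rate = 2.5e-8, locus_length = 1000L,
    sample_config = c(A = 20))
  g <- simulate_coalescent_sfs_data(m, 600, seed = 7)
  est <- fis_multilocus(g)
  expect_equal(est$fis, 0.6486 / (2 - 0.6486), tolerance = 0.12)
})

test_that("F_ST increases with split time between isolated populations", {
  hudson_fst <- function(g) {
    # ratio-of-averages Hudson estimator from per-population frequencies
    f <- vapply(unique(g$pop), function(lab) {
      sub <- g$geno[, g$pop == lab, drop = FALSE]
      rowSums(sub) / (2 * ncol(sub))
    }, numeric(n_sites(g)))
    n <- 2 * sum(g$pop == g$pop[1])
    num <- (f[, 1] - f[, 2])^2 -
      f[, 1] * (1 - f[, 1]) / (n - 1) - f[, 2] * (1 - f[, 2]) / (n - 1)
    den <- f[, 1] * (1 - f[, 2]) + f[, 2] * (1 - f[, 1])
    sum(num) / sum(den)
  }
  fst <- vapply(c(1000, 5000, 20000), function(t_split) {
    m <- demographic_model(
      populations = data.frame(label = c("A", "B"), N = 10000, selfing = 0),
      splits = data.frame(time = t_split, derived = "B", ancestral = "A"),
      mutation_rate = 2.5e-8, locus_length = 1000L,
      sample_config = c(A = 4, B = 4))
    hudson_fst(simulate_coalescent_sfs_data(m, 800, seed = 5))
  }, numeric(1))
  expect_true(all(diff(fst) > 0))
})

test_that("all generators are bit-reproducible under a fixed seed", {
  m <- watterson_model()
  expect_identical(simulate_coalescent_sfs_data(m, 30, seed = 99),
                   simulate_coalescent_sfs_data(m, 30, seed = 99))
  expect_identical(simulate_zygosity_tracts(0.1, 0.9, 5000, seed = 3),
                   simulate_zygosity_tracts(0.1, 0.9, 5000, seed = 3))
  expect_identical(simulate_progeny_arrays(3, 4, 5, 0.5, seed = 8),
                   simulate_progeny_arrays(3, 4, 5, 0.5, seed = 8))
  expect_identical(simulate_equilibrium_genotypes(10, 5, 0.5, seed = 2),
                   simulate_equilibrium_genotypes(10, 5, 0.5, seed = 2))
})

test_that("zygosity tracts have the prescribed mean and autocorrelation", {
  # rho = 0: i.i.d. sites, lag-1 correlation ~ 0
  z0 <- simulate_zygosity_tracts(0.3, 0, 1e5, seed = 1)
  expect_lt(abs(cor(z0[-1e5], z0[-1])), 0.02)
  # stationary mean: theta = 0.01, rho = 0.999; SE of mean =
  # sqrt(theta(1-theta)(1+rho)/((1-rho) n)) = 0.0044
  z <- simulate_zygosity_tracts(0.01, 0.999, 1e6, seed = 4)
  expect_lt(abs(mean(z) - 0.01), 3 * 0.0045)
  # lag-d autocorrelation rho^d; measured where tracts are plentiful
  z2 <- simulate_zygosity_tracts(0.2, 0.999, 1e6, seed = 6)
  lag100 <- cor(z2[1:(1e6 - 100)], z2[101:1e6])
  expect_equal(lag100, 0.999^100, tolerance = 0.03)
})

test_that("progeny-array generator respects maternal transmission", {
  # s = 1: every offspring is a pair of maternal gametes
  arr <- simulate_progeny_arrays(6, 8, 10, selfing_rate = 1, seed = 2)
  for (a in arr) {
    lower <- ifelse(a$maternal == 0L, 0L, ifelse(a$maternal == 2L, 1L, 0L))
    upper <- ifelse(a$maternal == 0L, 1L, 2L)
    # offspring alleles drawn only from the mother: hom mothers bound
    # the offspring genotype to their own allele
    hom0 <- a$maternal == 0L
    hom2 <- a$maternal == 2L
    expect_true(all(a$offspring[, hom0] == 0L))
    expect_true(all(a$offspring[, hom2] == 2L))
    expect_true(all(a$offspring >= rep(lower, each = a$n_offspring)))
    expect_true(all(a$offspring <= rep(upper, each = a$n_offspring)))
  }
  # s = 0: one gamete is always maternal
  arr0 <- simulate_progeny_arrays(6, 8, 10, selfing_rate = 0, seed = 3)
  for (a in arr0) {
    hom0 <- a$maternal == 0L
    hom2 <- a$maternal == 2L
    expect_true(all(a$offspring[, hom0] <= 1L))
    expect_true(all(a$offspring[, hom2] >= 1L))
  }
})

test_that("detectable outcrossing fraction matches the enumeration oracle", {
  # with mixed mating, P(offspring detected) = (1 - s) * P_det where
  # P_det = 1 - prod_loci P(pollen allele among maternal alleles)
  s <- 0.5
  arrays <- simulate_progeny_arrays(40, 30, 6, selfing_rate = s,
                                    pollen_pool_freqs = 0.5, seed = 11)
  detected <- expected <- 0
  for (a in arrays) {
    p_in <- ifelse(a$maternal == 1L, 1,
                   ifelse(a$maternal == 2L, a$pollen_freqs,
                          1 - a$pollen_freqs))
    p_det <- 1 - prod(p_in)
    non_maternal <- sweep(a$offspring, 2, a$maternal, function(o, m)
      (m == 0L & o >= 1L) | (m == 2L & o <= 1L))
    detected <- detected + sum(rowSums(non_maternal) > 0)
    expected <- expected + a$n_offspring * (1 - s) * p_det
  }
  n_total <- 40 * 30
  expect_equal(detected / n_total, expected / n_total, tolerance = 0.15)
})

test_that("annotated VCF generator emits exact ground-truth loads", {
  path <- withr::local_tempfile(fileext = ".vcf")
  res <- simulate_annotated_vcf(5, 40, hom_alt_prob = 0, seed = 1,
                                path = path)
  expect_true(all(res$truth$load == 0))
  res2 <- simulate_annotated_vcf(5, 40, impact_probs = c(LOW = 1),
                                 hom_alt_prob = 0.5, seed = 2, path = path)
  expect_true(all(res2$truth$load == 0))
  # n_variants = 100 all HIGH, hom_alt_prob = 0.3: binomial mean 30
  res3 <- simulate_annotated_vcf(20, 100, impact_probs = c(HIGH = 1),
                                 hom_alt_prob = 0.3, seed = 3, path = path)
  expect_equal(mean(res3$truth$load), 30, tolerance = 0.12)
  expect_true(file.exists(paste0(path, ".truth.tsv")))
})
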