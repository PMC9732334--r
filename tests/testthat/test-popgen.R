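# --- Patterson's D ----------------------------------------------------

test_that("D equals the ABBA/BABA site-pattern asymmetry", {
  # haploid-like quartet emulated by homozygous diploids: ABBA site has
  # frequencies (0, 1, 1, 0), BABA (1, 0, 1, 0)
  abba <- c(0, 2, 2, 0)
  baba <- c(2, 0, 2, 0)
  qset <- list(P1 = "s1", P2 = "s2", P3 = "s3", O = "s4")
  balanced <- gm_from_rows(c(rep(list(abba), 10), rep(list(baba), 10)))
  d0 <- patterson_d(balanced, qset, block_size_bp = 1e6)
  expect_equal(d0$D, 0)
  skewed <- gm_from_rows(c(rep(list(abba), 15), rep(list(baba), 5)))
  d1 <- patterson_d(skewed, qset, block_size_bp = 1e6)
  expect_equal(d1$D, 0.5)
  expect_equal(d1$abba, 15)
  expect_equal(d1$baba, 5)
  # all 20 sites sit in one block: jackknife refused
  expect_true(d1$jackknife_refused)
  # monomorphic-only input: denominator zero, undefined flag
  mono <- gm_from_rows(rep(list(c(0, 0, 0, 0)), 4))
  expect_true(patterson_d(mono, qset)$undefined)
  expect_error(patterson_d(balanced, list(P1 = "s1", P2 = "s1",
                                          P3 = "s3", O = "s4")),
               "disjoint")
})

test_that("D is antisymmetric under swapping P1 and P2", {
  g <- simulate_coalescent_sfs_data(quartet_model(), 300, seed = 14)
  q <- quartet_sets()
  d <- patterson_d(g, q, block_size_bp = 1e6)
  q_swapped <- list(P1 = q$P2, P2 = q$P1, P3 = q$P3, O = q$O)
  d_swapped <- patterson_d(g, q_swapped, block_size_bp = 1e6)
  expect_equal(d_swapped$D, -d$D, tolerance = 1e-12)
  expect_gt(d$n_blocks, 3)
  expect_false(is.na(d$z))
})

# --- F_IS and conversions ---------------------------------------------

test_that("F_IS has the right sign and bounds on canonical configurations", {
  # every individual heterozygous at p = 0.5: excess heterozygosity
  g_het <- gm_from_rows(list(c(1, 1, 1, 1)), polarized = FALSE)
  expect_lt(fis_multilocus(g_het)$fis, 0)
  # no heterozygotes at p = 0.5: F_IS = 1
  g_hom <- gm_from_rows(list(c(0, 0, 2, 2)), polarized = FALSE)
  expect_equal(fis_multilocus(g_hom)$fis, 1)
  # all loci monomorphic: undefined, mirrors low-polymorphism failure
  g_mono <- gm_from_rows(list(c(0, 0, 0, 0), c(2, 2, 2, 2)),
                         polarized = FALSE)
  est <- fis_multilocus(g_mono)
  expect_true(est$undefined)
  expect_true(is.na(est$fis))
  # allele relabeling (dosage flip) leaves the estimate unchanged
  set.seed(17)
  geno <- matrix(sample(0:2, 200, replace = TRUE, prob = c(.5, .2, .3)),
                 20, 10)
  g <- gm_from_rows(asplit(geno, 1), polarized = FALSE)
  g_flip <- gm_from_rows(asplit(2L - geno, 1), polarized = FALSE)
  expect_equal(fis_multilocus(g)$fis, fis_multilocus(g_flip)$fis)
})

test_that("equilibrium genotypes recover F = s/(2-s)", {
  f_hat <- vapply(1:5, function(s)
    fis_multilocus(simulate_equilibrium_genotypes(50, 19, 0.6486,
                                                  seed = s))$fis,
    numeric(1))
  expect_equal(mean(f_hat), 0.48, tolerance = 0.1)
})

test_that("mating-system identities convert F, s and t consistently", {
  expect_equal(mating_system_conversions(F = 0)$t, 1)
  expect_equal(mating_system_conversions(F = 1)$t, 0)
  expect_equal(mating_system_conversions(F = 1 / 3)$t, 0.5)
  cv <- mating_system_conversions(s = 0.6486)
  expect_equal(cv$F, 0.6486 / (2 - 0.6486))
  expect_equal(cv$t, 1 - 0.6486)
  # round trip through t
  expect_equal(mating_system_conversions(t = cv$t)$F, cv$F)
  expect_error(mating_system_conversions(F = 1.2), "must lie")
  expect_error(mating_system_conversions(F = 0.2, s = 0.3), "exactly one")
  # empirical calibration table overrides the equilibrium identity
  calib <- data.frame(F = c(0, 0.5, 1), t = c(1, 0.15, 0))
  expect_equal(fis_to_outcrossing(0.5, calib), 0.15)
  expect_equal(fis_to_outcrossing(0.25, calib), (1 + 0.15) / 2)
  expect_equal(fis_to_outcrossing(0.5), 1 / 3)
})

# --- progeny arrays ---------------------------------------------------

test_that("progeny-array estimator applies the detection correction", {
  # one locus, mother aa, pollen freq of A = 0.5 -> P_det = 0.5;
  # detected fraction 2/8 = 0.25 -> t_m = 0.5
  arr <- make_array(maternal = 0,
                    offspring = c(1, 1, 0, 0, 0, 0, 0, 0),
                    pollen_freqs = 0.5)
  est <- outcrossing_progeny_array(list(arr), n_boot = 50, seed = 1)
  expect_equal(est$t_m, 0.5)
  expect_equal(est$n_detected, 2)
  # mother aa, offspring Aa: detected outcross
  arr2 <- make_array(0, c(1), 0.5)
  expect_equal(outcrossing_progeny_array(list(arr2), n_boot = 10,
                                         seed = 1)$n_detected, 1)
  # offspring carrying no maternal allele is a genotyping error
  arr3 <- make_array(0, c(2, 0), 0.5)
  expect_message(est3 <- outcrossing_progeny_array(list(arr3),
                                                   n_boot = 10, seed = 1),
                 "excluded 1")
  expect_equal(est3$n_excluded, 1)
  expect_equal(est3$n_offspring, 1)
})

test_that("progeny-array estimator recovers t = 1 - s on synthetic arrays", {
  for (s in c(0, 0.5, 1)) {
    arrays <- simulate_progeny_arrays(20, 10, 12, selfing_rate = s,
                                      seed = 40 + round(10 * s))
    est <- outcrossing_progeny_array(arrays, n_boot = 100,
                                     seed = 40 + round(10 * s))
    if (s == 1) {
      expect_identical(est$t_m, 0)
      expect_identical(est$t_sd, 0)
    } else {
      expect_lt(abs(est$t_m - (1 - s)), max(4 * est$t_sd, 0.1))
    }
  }
})

# --- correlation of zygosity ------------------------------------------

test_that("zygosity correlation is ~0 for i.i.d. sites and 1 for copies", {
  set.seed(51)
  z <- rbinom(20000, 1, 0.3)
  prof <- correlation_of_zygosity(z, bin_edges = c(1, 11, 101, 1001))
  expect_true(all(abs(prof$profile$delta) < 0.03))
  expect_equal(prof$theta, mean(z))
  # exact copies two apart: Delta = 1 in the lag-2 bin
  z2 <- rep(c(1L, 0L), 500)
  prof2 <- correlation_of_zygosity(z2, bin_edges = c(2, 3))
  expect_equal(prof2$profile$delta, 1)
  # theta = 0 profile is flagged undefined
  prof0 <- correlation_of_zygosity(rep(0L, 100), bin_edges = c(1, 10))
  expect_true(prof0$undefined)
})

test_that("Markov-tract input reproduces the rho^d closed form", {
  z <- simulate_zygosity_tracts(0.2, 0.999, 1e6, seed = 6)
  prof <- correlation_of_zygosity(z, bin_edges = c(95, 106))
  expect_equal(prof$profile$delta, 0.999^100, tolerance = 0.05)
  # pairs never span region boundaries: an all-het region next to an
  # all-hom region yields only concordant (1,1)/(0,0) pairs, so the
  # pooled correlation is exactly 1; any cross-boundary (1,0) pair
  # would pull it below 1
  z_reg <- c(rep(1L, 50), rep(0L, 50))
  p_reg <- correlation_of_zygosity(z_reg, bin_edges = c(1, 100),
                                   regions = rep(1:2, each = 50))
  expect_equal(p_reg$profile$delta, 1)
  expect_equal(p_reg$profile$n_pairs, sum(49:1) * 2)
})

test_that("zygosity profile works from a genotype matrix individual", {
  g <- gm_from_rows(list(c(1, 0), c(1, 2), c(0, 1), c(1, 1)),
                    pos = c(10L, 20L, 30L, 40L))
  prof <- correlation_of_zygosity(g, bin_edges = c(1, 100), sample = "s1")
  expect_equal(prof$theta, 0.75)
  expect_equal(prof$id, "s1")
  expect_error(correlation_of_zygosity(g, bin_edges = c(1, 100),
                                       sample = "nope"), "unknown sample")
})

test_that("LD extent matches the analytic tract decay and censors correctly", {
  # analytic profile Delta(d) = rho^d at log-spaced bin centers
  rho <- 0.999
  centers <- 10^seq(0, 4, by = 0.25)
  prof <- structure(list(
    profile = data.frame(bin_lo = centers, bin_hi = centers * 1.2,
                         distance = centers, n_pairs = 1e6,
                         delta = rho^centers, delta_cov = rho^centers),
    theta = 0.1, id = "analytic", n_sites = 1L, undefined = FALSE),
    class = "zygosity_profile")
  ext <- ld_extent(prof, threshold = 0.1)
  target <- log(0.1) / log(rho)  # 2301.4 bp
  # within one log-spaced bin (factor 10^0.25)
  expect_lt(abs(log10(ext$extent_bp) - log10(target)), 0.25)
  # threshold 1: extent is the first bin
  expect_equal(ld_extent(prof, threshold = 1)$extent_bp, 1)
  # constant profile never decays: right-censored
  flat <- prof
  flat$profile$delta <- rep(0.5, length(centers))
  expect_true(ld_extent(flat, threshold = 0.1)$censored)
})

test_that("LD extent from the generator is monotone in tract persistence", {
  exts <- vapply(c(0.99, 0.999, 0.9999), function(r) {
    z <- simulate_zygosity_tracts(0.3, r, 2e6, seed = 11)
    p <- correlation_of_zygosity(z, bin_edges = 10^seq(0, 5.5, by = 0.25))
    ld_extent(p, 0.1)$extent_bp
  }, numeric(1))
  expect_true(all(diff(exts) > 0))
})
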