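# helper: minimal hand-built fit_result for the AIC comparison contract
fake_fit <- function(id, lnCL, k, digest = c(1, 2, 3)) {
  structure(list(model_id = id, estimates = numeric(0), lnCL = lnCL,
                 k = k, AIC = 2 * k - 2 * lnCL, n_starts = 1,
                 converged = TRUE, converged_best = TRUE,
                 obs_digest = digest),
            class = "fit_result")
}

test_that("composite log-likelihood is the multinomial sum over cells", {
  # counts (4, 2) with p = (0.5, 0.5): 6 ln 0.5 = -4.1589
  expect_equal(composite_loglik(c(4, 2), c(0.5, 0.5)), 6 * log(0.5),
               tolerance = 1e-10)
  # p proportional to observed counts maximizes lnCL over the simplex
  obs <- c(5, 3, 2)
  mle <- obs / sum(obs)
  ln_mle <- composite_loglik(obs, mle)
  for (eps in c(0.05, -0.08)) {
    p <- mle + c(eps, -eps, 0)
    expect_lt(composite_loglik(obs, p), ln_mle)
  }
  # permutation of the cell enumeration leaves lnCL unchanged
  perm <- c(3, 1, 2)
  expect_equal(composite_loglik(obs[perm], mle[perm]), ln_mle)
  expect_error(composite_loglik(c(1, 2), c(0.3, 0.3, 0.4)), "shapes")
})

test_that("expected SFS reproduces xi_i proportions, sums to 1 and floors zeros", {
  m <- demographic_model(
    populations = data.frame(label = "A", N = 10000, selfing = 0),
    sample_config = c(A = 2))
  es <- expected_sfs(m, n_sims = 20000, seed = 1)
  expect_equal(sum(es$p), 1, tolerance = 1e-12)
  p <- as.vector(es$p)[2:4]
  expect_equal(p, (1 / (1:3)) / sum(1 / (1:3)), tolerance = 0.05)
  # flooring: with tiny n_sims some polymorphic cells are unvisited but
  # still carry positive mass, so any observed cell has finite lnCL
  big <- reference_split_model()
  es2 <- expected_sfs(big, n_sims = 20, seed = 2)
  poly <- as.vector(es2$p)[-c(1, length(es2$p))]
  expect_true(all(poly > 0))
  expect_equal(sum(es2$p), 1, tolerance = 1e-12)
  obs <- rep(1, length(poly))
  expect_true(is.finite(composite_loglik(obs, poly)))
})

test_that("symmetric two-population island model gives a label-symmetric SFS", {
  m <- demographic_model(
    populations = data.frame(label = c("A", "B"), N = 10000, selfing = 0),
    migration = data.frame(from = c("A", "B"), to = c("B", "A"),
                           rate = 1e-4),
    sample_config = c(A = 2, B = 2))
  es <- expected_sfs(m, n_sims = 30000, seed = 3)
  expect_lt(max(abs(es$p - t(es$p))), 0.02)
})

test_that("older splits concentrate mass on private and fixed-difference cells", {
  mk <- function(t_split) demographic_model(
    populations = data.frame(label = c("A", "B"), N = 10000, selfing = 0),
    splits = data.frame(time = t_split, derived = "B", ancestral = "A"),
    sample_config = c(A = 2, B = 2))
  shared_mass <- function(t_split) {
    p <- expected_sfs(mk(t_split), n_sims = 10000, seed = 4)$p
    # shared polymorphism: both populations segregating
    sum(p[2:4, 2:4])
  }
  fixed_diff_mass <- function(t_split) {
    p <- expected_sfs(mk(t_split), n_sims = 10000, seed = 4)$p
    p[5, 1] + p[1, 5]
  }
  expect_gt(shared_mass(500), shared_mass(100000))
  expect_gt(fixed_diff_mass(100000), fixed_diff_mass(500))
})

test_that("ECM finds the argmax of a 1-D likelihood, consistent with a grid oracle", {
  gen <- topo_model()  # ((P1,P2),P3), split at 2000
  g <- simulate_coalescent_sfs_data(gen, 400, seed = 21)
  obs <- compute_joint_sfs(g)
  # brute-force grid oracle with one fixed simulation seed
  grid <- 10^seq(log10(500), log10(20000), length.out = 15)
  lnl <- vapply(grid, function(tv) {
    m <- splitself:::set_model_param(gen, "t_P2", tv)
    composite_loglik(obs, expected_sfs(m, n_sims = 4000, seed = 77))
  }, numeric(1))
  t_grid <- grid[which.max(lnl)]
  fit <- fit_model(obs, gen, free = list(t_P2 = c(500, 20000)),
                   n_starts = 4, n_sims = 4000, seed = 5)
  t_hat <- fit$estimates[["t_P2"]]
  # within one grid step (factor ~1.3) of the grid argmax
  expect_lt(abs(log(t_hat / t_grid)), log(1.7))
  # and the grid maximum cannot materially beat the ECM optimum
  m_hat <- splitself:::set_model_param(gen, "t_P2", t_hat)
  ln_hat <- composite_loglik(obs, expected_sfs(m_hat, 4000, seed = 77))
  expect_gt(ln_hat, max(lnl) - 5)
})

test_that("best-of-starts contract holds and results are seed-reproducible", {
  gen <- topo_model()
  g <- simulate_coalescent_sfs_data(gen, 150, seed = 22)
  obs <- compute_joint_sfs(g)
  fit <- fit_model(obs, gen, free = list(t_P2 = c(500, 20000)),
                   n_starts = 2, n_sims = 500, seed = 9)
  expect_equal(fit$lnCL, max(fit$start_lnCL))
  expect_equal(fit$AIC, 2 * fit$k - 2 * fit$lnCL)
  fit2 <- fit_model(obs, gen, free = list(t_P2 = c(500, 20000)),
                    n_starts = 2, n_sims = 500, seed = 9)
  expect_identical(fit$estimates, fit2$estimates)
})

test_that("AIC comparison ranks, breaks ties by k then id, and validates", {
  # lnCL -100, k 3 (AIC 206) beats lnCL -99, k 5 (AIC 208)
  f1 <- fake_fit("simple", -100, 3)
  f2 <- fake_fit("complex", -99, 5)
  cmp <- compare_models_aic(list(f2, f1))
  expect_equal(cmp$selected$model_id, "simple")
  expect_equal(cmp$table$AIC, c(206, 208))
  # ties: equal AIC resolved by smaller k, then lexicographic id
  t1 <- fake_fit("b_model", -100, 3)
  t2 <- fake_fit("a_model", -101, 2)  # AIC 206 too
  expect_equal(compare_models_aic(list(t1, t2))$selected$model_id,
               "a_model")
  t3 <- fake_fit("a_model", -100, 3)
  expect_equal(compare_models_aic(list(t1, t3))$selected$model_id,
               "a_model")
  expect_error(compare_models_aic(list(f1)), "at least two")
  f3 <- fake_fit("other", -99, 3, digest = c(9, 9, 9))
  expect_error(compare_models_aic(list(f1, f3)), "identical observed")
})

test_that("hierarchical selection records a trace and enforces consistency", {
  gen <- topo_model()
  g <- simulate_coalescent_sfs_data(gen, 100, seed = 23)
  obs <- compute_joint_sfs(g)
  # one candidate per step: selected, trace recorded
  steps <- list(
    scenario_set(list(only = list(model = gen, provides = "topo"))),
    scenario_set(list(next_one = list(model = gen, requires = "topo"))))
  hs <- hierarchical_selection(steps, obs, n_starts = 1, n_sims = 200)
  expect_equal(hs$final$model_id, "next_one")
  expect_equal(nrow(hs$trace), 2L)
  expect_true(all(hs$trace$selected))
  # a candidate requiring an unestablished constraint is refused
  bad <- list(
    scenario_set(list(only = list(model = gen, provides = "topo"))),
    scenario_set(list(bad = list(model = gen, requires = "pruned_pop"))))
  expect_error(hierarchical_selection(bad, obs, n_starts = 1,
                                      n_sims = 200), "requires")
})

test_that("bootstrap intervals are percentile-based and refuse bad input", {
  gen <- topo_model()
  g <- simulate_coalescent_sfs_data(gen, 200, seed = 24)
  obs <- compute_joint_sfs(g)
  fit <- fit_model(obs, gen, free = list(t_P2 = c(500, 20000)),
                   n_starts = 1, n_sims = 400, seed = 2)
  ci <- bootstrap_ci(fit, obs, n_boot = 12, level = 0.95, seed = 3,
                     n_starts = 1)
  q <- quantile(ci$replicates[, "t_P2"], c(0.025, 0.975))
  expect_equal(unname(c(ci$intervals$lower, ci$intervals$upper)),
               unname(q))
  expect_error(bootstrap_ci(fit, obs, n_boot = 0), "n_boot")
  broken <- fit
  broken$converged_best <- FALSE
  expect_error(bootstrap_ci(broken, obs, n_boot = 5), "converge")
})

test_that("generation-time conversion handles scalars and ranges", {
  expect_equal(generations_to_years(6007, 2), 12014)
  expect_equal(generations_to_years(6007, 1), 6007)
  expect_equal(generations_to_years(0, 2), 0)
  rng <- generations_to_years(6007, c(1, 2))
  expect_equal(unname(rng), c(6007, 12014))
  expect_error(generations_to_years(-1, 2), "non-negative")
})
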