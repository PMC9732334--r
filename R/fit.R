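#' Monte-Carlo expected SFS under a demographic model
#'
#' Approximates the probability that a segregating site falls in each
#' polymorphic cell of the joint unfolded SFS, conditioned on the site
#' being polymorphic in the pooled sample. Genealogies are simulated
#' under the structured coalescent of the model and each branch
#' contributes its length to the cell given by the derived-allele-count
#' tuple of the leaves it subtends (under infinite sites, expected cell
#' probabilities are proportional to these expected branch lengths,
#' which is the same estimand as placing Poisson mutations but with
#' lower Monte-Carlo variance). Cells with zero simulated mass receive
#' a pseudo-probability of `0.5 / n_sims` before renormalization so
#' observed cells always have finite likelihood.
#'
#' @param model a [demographic_model()].
#' @param n_sims number of coalescent simulations (the field-standard
#'   full-scale value is 100,000; desk scale 2,000).
#' @param seed integer seed (fix it across evaluations for common random
#'   numbers during optimization).
#' @return An object of class `expected_sfs`: list with `p` (array of
#'   cell probabilities; monomorphic cells 0), `pop_labels`,
#'   `sample_sizes`, `n_sims`.
#' @export
expected_sfs <- function(model, n_sims = 2000, seed = 1) {
  stopifnot(inherits(model, "demographic_model"), n_sims >= 1)
  set.seed(seed)
  lg <- leaf_groups(model)
  W <- .sim_sfs_weights(demography_payload(model), lg$leaf_group,
                        lg$haploid, as.integer(n_sims))
  dims <- lg$haploid + 1L
  mono <- c(1L, prod(dims))
  w <- W
  w[mono] <- 0
  if (sum(w) <= 0)
    stop("degenerate model: zero expected polymorphism")
  p <- w / sum(w)
  floor_p <- 0.5 / n_sims
  zero <- p == 0
  zero[mono] <- FALSE
  p[zero] <- floor_p
  p[mono] <- 0
  p <- p / sum(p)
  structure(list(p = array(p, dim = dims), pop_labels = lg$labels,
                 sample_sizes = lg$haploid, n_sims = n_sims),
            class = "expected_sfs")
}

#' Composite log-likelihood of an observed SFS
#'
#' The multinomial composite log-likelihood over polymorphic SFS cells,
#' `lnCL = sum(m_cell * ln p_cell)`, treating sites as independent.
#' Monomorphic cells are excluded (the likelihood conditions on
#' polymorphism). Both arguments may also be bare numeric vectors of
#' polymorphic-cell counts and probabilities.
#'
#' @param obs a `joint_sfs` (or numeric vector of cell counts).
#' @param expected an `expected_sfs` (or numeric vector of cell
#'   probabilities).
#' @return The composite log-likelihood (natural log).
#' @export
composite_loglik <- function(obs, expected) {
  if (inherits(obs, "joint_sfs")) {
    if (!inherits(expected, "expected_sfs"))
      stop("expected must be an expected_sfs when obs is a joint_sfs")
    if (!identical(dim(obs$counts), dim(expected$p)))
      stop("observed and expected SFS shapes disagree")
    m <- sfs_poly_counts(obs)
    p <- as.vector(expected$p)[-obs$monomorphic_cells]
  } else {
    m <- as.numeric(obs)
    p <- as.numeric(expected)
    if (length(m) != length(p))
      stop("observed and expected SFS shapes disagree")
  }
  use <- m > 0
  if (any(p[use] <= 0))
    stop("expected probability is zero at an observed cell")
  sum(m[use] * log(p[use]))
}

#' Fit free parameters of a demographic model by ECM
#'
#' Maximizes the Monte-Carlo composite likelihood over the model's free
#' parameters by expectation conditional maximization: parameters are
#' partitioned into blocks (split times, then sizes, then migration
#' rates, then selfing), and each block is maximized conditionally by
#' bounded one-dimensional search, cycling until the relative
#' improvement of lnCL drops below `tol` or `max_cycles` is reached.
#' Within a cycle all likelihood evaluations share one simulation seed
#' (common random numbers), without which noisy line searches diverge.
#' Starts are initialized uniformly within bounds — log-uniformly when
#' the bounds span more than one order of magnitude — and the best of
#' `n_starts` runs is returned.
#'
#' @param obs observed `joint_sfs` (its haploid sample sizes must match
#'   the model's sample configuration).
#' @param model a [demographic_model()] template.
#' @param free named list of parameter bounds, e.g.
#'   `list(t_ARE = c(500, 60000))`; names follow `t_<derived>`,
#'   `N_<label>`, `m_<from>_<to>`, `s_<label>`. Defaults to the model's
#'   `free` attribute.
#' @param n_starts independent optimization starts (field-standard 100;
#'   desk scale 10).
#' @param max_cycles maximum ECM cycles per start (field-standard 100;
#'   desk scale 20).
#' @param tol relative lnCL stopping criterion (0.001).
#' @param n_sims coalescent simulations per likelihood evaluation.
#' @param seed integer seed governing starts and common random numbers.
#' @param model_id identifier stored in the result.
#' @return An object of class `fit_result`: parameter estimates, `lnCL`,
#'   `k`, `AIC = 2k - 2 lnCL`, per-start convergence flags, and the
#'   fitted model. A start that exhausts `max_cycles` is flagged
#'   non-converged rather than raising an error.
#' @export
fit_model <- function(obs, model, free = attr(model, "free"),
                      n_starts = 10, max_cycles = 20, tol = 1e-3,
                      n_sims = 2000, seed = 1, model_id = "model") {
  stopifnot(inherits(obs, "joint_sfs"), inherits(model, "demographic_model"))
  lg <- leaf_groups(model)
  if (!identical(as.integer(lg$haploid), as.integer(obs$sample_sizes)))
    stop("observed SFS sample sizes do not match the model")
  if (n_starts < 1) stop("n_starts must be at least 1")
  if (!is.null(free) && length(free)) {
    for (nm in names(free)) {
      b <- free[[nm]]
      if (length(b) != 2 || !all(is.finite(b)) || b[1] >= b[2] || b[1] <= 0)
        stop("free parameter '", nm, "' needs finite positive bounds")
      get_model_param(model, nm)  # validates the name
    }
  }
  k <- length(free)
  obs_counts <- sfs_poly_counts(obs)
  mono <- obs$monomorphic_cells

  eval_model <- function(m, crn_seed) {
    es <- expected_sfs(m, n_sims = n_sims, seed = crn_seed)
    composite_loglik(obs_counts, as.vector(es$p)[-mono])
  }

  # block order: times | sizes | migrations | selfing
  block_rank <- function(nm) match(substr(nm, 1, 2),
                                   c("t_", "N_", "m_", "s_"))
  free_names <- names(free)[order(vapply(names(free), block_rank,
                                         numeric(1)))]
  log_scale <- vapply(free, function(b) b[2] / b[1] > 10, logical(1))

  set.seed(seed)
  crn_seeds <- matrix(sample.int(.Machine$integer.max - 1,
                                 n_starts * (max_cycles + 1)),
                      n_starts, max_cycles + 1)
  inits <- lapply(seq_len(n_starts), function(st) {
    vapply(free_names, function(nm) {
      b <- free[[nm]]
      if (log_scale[[nm]]) exp(runif(1, log(b[1]), log(b[2])))
      else runif(1, b[1], b[2])
    }, numeric(1))
  })

  run_start <- function(st) {
    params <- if (k > 0) inits[[st]] else numeric(0)
    cur <- set_model_params(model, as.list(params))
    ln_old <- -Inf
    converged <- k == 0
    cycles <- 0L
    for (cy in seq_len(if (k == 0) 1L else max_cycles)) {
      crn <- crn_seeds[st, cy]
      if (k > 0) {
        for (nm in free_names) {
          b <- free[[nm]]
          f <- if (log_scale[[nm]]) {
            function(lv) -eval_model(set_model_param(cur, nm, exp(lv)), crn)
          } else {
            function(v) -eval_model(set_model_param(cur, nm, v), crn)
          }
          iv <- if (log_scale[[nm]]) log(b) else b
          opt <- optimize(f, interval = iv, tol = diff(iv) * 1e-3)
          val <- if (log_scale[[nm]]) exp(opt$minimum) else opt$minimum
          params[nm] <- val
          cur <- set_model_param(cur, nm, val)
        }
      }
      ln_new <- eval_model(cur, crn)
      cycles <- cy
      if (k == 0) { ln_old <- ln_new; converged <- TRUE; break }
      if (is.finite(ln_old) &&
          abs(ln_new - ln_old) < tol * abs(ln_old)) {
        ln_old <- ln_new
        converged <- TRUE
        break
      }
      ln_old <- ln_new
    }
    list(params = params, converged = converged, cycles = cycles,
         model = cur)
  }

  starts <- lapply(seq_len(n_starts), run_start)
  # final comparable evaluation with one fresh common seed
  final_seed <- crn_seeds[1, max_cycles + 1]
  lnls <- vapply(starts, function(s) eval_model(s$model, final_seed),
                 numeric(1))
  best <- which.max(lnls)
  lnCL <- lnls[best]
  structure(
    list(model_id = model_id,
         estimates = starts[[best]]$params,
         lnCL = lnCL, k = k, AIC = 2 * k - 2 * lnCL,
         n_starts = n_starts,
         start_lnCL = lnls,
         converged = vapply(starts, `[[`, logical(1), "converged"),
         converged_best = starts[[best]]$converged,
         seed = seed, n_sims = n_sims,
         free = free, tol = tol, max_cycles = max_cycles,
         fitted_model = starts[[best]]$model,
         obs_digest = sfs_digest(obs)),
    class = "fit_result"
  )
}

sfs_digest <- function(obs) {
  cnt <- as.vector(obs$counts)
  c(sum(cnt), sum(cnt * seq_along(cnt)), length(cnt))
}

#' @export
print.fit_result <- function(x, ...) {
  cat("fit_result '", x$model_id, "': lnCL = ", format(x$lnCL),
      ", k = ", x$k, ", AIC = ", format(x$AIC), "\n", sep = "")
  if (x$k > 0) {
    est <- paste(names(x$estimates), signif(x$estimates, 4), sep = " = ")
    cat("  estimates:", paste(est, collapse = ", "), "\n")
  }
  cat("  ", sum(x$converged), "/", x$n_starts, " start(s) converged\n",
      sep = "")
  invisible(x)
}

#' Compare fitted models by AIC
#'
#' Ranks fits of concurrent models on identical observed data by
#' `AIC = 2k - 2 lnCL` (ascending); ties are broken by smaller `k`, then
#' by model id.
#'
#' @param fits list of `fit_result` objects (>= 2) fitted to the same
#'   observed SFS.
#' @return List with `table` (data frame of model_id, k, lnCL, AIC,
#'   delta_AIC in ranked order) and `selected` (the winning
#'   `fit_result`).
#' @export
compare_models_aic <- function(fits) {
  if (!is.list(fits) || length(fits) < 2)
    stop("at least two fits are required for model comparison")
  stopifnot(all(vapply(fits, inherits, logical(1), "fit_result")))
  digests <- lapply(fits, `[[`, "obs_digest")
  if (!all(vapply(digests, identical, logical(1), digests[[1]])))
    stop("fits were not computed on identical observed data")
  tab <- data.frame(
    model_id = vapply(fits, `[[`, character(1), "model_id"),
    k = vapply(fits, `[[`, numeric(1), "k"),
    lnCL = vapply(fits, `[[`, numeric(1), "lnCL"),
    AIC = vapply(fits, `[[`, numeric(1), "AIC"))
  ord <- order(tab$AIC, tab$k, tab$model_id)
  tab <- tab[ord, , drop = FALSE]
  tab$delta_AIC <- tab$AIC - tab$AIC[1]
  rownames(tab) <- NULL
  list(table = tab, selected = fits[[ord[1]]])
}

#' Define one step of a hierarchical scenario comparison
#'
#' @param candidates named list of candidate specifications, each a list
#'   with `model` (a [demographic_model()]), optional `free` bounds,
#'   optional `provides` (character tags the candidate establishes if it
#'   wins) and optional `requires` (tags that must have been established
#'   by earlier winners).
#' @return An object of class `scenario_set`.
#' @export
scenario_set <- function(candidates) {
  if (length(candidates) < 1) stop("a scenario set needs candidates")
  if (is.null(names(candidates)) || any(!nzchar(names(candidates))))
    stop("candidates must be named")
  structure(list(candidates = candidates), class = "scenario_set")
}

#' Hierarchical scenario selection by AIC
#'
#' Runs the sequential, hierarchical model-selection procedure: at each
#' step every candidate model is fitted to that step's observed SFS, the
#' candidates are compared by AIC, and the winner's `provides` tags are
#' carried forward as constraints; a later candidate whose `requires`
#' tags are not all established by earlier winners is a contract
#' violation and raises an error.
#'
#' @param steps list of [scenario_set()] objects, in order.
#' @param obs a single `joint_sfs` shared by all steps, or a list with
#'   one `joint_sfs` per step.
#' @param ... further arguments passed to [fit_model()] (`n_starts`,
#'   `n_sims`, ...).
#' @param seed integer seed; each step/candidate fit gets a
#'   deterministic sub-seed.
#' @return List with `winners` (per-step winning `fit_result`), `final`
#'   (last winner), and `trace` (data frame recording every comparison).
#' @export
hierarchical_selection <- function(steps, obs, ..., seed = 1) {
  stopifnot(all(vapply(steps, inherits, logical(1), "scenario_set")))
  obs_list <- if (inherits(obs, "joint_sfs"))
    rep(list(obs), length(steps)) else obs
  if (length(obs_list) != length(steps))
    stop("provide one observed SFS, or one per step")
  provides <- character(0)
  winners <- vector("list", length(steps))
  trace <- list()
  for (st in seq_along(steps)) {
    cands <- steps[[st]]$candidates
    fits <- vector("list", length(cands))
    for (ci in seq_along(cands)) {
      cand <- cands[[ci]]
      req <- cand$requires
      if (length(req) && !all(req %in% provides))
        stop("candidate '", names(cands)[ci], "' in step ", st,
             " requires '", paste(setdiff(req, provides), collapse = ", "),
             "' not established by earlier winners")
      fits[[ci]] <- fit_model(obs_list[[st]], cand$model,
                              free = cand$free,
                              seed = seed + 1000L * st + ci,
                              model_id = names(cands)[ci], ...)
    }
    if (length(fits) == 1L) {
      winners[[st]] <- fits[[1]]
      sel_tab <- data.frame(model_id = fits[[1]]$model_id,
                            k = fits[[1]]$k, lnCL = fits[[1]]$lnCL,
                            AIC = fits[[1]]$AIC, delta_AIC = 0)
    } else {
      cmp <- compare_models_aic(fits)
      winners[[st]] <- cmp$selected
      sel_tab <- cmp$table
    }
    sel_tab$step <- st
    sel_tab$selected <- sel_tab$model_id == winners[[st]]$model_id
    trace[[st]] <- sel_tab
    win_cand <- cands[[winners[[st]]$model_id]]
    provides <- union(provides, win_cand$provides)
  }
  list(winners = winners, final = winners[[length(winners)]],
       trace = do.call(rbind, trace))
}

#' Parametric-bootstrap confidence intervals for fitted parameters
#'
#' Simulates `n_boot` datasets of the observed size under the fitted
#' model — multinomial draws of the observed polymorphic-site total from
#' the fitted cell probabilities — refits each with a reduced number of
#' starts, and returns percentile intervals.
#'
#' @param fit a converged `fit_result`.
#' @param obs the observed `joint_sfs` the fit used.
#' @param n_boot bootstrap replicates (>= 1).
#' @param level confidence level (default 0.95: the 2.5th and 97.5th
#'   percentiles).
#' @param seed integer seed.
#' @param n_starts starts per bootstrap refit (reduced; default 2).
#' @param ... further arguments passed to [fit_model()].
#' @return List with `intervals` (data frame: parameter, lower, upper,
#'   level) and `replicates` (matrix of bootstrap estimates).
#' @export
bootstrap_ci <- function(fit, obs, n_boot = 100, level = 0.95, seed = 1,
                         n_starts = 2, ...) {
  stopifnot(inherits(fit, "fit_result"), inherits(obs, "joint_sfs"))
  if (!isTRUE(fit$converged_best))
    stop("refusing bootstrap: the best start did not converge")
  if (n_boot < 1) stop("n_boot must be at least 1")
  if (level <= 0 || level >= 1) stop("level must lie in (0, 1)")
  if (fit$k == 0) stop("the fit has no free parameters")
  es <- expected_sfs(fit$fitted_model, n_sims = fit$n_sims, seed = seed)
  p <- as.vector(es$p)[-obs$monomorphic_cells]
  S <- sum(sfs_poly_counts(obs))
  set.seed(seed)
  boot_seeds <- sample.int(.Machine$integer.max - 1, n_boot)
  boot_counts <- rmultinom(n_boot, S, p)
  reps <- matrix(NA_real_, n_boot, fit$k,
                 dimnames = list(NULL, names(fit$free)))
  template <- obs
  for (b in seq_len(n_boot)) {
    cnt <- as.vector(template$counts)
    cnt[] <- 0
    cnt[-template$monomorphic_cells] <- boot_counts[, b]
    boot_obs <- new_joint_sfs(template$pop_labels, template$sample_sizes,
                              array(cnt, dim = dim(template$counts)))
    bf <- fit_model(boot_obs, fit$fitted_model, free = fit$free,
                    n_starts = n_starts, max_cycles = fit$max_cycles,
                    tol = fit$tol, n_sims = fit$n_sims,
                    seed = boot_seeds[b], model_id = fit$model_id, ...)
    reps[b, ] <- bf$estimates[colnames(reps)]
  }
  a <- (1 - level) / 2
  ci <- t(apply(reps, 2, quantile, probs = c(a, 1 - a), na.rm = TRUE))
  list(intervals = data.frame(parameter = rownames(ci),
                              lower = ci[, 1], upper = ci[, 2],
                              level = level, row.names = NULL),
       replicates = reps)
}

#' Convert split times from generations to years
#'
#' @param t_generations time(s) in generations (>= 0).
#' @param generation_time_years generation time in years; a length-2
#'   range yields the corresponding range of years.
#' @return `t * g`; for a range of generation times, a named vector
#'   (or matrix for vector `t`) spanning the range.
#' @export
generations_to_years <- function(t_generations, generation_time_years) {
  if (any(t_generations < 0)) stop("times must be non-negative")
  if (any(generation_time_years <= 0))
    stop("generation time must be positive")
  if (length(generation_time_years) == 1L)
    return(t_generations * generation_time_years)
  out <- outer(t_generations, generation_time_years)
  colnames(out) <- paste0("g", generation_time_years)
  if (length(t_generations) == 1L) out[1, ] else out
}
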