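#' Specify a demographic model
#'
#' A demographic model describes a set of populations with diploid
#' effective sizes and selfing rates, backward-in-time split events that
#' pool a derived population into its ancestral population, a backward
#' migration matrix between coexisting populations, and the mutational
#' parameters used to simulate sequence data. Time is measured in
#' generations before sampling; conversion to years happens only at
#' reporting via `generation_time_years`.
#'
#' @param populations data frame with columns `label`, `N` (diploid
#'   effective size, > 0) and `selfing` (selfing rate in \[0, 1\]).
#' @param splits data frame with columns `time` (generations backward,
#'   > 0), `derived` and `ancestral` (population labels); each derived
#'   population may split only once and both populations must still exist
#'   at the split time, so the events form a tree.
#' @param migration data frame with columns `from`, `to` and `rate`: the
#'   per-generation backward probability that a lineage currently in
#'   `from` traces its ancestry to `to`. Applied only while both
#'   populations exist.
#' @param mutation_rate per-site per-generation mutation rate.
#' @param locus_length locus length in bp for simulated loci.
#' @param sample_config named integer vector: diploid samples per
#'   population label (populations absent from it are unsampled).
#' @param generation_time_years generation time in years; may be a range
#'   such as `c(1, 2)`.
#' @return An object of class `demographic_model`.
#' @export
demographic_model <- function(populations, splits = NULL, migration = NULL,
                              mutation_rate = 0.355e-8,
                              locus_length = 5000L,
                              sample_config,
                              generation_time_years = c(1, 2)) {
  populations <- as.data.frame(populations)
  stopifnot(all(c("label", "N", "selfing") %in% names(populations)))
  labels <- as.character(populations$label)
  if (anyDuplicated(labels)) stop("population labels must be unique")
  if (any(populations$N <= 0)) stop("all effective sizes must be positive")
  if (any(populations$selfing < 0 | populations$selfing > 1))
    stop("selfing rates must lie in [0, 1]")
  if (mutation_rate < 0) stop("mutation_rate must be non-negative")
  if (locus_length < 1) stop("locus_length must be at least 1 bp")
  if (any(generation_time_years < 1) || any(generation_time_years > 2))
    stop("generation_time_years must lie in [1, 2]")

  if (is.null(splits)) {
    splits <- data.frame(time = numeric(0), derived = character(0),
                         ancestral = character(0))
  }
  splits <- as.data.frame(splits)
  if (nrow(splits)) {
    stopifnot(all(c("time", "derived", "ancestral") %in% names(splits)))
    splits$derived <- as.character(splits$derived)
    splits$ancestral <- as.character(splits$ancestral)
    unknown <- setdiff(c(splits$derived, splits$ancestral), labels)
    if (length(unknown))
      stop("split references unknown population(s): ",
           paste(unknown, collapse = ", "))
    if (any(splits$time <= 0)) stop("split times must be positive")
    splits <- splits[order(splits$time), , drop = FALSE]
    active <- setNames(rep(TRUE, length(labels)), labels)
    for (i in seq_len(nrow(splits))) {
      d <- splits$derived[i]; a <- splits$ancestral[i]
      if (d == a) stop("a population cannot split into itself")
      if (!active[d] || !active[a])
        stop("non-tree split sequence: population '",
             if (!active[d]) d else a,
             "' no longer exists at time ", splits$time[i])
      active[d] <- FALSE
    }
    if (sum(active) != 1L)
      stop("splits must reduce the populations to a single ancestor ",
           "for lineages to fully coalesce")
  } else if (length(labels) > 1L) {
    # multiple isolated populations are allowed only with migration
    if (is.null(migration) || !nrow(as.data.frame(migration)))
      stop("multiple populations require splits or migration to coalesce")
  }

  if (is.null(migration)) {
    migration <- data.frame(from = character(0), to = character(0),
                            rate = numeric(0))
  }
  migration <- as.data.frame(migration)
  if (nrow(migration)) {
    stopifnot(all(c("from", "to", "rate") %in% names(migration)))
    migration$from <- as.character(migration$from)
    migration$to <- as.character(migration$to)
    unknown <- setdiff(c(migration$from, migration$to), labels)
    if (length(unknown))
      stop("migration references unknown population(s): ",
           paste(unknown, collapse = ", "))
    if (any(migration$from == migration$to))
      stop("migration requires two distinct populations")
    if (any(migration$rate < 0)) stop("migration rates must be non-negative")
  }

  sample_config <- sample_config[sample_config > 0]
  if (!length(sample_config) || is.null(names(sample_config)))
    stop("sample_config must be a named vector of diploid sample counts")
  unknown <- setdiff(names(sample_config), labels)
  if (length(unknown))
    stop("sample_config references unknown population(s): ",
         paste(unknown, collapse = ", "))

  structure(
    list(populations = data.frame(label = labels, N = populations$N,
                                  selfing = populations$selfing),
         splits = splits, migration = migration,
         mutation_rate = mutation_rate,
         locus_length = as.integer(locus_length),
         sample_config = sample_config,
         generation_time_years = generation_time_years),
    class = "demographic_model"
  )
}

#' @export
print.demographic_model <- function(x, ...) {
  cat("demographic_model:", nrow(x$populations), "population(s),",
      nrow(x$splits), "split event(s),", nrow(x$migration),
      "migration edge(s)\n")
  cat("  mu =", format(x$mutation_rate), "per bp/gen; locus",
      x$locus_length, "bp; samples:",
      paste(names(x$sample_config), x$sample_config, sep = ":",
            collapse = " "), "\n")
  invisible(x)
}

#' Load a demographic model from a YAML config file
#'
#' The config is a YAML mapping with sections `populations` (list of
#' `label`/`Ne`/`selfing`; `Ne` is the diploid effective size — YAML
#' would parse a bare `N` key as a boolean), `splits` (list of
#' `time`/`derived`/
#' `ancestral`), `migration` (list of `from`/`to`/`rate`),
#' `mutation_rate`, `locus_length`, `sample_config` (mapping label to
#' diploid count), `generation_time_years`, and optionally `free`
#' (mapping parameter name, e.g. `t_POP` or `N_POP` or `m_A_B`, to
#' `[lower, upper]` bounds).
#'
#' @param path path to the YAML file.
#' @return A `demographic_model`; free-parameter bounds, if present, are
#'   attached as the `free` attribute (a named list of length-2 vectors).
#' @export
load_model_config <- function(path) {
  if (!file.exists(path)) stop("model config not found: ", path)
  cfg <- yaml::read_yaml(path)
  to_df <- function(x) if (is.null(x)) NULL else
    do.call(rbind, lapply(x, function(r) as.data.frame(r)))
  pops <- to_df(cfg$populations)
  if (!is.null(pops)) {
    # the schema key is Ne; tolerate an unquoted N key, which YAML 1.1
    # delivers as the boolean FALSE
    names(pops)[names(pops) %in% c("Ne", "FALSE.")] <- "N"
  }
  m <- demographic_model(
    populations = pops,
    splits = to_df(cfg$splits),
    migration = to_df(cfg$migration),
    mutation_rate = if (is.null(cfg$mutation_rate)) 0.355e-8 else
      cfg$mutation_rate,
    locus_length = if (is.null(cfg$locus_length)) 5000L else
      cfg$locus_length,
    sample_config = unlist(cfg$sample_config),
    generation_time_years = if (is.null(cfg$generation_time_years))
      c(1, 2) else unlist(cfg$generation_time_years)
  )
  if (!is.null(cfg$free)) {
    free <- lapply(cfg$free, function(b) {
      b <- unlist(b)
      if (length(b) != 2L || b[1] >= b[2] || b[1] <= 0)
        stop("free-parameter bounds must be positive [lower, upper]")
      b
    })
    for (nm in names(free)) get_model_param(m, nm)  # validates names
    attr(m, "free") <- free
  }
  m
}

# --- parameter access for the optimizer -------------------------------

# names: t_<derived label>, N_<label>, m_<from>_<to>, s_<label>
get_model_param <- function(model, name) {
  if (startsWith(name, "t_")) {
    lab <- substring(name, 3L)
    i <- match(lab, model$splits$derived)
    if (is.na(i)) stop("unknown split-time parameter: ", name)
    return(model$splits$time[i])
  }
  if (startsWith(name, "N_")) {
    lab <- substring(name, 3L)
    i <- match(lab, model$populations$label)
    if (is.na(i)) stop("unknown size parameter: ", name)
    return(model$populations$N[i])
  }
  if (startsWith(name, "s_")) {
    lab <- substring(name, 3L)
    i <- match(lab, model$populations$label)
    if (is.na(i)) stop("unknown selfing parameter: ", name)
    return(model$populations$selfing[i])
  }
  if (startsWith(name, "m_")) {
    parts <- strsplit(substring(name, 3L), "_", fixed = TRUE)[[1L]]
    if (length(parts) != 2L) stop("migration parameter must be m_<from>_<to>")
    i <- which(model$migration$from == parts[1] &
                 model$migration$to == parts[2])
    if (!length(i)) stop("unknown migration parameter: ", name)
    return(model$migration$rate[i[1]])
  }
  stop("unknown parameter: ", name)
}

set_model_param <- function(model, name, value) {
  if (startsWith(name, "t_")) {
    lab <- substring(name, 3L)
    i <- match(lab, model$splits$derived)
    if (is.na(i)) stop("unknown split-time parameter: ", name)
    model$splits$time[i] <- value
    ord <- order(model$splits$time)
    model$splits <- model$splits[ord, , drop = FALSE]
  } else if (startsWith(name, "N_")) {
    i <- match(substring(name, 3L), model$populations$label)
    if (is.na(i)) stop("unknown size parameter: ", name)
    model$populations$N[i] <- value
  } else if (startsWith(name, "s_")) {
    i <- match(substring(name, 3L), model$populations$label)
    if (is.na(i)) stop("unknown selfing parameter: ", name)
    model$populations$selfing[i] <- value
  } else if (startsWith(name, "m_")) {
    parts <- strsplit(substring(name, 3L), "_", fixed = TRUE)[[1L]]
    i <- which(model$migration$from == parts[1] &
                 model$migration$to == parts[2])
    if (!length(i)) stop("unknown migration parameter: ", name)
    model$migration$rate[i[1]] <- value
  } else stop("unknown parameter: ", name)
  model
}

set_model_params <- function(model, params) {
  for (nm in names(params)) model <- set_model_param(model, nm, params[[nm]])
  model
}

# flatten a demographic_model into the list the C++ engine consumes
demography_payload <- function(model) {
  labels <- model$populations$label
  sampled <- names(model$sample_config)
  n_dip <- setNames(integer(length(labels)), labels)
  n_dip[sampled] <- as.integer(model$sample_config)
  mig <- matrix(0, length(labels), length(labels),
                dimnames = list(labels, labels))
  if (nrow(model$migration))
    for (i in seq_len(nrow(model$migration)))
      mig[model$migration$from[i], model$migration$to[i]] <-
        model$migration$rate[i]
  sp <- model$splits[order(model$splits$time), , drop = FALSE]
  list(N = model$populations$N,
       selfing = model$populations$selfing,
       n_dip = unname(n_dip),
       split_time = as.numeric(sp$time),
       split_derived = match(sp$derived, labels) - 1L,
       split_anc = match(sp$ancestral, labels) - 1L,
       mig = mig)
}

# sampled-population labels in engine leaf order, plus per-leaf group index
leaf_groups <- function(model) {
  labels <- model$populations$label
  sampled <- labels[labels %in% names(model$sample_config)]
  n_dip <- as.integer(model$sample_config[sampled])
  group <- rep(seq_along(sampled) - 1L, times = 2L * n_dip)
  list(labels = sampled, n_dip = n_dip, haploid = 2L * n_dip,
       leaf_group = group)
}

#' Two-population split-with-gene-flow model at the inferred scale
#'
#' Builds the split model used throughout the documentation and tests: a
#' selfing derived population (`ARE`, the new arctic-expanding species)
#' splitting from its outcrossing-turned-selfing parental population
#' (`LSA`, northwestern Lake Superior) `t_split` generations ago, with
#' weak bidirectional gene flow. Sizes, selfing and migration are fixed
#' at field-realistic values for this system; mutation rate is
#' 0.355e-8 per bp per generation.
#'
#' @param t_split split time in generations backward (default 6007).
#' @param n_dip diploid samples per population (default 3, i.e. 6
#'   haploids, one fully sequenced individual from each of three nearby
#'   populations pooled into a super-population).
#' @return A `demographic_model` with the split time declared free over
#'   \[500, 60000\] in the `free` attribute.
#' @export
reference_split_model <- function(t_split = 6007, n_dip = 3L) {
  m <- demographic_model(
    populations = data.frame(label = c("ARE", "LSA"),
                             N = c(5000, 50000),
                             selfing = c(0.95, 0)),
    splits = data.frame(time = t_split, derived = "ARE",
                        ancestral = "LSA"),
    migration = data.frame(from = c("ARE", "LSA"), to = c("LSA", "ARE"),
                           rate = c(1e-6, 1e-6)),
    mutation_rate = 0.355e-8,
    locus_length = 5000L,
    sample_config = c(ARE = n_dip, LSA = n_dip),
    generation_time_years = c(1, 2)
  )
  attr(m, "free") <- list(t_ARE = c(500, 60000))
  m
}
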