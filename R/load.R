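#' Count per-sample mutational load from impact annotations
#'
#' Mutational load is the per-individual count of variants that are
#' homozygous for the alternate (putatively derived, deleterious) allele
#' and annotated MODERATE (e.g. missense changes) or HIGH (e.g. start-
#' and stop-codon changes) impact. Heterozygous and homozygous-reference
#' genotypes are never counted; missing genotypes are skipped.
#'
#' @param vcf a `vcf_data` object from [read_vcf()] (its `variants`
#'   table must carry impact annotations), or a list with elements
#'   `genotypes` ([genotype_matrix()]) and `variants` (data frame with
#'   an `impact` column aligned to the sites).
#' @param samples sample ids to count (default all).
#' @return Data frame of class `load_record`: sample_id,
#'   n_hom_moderate, n_hom_high, load.
#' @export
count_load <- function(vcf, samples = NULL) {
  g <- vcf$genotypes
  variants <- vcf$variants
  stopifnot(inherits(g, "genotype_matrix"),
            "impact" %in% names(variants),
            nrow(variants) == n_sites(g))
  if (is.null(samples)) samples <- g$sample_ids
  absent <- setdiff(samples, g$sample_ids)
  if (length(absent))
    stop("sample(s) absent from the VCF: ", paste(absent, collapse = ", "))
  mod <- !is.na(variants$impact) & variants$impact == "MODERATE"
  hig <- !is.na(variants$impact) & variants$impact == "HIGH"
  gg <- g$geno[, samples, drop = FALSE]
  hom <- !is.na(gg) & gg == 2L
  out <- data.frame(
    sample_id = samples,
    n_hom_moderate = colSums(hom & mod),
    n_hom_high = colSums(hom & hig),
    row.names = NULL
  )
  out$load <- out$n_hom_moderate + out$n_hom_high
  class(out) <- c("load_record", "data.frame")
  out
}

#' Mean mutational load per population
#'
#' @param records a `load_record` data frame (or any data frame with
#'   `sample_id` and `load`).
#' @param metadata data frame mapping `sample_id` to `population`.
#' @return Data frame with population, mean_load and n_samples.
#' @export
population_mean_load <- function(records, metadata) {
  stopifnot(all(c("sample_id", "load") %in% names(records)),
            all(c("sample_id", "population") %in% names(metadata)))
  i <- match(records$sample_id, metadata$sample_id)
  if (anyNA(i))
    stop("sample(s) absent from metadata: ",
         paste(records$sample_id[is.na(i)], collapse = ", "))
  pop <- metadata$population[i]
  agg <- aggregate(records$load, by = list(population = pop),
                   FUN = function(x) c(mean = mean(x), n = length(x)))
  data.frame(population = agg$population,
             mean_load = agg$x[, "mean"],
             n_samples = as.integer(agg$x[, "n"]),
             row.names = NULL)
}

#' Great-circle distance in kilometres
#'
#' Haversine distance on a sphere of mean Earth radius 6371.0088 km.
#'
#' @param lat1,lon1,lat2,lon2 coordinates in decimal degrees
#'   (vectorized).
#' @return Distance(s) in km.
#' @export
geodesic_km <- function(lat1, lon1, lat2, lon2) {
  if (any(abs(c(lat1, lat2)) > 90)) stop("latitude out of range")
  if (any(abs(c(lon1, lon2)) > 180)) stop("longitude out of range")
  geosphere::distHaversine(cbind(lon1, lat1), cbind(lon2, lat2),
                           r = 6371.0088 * 1000) / 1000
}

#' Expansion route along ordered waypoints
#'
#' An expansion route is an ordered list of nodes from the expansion
#' origin to a sample's terminal location — e.g. the map-projected
#' internal nodes of a population tree along a post-glacial colonization
#' path. Node coordinates are supplied by the user (or a YAML config via
#' [read_route_config()]); the package computes distances, not the tree
#' projection itself.
#'
#' @param nodes data frame with columns `label`, `latitude`,
#'   `longitude`, ordered from origin to endpoint.
#' @return An object of class `expansion_route`.
#' @export
expansion_route <- function(nodes) {
  nodes <- as.data.frame(nodes)
  stopifnot(all(c("label", "latitude", "longitude") %in% names(nodes)))
  if (nrow(nodes) < 1L) stop("a route needs at least one node")
  if (any(abs(nodes$latitude) > 90) || any(abs(nodes$longitude) > 180))
    stop("route coordinates out of range")
  structure(list(nodes = nodes), class = "expansion_route")
}

#' @rdname expansion_route
#' @param path YAML file with a `route` list of `label`/`latitude`/
#'   `longitude` nodes.
#' @export
read_route_config <- function(path) {
  if (!file.exists(path)) stop("route config not found: ", path)
  cfg <- yaml::read_yaml(path)
  nodes <- do.call(rbind, lapply(cfg$route, as.data.frame))
  expansion_route(nodes)
}

#' Total geodesic length of an expansion route
#'
#' Sum of great-circle distances over consecutive node pairs; a
#' single-node route has distance 0.
#'
#' @param route an [expansion_route()].
#' @return Distance in km.
#' @export
route_distance <- function(route) {
  stopifnot(inherits(route, "expansion_route"))
  n <- nrow(route$nodes)
  if (n < 2L) return(0)
  sum(geodesic_km(route$nodes$latitude[-n], route$nodes$longitude[-n],
                  route$nodes$latitude[-1L], route$nodes$longitude[-1L]))
}

#' Regress mutational load on log expansion distance
#'
#' Ordinary least squares of individual load on log10(expansion distance
#' in km), with a two-sided t-test on the slope — the standard check
#' that load accumulates along a serial-founder expansion route. Zero
#' distances are offset by +1 km before the log (logged).
#'
#' @param records data frame with columns `load` and
#'   `expansion_distance_km` (>= 3 rows).
#' @return List with `slope`, `intercept`, `r` (correlation of load
#'   with log10 distance), `p` (slope t-test), `n` and the underlying
#'   `lm` fit.
#' @export
load_distance_regression <- function(records) {
  stopifnot(all(c("load", "expansion_distance_km") %in% names(records)))
  if (nrow(records) < 3L)
    stop("at least 3 records are required for the regression")
  d <- records$expansion_distance_km
  if (any(d < 0)) stop("distances must be non-negative")
  if (any(d == 0)) {
    message("load_distance_regression: offset ", sum(d == 0),
            " zero distance(s) by +1 km before log transform")
    d[d == 0] <- 1
  }
  if (length(unique(d)) == 1L)
    stop("regression refused: all distances are equal")
  x <- log10(d)
  fit <- lm(records$load ~ x)
  sm <- summary(fit)$coefficients
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       r = cor(records$load, x), p = sm[2, 4], n = nrow(records),
       fit = fit)
}
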