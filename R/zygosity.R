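#' Correlation of zygosity (individual-level LD profile)
#'
#' Within a single genome, let z(x) = 1 if the individual is
#' heterozygous at site x and 0 otherwise; the genome-wide
#' heterozygosity is theta = mean(z). For each distance bin, the
#' correlation of zygosity Delta is the Pearson correlation of
#' (z(x), z(y)) over all ordered within-region site pairs whose distance
#' falls in the bin — an individual-based measure of linkage
#' disequilibrium that does not require phasing, sensitive to the long
#' heterozygosity tracts produced by selfing and expansion bottlenecks.
#' Pairs never span region boundaries.
#'
#' @param x either a 0/1 heterozygosity indicator vector (dense
#'   sequence; positions default to 1, 2, ...), or a
#'   [genotype_matrix()], in which case `sample` selects one individual
#'   and z is the indicator of genotype 1 at its non-missing sites.
#' @param bin_edges strictly increasing distance-bin edges in bp; bin i
#'   is `[edges[i], edges[i+1])`.
#' @param positions site positions (defaults to `seq_along(x)` for a
#'   vector, or the matrix positions).
#' @param regions region id per site (defaults to one region for a
#'   vector, chromosome for a matrix); pairs are formed within regions
#'   only. Supply e.g. genic-interval ids to restrict pairing to genic
#'   regions.
#' @param sample sample id when `x` is a genotype matrix.
#' @param id individual id recorded in the profile.
#' @return An object of class `zygosity_profile`: data frame `profile`
#'   with bin bounds, mean pair distance, pair count, `delta` (Pearson
#'   correlation) and `delta_cov` (covariance scaled by
#'   theta (1 - theta), an alternative scaling), plus `theta`, `id`,
#'   `n_sites` and flag `undefined` (theta = 0).
#' @export
correlation_of_zygosity <- function(x, bin_edges, positions = NULL,
                                    regions = NULL, sample = NULL,
                                    id = "individual") {
  if (inherits(x, "genotype_matrix")) {
    if (is.null(sample)) {
      if (length(x$sample_ids) != 1L)
        stop("supply `sample` to pick one individual")
      sample <- x$sample_ids[1]
    }
    j <- match(sample, x$sample_ids)
    if (is.na(j)) stop("unknown sample: ", sample)
    gv <- x$geno[, j]
    keep <- !is.na(gv)
    z <- as.integer(gv[keep] == 1L)
    positions <- x$pos[keep]
    regions <- x$chrom[keep]
    id <- sample
  } else {
    z <- as.integer(x)
    if (any(is.na(z)) || any(!z %in% c(0L, 1L)))
      stop("x must be a 0/1 heterozygosity indicator")
    if (is.null(positions)) positions <- seq_along(z)
    if (is.null(regions)) regions <- rep(1L, length(z))
  }
  if (length(z) < 2L) stop("at least 2 informative sites are required")
  if (length(bin_edges) < 2L || any(diff(bin_edges) <= 0))
    stop("bin_edges must be strictly increasing with >= 2 values")
  theta <- mean(z)
  lo <- bin_edges[-length(bin_edges)]
  hi <- bin_edges[-1L]
  if (theta == 0) {
    prof <- data.frame(bin_lo = lo, bin_hi = hi, distance = NA_real_,
                       n_pairs = 0, delta = NA_real_,
                       delta_cov = NA_real_)
    return(structure(list(profile = prof, theta = 0, id = id,
                          n_sites = length(z), undefined = TRUE),
                     class = "zygosity_profile"))
  }
  reg <- as.integer(factor(regions, levels = unique(regions)))
  st <- .zygosity_pair_stats(as.numeric(positions), z, reg, lo, hi)
  n <- st$n
  delta <- delta_cov <- dist <- rep(NA_real_, length(lo))
  pos_ok <- n > 1
  vx <- st$Sx / n - (st$Sx / n)^2  # z in {0,1}: Sxx = Sx
  vy <- st$Sy / n - (st$Sy / n)^2
  covxy <- st$Sxy / n - (st$Sx / n) * (st$Sy / n)
  good <- pos_ok & vx > 0 & vy > 0
  delta[good] <- covxy[good] / sqrt(vx[good] * vy[good])
  delta_cov[pos_ok] <- covxy[pos_ok] / (theta * (1 - theta))
  dist[n > 0] <- st$Sd[n > 0] / n[n > 0]
  prof <- data.frame(bin_lo = lo, bin_hi = hi, distance = dist,
                     n_pairs = n, delta = delta, delta_cov = delta_cov)
  structure(list(profile = prof, theta = theta, id = id,
                 n_sites = length(z), undefined = FALSE),
            class = "zygosity_profile")
}

#' @export
print.zygosity_profile <- function(x, ...) {
  cat(sprintf("zygosity_profile '%s': theta = %.4g over %d site(s)\n",
              x$id, x$theta, x$n_sites))
  if (x$undefined) cat("  undefined: no heterozygous sites\n")
  else print(x$profile, row.names = FALSE)
  invisible(x)
}

#' Extent of individual-level LD
#'
#' Rescales the correlation-of-zygosity profile to its value in the
#' shortest-distance bin (`scaled = delta(d) / delta(d_min)`) and
#' returns the distance at which the scaled profile first drops to
#' `threshold`, interpolating linearly between adjacent bins in log10
#' distance. If the profile never reaches the threshold the extent is
#' right-censored.
#'
#' @param profile a `zygosity_profile`.
#' @param threshold scaled-Delta threshold in (0, 1\]; the conventional
#'   low value is 0.1.
#' @return List with `extent_bp` (NA when censored) and `censored`.
#' @export
ld_extent <- function(profile, threshold = 0.1) {
  stopifnot(inherits(profile, "zygosity_profile"))
  if (profile$undefined) stop("profile is undefined (theta = 0)")
  if (threshold <= 0 || threshold > 1)
    stop("threshold must lie in (0, 1]")
  pr <- profile$profile
  ok <- !is.na(pr$delta) & !is.na(pr$distance) & pr$distance > 0
  pr <- pr[ok, , drop = FALSE]
  if (nrow(pr) < 1L) stop("profile has no defined bins")
  ref <- pr$delta[1]
  if (!is.finite(ref) || ref <= 0)
    stop("reference (shortest-distance) bin has non-positive delta")
  scaled <- pr$delta / ref
  if (scaled[1] <= threshold)
    return(list(extent_bp = pr$distance[1], censored = FALSE))
  below <- which(scaled <= threshold)
  if (!length(below)) return(list(extent_bp = NA_real_, censored = TRUE))
  i <- below[1]
  x0 <- log10(pr$distance[i - 1]); x1 <- log10(pr$distance[i])
  y0 <- scaled[i - 1]; y1 <- scaled[i]
  xt <- x0 + (threshold - y0) * (x1 - x0) / (y1 - y0)
  list(extent_bp = 10^xt, censored = FALSE)
}
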