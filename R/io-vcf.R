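#' Read a VCF into a genotype matrix and annotated variant table
#'
#' Reads a VCF 4.x file with a GT FORMAT field. Only biallelic SNP records
#' are kept; multiallelic records and indels are skipped with a logged
#' count. If the INFO column carries SnpEff-style `ANN` entries, the
#' functional impact (LOW, MODERATE, HIGH or MODIFIER) of the first
#' annotation — by SnpEff convention the most severe — is attached to each
#' variant.
#'
#' @param path path to a VCF file (plain text or gzipped).
#' @param require_ann if `TRUE`, fail when no record carries an ANN entry.
#' @return A list of class `vcf_data` with elements `genotypes`
#'   (a [genotype_matrix()], alternate-allele counts, unpolarized),
#'   `variants` (data frame with chrom, pos, ref, alt and impact), and
#'   `counts` (records read / kept / skipped).
#' @export
read_vcf <- function(path, require_ann = FALSE) {
  if (!file.exists(path)) stop("VCF file not found: ", path)
  v <- tryCatch(vcfR::read.vcfR(path, verbose = FALSE),
                error = function(e) stop("malformed VCF: ", conditionMessage(e)))
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  n_read <- nrow(fix)
  if (n_read == 0L) stop("VCF contains no records")
  fmt <- v@gt[, "FORMAT"]
  if (!all(vapply(strsplit(fmt, ":"), function(f) "GT" %in% f, logical(1))))
    stop("VCF FORMAT lacks a GT field")
  ref <- fix[, "REF"]; alt <- fix[, "ALT"]
  snp <- !is.na(alt) & !grepl(",", alt, fixed = TRUE) &
    ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T")
  n_skip <- sum(!snp)
  if (n_skip > 0)
    message("read_vcf: skipped ", n_skip,
            " multiallelic/indel record(s); kept ", sum(snp))
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = n_read)
  samples <- colnames(v@gt)[-1L]
  geno <- gt_to_dosage(gt[snp, , drop = FALSE])
  ann <- vcfR::extract.info(v, element = "ANN")
  impact <- rep(NA_character_, n_read)
  if (!all(is.na(ann))) impact <- parse_ann_impact(ann)
  if (require_ann && all(is.na(impact)))
    stop("require_ann = TRUE but no ANN annotations found")
  g <- genotype_matrix(geno, fix[snp, "CHROM"], as.integer(fix[snp, "POS"]),
                       samples, polarized = FALSE)
  variants <- data.frame(
    chrom = fix[snp, "CHROM"], pos = as.integer(fix[snp, "POS"]),
    ref = ref[snp], alt = alt[snp], impact = impact[snp],
    stringsAsFactors = FALSE, row.names = NULL
  )
  structure(list(genotypes = g, variants = variants,
                 counts = c(read = n_read, kept = sum(snp),
                            skipped = n_skip)),
            class = "vcf_data")
}

# "0/1", "0|1", "./." etc -> alternate-allele dosage
gt_to_dosage <- function(gt) {
  out <- matrix(NA_integer_, nrow(gt), ncol(gt))
  clean <- gsub("\\|", "/", gt)
  out[clean %in% c("0/0")] <- 0L
  out[clean %in% c("0/1", "1/0")] <- 1L
  out[clean %in% c("1/1")] <- 2L
  out
}

# impact = third pipe-delimited field (Allele|Annotation|Impact|...) of the
# first comma-separated ANN annotation
parse_ann_impact <- function(ann) {
  vapply(ann, function(a) {
    if (is.na(a) || !nzchar(a)) return(NA_character_)
    first <- strsplit(a, ",", fixed = TRUE)[[1L]][1L]
    fields <- strsplit(first, "|", fixed = TRUE)[[1L]]
    if (length(fields) < 3L) return(NA_character_)
    imp <- fields[3L]
    if (imp %in% c("LOW", "MODERATE", "HIGH", "MODIFIER")) imp
    else NA_character_
  }, character(1), USE.NAMES = FALSE)
}

#' Write a genotype matrix as a VCF file
#'
#' Serializes a [genotype_matrix()] (and optional per-site impact
#' annotations) as an uncompressed VCF 4.2 file with a GT field.
#' `write_vcf(read_vcf(f))` preserves genotypes and ANN impact for every
#' record kept.
#'
#' @param g a [genotype_matrix()].
#' @param path output file path.
#' @param impact optional character vector of SnpEff impact levels per
#'   site; written as a minimal ANN INFO entry.
#' @param ref,alt optional reference/alternate alleles per site (defaults
#'   A and T).
#' @return Invisibly, the output path.
#' @export
write_vcf <- function(g, path, impact = NULL, ref = NULL, alt = NULL) {
  stopifnot(inherits(g, "genotype_matrix"))
  n <- n_sites(g)
  if (is.null(ref)) ref <- rep("A", n)
  if (is.null(alt)) alt <- rep("T", n)
  if (!is.null(impact) && length(impact) != n)
    stop("impact must have one entry per site")
  hdr <- c("##fileformat=VCFv4.2",
           "##source=splitself",
           paste0("##INFO=<ID=ANN,Number=.,Type=String,",
                  "Description=\"Functional annotations: ",
                  "'Allele|Annotation|Impact|Gene'\">"),
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", g$sample_ids), collapse = "\t"))
  code <- c("0/0", "0/1", "1/1")
  gt <- matrix("./.", n, length(g$sample_ids))
  ok <- !is.na(g$geno)
  gt[ok] <- code[g$geno[ok] + 1L]
  info <- rep(".", n)
  if (!is.null(impact)) {
    has <- !is.na(impact)
    info[has] <- paste0("ANN=", alt[has], "|custom_variant|", impact[has],
                        "|gene1")
  }
  body <- paste(g$chrom, g$pos, ".", ref, alt, ".", "PASS", info, "GT",
                apply(gt, 1, paste, collapse = "\t"), sep = "\t")
  if (n == 0L) body <- character(0)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(hdr, body), con)
  invisible(path)
}

#' Read a sample metadata table
#'
#' Reads a tab-separated table with header columns `sample_id`,
#' `population`, `super_population`, `species`, `latitude`, `longitude`
#' and `mating_system`. Mating system must be one of `outcrossing`,
#' `selfing` or `unknown`; empty values default to `unknown`.
#'
#' @param path path to the TSV file.
#' @return A data frame with one validated row per sample.
#' @export
read_metadata <- function(path) {
  if (!file.exists(path)) stop("metadata file not found: ", path)
  md <- read.delim(path, stringsAsFactors = FALSE)
  req <- c("sample_id", "population", "super_population", "species",
           "latitude", "longitude", "mating_system")
  missing_cols <- setdiff(req, names(md))
  if (length(missing_cols))
    stop("metadata lacks required column(s): ",
         paste(missing_cols, collapse = ", "))
  if (anyDuplicated(md$sample_id))
    stop("duplicate sample_id in metadata")
  if (any(!is.na(md$latitude) & abs(md$latitude) > 90))
    stop("latitude out of range [-90, 90]")
  if (any(!is.na(md$longitude) & abs(md$longitude) > 180))
    stop("longitude out of range [-180, 180]")
  ms <- as.character(md$mating_system)
  ms[is.na(ms) | !nzchar(ms)] <- "unknown"
  if (!all(ms %in% c("outcrossing", "selfing", "unknown")))
    stop("mating_system must be outcrossing, selfing or unknown")
  md$mating_system <- ms
  md
}
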