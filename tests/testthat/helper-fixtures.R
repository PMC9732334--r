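# Shared fixtures built in code.

# minimal VCF with a multiallelic record and SnpEff-style ANN entries
write_fixture_vcf <- function(path) {
  writeLines(c(
    "##fileformat=VCFv4.2",
    paste0("##INFO=<ID=ANN,Number=.,Type=String,Description=",
           "\"Functional annotations\">"),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "A", "B", sep = "\t"),
    paste("chr1", "100", ".", "A", "T", "50", "PASS",
          "ANN=T|missense_variant|MODERATE|gene1", "GT", "0/1", "1/1",
          sep = "\t"),
    paste("chr1", "200", ".", "G", "T,C", "50", "PASS", ".", "GT", "1/2",
          "0/0", sep = "\t"),
    paste("chr1", "300", ".", "C", "G", "50", "PASS",
          "ANN=G|stop_gained|HIGH|gene2", "GT", "./.", "0/0",
          sep = "\t")
  ), path)
  path
}

write_fixture_metadata <- function(path, lat = c(58.7, 47.1)) {
  writeLines(c(
    paste("sample_id", "population", "super_population", "species",
          "latitude", "longitude", "mating_system", sep = "\t"),
    paste("A", "pop1", "LS", "lyrata", lat[1], "-94.1", "selfing",
          sep = "\t"),
    paste("B", "pop2", "WI", "lyrata", lat[2], "-90.5", "", sep = "\t")
  ), path)
  path
}

# small polarized genotype matrix from explicit per-site dosage rows
gm_from_rows <- function(rows, pop = NULL, polarized = TRUE,
                         chrom = NULL, pos = NULL) {
  geno <- do.call(rbind, rows)
  n <- nrow(geno)
  genotype_matrix(geno,
                  chrom = if (is.null(chrom)) rep("chr1", n) else chrom,
                  pos = if (is.null(pos)) seq_len(n) * 1000L else pos,
                  sample_ids = paste0("s", seq_len(ncol(geno))),
                  pop = pop, polarized = polarized)
}

# one-population neutral model with theta_locus = 4 N mu L = 1
watterson_model <- function(n_dip = 3L) {
  demographic_model(
    populations = data.frame(label = "A", N = 10000, selfing = 0),
    mutation_rate = 2.5e-8, locus_length = 1000L,
    sample_config = c(A = n_dip))
}

# ((P1, P2), P3, O) quartet with no gene flow, for D-statistic nulls
quartet_model <- function() {
  demographic_model(
    populations = data.frame(label = c("P1", "P2", "P3", "O"), N = 10000,
                             selfing = 0),
    splits = data.frame(time = c(2000, 6000, 20000),
                        derived = c("P2", "P3", "O"),
                        ancestral = c("P1", "P1", "P1")),
    mutation_rate = 1.25e-8, locus_length = 2000L,
    sample_config = c(P1 = 2, P2 = 2, P3 = 2, O = 2))
}

quartet_sets <- function() {
  list(P1 = c("P1_1", "P1_2"), P2 = c("P2_1", "P2_2"),
       P3 = c("P3_1", "P3_2"), O = c("O_1", "O_2"))
}

# three-population tree with a configurable sister pair; the generating
# topology used in model-selection checks is ((P1, P2), P3)
topo_model <- function(anc = "P1", sister = "P2", outer = "P3",
                       migration = NULL) {
  demographic_model(
    populations = data.frame(label = c("P1", "P2", "P3"), N = 10000,
                             selfing = 0),
    splits = data.frame(time = c(2000, 8000),
                        derived = c(sister, outer),
                        ancestral = c(anc, anc)),
    migration = migration,
    mutation_rate = 1.25e-8, locus_length = 2000L,
    sample_config = c(P1 = 2, P2 = 2, P3 = 2))
}

# hand-built progeny array (genotypes are counts of allele 1)
make_array <- function(maternal, offspring, pollen_freqs) {
  structure(list(maternal = as.integer(maternal),
                 offspring = matrix(as.integer(offspring),
                                    ncol = length(maternal)),
                 pollen_freqs = pollen_freqs,
                 n_loci = length(maternal),
                 n_offspring = nrow(matrix(offspring,
                                           ncol = length(maternal)))),
            class = "progeny_array")
}
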