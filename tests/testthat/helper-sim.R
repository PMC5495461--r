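# Small simulation configurations reused across tests.

tiny_config <- function(seed = 11, ...) {
  args <- list(genome_length = 120000L, n_genes = 8L, n_duplex_loci = 10L,
               n_cleavage_links = 3L, n_methyl_links = 2L,
               n_decoy_de_genes = 2L, n_decoy_tags = 5L,
               n_background_regions = 4L, de_fraction = 0.6, seed = seed)
  do.call(sim_config, utils::modifyList(args, list(...)))
}

# A bare genome with duplex loci and no genes, for catalog-level tests.
loci_only_config <- function(seed = 3, genome_length = 50000L,
                             n_duplex_loci = 15L, ...) {
  sim_config(genome_length = genome_length, n_genes = 0L,
             n_duplex_loci = n_duplex_loci, n_cleavage_links = 0L,
             n_methyl_links = 0L, n_decoy_de_genes = 0L,
             seed = seed, ...)
}

# Run generator components up to tag emission without gene links.
make_catalog_fixture <- function(config) {
  g <- generate_genome(config)
  planted <- plant_duplex_loci(g, config)
  lk <- plant_target_links(g, planted, config)
  gt <- lk$ground_truth
  tags <- simulate_srna_libraries(gt, config)
  list(genome = lk$genome_obj, ground_truth = gt, tags = tags)
}

lib_cols <- paste0("count_", c("CK", "I", "II", "III"))

# Three-pattern fold-change profiles (sustained up / sustained down /
# transient up) with planted labels.
make_pattern_profiles <- function(n_per = 20, noise_sd = 0.1, seed = 99) {
  set.seed(seed)
  centroids <- rbind(c(2, 2, 2), c(-2, -2, -2), c(2, 0, 0))
  truth <- rep(1:3, each = n_per)
  x <- centroids[truth, ] + matrix(rnorm(3 * n_per * 3, 0, noise_sd),
                                   ncol = 3)
  df <- data.frame(gene_id = sprintf("g%03d", seq_along(truth)),
                   lfc_I = x[, 1], lfc_II = x[, 2], lfc_III = x[, 3],
                   stringsAsFactors = FALSE)
  list(profiles = df, truth = truth)
}

random_intervals <- function(n, seed = 1) {
  set.seed(seed)
  start <- sample.int(1e6, n)
  data.frame(chrom = paste0("chr", sample(1:3, n, replace = TRUE)),
             start = start, end = start + sample.int(5000, n),
             name = sprintf("iv%05d", seq_len(n)),
             strand = sample(c("+", "-"), n, replace = TRUE),
             stringsAsFactors = FALSE)
}
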