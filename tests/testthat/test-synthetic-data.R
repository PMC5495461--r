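test_that("generator is deterministic and validates its configuration", {
  cfg <- sim_config(genome_length = 100000L, n_genes = 5L,
                    n_duplex_loci = 8L, n_cleavage_links = 2L,
                    n_methyl_links = 1L, n_decoy_de_genes = 1L, seed = 7)
  a <- simulate_dataset(cfg)
  b <- simulate_dataset(cfg)
  expect_identical(a$genome$genome, b$genome$genome)
  expect_identical(a$srna_tags, b$srna_tags)
  expect_identical(a$gene_counts, b$gene_counts)
  expect_identical(a$methyl$signal, b$methyl$signal)
  expect_identical(a$ground_truth$loci, b$ground_truth$loci)
  # weight vector must be a distribution over 20..25
  expect_error(sim_config(sirna_length_weights = c("20" = 1)), "20..25")
  expect_error(sim_config(planted_lfc = 0), "planted_lfc")
})

test_that("genome generation handles empty and impossible requests", {
  g0 <- generate_genome(sim_config(n_genes = 0L, n_duplex_loci = 4L,
                                   n_cleavage_links = 0L,
                                   n_methyl_links = 0L,
                                   n_decoy_de_genes = 0L,
                                   genome_length = 30000L))
  expect_equal(nrow(g0$genes), 0)
  expect_gt(nrow(g0$excluded), 0)
  expect_error(
    generate_genome(sim_config(genome_length = 1000L, n_genes = 500L)),
    "too short")
  # gene models are disjoint and within bounds
  g <- generate_genome(sim_config(seed = 4))
  genes <- g$genes[order(g$genes$start), ]
  expect_true(all(genes$start >= 0 & genes$end <= 600000))
  expect_true(all(utils::head(genes$end, -1) <= genes$start[-1]))
})

test_that("planted pairs satisfy the duplex geometry; near-misses do not", {
  cfg <- loci_only_config(seed = 31, n_duplex_loci = 20L)
  fx <- make_catalog_fixture(cfg)
  loci <- fx$ground_truth$loci
  planted <- loci[loci$type == "planted", ]
  near <- loci[loci$type == "near_miss", ]
  expect_equal(nrow(near), round(0.2 * 20))
  geom_ok <- function(l) {
    l$plus_start - l$minus_start == 2 & l$plus_end - l$minus_end == 2
  }
  expect_true(all(geom_ok(planted)))
  expect_false(any(geom_ok(near)))
  # loci avoid excluded-class intervals
  ex <- fx$genome$excluded
  for (i in seq_len(nrow(loci))) {
    expect_false(any(loci$start[i] < ex$end & loci$end[i] > ex$start))
  }
})

test_that("tag counts follow the configured count model", {
  # dispersion 0: Poisson moments, sample mean within 3 SE over 1000 tags
  cfg <- loci_only_config(seed = 13, genome_length = 3e6, n_duplex_loci = 500L,
                          baseline_mean = 100, dispersion = 0,
                          de_fraction = 0, noise_sd = 0)
  fx <- make_catalog_fixture(cfg)
  cnt <- fx$tags$count_CK
  n <- length(cnt)
  expect_gte(n, 1000)
  se <- sqrt(100 / n)
  expect_lt(abs(mean(cnt) - 100), 3 * se)
  expect_lt(abs(var(cnt) / 100 - 1), 0.2)
  # planted log2 fold change 2: stage-I/CK mean ratio inside the 3 SE band
  cfg2 <- loci_only_config(seed = 14, genome_length = 2e6,
                           n_duplex_loci = 300L, baseline_mean = 100,
                           de_fraction = 1, planted_lfc = 2, noise_sd = 0)
  fx2 <- make_catalog_fixture(cfg2)
  loci <- fx2$ground_truth$loci
  up_loci <- loci$locus_id[loci$type == "planted" & loci$de_I == "up"]
  gt_tags <- fx2$ground_truth$tags
  up_tags <- gt_tags$tag_id[gt_tags$locus_id %in% up_loci]
  sel <- fx2$tags$tag_id %in% up_tags
  expect_gte(sum(sel), 150)
  ratio <- mean(fx2$tags$count_I[sel]) / mean(fx2$tags$count_CK[sel])
  expect_gt(ratio, 3)
  expect_lt(ratio, 5.3)
})

test_that("linked genes are planted exactly anti-proportional to siRNAs", {
  cfg <- tiny_config(seed = 23)
  sim <- simulate_dataset(cfg)
  gt <- sim$ground_truth
  stage_lfc <- function(locus) {
    d <- unlist(locus[c("de_I", "de_II", "de_III")], use.names = FALSE)
    ifelse(d == "up", cfg$planted_lfc, ifelse(d == "down",
                                              -cfg$planted_lfc, 0))
  }
  links <- rbind(gt$cleavage_links[, c("locus_id", "gene_id")],
                 gt$methyl_links[, c("locus_id", "gene_id")])
  for (i in seq_len(nrow(links))) {
    locus <- gt$loci[gt$loci$locus_id == links$locus_id[i], ]
    s_lfc <- stage_lfc(locus)
    # the noiseless planted construction is an exact negation, so the
    # noiseless profile correlation is -1; verify on realized counts
    # that the anticorrelation survives counting noise
    tagid <- paste0(locus$locus_id, "_p")
    gtag <- sim$srna_tags[sim$srna_tags$tag_id == tagid, lib_cols]
    ggene <- sim$gene_counts[sim$gene_counts$gene_id == links$gene_id[i],
                             lib_cols]
    r <- profile_correlation(log2(unlist(gtag) + 0.5),
                             log2(unlist(ggene) + 0.5))
    expect_lt(r, -0.9)
    expect_true(any(s_lfc != 0))  # every linked locus carries a planted DE
  }
  # unlinked, non-decoy genes have equal means: realized counts stay close
  lab <- gt$cluster_labels
  quiet <- setdiff(sim$gene_counts$gene_id, lab$gene_id)
  qc <- sim$gene_counts[sim$gene_counts$gene_id %in% quiet, lib_cols]
  fold <- as.matrix(qc[, -1]) / qc[, 1]
  expect_lt(max(abs(log2(fold))), 1)
})

test_that("links and labels keep referential integrity", {
  sim <- simulate_dataset(tiny_config(seed = 29))
  gt <- sim$ground_truth
  expect_true(all(gt$cleavage_links$gene_id %in% sim$gene_counts$gene_id))
  expect_true(all(gt$cleavage_links$sirna_tag %in% gt$tags$tag_id))
  expect_true(all(gt$methyl_links$region_id %in%
                    sim$methyl$regions$region_id))
  expect_true(all(gt$cluster_labels$class %in% 1:3))
  # a link to a non-existent gene is refused
  broken <- gt
  broken$cleavage_links$gene_id[1] <- "gXXX"
  expect_error(
    simulate_gene_expression(sim$genome$genes, broken, sim$config),
    "referential-integrity")
})

test_that("methylation signal carries the planted ratio and clean nulls", {
  cfg <- tiny_config(seed = 37, methyl_ratio = 4)
  sim <- simulate_dataset(cfg)
  gt <- sim$ground_truth
  sig <- sim$methyl$signal
  hyper <- gt$methyl_links[gt$methyl_links$direction == "hyper", ]
  for (i in seq_len(nrow(hyper))) {
    row <- sig[sig$region_id == hyper$region_id[i], ]
    ratio <- row$count_I / row$count_CK
    # planted ratio 4 at baseline 50: 3 SE of the per-region ratio is wide,
    # accept [2, 8]
    expect_gt(ratio, 2)
    expect_lt(ratio, 8)
  }
  # with no links every region is stationary and the screen stays silent
  cfg0 <- tiny_config(seed = 41, n_methyl_links = 0L,
                      n_background_regions = 40L)
  sim0 <- simulate_dataset(cfg0)
  calls <- call_methyl_regions(sim0$methyl$signal)
  expect_lte(mean(calls$direction != "ns"), 0.05)
})
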