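#' Simulation configuration
#'
#' Builds and validates the configuration for the synthetic-data generator.
#' The generator emulates a four-library staged small-RNA study (an
#' uninduced control CK and three induction stages I-III, each a single
#' pooled library): duplex-forming siRNA loci with the two-nucleotide 3'
#' overhang geometry, negative-binomial tag counts with planted fold
#' changes, genes whose expression is anti-proportional to their planted
#' siRNAs, and methylation regions hyper- or hypo-methylated in concert
#' with planted 24-nt siRNAs.
#'
#' @param genome_length genome size in bases (single chromosome `chr1`).
#' @param n_genes number of non-overlapping gene models (each with 5' UTR,
#'   CDS, and 3' UTR).
#' @param n_duplex_loci number of planted duplex-forming siRNA loci.
#' @param sirna_length_weights probability weights over tag lengths
#'   20-25 nt (named `"20"` ... `"25"`, summing to 1); the default peaks at
#'   24 nt with 22 nt second, the typical plant class abundances.
#' @param n_24nt_loci minimum number of 24-nt loci among the planted loci;
#'   defaults to whichever is larger of `n_methyl_links` and the expected
#'   count under the length weights.
#' @param baseline_mean expected raw reads per tag per million-read library.
#' @param dispersion negative-binomial overdispersion (`var = mu +
#'   dispersion * mu^2`); 0 gives Poisson counts. The default 0.005 models
#'   single pooled libraries measured technically (near-Poisson with a
#'   small technical excess).
#' @param de_fraction fraction of planted loci given a planted fold change.
#' @param planted_lfc magnitude of the planted log2 fold change.
#' @param n_cleavage_links planted siRNA-to-gene cleavage links (non-24-nt
#'   siRNAs with a perfect sense-strand complementarity site).
#' @param n_methyl_links planted 24-nt siRNA / methylation-region / gene
#'   links (alternating hyper- and hypo-methylation).
#' @param library_sizes clean-read totals for CK, I, II, III.
#' @param noise_sd lognormal scale of per-feature baseline variability
#'   (constant across libraries, so it does not distort stage contrasts).
#' @param near_miss_fraction fraction (of `n_duplex_loci`) of additional
#'   decoy pairs violating the overhang geometry (offset 3 instead of 2).
#' @param n_decoy_tags single-stranded decoy tags with no duplex partner.
#' @param n_decoy_de_genes differentially expressed genes with no siRNA
#'   link (specificity decoys for the target-association chain).
#' @param methyl_baseline_mean expected methylation-region reads per
#'   million-read library.
#' @param methyl_ratio planted stage/CK methylation signal ratio for
#'   hyper-methylated links (inverted for hypo).
#' @param gene_baseline_mean expected gene counts per million-read library.
#' @param utr5_length,cds_length,utr3_length gene model part lengths.
#' @param n_background_regions methylation regions with stationary signal.
#' @param n_terms annotation terms for the enrichment stage (the first
#'   three are pattern-class signature terms).
#' @param seed integer master seed; every generator component draws from
#'   its own sub-stream derived from it.
#' @return a validated `sim_config` list.
#' @export
sim_config <- function(genome_length = 600000L, n_genes = 40L,
                       n_duplex_loci = 60L,
                       sirna_length_weights = c("20" = 0.05, "21" = 0.15,
                                                "22" = 0.25, "23" = 0.05,
                                                "24" = 0.45, "25" = 0.05),
                       n_24nt_loci = NULL,
                       baseline_mean = 50, dispersion = 0.005,
                       de_fraction = 0.5, planted_lfc = 2,
                       n_cleavage_links = 12L, n_methyl_links = 6L,
                       library_sizes = c(CK = 1e6, I = 1e6,
                                         II = 1e6, III = 1e6),
                       noise_sd = 0.1, near_miss_fraction = 0.2,
                       n_decoy_tags = 20L, n_decoy_de_genes = 4L,
                       methyl_baseline_mean = 50, methyl_ratio = 4,
                       gene_baseline_mean = 200,
                       utr5_length = 150L, cds_length = 900L,
                       utr3_length = 300L,
                       n_background_regions = 20L, n_terms = 25L,
                       seed = 1L) {
  cfg <- as.list(environment())
  counts <- c("genome_length", "n_genes", "n_duplex_loci", "n_cleavage_links",
              "n_methyl_links", "n_decoy_tags", "n_decoy_de_genes",
              "n_background_regions", "n_terms", "utr5_length", "cds_length",
              "utr3_length")
  for (f in counts) {
    if (length(cfg[[f]]) != 1 || cfg[[f]] < 0) stop(f, " must be >= 0")
  }
  if (any(library_sizes <= 0)) stop("library_sizes must be positive")
  if (is.null(names(library_sizes))) names(cfg$library_sizes) <- .LIBS
  if (!all(.LIBS %in% names(cfg$library_sizes))) {
    stop("library_sizes must be named CK, I, II, III")
  }
  cfg$library_sizes <- cfg$library_sizes[.LIBS]
  if (planted_lfc <= 0) stop("planted_lfc must be > 0")
  if (de_fraction < 0 || de_fraction > 1) stop("de_fraction must be in [0,1]")
  w <- sirna_length_weights
  if (!setequal(names(w), as.character(20:25)) ||
      abs(sum(w) - 1) > 1e-8 || any(w < 0)) {
    stop("sirna_length_weights must be non-negative, named 20..25, sum to 1")
  }
  cfg$sirna_length_weights <- w[as.character(20:25)]
  if (is.null(n_24nt_loci)) {
    cfg$n_24nt_loci <- max(n_methyl_links,
                           round(w[["24"]] * n_duplex_loci))
  }
  if (cfg$n_24nt_loci > n_duplex_loci) {
    stop("n_24nt_loci cannot exceed n_duplex_loci")
  }
  n_de <- max(n_cleavage_links + n_methyl_links,
              round(de_fraction * n_duplex_loci))
  if (n_de > n_duplex_loci) {
    stop("too many links for n_duplex_loci at the requested de_fraction")
  }
  if (dispersion < 0) stop("dispersion must be >= 0")
  if (methyl_ratio <= 1) stop("methyl_ratio must be > 1")
  structure(cfg, class = "sim_config")
}

.gene_length <- function(config) {
  config$utr5_length + config$cds_length + config$utr3_length
}

#' Generate a synthetic genome with gene models
#'
#' Produces a random nucleotide sequence, `n_genes` non-overlapping gene
#' models (strand, 5' UTR, CDS, 3' UTR), and a set of intervals annotated
#' with the excluded small-RNA classes (rRNA, tRNA, snRNA, snoRNA, miRNA)
#' for subtraction testing. Deterministic for a fixed seed. Coordinates are
#' 0-based half-open.
#'
#' @param config a [sim_config()].
#' @return a `sim_genome` list: `genome` (named character, `chr1`),
#'   `genes` (data frame with genomic part spans), `excluded` (data frame
#'   `chrom`, `start`, `end`, `class`), and the `config`.
#' @export
generate_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  glen <- config$genome_length
  gene_len <- .gene_length(config)
  need <- 10 * config$n_genes * gene_len
  if (config$n_genes > 0 && glen < need) {
    stop("genome too short to place requested features: need at least ",
         need, " bases for ", config$n_genes, " genes, have ", glen,
         " (deficit ", need - glen, ")")
  }
  set.seed(.sub_seed(config$seed, "genome"))
  genome <- paste(sample(c("A", "C", "G", "T"), glen, replace = TRUE),
                  collapse = "")

  genes <- data.frame(gene_id = character(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), stringsAsFactors = FALSE)
  if (config$n_genes > 0) {
    slot <- glen %/% config$n_genes
    pad <- slot - gene_len - 20L
    offs <- sample.int(max(pad, 1L), config$n_genes, replace = TRUE) - 1L
    starts <- (seq_len(config$n_genes) - 1L) * slot + 10L + offs
    strands <- sample(c("+", "-"), config$n_genes, replace = TRUE)
    genes <- data.frame(
      gene_id = sprintf("g%03d", seq_len(config$n_genes)), chrom = "chr1",
      start = starts, end = starts + gene_len, strand = strands,
      stringsAsFactors = FALSE)
    u5 <- config$utr5_length; cd <- config$cds_length
    u3 <- config$utr3_length
    plus <- genes$strand == "+"
    genes$utr5_start <- ifelse(plus, genes$start, genes$end - u5)
    genes$utr5_end <- ifelse(plus, genes$start + u5, genes$end)
    genes$cds_start <- ifelse(plus, genes$start + u5, genes$start + u3)
    genes$cds_end <- ifelse(plus, genes$start + u5 + cd, genes$end - u5)
    genes$utr3_start <- ifelse(plus, genes$end - u3, genes$start)
    genes$utr3_end <- ifelse(plus, genes$end, genes$start + u3)
  }

  n_excl <- max(4L, config$n_genes %/% 5L)
  excluded <- .place_intervals(glen, n_excl, len_range = c(80L, 300L),
                               forbidden = genes[, c("start", "end")],
                               pad = 10L)
  excluded$class <- sample(.EXCLUDED_CLASSES, nrow(excluded), replace = TRUE)
  excluded <- data.frame(chrom = "chr1", excluded, stringsAsFactors = FALSE)

  structure(list(genome = c(chr1 = genome), genes = genes,
                 excluded = excluded, config = config),
            class = "sim_genome")
}

# Sample n non-overlapping [start, end) intervals avoiding `forbidden`.
.place_intervals <- function(glen, n, len_range, forbidden, pad = 5L,
                             max_retries = 500L) {
  starts <- integer(0); ends <- integer(0)
  occ_s <- c(forbidden$start - pad); occ_e <- c(forbidden$end + pad)
  for (i in seq_len(n)) {
    len <- if (len_range[1] == len_range[2]) len_range[1] else
      sample(len_range[1]:len_range[2], 1)
    placed <- FALSE
    for (try in seq_len(max_retries)) {
      s <- sample.int(glen - len - 6L, 1) + 3L
      e <- s + len
      if (!any(s < occ_e & e > occ_s)) {
        starts <- c(starts, s); ends <- c(ends, e)
        occ_s <- c(occ_s, s - pad); occ_e <- c(occ_e, e + pad)
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      stop("placement error: could not place interval ", i, " of ", n,
           " after ", max_retries, " retries")
    }
  }
  data.frame(start = starts, end = ends, stringsAsFactors = FALSE)
}

.shape_directions <- function(shape) {
  switch(shape,
    sustained_up = c(I = "up", II = "up", III = "up"),
    sustained_down = c(I = "down", II = "down", III = "down"),
    transient_down = c(I = "down", II = "ns", III = "ns"),
    c(I = "ns", II = "ns", III = "ns"))
}

# Pattern class of a gene anti-regulated by a siRNA of the given shape:
# class 1 sustained up, class 2 sustained down, class 3 transient up.
.shape_gene_class <- function(shape) {
  switch(shape, sustained_up = 2L, sustained_down = 1L,
         transient_down = 3L, NA_integer_)
}

#' Plant duplex-forming siRNA loci
#'
#' Places `n_duplex_loci` loci in intergenic, non-excluded space and emits
#' for each a plus-strand tag and a minus-strand tag whose perfect-match
#' alignments satisfy the duplex geometry of [call_duplexes()] (minus
#' alignment shifted two bases left of the plus alignment). Also emits
#' near-miss pairs (offset 3, violating the geometry) and single-stranded
#' decoy tags for specificity testing, assigns planted differential
#' expression shapes, and reserves link roles for downstream planting.
#'
#' @param genome_obj a `sim_genome` from [generate_genome()].
#' @param config the same [sim_config()].
#' @return list with `loci` (locus table: spans, lengths, role, shape,
#'   per-stage planted direction) and `tags` (tag table: id, locus,
#'   strand, sequence).
#' @export
plant_duplex_loci <- function(genome_obj, config) {
  stopifnot(inherits(genome_obj, "sim_genome"))
  set.seed(.sub_seed(config$seed, "loci"))
  glen <- config$genome_length
  genome <- genome_obj$genome[["chr1"]]
  n_real <- config$n_duplex_loci
  n_near <- round(config$near_miss_fraction * n_real)
  n_dec <- config$n_decoy_tags
  n_tot <- n_real + n_near + n_dec

  forbidden <- rbind(
    genome_obj$genes[, c("start", "end")],
    genome_obj$excluded[, c("start", "end")])
  iv <- .place_intervals(glen, n_tot, len_range = c(25L, 25L),
                         forbidden = forbidden, pad = 15L)

  lens <- as.integer(sample(20:25, n_tot, replace = TRUE,
                            prob = config$sirna_length_weights))
  n_cl <- config$n_cleavage_links
  n_ml <- config$n_methyl_links
  if (n_cl + n_ml > n_real) stop("more links requested than planted loci")
  # cleavage-linked loci must not be 24 nt (the 24-nt exclusion filter
  # would veto their target genes); methyl-linked loci must be 24 nt
  if (n_cl > 0) {
    idx <- seq_len(n_cl)
    non24 <- c(20:23, 25L)
    w <- config$sirna_length_weights[as.character(non24)]
    if (sum(w) == 0) w <- rep(1, 5)
    lens[idx] <- as.integer(sample(non24, n_cl, replace = TRUE, prob = w))
  }
  if (n_ml > 0) lens[n_cl + seq_len(n_ml)] <- 24L
  # top up forced 24-nt loci among the remaining real loci
  real_idx <- seq_len(n_real)
  short <- config$n_24nt_loci - sum(lens[real_idx] == 24L)
  if (short > 0) {
    cand <- setdiff(which(lens[real_idx] != 24L), seq_len(n_cl))
    lens[utils::head(cand, short)] <- 24L
  }

  n_de <- max(n_cl + n_ml, round(config$de_fraction * n_real))
  roles <- rep("free", n_real)
  if (n_cl > 0) roles[seq_len(n_cl)] <- "cleavage_link"
  if (n_ml > 0) roles[n_cl + seq_len(n_ml)] <- "methyl_link"
  if (n_de > n_cl + n_ml) {
    roles[(n_cl + n_ml + 1):n_de] <- "free_de"
  }
  shapes <- rep("none", n_real)
  base_shapes <- c("sustained_up", "sustained_down", "transient_down")
  if (n_cl > 0) shapes[seq_len(n_cl)] <- rep_len(base_shapes, n_cl)
  if (n_ml > 0) {
    shapes[n_cl + seq_len(n_ml)] <- rep_len(
      c("sustained_up", "sustained_down"), n_ml)
  }
  n_free_de <- sum(roles == "free_de")
  if (n_free_de > 0) {
    shapes[roles == "free_de"] <- sample(base_shapes, n_free_de,
                                         replace = TRUE)
  }

  sub <- function(s, e) substr(genome, s + 1L, e)
  loci <- list(); tag_rows <- list()
  for (i in seq_len(n_real + n_near)) {
    L <- lens[i]
    s <- iv$start[i]
    offset <- if (i <= n_real) 2L else 3L
    type <- if (i <= n_real) "planted" else "near_miss"
    plus_seq <- sub(s, s + L)
    minus_seq <- .revcomp(sub(s - offset, s + L - offset))
    lid <- sprintf("loc%03d", i)
    dirs <- if (i <= n_real) .shape_directions(shapes[i])
            else .shape_directions("none")
    loci[[i]] <- data.frame(
      locus_id = lid, chrom = "chr1",
      start = s - offset, end = s + L, length = L, type = type,
      role = if (i <= n_real) roles[i] else "near_miss",
      shape = if (i <= n_real) shapes[i] else "none",
      plus_start = s, plus_end = s + L,
      minus_start = s - offset, minus_end = s + L - offset,
      de_I = dirs[["I"]], de_II = dirs[["II"]], de_III = dirs[["III"]],
      stringsAsFactors = FALSE)
    tag_rows[[length(tag_rows) + 1]] <- data.frame(
      tag_id = paste0(lid, "_p"), locus_id = lid, strand = "+",
      sequence = plus_seq, stringsAsFactors = FALSE)
    tag_rows[[length(tag_rows) + 1]] <- data.frame(
      tag_id = paste0(lid, "_m"), locus_id = lid, strand = "-",
      sequence = minus_seq, stringsAsFactors = FALSE)
  }
  for (j in seq_len(n_dec)) {
    i <- n_real + n_near + j
    L <- lens[i]
    s <- iv$start[i]
    tag_rows[[length(tag_rows) + 1]] <- data.frame(
      tag_id = sprintf("dec%03d", j), locus_id = NA_character_,
      strand = "+", sequence = sub(s, s + L), stringsAsFactors = FALSE)
  }
  loci <- do.call(rbind, loci)
  tags <- do.call(rbind, tag_rows)
  rownames(loci) <- rownames(tags) <- NULL
  list(loci = loci, tags = tags)
}

#' Plant siRNA-target links and assemble the ground truth
#'
#' Assigns genes to the reserved cleavage-link and methylation-link loci,
#' embeds the exact reverse complement of each linked siRNA into its target
#' transcript (sense-strand site; for half of the methylation links the
#' siRNA sequence itself is additionally embedded, creating a dual-strand
#' target), marks decoy differentially expressed genes with no siRNA link,
#' and records everything -- loci, tags, links, planted pattern classes --
#' in a `ground_truth` object.
#'
#' @param genome_obj a `sim_genome`.
#' @param planted output of [plant_duplex_loci()].
#' @param config the same [sim_config()].
#' @return list with the edited `genome_obj` and the `ground_truth`.
#' @export
plant_target_links <- function(genome_obj, planted, config) {
  set.seed(.sub_seed(config$seed, "links"))
  genes <- genome_obj$genes
  loci <- planted$loci
  tags <- planted$tags
  n_cl <- config$n_cleavage_links
  n_ml <- config$n_methyl_links
  n_dg <- config$n_decoy_de_genes
  if (n_cl + n_ml + n_dg > nrow(genes)) {
    stop("not enough genes for the requested links and decoys")
  }
  genome <- genome_obj$genome[["chr1"]]
  u5 <- config$utr5_length; cd <- config$cds_length
  u3 <- config$utr3_length
  tlen <- u5 + cd + u3

  embed <- function(genome, gene, t0, what) {
    # write `what` at transcript coordinates [t0, t0 + L) of `gene`
    L <- nchar(what)
    if (gene$strand == "+") {
      g0 <- gene$start + t0
      piece <- what
    } else {
      g0 <- gene$end - t0 - L
      piece <- .revcomp(what)
    }
    paste0(substr(genome, 1, g0), piece,
           substr(genome, g0 + L + 1, nchar(genome)))
  }

  cleavage <- list(); methyl <- list(); labels <- list()
  regions <- c("CDS", "5'UTR", "3'UTR")
  for (i in seq_len(n_cl)) {
    locus <- loci[i, ]
    gene <- genes[i, ]
    tag_seq <- tags$sequence[tags$tag_id == paste0(locus$locus_id, "_p")]
    L <- nchar(tag_seq)
    reg <- regions[(i - 1) %% 3 + 1]
    span <- switch(reg,
      "5'UTR" = c(0L, u5), "CDS" = c(u5, u5 + cd),
      "3'UTR" = c(u5 + cd, tlen))
    if (span[2] - span[1] < L + 24L) { reg <- "CDS"; span <- c(u5, u5 + cd) }
    t0 <- span[1] + 12L + sample.int(span[2] - span[1] - L - 23L, 1)
    genome <- embed(genome, gene, t0, .revcomp(tag_seq))
    cleavage[[i]] <- data.frame(
      sirna_tag = paste0(locus$locus_id, "_p"), locus_id = locus$locus_id,
      gene_id = gene$gene_id, site_start = t0, site_end = t0 + L,
      region = reg, stringsAsFactors = FALSE)
    labels[[length(labels) + 1]] <- data.frame(
      gene_id = gene$gene_id, class = .shape_gene_class(locus$shape),
      origin = "cleavage", stringsAsFactors = FALSE)
  }
  for (j in seq_len(n_ml)) {
    locus <- loci[n_cl + j, ]
    gene <- genes[n_cl + j, ]
    tag_seq <- tags$sequence[tags$tag_id == paste0(locus$locus_id, "_p")]
    L <- nchar(tag_seq)
    utr3_span <- c(u5 + cd, tlen)
    t0 <- utr3_span[1] + 4L
    genome <- embed(genome, gene, t0, .revcomp(tag_seq))
    both <- (j %% 2 == 0)
    if (both) {
      t1 <- t0 + L + 12L
      if (t1 + L > tlen) stop("3' UTR too short for a dual-strand site")
      genome <- embed(genome, gene, t1, tag_seq)
    }
    direction <- if (locus$shape == "sustained_up") "hyper" else "hypo"
    methyl[[j]] <- data.frame(
      sirna_tag = paste0(locus$locus_id, "_p"), locus_id = locus$locus_id,
      gene_id = gene$gene_id, region_id = paste0("reg_", gene$gene_id),
      region_start = gene$utr3_start, region_end = gene$utr3_end,
      direction = direction, both_strands = both, stringsAsFactors = FALSE)
    labels[[length(labels) + 1]] <- data.frame(
      gene_id = gene$gene_id, class = .shape_gene_class(locus$shape),
      origin = "methylation", stringsAsFactors = FALSE)
  }
  decoy_genes <- character(0)
  if (n_dg > 0) {
    dg <- genes$gene_id[n_cl + n_ml + seq_len(n_dg)]
    decoy_genes <- dg
    for (d in seq_len(n_dg)) {
      labels[[length(labels) + 1]] <- data.frame(
        gene_id = dg[d], class = (d - 1L) %% 3L + 1L,
        origin = "decoy_de", stringsAsFactors = FALSE)
    }
  }

  genome_obj$genome[["chr1"]] <- genome
  gt <- structure(list(
    loci = loci, tags = tags,
    cleavage_links = if (length(cleavage)) do.call(rbind, cleavage) else
      data.frame(sirna_tag = character(0), locus_id = character(0),
                 gene_id = character(0), site_start = integer(0),
                 site_end = integer(0), region = character(0)),
    methyl_links = if (length(methyl)) do.call(rbind, methyl) else
      data.frame(sirna_tag = character(0), locus_id = character(0),
                 gene_id = character(0), region_id = character(0),
                 region_start = integer(0), region_end = integer(0),
                 direction = character(0), both_strands = logical(0)),
    cluster_labels = if (length(labels)) do.call(rbind, labels) else
      data.frame(gene_id = character(0), class = integer(0),
                 origin = character(0)),
    decoy_de_genes = decoy_genes), class = "ground_truth")
  list(genome_obj = genome_obj, ground_truth = gt)
}

.draw_counts <- function(mu, dispersion) {
  if (dispersion == 0) stats::rpois(length(mu), mu)
  else stats::rnbinom(length(mu), mu = mu, size = 1 / dispersion)
}

# Signed per-stage log2 fold change profile of a locus row.
.locus_lfc <- function(locus, lfc) {
  dirs <- c(locus$de_I, locus$de_II, locus$de_III)
  ifelse(dirs == "up", lfc, ifelse(dirs == "down", -lfc, 0))
}

#' Simulate small-RNA tag counts for the four libraries
#'
#' Draws raw counts for every planted tag from a negative binomial with
#' mean `baseline_mean` (scaled by each library's size and jittered per
#' tag by the lognormal `noise_sd`) and the configured dispersion;
#' planted-DE loci have their stage means multiplied by `2^planted_lfc`
#' (up) or `2^-planted_lfc` (down) in the flagged stages. The configured
#' library sizes are recorded as the clean-read totals in the
#' `library_totals` attribute.
#'
#' @param ground_truth a `ground_truth` (or the list from
#'   [plant_duplex_loci()]).
#' @param config the [sim_config()].
#' @return tag count table: `tag_id`, `sequence`, `length`,
#'   `count_CK` ... `count_III`, with `library_totals` attribute.
#' @export
simulate_srna_libraries <- function(ground_truth, config) {
  set.seed(.sub_seed(config$seed, "srna"))
  tags <- ground_truth$tags
  loci <- ground_truth$loci
  n <- nrow(tags)
  base <- config$baseline_mean * exp(stats::rnorm(n, 0, config$noise_sd))
  lfc_mat <- matrix(0, n, 3, dimnames = list(NULL, .STAGES))
  li <- match(tags$locus_id, loci$locus_id)
  for (k in which(!is.na(li))) {
    lfc_mat[k, ] <- .locus_lfc(loci[li[k], ], config$planted_lfc)
  }
  out <- data.frame(tag_id = tags$tag_id, sequence = tags$sequence,
                    length = nchar(tags$sequence),
                    stringsAsFactors = FALSE)
  for (lib in .LIBS) {
    scale <- config$library_sizes[[lib]] / 1e6
    mult <- if (lib == "CK") rep(1, n) else 2^lfc_mat[, lib]
    out[[paste0("count_", lib)]] <- .draw_counts(base * scale * mult,
                                                 config$dispersion)
  }
  attr(out, "library_totals") <- config$library_sizes
  out
}

#' Simulate gene expression counts
#'
#' Unlinked genes receive stationary counts. Genes linked to a planted
#' siRNA (cleavage or methylation route) receive stage means
#' anti-proportional to the siRNA's planted profile, so the noiseless
#' profile correlation is exactly -1. Decoy-DE genes follow the three
#' pattern classes (sustained up; sustained down; transient up) with no
#' siRNA link.
#'
#' @param genes gene model table from [generate_genome()].
#' @param ground_truth the assembled `ground_truth`.
#' @param config the [sim_config()].
#' @return gene count table with `library_totals` attribute.
#' @export
simulate_gene_expression <- function(genes, ground_truth, config) {
  set.seed(.sub_seed(config$seed, "genes"))
  links <- rbind(
    ground_truth$cleavage_links[, c("locus_id", "gene_id")],
    ground_truth$methyl_links[, c("locus_id", "gene_id")])
  unknown <- setdiff(links$gene_id, genes$gene_id)
  if (length(unknown)) {
    stop("referential-integrity error: link references unknown gene(s): ",
         paste(unknown, collapse = ", "))
  }
  n <- nrow(genes)
  base <- config$gene_baseline_mean * exp(stats::rnorm(n, 0, config$noise_sd))
  lfc_mat <- matrix(0, n, 3, dimnames = list(genes$gene_id, .STAGES))
  loci <- ground_truth$loci
  for (k in seq_len(nrow(links))) {
    locus <- loci[loci$locus_id == links$locus_id[k], ]
    lfc_mat[links$gene_id[k], ] <- -.locus_lfc(locus, config$planted_lfc)
  }
  class_lfc <- rbind(`1` = c(1, 1, 1), `2` = c(-1, -1, -1),
                     `3` = c(1, 0, 0)) * config$planted_lfc
  lab <- ground_truth$cluster_labels
  for (g in ground_truth$decoy_de_genes) {
    cls <- lab$class[lab$gene_id == g][1]
    lfc_mat[g, ] <- class_lfc[as.character(cls), ]
  }
  out <- data.frame(gene_id = genes$gene_id, stringsAsFactors = FALSE)
  for (lib in .LIBS) {
    scale <- config$library_sizes[[lib]] / 1e6
    mult <- if (lib == "CK") rep(1, n) else 2^lfc_mat[, lib]
    out[[paste0("count_", lib)]] <- .draw_counts(base * scale * mult,
                                                 config$dispersion)
  }
  attr(out, "library_totals") <- config$library_sizes
  out
}

#' Simulate methylation region signal
#'
#' Emits one region per methylation-linked gene spanning its 3' UTR, plus
#' background regions over unlinked genes' 3' UTRs. Hyper links have the
#' region signal multiplied by `methyl_ratio` in the stages where the
#' linked siRNA is planted; hypo links are inverted; background regions
#' are stationary. Signal is reported as raw counts with clean-read totals
#' attached (reads-per-million scale downstream).
#'
#' @inheritParams simulate_gene_expression
#' @return list with `regions` (data frame `region_id`, `chrom`, `start`,
#'   `end`, `gene_id`, `role`; 0-based half-open) and `signal` (count
#'   table with `library_totals` attribute).
#' @export
simulate_methylation <- function(genes, ground_truth, config) {
  set.seed(.sub_seed(config$seed, "methyl"))
  ml <- ground_truth$methyl_links
  unknown <- setdiff(ml$gene_id, genes$gene_id)
  if (length(unknown)) {
    stop("referential-integrity error: methyl link to unknown gene(s): ",
         paste(unknown, collapse = ", "))
  }
  linked <- data.frame(region_id = ml$region_id,
                       chrom = rep("chr1", nrow(ml)),
                       start = ml$region_start, end = ml$region_end,
                       gene_id = ml$gene_id,
                       role = rep("3'UTR", nrow(ml)),
                       stringsAsFactors = FALSE)
  for (k in seq_len(nrow(ml))) {
    g <- genes[genes$gene_id == ml$gene_id[k], ]
    if (ml$region_start[k] < g$start || ml$region_end[k] > g$end) {
      stop("placement error: region ", ml$region_id[k],
           " lies outside its gene span")
    }
  }
  free_genes <- setdiff(genes$gene_id, ml$gene_id)
  n_bg <- min(config$n_background_regions, length(free_genes))
  bg_ids <- if (n_bg > 0) sort(sample(free_genes, n_bg)) else character(0)
  bg <- genes[match(bg_ids, genes$gene_id), , drop = FALSE]
  background <- data.frame(
    region_id = paste0("reg_", bg$gene_id), chrom = "chr1",
    start = bg$utr3_start, end = bg$utr3_end, gene_id = bg$gene_id,
    role = "background", stringsAsFactors = FALSE)
  regions <- rbind(linked, background)
  rownames(regions) <- NULL

  n <- nrow(regions)
  base <- config$methyl_baseline_mean *
    exp(stats::rnorm(n, 0, config$noise_sd))
  ratio_mat <- matrix(1, n, 3, dimnames = list(regions$region_id, .STAGES))
  loci <- ground_truth$loci
  for (k in seq_len(nrow(ml))) {
    locus <- loci[loci$locus_id == ml$locus_id[k], ]
    on <- c(locus$de_I, locus$de_II, locus$de_III) != "ns"
    r <- if (ml$direction[k] == "hyper") config$methyl_ratio
         else 1 / config$methyl_ratio
    ratio_mat[ml$region_id[k], on] <- r
  }
  signal <- data.frame(region_id = regions$region_id,
                       stringsAsFactors = FALSE)
  for (lib in .LIBS) {
    scale <- config$library_sizes[[lib]] / 1e6
    mult <- if (lib == "CK") rep(1, n) else ratio_mat[, lib]
    signal[[paste0("count_", lib)]] <- .draw_counts(base * scale * mult,
                                                    config$dispersion)
  }
  attr(signal, "library_totals") <- config$library_sizes
  list(regions = regions, signal = signal)
}

#' Simulate degradome 5'-end evidence for planted cleavage links
#'
#' For each planted cleavage link, produces per-transcript 5'-end position
#' counts with sparse background and a dominant peak at the predicted
#' cleavage position (the transcript base opposite siRNA position 10).
#'
#' @param ground_truth the assembled `ground_truth`.
#' @param transcripts transcript table from [transcripts_from_genes()].
#' @param config the [sim_config()].
#' @return data frame `transcript_id`, `position` (1-based), `count`.
#' @export
simulate_degradome <- function(ground_truth, transcripts, config) {
  set.seed(.sub_seed(config$seed, "degradome"))
  cl <- ground_truth$cleavage_links
  rows <- list()
  for (k in seq_len(nrow(cl))) {
    tlen <- transcripts$length[transcripts$gene_id == cl$gene_id[k]]
    L <- cl$site_end[k] - cl$site_start[k]
    peak <- cl$site_start[k] + L - 9L  # 1-based, opposite siRNA position 10
    bgpos <- sort(sample.int(tlen, 25))
    cnt <- sample(1:3, 25, replace = TRUE)
    cnt[bgpos == peak] <- 0L
    rows[[k]] <- data.frame(
      transcript_id = cl$gene_id[k],
      position = c(bgpos, peak), count = c(cnt, 60L),
      stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(transcript_id = character(0), position = integer(0),
               count = integer(0))
  out <- out[out$count > 0, , drop = FALSE]
  out <- out[order(out$transcript_id, out$position), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Simulate a gene-to-term annotation map
#'
#' Assigns each gene one to three generic functional terms; the first
#' three terms are signature terms preferentially given to genes of the
#' corresponding planted pattern class, so the enrichment stage has real
#' structure to find.
#'
#' @inheritParams simulate_degradome
#' @param genes gene model table.
#' @return data frame `gene_id`, `term_id`, `term_name`.
#' @export
simulate_annotation <- function(genes, ground_truth, config) {
  set.seed(.sub_seed(config$seed, "annotation"))
  n_terms <- max(config$n_terms, 4L)
  term_ids <- sprintf("T%03d", seq_len(n_terms))
  term_names <- c("pattern-class-1 signature", "pattern-class-2 signature",
                  "pattern-class-3 signature",
                  paste("generic function", seq_len(n_terms - 3)))
  lab <- ground_truth$cluster_labels
  rows <- list()
  for (i in seq_len(nrow(genes))) {
    g <- genes$gene_id[i]
    cls <- lab$class[lab$gene_id == g]
    picks <- character(0)
    for (c3 in 1:3) {
      p <- if (length(cls) && cls[1] == c3) 0.9 else 0.03
      if (stats::runif(1) < p) picks <- c(picks, term_ids[c3])
    }
    k <- sample(1:3, 1)
    picks <- unique(c(picks, sample(term_ids[-(1:3)], k)))
    rows[[i]] <- data.frame(gene_id = g, term_id = picks,
                            term_name = term_names[match(picks, term_ids)],
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Generate a complete synthetic dataset with planted ground truth
#'
#' Runs the full generator: genome and gene models, duplex loci with
#' decoys and near-misses, planted target links (with complementarity
#' sites embedded in the genome), small-RNA libraries, gene expression,
#' methylation regions, degradome evidence, and an annotation map. Every
#' component draws from its own seed sub-stream, so outputs are
#' byte-identical for identical configurations.
#'
#' @param config a [sim_config()].
#' @return list with `genome` (`sim_genome`, post-editing),
#'   `ground_truth`, `srna_tags`, `gene_counts`, `methyl`
#'   (`$regions`, `$signal`), `degradome`, `annotation`, `transcripts`,
#'   and the `config`.
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  g <- generate_genome(config)
  planted <- plant_duplex_loci(g, config)
  lk <- plant_target_links(g, planted, config)
  gt <- lk$ground_truth
  genome_obj <- lk$genome_obj
  srna <- simulate_srna_libraries(gt, config)
  gene_counts <- simulate_gene_expression(genome_obj$genes, gt, config)
  methyl <- simulate_methylation(genome_obj$genes, gt, config)
  transcripts <- transcripts_from_genes(genome_obj)
  degradome <- simulate_degradome(gt, transcripts, config)
  annotation <- simulate_annotation(genome_obj$genes, gt, config)
  list(genome = genome_obj, ground_truth = gt, srna_tags = srna,
       gene_counts = gene_counts, methyl = methyl, degradome = degradome,
       annotation = annotation, transcripts = transcripts, config = config)
}
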