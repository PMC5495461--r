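# Standard-format I/O (FASTA / GFF3 / BED / TSV) with exact coordinate
# conversion, and the end-to-end pipeline orchestrator.

.read_fasta <- function(path, format = "fasta") {
  x <- tryCatch(
    Biostrings::readDNAStringSet(path, format = format),
    error = function(e) {
      stop("failed to parse ", format, " file '", path, "': ",
           conditionMessage(e), call. = FALSE)
    })
  if (any(Biostrings::width(x) == 0)) {
    bad <- which(Biostrings::width(x) == 0)[1]
    stop("failed to parse ", format, " file '", path, "': record ", bad,
         " ('", names(x)[bad], "') is truncated (empty sequence)",
         call. = FALSE)
  }
  names(x) <- sub("\\s.*$", "", names(x))
  x
}

#' Write / read genomic intervals as GFF3
#'
#' Interval tables use 0-based half-open coordinates internally; GFF3 is
#' 1-based inclusive. The conversion is inverted exactly on read, so
#' write-then-read is an identity map on coordinates.
#'
#' @param intervals data frame `chrom`, `start`, `end`, `name`, and
#'   optionally `strand` and `type`.
#' @param path output file.
#' @param source GFF3 source column.
#' @return `intervals_to_gff3` returns `path` invisibly;
#'   `gff3_to_intervals` returns the interval data frame.
#' @export
intervals_to_gff3 <- function(intervals, path, source = "sirnaflow") {
  strand <- if ("strand" %in% names(intervals)) intervals$strand else "*"
  type <- if ("type" %in% names(intervals)) intervals$type else "region"
  gr <- GenomicRanges::GRanges(
    intervals$chrom,
    IRanges::IRanges(intervals$start + 1L, intervals$end),
    strand = strand)
  gr$source <- source
  gr$type <- type
  gr$ID <- intervals$name
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' @rdname intervals_to_gff3
#' @export
gff3_to_intervals <- function(path) {
  gr <- tryCatch(rtracklayer::import(path, format = "gff3"),
                 error = function(e) {
                   stop("failed to parse GFF3 file '", path, "': ",
                        conditionMessage(e), call. = FALSE)
                 })
  data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = BiocGenerics::start(gr) - 1L,
    end = BiocGenerics::end(gr),
    name = if (!is.null(gr$ID)) as.character(gr$ID) else NA_character_,
    strand = as.character(BiocGenerics::strand(gr)),
    type = if (!is.null(gr$type)) as.character(gr$type) else "region",
    stringsAsFactors = FALSE)
}

#' Write / read genomic intervals as BED
#'
#' BED is natively 0-based half-open, matching the internal convention;
#' round trips are exact.
#'
#' @inheritParams intervals_to_gff3
#' @return `intervals_to_bed` returns `path` invisibly;
#'   `bed_to_intervals` returns the interval data frame.
#' @export
intervals_to_bed <- function(intervals, path) {
  strand <- if ("strand" %in% names(intervals)) intervals$strand else "*"
  gr <- GenomicRanges::GRanges(
    intervals$chrom,
    IRanges::IRanges(intervals$start + 1L, intervals$end),
    strand = strand)
  gr$name <- intervals$name
  if ("score" %in% names(intervals)) gr$score <- intervals$score
  rtracklayer::export(gr, path, format = "bed")
  invisible(path)
}

#' @rdname intervals_to_gff3
#' @export
bed_to_intervals <- function(path) {
  gr <- tryCatch(rtracklayer::import(path, format = "bed"),
                 error = function(e) {
                   stop("failed to parse BED file '", path, "': ",
                        conditionMessage(e), call. = FALSE)
                 })
  data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = BiocGenerics::start(gr) - 1L,
    end = BiocGenerics::end(gr),
    name = if (!is.null(gr$name)) as.character(gr$name) else NA_character_,
    score = if (!is.null(gr$score)) as.numeric(gr$score) else NA_real_,
    strand = as.character(BiocGenerics::strand(gr)),
    stringsAsFactors = FALSE)
}

#' Write gene models as GFF3
#'
#' Each gene is written as a `gene` feature plus `five_prime_UTR`, `CDS`,
#' and `three_prime_UTR` parts with `Parent` attributes.
#'
#' @param genes gene model table (as produced by [generate_genome()]).
#' @param path output file.
#' @export
write_gene_models <- function(genes, path) {
  rows <- list()
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    rows[[length(rows) + 1]] <- data.frame(
      chrom = g$chrom,
      start = c(g$start, g$utr5_start, g$cds_start, g$utr3_start),
      end = c(g$end, g$utr5_end, g$cds_end, g$utr3_end),
      name = c(g$gene_id, paste0(g$gene_id, c(".utr5", ".cds", ".utr3"))),
      strand = g$strand,
      type = c("gene", "five_prime_UTR", "CDS", "three_prime_UTR"),
      parent = c(NA_character_, rep(g$gene_id, 3)),
      stringsAsFactors = FALSE)
  }
  iv <- do.call(rbind, rows)
  gr <- GenomicRanges::GRanges(
    iv$chrom, IRanges::IRanges(iv$start + 1L, iv$end), strand = iv$strand)
  gr$source <- "sirnaflow"
  gr$type <- iv$type
  gr$ID <- iv$name
  gr$Parent <- ifelse(is.na(iv$parent), "", iv$parent)
  gr$phase <- ifelse(iv$type == "CDS", 0L, NA_integer_)
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read gene models from GFF3
#'
#' Inverse of [write_gene_models()]; returns the internal 0-based
#' half-open gene model table.
#'
#' @param path GFF3 file.
#' @export
read_gene_models <- function(path) {
  iv <- gff3_to_intervals(path)
  genes <- iv[iv$type == "gene", , drop = FALSE]
  part <- function(gene_id, suffix) {
    r <- iv[iv$name == paste0(gene_id, suffix), , drop = FALSE]
    if (nrow(r) != 1) stop("gene ", gene_id, " lacks part ", suffix,
                           " in ", path)
    r
  }
  out <- lapply(seq_len(nrow(genes)), function(i) {
    g <- genes[i, ]
    u5 <- part(g$name, ".utr5"); cd <- part(g$name, ".cds")
    u3 <- part(g$name, ".utr3")
    data.frame(gene_id = g$name, chrom = g$chrom, start = g$start,
               end = g$end, strand = g$strand,
               utr5_start = u5$start, utr5_end = u5$end,
               cds_start = cd$start, cds_end = cd$end,
               utr3_start = u3$start, utr3_end = u3$end,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Write a synthetic dataset to disk
#'
#' Serializes every component of a [simulate_dataset()] result in the
#' standard plain-text formats: genome FASTA; gene models and excluded
#' classes as GFF3 (1-based inclusive); tag, gene, methylation-signal,
#' degradome, and annotation tables as TSV; methylation regions as BED
#' (0-based half-open); ground truth as a documented TSV set; library
#' totals and the configuration as JSON. All output is deterministic.
#'
#' @param sim result of [simulate_dataset()].
#' @param outdir output directory (created if needed).
#' @return named character vector of written paths, invisibly.
#' @export
write_dataset <- function(sim, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(outdir, ...)
  paths <- c(genome = p("genome.fa"), genes = p("genes.gff3"),
             excluded = p("excluded.gff3"), tags = p("srna_tags.tsv"),
             gene_counts = p("gene_counts.tsv"),
             methyl_regions = p("methyl_regions.bed"),
             methyl_signal = p("methyl_signal.tsv"),
             degradome = p("degradome.tsv"),
             annotation = p("annotation.tsv"),
             library_totals = p("library_totals.json"),
             config = p("sim_config.json"),
             gt_loci = p("truth_loci.tsv"), gt_tags = p("truth_tags.tsv"),
             gt_cleavage = p("truth_cleavage_links.tsv"),
             gt_methyl = p("truth_methyl_links.tsv"),
             gt_labels = p("truth_cluster_labels.tsv"))
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(sim$genome$genome), paths[["genome"]])
  write_gene_models(sim$genome$genes, paths[["genes"]])
  ex <- sim$genome$excluded
  intervals_to_gff3(
    data.frame(chrom = ex$chrom, start = ex$start, end = ex$end,
               name = sprintf("excl%03d", seq_len(nrow(ex))),
               type = ex$class, stringsAsFactors = FALSE),
    paths[["excluded"]])
  .write_tsv(sim$srna_tags, paths[["tags"]])
  .write_tsv(sim$gene_counts, paths[["gene_counts"]])
  reg <- sim$methyl$regions
  intervals_to_bed(
    data.frame(chrom = reg$chrom, start = reg$start, end = reg$end,
               name = reg$region_id, stringsAsFactors = FALSE),
    paths[["methyl_regions"]])
  .write_tsv(sim$methyl$signal, paths[["methyl_signal"]])
  .write_tsv(sim$degradome, paths[["degradome"]])
  .write_tsv(sim$annotation, paths[["annotation"]])
  jsonlite::write_json(as.list(attr(sim$srna_tags, "library_totals")),
                       paths[["library_totals"]], auto_unbox = TRUE,
                       digits = NA)
  cfg <- unclass(sim$config)
  cfg$library_sizes <- as.list(cfg$library_sizes)
  cfg$sirna_length_weights <- as.list(cfg$sirna_length_weights)
  jsonlite::write_json(cfg, paths[["config"]], auto_unbox = TRUE,
                       digits = NA)
  gt <- sim$ground_truth
  .write_tsv(gt$loci, paths[["gt_loci"]])
  .write_tsv(gt$tags, paths[["gt_tags"]])
  .write_tsv(gt$cleavage_links, paths[["gt_cleavage"]])
  .write_tsv(gt$methyl_links, paths[["gt_methyl"]])
  .write_tsv(gt$cluster_labels, paths[["gt_labels"]])
  invisible(paths)
}

#' Pipeline configuration
#'
#' Bundles input locations (or a simulation block), every stage threshold
#' (defaulting to the staged small-RNA study conventions), and the seed.
#'
#' @param outdir output directory for stage tables and the manifest.
#' @param simulate optional [sim_config()]; when given, inputs are
#'   generated and written under `outdir/sim` and used directly.
#' @param genome_fasta,gene_models_gff3,excluded_gff3 input paths
#'   (ignored when `simulate` is set).
#' @param srna_tags_tsv pre-collapsed tag table
#'   (`tag_id`/`sequence`/`count_*`).
#' @param gene_counts_tsv gene count table.
#' @param methyl_regions_bed,methyl_signal_tsv methylation region spans
#'   and per-library signal counts; both `NULL` skips the methylation
#'   route.
#' @param degradome_tsv optional degradome 5'-end counts.
#' @param annotation_tsv optional gene-to-term map; `NULL` skips
#'   enrichment.
#' @param library_totals named clean-read totals for CK, I, II, III
#'   (required with file inputs; taken from the simulation otherwise).
#' @param min_len,max_len tag length bounds.
#' @param min_support duplex support threshold (strict `>`).
#' @param require_overlap,min_overlap duplex overlap requirement.
#' @param sirna_p,sirna_lfc siRNA DE thresholds (raw p, `|log2fc| >=`).
#' @param gene_q,gene_lfc gene DE thresholds (BH q, `|log2fc| >`).
#' @param corr_thresh profile-correlation ceiling.
#' @param max_penalty complementarity penalty cutoff.
#' @param methyl_q,methyl_signal,methyl_ratio methylation screen.
#' @param k,restarts clustering parameters.
#' @param enrich_p enrichment raw-p flag threshold.
#' @param pseudocount RPM pseudocount.
#' @param exclude_24nt 24-nt veto set for the cleavage route
#'   (`"de"` or `"all"`).
#' @param seed integer seed.
#' @param resume reuse stage outputs already present in `outdir`.
#' @return a validated `pipeline_config` list.
#' @export
pipeline_config <- function(outdir, simulate = NULL,
                            genome_fasta = NULL, gene_models_gff3 = NULL,
                            excluded_gff3 = NULL, srna_tags_tsv = NULL,
                            gene_counts_tsv = NULL,
                            methyl_regions_bed = NULL,
                            methyl_signal_tsv = NULL, degradome_tsv = NULL,
                            annotation_tsv = NULL, library_totals = NULL,
                            min_len = 18L, max_len = 30L, min_support = 5,
                            require_overlap = TRUE, min_overlap = 15L,
                            sirna_p = 0.01, sirna_lfc = 1,
                            gene_q = 0.001, gene_lfc = 1,
                            corr_thresh = -0.4, max_penalty = 4,
                            methyl_q = 0.05, methyl_signal = 0.25,
                            methyl_ratio = 2, k = 3L, restarts = 50L,
                            enrich_p = 0.05, pseudocount = 0.5,
                            exclude_24nt = "de", seed = 1L,
                            resume = FALSE) {
  cfg <- as.list(environment())
  if (is.null(simulate)) {
    needed <- c("genome_fasta", "gene_models_gff3", "srna_tags_tsv",
                "gene_counts_tsv")
    miss <- needed[vapply(cfg[needed], is.null, logical(1))]
    if (length(miss)) {
      stop("without a simulation block these inputs are required: ",
           paste(miss, collapse = ", "))
    }
    for (f in c("genome_fasta", "gene_models_gff3", "excluded_gff3",
                "srna_tags_tsv", "gene_counts_tsv", "methyl_regions_bed",
                "methyl_signal_tsv", "degradome_tsv", "annotation_tsv")) {
      if (!is.null(cfg[[f]]) && !file.exists(cfg[[f]])) {
        stop("input file not found: ", cfg[[f]])
      }
    }
    if (is.null(library_totals)) {
      stop("library_totals are required with file inputs")
    }
  } else {
    stopifnot(inherits(simulate, "sim_config"))
  }
  stopifnot(sirna_p > 0, sirna_p <= 1, gene_q > 0, gene_q <= 1,
            methyl_q > 0, methyl_q <= 1, corr_thresh >= -1,
            corr_thresh <= 1, max_penalty >= 0, min_support >= 0,
            methyl_ratio > 1, k >= 1, restarts >= 1)
  structure(cfg, class = "pipeline_config")
}

.md5 <- function(paths) {
  v <- tools::md5sum(paths)
  names(v) <- basename(names(v))
  as.list(v)
}

#' Run the full analysis pipeline
#'
#' Executes catalog building, duplex calling, siRNA and gene differential
#' expression, cleavage-route and methylation-route target association,
#' degradome validation, pattern clustering, and term enrichment, in
#' order, writing one TSV per stage plus a JSON run manifest with record
#' counts, file checksums, and wall times. Stages whose inputs are absent
#' (methylation, degradome, annotation) are skipped with a logged notice.
#' With `resume = TRUE`, stages whose output files already exist are read
#' back instead of recomputed.
#'
#' @param config a [pipeline_config()].
#' @return invisibly, a list with the manifest and every stage table.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  outdir <- config$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(tool = "sirnaflow",
                   version = as.character(utils::packageVersion("sirnaflow")),
                   seed = config$seed, stages = list())
  t_all <- proc.time()[["elapsed"]]

  stage <- function(name, file, compute, reader = .read_tsv,
                    writer = .write_tsv) {
    path <- file.path(outdir, file)
    t0 <- proc.time()[["elapsed"]]
    if (isTRUE(config$resume) && file.exists(path)) {
      val <- reader(path)
      resumed <- TRUE
    } else {
      val <- compute()
      writer(val, path)
      resumed <- FALSE
    }
    manifest$stages[[name]] <<- list(
      file = file, n_records = nrow(val), resumed = resumed,
      seconds = round(proc.time()[["elapsed"]] - t0, 3))
    val
  }

  # ---- inputs -------------------------------------------------------
  if (!is.null(config$simulate)) {
    sim <- simulate_dataset(config$simulate)
    simdir <- file.path(outdir, "sim")
    write_dataset(sim, simdir)
    genome <- Biostrings::DNAStringSet(sim$genome$genome)
    genes <- sim$genome$genes
    excluded <- sim$genome$excluded
    raw_tags <- sim$srna_tags
    gene_counts <- sim$gene_counts
    methyl_regions <- sim$methyl$regions
    methyl_signal <- sim$methyl$signal
    degradome <- sim$degradome
    annotation <- sim$annotation
    totals <- .get_totals(sim$srna_tags)
  } else {
    genome <- .read_fasta(config$genome_fasta)
    genes <- read_gene_models(config$gene_models_gff3)
    excluded <- if (is.null(config$excluded_gff3)) {
      data.frame(chrom = character(0), start = integer(0),
                 end = integer(0), class = character(0))
    } else {
      iv <- gff3_to_intervals(config$excluded_gff3)
      data.frame(chrom = iv$chrom, start = iv$start, end = iv$end,
                 class = iv$type, stringsAsFactors = FALSE)
    }
    raw_tags <- .read_tsv(config$srna_tags_tsv)
    gene_counts <- .read_tsv(config$gene_counts_tsv)
    methyl_regions <- NULL; methyl_signal <- NULL
    if (!is.null(config$methyl_regions_bed) &&
        !is.null(config$methyl_signal_tsv)) {
      iv <- bed_to_intervals(config$methyl_regions_bed)
      methyl_regions <- data.frame(region_id = iv$name, chrom = iv$chrom,
                                   start = iv$start, end = iv$end,
                                   stringsAsFactors = FALSE)
      methyl_signal <- .read_tsv(config$methyl_signal_tsv)
    }
    degradome <- if (is.null(config$degradome_tsv)) NULL else
      .read_tsv(config$degradome_tsv)
    annotation <- if (is.null(config$annotation_tsv)) NULL else
      .read_tsv(config$annotation_tsv)
    totals <- .get_totals(NULL, config$library_totals)
  }

  # ---- catalog ------------------------------------------------------
  tags <- stage("catalog", "catalog.tsv", function() {
    collapse_and_filter_reads(raw_tags, config$min_len, config$max_len)
  })
  alignments <- stage("alignments", "alignments.tsv", function() {
    aln <- map_tags(tags, genome)
    subtract_annotated_classes(aln, excluded)
  })
  tags <- tags[tags$tag_id %in% alignments$tag_id, , drop = FALSE]
  duplexes <- stage("duplexes", "duplexes.tsv", function() {
    call_duplexes(alignments, tags, min_support = config$min_support,
                  require_overlap = config$require_overlap,
                  min_overlap = config$min_overlap)
  })

  # ---- differential expression -------------------------------------
  duplex_tags <- unique(c(duplexes$plus_tag, duplexes$minus_tag))
  sirna_tab <- tags[tags$tag_id %in% duplex_tags, , drop = FALSE]
  names(sirna_tab)[names(sirna_tab) == "tag_id"] <- "feature_id"
  sirna_de <- stage("sirna_de", "sirna_de.tsv", function() {
    call_de(sirna_tab, totals, mode = "sirna",
            p_thresh = config$sirna_p, lfc_thresh = config$sirna_lfc,
            pseudocount = config$pseudocount)
  })
  gc2 <- gene_counts
  names(gc2)[names(gc2) == "gene_id"] <- "feature_id"
  gene_de <- stage("gene_de", "gene_de.tsv", function() {
    call_de(gc2, totals, mode = "gene", q_thresh = config$gene_q,
            lfc_thresh = config$gene_lfc,
            pseudocount = config$pseudocount)
  })

  # ---- target association ------------------------------------------
  transcripts <- transcripts_from_genes(genome, genes)
  sirna_lengths <- stats::setNames(sirna_tab$length, sirna_tab$feature_id)
  de_ids <- .de_features(sirna_de)
  scan_ids <- union(de_ids,
                    sirna_tab$feature_id[sirna_tab$length == 24L])
  scan_tab <- data.frame(tag_id = scan_ids,
                         sequence = sirna_tab$sequence[
                           match(scan_ids, sirna_tab$feature_id)],
                         stringsAsFactors = FALSE)
  sites <- stage("target_sites", "target_sites.tsv", function() {
    find_target_sites(scan_tab, transcripts,
                      max_penalty = config$max_penalty,
                      strands = c("sense", "antisense"))
  })
  profiles <- list(
    sirna = .log_rpm_profiles(sirna_tab, totals, config$pseudocount),
    gene = .log_rpm_profiles(gene_counts, totals, config$pseudocount))

  cleavage <- stage("cleavage_targets", "cleavage_targets.tsv", function() {
    select_cleavage_targets(sirna_de, sites, gene_de, profiles,
                            sirna_lengths, corr_thresh = config$corr_thresh,
                            exclude_24nt = config$exclude_24nt)
  })

  methyl_calls <- NULL; methyl_targets <- .empty_interactions()
  if (!is.null(methyl_signal)) {
    methyl_calls <- stage("methyl_calls", "methyl_calls.tsv", function() {
      call_methyl_regions(methyl_signal, totals,
                          q_thresh = config$methyl_q,
                          min_signal = config$methyl_signal,
                          min_ratio = config$methyl_ratio)
    })
    gene_gr <- GenomicRanges::GRanges(
      genes$chrom, IRanges::IRanges(genes$start + 1L, genes$end))
    reg_gr <- GenomicRanges::GRanges(
      methyl_regions$chrom,
      IRanges::IRanges(methyl_regions$start + 1L, methyl_regions$end))
    ov <- GenomicRanges::findOverlaps(reg_gr, gene_gr)
    region_gene_map <- data.frame(
      region_id = methyl_regions$region_id[S4Vectors::queryHits(ov)],
      gene_id = genes$gene_id[S4Vectors::subjectHits(ov)],
      stringsAsFactors = FALSE)
    profiles$methyl <- .log_rpm_profiles(methyl_signal, totals,
                                         config$pseudocount)
    methyl_targets <- stage("methylation_targets",
                            "methylation_targets.tsv", function() {
      select_methylation_targets(sirna_de, sites, methyl_calls, gene_de,
                                 profiles, sirna_lengths, region_gene_map,
                                 corr_thresh = config$corr_thresh)
    })
  } else {
    message("methylation inputs absent; methylation stages skipped")
  }
  interactions <- rbind(cleavage, methyl_targets)

  degradome_validation <- NULL
  if (!is.null(degradome) && nrow(cleavage) > 0) {
    degradome_validation <- stage("degradome_validation",
                                  "degradome_validation.tsv", function() {
      cl_sites <- merge(cleavage[, c("sirna_id", "gene_id")], sites,
                        by = c("sirna_id", "gene_id"))
      cl_sites <- cl_sites[cl_sites$strand_targeted == "sense", ,
                           drop = FALSE]
      validate_cleavage_with_degradome(cl_sites, degradome)
    })
  }

  # ---- clustering and enrichment -----------------------------------
  clusters <- NULL; enrichment <- NULL
  target_genes <- unique(interactions$gene_id)
  if (length(target_genes) >= config$k) {
    feat <- do.call(rbind, lapply(target_genes, function(g) {
      lfc <- gene_de$log2fc[gene_de$feature_id == g]
      data.frame(gene_id = g, lfc_I = lfc[1], lfc_II = lfc[2],
                 lfc_III = lfc[3], stringsAsFactors = FALSE)
    }))
    km <- kmeans_profiles(feat, k = config$k, seed = config$seed,
                          restarts = config$restarts)
    clusters <- stage("clusters", "clusters.tsv", function() {
      merge(km$assignments, feat, by = "gene_id")
    })
    if (!is.null(annotation)) {
      enrichment <- stage("enrichment", "enrichment.tsv", function() {
        background <- unique(gene_counts$gene_id)
        out <- lapply(sort(unique(clusters$cluster)), function(cl) {
          res <- hypergeometric_enrichment(
            clusters$gene_id[clusters$cluster == cl], background,
            annotation, p_thresh = config$enrich_p)
          if (nrow(res)) cbind(cluster = cl, res) else NULL
        })
        out <- do.call(rbind, out)
        if (is.null(out)) data.frame(cluster = integer(0)) else out
      })
    } else {
      message("annotation map absent; enrichment skipped")
    }
  } else {
    message("fewer target genes than k; clustering skipped")
  }

  # ---- manifest -----------------------------------------------------
  files <- list.files(outdir, pattern = "\\.tsv$", full.names = TRUE)
  manifest$checksums <- .md5(files)
  manifest$counts <- list(
    tags_kept = nrow(tags), duplexes = nrow(duplexes),
    de_sirnas_per_stage = as.list(table(
      factor(sirna_de$comparison[sirna_de$direction != "ns"],
             levels = .STAGES))),
    de_sirnas_total = length(.de_features(sirna_de)),
    de_genes_total = length(.de_features(gene_de)),
    cleavage_targets = nrow(cleavage),
    methylation_targets = nrow(methyl_targets),
    dual_strand_genes = length(unique(
      methyl_targets$gene_id[methyl_targets$both_strands %in% TRUE])),
    target_genes_total = length(target_genes),
    clusters = if (is.null(clusters)) 0L else
      length(unique(clusters$cluster)),
    enriched_terms = if (is.null(enrichment) || !nrow(enrichment)) 0L else
      sum(enrichment$enriched))
  manifest$total_seconds <- round(proc.time()[["elapsed"]] - t_all, 3)
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(manifest = manifest, tags = tags,
                 alignments = alignments, duplexes = duplexes,
                 sirna_de = sirna_de, gene_de = gene_de, sites = sites,
                 cleavage = cleavage, methyl_calls = methyl_calls,
                 methylation = methyl_targets,
                 degradome_validation = degradome_validation,
                 clusters = clusters, enrichment = enrichment))
}
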