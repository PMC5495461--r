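#' Extract transcript sequences from gene models
#'
#' Builds the spliced (here single-exon) transcript sequence for every gene
#' -- the genomic span on the gene strand, reverse-complemented for minus
#' strand genes -- together with the 5' UTR / CDS / 3' UTR part lengths in
#' transcript coordinates.
#'
#' @param genome_obj a `sim_genome`, or a genome acceptable to
#'   [map_tags()] when `genes` is supplied.
#' @param genes gene model table (defaults to `genome_obj$genes`).
#' @return data frame `gene_id`, `sequence`, `length`, `utr5_len`,
#'   `cds_len`, `utr3_len`.
#' @export
transcripts_from_genes <- function(genome_obj, genes = NULL) {
  if (inherits(genome_obj, "sim_genome")) {
    genome <- Biostrings::DNAStringSet(genome_obj$genome)
    if (is.null(genes)) genes <- genome_obj$genes
  } else {
    genome <- .as_genome(genome_obj)
    if (is.null(genes)) stop("supply `genes` with a plain genome")
  }
  if (nrow(genes) == 0) {
    return(data.frame(gene_id = character(0), sequence = character(0),
                      length = integer(0), utr5_len = integer(0),
                      cds_len = integer(0), utr3_len = integer(0)))
  }
  seqs <- character(nrow(genes))
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    s <- as.character(Biostrings::subseq(genome[[g$chrom]],
                                         g$start + 1L, g$end))
    seqs[i] <- if (g$strand == "-") .revcomp(s) else s
  }
  data.frame(gene_id = genes$gene_id, sequence = seqs,
             length = nchar(seqs),
             utr5_len = genes$utr5_end - genes$utr5_start,
             cds_len = genes$cds_end - genes$cds_start,
             utr3_len = genes$utr3_end - genes$utr3_start,
             stringsAsFactors = FALSE)
}

#' Score siRNA-transcript complementarity
#'
#' Slides the reverse complement of the siRNA along the transcript
#' (ungapped) and scores each window with a position-weighted penalty:
#' mismatch 1.0, G:U wobble 0.5 (siRNA G opposite target U, or siRNA U
#' opposite target G), both doubled over siRNA positions 2-13 counted from
#' the siRNA 5' end (the seed-proximal core whose pairing licenses
#' slicing). Windows with penalty at or below `max_penalty` are reported,
#' each with the predicted cleavage site between the transcript bases
#' opposite siRNA positions 10 and 11.
#'
#' @param sirna_sequence siRNA sequence, 5' to 3' (U accepted, mapped to T).
#' @param transcript_sequence transcript sequence, 5' to 3'.
#' @param max_penalty report windows with penalty `<= max_penalty`.
#' @return data frame `site_start`, `site_end` (transcript coordinates,
#'   0-based half-open), `penalty`, `cleavage_5p`, `cleavage_3p` (the
#'   1-based transcript positions flanking the predicted cut). A siRNA
#'   longer than the transcript yields an empty result.
#' @export
score_complementarity <- function(sirna_sequence, transcript_sequence,
                                  max_penalty = 4) {
  s <- .clean_seqs(sirna_sequence)
  tr <- .clean_seqs(transcript_sequence)
  if (is.na(s) || is.na(tr)) stop("sequences must be over A/C/G/T/U")
  L <- nchar(s); Tn <- nchar(tr)
  empty <- data.frame(site_start = integer(0), site_end = integer(0),
                      penalty = numeric(0), cleavage_5p = integer(0),
                      cleavage_3p = integer(0))
  if (L > Tn) {
    message("siRNA longer than transcript; no windows scored")
    return(empty)
  }
  bases <- c("A", "C", "G", "T")
  sc <- match(strsplit(s, "")[[1]], bases)
  tc <- match(strsplit(tr, "")[[1]], bases)
  cost <- matrix(1, 4, 4, dimnames = list(bases, bases))
  cost[cbind(1:4, 4:1)] <- 0            # Watson-Crick: A:T C:G G:C T:A
  cost["G", "T"] <- 0.5                  # siRNA G opposite target U
  cost["T", "G"] <- 0.5                  # siRNA U opposite target G
  w <- ifelse(seq_len(L) >= 2 & seq_len(L) <= 13, 2, 1)
  nw <- Tn - L + 1L
  pen <- numeric(nw)
  for (i in seq_len(L)) {
    # siRNA position i (from its 5' end) pairs transcript position
    # w0 + L - i + 1 (1-based) in the window starting at 0-based w0
    idx <- seq_len(nw) + (L - i)
    pen <- pen + w[i] * cost[sc[i], ][tc[idx]]
  }
  keep <- which(pen <= max_penalty)
  data.frame(site_start = keep - 1L, site_end = keep - 1L + L,
             penalty = pen[keep],
             cleavage_5p = keep + L - 11L, cleavage_3p = keep + L - 10L,
             row.names = NULL)
}

#' Find complementarity sites of siRNAs on transcripts
#'
#' Applies [score_complementarity()] to every (siRNA, transcript) pair on
#' the requested strands. Sense sites are scored on the transcript itself;
#' antisense sites on its reverse complement, with coordinates mapped back
#' to sense transcript space. Each site is annotated with the transcript
#' region (5'UTR / CDS / 3'UTR) containing its predicted cleavage position.
#'
#' @param sirnas data frame with `tag_id` and `sequence`.
#' @param transcripts table from [transcripts_from_genes()].
#' @param max_penalty penalty cutoff.
#' @param strands subset of `c("sense", "antisense")`.
#' @return data frame `sirna_id`, `gene_id`, `strand_targeted`,
#'   `site_start`, `site_end` (sense transcript coordinates, 0-based
#'   half-open), `penalty`, `cleavage_5p`, `cleavage_3p`, `region`.
#' @export
find_target_sites <- function(sirnas, transcripts, max_penalty = 4,
                              strands = c("sense", "antisense")) {
  strands <- match.arg(strands, several.ok = TRUE)
  rows <- list()
  for (ti in seq_len(nrow(transcripts))) {
    tr <- transcripts[ti, ]
    u5 <- tr$utr5_len; cd <- tr$cds_len
    region_of <- function(pos) {
      ifelse(pos <= u5, "5'UTR", ifelse(pos <= u5 + cd, "CDS", "3'UTR"))
    }
    anti <- if ("antisense" %in% strands) .revcomp(tr$sequence) else NULL
    for (si in seq_len(nrow(sirnas))) {
      if ("sense" %in% strands) {
        hit <- score_complementarity(sirnas$sequence[si], tr$sequence,
                                     max_penalty)
        if (nrow(hit)) {
          rows[[length(rows) + 1]] <- data.frame(
            sirna_id = sirnas$tag_id[si], gene_id = tr$gene_id,
            strand_targeted = "sense", hit[, 1:2], penalty = hit$penalty,
            cleavage_5p = hit$cleavage_5p, cleavage_3p = hit$cleavage_3p,
            region = region_of(hit$cleavage_3p), stringsAsFactors = FALSE)
        }
      }
      if (!is.null(anti)) {
        hit <- score_complementarity(sirnas$sequence[si], anti, max_penalty)
        if (nrow(hit)) {
          # map antisense coordinates back to sense transcript space
          ss <- tr$length - hit$site_end
          cp <- tr$length - hit$cleavage_3p + 1L
          rows[[length(rows) + 1]] <- data.frame(
            sirna_id = sirnas$tag_id[si], gene_id = tr$gene_id,
            strand_targeted = "antisense",
            site_start = ss, site_end = ss + (hit$site_end - hit$site_start),
            penalty = hit$penalty,
            cleavage_5p = cp, cleavage_3p = cp + 1L,
            region = region_of(cp), stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(sirna_id = character(0), gene_id = character(0),
                      strand_targeted = character(0), site_start = integer(0),
                      site_end = integer(0), penalty = numeric(0),
                      cleavage_5p = integer(0), cleavage_3p = integer(0),
                      region = character(0)))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

.de_features <- function(de) {
  unique(de$feature_id[de$direction != "ns"])
}

.de_direction <- function(de, id, stage) {
  d <- de$direction[de$feature_id == id & de$comparison == stage]
  if (length(d)) d[1] else "ns"
}

#' Select cleavage-mode target interactions
#'
#' Applies the sense-strand targeting filter chain: keeps (siRNA, gene)
#' pairs where (a) the siRNA is differentially expressed in at least one
#' stage, (b) it has a sense-strand complementarity site on the gene's
#' transcript, (c) no 24-nt siRNA has a sense-strand site on that gene
#' (the heterochromatic-class exclusion; by default only differentially
#' expressed 24-nt siRNAs veto, `exclude_24nt = "all"` widens this to the
#' whole catalog), (d) the gene is differentially expressed, and (e) the
#' siRNA-gene expression profile correlation is below `corr_thresh`.
#'
#' @param sirna_de siRNA DE table from [call_de()] (mode `"sirna"`).
#' @param target_sites site table from [find_target_sites()] covering at
#'   least the DE siRNAs and all 24-nt siRNAs used for the exclusion.
#' @param gene_de gene DE table from [call_de()] (mode `"gene"`).
#' @param profiles list with elements `sirna` and `gene`: matrices of
#'   `log2(RPM + pseudocount)` with libraries in columns and feature ids
#'   as rownames.
#' @param sirna_lengths named integer vector: tag id to tag length.
#' @param corr_thresh correlation ceiling (default -0.4).
#' @param exclude_24nt `"de"` or `"all"`; which 24-nt siRNA set vetoes.
#' @return data frame of interactions: `sirna_id`, `gene_id`,
#'   `mode = "cleavage"`, best site coordinates and penalty, `region`,
#'   `corr_sirna_gene`, `corr_methyl_gene` (NA), `stages_supported`
#'   (comma-joined stages where the pair is DE in opposite directions),
#'   `methyl_direction = "na"`, `both_strands` (NA).
#' @export
select_cleavage_targets <- function(sirna_de, target_sites, gene_de,
                                    profiles, sirna_lengths,
                                    corr_thresh = -0.4,
                                    exclude_24nt = c("de", "all")) {
  exclude_24nt <- match.arg(exclude_24nt)
  unknown <- setdiff(target_sites$gene_id, rownames(profiles$gene))
  if (length(unknown)) {
    stop("referential-integrity error: site references unknown gene(s): ",
         paste(unique(unknown), collapse = ", "))
  }
  de_sirnas <- .de_features(sirna_de)
  de_genes <- .de_features(gene_de)
  sense <- target_sites[target_sites$strand_targeted == "sense", ,
                        drop = FALSE]
  tags24 <- names(sirna_lengths)[sirna_lengths == 24L]
  if (exclude_24nt == "de") tags24 <- intersect(tags24, de_sirnas)
  blocked_genes <- unique(sense$gene_id[sense$sirna_id %in% tags24])

  cand <- sense[sense$sirna_id %in% de_sirnas &
                  sense$gene_id %in% de_genes &
                  !(sense$gene_id %in% blocked_genes), , drop = FALSE]
  if (nrow(cand) == 0) return(.empty_interactions())
  cand <- cand[order(cand$penalty, cand$site_start), , drop = FALSE]
  pairs <- !duplicated(cand[, c("sirna_id", "gene_id")])
  cand <- cand[pairs, , drop = FALSE]

  keep <- logical(nrow(cand)); corr <- numeric(nrow(cand))
  stages <- character(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    r <- profile_correlation(profiles$sirna[cand$sirna_id[i], ],
                             profiles$gene[cand$gene_id[i], ])
    corr[i] <- r
    keep[i] <- !is.na(r) && r < corr_thresh
    supp <- vapply(.STAGES, function(st) {
      ds <- .de_direction(sirna_de, cand$sirna_id[i], st)
      dg <- .de_direction(gene_de, cand$gene_id[i], st)
      ds != "ns" && dg != "ns" && ds != dg
    }, logical(1))
    stages[i] <- paste(.STAGES[supp], collapse = ",")
  }
  out <- data.frame(
    sirna_id = cand$sirna_id, gene_id = cand$gene_id, mode = "cleavage",
    site_start = cand$site_start, site_end = cand$site_end,
    region = cand$region, penalty = cand$penalty,
    corr_sirna_gene = corr, corr_methyl_gene = NA_real_,
    stages_supported = stages, methyl_direction = "na",
    both_strands = NA, stringsAsFactors = FALSE)[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

.empty_interactions <- function() {
  data.frame(sirna_id = character(0), gene_id = character(0),
             mode = character(0), site_start = integer(0),
             site_end = integer(0), region = character(0),
             penalty = numeric(0), corr_sirna_gene = numeric(0),
             corr_methyl_gene = numeric(0), stages_supported = character(0),
             methyl_direction = character(0), both_strands = logical(0),
             stringsAsFactors = FALSE)
}

#' Call differentially methylated regions
#'
#' Per region and stage, computes the exact tag-count p-value on the raw
#' region counts, adjusts across regions within each stage
#' (Benjamini-Hochberg), and applies the three-part screen: adjusted
#' `q < q_thresh`, signal above `min_signal` reads per million in at least
#' one library, and a direction-agnostic stage/CK ratio above `min_ratio`
#' (a small RPM floor avoids division by zero). Direction is `hyper` when
#' the stage signal exceeds CK, `hypo` otherwise, `ns` when any criterion
#' fails; a region with zero signal everywhere is `ns`, not an error.
#'
#' @param region_signal data frame `region_id` plus `count_CK` ...
#'   `count_III`.
#' @param library_totals named clean-read totals (or a `library_totals`
#'   attribute on `region_signal`).
#' @param q_thresh,min_signal,min_ratio the three screen thresholds.
#' @param rpm_floor floor applied to RPM values before forming the ratio.
#' @return data frame `region_id`, `comparison`, `x`, `y`, `rpm_ck`,
#'   `rpm_stage`, `p`, `q`, `ratio`, `direction`.
#' @export
call_methyl_regions <- function(region_signal, library_totals = NULL,
                                q_thresh = 0.05, min_signal = 0.25,
                                min_ratio = 2, rpm_floor = 0.01) {
  totals <- .get_totals(region_signal, library_totals)
  m <- .count_matrix(region_signal)
  ids <- as.character(region_signal$region_id)
  rpm <- normalize_rpm(m, totals)
  any_signal <- apply(rpm, 1, max) > min_signal
  out <- lapply(.STAGES, function(st) {
    x <- m[, "CK"]; y <- m[, st]
    p <- ac_pvalue(x, y, totals[["CK"]], totals[[st]])
    q <- bh_adjust(p)
    rc <- pmax(rpm[, "CK"], rpm_floor)
    rs <- pmax(rpm[, st], rpm_floor)
    ratio <- pmax(rs / rc, rc / rs)
    called <- q < q_thresh & any_signal & ratio > min_ratio
    dir <- ifelse(called, ifelse(rpm[, st] > rpm[, "CK"], "hyper", "hypo"),
                  "ns")
    data.frame(region_id = ids, comparison = st, x = x, y = y,
               rpm_ck = rpm[, "CK"], rpm_stage = rpm[, st], p = p, q = q,
               ratio = ratio, direction = dir, stringsAsFactors = FALSE,
               row.names = NULL)
  })
  do.call(rbind, out)
}

#' Select methylation-mode target interactions
#'
#' Links 24-nt differentially expressed siRNAs to genes through
#' RNA-directed DNA methylation: keeps (siRNA, gene) pairs where the siRNA
#' has a complementarity site on either strand of the gene, the gene
#' carries a methylation region whose call is concordant with the siRNA
#' and gene directions in at least one stage -- (siRNA up, region hyper,
#' gene down) or (siRNA down, region hypo, gene up) -- and both the
#' gene-methylation and gene-siRNA profile correlations fall below
#' `corr_thresh`. Genes targeted on both strands are flagged.
#'
#' @param sirna_de siRNA DE table ([call_de()], mode `"sirna"`).
#' @param target_sites sites from [find_target_sites()] scanned on both
#'   strands.
#' @param methyl_calls output of [call_methyl_regions()].
#' @param gene_de gene DE table ([call_de()], mode `"gene"`).
#' @param profiles list with `sirna`, `gene`, and `methyl`
#'   log2-RPM matrices (rownames: tag, gene, region ids).
#' @param sirna_lengths named tag lengths; only 24-nt tags are eligible.
#' @param region_gene_map data frame `region_id`, `gene_id`.
#' @param corr_thresh correlation ceiling (default -0.4).
#' @return interaction data frame as in [select_cleavage_targets()], with
#'   `mode = "methylation"`, `corr_methyl_gene`, `methyl_direction`, and
#'   `both_strands` filled.
#' @export
select_methylation_targets <- function(sirna_de, target_sites, methyl_calls,
                                       gene_de, profiles, sirna_lengths,
                                       region_gene_map, corr_thresh = -0.4) {
  de_sirnas <- .de_features(sirna_de)
  eligible <- intersect(de_sirnas,
                        names(sirna_lengths)[sirna_lengths == 24L])
  sites <- target_sites[target_sites$sirna_id %in% eligible, , drop = FALSE]
  if (nrow(sites) == 0) return(.empty_interactions())
  de_genes <- .de_features(gene_de)

  pair_key <- unique(sites[, c("sirna_id", "gene_id")])
  rows <- list()
  for (i in seq_len(nrow(pair_key))) {
    sid <- pair_key$sirna_id[i]; gid <- pair_key$gene_id[i]
    if (!(gid %in% de_genes)) next
    regs <- region_gene_map$region_id[region_gene_map$gene_id == gid]
    regs <- intersect(regs, rownames(profiles$methyl))
    if (!length(regs)) next
    gsites <- sites[sites$sirna_id == sid & sites$gene_id == gid, ,
                    drop = FALSE]
    both <- all(c("sense", "antisense") %in% gsites$strand_targeted)
    for (reg in regs) {
      supp <- character(0); mdir <- character(0)
      for (st in .STAGES) {
        ds <- .de_direction(sirna_de, sid, st)
        dg <- .de_direction(gene_de, gid, st)
        dm <- methyl_calls$direction[methyl_calls$region_id == reg &
                                       methyl_calls$comparison == st]
        dm <- if (length(dm)) dm[1] else "ns"
        ok <- (ds == "up" && dm == "hyper" && dg == "down") ||
              (ds == "down" && dm == "hypo" && dg == "up")
        if (ok) { supp <- c(supp, st); mdir <- c(mdir, dm) }
      }
      if (!length(supp)) next
      r_sg <- profile_correlation(profiles$sirna[sid, ],
                                  profiles$gene[gid, ])
      r_mg <- profile_correlation(profiles$methyl[reg, ],
                                  profiles$gene[gid, ])
      if (is.na(r_sg) || is.na(r_mg) ||
          r_sg >= corr_thresh || r_mg >= corr_thresh) next
      best <- gsites[which.min(gsites$penalty), ]
      rows[[length(rows) + 1]] <- data.frame(
        sirna_id = sid, gene_id = gid, mode = "methylation",
        site_start = best$site_start, site_end = best$site_end,
        region = best$region, penalty = best$penalty,
        corr_sirna_gene = r_sg, corr_methyl_gene = r_mg,
        stages_supported = paste(supp, collapse = ","),
        methyl_direction = mdir[1], both_strands = both,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) return(.empty_interactions())
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Validate predicted cleavage sites against degradome evidence
#'
#' A site is confirmed when the degradome 5'-end signal at the predicted
#' cleavage position (the transcript base opposite siRNA position 10) is
#' non-zero and strictly exceeds every other 5'-end count within
#' `window` nucleotides. Transcripts without degradome coverage are
#' unconfirmed, not errors.
#'
#' @param sites data frame with `sirna_id`, `gene_id`, and `cleavage_3p`
#'   (1-based predicted position), e.g. rows of [find_target_sites()]
#'   output or of the interaction table.
#' @param degradome data frame `transcript_id`, `position` (1-based),
#'   `count`.
#' @param window half-width of the comparison window in nucleotides.
#' @return data frame `sirna_id`, `gene_id`, `predicted_position`,
#'   `peak_position`, `peak_count`, `confirmed`.
#' @export
validate_cleavage_with_degradome <- function(sites, degradome,
                                             window = 20L) {
  n <- nrow(sites)
  out <- data.frame(sirna_id = sites$sirna_id, gene_id = sites$gene_id,
                    predicted_position = sites$cleavage_3p,
                    peak_position = NA_integer_, peak_count = NA_real_,
                    confirmed = FALSE, stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    pred <- sites$cleavage_3p[i]
    dg <- degradome[degradome$transcript_id == sites$gene_id[i], ,
                    drop = FALSE]
    if (nrow(dg) == 0) next
    win <- dg[abs(dg$position - pred) <= window, , drop = FALSE]
    if (nrow(win) == 0) next
    pk <- which.max(win$count)
    out$peak_position[i] <- win$position[pk]
    out$peak_count[i] <- win$count[pk]
    at_pred <- win$count[win$position == pred]
    at_pred <- if (length(at_pred)) at_pred[1] else 0
    others <- win$count[win$position != pred]
    out$confirmed[i] <- at_pred > 0 &&
      (length(others) == 0 || at_pred > max(others))
  }
  out
}
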