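#' Collapse small-RNA reads into a tag catalog
#'
#' Collapses identical read sequences into distinct tags with per-library
#' raw counts, maps U to T, removes tags outside the accepted length range
#' (default 18-30 nt), and rejects records containing non-nucleotide
#' characters (the number rejected per library is reported via `message`).
#' Inputs are assumed to be clean reads (adapter/quality trimming upstream).
#'
#' @param reads either (a) a named list over libraries `CK`, `I`, `II`,
#'   `III`, each element a character vector of read sequences, a
#'   `DNAStringSet`, or a path to a FASTA/FASTQ file; or (b) a
#'   pre-collapsed tag table (data frame with `sequence` and
#'   `count_CK` ... `count_III` columns), which is re-filtered.
#' @param min_len,max_len inclusive tag length bounds.
#' @return data frame with `tag_id`, `sequence`, `length`, and
#'   `count_CK`, `count_I`, `count_II`, `count_III`, ordered by decreasing
#'   total count (ties by sequence) with deterministic tag ids.
#' @export
collapse_and_filter_reads <- function(reads, min_len = 18L, max_len = 30L) {
  cc <- .count_cols()
  if (is.data.frame(reads)) {
    if (!all(c("sequence", cc) %in% names(reads))) {
      stop("tag table must have columns sequence, ", paste(cc, collapse = ", "))
    }
    seqs <- .clean_seqs(reads$sequence)
    ok <- !is.na(seqs)
    if (any(!ok)) message(sum(!ok), " tag records rejected (non-nucleotide)")
    tab <- data.frame(sequence = seqs[ok], reads[ok, cc, drop = FALSE],
                      stringsAsFactors = FALSE)
  } else {
    if (is.null(names(reads)) || !all(names(reads) %in% .LIBS)) {
      stop("reads must be a named list over libraries ",
           paste(.LIBS, collapse = ", "))
    }
    per_lib <- lapply(.LIBS, function(lib) {
      v <- reads[[lib]]
      if (is.null(v)) return(character(0))
      if (length(v) == 1 && is.character(v) && file.exists(v)) {
        fmt <- if (grepl("\\.f(ast)?q(\\.gz)?$", v)) "fastq" else "fasta"
        v <- as.character(.read_fasta(v, format = fmt))
      }
      v <- as.character(v)
      cl <- .clean_seqs(v)
      bad <- sum(is.na(cl) & nzchar(v))
      if (bad > 0) message(bad, " reads rejected in ", lib,
                           " (non-nucleotide characters)")
      cl[!is.na(cl)]
    })
    names(per_lib) <- .LIBS
    all_seq <- sort(unique(unlist(per_lib)))
    if (length(all_seq) == 0) {
      tab <- data.frame(sequence = character(0))
      for (col in cc) tab[[col]] <- integer(0)
    } else {
      tab <- data.frame(sequence = all_seq, stringsAsFactors = FALSE)
      for (i in seq_along(.LIBS)) {
        cnt <- table(factor(per_lib[[i]], levels = all_seq))
        tab[[cc[i]]] <- as.integer(cnt)
      }
    }
  }
  # collapse duplicates (possible in a supplied tag table)
  if (anyDuplicated(tab$sequence)) {
    agg <- stats::aggregate(tab[, cc, drop = FALSE],
                            by = list(sequence = tab$sequence), FUN = sum)
    tab <- agg
  }
  len <- nchar(tab$sequence)
  tab <- tab[len >= min_len & len <= max_len, , drop = FALSE]
  tot <- rowSums(tab[, cc, drop = FALSE])
  ord <- order(-tot, tab$sequence)
  tab <- tab[ord, , drop = FALSE]
  out <- data.frame(tag_id = sprintf("tag%05d", seq_len(nrow(tab))),
                    sequence = tab$sequence, length = nchar(tab$sequence),
                    stringsAsFactors = FALSE, row.names = NULL)
  for (col in cc) out[[col]] <- as.integer(tab[[col]])
  out
}

.clean_seqs <- function(x) {
  x <- chartr("U", "T", toupper(x))
  x[!grepl("^[ACGT]+$", x)] <- NA_character_
  x
}

.as_genome <- function(genome) {
  if (is.character(genome)) {
    if (length(genome) == 1 && file.exists(genome) &&
        grepl("\\.f(ast)?a$", genome)) {
      genome <- .read_fasta(genome)
    } else {
      if (is.null(names(genome))) names(genome) <- paste0("chr", seq_along(genome))
      genome <- Biostrings::DNAStringSet(genome)
    }
  }
  if (!methods::is(genome, "DNAStringSet")) {
    stop("genome must be a DNAStringSet, named character vector, or FASTA path")
  }
  genome
}

#' Map tags to a genome by exact matching
#'
#' Reports every perfect-match occurrence of each tag on both genome
#' strands. Coordinates are 0-based half-open in genome (plus-strand)
#' space; a minus-strand alignment means the tag equals the reverse
#' complement of the genome subsequence. Tags with no hits are dropped
#' (their ids are available in the `unmapped` attribute); multi-hit tags
#' yield one row per occurrence with the tag's total hit count recorded.
#'
#' @param tags tag table from [collapse_and_filter_reads()] (needs
#'   `tag_id` and `sequence`).
#' @param genome `DNAStringSet`, named character vector of chromosome
#'   sequences, or a FASTA path.
#' @return data frame `tag_id`, `chrom`, `start`, `end`, `strand`,
#'   `hit_count`, sorted by (`chrom`, `start`, `strand`).
#' @export
map_tags <- function(tags, genome) {
  genome <- .as_genome(genome)
  chroms <- names(genome)
  rows <- vector("list", nrow(tags))
  for (i in seq_len(nrow(tags))) {
    sq <- tags$sequence[i]
    hits <- list()
    for (strand in c("+", "-")) {
      pat <- if (strand == "+") sq else .revcomp(sq)
      mi <- Biostrings::vmatchPattern(pat, genome)
      for (ci in seq_along(chroms)) {
        ir <- mi[[ci]]
        if (length(ir) == 0) next
        hits[[length(hits) + 1]] <- data.frame(
          tag_id = tags$tag_id[i], chrom = chroms[ci],
          start = BiocGenerics::start(ir) - 1L, end = BiocGenerics::end(ir),
          strand = strand, stringsAsFactors = FALSE)
      }
    }
    if (length(hits)) rows[[i]] <- do.call(rbind, hits)
  }
  aln <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  unmapped <- setdiff(tags$tag_id, if (is.null(aln)) character(0) else aln$tag_id)
  if (length(unmapped)) {
    message(length(unmapped), " tags had no perfect match and were dropped")
  }
  if (is.null(aln)) {
    aln <- data.frame(tag_id = character(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), hit_count = integer(0),
                      stringsAsFactors = FALSE)
  } else {
    hc <- table(aln$tag_id)
    aln$hit_count <- as.integer(hc[aln$tag_id])
    aln <- aln[order(aln$chrom, aln$start, aln$strand, aln$tag_id), ,
               drop = FALSE]
    rownames(aln) <- NULL
  }
  attr(aln, "unmapped") <- unmapped
  aln
}

#' Remove tags overlapping excluded annotation classes
#'
#' Any alignment overlapping (by at least one base) an interval annotated
#' as rRNA, tRNA, snRNA, snoRNA, or miRNA removes the whole tag -- all of
#' its alignments -- from the catalog.
#'
#' @param alignments alignment table from [map_tags()].
#' @param annotation data frame `chrom`, `start`, `end` (0-based
#'   half-open), `class`; or a `GRanges` with a `class` metadata column.
#' @return filtered alignment table; removed tag ids in the
#'   `removed_tags` attribute.
#' @export
subtract_annotated_classes <- function(alignments, annotation) {
  if (methods::is(annotation, "GRanges")) {
    annotation <- data.frame(
      chrom = as.character(GenomicRanges::seqnames(annotation)),
      start = BiocGenerics::start(annotation) - 1L,
      end = BiocGenerics::end(annotation),
      class = annotation$class, stringsAsFactors = FALSE)
  }
  if (nrow(annotation) == 0 || nrow(alignments) == 0) {
    attr(alignments, "removed_tags") <- character(0)
    return(alignments)
  }
  bad <- setdiff(unique(annotation$class), .EXCLUDED_CLASSES)
  if (length(bad)) {
    stop("unknown annotation class(es): ", paste(bad, collapse = ", "))
  }
  gr_a <- GenomicRanges::GRanges(
    alignments$chrom,
    IRanges::IRanges(alignments$start + 1L, alignments$end))
  gr_x <- GenomicRanges::GRanges(
    annotation$chrom,
    IRanges::IRanges(annotation$start + 1L, annotation$end))
  ov <- GenomicRanges::findOverlaps(gr_a, gr_x, minoverlap = 1L)
  drop_tags <- unique(alignments$tag_id[S4Vectors::queryHits(ov)])
  keep <- !(alignments$tag_id %in% drop_tags)
  out <- alignments[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "removed_tags") <- drop_tags
  out
}

#' Call siRNA duplexes from opposite-strand alignments
#'
#' Reports every (plus, minus) alignment pair on the same chromosome with
#' the canonical Dicer duplex geometry -- two-nucleotide 3' overhangs on
#' both ends, which for perfect-match co-located alignments in 0-based
#' half-open coordinates is exactly
#' `plus$start - minus$start == 2` and `plus$end - minus$end == 2` --
#' where the larger per-library raw count of either tag exceeds
#' `min_support` (strict: more than `min_support` reads in at least one
#' library). Pairs are deduplicated by the alignment pair; a tag may
#' participate in several duplexes. Optionally requires a minimum paired
#' overlap to exclude degenerate short pairings.
#'
#' @param alignments alignment table from [map_tags()] (after class
#'   subtraction).
#' @param tags tag table with per-library counts.
#' @param min_support support threshold; a duplex needs
#'   `max(count) > min_support` over both tags and all libraries.
#' @param require_overlap if `TRUE`, drop pairs overlapping fewer than
#'   `min_overlap` bases.
#' @param min_overlap minimum paired overlap in nucleotides.
#' @return data frame with `duplex_id`, `chrom`, `locus_start`,
#'   `locus_end` (merged span), plus/minus tag ids and spans, `overlap`,
#'   and `support`, sorted by (`chrom`, `locus_start`).
#' @export
call_duplexes <- function(alignments, tags, min_support = 5,
                          require_overlap = TRUE, min_overlap = 15L) {
  empty <- data.frame(duplex_id = character(0), chrom = character(0),
                      locus_start = integer(0), locus_end = integer(0),
                      plus_tag = character(0), plus_start = integer(0),
                      plus_end = integer(0), minus_tag = character(0),
                      minus_start = integer(0), minus_end = integer(0),
                      overlap = integer(0), support = numeric(0),
                      stringsAsFactors = FALSE)
  plus <- alignments[alignments$strand == "+", , drop = FALSE]
  minus <- alignments[alignments$strand == "-", , drop = FALSE]
  if (nrow(plus) == 0 || nrow(minus) == 0) return(empty)

  key_p <- paste(plus$chrom, plus$start - 2L, plus$end - 2L)
  key_m <- paste(minus$chrom, minus$start, minus$end)
  idx <- split(seq_len(nrow(minus)), key_m)
  hit <- match(key_p, names(idx))
  pair_p <- integer(0); pair_m <- integer(0)
  for (i in which(!is.na(hit))) {
    ms <- idx[[hit[i]]]
    pair_p <- c(pair_p, rep(i, length(ms)))
    pair_m <- c(pair_m, ms)
  }
  if (length(pair_p) == 0) return(empty)

  d <- data.frame(
    chrom = plus$chrom[pair_p],
    plus_tag = plus$tag_id[pair_p],
    plus_start = plus$start[pair_p], plus_end = plus$end[pair_p],
    minus_tag = minus$tag_id[pair_m],
    minus_start = minus$start[pair_m], minus_end = minus$end[pair_m],
    stringsAsFactors = FALSE)
  d$overlap <- pmin(d$plus_end, d$minus_end) - pmax(d$plus_start, d$minus_start)
  if (require_overlap) d <- d[d$overlap >= min_overlap, , drop = FALSE]
  if (nrow(d) == 0) return(empty)

  cm <- .count_matrix(tags)
  rownames(cm) <- tags$tag_id
  d$support <- pmax(apply(cm[d$plus_tag, , drop = FALSE], 1, max),
                    apply(cm[d$minus_tag, , drop = FALSE], 1, max))
  d <- d[d$support > min_support, , drop = FALSE]
  if (nrow(d) == 0) return(empty)

  d$locus_start <- pmin(d$plus_start, d$minus_start)
  d$locus_end <- pmax(d$plus_end, d$minus_end)
  d <- d[!duplicated(d[, c("chrom", "plus_start", "plus_end", "plus_tag",
                           "minus_start", "minus_end", "minus_tag")]), ,
         drop = FALSE]
  d <- d[order(d$chrom, d$locus_start, d$plus_tag, d$minus_tag), , drop = FALSE]
  rownames(d) <- NULL
  d$duplex_id <- sprintf("dpx%05d", seq_len(nrow(d)))
  d[, c("duplex_id", "chrom", "locus_start", "locus_end",
        "plus_tag", "plus_start", "plus_end",
        "minus_tag", "minus_start", "minus_end", "overlap", "support")]
}
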