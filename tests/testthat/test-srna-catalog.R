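test_that("read collapsing counts per library and filters by length", {
  s20 <- paste(rep("ACGT", 5), collapse = "")
  reads <- list(CK = c(s20, s20, s20, "ACGTACGTACGTACGT"),  # 16-nt decoy
                I = s20, II = character(0), III = character(0))
  tags <- collapse_and_filter_reads(reads)
  expect_equal(nrow(tags), 1)  # the 16-nt read is removed
  expect_equal(tags$sequence, s20)
  expect_equal(unlist(tags[1, lib_cols], use.names = FALSE), c(3, 1, 0, 0))
  # U is mapped to T; non-nucleotide reads are rejected with a message
  u <- chartr("T", "U", s20)
  expect_message(
    tags2 <- collapse_and_filter_reads(list(CK = c(u, "ACGTNCGTACGTACGTACGTA"),
                                            I = NULL, II = NULL, III = NULL)),
    "rejected")
  expect_equal(tags2$sequence, s20)
  # empty input gives an empty catalog
  empty <- collapse_and_filter_reads(list(CK = character(0), I = NULL,
                                          II = NULL, III = NULL))
  expect_equal(nrow(empty), 0)
})

test_that("exact mapping reports every occurrence on both strands", {
  set.seed(5)
  g <- paste(sample(c("A", "C", "G", "T"), 2000, replace = TRUE),
             collapse = "")
  fwd <- substr(g, 101, 121)          # spans [100, 121)
  rcm <- substr(g, 99, 119)           # [98, 119) on the minus strand
  tags <- data.frame(
    tag_id = c("t1", "t2", "t3"),
    sequence = c(
      fwd,
      as.character(Biostrings::reverseComplement(Biostrings::DNAString(rcm))),
      paste(rep("A", 21), collapse = "")),
    stringsAsFactors = FALSE)
  expect_message(aln <- map_tags(tags, c(chr1 = g)), "no perfect match")
  t1 <- aln[aln$tag_id == "t1", ]
  expect_equal(unlist(t1[, c("start", "end")], use.names = FALSE),
               c(100L, 121L))
  expect_equal(t1$strand, "+")
  t2 <- aln[aln$tag_id == "t2", ]
  expect_equal(unlist(t2[, c("start", "end")], use.names = FALSE),
               c(98L, 119L))
  expect_equal(t2$strand, "-")
  expect_false("t3" %in% aln$tag_id)
  # a duplicated motif yields one alignment per occurrence
  g2 <- paste0(g, substr(g, 101, 121))
  aln2 <- suppressMessages(map_tags(tags[1, ], c(chr1 = g2)))
  expect_equal(nrow(aln2), 2)
  expect_true(all(aln2$hit_count == 2))
})

test_that("mapped spans reproduce the tag sequence after strand handling", {
  fx <- make_catalog_fixture(loci_only_config(seed = 9))
  tags <- collapse_and_filter_reads(fx$tags)
  genome <- fx$genome$genome[["chr1"]]
  aln <- map_tags(tags, c(chr1 = genome))
  expect_gt(nrow(aln), 0)
  seq_of <- setNames(tags$sequence, tags$tag_id)
  for (i in seq_len(nrow(aln))) {
    sub <- substr(genome, aln$start[i] + 1, aln$end[i])
    if (aln$strand[i] == "-") {
      sub <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(sub)))
    }
    expect_identical(sub, unname(seq_of[aln$tag_id[i]]))
  }
})

test_that("class subtraction removes whole tags on any overlap", {
  aln <- data.frame(
    tag_id = c("t1", "t1", "t2"), chrom = "chr1",
    start = c(100L, 500L, 300L), end = c(121L, 521L, 321L),
    strand = "+", hit_count = c(2L, 2L, 1L), stringsAsFactors = FALSE)
  # one-base overlap with an rRNA interval removes t1 everywhere
  ann <- data.frame(chrom = "chr1", start = 120L, end = 200L,
                    class = "rRNA", stringsAsFactors = FALSE)
  out <- subtract_annotated_classes(aln, ann)
  expect_equal(unique(out$tag_id), "t2")
  expect_equal(attr(out, "removed_tags"), "t1")
  # adjacent (non-overlapping) interval removes nothing
  ann2 <- data.frame(chrom = "chr1", start = 121L, end = 200L,
                     class = "tRNA", stringsAsFactors = FALSE)
  expect_equal(nrow(subtract_annotated_classes(aln, ann2)), 3)
  # empty annotation leaves the catalog unchanged
  empty <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), class = character(0))
  expect_equal(nrow(subtract_annotated_classes(aln, empty)), 3)
  expect_error(
    subtract_annotated_classes(aln, transform(ann, class = "lncRNA")),
    "unknown annotation class")
})

test_that("subtraction is monotone: more intervals never grow the catalog", {
  fx <- make_catalog_fixture(loci_only_config(seed = 21))
  tags <- collapse_and_filter_reads(fx$tags)
  aln <- map_tags(tags, fx$genome$genome)
  set.seed(77)
  sizes <- integer(5)
  ann <- data.frame(chrom = character(0), start = integer(0),
                    end = integer(0), class = character(0))
  for (i in 1:5) {
    s <- sample.int(49000, 3)
    ann <- rbind(ann, data.frame(chrom = "chr1", start = s, end = s + 500L,
                                 class = "miRNA"))
    sizes[i] <- length(unique(subtract_annotated_classes(aln, ann)$tag_id))
  }
  expect_true(all(diff(sizes) <= 0))
})

test_that("duplex calling implements geometry and strict support", {
  g <- make_catalog_fixture(loci_only_config(seed = 2))$genome$genome
  gs <- g[["chr1"]]
  plus_seq <- substr(gs, 101, 121)
  minus_seq <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(substr(gs, 99, 119))))
  far_minus <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(substr(gs, 98, 118))))   # overhang 3
  mk <- function(counts_p, counts_m) {
    tags <- data.frame(tag_id = c("p", "m", "f"),
                       sequence = c(plus_seq, minus_seq, far_minus),
                       length = 21L, stringsAsFactors = FALSE)
    tags[lib_cols] <- 0L
    tags[1, lib_cols] <- counts_p
    tags[2, lib_cols] <- counts_m
    tags[3, lib_cols] <- counts_p
    tags
  }
  tags <- mk(c(7L, 0L, 0L, 0L), c(1L, 0L, 0L, 0L))
  aln <- map_tags(tags, g)
  d <- call_duplexes(aln, tags)
  d <- d[d$plus_tag == "p" & d$minus_tag == "m", ]
  expect_equal(nrow(d), 1)
  expect_equal(d$plus_start, 100L)
  expect_equal(d$minus_start, 98L)
  expect_equal(d$locus_start, 98L)
  expect_equal(d$locus_end, 121L)
  expect_equal(d$support, 7)
  # the overhang-3 pair is never called
  expect_false(any(call_duplexes(aln, tags)$minus_tag == "f"))
  # "more than 5 reads" is strict: a maximum of exactly 5 fails
  tags5 <- mk(c(5L, 5L, 5L, 5L), c(5L, 5L, 5L, 5L))
  aln5 <- map_tags(tags5, g)
  d5 <- call_duplexes(aln5, tags5)
  expect_equal(nrow(d5[d5$plus_tag == "p" & d5$minus_tag == "m", ]), 0)
  # 6 in a single library of either tag suffices
  tags6 <- mk(c(5L, 5L, 5L, 5L), c(0L, 6L, 0L, 0L))
  d6 <- call_duplexes(map_tags(tags6, g), tags6)
  expect_equal(nrow(d6[d6$plus_tag == "p" & d6$minus_tag == "m", ]), 1)
})

test_that("duplex calls equal the brute-force all-pairs oracle", {
  for (seed in c(101, 202)) {
    fx <- make_catalog_fixture(loci_only_config(seed = seed))
    tags <- collapse_and_filter_reads(fx$tags)
    aln <- map_tags(tags, fx$genome$genome)
    got <- duplex_keys(call_duplexes(aln, tags))
    want <- brute_force_duplexes(aln, tags)
    expect_identical(got, want)
    expect_gt(length(got), 0)
  }
})
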