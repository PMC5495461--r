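revcomp_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

test_that("complementarity scoring applies the position-weighted scheme", {
  set.seed(8)
  tr <- paste(sample(c("A", "C", "G", "T"), 300, replace = TRUE),
              collapse = "")
  sirna <- revcomp_chr(substr(tr, 101, 121))  # perfect 21-nt complement
  hit <- score_complementarity(sirna, tr)
  exact <- hit[hit$penalty == 0, ]
  expect_equal(nrow(exact), 1)
  expect_equal(exact$site_start, 100L)
  expect_equal(exact$site_end, 121L)
  # cleavage between transcript bases opposite siRNA positions 10/11:
  # window [100,121) 1-based start 101, so 5p = 101+21-11-1+1... check
  # directly: positions 111 and 112 for a 21-nt siRNA at 1-based 101
  expect_equal(exact$cleavage_5p, 111L)
  expect_equal(exact$cleavage_3p, 112L)

  # one G:U wobble at siRNA position 5 (inside the doubled 2-13 core):
  # siRNA base G pairing target T scores 0.5, doubled to 1.0
  s2 <- sirna
  # force target base opposite siRNA pos 5 to T and siRNA pos 5 to G
  substr(s2, 5, 5) <- "G"
  tr2 <- tr
  substr(tr2, 101 + 21 - 5, 101 + 21 - 5) <- "T"  # 1-based 117
  hit2 <- score_complementarity(s2, tr2)
  w <- hit2[hit2$site_start == 100, ]
  expect_equal(w$penalty, 1.0)

  # five core mismatches cost 10 and fall outside the default cutoff
  s3 <- chartr("ACGT", "CAAC", substr(sirna, 3, 7))
  s3 <- paste0(substr(sirna, 1, 2), s3, substr(sirna, 8, 21))
  hit3 <- score_complementarity(s3, tr, max_penalty = 25)
  w3 <- hit3[hit3$site_start == 100, ]
  expect_gte(w3$penalty, 10)
  hit3d <- score_complementarity(s3, tr)
  expect_false(any(hit3d$site_start == 100))

  # siRNA longer than the transcript yields an empty result
  expect_message(
    none <- score_complementarity(paste(rep("A", 30), collapse = ""),
                                  "ACGTACGT"),
    "longer")
  expect_equal(nrow(none), 0)
})

test_that("zero-penalty scoring equals brute-force perfect-match search", {
  set.seed(12)
  for (rep in 1:5) {
    tr <- paste(sample(c("A", "C", "G", "T"), 500, replace = TRUE),
                collapse = "")
    pos <- sample(50:400, 1)
    sirna <- revcomp_chr(substr(tr, pos, pos + 20))
    hits <- score_complementarity(sirna, tr, max_penalty = 0)
    rc <- revcomp_chr(sirna)
    want <- integer(0)
    for (w in 1:(nchar(tr) - 20)) {
      if (substr(tr, w, w + 20) == rc) want <- c(want, w - 1L)
    }
    expect_identical(hits$site_start, want)
  }
})

test_that("raising the penalty cutoff only ever adds sites", {
  set.seed(19)
  tr <- paste(sample(c("A", "C", "G", "T"), 400, replace = TRUE),
              collapse = "")
  sirna <- revcomp_chr(substr(tr, 201, 221))
  prev <- -1
  for (mp in c(0, 2, 4, 8, 16)) {
    n <- nrow(score_complementarity(sirna, tr, max_penalty = mp))
    expect_gte(n, prev)
    prev <- n
  }
})

# -- a hand-built mini scenario for the cleavage filter chain ------------

make_chain_fixture <- function() {
  set.seed(33)
  tot <- c(CK = 1e6, I = 1e6, II = 1e6, III = 1e6)
  tr_seq <- vapply(1:3, function(i) {
    paste(sample(c("A", "C", "G", "T"), 400, replace = TRUE), collapse = "")
  }, character(1))
  sir21 <- revcomp_chr(substr(tr_seq[1], 101, 121))
  sir24 <- revcomp_chr(substr(tr_seq[2], 151, 174))
  sirnas <- data.frame(tag_id = c("s21", "s24"),
                       sequence = c(sir21, sir24), stringsAsFactors = FALSE)
  # s24 also hits transcript g2's sense strand, blocking it
  transcripts <- data.frame(
    gene_id = c("g1", "g2", "g3"), sequence = tr_seq, length = 400L,
    utr5_len = 100L, cds_len = 200L, utr3_len = 100L,
    stringsAsFactors = FALSE)
  transcripts$sequence[2] <- paste0(substr(tr_seq[2], 1, 150),
                                    revcomp_chr(sir24),
                                    substr(tr_seq[2], 175, 400))
  # g2 additionally carries a perfect site for s21
  transcripts$sequence[2] <- paste0(substr(transcripts$sequence[2], 1, 250),
                                    revcomp_chr(sir21),
                                    substr(transcripts$sequence[2], 272, 400))
  sirna_counts <- data.frame(
    feature_id = c("s21", "s24"), count_CK = c(20L, 20L),
    count_I = c(100L, 100L), count_II = c(100L, 100L),
    count_III = c(100L, 100L))
  gene_counts <- data.frame(
    feature_id = c("g1", "g2", "g3"), count_CK = c(400L, 400L, 400L),
    count_I = c(80L, 80L, 400L), count_II = c(80L, 80L, 400L),
    count_III = c(80L, 80L, 400L))
  sirna_de <- call_de(sirna_counts, tot, mode = "sirna")
  gene_de <- call_de(gene_counts, tot, mode = "gene")
  profiles <- list(
    sirna = sirnaflow:::.log_rpm_profiles(sirna_counts, tot),
    gene = sirnaflow:::.log_rpm_profiles(gene_counts, tot))
  sites <- find_target_sites(sirnas, transcripts, strands = "sense")
  list(tot = tot, sirna_de = sirna_de, gene_de = gene_de,
       profiles = profiles, sites = sites,
       lengths = c(s21 = 21L, s24 = 24L))
}

test_that("the cleavage filter chain keeps hits and vetoes correctly", {
  fx <- make_chain_fixture()
  out <- select_cleavage_targets(fx$sirna_de, fx$sites, fx$gene_de,
                                 fx$profiles, fx$lengths)
  # s21 -> g1: DE siRNA, sense site, DE gene, corr -1 => retained
  expect_true(any(out$sirna_id == "s21" & out$gene_id == "g1"))
  # g2 carries a sense site of the DE 24-nt siRNA => vetoed for everyone
  expect_false(any(out$gene_id == "g2"))
  # g3 is not differentially expressed => absent
  expect_false(any(out$gene_id == "g3"))
  expect_true(all(out$corr_sirna_gene < -0.4))
  expect_equal(out$stages_supported[out$gene_id == "g1"], "I,II,III")
  # a correlation above the ceiling excludes the pair: flatten the gene
  prof2 <- fx$profiles
  prof2$gene["g1", ] <- c(1, 2, 1.5, 1.8)  # weak positive relation
  out2 <- select_cleavage_targets(fx$sirna_de, fx$sites, fx$gene_de,
                                  prof2, fx$lengths)
  expect_false(any(out2$gene_id == "g1"))
  # widening the veto to all cataloged 24-nt siRNAs is at most as permissive
  out3 <- select_cleavage_targets(fx$sirna_de, fx$sites, fx$gene_de,
                                  fx$profiles, fx$lengths,
                                  exclude_24nt = "all")
  expect_lte(nrow(out3), nrow(out))
})

test_that("methylation region screen applies all three printed criteria", {
  tot <- c(CK = 1e6, I = 1e6, II = 1e6, III = 1e6)
  sig <- data.frame(
    region_id = c("hyper", "weak_ratio", "low_signal", "flat", "zero"),
    count_CK = c(50L, 1000L, 0L, 60L, 0L),
    count_I = c(220L, 1500L, 0L, 60L, 0L),
    count_II = c(220L, 1500L, 1L, 61L, 0L),
    count_III = c(220L, 1500L, 0L, 59L, 0L))
  calls <- call_methyl_regions(sig, tot)
  get <- function(id, st) {
    calls$direction[calls$region_id == id & calls$comparison == st]
  }
  expect_equal(get("hyper", "I"), "hyper")
  # ratio 1.5 with a tiny q stays ns
  expect_lt(calls$q[calls$region_id == "weak_ratio" &
                      calls$comparison == "I"], 0.01)
  expect_equal(get("weak_ratio", "I"), "ns")
  # below the 0.25 RPM signal floor stays ns
  expect_equal(get("low_signal", "II"), "ns")
  expect_equal(get("flat", "I"), "ns")
  # all-zero region is ns, not an error
  expect_equal(get("zero", "I"), "ns")
})

# -- methylation-route concordance -----------------------------------

make_methyl_fixture <- function(sirna_dir, methyl_dir, gene_dir,
                                sirna_len = 24L) {
  tot <- c(CK = 1e6, I = 1e6, II = 1e6, III = 1e6)
  set.seed(55)
  tr <- paste(sample(c("A", "C", "G", "T"), 400, replace = TRUE),
              collapse = "")
  sirna <- revcomp_chr(substr(tr, 321, 320 + sirna_len))
  transcripts <- data.frame(gene_id = "g1", sequence = tr, length = 400L,
                            utr5_len = 100L, cds_len = 200L,
                            utr3_len = 100L, stringsAsFactors = FALSE)
  flip <- function(dirn, hi, lo) if (dirn == "up") c(lo, hi) else c(hi, lo)
  s <- flip(sirna_dir, 100L, 20L)
  g <- flip(gene_dir, 400L, 80L)
  m <- if (methyl_dir == "hyper") c(50L, 200L) else c(200L, 50L)
  sirna_counts <- data.frame(feature_id = "s1", count_CK = s[1],
                             count_I = s[2], count_II = s[2],
                             count_III = s[2])
  gene_counts <- data.frame(feature_id = "g1", count_CK = g[1],
                            count_I = g[2], count_II = g[2],
                            count_III = g[2])
  methyl_counts <- data.frame(region_id = "r1", count_CK = m[1],
                              count_I = m[2], count_II = m[2],
                              count_III = m[2])
  sirnas <- data.frame(tag_id = "s1", sequence = sirna,
                       stringsAsFactors = FALSE)
  sites <- find_target_sites(sirnas, transcripts)
  profiles <- list(
    sirna = sirnaflow:::.log_rpm_profiles(sirna_counts, tot),
    gene = sirnaflow:::.log_rpm_profiles(gene_counts, tot),
    methyl = sirnaflow:::.log_rpm_profiles(methyl_counts, tot))
  list(
    sirna_de = call_de(sirna_counts, tot, mode = "sirna"),
    gene_de = call_de(gene_counts, tot, mode = "gene"),
    methyl_calls = call_methyl_regions(methyl_counts, tot),
    sites = sites, profiles = profiles,
    lengths = c(s1 = sirna_len),
    map = data.frame(region_id = "r1", gene_id = "g1",
                     stringsAsFactors = FALSE))
}

run_methyl_case <- function(sirna_dir, methyl_dir, gene_dir,
                            sirna_len = 24L) {
  fx <- make_methyl_fixture(sirna_dir, methyl_dir, gene_dir, sirna_len)
  select_methylation_targets(fx$sirna_de, fx$sites, fx$methyl_calls,
                             fx$gene_de, fx$profiles, fx$lengths, fx$map)
}

test_that("methylation targets follow the concordance truth table", {
  dirs <- c("up", "down")
  meth <- c("hyper", "hypo")
  for (sd in dirs) for (md in meth) for (gd in dirs) {
    out <- run_methyl_case(sd, md, gd)
    concordant <- (sd == "up" && md == "hyper" && gd == "down") ||
      (sd == "down" && md == "hypo" && gd == "up")
    info <- paste(sd, md, gd)
    if (concordant) {
      expect_equal(nrow(out), 1, info = info)
      expect_equal(out$methyl_direction, md, info = info)
      expect_lt(out$corr_sirna_gene, -0.4)
      expect_lt(out$corr_methyl_gene, -0.4)
    } else {
      expect_equal(nrow(out), 0, info = info)
    }
  }
  # a 22-nt siRNA is ineligible for the methylation route
  expect_equal(nrow(run_methyl_case("up", "hyper", "down",
                                    sirna_len = 22L)), 0)
})

test_that("degradome validation accepts exact peaks and rejects others", {
  site <- data.frame(sirna_id = "s1", gene_id = "g1", cleavage_3p = 112L,
                     stringsAsFactors = FALSE)
  peak_at <- function(pos, count = 50L) {
    data.frame(transcript_id = "g1",
               position = c(95L, 100L, pos, 120L),
               count = c(2L, 3L, count, 1L))
  }
  v1 <- validate_cleavage_with_degradome(site, peak_at(112L))
  expect_true(v1$confirmed)
  expect_equal(v1$peak_position, 112L)
  # peak displaced by 5 nt: unconfirmed
  v2 <- validate_cleavage_with_degradome(site, peak_at(117L))
  expect_false(v2$confirmed)
  # flat coverage: no strict maximum at the prediction
  flat <- data.frame(transcript_id = "g1", position = 100:124,
                     count = rep(4L, 25))
  expect_false(validate_cleavage_with_degradome(site, flat)$confirmed)
  # no coverage at all: unconfirmed, not an error
  none <- data.frame(transcript_id = "other", position = 1L, count = 9L)
  expect_false(validate_cleavage_with_degradome(site, none)$confirmed)
})
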