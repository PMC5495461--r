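# Independent oracles used by the test suite. Each is deliberately naive
# (brute force, enumeration, or exact rational arithmetic) and never shares
# code with the implementation it checks.

# Exact rational-arithmetic evaluation of the tag-count mass formula
# (N2/N1)^y (x+y)!/(x! y!) (1+N2/N1)^-(x+y+1) over a grid, via Python's
# fractions module (exact big-integer rationals), with a single correctly
# rounded conversion to double at the end.
ac_mass_rational_oracle <- function(xmax = 50L, ymax = 50L) {
  script <- c(
    "from fractions import Fraction",
    "import math",
    sprintf("xmax, ymax = %d, %d", xmax, ymax),
    "for pnum, pden in ((1, 2), (1, 1), (2, 1)):",
    "    r = Fraction(pnum, pden)",
    "    for x in range(xmax + 1):",
    "        for y in range(ymax + 1):",
    "            m = (r ** y) * Fraction(math.comb(x + y, y), 1)",
    "            m /= (1 + r) ** (x + y + 1)",
    "            print('%d/%d\\t%d\\t%d\\t%r' % (pnum, pden, x, y, float(m)))")
  f <- tempfile(fileext = ".py")
  writeLines(script, f)
  out <- tryCatch(system2("python", f, stdout = TRUE),
                  error = function(e) NULL)
  unlink(f)
  if (is.null(out) || length(out) == 0) {
    stop("python rational-arithmetic oracle unavailable")
  }
  df <- utils::read.delim(text = out, header = FALSE,
                          col.names = c("ratio", "x", "y", "mass"))
  df$r <- vapply(strsplit(df$ratio, "/"), function(v) {
    as.numeric(v[1]) / as.numeric(v[2])
  }, numeric(1))
  df
}

# Quadratic all-pairs duplex scan: every (plus, minus) alignment pair is
# tested literally against the overhang geometry and support rule.
brute_force_duplexes <- function(alignments, tags, min_support = 5,
                                 require_overlap = TRUE, min_overlap = 15L) {
  plus <- alignments[alignments$strand == "+", , drop = FALSE]
  minus <- alignments[alignments$strand == "-", , drop = FALSE]
  cm <- as.matrix(tags[, paste0("count_", c("CK", "I", "II", "III"))])
  rownames(cm) <- tags$tag_id
  keys <- character(0)
  for (i in seq_len(nrow(plus))) {
    for (j in seq_len(nrow(minus))) {
      p <- plus[i, ]; m <- minus[j, ]
      if (p$chrom != m$chrom) next
      if (p$start - m$start != 2L || p$end - m$end != 2L) next
      ov <- min(p$end, m$end) - max(p$start, m$start)
      if (require_overlap && ov < min_overlap) next
      if (max(cm[p$tag_id, ], cm[m$tag_id, ]) <= min_support) next
      keys <- c(keys, paste(p$chrom, p$tag_id, p$start, p$end,
                            m$tag_id, m$start, m$end))
    }
  }
  sort(unique(keys))
}

duplex_keys <- function(duplexes) {
  sort(unique(paste(duplexes$chrom, duplexes$plus_tag, duplexes$plus_start,
                    duplexes$plus_end, duplexes$minus_tag,
                    duplexes$minus_start, duplexes$minus_end)))
}

# Literal step-up FDR: q_i = min over admissible thresholds t >= p_i of
# t * n / #{p <= t}, capped at 1.
bh_brute_force <- function(p) {
  n <- length(p)
  vapply(p, function(pi) {
    ts <- p[p >= pi]
    min(1, min(vapply(ts, function(t) t * n / sum(p <= t), numeric(1))))
  }, numeric(1))
}

# Exhaustive-enumeration hypergeometric upper tail: the fraction of all
# C(N, n) draws whose overlap with the first K genes is >= k.
hyper_enum_oracle <- function(N, K, n, k) {
  draws <- utils::combn(N, n)
  mean(colSums(draws <= K) >= k)
}

adjusted_rand <- function(a, b) mclust::adjustedRandIndex(a, b)
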