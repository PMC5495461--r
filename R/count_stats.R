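#' Reads-per-million normalization
#'
#' Converts raw tag counts to reads per million clean reads (RPM):
#' `rpm = count * 1e6 / library_total`. When the totals are computed from
#' the table itself, per-library RPM values sum to exactly one million.
#'
#' @param counts numeric vector (one value per library), matrix or data
#'   frame with one column per library.
#' @param library_totals positive clean-read totals, one per library
#'   (recycled against vector input, matched to columns otherwise).
#' @return RPM values with the shape of `counts`.
#' @examples
#' normalize_rpm(c(50, 0), c(1e6, 1e6))
#' @export
normalize_rpm <- function(counts, library_totals) {
  if (any(library_totals <= 0)) stop("library totals must be positive")
  if (is.null(dim(counts))) {
    if (length(library_totals) != 1 &&
        length(library_totals) != length(counts)) {
      stop("library_totals must have length 1 or length(counts)")
    }
    return(counts * 1e6 / library_totals)
  }
  m <- as.matrix(counts)
  if (length(library_totals) != ncol(m)) {
    stop("need one library total per count column")
  }
  sweep(m, 2, library_totals, function(cnt, tot) cnt * 1e6 / tot)
}

#' Exact tag-count probability mass
#'
#' Probability of observing `y` reads of a tag in a library of `N2` total
#' reads given `x` reads in a library of `N1` total reads:
#' \deqn{P(y \mid x) = (N_2/N_1)^y \frac{(x+y)!}{x!\,y!}
#'   (1 + N_2/N_1)^{-(x+y+1)}}
#' Evaluated in log space via `lgamma`, finite for `x + y` well beyond 1e6.
#' For fixed `x` this is a negative-binomial mass in `y` with size `x + 1`
#' and success probability `N1 / (N1 + N2)`, so it sums to one over `y`.
#'
#' @param x,y non-negative integer read counts in the two libraries.
#' @param N1,N2 positive clean-read totals of the two libraries.
#' @param log if `TRUE`, return the log mass.
#' @return numeric vector of probability masses (vectorized over inputs).
#' @seealso [ac_pvalue()] for the two-sided tail probability.
#' @examples
#' ac_mass(0, 0, 1e6, 1e6)  # 0.5
#' ac_mass(1, 1, 1e6, 1e6)  # 0.25
#' @export
ac_mass <- function(x, y, N1, N2, log = FALSE) {
  if (any(x < 0) || any(y < 0)) stop("counts must be non-negative")
  if (any(x != round(x)) || any(y != round(y))) {
    stop("counts must be integers")
  }
  if (any(N1 <= 0) || any(N2 <= 0)) stop("library totals must be positive")
  lr <- log(N2) - log(N1)
  lm <- y * lr + lgamma(x + y + 1) - lgamma(x + 1) - lgamma(y + 1) -
    (x + y + 1) * log1p(exp(lr))
  if (log) lm else exp(lm)
}

# One tail of the distribution of y conditional on the observed sum
# s = x + y, which is Binomial(s, N2/(N1+N2)) -- the anti-diagonal
# normalization of ac_mass. Full log-space summation; no truncation.
.cond_tail <- function(x, y, N1, N2, upper) {
  s <- x + y
  lq <- log(N2) - log(N1 + N2)
  l1q <- log(N1) - log(N1 + N2)
  ks <- if (upper) y:s else 0:y
  lm <- lchoose(s, ks) + ks * lq + (s - ks) * l1q
  mx <- max(lm)
  min(1, sum(exp(lm - mx)) * exp(mx))
}

.ac_pvalue1 <- function(x, y, N1, N2, alternative) {
  if (x + y == 0) return(1)
  if (alternative == "greater") return(.cond_tail(x, y, N1, N2, upper = TRUE))
  if (alternative == "less") return(.cond_tail(x, y, N1, N2, upper = FALSE))
  # Two-sided: canonical orientation (stage-side count at or below its
  # conditional expectation) makes p exactly invariant under swapping
  # (x, N1) with (y, N2).
  if (y * N1 > x * N2) {
    tmp <- x; x <- y; y <- tmp
    tmp <- N1; N1 <- N2; N2 <- tmp
  }
  min(1, 2 * .cond_tail(x, y, N1, N2, upper = FALSE))
}

#' Exact tag-count p-value
#'
#' Significance of the difference between counts `x` (library total `N1`)
#' and `y` (library total `N2`) of one tag. Conditional on the observed sum
#' `x + y`, `y` follows a Binomial(`x + y`, `N2/(N1+N2)`) distribution (the
#' normalized anti-diagonal of [ac_mass()]); the two-sided p-value doubles
#' the smaller tail of that distribution and is capped at 1. The tail is an
#' exact log-space summation of the conditional masses. The two-sided value
#' is symmetric under exchanging the two libraries.
#'
#' @inheritParams ac_mass
#' @param alternative `"two.sided"` (default), `"greater"` (second library
#'   higher), or `"less"`.
#' @return p-values in `[0, 1]`, vectorized over `x`, `y`, `N1`, `N2`.
#' @examples
#' ac_pvalue(100, 0, 1e6, 1e6)   # very small
#' ac_pvalue(7, 7, 1e6, 1e6)     # 1
#' @export
ac_pvalue <- function(x, y, N1, N2, alternative = "two.sided") {
  alternative <- match.arg(alternative, c("two.sided", "greater", "less"))
  if (any(x < 0) || any(y < 0)) stop("counts must be non-negative")
  if (any(x != round(x)) || any(y != round(y))) {
    stop("counts must be integers")
  }
  if (any(N1 <= 0) || any(N2 <= 0)) stop("library totals must be positive")
  n <- max(length(x), length(y), length(N1), length(N2))
  x <- rep_len(x, n); y <- rep_len(y, n)
  N1 <- rep_len(N1, n); N2 <- rep_len(N2, n)
  vapply(seq_len(n), function(i) {
    .ac_pvalue1(x[i], y[i], N1[i], N2[i], alternative)
  }, numeric(1))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment with enforced monotonicity;
#' ties are preserved and the output order matches the input order.
#'
#' @param p p-values in `[0, 1]` (`NA` allowed and propagated).
#' @return adjusted p-values, same length and order as `p`.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Call differential expression stage versus control
#'
#' For each feature and each stage-vs-CK comparison, computes RPM values,
#' a pseudocounted log2 fold change `log2((rpm_stage + pc)/(rpm_ck + pc))`,
#' the exact tag-count p-value ([ac_pvalue()]), and a BH-adjusted q across
#' features within each comparison. A feature is directional (`up`/`down`)
#' only when the significance and fold-change criteria both pass; otherwise
#' `ns`.
#'
#' Modes preset the thresholds used in staged small-RNA studies:
#' \describe{
#'   \item{`sirna`}{raw `p < 0.01` and `|log2fc| >= 1`}
#'   \item{`gene`}{BH `q < 0.001` and `|log2fc| > 1`}
#'   \item{`methyl`}{BH `q < 0.05` (fold screen applied separately by
#'     [call_methyl_regions()])}
#' }
#'
#' @param counts data frame with `feature_id` and columns
#'   `count_CK`, `count_I`, `count_II`, `count_III`.
#' @param library_totals named clean-read totals (`CK`, `I`, `II`, `III`);
#'   defaults to the `library_totals` attribute of `counts`.
#' @param mode threshold preset, see Details.
#' @param comparisons stages to compare against CK.
#' @param p_thresh,q_thresh,lfc_thresh optional overrides of the preset
#'   thresholds (`p_thresh` gates on raw p, `q_thresh` on BH q).
#' @param lfc_strict if `TRUE` the fold-change test is strict (`>`),
#'   otherwise `>=`; preset per mode.
#' @param pseudocount RPM pseudocount added to both ratio sides.
#' @param alternative passed to [ac_pvalue()].
#' @return data frame with one row per feature per comparison: `feature_id`,
#'   `comparison`, `x`, `y`, `N1`, `N2`, `rpm_ck`, `rpm_stage`, `log2fc`,
#'   `p`, `q`, `direction`.
#' @export
call_de <- function(counts, library_totals = NULL,
                    mode = c("sirna", "gene", "methyl"),
                    comparisons = c("I", "II", "III"),
                    p_thresh = NULL, q_thresh = NULL, lfc_thresh = NULL,
                    lfc_strict = NULL, pseudocount = 0.5,
                    alternative = "two.sided") {
  mode <- match.arg(mode)
  defaults <- switch(mode,
    sirna  = list(p = 0.01, q = NA_real_, lfc = 1, strict = FALSE),
    gene   = list(p = NA_real_, q = 0.001, lfc = 1, strict = TRUE),
    methyl = list(p = NA_real_, q = 0.05, lfc = 0, strict = FALSE))
  if (is.null(p_thresh)) p_thresh <- defaults$p
  if (is.null(q_thresh)) q_thresh <- defaults$q
  if (is.null(lfc_thresh)) lfc_thresh <- defaults$lfc
  if (is.null(lfc_strict)) lfc_strict <- defaults$strict
  stopifnot(all(comparisons %in% .STAGES))

  totals <- .get_totals(counts, library_totals)
  m <- .count_matrix(counts)
  ids <- as.character(counts$feature_id %||% counts$tag_id %||% counts$gene_id)
  if (length(ids) != nrow(m) || anyNA(ids)) {
    stop("count table needs a feature_id (or tag_id / gene_id) column")
  }

  out <- lapply(comparisons, function(st) {
    x <- m[, "CK"]; y <- m[, st]
    N1 <- totals[["CK"]]; N2 <- totals[[st]]
    rpm_ck <- normalize_rpm(x, N1)
    rpm_st <- normalize_rpm(y, N2)
    lfc <- log2((rpm_st + pseudocount) / (rpm_ck + pseudocount))
    p <- ac_pvalue(x, y, N1, N2, alternative = alternative)
    q <- bh_adjust(p)
    sig <- if (!is.na(q_thresh)) q < q_thresh else p < p_thresh
    big <- if (lfc_strict) abs(lfc) > lfc_thresh else abs(lfc) >= lfc_thresh
    dir <- ifelse(sig & big, ifelse(lfc > 0, "up", "down"), "ns")
    data.frame(feature_id = ids, comparison = st, x = x, y = y,
               N1 = N1, N2 = N2, rpm_ck = rpm_ck, rpm_stage = rpm_st,
               log2fc = lfc, p = p, q = q, direction = dir,
               stringsAsFactors = FALSE, row.names = NULL)
  })
  do.call(rbind, out)
}

#' Pearson correlation between two expression profiles
#'
#' Correlation over matched library values (typically `log2(RPM + 0.5)`
#' across CK and Stages I-III). Returns `NA` when either profile has zero
#' variance (the correlation is undefined).
#'
#' @param a,b numeric vectors of equal length (>= 2).
#' @return Pearson correlation coefficient, or `NA_real_`.
#' @export
profile_correlation <- function(a, b) {
  if (length(a) != length(b)) stop("profiles differ in length")
  if (length(a) < 2) stop("profiles need at least two values")
  if (anyNA(a) || anyNA(b)) stop("profiles must not contain NA")
  if (stats::sd(a) == 0 || stats::sd(b) == 0) return(NA_real_)
  stats::cor(a, b)
}

# log2(RPM + pseudocount) profile matrix from a count table.
.log_rpm_profiles <- function(counts, library_totals = NULL,
                              pseudocount = 0.5) {
  totals <- .get_totals(counts, library_totals)
  m <- .count_matrix(counts)
  ids <- as.character(counts$feature_id %||% counts$tag_id %||%
                        counts$gene_id %||% counts$region_id)
  rpm <- normalize_rpm(m, totals)
  lp <- log2(rpm + pseudocount)
  rownames(lp) <- ids
  lp
}

`%||%` <- function(a, b) if (is.null(a)) b else a
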