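#' Cluster expression-pattern profiles with K-means
#'
#' Euclidean K-means (Lloyd iterations via [stats::kmeans()]) over
#' stage-vs-CK log2 fold-change profiles, with k-means++ seeding and the
#' best of `restarts` runs by total within-cluster sum of squares.
#' Deterministic for a fixed seed. Cluster labels are stabilized by
#' relabeling in order of descending Stage-I centroid coordinate, ties
#' broken by descending mean over the later stages, so that label 1 is the
#' most strongly Stage-I-up-regulated pattern.
#'
#' @param profiles data frame with `gene_id` and three numeric feature
#'   columns (log2 fold change at Stages I, II, III versus CK).
#' @param k number of clusters (default 3, the three canonical patterns:
#'   sustained up, sustained down, transient up).
#' @param seed integer seed.
#' @param restarts number of seeded restarts.
#' @return list with `assignments` (data frame `gene_id`, `cluster`),
#'   `centroids` (k x 3 matrix, relabeled), and `tot_withinss`.
#' @export
kmeans_profiles <- function(profiles, k = 3L, seed = 1L, restarts = 50L) {
  feat_cols <- setdiff(names(profiles), "gene_id")
  x <- as.matrix(profiles[, feat_cols, drop = FALSE])
  storage.mode(x) <- "double"
  if (k < 1) stop("k must be >= 1")
  if (k > nrow(x)) stop("k exceeds the number of profiles")
  set.seed(.sub_seed(seed, "kmeans"))
  best <- NULL
  for (r in seq_len(restarts)) {
    centers <- .kmeanspp_init(x, k)
    fit <- tryCatch(
      stats::kmeans(x, centers = centers, iter.max = 100L,
                    algorithm = "Lloyd"),
      error = function(e) NULL,
      warning = function(w) suppressWarnings(
        stats::kmeans(x, centers = centers, iter.max = 200L,
                      algorithm = "Lloyd")))
    if (is.null(fit)) next
    if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
  }
  if (is.null(best)) stop("k-means failed on all restarts")
  ord <- order(-best$centers[, 1],
               -rowMeans(best$centers[, -1, drop = FALSE]))
  relabel <- match(seq_len(k), ord)
  cl <- relabel[best$cluster]
  centroids <- best$centers[ord, , drop = FALSE]
  rownames(centroids) <- seq_len(k)
  list(assignments = data.frame(gene_id = profiles$gene_id, cluster = cl,
                                stringsAsFactors = FALSE),
       centroids = centroids, tot_withinss = best$tot.withinss)
}

# k-means++ seeding: first center uniform, later centers with probability
# proportional to squared distance from the nearest chosen center.
.kmeanspp_init <- function(x, k) {
  n <- nrow(x)
  idx <- integer(k)
  idx[1] <- sample.int(n, 1)
  if (k > 1) {
    d2 <- colSums((t(x) - x[idx[1], ])^2)
    for (j in 2:k) {
      pr <- d2
      pr[idx[seq_len(j - 1)]] <- 0
      if (sum(pr) == 0) {
        pool <- setdiff(seq_len(n), idx[seq_len(j - 1)])
        idx[j] <- if (length(pool)) pool[sample.int(length(pool), 1)] else
          sample.int(n, 1)
      } else {
        idx[j] <- sample.int(n, 1, prob = pr)
      }
      d2 <- pmin(d2, colSums((t(x) - x[idx[j], ])^2))
    }
  }
  centers <- x[idx, , drop = FALSE]
  # Lloyd requires distinct centers; nudge exact duplicates
  dup <- duplicated(centers)
  if (any(dup)) {
    centers[dup, ] <- centers[dup, , drop = FALSE] +
      matrix(stats::rnorm(sum(dup) * ncol(x), 0, 1e-8), sum(dup))
  }
  centers
}

#' Term over-representation by the hypergeometric test
#'
#' One-sided upper-tail hypergeometric p-value per annotation term for a
#' gene cluster against a background: the probability of drawing at least
#' the observed number of term-annotated genes in a cluster-sized sample
#' without replacement. Terms with no annotated gene in the cluster are
#' not reported. BH adjustment is applied across the reported terms of the
#' cluster; the raw `p < p_thresh` flag is the headline call and `q` is
#' reported alongside.
#'
#' @param cluster_genes character vector of cluster member gene ids (must
#'   be a subset of the background).
#' @param background_genes character vector of background gene ids.
#' @param annotation data frame `gene_id`, `term_id` (optionally
#'   `term_name`).
#' @param p_thresh raw-p enrichment flag threshold.
#' @return data frame `term_id`, `term_name`, `k_in`, `n_cluster`, `K_in`,
#'   `N_bg`, `p`, `q`, `enriched`, ordered by `p`.
#' @export
hypergeometric_enrichment <- function(cluster_genes, background_genes,
                                      annotation, p_thresh = 0.05) {
  background_genes <- unique(background_genes)
  cluster_genes <- unique(cluster_genes)
  missing <- setdiff(cluster_genes, background_genes)
  if (length(missing)) {
    stop("referential-integrity error: cluster gene(s) absent from ",
         "background: ", paste(missing, collapse = ", "))
  }
  ann <- annotation[annotation$gene_id %in% background_genes, , drop = FALSE]
  if (!"term_name" %in% names(ann)) ann$term_name <- ann$term_id
  N <- length(background_genes)
  n <- length(cluster_genes)
  terms <- unique(ann[, c("term_id", "term_name")])
  rows <- list()
  for (i in seq_len(nrow(terms))) {
    tg <- unique(ann$gene_id[ann$term_id == terms$term_id[i]])
    K <- length(tg)
    k <- length(intersect(tg, cluster_genes))
    if (k == 0) next
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    rows[[length(rows) + 1]] <- data.frame(
      term_id = terms$term_id[i], term_name = terms$term_name[i],
      k_in = k, n_cluster = n, K_in = K, N_bg = N, p = p,
      stringsAsFactors = FALSE)
  }
  if (!length(rows)) {
    return(data.frame(term_id = character(0), term_name = character(0),
                      k_in = integer(0), n_cluster = integer(0),
                      K_in = integer(0), N_bg = integer(0), p = numeric(0),
                      q = numeric(0), enriched = logical(0)))
  }
  out <- do.call(rbind, rows)
  out$q <- bh_adjust(out$p)
  out$enriched <- out$p < p_thresh
  out <- out[order(out$p, out$term_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
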