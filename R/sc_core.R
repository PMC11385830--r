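#' Per-cell quality-control metrics
#'
#' Computes library size (total counts), number of detected genes
#' (count > 0), and mitochondrial percentage for every cell.
#'
#' @param counts genes x cells count matrix (dense or dgCMatrix), non-negative
#'   integers.
#' @param mito_flags logical per-gene vector marking mitochondrial genes. If
#'   \code{NULL}, genes are matched against \code{mito_prefix} on rownames.
#' @param mito_prefix prefix rule for mitochondrial genes (default
#'   \code{"MT-"}).
#' @return data.frame with columns \code{cell}, \code{library_size},
#'   \code{n_detected}, \code{mito_pct} (in [0,100]; all-zero cells get 0 by
#'   convention).
#' @export
compute_qc_metrics <- function(counts, mito_flags = NULL, mito_prefix = "MT-") {
  if (is.null(mito_flags)) {
    if (is.null(rownames(counts))) stopf("counts must have gene rownames when mito_flags is NULL")
    mito_flags <- startsWith(rownames(counts), mito_prefix)
  }
  if (length(mito_flags) != nrow(counts))
    stopf("mito_flags length (%d) does not match gene count (%d)",
          length(mito_flags), nrow(counts))
  lib <- Matrix::colSums(counts)
  det <- Matrix::colSums(counts > 0)
  mito <- if (any(mito_flags)) Matrix::colSums(counts[mito_flags, , drop = FALSE]) else
    rep(0, ncol(counts))
  pct <- ifelse(lib > 0, 100 * mito / lib, 0)
  data.frame(cell = if (is.null(colnames(counts))) paste0("cell", seq_len(ncol(counts)))
             else colnames(counts),
             library_size = as.numeric(lib), n_detected = as.numeric(det),
             mito_pct = pct, row.names = NULL)
}

#' MAD-based QC outlier flagging
#'
#' Drops cells whose log1p library size or log1p detected-gene count falls
#' more than \code{k} MADs below the median, or whose mitochondrial
#' percentage rises more than \code{k_mito} MADs above the median. The MAD
#' uses the 1.4826 normal-consistency constant. Cuts are one-sided: low tail
#' for size/detection, high tail for mito.
#'
#' @param metrics output of [compute_qc_metrics()].
#' @param k_libsize,k_detected,k_mito MAD multipliers (defaults 5, 5, 3).
#' @return data.frame with \code{cell}, \code{keep}, and per-metric reason
#'   flags; thresholds attached as attribute \code{"thresholds"}.
#' @export
flag_outliers_mad <- function(metrics, k_libsize = 5, k_detected = 5, k_mito = 3) {
  if (nrow(metrics) < 3) stopf("at least 3 cells required for MAD-based QC")
  lls <- log1p(metrics$library_size)
  ldt <- log1p(metrics$n_detected)
  mp <- metrics$mito_pct
  thr <- c(
    libsize_lo = median(lls) - k_libsize * mad(lls),
    detected_lo = median(ldt) - k_detected * mad(ldt),
    mito_hi = median(mp) + k_mito * mad(mp)
  )
  low_lib <- lls < thr[["libsize_lo"]]
  low_det <- ldt < thr[["detected_lo"]]
  hi_mito <- mp > thr[["mito_hi"]]
  keep <- !(low_lib | low_det | hi_mito)
  if (!any(keep))
    stopf("all cells flagged as outliers; review the MAD thresholds (k = %g, %g, %g)",
          k_libsize, k_detected, k_mito)
  out <- data.frame(cell = metrics$cell, keep = keep,
                    low_library = low_lib, low_detected = low_det,
                    high_mito = hi_mito)
  attr(out, "thresholds") <- thr
  out
}

#' Gene-level filter: expressed in at least \code{min_cells} cells
#'
#' The default \code{min_cells = 6} encodes "expressed in more than five
#' cells".
#'
#' @param counts genes x cells count matrix.
#' @param min_cells minimum number of cells with count > 0.
#' @return the filtered count matrix (possibly with zero rows, with warning).
#' @export
filter_genes_min_cells <- function(counts, min_cells = 6) {
  n_expr <- Matrix::rowSums(counts > 0)
  keep <- n_expr >= min_cells
  if (!any(keep)) warnf("no genes pass the min_cells = %d filter", min_cells)
  counts[keep, , drop = FALSE]
}

#' Log2 counts-per-10k normalization
#'
#' \eqn{x_{gc} = \log_2(1 + count_{gc} \cdot target / L_c)} with \eqn{L_c}
#' the cell's library size. Deterministic, monotone in counts per cell, and
#' invariant to per-cell scaling of the raw counts. This fixed log2 scale is
#' what the unit-width VIM staging bins are defined on.
#'
#' @param counts genes x cells count matrix.
#' @param target_sum library-size target (default 1e4, i.e. CP10K).
#' @return dense genes x cells matrix with attributes \code{target_sum} and
#'   \code{pseudocount}.
#' @export
normalize_log <- function(counts, target_sum = 1e4) {
  lib <- Matrix::colSums(counts)
  if (any(lib == 0))
    stopf("%d cell(s) have zero library size; remove them in QC before normalizing",
          sum(lib == 0))
  x <- as_dense(counts)
  x <- log2(1 + sweep(x, 2, target_sum / lib, `*`))
  attr(x, "target_sum") <- target_sum
  attr(x, "pseudocount") <- 1
  x
}

#' Highly variable gene selection
#'
#' Ranks genes by standardized variance: per-gene variance of the normalized
#' values divided by a mean-variance trend fitted as a rolling median of
#' variance over genes ordered by mean expression. Ties break
#' lexicographically by gene identifier for determinism.
#'
#' @param norm normalized matrix from [normalize_log()].
#' @param n_top number of genes to return (default 3000).
#' @param window rolling-median window width (odd; default adapts to gene
#'   count).
#' @return character vector of the selected gene names, ranked.
#' @export
select_hvg <- function(norm, n_top = 3000, window = NULL) {
  n_genes <- nrow(norm)
  if (n_top > n_genes) stopf("n_top = %d exceeds the %d available genes", n_top, n_genes)
  mu <- rowMeans(norm)
  v <- apply(norm, 1, var)
  if (is.null(window)) window <- max(11L, 2L * floor(n_genes / 40) + 1L)
  window <- min(window, if (n_genes %% 2 == 1) n_genes else n_genes - 1L)
  ord <- order(mu)
  trend_sorted <- stats::runmed(v[ord], k = window, endrule = "median")
  trend <- numeric(n_genes)
  trend[ord] <- pmax(trend_sorted, 1e-12)
  std_var <- v / trend
  std_var[v == 0] <- 0     # constant genes can never beat a varying gene
  ids <- rownames(norm)
  sel <- order(-std_var, ids)[seq_len(n_top)]
  ids[sel]
}

#' PCA embedding of the HVG submatrix
#'
#' Centers and unit-scales each HVG, then decomposes by SVD. Components are
#' ordered by decreasing explained variance and each component's sign is
#' fixed so its largest-magnitude gene loading is positive.
#'
#' @param norm normalized matrix (genes x cells).
#' @param hvgs genes to use (rows of \code{norm}).
#' @param n_pcs number of components (default 13).
#' @param seed unused (the decomposition is deterministic); kept so pipeline
#'   configs can carry one seed registry.
#' @return cells x n_pcs matrix; attribute \code{"explained_variance"}.
#' @export
pca_embed <- function(norm, hvgs = rownames(norm), n_pcs = 13, seed = NULL) {
  x <- norm[hvgs, , drop = FALSE]
  sds <- apply(x, 1, sd)
  x <- x[sds > 0, , drop = FALSE]
  x <- (x - rowMeans(x)) / apply(x, 1, sd)
  m <- t(x)                                  # cells x genes
  pc <- stats::prcomp(m, center = TRUE, scale. = FALSE, rank. = n_pcs)
  achievable <- sum(pc$sdev > max(pc$sdev) * 1e-8)
  if (n_pcs > achievable)
    stopf("requested %d PCs but matrix rank is only %d", n_pcs, achievable)
  flip <- vapply(seq_len(ncol(pc$rotation)), function(j) {
    l <- pc$rotation[, j]
    sign(l[which.max(abs(l))])
  }, numeric(1))
  emb <- sweep(pc$x, 2, flip, `*`)
  attr(emb, "explained_variance") <- (pc$sdev[seq_len(n_pcs)])^2
  emb
}

#' Shared-nearest-neighbor graph clustering
#'
#' Builds a k-nearest-neighbor graph on Euclidean distances in the embedding,
#' weights edges by the Jaccard overlap of neighborhoods (shared nearest
#' neighbors), and optimizes modularity (Louvain) at the given resolution.
#'
#' @param embedding cells x dims matrix from [pca_embed()].
#' @param k neighbors (default 20).
#' @param resolution modularity resolution (default 1).
#' @param seed RNG seed for the community search.
#' @return integer cluster labels (contiguous from 1), with parameters as
#'   attributes.
#' @export
knn_cluster <- function(embedding, k = 20, resolution = 1.0, seed = 1L) {
  n <- nrow(embedding)
  if (k >= n) stopf("k = %d must be smaller than the number of cells (%d)", k, n)
  nn <- FNN::get.knn(embedding, k = k)$nn.index
  # SNN with Jaccard weights over (self + neighbors) sets
  nbr <- cbind(seq_len(n), nn)
  edges <- cbind(rep(seq_len(n), each = k), as.vector(t(nn)))
  shared <- vapply(seq_len(nrow(edges)), function(e) {
    length(intersect(nbr[edges[e, 1], ], nbr[edges[e, 2], ]))
  }, numeric(1))
  w <- shared / (2 * (k + 1) - shared)
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  igraph::E(g)$weight <- w
  g <- igraph::simplify(g, edge.attr.comb = "max")
  memb <- with_seed(seed,
    igraph::membership(igraph::cluster_louvain(g, resolution = resolution)))
  labels <- as.integer(factor(as.integer(memb)))
  attr(labels, "params") <- list(k = k, resolution = resolution, seed = seed)
  labels
}
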