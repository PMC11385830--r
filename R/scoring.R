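#' Single-sample gene-set enrichment scores per cell
#'
#' For every cell, genes are ranked by expression (descending, ties broken
#' lexicographically by gene id). With \eqn{N} genes, the gene at descending
#' position \eqn{i} receives rank value \eqn{r_i = N - i + 1} and weight
#' \eqn{r_i^{\tau}} (default \eqn{\tau = 0.25}). The enrichment score of a
#' set \eqn{S} is the running-sum
#' \deqn{ES = \sum_i \left[ P^w_{in}(i) - P_{out}(i) \right]}
#' where \eqn{P^w_{in}} is the weighted empirical CDF of the in-set genes and
#' \eqn{P_{out}} the unweighted CDF of the rest. The normalized score (NES)
#' divides every ES by the maximum absolute ES observed across all sets and
#' cells, mapping the matrix into \eqn{[-1, 1]}; being rank-based, scores
#' are invariant to any monotone transform of a cell's expression vector.
#'
#' @param norm normalized genes x cells matrix (any monotone scale).
#' @param sets named list of gene-id character vectors.
#' @param weight_exponent rank weight exponent tau (default 0.25).
#' @param min_genes sets matched by fewer genes are skipped with a warning
#'   (default 2).
#' @return list with \code{es} and \code{nes} (set x cell matrices),
#'   \code{coverage} (matched / set size), and \code{skipped}.
#' @export
ssgsea_cell_scores <- function(norm, sets, weight_exponent = 0.25, min_genes = 2) {
  if (is.null(names(sets)) || anyDuplicated(names(sets)))
    stopf("sets must be a uniquely named list")
  genes <- rownames(norm)
  n <- length(genes)
  matched <- lapply(sets, function(s) intersect(s, genes))
  sizes <- lengths(matched)
  skipped <- names(sets)[sizes < min_genes]
  if (length(skipped))
    warnf("skipping %d set(s) with < %d matched genes: %s",
          length(skipped), min_genes, paste(skipped, collapse = ", "))
  keep <- setdiff(names(sets), skipped)
  if (!length(keep)) stopf("no gene set has >= %d genes in the matrix", min_genes)
  in_set <- vapply(keep, function(nm) genes %in% matched[[nm]], logical(n))
  es <- matrix(NA_real_, length(keep), ncol(norm),
               dimnames = list(keep, colnames(norm)))
  rank_val <- (n:1)^weight_exponent     # weight by descending-rank position
  for (c_i in seq_len(ncol(norm))) {
    ord <- order(-norm[, c_i], genes)
    ins <- in_set[ord, , drop = FALSE]
    for (s_i in seq_along(keep)) {
      flag <- ins[, s_i]
      w <- rank_val * flag
      p_in <- cumsum(w) / sum(w)
      n_out <- n - sum(flag)
      p_out <- cumsum(!flag) / n_out
      es[s_i, c_i] <- sum(p_in - p_out)
    }
  }
  denom <- max(abs(es))
  nes <- if (denom > 0) es / denom else es
  list(es = es, nes = nes,
       coverage = sizes[keep] / lengths(sets)[keep], skipped = skipped)
}

#' Per-set, per-stage median enrichment scores
#'
#' @param scores \code{nes} matrix (set x cell) or the list returned by
#'   [ssgsea_cell_scores()].
#' @param assign stratum assignment from [stratify_by_marker()].
#' @return set x stage matrix of medians; stages with no cells are NA.
#' @export
stratum_median_nes <- function(scores, assign) {
  nes <- if (is.list(scores)) scores$nes else scores
  m <- match(colnames(nes), assign$cell)
  if (anyNA(m)) stopf("%d scored cell(s) lack a stage assignment", sum(is.na(m)))
  stage <- assign$stage[m]
  levs <- levels(stage)
  out <- matrix(NA_real_, nrow(nes), length(levs), dimnames = list(rownames(nes), levs))
  for (lv in levs) {
    j <- which(stage == lv)
    if (length(j)) out[, lv] <- apply(nes[, j, drop = FALSE], 1, median)
  }
  out
}

#' Spearman correlation between EMT stage and enrichment score
#'
#' Correlates each set's per-cell score with the ordinal stage index
#' (average-rank ties), returning sets sorted by decreasing rho. With
#' \code{by_stage_median = TRUE} the correlation is instead computed on the
#' per-stage medians (a sensitivity mode for the ambiguous per-cell vs
#' per-stage reading).
#'
#' @param scores as in [stratum_median_nes()].
#' @param assign stratum assignment.
#' @param by_stage_median correlate the stage medians instead of cells.
#' @return data.frame: set, rho, p (t-approximation), sorted by rho
#'   descending.
#' @export
spearman_trend <- function(scores, assign, by_stage_median = FALSE) {
  nes <- if (is.list(scores)) scores$nes else scores
  m <- match(colnames(nes), assign$cell)
  if (anyNA(m)) stopf("scored cells lack stage assignments")
  stage_idx <- as.integer(assign$stage[m])
  if (length(unique(stage_idx)) < 2)
    stopf("at least 2 populated stages are required for a trend")
  res <- lapply(rownames(nes), function(set) {
    if (by_stage_median) {
      med <- stratum_median_nes(nes[set, , drop = FALSE], assign)[1, ]
      ok <- !is.na(med)
      x <- seq_along(med)[ok]; y <- med[ok]
    } else {
      x <- stage_idx; y <- nes[set, ]
    }
    rho <- cor(rank(x), rank(y))
    nn <- length(x)
    p <- if (nn > 2 && is.finite(rho) && abs(rho) < 1) {
      tstat <- rho * sqrt((nn - 2) / (1 - rho^2))
      2 * pt(-abs(tstat), df = nn - 2)
    } else if (isTRUE(abs(rho) == 1)) 0 else NA_real_
    data.frame(set = set, rho = rho, p = p)
  })
  out <- do.call(rbind, res)
  out <- out[order(-out$rho, out$set), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Weighted EMT signature score per cell
#'
#' Computes \eqn{score_c = \sum_g w_g x_{gc}} over the signature genes and
#' centers the scores to a grand mean of exactly zero. Genes absent from the
#' matrix contribute zero expression (a coverage warning is raised rather
#' than renormalizing the weights). After centering, negative scores read as
#' mesenchymal and positive as epithelial when the canonical 76-gene weight
#' convention is used.
#'
#' @param norm normalized genes x cells matrix.
#' @param weights data.frame with columns \code{gene}, \code{weight} (or a
#'   named numeric vector).
#' @return named numeric per-cell score vector (mean zero); attribute
#'   \code{"coverage"} gives the matched fraction.
#' @export
emt_score_weighted <- function(norm, weights) {
  if (is.data.frame(weights)) {
    if (anyDuplicated(weights$gene)) stopf("duplicate genes in the weight table")
    w <- setNames(weights$weight, weights$gene)
  } else w <- weights
  if (!any(w != 0)) stopf("at least one weight must be nonzero")
  present <- intersect(names(w), rownames(norm))
  if (!length(present)) stopf("no weight genes present in the matrix")
  if (length(present) < length(w))
    warnf("%d of %d signature genes absent from the matrix; imputed as zero expression",
          length(w) - length(present), length(w))
  raw <- drop(crossprod(norm[present, , drop = FALSE], w[present]))
  centered <- raw - mean(raw)
  names(centered) <- colnames(norm)
  attr(centered, "coverage") <- length(present) / length(w)
  centered
}

#' Relative quantification by the 2^-ddCt method
#'
#' \eqn{\Delta Ct_s = Ct_{target,s} - Ct_{ref,s}};
#' \eqn{\Delta\Delta Ct_s = \Delta Ct_s - \Delta Ct_{baseline}};
#' fold change \eqn{= 2^{-\Delta\Delta Ct_s}}. The baseline sample's fold is
#' 1 by construction.
#'
#' @param ct data.frame with columns \code{sample}, \code{gene}, \code{ct}.
#' @param target target gene id.
#' @param reference internal control gene id (e.g. \code{"GAPDH"}).
#' @param baseline baseline sample id.
#' @return data.frame: sample, dct, ddct, fold.
#' @export
ddct_fold_change <- function(ct, target, reference, baseline) {
  need <- c("sample", "gene", "ct")
  if (!all(need %in% names(ct))) stopf("ct table needs columns sample, gene, ct")
  samples <- unique(ct$sample)
  if (!baseline %in% samples) stopf("baseline sample '%s' not present", baseline)
  get_ct <- function(s, g) {
    v <- ct$ct[ct$sample == s & ct$gene == g]
    if (!length(v)) stopf("missing Ct for gene '%s' in sample '%s'", g, s)
    if (!all(is.finite(v))) stopf("non-finite Ct for gene '%s' in sample '%s'", g, s)
    mean(v)
  }
  dct <- vapply(samples, function(s) get_ct(s, target) - get_ct(s, reference), numeric(1))
  ddct <- dct - dct[[baseline]]
  data.frame(sample = samples, dct = as.numeric(dct), ddct = as.numeric(ddct),
             fold = 2^(-as.numeric(ddct)), row.names = NULL)
}
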