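#' Stratify cells into ordinal EMT stages by marker expression
#'
#' Assigns each cell to one of \code{n_bins} ordinal stages from its log2
#' normalized expression of the marker gene (vimentin by default), using
#' half-open \eqn{(a, b]} bins of width \code{bin_width}: a cell with marker
#' value \eqn{x} lands in bin \eqn{\lceil x / w \rceil}, clamped to
#' \eqn{[1, n\_bins]}. Zero-marker cells join the lowest stage (the
#' epithelial reference must contain them); values above the top edge clamp
#' to the top stage. Labels read \code{"VIM 0-1"} ... \code{"VIM 5-6"}.
#'
#' @param norm normalized matrix from [normalize_log()].
#' @param marker marker gene id (default \code{"VIM"}).
#' @param bin_width stage width on the log2 scale (default 1).
#' @param n_bins number of stages (default 6).
#' @param drop_zero if TRUE, cells with marker value exactly 0 are excluded
#'   (the strict reading of a "0 < x" lower bound) instead of joining bin 1.
#' @return data.frame with \code{cell}, \code{marker_value}, \code{stage}
#'   (ordered factor); marker recorded as attribute.
#' @export
stratify_by_marker <- function(norm, marker = "VIM", bin_width = 1, n_bins = 6,
                               drop_zero = FALSE) {
  if (!marker %in% rownames(norm))
    stopf("marker gene '%s' not present in the matrix", marker)
  x <- norm[marker, ]
  cells <- colnames(norm)
  if (drop_zero) {
    keep <- x > 0
    x <- x[keep]; cells <- cells[keep]
  }
  bin <- pmin(n_bins, pmax(1L, as.integer(ceiling(x / bin_width))))
  labs <- stage_labels(n_bins)
  out <- data.frame(cell = cells, marker_value = as.numeric(x),
                    stage = factor(labs[bin], levels = labs, ordered = TRUE),
                    row.names = NULL)
  attr(out, "marker") <- marker
  attr(out, "bin_width") <- bin_width
  out
}

#' Merge ordinal strata into coarser groups
#'
#' The default scheme merges the two lowest stages into a \code{"VIM 0-2"}
#' reference, yielding the five survival-analysis groups VIM 0-2, 2-3, 3-4,
#' 4-5, 5-6. The scheme must cover every existing stage label exactly once.
#'
#' @param assign output of [stratify_by_marker()].
#' @param scheme named list: new label -> character vector of old labels.
#' @return data.frame like \code{assign} with remapped ordered \code{stage}.
#' @export
regroup_strata <- function(assign, scheme = NULL) {
  old_levels <- levels(assign$stage)
  if (is.null(scheme)) {
    scheme <- c(list("VIM 0-2" = old_levels[1:2]),
                setNames(as.list(old_levels[-(1:2)]), old_levels[-(1:2)]))
  }
  flat <- unlist(scheme, use.names = FALSE)
  if (anyDuplicated(flat)) stopf("regrouping scheme maps some stage more than once")
  missing <- setdiff(old_levels, flat)
  if (length(missing))
    stopf("regrouping scheme omits stage(s): %s", paste(missing, collapse = ", "))
  extra <- setdiff(flat, old_levels)
  if (length(extra))
    stopf("regrouping scheme references unknown stage(s): %s", paste(extra, collapse = ", "))
  map <- setNames(rep(names(scheme), lengths(scheme)), flat)
  # order new levels by the position of their earliest constituent
  first_pos <- vapply(names(scheme), function(nm)
    min(match(scheme[[nm]], old_levels)), numeric(1))
  new_levels <- names(scheme)[order(first_pos)]
  out <- assign
  out$stage <- factor(map[as.character(assign$stage)], levels = new_levels, ordered = TRUE)
  attr(out, "marker") <- attr(assign, "marker")
  out
}

# Exact two-sided rank-sum p-value by enumeration of all C(nA+nB, nA)
# assignments of the observed (possibly tied) values. Also the oracle used
# in the tests for the normal approximation.
ranksum_exact_p <- function(ranks_a, all_ranks) {
  n <- length(all_ranks); na <- length(ranks_a)
  combs <- combn(n, na)
  sums <- colSums(matrix(all_ranks[combs], nrow = na))
  w_obs <- sum(ranks_a)
  eps <- 1e-9
  p_le <- mean(sums <= w_obs + eps)
  p_ge <- mean(sums >= w_obs - eps)
  min(1, 2 * min(p_le, p_ge))
}

# Normal approximation with tie correction and continuity correction.
ranksum_normal_p <- function(ranks_a, all_ranks) {
  na <- length(ranks_a); n <- length(all_ranks); nb <- n - na
  w <- sum(ranks_a)
  mu_w <- na * (n + 1) / 2
  ties <- rle(sort.int(all_ranks))$lengths
  tie_term <- sum(ties^3 - ties) / (n * (n - 1))
  sig2 <- na * nb / 12 * ((n + 1) - tie_term)
  if (sig2 <= 0) return(1)
  z <- (w - mu_w - sign(w - mu_w) * 0.5) / sqrt(sig2)
  min(1, 2 * pnorm(-abs(z)))
}

#' Wilcoxon rank-sum differential expression between two cell sets
#'
#' Per-gene two-sided rank-sum test of group A versus group B on the
#' normalized values, with exact enumeration when both groups have at most
#' \code{exact_max} cells and a tie- and continuity-corrected normal
#' approximation otherwise. The log2 fold change compares de-logged means:
#' \eqn{\log_2((\bar{e}_A + \epsilon)/(\bar{e}_B + \epsilon))} with
#' \eqn{e = 2^x - 1}. p-values are BH-adjusted across genes.
#'
#' @param norm normalized matrix.
#' @param cells_a,cells_b disjoint cell-name (or index) sets, each >= 3.
#' @param pseudo pseudocount on the de-logged scale (default 1e-9).
#' @param exact_max largest group size for exact enumeration (default 8).
#' @param contrast optional label stored in the result.
#' @return data.frame: gene, log2fc, p_raw, p_adj, direction ("up"/"down"/
#'   "none"), contrast.
#' @export
de_rank_sum <- function(norm, cells_a, cells_b, pseudo = 1e-9, exact_max = 8,
                        contrast = "A_vs_B") {
  idx <- function(cells) {
    if (is.character(cells)) match(cells, colnames(norm)) else as.integer(cells)
  }
  ia <- idx(cells_a); ib <- idx(cells_b)
  if (anyNA(ia) || anyNA(ib)) stopf("some cells not found in the matrix")
  if (length(intersect(ia, ib))) stopf("cells_a and cells_b overlap")
  if (length(ia) < 3 || length(ib) < 3) stopf("each group needs at least 3 cells")
  a <- norm[, ia, drop = FALSE]
  b <- norm[, ib, drop = FALSE]
  na <- length(ia); nb <- length(ib)
  exact <- na <= exact_max && nb <= exact_max
  p <- numeric(nrow(norm))
  for (g in seq_len(nrow(norm))) {
    vals <- c(a[g, ], b[g, ])
    r <- rank(vals)
    ra <- r[seq_len(na)]
    p[g] <- if (exact) ranksum_exact_p(ra, r) else ranksum_normal_p(ra, r)
  }
  ea <- rowMeans(2^a - 1)
  eb <- rowMeans(2^b - 1)
  ratio <- (ea + pseudo) / (eb + pseudo)
  lfc <- ifelse(ratio > 0, log2(ratio), NA_real_)  # guards non-count input
  lfc[ea == eb] <- 0
  padj <- p.adjust(p, method = "BH")
  data.frame(gene = rownames(norm), log2fc = lfc, p_raw = p, p_adj = padj,
             direction = ifelse(lfc > 0, "up", ifelse(lfc < 0, "down", "none")),
             contrast = contrast, row.names = NULL)
}

#' Per-stratum differential expression against a reference stratum
#'
#' Convenience wrapper running [de_rank_sum()] for every non-reference stage
#' versus the reference.
#'
#' @param norm normalized matrix.
#' @param assign stratum assignment from [stratify_by_marker()] (or
#'   regrouped).
#' @param reference reference stage label (default the lowest populated
#'   stage).
#' @param min_cells minimum cells per stratum to run the contrast.
#' @param ... passed to [de_rank_sum()].
#' @return named list of DEG tables, one per non-reference stage, in stage
#'   order. Stages with too few cells are omitted with a warning.
#' @export
de_by_stage <- function(norm, assign, reference = NULL, min_cells = 3, ...) {
  levs <- levels(assign$stage)
  if (is.null(reference)) reference <- levs[1]
  if (!reference %in% levs) stopf("reference stage '%s' unknown", reference)
  ref_cells <- assign$cell[assign$stage == reference]
  if (length(ref_cells) < min_cells)
    stopf("reference stratum '%s' has fewer than %d cells", reference, min_cells)
  out <- list()
  for (st in setdiff(levs, reference)) {
    cells <- assign$cell[assign$stage == st]
    if (length(cells) < min_cells) {
      warnf("stratum '%s' has %d cells (< %d); contrast skipped", st, length(cells), min_cells)
      next
    }
    out[[st]] <- de_rank_sum(norm, cells, ref_cells,
                             contrast = paste0(st, "_vs_", reference), ...)
  }
  out
}

#' Classify transcription-factor onset stage and persistence
#'
#' For each TF, the onset is the earliest stage whose contrast against the
#' reference calls it significantly upregulated (p below \code{alpha} and
#' log2FC at least \code{min_lfc}); a TF is persistent when it stays
#' significantly up in every stage at or above its onset. The p-value gate
#' uses the BH-adjusted value by default; set \code{use_adjusted = FALSE}
#' for the permissive raw-p reading.
#'
#' @param degs_by_stage named list of DEG tables in increasing stage order
#'   (e.g. from [de_by_stage()]).
#' @param tf_list TFs to classify; genes absent from every table are listed
#'   in the \code{"skipped"} attribute rather than erroring.
#' @param alpha significance level (default 0.05).
#' @param min_lfc log2FC gate (default 1).
#' @param use_adjusted gate on \code{p_adj} (default) or \code{p_raw}.
#' @return data.frame sorted by onset stage then gene: gene, onset_stage
#'   (NA = never significant), persistent, and the per-stage significance
#'   matrix as attribute \code{"sig_matrix"}.
#' @export
classify_tf_onset <- function(degs_by_stage, tf_list, alpha = 0.05, min_lfc = 1,
                              use_adjusted = TRUE) {
  stages <- names(degs_by_stage)
  if (is.null(stages) || !length(stages)) stopf("degs_by_stage must be a named list")
  present <- tf_list[tf_list %in% unique(unlist(lapply(degs_by_stage, `[[`, "gene")))]
  skipped <- setdiff(tf_list, present)
  sig <- matrix(FALSE, nrow = length(present), ncol = length(stages),
                dimnames = list(present, stages))
  for (s in stages) {
    tab <- degs_by_stage[[s]]
    pv <- if (use_adjusted) tab$p_adj else tab$p_raw
    m <- match(present, tab$gene)
    ok <- !is.na(m)
    sig[present[ok], s] <- pv[m[ok]] < alpha & tab$log2fc[m[ok]] >= min_lfc
  }
  onset_idx <- apply(sig, 1, function(row) if (any(row)) which(row)[1] else NA_integer_)
  persistent <- vapply(seq_along(present), function(i) {
    if (is.na(onset_idx[i])) return(NA)
    all(sig[i, onset_idx[i]:length(stages)])
  }, logical(1))
  out <- data.frame(gene = present,
                    onset_stage = ifelse(is.na(onset_idx), NA_character_, stages[onset_idx]),
                    persistent = persistent, row.names = NULL)
  out <- out[order(ifelse(is.na(onset_idx), Inf, onset_idx), out$gene), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "sig_matrix") <- sig
  attr(out, "skipped") <- skipped
  out
}
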