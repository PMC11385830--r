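# Newton inversion of the trigamma function (for the prior-df moment match).
trigamma_inverse <- function(x) {
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2)
    y <- y + dif
    if (abs(dif / y) < 1e-8) break
  }
  y
}

# Moment-matching estimate of the scaled-F prior on gene variances:
# log s^2_g ~ log s0^2 + log F(d_g, d0) gives first two moments in terms of
# digamma/trigamma; solve for (d0, s0^2).
fit_f_dist <- function(s2, df) {
  ok <- s2 > 0 & is.finite(s2)
  z <- log(s2[ok])
  e <- z - digamma(df / 2) + log(df / 2)
  emean <- mean(e)
  evar <- var(e) - trigamma(df / 2)
  if (is.finite(evar) && evar > 0) {
    d0 <- 2 * trigamma_inverse(evar)
    s0 <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
  } else {
    d0 <- Inf
    s0 <- exp(emean)
  }
  list(df_prior = d0, var_prior = s0)
}

#' Empirical-Bayes moderated t-test for a two-group contrast
#'
#' Per-gene two-sample linear contrast on a (log-scale) expression matrix,
#' with residual variances shrunk toward a common prior:
#' \deqn{s^2_{post} = (d_0 s_0^2 + d_g s_g^2) / (d_0 + d_g)}
#' where the prior degrees of freedom \eqn{d_0} and prior variance
#' \eqn{s_0^2} are estimated by moment matching on the log sample variances
#' (scaled-F model). The moderated t is referred to a t-distribution on
#' \eqn{d_0 + d_g} degrees of freedom; p-values are BH-adjusted.
#'
#' @param expr genes x samples normalized (log-scale) matrix.
#' @param groups two-level factor over columns; log2FC is level2 - level1.
#' @param df_prior,var_prior optional fixed prior (sensitivity analyses and
#'   limit checks); both NULL (default) estimates them from the data.
#'   \code{df_prior = 0} reproduces the ordinary t exactly.
#' @return data.frame: gene, log2fc, t_ordinary, t_moderated, df_total,
#'   p_raw, p_adj; prior estimates as attributes \code{df_prior},
#'   \code{var_prior}.
#' @export
moderated_t_test <- function(expr, groups, df_prior = NULL, var_prior = NULL) {
  groups <- droplevels(factor(groups))
  if (nlevels(groups) != 2) stopf("exactly 2 groups required")
  i1 <- which(groups == levels(groups)[1]); i2 <- which(groups == levels(groups)[2])
  n1 <- length(i1); n2 <- length(i2)
  if (n1 < 2 || n2 < 2) stopf("at least 2 samples per group required")
  df_res <- n1 + n2 - 2
  m1 <- rowMeans(expr[, i1, drop = FALSE]); m2 <- rowMeans(expr[, i2, drop = FALSE])
  ss1 <- rowSums((expr[, i1, drop = FALSE] - m1)^2)
  ss2 <- rowSums((expr[, i2, drop = FALSE] - m2)^2)
  s2 <- (ss1 + ss2) / df_res
  fc <- m2 - m1
  sed_unit <- sqrt(1 / n1 + 1 / n2)
  t_ord <- fc / (sqrt(s2) * sed_unit)
  if (is.null(df_prior) || is.null(var_prior)) {
    prior <- fit_f_dist(s2, df_res)
    d0 <- if (is.null(df_prior)) prior$df_prior else df_prior
    s0 <- if (is.null(var_prior)) prior$var_prior else var_prior
  } else {
    d0 <- df_prior; s0 <- var_prior
  }
  s2_post <- if (is.infinite(d0)) rep(s0, length(s2)) else
    (d0 * s0 + df_res * s2) / (d0 + df_res)
  t_mod <- fc / (sqrt(s2_post) * sed_unit)
  df_tot <- min(d0 + df_res, 1e9)          # finite df for pt()
  p <- 2 * pt(-abs(t_mod), df = df_tot)
  data.frame(gene = rownames(expr), log2fc = fc, t_ordinary = t_ord,
             t_moderated = t_mod, df_total = df_tot, p_raw = p,
             p_adj = p.adjust(p, "BH"), row.names = NULL) |>
    structure(df_prior = d0, var_prior = s0)
}

#' Q3 (upper-quartile) normalization for DSP segment matrices
#'
#' Scales each AOI column so its 75th-percentile value equals the geometric
#' mean of the 75th percentiles across all AOIs (a scale-free anchor).
#' Positive scaling preserves within-AOI gene ranking.
#'
#' @param values genes x AOI matrix (non-negative).
#' @return matrix of the same shape; scale factors as attribute
#'   \code{"scale_factors"}.
#' @export
q3_normalize <- function(values) {
  q3 <- apply(values, 2, quantile, probs = 0.75, names = FALSE)
  if (any(q3 <= 0)) {
    bad <- colnames(values)[q3 <= 0]
    stopf("AOI(s) with non-positive 75th percentile: %s", paste(bad, collapse = ", "))
  }
  anchor <- exp(mean(log(q3)))
  f <- anchor / q3
  out <- sweep(values, 2, f, `*`)
  attr(out, "scale_factors") <- f
  out
}

#' Per-gene paired t-test between Vim+ and Vim- segments
#'
#' Transforms values (log2(x+1) by default), takes the within-ROI
#' vim_pos - vim_neg difference, and tests the mean difference across ROIs.
#' Genes with all-zero differences report t = 0, p = 1.
#'
#' @param values genes x AOI matrix.
#' @param aoi_info data.frame with columns \code{aoi}, \code{roi_id},
#'   \code{segment} (values \code{vim_pos}/\code{vim_neg}), one row per
#'   column of \code{values}.
#' @param transform function applied to values first (default
#'   \code{log2(x+1)}; use \code{identity} for pre-logged input).
#' @return data.frame: gene, mean_diff, t, p_raw, p_adj.
#' @export
paired_t_per_gene <- function(values, aoi_info, transform = function(x) log2(x + 1)) {
  if (anyDuplicated(aoi_info$roi_id[aoi_info$segment == "vim_pos"]))
    stopf("duplicate vim_pos segment for an ROI")
  rois <- unique(aoi_info$roi_id)
  pos <- match(paste0(rois, ".vim_pos"), paste0(aoi_info$roi_id, ".", aoi_info$segment))
  neg <- match(paste0(rois, ".vim_neg"), paste0(aoi_info$roi_id, ".", aoi_info$segment))
  if (anyNA(pos) || anyNA(neg)) {
    bad <- rois[is.na(pos) | is.na(neg)]
    stopf("ROI(s) missing a segment: %s", paste(bad, collapse = ", "))
  }
  if (length(rois) < 3) stopf("at least 3 complete ROI pairs required")
  x <- transform(values)
  d <- x[, pos, drop = FALSE] - x[, neg, drop = FALSE]
  n <- length(rois)
  md <- rowMeans(d)
  sdd <- apply(d, 1, sd)
  t <- ifelse(sdd > 0, md / (sdd / sqrt(n)), 0)
  p <- ifelse(sdd > 0, 2 * pt(-abs(t), df = n - 1), 1)
  data.frame(gene = rownames(values), mean_diff = md, t = t, p_raw = p,
             p_adj = p.adjust(p, "BH"), row.names = NULL)
}

# Weighted KS enrichment score of a set over a ranked metric (exponent 1 by
# default). Returns the signed extreme deviation of the running sum.
gsea_es <- function(metric_sorted, in_set, exponent = 1) {
  w <- abs(metric_sorted)^exponent * in_set
  sw <- sum(w)
  n_out <- length(in_set) - sum(in_set)
  if (sw == 0 || n_out == 0) return(0)
  run <- cumsum(w) / sw - cumsum(!in_set) / n_out
  run[which.max(abs(run))]
}

#' Preranked gene-set enrichment analysis
#'
#' Weighted Kolmogorov-Smirnov running-sum enrichment (weight =
#' |metric|^exponent, exponent 1) on a signed per-gene ranking metric. The
#' null is generated by gene-label permutation (random same-size sets);
#' NES = ES divided by the mean |permuted ES| of matching sign; nominal p is
#' the same-sign permutation tail with the +1 correction; FDR q compares the
#' pooled sign-matched permutation NES distribution to the observed NES, as
#' in the standard preranked procedure.
#'
#' @param metric named numeric vector (gene-level signed statistic).
#' @param sets named list of gene sets.
#' @param n_perm permutations (default 1000).
#' @param exponent KS weight exponent (default 1; 0 = classic unweighted KS).
#' @param min_genes sets matched by fewer genes are skipped (default 5).
#' @param seed RNG seed.
#' @return data.frame: set, size, es, nes, p, q, leading_edge (semicolon
#'   separated), sorted by nes descending.
#' @export
preranked_gsea <- function(metric, sets, n_perm = 1000, exponent = 1,
                           min_genes = 5, seed = 1L) {
  if (length(metric) < 10) stopf("ranking needs at least 10 genes")
  if (is.null(names(metric))) stopf("metric must be a named vector")
  metric <- metric[is.finite(metric)]
  ord <- order(-metric, names(metric))
  ms <- metric[ord]
  genes <- names(ms)
  n <- length(genes)
  matched <- lapply(sets, function(s) intersect(s, genes))
  keep <- names(sets)[lengths(matched) >= min_genes]
  skipped <- setdiff(names(sets), keep)
  if (length(skipped))
    warnf("skipping set(s) with < %d matched genes: %s", min_genes,
          paste(skipped, collapse = ", "))
  if (!length(keep)) stopf("no testable gene sets")

  res <- with_seed(seed, {
    rows <- list()
    perm_nes_pool <- numeric()
    obs <- list()
    for (nm in keep) {
      flag <- genes %in% matched[[nm]]
      es <- gsea_es(ms, flag, exponent)
      size <- sum(flag)
      perm_es <- vapply(seq_len(n_perm), function(i) {
        f <- logical(n); f[sample.int(n, size)] <- TRUE
        gsea_es(ms, f, exponent)
      }, numeric(1))
      pos <- perm_es[perm_es >= 0]; neg <- perm_es[perm_es < 0]
      norm_of <- function(e) {
        if (e >= 0) e / max(mean(pos), .Machine$double.eps)
        else e / max(mean(abs(neg)), .Machine$double.eps)
      }
      nes <- norm_of(es)
      p <- if (es >= 0) (1 + sum(pos >= es)) / (1 + length(pos))
           else (1 + sum(neg <= es)) / (1 + length(neg))
      perm_nes <- vapply(perm_es, norm_of, numeric(1))
      perm_nes_pool <- c(perm_nes_pool, perm_nes)
      # leading edge: genes up to (and including) the running-sum extremum
      w <- abs(ms)^exponent * flag
      run <- cumsum(w) / sum(w) - cumsum(!flag) / (n - size)
      peak <- which.max(abs(run))
      le <- if (es >= 0) genes[seq_len(peak)][flag[seq_len(peak)]] else
        genes[peak:n][flag[peak:n]]
      obs[[nm]] <- list(es = es, nes = nes, p = p, size = size,
                        le = paste(le, collapse = ";"))
    }
    obs_nes <- vapply(obs, `[[`, numeric(1), "nes")
    q <- vapply(names(obs), function(nm) {
      nes <- obs[[nm]]$nes
      if (nes >= 0) {
        num <- mean(perm_nes_pool >= nes)
        den <- mean(obs_nes >= nes)
      } else {
        num <- mean(perm_nes_pool <= nes)
        den <- mean(obs_nes <= nes)
      }
      min(1, num / max(den, .Machine$double.eps))
    }, numeric(1))
    data.frame(set = names(obs),
               size = vapply(obs, `[[`, numeric(1), "size"),
               es = vapply(obs, `[[`, numeric(1), "es"),
               nes = obs_nes,
               p = vapply(obs, `[[`, numeric(1), "p"),
               q = q,
               leading_edge = vapply(obs, `[[`, character(1), "le"),
               row.names = NULL)
  })
  res <- res[order(-res$nes, res$set), , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "n_perm") <- n_perm
  attr(res, "seed") <- seed
  attr(res, "skipped") <- skipped
  res
}

#' Signed ranking metric from a paired t-test table
#'
#' The default DSP ranking for preranked GSEA:
#' \eqn{-\log_{10}(p_{raw}) \cdot sign(mean\ difference)}. Zero-variance
#' genes (p exactly 1 with zero difference) are excluded with a report.
#'
#' @param paired_t output of [paired_t_per_gene()].
#' @return named numeric metric; excluded genes as attribute
#'   \code{"excluded"}.
#' @export
ranking_from_paired_t <- function(paired_t) {
  excl <- paired_t$gene[paired_t$t == 0 & paired_t$mean_diff == 0]
  tab <- paired_t[!paired_t$gene %in% excl, , drop = FALSE]
  m <- -log10(pmax(tab$p_raw, 1e-300)) * sign(tab$mean_diff)
  names(m) <- tab$gene
  attr(m, "excluded") <- excl
  m
}

#' Average-linkage hierarchical clustering on correlation distance
#'
#' Distance = 1 - Pearson correlation between columns; agglomeration by
#' average linkage. Used for heatmap column ordering.
#'
#' @param mat genes x samples matrix.
#' @return an \code{hclust} object (labels = column names).
#' @export
hier_cluster <- function(mat) {
  if (ncol(mat) < 2) stopf("at least 2 columns required")
  sds <- apply(mat, 2, sd)
  if (any(sds == 0))
    stopf("constant column(s) have undefined correlation: %s",
          paste(colnames(mat)[sds == 0], collapse = ", "))
  d <- stats::as.dist(1 - cor(mat))
  stats::hclust(d, method = "average")
}
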