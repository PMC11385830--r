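test_that("trigamma inverse inverts trigamma over the useful range", {
  for (y in c(0.05, 0.5, 2, 10, 200)) {
    expect_equal(emtstage:::trigamma_inverse(trigamma(y)), y, tolerance = 1e-6)
  }
})

test_that("prior moment matching recovers a planted scaled-F model", {
  set.seed(21)
  d0 <- 8; s0 <- 0.5; dg <- 4
  s2 <- s0 * stats::rf(20000, dg, d0) # s^2_g ~ s0^2 * F(d_g, d0)
  fit <- emtstage:::fit_f_dist(s2, dg)
  expect_equal(fit$df_prior, d0, tolerance = 0.5)
  expect_equal(fit$var_prior, s0, tolerance = 0.05)
})

test_that("posterior variance follows the shrinkage formula on a 3v3 toy", {
  set.seed(22)
  # heterogeneous gene variances so the estimated prior df is finite
  expr <- toy_norm(matrix(rnorm(60, 5), 10, 6) * seq(0.2, 3, length.out = 10))
  groups <- factor(rep(c("E", "M"), each = 3))
  res <- moderated_t_test(expr, groups)
  d0 <- attr(res, "df_prior"); s0 <- attr(res, "var_prior")
  # recompute the ingredients by hand
  s2 <- apply(expr, 1, function(v) (sum((v[1:3] - mean(v[1:3]))^2) +
                                      sum((v[4:6] - mean(v[4:6]))^2)) / 4)
  fc <- rowMeans(expr[, 4:6]) - rowMeans(expr[, 1:3])
  s2_post <- (d0 * s0 + 4 * s2) / (d0 + 4)
  t_hand <- fc / sqrt(s2_post * (1 / 3 + 1 / 3))
  expect_equal(res$t_moderated, unname(t_hand), tolerance = 1e-12)
  # s2_post lies between the prior and sample variance for every gene
  expect_true(all(s2_post >= pmin(s0, s2) - 1e-12 & s2_post <= pmax(s0, s2) + 1e-12))
})

test_that("prior df limits: 0 recovers ordinary t, Inf gives the pooled z", {
  set.seed(23)
  expr <- toy_norm(matrix(rnorm(120, 3), 20, 6))
  groups <- factor(rep(c("A", "B"), each = 3))
  r0 <- moderated_t_test(expr, groups, df_prior = 0, var_prior = 1)
  expect_equal(r0$t_moderated, r0$t_ordinary, tolerance = 1e-12)
  rInf <- moderated_t_test(expr, groups, df_prior = Inf, var_prior = 0.7)
  fc <- rowMeans(expr[, 4:6]) - rowMeans(expr[, 1:3])
  expect_equal(rInf$t_moderated, unname(fc / sqrt(0.7 * (2 / 3))), tolerance = 1e-12)
})

test_that("moderated t agrees with the limma reference implementation", {
  skip_if_not_installed("limma")
  set.seed(24)
  sim <- simulate_bulk_groups(n_per_group = 3, n_genes = 400, de_fraction = 0.1,
                              effect_log2fc = 1.5, seed = 24)
  norm <- log2(1 + sweep(sim$counts, 2, 1e6 / colSums(sim$counts), `*`))
  res <- moderated_t_test(norm, sim$groups)
  design <- cbind(1, as.numeric(sim$groups == "M"))
  fit <- limma::eBayes(limma::lmFit(norm, design))
  expect_equal(attr(res, "df_prior"), fit$df.prior, tolerance = 1e-6)
  expect_equal(attr(res, "var_prior"), fit$s2.prior, tolerance = 1e-6)
  expect_equal(res$t_moderated, unname(fit$t[, 2]), tolerance = 1e-8)
  expect_equal(res$p_raw, unname(fit$p.value[, 2]), tolerance = 1e-8)
})

test_that("Q3 normalization anchors to the geometric mean of quartiles", {
  set.seed(25)
  base <- matrix(rexp(200, 0.1), 100, 2, dimnames = list(paste0("g", 1:100),
                                                         c("a1", "a2")))
  base[, 2] <- base[, 1] * 2                   # one AOI exactly 2x the other
  out <- q3_normalize(base)
  f <- attr(out, "scale_factors")
  expect_equal(unname(f), c(sqrt(2), 1 / sqrt(2)), tolerance = 1e-12)
  expect_equal(out[, 1], out[, 2], ignore_attr = TRUE)
  # identical AOIs get unit factors; ranking within AOI preserved
  same <- cbind(base[, 1], base[, 1])
  colnames(same) <- c("a1", "a2")
  expect_equal(unname(attr(q3_normalize(same), "scale_factors")), c(1, 1))
  expect_identical(order(out[, 1]), order(base[, 1]))
  zero <- base; zero[, 1] <- 0
  expect_error(q3_normalize(zero), "non-positive")
})

test_that("paired t: hand arithmetic, zero differences, sign flip", {
  rois <- data.frame(aoi = paste0("R", rep(1:4, each = 2), "|",
                                  rep(c("vim_pos", "vim_neg"), 4)),
                     roi_id = paste0("R", rep(1:4, each = 2)),
                     segment = rep(c("vim_pos", "vim_neg"), 4))
  # gene with log2 differences (1, 2, 1, 2)
  neg <- matrix(2, 1, 4); pos <- 2 + c(1, 2, 1, 2)
  vals <- matrix(0, 1, 8, dimnames = list("g1", rois$aoi))
  vals[1, seq(1, 8, 2)] <- 2^pos - 1
  vals[1, seq(2, 8, 2)] <- 2^2 - 1
  res <- paired_t_per_gene(vals, rois)
  d <- c(1, 2, 1, 2)
  expect_equal(res$t, mean(d) / (sd(d) / 2), tolerance = 1e-12)
  # identical segments: t = 0, p = 1
  same <- matrix(5, 2, 8, dimnames = list(c("g1", "g2"), rois$aoi))
  res0 <- paired_t_per_gene(same, rois)
  expect_true(all(res0$t == 0 & res0$p_raw == 1))
  # swapping segment labels negates t exactly
  rois_fl <- rois
  rois_fl$segment <- ifelse(rois$segment == "vim_pos", "vim_neg", "vim_pos")
  res_fl <- paired_t_per_gene(vals, rois_fl)
  expect_equal(res_fl$t, -res$t, tolerance = 1e-12)
  # unpaired AOI errors naming the ROI
  expect_error(paired_t_per_gene(vals[, -2, drop = FALSE], rois[-2, ]), "R1")
})

test_that("injected DSP effect enriches EMT genes among small p-values", {
  dsp <- simulate_dsp_rois(n_rois = 9, n_genes = 400,
                           emt_genes = paste0("EMT", 1:50),
                           effect_log2fc = 1.5, seed = 26)
  vals <- q3_normalize(dsp$values)
  pt_tab <- paired_t_per_gene(vals, dsp$aoi_info)
  emt_rank <- rank(pt_tab$p_raw)[dsp$truth$is_emt]
  expect_lt(median(emt_rank), 60)       # injected genes dominate the top
})

test_that("preranked GSEA: extreme set, antisymmetry, null behavior", {
  set.seed(27)
  metric <- setNames(sort(rnorm(100), decreasing = TRUE), paste0("g", 1:100))
  res <- preranked_gsea(metric, list(top = paste0("g", 1:5)), n_perm = 1000,
                        seed = 1)
  expect_gt(res$es, 0)
  expect_gt(res$nes, 0)
  expect_lte(res$p, 0.01)
  # unweighted ES of a set equals -ES of its complement
  in_set <- names(metric) %in% paste0("g", 1:30)
  es_a <- emtstage:::gsea_es(metric, in_set, exponent = 0)
  es_b <- emtstage:::gsea_es(metric, !in_set, exponent = 0)
  expect_equal(es_a, -es_b, tolerance = 1e-12)
  # random sets under a random ranking are collectively unremarkable
  set.seed(28)
  rnd_metric <- setNames(rnorm(200), paste0("g", 1:200))
  rnd_sets <- lapply(1:20, function(i) sample(names(rnd_metric), 15))
  names(rnd_sets) <- paste0("rand", 1:20)
  rnd <- preranked_gsea(rnd_metric, rnd_sets, n_perm = 300, seed = 2)
  expect_gt(median(rnd$p), 0.2)
  expect_gt(median(rnd$q), 0.2)
  # determinism and skipping small sets
  res2 <- preranked_gsea(metric, list(top = paste0("g", 1:5)), n_perm = 1000,
                         seed = 1)
  expect_equal(res$nes, res2$nes, tolerance = 1e-15)
  expect_warning(
    mixed <- preranked_gsea(metric, list(small = "g1", top = paste0("g", 1:5)),
                            n_perm = 100, seed = 3),
    "skipping")
  expect_identical(attr(mixed, "skipped"), "small")
})

test_that("paired-t ranking metric is signed -log10 p with exclusions", {
  tab <- data.frame(gene = c("a", "b", "c"), mean_diff = c(1, -1, 0),
                    t = c(2, -2, 0), p_raw = c(0.01, 0.01, 1),
                    p_adj = c(0.03, 0.03, 1))
  m <- ranking_from_paired_t(tab)
  expect_equal(unname(m), c(2, -2), ignore_attr = TRUE)
  expect_identical(attr(m, "excluded"), "c")
})

test_that("average-linkage correlation clustering matches a manual trace", {
  # four columns engineered so the merge order is unambiguous
  set.seed(29)
  base1 <- rnorm(30); base2 <- rnorm(30)
  mat <- cbind(s1 = base1, s2 = base1 + rnorm(30, 0, 0.1),
               s3 = base2, s4 = base2 + rnorm(30, 0, 0.4))
  hc <- hier_cluster(mat)
  # manual average-linkage on the 1 - cor distance matrix
  d <- 1 - cor(mat)
  # first merge: smallest off-diagonal distance (s1, s2)
  expect_equal(sort(hc$labels[-hc$merge[1, ]]), c("s1", "s2"))
  expect_equal(hc$height[1], d["s1", "s2"], tolerance = 1e-12)
  # second merge: (s3, s4); final height = average of the 4 cross distances
  expect_equal(hc$height[2], d["s3", "s4"], tolerance = 1e-12)
  cross <- mean(d[c("s1", "s2"), c("s3", "s4")])
  expect_equal(hc$height[3], cross, tolerance = 1e-12)
  # duplicated column groups split at the root
  expect_equal(sort(stats::cutree(hc, 2)), sort(setNames(c(1, 1, 2, 2),
                                                         c("s1", "s2", "s3", "s4"))))
  const <- mat; const[, 2] <- 3
  expect_error(hier_cluster(const), "s2")
})

test_that("simulated Vim+/Vim- segments cluster by segment after centering", {
  dsp <- simulate_dsp_rois(n_rois = 6, n_genes = 300, effect_log2fc = 2,
                           roi_sd = 0.2, seed = 30)
  x <- log2(1 + q3_normalize(dsp$values))
  hc <- hier_cluster(x - rowMeans(x))
  groups <- stats::cutree(hc, 2)
  seg <- dsp$aoi_info$segment[match(names(groups), dsp$aoi_info$aoi)]
  expect_equal(adjusted_rand(groups, seg), 1)
})
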