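#' Configuration for the synthetic EMT-continuum generator
#'
#' Builds and validates the parameter set for [simulate_emt_continuum()].
#' Each cell carries a latent EMT coordinate \eqn{u \in [0,1]}. The
#' mesenchymal marker (default \code{VIM}) has mean log2 expression
#' \code{marker_slope * u} (rising 0 to 6 by default), while epithelial
#' markers (\code{CDH1}, \code{EPCAM}) fall as \code{marker_slope * (1-u)}.
#' Transcription factors switch on as a persistent step: gene \eqn{g} with
#' onset \eqn{o_g} and amplitude \eqn{a_g} has mean log2 expression
#' \eqn{b_g + a_g \cdot 1[u \ge o_g]}. Counts are negative binomial with
#' dispersion \code{nb_dispersion} (\eqn{\theta}), parameterized so that
#' \eqn{Var = \mu + \mu^2/\theta}; cell size factors are lognormal.
#'
#' @param n_cells number of (non-outlier) cells to simulate.
#' @param n_genes total number of genes, including markers, TFs and the
#'   mitochondrial block.
#' @param latent latent distribution for \eqn{u}: \code{"uniform"} populates
#'   all strata evenly; \code{"mixture"} draws an epithelial/mesenchymal
#'   two-component mixture (Beta(2,8) / Beta(8,2)).
#' @param mixture_prop mesenchymal component weight when
#'   \code{latent = "mixture"}.
#' @param marker_gene name of the rising mesenchymal marker.
#' @param marker_slope slope of the marker mean log2 expression in \eqn{u};
#'   the default 6 spans the six unit-width staging bins.
#' @param epithelial_markers genes whose mean log2 expression falls as
#'   \code{marker_slope * (1 - u)}.
#' @param tf_onsets named list; each element \code{list(onset=, amplitude=)}
#'   with onset in (0,1) and amplitude \eqn{\ge 0} in log2 units.
#' @param tf_shape \code{"step"} (default; once on, stays on) or
#'   \code{"sigmoid"} (logistic ramp of steepness \code{sigmoid_steepness}).
#' @param sigmoid_steepness logistic slope when \code{tf_shape="sigmoid"}.
#' @param tf_baseline baseline mean log2 expression \eqn{b_g} for TF genes.
#' @param nb_dispersion NB dispersion \eqn{\theta > 0} (larger = less noise).
#' @param libsize_sigma lognormal sdlog of per-cell size factors.
#' @param mito_fraction target mean mitochondrial count proportion.
#' @param mito_gene_frac fraction of genes placed in the annotated
#'   mitochondrial block (named \code{MT-<i>}).
#' @param n_outlier_cells cells injected with QC-failing profiles (tiny
#'   libraries; half additionally mito-inflated).
#' @param seed integer RNG seed.
#' @return an object of class \code{emt_sim_config}.
#' @export
emt_sim_config <- function(n_cells = 3000, n_genes = 2000,
                           latent = c("uniform", "mixture"),
                           mixture_prop = 0.5,
                           marker_gene = "VIM", marker_slope = 6,
                           epithelial_markers = c("CDH1", "EPCAM"),
                           tf_onsets = list(),
                           tf_shape = c("step", "sigmoid"),
                           sigmoid_steepness = 30,
                           tf_baseline = 1.5,
                           nb_dispersion = 10, libsize_sigma = 0.3,
                           mito_fraction = 0.05, mito_gene_frac = 0.05,
                           n_outlier_cells = 0, seed = 1L) {
  latent <- match.arg(latent)
  tf_shape <- match.arg(tf_shape)
  if (!is_count(n_cells) || n_cells < 1) stopf("n_cells must be a positive count")
  if (!is_count(n_genes)) stopf("n_genes must be a count")
  if (nb_dispersion <= 0) stopf("nb_dispersion (theta) must be > 0")
  if (libsize_sigma < 0) stopf("libsize_sigma must be >= 0")
  if (mito_fraction < 0 || mito_fraction >= 1) stopf("mito_fraction must be in [0,1)")
  if (marker_slope < 0) stopf("marker means must be non-negative: marker_slope >= 0")
  if (length(tf_onsets)) {
    if (is.null(names(tf_onsets)) || anyDuplicated(names(tf_onsets)))
      stopf("tf_onsets must be a uniquely named list")
    for (g in names(tf_onsets)) {
      o <- tf_onsets[[g]]$onset; a <- tf_onsets[[g]]$amplitude
      if (is.null(o) || o <= 0 || o >= 1)
        stopf("onset for %s must lie in (0,1)", g)
      if (is.null(a) || a < 0) stopf("amplitude for %s must be >= 0", g)
    }
  }
  n_mito <- round(mito_gene_frac * n_genes)
  n_named <- 1L + length(epithelial_markers) + length(tf_onsets) + n_mito
  if (n_genes < n_named + 10)
    stopf("n_genes = %d cannot accommodate %d named genes (markers, TFs, mito block) plus background",
          n_genes, n_named)
  structure(list(
    n_cells = as.integer(n_cells), n_genes = as.integer(n_genes),
    latent = latent, mixture_prop = mixture_prop,
    marker_gene = marker_gene, marker_slope = marker_slope,
    epithelial_markers = epithelial_markers,
    tf_onsets = tf_onsets, tf_shape = tf_shape,
    sigmoid_steepness = sigmoid_steepness, tf_baseline = tf_baseline,
    nb_dispersion = nb_dispersion, libsize_sigma = libsize_sigma,
    mito_fraction = mito_fraction, n_mito = as.integer(n_mito),
    n_outlier_cells = as.integer(n_outlier_cells), seed = as.integer(seed)
  ), class = "emt_sim_config")
}

# TF activation profile on the log2 scale for latent coordinate u.
tf_activation <- function(u, onset, amplitude, shape, steepness) {
  if (shape == "step") amplitude * as.numeric(u >= onset)
  else amplitude / (1 + exp(-steepness * (u - onset)))
}

# Map a latent onset threshold through the linear marker profile into the
# ordinal stage bin ((a, b], unit width, clamped to [1, n_bins]).
onset_to_stage <- function(onset, marker_slope, n_bins = 6) {
  m <- marker_slope * onset
  as.integer(min(n_bins, max(1, ceiling(m))))
}

stage_labels <- function(n_bins = 6, prefix = "VIM") {
  paste0(prefix, " ", seq_len(n_bins) - 1L, "-", seq_len(n_bins))
}

#' Simulate a single-cell EMT continuum with ground truth
#'
#' Draws cells along a latent EMT axis and genes as negative binomial counts
#' whose per-cell means follow the configured log2 profiles (see
#' [emt_sim_config()]). The background gene block is scaled so a typical cell
#' totals about 1e4 counts; on the log2 CP10K scale of [normalize_log()] the
#' marker's normalized expression therefore tracks its configured mean, which
#' is what anchors the latent onsets to observable staging bins.
#'
#' @param config an [emt_sim_config()] object.
#' @return list with \code{counts} (sparse genes x cells dgCMatrix),
#'   \code{gene_info} (gene, type, is_mito), \code{cell_info}
#'   (barcode, u, is_outlier), and \code{truth} — per-cell latent \code{u} and
#'   a TF table (gene, onset, amplitude, onset_stage index and label; non-TF
#'   genes have no onset).
#' @export
simulate_emt_continuum <- function(config) {
  stopifnot(inherits(config, "emt_sim_config"))
  cfg <- config
  with_seed(cfg$seed, {
    n_tot <- cfg$n_cells + cfg$n_outlier_cells
    u <- if (cfg$latent == "uniform") runif(n_tot) else {
      comp <- rbinom(n_tot, 1, cfg$mixture_prop)
      ifelse(comp == 1, stats::rbeta(n_tot, 8, 2), stats::rbeta(n_tot, 2, 8))
    }
    tf_genes <- names(cfg$tf_onsets)
    mito_genes <- if (cfg$n_mito > 0) paste0("MT-", seq_len(cfg$n_mito)) else character()
    named <- c(cfg$marker_gene, cfg$epithelial_markers, tf_genes, mito_genes)
    n_bg <- cfg$n_genes - length(named)
    bg_genes <- paste0("GENE", formatC(seq_len(n_bg), width = 5, flag = "0"))
    genes <- c(named, bg_genes)

    # background baseline log2 means; scaled so a typical cell sums to ~1e4
    bg_mu <- runif(n_bg, 1, 3.5)
    bg_expr <- 2^bg_mu - 1
    target_bg <- 1e4 * (1 - cfg$mito_fraction) - sum(2^(cfg$marker_slope * 0.5) - 1) -
      length(cfg$epithelial_markers) * (2^(cfg$marker_slope * 0.5) - 1) -
      length(tf_genes) * (2^cfg$tf_baseline - 1)
    bg_expr <- bg_expr * max(target_bg, 1e3) / sum(bg_expr)
    mito_expr <- if (cfg$n_mito > 0) {
      tot <- 1e4 * cfg$mito_fraction
      w <- runif(cfg$n_mito, 0.5, 1.5)
      tot * w / sum(w)
    } else numeric()

    # per-gene x per-cell mean matrix (linear scale, before size factors)
    mu <- matrix(0, nrow = cfg$n_genes, ncol = n_tot, dimnames = list(genes, NULL))
    mu[cfg$marker_gene, ] <- 2^(cfg$marker_slope * u) - 1
    for (g in cfg$epithelial_markers) mu[g, ] <- 2^(cfg$marker_slope * (1 - u)) - 1
    for (g in tf_genes) {
      act <- tf_activation(u, cfg$tf_onsets[[g]]$onset, cfg$tf_onsets[[g]]$amplitude,
                           cfg$tf_shape, cfg$sigmoid_steepness)
      mu[g, ] <- 2^(cfg$tf_baseline + act) - 1
    }
    if (cfg$n_mito > 0) mu[mito_genes, ] <- matrix(mito_expr, cfg$n_mito, n_tot)
    mu[bg_genes, ] <- matrix(bg_expr, n_bg, n_tot)

    s <- exp(rnorm(n_tot, 0, cfg$libsize_sigma))
    is_outlier <- rep(FALSE, n_tot)
    if (cfg$n_outlier_cells > 0) {
      idx <- cfg$n_cells + seq_len(cfg$n_outlier_cells)
      is_outlier[idx] <- TRUE
      s[idx] <- s[idx] * 0.02            # tiny libraries: fail size/detection QC
      half <- idx[seq_len(ceiling(length(idx) / 2))]
      if (cfg$n_mito > 0) mu[mito_genes, half] <- mu[mito_genes, half] * 40
    }
    mu <- sweep(mu, 2, s, `*`)
    counts <- matrix(rnbinom(length(mu), size = cfg$nb_dispersion, mu = as.vector(mu)),
                     nrow = cfg$n_genes, dimnames = list(genes, NULL))
    colnames(counts) <- paste0("CELL", formatC(seq_len(n_tot), width = 5, flag = "0"))

    tf_table <- if (length(tf_genes)) {
      data.frame(
        gene = tf_genes,
        onset = vapply(cfg$tf_onsets, function(x) x$onset, numeric(1)),
        amplitude = vapply(cfg$tf_onsets, function(x) x$amplitude, numeric(1)),
        onset_stage = vapply(cfg$tf_onsets, function(x)
          onset_to_stage(x$onset, cfg$marker_slope), integer(1)),
        row.names = NULL
      )
    } else data.frame(gene = character(), onset = numeric(),
                      amplitude = numeric(), onset_stage = integer())
    if (nrow(tf_table))
      tf_table$onset_stage_label <- stage_labels()[tf_table$onset_stage]

    list(
      counts = methods::as(Matrix::Matrix(counts, sparse = TRUE), "CsparseMatrix"),
      gene_info = data.frame(
        gene = genes,
        type = c("marker_mes", rep("marker_epi", length(cfg$epithelial_markers)),
                 rep("tf", length(tf_genes)), rep("mito", length(mito_genes)),
                 rep("background", n_bg)),
        is_mito = genes %in% mito_genes
      ),
      cell_info = data.frame(barcode = colnames(counts), u = u, is_outlier = is_outlier),
      truth = list(u = u, tf_table = tf_table, config = cfg)
    )
  })
}

#' Simulate two bulk expression groups with planted differential expression
#'
#' Emulates a small epithelial-vs-mesenchymal bulk RNA-seq design: two labeled
#' groups of negative binomial count columns in which a fraction of genes is
#' shifted by \code{effect_log2fc} in group M.
#'
#' @param n_per_group samples per group (>= 2; two residual df are needed for
#'   a per-gene variance).
#' @param n_genes number of genes.
#' @param de_fraction fraction of genes truly differential in group M.
#' @param effect_log2fc log2 fold change applied to the DE genes.
#' @param nb_dispersion NB dispersion theta.
#' @param seed RNG seed.
#' @return list with \code{counts} (genes x samples), \code{groups}
#'   (factor E/M), and \code{truth$is_de}.
#' @export
simulate_bulk_groups <- function(n_per_group = 3, n_genes = 2000,
                                 de_fraction = 0.1, effect_log2fc = 2,
                                 nb_dispersion = 10, seed = 1L) {
  if (!is_count(n_per_group) || n_per_group < 2)
    stopf("n_per_group must be >= 2 (at least one residual degree of freedom per group)")
  if (de_fraction < 0 || de_fraction > 1) stopf("de_fraction must be in [0,1]")
  with_seed(seed, {
    genes <- paste0("GENE", formatC(seq_len(n_genes), width = 5, flag = "0"))
    base_mu <- 2^runif(n_genes, 3, 9)
    is_de <- rep(FALSE, n_genes)
    if (de_fraction > 0) is_de[sample.int(n_genes, round(de_fraction * n_genes))] <- TRUE
    mu_e <- matrix(base_mu, n_genes, n_per_group)
    mu_m <- matrix(base_mu * ifelse(is_de, 2^effect_log2fc, 1), n_genes, n_per_group)
    mu <- cbind(mu_e, mu_m)
    counts <- matrix(rnbinom(length(mu), size = nb_dispersion, mu = as.vector(mu)),
                     nrow = n_genes,
                     dimnames = list(genes, c(paste0("E", seq_len(n_per_group)),
                                              paste0("M", seq_len(n_per_group)))))
    list(counts = counts,
         groups = factor(rep(c("E", "M"), each = n_per_group), levels = c("E", "M")),
         truth = list(is_de = is_de, effect_log2fc = effect_log2fc))
  })
}

#' Simulate a survival cohort whose hazard depends on a signature activity
#'
#' Each sample carries a latent signature activity \eqn{z \sim N(0,1)};
#' signature genes are shifted by \eqn{z} on the log2 scale, and event times
#' are exponential with hazard \eqn{\lambda_0 \exp(\beta_{true} z)}.
#' Censoring is independent exponential tuned to the requested rate.
#'
#' @param n samples (>= 20).
#' @param signature_genes character vector of signature gene names.
#' @param beta_true true log hazard ratio per unit of \eqn{z}.
#' @param censor_rate target fraction censored, in [0,1).
#' @param n_genes total genes (signature plus background).
#' @param base_hazard baseline exponential hazard.
#' @param nb_dispersion NB dispersion for the expression counts.
#' @param seed RNG seed.
#' @return list with \code{counts}, \code{cohort} (sample, time, event, z),
#'   and \code{truth} (beta_true, z).
#' @export
simulate_survival_cohort <- function(n = 400, signature_genes = paste0("SIG", 1:25),
                                     beta_true = 1, censor_rate = 0.3,
                                     n_genes = 500, base_hazard = 0.1,
                                     nb_dispersion = 10, seed = 1L) {
  if (!is_count(n) || n < 20) stopf("n must be a count >= 20")
  if (censor_rate < 0 || censor_rate >= 1) stopf("censor_rate must be in [0,1)")
  if (n_genes < length(signature_genes) + 10)
    stopf("n_genes too small for %d signature genes", length(signature_genes))
  with_seed(seed, {
    z <- rnorm(n)
    n_bg <- n_genes - length(signature_genes)
    genes <- c(signature_genes, paste0("BG", formatC(seq_len(n_bg), width = 5, flag = "0")))
    base_mu_log2 <- runif(n_genes, 3, 8)
    shift <- rbind(matrix(rep(z, each = length(signature_genes)),
                          nrow = length(signature_genes)),
                   matrix(0, n_bg, n))
    mu <- 2^(base_mu_log2 + shift)
    counts <- matrix(rnbinom(length(mu), size = nb_dispersion, mu = as.vector(mu)),
                     nrow = n_genes,
                     dimnames = list(genes, paste0("S", formatC(seq_len(n), width = 4, flag = "0"))))
    t_event <- rexp(n, rate = base_hazard * exp(beta_true * z))
    if (censor_rate > 0) {
      # exponential censoring; rate solved so the expected censored fraction
      # over the realized hazards equals censor_rate
      haz <- base_hazard * exp(beta_true * z)
      lam_c <- stats::uniroot(function(lc) mean(lc / (lc + haz)) - censor_rate,
                              lower = 1e-10, upper = 1e6 * base_hazard,
                              tol = 1e-10)$root
      t_cens <- rexp(n, rate = lam_c)
    } else t_cens <- rep(Inf, n)
    time <- pmin(t_event, t_cens)
    event <- as.integer(t_event <= t_cens)
    list(counts = counts,
         cohort = data.frame(sample = colnames(counts), time = time, event = event, z = z),
         truth = list(beta_true = beta_true, z = z))
  })
}

#' Simulate paired Vim+/Vim- spatial profiling segments
#'
#' For each region of interest (ROI) two segment columns (vim_pos, vim_neg)
#' share a lognormal ROI random effect; the designated EMT genes are elevated
#' by \code{effect_log2fc} in the vim_pos segment. Values are continuous
#' non-negative normalized counts \eqn{2^x - 1} where \eqn{x} is the log2
#' signal, so setting all noise components to zero yields exactly paired
#' columns.
#'
#' @param n_rois number of ROIs (>= 3).
#' @param n_genes total genes.
#' @param emt_genes genes elevated in vim_pos segments.
#' @param effect_log2fc elevation in log2 units.
#' @param roi_sd sd of the shared ROI effect (log2 scale).
#' @param noise_sd sd of segment-level noise (log2 scale).
#' @param seed RNG seed.
#' @return list with \code{values} (genes x AOIs), \code{aoi_info}
#'   (aoi, roi_id, segment) and \code{truth$is_emt}.
#' @export
simulate_dsp_rois <- function(n_rois = 9, n_genes = 1800,
                              emt_genes = paste0("EMT", 1:50),
                              effect_log2fc = 1.5, roi_sd = 0.5,
                              noise_sd = 0.4, seed = 1L) {
  if (!is_count(n_rois) || n_rois < 3) stopf("n_rois must be a count >= 3")
  if (n_genes < length(emt_genes) + 10) stopf("n_genes too small for the EMT gene list")
  if (anyDuplicated(emt_genes)) stopf("duplicate gene identifiers in emt_genes")
  with_seed(seed, {
    n_bg <- n_genes - length(emt_genes)
    genes <- c(emt_genes, paste0("BG", formatC(seq_len(n_bg), width = 5, flag = "0")))
    base_mu <- runif(n_genes, 2, 8)
    roi_ids <- paste0("ROI", seq_len(n_rois))
    roi_eff <- rnorm(n_rois, 0, roi_sd)
    aois <- as.vector(t(outer(roi_ids, c("vim_pos", "vim_neg"), paste, sep = "|")))
    x <- matrix(0, n_genes, length(aois), dimnames = list(genes, aois))
    for (r in seq_len(n_rois)) {
      for (seg in c("vim_pos", "vim_neg")) {
        j <- (r - 1) * 2 + if (seg == "vim_pos") 1 else 2
        eff <- if (seg == "vim_pos") c(rep(effect_log2fc, length(emt_genes)), rep(0, n_bg)) else 0
        x[, j] <- base_mu + roi_eff[r] + eff +
          if (noise_sd > 0) rnorm(n_genes, 0, noise_sd) else 0
      }
    }
    values <- 2^x - 1
    aoi_info <- data.frame(
      aoi = aois,
      roi_id = rep(roi_ids, each = 2),
      segment = rep(c("vim_pos", "vim_neg"), n_rois)
    )
    list(values = values, aoi_info = aoi_info,
         truth = list(is_emt = genes %in% emt_genes, effect_log2fc = effect_log2fc))
  })
}
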