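#' Derive a stage-specific EMT signature
#'
#' Intersects the significantly upregulated genes of a stage-vs-reference
#' contrast (p below \code{alpha}, log2FC at least \code{min_lfc}) with the
#' hallmark EMT gene set.
#'
#' @param degs DEG table from [de_rank_sum()] for a merged-stratum contrast.
#' @param hallmark_emt character vector of EMT gene-set members.
#' @param alpha,min_lfc significance gates (defaults 0.05 and 1).
#' @param use_adjusted gate on adjusted (default) or raw p.
#' @return list of class \code{stage_signature}: \code{genes},
#'   \code{contrast}, \code{thresholds}. An empty intersection yields a
#'   warning and an empty signature, not an error.
#' @export
derive_stage_signature <- function(degs, hallmark_emt, alpha = 0.05, min_lfc = 1,
                                   use_adjusted = TRUE) {
  if (!length(hallmark_emt)) stopf("hallmark EMT set is empty")
  pv <- if (use_adjusted) degs$p_adj else degs$p_raw
  up <- degs$gene[pv < alpha & degs$log2fc >= min_lfc]
  sig <- sort(intersect(up, hallmark_emt))
  if (!length(sig)) warnf("empty signature for contrast '%s'", degs$contrast[1])
  structure(list(genes = sig, contrast = unique(degs$contrast),
                 thresholds = c(alpha = alpha, min_lfc = min_lfc)),
            class = "stage_signature")
}

#' Score a bulk cohort with a gene signature
#'
#' Applies the single-sample enrichment score of [ssgsea_cell_scores()]
#' sample-wise. Raw counts are first normalized to log2 CPM; pre-normalized
#' matrices are used as-is (the score is rank-based, so any monotone
#' per-sample scale works).
#'
#' @param expr genes x samples matrix.
#' @param signature \code{stage_signature} or a character gene vector.
#' @param input \code{"counts"} (log2-CPM normalized internally) or
#'   \code{"normalized"}.
#' @return named per-sample score vector (the NES row).
#' @export
score_cohort <- function(expr, signature, input = c("counts", "normalized")) {
  input <- match.arg(input)
  genes <- if (inherits(signature, "stage_signature")) signature$genes else signature
  if (length(intersect(genes, rownames(expr))) < 2)
    stopf("fewer than 2 signature genes present in the cohort matrix")
  x <- if (input == "counts") {
    lib <- Matrix::colSums(expr)
    if (any(lib == 0)) stopf("sample(s) with zero total counts")
    log2(1 + sweep(as_dense(expr), 2, 1e6 / lib, `*`))
  } else as_dense(expr)
  sc <- ssgsea_cell_scores(x, list(signature = genes))
  drop(sc$nes[1, ])
}

#' Split samples into High/Low groups at the mean score
#'
#' High iff score strictly above the mean; ties at exactly the mean go Low.
#'
#' @param scores named per-sample numeric vector.
#' @return factor with levels \code{Low}, \code{High}.
#' @export
split_by_mean <- function(scores) {
  if (length(scores) < 2) stopf("at least 2 samples required")
  if (diff(range(scores)) == 0) stopf("all scores identical; no High/Low split possible")
  grp <- factor(ifelse(scores > mean(scores), "High", "Low"), levels = c("Low", "High"))
  names(grp) <- names(scores)
  grp
}

#' Kaplan-Meier product-limit estimator
#'
#' \eqn{S(t) = \prod_{t_i \le t} (1 - d_i / n_i)} over distinct event times
#' \eqn{t_i}, with \eqn{d_i} events and \eqn{n_i} at risk. Censored
#' observations shrink later risk sets but do not step the curve.
#'
#' @param time non-negative follow-up times.
#' @param event 1 = event, 0 = censored.
#' @return data.frame: time (distinct event times), n_risk, n_event, surv.
#' @export
km_estimate <- function(time, event) {
  if (any(time < 0)) stopf("negative follow-up times")
  if (length(time) != length(event)) stopf("time and event lengths differ")
  ev_times <- sort(unique(time[event == 1]))
  if (!length(ev_times))
    return(data.frame(time = numeric(), n_risk = numeric(), n_event = numeric(),
                      surv = numeric()))
  n_risk <- vapply(ev_times, function(t) sum(time >= t), numeric(1))
  n_event <- vapply(ev_times, function(t) sum(time == t & event == 1), numeric(1))
  surv <- cumprod(1 - n_event / n_risk)
  data.frame(time = ev_times, n_risk = n_risk, n_event = n_event, surv = surv)
}

#' Two-group log-rank test
#'
#' Standard chi-square on observed-minus-expected events accumulated over the
#' pooled distinct event times, referred to \eqn{\chi^2_1}.
#'
#' @param time,event as in [km_estimate()].
#' @param group two-level factor.
#' @return list: statistic, p, observed and expected events per group.
#' @export
logrank_test <- function(time, event, group) {
  group <- droplevels(factor(group))
  if (nlevels(group) != 2) stopf("exactly 2 non-empty groups required")
  g1 <- levels(group)[1]
  ev_times <- sort(unique(time[event == 1]))
  o1 <- e1 <- v1 <- 0
  for (t in ev_times) {
    at_risk <- time >= t
    n <- sum(at_risk); n1 <- sum(at_risk & group == g1)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & group == g1)
    o1 <- o1 + d1
    e1 <- e1 + d * n1 / n
    if (n > 1) v1 <- v1 + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  if (v1 <= 0) return(list(statistic = 0, p = 1, observed = c(o1, sum(event) - o1),
                           expected = c(e1, sum(event) - e1)))
  chisq <- (o1 - e1)^2 / v1
  list(statistic = chisq, p = pchisq(chisq, df = 1, lower.tail = FALSE),
       observed = c(o1, sum(event) - o1), expected = c(e1, sum(event) - e1))
}

#' Cox proportional-hazards fit (single covariate, Breslow ties)
#'
#' Maximizes the Breslow partial likelihood by damped Newton iteration
#' (step halving when the log-likelihood does not improve; tolerance 1e-8,
#' at most 100 iterations). The standard error comes from the observed
#' information at the optimum.
#'
#' @param time,event as in [km_estimate()].
#' @param x covariate: numeric, or a 2-level factor (coded 0/1 on the second
#'   level).
#' @param tol convergence tolerance on the coefficient step.
#' @param max_iter iteration cap.
#' @return list of class \code{cox_fit}: beta, se, hr, ci (95% Wald),
#'   p_wald, p_lrt, loglik, iterations.
#' @export
cox_fit <- function(time, event, x, tol = 1e-8, max_iter = 100) {
  if (is.factor(x)) {
    if (nlevels(droplevels(x)) != 2) stopf("factor covariate must have 2 levels")
    x <- as.numeric(x == levels(droplevels(x))[2])
  }
  x <- as.numeric(x)
  if (sum(event) < 1) stopf("at least one event required")
  if (sd(x) == 0) stopf("covariate is constant")
  ev_times <- sort(unique(time[event == 1]))
  risk_sets <- lapply(ev_times, function(t) which(time >= t))
  death_sets <- lapply(ev_times, function(t) which(time == t & event == 1))

  loglik <- function(b) {
    ll <- 0
    for (i in seq_along(ev_times)) {
      r <- risk_sets[[i]]; d <- death_sets[[i]]
      ll <- ll + b * sum(x[d]) - length(d) * log(sum(exp(b * x[r])))
    }
    ll
  }
  deriv <- function(b) {
    u <- info <- 0
    for (i in seq_along(ev_times)) {
      r <- risk_sets[[i]]; d <- death_sets[[i]]
      w <- exp(b * x[r]); sw <- sum(w)
      xbar <- sum(w * x[r]) / sw
      x2bar <- sum(w * x[r]^2) / sw
      u <- u + sum(x[d]) - length(d) * xbar
      info <- info + length(d) * (x2bar - xbar^2)
    }
    c(u = u, info = info)
  }

  b <- 0; ll0 <- loglik(0); ll <- ll0; iter <- 0
  repeat {
    iter <- iter + 1
    d <- deriv(b)
    if (d[["info"]] <= 1e-12)
      stopf("monotone partial likelihood (complete separation); Cox fit undefined")
    step <- d[["u"]] / d[["info"]]
    step <- sign(step) * min(abs(step), 5)   # damp wild early steps
    b_new <- b + step
    ll_new <- loglik(b_new)
    halvings <- 0
    while (ll_new < ll - 1e-12 && halvings < 30) {
      step <- step / 2; b_new <- b + step; ll_new <- loglik(b_new); halvings <- halvings + 1
    }
    converged <- abs(step) < tol
    b <- b_new; ll <- ll_new
    if (converged || iter >= max_iter) break
  }
  if (!converged && iter >= max_iter)
    stopf("Cox fit did not converge in %d iterations", max_iter)
  info <- deriv(b)[["info"]]
  se <- 1 / sqrt(info)
  zcrit <- qnorm(0.975)
  structure(list(
    beta = b, se = se, hr = exp(b),
    ci = exp(c(lower = b - zcrit * se, upper = b + zcrit * se)),
    p_wald = 2 * pnorm(-abs(b / se)),
    p_lrt = pchisq(2 * (ll - ll0), df = 1, lower.tail = FALSE),
    loglik = c(null = ll0, fitted = ll), iterations = iter
  ), class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, ...) {
  cat(sprintf("Cox PH fit: beta = %.4f (SE %.4f), HR = %.3f [%.3f, %.3f], Wald p = %.3g\n",
              x$beta, x$se, x$hr, x$ci[["lower"]], x$ci[["upper"]], x$p_wald))
  invisible(x)
}
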