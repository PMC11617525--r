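#' Cochran's Q heterogeneity test
#'
#' Q = sum_j w_j (theta_j - theta_ivw)^2 over the per-SNP Wald ratios
#' theta_j, with first-order weights w_j = beta_exp_j^2 / se_out_j^2 and
#' theta_ivw the fixed-effect IVW estimate; the p-value is the upper tail
#' of chi-square on nSnp - 1 degrees of freedom.  Excess Q indicates
#' heterogeneity of the per-SNP causal estimates (invalid instruments or
#' balanced pleiotropy).
#'
#' @param set a [HarmonizedSet] with at least 2 retained SNPs.
#' @return a [HeterogeneityResult].
#' @export
cochranQ <- function(set) {
  d <- .retained_checked(set, 2L, "Cochran's Q (df would be 0)")
  theta <- d$beta_out / d$beta_exp
  w <- (d$beta_exp / d$se_out)^2
  pooled <- mrBeta(mrIvw(set, mode = "fixed"))
  q <- sum(w * (theta - pooled)^2)
  df <- nrow(d) - 1L
  new("HeterogeneityResult", q = q, df = df,
      pval = pchisq(q, df, lower.tail = FALSE))
}

#' MR-Egger intercept test for directional pleiotropy
#'
#' Exposes the intercept triple of the [mrEgger()] fit.  An intercept
#' significantly different from zero (p < 0.05 by convention) indicates a
#' directional pleiotropic pathway: the screening pipeline treats such an
#' exposure-outcome pair as pleiotropic.
#'
#' @param set a [HarmonizedSet] with at least 3 retained SNPs.
#' @return a [PleiotropyTest].
#' @export
eggerInterceptTest <- function(set) {
  e <- mrEgger(set)@extra
  new("PleiotropyTest", intercept = e$intercept, se = e$intercept_se,
      pval = e$intercept_pval)
}

#' Leave-one-out influence analysis
#'
#' Refits the IVW estimate excluding each retained SNP in turn.  A SNP is
#' flagged influential when its exclusion flips the sign of the all-SNP
#' estimate or its significance at 0.05.
#'
#' @param set a [HarmonizedSet] with at least 3 retained SNPs.
#' @param mode IVW variance mode used for all fits.
#' @return a data.frame with one row per retained SNP: \code{snp},
#'   \code{ivw_beta}, \code{ivw_se}, \code{ivw_p}, \code{flag_influential};
#'   the all-SNP estimate is attached as \code{attr(x, "full")}.
#' @export
leaveOneOut <- function(set, mode = "hybrid") {
  d <- .retained_checked(set, 3L, "leave-one-out")
  full <- mrIvw(set, mode = mode)
  rows <- lapply(seq_len(nrow(d)), function(j) {
    sub <- .harmonized_from_vectors(d$beta_exp[-j], d$se_exp[-j],
                                    d$beta_out[-j], d$se_out[-j],
                                    snp = d$snp[-j])
    est <- mrIvw(sub, mode = mode)
    data.frame(snp = d$snp[j], ivw_beta = mrBeta(est), ivw_se = mrSe(est),
               ivw_p = mrPval(est), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$flag_influential <- sign(out$ivw_beta) != sign(mrBeta(full)) |
    (out$ivw_p < 0.05) != (mrPval(full) < 0.05)
  attr(out, "full") <- full
  out
}

#' MR-PRESSO global heterogeneity test and outlier correction
#'
#' Detects pleiotropic outlier instruments by comparing each SNP's
#' contribution to the residual sum of squares of the leave-one-out
#' predicted outcome effects against a parametric null.  The observed RSS
#' uses, for each SNP j, the IVW slope fitted without j to predict its
#' outcome effect; \code{nSim} simulated datasets are drawn under the
#' no-pleiotropy model (exposure effects from normal(beta_exp, se_exp),
#' outcome effects from normal(slope_-j * beta_exp, se_out)) and the same
#' statistic recomputed.  The global p-value is the fraction of simulated
#' RSS at least as large as observed; per-SNP outlier p-values use the
#' analogous per-observation comparison, Bonferroni-adjusted across SNPs,
#' and SNPs below \code{outlierP} are flagged.  The corrected estimate is
#' the IVW fit on the non-flagged set; the raw estimate is always the IVW
#' fit on all SNPs in the same mode.
#'
#' @param set a [HarmonizedSet] with at least 4 retained SNPs.
#' @param nSim number of parametric simulations (>= 100; default 1000).
#' @param seed RNG seed; results are fully reproducible under it.
#' @param outlierP per-SNP flagging threshold on the Bonferroni-adjusted
#'   outlier p-value (default 0.05).
#' @param mode IVW variance mode for the raw and corrected estimates.
#' @return a [PressoResult].
#' @export
mrPresso <- function(set, nSim = 1000, seed = 1L, outlierP = 0.05,
                     mode = "hybrid") {
  d <- .retained_checked(set, 4L, "MR-PRESSO")
  if (nSim < 100) stop("nSim must be at least 100")
  n <- nrow(d)
  w <- 1 / d$se_out^2

  loo_rss <- function(bx, by) {
    # per-SNP leave-one-out IVW slope and weighted squared residual;
    # bx, by may be matrices (SNP x simulation)
    sxy <- colSums(w * bx * by)
    sxx <- colSums(w * bx * bx)
    slope <- (rep(sxy, each = n) - w * bx * by) /
      (rep(sxx, each = n) - w * bx * bx)
    w * (by - slope * bx)^2
  }

  obs <- loo_rss(cbind(d$beta_exp), cbind(d$beta_out))
  obs_global <- sum(obs)

  # expected outcome effects under the no-pleiotropy null
  sxy <- sum(w * d$beta_exp * d$beta_out)
  sxx <- sum(w * d$beta_exp^2)
  slope_neg <- (sxy - w * d$beta_exp * d$beta_out) /
    (sxx - w * d$beta_exp^2)
  mu_out <- slope_neg * d$beta_exp

  set.seed(seed)
  bx_s <- matrix(rnorm(n * nSim, d$beta_exp, d$se_exp), nrow = n)
  by_s <- matrix(rnorm(n * nSim, mu_out, d$se_out), nrow = n)
  sim <- loo_rss(bx_s, by_s)

  global_p <- mean(colSums(sim) >= obs_global)
  snp_p <- rowMeans(sim >= as.vector(obs))
  snp_p_adj <- setNames(pmin(1, n * snp_p), d$snp)
  outliers <- d$snp[snp_p_adj < outlierP]

  raw <- mrIvw(set, mode = mode)
  corrected <- NULL
  if (length(outliers)) {
    keep <- !(d$snp %in% outliers)
    if (sum(keep) < 1)
      stop("MR-PRESSO flagged every SNP; no corrected estimate possible")
    corrected <- mrIvw(.harmonized_from_vectors(
      d$beta_exp[keep], d$se_exp[keep], d$beta_out[keep], d$se_out[keep],
      snp = d$snp[keep]), mode = mode)
  }
  new("PressoResult", globalPval = global_p, outliers = outliers,
      raw = raw, corrected = corrected, outlierPvals = snp_p_adj,
      nSim = as.integer(nSim), seed = as.integer(seed))
}
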