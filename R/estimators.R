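.mr_estimate <- function(method, beta, se, pval, nSnp, extra = list())
  new("MREstimate", method = method, beta = beta, se = se, pval = pval,
      nSnp = as.integer(nSnp), extra = extra)

# retained rows of a HarmonizedSet, with minimum-count check
.retained_checked <- function(set, min_n, what) {
  d <- retained(set)
  if (nrow(d) < min_n)
    stop(sprintf("%s needs at least %d retained SNPs (got %d)", what, min_n,
                 nrow(d)))
  d
}

#' Wald ratio estimate for a single instrument
#'
#' The per-SNP causal estimate: outcome effect divided by exposure effect.
#' The default standard error is the first-order delta approximation
#' |se_out / beta_exp|; \code{secondOrder = TRUE} adds the exposure
#' uncertainty term, sqrt(se_out^2/beta_exp^2 +
#' beta_out^2 se_exp^2 / beta_exp^4).
#'
#' @param betaExp,seExp exposure effect and standard error.
#' @param betaOut,seOut outcome effect and standard error.
#' @param secondOrder use the second-order delta standard error.
#' @return an [MREstimate] with method \code{"wald"}.
#' @examples
#' waldRatio(0.1, 0.02, 0.05, 0.01)  # beta 0.5, se 0.1
#' @export
waldRatio <- function(betaExp, seExp, betaOut, seOut, secondOrder = FALSE) {
  if (betaExp == 0)
    stop("undefined Wald ratio: exposure effect is zero")
  beta <- betaOut / betaExp
  se <- if (secondOrder)
    sqrt(seOut^2 / betaExp^2 + betaOut^2 * seExp^2 / betaExp^4)
  else
    abs(seOut / betaExp)
  .mr_estimate("wald", beta, se, 2 * pnorm(-abs(beta / se)), 1L)
}

#' Inverse-variance weighted (IVW) causal estimate
#'
#' The primary two-sample MR estimator: a weighted regression of the
#' outcome effects on the exposure effects through the origin with weights
#' 1/se_out^2 (equivalently, the inverse-variance-weighted meta-analysis of
#' the per-SNP Wald ratios).  Three variance models are available:
#' \describe{
#'   \item{fixed}{standard error from the weighted sum alone (residual
#'     scale forced to 1).}
#'   \item{mre}{multiplicative random effects: standard error scaled by the
#'     residual standard deviation.}
#'   \item{hybrid}{the default: residual scaling floored at 1, so the
#'     standard error is never smaller than the fixed-effect one.}
#' }
#' With one instrument every mode reduces to the Wald ratio.  P-values are
#' two-sided normal.
#'
#' @param set a [HarmonizedSet] with at least one retained SNP.
#' @param mode variance model, see above.
#' @return an [MREstimate]; \code{extra$sigma} holds the residual scale.
#' @seealso [mrEgger()], [mrWeightedMedian()], [cochranQ()]
#' @export
mrIvw <- function(set, mode = c("hybrid", "fixed", "mre")) {
  mode <- match.arg(mode)
  d <- .retained_checked(set, 1L, "IVW")
  w <- 1 / d$se_out^2
  sxx <- sum(w * d$beta_exp^2)
  beta <- sum(w * d$beta_exp * d$beta_out) / sxx
  se_fixed <- sqrt(1 / sxx)
  n <- nrow(d)
  sigma <- if (n > 1)
    sqrt(sum(w * (d$beta_out - beta * d$beta_exp)^2) / (n - 1))
  else 1
  se <- switch(mode,
               fixed = se_fixed,
               mre = se_fixed * sigma,
               hybrid = se_fixed * max(1, sigma))
  .mr_estimate(paste0("ivw_", mode), beta, se, 2 * pnorm(-abs(beta / se)),
               n, extra = list(sigma = sigma))
}

#' MR-Egger regression
#'
#' Weighted regression of outcome effects on exposure effects with a free
#' intercept (weights 1/se_out^2), after orienting every SNP so its
#' exposure effect is non-negative.  The slope is a pleiotropy-robust
#' causal estimate under the InSIDE assumption; a non-zero intercept
#' indicates directional horizontal pleiotropy (see
#' [eggerInterceptTest()]).  Standard errors use residual scaling floored
#' at 1 and p-values come from t with nSnp - 2 degrees of freedom.
#'
#' @param set a [HarmonizedSet] with at least 3 retained SNPs and
#'   non-constant exposure effects.
#' @return an [MREstimate] with method \code{"egger_slope"};
#'   \code{extra} carries \code{intercept}, \code{intercept_se},
#'   \code{intercept_pval} and \code{sigma}.
#' @export
mrEgger <- function(set) {
  d <- .retained_checked(set, 3L, "MR-Egger")
  flip <- ifelse(d$beta_exp < 0, -1, 1)
  bx <- d$beta_exp * flip
  by <- d$beta_out * flip
  if (var(bx) == 0)
    stop("rank-deficient MR-Egger fit: exposure effects are constant")
  w <- 1 / d$se_out^2
  n <- nrow(d)
  # weighted normal equations, solved explicitly so the max(1, sigma)
  # floor applies even on an exact fit (residual scale 0)
  X <- cbind(intercept = 1, slope = bx)
  xtwx_inv <- solve(crossprod(X, w * X))
  est <- drop(xtwx_inv %*% crossprod(X, w * by))
  sigma <- sqrt(sum(w * (by - drop(X %*% est))^2) / (n - 2))
  se <- sqrt(diag(xtwx_inv)) * max(1, sigma)
  pv <- 2 * pt(-abs(est / se), df = n - 2)
  .mr_estimate("egger_slope", est[["slope"]], se[["slope"]], pv[["slope"]],
               n,
               extra = list(intercept = est[["intercept"]],
                            intercept_se = se[["intercept"]],
                            intercept_pval = pv[["intercept"]],
                            sigma = sigma))
}

# interpolated weighted 50th percentile on cumulative standardized weights
.weighted_median <- function(theta, w) {
  ord <- order(theta)
  theta <- theta[ord]
  w <- w[ord]
  p <- (cumsum(w) - w / 2) / sum(w)
  if (0.5 <= p[1]) return(theta[1])
  if (0.5 >= p[length(p)]) return(theta[length(theta)])
  approx(p, theta, xout = 0.5, ties = "ordered")$y
}

#' Weighted-median causal estimate
#'
#' The weighted 50th percentile of the per-SNP Wald ratios, consistent when
#' at least half the weight comes from valid instruments.  Ratios are
#' weighted by the inverse variance of the first-order ratio standard error
#' (se_out/|beta_exp|); the percentile is interpolated on cumulative
#' standardized weights using the (cumulative - w/2) convention.  The
#' standard error comes from a parametric bootstrap: per-SNP effects are
#' resampled from normal(beta, se), the median recomputed, and the SD over
#' \code{nBoot} iterations reported; reproducible under \code{seed}.
#'
#' @param set a [HarmonizedSet] with at least 3 retained SNPs.
#' @param nBoot bootstrap iterations (default 1000).
#' @param seed RNG seed for the bootstrap.
#' @return an [MREstimate]; \code{extra$n_boot} records the iterations.
#' @export
mrWeightedMedian <- function(set, nBoot = 1000, seed = 1L) {
  d <- .retained_checked(set, 3L, "weighted median")
  if (any(d$beta_exp == 0))
    stop("weighted median requires nonzero exposure effects")
  # orient to non-negative exposure effects: ratios and weights are
  # unaffected, and the bootstrap becomes exactly orientation-invariant
  flip <- ifelse(d$beta_exp < 0, -1, 1)
  d$beta_exp <- d$beta_exp * flip
  d$beta_out <- d$beta_out * flip
  theta <- d$beta_out / d$beta_exp
  w <- (d$beta_exp / d$se_out)^2   # 1 / se(ratio)^2, first order
  beta <- .weighted_median(theta, w)
  n <- nrow(d)
  boot <- local({
    set.seed(seed)
    bx <- matrix(rnorm(n * nBoot, d$beta_exp, d$se_exp), nrow = n)
    by <- matrix(rnorm(n * nBoot, d$beta_out, d$se_out), nrow = n)
    vapply(seq_len(nBoot), function(b) {
      .weighted_median(by[, b] / bx[, b], (bx[, b] / d$se_out)^2)
    }, numeric(1))
  })
  se <- sd(boot)
  .mr_estimate("weighted_median", beta, se, 2 * pnorm(-abs(beta / se)), n,
               extra = list(n_boot = nBoot, seed = seed))
}
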