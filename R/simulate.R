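#' Build a simulation configuration
#'
#' Defaults describe a well-powered two-sample design: three non-overlapping
#' cohorts of 20,000, 30 exposure and 30 mediator instruments with
#' per-allele effects around 0.12 (per-SNP F near 100 at these sizes, so
#' weak-instrument bias is negligible relative to sampling error), minor
#' allele frequencies uniform on [0.1, 0.5], unit-scale traits, and no
#' pleiotropy.  See [SimulationConfig] for the structural model.
#'
#' @param seed RNG seed (mandatory discipline: every study is reproducible).
#' @param nExp,nMed,nOut cohort sizes.
#' @param jExp,jMed instrument counts for exposure and mediator.
#' @param mafRange minor-allele frequency range.
#' @param gammaMean,gammaSd,zetaMean,zetaSd instrument effect distributions.
#' @param alpha,theta,tauDirect structural effects (exposure to mediator,
#'   mediator to outcome, direct exposure to outcome).
#' @param pleioFrac,pleioMean,pleioSd pleiotropic direct-effect settings.
#' @param noiseSd residual SDs for X, M, Y.
#' @param binaryOutcome,caseFraction case-control outcome emulation.
#' @return a [SimulationConfig].
#' @export
simulationConfig <- function(seed = 1L, nExp = 20000L, nMed = 20000L,
                             nOut = 20000L, jExp = 30L, jMed = 30L,
                             mafRange = c(0.1, 0.5), gammaMean = 0.12,
                             gammaSd = 0.03, zetaMean = 0.12,
                             zetaSd = 0.03, alpha = 0.2, theta = 0.3,
                             tauDirect = 0.1, pleioFrac = 0,
                             pleioMean = 0, pleioSd = 0.03,
                             noiseSd = c(0.9, 0.9, 0.9),
                             binaryOutcome = FALSE, caseFraction = 0.25) {
  new("SimulationConfig", seed = as.integer(seed), nExp = as.integer(nExp),
      nMed = as.integer(nMed), nOut = as.integer(nOut),
      jExp = as.integer(jExp), jMed = as.integer(jMed),
      mafRange = mafRange, gammaMean = gammaMean, gammaSd = gammaSd,
      zetaMean = zetaMean, zetaSd = zetaSd, alpha = alpha, theta = theta,
      tauDirect = tauDirect, pleioFrac = pleioFrac, pleioMean = pleioMean,
      pleioSd = pleioSd, noiseSd = noiseSd, binaryOutcome = binaryOutcome,
      caseFraction = caseFraction)
}

#' Closed-form expected effects of a simulation configuration
#'
#' The structural truths every recovery test compares against:
#' indirect = alpha * theta, direct = tauDirect,
#' total = direct + indirect (exactly), and the proportion mediated
#' indirect/total (NA when the total is zero; flagged inconsistent when
#' the two disagree in sign).
#'
#' @param config a [SimulationConfig].
#' @return a list: \code{total}, \code{indirect}, \code{direct},
#'   \code{prop_mediated}, \code{inconsistent}.
#' @export
expectedEffects <- function(config) {
  stopifnot(is(config, "SimulationConfig"))
  indirect <- config@alpha * config@theta
  direct <- config@tauDirect
  total <- direct + indirect
  if (total == 0) {
    prop <- NA_real_
    incons <- FALSE
  } else {
    pm <- proportionMediated(indirect, total)
    prop <- pm$proportion
    incons <- pm$inconsistent
  }
  list(total = total, indirect = indirect, direct = direct,
       prop_mediated = prop, inconsistent = incons)
}

# non-palindromic effect/other allele pairs to assign to simulated SNPs
.ALLELE_PAIRS <- rbind(c("A", "G"), c("A", "C"), c("T", "G"), c("T", "C"),
                       c("G", "A"), c("C", "A"), c("G", "T"), c("C", "T"))

# per-SNP simple linear regressions of y on each genotype column, vectorized
.gwas_scan <- function(G, y) {
  n <- nrow(G)
  gc <- sweep(G, 2, colMeans(G))
  yc <- y - mean(y)
  sxx <- colSums(gc^2)
  beta <- colSums(gc * yc) / sxx
  rss <- sum(yc^2) - beta^2 * sxx
  se <- sqrt(pmax(rss, 0) / (n - 2) / sxx)
  tstat <- beta / se
  list(beta = beta, se = se,
       pval = pmin(1, 2 * pt(-abs(tstat), df = n - 2)),
       eaf = colMeans(G) / 2, n = n)
}

# per-SNP logistic regressions (log-odds scale) for the binary option
.gwas_scan_binary <- function(G, case) {
  res <- vapply(seq_len(ncol(G)), function(j) {
    fit <- suppressWarnings(
      stats::glm(case ~ G[, j], family = stats::binomial()))
    cf <- coef(summary(fit))
    cf["G[, j]", c("Estimate", "Std. Error", "Pr(>|z|)")]
  }, numeric(3))
  list(beta = res[1, ], se = res[2, ], pval = pmax(.Machine$double.xmin,
                                                   res[3, ]),
       eaf = colMeans(G) / 2, n = nrow(G))
}

.scan_to_sumstats <- function(scan, snp, chrom, pos, alleles, traitId,
                              traitLabel) {
  sumStats(data.frame(snp = snp, chrom = chrom, pos = pos,
                      effect_allele = alleles[, 1],
                      other_allele = alleles[, 2], eaf = scan$eaf,
                      beta = scan$beta, se = scan$se, pval = scan$pval,
                      n = scan$n, stringsAsFactors = FALSE),
           traitId = traitId, traitLabel = traitLabel)
}

# draw the SNP panel (maf, alleles, coordinates) and structural effects
.draw_snp_panel <- function(config, n_med_blocks = 1L) {
  j_exp <- config@jExp
  j_med_total <- config@jMed * n_med_blocks
  J <- j_exp + j_med_total
  maf <- runif(J, config@mafRange[1], config@mafRange[2])
  alleles <- .ALLELE_PAIRS[sample.int(nrow(.ALLELE_PAIRS), J, TRUE), ,
                           drop = FALSE]
  gamma <- rnorm(j_exp, config@gammaMean, config@gammaSd)
  zeta <- rnorm(j_med_total, config@zetaMean, config@zetaSd)
  pleio <- rep(0, j_exp)
  is_pleio <- runif(j_exp) < config@pleioFrac
  pleio[is_pleio] <- rnorm(sum(is_pleio), config@pleioMean, config@pleioSd)
  list(snp = sprintf("rs%05d", seq_len(J)),
       chrom = as.character(((seq_len(J) - 1) %% 22) + 1),
       pos = 1e6 * (1 + ((seq_len(J) - 1) %/% 22)),
       maf = maf, alleles = alleles, gamma = gamma, zeta = zeta,
       pleio = pleio, j_exp = j_exp)
}

# genotype matrix + the three traits for one cohort under the structural
# model; mediator effects may be a matrix (one column per mediator block)
.draw_cohort <- function(n, panel, config, alphas = config@alpha,
                         thetas = config@theta) {
  J <- length(panel$maf)
  G <- matrix(rbinom(n * J, 2, rep(panel$maf, each = n)), nrow = n)
  idx_exp <- seq_len(panel$j_exp)
  X <- as.vector(G[, idx_exp, drop = FALSE] %*% panel$gamma) +
    rnorm(n, 0, config@noiseSd[1])
  K <- length(alphas)
  jm <- config@jMed
  M <- matrix(0, n, K)
  for (k in seq_len(K)) {
    cols <- panel$j_exp + (k - 1) * jm + seq_len(jm)
    M[, k] <- alphas[k] * X +
      as.vector(G[, cols, drop = FALSE] %*% panel$zeta[cols - panel$j_exp]) +
      rnorm(n, 0, config@noiseSd[2])
  }
  Y <- config@tauDirect * X + as.vector(M %*% thetas) +
    as.vector(G[, idx_exp, drop = FALSE] %*% panel$pleio) +
    rnorm(n, 0, config@noiseSd[3])
  list(G = G, X = X, M = M, Y = Y)
}

#' Simulate a two-sample MR mediation study
#'
#' Draws three non-overlapping cohorts under the structural model of
#' [SimulationConfig], computes per-SNP simple linear regressions of each
#' cohort's measured trait (exposure, mediator, outcome respectively) on
#' every SNP, and returns the three summary-statistics tables plus the
#' generating truth.  Summary statistics come from actually regressing
#' simulated individuals, so standard errors, allele frequencies and
#' p-values carry genuine sampling noise.  With \code{binaryOutcome} the
#' outcome is dichotomized at the (1 - caseFraction) quantile and per-SNP
#' log-odds are fitted, emulating a case-control outcome scale.
#' Deterministic under \code{config@seed}.
#'
#' @param config a [SimulationConfig].
#' @return a list: \code{exposure}, \code{mediator}, \code{outcome}
#'   ([SumStats] each, covering all SNPs) and \code{truth} (SNP panel,
#'   structural effects, and [expectedEffects()]).
#' @export
simulateStudy <- function(config) {
  stopifnot(is(config, "SimulationConfig"))
  validObject(config)
  set.seed(config@seed)
  panel <- .draw_snp_panel(config)

  mk <- function(n, trait) {
    cohort <- .draw_cohort(n, panel, config)
    y <- switch(trait, exposure = cohort$X, mediator = cohort$M[, 1],
                outcome = cohort$Y)
    if (trait == "outcome" && config@binaryOutcome) {
      case <- y > quantile(y, 1 - config@caseFraction)
      .gwas_scan_binary(cohort$G, case)
    } else {
      .gwas_scan(cohort$G, y)
    }
  }
  exposure <- .scan_to_sumstats(mk(config@nExp, "exposure"), panel$snp,
                                panel$chrom, panel$pos, panel$alleles,
                                "sim-exposure", "simulated exposure")
  mediator <- .scan_to_sumstats(mk(config@nMed, "mediator"), panel$snp,
                                panel$chrom, panel$pos, panel$alleles,
                                "sim-mediator", "simulated mediator")
  outcome <- .scan_to_sumstats(mk(config@nOut, "outcome"), panel$snp,
                               panel$chrom, panel$pos, panel$alleles,
                               "sim-outcome", "simulated outcome")
  list(exposure = exposure, mediator = mediator, outcome = outcome,
       truth = list(panel = panel, expected = expectedEffects(config),
                    config = config))
}

#' Simulate a mediator panel for screening
#'
#' One exposure cohort, one outcome cohort, and one cohort per mediator,
#' all non-overlapping, under a shared structural model in which mediator k
#' has its own instrument block and effects alpha_k (exposure to mediator)
#' and theta_k (mediator to outcome):
#' Y = tauDirect X + sum_k theta_k M_k + e_y.  Mediators with
#' alpha_k = theta_k = 0 are inactive decoys.
#'
#' @param config a [SimulationConfig]; its \code{alpha}/\code{theta} are
#'   ignored in favour of the vectors below.
#' @param alphas,thetas per-mediator structural effects (equal length).
#' @return a list: \code{exposure} and \code{exposureFallback} ([SumStats];
#'   the fallback is an independent second exposure cohort), \code{mediators}
#'   (named list of [SumStats]), \code{outcome} ([SumStats]), and \code{truth}
#'   with the per-mediator indirect effects and the true mediator set
#'   (nonzero alpha_k * theta_k).
#' @export
simulatePanel <- function(config, alphas, thetas) {
  stopifnot(is(config, "SimulationConfig"), length(alphas) == length(thetas))
  K <- length(alphas)
  set.seed(config@seed)
  panel <- .draw_snp_panel(config, n_med_blocks = K)

  scan_trait <- function(n, which_trait, k = 1L) {
    cohort <- .draw_cohort(n, panel, config, alphas = alphas,
                           thetas = thetas)
    y <- switch(which_trait, exposure = cohort$X, mediator = cohort$M[, k],
                outcome = cohort$Y)
    .gwas_scan(cohort$G, y)
  }
  to_tab <- function(scan, id, label)
    .scan_to_sumstats(scan, panel$snp, panel$chrom, panel$pos,
                      panel$alleles, id, label)

  exposure <- to_tab(scan_trait(config@nExp, "exposure"), "sim-exposure",
                     "simulated exposure")
  # an independent second exposure cohort, usable as the fallback dataset
  # when step-1 pleiotropy is (spuriously or truly) detected
  exposure_fallback <- to_tab(scan_trait(config@nExp, "exposure"),
                              "sim-exposure-alt",
                              "simulated exposure (alternative cohort)")
  mediators <- lapply(seq_len(K), function(k)
    to_tab(scan_trait(config@nMed, "mediator", k),
           sprintf("sim-mediator-%02d", k),
           sprintf("simulated mediator %d", k)))
  names(mediators) <- vapply(mediators, traitId, "")
  outcome <- to_tab(scan_trait(config@nOut, "outcome"), "sim-outcome",
                    "simulated outcome")
  indirect <- alphas * thetas
  list(exposure = exposure, exposureFallback = exposure_fallback,
       mediators = mediators, outcome = outcome,
       truth = list(panel = panel, alphas = alphas, thetas = thetas,
                    indirect = indirect,
                    true_mediators = names(mediators)[indirect != 0]))
}
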