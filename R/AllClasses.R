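#' @import methods
#' @importFrom stats approx coef p.adjust pchisq pnorm pt quantile
#'   rbinom rnorm runif sd setNames var
#' @importFrom utils read.delim write.table
NULL

SUMSTAT_COLS <- c("snp", "chrom", "pos", "effect_allele", "other_allele",
                  "eaf", "beta", "se", "pval", "n")

HARMONIZE_ACTIONS <- c("unchanged", "allele_swap", "strand_flip",
                       "dropped_palindromic", "dropped_incompatible")

#' GWAS summary statistics for one trait
#'
#' A table of per-SNP association statistics (one row per variant) for a
#' single trait, the atomic input to every analysis in the package.  The
#' \code{data} slot holds columns \code{snp}, \code{chrom}, \code{pos},
#' \code{effect_allele}, \code{other_allele}, \code{eaf}, \code{beta},
#' \code{se}, \code{pval} and \code{n}; \code{chrom}, \code{pos}, \code{eaf}
#' and \code{n} may be \code{NA}.  Effects (\code{beta}) are additive
#' per-effect-allele estimates on the trait scale (log-odds for case-control
#' traits).
#'
#' @slot traitId character identifier (accession-style) for the trait.
#' @slot traitLabel human-readable trait name.
#' @slot data data.frame of per-SNP records (see above).
#' @slot nDefault sample size applied when a record has no per-SNP n
#'   (\code{NA_real_} when unset).
#'
#' @seealso [sumStats()], [readSumstats()], [harmonize()]
#' @export
setClass("SumStats",
  representation(traitId = "character", traitLabel = "character",
                 data = "data.frame", nDefault = "numeric"),
  prototype(traitId = NA_character_, traitLabel = NA_character_,
            nDefault = NA_real_))

setValidity("SumStats", function(object) {
  d <- object@data
  msg <- character()
  if (!all(SUMSTAT_COLS %in% names(d)))
    msg <- c(msg, paste("missing columns:",
                        paste(setdiff(SUMSTAT_COLS, names(d)), collapse = ", ")))
  else if (nrow(d) > 0) {
    if (anyDuplicated(d$snp))
      msg <- c(msg, "duplicated snp ids")
    if (any(!is.finite(d$se) | d$se <= 0))
      msg <- c(msg, "se must be finite and > 0")
    if (any(!is.na(d$eaf) & (d$eaf < 0 | d$eaf > 1)))
      msg <- c(msg, "eaf must lie in [0, 1]")
    if (any(!is.finite(d$pval) | d$pval <= 0 | d$pval > 1))
      msg <- c(msg, "pval must lie in (0, 1]")
    if (any(d$effect_allele == d$other_allele))
      msg <- c(msg, "effect_allele must differ from other_allele")
  }
  if (length(msg)) msg else TRUE
})

#' Harmonized exposure-outcome instrument set
#'
#' Per-SNP exposure and outcome effects expressed on a common effect allele,
#' the input consumed by every causal estimator.  The \code{data} slot has
#' one row per SNP in the exposure/outcome intersection with columns
#' \code{snp}, \code{beta_exp}, \code{se_exp}, \code{beta_out},
#' \code{se_out}, \code{eaf_exp} and \code{action}; SNPs whose
#' \code{action} starts with \code{"dropped"} carry NA effects and are
#' excluded from estimation.
#'
#' @slot exposureId,outcomeId trait identifiers of the two tables.
#' @slot data per-SNP harmonization results (see above).
#' @seealso [harmonize()], [retained()], [mrIvw()]
#' @export
setClass("HarmonizedSet",
  representation(exposureId = "character", outcomeId = "character",
                 data = "data.frame"))

setValidity("HarmonizedSet", function(object) {
  d <- object@data
  msg <- character()
  need <- c("snp", "beta_exp", "se_exp", "beta_out", "se_out", "eaf_exp",
            "action")
  if (!all(need %in% names(d)))
    return(paste("missing columns:",
                 paste(setdiff(need, names(d)), collapse = ", ")))
  if (!all(d$action %in% HARMONIZE_ACTIONS))
    msg <- c(msg, "unknown harmonization action")
  keep <- !startsWith(d$action, "dropped")
  if (any(keep) &&
      (any(!is.finite(d$se_exp[keep]) | d$se_exp[keep] <= 0) ||
       any(!is.finite(d$se_out[keep]) | d$se_out[keep] <= 0)))
    msg <- c(msg, "retained SNPs must have positive standard errors")
  if (length(msg)) msg else TRUE
})

#' A causal-effect estimate from one MR method
#'
#' @slot method one of \code{"wald"}, \code{"ivw_fixed"}, \code{"ivw_mre"},
#'   \code{"ivw_hybrid"}, \code{"egger_slope"}, \code{"weighted_median"}.
#' @slot beta causal-effect estimate (outcome units per exposure unit).
#' @slot se standard error of \code{beta}.
#' @slot pval two-sided p-value.
#' @slot nSnp number of instruments used.
#' @slot extra method-specific fields (Egger intercept triple, bootstrap
#'   iteration count, residual scale).
#' @seealso [mrIvw()], [mrEgger()], [mrWeightedMedian()], [waldRatio()]
#' @export
setClass("MREstimate",
  representation(method = "character", beta = "numeric", se = "numeric",
                 pval = "numeric", nSnp = "integer", extra = "list"),
  prototype(extra = list()))

setValidity("MREstimate", function(object) {
  min_n <- c(wald = 1L, ivw_fixed = 1L, ivw_mre = 1L, ivw_hybrid = 1L,
             egger_slope = 3L, weighted_median = 3L)
  if (!object@method %in% names(min_n))
    return("unknown method")
  if (!is.finite(object@se) || object@se <= 0)
    return("se must be finite and > 0")
  if (object@nSnp < min_n[[object@method]])
    return(sprintf("method %s needs at least %d SNPs", object@method,
                   min_n[[object@method]]))
  TRUE
})

#' Cochran's Q heterogeneity test result
#'
#' @slot q Cochran's Q statistic.
#' @slot df degrees of freedom (number of instruments minus one).
#' @slot pval upper-tail chi-square p-value.
#' @seealso [cochranQ()]
#' @export
setClass("HeterogeneityResult",
  representation(q = "numeric", df = "integer", pval = "numeric"))

#' MR-Egger intercept (directional pleiotropy) test result
#'
#' @slot intercept Egger regression intercept.
#' @slot se its standard error.
#' @slot pval two-sided p-value from t(nSnp - 2); p < 0.05 is read as
#'   evidence of directional horizontal pleiotropy.
#' @seealso [eggerInterceptTest()], [mrEgger()]
#' @export
setClass("PleiotropyTest",
  representation(intercept = "numeric", se = "numeric", pval = "numeric"))

#' MR-PRESSO global test and outlier-correction result
#'
#' @slot globalPval simulation p-value of the global residual-sum-of-squares
#'   test under the no-pleiotropy null.
#' @slot outliers snp ids flagged as outliers (may be empty).
#' @slot raw IVW estimate on all SNPs.
#' @slot corrected IVW estimate after outlier removal; \code{NULL} when no
#'   outlier was flagged.
#' @slot outlierPvals named per-SNP Bonferroni-adjusted outlier p-values.
#' @slot nSim number of parametric simulations used.
#' @slot seed RNG seed used (for audit).
#' @seealso [mrPresso()]
#' @export
setClass("PressoResult",
  representation(globalPval = "numeric", outliers = "character",
                 raw = "MREstimate", corrected = "ANY",
                 outlierPvals = "numeric", nSim = "integer",
                 seed = "integer"))

setValidity("PressoResult", function(object) {
  has_corr <- !is.null(object@corrected)
  if (has_corr != (length(object@outliers) > 0))
    return("corrected estimate must be present iff outliers were flagged")
  TRUE
})

#' Two-step MR mediation result
#'
#' The indirect (mediated) effect of an exposure on an outcome through one
#' mediator: the product of the exposure-to-mediator effect (beta1) and the
#' mediator-to-outcome effect (beta2), with a delta-method Z statistic.
#' Both Z variants are always computed: \code{"paper"} pairs each
#' coefficient with its own standard error,
#' z = b1 b2 / sqrt(b1^2 se1^2 + b2^2 se2^2); \code{"sobel"} is the
#' classical cross pairing, z = b1 b2 / sqrt(b1^2 se2^2 + b2^2 se1^2).
#'
#' @slot mediatorId mediator trait identifier.
#' @slot beta1,se1 exposure-to-mediator IVW estimate and SE.
#' @slot beta2,se2 mediator-to-outcome IVW estimate and SE.
#' @slot indirect beta1 * beta2.
#' @slot z the Z statistic of the selected variant.
#' @slot zPaper,zSobel both variants, always reported.
#' @slot variant which variant \code{z} holds.
#' @slot significant TRUE iff |z| > 1.96 (strict).
#' @slot total total exposure-to-outcome effect (NA when not supplied).
#' @slot propMediated indirect/total (NA when total is absent or zero).
#' @slot inconsistent TRUE when indirect and total have opposite signs
#'   (inconsistent mediation: the proportion is negative).
#' @slot exposureUsed identifier of the exposure dataset behind beta1
#'   (records fallback substitution).
#' @seealso [twoStepMediation()], [mediationZ()]
#' @export
setClass("MediationResult",
  representation(mediatorId = "character", beta1 = "numeric", se1 = "numeric",
                 beta2 = "numeric", se2 = "numeric", indirect = "numeric",
                 z = "numeric", zPaper = "numeric", zSobel = "numeric",
                 variant = "character", significant = "logical",
                 total = "numeric", propMediated = "numeric",
                 inconsistent = "logical", exposureUsed = "character"),
  prototype(total = NA_real_, propMediated = NA_real_, inconsistent = FALSE,
            exposureUsed = NA_character_))

setValidity("MediationResult", function(object) {
  msg <- character()
  if (!isTRUE(all.equal(object@indirect, object@beta1 * object@beta2)))
    msg <- c(msg, "indirect must equal beta1 * beta2")
  if (is.finite(object@z) &&
      object@significant != (abs(object@z) > 1.96))
    msg <- c(msg, "significant must mean |z| > 1.96")
  if (length(msg)) msg else TRUE
})

#' Instrument-selection settings
#'
#' @slot pThreshold genome-wide significance cutoff for instrument inclusion
#'   (default 5e-8, strict inequality).
#' @slot clumpR2 LD r-squared cutoff for greedy clumping (default 0.001).
#' @slot clumpWindowKb clumping window in kilobases (default 10000).
#' @slot outcomeExclusionP instruments with outcome-association p below this
#'   are removed (default 1e-8).
#' @seealso [selectInstruments()], [ldClump()]
#' @export
setClass("InstrumentConfig",
  representation(pThreshold = "numeric", clumpR2 = "numeric",
                 clumpWindowKb = "numeric", outcomeExclusionP = "numeric"),
  prototype(pThreshold = 5e-8, clumpR2 = 0.001, clumpWindowKb = 10000,
            outcomeExclusionP = 1e-8))

setValidity("InstrumentConfig", function(object) {
  msg <- character()
  if (object@pThreshold <= 0 || object@pThreshold >= 1)
    msg <- c(msg, "pThreshold must lie in (0, 1)")
  if (object@clumpR2 < 0 || object@clumpR2 > 1)
    msg <- c(msg, "clumpR2 must lie in [0, 1]")
  if (object@clumpWindowKb <= 0)
    msg <- c(msg, "clumpWindowKb must be > 0")
  if (object@outcomeExclusionP <= 0 || object@outcomeExclusionP >= 1)
    msg <- c(msg, "outcomeExclusionP must lie in (0, 1)")
  if (length(msg)) msg else TRUE
})

#' Generative model settings for synthetic GWAS cohorts
#'
#' Parameters of the structural model X -> M -> Y used by
#' [simulateStudy()]: X = sum(gamma_j G_j) + e_x,
#' M = alpha X + sum(zeta_k G_k) + e_m,
#' Y = tau X + theta M + sum(eta_j G_j) + e_y, with genotypes
#' G ~ Binomial(2, maf) drawn independently in three non-overlapping
#' cohorts (two-sample design).  eta is nonzero only for the pleiotropic
#' fraction of exposure instruments.
#'
#' @slot seed RNG seed; the whole study is deterministic given it.
#' @slot nExp,nMed,nOut cohort sizes (>= 100).
#' @slot jExp,jMed numbers of exposure- and mediator-specific instruments.
#' @slot mafRange minor-allele-frequency interval within (0, 0.5].
#' @slot gammaMean,gammaSd exposure instrument effect distribution.
#' @slot zetaMean,zetaSd mediator instrument effect distribution.
#' @slot alpha exposure-to-mediator effect.
#' @slot theta mediator-to-outcome effect.
#' @slot tauDirect direct exposure-to-outcome effect.
#' @slot pleioFrac fraction of exposure instruments with direct outcome
#'   effects (exclusion-restriction violations).
#' @slot pleioMean,pleioSd distribution of those direct effects; a nonzero
#'   mean makes the pleiotropy directional.
#' @slot noiseSd residual standard deviations for X, M, Y.
#' @slot binaryOutcome dichotomize Y and fit per-SNP log-odds instead of
#'   linear effects (case-control emulation).
#' @slot caseFraction case fraction used when \code{binaryOutcome} is TRUE.
#' @seealso [simulationConfig()], [simulateStudy()], [expectedEffects()]
#' @export
setClass("SimulationConfig",
  representation(seed = "integer", nExp = "integer", nMed = "integer",
                 nOut = "integer", jExp = "integer", jMed = "integer",
                 mafRange = "numeric", gammaMean = "numeric",
                 gammaSd = "numeric", zetaMean = "numeric",
                 zetaSd = "numeric", alpha = "numeric", theta = "numeric",
                 tauDirect = "numeric", pleioFrac = "numeric",
                 pleioMean = "numeric", pleioSd = "numeric",
                 noiseSd = "numeric", binaryOutcome = "logical",
                 caseFraction = "numeric"))

setValidity("SimulationConfig", function(object) {
  msg <- character()
  if (any(c(object@nExp, object@nMed, object@nOut) < 100))
    msg <- c(msg, "cohort sizes must be >= 100")
  if (length(object@mafRange) != 2 || object@mafRange[1] <= 0 ||
      object@mafRange[2] > 0.5 || object@mafRange[1] > object@mafRange[2])
    msg <- c(msg, "mafRange must be an interval within (0, 0.5]")
  if (object@pleioFrac < 0 || object@pleioFrac > 1)
    msg <- c(msg, "pleioFrac must lie in [0, 1]")
  if (length(object@noiseSd) != 3 || any(object@noiseSd <= 0))
    msg <- c(msg, "noiseSd must be three positive values (X, M, Y)")
  if (object@caseFraction <= 0 || object@caseFraction >= 1)
    msg <- c(msg, "caseFraction must lie in (0, 1)")
  if (length(msg)) msg else TRUE
})

#' Mediator-screening pipeline settings
#'
#' @slot exposure primary exposure [SumStats].
#' @slot exposureFallback alternative exposure dataset substituted for a
#'   mediator path when the primary exposure shows step-1 pleiotropy
#'   (\code{NULL} to disable).
#' @slot outcome outcome [SumStats].
#' @slot mediators named list of mediator [SumStats] tables (the panel).
#' @slot instruments an [InstrumentConfig].
#' @slot ivwMode IVW variant used throughout ("hybrid", "fixed", "mre").
#' @slot nBoot weighted-median bootstrap iterations.
#' @slot seed RNG seed governing every stochastic step of the run.
#' @slot qCutoff FDR significance level (default 0.05).
#' @slot pleiotropyP Egger-intercept p cutoff for pleiotropy exclusion.
#' @slot fallbackToRawP when no mediator survives the FDR screen, rescreen
#'   at uncorrected p < 0.05 and flag the report accordingly.
#' @seealso [screeningConfig()], [runScreen()]
#' @export
setClass("ScreeningConfig",
  representation(exposure = "SumStats", exposureFallback = "ANY",
                 outcome = "SumStats", mediators = "list",
                 instruments = "InstrumentConfig", ivwMode = "character",
                 nBoot = "integer", seed = "integer", qCutoff = "numeric",
                 pleiotropyP = "numeric", fallbackToRawP = "logical"))

setValidity("ScreeningConfig", function(object) {
  msg <- character()
  if (length(object@mediators) < 1)
    msg <- c(msg, "at least one mediator is required")
  if (!all(vapply(object@mediators, is, logical(1), "SumStats")))
    msg <- c(msg, "mediators must be SumStats objects")
  if (object@qCutoff <= 0 || object@qCutoff >= 1)
    msg <- c(msg, "qCutoff must lie in (0, 1)")
  if (object@pleiotropyP <= 0 || object@pleiotropyP >= 1)
    msg <- c(msg, "pleiotropyP must lie in (0, 1)")
  if (!object@ivwMode %in% c("hybrid", "fixed", "mre"))
    msg <- c(msg, "ivwMode must be hybrid, fixed or mre")
  if (!is.null(object@exposureFallback) &&
      !is(object@exposureFallback, "SumStats"))
    msg <- c(msg, "exposureFallback must be NULL or a SumStats")
  if (length(msg)) msg else TRUE
})

#' Result of a mediator-screening run
#'
#' @slot records one row per mediator: step-1 and step-2 estimates and
#'   diagnostics, family q-values, the exclusion reason (NA for retained
#'   mediators, \code{"untestable"} for mediators without instruments), and
#'   for retained mediators the mediation columns.
#' @slot mediations named list of [MediationResult] for retained mediators.
#' @slot total the exposure-to-outcome total-effect [MREstimate].
#' @slot manifest named list recording seeds, settings, dataset provenance
#'   and per-stage filter counts.
#' @seealso [runScreen()], [writeReport()]
#' @export
setClass("ScreenResult",
  representation(records = "data.frame", mediations = "list",
                 total = "MREstimate", manifest = "list"))
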