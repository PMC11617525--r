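#' Indirect (mediated) effect
#'
#' The product-of-coefficients mediation estimate: the exposure-to-mediator
#' effect times the mediator-to-outcome effect, beta1 * beta2.  Its sign is
#' the direction of the mediated pathway.
#'
#' @param beta1 exposure-to-mediator effect.
#' @param beta2 mediator-to-outcome effect.
#' @return the exact product.
#' @export
indirectEffect <- function(beta1, beta2) {
  stopifnot(is.finite(beta1), is.finite(beta2))
  beta1 * beta2
}

#' Delta-method Z statistic for the indirect effect
#'
#' Two variants of the large-sample Z test for beta1 * beta2:
#' \describe{
#'   \item{paper}{z = b1 b2 / sqrt(b1^2 se1^2 + b2^2 se2^2) — each
#'     coefficient paired with its OWN standard error.  This is the default
#'     because it exactly reproduces published mediation tables this
#'     package ships as worked examples; it is not the classical pairing.}
#'   \item{sobel}{z = b1 b2 / sqrt(b1^2 se2^2 + b2^2 se1^2) — the
#'     classical (Sobel) first-order delta variance of a product, each
#'     coefficient paired with the other's standard error.}
#' }
#' Both are exposed so the discrepancy is always inspectable; see the
#' methods vignette for the full discussion.
#'
#' @param beta1,se1 first-step estimate and standard error (se1 > 0).
#' @param beta2,se2 second-step estimate and standard error (se2 > 0).
#' @param variant \code{"paper"} (default) or \code{"sobel"}.
#' @return the Z statistic.
#' @examples
#' mediationZ(-0.173062555, 0.034780511, 0.089986833, 0.026334123)
#' @export
mediationZ <- function(beta1, se1, beta2, se2,
                       variant = c("paper", "sobel")) {
  variant <- match.arg(variant)
  stopifnot(se1 > 0, se2 > 0)
  denom2 <- switch(variant,
                   paper = beta1^2 * se1^2 + beta2^2 * se2^2,
                   sobel = beta1^2 * se2^2 + beta2^2 * se1^2)
  if (denom2 == 0)
    stop("zero delta-method denominator: both effects are zero")
  beta1 * beta2 / sqrt(denom2)
}

#' Significance call for a mediation Z statistic
#'
#' TRUE iff |z| > 1.96, strictly: z-values falling between -1.96 and 1.96
#' inclusive are read as statistically nonsignificant.
#'
#' @param z finite Z statistic.
#' @return logical.
#' @export
significanceCall <- function(z) {
  stopifnot(is.finite(z))
  abs(z) > 1.96
}

#' Proportion of the total effect that is mediated
#'
#' indirect / total.  When the two disagree in sign the ratio is negative
#' and flagged as inconsistent mediation (the mediated pathway opposes the
#' total effect, so the "proportion" is not interpretable as a share).
#'
#' @param indirect indirect effect (beta1 * beta2).
#' @param total total exposure-to-outcome effect (nonzero).
#' @return a list with \code{proportion} and logical \code{inconsistent}.
#' @export
proportionMediated <- function(indirect, total) {
  if (total == 0) stop("total effect is zero: proportion undefined")
  list(proportion = indirect / total,
       inconsistent = sign(indirect) != sign(total) && indirect != 0)
}

#' Assemble a two-step MR mediation result
#'
#' Combines the step-1 (exposure to mediator) and step-2 (mediator to
#' outcome) MR estimates into a [MediationResult]: indirect effect,
#' both delta-method Z variants, the strict significance call, and — when
#' the total exposure-to-outcome estimate is supplied — the proportion
#' mediated.  \code{exposureUsed} records which exposure dataset produced
#' step 1, supporting substitution of an alternative exposure when the
#' primary shows step-1 pleiotropy.
#'
#' @param mediatorId mediator identifier.
#' @param step1 exposure-to-mediator [MREstimate] (exposure's instruments).
#' @param step2 mediator-to-outcome [MREstimate] (mediator's instruments).
#' @param total optional total-effect [MREstimate].
#' @param variant which Z variant drives \code{z} and the call.
#' @param exposureUsed provenance label for the step-1 exposure dataset.
#' @return a [MediationResult].
#' @export
twoStepMediation <- function(mediatorId, step1, step2, total = NULL,
                             variant = c("paper", "sobel"),
                             exposureUsed = NA_character_) {
  variant <- match.arg(variant)
  stopifnot(is(step1, "MREstimate"), is(step2, "MREstimate"))
  b1 <- mrBeta(step1); s1 <- mrSe(step1)
  b2 <- mrBeta(step2); s2 <- mrSe(step2)
  indirect <- indirectEffect(b1, b2)
  zp <- if (b1 == 0 && b2 == 0) 0 else mediationZ(b1, s1, b2, s2, "paper")
  zs <- if (b1 == 0 && b2 == 0) 0 else mediationZ(b1, s1, b2, s2, "sobel")
  z <- if (variant == "paper") zp else zs
  tot <- NA_real_
  prop <- NA_real_
  incons <- FALSE
  if (!is.null(total)) {
    stopifnot(is(total, "MREstimate"))
    tot <- mrBeta(total)
    if (tot != 0) {
      pm <- proportionMediated(indirect, tot)
      prop <- pm$proportion
      incons <- pm$inconsistent
    }
  }
  new("MediationResult", mediatorId = mediatorId, beta1 = b1, se1 = s1,
      beta2 = b2, se2 = s2, indirect = indirect, z = z, zPaper = zp,
      zSobel = zs, variant = variant, significant = significanceCall(z),
      total = tot, propMediated = prop, inconsistent = incons,
      exposureUsed = exposureUsed)
}
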