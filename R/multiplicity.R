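.check_pvals <- function(p) {
  if (length(p) == 0) stop("empty p-value collection")
  if (any(!is.finite(p) | p <= 0 | p > 1))
    stop("p-values must lie in (0, 1]")
  p
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Standard step-up q-values: with p sorted ascending,
#' q_(i) = min over j >= i of min(1, m p_(j) / j), returned in the input
#' order.  Controls the expected false-discovery proportion within one
#' analysis family.
#'
#' @param p p-values in (0, 1].
#' @return q-values, same length and order as \code{p}.
#' @examples
#' bhAdjust(c(2.21e-3, 4.28e-3, 3.43e-4))
#' @export
bhAdjust <- function(p) {
  p.adjust(.check_pvals(p), method = "BH")
}

#' Bonferroni adjustment
#'
#' min(1, m p) elementwise; \code{m} may exceed the collection length when
#' the family is larger than the p-values at hand.
#'
#' @param p p-values in (0, 1].
#' @param m family size (>= length(p)).
#' @return adjusted p-values, capped at 1.
#' @export
bonferroniAdjust <- function(p, m = length(p)) {
  .check_pvals(p)
  if (m < 1) stop("family size m must be >= 1")
  if (m < length(p)) stop("family size m must be >= length(p)")
  pmin(1, m * p)
}

#' Adjust one analysis family both ways
#'
#' @param p p-values in (0, 1].
#' @param familyId label for the family (e.g. an outcome id).
#' @param m family size for Bonferroni (default length(p)).
#' @return a data.frame with columns \code{family_id}, \code{raw_p},
#'   \code{q_bh}, \code{p_bonf}; family size attached as
#'   \code{attr(x, "m")}.
#' @export
adjustFamily <- function(p, familyId = "family", m = length(p)) {
  out <- data.frame(family_id = familyId, raw_p = p, q_bh = bhAdjust(p),
                    p_bonf = bonferroniAdjust(p, m),
                    stringsAsFactors = FALSE)
  attr(out, "m") <- m
  out
}
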