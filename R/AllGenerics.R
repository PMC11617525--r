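#' Accessors for package classes
#'
#' Small accessor generics so user code never touches slots directly:
#' \code{traitId} and \code{records} for [SumStats], \code{retained} and
#' \code{nRetained} for [HarmonizedSet], \code{mrBeta}, \code{mrSe},
#' \code{mrPval} and \code{nSnp} for [MREstimate].
#'
#' @param x an object of the documented class.
#' @return the slot value; \code{retained} returns the data.frame of
#'   non-dropped SNPs, \code{records} the full per-SNP table.
#' @name accessors
#' @aliases traitId records retained nRetained mrBeta mrSe mrPval nSnp
#' @examples
#' est <- waldRatio(0.1, 0.02, 0.05, 0.01)
#' mrBeta(est); mrSe(est); mrPval(est); nSnp(est)
NULL

#' @rdname accessors
#' @export
setGeneric("traitId", function(x) standardGeneric("traitId"))
#' @rdname accessors
#' @export
setGeneric("records", function(x) standardGeneric("records"))
#' @rdname accessors
#' @export
setGeneric("retained", function(x) standardGeneric("retained"))
#' @rdname accessors
#' @export
setGeneric("nRetained", function(x) standardGeneric("nRetained"))
#' @rdname accessors
#' @export
setGeneric("mrBeta", function(x) standardGeneric("mrBeta"))
#' @rdname accessors
#' @export
setGeneric("mrSe", function(x) standardGeneric("mrSe"))
#' @rdname accessors
#' @export
setGeneric("mrPval", function(x) standardGeneric("mrPval"))
#' @rdname accessors
#' @export
setGeneric("nSnp", function(x) standardGeneric("nSnp"))

#' @rdname accessors
setMethod("traitId", "SumStats", function(x) x@traitId)
#' @rdname accessors
setMethod("records", "SumStats", function(x) x@data)
#' @rdname accessors
setMethod("records", "HarmonizedSet", function(x) x@data)
#' @rdname accessors
setMethod("retained", "HarmonizedSet", function(x)
  x@data[!startsWith(x@data$action, "dropped"), , drop = FALSE])
#' @rdname accessors
setMethod("nRetained", "HarmonizedSet", function(x) nrow(retained(x)))
#' @rdname accessors
setMethod("mrBeta", "MREstimate", function(x) x@beta)
#' @rdname accessors
setMethod("mrSe", "MREstimate", function(x) x@se)
#' @rdname accessors
setMethod("mrPval", "MREstimate", function(x) x@pval)
#' @rdname accessors
setMethod("nSnp", "MREstimate", function(x) x@nSnp)

setMethod("show", "SumStats", function(object) {
  cat(sprintf("SumStats: %s (%s)\n", object@traitId, object@traitLabel))
  cat(sprintf("  %d SNP records", nrow(object@data)))
  if (!is.na(object@nDefault))
    cat(sprintf(", default n = %g", object@nDefault))
  cat("\n")
})

setMethod("show", "HarmonizedSet", function(object) {
  acts <- table(factor(object@data$action, levels = HARMONIZE_ACTIONS))
  cat(sprintf("HarmonizedSet: %s -> %s\n", object@exposureId,
              object@outcomeId))
  cat(sprintf("  %d SNPs shared, %d retained\n", nrow(object@data),
              nRetained(object)))
  for (a in names(acts)[acts > 0])
    cat(sprintf("    %-22s %d\n", a, acts[[a]]))
})

setMethod("show", "MREstimate", function(object) {
  cat(sprintf("MREstimate [%s]: beta = %.6g (se %.6g), p = %.3g, %d SNPs\n",
              object@method, object@beta, object@se, object@pval,
              object@nSnp))
  if (!is.null(object@extra$intercept))
    cat(sprintf("  intercept = %.6g (se %.6g), p = %.3g\n",
                object@extra$intercept, object@extra$intercept_se,
                object@extra$intercept_pval))
})

setMethod("show", "HeterogeneityResult", function(object) {
  cat(sprintf("Cochran's Q = %.4g on %d df, p = %.3g\n", object@q,
              object@df, object@pval))
})

setMethod("show", "PleiotropyTest", function(object) {
  cat(sprintf("Egger intercept = %.6g (se %.6g), p = %.3g%s\n",
              object@intercept, object@se, object@pval,
              if (object@pval < 0.05) " [pleiotropy indicated]" else ""))
})

setMethod("show", "PressoResult", function(object) {
  cat(sprintf("MR-PRESSO: global p = %.3g (%d simulations)\n",
              object@globalPval, object@nSim))
  if (length(object@outliers)) {
    cat(sprintf("  outliers: %s\n", paste(object@outliers, collapse = ", ")))
    cat(sprintf("  raw beta = %.6g, corrected beta = %.6g\n",
                object@raw@beta, object@corrected@beta))
  } else {
    cat(sprintf("  no outliers; raw beta = %.6g\n", object@raw@beta))
  }
})

setMethod("show", "MediationResult", function(object) {
  cat(sprintf("MediationResult: %s\n", object@mediatorId))
  cat(sprintf("  beta1 = %.6g (se %.6g), beta2 = %.6g (se %.6g)\n",
              object@beta1, object@se1, object@beta2, object@se2))
  cat(sprintf("  indirect = %.6g, z[%s] = %.4f (%ssignificant)\n",
              object@indirect, object@variant, object@z,
              if (object@significant) "" else "not "))
  if (is.finite(object@propMediated))
    cat(sprintf("  proportion mediated = %.4g%s\n", object@propMediated,
                if (object@inconsistent) " [inconsistent mediation]" else ""))
})

setMethod("show", "ScreenResult", function(object) {
  r <- object@records
  cat(sprintf("ScreenResult: %d mediators (%d retained, %d excluded, %d untestable)\n",
              nrow(r), sum(is.na(r$exclusion_reason)),
              sum(!is.na(r$exclusion_reason) & r$exclusion_reason != "untestable"),
              sum(r$exclusion_reason %in% "untestable")))
  if (isTRUE(object@manifest$uncorrected_p_screen))
    cat("  note: uncorrected-p screen (no mediator survived FDR)\n")
})
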