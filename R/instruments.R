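#' Instrument-selection settings
#'
#' Constructor for [InstrumentConfig] with the conventional genome-wide
#' defaults: significance p < 5e-8, clumping at r^2 < 0.001 within a
#' 10,000 kb window, and removal of instruments associated with the
#' outcome at p < 1e-8.
#'
#' @param pThreshold,clumpR2,clumpWindowKb,outcomeExclusionP see
#'   [InstrumentConfig].
#' @return an [InstrumentConfig].
#' @export
instrumentConfig <- function(pThreshold = 5e-8, clumpR2 = 0.001,
                             clumpWindowKb = 10000,
                             outcomeExclusionP = 1e-8) {
  new("InstrumentConfig", pThreshold = pThreshold, clumpR2 = clumpR2,
      clumpWindowKb = clumpWindowKb, outcomeExclusionP = outcomeExclusionP)
}

.subset_sumstats <- function(x, keep) {
  d <- x@data[keep, , drop = FALSE]
  rownames(d) <- NULL
  new("SumStats", traitId = x@traitId, traitLabel = x@traitLabel, data = d,
      nDefault = x@nDefault)
}

#' Filter SNPs by association p-value
#'
#' Strict-inequality filter (p < cutoff) preserving row order; the
#' genome-wide significance screen for instrument candidates.
#'
#' @param table a [SumStats].
#' @param pThreshold cutoff (default 5e-8).
#' @return the filtered [SumStats] (possibly empty).
#' @export
selectByPvalue <- function(table, pThreshold = 5e-8) {
  stopifnot(is(table, "SumStats"))
  .subset_sumstats(table, table@data$pval < pThreshold)
}

#' Validate an LD r-squared matrix
#'
#' @param ld square numeric matrix of pairwise r^2 with snp ids as
#'   dimnames, symmetric with unit diagonal and values in [0, 1].
#' @return the matrix, invisibly, after validation.
#' @export
validateLdMatrix <- function(ld) {
  if (!is.matrix(ld) || nrow(ld) != ncol(ld))
    stop("LD matrix must be square")
  if (is.null(rownames(ld)) || !identical(rownames(ld), colnames(ld)))
    stop("LD matrix needs identical snp-id row and column names")
  if (any(ld < 0 | ld > 1, na.rm = TRUE))
    stop("LD r^2 values must lie in [0, 1]")
  if (!isTRUE(all.equal(unname(diag(ld)), rep(1, nrow(ld)))))
    stop("LD matrix diagonal must be 1")
  if (!isTRUE(all.equal(ld, t(ld))))
    stop("LD matrix must be symmetric")
  invisible(ld)
}

#' Read an LD matrix from a TSV file
#'
#' Accepts either a square matrix (header row and first column are snp
#' ids) or a long format with columns \code{snp_a}, \code{snp_b},
#' \code{r2} (symmetrized; unlisted pairs are 0).
#'
#' @param path file to read.
#' @return a validated square r^2 matrix.
#' @export
readLdMatrix <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- read.delim(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, check.names = FALSE)
  if (all(c("snp_a", "snp_b", "r2") %in% names(raw))) {
    ids <- sort(unique(c(raw$snp_a, raw$snp_b)))
    ld <- diag(1, length(ids))
    dimnames(ld) <- list(ids, ids)
    ld[cbind(match(raw$snp_a, ids), match(raw$snp_b, ids))] <- raw$r2
    ld[cbind(match(raw$snp_b, ids), match(raw$snp_a, ids))] <- raw$r2
  } else {
    ld <- as.matrix(raw[, -1, drop = FALSE])
    rownames(ld) <- as.character(raw[[1]])
  }
  validateLdMatrix(ld)
  ld
}

#' Greedy LD clumping
#'
#' Prunes correlated instruments: repeatedly takes the lowest-p unclaimed
#' SNP as an index (ties broken lexicographically on snp id) and removes
#' every unclaimed SNP linked to it, i.e. with r^2 >= \code{r2Cutoff} to
#' the index AND within \code{windowKb} on the same chromosome.  Without
#' an LD matrix all SNPs are treated as unlinked (input returned); when
#' chromosome/position are missing the window test is skipped and the LD
#' matrix alone governs.
#'
#' @param table a [SumStats].
#' @param ld optional square r^2 matrix (snp ids as dimnames) covering at
#'   least the table's SNPs.
#' @param r2Cutoff LD threshold (default 0.001).
#' @param windowKb distance window in kb (default 10000).
#' @return the clumped [SumStats], in original row order.
#' @export
ldClump <- function(table, ld = NULL, r2Cutoff = 0.001, windowKb = 10000) {
  stopifnot(is(table, "SumStats"))
  d <- table@data
  if (is.null(ld) || nrow(d) <= 1) return(table)
  validateLdMatrix(ld)
  if (!all(d$snp %in% rownames(ld)))
    stop("LD matrix does not cover all table SNPs: ",
         paste(setdiff(d$snp, rownames(ld)), collapse = ", "))
  ld <- ld[d$snp, d$snp, drop = FALSE]

  unclaimed <- rep(TRUE, nrow(d))
  keep <- logical(nrow(d))
  ord <- order(d$pval, d$snp)   # deterministic tie-break on snp id
  for (i in ord) {
    if (!unclaimed[i]) next
    keep[i] <- TRUE
    unclaimed[i] <- FALSE
    linked <- unclaimed & ld[i, ] >= r2Cutoff
    # window condition only where both positions are known
    same_chr <- !is.na(d$chrom) & !is.na(d$chrom[i]) & d$chrom == d$chrom[i]
    have_pos <- !is.na(d$pos) & !is.na(d$pos[i])
    within <- ifelse(have_pos & !is.na(d$chrom[i]) & !is.na(d$chrom),
                     same_chr & abs(d$pos - d$pos[i]) <= windowKb * 1000,
                     TRUE)
    unclaimed[linked & within] <- FALSE
  }
  .subset_sumstats(table, keep)
}

#' Remove instruments associated with the outcome
#'
#' Confounding guard: instruments whose outcome-association p-value falls
#' below \code{pCutoff} are removed.  Instruments absent from the outcome
#' table are retained with a warning.
#'
#' @param instruments instrument [SumStats] (exposure side).
#' @param outcome outcome [SumStats].
#' @param pCutoff removal threshold (default 1e-8).
#' @return the filtered [SumStats]; removals (with their outcome p) are
#'   recorded in \code{attr(x, "removed")}.
#' @export
excludeOutcomeAssociated <- function(instruments, outcome, pCutoff = 1e-8) {
  stopifnot(is(instruments, "SumStats"), is(outcome, "SumStats"))
  p_out <- outcome@data$pval[match(instruments@data$snp, outcome@data$snp)]
  absent <- is.na(p_out)
  if (any(absent))
    warning(sprintf("%d instrument(s) absent from outcome table, retained: %s",
                    sum(absent),
                    paste(instruments@data$snp[absent], collapse = ", ")),
            call. = FALSE)
  drop <- !absent & p_out < pCutoff
  out <- .subset_sumstats(instruments, !drop)
  attr(out, "removed") <- data.frame(snp = instruments@data$snp[drop],
                                     outcome_pval = p_out[drop],
                                     stringsAsFactors = FALSE)
  out
}

#' Per-SNP instrument strength
#'
#' Variance in the exposure explained by one instrument and the
#' corresponding F statistic, under the standardized-trait approximation:
#' R^2 = 2 eaf (1 - eaf) beta^2 and F = (n - 2) R^2 / (1 - R^2).  The
#' chi-square approximation (beta/se)^2 is reported alongside as a
#' cross-check.  When eaf or n is unavailable the R^2/F pair is NA (the
#' chi-square approximation only needs beta and se).
#'
#' @param record one-row data.frame (or list) with \code{snp}, \code{eaf},
#'   \code{beta}, \code{se} and optionally \code{n}.
#' @param n sample size override.
#' @return a one-row data.frame: \code{snp}, \code{r_squared},
#'   \code{f_stat}, \code{f_chisq_approx}.
#' @export
instrumentStrength <- function(record, n = record$n) {
  eaf <- record$eaf
  f_approx <- (record$beta / record$se)^2
  if (is.null(n)) n <- NA_real_
  if (is.na(eaf) || is.na(n)) {
    r2 <- NA_real_
    f <- NA_real_
  } else {
    r2 <- 2 * eaf * (1 - eaf) * record$beta^2
    f <- (n - 2) * r2 / (1 - r2)
  }
  data.frame(snp = as.character(record$snp), r_squared = r2, f_stat = f,
             f_chisq_approx = f_approx, stringsAsFactors = FALSE)
}

#' Select instruments for one exposure
#'
#' The standard cascade: genome-wide significance filter, greedy LD
#' clumping, then removal of outcome-associated SNPs (when an outcome
#' table is supplied).
#'
#' @param exposure exposure [SumStats].
#' @param outcome optional outcome [SumStats] for the exclusion step.
#' @param config an [InstrumentConfig].
#' @param ld optional LD r^2 matrix for clumping.
#' @return the instrument [SumStats].
#' @export
selectInstruments <- function(exposure, outcome = NULL,
                              config = instrumentConfig(), ld = NULL) {
  out <- selectByPvalue(exposure, config@pThreshold)
  out <- ldClump(out, ld = ld, r2Cutoff = config@clumpR2,
                 windowKb = config@clumpWindowKb)
  if (!is.null(outcome))
    out <- excludeOutcomeAssociated(out, outcome, config@outcomeExclusionP)
  out
}
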