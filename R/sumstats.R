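#' Construct a summary-statistics table
#'
#' Validates and packages a data.frame of per-SNP association records.  Rows
#' violating the record invariants (non-positive SE, frequency outside
#' [0, 1], p-value outside (0, 1], identical alleles, duplicated snp id) can
#' either abort or be dropped with row-indexed diagnostics.
#'
#' @param data data.frame with columns \code{snp}, \code{effect_allele},
#'   \code{other_allele}, \code{beta}, \code{se}, \code{pval} and optionally
#'   \code{chrom}, \code{pos}, \code{eaf}, \code{n}.
#' @param traitId,traitLabel trait identifier and label.
#' @param nDefault sample size used when per-SNP \code{n} is missing.
#' @param onInvalid \code{"error"} to abort on an invalid row, \code{"drop"}
#'   to discard invalid rows with a warning naming each row and the violated
#'   invariant.
#' @return a [SumStats] object; when rows were dropped, the diagnostics are
#'   attached as \code{attr(x, "rejected")}.
#' @examples
#' tab <- sumStats(data.frame(snp = "rs1", effect_allele = "A",
#'   other_allele = "G", eaf = 0.3, beta = 0.1, se = 0.02, pval = 1e-9),
#'   traitId = "trait-1")
#' @export
sumStats <- function(data, traitId = "trait", traitLabel = traitId,
                     nDefault = NA_real_, onInvalid = c("error", "drop")) {
  onInvalid <- match.arg(onInvalid)
  mandatory <- c("snp", "effect_allele", "other_allele", "beta", "se", "pval")
  miss <- setdiff(mandatory, names(data))
  if (length(miss))
    stop("missing mandatory column(s): ", paste(miss, collapse = ", "))
  for (col in setdiff(SUMSTAT_COLS, names(data)))
    data[[col]] <- if (col %in% c("chrom")) NA_character_ else NA_real_
  data <- data[SUMSTAT_COLS]
  data$snp <- as.character(data$snp)
  data$chrom <- as.character(data$chrom)
  data$effect_allele <- toupper(as.character(data$effect_allele))
  data$other_allele <- toupper(as.character(data$other_allele))
  for (col in c("pos", "eaf", "beta", "se", "pval", "n"))
    data[[col]] <- as.numeric(data[[col]])

  bad <- .invalid_rows(data)
  if (nrow(bad) > 0) {
    diag <- sprintf("row %d (%s): %s", bad$row, bad$snp, bad$why)
    if (onInvalid == "error")
      stop("invalid summary-statistic rows:\n  ",
           paste(diag, collapse = "\n  "))
    warning(sprintf("dropped %d invalid row(s):\n  %s", nrow(bad),
                    paste(diag, collapse = "\n  ")), call. = FALSE)
    data <- data[-bad$row, , drop = FALSE]
  }
  rownames(data) <- NULL
  out <- new("SumStats", traitId = traitId, traitLabel = traitLabel,
             data = data, nDefault = as.numeric(nDefault))
  if (nrow(bad) > 0) attr(out, "rejected") <- bad
  out
}

# row-indexed invariant diagnostics for a normalized record data.frame
.invalid_rows <- function(d) {
  why <- vector("list", nrow(d))
  flag <- function(idx, msg) {
    for (i in which(idx)) why[[i]] <<- c(why[[i]], msg)
  }
  flag(is.na(d$snp) | d$snp == "", "missing snp id")
  flag(duplicated(d$snp), "duplicated snp id")
  flag(!is.finite(d$beta), "beta not numeric")
  flag(!is.finite(d$se) | d$se <= 0, "se must be > 0")
  flag(!is.finite(d$pval) | d$pval <= 0 | d$pval > 1,
       "pval must lie in (0, 1]")
  flag(!is.na(d$eaf) & (d$eaf < 0 | d$eaf > 1), "eaf must lie in [0, 1]")
  flag(!is.na(d$effect_allele) & d$effect_allele == d$other_allele,
       "effect_allele equals other_allele")
  rows <- which(lengths(why) > 0)
  data.frame(row = rows, snp = d$snp[rows],
             why = vapply(why[rows], paste, "", collapse = "; "),
             stringsAsFactors = FALSE)
}

#' Read GWAS summary statistics from a delimited file
#'
#' Reads a tab-separated table with a header row into a [SumStats] object.
#' Column names can be remapped through \code{dialect} so that both the
#' package's canonical format and external exports load.  Rows violating the
#' record invariants are rejected with row-indexed diagnostics.
#'
#' @param path file to read.
#' @param traitId,traitLabel trait metadata (default: the file name).
#' @param dialect named character vector mapping canonical column names
#'   (\code{snp}, \code{chrom}, \code{pos}, \code{effect_allele},
#'   \code{other_allele}, \code{eaf}, \code{beta}, \code{se}, \code{pval},
#'   \code{n}) to the names used in the file.
#' @param nDefault default sample size.
#' @param sep field separator (tab by default).
#' @return a [SumStats]; invalid rows are dropped with a warning and
#'   reported in \code{attr(x, "rejected")}.
#' @seealso [writeSumstats()]
#' @export
readSumstats <- function(path, traitId = basename(path),
                         traitLabel = traitId, dialect = character(),
                         nDefault = NA_real_, sep = "\t") {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- read.delim(path, sep = sep, header = TRUE, stringsAsFactors = FALSE,
                    na.strings = c("NA", ""), check.names = FALSE)
  for (canon in names(dialect)) {
    src <- dialect[[canon]]
    if (!src %in% names(raw))
      stop(sprintf("mapped column '%s' (for '%s') not in header", src, canon))
    names(raw)[names(raw) == src] <- canon
  }
  mandatory <- c("snp", "effect_allele", "other_allele", "beta", "se", "pval")
  miss <- setdiff(mandatory, names(raw))
  if (length(miss))
    stop("missing mandatory column(s): ", paste(miss, collapse = ", "))
  sumStats(raw, traitId = traitId, traitLabel = traitLabel,
           nDefault = nDefault, onInvalid = "drop")
}

#' Write a summary-statistics table
#'
#' Serializes a [SumStats] to a tab-separated file with the canonical
#' header; missing values are written as \code{"NA"}.  The output
#' round-trips bit-identically through [readSumstats()].
#'
#' @param x a [SumStats].
#' @param path destination file.
#' @return \code{path}, invisibly.
#' @export
writeSumstats <- function(x, path) {
  stopifnot(is(x, "SumStats"))
  d <- x@data
  num <- vapply(d, is.numeric, logical(1))
  d[num] <- lapply(d[num], function(v) {
    out <- sprintf("%.17g", v)
    out[is.na(v)] <- NA_character_
    out
  })
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA")
  invisible(path)
}

.COMPLEMENT <- c(A = "T", T = "A", C = "G", G = "C")

.complement <- function(a) {
  out <- .COMPLEMENT[a]
  out[is.na(out)] <- NA_character_
  unname(out)
}

.is_palindromic <- function(a1, a2) {
  !is.na(a1) & !is.na(a2) & a1 %in% names(.COMPLEMENT) &
    .COMPLEMENT[a1] == a2
}

#' Harmonize exposure and outcome summary statistics
#'
#' Aligns the outcome effects of every SNP shared between two tables onto
#' the exposure's effect allele, the prerequisite for every two-sample MR
#' estimator.  Per SNP: identical alleles are kept unchanged; swapped
#' alleles have the outcome beta negated (action \code{allele_swap}); strand
#' complements are complemented and re-matched (\code{strand_flip}; a
#' complement that also needs swapping is recorded as \code{allele_swap}
#' since the sign change is the estimand-relevant action); palindromic (A/T
#' or C/G) SNPs are dropped under \code{palindromePolicy = "drop"}, and
#' under \code{"infer_by_eaf"} are aligned by allele frequency unless either
#' frequency lies within \code{eafWindow} of 0.5 (or is missing), in which
#' case alignment is undecidable and the SNP is dropped
#' (\code{dropped_palindromic}); irreconcilable allele pairs are dropped
#' (\code{dropped_incompatible}).
#'
#' @param exposure,outcome [SumStats] tables sharing at least one snp id.
#' @param palindromePolicy \code{"infer_by_eaf"} (default) or \code{"drop"}.
#' @param eafWindow half-width of the ambiguity window around 0.5 used by
#'   \code{"infer_by_eaf"} (default 0.08: drop when eaf is in [0.42, 0.58]).
#' @return a [HarmonizedSet]; every action is recorded per SNP.
#' @examples
#' exp <- sumStats(data.frame(snp = "rs1", effect_allele = "A",
#'   other_allele = "G", eaf = 0.3, beta = 0.1, se = 0.02, pval = 1e-9))
#' out <- sumStats(data.frame(snp = "rs1", effect_allele = "G",
#'   other_allele = "A", eaf = 0.7, beta = -0.05, se = 0.01, pval = 1e-6),
#'   traitId = "outcome")
#' retained(harmonize(exp, out))  # beta_out back on the A allele: +0.05
#' @export
harmonize <- function(exposure, outcome,
                      palindromePolicy = c("infer_by_eaf", "drop"),
                      eafWindow = 0.08) {
  stopifnot(is(exposure, "SumStats"), is(outcome, "SumStats"))
  palindromePolicy <- match.arg(palindromePolicy)
  if (nrow(exposure@data) == 0 || nrow(outcome@data) == 0)
    stop("empty input table: both exposure and outcome need records")
  shared <- intersect(exposure@data$snp, outcome@data$snp)
  if (length(shared) == 0)
    stop("no shared SNPs between exposure and outcome tables")

  e <- exposure@data[match(shared, exposure@data$snp), ]
  o <- outcome@data[match(shared, outcome@data$snp), ]
  n <- length(shared)
  beta_out <- o$beta
  action <- character(n)

  for (i in seq_len(n)) {
    e1 <- e$effect_allele[i]; e2 <- e$other_allele[i]
    o1 <- o$effect_allele[i]; o2 <- o$other_allele[i]
    pal <- .is_palindromic(e1, e2)
    if (pal) {
      if (!setequal(c(e1, e2), c(o1, o2))) {
        action[i] <- "dropped_incompatible"
        next
      }
      if (palindromePolicy == "drop") {
        action[i] <- "dropped_palindromic"
        next
      }
      fe <- e$eaf[i]
      fo <- if (o1 == e1) o$eaf[i] else 1 - o$eaf[i]
      if (is.na(fe) || is.na(fo) ||
          abs(fe - 0.5) <= eafWindow || abs(fo - 0.5) <= eafWindow) {
        action[i] <- "dropped_palindromic"
        next
      }
      # frequencies on the exposure effect allele: same side of 0.5 means
      # the outcome effect allele is the same physical allele
      if ((fe - 0.5) * (fo - 0.5) > 0) {
        action[i] <- "unchanged"
      } else {
        beta_out[i] <- -beta_out[i]
        action[i] <- "allele_swap"
      }
      next
    }
    if (o1 == e1 && o2 == e2) {
      action[i] <- "unchanged"
    } else if (o1 == e2 && o2 == e1) {
      beta_out[i] <- -beta_out[i]
      action[i] <- "allele_swap"
    } else {
      c1 <- .complement(o1); c2 <- .complement(o2)
      if (!is.na(c1) && !is.na(c2) && c1 == e1 && c2 == e2) {
        action[i] <- "strand_flip"
      } else if (!is.na(c1) && !is.na(c2) && c1 == e2 && c2 == e1) {
        beta_out[i] <- -beta_out[i]
        action[i] <- "allele_swap"
      } else {
        action[i] <- "dropped_incompatible"
      }
    }
  }

  dropped <- startsWith(action, "dropped")
  d <- data.frame(snp = shared,
                  beta_exp = ifelse(dropped, NA_real_, e$beta),
                  se_exp = ifelse(dropped, NA_real_, e$se),
                  beta_out = ifelse(dropped, NA_real_, beta_out),
                  se_out = ifelse(dropped, NA_real_, o$se),
                  eaf_exp = e$eaf,
                  action = action,
                  stringsAsFactors = FALSE)
  new("HarmonizedSet", exposureId = exposure@traitId,
      outcomeId = outcome@traitId, data = d)
}

# internal: build a HarmonizedSet straight from aligned effect vectors
# (simulator output and tests use it to bypass allele bookkeeping)
.harmonized_from_vectors <- function(beta_exp, se_exp, beta_out, se_out,
                                     snp = sprintf("snp_%03d",
                                                   seq_along(beta_exp)),
                                     eaf_exp = NA_real_,
                                     exposureId = "exposure",
                                     outcomeId = "outcome") {
  new("HarmonizedSet", exposureId = exposureId, outcomeId = outcomeId,
      data = data.frame(snp = snp, beta_exp = beta_exp, se_exp = se_exp,
                        beta_out = beta_out, se_out = se_out,
                        eaf_exp = eaf_exp, action = "unchanged",
                        stringsAsFactors = FALSE))
}

#' Pair two summary-statistics tables on a set of instruments
#'
#' Convenience wrapper: restricts \code{exposure} to \code{snps} (when
#' given) and harmonizes against \code{outcome}.
#'
#' @param exposure,outcome [SumStats] tables.
#' @param snps optional snp ids (instruments) to keep on the exposure side.
#' @param ... passed to [harmonize()].
#' @return a [HarmonizedSet].
#' @export
harmonizePair <- function(exposure, outcome, snps = NULL, ...) {
  if (!is.null(snps)) {
    d <- exposure@data[exposure@data$snp %in% snps, , drop = FALSE]
    exposure <- new("SumStats", traitId = exposure@traitId,
                    traitLabel = exposure@traitLabel, data = d,
                    nDefault = exposure@nDefault)
  }
  harmonize(exposure, outcome, ...)
}
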