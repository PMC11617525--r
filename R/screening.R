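#' Build a mediator-screening configuration
#'
#' Arguments may be [SumStats] objects or file paths (paths are loaded with
#' [readSumstats()]).
#'
#' @param exposure primary exposure table or path.
#' @param outcome outcome table or path.
#' @param mediators list of mediator tables or character vector of paths.
#' @param exposureFallback optional alternative exposure dataset used for a
#'   mediator path when the primary shows step-1 pleiotropy.
#' @param instruments an [InstrumentConfig].
#' @param ivwMode IVW variance mode used throughout ("hybrid" default).
#' @param nBoot weighted-median bootstrap iterations.
#' @param seed RNG seed for every stochastic step of the run.
#' @param qCutoff FDR level for the q-value gates (default 0.05).
#' @param pleiotropyP Egger-intercept cutoff for pleiotropy exclusion.
#' @param fallbackToRawP rescreen at uncorrected p < 0.05 when no mediator
#'   survives the FDR screen (default TRUE).
#' @return a [ScreeningConfig].
#' @export
screeningConfig <- function(exposure, outcome, mediators,
                            exposureFallback = NULL,
                            instruments = instrumentConfig(),
                            ivwMode = "hybrid", nBoot = 1000L, seed = 1L,
                            qCutoff = 0.05, pleiotropyP = 0.05,
                            fallbackToRawP = TRUE) {
  load_tab <- function(x, role) {
    if (is(x, "SumStats")) return(x)
    if (is.character(x) && length(x) == 1)
      return(readSumstats(x, traitId = basename(x)))
    stop(role, " must be a SumStats object or a file path")
  }
  exposure <- load_tab(exposure, "exposure")
  outcome <- load_tab(outcome, "outcome")
  if (is.character(mediators)) mediators <- as.list(mediators)
  if (!is.list(mediators) || length(mediators) == 0)
    stop("mediators must be a non-empty list of tables or paths")
  mediators <- lapply(mediators, load_tab, role = "mediator")
  nm <- names(mediators)
  ids <- vapply(mediators, traitId, "")
  names(mediators) <- if (is.null(nm)) ids else ifelse(nm == "", ids, nm)
  if (!is.null(exposureFallback))
    exposureFallback <- load_tab(exposureFallback, "exposureFallback")
  new("ScreeningConfig", exposure = exposure,
      exposureFallback = exposureFallback, outcome = outcome,
      mediators = mediators, instruments = instruments, ivwMode = ivwMode,
      nBoot = as.integer(nBoot), seed = as.integer(seed),
      qCutoff = qCutoff, pleiotropyP = pleiotropyP,
      fallbackToRawP = fallbackToRawP)
}

# one exposure -> outcome MR fit: instrument selection, harmonization,
# IVW + Egger-intercept diagnostics; NULL estimate when untestable
.mr_pair <- function(exposure, outcome, config) {
  inst <- selectInstruments(exposure, outcome = outcome,
                            config = config@instruments)
  if (nrow(records(inst)) == 0)
    return(list(untestable = TRUE, reason = "no genome-wide-significant SNPs"))
  set <- suppressWarnings(harmonize(exposure = inst, outcome = outcome))
  if (nRetained(set) < 1)
    return(list(untestable = TRUE,
                reason = "no harmonizable instruments"))
  est <- mrIvw(set, mode = config@ivwMode)
  pleio <- if (nRetained(set) >= 3 &&
               var(retained(set)$beta_exp) > 0) eggerInterceptTest(set)
           else NULL
  list(untestable = FALSE, set = set, estimate = est, pleiotropy = pleio,
       n_snp = nRetained(set))
}

.rec_block <- function(fit) {
  if (isTRUE(fit$untestable))
    return(data.frame(n_snp = NA_integer_, beta = NA_real_, se = NA_real_,
                      pval = NA_real_, egger_intercept = NA_real_,
                      egger_se = NA_real_, egger_pval = NA_real_))
  p <- fit$pleiotropy
  data.frame(n_snp = fit$n_snp, beta = mrBeta(fit$estimate),
             se = mrSe(fit$estimate), pval = mrPval(fit$estimate),
             egger_intercept = if (is.null(p)) NA_real_ else p@intercept,
             egger_se = if (is.null(p)) NA_real_ else p@se,
             egger_pval = if (is.null(p)) NA_real_ else p@pval)
}

#' Run the mediator-screening cascade
#'
#' The end-to-end two-step MR mediation screen over a mediator panel:
#' \enumerate{
#'   \item total exposure-to-outcome effect (IVW on the exposure's
#'     instruments);
#'   \item per mediator, step 1: exposure-to-mediator MR; when the primary
#'     exposure shows an Egger-intercept p below \code{pleiotropyP} and a
#'     fallback exposure is configured, the fallback dataset is substituted
#'     for that path (provenance recorded);
#'   \item per mediator, step 2: mediator-to-outcome MR with the mediator's
#'     own instruments;
#'   \item Benjamini-Hochberg q-values within the step-1 and step-2
#'     families (family size = mediators actually testable);
#'   \item exclusions applied in a fixed, logged order: step-2 nominal
#'     p >= 0.05; step-2 q >= qCutoff; Egger-intercept p < pleiotropyP in
#'     either step; step-1 q >= qCutoff; |Z| <= 1.96;
#'   \item retained mediators get a [MediationResult] including the
#'     proportion mediated against the total effect.
#' }
#' When no mediator passes the step-2 FDR screen and \code{fallbackToRawP}
#' is set, the q-value gates are replaced by uncorrected p < 0.05 gates and
#' the manifest flags the run as an uncorrected-p screen.  A mediator whose
#' tables yield no genome-wide-significant instruments is marked untestable
#' rather than failing the run.
#'
#' @param config a [ScreeningConfig].
#' @return a [ScreenResult]: per-mediator records, mediation results for
#'   survivors, the total-effect estimate, and a manifest with seeds,
#'   provenance and per-stage filter counts.
#' @export
runScreen <- function(config) {
  stopifnot(is(config, "ScreeningConfig"))
  validObject(config)
  K <- length(config@mediators)
  med_ids <- names(config@mediators)

  total_fit <- .mr_pair(config@exposure, config@outcome, config)
  if (isTRUE(total_fit$untestable))
    stop("exposure-outcome total effect untestable: ", total_fit$reason)
  total <- total_fit$estimate

  step1 <- vector("list", K)
  step2 <- vector("list", K)
  provenance <- character(K)
  for (k in seq_len(K)) {
    med <- config@mediators[[k]]
    s1 <- .mr_pair(config@exposure, med, config)
    provenance[k] <- traitId(config@exposure)
    if (!isTRUE(s1$untestable) && !is.null(s1$pleiotropy) &&
        s1$pleiotropy@pval < config@pleiotropyP &&
        !is.null(config@exposureFallback)) {
      s1_alt <- .mr_pair(config@exposureFallback, med, config)
      if (!isTRUE(s1_alt$untestable)) {
        s1 <- s1_alt
        provenance[k] <- traitId(config@exposureFallback)
      }
    }
    step1[[k]] <- s1
    step2[[k]] <- .mr_pair(med, config@outcome, config)
  }

  untestable <- vapply(seq_len(K), function(k)
    isTRUE(step1[[k]]$untestable) || isTRUE(step2[[k]]$untestable),
    logical(1))
  testable <- which(!untestable)

  b1 <- do.call(rbind, lapply(step1, .rec_block))
  names(b1) <- paste0("step1_", names(b1))
  b2 <- do.call(rbind, lapply(step2, .rec_block))
  names(b2) <- paste0("step2_", names(b2))
  rec <- cbind(data.frame(mediator_id = med_ids,
                          exposure_used = provenance,
                          stringsAsFactors = FALSE), b1, b2)
  rec$step1_q <- NA_real_
  rec$step2_q <- NA_real_
  if (length(testable)) {
    rec$step1_q[testable] <- bhAdjust(rec$step1_pval[testable])
    rec$step2_q[testable] <- bhAdjust(rec$step2_pval[testable])
  }

  # fallback to the uncorrected-p screen iff nothing survives the step-2
  # FDR screen
  fdr_survivors <- sum(rec$step2_q[testable] < config@qCutoff)
  raw_screen <- config@fallbackToRawP && length(testable) > 0 &&
    fdr_survivors == 0

  reason <- rep(NA_character_, K)
  reason[untestable] <- "untestable"
  z <- rep(NA_real_, K)
  for (k in testable) {
    z[k] <- mediationZ(rec$step1_beta[k], rec$step1_se[k],
                       rec$step2_beta[k], rec$step2_se[k],
                       variant = "paper")
    gate2_fdr <- if (raw_screen) rec$step2_pval[k] >= 0.05
                 else rec$step2_q[k] >= config@qCutoff
    gate1_fdr <- if (raw_screen) rec$step1_pval[k] >= 0.05
                 else rec$step1_q[k] >= config@qCutoff
    pleio <- (!is.na(rec$step1_egger_pval[k]) &&
                rec$step1_egger_pval[k] < config@pleiotropyP) ||
             (!is.na(rec$step2_egger_pval[k]) &&
                rec$step2_egger_pval[k] < config@pleiotropyP)
    reason[k] <- if (rec$step2_pval[k] >= 0.05) "step2_not_significant"
      else if (gate2_fdr) "failed_fdr"
      else if (pleio) "horizontal_pleiotropy"
      else if (gate1_fdr) "step1_not_significant"
      else if (abs(z[k]) <= 1.96) "mediation_z_nonsignificant"
      else NA_character_
  }
  rec$z <- z
  rec$indirect <- rec$step1_beta * rec$step2_beta
  rec$exclusion_reason <- reason
  retained_ids <- rec$mediator_id[is.na(reason)]

  mediations <- lapply(which(is.na(reason)), function(k) {
    twoStepMediation(rec$mediator_id[k],
                     step1[[k]]$estimate, step2[[k]]$estimate,
                     total = total, variant = "paper",
                     exposureUsed = provenance[k])
  })
  names(mediations) <- retained_ids
  rec$prop_mediated <- NA_real_
  rec$prop_mediated[is.na(reason)] <-
    vapply(mediations, function(m) m@propMediated, numeric(1))

  counts <- c(panel = K, untestable = sum(untestable),
              testable = length(testable),
              step2_not_significant = sum(reason %in% "step2_not_significant"),
              failed_fdr = sum(reason %in% "failed_fdr"),
              horizontal_pleiotropy = sum(reason %in% "horizontal_pleiotropy"),
              step1_not_significant = sum(reason %in% "step1_not_significant"),
              mediation_z_nonsignificant =
                sum(reason %in% "mediation_z_nonsignificant"),
              retained = length(retained_ids))
  manifest <- list(
    seed = config@seed, ivw_mode = config@ivwMode,
    q_cutoff = config@qCutoff, pleiotropy_p = config@pleiotropyP,
    fallback_to_raw_p = config@fallbackToRawP,
    uncorrected_p_screen = raw_screen,
    exposure_id = traitId(config@exposure),
    exposure_fallback_id = if (is.null(config@exposureFallback))
      NA_character_ else traitId(config@exposureFallback),
    outcome_id = traitId(config@outcome),
    total_beta = mrBeta(total), total_se = mrSe(total),
    total_pval = mrPval(total), total_n_snp = nSnp(total),
    exposure_used = setNames(provenance, med_ids),
    filter_counts = counts)
  new("ScreenResult", records = rec, mediations = mediations,
      total = total, manifest = manifest)
}

.fmt_num <- function(v) {
  out <- sprintf("%.15g", v)
  out[is.na(v)] <- "NA"
  out
}

#' Write screening reports
#'
#' Serializes a [ScreenResult] into three files under \code{dir}: the main
#' report \code{mediators.tsv} (one row per retained mediator, step-1 and
#' step-2 blocks of SNP count, IVW estimate, q-value and Egger-intercept
#' triple, then Z and the indirect-effect product and proportion mediated),
#' the exclusion log \code{exclusions.tsv} (one row per excluded or
#' untestable mediator with its reason), and \code{manifest.txt} (flat
#' key: value text).  Numbers are written at full double precision, so a
#' re-read reproduces the in-memory results exactly; reruns with the same
#' seeds are byte-identical.
#'
#' @param result a [ScreenResult].
#' @param dir output directory (created if needed).
#' @return invisibly, the three file paths.
#' @export
writeReport <- function(result, dir) {
  stopifnot(is(result, "ScreenResult"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  rec <- result@records
  keep <- is.na(rec$exclusion_reason)

  main_cols <- c("mediator_id", "exposure_used",
                 paste0("step1_", c("n_snp", "beta", "se", "pval", "q",
                                    "egger_intercept", "egger_se",
                                    "egger_pval")),
                 paste0("step2_", c("n_snp", "beta", "se", "pval", "q",
                                    "egger_intercept", "egger_se",
                                    "egger_pval")),
                 "z", "indirect", "prop_mediated")
  main <- rec[keep, main_cols, drop = FALSE]
  excl <- rec[!keep, c("mediator_id", "exclusion_reason", "step1_pval",
                       "step1_q", "step2_pval", "step2_q",
                       "step1_egger_pval", "step2_egger_pval", "z"),
              drop = FALSE]
  fmt <- function(d) {
    num <- vapply(d, is.numeric, logical(1))
    d[num] <- lapply(d[num], .fmt_num)
    d
  }
  main_path <- file.path(dir, "mediators.tsv")
  excl_path <- file.path(dir, "exclusions.tsv")
  man_path <- file.path(dir, "manifest.txt")
  write.table(fmt(main), main_path, sep = "\t", quote = FALSE,
              row.names = FALSE, na = "NA")
  write.table(fmt(excl), excl_path, sep = "\t", quote = FALSE,
              row.names = FALSE, na = "NA")

  m <- result@manifest
  lines <- character()
  for (key in names(m)) {
    v <- m[[key]]
    if (is.null(names(v)) || length(v) == 1) {
      lines <- c(lines, sprintf("%s: %s", key,
                                paste(.fmt_chr(v), collapse = ",")))
    } else {
      lines <- c(lines, sprintf("%s.%s: %s", key, names(v), .fmt_chr(v)))
    }
  }
  writeLines(lines, man_path)
  invisible(c(mediators = main_path, exclusions = excl_path,
              manifest = man_path))
}

.fmt_chr <- function(v) {
  if (is.numeric(v)) .fmt_num(v) else as.character(v)
}
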