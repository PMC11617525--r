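# an analytically constructed panel: every estimate is exact because all
# instrument ratios are noiseless, so each gate's p-values are controlled
# precisely.  Exposure has 5 strong instruments; each mediator has 4 of
# its own.  step1_z / step2_z set the IVW z-statistics of the two steps.
make_panel <- function(step1_z, step2_z, se1 = rep(0.02, length(step1_z)),
                       n_med = length(step1_z)) {
  j_exp <- 5
  j_med <- 4
  exp_snps <- sprintf("e%02d", seq_len(j_exp))
  bx <- seq(0.10, 0.18, length.out = j_exp)
  exposure <- make_table(exp_snps, bx, 0.005, pval = 1e-20,
                         traitId = "exposure")
  outcome_rows <- list(data.frame(snp = exp_snps, beta = 0.2 * bx,
                                  se = 0.02, pval = 0.5))
  mediators <- list()
  for (k in seq_len(n_med)) {
    med_snps <- sprintf("m%02d_%d", seq_len(j_med), k)
    bz <- seq(0.12, 0.2, length.out = j_med)
    # step 1: exposure's instruments act on the mediator with a slope
    # chosen to give the requested z at se determined by the weights
    slope1 <- step1_z[k] * se1[k] / sqrt(sum(bx^2))
    med <- rbind(
      data.frame(snp = exp_snps, beta = slope1 * bx, se = se1[k],
                 pval = 0.5),
      data.frame(snp = med_snps, beta = bz, se = 0.005, pval = 1e-20))
    mediators[[k]] <- sumStats(cbind(med, effect_allele = "A",
                                     other_allele = "G", eaf = 0.3),
                               traitId = sprintf("med-%02d", k))
    se2 <- 0.02
    slope2 <- step2_z[k] * se2 / sqrt(sum(bz^2))
    outcome_rows[[k + 1]] <- data.frame(snp = med_snps, beta = slope2 * bz,
                                        se = se2, pval = 0.5)
  }
  out <- do.call(rbind, outcome_rows)
  outcome <- sumStats(cbind(out, effect_allele = "A", other_allele = "G",
                            eaf = 0.3), traitId = "outcome")
  screeningConfig(exposure = exposure, outcome = outcome,
                  mediators = mediators, seed = 1L)
}

z_for_p <- function(p) qnorm(1 - p / 2)

test_that("screening retains exactly the active mediators with reasons", {
  # 5 mediators: two fully active, one inactive in step 1, one inactive
  # in step 2, one whose steps pass individually but whose step-1
  # uncertainty (a 10x wider SE) sinks the combined mediation Z
  cfg <- make_panel(step1_z = c(9, 8, 0.5, 9, 9),
                    step2_z = c(9, 8, 9, 0.5, 2.5),
                    se1 = c(0.02, 0.02, 0.02, 0.02, 0.2))
  res <- runScreen(cfg)
  rec <- res@records
  expect_identical(rec$mediator_id[is.na(rec$exclusion_reason)],
                   c("med-01", "med-02"))
  expect_identical(rec$exclusion_reason[3], "step1_not_significant")
  expect_identical(rec$exclusion_reason[4], "step2_not_significant")
  expect_identical(rec$exclusion_reason[5], "mediation_z_nonsignificant")
  expect_false(res@manifest$uncorrected_p_screen)
  expect_length(res@mediations, 2)
  expect_s4_class(res@mediations[["med-01"]], "MediationResult")
  # conservation across the exclusion log
  cnt <- res@manifest$filter_counts
  expect_identical(unname(cnt["retained"] + cnt["untestable"] +
                            cnt["step2_not_significant"] +
                            cnt["failed_fdr"] +
                            cnt["horizontal_pleiotropy"] +
                            cnt["step1_not_significant"] +
                            cnt["mediation_z_nonsignificant"]),
                   unname(cnt["panel"]))
})

test_that("the uncorrected-p fallback engages when FDR annihilates all", {
  # four mediators whose step-2 p-values survive nominally but not BH
  # (q >= 0.05 for every one); three of them pass raw p < 0.05
  p2 <- c(0.02, 0.028, 0.04, 0.3)
  cfg <- make_panel(step1_z = c(9, 9, 9, 9), step2_z = z_for_p(p2))
  res <- runScreen(cfg)
  expect_true(res@manifest$uncorrected_p_screen)
  rec <- res@records
  expect_identical(sum(is.na(rec$exclusion_reason)), 3L)
  expect_identical(rec$exclusion_reason[4], "step2_not_significant")

  # with the fallback disabled the report is empty but valid
  cfg2 <- make_panel(step1_z = c(9, 9, 9, 9), step2_z = z_for_p(p2))
  cfg2@fallbackToRawP <- FALSE
  res2 <- runScreen(cfg2)
  expect_identical(sum(is.na(res2@records$exclusion_reason)), 0L)
  expect_true(all(res2@records$exclusion_reason %in%
                    c("failed_fdr", "step2_not_significant")))
  dir <- tempfile()
  paths <- writeReport(res2, dir)
  expect_identical(nrow(read.delim(paths[["mediators"]])), 0L)
  expect_identical(nrow(read.delim(paths[["exclusions"]])), 4L)
})

test_that("lowering the q cutoff never enlarges the retained set", {
  cfg <- make_panel(step1_z = c(9, 8, 7, 3, 9),
                    step2_z = c(9, 5, 3.5, 9, 2.5))
  cfg@fallbackToRawP <- FALSE
  retained_at <- function(q) {
    cfg@qCutoff <- q
    r <- runScreen(cfg)@records
    r$mediator_id[is.na(r$exclusion_reason)]
  }
  sets <- lapply(c(0.2, 0.05, 0.01, 0.001), retained_at)
  for (i in seq_len(length(sets) - 1))
    expect_true(all(sets[[i + 1]] %in% sets[[i]]))
})

test_that("a mediator without instruments is untestable, not fatal", {
  cfg <- make_panel(step1_z = c(9, 9), step2_z = c(9, 9))
  # strip genome-wide significance from mediator 2's own instruments
  med2 <- records(cfg@mediators[[2]])
  med2$pval[med2$pval < 5e-8] <- 1e-4
  cfg@mediators[[2]] <- sumStats(med2, traitId = "med-02")
  res <- runScreen(cfg)
  expect_identical(res@records$exclusion_reason[2], "untestable")
  expect_identical(res@records$mediator_id[is.na(res@records$exclusion_reason)],
                   "med-01")
  expect_identical(unname(res@manifest$filter_counts["untestable"]), 1L)
})

test_that("empty mediator panels are a configuration error", {
  cfg <- make_panel(step1_z = 9, step2_z = 9)
  expect_error(screeningConfig(cfg@exposure, cfg@outcome, list()),
               "non-empty")
})

test_that("reports round-trip at full precision and reruns are identical", {
  cfg <- make_panel(step1_z = c(9, 8, 0.5), step2_z = c(9, 8, 9))
  res <- runScreen(cfg)
  d1 <- tempfile(); d2 <- tempfile()
  p1 <- writeReport(res, d1)
  p2 <- writeReport(runScreen(cfg), d2)
  for (f in names(p1))
    expect_identical(readLines(p1[[f]]), readLines(p2[[f]]),
                     label = paste("deterministic rerun of", f))
  back <- read.delim(p1[["mediators"]])
  rec <- res@records[is.na(res@records$exclusion_reason), ]
  expect_equal(back$z, rec$z, tolerance = 1e-15)
  expect_equal(back$step1_beta, rec$step1_beta, tolerance = 1e-15)
  expect_equal(back$indirect, rec$indirect, tolerance = 1e-15)
})

test_that("step-1 pleiotropy triggers the exposure fallback with provenance", {
  cfg <- make_panel(step1_z = c(9, 9), step2_z = c(9, 9))
  # distort the primary exposure's instrument effects on mediator 1 with a
  # strong constant offset so the Egger intercept fires, and provide a
  # clean fallback exposure dataset
  fallback <- cfg@exposure
  fallback@traitId <- "exposure-fallback"
  med1 <- records(cfg@mediators[[1]])
  on_exp <- startsWith(med1$snp, "e")
  bx <- records(cfg@exposure)$beta
  med1$beta[on_exp] <- 0.08 + 0.2 * bx + c(0.001, -0.001, 0.002, -0.002, 0)
  med1$se[on_exp] <- 0.001
  cfg@mediators[[1]] <- sumStats(med1, traitId = "med-01")
  cfg@exposureFallback <- fallback
  res <- runScreen(cfg)
  expect_identical(unname(res@manifest$exposure_used["med-01"]),
                   "exposure-fallback")
  expect_identical(unname(res@manifest$exposure_used["med-02"]),
                   "exposure")
})
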