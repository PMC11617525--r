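test_that("read/write round-trips tables bit-identically", {
  set.seed(42)
  k <- 100
  tab <- sumStats(data.frame(
    snp = sprintf("rs%04d", sample.int(9999, k)),
    chrom = as.character(sample.int(22, k, TRUE)),
    pos = sample.int(1e8, k),
    effect_allele = sample(c("A", "C", "G", "T"), k, TRUE),
    other_allele = "I",   # indel code: never equals the effect allele
    eaf = ifelse(runif(k) < 0.1, NA, runif(k)),
    beta = rnorm(k), se = runif(k, 0.001, 0.1),
    pval = runif(k, 1e-12, 1), n = sample.int(1e5, k),
    stringsAsFactors = FALSE), traitId = "rt", traitLabel = "round trip")
  p1 <- tempfile(fileext = ".tsv")
  p2 <- tempfile(fileext = ".tsv")
  writeSumstats(tab, p1)
  back <- readSumstats(p1, traitId = "rt", traitLabel = "round trip")
  expect_equal(records(back), records(tab))
  writeSumstats(back, p2)
  expect_identical(readBin(p1, "raw", file.size(p1)),
                   readBin(p2, "raw", file.size(p2)))
})

test_that("missing eaf serializes as NA and header-only files load", {
  tab <- make_table("rs1", 0.1, 0.02, eaf = NA)
  p <- tempfile(fileext = ".tsv")
  writeSumstats(tab, p)
  row <- strsplit(readLines(p)[2], "\t")[[1]]
  expect_identical(row[6], "NA")

  empty <- sumStats(records(tab)[0, ], traitId = "empty")
  writeSumstats(empty, p)
  expect_identical(length(readLines(p)), 1L)
  back <- readSumstats(p, traitId = "empty")
  expect_identical(nrow(records(back)), 0L)
  expect_identical(traitId(back), "empty")
})

test_that("invalid rows are rejected with row-indexed diagnostics", {
  d <- data.frame(snp = c("rs1", "rs2", "rs3"),
                  effect_allele = c("A", "A", "A"),
                  other_allele = c("G", "G", "G"),
                  eaf = c(0.2, 0.3, 0.4),
                  beta = c(0.1, 0.2, 0.3),
                  se = c(0.01, 0, 0.02),
                  pval = c(1e-9, 1e-9, 1e-9))
  expect_error(sumStats(d), "row 2.*rs2.*se must be > 0")
  expect_warning(tab <- sumStats(d, onInvalid = "drop"),
                 "row 2 \\(rs2\\): se must be > 0")
  expect_identical(records(tab)$snp, c("rs1", "rs3"))
  expect_identical(attr(tab, "rejected")$row, 2L)

  expect_error(sumStats(d[, setdiff(names(d), "se")]),
               "missing mandatory column")
})

test_that("dialect remapping loads external column names", {
  p <- tempfile(fileext = ".tsv")
  writeLines(c("rsid\tEA\tOA\tb\tstderr\tp",
               "rs1\tA\tG\t0.1\t0.02\t1e-9"), p)
  tab <- readSumstats(p, dialect = c(snp = "rsid", effect_allele = "EA",
                                     other_allele = "OA", beta = "b",
                                     se = "stderr", pval = "p"))
  expect_identical(records(tab)$snp, "rs1")
  expect_error(readSumstats(p, dialect = c(snp = "nope")),
               "not in header")
})

# hand-written truth table over the allele configurations of an A/G
# exposure SNP (plus indel and palindromic special cases)
harmonization_truth <- data.frame(
  o1 = c("A", "G", "T", "C", "A", "A"),
  o2 = c("G", "A", "C", "T", "C", "T"),
  action = c("unchanged", "allele_swap", "strand_flip", "allele_swap",
             "dropped_incompatible", "dropped_incompatible"),
  sign = c(1, -1, 1, -1, NA, NA),
  stringsAsFactors = FALSE)

test_that("harmonization matches the allele-configuration truth table", {
  exposure <- make_table("rs1", 0.10, 0.02, effect_allele = "A",
                         other_allele = "G", eaf = 0.25, traitId = "exp")
  for (i in seq_len(nrow(harmonization_truth))) {
    tr <- harmonization_truth[i, ]
    outcome <- make_table("rs1", 0.05, 0.01, effect_allele = tr$o1,
                          other_allele = tr$o2, eaf = 0.25,
                          traitId = "out")
    h <- records(harmonize(exposure, outcome))
    expect_identical(h$action, tr$action,
                     label = paste("alleles", tr$o1, tr$o2))
    if (!is.na(tr$sign))
      expect_equal(h$beta_out, tr$sign * 0.05)
    else
      expect_true(is.na(h$beta_out))
  }
})

test_that("palindromic SNPs follow the policy and frequency window", {
  pal_exp <- function(eaf) make_table("rs1", 0.1, 0.02, effect_allele = "A",
                                      other_allele = "T", eaf = eaf,
                                      traitId = "exp")
  pal_out <- function(eaf) make_table("rs1", 0.05, 0.01,
                                      effect_allele = "A",
                                      other_allele = "T", eaf = eaf,
                                      traitId = "out")
  # ambiguous frequency (0.5) is always dropped under infer_by_eaf
  h <- records(harmonize(pal_exp(0.5), pal_out(0.2),
                         palindromePolicy = "infer_by_eaf",
                         eafWindow = 0.08))
  expect_identical(h$action, "dropped_palindromic")
  # drop policy drops regardless of frequency
  h <- records(harmonize(pal_exp(0.2), pal_out(0.2),
                         palindromePolicy = "drop"))
  expect_identical(h$action, "dropped_palindromic")
  # clear frequencies on the same side of 0.5: aligned, kept
  h <- records(harmonize(pal_exp(0.2), pal_out(0.25)))
  expect_identical(h$action, "unchanged")
  expect_equal(h$beta_out, 0.05)
  # opposite sides: the outcome effect allele is the complement; swap
  h <- records(harmonize(pal_exp(0.2), pal_out(0.8)))
  expect_identical(h$action, "allele_swap")
  expect_equal(h$beta_out, -0.05)
  # missing frequency: alignment undecidable
  h <- records(harmonize(pal_exp(NA), pal_out(0.2)))
  expect_identical(h$action, "dropped_palindromic")
})

test_that("harmonization is idempotent and sign-consistent", {
  set.seed(7)
  k <- 25L
  alle <- mrmediate:::.ALLELE_PAIRS[sample.int(8, k, TRUE), ]
  exposure <- sumStats(data.frame(
    snp = sprintf("rs%03d", 1:k), effect_allele = alle[, 1],
    other_allele = alle[, 2], eaf = runif(k, 0.05, 0.95),
    beta = rnorm(k, 0, 0.1), se = runif(k, 0.01, 0.05),
    pval = runif(k), stringsAsFactors = FALSE), traitId = "exp")
  outcome <- sumStats(data.frame(
    snp = sprintf("rs%03d", 1:k), effect_allele = alle[, 1],
    other_allele = alle[, 2], eaf = runif(k, 0.05, 0.95),
    beta = rnorm(k, 0, 0.05), se = runif(k, 0.01, 0.05),
    pval = runif(k), stringsAsFactors = FALSE), traitId = "out")

  h1 <- harmonize(exposure, outcome)
  expect_true(all(records(h1)$action == "unchanged"))

  # re-harmonizing the aligned pair changes nothing
  aligned_out <- sumStats(data.frame(
    snp = records(h1)$snp, effect_allele = alle[, 1],
    other_allele = alle[, 2], eaf = runif(k, 0.05, 0.95),
    beta = records(h1)$beta_out, se = records(h1)$se_out,
    pval = runif(k), stringsAsFactors = FALSE), traitId = "out")
  h2 <- harmonize(exposure, aligned_out)
  expect_equal(records(h2)$beta_out, records(h1)$beta_out)
  expect_true(all(records(h2)$action == "unchanged"))

  # swapping every outcome record's alleles restores the estimand
  swapped <- sumStats(data.frame(
    snp = sprintf("rs%03d", 1:k), effect_allele = alle[, 2],
    other_allele = alle[, 1], eaf = 1 - records(outcome)$eaf,
    beta = -records(outcome)$beta, se = records(outcome)$se,
    pval = records(outcome)$pval, stringsAsFactors = FALSE),
    traitId = "out")
  h3 <- harmonize(exposure, swapped)
  expect_equal(records(h3)$beta_out, records(h1)$beta_out)

  # retained + dropped equals the intersection size
  expect_identical(nrow(records(h1)), k)
  expect_identical(nRetained(h1) +
                     sum(startsWith(records(h1)$action, "dropped")), k)
})

test_that("empty intersection and empty inputs raise distinct errors", {
  a <- make_table("rs1", 0.1, 0.02, traitId = "a")
  b <- make_table("rs2", 0.1, 0.02, traitId = "b")
  expect_error(harmonize(a, b), "no shared SNPs")
  empty <- sumStats(records(a)[0, ], traitId = "empty")
  expect_error(harmonize(empty, b), "empty input")
})
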