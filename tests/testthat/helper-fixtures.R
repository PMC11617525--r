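# shared fixture builders; everything is generated in code

# quick SumStats from per-field vectors, with sensible filler
make_table <- function(snp, beta, se, pval = 2 * pnorm(-abs(beta / se)),
                       effect_allele = "A", other_allele = "G",
                       eaf = 0.3, chrom = NA_character_, pos = NA_real_,
                       n = NA_real_, traitId = "trait") {
  k <- length(snp)
  sumStats(data.frame(snp = snp, chrom = rep_len(chrom, k),
                      pos = rep_len(pos, k),
                      effect_allele = rep_len(effect_allele, k),
                      other_allele = rep_len(other_allele, k),
                      eaf = rep_len(eaf, k), beta = beta, se = se,
                      pval = rep_len(pval, k), n = rep_len(n, k),
                      stringsAsFactors = FALSE),
           traitId = traitId)
}

# aligned instrument set straight from effect vectors
make_set <- function(beta_exp, se_exp, beta_out, se_out, ...)
  mrmediate:::.harmonized_from_vectors(beta_exp, se_exp, beta_out, se_out,
                                       ...)

# a random but reproducible instrument set with a common causal slope
random_set <- function(n_snp, slope = 0.3, het_sd = 0, seed = 1) {
  set.seed(seed)
  bx <- runif(n_snp, 0.05, 0.3)
  se_x <- runif(n_snp, 0.005, 0.02)
  se_y <- runif(n_snp, 0.01, 0.05)
  by <- slope * bx + rnorm(n_snp, 0, het_sd) + rnorm(n_snp, 0, se_y)
  make_set(bx, se_x, by, se_y)
}

# summary-level draws under the no-pleiotropy two-sample null: true
# instrument effects gamma, observed effects with known SEs, outcome
# effects generated from slope * gamma
draw_null_summary <- function(n_snp, slope = 0, se_x = 0.01, se_y = 0.02,
                              intercept = 0) {
  gamma <- runif(n_snp, 0.05, 0.25)
  bx <- rnorm(n_snp, gamma, se_x)
  by <- rnorm(n_snp, intercept + slope * gamma, se_y)
  make_set(bx, rep(se_x, n_snp), by, rep(se_y, n_snp))
}

extdata <- function(name)
  system.file("extdata", name, package = "mrmediate", mustWork = TRUE)

read_fixture <- function(name)
  read.delim(extdata(name), stringsAsFactors = FALSE)

# independent weighted-regression oracle via explicit normal equations,
# computed with generic matrix algebra (no reuse of package internals)
egger_oracle <- function(bx, by, w) {
  flip <- ifelse(bx < 0, -1, 1)
  x <- bx * flip; y <- by * flip
  n <- length(x)
  sw <- sum(w); swx <- sum(w * x); swy <- sum(w * y)
  sxx <- sum(w * x^2); sxy <- sum(w * x * y)
  det <- sw * sxx - swx^2
  slope <- (sw * sxy - swx * swy) / det
  inter <- (sxx * swy - swx * sxy) / det
  sigma2 <- sum(w * (y - inter - slope * x)^2) / (n - 2)
  scale2 <- max(1, sigma2)
  list(slope = slope, inter = inter,
       slope_se = sqrt(scale2 * sw / det),
       inter_se = sqrt(scale2 * sxx / det))
}
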