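test_that("Wald ratio arithmetic, zero case and error case", {
  est <- waldRatio(0.1, 0.02, 0.05, 0.01)
  expect_equal(mrBeta(est), 0.5)
  expect_equal(mrSe(est), 0.1)

  est0 <- waldRatio(0.1, 0.02, 0, 0.01)
  expect_equal(mrBeta(est0), 0)
  expect_equal(mrPval(est0), 1)

  expect_error(waldRatio(0, 0.02, 0.05, 0.01), "exposure effect is zero")
})

test_that("second-order Wald SE agrees with a sampling oracle", {
  bx <- 0.2; sx <- 0.01; by <- 0.1; sy <- 0.01
  est <- waldRatio(bx, sx, by, sy, secondOrder = TRUE)
  set.seed(99)
  draws <- rnorm(5e5, by, sy) / rnorm(5e5, bx, sx)
  expect_equal(mrSe(est), sd(draws), tolerance = 0.01)
  expect_true(mrSe(est) > mrSe(waldRatio(bx, sx, by, sy)))
})

test_that("IVW reduces to the Wald ratio for a single SNP", {
  s <- make_set(0.1, 0.02, 0.05, 0.01)
  w <- waldRatio(0.1, 0.02, 0.05, 0.01)
  for (mode in c("fixed", "mre", "hybrid")) {
    est <- mrIvw(s, mode = mode)
    expect_equal(mrBeta(est), mrBeta(w))
    expect_equal(mrSe(est), mrSe(w))
  }
})

test_that("IVW degenerate fit: equal ratios give c with the fixed-mode SE", {
  bx <- c(0.1, 0.2, 0.3); sy <- c(0.01, 0.02, 0.015)
  s <- make_set(bx, 0.01, 0.4 * bx, sy)
  est <- mrIvw(s, mode = "fixed")
  expect_equal(mrBeta(est), 0.4)
  expect_equal(mrSe(est), 1 / sqrt(sum(bx^2 / sy^2)))
  # zero residuals: hybrid floors the scale at 1, reproducing fixed
  expect_equal(mrSe(mrIvw(s, mode = "hybrid")), mrSe(est))
})

test_that("IVW equals the closed-form weighted-least-squares oracle", {
  bx <- c(0.10, 0.20, 0.30); by <- c(0.05, 0.12, 0.14)
  sy <- c(0.01, 0.02, 0.015)
  s <- make_set(bx, 0.01, by, sy)
  oracle <- sum(bx * by / sy^2) / sum(bx^2 / sy^2)
  expect_equal(mrBeta(mrIvw(s, mode = "fixed")), oracle)
  expect_equal(mrBeta(mrIvw(s, mode = "hybrid")), oracle)
})

test_that("MR-Egger recovers an exact linear law and nests IVW", {
  bx <- c(0.1, 0.15, 0.2, 0.3)
  s <- make_set(bx, 0.01, 0.01 + 0.4 * bx, 0.02)
  est <- mrEgger(s)
  expect_equal(mrBeta(est), 0.4)
  expect_equal(est@extra$intercept, 0.01)
  expect_equal(est@extra$sigma, 0)

  # zero-intercept noiseless data: Egger slope equals the IVW estimate
  s0 <- make_set(bx, 0.01, 0.4 * bx, 0.02)
  expect_equal(mrBeta(mrEgger(s0)), mrBeta(mrIvw(s0)))

  expect_error(mrEgger(make_set(0.1, 0.01, 0.05, 0.01)), "at least 3")
  expect_error(mrEgger(make_set(rep(0.1, 4), 0.01, rnorm(4), 0.02)),
               "rank-deficient")
})


test_that("MR-Egger equals the normal-equations oracle on random data", {
  for (seed in 1:4) {
    set.seed(seed)
    bx <- rnorm(8, 0, 0.2); by <- 0.01 + 0.3 * bx + rnorm(8, 0, 0.05)
    sy <- runif(8, 0.01, 0.05)
    s <- make_set(bx, 0.01, by, sy)
    est <- mrEgger(s)
    o <- egger_oracle(bx, by, 1 / sy^2)
    expect_equal(mrBeta(est), o$slope, tolerance = 1e-10)
    expect_equal(mrSe(est), o$slope_se, tolerance = 1e-10)
    expect_equal(est@extra$intercept, o$inter, tolerance = 1e-10)
    expect_equal(est@extra$intercept_se, o$inter_se, tolerance = 1e-10)
  }
})

test_that("weighted median: symmetry, constancy and the percentile oracle", {
  # equal weights, ratios 1,2,3: the middle one
  s <- make_set(c(0.1, 0.1, 0.1), 0.01, c(0.1, 0.2, 0.3), 0.01)
  expect_equal(mrBeta(mrWeightedMedian(s, nBoot = 100, seed = 1)), 2)

  # all ratios equal c
  bx <- c(0.1, 0.2, 0.3)
  s <- make_set(bx, 0.01, 0.25 * bx, c(0.01, 0.03, 0.02))
  expect_equal(mrBeta(mrWeightedMedian(s, nBoot = 100, seed = 1)), 0.25)

  # brute-force interpolated weighted percentile on a 7-SNP instance
  set.seed(5)
  bx <- runif(7, 0.05, 0.3); by <- rnorm(7, 0.3 * bx, 0.03)
  sy <- runif(7, 0.01, 0.05)
  s <- make_set(bx, 0.01, by, sy)
  theta <- by / bx
  w <- (bx / sy)^2
  ord <- order(theta)
  p <- (cumsum(w[ord]) - w[ord] / 2) / sum(w)
  j <- max(which(p < 0.5))
  oracle <- theta[ord][j] + (theta[ord][j + 1] - theta[ord][j]) *
    (0.5 - p[j]) / (p[j + 1] - p[j])
  est <- mrWeightedMedian(s, nBoot = 2000, seed = 1)
  expect_equal(mrBeta(est), oracle, tolerance = 1e-12)

  # bootstrap SE stable to < 5% across seeds
  se2 <- mrSe(mrWeightedMedian(s, nBoot = 2000, seed = 2))
  expect_lt(abs(mrSe(est) - se2) / mrSe(est), 0.05)
  # and reproducible under the same seed
  expect_identical(mrSe(mrWeightedMedian(s, nBoot = 500, seed = 9)),
                   mrSe(mrWeightedMedian(s, nBoot = 500, seed = 9)))

  expect_error(mrWeightedMedian(make_set(0.1, 0.01, 0.1, 0.01)),
               "at least 3")
})

test_that("estimators are scale-equivariant and orientation-invariant", {
  for (seed in 1:3) {
    s <- random_set(10, slope = 0.25, het_sd = 0.02, seed = seed)
    d <- records(s)
    k <- 3.7
    scaled <- make_set(d$beta_exp, d$se_exp, k * d$beta_out, k * d$se_out)
    set.seed(123)
    flip <- sample(c(-1, 1), 10, TRUE)
    flipped <- make_set(flip * d$beta_exp, d$se_exp, flip * d$beta_out,
                        d$se_out)
    for (fit in list(function(x) mrIvw(x, "hybrid"),
                     function(x) mrIvw(x, "fixed"),
                     mrEgger,
                     function(x) mrWeightedMedian(x, nBoot = 300,
                                                  seed = 42))) {
      base <- fit(s)
      expect_equal(mrBeta(fit(scaled)), k * mrBeta(base))
      expect_equal(mrSe(fit(scaled)), k * mrSe(base))
      expect_equal(mrBeta(fit(flipped)), mrBeta(base))
      expect_equal(mrSe(fit(flipped)), mrSe(base))
    }
    # fixed-mode SE never exceeds hybrid-mode SE
    expect_lte(mrSe(mrIvw(s, "fixed")), mrSe(mrIvw(s, "hybrid")))
  }
})
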