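test_that("imputation strategies follow their contracts", {
  expect_equal(impute(c(1, NA, 3), "zeros"), c(1, 0, 3))
  # near-zero noise: bounded by ~3 sd of the half-normal, deterministic per seed
  x <- c(1, NA)
  a <- impute(x, "near_zero_noise", sigma = 1e-4, seed = 99L)
  b <- impute(x, "near_zero_noise", sigma = 1e-4, seed = 99L)
  expect_identical(a, b)
  expect_gt(a[2], 0)
  expect_lt(a[2], 5e-4)
  expect_equal(impute(c(1, NA, 3), "na_pairwise"), c(1, NA, 3))
  # identity when nothing is missing
  y <- c(2, 4, 6)
  for (s in c("zeros", "near_zero_noise", "na_pairwise"))
    expect_equal(impute(y, s), y)
  expect_error(impute(c(NA_real_, NA_real_), "near_zero_noise"), "all-missing")
})

test_that("distance correlation matches the sum-formula oracle and its bounds", {
  expect_equal(distance_correlation(c(1, 2, 3, 4), c(1, 3, 2, 5)),
               bf_dcor(c(1, 2, 3, 4), c(1, 3, 2, 5)), tolerance = 1e-12)
  set.seed(1)
  for (i in 1:25) {
    n <- sample(4:12, 1)
    x <- runif(n); y <- runif(n)
    expect_equal(distance_correlation(x, y), bf_dcor(x, y),
                 tolerance = 1e-12)
  }
  x <- c(3, 1, 4, 1, 5)
  expect_equal(distance_correlation(x, x), 1)
  expect_equal(distance_correlation(x, rep(2, 5)), 0)
  # affine invariance
  expect_equal(distance_correlation(2 * x + 7, x),
               distance_correlation(x, x), tolerance = 1e-12)
  expect_error(distance_correlation(1:3, 1:4), "equal length")
})

test_that("weighted cross-correlation reduces to Pearson at L=0 and rewards lag", {
  set.seed(2)
  x <- runif(20); y <- runif(20)
  expect_equal(weighted_cross_correlation(x, y, L = 0L), cor(x, y),
               tolerance = 1e-12)
  expect_equal(weighted_cross_correlation(x, x, L = 1L), 1)
  # a peak shifted by one fraction: WCC(L=1) exceeds Pearson
  p <- gauss_peak(30, 15)
  p_shift <- gauss_peak(30, 16)
  expect_gt(weighted_cross_correlation(p, p_shift, L = 1L),
            cor(p, p_shift))
  expect_warning(weighted_cross_correlation(rep(1, 5), x[1:5]),
                 "zero denominator")
})

test_that("cosine similarity obeys orthogonality, scale invariance and errors", {
  expect_equal(cosine(c(1, 0), c(0, 1)), 0)
  x <- c(1, 2, 3)
  expect_equal(cosine(x, 3 * x), 1)
  expect_error(cosine(c(0, 0), x[1:2]), "zero-norm")
})

test_that("imputed cosine of disjointly detected profiles stays near zero", {
  # two proteins never detected in the same fraction: similarity is driven
  # entirely by the near-zero noise, so it must be tiny
  x <- c(10, 20, 10, NA, NA, NA)
  y <- c(NA, NA, NA, 10, 30, 10)
  vals <- for (s in 1:100) {
    xi <- impute(x, "near_zero_noise", sigma = 1e-4, seed = s)
    yi <- impute(y, "near_zero_noise", sigma = 1e-4, seed = s + 1000L)
    expect_lt(abs(cosine(xi, yi)), 0.01)
  }
})

test_that("mutual information matches the triple-loop oracle", {
  set.seed(3)
  for (i in 1:10) {
    n <- sample(12:30, 1)
    x <- runif(n); y <- runif(n)
    x[sample(n, 2)] <- NA
    expect_equal(mutual_information(x, y), bf_mi(x, y), tolerance = 1e-12)
  }
  # MI(x, x) equals the entropy of x's binning
  x <- runif(40)
  bx <- table(cut(x, breaks = seq(min(x), max(x), length.out = 11),
                  include.lowest = TRUE)) / 40
  expect_equal(mutual_information(x, x), -sum(bx[bx > 0] * log(bx[bx > 0])),
               tolerance = 1e-10)
  # insufficient overlap -> missing-feature marker
  expect_true(is.na(mutual_information(c(1:5, rep(NA, 5)),
                                       c(rep(NA, 5), 1:5))))
})

test_that("mutual information of independent uniforms is near zero", {
  set.seed(4)
  x <- runif(1e4); y <- runif(1e4)
  expect_lt(mutual_information(x, y), 0.05)
})

test_that("all-pairs feature tables are symmetric and match scalar calls", {
  set.seed(5)
  vals <- matrix(runif(3 * 12, 1, 100), 3, 12,
                 dimnames = list(c("B", "A", "C"), NULL))
  vals[1, 3] <- NA; vals[2, 7] <- NA
  m <- elution_matrix(vals)
  ft <- pairwise_features(m, measure_spec("distance_correlation"))
  expect_equal(nrow(ft), 3L)                     # 3 proteins -> 3 pairs
  expect_true(all(ft$protein_a < ft$protein_b))  # alphabetized only
  # table equals per-pair scalar calls for the deterministic measures
  specs <- list(measure_spec("distance_correlation"),
                measure_spec("weighted_cross_correlation"),
                measure_spec("mutual_information", B = 5L),
                measure_spec("pearson"))
  ft2 <- pairwise_features(m, specs)
  for (r in seq_len(nrow(ft2))) {
    x <- unclass(m)[ft2$protein_a[r], ]; y <- unclass(m)[ft2$protein_b[r], ]
    expect_equal(ft2$distance_correlation[r],
                 distance_correlation(impute(x, "zeros"),
                                      impute(y, "zeros")),
                 tolerance = 1e-10)
    expect_equal(ft2$weighted_cross_correlation[r],
                 weighted_cross_correlation(impute(x, "zeros"),
                                            impute(y, "zeros")),
                 tolerance = 1e-10)
    expect_equal(ft2$mutual_information[r], mutual_information(x, y, 5L),
                 tolerance = 1e-10)
    expect_equal(ft2$pearson[r], pearson(x, y), tolerance = 1e-10)
  }
  # cosine feature is deterministic end-to-end for a fixed seed
  c1 <- pairwise_features(m, measure_spec("cosine", seed = 3L))
  c2 <- pairwise_features(m, measure_spec("cosine", seed = 3L))
  expect_identical(c1, c2)
})
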