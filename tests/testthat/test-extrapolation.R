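test_that("common_species inner-joins on normalized names and enforces the minimum", {
  a <- tibble::tibble(species = c("A sp", "B sp", "C sp", "D sp"),
                      chemical = "Cu", smav = c(10, 20, 30, 40))
  b <- tibble::tibble(species = c("b SP", "C sp", "D sp", "E sp"),
                      chemical = "Zn", smav = c(2, 3, 4, 5))
  pairs <- common_species(a, b)
  expect_equal(nrow(pairs), 3)
  expect_equal(pairs$x, log10(c(20, 30, 40)))
  expect_equal(pairs$y, log10(c(2, 3, 4)))

  disjoint <- dplyr::mutate(b, species = paste0("Z", species))
  expect_error(common_species(a, disjoint), "insufficient overlap.*Cu -> Zn")

  self <- dplyr::mutate(a, chemical = "Zn")
  pairs_self <- common_species(a, self)
  expect_equal(pairs_self$x, pairs_self$y)
  expect_error(common_species(a, a), "must differ")
})

test_that("pair-model OLS matches the brute-force oracle and exact lines", {
  x <- seq(0, 3, length.out = 8)
  pairs <- tibble::tibble(species = letters[1:8], surrogate_chemical = "Cu",
                          predicted_chemical = "Zn", x = x, y = 0.8 * x + 0.3)
  m <- suppressWarnings(fit_pair_model(pairs))  # perfect-fit summary warning
  expect_equal(m$slope, 0.8, tolerance = 1e-12)
  expect_equal(m$intercept, 0.3, tolerance = 1e-12)
  expect_equal(m$r_squared, 1, tolerance = 1e-12)
  expect_equal(m$rmsep_loo, 0, tolerance = 1e-9)

  set.seed(40)
  for (i in 1:50) {
    n <- sample(4:20, 1)
    pr <- tibble::tibble(species = as.character(seq_len(n)),
                         surrogate_chemical = "A", predicted_chemical = "B",
                         x = rnorm(n), y = rnorm(n))
    m <- fit_pair_model(pr, loo = FALSE)
    oracle <- ols_oracle(pr$x, pr$y)
    expect_equal(m$slope, oracle$slope, tolerance = 1e-10)
    expect_equal(m$intercept, oracle$intercept, tolerance = 1e-10)
    # slope t-test and regression F-test agree for simple OLS
    f <- summary(lm(y ~ x, data = pr))$fstatistic
    expect_equal(m$p_value, unname(pf(f[1], f[2], f[3], lower.tail = FALSE)),
                 tolerance = 1e-9)
  }

  degenerate <- tibble::tibble(species = letters[1:4], surrogate_chemical = "A",
                               predicted_chemical = "B", x = rep(1, 4), y = 1:4)
  expect_error(fit_pair_model(degenerate), "singular")
})

test_that("pair-model fit recovers generating parameters from noisy data", {
  set.seed(41)
  n <- 50
  x <- rnorm(n, 2, 0.8)
  y <- 0.7 * x + 0.2 + rnorm(n, 0, 0.3)
  pairs <- tibble::tibble(species = as.character(1:n), surrogate_chemical = "A",
                          predicted_chemical = "B", x = x, y = y)
  m <- fit_pair_model(pairs)
  se <- sqrt(diag(attr(m, "vcov")))
  expect_lt(abs(m$slope - 0.7), 3 * se[2])
  expect_lt(abs(m$intercept - 0.2), 3 * se[1])
  expect_lt(m$p_value, 0.05)
})

test_that("significance filtering removes p > alpha only, keeping the boundary", {
  models <- tibble::tibble(
    surrogate_chemical = c("A", "A", "B"), predicted_chemical = c("B", "C", "C"),
    slope = 1, intercept = 0, r_squared = 0.5,
    p_value = c(0.01, 0.30, 0.05), n_common = 5, rmsep_loo = 0.1
  )
  kept <- filter_models(models)
  expect_equal(kept$p_value, c(0.01, 0.05))
  expect_equal(kept$predicted_chemical, c("B", "C"))
})

test_that("LOO RMSEP matches the hand-computed oracle and its invariances", {
  # collinear data: every refit reproduces the full-line prediction
  collinear <- tibble::tibble(species = as.character(1:10),
                              surrogate_chemical = "A", predicted_chemical = "B",
                              x = 1:10, y = 2 * (1:10) - 3)
  expect_equal(loo_rmsep(collinear), 0, tolerance = 1e-9)

  # explicit 4-point brute-force value: held-out errors 2/3, -1/7, -4/7, 1
  toy <- tibble::tibble(species = letters[1:4], surrogate_chemical = "A",
                        predicted_chemical = "B", x = 0:3, y = c(0, 1, 2, 4))
  expect_equal(loo_rmsep(toy), 0.669212824884, tolerance = 1e-10)

  # invariant under reordering of the pairs
  expect_equal(loo_rmsep(toy[c(3, 1, 4, 2), ]), loo_rmsep(toy))
  expect_error(loo_rmsep(toy[1:3, ]), "at least 4")

  # LOO pessimism: RMSEP >= in-sample RMSE on seeded random data
  set.seed(42)
  for (i in 1:20) {
    n <- sample(5:15, 1)
    pr <- tibble::tibble(species = as.character(1:n), surrogate_chemical = "A",
                         predicted_chemical = "B", x = rnorm(n),
                         y = rnorm(n))
    rmse_in <- sqrt(mean(resid(lm(y ~ x, data = pr))^2))
    expect_gte(loo_rmsep(pr), rmse_in)
  }
})

test_that("prediction applies the log-log model and validation reproduces published arithmetic", {
  ident <- tibble::tibble(slope = 1, intercept = 0)
  expect_equal(predict_toxicity(ident, 222), 222)
  expect_equal(predict_toxicity(tibble::tibble(slope = 0.5, intercept = 1), 100), 100)
  const <- tibble::tibble(slope = 0, intercept = 2)
  expect_equal(predict_toxicity(const, c(1, 10, 5000)), rep(100, 3))
  expect_error(predict_toxicity(ident, -1), "positive")

  # monotone in the surrogate value for positive slope
  m <- tibble::tibble(slope = 0.7, intercept = 0.2)
  v <- predict_toxicity(m, c(10, 100, 1000))
  expect_true(all(diff(v) > 0))

  # external-validation arithmetic from published observed/predicted values
  expect_equal(round(100 * relative_error(665, 514)), 29)
  expect_equal(round(100 * relative_error(17, 134)), 87)
  expect_equal(relative_error(100, 100), 0)
  expect_error(relative_error(1, 0), "positive")

  expect_true(within_fold(665, 514))
  expect_false(within_fold(37, 734))
  expect_true(within_fold(100, 100))
  expect_true(within_fold(500, 100, fold = 5))  # boundary inclusive
})

test_that("noiseless round trip recovers the generating model across the whole module", {
  smavs <- toy_smav_long(n_species = 12, slope = 0.8, intercept = 0.3)
  pairs <- common_species(smavs[smavs$chemical == "A", ],
                          smavs[smavs$chemical == "B", ])
  m <- suppressWarnings(fit_pair_model(pairs))  # noiseless data: perfect fit
  expect_equal(m$slope, 0.8, tolerance = 1e-9)
  expect_equal(m$intercept, 0.3, tolerance = 1e-9)
  expect_equal(m$rmsep_loo, 0, tolerance = 1e-9)

  models <- suppressWarnings(fit_pair_models(smavs))
  expect_equal(nrow(models), 2)  # both directions of the single unordered pair
  expect_setequal(models$surrogate_chemical, c("A", "B"))

  obs <- tibble::tibble(chemical = c("A", "B"), value = c(100, 10^(0.8 * 2 + 0.3)))
  val <- validate_models(models, obs)
  fwd <- val[val$surrogate_chemical == "A", ]
  expect_equal(fwd$predicted, fwd$observed, tolerance = 1e-9)
  expect_equal(fwd$relative_error, 0, tolerance = 1e-9)
  expect_true(all(val$within_fold))
})
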