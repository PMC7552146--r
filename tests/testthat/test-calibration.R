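test_that("spectra standardization is exact and invertible", {
  set.seed(2)
  S <- matrix(rnorm(40 * 12, mean = 3), 40, 12)
  std <- standardize_spectra(S)
  expect_lt(max(abs(colMeans(std$values))), 1e-12)
  expect_lt(max(abs(apply(std$values, 2, sd) - 1)), 1e-12)
  expect_equal(unstandardize_spectra(std), S, tolerance = 1e-12)
  # projection of new samples uses the stored constants
  S2 <- matrix(rnorm(5 * 12), 5, 12)
  proj <- standardize_spectra(S2, center = std$center, scale = std$scale)
  expect_equal(proj$values, sweep(sweep(S2, 2, std$center), 2, std$scale, "/"))
  # constant column rule: sd -> 1, column zeroed, with warning
  S[, 3] <- 7
  expect_warning(std3 <- standardize_spectra(S), "constant")
  expect_true(all(std3$values[, 3] == 0))
  # two identical rows: everything constant, all zeros
  expect_warning(d <- standardize_spectra(S[c(1, 1), ]), "constant")
  expect_true(all(d$values == 0))
  expect_error(standardize_spectra(matrix(c(1, NA), 1, 2)), "missing")
})

test_that("BayesB recovers a planted signal and shrinks a constant response", {
  set.seed(3)
  n <- 400; p <- 120
  X <- matrix(rnorm(n * p), n, p)
  y <- 3 * X[, 17] + rnorm(n, sd = 0.01)
  fit <- fit_bayesb(y, X, chain = test_chain(), seed = 4)
  Xn <- matrix(rnorm(200 * p), 200, p)
  yn <- 3 * Xn[, 17]
  expect_gt(cor(predict(fit, Xn), yn)^2, 0.95)
  expect_gt(fit$pip[17], 0.9)

  yc <- rep(5, n) + rnorm(n, sd = 1e-8)
  fitc <- fit_bayesb(yc, X, chain = test_chain(), seed = 4)
  expect_equal(fitc$intercept, 5, tolerance = 1e-3)
  expect_lt(max(abs(fitc$coefficients)), 1e-3)

  expect_error(fit_bayesb(c(y[-1], NA), X), "missing")
  expect_error(fit_bayesb(y, X, chain = chain_settings(100, 99, 5)),
               "chain too short")
})

test_that("BayesB with inclusion forced on behaves like ridge and stays finite", {
  set.seed(8)
  n <- 100; p <- 30
  X <- matrix(rnorm(n * p), n, p)
  y <- X %*% rnorm(p, sd = 0.3) + rnorm(n)
  fit <- fit_bayesb(y, X, pi0 = 0, chain = test_chain(), seed = 1)
  expect_true(all(is.finite(fit$coefficients)))
  expect_true(all(fit$pip == 1))
  expect_true(all(is.finite(predict(fit, matrix(rnorm(10 * p), 10, p)))))
})

test_that("crossvalidate pools out-of-fold predictions correctly", {
  set.seed(5)
  n <- 60; p <- 40
  X <- matrix(rnorm(n * p), n, p)
  beta <- numeric(p); beta[c(3, 9, 15, 22, 30)] <- c(2, -1.5, 1, 2, -2)
  y <- as.numeric(X %*% beta)   # deterministic linear signal
  cv <- crossvalidate(y, X, repetitions = 4, chain = test_chain(), seed = 6)
  expect_gt(cv$r2_cv, 0.95)
  # RMSE identity against the stored out-of-fold residuals
  tested <- !is.na(cv$predictions)
  res <- cv$predictions[tested] - matrix(y, n, 4)[tested]
  expect_equal(cv$rmse_cv^2, mean(res^2))
  # no leakage by construction: each sample predicted only when held out
  for (r in seq_along(cv$splits))
    expect_equal(which(!is.na(cv$predictions[, r])), cv$splits[[r]])
  expect_error(crossvalidate(y[1:10], X[1:10, ], seed = 1), "too few")
})

test_that("a null response yields R2cv near zero", {
  set.seed(9)
  n <- 80; p <- 50
  X <- matrix(rnorm(n * p), n, p)
  y <- rnorm(n)  # independent of the spectra
  cv <- crossvalidate(y, X, repetitions = 4, chain = test_chain(), seed = 2)
  expect_lt(cv$r2_cv, 0.1)
})

test_that("validation database averages repeated tests and drops the rest", {
  cv <- structure(list(predictions = matrix(c(1, NA, NA,
                                              3, NA, NA,
                                              NA, NA, 4), 3, 3),
                       splits = list(1, c(1, 3), 3), r2_cv = NA, rmse_cv = NA,
                       seed = 1), class = "cv_result")
  db <- assemble_validation_db(cv, ids = c("a", "b", "c"))
  expect_equal(db$id, c("a", "c"))           # b never tested -> dropped
  expect_equal(db$phenotype, c(2, 4))        # mean of 1 and 3; single 4
  expect_equal(db$times_tested, c(2, 1))
})

test_that("never-tested fraction matches 0.8^R across seeds", {
  fracs <- sapply(1:30, function(s) {
    splits <- training_testing_splits(200, repetitions = 10, test_frac = 0.2,
                                      seed = s)
    1 - length(unique(unlist(splits))) / 200
  })
  expect_lt(abs(mean(fracs) - 0.8^10), 0.015)
})

test_that("indirect predictions compose the stated identities", {
  set.seed(12)
  n <- 25
  recs <- data.frame(cow_id = 1:n, dmy = runif(n, 15, 35),
                     fat_pct = runif(n, 3.5, 5), protein_pct = runif(n, 3.2, 4),
                     cy_curd_pct = runif(n, 12, 17),
                     cy_solids_pct = runif(n, 6, 8.5),
                     c4_0 = runif(n, 2.5, 3.8), c16_0iso = runif(n, .15, .4),
                     c18_1_t10 = runif(n, .1, .5), c18_1_t11 = runif(n, 1, 2),
                     c18_1_c9 = runif(n, 14, 21), c18_2_c9c12 = runif(n, 1, 2))
  recs <- compute_all_eme(recs)
  # "predictions" equal to the truth: indirect traits must equal reference
  db <- recs[c("cow_id", informative_trait_names())]
  names(db)[1] <- "id"
  db$ch4_cm_ir <- recs$ch4_cm
  out <- indirect_predictions(db, recs)
  expect_equal(out$ch4_dm_fair, recs$ch4_dm)
  expect_equal(out$ch4_cm_fair, recs$ch4_cm)
  expect_equal(out$dch4_cm_ir, recs$dch4)
  expect_equal(out$dch4_ir_ir, recs$dch4)
  expect_equal(out$ch4_cy_curd_ir_ir, recs$ch4_cy_curd)
  expect_equal(out$ch4_cy_solids_ir_ir, recs$ch4_cy_solids)
  # worked example: measured corrected yield times predicted intensity
  db2 <- db[1, ]; db2$dcmy <- 25.8; db2$ch4_cm_ir <- 14.19
  out2 <- indirect_predictions(db2, recs[1, ])
  expect_equal(out2$dch4_ir_ir, 25.8 * 14.19)
  # guard: non-positive predicted cheese yield excluded with warning
  db$cy_curd_pct[2] <- -0.5
  expect_warning(out3 <- indirect_predictions(db, recs), "CY_CURD")
  expect_true(is.na(out3$ch4_cy_curd_ir_ir[2]))
  expect_false(is.na(out3$ch4_cy_solids_ir_ir[2]))
})
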