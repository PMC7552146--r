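# replicate a template pedigree R times as independent blocks so one call to
# simulate_effects yields R iid replicates of its breeding values
replicate_pedigree <- function(ped, R) {
  n <- nrow(ped)
  off <- rep((seq_len(R) - 1L) * n, each = n)
  par <- function(p) ifelse(rep(ped[[p]], R) == 0L, 0L, rep(ped[[p]], R) + off)
  pedigree(rep(ped$animal, R) + off, par("sire"), par("dam"))
}

effects_for <- function(ped, va = 1, rg = 0, k = 1, seed = 1) {
  tm <- if (k == 1) c(y = 0) else c(y1 = 0, y2 = 0)
  cfg <- sim_config(n_herds = 2, cows_per_herd = 2, trait_means = tm,
                    trait_sds = setNames(rep(1, k), names(tm)),
                    true_var_additive = setNames(rep(va, k), names(tm)),
                    genetic_correlation = rg, seed = seed)
  pedsim <- list(ped = ped, cows = c(1L, 2L, 3L, 4L),
                 herd = c(1L, 1L, 2L, 2L))
  simulate_effects(pedsim, cfg)
}

test_that("breeding-value generator matches sigma_a^2 * A elementwise", {
  set.seed(1)
  tmpl <- random_pedigree(12, n_founders = 4, p_unknown = 0.1)
  A <- tabular_A(tmpl)
  R <- 20000
  big <- replicate_pedigree(tmpl, R)
  bv <- matrix(effects_for(big, va = 1, seed = 5)$breeding_values,
               nrow = 12)  # animals x replicates
  emp <- tcrossprod(bv) / R
  expect_lt(max(abs(emp - A)), 0.05)
})

test_that("parent-offspring covariance is sigma_a^2 / 2", {
  trio <- pedigree(1:3, c(0, 0, 1), c(0, 0, 2))
  big <- replicate_pedigree(trio, 10000)
  bv <- matrix(effects_for(big, va = 1, seed = 8)$breeding_values, nrow = 3)
  expect_lt(abs(cov(bv[1, ], bv[3, ]) - 0.5), 0.05)
  expect_lt(abs(cov(bv[2, ], bv[3, ]) - 0.5), 0.05)
  expect_lt(abs(cov(bv[1, ], bv[2, ])), 0.05)
})

test_that("zero additive variance gives identically zero breeding values", {
  ped <- random_pedigree(30)
  expect_true(all(effects_for(ped, va = 0)$breeding_values == 0))
})

test_that("bivariate founder correlation matches the configured value", {
  founders <- pedigree(1:10000, rep(0L, 10000), rep(0L, 10000))
  tv <- effects_for(founders, va = 1, rg = 0.8, k = 2, seed = 11)
  expect_equal(cor(tv$breeding_values[, 1], tv$breeding_values[, 2]), 0.8,
               tolerance = 0.03)
})

test_that("records carry the stated world and conserve variance", {
  cfg <- recovery_config(seed = 17)
  ps <- simulate_pedigree(cfg)
  tv <- simulate_effects(ps, cfg)
  out <- simulate_records(ps, tv, cfg)
  rec <- out$records
  expect_equal(nrow(rec), 85 * 15)
  expect_true(all(rec$parity_class %in% 1:4))
  expect_true(all(rec$dim_class %in% 1:6))
  expect_equal(ncol(out$spectra), 1060)
  # phenotypic variance ~ va + vh + ve (+ small fixed-effect spread)
  expect_equal(var(rec$y), 2.5, tolerance = 0.5)
  # empirical intra-herd heritability near 0.2 / 0.7
  h2_emp <- mean(sapply(1:3, function(s) {
    cfgs <- recovery_config(seed = 100 + s)
    pss <- simulate_pedigree(cfgs)
    tvs <- simulate_effects(pss, cfgs)
    va <- var(tvs$breeding_values[pss$cows, 1])
    va / (va + var(tvs$residuals[, 1]))
  }))
  expect_equal(h2_emp, 0.2 / 0.7, tolerance = 0.05)
})

test_that("milk-trait truncation is rare at default settings", {
  cfg <- sim_config(seed = 23)
  dat <- simulate_dataset(cfg)
  expect_lt(dat$n_truncated /
              (nrow(dat$records) * length(cfg$trait_names)), 0.01)
  # survey-scale magnitudes: derived methane traits near published means
  eme <- compute_all_eme(dat$records)
  expect_equal(mean(eme$ch4_dm), 21.3, tolerance = 1)
  expect_equal(mean(eme$ch4_cm), 14.1, tolerance = 1)
  expect_equal(mean(eme$dcmy), 25.8, tolerance = 2.5)
})

test_that("noiseless spectra with identity loadings reproduce latent traits", {
  k <- 2
  L <- matrix(0, k, 10); L[1, 1] <- 1; L[2, 2] <- 1
  cfg <- sim_config(n_herds = 4, cows_per_herd = 10, n_founders = 20,
                    n_generations = 1, n_active_sires = 3,
                    trait_means = c(y1 = 5, y2 = 9),
                    trait_sds = c(y1 = 1, y2 = 2),
                    n_wavelengths = 10, spectral_loadings = L,
                    spectral_noise_sd = 0, seed = 4)
  dat <- simulate_dataset(cfg)
  z1 <- as.numeric(scale(dat$records$y1))
  z2 <- as.numeric(scale(dat$records$y2))
  expect_equal(dat$spectra[, 1], z1, ignore_attr = TRUE, tolerance = 1e-12)
  expect_equal(dat$spectra[, 2], z2, ignore_attr = TRUE, tolerance = 1e-12)
  expect_true(all(dat$spectra[, 3:10] == 0))
})

test_that("the full dataset is deterministic under a fixed seed", {
  cfg <- sim_config(n_herds = 5, cows_per_herd = 4, n_founders = 40,
                    n_generations = 2, n_active_sires = 5,
                    n_wavelengths = 50, seed = 31)
  d1 <- simulate_dataset(cfg)
  d2 <- simulate_dataset(cfg)
  expect_identical(d1, d2)
})
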