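test_that("posterior summaries: mean, HPD95, sign probability", {
  s <- posterior_summaries(rep(5, 200))
  expect_equal(s$mean, 5)
  expect_equal(c(s$hpd_low, s$hpd_high), c(5, 5))
  expect_equal(s$p_sign, 1)
  expect_true(s$relevant)

  coin <- rep(c(-1, 1), 500)
  sc <- posterior_summaries(coin)
  expect_equal(sc$p_sign, 0.5, tolerance = 0.01)
  expect_false(sc$relevant)

  set.seed(14)
  z <- rnorm(10000) + 2
  sz <- posterior_summaries(z)
  # normal-quantile oracle for the shortest 95% interval
  expect_equal(sz$hpd_low, 2 - 1.959964, tolerance = 0.1)
  expect_equal(sz$hpd_high, 2 + 1.959964, tolerance = 0.1)
  expect_error(posterior_summaries(rnorm(50)), ">= 100")
})

test_that("heritability and herd fraction reproduce the table arithmetic", {
  mk <- function(va, vh, ve)
    structure(list(va = rep(va, 200), vh = rep(vh, 200), ve = rep(ve, 200)),
              class = "posterior_draws")
  # direct-IR methane yield column of the published survey
  expect_lt(abs(heritability(mk(0.114, 0.952, 0.367))$mean - 0.237), 5e-4)
  # gas-chromatography reference of daily methane production
  expect_lt(abs(heritability(mk(786, 4679, 4762))$mean - 0.142), 5e-4)
  expect_equal(heritability(mk(1, 1, 0))$mean, 1.0)
  expect_equal(herd_fraction(mk(0, 1, 0))$mean, 1.0)
  expect_equal(herd_fraction(mk(1, 1, 2))$mean, 0.25)
  expect_lt(abs(herd_fraction(mk(0.204, 1.819, 0.539))$mean - 0.7100), 5e-4)
})

test_that("flat-prior posterior matches the frequentist residual variance", {
  # founders-only single-herd design: residual variance should approach the
  # classical mean square around the herd/intercept fit
  set.seed(20)
  n <- 400
  ped <- pedigree(1:n, rep(0L, n), rep(0L, n))
  # herd variance needs >= 3 levels; use 3 balanced herds
  herd <- rep(1:3, length.out = n)
  y <- 10 + c(0, 1, 2)[herd] + rnorm(n, sd = 2)
  pheno <- data.frame(cow_id = 1:n, herd_date_id = herd,
                      dim_class = 1L, parity_class = 1L, y = y)
  ai <- build_a_inverse(ped)
  dr <- gibbs_univariate(pheno, ai,
                         model_spec("y", chain_settings(4000, 1000, 5),
                                    seed = 2))
  resid_ms <- summary(lm(y ~ factor(herd)))$sigma^2
  # unrelated founders with one record each: va and ve compete, so compare
  # the total non-herd variance against the residual mean square
  expect_equal(mean(dr$va + dr$ve), resid_ms, tolerance = 0.15 * resid_ms)
})

test_that("univariate sampler recovers simulated variance partitions", {
  cfg <- recovery_config(seed = 33, n_herds = 40, cows_per_herd = 15)
  ps <- simulate_pedigree(cfg)
  tv <- simulate_effects(ps, cfg)
  rec <- simulate_records(ps, tv, cfg)$records
  ai <- build_a_inverse(ps$ped)
  dr <- gibbs_univariate(rec, ai,
                         model_spec("y", chain_settings(6000, 1500, 5),
                                    seed = 7))
  expect_lt(abs(heritability(dr)$mean - 0.286), 0.12)
  expect_lt(abs(herd_fraction(dr)$mean - 1.8 / 2.5), 0.12)
  expect_true(all(dr$va > 0 & dr$vh > 0 & dr$ve > 0))
  # chain-length robustness: doubling iterations moves the mean < 2 MCSE-ish
  dr2 <- gibbs_univariate(rec, ai,
                          model_spec("y", chain_settings(12000, 1500, 5),
                                     seed = 7))
  mcse <- sd(dr$va) / sqrt(length(dr$va) / 10)  # crude autocorrelation-inflated
  expect_lt(abs(mean(dr2$va) - mean(dr$va)), 4 * mcse)
  expect_silent(check_convergence(dr2))
})

test_that("null additive variance is detected", {
  cfg <- recovery_config(seed = 41, va = 1e-4, vh = 1.8, ve = 0.7)
  ps <- simulate_pedigree(cfg)
  tv <- simulate_effects(ps, cfg)
  rec <- simulate_records(ps, tv, cfg)$records
  ai <- build_a_inverse(ps$ped)
  dr <- gibbs_univariate(rec, ai,
                         model_spec("y", chain_settings(5000, 1000, 5),
                                    seed = 3))
  expect_lt(heritability(dr)$mean, 0.10)
})

test_that("degenerate and malformed inputs error cleanly", {
  ped <- pedigree(1:10, rep(0L, 10), rep(0L, 10))
  ai <- build_a_inverse(ped)
  pheno <- data.frame(cow_id = 1:10, herd_date_id = rep(1:5, 2),
                      dim_class = 1L, parity_class = 1L, y = 1)
  expect_error(gibbs_univariate(pheno, ai, model_spec("y")), "constant")
  pheno$y <- rnorm(10)
  pheno$cow_id[1] <- 99
  expect_error(gibbs_univariate(pheno, ai, model_spec("y")),
               "absent from the pedigree")
  pheno$cow_id[1] <- 1
  pheno$dim_class[1] <- 9
  expect_error(gibbs_univariate(pheno, ai, model_spec("y")), "dim_class")
})

test_that("bivariate sampler: self-correlation limit and missing records", {
  set.seed(50)
  cfg <- recovery_config(seed = 52, va = 0.3, vh = 0.35, ve = 0.35,
                         rg = 0, bivariate = TRUE, n_herds = 30,
                         cows_per_herd = 15)
  ps <- simulate_pedigree(cfg)
  tv <- simulate_effects(ps, cfg)
  rec <- simulate_records(ps, tv, cfg)$records
  # same trait twice with independent small measurement noise -> r_G ~ 1
  rec$y2 <- rec$y1 + rnorm(nrow(rec), sd = 0.05)
  ai <- build_a_inverse(ps$ped)
  dr <- gibbs_bivariate(rec, ai,
                        model_spec(c("y1", "y2"),
                                   chain_settings(4000, 1000, 5), seed = 5))
  cors <- component_correlations(dr)
  expect_gt(cors$r_G$mean, 0.9)
  expect_gt(cors$r_P$mean, 0.95)
  expect_true(all(abs(sapply(cors, `[[`, "mean")) <= 1))
  # PD of every retained draw
  expect_true(all(dr$G[, "v1"] * dr$G[, "v2"] - dr$G[, "cov"]^2 > 0))
  expect_true(all(dr$R[, "v1"] * dr$R[, "v2"] - dr$R[, "cov"]^2 > 0))

  # unequal coverage: drop one trait for a third of the records
  rec2 <- simulate_records(ps, tv, cfg)$records
  rec2$y2[seq(1, nrow(rec2), by = 3)] <- NA
  dr2 <- gibbs_bivariate(rec2, ai,
                         model_spec(c("y1", "y2"),
                                    chain_settings(3000, 1000, 5), seed = 6))
  expect_true(all(is.finite(dr2$G)))
  expect_true(all(component_correlations(dr2)$r_G$mean <= 1))
})

test_that("boundary correlation draws are handled", {
  mkbiv <- function(M) {
    m <- matrix(rep(M, each = 150), 150, 3,
                dimnames = list(NULL, c("v1", "cov", "v2")))
    structure(list(G = m, H = m, R = m), class = "posterior_draws")
  }
  expect_equal(component_correlations(mkbiv(c(1, 0, 1)))$r_G$mean, 0)
  expect_equal(component_correlations(mkbiv(c(1, 1, 1)))$r_G$mean, 1)
})
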