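#' Centre and standardize a spectra matrix
#'
#' Each wavelength column is centred and scaled to unit SD; the constants
#' are kept so new samples can be projected onto the same scale. A constant
#' column has its SD replaced by 1 (the column standardizes to all zeros)
#' with a warning. No other spectral pretreatment is applied.
#'
#' @param S samples x wavelengths numeric matrix.
#' @param center,scale optional constants from a previous call, to project
#'   new samples instead of re-estimating.
#' @return list of class `std_spectra`: `values`, `center`, `scale`.
#' @export
standardize_spectra <- function(S, center = NULL, scale = NULL) {
  S <- as.matrix(S)
  if (any(!is.finite(S))) stop("spectra contain missing or non-finite cells")
  if (is.null(center)) {
    if (nrow(S) < 2) stop("need >= 2 samples to estimate standardization")
    center <- colMeans(S)
    scale <- apply(S, 2, stats::sd)
    if (any(scale == 0)) {
      warning(sum(scale == 0), " constant wavelength column(s): sd set to 1")
      scale[scale == 0] <- 1
    }
  }
  values <- sweep(sweep(S, 2, center), 2, scale, "/")
  structure(list(values = values, center = center, scale = scale),
            class = "std_spectra")
}

#' Undo spectra standardization
#' @param std a `std_spectra` object.
#' @return the matrix on the original absorbance scale.
#' @export
unstandardize_spectra <- function(std) {
  sweep(sweep(std$values, 2, std$scale, "*"), 2, std$center, "+")
}

#' Chain settings for the Gibbs samplers
#'
#' @param n_iter total iterations; @param burn_in discarded iterations;
#' @param thin keep every `thin`-th post-burn-in sample.
#' @return list of class `chain_settings`.
#' @export
chain_settings <- function(n_iter = 12000, burn_in = 2000, thin = 5) {
  stopifnot(n_iter > burn_in, burn_in >= 0, thin >= 1)
  structure(list(n_iter = as.integer(n_iter), burn_in = as.integer(burn_in),
                 thin = as.integer(thin)), class = "chain_settings")
}

#' Fit a BayesB whole-spectrum calibration
#'
#' Regresses a phenotype on standardized wavelength absorbances under the
#' BayesB prior: each coefficient is zero with probability `pi0` and
#' otherwise normal with its own variance following a scaled-inverse-
#' chi-square prior (df `df_slab`). The slab scale is set so the included
#' coefficients jointly account for half the phenotypic variance a priori.
#' Returned coefficients are posterior means (model-averaged over
#' inclusion).
#'
#' @param y numeric phenotype vector.
#' @param spectra samples x wavelengths matrix, or a `std_spectra`
#'   (raw matrices are standardized internally).
#' @param pi0 prior exclusion probability (default 0.95).
#' @param df_slab slab degrees of freedom (default 5).
#' @param chain a [chain_settings()].
#' @param seed optional seed applied before sampling.
#' @return object of class `calibration_model` with `intercept`,
#'   `coefficients`, `center`, `scale`, `pip` (posterior inclusion
#'   probabilities) and `residual_variance` draws.
#' @export
fit_bayesb <- function(y, spectra, pi0 = 0.95, df_slab = 5,
                       chain = chain_settings(), seed = NULL) {
  if (any(!is.finite(y))) stop("phenotype contains missing/non-finite values")
  std <- if (inherits(spectra, "std_spectra")) spectra
         else standardize_spectra(spectra)
  X <- std$values
  if (nrow(X) != length(y)) stop("length(y) must match rows(spectra)")
  if (!is.null(seed)) set.seed(seed)
  p <- ncol(X)
  vy <- stats::var(y)
  # slab scale: E[var per included coefficient] = 0.5 vy / ((1-pi0) p)
  exp_in <- max((1 - pi0) * p, 1)
  s0 <- 0.5 * max(vy, 1e-12) * (df_slab - 2) / (df_slab * exp_in)
  fit <- bayesb_gibbs(as.numeric(y), X, pi0, df_slab, s0,
                      chain$n_iter, chain$burn_in, chain$thin)
  structure(list(intercept = fit$mu, coefficients = as.numeric(fit$beta),
                 pip = as.numeric(fit$pip),
                 center = std$center, scale = std$scale,
                 residual_variance = as.numeric(fit$ve_draws),
                 pi0 = pi0, df_slab = df_slab, chain = chain),
            class = "calibration_model")
}

#' @describeIn fit_bayesb predict from a fitted calibration on raw spectra.
#' @param object a `calibration_model`; @param newdata raw spectra matrix;
#' @param ... unused.
#' @export
predict.calibration_model <- function(object, newdata, ...) {
  Z <- standardize_spectra(as.matrix(newdata), center = object$center,
                           scale = object$scale)$values
  as.numeric(object$intercept + Z %*% object$coefficients)
}

#' Random training-testing splits
#'
#' The split sequence behind [crossvalidate()]: `repetitions` independent
#' random draws of `round(test_frac * n)` held-out samples. Exposed so the
#' sampling design (e.g. the expected `(1 - test_frac)^repetitions`
#' never-tested fraction) can be studied without fitting anything.
#'
#' @param n number of samples; @param repetitions number of splits;
#' @param test_frac held-out fraction; @param seed RNG seed.
#' @return list of sorted test-index vectors, one per repetition.
#' @export
training_testing_splits <- function(n, repetitions = 10, test_frac = 0.2,
                                    seed = 1L) {
  n_test <- round(test_frac * n)
  if (n_test < 1 || n_test >= n) stop("test fraction leaves no train/test data")
  set.seed(seed)
  split_seeds <- sample.int(2^30, repetitions)
  lapply(split_seeds, function(s) {
    set.seed(s)
    sort(sample.int(n, n_test))
  })
}

#' Repeated random training-testing validation
#'
#' Repeats `repetitions` independent random splits holding out
#' `test_frac` of the samples, fits the calibration on the training part
#' only (standardization constants included), and predicts the held-out
#' part. Out-of-fold predictions are pooled across repetitions for the
#' cross-validation statistics: `r2_cv` is the squared Pearson correlation
#' of pooled predictions with the observed values and `rmse_cv` the root
#' mean squared out-of-fold error. A sample tested several times
#' contributes each time; samples never tested contribute nothing.
#'
#' @inheritParams fit_bayesb
#' @param repetitions number of random splits (default 10).
#' @param test_frac held-out fraction per split (default 0.2).
#' @param seed seed for the split sequence and samplers.
#' @return object of class `cv_result`: `predictions` (samples x
#'   repetitions, `NA` when not tested), `r2_cv`, `rmse_cv`, `splits`,
#'   `seed`.
#' @export
crossvalidate <- function(y, spectra, repetitions = 10, test_frac = 0.2,
                          pi0 = 0.95, df_slab = 5, chain = chain_settings(),
                          seed = 1L) {
  S <- if (inherits(spectra, "std_spectra")) unstandardize_spectra(spectra)
       else as.matrix(spectra)
  n <- length(y)
  if (nrow(S) != n) stop("length(y) must match rows(spectra)")
  n_test <- round(test_frac * n)
  if (n < 25 || n_test < 2) stop("too few samples for training-testing")
  splits <- training_testing_splits(n, repetitions, test_frac, seed)
  preds <- matrix(NA_real_, n, repetitions)
  for (r in seq_len(repetitions)) {
    test <- splits[[r]]
    fit <- fit_bayesb(y[-test], S[-test, , drop = FALSE], pi0 = pi0,
                      df_slab = df_slab, chain = chain,
                      seed = seed_for(seed, paste0("rep", r)))
    preds[test, r] <- predict(fit, S[test, , drop = FALSE])
  }
  tested <- !is.na(preds)
  obs <- matrix(y, n, repetitions)[tested]
  fit_pool <- preds[tested]
  r2 <- stats::cor(fit_pool, obs)^2
  rmse <- sqrt(mean((fit_pool - obs)^2))
  structure(list(predictions = preds, r2_cv = r2, rmse_cv = rmse,
                 splits = splits, seed = seed),
            class = "cv_result")
}

#' Validation-only phenotype per sample
#'
#' Collapses a `cv_result` to one inflation-safe phenotype per sample: the
#' mean of its out-of-fold predictions over the repetitions in which it was
#' held out. Samples never held out are dropped (with 10 repetitions of
#' 80/20 splits about `0.8^10 ~ 10.7%` of samples). Training-set
#' predictions never enter, so the retained phenotype of a sample only ever
#' comes from models that excluded it.
#'
#' @param cv a `cv_result` (or a named list of them, one per trait).
#' @param ids optional sample ids (defaults to row numbers).
#' @return data.frame `id`, `phenotype`, `times_tested` (one row per
#'   retained sample); for a list input, a wide data.frame with one column
#'   per trait (`NA` where a trait never tested that sample) and the
#'   attribute `retained_n` per trait.
#' @export
assemble_validation_db <- function(cv, ids = NULL) {
  if (inherits(cv, "cv_result")) {
    p <- cv$predictions
    if (is.null(ids)) ids <- seq_len(nrow(p))
    k <- rowSums(!is.na(p))
    keep <- k >= 1
    if (!any(keep)) stop("no sample was ever in a test subset")
    return(data.frame(id = ids[keep],
                      phenotype = rowMeans(p, na.rm = TRUE)[keep],
                      times_tested = k[keep]))
  }
  stopifnot(is.list(cv), length(cv) >= 1, !is.null(names(cv)))
  n <- nrow(cv[[1]]$predictions)
  if (is.null(ids)) ids <- seq_len(n)
  out <- data.frame(id = ids)
  retained <- integer(0)
  for (tr in names(cv)) {
    p <- cv[[tr]]$predictions
    k <- rowSums(!is.na(p))
    v <- rowMeans(p, na.rm = TRUE)
    v[k == 0] <- NA_real_
    out[[tr]] <- v
    retained[tr] <- sum(k > 0)
  }
  tested_per_row <- rowSums(!is.na(out[names(cv)]))
  if (!any(tested_per_row == length(cv)))
    stop("empty intersection: no sample was tested for every trait")
  keep <- tested_per_row > 0
  out <- out[keep, , drop = FALSE]
  attr(out, "retained_n") <- retained
  out
}

#' The eight indirect methane predictions
#'
#' Combines validation-database predictions of the informative traits (six
#' fatty acids, the two cheese-yield percentages and corrected milk yield)
#' with the direct spectral predictions and the measured records to form the
#' eight indirect methane phenotypes:
#' `ch4_dm_fair`, `ch4_cm_fair` (methane equations applied to predicted
#' fatty acids), `ch4_cy_curd_ir_ir`, `ch4_cy_solids_ir_ir` (daily methane
#' built from the direct milk-intensity prediction divided by milk yield
#' times the predicted cheese-yield percentage), `dch4_cm_ir`,
#' `dch4_cm_fair` (measured corrected milk yield times predicted
#' intensity), and `dch4_ir_ir`, `dch4_ir_fair` (predicted corrected milk
#' yield times predicted intensity).
#'
#' A non-positive predicted cheese yield leaves the affected cheese trait
#' `NA` with a warning; other traits are unaffected.
#'
#' @param db validation data.frame from [assemble_validation_db()] (list
#'   form) holding columns for the informative traits and `ch4_cm_ir` (the
#'   direct spectral prediction of methane intensity-milk).
#' @param records measured records (needs `cow_id`, `dmy`, `fat_pct`,
#'   `protein_pct`).
#' @return `db` with the eight indirect columns appended.
#' @export
indirect_predictions <- function(db, records) {
  need <- c(informative_trait_names(), "ch4_cm_ir")
  missing <- setdiff(need, names(db))
  if (length(missing))
    stop("validation db lacks prediction column(s): ",
         paste(missing, collapse = ", "))
  m <- match(db$id, records$cow_id)
  if (anyNA(m)) stop("validation db ids absent from records")
  dmy <- records$dmy[m]
  dcmy_meas <- corrected_milk_yield(dmy, records$fat_pct[m],
                                    records$protein_pct[m])
  fa_ir <- db[informative_trait_names()[1:6]]
  # equations tolerate slightly negative predicted FA: clamp into range for
  # evaluation, the prediction itself is untouched
  fa_eval <- as.data.frame(lapply(fa_ir, function(x) pmin(pmax(x, 0), 100)))
  db$ch4_dm_fair <- methane_yield(fa_eval)
  db$ch4_cm_fair <- methane_intensity_milk(fa_eval)

  dch4_from_ir <- db$ch4_cm_ir * dcmy_meas
  for (tr in c("curd", "solids")) {
    pct <- db[[paste0("cy_", tr, "_pct")]]
    dcy <- dmy * pct / 100
    bad <- !is.na(dcy) & dcy <= 0
    if (any(bad))
      warning(sum(bad), " sample(s) with non-positive predicted %CY_",
              toupper(tr), " excluded from the cheese-intensity prediction")
    val <- rep(NA_real_, nrow(db))
    ok <- !is.na(dcy) & dcy > 0
    val[ok] <- dch4_from_ir[ok] / dcy[ok]
    db[[paste0("ch4_cy_", tr, "_ir_ir")]] <- val
  }
  db$dch4_cm_ir <- dcmy_meas * db$ch4_cm_ir
  db$dch4_cm_fair <- dcmy_meas * db$ch4_cm_fair
  db$dch4_ir_ir <- db$dcmy * db$ch4_cm_ir
  db$dch4_ir_fair <- db$dcmy * db$ch4_cm_fair
  db
}
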