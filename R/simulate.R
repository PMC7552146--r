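#' Derive a reproducible per-stage seed from a master seed
#'
#' Each pipeline stage draws its own seed from the master seed so stages can
#' be rerun in isolation and still be byte-identical. Kept below 2^31.
#'
#' @param seed master seed (integer).
#' @param stage stage name.
#' @return an integer seed.
#' @export
seed_for <- function(seed, stage) {
  off <- sum(utf8ToInt(stage)) * 131
  as.integer((abs(as.double(seed)) * 7919 + off) %% 2147483629)
}

default_trait_means <- function() {
  c(c4_0 = 3.1, c16_0iso = 0.25, c18_1_t10 = 0.3, c18_1_t11 = 1.5,
    c18_1_c9 = 17.5, c18_2_c9c12 = 1.5,
    dmy = 24.8, fat_pct = 4.22, protein_pct = 3.70,
    cy_curd_pct = 14.96, cy_solids_pct = 7.21)
}

default_trait_sds <- function() {
  c(c4_0 = 0.35, c16_0iso = 0.05, c18_1_t10 = 0.12, c18_1_t11 = 0.45,
    c18_1_c9 = 2.0, c18_2_c9c12 = 0.30,
    dmy = 8.0, fat_pct = 0.70, protein_pct = 0.43,
    cy_curd_pct = 1.89, cy_solids_pct = 0.93)
}

#' Simulation configuration
#'
#' The stated world of the generator: an alpine-survey-like design of
#' `n_herds` herd/date visits of `cows_per_herd` cows each, a discrete
#' pedigree of `n_generations` complete ancestor generations above the
#' phenotyped cows, and per-trait variance partitions. Defaults emulate the
#' target population: 85 herds x 15 cows = 1275 records, 4 ancestor
#' generations over 1890 founders (~8835 pedigree animals), 264 active sires
#' with skewed usage, milk-trait means/SDs of survey magnitude, and a
#' phenotypic variance split of 15% additive / 50% herd-date / 35% residual
#' (intra-herd h2 = 0.30, herd fraction 0.50), matching the order of the
#' published variance components for these traits.
#'
#' @param n_herds number of herd/date levels.
#' @param cows_per_herd phenotyped cows per herd/date.
#' @param n_founders founder-generation size.
#' @param n_generations complete generations between founders and cows.
#' @param n_active_sires sires serving the phenotyped generation.
#' @param trait_means,trait_sds named per-trait location/scale. Trait set is
#'   taken from `names(trait_means)`.
#' @param frac_additive,frac_herd,frac_residual default phenotypic-variance
#'   fractions used when the explicit variances are not given; must sum to 1.
#' @param true_var_additive,true_var_herd,true_var_residual optional named
#'   per-trait variances (trait units^2), overriding the fractions.
#' @param genetic_correlation genetic correlation in `[-1, 1]` applied
#'   between the first two traits (bivariate recovery experiments); other
#'   pairs are genetically independent.
#' @param parity_effect_scale,dim_effect_scale magnitude of the fixed parity
#'   (4 classes) and days-in-milk (6 classes) shifts, in phenotypic SD.
#' @param n_wavelengths spectral points per sample.
#' @param spectral_loadings optional latent-trait x wavelength loading
#'   matrix; `NULL` generates Gaussian-bump loadings (20 bumps per trait).
#' @param spectral_noise_sd iid absorbance noise SD.
#' @param seed master seed; every stage derives its own via [seed_for()].
#' @return object of class `sim_config`.
#' @export
sim_config <- function(n_herds = 85, cows_per_herd = 15, n_founders = 1890,
                       n_generations = 4, n_active_sires = 264,
                       trait_means = default_trait_means(),
                       trait_sds = default_trait_sds(),
                       frac_additive = 0.15, frac_herd = 0.50,
                       frac_residual = 0.35,
                       true_var_additive = NULL, true_var_herd = NULL,
                       true_var_residual = NULL,
                       genetic_correlation = 0,
                       parity_effect_scale = 0.25, dim_effect_scale = 0.25,
                       n_wavelengths = 1060, spectral_loadings = NULL,
                       spectral_noise_sd = 0.2, seed = 1L) {
  stopifnot(n_herds >= 1, cows_per_herd >= 1, n_founders >= 1,
            n_generations >= 0, n_wavelengths >= 1,
            abs(genetic_correlation) <= 1, spectral_noise_sd >= 0)
  if (is.null(names(trait_means)) || is.null(names(trait_sds)))
    stop("trait_means and trait_sds must be named")
  traits <- names(trait_means)
  trait_sds <- trait_sds[traits]
  if (anyNA(trait_sds)) stop("trait_sds must cover every trait in trait_means")
  vp <- trait_sds^2
  fill <- function(x, frac) {
    out <- vp * frac
    if (is.null(x)) return(out)
    if (is.null(names(x))) out[] <- rep_len(x, length(out))
    else out[names(x)] <- x
    out
  }
  if (abs(frac_additive + frac_herd + frac_residual - 1) > 1e-8)
    stop("variance fractions must sum to 1")
  va <- fill(true_var_additive, frac_additive)
  vh <- fill(true_var_herd, frac_herd)
  ve <- fill(true_var_residual, frac_residual)
  if (any(va < 0) || any(vh < 0) || any(ve < 0))
    stop("variances must be >= 0")
  structure(list(
    n_herds = as.integer(n_herds), cows_per_herd = as.integer(cows_per_herd),
    n_founders = as.integer(n_founders),
    n_generations = as.integer(n_generations),
    n_active_sires = as.integer(n_active_sires),
    trait_names = traits, trait_means = trait_means, trait_sds = trait_sds,
    true_var_additive = va, true_var_herd = vh, true_var_residual = ve,
    genetic_correlation = genetic_correlation,
    parity_effect_scale = parity_effect_scale,
    dim_effect_scale = dim_effect_scale,
    n_wavelengths = as.integer(n_wavelengths),
    spectral_loadings = spectral_loadings,
    spectral_noise_sd = spectral_noise_sd,
    seed = seed), class = "sim_config")
}

# genetic covariance matrix across the config's traits: diagonal except a
# single correlation between the first two traits (bivariate experiments)
genetic_covariance <- function(cfg) {
  k <- length(cfg$trait_names)
  G <- diag(cfg$true_var_additive, k, k)
  if (k >= 2 && cfg$genetic_correlation != 0) {
    G[1, 2] <- G[2, 1] <- cfg$genetic_correlation *
      sqrt(cfg$true_var_additive[1] * cfg$true_var_additive[2])
  }
  dimnames(G) <- list(cfg$trait_names, cfg$trait_names)
  ev <- eigen(G, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev < -1e-10)) stop("genetic covariance matrix not positive definite")
  G
}

# matrix square root that tolerates exact zeros on the diagonal
cov_sqrt <- function(G) {
  e <- eigen(G, symmetric = TRUE)
  e$vectors %*% diag(sqrt(pmax(e$values, 0)), nrow(G)) %*% t(e$vectors)
}

#' Simulate breeding values, herd effects and residuals
#'
#' Breeding values follow the pedigree by the Mendelian-sampling recursion:
#' founders draw from `MVN(0, G)`; an offspring gets half of each parent's
#' value plus a Mendelian deviation with covariance
#' `G * (0.5 - 0.25 (F_sire + F_dam))`. This reproduces `cov(a) = G (x) A`
#' exactly while scaling linearly in pedigree size. Herd effects and
#' per-record residuals are iid normal with the config's variances.
#'
#' @param pedsim output of [simulate_pedigree()].
#' @param cfg a [sim_config()].
#' @return list of class `true_values`: `breeding_values` (pedigree animals x
#'   traits), `herd_effects` (herds x traits), `residuals` (records x traits).
#' @export
simulate_effects <- function(pedsim, cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  ped <- pedsim$ped
  validate_pedigree(ped)
  if (!is.null(cfg$seed)) set.seed(seed_for(cfg$seed, "effects"))
  n <- nrow(ped)
  k <- length(cfg$trait_names)
  G <- genetic_covariance(cfg)
  Gs <- cov_sqrt(G)
  s <- match(ped$sire, ped$animal, nomatch = 0L)
  d <- match(ped$dam, ped$animal, nomatch = 0L)
  f <- ped_inbreeding(s - 1L, d - 1L)

  z <- matrix(stats::rnorm(n * k), n, k)
  bv <- matrix(0, n, k, dimnames = list(ped$animal, cfg$trait_names))
  for (i in seq_len(n)) {
    if (s[i] == 0L && d[i] == 0L) {
      bv[i, ] <- Gs %*% z[i, ]
    } else {
      pa <- if (s[i] > 0L) bv[s[i], ] else 0
      pb <- if (d[i] > 0L) bv[d[i], ] else 0
      fs <- if (s[i] > 0L) f[s[i]] else -1
      fd <- if (d[i] > 0L) f[d[i]] else -1
      msv <- 0.5 - 0.25 * (fs + fd)
      bv[i, ] <- 0.5 * (pa + pb) + sqrt(msv) * (Gs %*% z[i, ])
    }
  }
  herd_effects <- matrix(stats::rnorm(cfg$n_herds * k), cfg$n_herds, k) %*%
    diag(sqrt(cfg$true_var_herd), k, k)
  n_rec <- length(pedsim$cows)
  residuals <- matrix(stats::rnorm(n_rec * k), n_rec, k) %*%
    diag(sqrt(cfg$true_var_residual), k, k)
  colnames(herd_effects) <- colnames(residuals) <- cfg$trait_names
  structure(list(breeding_values = bv, herd_effects = herd_effects,
                 residuals = residuals), class = "true_values")
}

# Gaussian-bump loadings: each latent trait projects onto `bumps` random
# wavelength neighbourhoods
make_spectral_loadings <- function(n_traits, n_wavelengths, bumps = 20) {
  L <- matrix(0, n_traits, n_wavelengths)
  wl <- seq_len(n_wavelengths)
  for (t in seq_len(n_traits)) {
    centers <- sample.int(n_wavelengths, bumps, replace = TRUE)
    widths <- stats::runif(bumps, 3, 8)
    amps <- stats::rnorm(bumps)
    for (b in seq_len(bumps))
      L[t, ] <- L[t, ] + amps[b] * exp(-0.5 * ((wl - centers[b]) / widths[b])^2)
  }
  L
}

#' Simulate milk records and FTIR-like spectra
#'
#' Each phenotyped cow gets a record: herd/date, parity class (1-4),
#' days-in-milk class (1-6), and every configured trait as
#' mean + fixed class shifts + breeding value + herd effect + residual.
#' Strictly non-negative milk traits are truncated at zero; the truncation
#' count is reported (it must be negligible at default settings). Spectra
#' are a linear map of the standardized latent informative traits through
#' Gaussian-bump loadings plus iid noise - a learnable linear signal, not a
#' physical model of mid-infrared absorbance.
#'
#' @param pedsim output of [simulate_pedigree()].
#' @param tv output of [simulate_effects()].
#' @param cfg a [sim_config()].
#' @return list: `records` (data.frame, one row per cow), `spectra`
#'   (records x `n_wavelengths` matrix), `loadings`, `n_truncated`.
#' @export
simulate_records <- function(pedsim, tv, cfg) {
  stopifnot(inherits(cfg, "sim_config"), inherits(tv, "true_values"))
  if (!is.null(cfg$seed)) set.seed(seed_for(cfg$seed, "records"))
  cows <- pedsim$cows
  n <- length(cows)
  traits <- cfg$trait_names
  k <- length(traits)

  parity <- sample.int(4L, n, replace = TRUE, prob = c(0.35, 0.27, 0.2, 0.18))
  dimc <- sample.int(6L, n, replace = TRUE)
  # deterministic class-shift patterns scaled per trait
  par_pat <- c(0, 0.5, 0.8, 1.0)
  dim_pat <- c(0, -0.4, -0.7, -1.0, -0.8, -0.5)

  rec <- data.frame(cow_id = pedsim$ped$animal[cows],
                    herd_date_id = pedsim$herd,
                    parity_class = parity, dim_class = dimc)
  n_trunc <- 0L
  for (j in seq_len(k)) {
    tr <- traits[j]
    shift <- cfg$parity_effect_scale * cfg$trait_sds[j] * par_pat[parity] +
      cfg$dim_effect_scale * cfg$trait_sds[j] * dim_pat[dimc]
    val <- cfg$trait_means[j] + shift +
      tv$breeding_values[cows, j] +
      tv$herd_effects[pedsim$herd, j] +
      tv$residuals[, j]
    # truncation only makes sense for inherently non-negative milk traits;
    # generic experimental traits (arbitrary scale) are left untouched
    if (tr %in% names(default_trait_means())) {
      neg <- val < 0
      n_trunc <- n_trunc + sum(neg)
      val[neg] <- 0
    }
    rec[[tr]] <- val
  }
  if (n_trunc > 0)
    message(n_trunc, " trait value(s) truncated at 0 (",
            sprintf("%.2f", 100 * n_trunc / (n * k)), "% of cells)")

  # latent informative traits feeding the spectra
  milk <- all(c("dmy", "fat_pct", "protein_pct", "cy_curd_pct",
                "cy_solids_pct") %in% traits) &&
    all(informative_trait_names()[1:6] %in% traits)
  if (milk) {
    lat <- cbind(as.matrix(rec[informative_trait_names()[1:8]]),
                 dmy = rec$dmy,
                 fat_pct = rec$fat_pct, protein_pct = rec$protein_pct,
                 dcmy = corrected_milk_yield(rec$dmy, rec$fat_pct,
                                             rec$protein_pct),
                 dcy_curd = rec$dmy * rec$cy_curd_pct / 100,
                 dcy_solids = rec$dmy * rec$cy_solids_pct / 100)
  } else {
    lat <- as.matrix(rec[traits])
  }
  latz <- scale(lat)
  latz[, attr(latz, "scaled:scale") == 0] <- 0
  L <- cfg$spectral_loadings
  if (is.null(L)) L <- make_spectral_loadings(ncol(latz), cfg$n_wavelengths)
  if (ncol(L) != cfg$n_wavelengths || nrow(L) != ncol(latz))
    stop("spectral_loadings must be (n latent traits) x n_wavelengths")
  spectra <- latz %*% L +
    matrix(stats::rnorm(n * cfg$n_wavelengths, sd = cfg$spectral_noise_sd),
           n, cfg$n_wavelengths)
  rownames(spectra) <- rec$cow_id
  list(records = rec, spectra = spectra, loadings = L, n_truncated = n_trunc)
}

#' One-call synthetic dataset
#'
#' Convenience wrapper running [simulate_pedigree()], [simulate_effects()]
#' and [simulate_records()] with one config.
#'
#' @param cfg a [sim_config()].
#' @return list with `pedsim`, `true_values`, `records`, `spectra`.
#' @export
simulate_dataset <- function(cfg) {
  pedsim <- simulate_pedigree(cfg)
  tv <- simulate_effects(pedsim, cfg)
  recs <- simulate_records(pedsim, tv, cfg)
  list(pedsim = pedsim, true_values = tv, records = recs$records,
       spectra = recs$spectra, loadings = recs$loadings,
       n_truncated = recs$n_truncated)
}
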