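#' Animal-model specification
#'
#' Describes the mixed model `y = Xb + Z1 h + Z2 a + e`: fixed days-in-milk
#' (6 classes) and parity (4 classes) effects, a random herd/date effect and
#' a pedigree-correlated additive genetic effect. The first level of each
#' fixed factor is constrained to zero for identifiability; an intercept is
#' always included. Priors are flat for b and all variance components.
#'
#' @param traits character, one (univariate) or two (bivariate) trait names.
#' @param chain a [chain_settings()]; the field-scale chains of animal
#'   breeding (hundreds of thousands of iterations) are configurable but the
#'   default is a desk-scale 50,000 / 10,000 / thin 10.
#' @param seed seed applied before sampling.
#' @return object of class `model_spec`.
#' @export
model_spec <- function(traits, chain = chain_settings(50000, 10000, 10),
                       seed = 1L) {
  stopifnot(length(traits) %in% 1:2, inherits(chain, "chain_settings"))
  structure(list(traits = traits, chain = chain, seed = seed),
            class = "model_spec")
}

# dense fixed-effect design: intercept + DIM classes 2..6 + parity 2..4
build_fixed_design <- function(pheno) {
  need <- c("dim_class", "parity_class")
  missing <- setdiff(need, names(pheno))
  if (length(missing))
    stop("phenotypes lack column(s): ", paste(missing, collapse = ", "))
  if (!all(pheno$dim_class %in% 1:6)) stop("dim_class must be in 1..6")
  if (!all(pheno$parity_class %in% 1:4)) stop("parity_class must be in 1..4")
  n <- nrow(pheno)
  X <- matrix(0, n, 1 + 5 + 3)
  X[, 1] <- 1
  for (l in 2:6) X[, l] <- as.numeric(pheno$dim_class == l)
  for (l in 2:4) X[, 5 + l] <- as.numeric(pheno$parity_class == l)
  colnames(X) <- c("intercept", paste0("dim", 2:6), paste0("parity", 2:4))
  X
}

prepare_model_frame <- function(pheno, ainv) {
  need <- c("cow_id", "herd_date_id")
  missing <- setdiff(need, names(pheno))
  if (length(missing))
    stop("phenotypes lack column(s): ", paste(missing, collapse = ", "))
  aidx <- match(pheno$cow_id, ainv$animal)
  if (anyNA(aidx))
    stop("cow id(s) absent from the pedigree: ",
         paste(utils::head(pheno$cow_id[is.na(aidx)], 5), collapse = ", "))
  herd_levels <- sort(unique(pheno$herd_date_id))
  hidx <- match(pheno$herd_date_id, herd_levels)
  list(X = build_fixed_design(pheno), aidx = as.integer(aidx - 1L),
       hidx = as.integer(hidx - 1L), nh = length(herd_levels),
       herd_levels = herd_levels)
}

ainv_slots <- function(ainv) {
  A <- methods::as(methods::as(ainv$Ainv, "generalMatrix"), "CsparseMatrix")
  list(p = A@p, i = A@i, x = A@x, q = nrow(A))
}

#' Univariate Gibbs sampling of the animal model
#'
#' Single-site Gibbs sampler: location effects from their normal full
#' conditionals, each variance component from the scaled-inverse-chi-square
#' full conditional implied by the flat prior (df = count - 2). Thinned
#' post-burn-in draws of the additive, herd/date and residual variances are
#' returned together with posterior-mean effects.
#'
#' @param pheno data.frame with `cow_id`, `herd_date_id`, `dim_class`,
#'   `parity_class` and the trait column.
#' @param ainv result of [build_a_inverse()] (pedigree must contain every
#'   phenotyped cow).
#' @param spec a [model_spec()] with one trait.
#' @return object of class `posterior_draws` with elements `va`, `vh`,
#'   `ve` (draw vectors), effect means, and the spec.
#' @export
gibbs_univariate <- function(pheno, ainv, spec) {
  stopifnot(inherits(spec, "model_spec"), length(spec$traits) == 1)
  tr <- spec$traits
  if (!tr %in% names(pheno)) stop("trait column not found: ", tr)
  y <- pheno[[tr]]
  keep <- is.finite(y)
  if (!all(keep)) {
    message(sum(!keep), " record(s) without ", tr, " dropped")
    pheno <- pheno[keep, , drop = FALSE]
    y <- y[keep]
  }
  if (length(unique(y)) < 2) stop("degenerate input: trait is constant")
  mf <- prepare_model_frame(pheno, ainv)
  As <- ainv_slots(ainv)
  if (!is.null(spec$seed)) set.seed(seed_for(spec$seed, paste0("uni_", tr)))
  ch <- spec$chain
  fit <- animal_gibbs_uni(y, mf$X, mf$hidx, mf$nh, mf$aidx,
                          As$p, As$i, As$x, ch$n_iter, ch$burn_in, ch$thin)
  structure(list(va = fit$va, vh = fit$vh, ve = fit$ve,
                 b_mean = stats::setNames(fit$b_mean, colnames(mf$X)),
                 h_mean = stats::setNames(fit$h_mean, mf$herd_levels),
                 a_mean = stats::setNames(fit$a_mean, ainv$animal),
                 n = length(y), spec = spec, traits = tr),
            class = "posterior_draws")
}

#' Bivariate Gibbs sampling of the animal model
#'
#' Two-trait version with unstructured 2x2 additive (`G0`), herd/date
#' (`H0`) and residual (`R0`) covariance matrices sampled from their
#' inverse-Wishart full conditionals. Records missing one trait are handled
#' by data augmentation (missing-at-random), so the phenotyped sets may
#' differ between traits. Every retained draw of each 2x2 matrix is
#' positive definite by construction.
#'
#' @inheritParams gibbs_univariate
#' @param spec a [model_spec()] with two traits.
#' @return `posterior_draws` with matrices `G`, `H`, `R` (columns
#'   `v1, cov, v2`, one row per retained draw).
#' @export
gibbs_bivariate <- function(pheno, ainv, spec) {
  stopifnot(inherits(spec, "model_spec"), length(spec$traits) == 2)
  trs <- spec$traits
  missing <- setdiff(trs, names(pheno))
  if (length(missing)) stop("trait column not found: ", missing[1])
  Y <- as.matrix(pheno[trs])
  obs <- is.finite(Y)
  keep <- rowSums(obs) > 0
  if (!all(keep)) pheno <- pheno[keep, , drop = FALSE]
  Y <- Y[keep, , drop = FALSE]
  Y[!is.finite(Y)] <- NA_real_
  for (t in 1:2)
    if (length(unique(stats::na.omit(Y[, t]))) < 2)
      stop("degenerate input: trait ", trs[t], " is constant")
  mf <- prepare_model_frame(pheno, ainv)
  As <- ainv_slots(ainv)
  if (!is.null(spec$seed))
    set.seed(seed_for(spec$seed, paste0("biv_", paste(trs, collapse = "_"))))
  ch <- spec$chain
  fit <- animal_gibbs_biv(Y, mf$X, mf$hidx, mf$nh, mf$aidx,
                          As$p, As$i, As$x, ch$n_iter, ch$burn_in, ch$thin)
  colnames(fit$G) <- colnames(fit$H) <- colnames(fit$R) <- c("v1", "cov", "v2")
  structure(list(G = fit$G, H = fit$H, R = fit$R,
                 n = nrow(Y), spec = spec, traits = trs),
            class = "posterior_draws")
}

#' Posterior summary of a scalar functional
#'
#' Point estimate (posterior mean), shortest interval holding 95% of the
#' sorted draws (HPD95), and the sign probability `p`: the share of draws on
#' the same side of zero as the mean. An estimate is flagged `relevant`
#' when `p > 0.95`.
#'
#' @param samples numeric draws (>= 100).
#' @param prob interval mass (default 0.95).
#' @return list of class `posterior_summary`: `mean`, `hpd_low`,
#'   `hpd_high`, `p_sign`, `relevant`, `n_draws`.
#' @export
posterior_summaries <- function(samples, prob = 0.95) {
  samples <- samples[is.finite(samples)]
  if (length(samples) < 100) stop("need >= 100 posterior draws")
  m <- mean(samples)
  s <- sort(samples)
  n <- length(s)
  k <- max(1L, ceiling(prob * n))
  if (k >= n) {
    lo <- s[1]; hi <- s[n]
  } else {
    width <- s[(k + 1):n] - s[seq_len(n - k)]
    j <- which.min(width)
    lo <- s[j]; hi <- s[j + k]
  }
  p <- if (m >= 0) mean(samples > 0) else mean(samples < 0)
  structure(list(mean = m, hpd_low = lo, hpd_high = hi, p_sign = p,
                 relevant = p > 0.95, n_draws = n),
            class = "posterior_summary")
}

#' @export
print.posterior_summary <- function(x, ...) {
  cat(sprintf("mean %.4f  HPD95 [%.4f, %.4f]  p(sign) %.3f%s\n",
              x$mean, x$hpd_low, x$hpd_high, x$p_sign,
              if (x$relevant) "  (relevant)" else ""))
  invisible(x)
}

draws_variances <- function(draws, which_trait = 1) {
  if (!is.null(draws$va))
    return(list(va = draws$va, vh = draws$vh, ve = draws$ve))
  col <- if (which_trait == 1) "v1" else "v2"
  list(va = draws$G[, col], vh = draws$H[, col], ve = draws$R[, col])
}

#' Intra-herd heritability
#'
#' Per-draw ratio `h2 = va / (va + ve)` (herd/date variance excluded from
#' the denominator), summarized over the posterior: the reported mean is
#' the mean of per-draw ratios.
#'
#' @param draws a `posterior_draws`; @param which_trait 1 or 2 for
#'   bivariate draws.
#' @return a [posterior_summaries()] object.
#' @export
heritability <- function(draws, which_trait = 1) {
  v <- draws_variances(draws, which_trait)
  posterior_summaries(v$va / (v$va + v$ve))
}

#' Herd/date fraction of phenotypic variance
#'
#' Per-draw ratio `h_herd = vh / (va + vh + ve)`, summarized as in
#' [heritability()].
#'
#' @inheritParams heritability
#' @return a [posterior_summaries()] object.
#' @export
herd_fraction <- function(draws, which_trait = 1) {
  v <- draws_variances(draws, which_trait)
  posterior_summaries(v$vh / (v$va + v$vh + v$ve))
}

#' Component correlations from bivariate draws
#'
#' Per retained draw: `r_G`, `r_H`, `r_E` as `cov / sqrt(v1 v2)` of the
#' corresponding 2x2 matrix, and the phenotypic correlation `r_P` as the
#' summed covariances over the geometric mean of the summed (phenotypic)
#' variances. Draws with a non-positive variance are skipped with a logged
#' count.
#'
#' @param draws bivariate `posterior_draws`.
#' @return named list of [posterior_summaries()]: `r_G`, `r_H`, `r_E`,
#'   `r_P`.
#' @export
component_correlations <- function(draws) {
  if (is.null(draws$G)) stop("component correlations need bivariate draws")
  corr <- function(M) {
    ok <- M[, "v1"] > 0 & M[, "v2"] > 0
    if (any(!ok)) message(sum(!ok), " zero-variance draw(s) skipped")
    M[ok, "cov"] / sqrt(M[ok, "v1"] * M[ok, "v2"])
  }
  p1 <- draws$G[, "v1"] + draws$H[, "v1"] + draws$R[, "v1"]
  p2 <- draws$G[, "v2"] + draws$H[, "v2"] + draws$R[, "v2"]
  covp <- draws$G[, "cov"] + draws$H[, "cov"] + draws$R[, "cov"]
  list(r_G = posterior_summaries(corr(draws$G)),
       r_H = posterior_summaries(corr(draws$H)),
       r_E = posterior_summaries(corr(draws$R)),
       r_P = posterior_summaries(covp / sqrt(p1 * p2)))
}

#' Split-chain convergence check
#'
#' Compares the first and second halves of each variance chain via the
#' potential-scale-reduction statistic of the split halves; warns above the
#' conventional 1.1 threshold.
#'
#' @param draws a `posterior_draws`.
#' @return named vector of split-Rhat values (invisible); warns if any
#'   exceeds 1.1.
#' @export
check_convergence <- function(draws) {
  split_rhat <- function(x) {
    n <- floor(length(x) / 2)
    a <- x[seq_len(n)]; b <- x[n + seq_len(n)]
    w <- (stats::var(a) + stats::var(b)) / 2
    bm <- n * (mean(a) - mean(b))^2 / 2
    sqrt(((n - 1) / n * w + bm / n) / w)
  }
  chains <- if (!is.null(draws$va)) {
    c(va = split_rhat(draws$va), vh = split_rhat(draws$vh),
      ve = split_rhat(draws$ve))
  } else {
    c(ga = split_rhat(draws$G[, "v1"]), gb = split_rhat(draws$G[, "v2"]),
      ra = split_rhat(draws$R[, "v1"]), rb = split_rhat(draws$R[, "v2"]))
  }
  if (any(chains > 1.1, na.rm = TRUE))
    warning("split-chain diagnostic above 1.1; consider a longer chain")
  invisible(chains)
}
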