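# Independent oracles kept free of the package's own A-inverse code path.

# Dense numerator relationship matrix by the tabular method:
#   A[i,i] = 1 + 0.5 * A[s,d];  A[i,j] = 0.5 * (A[j,s] + A[j,d]) for j < i.
tabular_A <- function(ped) {
  n <- nrow(ped)
  s <- match(ped$sire, ped$animal, nomatch = 0L)
  d <- match(ped$dam, ped$animal, nomatch = 0L)
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    asd <- if (s[i] > 0 && d[i] > 0) A[s[i], d[i]] else 0
    A[i, i] <- 1 + 0.5 * asd
    if (i > 1) for (j in seq_len(i - 1)) {
      v <- 0
      if (s[i] > 0) v <- v + 0.5 * A[j, s[i]]
      if (d[i] > 0) v <- v + 0.5 * A[j, d[i]]
      A[i, j] <- A[j, i] <- v
    }
  }
  A
}

# Random sorted pedigree: founders plus animals whose parents (possibly
# unknown) come from earlier positions.
random_pedigree <- function(n, n_founders = max(3, n %/% 4), p_unknown = 0.15) {
  sire <- dam <- integer(n)
  for (i in seq_len(n)) {
    if (i <= n_founders) next
    cand <- seq_len(i - 1)
    sire[i] <- if (stats::runif(1) < p_unknown) 0L else sample(cand, 1)
    dam[i] <- if (stats::runif(1) < p_unknown) 0L else {
      pick <- sample(cand, 1)
      if (pick == sire[i] && i > 2) pick <- sample(setdiff(cand, sire[i]), 1)
      if (pick == sire[i]) 0L else pick
    }
  }
  pedigree(seq_len(n), sire, dam)
}

# single-trait world used by the recovery experiments
recovery_config <- function(seed, va = 0.2, vh = 1.8, ve = 0.5, rg = 0,
                            bivariate = FALSE, n_herds = 85,
                            cows_per_herd = 15) {
  if (bivariate) {
    sim_config(n_herds = n_herds, cows_per_herd = cows_per_herd,
               trait_means = c(y1 = 0, y2 = 0),
               trait_sds = c(y1 = sqrt(va + vh + ve), y2 = sqrt(va + vh + ve)),
               true_var_additive = c(y1 = va, y2 = va),
               true_var_herd = c(y1 = vh, y2 = vh),
               true_var_residual = c(y1 = ve, y2 = ve),
               genetic_correlation = rg, seed = seed)
  } else {
    sim_config(n_herds = n_herds, cows_per_herd = cows_per_herd,
               trait_means = c(y = 20), trait_sds = c(y = sqrt(va + vh + ve)),
               true_var_additive = c(y = va), true_var_herd = c(y = vh),
               true_var_residual = c(y = ve), seed = seed)
  }
}

# small fast chains for unit tests
test_chain <- function() chain_settings(2000, 500, 5)
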