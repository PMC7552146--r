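# methaphen

Genetic analysis of infrared-predicted enteric methane phenotypes in dairy
cattle.

Enteric methane emission (EME) of a cow cannot be measured at scale, but it
can be proxied from her milk: fixed meta-analysis equations turn the milk
fatty-acid (FA) profile into methane phenotypes, and the FA profile itself —
or the methane phenotypes directly — can be predicted from the milk's
Fourier-transform infrared (FTIR) absorbance spectrum, which every milk
recording lab acquires routinely. `methaphen` implements the complete chain
needed to ask whether such spectra-predicted phenotypes are usable for
selective breeding:

1. **EME traits** from the FA profile and yields:
   - methane yield `CH4/DM = 23.39 + 9.74 C16:0iso − 1.06 (C18:1 t10+t11) − 1.75 C18:2 c9c12` (g/kg DMI),
   - methane intensity `CH4/CM = 21.13 − 1.38 C4:0 + 8.53 C16:0iso − 0.22 C18:1 c9 − 0.59 (C18:1 t10+t11)` (g/kg corrected milk),
   - daily production `dCH4 = CH4/CM × dCMY` with
     `dCMY = dMY × (0.337 + 0.116 fat% + 0.06 protein%)`,
   - cheese intensities `dCH4 / dCY_CURD` and `dCH4 / dCY_SOLIDS`.
2. **BayesB whole-spectrum calibration**: `y = β0 + Σ_j x_j β_j + ε` over
   1060 standardized wavelengths with a spike-and-slab prior per
   coefficient, fitted by Gibbs sampling; validated by repeated random
   80/20 training–testing; indirect predictions composed from
   spectra-predicted components; an inflation-safe validation database
   (training predictions excluded, repeated test predictions averaged,
   never-tested samples dropped).
3. **Pedigree animal models** `y = Xb + Z1 h + Z2 a` + `e`, with fixed
   days-in-milk and parity classes, random herd/date effects and additive
   genetic effects `a ~ N(0, σa² A)` (bivariate: `a ~ N(0, G0 ⊗ A)`),
   fitted by single-site Gibbs sampling with flat priors. Reported:
   intra-herd heritability `h² = σa²/(σa²+σe²)`, herd fraction
   `h_herd = σh²/(σa²+σh²+σe²)`, genetic/herd/residual/phenotypic
   correlations with HPD95 intervals and the `p > 0.95` sign-probability
   relevance rule. `A⁻¹` is assembled sparsely by Henderson's rules with
   Meuwissen–Luo inbreeding.
4. **A synthetic-data generator** (pedigree, herd structure, milk records,
   spectra) with known variance partitions, standing in for the 1158-cow
   alpine survey this design emulates, so every stage is testable offline.

## Worked example

```r
library(methaphen)
cfg <- run_config(
  sim = sim_config(n_herds = 20, cows_per_herd = 12, n_founders = 200,
                   n_generations = 2, n_active_sires = 25,
                   n_wavelengths = 300, spectral_noise_sd = 0.2),
  repetitions = 5,
  calibration_chain = chain_settings(1200, 400, 4),
  genetics_chain = chain_settings(6000, 1500, 5),
  genetics_traits = c("ch4_cm", "ch4_cm_ir"),
  genetics_pairs = list(c("ch4_cm", "ch4_cm_ir")),
  seed = 42)
res <- run_pipeline(cfg, out_dir = "demo")
```

prints (abridged):

```
[calibrate] ch4_cm_ir R2cv=0.997 RMSEcv=0.047
[assemble] 162 of 240 samples retained
[genetics] ch4_cm h2=0.240 h_herd=0.474
[genetics] ch4_cm_ir h2=0.232 h_herd=0.492
[genetics] ch4_cm~ch4_cm_ir rG=1.00 rP=1.00
```

Reading: the spectral calibration of methane intensity reaches a
cross-validation R² of 0.997 on these (deliberately learnable) synthetic
spectra; 162 of 240 samples were ever held out in 5 random 80/20 splits
(expected fraction `1 − 0.8⁵ = 67%`) and keep an inflation-safe phenotype;
the reference trait and its spectral prediction both show intra-herd
heritabilities near the simulated 0.3/1.0 partition with about half the
variance due to herd/date; and their genetic correlation is ≈ 1, as it must
be when the prediction is essentially the trait itself. On such generator
output a high R²cv validates the machinery, not real-world FTIR accuracy
(see the methods vignette).

Stamped CSV tables (`records.csv`, `calibration_metrics.csv`,
`validation_db.csv`, `genetics_univariate.csv`, `genetics_bivariate.csv`,
`summary.txt`) are written under `demo/`, each headed by
`# seed=42 config=<hash>`.

A command-line wrapper is included:

```sh
Rscript inst/cli/methaphen.R simulate --config cfg.json --out-dir sim --seed 5
Rscript inst/cli/methaphen.R genetics --trait1 ch4_cm --pheno pheno.csv \
    --pedigree ped.csv --iters 50000 --burnin 10000 --thin 10 --seed 1
```

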