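---
title: "Models and design choices in methaphen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and design choices in methaphen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The scientific problem

Enteric methane is the dominant greenhouse-gas term of dairy production,
but measuring it per cow (respiration chambers, SF6 tracers) is impossible
at population scale. Two proxies make selective breeding thinkable. First,
fixed linear equations from respiration-chamber meta-analyses map the milk
fatty-acid (FA) profile onto methane phenotypes: methane yield per kg
dry-matter intake, and methane intensity per kg of fat/protein-corrected
milk. Multiplying intensity by corrected milk yield gives daily methane
production, and dividing that by the daily yields of fresh cheese or cheese
solids gives two cheese-oriented intensities relevant to mountain dairy
chains. Second, the mid-infrared absorbance spectrum of the same milk
sample — collected routinely by milk labs — can be calibrated against these
phenotypes (or against their FA and yield components), turning every
recorded cow into a phenotyped cow. The question the pipeline answers is a
genetic one: are the spectra-predicted phenotypes heritable, and are they
genetically the same trait as the FA-derived references?

`methaphen` implements the full chain — trait equations, Bayesian spectral
calibration with leakage-safe validation, and pedigree animal models — plus
a synthetic-data generator with known ground truth, so the whole chain is
verifiable without access to the original survey data (which were never
deposited).

## EME trait equations

The six informative FAs (g/100 g total FA) are butyric (C4:0), iso-palmitic
(C16:0 iso), iso-oleic (C18:1 trans-10), vaccenic (C18:1 trans-11), oleic
(C18:1 cis-9) and linoleic (C18:2 cis-9,cis-12) acid. The two trans C18:1
isomers are stored separately — gas chromatography resolves them — and
summed at evaluation time because the equations use one shared coefficient
for the sum. Equation outputs are never clipped: a negative prediction for
an extreme profile is retained with a warning, since silent truncation
would bias downstream variance components. Records with non-positive
cheese yields keep all other traits and get `NA` for the cheese
intensities only; this mirrors the per-trait record counts that differ
between analyses in field data.

## BayesB spectral calibration

Phenotypes are regressed on all 1060 centred and standardized wavelength
absorbances (no derivative/scatter pretreatments). The prior is the
standard BayesB spike-and-slab: a coefficient is zero with probability
`pi0` (default 0.95) and otherwise normal with a per-coefficient variance
under a scaled-inverse-chi-square prior (df 5). The slab scale is set so
the included coefficients jointly account for half of `var(y)` a priori —
a conventional, weakly informative choice; both `pi0` and the df are
arguments. With `pi0 = 0` every coefficient is included and the model
behaves like ridge regression, a useful sanity limit. The sampler draws
the indicator with the coefficient integrated out (conjugate given the
current slab variance), then the coefficient, then the slab variance and
residual variance; the intercept and residual variance carry flat priors.
Default chain 12,000/2,000/thin 5; tests use shorter chains since
posterior means of this model stabilize quickly.

**Training–testing.** Accuracy is assessed by repeated random splits: 10
repetitions of 80% training / 20% testing. The repeated-random reading
(rather than disjoint 10-fold) is the only one consistent with a
never-tested fraction of `0.8^10 ≈ 10.7%` ("about 10%") of samples.
`R²CV` is the squared Pearson correlation between pooled out-of-fold
predictions and observations, `RMSECV` the pooled out-of-fold root mean
squared error; pooling over repetitions (rather than averaging
per-repetition statistics) is the common chemometrics convention and was
adopted since the alternative is not distinguishable from the published
summary.

**Inflation-safe phenotypes.** Predictions of training samples never reach
the genetic analyses: a sample's retained phenotype is the average of its
out-of-fold predictions over the repetitions in which it was held out, and
samples never held out are dropped. By construction (and by test) every
retained prediction comes from a model whose training set excluded that
sample.

**Shared splits.** Within one pipeline run, all traits share the same
split sequence. The eight indirect predictions combine several component
predictions per sample (e.g. six FAs for the FA-based methane yield);
with independent splits per trait the joint out-of-fold coverage collapses
to `(1 − 0.8^R)^k`, which would leave almost no usable samples, whereas
shared splits keep it at the per-trait coverage — the only reading
consistent with the published per-trait sample counts. The
`crossvalidate()` function itself is agnostic: callers may seed splits
independently.

**Indirect predictions.** Eight compositions are produced: the two FA
equations applied to spectra-predicted FAs; cheese intensities from the
direct intensity prediction times measured corrected milk yield, divided
by milk yield times the predicted cheese-yield percentage; and the four
daily-methane variants crossing measured vs predicted corrected milk yield
with directly vs FA-predicted intensity. Predicted FAs are clamped into
[0, 100] g/100 g for equation evaluation only; non-positive predicted
cheese yields exclude the sample from that cheese trait with a warning.

## The animal model

Univariate: `y = Xb + Z1 h + Z2 a + e` with fixed days-in-milk (6 classes,
half-open boundaries `[lo, hi)`) and parity (4 classes) effects, random
herd/date effects `h ~ N(0, σh² I)` over 85 combined herd/date levels (one
visit per herd, so herd and visit date are a single factor), and additive
effects `a ~ N(0, σa² A)` over the full pedigree. The first level of each
fixed factor is constrained to zero; an intercept is retained. "Flat
priors" on variance components are implemented as improper uniforms, whose
full conditionals are scaled-inverse-chi-squares with df = count − 2; the
bivariate analogue uses inverse-Wisharts with minimal proper df. Location
effects are updated single-site (Gauss–Seidel sweep) in compiled code;
`A⁻¹` is assembled directly by Henderson's rules with inbreeding from the
Meuwissen–Luo recursion, never forming dense `A`.

Bivariate: unstructured 2×2 `G0`, `H0`, `R0`; records missing one trait
are data-augmented from the conditional of the missing residual given the
observed one (missing-at-random), so phenotyped sets may differ between
traits. Inverse-Wishart draws are positive definite almost surely, so no
jitter-and-redraw is needed; the retained draws are checked PD in tests.

**Functionals.** Intra-herd heritability `h² = σa²/(σa²+σe²)` and herd
fraction `h_herd = σh²/(σa²+σh²+σe²)` are computed per draw and then
summarized (mean of ratios). The published tables evidently did the same:
recomputing the ratio from the printed posterior-mean components matches
the printed ratios only to about the third decimal (up to 0.003 in one
column), exactly the gap expected between mean-of-ratios and
ratio-of-means. Correlations `r_G, r_H, r_E` are per-draw
`cov/√(v1·v2)`; the phenotypic correlation — whose formula the survey never
printed — is defined per draw as the summed covariances over the geometric
mean of the summed variances, consistent with the phenotypic-variance
definition used in `h_herd`. HPD95 is the shortest window containing 95%
of sorted draws; the sign probability `p` is the posterior mass on the
mean's side of zero, with `p > 0.95` flagged "relevant".

**Chains.** The survey-scale practice was 850,000 iterations / 50,000
burn-in / thin 100. That is configurable but pointless at desk scale; the
default `model_spec()` chain is 50,000/10,000/10, and the recovery tests
use 6,000–8,000 iterations, where posterior means of this model are stable
(verified by the chain-doubling test). A split-half potential-scale-
reduction check (threshold 1.1) replaces visual trace inspection.

## The synthetic world

The generator states one world and keeps it: 85 herd/date levels × 15 cows
= 1275 records; four complete ancestor generations over 1890 founders
(8835 pedigree animals, close to the published 8845) with 264 candidate
sires whose gamma-skewed usage yields half-sib families from singletons to
several tens of daughters spread across herds. Breeding values follow the
Mendelian-sampling recursion — founders `N(0, G)`, offspring half-parent
average plus a deviation with variance `G(0.5 − 0.25(F_s + F_d))` — which
reproduces `cov(a) = G ⊗ A` exactly and scales linearly (tested against
the tabular-method A on replicated small pedigrees). Trait means and SDs
default to survey magnitudes; the FA means were chosen once so the derived
methane traits land near the published means (≈21.3 g/kg yield, ≈14.1 g/kg
intensity). The default variance partition is 15% additive / 50%
herd-date / 35% residual (intra-herd h² = 0.30, h_herd = 0.50), the order
of magnitude of the published components. Parity and days-in-milk act as
fixed deterministic shifts of ≤ 0.25 phenotypic SD so fixed-effect
estimation is exercised; no effect sizes were published, so the pattern is
a design choice. Strictly non-negative milk traits are truncated at zero
(rate required < 1% at defaults and tested); generic experiment traits are
not truncated.

Spectra are a *learnable linear signal*, not physics: each of the 14
informative traits (6 FAs, fat, protein, two cheese-yield percentages,
four daily yields), standardized, projects onto 20 random Gaussian bumps
across the 1060 wavelengths, plus iid noise (SD 0.2). Water-absorption
bands, scattering and collinearity structure of real FTIR spectra are
deliberately absent. Consequently a green calibration test establishes
that the BayesB machinery recovers linear signal without leakage — not
that real milk spectra predict methane with any particular accuracy; the
published cross-validation accuracies (R² ≈ 0.36–0.57 for direct
predictions) cannot be reproduced without the survey data.

## Numerical and interface choices

- Constant spectral columns standardize to zero with SD set to 1, with a
  warning, so degenerate inputs cannot produce NaNs.
- Variance draws are floored at 1e−12 to avoid absorbing states in the
  Gibbs sweep; samplers start from an equal-parts variance split.
- All samplers use R's RNG (also inside the compiled code), so a single
  `set.seed` — or the pipeline's master seed, from which each stage derives
  a stage-named seed below 2³¹ — makes every run byte-identical.
- Pipeline outputs are CSVs with a `# seed=… config=<hash>` header; the
  pedigree is the 3-column headerless exchange format with 0 for unknown
  parents.
- Configs are JSON (YAML accepted when the optional `yaml` package is
  present); the CLI wrapper lives at `inst/cli/methaphen.R`.

## Known limitations

- No REML baseline, genomic relationships, maternal or permanent-
  environment effects; single record per cow.
- The BayesB hyperpriors and chain lengths of the original calibration
  software were not published; the defaults here are conventional, not
  claims of fidelity.
- Indirect cheese-intensity predictions inherit the noise of three
  component models; their sampling behaviour is only qualitatively like
  the published one.
- The generator's spectra make calibration much easier than real FTIR
  data; calibration R²cv from synthetic runs must not be compared with
  published accuracies.
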