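---
title: "Model and methods behind baysub"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model and methods behind baysub}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(baysub)
```

`baysub` clusters cancer patients into subtypes from paired tumor/normal
DNA-methylation M-value profiles while inferring, per subtype, the binary
signature of methylation changes that accompany cancerization. This
vignette documents the generative model, the sampler's full conditionals,
every tunable that matters, the synthetic-data generators, and the design
decisions taken where more than one reasonable choice existed.

## The generative model

Observed data are `n` matched pairs of M-value vectors over `m` CpG
sites: `x_i` (normal tissue) and `y_i` (tumor) for patient `i`. M-values
are `log2(beta / (1 - beta))` transforms of array beta-values —
approximately homoscedastic and so amenable to Gaussian modeling; zero is
the natural threshold between unmethylated (negative) and methylated
(positive) sites. `beta_to_m()` performs the conversion, clamping
beta-values to `[1e-6, 1 - 1e-6]` so boundary probes stay finite.

The hierarchy, top down:

* **Reference cell** `r_j ~ Bernoulli(gamma)`: one latent binary
  methylation profile from which all normal samples derive.
* **Normal profiles** `z_ij = r_j XOR Bernoulli(1 - delta)`: each
  patient's normal tissue retains the reference status at a site with
  probability `delta` (close to 1 in practice).
* **Modification paths** `w_kj ~ Bernoulli(beta)`: subtype `k` flips the
  methylation status of site `j` iff `w_kj = 1`. A row of `W` *is* the
  subtype's signature.
* **Membership** `lambda_i ~ Multinomial(1; p)`: each tumor carries
  exactly one subtype. Within-tumor mixtures of subtypes are outside the
  model (the contaminated simulator probes exactly this misspecification).
* **Tumor profiles** `phi_ij = z_ij XOR w_{k(i) j}` (`compose_phi()`).
* **Emissions**: `x_ij ~ N(mu_{z_ij}, sigma_{z_ij}^2)`,
  `y_ij ~ N(alpha_{phi_ij}, eta_{phi_ij}^2)` — a two-component Gaussian
  per tissue, indexed by the binary status.

### Identifiability and priors

All continuous parameters carry flat priors, truncated to break three
exact symmetries of the likelihood:

* swapping the two emission components together with complementing the
  binary status — broken by `mu0 < mu1` and `alpha0 < alpha1`;
* complementing the reference vector (`R -> 1 - R`, `gamma -> 1 - gamma`,
  `delta -> 1 - delta` leaves the law of `Z` unchanged) — broken by
  `delta > 0.5`;
* complementing a path row against the membership structure — broken by
  `beta < 0.5`, which also encodes that cancerization changes a minority
  of sites.

The exact truncation bounds are a package choice (the symmetry argument
fixes only the half-spaces); `model_parameters()` enforces them at
construction. Subtype labels remain exchangeable — nothing identifies
"subtype 1" — which is handled at evaluation time, not in the prior (see
*Label switching*).

## The sampler

One sweep updates, in a fixed systematic scan:
`R`, `Z`, `W`, `Lambda`, then the continuous parameters. The binary
blocks are two-point (or categorical) exact conditionals computed in log
space; the scan order is fixed for reproducibility. The full conditionals
were derived from the joint density:

* `P(r_j = 1 | .) / P(r_j = 0 | .)`: prior odds `gamma / (1 - gamma)`
  times `(delta / (1 - delta))^(n1 - n0)` where `n1`, `n0` count samples
  whose `z_ij` agrees with `r_j = 1` resp. `0`.
* `z_ij`: combines the retain/flip channel against `r_j`, the
  normal-emission density of `x_ij` under each component, and the
  tumor-emission density of `y_ij` through `phi = z XOR w`.
* `w_kj`: prior odds `beta / (1 - beta)` times the product over subtype
  members of the tumor-density ratio between flipped and unflipped
  status. An empty subtype's row reduces to its `Bernoulli(beta)` prior.
* `lambda_i`: categorical with weight `p_k` times the tumor likelihood of
  sample `i` under path `k`.
* Continuous: `gamma`, `delta`, `beta` are Beta draws (counts + 1) —
  `delta` and `beta` truncated by inverse-CDF sampling; `p` is a
  Dirichlet draw (counts + 1); emission means are Gaussian draws around
  the assigned-observation average, truncated to the orderings (each mean
  conditions on the current value of its partner); emission SDs follow
  the flat-prior conditional on the SD scale,
  `p(sigma) ∝ sigma^-c exp(-SS / (2 sigma^2))`, sampled exactly as
  `sigma^2 ~ InvGamma((c - 1) / 2, SS / 2)`.

The binary blocks run in compiled code (Rcpp); each block can be invoked
alone (`gibbs_update_R()` and friends), which is how the test suite
compares single-block frequencies against exhaustive enumeration of the
conditionals. The sufficient statistics for the continuous draws are
accumulated during the same compiled pass.

### Initialization

Chains start data-driven so a 200-sweep run suffices on well-separated
data: emission means at the 25th/75th percentiles of `X` (resp. `Y`),
SDs at the global SD, `gamma = 0.5`, `delta = 0.95`, `beta = 0.1`,
`Z` by thresholding `X` at the midpoint of the two initial means, `R` by
per-site majority of `Z`, `W` all zeros, memberships uniform at random.
The latent initialization is deliberately crude; the first sweeps move it
to the data's basin quickly, which is visible in the log-likelihood
trace.

### Estimates, chains and label switching

Defaults mirror the study protocol: 200 iterations, 10 chains (reduced in
the package's own experiments, see *Problem sizes*), estimates from the
final 30 iterations — posterior means for continuous parameters,
posterior frequency thresholded at 0.5 for `W`, and the per-sample modal
subtype for the labels (ties broken by the final sweep). `run_multichain()`
spawns per-chain seeds from the master seed, and reports the chain with
the highest mean retained log-likelihood. Latent estimates are never
pooled across chains: subtype indices are only coherent within a chain,
and within-chain switching is not corrected — on data with clear
structure a chain locks into one labeling almost immediately, and
`match_subtypes()` aligns the reported labeling to any reference by
minimal Hamming distance on `W` rows before accuracy is scored.

### Convergence

`gelman_rubin()` implements the split protocol used in the study: the
last 60 iterations of a trace are halved into two sequences of 30, and
`R-hat = sqrt(((w-1)/w * Wv + Bv/w) / Wv)` with `w = 30`, `Wv` the mean
within-half variance, `Bv = w * var(half means)`. Constant halves give
`Wv = 0` and `NaN` by convention. Values at or below 1.1 for `mu0`,
`mu1` and `gamma` are treated as adequate convergence.

## Model selection

`select_s()` fits every candidate `s` and tabulates
`AIC = 2k - 2L`, `BIC = k log(N) - 2L`. Two conventions are the
package's own:

* `L` is a **plug-in observed likelihood**: at the posterior-mean
  continuous parameters with `W` and the labels fixed at their estimates,
  `(r_j, z_ij)` are marginalized exactly per site (conditional on the
  membership, sites factorize). This is deterministic and cheap, and in
  the package's experiments puts the criterion minima at the generating
  subtype count.
* `k = 11 + (s - 1) + s·m` and `N = 2nm`: the 11 continuous parameters,
  the free proportions, and — crucially — the `s·m` path bits. Without
  counting `W`, neither criterion could penalize the growth of the
  signature structure with `s` and no interior minimum would exist.

`observed_log_likelihood()` without plug-in arguments performs the exact
full marginalization (enumerating memberships and, per site, the
reference/path/profile bits); it is exponential in `n` and guarded to
small instances — its role is to validate the factorized computation in
the tests, not production use.

## Synthetic-data generators

Three regimes, in decreasing fidelity to the model:

* `simulate_pure()` draws exactly from the hierarchy above. Generator
  defaults follow the study's generating values (`gamma = 0.5`,
  `delta = 0.99`, `beta = 0.2`, `mu = (-2.6, 1.5)`,
  `sigma = (1.3, 1.4)`, `alpha = (-2.9, 1.1)`, `eta = (1.1, 1.7)`), with
  uniform subtype proportions — the study states the multinomial but not
  `p`; uniform matches its roughly balanced subtype sizes.
* `simulate_contaminated()` emulates impure dissections: each observed
  pair is `P_A`, `P_B`, `P_N` parts major subtype, minor subtype and
  normal tissue. One latent normal profile per patient is shared by all
  components (the package's resolution of an ambiguity: a patient has one
  matched normal); the normal component's tumor-side vector is emitted
  through the tumor channel with `phi = z`. Component draws are stored on
  the result so the linear combination can be verified exactly. The
  truth label is the major subtype, which must be strictly major.
* `simulate_correlated()` breaks the i.i.d.-site and Gaussian
  assumptions: `R` and each row of `W` are split into `n_regions`
  contiguous regions (cut points drawn uniformly without replacement from
  the gaps — the simplest reading of random segmentation); `R` regions
  alternate rates `p_high`/`p_low` strictly (first region's rate chosen
  at random), `W` regions are constant with value `Bernoulli(p_w)`;
  emissions are location-scale t with `df` degrees of freedom (default
  3 — heavy-tailed enough to matter), the model's SD parameters serving
  as the scale.

What passing on these generators does **not** show: real 450K data have
probe-type effects, spatially varying coverage, missing values, batch
structure, tumor purity varying per patient rather than fixed mixture
weights, and subtype proportions far from uniform. The generators probe
model misspecification along two axes only (mixture contamination;
dependence + heavy tails).

## Numerical choices

* Probability floors: exact zeros propagate as `-Inf` (a degenerate
  parameter contradicted by a latent is reported as impossible, not an
  error), while positive densities are floored at `1e-300` before `log`
  so products cannot underflow to `NaN`.
* Truncated draws use inverse-CDF transforms (`qbeta`/`qnorm` on a
  uniform restricted to the truncated CDF range), never rejection, so
  each draw consumes exactly one uniform; degenerate truncation windows
  collapse to the nearest interior point.
* An emission component with no assigned observations keeps its previous
  mean (and with fewer than two, its previous SD) for that sweep.
* Modal-label ties across the retained window break to the final sweep's
  value.
* All randomness flows through R's RNG (also inside the compiled code,
  via R's `unif_rand`), so a single seed reproduces a run bit-for-bit.

## Problem sizes

The package's own experiments run at reduced scale, chosen once: the
acceptance script uses `n = 100` pairs, `m = 4000` sites, 3 chains of
200 sweeps, with 5 replicates of the 2-subtype experiment and 3 of the
3-subtype experiment; the test suite uses `m = 500`–`2000` and 1–2
chains. At these sizes the subtype signal (about `beta * m` differing
sites between any two paths) is still overwhelming, which is the regime
the study reports.

## Known limitations

* Per-site independence: nearby CpG sites are correlated in reality; the
  correlated generator quantifies robustness but the model itself ignores
  it.
* One subtype per tumor; purity is not modeled or estimated.
* Exchangeable subtype labels: results are reported per chain, and
  chain-level multimodality shows up as disagreeing chains rather than a
  mixed estimate — the best-chain rule picks one mode.
* `match_subtypes()` is exhaustive over permutations and supports up to
  8 subtypes.
* The exact full marginal likelihood is exponential in `n`; AIC/BIC rest
  on the plug-in convention described above.
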