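# baysub

Bayesian subtyping of cancers from paired tumor/normal DNA-methylation
profiles.

## The problem

Clustering tumors by their methylation profiles alone tends to recover
whatever dominates the variance — often confounders such as age or tissue
composition rather than disease mechanism. When a study collects a matched
normal sample alongside each tumor, the more informative signal is the
*change* from normal to tumor: which CpG sites flipped their methylation
status on the way to cancer. `baysub` clusters patients by these
aberrant-change patterns, simultaneously inferring each subtype's binary
methylation-change signature, for epigenomics researchers working with
paired methylation-array data (M-values, or β-values converted via
`M = log2(β / (1 − β))`).

## The model

For `n` matched pairs of M-value vectors over `m` CpG sites, with `s`
subtypes:

- `r_j ~ Bernoulli(γ)` — methylation status of a reference normal cell at
  site `j`;
- `z_ij = r_j ⊕ Bernoulli(1 − δ)` — patient `i`'s normal-tissue profile,
  a noisy copy of the reference (`δ` = probability of retaining the
  reference status; `⊕` is XOR);
- `w_kj ~ Bernoulli(β)` — subtype `k`'s modification path: the sites whose
  status flips during cancerization;
- `λ_i ~ Multinomial(1; p_1..p_s)` — patient `i`'s subtype membership
  (each tumor carries exactly one subtype);
- `φ_ij = z_ij ⊕ w_{k(i) j}` — the tumor profile;
- emissions: `x_ij ~ N(μ_{z_ij}, σ²_{z_ij})` for normal tissue and
  `y_ij ~ N(α_{φ_ij}, η²_{φ_ij})` for tumor tissue.

Inference is systematic-scan Gibbs sampling over the binary latents
(`R`, `Z`, `W`, `Λ`) and the continuous parameters (conjugate Beta /
Dirichlet / truncated-Gaussian / root-inverse-gamma conditionals under flat
priors, truncated for identifiability: `μ0 < μ1`, `α0 < α1`,
`δ ∈ (0.5, 1]`, `β ∈ [0, 0.5)`). Multiple independent chains are run and
the chain with the highest mean retained log-likelihood is reported;
convergence is monitored with a split Gelman–Rubin statistic. The number
of subtypes can be chosen by AIC/BIC over a candidate range.

## Worked example

```r
library(baysub)

## draw a synthetic cohort: 100 pairs, 2000 sites, 2 subtypes
sim <- simulate_pure(n = 100, m = 2000, s = 2, seed = 1)

## fit with 3 chains of 200 sweeps
fit <- run_multichain(sim$data, run_config(s = 2, n_chains = 3, seed = 2))
fit
#> Paired-methylation subtype fit: s = 2, 3 chains (best: #2)
#>   subtype sizes: 43 57
#>   R-hat (mu0, mu1, gamma): 0.9861 1.078 0.9911
#> Paired-methylation mixture parameters (2 subtypes)
#>   gamma=0.4804 delta=0.99 beta=0.2125
#>   p = 0.4306 0.5694
#>   normal: mu=(-2.598, 1.501) sigma=(1.299, 1.401)
#>   tumor:  alpha=(-2.897, 1.092) eta=(1.102, 1.692)

evaluate_fit(fit, sim$true_labels, sim$state$W)
#> $ari
#> [1] 1
#> $nmi
#> [1] 1
#> $ae
#> [1] 100
#> $as
#> [1] 100
```

The fit recovers the generating parameters (compare `gamma = 0.4804` with
the generating 0.5, `mu0 = -2.598` with −2.6), clusters every sample into
its true subtype (`ari = nmi = 1`) and reconstructs every entry of the
modification matrix (`ae = as = 100%`). `select_s(sim$data, 2:6, ...)`
returns AIC/BIC per candidate subtype count, and
`plot_signature_heatmap(sim$data, fit$estimate_W, fit$estimate_labels)`
draws the differentially methylated sites with samples ordered by subtype.

A command-line front end over the same functions ships at
`inst/cli/baysub.R`:

```sh
Rscript inst/cli/baysub.R simulate --n 100 --m 2000 --s 2 --seed 1 --out sim/
Rscript inst/cli/baysub.R fit --x sim/sim_normal.tsv --y sim/sim_tumor.tsv \
    --s 2 --chains 3 --seed 2 --out fit/
Rscript inst/cli/baysub.R evaluate --fit fit/ --truth sim/sim_truth.tsv \
    --w sim/sim_W.tsv --out eval/
```

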