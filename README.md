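# hmmc — hidden Markov model clustering of tumour copy-number profiles

`hmmc` identifies tumour subtypes from segmented DNA copy-number data
(array-CGH / SNP arrays). Samples are clustered with a **mixture of hidden
Markov models**: each candidate group g is scored by the Viterbi
log-likelihood Δ<sub>g</sub> of a shared six-state copy-number chain
(states 0.1, 1.5, 2, 3, 4, 5; exchangeable transitions with stay
probability p<sub>same</sub>; lognormal emissions with median at the state
value and log-scale sd σ, both estimated from the data). The clustering
maximizes Σ<sub>g</sub> Δ<sub>g</sub> by a stochastic two-sample
relabelling search seeded with NMF, stopping after m = n² consecutive
non-improving proposals. The number of groups minimizes

    BIC = −2 Σ_g Δ_g + T·G·ln(n)

with T segments, G groups, n samples. Unlike feature-based clustering
(k-means, NMF), the hidden chain models the spatial correlation of
neighbouring genomic segments.

The package also provides: union-grid summarization of per-sample SEG
tables into a common sample × segment matrix, a random-forest filter for
normal-tissue-contaminated samples, leave-10%-out stability
cross-validation, and a calibrated simulator of two-group aCGH cohorts
with AR(1) noise for benchmarking HMMC against plain NMF clustering.

## Worked example

```r
library(hmmc)

# a separable synthetic cohort: 2 groups of 6 samples, 60 segments,
# 15-segment amplified block in group 2
d <- generate_dataset(sim_config(n_per_group = 6, T_segments = 60,
                                 amp_segments = 15, s = 0.5,
                                 noise_amp_count = 0, rho = 0, seed = 42))
d$matrix
#> Copy-number matrix: 12 samples x 60 segments on 1 chromosome(s)
#> Value range: [0.5035, 5.615]

res <- run_pipeline(d$matrix, G = 1:4, seed = 1)
res$scores
#>   G total_loglik   k      bic
#> 1 1    -786.5978  60 1722.290
#> 2 2    -701.9003 120 1701.989
#> 3 3    -754.8310 180 1956.945
#> 4 4    -799.9301 240 2196.238
res$best_G
#> [1] 2
res$fit
#> HMMC fit: G = 2 groups; sizes: 6, 6
#>   total log-likelihood: -701.90028  ( 0 accepted moves in 144 proposals )
error_rate(d$truth, res$fit$assignment)
#> [1] 0
```

The BIC table reads as in a model-selection scan: the two-group model
gains ~85 log-likelihood units over one group — more than the penalty
increment T·ln(n) ≈ 149 is lost again at G = 3 — so BIC bottoms out at
G = 2, and the recovered partition matches the planted truth exactly (the
NMF seed was already optimal here, so the search accepted no moves and
stopped after 144 = 12² proposals).

`res$params` shows the empirical HMM parameters used
(σ = 0.30, p_same = 0.40 for this dataset).

## Command line

A thin wrapper over the same functions is installed at
`inst/cli/hmmc.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/hmmc.R", package="hmmc"))')" \
    cluster --matrix matrix.tsv --groups 3 --seed 1 --out run
# subcommands: cluster, select-g, simulate, stability, qc, summarize
```

`summarize` converts a SEG-like table (columns
`sample  chromosome  start  end  mean`) into the matrix TSV used by the
other subcommands; each run writes an assignment TSV and a JSON summary
carrying the seed, estimated parameters, and the improvement trace.

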