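# netlag

Resting-state fMRI network connectivity analysis in R: group spatial ICA
with back-reconstruction, voxelwise intra-network group statistics with
permutation cluster-level familywise-error control, and inter-network
coupling through the **constrained maximal lagged correlation** — the
largest-magnitude Pearson correlation between two network time courses over
circularly shifted integer lags.

The package is aimed at studies that compare resting-state functional
connectivity across small clinical groups — the motivating design is a
Parkinson-disease genetics cohort with 22 healthy controls, 12 heterozygous
and 8 homozygous carriers of recessive parkinsonism mutations — and at
anyone who wants a fully seeded, end-to-end testable implementation of this
analysis style. Because such cohorts are rare and not publicly deposited,
`netlag` ships a synthetic BOLD cohort generator with known ground truth
(network geometry, group-specific amplitude deficits, lagged inter-network
couplings, matched phenotype covariates), so every stage of the pipeline can
be validated against what was injected.

## The statistics at the core

For detrended network time courses `x_t`, `y_t` (t = 1..T) the circular
lagged correlation at lag `l` is

    r(l) = cor(x_t, y_{(t+l) mod T}),

and the constrained maximal lagged correlation scans all integer lags
`|l| <= 12`, keeping the lag with the best p value — for fixed T this is the
lag maximizing `|r|` (ties: smaller `|l|`, then the negative lag). Each
subject's selected `r` is variance-stabilized with Fisher's transform
`z = atanh(r)`; per network pair the `z` values enter a between-subject
ANCOVA on group (HC / HET / HOM) with years of education and total
grey-matter volume as nuisance covariates, Bonferroni-corrected over the
pairs tested (10 for 5 networks). Brain–behaviour association uses the
partial correlation of `z` with a cognitive score (Corsi spatial span),
residualized on grey-matter volume.

Intra-network connectivity is analysed voxelwise on the subject-specific
component maps (ordinary least squares per voxel), with cluster-level
familywise-error control by Freedman–Lane label permutation of the maximal
cluster size at 26-connectivity — a permutation replacement for parametric
random-field cluster correction.

Networks are obtained by temporal-concatenation group spatial ICA
(subject-level PCA, group PCA, fixed-point ICA with tanh contrast), maps are
z-scored, and the five networks of interest (DMN, SN, ExN, rFP, lFP) are
identified by exact optimal bipartite matching against template maps.

## Worked example

Simulate the default cohort's network time courses and run the
inter-network stage:

```r
library(netlag)

maps  <- make_network_maps(voxel_grid(), seed = 42)
truth <- ground_truth(maps)     # per-group couplings, lags, amplitudes
round(truth$coupling$HOM, 2)    # homozygous group: SN-rFP raised to 0.60
#>       DMN    SN   ExN   rFP   lFP
#> DMN  0.00 -0.15 -0.30 -0.15 -0.15
#> SN  -0.15  0.00  0.10  0.60  0.10
#> ExN -0.30  0.10  0.00  0.10  0.15
#> rFP -0.15  0.60  0.10  0.00  0.10
#> lFP -0.15  0.10  0.15  0.10  0.00

part <- netlag:::simulate_participants(cohort_config(seed = 42))
tcs <- lapply(seq_len(nrow(part)), function(i) {
  g <- part$group[i]
  simulate_network_timecourses(216, 2.08, truth$coupling[[g]],
                               truth$coupling_lags[[g]],
                               seed = derive_seed(42, part$participant_id[i]))
})
names(tcs) <- part$participant_id

res <- inter_network_analysis(tcs, part)
res$contrast_table[res$contrast_table$pair == "SN_rFP", ]
#>  contrast   estimate         t df          p   pair
#>    HET-HC 0.02230061 0.4015168 37 0.69034944 SN_rFP
#>    HOM-HC 0.25588285 3.1237162 37 0.00346238 SN_rFP
#>   HOM-HET 0.23358225 2.7018067 37 0.01034672 SN_rFP
```

The homozygous group's injected SN–rFP coupling increase (+0.2 in r) shows
up as a covariate-adjusted Fisher-z difference of 0.26 versus controls
(t(37) = 3.12, p = 0.003), while HET and HC do not differ — the
group-specific pattern the generator encodes. The omnibus 2-df group ANOVA
for this pair in this single draw is F(2,37) = 4.96 (raw p = 0.012,
Bonferroni x10 p = 0.12); detection rates across seeds are what
`scripts/acceptance.R` quantifies.

The full image-level pipeline (simulate → preprocess → group ICA → intra →
inter → report) runs from one seeded config:

```r
res <- run_all(run_config(seed = 7), "rundir")
```

writing NIfTI maps, TSV tables, a markdown report and an md5 manifest that
is byte-identical across reruns of the same config.

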