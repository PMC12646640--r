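# shallowcnv

Copy-number variant (CNV) detection from shallow whole-genome sequencing
(sWGS, ~0.1–5× coverage), for analysts working with low-input material such
as NIPT or liquid-biopsy samples where high-depth sequencing is not an
option.

At these depths per-base read depth is strongly zero-inflated — most
positions have no reads — so Poisson/negative-binomial callers misjudge
both the zero mass and the variance, and fixed-bin callers cannot serve
small and large CNVs with one bin size. `shallowcnv` models per-base depth
as zero-inflated Poisson,

    P(X = 0) = π + (1 − π) e^(−λ),   P(X = x) = (1 − π) e^(−λ) λ^x / x!,

smooths it with a segment sliding window (mean of the n = 3000 bases
starting at each position), whose mean is approximately
N((1 − π)λ, (1 − π)λ(1 + πλ)/n) by the CLT, and monitors the log2 ratio
R_t = log2(x̄_t / p̄_t) against a panel-of-normals baseline with a
two-sided CUSUM control chart:

    C⁺_t = max(0, R_t − K + C⁺_{t−1}),   C⁻_t = min(0, R_t + K + C⁻_{t−1}),

with reference value K = 0.3 and control limits UCL = n·log2(3/2),
LCL = n·log2(1/2). Chart alarms delimit candidate CNV regions; each region
is then re-scored with a single *dynamic* window sized to the region,
logR = log2(Σx_i / Σp_i), and classified as gain (logR > 0.3) or loss
(logR < −0.3). A ZIP coverage simulator with implanted CNVs and a
benchmark-style evaluator (50% reciprocal-overlap matching,
sensitivity/precision/F1 with size strata) are included, so the whole
pipeline is testable without external data.

## Worked example

Simulate a panel of 20 controls and a test sample carrying one 50 kb
single-copy gain on a 2 Mb chromosome at 1× coverage, then call CNVs:

```r
library(shallowcnv)

params   <- coverage_params(1, pi = 0.9)         # mean depth 1x, 90% zeros
baseline <- simulate_baseline(20, 2e6, params, seed = 700, n = 3000)

truth <- sim_truth(2e6, params,
                   cnvs = data.frame(start = 8e5, end = 8.5e5,
                                     copy_ratio = 1.5),
                   seed = 702)
scan <- call_cnvs(simulate_track(truth), baseline, caller_config())
scan
#> <cnv_scan> 1 call(s) on 1 chromosome(s)
#>  chrom  start    end type      logR  size
#>   chr1 798216 848720 gain 0.5689908 50504

match_calls(scan, truth)
#> <cnv_eval> TP=1 FP=0 FN=0  sens=1.000 prec=1.000 F1=1.000
#>  stratum TP FP FN sensitivity precision f1
#>     <10k  0  0  0           0         0  0
#>   10k-1M  1  0  0           1         1  1
#>      >1M  0  0  0           0         0  0
```

The single call recovers the implant: boundaries within ~2 kb of the true
breakpoints (798,216–848,720 vs 800,000–850,000), type `gain`, and a
region logR of 0.569, close to the log2(1.5) ≈ 0.585 expected for a
single-copy gain (the small shortfall comes from the normal flanks inside
the estimated boundaries). `summary(scan)` reports the candidate-region
partition, and `plot(scan)` (with `keep_chart = TRUE` in the config) draws
the logR series and the CUSUM chart with its control limits.

A command-line front end is installed at `exec/shallowcnv` with
`simulate`, `baseline`, `call` and `evaluate` subcommands; every output
file header records the tool version and the fully resolved configuration.

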