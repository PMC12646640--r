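---
title: "Detecting copy-number variants in shallow WGS with a CUSUM control chart"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting copy-number variants in shallow WGS with a CUSUM control chart}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(shallowcnv)
```

## The problem

Shallow whole-genome sequencing (sWGS, roughly 0.1–5× mean coverage) is the
workhorse of non-invasive prenatal testing, liquid biopsy and other
low-input assays. At these depths the per-base read-depth signal is strongly
*zero-inflated*: a large fraction of positions receives no reads at all, and
those zeros mix two very different things — genuinely deleted sequence and
sequence that simply was not sampled. Treating depth as Poisson or negative
binomial underestimates both the zero mass and the variance, so random
coverage blips get called as gains and true deletions drown in
zero-coverage noise. A second, independent problem is window size: callers
that tile the genome with fixed bins must choose one scale, and any single
choice either dilutes small events or shreds large ones.

`shallowcnv` addresses both problems with a three-stage design:

1. **Smooth**: model per-base depth as zero-inflated Poisson (ZIP) and
   average it over a segment sliding window so the smoothed statistic is
   approximately normal;
2. **Monitor**: run a two-sided CUSUM control chart on the log2 ratio of
   smoothed sample depth to a panel-of-normals baseline, partitioning each
   chromosome into candidate and non-candidate CNV regions;
3. **Call**: re-score every candidate region with a single *dynamic* window
   sized to the region itself and classify it by a fixed logR threshold.

## The coverage model and the smoothing step

Per-base depth is modelled as
$$P(X = x) = \begin{cases}\pi + (1-\pi)e^{-\lambda}, & x = 0\\
(1-\pi)e^{-\lambda}\lambda^x/x!, & x > 0,\end{cases}$$
with structural-zero fraction $\pi$ and Poisson rate $\lambda$
(`zip_pmf()`). A zero-inflated negative binomial would also fit, but its
extra dispersion parameter is unstable at these depths and materially more
expensive to work with, so the ZIP form is used throughout.

The segment sliding window assigns to position $t$ the mean
$\bar{x}_t = \frac{1}{n}\sum_{i=t}^{t+n-1} x_i$ of the $n$ bases starting
there (`segment_means()`, computed with rolling sums in $O(L)$). For
independent ZIP draws the window mean has mean $(1-\pi)\lambda$ and
variance $(1-\pi)\lambda(1+\pi\lambda)/n$, and by the central limit theorem
its distribution is approximately normal once $n$ is in the thousands
(`zip_segment_moments()`; the test suite checks this with a
Kolmogorov–Smirnov test on disjoint window means of a simulated null
track). The default $n = 3000$ bp keeps the normal approximation sound even
at 0.1× coverage; `n` is configurable but values much below 3000 undermine
the normality the control chart assumes. Monitoring points default to every
base (`stride = 1`) because candidate-region boundaries are defined at base
resolution; larger strides trade boundary resolution for speed.

## The control chart

The monitored target is the log2 copy ratio
$R_t = \log_2(\bar{x}_t/\bar{p}_t)$, where $\bar{p}_t$ is the smoothed
expected depth from the baseline (`log_ratio()`). A pseudocount
$\varepsilon = 1/n$ in numerator and denominator keeps $R_t$ finite where a
smoothed value is zero without noticeably moving typical values; positions
where the baseline expectation itself is zero are masked instead.

The two-sided tabular CUSUM (`cusum_series()`) is
$$C_t^+ = \max(0,\, R_t - K + C_{t-1}^+), \qquad
  C_t^- = \min(0,\, R_t + K + C_{t-1}^-),$$
both started at zero. Gains and losses accumulate independently, so the two
statistics never interfere. The reference value $K$ is the per-step
allowance: deviations within $\pm K$ never accumulate. The default
$K = 0.3$ matches the logR alert threshold most depth-based callers use.
CUSUM charts are asymptotically optimal for exactly this regime — a weak
but *persistent* mean shift in approximately normal observations — which is
what a CNV looks like after smoothing.

Control limits are $UCL = n\log_2 a$ and $LCL = n\log_2 b$
(`control_limits()`), defaults $a = 3/2$, $b = 1/2$: the cumulative
deviation a single-copy gain or loss sustained over one smoothing window
would produce. With the defaults, a sustained single-copy-gain shift
($R = \log_2 1.5$) first crosses the UCL after
$\lceil UCL/(\log_2 1.5 - K)\rceil = 6159$ monitoring points — about 6 kb
at base resolution, which is the method's intrinsic detection scale for
single-copy events.

### Alarm boundaries

The chart marks *when* the statistic crosses a limit; turning that into a
region requires boundary estimates (`extract_candidates()`). The start of
an alarm is the last monitoring point at which the triggering statistic was
zero before the crossing — the standard CUSUM changepoint estimate. For the
end of the alarm two rules are provided:

* `end_rule = "peak"` (default): the position of the statistic's extreme
  within the excursion. Once the shifted stretch ends, the statistic drifts
  back toward zero at rate $K$ per step, so the extreme marks where the
  shift stopped.
* `end_rule = "zero"`: the first return of the statistic to zero. This is
  the naive reading of the excursion but overshoots the true end by roughly
  $\text{peak}/K$ positions — for a 200 kb single-copy loss the overshoot
  is several hundred kb, which destroys both the 50% reciprocal overlap
  with the true event and the region-level logR (the region is diluted
  toward zero). It is retained for diagnostics only.

Alarms of the same direction closer than `merge_gap` (default $n$: gaps
shorter than one smoothing window are artifacts of the smoother) are
merged; alarms spanning fewer than `min_span = 1000` bp are discarded as
transient alerts, in line with the conventional minimum CNV size. In the
rare case that a gain and a loss alarm overlap on oscillating data, both
are trimmed at the midpoint of the overlap and final arbitration is left to
the region-level classification. The complement of the surviving alarms is
emitted as `none` regions so the partition tiles the chromosome.

## Dynamic-window calling

Each candidate region $[s, e)$ is scored with one window sized to the
region: $\mathrm{logR} = \log_2(\sum_{i=s}^{e} x_i / \sum_{i=s}^{e} p_i)$
over unmasked positions (`region_logr()`), then classified by the fixed
threshold $\pm 0.3$ with strict inequalities (`classify_logr()`): gain
above $+0.3$, loss below $-0.3$, otherwise no CNV. Because the window
matches the region, a 30 kb event is not averaged away inside a 100 kb bin
(the package keeps a deliberately naive fixed-bin caller,
`fixed_window_calls()`, as an internal point of comparison; the test suite
exercises the scenario where the fixed window misses an implant the
dynamic window recovers). Non-candidate regions are scored too but are
reported only under the `all_regions` diagnostic flag, since calling is
framed on candidates; calls shorter than `min_cnv_size = 1000` bp are
dropped.

## The reference baseline

The expected depth $p_i$ comes from a panel of control samples
(`build_baseline()`): each control is corrected, normalized to unit mean,
and pooled per position. Two pooling statistics are offered. The
cross-control **mean** is the default: at shallow coverage the majority of
per-base depths are zero, so the per-position **median** of a small panel
collapses to zero almost everywhere and leaves no usable baseline; the
median remains available (`method = "median"`) for deeper data where its
robustness to outlier controls is worth having. Positions with zero depth
in *every* control are masked — with a realistically sized panel (the
simulated cohorts use 50 controls) this flags a few percent of positions at
0.1× and essentially none at higher depths. After pooling, $p$ is rescaled
to unit mean over unmasked positions; this removes the upward bias that
conditioning on "not all controls zero" would otherwise leave in the
baseline (a few percent at 0.1×, which would otherwise shift every $R_t$
by a constant).

Masked positions are excluded from window means, and a monitoring point is
masked when more than half its window is masked; masked monitoring points
carry the CUSUM statistics forward unchanged rather than resetting them.

## GC correction and normalization

Both procedures are this package's own, deliberately simple choices, and
both can be switched off. GC correction (`gc_correct()`) divides each
position's depth by the median depth of all bins sharing its GC decile and
rescales to preserve the overall mean — a coarse median-ratio correction
adequate for the bin-level bias seen in practice. Normalization
(`normalize_depth()`) divides by the mean depth over unmasked positions so
samples at different total coverage are comparable with the unit-mean
baseline.

## The simulator

`simulate_track()` draws per-base depth under exactly the model the method
assumes: structural zeros with probability $\pi$, otherwise Poisson with
rate $\lambda r_i$, where $r_i$ is the copy ratio of the covering implant
(1 elsewhere). Two modelling choices are worth stating. First, $\pi$ is
*not* scaled inside implants — a deletion reduces the sampling rate, not
the fraction of unsampleable genome; this is the simplest faithful
extension of the base model to CNVs. Second, coverage presets map mean
depth to the rate via $\lambda = \text{coverage}/(1-\pi)$
(`coverage_params()`), a convention of this package. All randomness flows
from one explicit seed.

Because the simulator emits exactly the assumed model, passing tests show
that the chart and caller do what the theory says under ZIP coverage with
clean breakpoints; they do not show robustness to mappability structure,
GC waves, replication timing, batch effects between sample and panel, or
fuzzy breakpoints in real data. `make_alignment_fixture()` writes small
indexed BAMs whose pileup matches the ZIP model in expectation (35 bp
reads, mirroring typical NIPT read lengths); it exists to integration-test
the BAM reader, not to emulate a sequencer.

## Evaluation protocol

`match_calls()` scores a call set against a truth set with the structural
variant benchmarking convention: a call matches a truth interval when they
share at least 50% *reciprocal* overlap (the one-sided reading — at least
50% of the truth interval — is available via `reciprocal = FALSE`, since
"overlapped by at least 50%" is ambiguous between the two) and types
agree. Matching is one-to-one and greedy by descending overlap; on
non-overlapping call and truth sets, the geometry of the 50% reciprocal
rule makes double eligibility rare enough that greedy matching attains the
exhaustive optimum (property-tested on small random instances).
Sensitivity, precision and F1 follow, with per-size strata (default
`<10k`, `10k-1M`, `>1M`); ratios with a zero denominator are reported as 0
and flagged rather than as NaN.

## Problem sizes and numerical choices

The test suite and the acceptance script rerun the whole pipeline at
reduced but representative scale: 5 Mb chromosomes (large enough for
implants up to 200 kb plus wide flanks), implants of 10–200 kb at copy
ratios 1.5 and 0.5, coverages 0.1× and 3×, panels of 50 controls as in the
simulated-cohort design, and matched null tracks for false-positive
accounting. Rolling sums are accumulated in extended precision; the CUSUM
recursion is implemented in C++ (with a literal R loop kept in the tests
as an independent oracle) because per-base monitoring of megabase
chromosomes makes an interpreted recursion the only slow step. Ties in the
GC decile assignment collapse gracefully when GC is uniform; an all-zero
track is returned unchanged from GC correction with a warning rather than
an error, because a legitimately empty chromosome should not abort a
whole-genome run.

## Known limitations

* Read-depth evidence alone cannot resolve balanced events (inversions,
  translocations) or distinguish a homozygous from a heterozygous loss
  beyond the logR magnitude; no integer copy-number estimation is
  attempted.
* Breakpoint precision is limited to the monitoring resolution and the
  $\approx n/2$ ramp of the smoothing window at each boundary.
* The baseline must be representative: the package treats sex chromosomes
  as diploid and applies no mappability correction, so panels should be
  matched on sex and platform.
* Events shorter than the intrinsic detection scale
  ($\approx$ 6 kb for single-copy gains at default settings) are not
  reliably detectable, even though the minimum reported size is 1 kb.
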