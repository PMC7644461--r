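---
title: "Methods: correlation networks of the microbial food web"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: correlation networks of the microbial food web}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(planktonnet)
```

This vignette documents the statistical machinery of `planktonnet`: the
models and rules each stage implements, the assumptions they carry, the
tunable parameters and their defaults, what the synthetic-data generator
does and does not emulate, and the numerical choices made where the
procedure leaves room.

## 1. Bloom segmentation from fluorescence growth rates

Phytoplankton biomass is proxied by the daily mean of chlorophyll-*a*
fluorescence, $F_t$. The daily net growth rate is the log-ratio

$$ r_t = \ln(F_t / F_{t-1}), $$

the standard net growth estimator for phytoplankton: summing $r_t$ over a
window equals the net log-change over that window, which is what makes the
"positive sum over at least five days" rule equivalent to a net biomass
increase. A bloom

* **starts** on the first day of a run of at least `min_pos_start = 2`
  consecutive positive rates from which some window of at least
  `min_window = 5` consecutive days has a positive rate sum, and
* **ends** on the day before the first subsequent run of
  `end_neg_run = 5` consecutive negative rates.

Zero rates count as neither positive nor negative (a strict reading of
"positive"/"negative"). A bloom interrupted by the campaign end is closed
at the last day and flagged in the provenance log. Consecutive blooms
separated by at most `max_gap_weeks = 2` weeks (7 days per week) of
non-bloom are pooled into a single analysis period.

One point the rules leave open is whether the five-day positivity window
must start at the bloom's first day or merely overlap the bloom. We anchor
it at the start day, and accept *any* window length of at least five days.
A consequence worth knowing: a brief positive blip that lies on a rising
trajectory towards a later bloom can qualify (its long-window sum is
positive), opening the bloom early. On noisy series this shows up as small
spurious bloom fragments; the pipeline's `min_samples = 4` filter keeps
them out of the network analysis.

## 2. Permutation Spearman networks

Within each analysis period, every unordered taxon pair of the weekly
abundance matrix is tested with Spearman's rank correlation (Pearson on
mid-ranks, so ties are averaged) and a two-sided Monte-Carlo permutation
test: one series is shuffled `n_permutations = 9999` times and

$$ p = \frac{1 + \#\{b : |\rho_b| \ge |\rho_{obs}|\}}{B + 1}. $$

The add-one estimator keeps $p$ strictly positive and valid under
exchangeability. Edges with $p < \alpha$ (default $\alpha = 0.05$) are
kept; three networks are reported per period — negative-only,
positive-only, and their disjoint union — and node sets contain only
non-isolated taxa, which is the accounting under which the descriptor
table's N differs across sign modes.

Deliberate choices:

* **No multiple-testing correction.** Thousands of pairs are tested at raw
  $p < 0.05$, so roughly $0.05\binom{K}{2}$ false edges are expected per
  period; with ~110 taxa that is ~300 edges even under complete
  independence. This is the method as practised — single-edge identities
  should be read with that in mind, which is exactly why the null-model
  stage (Section 3) works at the level of label-pair counts rather than
  single edges.
* **Per-pair seeding.** Each pair's permutation stream is seeded by a
  stable hash (splitmix64) of the master seed and the ordered taxon-id
  pair, so any edge's p-value is reproducible regardless of which other
  taxa are present or in what order pairs are evaluated. The permutation
  kernel is compiled (Rcpp) and does not consume R's RNG stream.
* **Constant columns** (taxa absent in a period) carry no rank information
  and are dropped with a log entry rather than raising an error.
* **Autocorrelation** of the weekly series is reported (`acf` at lags 1–5
  against the $\pm 1.96/\sqrt{n}$ band) as a diagnostic only; no series is
  altered, since the downstream permutation test conditions on the
  observed margins.
* **Reporting rounding**: mean degree $2E/N$ to 2 decimals, percent
  negative to the nearest integer. For three of the nine published-style
  descriptor rows a 2E/N recomputation differs from the printed mean
  degree by 0.01–0.02 (7.29 vs 7.30, 3.49 vs 3.50, 6.06 vs 6.04); the
  package reports $2E/N$ and documents the discrepancy rather than guess
  the original rounding path.

## 3. Erdős–Rényi null model for label-pair edge counts

To compare how edges distribute between functional groups (or ESD
classes), each empirical network is matched by `n_random = 999` random
graphs drawn from $G(n, m)$ — uniform over simple graphs with the same
node set and edge count. For every unordered label pair (self-pairs
included) the empirical edge count is compared against the 2.5th and
97.5th percentiles of the null counts, taken as order statistics at ranks
$\lceil 0.025R \rceil$ and $\lceil 0.975R \rceil$ (ranks 25 and 975 for
$R = 999$). Counts strictly below the lower threshold are **rare**,
strictly above the upper **dominant**; ties with the threshold are
conservatively neutral. Because counts are discrete, the realised two-tail
rate under a true ER world is a little below the nominal 5% — in our
checks it sits around 3–4.5% — which is the conservative side to err on.

Choices and limitations:

* $G(n,m)$ rather than $G(n,p)$, because the procedure fixes both node and
  edge counts exactly.
* Labels ride on node identity; the **degree sequence is not preserved**.
  A hub-dominated empirical network will deviate from pure ER for that
  reason alone; verdicts describe deviation from uniform edge placement,
  not from a degree-matched world. A configuration-model null is out of
  scope.
* The random graphs are built on the empirical network's non-isolated
  nodes (consistent with the descriptor table's N). Whether isolated taxa
  should be retained is a judgement call; `classify_pairs(nodes = ...)`
  accepts the full taxon set for the alternative.
* The summary network draws one node per label and an edge per non-neutral
  (pair, sign mode): solid for "more correlations than random"
  (dominant), dotted for "fewer" (rare), with both-mode deviations kept as
  parallel records.

## 4. Size classes, biovolume, dominant taxa

Within each multi-taxon group, taxa ordered by mean ESD are segmented with
PELT (pruned exact dynamic programming) under a Gaussian change-in-mean
cost: segment cost is the residual sum of squares around the segment mean
scaled by a pooled variance estimate (half the variance of first
differences, robust to mean shifts), and each changepoint pays a penalty,
default $2\log n$. The implementation prunes candidates only once the
pruning time itself becomes a legal last-changepoint (the minimum segment
length delays this by `min_segment = 2` steps); with that correction the
pruned search provably returns the exhaustive optimal partition, and the
test suite checks equality against an independent unpruned $O(n^2)$
dynamic program on hundreds of random series.

Class boundaries are reported as the midpoint between the ESDs flanking
each changepoint, rounded to integers for labels of the form `<6`, `6-12`,
`>25`; class membership follows the exact segmentation, not the rounded
boundary. Whether to segment raw or log ESDs is not dictated by anything
in the data model; the default is raw ESDs.

Biovolume is the sphere volume $(\pi/6)\,\mathrm{ESD}^3$; mean biovolume
per mL (biovolume × mean abundance) ranks taxa within the phytoplankton,
naked-ciliate and tintinnid groups, and the minimal prefix covering
`share_threshold = 0.90` of the group's biovolume — inclusive of ties at
the cut — defines the dominant taxa. Virus, bacteria and HF are pooled
groups and pass through whole. Non-spherical shape corrections (e.g.
tintinnid loricae) are deliberately not modelled.

## 5. Inter-annual comparison

Two campaigns are paired by ISO-8601 week number (so 2015-01-08 and
2016-01-12 pair as week 2), which with `truncate_to_common = TRUE` drops a
longer campaign's unmatched trailing weeks — reproducing the situation
where a 23-week campaign is cut to the 19 weeks shared with the other
year. Comparisons use weekly paired values (not period means): the paired
Wilcoxon signed-rank test discards zero differences (Wilcoxon's original
treatment, not Pratt's), mid-ranks the absolute differences, and takes
$W = \min(W^+, W^-)$. The two-sided p-value is exact for up to 25 non-zero
pairs via the shift-convolution of the observed (possibly tied) mid-ranks
— so ties are handled exactly, which `stats::wilcox.test` declines to do —
and switches to the normal approximation with continuity and tie
correction above. No correction across the per-group tests is applied;
individual p-values are reported.

## 6. What the synthetic generator does and does not emulate

`generate_taxa()` draws a community with the canonical partition (1 virus,
2 bacteria, 46 phytoplankton, 4 HF, 28 naked ciliates, 29 tintinnids) and
per-group ESDs uniform within plausible ranges; ids are assigned in guild
order so network node numbering groups organisms by guild.
`generate_fluorescence()` plants bloom windows as linear ramps to
`base_level × (1 + bloom_amplitude)` with a 5-day decay back to baseline,
multiplicative lognormal noise, and an optional baseline log-drift.
`generate_abundances()` plants rank correlations through a Gaussian copula:
a latent multivariate normal with the planted correlations (identity
elsewhere) is pushed through monotone lognormal quantile transforms with
per-group scales (10^7 viruses, 10^6 bacteria, 10^3 phytoplankton, 5·10^2
HF, 10 ciliates per mL; log-sd 1). Monotonicity means the planted latent
correlations *are* the Spearman targets, making planted truth directly
comparable to inferred edges.

Campaign-level defaults (`simulate_campaign()`) are: daily noise
`noise_sd = 0.02` — daily means of a high-frequency sensor average out
most measurement noise — and `baseline_drift = -0.02` per day outside
blooms, encoding the net biomass loss that defines non-bloom conditions.
The drift matters: around a *flat* noisy baseline, five-day rate sums
telescope to a difference of two noise terms and are positive half the
time, so the bloom rules fire spuriously; under net negative drift the
non-bloom periods stay quiet, which is also the biologically coherent
reading of "non-bloom".

Not emulated, deliberately: mechanistic dynamics (no NPZ model, no
predator–prey ODEs), seasonal succession, temporal autocorrelation of
abundances (weeks are exchangeable draws), sampling error of microscopy
counts (a Poisson layer is omitted since abundances are per-mL estimates),
and weekly subsampling of a daily latent process (abundances are generated
directly at the weekly grain, the analysis grain). Passing tests therefore
certify the statistical machinery — error rates, recovery of planted rank
structure, exactness of combinatorial procedures — not robustness to
autocorrelated, zero-inflated or compositional real-world data.

Numerical details of the generator: if a planted correlation set is not
positive definite, the matrix is repaired by eigenvalue clipping (floor
$10^{-8}$) followed by rescaling to unit diagonal, with a warning; if the
repair moves any planted entry by more than `repair_tol = 0.1` the
generator aborts and lists the offending pairs rather than silently
planting something else.

## 7. Determinism and problem sizes

Every stochastic stage is a pure function of (configuration, seed):
generators save and restore R's RNG state; the permutation kernel uses its
own counter-based RNG; `run_pipeline()` derives per-stage child seeds from
the master seed. Two pipeline runs with one seed produce byte-identical
output trees, which the test suite verifies by hashing.

The test suite exercises: permutation-test size with 1000 null
simulations at $B = 999$ and $n = 19$ (the weekly sample size of a
19-week campaign); planted-edge recovery with 10 pairs at $|\rho^*| = 0.9$
over 25 seeds; PELT-versus-oracle equality on 200 random series of length
up to 20 at several penalties; ER verdict rates over 60 simulated
networks of 40 nodes and 150 edges with 999 null replicates; Wilcoxon
exactness against full $2^n$ enumeration up to $n = 12$; and two full
pipeline runs on a 22-taxon, 25-week campaign for the byte-identity check.
The acceptance script scales the community back up to the full 110 taxa
with $B = 9999$ and 999 random networks.

## 8. Known limitations

* Correlation is not interaction: edges mix direct effects, indirect
  (shared-predator, shared-forcing) effects and artefacts of the raw-p
  threshold; the package quantifies structure, interpretation stays with
  the analyst.
* The ER null ignores degree heterogeneity (Section 3).
* Time order is ignored within periods (no lagged correlations), and ACF
  results are advisory only.
* The exact Wilcoxon path assumes the discarded-zeros convention;
  switching to Pratt's treatment would change small-sample p-values.
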