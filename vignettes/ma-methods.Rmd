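---
title: "Methods: MA-experiment statistics in marates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: MA-experiment statistics in marates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(marates)
```

## The experimental model

A mutation-accumulation (MA) experiment propagates many independent lines
through repeated single-cell bottlenecks (here, single-colony streaking
every few days). Because each transfer passes the lineage through one
cell, the effective population size is tiny and drift dominates selection:
mutations accumulate at close to the rate at which they arise. After `k`
transfers of `T` divisions each, a line has undergone about `k × T` cell
divisions, and each of its `S` callable genome sites had `S × k × T`
opportunities to mutate.

`marates` models the curated mutation counts of such an experiment as
Poisson: the number of events of a class in a group of lines is
Poisson with mean `μ × g`, where `μ` is the per-site per-division rate and
`g = Σ_lines S_l × D_l` (callable sites × total divisions, summed over
lines) is the group's **exposure denominator**. Everything downstream —
interval estimation, the two-group test, the power analysis — follows
from this Poisson model. The assumptions it encodes:

* mutations arise independently at a constant per-division rate (no
  mutator lines, no rate heterogeneity in time);
* the curated calls are complete within the callable fraction of the
  genome (calling sensitivity is absorbed into `S_l`);
* lines are independent replicates.

## Estimators and tests

**Rates and exact intervals.** The point estimate is `μ̂ = x / g`. Because
MA counts are small (tens of events), a normal interval would be badly
anti-conservative; the package uses the exact chi-square (Garwood) bounds

```
low  = ½ χ²(α/2;   2x)     / g      (0 when x = 0)
high = ½ χ²(1−α/2; 2x + 2) / g
```

which guarantee coverage at least `1 − α` for every true rate. The
interval is deliberately conservative; the parameter-recovery tests
therefore check coverage `≥ 95%`, not `≈ 95%`.

**Two-group comparison.** `rate_ratio_test()` reports the rate ratio
`RR = (x₂/g₂)/(x₁/g₁)` two ways: the Wald log-RR interval and test
(`se = √(1/x₁ + 1/x₂)`), and the exact conditional binomial test — given
the total `n = x₁ + x₂`, `x₂ ~ Binomial(n, g₂/(g₁+g₂))` under equal
rates. The Wald form is the headline (it is what rate-ratio CIs in MA
papers are), the exact form is the robust small-count check; both
p-values are always reported. Its upper Wald bound is reported unrounded;
with counts 18 and 24 the closed form gives 2.2996, which rounds to 2.30
rather than the 2.29 sometimes produced by rounding the log-scale pieces
first.

**Spectra.** Substitutions are strand-collapsed into six classes keyed by
the ref:ref-complement pair (a C>T and a G>A are the same `G:C>A:T`
event). Class rates are conditioned on the origin base content: the
per-line rate of an `A:T>·` class divides the line's class count by its
A/T sites (genome A/T count scaled by the line's callable fraction) times
its divisions. The plotted error bar is the between-line SEM. Because
per-line base composition is rarely available, the callable fraction is
applied uniformly to A/T and G/C sites — adequate unless callable regions
are strongly composition-biased.

The **A/T bias** is the ratio of conditional rates toward A/T
(`G:C>A:T` + `G:C>T:A`, per G/C site) over toward G/C
(`A:T>G:C` + `A:T>C:G`, per A/T site). The direction-neutral classes
(`G:C>C:G`, `A:T>T:A`) change neither composition and are excluded: the
bias names a direction, not a class list.

**Selection tests.** Under neutral accumulation, coding substitutions
should split between nonsynonymous and synonymous in proportion to the
genomic site totals. The goodness-of-fit statistic uses the Yates
continuity correction with the deviation floored at zero,
`Σ (max(|O−E|−0.5, 0))² / E`, so a near-perfect fit cannot be inflated
into a positive statistic. The 2×2 between-group test uses the margin
shortcut `N(|ad−bc|−N/2)²/[(a+b)(c+d)(a+c)(b+d)]`, clamped the same way;
the two forms are algebraically identical and the tests verify this on
1,000 random tables (and against `chisq.test(correct = TRUE)`).

**Site counting.** `count_syn_nonsyn_sites()` uses the degeneracy-fraction
definition: each codon position contributes `f/3` synonymous sites, `f`
being how many of its three single-base changes preserve the amino acid,
so every codon contributes exactly 3 sites. An alternative would weight
opportunities by a mutation model; the unweighted fraction is the common
convention and is what genome-wide nonsyn/syn site totals in MA papers
mean. Changes creating a stop codon count as nonsynonymous by default
(`stop_changes = "exclude"` drops them); genome-wide totals are too
coarse to adjudicate this, so it is a documented switch.

**Effective population size.** Between transfers the colony passes
through census sizes `1, 2, …, 2^T`; the variance-effective size of the
cycle is the harmonic mean `Ne = (T+1)/Σ_{i=0}^{T} 2^{−i}`. The geometric
sum is evaluated in closed form as `2 − 2^{−T}`, which agrees with the
term-by-term sum at integer `T` to machine precision and extends it
continuously and monotonically to the real-valued `T` that comes out of
averaging CFU measurements. `T` itself is estimated as the mean of
`log2(CFU)` over colonies (the log of the geometric mean): under
multiplicative plating noise this is unbiased for `T`, whereas the log of
the arithmetic mean inherits a `σ²/2` bias. For noise-free or single
measurements the two coincide.

## The power analysis

`power_curve()` estimates the probability of detecting a multiplicative
rate increase `e`: per replicate, `x₁ ~ Poisson(μ g₁)` and
`x₂ ~ Poisson(μ(1+e) g₂)`, and the one-sided exact conditional binomial
test (toward an increase — the mutagenicity alternative) is applied at
`α = 0.05`. Power is the rejection fraction; its Monte-Carlo SE is
`√(p(1−p)/reps)`. Each effect size draws from an independent,
deterministic substream of the seed, so curves are bitwise reproducible
and extending the grid never perturbs existing points. Replicates with
`x₁ + x₂ = 0` cannot reject.

Two design choices were genuinely open:

* **Sidedness.** One-sided toward an increase is the default: the
  scientific question is mutagenicity, and a two-sided exact test at the
  same α is markedly less powerful at these counts. A `sided = "two"`
  flag is provided.
* **Conditioning on the observed control count.** Both modes exist. With
  both counts simulated (the default, matching the description of
  simulating "mutation counts"), the package's own simulations put power
  at a doubling slightly below 0.8; holding the control count at its
  observed value of 18 — i.e. asking "would a treatment arm with twice
  the rate have looked significantly different from the control data we
  actually have?" — puts it slightly above. The conventional "80% power
  at a 100% increase" summary of this design corresponds to the
  conditional formulation; the default mode is the more honest account
  of a future replication of both arms. The difference (a few points of power) is a
  useful reminder that "the power of the study" depends on what is held
  fixed.

## The synthetic-data generator

`simulate_experiment()` emulates the study design the statistics assume:
per line, class counts are Poisson at the configured rates over
`callable sites × divisions`; substitutions get a spectrum class,
a uniform position, a strand-uniform ref/alt pair, and a probabilistic
coding effect; indel sizes are geometric-tailed within 1–49 bp and SVs
start at 50 bp. Defaults are the study conditions of a two-group
fission-yeast experiment: 46 control and 48 treatment lines, a
12,521,788-bp genome at 36.06% GC, 46 transfers × 19.35 divisions
(~890 divisions per line), 98.08% of the genome callable (so the control
exposure is ~5.03×10¹¹ site·divisions), `μ_BPS = 3.58e-11`,
`μ_indel = 4.77e-11`, `μ_SV = 1.19e-11`, a treatment fold of 1.25, 7/8 of
indels insertions, and a spectrum with ts/tv = 2.0 whose
composition-conditioned A/T bias is 4.33 (the per-class split is not
published, so the default realizes the published summary statistics).
CFU noise is lognormal with σ = 0.2 on the natural-log scale, a typical
plating variability.

What the generator does **not** emulate — and hence what passing tests do
not establish about real data: calling errors and their curation,
per-line callable-site variation, mutation-rate heterogeneity among
lines, positional clustering (positions are uniform; duplicates are
dropped with a message, a negligible correction at MA rates), and
annotation-based coding effects (assignment is probabilistic; a
GFF-driven mode was considered and left out of scope since the selection
tests consume counts, not annotations).

Each line draws from a deterministic substream
(`seed × 1009 + 7 × line index`), so adding lines never changes earlier
lines' data.

## Numerical and degenerate-input choices

* Ratios with empty denominators (no transversions, no deletions, no
  A/T-direction events) return `Inf` with a `degenerate` attribute, not
  an error: a legitimate small spectrum can produce them.
* A rate ratio with `x₁ = 0` is `Inf`, flagged, with a one-sided
  continuity-corrected lower bound; `x₁ = x₂ = 0` is an error.
* Internal rates are never rounded; display rounds to 3 significant
  digits.
* The Yates floor (`max(|O−E|−0.5, 0)`) prevents the correction from
  manufacturing a positive statistic out of a near-perfect fit.
* Exposure uses the exact per-line sum when callable sites are given; the
  grand-mean product `n × mean_sites × mean_divisions` is a flagged
  fallback for published summary data.

## Problem sizes in the test suite

The suite simulates at the scales the inferences need, chosen as the
package's own trade-off between resolution and turnaround: 2,000 Poisson
draws per level for interval coverage, 2,000 replicates per effect size
for power properties (MC SE ≈ 1%), 200 study-scale experiments for
parameter recovery, 10,000 substitutions for spectrum recovery, and
1,000 random tables for the chi-square oracle equivalence. The whole
suite runs in well under a minute of simulation time.

## Known limitations

* Two groups only; no dose-response modelling across multiple
  concentrations, and no >2-group Poisson rate model.
* Rates assume a single pooled Poisson process per class; no
  per-line random effects (a dispersion test across lines is a natural
  extension).
* The conditional spectrum scales composition by a single callable
  fraction per line.
* No trinucleotide-context (96-class) signatures.
* `read_vcf_minimal()` is deliberately minimal: one line-genome per file,
  FILTER-based skipping, multi-allelic splitting — not a general VCF
  toolchain.
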