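---
title: "Resampling haplotype reference panels by simulated recombination"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Resampling haplotype reference panels by simulated recombination}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hapresample)
```

## The model and its assumptions

`hapresample` transforms a phased reference panel of `N` haplotypes and `L`
variant sites into a synthetic panel of identical dimensions by simulating
`K` generations of meiotic recombination. Rather than simulating each
generation forward (cost O(KNL)), all crossovers are drawn at once:

1. **Breakpoints.** Over a chromosome of genetic length `L_M` Morgans, the
   total event count is `M ~ Poisson(lambda)` with
   `lambda = L_M * (N/2) * K` — each of the `N/2` diploid lineages
   undergoes `K` meioses at one expected crossover per Morgan. Conditional
   on `M`, event positions are i.i.d. uniform in genetic coordinates and
   are mapped to base pairs by inverting the genetic map. This is the
   standard homogeneous Poisson process; the equivalent sequential
   formulation (exponential inter-arrival distances in cM) has the same
   law, but the count-then-positions realization has a fixed RNG
   consumption pattern, which is what makes exact replay possible.
2. **Permutation streaming.** The haplotype order is shuffled once
   (uniformly). The panel is then streamed site by site; whenever the
   stream passes a breakpoint, two haplotype slots drawn uniformly *with
   replacement* are exchanged. Every emitted site is therefore a column
   permutation of the input site, giving O(NL) total cost and O(N)
   resident state in the file-to-file path.

Modelling assumptions worth stating: no crossover interference (events are
independent), a single sex-averaged genetic map, and a panel that is phased
and fully called. Recombination outside the mapped interval is taken to be
absent (cM is clamped beyond the first/last map knot) — the map asserts no
rate there, so the conservative choice is zero. These assumptions matter
little for imputation-oriented use but mean the synthetic panel is not a
faithful sample from a population-genetic model; analyses that rely on,
say, interference or sex-specific maps should not use it.

## What is conserved, and what decays

Because each site is permuted, the per-site allele multiset — hence every
allele frequency, the MAF spectrum and the set of segregating sites — is
conserved *exactly*, for every `K`. What decays is the co-inheritance of
nearby alleles on the same haplotype: each breakpoint splices two
haplotypes, so linkage disequilibrium erodes gradually as `K` grows. The
package quantifies this with per-variant **LD scores** (the sum of r²
between a variant and all others within ±100 kb), compared across panels
by Pearson correlation ρ and by the slope β of an ordinary least-squares
regression (with intercept) of synthetic scores on original scores: β < 1
indicates globally depleted LD. The regression is oriented this way
precisely so that the β < 1 reading holds; with the opposite orientation a
uniform depletion would inflate the slope.

The probability that a given haplotype recombines at least once follows
from thinning the event process: an event involves a given haplotype with
probability `1 - ((N-1)/N)^2` (two with-replacement draws), so

```
P(at least one) = 1 - exp(-(L_cM/100) * K * (2N-1)/(2N))
```

with the `N -> Inf` limit `1 - exp(-(L_cM/100) * K)`. For a 62.79 cM
chromosome (the smallest human autosome) at `K = 8` this gives
`r round(recombination_probability(62.79, 8), 5)` — above 0.99, the usual
argument for `K = 8` as a default that recombines essentially every
haplotype while leaving LD (and imputation utility) largely intact.

## Reversibility and the RNG contract

The transform is a deterministic function of `(panel, map, K, N, seed)`.
All draws happen under one pinned generator
(Mersenne-Twister/Inversion/Rejection) in a fixed order: event count, event
positions, initial shuffle, then one `(i, j)` pair per breakpoint in
ascending order. Reversal replays the schedule and applies the inverse
permutation per inter-breakpoint segment, restoring the genotype matrix
byte-exactly. Two safeguards prevent silent corruption: the metadata stores
an MD5 fingerprint of the map table (reversal refuses a different map) and
the replayed breakpoint count is checked against the recorded `M`.
Metadata travels as `##hapresample_*` VCF header lines; original sample
names go only into an optional private JSON sidecar, since severing the
genome–identity link is the purpose of the forward transform.

Numerical conventions, chosen once and fixed:

* **Breakpoint/variant boundary.** An event at position `r` takes effect
  for the first variant with `pos > r`; a variant exactly at `r` is
  emitted under the pre-event state. Ties have measure zero but need a
  deterministic rule for replay.
* **Flat map segments.** Inverting the map at a cM value lying on a
  zero-rate segment returns the segment's leftmost bp — again a
  deterministic tie-break for a probability-zero set.
* **Self-swaps.** Pairs are drawn with replacement, so `i == j` events are
  kept as no-ops; this is also what makes the `(2N-1)/(2N)` thinning
  factor exact rather than approximate.
* **`K = 0`.** The initial shuffle is still applied, so a `K = 0` run is a
  global relabeling of haplotypes: nothing measurable changes (LD scores
  and all frequencies are invariant under a site-constant permutation),
  and reversal still restores the original labels.
* **One chromosome per run.** The transform refuses multi-chromosome
  input; each chromosome is run separately with its own map and seed,
  which keeps the replay contract a single-seed statement.

## Tunable parameters

| parameter | units | default | why |
|---|---|---|---|
| `K` | generations | 8 (CLI) | recombines >99% of haplotypes on every autosome while LD remains highly correlated with the original |
| `window_bp` | bp | 100000 | the conventional ±100 kb LD-score window; boundary inclusive |
| `strict` | flag | on | reversal requires an exactly reproducible matrix; unphased or missing genotypes make that impossible |

Monomorphic and multiallelic sites are reported by `validate_panel()` but
not removed: the permutation is allele-agnostic. They are, however,
excluded from r² (undefined at zero variance) and from ρ/β comparisons.

## The fixture generator

`simulate_mosaic_panel()` builds each haplotype as a Markov mosaic of a
small founder set: founders carry i.i.d. Bernoulli(0.3) alleles and the
copying founder switches between adjacent sites with probability
`1 - exp(-switch_rate * gap)`. Defaults — 100 haplotypes, 500 sites over
1 Mb, 8 founders, switch rate 2e-6/bp — give a dense region with strong
block LD (about two founder switches per haplotype), which is the regime
the transform's LD metrics need to be sensitive in. These sizes were chosen
as a realistic desk-scale stand-in for a dense 1 Mb slice of a real panel.
What the mosaic model does *not* emulate: a realistic allele-frequency
spectrum (no excess of rare variants), mutation on the tree, or genuine
population structure. Tests passing on these fixtures therefore demonstrate
the transform's exactness properties (reversibility, conservation,
process law) on any panel, but statements about LD preservation magnitudes
on *real* panels (specific ρ/β values at a given `K`) do not transfer —
only the qualitative monotone decay does.

`make_toy_map()` provides the two map shapes the tests need: `constant`
(the null map: linear cM in bp, same construction as
`make_constant_rate_map()` applied to any real map) and `hotspot` (90% of
the genetic length in the central 10% of the span), which verifies that
breakpoints follow cM mass, not physical distance.

## Problem sizes used in the test suite

The statistical suites run at sizes a laptop handles in seconds while
retaining power: Poisson goodness of fit over 1,000 seeded draws at
`lambda = 20`; uniformity of pooled breakpoint positions over 200 draws;
per-haplotype hit rates over 2,000 replicates at `N = 100` against the
closed form within 3 binomial standard errors; reversibility over 100
fixture-by-`K` combinations (`N` up to 200, `L` up to 800, `K` in
{0, 1, 8, 128}) plus byte-level VCF round trips; and the Monte-Carlo
cross-check of the headline probability at `N = 1000` over 10,000
replicates. The hotspot concentration check asserts the observed fraction
of events in the hotspot against its expectation (0.9) minus three
binomial standard errors, since the expected fraction sits exactly at the
nominal boundary.

## Known limitations

* Imputation accuracy itself is out of scope: evaluating it requires an
  external imputation engine and gold-standard panels; this package stops
  at the LD-preservation metrics that predict it.
* Very rare variants are the first casualties of recombination-based
  mixing: a lone alt allele rides a single haplotype fragment, so its
  local haplotype background degrades fastest as `K` grows. The
  frequencies themselves remain exact.
* A synthetic panel is not anonymous against all attacks — long shared
  IBD-like segments survive small `K` by design (that is what keeps
  imputation working), and `plant_duplicate_haplotype()` exists precisely
  to let users measure that survival.
* The streaming path requires GT-only FORMAT fields; per-genotype
  annotations (DP, GQ, ...) cannot be carried through a haplotype-level
  permutation and are refused rather than silently dropped.
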