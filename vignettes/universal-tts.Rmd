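---
title: "Scoring RNA-DNA triplexes and calling universal target sites"
author: "triplexhub"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring RNA-DNA triplexes and calling universal target sites}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(triplexhub)
```

## The model

A chromatin-bound RNA can dock onto duplex DNA as a third strand in the
major groove, reading the purine-rich strand of the duplex through
Hoogsteen hydrogen bonds. Such triplex target sites (TTSs) are typically
poly-purine tracts. Because the Hoogsteen code is degenerate, one long
poly-purine tract can in principle accommodate windows from many
different transcripts; regions with that property are what this package
calls *universal* TTSs.

### Hoogsteen pairing rules

A triplex window is validated under one of three motif families, each
evaluated window-wide (families are never mixed inside a window):

| motif | orientation      | valid triples |
|-------|------------------|----------------|
| TC (pyrimidine) | parallel only | C·G, U·A |
| GA (purine) | antiparallel only | G·G, A·A |
| GT (mixed) | both | G·G, U·A |

Equivalently: DNA guanine binds RNA guanine in both orientations and RNA
cytosine in parallel only; DNA adenine binds RNA uracil in both
orientations and RNA adenine in antiparallel only. *Orientation* is the
direction of the third strand relative to the purine strand of the
duplex; both DNA strands are scanned for the purine tract.

### Window counting semantics

`enumerate_triplexes()` returns **every** window of length at least
`min_length` (default 10 nt) in which at most
`floor(max_error_rate / 100 * L)` positions (default 10%) violate the
pairing rules of at least one enabled motif family, with overlaps
allowed. Deduplication is on (RNA interval, DNA interval, strand,
orientation): a window validated by both TC and GT is one window; the
same interval pair found in parallel and in antiparallel counts twice.
A long perfect triplex therefore contributes all of its sub-windows:

```{r}
enumerate_triplexes("GAGAGAGAGAG", "GAGAGAGAGAG")
```

The 11-nt alignment is counted together with its two 10-nt sub-windows,
giving `N_tpx = 3`. This overlap-allowed total is deliberate: a single
long tract should produce a large count and hence a strong p-value.

By default windows must begin and end with a valid triple
(`require_terminal_match = TRUE`), preventing counts from being inflated
by error-padded window extensions at tract boundaries; the flag is
exposed because reasonable scanners differ here. Optional caps on
consecutive errors and on the minimum guanine fraction of the target
window exist but default to off — only the length and error-rate
thresholds define the standard search.

### The Poisson null

The count for random sequences grows with both lengths, so significance
is judged against a Poisson null whose mean is a linear function of the
lengths:

$$\lambda(L_{RNA}, L_{DNA}) = \theta_0 + \theta_1 L_{RNA} + \theta_2 L_{DNA},
\qquad p = P(X \ge N_{tpx} \mid X \sim \mathrm{Pois}(\lambda)).$$

The shipped `reference_calibration()` carries
$\theta_0 = -0.688,\ \theta_1 = 5.37\times10^{-4},\ \theta_2 =
6.03\times10^{-4}$, the reference coefficients for the standard search
configuration on uniform-composition random sequences; it is the default
scoring model so that given the same counts the same p-values are
produced everywhere. Refitting against the bundled engine is an explicit
user action:

```{r, eval = FALSE}
grid <- simulate_lambda_grid(engine_params(),
                             rna_lengths = c(500, 1000, 1500, 2000),
                             dna_lengths = seq(200, 2000, 200),
                             reps_per_side = 100, seed = 1)
fit_lambda_model(grid)
```

The grid draws `reps_per_side` RNA and DNA sequences per cell with equal
base frequencies and averages the count over all `reps_per_side^2`
pairs; ordinary least squares with intercept is fitted to the cell
means. Because the engine's exact counting conventions (terminal-match
rule, orientation deduplication) affect the absolute scale, a refit on
this engine need not reproduce the reference coefficients — only the
positive length effects and a high adjusted R² are expected, and the
test suite asserts exactly that at a reduced scale (4×10 cells, 10
sequences per side; chosen so a refit completes in minutes on one core).

**Numerical choices.** The linear plane dips below zero for short
inputs (e.g. raw $\lambda(500, 200) = -0.2989$). Since the Poisson null
requires $\lambda > 0$, predictions at or below zero are clamped to
`lambda_floor` ($10^{-3}$ by default) with a warning. Clamping makes any
observed window at such lengths highly significant — a conservative
choice in the opposite direction, which is why it is surfaced rather
than silent. Deep Poisson tails are computed by `ppois(lower.tail =
FALSE)` and may underflow to exactly 0 below about $10^{-308}$; the
Bonferroni step tolerates those zeros.

### Multiple testing and the universal call

Adjusted p-values are Bonferroni, `min(1, m p)`. The family is
configurable: `"per-rna"` (default) treats each transcript's scan over
all regions as one family ($m$ = number of regions), matching the
per-transcript presentation of adjusted p-values; `"global"` uses all
RNA×region tests. A pair is significant when the adjusted p-value is
strictly below `alpha = 0.01`, and a region is a universal TTS when the
fraction of the panel significant for it strictly exceeds
`universal_fraction = 0.9` ("more than 90%"). Both strict inequalities
are deliberate: 18 of 20 transcripts (exactly 90%) does not qualify.

## Composition measures

`ga_content()` is the maximum over the two duplex strands of the purine
(G/A) percentage — always ≥ 50% because a purine-poor strand faces a
purine-rich complement; ties report the forward strand.
`polypurine_content()` sums, per strand, the lengths of maximal purine
runs of at least `min_run` (default 10, the engine's minimum window
length) and reports the larger strand total as a percentage of region
length; runs from different strands are never mixed. Masked characters
(`N`) break runs and count as non-purines on both strands, and are
unconditional mismatches in the engine.

## Control RNAs

`dinucleotide_shuffle()` draws a uniform random sequence with the exact
dinucleotide count vector of the input (Altschul–Erickson Eulerian-path
sampling), preserving length, mononucleotide counts and terminal
residues. Exact preservation — rather than Markov resampling — matters
because the significance contrast between a transcript and its shuffles
should reflect sequence order only, with composition held fixed.

## The synthetic fixture

`make_fixture()` generates the study conditions for end-to-end tests
without any downloads: a 500 kb i.i.d. genome at GC 0.5; 50 planted
200 bp regions each containing a pure 100 bp poly-purine tract
(alternating poly-A and poly-G across regions, strand randomised to
exercise both-strand scanning); 50 length-matched control regions
sampled uniformly away from the planted set; and a panel of 20
transcripts of 1000 nt at GC 0.5.

Uniform i.i.d. transcripts almost never contain the ≥ 10 nt single-motif
runs that drive triplex counts, while real transcripts do carry such
low-complexity runs — so the generator injects them explicitly: each
transcript receives two pyrimidine runs and one purine run of 12 nt at
random non-overlapping positions. Injected runs are homopolymers cycling
through the motif alphabet (a poly-C and a poly-U run from {C,U}, a
poly-G run from {G,A}), so every transcript can read both a poly-A tract
(via U·A) and a poly-G tract (via C·G in parallel or G·G in either
orientation). Under these conditions every planted region should be
significant for the whole panel while i.i.d. background regions almost
never harbour a near-pure ≥ 10 bp homopurine tract, which is what the
planted-recovery test asserts (≥ 90% of planted vs ≤ 10% of background
called universal at a fixed seed).

What passing these tests does *not* show: the fixture has no repeat
structure, no chromatin context, no expression filtering and no
real peak length distribution, so recovery here demonstrates the
statistical machinery, not performance on real pulldown peaks.

## Conventions, sizes and limitations

* Coordinates are 0-based half-open (BED convention) everywhere; DNA
  records always denote the forward strand and the reverse strand is
  derived on demand.
* Ambiguous bases are rejected by default (regions containing `N` are
  expected to be removed upstream); `ambiguous = "mask"` hard-masks them
  instead.
* All stochastic steps (grid simulation, shuffling, fixture generation)
  take explicit seeds and are bit-reproducible.
* Test problem sizes — the oracle cross-validation uses 10⁴ random pairs
  of length ≤ 25 against a brute-force window enumerator; the refit uses
  the reduced 4×10 grid with 100 pairs per cell; the end-to-end fixture
  is as above. These sizes were chosen so the whole suite runs in
  minutes on a single core while still exercising every code path.
* The Poisson null is calibrated on means only; random counts are
  over-dispersed relative to Poisson (one long chance tract yields many
  windows at once), so the null is anti-conservative in the extreme tail
  and exact type-I control is not claimed — Bonferroni at α = 0.01 and
  the > 90% panel rule provide the practical guard.
* RNA secondary structure, chromatin accessibility and triplex
  thermodynamic stability are outside the model: every sequence window
  is treated as available for pairing.
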