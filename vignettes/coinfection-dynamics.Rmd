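---
title: "Modelling strain segregation and co-transmission of a heritable virus"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling strain segregation and co-transmission of a heritable virus}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(strainseg)
```

## The biological question

LbFV is a DNA virus of the parasitoid wasp *Leptopilina boulardi*,
transmitted almost perfectly from mother to offspring and, during
superparasitism, horizontally between unrelated wasp larvae sharing a
*Drosophila* host. Two viral strains can be told apart on a single PCR
marker: the reference strain amplifies a 399-bp fragment, a naturally
occurring variant carries a 111-bp deletion and amplifies 288 bp, and a
coinfected wasp shows both bands. Because the deletion length is a multiple
of three it leaves the reading frame intact, so the variant is predicted to
encode a shortened (168 aa instead of 205 aa) but otherwise colinear
protein — the two strains are near-equivalent competitors rather than a
functional virus and a defective one.

Coinfection raises a quantitative question: when a coinfected female
transmits, does each strain pass with the probability it shows in single
infection (independence), or do the strains interfere within the host
(competition)? `strainseg` implements the independence model and the tests
that confront it with data.

## The independence Markov chain

Write `P1` and `P2` for the single-infection vertical transmission
probabilities. Under independence, offspring status given mother status is
a four-state Markov chain over (uninfected, strain 1, strain 2, coinfected).
Uninfected is absorbing — the chain models vertical transmission only, so an
uninfected line can never regain the virus — and a mother cannot transmit a
strain she does not carry; the coinfected row factorises into the product of
two Bernoulli retention events:

```{r matrix}
params <- strain_params(0.96, 0.943, "LbFV1", "LbFV2")
transition_matrix(params)
```

Distributions propagate by right-multiplication, `G[n+1] = G[n] M`, and two
closed forms follow from the factorisation: a strain carried by a founder is
still present after `n` generations with probability `p^n`
(`retention_closed_form()`), and a line founded by a coinfected female is
still coinfected with probability `(P1 P2)^n`. Both identities are asserted
against repeated matrix multiplication in the test suite, to 1e-12, over
randomly drawn parameters.

The two measured rates, 0.96 and 0.943, are used exactly as printed
throughout: the model's own convention is that founding females are
generation 0 and a "four-generation" experiment applies the matrix four
times.

## Stochastic simulation and the Monte-Carlo test

The segregation experiment follows isofemale lines — each generation a
single female is kept — so realised statuses are a stochastic path of the
chain, not its expectation. `simulate_lineages()` implements the path by
drawing, for every line and generation, one Bernoulli retention event per
carried strain. This is exactly equivalent to sampling offspring status
from the mother's matrix row (the joint law of two independent Bernoulli
draws *is* the row); the equivalence is proven row-by-row analytically and
checked statistically against a categorical-sampling oracle in the tests.

`null_distribution()` repeats the whole experiment (default 40 lines, 4
generations, matching the design being emulated; 1000 replicates by
default) and records the final coinfected-line count of each replicate.
`empirical_p_value()` then places an observed count within those null
counts. Two choices deserve note:

* **Two-sided rule.** For a discrete, asymmetric null the phrase "more
  extreme than observed" is ambiguous. We use the doubled smaller tail with
  an add-one correction — `(#{counts <= obs} + 1) / (n_sims + 1)`, doubled
  and capped at 1 — the standard construction for Monte-Carlo tests: it is
  strictly positive (an observed value can never be "impossible" under a
  finite simulation) and mildly conservative. The uncorrected proportion is
  reported alongside for transparency.
* **Random numbers.** Each exported stochastic function takes one integer
  seed and draws everything it needs from a single vectorised stream
  (`withr::with_seed`, so the caller's RNG state is untouched). Results are
  exactly reproducible from the seed recorded in every report; the uniform
  stream has fixed length per generation regardless of realised statuses,
  which is what makes the trace and non-trace code paths, and hence the
  segregation generator and the null builder, agree draw-for-draw.

With the measured rates, the null mean is `40 * (0.96 * 0.943)^4 = 26.9`
coinfected lines; an observed count of 11 sits far below every simulated
replicate, giving p on the order of 2e-4 at 10,000 simulations. We default
to 1000 simulations (the scale of the original analysis) but use 10,000
where the tail bound matters, since 1000 replicates cannot resolve
p-values below 1e-3 .

## Exact tests and estimates

* `estimate_rate()` returns `k/n` with a Clopper–Pearson interval from the
  beta-quantile construction (level 0.95 by default). The interval method
  is our choice — the exact interval is the conservative default for the
  small `n` (a dozen to a hundred offspring) these experiments produce —
  and its coverage at nominal 95% is verified by simulation (≥ 93% at
  n = 50, p = 0.9).
* `cotransmission_test()` is the exact binomial test of an observed
  co-transmission count against the independence expectation `P1 P2`
  (`independence_expectation()`). The two-sided p-value follows the
  minimum-likelihood rule — sum `P(X = x)` over outcomes no more likely
  than the observed one, with the customary 1e-7 relative tolerance on the
  density comparison — chosen because it is the convention of the
  statistical environment this kind of analysis is normally run in, making
  published p-values reproducible. The implementation is direct
  enumeration; `stats::binom.test` serves as an independent cross-check in
  the tests (agreement to 1e-12 for all n ≤ 30).
* `protection_ratio()` summarises horizontal-transfer experiments as the
  ratio of acquisition rates into uninfected versus already-infected
  recipients; the measured rates (71% vs 33%, 78% vs 26%) give ratios of
  2.15 and 3.0 — the "about twofold" protection pattern.

## Genotype calling and display

`call_genotype()` maps a set of band lengths to a status given the marker
model (399-bp reference amplicon, 111-bp deletion): a band within
`tolerance_bp` of 399 indicates strain 1, within tolerance of 288 strain 2,
both bands coinfection, none uninfected. The default tolerance of 10 bp
reflects agarose-gel resolution; any value below 55 bp keeps the two
references unambiguous, and a band compatible with both references raises
an explicit ambiguity error rather than a silent call. Records whose
insect-control PCR failed can be flagged (`control_ok`) and are excluded.
`order_infection_matrix()` exports the 0/1 individuals-by-strains matrix
reordered for reading (coinfected, strain-1-only, strain-2-only,
uninfected; ties by identifier) — the display convention of
presence/absence infection plots — leaving column sums untouched.

## What the synthetic generators emulate

`generator_config()` fixes the data-generating conditions once:

| knob | default | meaning |
|------|---------|---------|
| `p1`, `p2` | 0.96, 0.943 | measured single-infection vertical rates |
| `gamma` | 1 | multiplier on each strain's vertical rate while the mother is coinfected; 1 = independence, < 1 = competition |
| `rho` | 0.45 | multiplier on horizontal acquisition into an already-infected recipient; reproduces the observed twofold protection |
| `h` | 0.75 | per-offspring horizontal acquisition probability, uninfected recipient; brackets the observed 71–78% |
| `false_negative` | 0 | probability a carried strain is missed by PCR (false negatives are rare in this assay) |
| `vial_effect_sd` | 0 | per-vial logit-normal effect on `h`, for vial-level clustering |

`gen_vertical_experiment()` emulates scoring offspring of infected mothers
(defaults 20 mothers × 5 offspring); `gen_segregation_experiment()` the
40-line, 4-generation isofemale design; `gen_horizontal_experiment()`
superparasitism trials (defaults 4 vials × 25 offspring, within the 46–100
offspring per condition of the emulated design). Competition is a
symmetric multiplicative penalty on both strains — the simplest mechanism
consistent with reduced co-transmission and no competitive asymmetry
between strains — and a coinfected donor transmits both strains as a single
package with probability `h`, so co-transfer is not rarer than single-strain
transfer, as observed.

At `gamma = 1`, `rho = 1`, `false_negative = 0` the generators collapse
exactly to the analytic model; the test suite verifies this and two
pipeline-level properties: the type-I error of the full
estimate-rates → build-null → test pipeline at `gamma = 1` lies in
[0.03, 0.07] at a nominal 0.05 (2000 replicates; the rate-estimation arm
uses 100 mothers × 5 offspring per strain), and power is non-increasing in
`gamma` over {0.6, …, 1.0} (500 replicates per value against a common
10,000-replicate null). These sizes keep the whole suite under two minutes
on one core while leaving Monte-Carlo noise well inside the asserted bands.

What the generators do **not** emulate: within-host viral load and its
dynamics (competition acts directly on transmission probabilities), wasp
life-history traits and behavioural-manipulation intensity, egg
distributions under superparasitism, host population dynamics, and real
PCR artefacts beyond a uniform per-strain false-negative rate. Passing
tests therefore show that the *statistical machinery* is calibrated under
the model's own assumptions, not that those assumptions hold in any given
dataset.

## Numerical choices and degenerate inputs

Probability vectors must sum to 1 within 1e-12 and matrix rows are
validated to the same tolerance; probability comparisons in tests use
absolute tolerance 1e-9 or tighter. `n_generations = 0` is the identity
everywhere (and a zero-generation segregation experiment is all-coinfected
by construction). `p0 ∈ {0, 1}` in the exact test is accepted only when the
data cannot contradict it, else a validation error names the offending
parameter. A zero infected-recipient rate makes the protection ratio
infinite, with a warning rather than an error. The empirical p-value's
add-one correction guarantees `0 < p ≤ 1`.

## Limitations

* The chain is hard-coded for two strains, faithful to the marker that
  distinguishes exactly two; the per-strain Bernoulli formulation in the
  simulator is the natural generalisation path.
* Horizontal transmission lives only in the synthetic generators; the
  Markov chain and its null distribution are strictly vertical.
* The competition knob `gamma` is a data-generating alternative for power
  studies, never part of the null model, and no attempt is made to
  *estimate* `gamma` from data.
* The Monte-Carlo p-value resolution is bounded by `1/(n_sims + 1)`;
  claims below 1e-3 need at least 10,000 simulations.
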