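---
title: "Methods: consensus fuzzy cognitive maps, structural metrics and scenario simulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: consensus fuzzy cognitive maps, structural metrics and scenario simulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fcmtools)
```

## The model

A fuzzy cognitive map is a signed weighted digraph over concepts, with link
weights in $[-1, 1]$ read as perceived causal influence: $w(i \to j) > 0$
means more of $i$ produces more of $j$, $w < 0$ the reverse. The package
treats the map as three coupled artefacts: the elicited respondent claims,
the aggregated consensus graph, and the dynamical system the graph induces
under activation spreading. Self-loops are excluded throughout (a concept is
not its own cause at this level of abstraction), and each ordered dyad
carries at most one link; re-specifying a dyad is an error rather than a
silent overwrite, because duplicated rows in elicitation data almost always
indicate a transcription mistake worth surfacing.

## From Likert ratings to fuzzy weights

Respondents rate each claimed link on a 1–5 scale with a declared direction.
The mapping to the fuzzy scale is $w = d \cdot m/5$, so magnitudes land on
$\{0.2, 0.4, 0.6, 0.8, 1.0\}$ and the top rating reaches the endpoint of the
causal scale. This is a design choice, not a law of nature: other anchorings
(e.g. leaving headroom below 1) are defensible, so `likert_to_fuzzy()` takes
the five-entry mapping table as an argument.

Before averaging, each respondent's weight magnitudes can be min–max rescaled
within their own map: $m' = (m - \min)/(\max - \min)$, signs preserved. The
intent is to damp inter-individual differences in scale use. Two consequences
deserve attention. First, a respondent's weakest claim rescales to magnitude
zero, i.e. rescaling deliberately discards that respondent's weakest link and
stretches the rest. Second, a constant map ($\max = \min$) is degenerate; the
package maps it to magnitude 1 everywhere, reading "no internal contrast" as
"every claim at the respondent's full strength". Rescaling defaults to on for
the consensus pipeline, but all comparisons against a known truth graph (the
recovery harness) run with it off, because rescaling changes the scale on
which weights live and exact recovery is then impossible by construction.

## Consensus aggregation

For each ordered dyad, the consensus weight is the arithmetic mean over the
respondents who claimed it — absence is non-response, not a zero. Averaging
zeros from non-claimants would drag every consensus weight toward zero and is
inconsistent with consensus maps whose retained links carry substantial
weight. A dyad is retained iff

* at least $\lceil p \cdot R \rceil$ of the $R$ respondents claimed it
  (default $p = 0.30$; the ceiling implements "at least 30%": with $R = 18$,
  $0.30 \times 18 = 5.4$, so six claimants are required), and
* the absolute mean weight reaches `weight_floor` (default 0.10; the floor is
  a data-quality guard against links that survive on presence but average to
  near-cancellation).

Claims outside median $\pm$ 1.5·IQR within their dyad are flagged as outliers
in the aggregation report but never dropped automatically: with at most a few
dozen claimants per dyad, automated trimming is more dangerous than a flag a
human can inspect. Dyads with fewer than four claims are not screened (the
IQR of two or three points is noise). The consensus graph is always passed
through the structural validator, which reports contradictory reciprocal
dyads (opposite signs on $i \to j$ and $j \to i$) and stranded concepts as
warnings.

## Structural metrics

Degrees use absolute weights: indegree$(v) = \sum_u |w(u \to v)|$,
outdegree symmetrically, centrality their sum. Absolute values are the only
convention under which a published degree table with non-negative entries can
coexist with maps containing negative links. The typology is total: *driver*
(outdegree only), *receiver* (indegree only), *ordinary* (both), *isolated*
(neither). Isolation is a reportable state, not an error, because aggregation
thresholds can strand a concept that respondents mentioned only rarely.

Density is $C / (N(N-1))$: self-loops are excluded from the map, so they are
excluded from the denominator. On the AMD fixture this yields
$40/(36 \times 35) = 0.0317\ldots \approx 0.032$ at three decimals; an $N^2$
denominator would give 0.031 and is therefore distinguishable at published
precision. The complexity score is the receiver/driver ratio and is undefined
(reported `NA`) in maps without drivers. Display tables round half-up at two
decimals — matching how such tables are conventionally printed — while
retaining unrounded values in adjacent columns. One published row of the AMD
centrality table ("Abandoned fishing", centrality printed 2.06 against
indegree 1.00 + outdegree 1.08) is internally inconsistent by 0.02; the
package treats the identity centrality = indegree + outdegree as exact and
does not anchor any check on that row.

## Scenario simulation

The update rule is pure propagation,
$x_i(t+1) = f\big(\sum_j w_{ji}\, x_j(t)\big)$, iterated from the zero vector
with clamped concepts held at their clamp values. The squashing $f$ defaults
to $\tanh$; a logistic variant rescaled to $(-1,1)$ and a linear clip are
available, and an optional self-memory term ($x_i$ added inside $f$) is a
switch. Three properties motivated the default:

* $f(0) = 0$, so the unclamped baseline is identically zero and scenario
  deltas equal the scenario steady state;
* activation only appears where influence arrives, so "unreached implies
  unchanged" holds exactly — concepts with no directed path from a clamped
  concept have delta exactly zero and are pruned (threshold
  `prune_epsilon = 1e-4`, comfortably above float noise at the default
  convergence tolerance of 1e-6 and far below any meaningful activation);
* $\tanh$ is odd, giving sign symmetry: negating all clamps negates all
  deltas.

Participatory FCM tools do not generally publish their update rules, so
equivalence with any specific tool is not claimed; the properties above are
the package's contract instead. Iteration stops when the maximum absolute
update falls below the tolerance or after `max_iterations` (default 1000);
non-convergence and period-2 oscillation are reported as flags, never thrown,
because cyclic maps can legitimately oscillate and the user needs the
diagnostic, not an abort.

The three AMD scenarios are cumulative clamp sets: (1) acid pollution at −1;
(2) additionally public awareness at +1 and lime expenditure at −1; (3)
additionally the seven ordinary impact concepts at −1. Clamp magnitude
defaults to full activation because the study states intervention directions
but not strengths; the magnitude is an argument. A negative delta on an
impact concept (e.g. income reduction) reads as that impact shrinking.

## Reconstruction from degree marginals

The AMD study released per-concept degree totals but not the edge list, so
the shipped 36-concept network is a *synthetic marginal-consistent
reconstruction*. Reconstruction is a constrained partition problem: find
exactly $E$ links, each with $|w| \in (0, 1]$, no self-loops, at most one per
ordered dyad, whose absolute row/column sums reproduce the published totals.
The allocator works in integer hundredths (the precision of the published
totals, so matching is exact, not approximate), processes receiving concepts
rigid-first (fewest minimum incoming links, then largest demand, then
lexicographic), fills each from the largest-residual sources with exact-fit
matches preferred, and backtracks from dead ends. The search order is fixed,
so identical inputs always return the identical graph. Feasibility is
prechecked: totals must balance, and $\sum_v \lceil \text{target}_v \rceil$
must fit within $E$ on both sides (for the AMD profile: 38 outgoing and 39
incoming minimum links against $E = 40$).

The allocator is designed for sparse profiles — consensus maps live far below
density 0.5 (the AMD map is at 0.032) — and resolves such instances in well
under a thousand search nodes. Very dense profiles can require interior
transportation splits outside its candidate moves; it then exhausts its
search budget and errors rather than returning an inexact graph.

Degree marginals are sign-blind, so link signs are interpretive: links
emitted by the two mitigation drivers are negative, impact cascades positive,
overridable per dyad. No claim is made that individual reconstructed links
match the unpublished elicited edge list — only that every degree-based
measure does, exactly.

## The synthetic respondent generator

`simulate_respondents()` emulates the study's interview conditions: 18
respondents (the saturation sample size) over a shared vocabulary, each
reporting a true link with probability 0.7, rating it `round(5|w|)` with ±1
Likert jitter clamped to 1–5, flipping the direction with probability 0.02,
and adding on average one spurious claim per respondent on dyads absent from
the truth. The presence probability, jitter and spurious rate are not stated
by any source; they were fixed once at values a field researcher would call
realistic for experienced respondents mapping a salient recent event, and the
binomial arithmetic they imply (claim counts $\sim \mathrm{Bin}(18, 0.7)$, so
a true link reaches the six-claim retention threshold with probability
$> 0.999$) is what the recovery tests then verify empirically. Magnitude
clamping matters at the edges of the scale: truth weights below 0.1 are
reported as at least rating 1 (weight 0.2), an asymmetry real instruments
share, and the top rating under jitter can only move down — so recovered
weights are mildly biased toward the interior at the scale ends.

The generator emulates *rating noise around a fixed shared structure*. It
does not emulate vocabulary disagreement between respondents, systematic
(correlated) perception biases, or respondent-specific sparsity patterns, so
passing recovery tests demonstrate the aggregation arithmetic and thresholds,
not robustness to the full messiness of field elicitation.

The recovery experiment (200 replicates at these defaults, run by
`analysis/04_recovery.R` and the acceptance tests, about a minute of compute)
reports link retention, false-link rate, per-link bias and RMSE; the headline
checks are retention at least 0.90 and mean per-link absolute bias at most
0.1, read as "the pipeline recovers what it was given, up to the quantisation
the Likert instrument itself imposes".

## Problem sizes and determinism

All computations are desk-scale: the case-study network has 36 concepts and
40 links, property tests use random maps of up to ten concepts at density
0.25–0.35, and the recovery study uses 200 replicates of 18 simulated
respondents. Every stochastic component takes a mandatory integer seed with
no wall-clock fallback; the scenario engine and the reconstruction allocator
are deterministic by construction.

## Known limitations

* Individual links of the shipped fixture are artefacts of the allocator;
  analyses that depend on specific paths (e.g. which concepts a scenario
  leaves unaffected beyond the structurally forced cases) are
  reconstruction-dependent and should be read accordingly.
* The scenario engine claims no equivalence with any proprietary simulation
  tool; only the documented propagation rule and its properties.
* Concept vocabularies must already be harmonised across respondents; the
  package does not align free-text concept names.
* The allocator's scope is sparse profiles; dense feasible profiles can be
  rejected with a search-budget error.
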