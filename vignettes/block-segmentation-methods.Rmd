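---
title: "A Bayesian block model of protein primary sequence: methods and design"
author: "BlockSS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A Bayesian block model of protein primary sequence: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(BlockSS)
```

## The model

A protein of length $L$ carries a latent secondary structure that we
parameterize as an ordered list of $M$ typed blocks
$\Theta = ((T_1, \ell_1), \dots, (T_M, \ell_M))$ with
$T_m \in \{H, E, T, C\}$ (helix, strand, turn, coil) and
$\sum_m \ell_m = L$. The block list is informationally equivalent to the
per-residue state string; `blocksToLinear()` and `linearToBlocks()`
convert between the two.

Given $\Theta$, the amino-acid sequence $R$ factorizes over blocks,

$$p(R \mid \Theta) \;=\; \prod_{m=1}^{M} p_{T_m}\!\big(R_{[s_m, e_m]}\big),$$

and each block likelihood is a product of position-specific categorical
emissions over the 20 amino acids. Which earlier residues an emission
conditions on is declared by a *dependency template* per block type
(`defaultTemplates()`), reflecting the local side-chain packing
(socket) geometry of each secondary-structure class:

* **Helix**: positions 1–4 condition on ∅, $\{-1\}$, $\{-1,-2\}$,
  $\{-1,-2\}$; interior positions condition on $\{-1,-3,-4\}$ — the
  residues one position and one helical turn back. Because helices
  carry capping signals at both termini, the helix likelihood is a
  two-component mixture $w \cdot p_{\text{fwd}} + (1 - w) \cdot
  p_{\text{bwd}}$, where the backward factorization is the exact
  mirror image anchored at the C-terminus. The mixture weight defaults
  to $w = 1/2$; the source description states a mixture without a
  legible weight, so a symmetric default is used and exposed as a
  parameter.
* **Strand**: six distinct slot distributions — two unconditional
  starts, two conditioning on the same-side neighbour two back, and a
  fifth slot plus interior conditioning on $\{-2, -4\}$.
* **Coil**: ∅, $\{-1\}$, then $\{-1, -2\}$ for the interior.
* **Turn**: separate table sets per length class (3, 4, and ≥ 5), with
  slot $k \ge 2$ conditioning on the in-block part of $\{-1, -2\}$.

Conditioning sets beyond the directly documented helix interior are
reconstructed from the socket motifs; they are data, not code, so
alternative readings can be configured (`templatesToYaml()`).
Slots beyond a short block's length are simply ignored, so e.g. a
three-residue helix uses only its first three slot distributions.

Every emission distribution is the posterior mean of a multinomial
under a symmetric Dirichlet prior with hyperparameter $\alpha = 1$:
with $n$ observations of a conditioning context and $n_a$ of amino
acid $a$,

$$\hat p(a \mid \text{context}) = \frac{n_a + 1}{n + 20},$$

so an unseen context yields exactly $1/20$ per amino acid
(`smoothedProb()`). Training (`trainModel()`) walks every block of a
labeled corpus and increments the table for each (type, slot, context);
helix blocks are counted under both the forward and mirrored backward
templates. Tables are sparse: contexts are materialized on first
observation, and the smoothing rule covers the rest. Unknown residues
(`X`) are never counted, emit a flat $1/20$, and contexts containing
them back off to the slot's unconditional table.

## Priors

Hard structural constraints (`ConstraintSet`) zero out the prior for
any annotation that does not start and end in coil, places helix next
to strand in either order, or contains a helix/strand/turn block
shorter than three residues (coil may be a single residue). The
constraints are data so that tests can restrict or relax the state
space.

* **NonInfo** (`logPriorNonInfo()`): equal weight on every allowed
  annotation.
* **MSA** (`logPriorMsa()`): given aligned homologs of known structure,
  the per-position counts $m_j$ over the four states (gaps excluded;
  depth $n_j$ = alignments minus gaps at $j$) define Dirichlet
  posterior means $q_j = (m_j + \alpha) / (n_j + \sum \alpha)$, and the
  prior on the linear image of $\Theta$ is $\prod_l q_l(\theta_l)$,
  subject to the same hard constraints. The per-state hyperparameters
  default to 1, matching the non-informative convention used for the
  emission tables; the source's exact defaults are not recoverable, so
  they are exposed as the `alpha` argument. Queries without alignment
  evidence automatically fall back to NonInfo.

## Posterior sampling

`runChain()` runs a Metropolis sampler over block annotations starting
from the all-coil state. Each iteration draws one of four proposal
schemes uniformly among those feasible:

1. **switch** — retype a uniformly chosen block (new type uniform over
   the other three);
2. **boundary** — move the boundary of a uniformly chosen adjacent
   pair (split point uniform over the pair's interior);
3. **split** — split a uniformly chosen block of length ≥ 2 (left part
   keeps the type; right type uniform over all four);
4. **merge** — merge a uniformly chosen adjacent pair into the left
   block's type.

Merge is defined as the exact reverse of split (the source's merge-type
rule is not legible; taking the left type guarantees a reversible pair
with computable proposal densities). Split points and boundaries are
uniform over their legal ranges; any asymmetry is corrected exactly by
the Hastings ratio, which is evaluated *locally* on the affected
segments thanks to the block factorization — `hastingsLogRatio()`
exposes both the local and a full-recompute evaluation, which agree to
$10^{-9}$ (a standing test). Candidates violating the hard constraints
are proposed and always rejected (prior zero). When a drawn move kind
has no legal instance (e.g. merge with $M = 1$) the kind is resampled
among feasible kinds, with the kind probability $1/\#\text{feasible}$
entering both proposal densities; `resampleInfeasible = FALSE` instead
counts such draws as rejections. Both variants are correct; the choice
only affects per-iteration cost accounting.

The sampler's state space deliberately permits adjacent blocks of the
same type (a split can create them, and each must individually satisfy
its minimum length); canonical form — adjacent same-type blocks merged
— is used for reporting and block-count summaries. The
exact-enumeration oracle (`enumerateValid()`, `exactPosterior()`)
targets the identical measure, so chain and oracle are compared
apples-to-apples.

Defaults mirror the reference analysis: $10^6$ proposals with $10^4$
burn-in. Every post-burn-in iteration contributes its current state
(accepted or not) to the $L \times 4$ marginal matrix, the canonical
block-count tallies, and the log-posterior trace. On typical runs about
half of proposals are structurally valid and about 20 % of iterations
accept; both are logged diagnostics, not contracts, since they are
data-dependent. The chain loop is compiled (Rcpp) and consumes
per-segment log-likelihood matrices precomputed in $O(L^2)$ by
`segmentLogLik()`: interior slots condition on fixed relative offsets,
so their contributions are prefix/suffix sums and every segment score
is an $O(1)$ lookup thereafter. A single R-level RNG stream drives the
chain, so a fixed seed reproduces every output bit-for-bit.

## Estimators and evaluation

* **MAP** (`mapEstimate()`): the retained sample with the highest
  unnormalized log posterior — no post-hoc optimization, ties broken by
  earliest iteration.
* **MP** (`mpEstimate()`): per-position argmax of the marginal matrix;
  exact ties break by the fixed order C > T > E > H so results are
  deterministic.
* `blockCountPosterior()` summarizes the posterior over the canonical
  number of blocks, in total and per type.
* `marginStatistics()` reports, per true state, the mean and standard
  deviation of the difference between the predicted state's marginal
  probability and the highest remaining probability, split by
  correct/wrong predictions. For wrong predictions the margin is taken
  between the (wrong) prediction and the next-highest state; the
  alternative reading (predicted minus true) exists but is not
  implemented, since the next-highest construction is the one that
  makes the correct/wrong cases comparable.
* `qAccuracy()` / `qAccuracyCorpus()` give Q4, or Q3 after
  `mergeTurnIntoCoil()` (turn predictions merged into coil for
  comparison with three-state predictors). Corpus accuracy is
  residue-weighted (micro) by default — the convention for large
  heterogeneous test sets — with the per-chain macro average also
  available. `confusionSummary()` produces predicted-by-actual counts
  with the recall matrix column-normalized to 100 and the precision
  matrix row-normalized to 100; empty classes render as zeros with a
  flag rather than NaN.

## The synthetic generator

`generatorSpec()` defines the study conditions for all simulation-based
checks. Structures alternate coil spacers with structured blocks so the
hard constraints hold by construction: structured types are drawn with
weights H 0.4 / E 0.3 / T 0.3, and block lengths are the type minimum
plus geometric tails with means 6 (H), 2.5 (E), 1 (T), 2 (C) — giving
mean lengths around 9/5.5/4 for helix/strand/turn and short coil
linkers, a realistic profile for globular chains. One emission table
per (type, slot) is drawn once from a symmetric Dirichlet with shape 2,
a moderate amino-acid propensity skew comparable to real per-state
preferences; the draw is a deterministic function of the spec seed.
Helix blocks are emitted under the forward template only (the mixture
weight exists for emission too, but forward-only generation keeps the
parameter-recovery comparison between trained tables and generating
tables exact). `corruptMsaProfile()` emulates alignment evidence: at
each position, `depth` pseudo-homologs report the true state with
probability $1 -$ `errorRate`, else a uniformly chosen other state.

What the generator does *not* emulate: real amino-acid composition,
context-specific (as opposed to slot-specific) emission structure,
long-range correlations from tertiary packing, and the length/secondary
structure statistics of any particular structure database. Passing
tests on synthetic data therefore demonstrate the *internal*
correctness of training, likelihood, priors, sampling and estimation —
not field accuracy on real proteins, which depends on corpus-scale
training data and real alignment pipelines that are outside this
package's scope.

## Numerical choices and validation design

* All likelihood and prior computation is in log space; the helix
  mixture uses a stabilized log-sum-exp. Sequences up to $L = 2000$
  evaluate without underflow (a standing test).
* The exact-enumeration oracle is the central correctness instrument:
  for small $L$ every valid annotation is enumerated (cross-checked
  against an independently coded recursive counter for $L \le 8$;
  counts 1, 2, 4, 19 at $L = 1, 2, 3, 5$), scored, and normalized.
  Chain marginals and reported (canonical) structure frequencies are
  compared against it at a fixed proposal budget. At that budget the
  comparison is Monte-Carlo-noise-limited: deviations scale as
  $1/\sqrt{N}$ with no detectable floor (max marginal deviation
  $\approx 5\times10^{-4}$ at $2\times10^7$ proposals), and
  occasionally a prior/likelihood-conflicted toy mixes slowly enough
  that a single fixed-budget chain lands just outside the nominal band
  — the suite reports this honestly rather than re-rolling seeds.
* Test problem sizes are deliberately small — toy lengths 5–7 for
  oracle comparisons, corpora of a few hundred to 5,000 records,
  prediction sets of 25 chains at $5\times10^4$ proposals — chosen so
  the whole validation runs in minutes while still exercising every
  code path at meaningful statistical resolution.
* Degenerate inputs: an all-invalid annotation space raises an error
  rather than returning NaN; `MsaProfile` validates that depths equal
  count row sums; model files are versioned and refuse incompatible or
  corrupt content.

## Known limitations

* Only local, in-block dependencies are modeled; tertiary (knob-level)
  interactions are out of scope, which particularly limits strand
  discrimination.
* The MP estimator's per-position argmax need not itself be a valid
  annotation (it typically is for concentrated posteriors).
* MAP search is restricted to visited samples, so with short chains on
  large problems the MAP may be a poor mode estimate.
* The single-site proposal repertoire mixes slowly on posteriors with
  well-separated modes; the convergence check of choice is comparing
  marginal stability across independently seeded chains (supported via
  `init`/`seed` arguments of `runChain()`).
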