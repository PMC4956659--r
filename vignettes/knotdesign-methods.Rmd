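---
title: "Designing pseudoknotted RNA by defect-weighted sampling: models and methods"
author: "knotdesign"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing pseudoknotted RNA by defect-weighted sampling: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(knotdesign)
```

## The problem

Inverse RNA folding asks for a sequence $\phi = \phi_1\ldots\phi_n$,
$\phi_i \in \{A,U,G,C\}$, whose thermodynamic ensemble is dominated by a
prescribed secondary structure $\tau$. Most designers ignore pseudoknots —
crossing base pairs between a loop and positions outside it — although
pseudoknots stabilize the functional fold of many catalytic and regulatory
RNAs (hammerhead and glmS ribozymes, SAM-II and SAH aptamers, viral
frameshift elements). `knotdesign` supports the *two-page* structure
class: pair sets that split into two internally non-crossing pages,
written with round (page 1, nested) and square (page 2, non-nested)
brackets. A structure $\tau$ is a set of pairs $(i,j)$, $1 \le i < j \le
n$, $j \ge i + 3$ (so every hairpin loop keeps at least two unpaired
bases), with each position in at most one pair.

Two pairs $(i,j)$ and $(k,l)$ *cross* iff $i < k < j < l$. The crossing
graph is 2-colored deterministically: pairs are visited in lexicographic
order, the 5'-most pair of each connected component is put on page 1, and
parity propagates along crossing edges. A non-bipartite crossing graph
(odd crossing cycle) lies outside the supported class and is rejected —
the same kind of class filter that a two-page folding engine imposes on
input data sets. `twoPageSplit()` implements this; `isTwoPage()` is the
predicate form used by the `filter` command.

## Equilibrium model

For a sequence $\phi$ and structure $\tau$ the free energy is additive:

$$\Delta G(\phi, \tau) \;=\; \sum_{(i,j)\in\tau} e\big(\phi_i,\phi_j\big)
\;+\; s \cdot \#\{\text{stacked pair adjacencies}\}
\;+\; p \cdot \#\{\text{page-2 pairs}\},$$

with pair-class energies $e(A\!-\!U) = -2.0$, $e(G\!-\!C) = -3.0$,
$e(G\!-\!U) = -1.0$ kcal/mol (orientation ignored), a stacking term
$s = -2.0$ kcal/mol for every pair $(i,j)$ whose neighbor $(i+1, j-1)$ is
also paired, and a pseudoknot penalty $p = +0.5$ kcal/mol per page-2
pair. The open chain has $\Delta G = 0$. The temperature is
$T = 310.15\,$K, so $k_BT = 0.0019872 \times 310.15 \approx 0.6163$
kcal/mol.

The stacking term deserves a comment, because it is the one place where
this package departs from the plainest possible pair-additive model. We
implemented the pairs-only model first and measured the best achievable
normalized ensemble defect by exhaustive search: about $0.10$ for a 12-nt
hairpin and $0.35$ for a 20-nt pseudoknot. The reason is structural:
without cooperativity, every register-scrambled matching of the same
letters is isoenergetic with the intended helix, the equilibrium ensemble
stays diffuse, and *no* sequence can reach a defect target such as
$N \le 0.05$ — the designer's stop condition would be unsatisfiable by
physics, not by algorithm. A single stacking increment per adjacent pair
of pairs is the minimal cooperative ingredient that lets contiguous
helices dominate scrambles; its magnitude sits inside the measured range
of nearest-neighbor stack free energies. With it, the same exhaustive
search reaches floors below $10^{-3}$. Setting `stackEnergy = 0` in
`energyModel()` recovers the pairs-only model exactly.

Over the ensemble $\Gamma$ of all admissible structures the partition
function, equilibrium probability, and augmented pair-probability matrix
are

$$Q(\phi) = \sum_{\tau\in\Gamma} e^{-\Delta G(\phi,\tau)/k_BT},\qquad
p(\phi,\tau) = \frac{e^{-\Delta G(\phi,\tau)/k_BT}}{Q(\phi)},\qquad
P_{i,j}(\phi) = \sum_{\tau\in\Gamma} p(\phi,\tau)\, S_{i,j}(\tau),$$

where $S(\tau)$ is the structure matrix augmented by an unpaired column
$n+1$, so the rows of both $S$ and $P$ sum to one. Each ensemble
structure's pairs are split by its own deterministic page assignment:
page-1 contributions accumulate into the nested matrix $P'$ and page-2
contributions into the non-nested matrix $P''$, with $P' + P'' = P$
elementwise. Note a subtlety that follows from the definition: a helix
that is non-crossing *within a particular ensemble structure* counts as
nested there even if the design target places it on page 2.

## Backends

* `exact` (default): exhaustive enumeration of the two-page ensemble in
  compiled code. Bipartiteness is maintained incrementally by a
  union-find with parity and rollback, so non-two-page branches are
  pruned as soon as they arise; the canonical page split is recomputed at
  each leaf. Cost is proportional to the number of structures, which
  grows exponentially: roughly $10^5$–$10^6$ structures near 20 nt,
  $10^7$ near 26 nt, beyond $10^8$ at 30 nt for arbitrary sequences.
  The `maxLength` and `maxStructures` guards make the cost explicit.
* `nested`: an $O(n^3)$ two-state inside recursion for the
  pseudoknot-free partition function
  ($Z^b(i,j) = q(i,j)\,[Z(i{+}1,j{-}1) + (s^* - 1) Z^b(i{+}1,j{-}1)]$ with
  $s^* = e^{-s/k_BT}$, the stack-aware pair state) and an $O(n^4)$
  outside recursion for pair probabilities. Values agree with nested-only
  enumeration to $10^{-9}$ relative; the dual route is tested, not
  assumed.
* `nupack`: a feature-gated adapter that shells out to an external
  pseudoknot-capable engine and parses its pair-probability triples. The
  triple format carries no page marker, so the $P'/P''$ split is only
  available when a fourth column provides it — an adapter limitation
  documented in `?parseNupackPairs`.

Boltzmann weights are accumulated unshifted; the enumerator refuses
models/lengths whose most favourable structure would overflow a double
(far beyond any enumerable problem). MFE ties within $10^{-9}$ kcal/mol
are broken by the lexicographically smallest dot-bracket string, making
`mfeStructure()` deterministic.

## Quality metrics

With $S(\tau)$ the augmented structure matrix:

* ensemble defect $n(\phi,\tau) = n - \sum_{i,j} P_{i,j} S_{i,j}$ and its
  normalization $N = n(\phi,\tau)/n$ — the expected number (fraction) of
  incorrectly paired nucleotides at equilibrium;
* probability defect $\pi = 1 - p(\phi,\tau)$;
* Boltzmann frequency $B_f = e^{-\Delta G(\phi,\tau)/k_BT}/Q$, which is
  algebraically identical to $p(\phi,\tau)$; the package computes one
  quantity and reports it under both names;
* MFE defect $\mu$: the per-position structure Hamming distance between
  the predicted MFE structure and the target (unpaired vs paired
  disagrees; different partners disagree once per endpoint), so $\mu = 0$
  exactly when the MFE structure *is* the target — the success criterion;
* sequence identity $S_{id}$: the mean over unordered distinct pairs of
  sequences of the fraction of identical positions. The printed form of
  this statistic sums over the full Cartesian square without an outer
  normalization; we average over distinct pairs so that $S_{id} \in
  [0,1]$ and lower still means more diverse.

If $\pi < 0.5$ the target holds more than half of the ensemble's mass, so
it must be the modal — hence MFE — structure and $\mu = 0$. This
modal-structure implication is asserted over enumerable fixtures in the
tests.

## The sampler

`designSequence()` implements adaptive defect-weighted sampling:

1. **Seed.** A random sequence compatible with the target: paired
   positions are drawn jointly as pair types, template-locked positions
   are copied verbatim, and unconstrained positions approximate the
   requested GC fraction (drawn uniformly from $[0.20, 0.80]$ per seed
   when unset).
2. **Iterate** until $N \le f_{stop}$ or `maxIt` iterations: select one
   of the applicable mutation operators uniformly at random, mutate,
   re-evaluate $P, P', P'', N, \pi$ through the backend.
3. **Report** the fittest (lowest-$N$) candidate seen anywhere in the
   run, with its metrics and the full per-iteration trace.

The operators weight mutation by positional defect contribution:

* *single nucleotide*: draw random unpaired positions, skip locked ones,
  accept position $i$ with probability $1 - P_{i,n+1}$, then replace its
  base uniformly among the three alternatives;
* *base pair*: draw random target pairs; both-ends-locked pairs are
  skipped; one-end-locked pairs mutate only the free end — immediately,
  without a probability gate — to a base that still pairs with the locked
  end; fully free nested pairs are accepted with probability
  $1 - P'_{i,j}$ and redrawn from the orientations A-U, G-C, G-U, while
  non-nested pairs are accepted with probability $1 - P''_{i,j}$ and
  redrawn from all six orientations. The asymmetric orientation alphabet
  follows the published operator verbatim; because seeds and the
  six-orientation non-nested moves reach every orientation anyway, the
  restriction is kept as the default, with
  `allNestedPairTypes = TRUE` available as a switch.
* *adaptive m-mutation*: draw
  $m = \max\!\big(1, \lfloor\,|\mathcal N(m', m'/5)|\,\rfloor\big)$ with
  $m' = N\,n/C$ (default $C = 5$), then make random calls to the two
  operators above until exactly $m$ counted positions are mutated — a
  pair call counts 2 even when only one base actually changes, and the
  guard at count $m-1$ forces a single-nucleotide call, so the count ends
  exactly at $m$. Mutation intensity therefore shrinks as the design
  approaches the target.

Degenerate-case choices, made once: operators are selected uniformly over
the *applicable* subset (a target with no unpaired positions excludes the
single-nucleotide operator, one with no mutable pair excludes the pair
operator) since a blind uniform draw over all three would deadlock;
acceptance loops fall back to ungated uniform position choice after
`retryCap` (default $100n$) rejected draws, which only triggers when the
defect is already near zero; "redraw until different" is implemented as a
uniform draw over the alternatives excluding the current assignment,
which is the loop-free equivalent; and a one-end-locked pair whose locked
base admits only the current partner base (locked A or C) is treated as
immutable rather than returned unchanged, preserving the invariant that
every operator call changes at least one position. Within the m-mutation
loop, when the required operator has no mutable site the other operator
substitutes, so the counted total can exceed $m$ by one in that corner
case only.

RNG discipline: a design run seeds R's generator once from its config;
trial $l$ of `runDesignTrials()` uses `seed + l`. Every stochastic
choice draws from that stream, so results are bit-reproducible.

## Synthetic targets

`randomTwoPageStructure()` generates H-type-like layouts: the nested
pairs form one or two contiguous helices and the page-2 pairs one
contiguous helix crossing the first stem — the dominant topology of
natural pseudoknot collections. Contiguity is not cosmetic: under the
stacking model, isolated single pairs are thermodynamically marginal, so
scattered-pair targets are unrealistic as design goals in the same way a
one-basepair "helix" is unrealistic in nature. The `paperlike` suite (20
targets, 21–35 nt) emulates a natural pseudoknot collection at reduced
length for structure-level work; `convergenceSuite()` (20 targets,
15–17 nt, 3–4 bp stem + 3 bp pseudoknot helix) is the set used for the
design-convergence and ablation studies, sized so that one exact-backend
evaluation costs tens of milliseconds and a full 400-iteration trial
stays in the seconds range. What passing those studies shows is that the
sampler converges on realistic desk-scale pseudoknots under an exact
ensemble; it does not show performance under nearest-neighbor energies or
at natural lengths (21–140 nt), which require an external
partition-function engine.

The bundled 85-nt Hammerhead fixture carries the conserved-motif template
`oooooooooooooooCCUGAUGAG…` with 18 locked nucleotides in three blocks
(CCUGAUGAG, GCGAAA, UCG). Its printed structure source renders unpaired
runs ambiguously, so the bundled dot-bracket is a *reconstruction* —
85 nt, the 5-pair pseudoknot helix starting at position 3, conserved
blocks unpaired — and is labelled synthetic wherever it appears. At 85 nt
the exact backend cannot enumerate, so template safety is exercised by
driving the full mutation pipeline (seed, all three operators, m-mutation)
over seeded chains on the real template, plus a complete
`designSequence()` run with a locked motif on an enumerable pseudoknotted
target with per-iteration assertions (`debug = TRUE`).

## Trial summaries and comparisons

`summarizeTrials()` reports, per target, $f_k$ (trials reaching the
defect threshold, default $0.01$), the success count ($\mu = 0$), medians
of $N$, $\pi$, $\Delta G$, $B_f$ and iterations (even-length medians are
central means), and $S_{id}$. `compareMethods()` counts per-target wins
(direction inferred from the metric), drops ties, and reports the exact
two-sided sign-test p-value. Wall-clock seconds are recorded in every
result but never asserted on — they are hardware, not science.

## Known limitations

* The exact backend is exponential; arbitrary sequences beyond ~26 nt are
  out of its practical reach, and the guards make this failure explicit
  rather than silent.
* The energy model has no loop-length terms, dangles, or coaxial
  stacking; absolute free energies are not comparable to
  nearest-neighbor values.
* The two-page class is a superset of the pseudoknot class of
  partition-function engines based on the standard gap-matrix recursion,
  so class decisions made here can admit structures such an engine would
  reject; the `filter` command reports per-target decisions so users can
  cross-check.
* Multi-strand and multi-target design are out of scope.
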