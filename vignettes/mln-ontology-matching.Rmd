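---
title: "Matching anatomy ontologies with Markov logic: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Matching anatomy ontologies with Markov logic: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mlnmatch)
```

## The matching problem

Two anatomy ontologies describe overlapping parts of reality with
different vocabularies and slightly different structure.  An alignment is
a set of equivalence correspondences between their classes; a good
alignment is lexically plausible (matched classes have similar labels),
structurally consistent (it does not invent or contradict subclass
structure), coherent (it never maps a subclass pair onto a pair of
disjoint classes) and one-to-one.

`mlnmatch` encodes these desiderata as a Markov logic network: weighted
first-order formulas over observed predicates (labels, `is_a`, `part_of`,
disjointness, label similarity) and one hidden predicate, `map(c1, c2)`.
Grounding the formulas over a candidate set produces a Markov network
whose maximum-a-posteriori (MAP) state — the most probable truth
assignment of the `map` atoms — is the output alignment.  Hard formulas
(cardinality, coherence) must hold in every solution; soft formulas
(stability, propagation, the per-candidate prior) trade off through their
weights.

## A priori similarity and pruning

The similarity of two labels is `1 - d/max(len)` on normalized strings
(lower-case, underscores and hyphens to spaces, whitespace collapsed),
with `d` the Levenshtein distance (computed by `utils::adist`).  The
normalization rule is fixed by the worked anchor pair:
"Vascular_Endothelium" vs "blood vessel endothelium" normalizes to strings
at edit distance 11 with a longer length of 24, giving
σ = 13/24 ≈ 0.5417 → 0.54 — the value the package's tests pin down.
Raw-string comparison cannot produce that value, which is why
normalization precedes the distance.

Classes may carry several labels; the class-level σ is the maximum over
the label product, ties broken lexicographically so results are
deterministic.  All pairs with σ ≥ τ become candidates (inclusive
threshold, so τ = 1 is a usable exact-match mode; `inclusiveTau = FALSE`
gives the strict variant).  Pairs below τ never enter the model — their
map atoms are implicitly false — which keeps the ground model linear in
the number of plausible pairs rather than quadratic in ontology size.

## The ground model and its MAP compilation

For candidates c = (a1, a2) and d = (b1, b2):

* **Prior**: selecting c contributes +σ(c).  The weight is σ itself, not
  σ − τ (a known variant); the plain σ is the documented default because
  it is what the model's description states, and no offset option is
  second-guessed.
* **Cardinality** (hard): at most one selected candidate per class per
  side, as at-most-one constraints over each row/column group of the
  candidate matrix.  The formula's equality conclusion is implemented as
  exclusion, since distinct ids denote distinct classes.
* **Coherence** (hard): mutual exclusion of c and d when a1 ⊑ b1 and
  {a2, b2} disjoint, or {a1, b1} disjoint and a2 ⊑ b2.
* **Stability** (soft, ω ≤ 0): a conjunction term that fires when both c
  and d are selected but the subclass edge exists on one side only.
* **Propagation** (soft, ω ≥ 0): an implication term penalized when the
  child pair c is selected but the parent pair d is not, for matching
  `is_a` edges and, separately, matching `part_of` edges (a pair matched
  by both relations contributes two groundings).

The MAP objective drops grounding constants: a soft conjunction with
negative weight contributes its weight exactly when both variables are 1;
a soft implication with positive weight contributes a penalty exactly in
the antecedent-true/consequent-false state.  These transformations
preserve the argmax exactly.  `exportLp()` writes the equivalent
integer-linear program (product variables for conjunctions, penalty
variables for implications) for external inspection.

### Direct edges vs transitive closure

The formula templates say "subclass of" without fixing whether asserted
edges or their closure are meant.  The package grounds **soft** formulas
over direct edges (default `useDirectSubForSoft = TRUE`): closing the
hierarchy would multiply near-redundant soft terms along chains and make
the effective weight depend on chain depth.  **Coherence** uses the
transitive closure (default `useTransitiveSubForCoherence = TRUE`):
disjointness semantically propagates to subclasses, and a hard constraint
missed along a chain is a genuine incoherence.  Both choices are exposed
as `matchConfig()` flags.

## Parameters

| parameter | default | meaning |
|---|---|---|
| `tau` | 0.8 | candidate threshold on σ (dimensionless, (0, 1]); 0.8 maximizes F on the anatomy-style regime |
| `wStability` | −0.01 | weight per stability grounding; small relative to σ so structure breaks ties rather than vetoing lexically strong matches |
| `wPropagation` | +0.05 | weight per propagation grounding; reciprocal idea to stability, same order of magnitude |
| `enabled` / `setting` | all five | ablations: `prior`, `ca`, `ca+co`, `ca+co+st`, `ca+co+st+mp` |
| `timeLimit` | 300 s | solver budget; on timeout the best solution found is returned with status `"time-limit"` |

With σ ∈ [τ, 1] and |ω| ≪ σ, a soft clause can reorder solutions only
where the prior is nearly tied — which is precisely the regime (ambiguous
near-duplicate labels) the structural formulas are meant to arbitrate.

## Exact inference

The solver decomposes the variable interaction graph (variables linked by
a shared hard constraint or soft clause) into connected components.
Isolated variables are selected iff their prior is positive.  Each
non-trivial component is solved by depth-first branch and bound in
decreasing-σ order, 1-branch first, with the admissible bound "current
value + Σσ of undecided variables" (soft terms only subtract).  This is
exact; on matching workloads components are small — most candidates
conflict with nobody — so worst-case exponential search is not reached in
practice.  The exhaustive oracle `bruteForceMap()` (≤ 20 variables,
all-subset enumeration, lexicographic tie-break) provides the independent
check: the test suite verifies objective equality on hundreds of random
models with mixed constraints.

Numerical choices: objective comparisons in the solver use an absolute
tolerance of 1e-9 (weights are of magnitude 0.01-1, so this is far below
any real difference); between equal-objective optima the solver's
selection is deterministic given the model but not contractual — tests
compare objectives, never raw selections, unless the optimum is unique.
Degenerate inputs (no candidates, a class with no labels, empty
ontologies) yield the empty alignment with objective 0.

## The synthetic generator

`generateOntologyPair()` creates the study conditions for testing without
benchmark downloads: a random `is_a` tree (breadth-first growth, Poisson
branching, mean 2.5 children), `part_of` cross-links on 30% of classes
(anatomy ontologies use partonomy extensively), and sibling disjointness
(rate 0.15) in the first ontology only — real anatomy benchmarks declare
`disjointWith` on one side only, and the generator reproduces that
asymmetry.  The second ontology is a structural clone with fresh ids,
labels perturbed by per-character edits (substitute/insert/delete with
equal probability) and classes dropped at random; the ground truth is
exactly the surviving clone pairs.  Labels are 1-4 token phrases over an
anatomy-flavored vocabulary, unique within each ontology, written
`Title_Case_Underscore` on one side and lower-case spaced on the other so
normalization is always exercised.  Character-edit noise creates exactly
the failure modes the matcher is designed around, including
similar-in-spelling bait pairs (the "Spiral_Artery"/"sural artery" kind of
false positive).

What it does **not** emulate: the size (thousands of classes), the label
length/token distribution, synonym annotations, or the multi-parent
structure of real anatomy ontologies.  Passing tests demonstrate the
machinery is correct and that structural formulas help in this regime;
they do not certify benchmark-level scores on real data, for which the
CLI can be pointed at the real OWL files.

Default rates (5% character-edit probability, 5% drops) keep most
true pairs above τ = 0.8 while leaving enough ambiguity that the
structural formulas have work to do.  Test and acceptance runs use
100-class pairs (10 seeds for the ablation comparison) and 200 random
ground models of ≤ 15 variables for the solver-oracle equivalence; these
sizes give stable medians while keeping the whole suite around ten
seconds.

## Evaluation conventions

Correctness is exact (id1, id2) membership in the reference; only
equivalence cells of OAEI alignment files are scored (others are dropped
with a warning).  An empty computed alignment has precision 0 by
convention — pessimistic, and it keeps F-measure defined as 0 rather than
undefined.

## Known limitations

* Lexical anchoring only: no synonym lexicon expansion; classes whose
  labels differ beyond τ are unreachable even when structure supports
  them (the "Tarsal_Plate"/"eyelid tarsus" kind of false negative).
* Equivalence only — no subsumption correspondences, no n:m cardinality,
  no property correspondences.
* Weights are set, not learned; the model deliberately exposes them as
  plain parameters.
* No OWL reasoning: subsumption is taken as asserted (plus transitive
  closure where configured), not inferred.
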