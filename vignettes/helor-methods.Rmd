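---
title: "Probabilistic research statements and the two reasoning engines"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Probabilistic research statements and the two reasoning engines}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(helor)
```

`helor` treats the probability of a research statement as a first-class,
recorded quantity rather than an implicit judgement. This vignette explains
the representation, the two reasoning engines built on it, the synthetic
data the package uses to exercise them, and the numerical and design
choices a user should know about.

## Research statements

An atomic statement is `PREDICATE(entity_i, entity_j)` — a relation between
two ontology-style entities, e.g. `regulates(SIRT1, human_life_span)`.
Atoms combine with AND, OR, NOT, IMPLIES and IFF into compound statements of
arbitrary depth, and a research statement wraps an expression with a role
from the statement hierarchy: research hypothesis, assumption, conclusion,
scientific law (production rules are laws with an IMPLIES expression), or
theorem.

Three semantics decisions matter in practice:

* **Identity is structural.** Two statements are equal when their
  connectives, operands and atom fields agree; operand order is ignored for
  the commutative connectives AND and OR (display order is preserved).
  Structural identity is what lets a knowledge base deduplicate statements
  arriving from different sources.
* **The logic is propositional.** Quantified prose such as "all genes with
  lactase activity" is not modelled; generality is expressed only by
  substituting an entity with a more generic parent class
  (`substitute_entity()`), which is how the worked examples use it. This
  keeps `evaluate_statement()` decidable by plain truth-table semantics,
  which the test suite verifies exhaustively against an independent
  enumeration oracle for all formulas of up to four atoms.
* **Entities are lightweight.** They carry an id, label, optional source
  ontology tag and optional parent id; resolving real ontology IRIs and
  description-logic reasoning are out of scope.

Statements render to and parse from a plain-text syntax
(`predicate(subject, object)` with parenthesised connectives), and the
parser/renderer pair round-trips exactly.

## Probability records and evidence

Every probability is a record: a value in [0, 1], a kind (prior or
posterior), the estimation method (Bayesian inference, expert estimation,
statistical calculation, deduction, abduction, induction, or homological
inference), an ISO-8601 timestamp, an optional procedure note, and an
optional link to the evidence item that triggered it. Trajectories are
append-only — an update never overwrites history — because the point of the
representation is to audit how a belief moved, not just where it is.
Timestamp ties are broken by insertion order, so replays are deterministic.

Evidence items attach to statements through `supports`, `refutes` and
`disputes` links. `disputes` is deliberately metadata-only: no quantitative
rule for it is defined, so it never changes a value.

### Homological inference

Much biological argument runs through model organisms: evidence about a
yeast or nematode ortholog bears on the human hypothesis. The package
encodes this as weighted homology links and a deliberately simple transfer
rule. When the source hypothesis's probability moves from `p_s_old` to
`p_s_new`, the target gains a posterior record

```
p_t_new = clip(p_t + w * (p_s_new - p_s_old), 0, 1)
```

with method `homological_inference`. The rule was chosen for being
monotone (the target moves in the source's direction whenever `w > 0` and
no clipping occurs), bounded, and auditable — the record stores the weight
and source hypothesis in its procedure note. The weight defaults to 0.5 per
link and is configurable; nothing deeper than "half-weight transfer from a
model organism" is claimed for it. `homological_update()` also appends the
source's new record, so both trajectories remain complete — an update that
silently consumed the source's change would break the audit trail.

The sirtuin fixture exercises this machinery on a real argument: h1 ("SIRT1
regulates human life span") sits at an expert posterior of 0.8 after the
2001 nematode result; the 2011 refutation in worm and fly lowers the
C. elegans hypothesis h2 and drags h1 down through its homology link; the
2012 male-mouse result supports the mouse hypothesis h4 and raises h1
again. Only the 0.8 value is anchored; the 2011/2012 steps assert direction
of change, not particular numbers. The fixture also includes the mouse
hypothesis h4 alongside h2/h3 because the 2012 evidence concerns the mouse
ortholog — routing it through the already-refuted nematode hypothesis would
misattribute the support. The near-1.0 record produced by literature
counting is attached to the yeast hypothesis h3, which is the hypothesis
the counted SIR2 sentences are about.

## Engine 1: hypothesis sets, elimination, Bayes, information gain

A hypothesis set is mutually exclusive and exhaustive: probabilities sum to
1, enforced to a tolerance of 1e-9 with an explicit renormalization after
every operation so floating-point drift cannot accumulate. Sets are
immutable values; each operation returns a new set.

* `eliminate()` removes rejected members and renormalizes — the mechanism
  behind experiment cycles that end with one hypothesis at posterior 1.
* `bayes_update()` multiplies priors by the observed outcome's likelihoods
  and renormalizes. Elimination is its special case with indicator
  likelihoods, and the suite tests that equivalence directly.
* `expected_information_gain()` is the expected entropy reduction
  `H(set) − Σ_o P(o) H(set | o)` in bits, with `0·log 0 = 0`.
* `select_experiment()` ranks candidates by gain per unit cost,
  `gain / (cost + 1e-9)`, ties broken by candidate order. The historical
  system's true multi-criteria policy is not documented, so the package
  implements the simplest policy honoring its three stated ingredients —
  hypothesis probabilities, compound cost, information gain — as a clearly
  replaceable strategy; the epsilon merely guards a free experiment against
  division by zero.

The elimination fixture supplies 8 gene-deletion hypotheses at uniform
prior 1/8 and a three-cycle rejection schedule (3, 2, 2 hypotheses). The
number rejected per cycle in the historical run is not documented, so the
schedule is illustrative; what the replay asserts — uniform 1/8 start,
survivors' probabilities rising every cycle, a single survivor at exactly
1 — is the documented behaviour.

## Engine 2: GP active k-optimization

The screening loop bootstraps by measuring 10 randomly chosen compounds,
then iterates: fit the surrogate to all measurements, predict every
untested compound, score candidates with the selection strategy, measure
the top scorer. The surrogate is a Gaussian process with a
squared-exponential kernel, one length-scale shared across feature
dimensions, and observation noise:

```
k(x, x') = a² exp(−‖x − x'‖² / (2ℓ²))
```

Responses are centered on their mean before fitting, so far from data the
predictive mean reverts to the training mean and the standard deviation to
the amplitude `a`. Defaults: `ℓ = 0.2` on the unit-cube feature scale
(about the width of the synthetic activity bumps), `a = sd(y)`
(data-driven), `noise_sd = 0.1` (the default library's measurement noise),
and a diagonal jitter of 1e-8. The jitter is the smallest value that keeps
Cholesky factorization stable while letting noiseless fits interpolate
their training data to ~1e-6; dense noiseless designs at this length-scale
are inherently ill-conditioned, so interpolation accuracy degrades beyond
roughly a dozen tightly packed points regardless of jitter. Setting
`optimize = TRUE` in `gp_control()` refits amplitude, length-scale and
noise by L-BFGS-B on the log marginal likelihood; the default keeps them
fixed because the loop refits the surrogate at every iteration and the
fixed values are well matched to the generator (and the comparison of
selection strategies, the quantity of interest, is insensitive to modest
hyperparameter misfit).

Acquisition functions use the closed Normal forms (MPI `Φ((μ − y₍ₖ₎)/σ)`,
MEI `(μ − y₍ₖ₎)Φ(z) + σφ(z)`, optimistic `μ + βσ`). The cited
confidence-bound criterion is a *lower* bound for minimization; activities
here are maximized, so the optimistic score adds `βσ` (default `β = 2`),
preserving the optimism-under-uncertainty semantics. `y₍ₖ₎` is the k-th
largest measured value so far, bootstrap included. At `σ = 0` the
point-mass limits are used directly (indicator for MPI, hinge for MEI) —
never a division. Acquisition ties break toward the lowest compound index,
and a measured compound is never scored again, so runs are fully
deterministic given a seed.

Per iteration the run records the selected compound's probability of
beating the best bootstrap measurement (P1), of beating the current k-th
best (P2), and the maximum such probability over the remaining library
(P3). The random strategy never consults the surrogate, so its records
carry `NA` probabilities.

## Synthetic libraries: what they emulate and what they do not

`gen_compound_library()` stands in for a real screening collection:
features uniform on `[0, 1]^d`, latent activity a baseline plus a sum of
Gaussian bumps, plus Normal measurement noise. The default
(`default_library_spec()`) uses n = 500 compounds, d = 2, three bumps of
heights 3.0/4.5/2.5 and widths 0.12/0.10/0.16 over baseline 4, noise 0.1 —
activities spanning roughly 4–8.5 on a pGI50-like scale, with one global
optimum and two decoy modes, sized so that informed strategies separate
from random selection within a 60-measurement budget averaged over 20
repetitions. These values were fixed once as a desk-scale analogue of a
large tumour-cell-line screen and are not tuned per experiment.

What passing on this generator shows: the surrogate-plus-acquisition loop
exploits smooth structure and beats unguided sampling. What it does not
show: performance on real chemical descriptor spaces, which are
high-dimensional, discontinuous and heteroscedastic, where kernel and
featurization choices dominate. The generator also makes measurement a
deterministic lookup of one noisy value per compound — there are no repeat
assays, batch effects, or censoring.

`compare_strategies()` repeats the loop over per-repetition seeds (library
and bootstrap shared across strategies within a repetition, so strategies
differ only in their selection rule) and averages 20 repetitions, the
replication count of the original computational experiments; the suite's
acceptance check asserts that random selection's mean best-found activity
at budget 60 is strictly the worst of the four strategies. The full
original study (59 tumour cell lines, tens of thousands of real compounds)
is not reproducible without external data; this property is the desk-scale
surrogate for its headline qualitative finding.

## Serialization

The knowledge base serializes to JSON with fixed key order (byte-identical
double export) and arrays for entities, statements, evidence, links,
homology links, probability records and hypothesis sets. Each record
carries a `helo_class` string naming its ontology class ("prior
probability", "expert estimation", …) so documents remain alignable with
the OWL vocabulary without the package serving OWL itself, and an
`@context` points at the ontology's public repository. Import revalidates
everything: unknown relations, out-of-range probabilities and dangling ids
are hard errors naming the offender; an unrecognized `helo_class` is a
warning only. Statement expressions serialize as their plain-text
rendering, which parses back to a structurally equal expression.

## Problem sizes and determinism in the test suite

The suite's heavier checks use: 1,000 random operation sequences for
probability-mass conservation; a 5×5×3 grid of (μ, σ, y₍ₖ₎) cells with 10⁶
Monte-Carlo draws per cell for the acquisition functions (held to 3
standard errors per cell, with an explicit multiplicity allowance of at
most 3 of the 150 comparisons between 3 and 5 SE — the expected behaviour
of a correct implementation under that many 3-SE tests — and quadrature
agreement to 1e-6 for MEI); 10 random 1-D problems against a direct
`solve()`-based GP oracle at 1e-8; and the 20-repetition, budget-60
strategy comparison. All randomness is seeded; every test is deterministic.

## Known limitations

* Homological transfer is linear-with-clipping by design; it is not a
  calibrated probabilistic model of cross-species evidence.
* The propositional statement model cannot express quantified laws; parent
  -class substitution is the only generalization mechanism.
* The GP uses one shared length-scale; strongly anisotropic feature spaces
  would need per-dimension scales the package does not currently fit.
* `select_experiment()`'s gain-per-cost policy is a stated stand-in for an
  undocumented multi-criteria policy, exposed so it can be replaced.
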