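# helor

Scientific knowledge is uncertain, and the probability that a research
hypothesis is true changes every time new evidence arrives. `helor` is an R
toolkit for making that bookkeeping explicit and computable, following the
HELO (HypothEsis and Law Ontology) scheme: research statements are logical
expressions over ontology-style entities, each statement carries an
append-only trajectory of timestamped probability records — prior or
posterior, together with the estimation method that produced them (Bayesian
inference, expert estimation, statistical calculation, deduction, abduction,
induction, homological inference) — and statements are linked to the
evidence items that support, refute, or dispute them.

On top of that record-keeping sit two reasoning engines:

* **Eliminative / Bayesian updating over hypothesis sets.** A hypothesis set
  is mutually exclusive and exhaustive, with probabilities summing to 1.
  Experiment cycles reject hypotheses (`eliminate()`) or reweight them with
  Bayes' rule (`bayes_update()`, posterior ∝ prior × likelihood), and the
  next experiment can be chosen by expected information gain per unit cost
  (`expected_information_gain()`, `select_experiment()`), in the style of
  the Robot Scientist's automated auxotrophic-experiment cycles.

* **Gaussian-process active k-optimization.** To find the *k* most potent
  compounds in a library with few assays, a GP surrogate (squared-exponential
  kernel) is fitted to the measured activities (pGI50-like; higher = more
  potent) and predicts a Normal distribution N(μᵢ, σᵢ²) for every untested
  compound. Candidates are scored by most probable improvement
  MPI = Φ((μ − y₍ₖ₎)/σ), maximum expected improvement
  MEI = (μ − y₍ₖ₎)Φ(z) + σφ(z), the optimistic confidence bound μ + βσ, or
  chosen at random, where y₍ₖ₎ is the current k-th best measured activity.

The package is aimed at researchers who want reproducible, auditable
probabilistic reasoning over hypotheses — robot-scientist style experiment
loops, evidence-timeline arguments, or budgeted compound screening on
tabular QSAR data.

## Worked example: the sirtuin hypothesis timeline

```r
library(helor)

kb <- sirtuin_fixture()
probability_trajectory(kb, "h1")[, c("value", "kind", "method", "timestamp")]
#> # A tibble: 4 × 4
#>   value kind      method                timestamp
#>   <dbl> <chr>     <chr>                 <chr>
#> 1  0.5  prior     expert_estimation     2000-01-01
#> 2  0.8  posterior expert_estimation     2001-03-08
#> 3  0.55 posterior homological_inference 2011-09-22
#> 4  0.7  posterior homological_inference 2012-02-23
```

h1 is "SIRT1 regulates human life span". The 2001 nematode lifespan result
leads an expert to 0.8; the 2011 refutation in worm and fly lowers the
model-organism hypothesis and, through a weight-0.5 homology link, drags
P(h1) down to 0.55; the 2012 male-mouse support pushes it back up to 0.70.
`plot_probability_trajectory(kb, "h1")` draws the timeline.

## Worked example: hypothesis elimination

```r
fx <- aaa_fixture()                       # 8 gene-deletion hypotheses, prior 1/8
replay <- replay_elimination(fx$set, fx$cycles, kb = fx$kb)
replay$set
#> # A tibble: 1 × 2
#>   member      prob
#>   <chr>      <dbl>
#> 1 aaa_h_ARO1     1
```

Each cycle rejects hypotheses inconsistent with the observed growth
phenotype and renormalizes the survivors; after the last cycle the surviving
hypothesis has posterior 1 and all others 0.

## Worked example: active compound screening

```r
lib <- gen_compound_library(default_library_spec(seed = 3))  # 500 compounds
run <- run_active_optimization(lib, "mei", k = 1, budget = 60, seed = 3)
glance(run)
#> # A tibble: 1 × 7
#>   strategy     k budget bootstrap_n  seed best_found kth_best_found
#>   <chr>    <dbl>  <dbl>       <dbl> <int>      <dbl>          <dbl>
#> 1 mei          1     60          10     3       8.41           8.41
```

Here 8.41 is also the library's true maximum activity: MEI located the best
compound within 60 of 500 measurements. `compare_strategies()` repeats this
over seeded libraries (20 repetitions by default) and shows random selection
trailing every informed strategy; `autoplot()` on the result plots mean best
activity against the measurement budget.

A command-line front end covering the same operations
(`record-statement`, `add-evidence`, `attach-prob`, `trajectory`,
`demo-adam`, `demo-sirtuin`, `activelearn`) is installed at
`system.file("cli", "helo.R", package = "helor")`.

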