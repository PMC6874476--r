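---
title: "Methods: enumerating and classifying the states of a multi-nutrient chemostat community"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: enumerating and classifying the states of a multi-nutrient chemostat community}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chemostates)
```

## The model and its assumptions

`chemostates` models a well-mixed chemostat supplied with `K` carbon and `M`
nitrogen metabolites at fixed rates `φ`, diluted at rate `δ`, and colonised
from a pool of `S` specialist species. Each species uses exactly one
metabolite of each class; its growth rate follows Liebig's law of the minimum,
`g = min(λ^(c) c, λ^(n) n)`, so at any moment exactly one of the two resources
limits growth (ties are measure-zero for generic parameters and are refused a
label rather than broken arbitrarily). Yields `Y^(c)`, `Y^(n)` convert
consumed resource to biomass; their ratio is the species' C:N stoichiometry.

Assumptions worth keeping in mind:

* linear (non-saturating) growth in the limiting concentration — no Monod
  half-saturation, no maintenance cost or death rate;
* specialists only — no species consumes two metabolites of the same class;
* a fixed pool — no mutation, migration beyond the pool, or cross-feeding.

A *community state* is the set of surviving species together with each one's
limiting nutrient; abundances are not part of the label. Two assignments that
differ only in which nutrient limits one species are different states.

## The high-supply regime

All enumeration and feasibility work is done in the regime `φ ≫ δ²/λ`, where
the steady-state concentration `δ/λ` of any limiting nutrient is negligible
against its abiotic level `φ/δ`. The defaults hard-wire this: `δ = 1`,
`λ ∈ [10, 100]`, supply box `[10, 1000]`, so `max(δ²/λ) = 0.1 ≪ 10`;
`model_config()` refuses configurations that break the inequality. `δ = 1` is
the package's reference time unit — with `λ ≥ 10` it is the unique choice that
makes the default box satisfy the regime with a factor-100 margin. In this
regime the outcome of any attempted invasion depends only on the *rank order*
of competitive abilities, never on the supply rates, which is what makes
exhaustive enumeration meaningful.

## Enumeration: exclusion rules, structured search, greedy uninvadable states

Two rules restate competitive exclusion for essential nutrients: (1) each
metabolite limits at most one species; (2) every species using a metabolite
non-limitingly must have a strictly larger `λ` for it than the species it
limits. `enumerate_steady_states()` iterates over all selections of
carbon-limited species (per carbon: each consumer or nobody), eliminates
species out-competed on carbon, and enumerates the admissible nitrogen-limited
additions per nitrogen metabolite. `candidate_assignments()` materialises the
full `3^S` cube so the structured search can be checked against brute force;
the tests do this for dozens of random pools up to `S = 9`.

For uninvadable states the nitrogen completion is forced: per nitrogen
metabolite, the carbon-surviving consumer with the largest `λ^(n)` either can
be added (making that metabolite defended) or would itself invade anything
built on that carbon selection. `enumerate_uninvadable()` runs this greedy
construction over every carbon selection in compiled code — a 6×6 grid has
`7^6 = 117,649` selections and takes well under a second. Lambda ties within a
resource column would make all of this ill-defined, so tied pools are rejected
at construction instead of being broken arbitrarily. Pools need not be full
grids: several species may share a resource pair (the classic two-species
bistability setting), and `K ≠ M` is supported.

## Feasibility and structural stability

At steady state each metabolite satisfies a conservation law
`c_i + Σ B_α / Y_α^(c) = φ_i^(c)/δ`. Dropping the negligible limiting
concentrations leaves a square linear system `φ/δ = R X` per state, where `X`
stacks the abundances of present species and the concentrations of undefended
metabolites. A state is feasible at `φ` iff all entries of `X = R⁻¹ φ/δ` are
strictly positive (tolerance `1e-12` guards the boundary).
`monte_carlo_feasibility()` factorises `R` once per state and sweeps all
sampled supplies in one BLAS product; the per-state feasible fraction is the
normalised feasible range, and `classify_structural_stability()` applies the
conventional 0.1 cutoff. `solve_state(..., exact = TRUE)` keeps the `δ/λ`
terms; it is the fixed point the ODE system actually converges to and differs
from the high-supply solution by well under 1% across the default box, which
is the cross-validation the dynamic tests rely on. States with singular `R`
(feasible only on a measure-zero slice of supply space — e.g. every
maximal-richness state of an equal-stoichiometry pool, whose carbon and
nitrogen rows are proportional) are skipped with a warning.

## Dynamics and dynamic stability

`integrate_community()` wraps a BDF stiff solver (`deSolve`, `rtol 1e-8`,
`atol 1e-10`) around the growth law; integration proceeds in chunks and clamps
populations below `1e-9` to exactly zero, which keeps near-extinction
transients from stalling the solver. `classify_endpoint()` requires the
relative change of every variable over the last tenth of the window to be
below `1e-6` before labelling the endpoint.

`test_dynamic_stability()` perturbs a state's exact fixed point
multiplicatively (default 1%, 20 draws per supply point, 3 points) on the
abundances of *present* species and all concentrations — perturbing absent
species would conflate invadability with dynamic stability — and asks whether
every run returns within a relative `1e-4`. Verdicts are expected to be
supply-independent; a mixed outcome warns.

For pools too large to integrate state by state, `infer_stability()` uses the
multiplicity patterns of the Monte-Carlo record: a state that is the unique
feasible uninvadable state somewhere must be stable (every environment needs a
dynamical endpoint), and the empirical rule that `V` feasible stable states
are accompanied by exactly `V−1` feasible unstable ones repairs the remainder:
while violations exist, the potentially-unstable state implicated in the most
violating samples is reclassified stable whenever that lowers the total count,
ties broken by smallest state index (a deterministic choice the method leaves
open). Residual violations reflect finite sampling — states with tiny feasible
ranges may never receive a unique point — and are reported, not hidden; they
shrink with the sample count.

## The transition network

Red (regime-shift) edges connect stable states co-feasible at at least one
sampled supply; each edge stores its witness count. Blue (smooth-transition)
edges come from a boundary probe: a state leaves its feasible region where one
entry of `X` crosses zero — a species goes extinct *or* a free metabolite
concentration vanishes (its consumer switches limiting resource). The probe
draws the remaining entries from `U(0,1]`, sets the chosen entry to `−0.01`,
maps through the conservation laws to a supply vector just across that face,
and tests which other stable states are feasible there. Probing every `X`
entry (not only species) is deliberate: limitation-switch boundaries —
including the single-species boundary at `φ^(n)/φ^(c) = Y^(c)/Y^(n)` — are
invisible to a species-only probe. Because feasibility depends only on the
signs of `R⁻¹φ`, which are invariant under positive rescaling of `φ`, the
probe supplies are usable regardless of where they land relative to the
sampling box. Modules are Louvain communities of the red-edge graph at
resolution 1.5 under a fixed seed; greedy modularity is not unique, so module
counts are reported rather than asserted.

## Downstream statistics

`multistability_histogram()` counts `V`, the simultaneously feasible stable
states per sample, and fits `V−1` by a Poisson rate (the maximum-likelihood
estimate is simply `mean(V−1)`). The supply balance of a sample is
`Σφ^(c)/Σφ^(n)` on a log axis — the axis definition is the package's choice,
as is binning by equal log-width. Species *prevalence* is the fraction of
samples at which the species occurs in at least one feasible uninvadable
state; the stricter "in every feasible state" variant is emitted alongside,
since either reading is defensible. The PCA projection uses relative
(compositional) abundances, centred but not rescaled.

`yield_variation_sweep()` redraws all yields from widening uniform intervals
(`U(0.45,0.55)` to `U(0.01,1)`) at fixed `λ`, recording each variant's
stoichiometry spread — the standard deviation of `log10(Y^(n)/Y^(c))`, base 10
matching the magnitudes usually quoted for real taxa — against its multistable
fraction. Two structural facts frame the sweep. First, pools in which every
species has the same stoichiometry admit no multistability and no dynamical
instability at all: the suite checks that every sampled environment then has
exactly one feasible uninvadable state. Second, at the 2×2 scale
multistability also needs the *competitive* ranks to allow a keystone switch —
two uninvadable states with disjoint species pairs — which only about one
random `λ` draw in eight provides; without it no yield combination helps. The
sweep (and the acceptance script's 2×2 realization) therefore starts from a
pool whose ranks admit the switch, found by a structural scan, mirroring the
fact that a small illustrative realization is only interesting when it
exhibits the phenomenon.

## What the generator does and does not emulate

`generate_pool()` draws `λ ~ U(10,100)` and `Y ~ U(0.1,1)` independently —
the distributions used throughout — giving every (carbon, nitrogen) pair one
specialist. Real communities have correlated traits (growth–yield tradeoffs,
`λ`–`λ` tradeoffs), generalists, cross-feeding and fluctuating supply; none of
that is modelled, so passing tests show the *combinatorial and dynamical
machinery* is right, not that any particular natural community is multistable.
Multistability predictions for real systems enter only through the
stoichiometry-spread sweep, where the spread can be matched to measured taxa.

## Problem sizes and numerical choices

The test suite runs brute-force cross-checks at `S ≤ 9`, equal-stoichiometry
and V/(V−1) properties at `10^4`–`10^5` supply samples, and direct ODE
stability on 2–4 species systems; the acceptance script samples `10^5`
supplies for the 2×2 realization, `10^6` for the 6×6 realization (where
per-state ranges are small), and `10^4` per yield variant — sizes chosen so a
single-core desk run finishes in minutes while keeping binomial error well
inside the effects of interest. Feasibility uses one LU factorisation per
state; positivity tolerance `1e-12`; extinction threshold `1e-9` in abundance
units; ODE tolerances as above. Known limitations: the Liebig minimum makes
the right-hand side non-smooth, so no Jacobian/eigenvalue classification is
attempted (the operational perturbation test is the definition used);
enumeration is exhaustive and practical to roughly nine nutrients of each
type; boundary detection and module partitions are stochastic procedures whose
ensemble sizes (1000 draws per face, one Louvain run) are reported defaults,
not convergence guarantees.
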