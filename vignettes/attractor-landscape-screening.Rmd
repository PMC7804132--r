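---
title: "Attractor-landscape analysis and in-silico drug-target screening for logical disease models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Attractor-landscape analysis and in-silico drug-target screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(attractorscreen)
```

## The model class

`attractorscreen` works with synchronous Boolean networks: each gene or
protein is a node whose state is ON (1) or OFF (0), and every node carries
one logical update rule over its regulators (AND/OR/NOT and the constants
0/1). All nodes update simultaneously from the previous full state, so the
dynamics are deterministic: from any initial state the trajectory must
eventually revisit a state, closing an **attractor** — a fixed point or a
cycle — which is interpreted as a stable cellular phenotype. The set of
initial states that converge to an attractor is its **basin of
attraction**; the basin's share of all initial states ("basin ratio")
measures the relative stability of that phenotype.

The intended application is a neuronal molecular regulatory model of
Alzheimer's-type pathology in which five output nodes report amyloid-beta
load, phosphorylated tau, synapse loss, apoptosis and autophagy, and in
which genetic risk factors (an ApoE &epsilon;4 allele, an LPL
loss-of-function variant) are represented as *differential wirings* of the
normal-state network: rule overrides and node pinnings
(`risk_factor_condition()`, `apply_risk_factor()`). Models are read and
written in the plain-text `targets, factors` rule format common to logical
modeling tools, with node roles (input / internal / output and phenotype
labels) in a YAML sidecar so the rule files stay interoperable.

Asynchronous updating, multi-valued logic and ODE semantics are out of
scope; SBML-qual import is not provided.

## Landscapes: exhaustive and sampled

`enumerate_landscape()` iterates every initial state over the free
(non-pinned) nodes and counts basins exactly. It refuses more than
`max_free = 20` free nodes (about a million states); beyond that,
`sample_landscape()` draws initial states uniformly **with replacement**
and tallies which attractor each one reaches. With-replacement counting
keeps the basin-ratio estimator unbiased; duplicate draws simply re-count.
The reference protocol for a ~77-node disease model is $10^6$ sampled
states. Both routines memoize every visited state's attractor within a
call, so a million samples on a 77-node model run in a couple of minutes
on one CPU; memoization cannot change counts because each *sample*, not
each state, contributes one count.

Attractor cycles are canonicalized by rotating the lexicographically
smallest state (as a bit string in node order) to the front, which makes
attractor identity a plain string comparison and landscape equality a set
comparison. Basin bookkeeping is integer-exact: counts always sum to the
enumeration or sample total.

**Node activity** is the mean value of a node over an attractor's cycle,
averaged across attractors with basin-ratio weights — an estimate of the
long-run activity level of the gene or protein. Pinned nodes always have
activity exactly equal to their pinned value.

## The phenotype score

The five output activities are collapsed to one 0–100 score
(`phenotype_score()`). Each phenotype $p$ has a weight (amyloid-beta 30,
p-tau 30, synapse loss 20, apoptosis 10, autophagy 10 — the clinical
priority ordering) and a desired direction: low for the four pathological
outputs, high for autophagy, whose up-regulation clears pathological
protein. With output activity $a_p$, the desirability is $1-a_p$ (desired
low) or $a_p$ (desired high), and

$$\mathrm{score} \;=\; \sum_p w_p \, d_p \in [0, 100],$$

so 100 is the desired non-pathological state. The complement is available
as `orientation = "pathology"`.

Two scoring modes are shipped because attractor-membership language
("basin ratio of attractors belonging to the same phenotype") is ambiguous
for cyclic attractors and for attractors with several outputs ON. The
default, continuous mode weights each output's activity by basin ratio;
the strict `mode = "membership"` assigns an attractor to a phenotype when
its mean output activity exceeds 0.5 and sums basin ratios. The two
coincide exactly whenever attractors are fixed points (activities are then
0/1), which is the case for the shipped fixture; continuous is the default
because the score is then a smooth, monotone function of output
activities, which the screening rank relies on.

## Perturbation screening

`screen_single()` / `screen_double()` emulate drug action by **pinning**:
a candidate node (or unordered pair) is clamped to 0 — inhibition, the
default, since the drug library is inhibitor-dominated — on top of the
risk-factor condition, the landscape is recomputed, and the phenotype
score ranks the perturbations. `delta` is measured against the *disease*
baseline (condition applied, no therapy), not the normal network: the
question is what helps given the risk factor.

Candidates exclude output nodes and designated inputs (pinning either
trivializes the score), condition-pinned nodes and condition-overridden
nodes (otherwise the screen "cures" the disease by deleting its defining
lesion rather than finding a downstream therapy). Ranking is a total
order: descending score, then fewer targets, then lexicographic target
names — stable across runs for a fixed seed. Landscapes inside a screen
are enumerated exhaustively when the free-node count permits and sampled
otherwise, with per-entry seeds derived deterministically from the base
seed (base + entry index). Triple and higher-order perturbations and
partial (dose-dependent) inhibition are not modeled.

## Drug mapping and exclusion filters

`map_targets_to_drugs()` joins top-ranked targets to an approved-drug
library (TSV: name, target node, action, blood-brain-barrier status,
safety flag, BBB waiver, original indication). A therapy is emitted only
when *every* target of an entry is covered by a drug with the matching
action (pin 0 ↔ inhibitor, pin 1 ↔ activator); partially covered entries
are skipped and logged. `filter_candidates()` then applies the
property-based exclusions: any possible-carcinogen member excludes the
therapy, as does poor or unknown BBB penetrability without a waiver (the
waiver models an agent kept despite unknown penetrability for its
plausible role in blood-brain-barrier integrity). Carcinogenicity is
reported in preference to BBB when both apply. The filter partitions —
every input row comes back with a status — and the packaged library plus
therapy list reproduce the published split of six selected versus five
excluded therapies.

The packaged library is data, not code: rows whose exact model target is
published only in supplementary material carry a synthetic placeholder
`target_node` flagged in the `note` column, and no test relies on those
targets — only on the printed BBB/safety properties. Pharmacokinetics,
dosing and potency are out of scope.

## Oxidative-stress dose-response

`run_dose_response()` sweeps the stress input (ROS) from 0% to 100%. A
graded level $p$ on a binary node is realized as per-run Bernoulli
pinning: each of `runs_per_level` independent runs pins ROS ON with
probability $p$, draws a uniform random initial state, and records the
attractor's output activities; per level the mean, standard error and a
normal-approximation 95% CI are reported. This interpretation makes the
semantics transparent through the mixture identity

$$\mathbb{E}[\bar a(p)] = (1-p)\,A_\mathrm{OFF} + p\,A_\mathrm{ON},$$

where $A_\mathrm{OFF}/A_\mathrm{ON}$ are the landscape activities with the
input pinned OFF/ON — and the identity is tested to within 3 standard
errors on the shipped fixture. Defaults: levels 0 to 1 in steps of 0.1,
1000 runs per level. With one run per level the CI has zero width by
convention. No attempt is made to reproduce any published numeric curve:
those values are figure-only, so checks are qualitative (e.g. amyloid-beta
rises with full stress) plus the mixture identity.

## Synthetic models and what they do (not) show

Two generators make the whole pipeline testable without any external
model file:

* `generate_random_network()` — Kauffman-style NK networks: each node gets
  `k` distinct random regulators and a random truth table with ON-bias
  `bias`, rendered to disjunctive normal form so generated models
  round-trip through the rule format. Used for property-based tests
  (sampled-versus-exhaustive equivalence, conservation, pinning
  invariants).
* `generate_surrogate_network()` — a random model with an *exact* node and
  link count (each node an AND- or OR-chain over distinct regulators with
  random negations, so every regulator appears irreducibly). The
  77-node/204-link default matches the scale of the published disease
  model, whose rule file is distributed as supplementary data and treated
  here as an optional input; the surrogate is a synthetic stand-in for
  scale and parsing checks, not a reconstruction of that model.
* `build_mini_ad_network()` — a fixed 18-node fixture whose rules encode,
  clause by clause, the qualitative causal claims of the core pathways
  (see `?build_mini_ad_network` for the full mapping). It is explicitly a
  hand-verifiable test double: small enough for exhaustive enumeration
  (its golden landscape is committed and regression-tested), rich enough
  to exhibit the mechanisms of interest — canonical WNT silencing GSK-3β,
  PTEN suppression rescuing p-tau via AKT, mTORC1 inhibition restoring
  autophagy, the Dkk1 vicious cycle.

Passing tests on these fixtures demonstrate the *machinery* — exact basin
accounting, unbiased sampling, correct score algebra, reproducibility —
not biological fidelity of any particular rule set: random networks have
no pathway semantics at all, and the mini fixture compresses entire
pathways into single nodes, omits pathways present in the full model
(Notch, RELN, Jak/Stat, calcium), and couples autophagy to mTORC1 so
tightly that p-tau can only be non-zero when the autophagy axis is
lesioned.

### Choices worth knowing about

* **Risk-factor reconstructions.** The shipped condition files for the
  mini fixture are reconstructions, documented in their comments. The
  ApoE-ε4-like condition silences canonical WNT and locks mTORC1 ON
  (representing TFEB-suppressed autophagy). It deliberately does *not*
  clamp MAPK ON or NMDAR OFF, although both shifts are part of the
  condition's phenotype: clamping them forces amyloid-beta permanently
  high and severs the NMDAR→AKT axis through which PTEN suppression acts,
  whereas leaving them free lets both shifts emerge dynamically. The
  LPL-like condition locks BACE1 and mTORC1 ON (cholesterol-driven
  β-secretase activity, autophagy suppression).
* **Inputs.** Input nodes are self-sustaining (`X, X`), so the initial
  condition or a pin determines them; the unstressed state is ROS = 0.
  Landscape functions leave inputs free unless pinned, and screens never
  propose an input as a target.
* **Seeds and reproducibility.** All randomness flows through R's RNG via
  `withr::with_seed`, so no call disturbs the caller's RNG state; sampled
  landscapes record their seed. Screens derive per-entry seeds as base +
  index.
* **Numerics.** Basin counting is integer; the only floating-point
  quantities are ratios, activities and scores. Attractor canonical form
  ensures tie-free identity; ranking ties are broken structurally, never
  by RNG.
* **Problem sizes.** The test suite enumerates up to $2^{18}$ states
  exhaustively and runs the sampled-versus-exhaustive equivalence on one
  hundred random networks of 4–9 nodes with $50\cdot 2^n$ samples each;
  the full-scale demonstration samples $10^6$ initial states on a 77-node
  surrogate. These sizes were chosen to keep a complete run on a single
  CPU in the minutes range while still exercising every code path at the
  published protocol's scale.

## Known limitations

Basins are estimated by simulation, not computed symbolically (no BDDs);
stability under asynchronous update is not assessed; the phenotype-score
weights are taken as given, not learned; and the drug layer knows nothing
of potency, dose or pharmacokinetics — it is a set filter over printed
properties. The mini fixture's reduced scale means quantitative outputs
(scores, deltas) are illustrative; only their directions and orderings
carry meaning.
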