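# attractorscreen

Attractor-landscape analysis and in-silico drug-target screening for
synchronous Boolean models of disease signaling.

Complex diseases such as Alzheimer's arise from the interplay of many
signaling pathways, and genetic risk factors (an ApoE ε4 allele, an LPL
loss-of-function variant) rewire that interplay differently in different
patients. This package implements the computational arm of a
network-based drug-repositioning workflow for researchers in systems
biology and neurodegeneration: represent the regulatory network as a
logical model, characterize its stable phenotypes, and ask which
drug-like interventions move a risk-factor-conditioned network back
toward the healthy state.

## The method

A Boolean network assigns each gene/protein a state in {0, 1} and one
logical update rule; all nodes update synchronously, so every trajectory
converges to an **attractor** (fixed point or cycle) interpreted as a
stable cellular phenotype. The **basin of attraction** — the set of
initial states converging to an attractor — measures that phenotype's
stability, and the basin-ratio-weighted mean of a node over attractors is
its long-run **activity**:

    activity(v) = Σ_a  basin_ratio(a) · mean_a(v)

Five output nodes report amyloid-beta (Aβ), phosphorylated tau, synapse
loss, apoptosis and autophagy. Their activities collapse to a 0–100
**phenotype score** with weights Aβ 30, p-tau 30, synapse loss 20,
apoptosis 10, autophagy 10 (desired low for the first four, high for
autophagy):

    score = Σ_p  w_p · d_p,   d_p = 1 − a_p (desired low)  or  a_p (desired high)

Risk factors enter as **differential wiring** (rule overrides + pinnings);
therapies are emulated by **pinning** one or two candidate nodes to 0
(inhibition) and re-ranking by score. Ranked targets are joined to an
FDA-approved drug library and filtered on printed properties
(carcinogenicity, blood–brain-barrier penetrability). A graded
oxidative-stress sweep (Bernoulli pinning of the ROS input at probability
p) provides input–output validation curves with 95% confidence bands.

The simulation core (synchronous stepping, cycle detection, memoized
exhaustive/sampled basin counting) is compiled C++, so the reference
protocol — 10⁶ sampled initial states on a 77-node model — runs in about
two minutes on one CPU.

## Worked example

```r
library(attractorscreen)

mini <- build_mini_ad_network()          # 18-node pathway fixture, 5 outputs
apoe4 <- read_condition(system.file("extdata", "apoe4_mini.yaml",
                                    package = "attractorscreen"))

sc <- screen_single(mini, apoe4)         # pin each candidate to 0, rank
sc$baseline$score
#> [1] 45
head(sc$entries[, c("targets", "score", "delta", "ptau", "autophagy")], 4)
#>   targets score delta ptau autophagy
#> 1     APP    70    25 0.50         0
#> 2   GSK3b    70    25 0.00         0
#> 3    MAPK    70    25 0.50         0
#> 4    PTEN    55    10 0.50         0
```

The ApoE4-like disease baseline scores 45/100; inhibiting PTEN raises the
score by 10 points and halves p-tau activity (0.75 → 0.5) by releasing
AKT signaling — the mechanism that motivates repositioning the PTEN
inhibitor Flibanserin. Mapping a ranked entry onto the packaged drug
library and applying the property filters:

```r
lib <- read_drug_library()
cand <- therapies_from_table(system.file("extdata", "therapy_candidates.tsv",
                                         package = "attractorscreen"), lib)
table(filter_candidates(cand, lib)$status)
#> excluded selected
#>        5        6
```

Six therapies survive; five are excluded (two possible carcinogens, two
with poor and one with unknown blood–brain-barrier penetration). See the
vignette (`vignettes/attractor-landscape-screening.Rmd`) for the model,
the scoring conventions, and what the synthetic fixtures do and do not
demonstrate.

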