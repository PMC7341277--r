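---
title: "Methods: leaky noisy-OR networks for genetic counseling"
author: "counselnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: leaky noisy-OR networks for genetic counseling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(counselnet)
```

## The counseling problem and the model

A breeder or veterinarian faces two recurring questions about a recessive
monogenic disease such as canine degenerative myelopathy (DM, associated
with SOD1 mutations): what is the risk that a tested animal will show
clinical signs, and what is the risk that an untested animal (or a planned
offspring) carries or is homozygous for the mutant allele? `counselnet`
answers both with a small discrete Bayesian network over a pedigree.

Each individual contributes five nodes: a three-state genotype `G`
(`AA`/`AB`/`BB`; `A` wild, `B` mutated), a binary phenotype `P` (clinical
signs present/absent), and three binary non-genetic risk factors — diet `D`,
exercise `E` and age `A` (age is used as a binary "within the most
susceptible age range" indicator, because eliciting more than two states
from owners is impractical). Offspring genotypes depend on both parental
genotypes through the Mendelian transmission CPT; founder genotypes carry a
prior, uniform (1/3, 1/3, 1/3) by default — the maximally non-committal
choice when nothing is known about the animal — or Hardy–Weinberg
$((1-q)^2,\,2q(1-q),\,q^2)$ when a mutant-allele frequency $q$ is trusted.

The phenotype CPT is a **leaky noisy-OR** gate over four causes: the
genetic cause (active when the genotype is `BB` under the default recessive
model) and the three non-genetic factors. Each active cause $i$ fires an
independent mechanism with its *link* probability $p_i$; unmodelled causes
fire with the *leak* probability $p_0$; signs appear iff some mechanism
fires:

$$\Pr(P = \mathrm{T} \mid X_p) \;=\; 1 - (1 - p_0)\prod_{i \in X_p}(1 - p_i).$$

The leak multiplies into every row (Dı́ez's convention, matching the formula
above); the alternative leak semantics of Henrion is deliberately not
offered, to keep one unambiguous reading of elicited links. The CPT of a
gate with $n$ causes needs only $n + 1$ elicited numbers instead of $2^n$
rows, which is the point of the construction.

## Prior uncertainty on the gate probabilities

Leak and link probabilities are rarely known; they carry Beta priors,
conjugate to the Bernoulli and flexible over $(0,1)$. Because published
accounts typically state only means, the default elicitation is **mean plus
concentration** $\nu = \alpha + \beta$ with $\nu = 9$, which at a mean of
10% gives an sd of 9.49% — a strongly right-skewed prior expressing that
the non-genetic effects are believed weak but poorly known. Where a
trusted sd exists, `beta_from_moments()` moment-matches instead (feasible
only when $s^2 < m(1-m)$; infeasible moments are an explicit error). The
seven packaged prior groups (`dm_prior_groups()`) cross non-genetic link
means of 10/30/50% with genetic link means of 10/50/90% (never below the
non-genetic mean), leak mean fixed at 1%, all at $\nu = 9$.

`summarize_risk()` propagates these priors by Monte Carlo: per draw it
samples the leak and the required links and evaluates the gate. Two draw
modes exist because it is ambiguous whether the three non-genetic causes
share one uncertain parameter or have independent ones:

* `independent` (default): each active cause gets its own draw. Each cause
  is then a separate mechanism, and the Monte Carlo mean converges to the
  closed form $1 - (1-m_0)\prod_i (1-m_i)$ in the prior means.
* `shared_ng`: one draw is reused for diet, exercise and age within a
  realization, inducing positive dependence between the mechanisms; means
  of multi-cause risks drop slightly below the closed form because
  $E[(1-p)^k] \ge (1-E[p])^k$.

The two agree exactly when priors are degenerate. Risk-table cells are
checked as an *ordering* property (risk grows with the number of active
causes; adding the genetic cause always increases it) plus closed-form
agreement within Monte Carlo error, not as fixed decimal values: externally
quoted tables of this kind depend on unpublished draw counts, seeds and
Beta shapes, and their printed sds are mutually inconsistent with any
single concentration (a 30% mean with sd 23.39% implies $\nu \approx 2.8$;
a 90% mean with sd 6.04% implies $\nu \approx 24$). Reproducing the
ordering and the analytic limit is the defensible claim; reproducing the
cells is not.

## Building CPTs from priors

`build_trio()` offers two CPT modes. `point_mean` (default) plugs the prior
means into the gate — deterministic, fast, and the right choice for
counseling numbers that must be reproducible. `mc_mean` averages the
noisy-OR row over sampled parameter realizations; with independent draws
this equals `point_mean` in expectation (the row is linear in each sampled
survival factor), so it matters only in `shared_ng` mode or as a
Monte Carlo consistency check. A third route, `posterior_over_draws()`,
rebuilds the network per parameter draw and averages *posteriors* rather
than CPT entries; it is exposed as an experimental mode because posterior
quantities are nonlinear in the parameters, so averaging at the posterior
level genuinely differs — some externally quoted posteriors (see
"documented discrepancies" below) can only plausibly arise from an
averaging scheme of this kind. It is never the default.

One parameter realization applies network-wide: the leak and links are
population-level quantities shared by every individual's gate, not
per-animal effects.

## Inference

Networks are small by construction, so inference is exact, twice over:

* **Exhaustive enumeration** (`joint_enumeration()`): all reduced CPTs are
  multiplied into one joint table. Used as the correctness oracle; capped
  at 24 nodes / two million cells.
* **Variable elimination** (`posterior()`): min-degree elimination ordering
  with ties broken lexicographically by node id — on networks this size the
  ordering is about reproducibility, not speed.

The two routes are required to agree within $10^{-10}$ on a thousand seeded
random scenarios (random pedigrees of three to five individuals, random
feasible Beta priors, random evidence rejection-checked to be viable,
capped at twelve nodes so the oracle stays cheap). Evidence with zero joint
probability — a Mendelian impossibility such as an `AA` parent with a `BB`
offspring — raises an explicit "inconsistent evidence" error rather than
returning a silently renormalized vector. Genetic tests with imperfect
sensitivity/specificity attach as child nodes of the true genotype;
heterozygote behaviour is stated explicitly (`detect_bb` vs
`detect_allele`) because test chemistry, not the model, decides whether a
carrier reads positive.

Seeding follows one rule throughout: a single root seed is split
deterministically per sampled quantity (keyed by name), so adding a query
or a node never perturbs another query's draws.

## The deterministic gate limit

The headline counseling numbers this package reproduces — offspring
(56.25, 37.5, 6.25)% under two healthy parents with all factors absent;
(0, 50, 50)% under an affected dam; parent (0, 33.3, 66.7)% given a
BB-tested offspring; expected utility 100 for an `AA × AA` mating — hold in
the **deterministic gate limit** (leak $\to 0$, genetic link $\to 1$):
there, a healthy animal with no active non-genetic factors is certainly not
`BB` and an affected one certainly is, and the posteriors reduce to pure
Mendelian counting. At the stated prior means (leak 1%, genetic link 90%)
the same queries give nearby but not identical values. Both
parameterizations are packaged as named scenarios, with the reproducing one
recorded per fixture; the limit is used for the reference checks because it
is the only parameterization under which those printed numbers are exact.

## Documented discrepancies

Five externally quoted reference values for these scenario families are
*not* reproduced, and `run_scenarios()` lists them explicitly rather than
dropping them:

* 6.42% for the offspring-`BB` posterior under healthy parents with all
  non-genetic factors active: for any point-valued gate, the non-genetic
  factors cancel out of the healthy-parent likelihood ratio (they multiply
  the survival probability of `BB` and non-`BB` rows alike), leaving 6.25%;
  only posterior-level parameter averaging moves it at all.
* 100% for a single parent being `BB` given only an affected offspring:
  with uniform founder priors the maximum is 2/3 even when the offspring is
  certainly `BB` (the other parent can be the carrier). Possibly "BB" meant
  "carries B", or extra evidence was set interactively.
* 66.5% for the same query with all offspring factors active: no stated
  parameterization produces it.
* Expected utilities 93.69 and 74.88 for the untested healthy mating: both
  imply $P(\text{offspring } BB) \approx 6.31\%$, i.e. an implied
  $P(\text{signs}\mid BB,\ \text{no factors}) \approx 0.997$, which no
  stated parameter set yields; the deterministic limit gives exactly 93.75
  and 75.00.

## Numerical and design choices

* Genotype order is fixed (`AA`, `AB`, `BB`) everywhere; CPT rows are
  indexed by named state assignments, never integer position.
* Boundary probabilities 0 and 1 are legal gate values (the deterministic
  limit requires them). The empty-active-set risk is returned as the leak
  *exactly*, avoiding the $1-(1-p_0)$ rounding wobble.
* Risk-factor root nodes default to $P(\mathrm{T}) = 0.5$: counseling
  queries instantiate them as evidence, so this prior only matters for
  unqueried individuals, and no principled population value is available.
* Percentages are formatted (two decimals) only at the presentation layer;
  all machine output is full-precision fractions.
* Scenario configurations are YAML with a strict key schema; Beta shapes
  are canonicalized to 12 significant digits so that load–save–load is the
  exact identity; packaged fixtures are frozen by checksum.
* `add_relative()` only adds founders or children of existing pairs, so
  existing CPTs are never rewritten; ancestry is therefore built top-down.
* Feedback loops are structurally impossible (DAG validation); the
  risk-factor → phenotype direction is one-way by design.

## Problem sizes used in the test suite

The suite checks the ordering property at 10,000 draws per prior group,
oracle equivalence on 1,000 random scenarios of up to 12 nodes, and the
mechanism brute force on 10,000 random gates with up to four causes; these
sizes give Monte Carlo standard errors well below the assertion margins
while keeping the whole suite under a minute on a single core.

## What the synthetic scenarios do and do not show

The random-scenario generator emulates the *structural* variety the engine
must handle — pedigree shapes, prior shapes, evidence patterns — and the
packaged scenarios pin the *named* counseling queries. Neither emulates
real clinical data: no breed-specific allele frequencies, no SP110-type
modifier loci, no genotyping-error rates beyond the explicit test node, no
age-dependent penetrance trajectories, and the two-state factor coding
compresses genuinely graded exposures. Passing tests therefore certify the
probabilistic machinery and its stated parameterizations, not the clinical
calibration of any particular prior group.

## Session info

```{r}
sessionInfo()
```
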