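---
title: "Models and methods: discrete-character ancestral states and DEC biogeography on fossil-bearing time trees"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paleoasr)
```

# Scope

`paleoasr` implements the computational core of a comparative
reconstruction workflow for clades with substantial fossil records:
ancestral-state inference for discrete ecological and behavioral
characters on time-calibrated trees that include extinct terminal taxa,
Dispersal-Extinction-Cladogenesis (DEC) biogeographic likelihoods with
rule-based, time-stratified dispersal matrices, and the construction of
fossil-calibration priors and initial age assignments for downstream
Bayesian dating. Tree inference itself (parsimony or Bayesian tree
search, MCMC dating) is out of scope: the package consumes rooted,
time-calibrated topologies and emits the quantities such analyses need.

Ages are in Ma and increase into the past; branch lengths are durations
in Myr. Fossil tips are ordinary tips with positive age, so trees need
not be ultrametric. Polytomies are preserved as read.

# The Mk machinery

Characters are modelled as k-state continuous-time Markov chains with
generator $Q$ and equal root frequencies $\pi_s = 1/k$ (the Mk
convention). Three nested parameterizations are supported: ER (one
rate), SYM ($k(k-1)/2$ symmetric rates) and ARD ($k(k-1)$ rates). No
ascertainment ("variable-characters-only") correction is applied:
ancestral-state reconstruction conditions on a particular observed
character, unlike the tree-inference setting where the Mkv correction
belongs. Likewise no gamma rate variation: each character gets its own
rate(s), which is where rate heterogeneity across characters enters.

Missing and polymorphic observations enter through tip priors used
directly as tip partial likelihoods: a missing cell contributes a flat
vector ($1/k$ per state), a cell polymorphic over $m$ listed states
contributes $1/m$ on each listed state and 0 elsewhere (for example
`{0,1}` with three states gives $(0.5, 0.5, 0)$), and a monomorphic
cell is an indicator. A consequence worth knowing: such tips are not
immutable during reconstruction — the model may effectively resolve a
polymorphic tip to whichever listed state the surrounding clade
supports, and the stochastic-mapping method reports those resolutions
as imputed tip states.

Likelihoods use Felsenstein pruning with per-node rescaling against
underflow. Transition matrices $e^{Qt}$ use the closed form for two
states, an eigendecomposition (validated by reconstructing $Q$; shared
across all branch lengths in a pass) for larger state counts, and dense
scaling-and-squaring (`Matrix::expm`) when the spectrum is unreliable.
Zero-length branches — common in consensus topologies — contribute
identity matrices and are accepted everywhere.

Rates are estimated by bounded quasi-Newton iteration on log rates with
jittered restarts (default 5; ARD surfaces can be multimodal), with a
convergence tolerance of about $10^{-8}$ on the log-likelihood. Model
selection walks the nested chain ER → SYM → ARD by chi-squared
likelihood-ratio tests at $\alpha = 0.05$, with degrees of freedom
equal to the difference in free parameters; for binary characters SYM
coincides with ER and the chain collapses to ER vs ARD. Selection stops
at the first non-significant step, and a p-value exactly equal to
$\alpha$ retains the simpler model. Each richer model is warm-started
from the accepted simpler fit so nested log-likelihoods never decrease.

# The three reconstruction methods

**Parsimony.** Unit-cost (unordered) parsimony via a two-pass dynamic
program over state costs, natively handling multifurcations and
state-set tips (missing = full set). For each node the package reports
the MPR union: exactly the states attainable in at least one assignment
achieving the minimum change count, plus that minimum. No step matrices
— the intended characters are unordered ecological states.

**Maximum-likelihood marginals.** The marginal posterior of the state
at each node given all tips, with $Q$ fixed at its ML estimate,
computed by an exact inside/outside two-pass. For reversible
generators (ER and SYM — in practice the classes selected for almost
every character) this is identical to the classical re-rooting
construction; for ARD it is the exact rooted-tree marginal, which we
consider the defensible generalization. Rows are normalized to
proportions of total likelihood (PTL).

**Stochastic mapping.** Empirical-Bayes stochastic character mapping:
$Q$ stays fixed at the ML estimate (matching common usage where the
mapping tool is run with default options) and `nsim` full histories are
sampled conditioned on the tip data — node states from their joint
conditional distribution (root first, then children given parents),
then each branch's substitution path conditioned on its endpoints.
Endpoint-conditioned paths use exact rejection sampling with a cap of
1000 attempts per branch and a uniformization fallback, since rejection
can stall on long branches with forced changes. Node posterior
probabilities (PP) are sampled frequencies; replicate-level change
counts and per-branch means are retained, and missing/polymorphic tips
receive imputed states (a state with zero prior can never be imputed).
The default of 5000 replicates keeps the Monte-Carlo error of any PP
under about 0.02.

A reconstruction at a target node is flagged FAILED when it is
uninformative. The threshold is a package choice (no standard numeric
criterion exists): for probability methods, the best state's
probability must exceed $1/k$ by more than $10^{-6}$; for parsimony,
the MPR set must not contain every state.

# DEC biogeography with rule-based dispersal

Geographic ranges are nonempty subsets of the inhabitable areas, plus
an absorbing null range; by default every combination is allowed (a
range-size cap is available, and required beyond 8 areas). Anagenesis
follows the DEC generator: range $R$ gains area $j$ at rate
$d \sum_{i \in R} p_{ij}$ and loses any occupied area at rate $e$
(single-area ranges fall to null). Cladogenesis allows sympatry for
single-area ranges and, for wider ranges, peripheral-isolate sympatry
and vicariance, with all ordered splits equally weighted — the
classical choice, kept as a documented default since nothing in this
workflow calls for reweighting. The root prior is flat over allowed
nonempty ranges; conditioning on survival is off by default.

The per-epoch relative dispersal matrix is built from separation
classes between landmass pairs: connected 0.9, close islands 0.5,
Atlantic-class ocean 0.1, Pacific-class ocean 0.01. Multi-step routes
multiply their edge weights, and each pair's entry is the maximum
product over all simple paths, found by exhaustive enumeration — exact
at the handful-of-landmasses scale this is meant for, and matching the
worked Quaternary example where an Atlantic crossing plus two
close-island hops ($0.1 \times 0.5 \times 0.5 = 0.025$) beats the
direct trans-Pacific crossing ($0.01$). Islands can be modelled either
as inhabitable areas or as waypoint-only vertices (config flag): a
waypoint contributes to path products but is excluded from the range
state space.

Epochs tile $[0, \text{root age}]$; a branch crossing $b$ boundaries is
cut into $b+1$ segments, each using its epoch's generator, with the
matrix factors composed in forward-time (old to young) order. Inserting
a boundary whose dispersal matrix equals its neighbour's provably
leaves the likelihood unchanged, which the tests exercise. Polytomies
are resolved internally into zero-duration virtual binary splits, each
applying the cladogenetic rule pairwise (equivalent to combining
daughters sequentially); the Mk methods, by contrast, handle
multifurcations natively.

`fit_dec` maximizes the likelihood over $(d, e)$ on the log scale from
a fixed grid of starts, so estimates are deterministic. A known
limitation, familiar from Lagrange-style analyses and reproduced by our
own recovery experiments: with realistic extant-biased sampling the
extinction rate $e$ is very weakly identified and its ML estimate
typically collapses to the zero boundary, while $d$ is recovered well.
Ancestral range tables report relative probabilities normalized to
100% per node, with ranges (marginals over cladogenetic scenarios) and
the scenario-level splits listed in one ranked table — the convention
used when percentages over ranges and range-splits are reported
jointly.

# Calibration priors and initial age assignment

For a geologic interval with bounds (old, young), the calibration prior
is exponential with hard minimum offset at the young bound and rate
$-\ln(1-0.95)/(\text{old}-\text{young})$, placing exactly 95% of its
mass inside the interval; support is $[\text{offset}, \infty)$ so the
hard minimum cannot be violated. A snapshot of the ICS chart (periods,
Cenozoic epochs, and Cretaceous–Late Jurassic stages) is bundled as
data and can be overridden by a user table.

`bladj_scale` reproduces the BLADJ idea: dated nodes (including fossil
tips, which are dated terminals) keep their ages exactly, the root is
fixed (150 Ma by default, an age of the kind used for squamate-scale
roots in divergence-dating practice), and undated nodes are placed by
even
spacing. Concretely, the algorithm walks down from each dated node
along every descent path, visiting children in order of the oldest
calibration beneath them (ties in stored order); the maximal run of
undated nodes on a path is spaced evenly between its dated ancestor
and the first dated node that path reaches, and once a node is dated
it bounds every later path through it. Spacing each shared region
against its oldest constraint first guarantees that ancestor ages
never fall below descendant ages, even when deep fossil calibrations
sit along side paths. This oldest-constraint-first assignment is our
deterministic resolution for polytomies and for nodes shared between
several chains, situations the original description leaves unstated.

# The synthetic-data generator

The simulator exists so that every stage is exercisable without any
external data, and its defaults emulate a realistic combined-evidence
study design: 58
extant plus 15 fossil tips (73 taxa), 11 characters with state counts
between 2 and 4, and two nested target clades. Trees come from a
forward constant-rate birth-death simulation stopped at a random time
after the extant count first reaches the target (so terminal branches
are positive); extinct lineages are retained as fossil tips either
independently at a stated fraction or as an exact count, with age equal
to their extinction time. Characters evolve under ER/SYM/ARD
generators; missingness (default 15%) and polymorphism (default 5%)
are injected afterwards, polymorphic cells always retaining the true
state. Ranges evolve under the epoch-stratified DEC generator with
cladogenetic draws at nodes; lineages that hit the null range are
recorded as extinct. Default birth and death rates (0.06 and 0.03 per
Myr) give root ages of roughly 60–130 Ma at this tip count — the
depth scale of a Cretaceous-rooted clade.

One master seed hierarchically derives per-component streams (tree,
each character, each factorial cell), so adding a character never
perturbs the tree, and identical configurations yield byte-identical
outputs.

What the simulations do *not* emulate: phylogenetic error (topologies
are known, not estimated), correlated evolution among characters,
rate variation along branches, and non-random fossil sampling. Passing
recovery and convergence tests on these simulations therefore validates
the machinery, not the biological fidelity of any particular empirical
reconstruction.

# Numerical choices and problem sizes

Likelihood tolerances: optimizer convergence about $10^{-8}$ on the
log-likelihood; rate bounds $[10^{-9}, 10^{4}]$ per Myr on the log
scale; age bookkeeping validated to $10^{-9}$ Myr. Ties in model
selection (p exactly $\alpha$) keep the simpler model. Degenerate
inputs are handled explicitly: zero-length branches give identity
transitions, constant characters drive rates to the boundary (and are
flagged invariant and excluded from partitions), and all-missing
columns are errors.

The bundled test and analysis runs use deliberately modest problem
sizes — oracle comparisons on trees of up to 5 tips against exhaustive
enumeration (where brute force is exact), recovery experiments with
500 characters on a 200-tip tree and 50 DEC replicates on 100-tip
trees, and stochastic-mapping convergence at 5000 replicates on a
20-tip tree — chosen so the full suite re-runs quickly on a laptop
while still pinning each method to an independent oracle.
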