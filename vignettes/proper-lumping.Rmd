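---
title: "Automated proper lumping of linear compartmental models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automated proper lumping of linear compartmental models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(autolump)
```

## The problem

Physiologically based pharmacokinetic (PBPK) models describe drug disposition
with one state per tissue or organ, each parameterised by blood flow $Q$,
volume $V$ and a tissue:blood partition coefficient $K_p$. For a linear,
time-invariant model the system is

$$\frac{dy}{dt} = K\,y,$$

with $y$ the vector of $n$ state concentrations and $K$ the $n \times n$
matrix of micro rate constants. Such models are faithful but too large for
data-driven estimation: a whole-body model easily has 15–20 states while a
clinical data set supports 2–4.

*Proper lumping* reduces the model by merging original states into
pseudo-states such that every original state belongs to exactly one lumped
state, so the reduced states keep their physical meaning. A lumping is a 0/1
matrix $M$ of shape $m \times n$ with unit column sums; the reduced system is

$$\hat K = M\,K\,M^{+}, \qquad \frac{d\hat y}{dt} = \hat K\,\hat y,
\qquad \hat y(0) = M\,y(0),$$

where $M^{+} = M^\top (M M^\top)^{-1}$ is the Moore–Penrose pseudo-inverse.
Because $M M^\top$ is the diagonal matrix of block sizes, $M^{+}$ simply
averages a lumped concentration back over its members, and $M M^{+} = I_m$.

A lumping matrix is equivalent to a set partition of the states, which is how
this package represents it internally: block labels are canonicalised by
order of first appearance (a restricted growth string), so relabelled copies
of the same partition are identical objects and the search space is the set
of set partitions, not the much larger set of labelled assignments. The count
of partitions of $f$ free states into $k$ blocks is the Stirling number of
the second kind $S(f,k)$; the naive labelled count $m^f$ is exposed in search
results for reporting because it is the convention older literature uses to
describe the size of the problem.

## Acceptance criterion

A candidate lumping is accepted when the output-state exposure of the reduced
model matches the original: the criterion is the absolute relative difference
of the areas under the output concentration–time curve, in percent,

$$\mathrm{ARD\%} = \frac{|\widehat{AUC} - AUC|}{AUC} \times 100,$$

with default tolerance $0.002\%$. The denominator is the *original* model's
AUC: it is the fixed reference, and at tolerances this tight the choice of
denominator is numerically immaterial anyway. For a decaying linear system
the AUC has the closed form $-\left[K^{-1} y_0\right]_{\text{output}}$, so a
candidate costs one small linear solve rather than an ODE integration —
this is what makes searches over $10^5$–$10^7$ partitions tractable.

Exposure is a deliberately coarse summary: two different profiles can share
an AUC. A pluggable sum-of-squares criterion on the output trajectory is
provided (`criterion_config("ss-trajectory")`) for applications where the
profile shape matters; the AUC criterion remains the default because the
input here is a single bolus and total exposure is the quantity of interest.

Partitions whose reduced matrix is singular or unstable (lumping does not
preserve stability in general) are reported as `Inf` with a diagnostic
attribute — "not acceptable" — rather than as an error, so searches can step
over them. This is not rare: on randomly generated systems the fully lumped
2-state model is frequently unstable.

## The incremental outer loop and the four inner algorithms

All methods share one outer loop: start from the fully lumped model (the
constrained states — by default the observation state — as singletons, all
remaining states in one block), ask an inner algorithm for an acceptable
partition at the current $m$, and increment $m$ until one is found. The
first accepted $m$ is returned, so the result is the *minimal* acceptable
size for that inner algorithm; the unlumped identity at $m = n$ is a
guaranteed terminal case with ARD% exactly 0.

* **Full enumeration** visits every partition in lexicographic
  restricted-growth order through a constant-memory iterator. It reports both
  the order-independent global minimum at fixed $m$ and the (order-dependent)
  first acceptable partition; only the former is a meaningful target for
  comparisons.
* **NARS** (non-adaptive random search) draws legal partitions uniformly —
  rejection sampling of labelled assignments until surjective, which is
  exactly uniform over set partitions — and short-circuits on the first
  acceptable draw. Levels with a single legal partition are evaluated once.
* **Scree-initialised NARS** starts the outer loop not at $m = 2$ but at the
  number of eigenvalues of $K$ with $\log_{10}|\lambda| > 0$ (at least 2).
  The base is 10 and the cutoff 0, i.e. modes faster than 1 per time unit;
  the base only shifts the cutoff. A slope-change (largest consecutive drop)
  rule is available as an alternative. The scree uses eigenvalue *rank*
  only: no correspondence between individual eigenvalues and individual
  compartments is claimed, because none exists in general.
* **Simulated annealing** minimises ARD% at fixed $m$ with a
  one-state-move neighbourhood (move one free state to another block,
  never emptying a block and never entering a constrained singleton),
  Metropolis acceptance $\min\{1, e^{-\Delta/T}\}$, and multiplicative
  cooling $T \leftarrow 0.999\,T$ with one proposal per cooling cycle.
  Defaults: $T_0 = 10^4$, cooling $0.999$, budget $2 \times 10^4$ proposals
  per level. The per-iteration temperature and energy traces are recorded
  for convergence diagnostics.

Ties on equal ARD% keep the first partition encountered. With a fixed seed
NARS and SA are bit-reproducible; determinism is part of the test contract.

## Simulation and numerics

Trajectories are computed in closed form, $y(t) = e^{Kt} y_0$, via the
matrix exponential (`Matrix::expm`), with $y(0)$ returned exactly. The AUC
uses the linear solve when $K$ is numerically nonsingular (smallest
eigenvalue magnitude above $10^{-12}$ of the matrix scale); otherwise a
quadrature fallback integrates the output trajectory by composite Simpson's
rule out to 60 times the slowest decaying timescale and raises an
"infinite AUC" error if the trajectory has not decayed there — a closed
subsystem holding mass means the criterion is undefined, and that is
reported, never silently numericised.

Tolerances used in validation (none are stated conventions of the field;
all are implementation choices): matrix-exponential trajectories agree with
an adaptive ODE solver to $10^{-8}$ relative; the closed-form AUC agrees
with dense quadrature to $10^{-6}$; the semigroup property holds to
$10^{-10}$; closed systems stay closed under lumping to $10^{-10}$. The
identity $M M^{+} = I_m$ is algebraically exact, but in double precision
summing $k$ copies of $\mathrm{fl}(1/k)$ is one ulp below 1 for
$k = 6, 7, 14$; it is therefore verified to one ulp.

One limitation worth stating: mass balance in the *volume-weighted* sense is
not preserved by lumping in general. If the original system satisfies
$V^\top (\mathrm{diag}(V) K \mathrm{diag}(V)^{-1}) = 0$ columnwise, the
lumped system with block volumes $\hat V_b = \sum_{i \in b} V_i$ need not,
unless member states have equal dynamics (the exactly lumpable case) or
equal volumes. What *is* preserved algebraically is closedness of the rate
matrix itself: if $\mathbf{1}^\top K = 0$ then
$\mathbf{1}^\top \hat K = \mathbf{1}^\top M K M^{+} = 0$ because the columns
of $M$ sum to one. The closedness tests therefore work in the amount basis
(unit volumes).

## From physiology to rate constants

`build_rate_matrix()` encodes perfusion-limited kinetics in the
concentration basis: tissue $i$ gains from arterial blood at $Q_i/V_i$ and
returns at $Q_i/(V_i K_{p,i})$; the lung carries the full cardiac output
between venous and arterial blood; portal tissues (spleen, gut) drain
through the liver, whose venous return runs at its total inflow (hepatic
arterial plus portal); intrinsic clearance $CL$ adds a loss term
$CL/(V K_p)$ on the eliminating state's column; and extra sub-compartments
exchange first-order with their parent tissue in the amount basis
($dA_s/dt = k_{in} A_p - k_{out} A_s$). Tissue flows must sum to the
cardiac output within $10^{-6}$ relative. Every constructed model is
validated for mass balance: the amount-basis matrix
$\mathrm{diag}(V)\,K\,\mathrm{diag}(V)^{-1}$ must have nonpositive column
sums, strictly negative only where there is elimination.

Lumped physiological parameters aggregate per block: volume and flow are
member sums; the lumped partition coefficient is the volume-weighted mean
$\sum V_i K_{p,i} / \sum V_i$, the unique choice that preserves the
steady-state amount of drug in the merged tissue (at blood concentration
$C$, tissue $i$ holds $V_i K_{p,i} C$). The rule is recorded in the result's
`kp_rule` attribute. Blocks mixing tissues with blood, lung or
sub-compartment states have no defined perfusion parameters and report `NA`.

## The bundled 17-state model and the synthetic generators

`fentanyl_pbpk()` ships the classic 17-state whole-body topology used for
strongly lipophilic opioids: arterial and venous blood, lung, nine perfused
tissues, one extra liver and spleen sub-compartment, two extra gut
sub-compartments, portal drainage, liver-only elimination, and a 750 µg
arterial bolus with arterial blood as the output state (minutes, litres,
micrograms). Its numeric parameter values are a **synthetic placeholder
set** — realistic adult human physiology with plausible partition
coefficients — not a transcription of any published drug-specific table;
the model carries `provenance = "synthetic-placeholder"` and the asset file
is named accordingly. Quantities computed from it (minimum ARD% at a given
$m$, the number of lumped states each search settles on) characterise this
parameter set, not any published parameterisation. Under these parameters
the strong adipose partitioning produces a long terminal tail, and the
searches typically need 5–10 lumped states at the 0.002% tolerance.

Two generators make every algorithm testable without external data:

* `exactly_lumpable_system(block_sizes)` builds a blood-plus-tissues system
  in which each block consists of identical-parameter tissue copies driven
  by the shared blood state. Identical dynamics with identical input give
  identical trajectories, so merging exactly those copies leaves the output
  unchanged — the true partition has ARD% = 0 up to round-off, and the true
  minimal $m$ is known by construction. This is the parameter-recovery
  fixture for all four methods.
* `random_compartmental_system(n)` draws log-uniform flows, volumes and
  partition coefficients (flows $10^{-1}$–$10^{0.5}$, volumes
  $10^{-0.5}$–$10$, $K_p$ $10^{-0.5}$–$10$ per time/volume unit) with
  first-order elimination from blood, so every draw is connected, mass
  balanced and stable with a finite AUC.

What the generators do not emulate: inter-tissue heterogeneity of real
organs (permeability limitation, nonlinear binding), measurement noise, and
the near-degenerate eigenvalue clusters of real whole-body models. Passing
the recovery tests shows the search machinery finds structure that is
exactly present; on real systems the structure is only approximate and the
achievable $m$ at a given tolerance is an empirical matter.

## Problem sizes and design choices in the test suite

The suite exercises enumeration up to the 32 767 partitions of 16 free
states into 2 blocks, NARS up to $10^5$ samples and SA at its default
$2 \times 10^4$-proposal budget on 6–8-state systems, where full enumeration
is available as the reference; the uniformity of the partition sampler is
checked against the seven partitions of four states into two blocks at
$10^5$ draws, and the Metropolis rule against its closed-form acceptance
probability at $10^5$ trials. Larger spaces (the $\sim 7.1$ million
partitions at $m = 4$ on 17 states) are supported by the constant-memory
iterator but are not part of the default suite; they are the reason the
enumeration API is an iterator and the hot path avoids constructing
partition objects.
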