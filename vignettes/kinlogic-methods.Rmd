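---
title: "Methods: kinetic logic, CTL synthesis, and hybrid Petri nets in kinlogic"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: kinetic logic, CTL synthesis, and hybrid Petri nets in kinlogic}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kinlogic)
```

This vignette is the package's own account of the science it
implements: the discrete formalism and its assumptions, the continuous
engine, the parameters that matter, what the synthetic generators do
and do not emulate, the numerical choices, and the places where the
design was genuinely open and a decision had to be made.

## The discrete formalism

An entity $n$ of a regulatory network takes qualitative levels
$x_n \in \{0,\dots,r_n\}$ (all Boolean in the shipped case study).
Each interaction $m \to n$ carries a threshold $j_{mn} \ge 1$ and a
sign. In state $x$, a regulator is a *resource* of $n$ when it
currently pushes $n$ up: an activator with $x_m \ge j_{mn}$, or an
inhibitor with $x_m < j_{mn}$ — the absence of an inhibitor helps. The
logical parameter table $K$ assigns every (entity, resource set) a
target level; totality of $K$ is enforced at construction and at
config-load time, with every missing row listed.

Dynamics are *asynchronous* and *unit-step*: state $x$ has one
successor per entity with $x_n \neq K_n(R_x(n))$, obtained by moving
that entity one level toward the target. This is deliberately not
jump-to-target, and not a synchronous or priority-class scheme (those
are out of scope): unit asynchronous steps are the standard
conservative abstraction when nothing is known about relative time
scales. A state where every entity sits at its target has no
successors — a fixed point, read biologically as a state the system
cannot leave (in the case study, the metastatic end-state).

The state graph is always built over the **full product space**
$\prod_n (r_n+1)$, not just the states reachable from a designated
initial state: the case-study zone lists cover all 32 states, and
fixed points unreachable from rest are still biologically meaningful.
A configurable cap (`max_states`, default $2^{20}$) guards against
accidental combinatorial blow-up.

## CTL evaluation and deadlock conventions

Formulas are evaluated by standard fixpoint labeling (least fixpoints
for `EF`/`EU`/`AF`/`AU`, greatest for `EG`/`AG`), linear in formula
size times graph size. Two conventions matter on graphs with
deadlocks, and the package fixes them explicitly:

* `EX φ` is **false** and `AX φ` **true** at a deadlock (no
  successors, so the existential fails and the universal holds
  vacuously).
* Path operators quantify over **maximal** paths: a path that ends in
  a deadlock counts as a complete path. Hence `AF φ` at a deadlock
  reduces to `φ`, and `EG φ` holds at a deadlock satisfying `φ`.

With these choices the classical dualities (`AX = ¬EX¬`, `AG = ¬EF¬`,
`AF = ¬EG¬`) hold on every graph, which the test suite checks on
random instances, alongside an independent naive path-enumeration
oracle on graphs of at most 64 states. Comparator atoms (`>=`, `<`,
…) beyond equality exist because multivalued synthetic networks need
them; the case study itself only uses `=`.

## Parameter synthesis

`filter_by_ctl()` re-implements the synthesis loop of the SMBioNet
approach: enumerate every admissible parameter table, build each
candidate's state graph, and keep the candidates whose graph satisfies
all supplied CTL formulas. The candidate space factorizes per entity,
so counting is a product of per-entity table counts and enumeration is
a deterministic odometer (lexicographic; last entity fastest).
Optional constraints:

* **Monotonicity** (Snoussi): adding a resource never lowers the
  target. The reference case-study table satisfies it.
* **Observability**: every regulator changes some table entry.

Both default to **off**, because the original selection procedure for
the case study does not record which options were active; the
unconstrained space for the case-study network has
$2^1 \cdot 2^4 \cdot 2^2 \cdot 2^8 \cdot 2^2 = 131{,}072$ candidates,
which the package filters in well under a minute. The evaluation mode
defaults to *initial-state* satisfaction (formulas must hold at the
supplied initial states), with an *all-states* mode available; the
case-study surrogate check uses the resting state $(0,0,0,0,0)$.

The exact CTL specification used to select the published reference
table exists only in supplementary material that is not redistributed
here; `compare_to_fixtures()` therefore reports the
"five accepted sets" check as **skipped** unless a transcribed formula
file is supplied, and the always-on surrogate asserts that the
reference table survives filtering by properties true of its own graph
(e.g. reachability of the metastatic deadlock).

## The case study and its free degrees of freedom

The shipped network fixes the coordinate order (IGF-1R/EGFR, ER-α,
BRCA1, p53, Mdm2). Six of the seven interaction signs are pinned by
the published description (receptor activation of ER-α; BRCA1
activating p53 while ER-α and Mdm2 repress it; p53 activating BRCA1
and Mdm2). The sign of p53 → ER-α is genuinely underdetermined, so
`confirm_sign_assignment()` brute-forces both options and keeps the
one reproducing the qualitative reference facts: the resting state's
successor set, the deadlock $(1,1,0,0,0)$ and its reachability, the
absence of cycles in the metastatic zone, oscillations connecting
zones P1 and P2a, and closure of P2b cycles. Exactly one option ("+")
passes; the pipeline errors loudly if neither or both do.

The zone rule keys on the two metastasis drivers: P1 (both off), P2a
(ER-α only), P2b (receptors on, plus the receptor-on states with p53
active but BRCA1 off), P3 (the rest: both drivers on). The carve-out
of the p53-active/BRCA1-off states from P3 into P2b is required to
reproduce the stored zone lists exactly; no mechanistic justification
for it is documented anywhere, so it is shipped as data
(`era_zone_scheme()`), not hard-wired.

### The cycle-census discrepancy

"Unique cyclic trajectories" is read here as *elementary directed
cycles up to rotation* — the only standard, tool-independent identity
for cycles of a finite graph. Under that reading, the reference graph
(32 states, 80 transitions) has **7** elementary cycles (three of
length 4, four of length 6), all avoiding P3, while the stored
reference census says **75**. This is a real, investigated
discrepancy, not a bug: the package's count is confirmed by an
independent rotate-and-deduplicate oracle, and an exhaustive sweep of
all 131,072 parameterizations (both candidate signs) finds no table
whose graph simultaneously has 75 elementary cycles, the published
deadlock, and cycle-free P3 — the handful of 75-cycle tables that do
exist contradict the other reference facts. Alternative identities
(rotations counted separately, closed trails, undirected cycles,
lasso or path counts between the named states) do not yield 75
either. The census value evidently originates from the counting
convention of the original analysis tool, which is not documented.
`compare_to_fixtures()` therefore reports `cycle_count: fail`
honestly; every other discrete fixture (32 states, deadlock,
reachability, the four zone lists of sizes 8/8/10/6) reproduces
exactly. A second fixed point, $(1,1,1,1,1)$, follows necessarily
from the reference parameter table (every entity at target); the
fixtures assert membership of $(1,1,0,0,0)$, not uniqueness.

## The continuous engine

Transitions fire continuously at mass-action rates
$v_t = k_t \prod_{p \in \text{in}(t)} x_p^{w_{pt}}$ over normal and
test inputs, gated to zero when any inhibitory input reaches its arc
weight. Normal inputs are consumed at $w v$, outputs produced at
$w v$; test inputs contribute to the rate with no net flux. The
inhibitory gate is a **hard threshold** by default (matching the
discrete reading of inhibition); a steep-sigmoid `smooth_gate` option
exists for stiff cases. Integration uses `lsoda` with relative
tolerance $10^{-6}$, absolute $10^{-9}$, dense output on a uniform
grid of 1001 points. Non-negativity needs no projection: mass-action
fluxes vanish as markings reach zero (the right-hand side clamps
negative excursions below integrator noise).

The stochastic engine fires unit token quanta with exponential
waiting times and the same propensity rule, and averages a fixed
number of runs from the same initial marking (seeded; the caller's
RNG state is untouched). It converges to the ODE for well-stirred
nets, which the suite checks on a one-reaction net at runs
$\in \{10, 100, 1000\}$.

### Reconstructed topologies

The two case-study net variants are constrained by their published
structural facts — 7 places, 8 transitions, 18 arcs each, ligand and
receptor starting at 5 tokens, every rate constant 1, an inhibitory
Mdm2 arc on ER-α production in the homeostatic variant, ER-α
suppression of p53 production and a conservative
Ligand → Complex → ER-α chain (no ER-α sink) in the pathological
one — but their exact wiring is available only as drawings. The
shipped topologies are one consistent reconstruction satisfying all
of those constraints plus the qualitative outcome contract
(homeostasis: every tumor suppressor settles above ER-α; disease:
ER-α plateaus at the initial ligand stock while the suppressors
decay). They live in config files, not code, precisely so that
alternative reconstructions can be dropped in and re-tested. Notable
choices: self-limiting production arcs (an inhibitory arc from a
transition's own product) implement saturating expression without
extra sink transitions; in the pathological variant, binding is
gated off once ER-α reaches level 2, which freezes a small residue of
free ligand (≈ 0.14) — this is what lets the disease condition show
*more* residual ligand than homeostasis, as the qualitative
comparison requires, while ER-α still accumulates ≈ 4.87 of the
5-token stock (within the 5% contract).

### The qualitative sign matrix

The homeostasis/disease comparison table is computed, not asserted:
for each readout entity the two plateaus (trailing 20% window at
$t = 100$) are compared; the larger side scores "+" (the other "−"),
upgraded to "++" when the gap exceeds 1.5 expression units, with a
0.05 tie margin. The thresholds are in the units of the token scale
(ceiling 5) and were fixed once from the reconstruction's design
targets: Mdm2 saturates at 2 in homeostasis (gap ≈ 2 → "++"), the
receptor retains ≈ 4 of 5 tokens (gap ≈ 1 → "+"), ER-α swings by
≈ 4.9 (→ "++"). Observation horizons default to 10/50/100 time units
and the stochastic engine defaults to 1000 runs, matching the
reference protocol; time and token units are dimensionless
throughout.

## Synthetic generators

`random_brn()` / `random_parameterization()` produce seeded,
reproducible networks with uniform signs and thresholds and optional
monotone tables (raw draws closed upward over subsets — every
monotone table remains reachable, though not uniformly). They emulate
the *structure* the analysis assumes — small multivalued networks
with signed thresholded edges and total parameter tables — and none
of the biology: no degree structure, no motif enrichment, no
parameter realism. Passing property tests on them certifies the
algorithms (oracle equivalence, dualities, partition properties), not
any claim about real regulatory networks. `motif()` adds four
hand-analyzed feedback archetypes (mutual inhibition, negative loop,
input chain, and the p53–Mdm2 oscillator that is the case study's
low-risk sub-loop) with machine-checkable expectation records, so the
pipeline self-tests on inputs with known dynamics.

## Problem sizes and determinism

The shipped analyses are sized to run interactively: the 32-state
case-study graph in milliseconds, the full 131,072-candidate
synthesis sweep in tens of seconds, ODE horizons of 100 time units in
under a second, and the run-averaged stochastic engine at 1000 runs
in seconds for the case-study nets. Tests use the same sizes, with
randomized property checks over a few hundred seeded instances.
Everything downstream of a seed is deterministic: enumeration order,
cycle canonicalization (minimum state first), writer output
(byte-stable YAML/CSV/DOT), and the fixpoint evaluator.

## Known limitations

* Michaelis–Menten kinetics are reserved but not implemented; the
  case study states mass action only.
* Cycle enumeration targets graphs of modest size (hundreds of
  states); it is exact, not symbolic.
* No fairness constraints, LTL/CTL*, or counterexample minimization;
  `find_paths()` provides simple witness paths only.
* The hard inhibitory gate makes the ODE right-hand side
  discontinuous; sliding regimes (production and consumption balanced
  exactly at a threshold) integrate slowly — use `smooth_gate` there.
* The stored reference cycle census is not reproducible under any
  identity this package could derive (see above); the diff reports it
  as a fail by design.
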