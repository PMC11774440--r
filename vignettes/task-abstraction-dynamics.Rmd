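---
title: "Gated linear networks on blocked curricula: model, reduction, and experiments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gated linear networks on blocked curricula}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gateflow)
```

## The learning problem

The package studies how task abstractions can emerge from plain gradient
descent in a linear network when some of its units behave like neurons:
fast, bounded, and nonnegative. The setting is a multi-task teacher–student
problem. Each of $M$ tasks is a linear map $W^{*}_m \in
\mathbb{R}^{d_{out} \times d_{in}}$ (a *teacher*) applied to
standard-Gaussian inputs, and tasks arrive in contiguous blocks of duration
$\tau_B$, cycling sequentially. The learner is never told which task is
active or when it switched.

The student is a gated linear network with $P$ pathways,

$$y = \sum_{p=1}^{P} c_p W_p x,$$

where each pathway couples a weight matrix $W_p$ (a *student*) with a
scalar gate $c_p$. Both are trained by gradient flow on
$\mathcal{L} = \mathcal{L}_{task} + \lambda_{norm}\mathcal{L}_{norm} +
\lambda_{nonneg}\mathcal{L}_{nonneg}$ with

* $\mathcal{L}_{task} = \tfrac12\lVert y^{*} - y\rVert^2$ (batch mean),
* $\mathcal{L}_{norm} = \tfrac12(\lVert c\rVert_k - 1)^2$ with $k = 1$ by
  default ($k = 2$ available), bounding total gate activity around 1,
* $\mathcal{L}_{nonneg} = \sum_p \max(0, -c_p)$, a hinge favouring
  nonnegative gates,

and with separate time constants
$\tau_w \frac{d}{dt}W_p = -\nabla_{W_p}\mathcal{L}$,
$\tau_c \frac{d}{dt}c_p = -\nabla_{c_p}\mathcal{L}$. The defining
constraint is a fast gate layer, $\tau_c < \tau_w$. Weights start small
(i.i.d. Gaussian, sd $\sigma_0/\sqrt{d_{in}}$ with $\sigma_0 = 0.01$) and
gates start at $1/2$. A `per_row` gate mode refines the gates to one per
pathway and output row, which is what makes row-wise (subtask) composition
expressible.

Under unit-covariance Gaussian inputs, the expected task loss has the
closed form $\tfrac12\lVert W^{*}_m - \sum_q c_q W_q\rVert_F^2$, and the
expected gradients follow from the error matrix
$E = W^{*}_m - \sum_q c_q W_q$ as $-c_p E$ (weights) and $-\langle W_p,
E\rangle$ (gates). *Expectation mode* integrates exactly these
deterministic flows; *minibatch mode* uses empirical gradients over freshly
sampled batches.

## Two learning regimes

With fast bounded gates the network passes through two phases on a blocked
two-task curriculum. Early on it behaves *forgetfully*: every block, both
students re-align toward the active teacher, overwriting what the previous
block built. Later the dynamics find a qualitatively different solution:
each student aligns with one teacher, and adaptation after a switch happens
almost entirely in the gates, which select the matching student within a
small fraction of a block. Knowledge is preserved (the mismatched student
is *protected*, because its gate closes much faster than its weights can
be overwritten), and switching accelerates with practice. A matched
control with $\tau_c = \tau_w$ and no gate regularization
([forgetful_baseline()]) never leaves the first phase.

```{r regimes, eval = FALSE}
teachers <- make_teachers(m = 2, d_in = 32, d_out = 8, seed = 1)
net <- gated_network(p = 2, d_in = 32, d_out = 8,
                     tau_w = 1.3, tau_c = 0.03, seed = 10001)
cur <- make_curriculum(n_blocks = 30, block_length = 1, n_tasks = 2)
traj <- simulate_dynamics(net, teachers, cur)
classify_regime(traj)   # "flexible"
autoplot(traj)
```

The regime classifier is our operationalization (the distinction is
described qualitatively in the literature this package models): a run is
*flexible* iff its final total alignment exceeds 0.9 **and** the mean
time-to-criterion (loss below 0.1) over the last quarter of blocks is lower
than over the first quarter. Both thresholds are exposed as arguments.

## Exact reduction to specialization coordinates

Because everything is linear, the expectation-mode dynamics close on a
small set of scalars: projecting each student onto the singular triplets of
the two teachers, $w^p_m = u^{*\top}_m W_p v^{*}_m$ (per mode), the flow
becomes

$$\tau_w \dot w^p = c_p\,\varepsilon, \qquad
  \tau_c \dot c_p = w^{p\top}\varepsilon - \lambda\nabla_{c_p}
  \mathcal{L}_{reg}, \qquad
  \varepsilon = y^{*} - \textstyle\sum_p c_p w^p.$$

This closure is exact when the students lie in the span of the teachers'
singular subspaces; [network_from_reduced()] builds such states, and the
test suite verifies that full and reduced trajectories then agree to
machine precision under identical Euler discretizations. (A generic random
initialization carries $O(\sigma_0^2 d_{out})$ out-of-subspace energy whose
Frobenius cross-terms enter the gate update, so exactness is stated on the
subspace.)

Specialization is measured by $\bar w_1 = w^1_1 - w^2_1$,
$\bar w_2 = w^2_2 - w^1_2$, $\bar w = (\bar w_1 + \bar w_2)/2$ and the gate
separation $\bar c = c_1 - c_2$, which obey

$$\tau_c \dot{\bar c} = \bar w_1 \varepsilon_1 - \bar w_2 \varepsilon_2,
 \qquad \tau_w \dot{\bar w} = \tfrac12 \bar c\,
 (\varepsilon_1 - \varepsilon_2).$$

These two equations exhibit the feedback loop behind the flexible regime:
specialized students make the gates move faster (the gate update scales
with both the alignment and the magnitude of $w^p$ — small initialization
attenuates it), and separated gates in turn drive specialization while
protecting the mismatched student.

### Closed-form symmetric adaptation

Under symmetry ($\bar w_1 = \bar w_2 = \bar w$, maintained on the gate
simplex $\sum_p c_p = 1$, i.e. strong L1 bounding), the ratio of the two
flows gives the separable ODE
$(\tau_c/\tau_w)\, d\bar c / d\bar w = 2\bar w/\bar c$ with first integral
$\bar w^2 - \frac{\tau_c}{2\tau_w}\bar c^2 = \text{const}$. From the fully
specialized state $(\bar c_0, \bar w_0) = (1, 1)$,

$$\bar w(\bar c) = \sqrt{1 - \tfrac{\tau_c}{2\tau_w}(1 - \bar c^2)}.$$

We derived this form by direct integration and certify it in the tests
against numerical integration of the defining ODE; note that a plausible
radical-free reading of the relation does not satisfy the ODE, so the
square-root form is the one implemented. Its content: while the gates
traverse from one task to the other ($\bar c: 1 \to -1$), specialization
dips by at most $\tau_c/2\tau_w$ and fully recovers — fast gates protect
knowledge, and the protection is perfect in the limit
$\tau_c/\tau_w \to 0$.

```{r fig4e, eval = FALSE}
ba <- block_adaptation(tau_c = 0.18, tau_w = 1)
autoplot(ba)    # simulated (c-bar, w-bar) path with the closed form dashed
```

`block_adaptation()` integrates one full adaptation block from the
specialized state with $\lambda_{norm} = \lambda_{nonneg} = 1000$ (which
keeps $\sum_p c_p$ within about $10^{-3}$ of 1); `constrain_sum = TRUE`
instead imposes the simplex exactly, which is what the conserved-quantity
property tests use.

## Numerical choices

* **Integrator (full model).** Explicit Euler with default
  $dt = \tau_c/50$, implemented in C++; $dt$ is snapped to an integer
  divisor of $\tau_B$ so block boundaries coincide with steps, and a guard
  rejects $dt > \tau_c/10$. A divergence check (loss $> 10^6$) aborts with
  the offending $dt$. Convergence is verified by a step-halving test
  (final loss changes by $<1\%$).
* **Integrator (reduced model).** `deSolve::lsoda` by default (the strong
  regularization makes the gate flow stiff; adaptive stepping resolves it),
  with `rtol = 1e-8`/`atol = 1e-10` defaults, tightened in the
  conservation tests. A fixed-step Euler mode exists solely to mirror the
  full model's discretization in exactness comparisons.
* **Recorded loss.** Always the closed-form expected task loss, also in
  minibatch mode, so timing metrics carry no sampling jitter.
* **Kinks.** Subgradient 0 at $c_p = 0$ for both the hinge and the L1 sign
  — gates start at $1/2$ and essentially never sit exactly on a kink.
* **Seeds.** Teacher construction, weight initialization and minibatch
  sampling are seeded independently; expectation-mode runs are
  deterministic given the initialization, and minibatch runs are
  bit-reproducible given the data seed.
* **Per-row regularization.** In `per_row` mode the two penalties act
  independently on each output row's gate vector $(c_{1,i},\dots,c_{P,i})$,
  preserving the mixture interpretation row by row. How (or whether) rows
  should share regularization is genuinely open; this is the simplest
  choice consistent with the scalar-gate model.

## The experiment suites and their problem sizes

All experiments generate their own data; sizes were chosen once as
desk-scale settings that exhibit the phenomena crisply.

* **Regime comparison** (`run_regime_comparison()`): $M = P = 2$,
  $d_{in} = 32$, $d_{out} = 8$, $\tau_w = 1.3$, $\tau_c = 0.03$,
  $\lambda = 1$, $\tau_B = 1$, 30 blocks, 10 seeds; the forgetful control
  shares each seed's initialization.
* **Composition** (`run_task_composition()`,
  `run_subtask_composition()`): $M = P = 3$; phase 1 trains 18 blocks on
  teachers A, B, C; phase 2 cycles the pairwise sums A+B, A+C, B+C (task
  composition, scalar gates) or row-interleavings (subtask composition,
  per-row gates) for 9 blocks. Speed is compared by per-seed median
  time-to-criterion in phase 2.
* **Phase diagram** (`run_phase_diagram()`): $8 \times 8$ grid of block
  length against gate timescale (or a regularization multiplier), 5 seeds
  per cell, $d_{in} = 16$, $d_{out} = 4$, total training time fixed at 48
  so short-block cells see more switches but the same amount of data.
  `block_length_monotonicity()` summarizes the claim that specialization
  grows with $\tau_B$ at fixed total time; because alignment saturates at
  1 deep in the flexible region (rank statistics degenerate under ties),
  it is evaluated on the regime-boundary band — the grid rows whose
  alignment actually varies across block lengths (range $> 0.1$).
* **Switch-speed trend** (`run_switch_trend()`): post-switch loss (first
  10% of each block) regressed on block index, 24 blocks, 10 seeds, block
  length 2. The longer block is deliberate: a switching-speed comparison is
  only well posed when both models re-master the task within every block
  (as human subjects do in the alternating-task experiments this mirrors).
  With one-unit blocks the forgetful control never converges in-block and
  its window-mean loss instead drifts slowly toward the two-teacher
  compromise, which measures nothing about switching.

## Deep-linear generalization

`deep_network()` drops the pathway architecture entirely: a two-layer
fully-connected linear network $y = W_2 W_1 x$ in which the second layer
learns faster ($\tau_2 < \tau_1$) and carries the gate-style regularizers
per output row ($W_2$'s entries play the role of gates; the regularizer
form for this layer is not uniquely dictated, and mirroring the gate
penalties row-wise is the natural transfer). $W_1$ starts small like the
shallow students; $W_2$ starts at scale $1/\sqrt{hidden}$ — a tiny second
layer would put the network on the deep-linear plateau, whereas an
order-one fast layer immediately routes learning signal to $W_1$ and is
itself reshaped quickly by its regularizers.

On the blocked curriculum this network reproduces the flexible signatures:
the first layer splits into teacher-specialized row groups, the second
layer develops emergent gates that alternate with the task (visible as
block-diagonal mass after [sort_network()]), and late-block adaptation
happens primarily in the fast layer. Without the timescale split and
regularization it stays forgetful. The sorting analysis assigns each hidden
unit to the teacher with the best absolute row-cosine (ties to the lowest
index), permutes both layers consistently (which provably leaves the
input–output map unchanged), and reads one gate per group as the mean of
its second-layer block.

## What the generator does and does not emulate

Inputs are i.i.d. standard Gaussian; teachers are random with exactly
orthogonal responses (a correlated-teacher hook exists for related tasks);
labels are noiseless; blocks are perfectly periodic. Real task streams have
input correlations, label noise, overlapping task structure and irregular
block lengths — none of which the theory here requires, but none of which
the tests exercise. Passing tests therefore validate the mechanism (gating
dynamics, protection, composition, regime boundaries) under the stated
idealized conditions, not performance on natural data. The nonlinear
large-scale behaviour of the mechanism is out of scope for this package.

## Known limitations

* The reduction and its coordinates are implemented for $M = 2$ teachers
  (and scalar gates), per its derivation; `project_network()` refuses other
  cases rather than silently extrapolating.
* The closed form assumes symmetry and the strong-L1 limit; away from
  those, `simulate_reduced()` is the tool.
* Explicit Euler is first-order; conclusions drawn at the default step are
  backed by the halving test, but stiff settings (very small $\tau_c$ with
  very large $\lambda$) should use the reduced lsoda path.
* `total_alignment()` uses exhaustive assignment search, exact but
  factorial in $\max(P, M)$ — fine for the $P, M \le 4$ regimes studied.
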