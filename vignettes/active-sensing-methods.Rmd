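---
title: "Cost-sensitive control of active sensing: models, solvers and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cost-sensitive control of active sensing: models, solvers and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(cdac)
```

This vignette documents the models implemented in `cdac`, the numerical
choices behind the solvers, what the simulator does and does not emulate, and
the design decisions that were genuinely open.

## 1. The inference model

A searcher must identify which of $k$ locations holds a target. While
fixating location $j$ it receives i.i.d. binary observations: $x = 1$ with
probability $\beta$ if $j$ holds the target and $1-\beta$ otherwise,
$\beta \in (0.5, 1]$. The belief state $\mathbf p_t$ (posterior over target
location) is updated multiplicatively by the likelihood and renormalized
(`bayes_update()`). Three consequences the tests rely on:

* **Martingale**: the predictive-weighted average of posteriors equals the
  prior. This is what makes one-step lookahead on the *expected posterior*
  uninformative, and is checked to $10^{-12}$.
* **Monotone informativeness**: observing $x=1$ at $j$ never decreases
  $p_j$ (for $\beta > 0.5$).
* **Absorbing corners**: a degenerate belief never moves.

The observation alphabet convention — "1" is the outcome favoured by the
target — is an implementation choice; the task's motion-direction evidence
is not intrinsically signed. Nothing downstream depends on the labelling.

In the peripheral-vision task the fixation set is enlarged to
$\{l_1,l_2,l_3,l_{12},l_{23},l_{13},l_{123}\}$ and each observation is a
binary 3-vector, one component per stimulus, with per-component reliabilities
$1 > \beta_1 > \beta_2 > \beta_3 > \beta_4 \ge 0.5$ assigned by geometry:
direct fixation $\to \beta_1$, the two neighbours of a midpoint
$\to \beta_2$, all three from the centre $\to \beta_3$, any far stimulus
$\to \beta_4$. Belief updates multiply the three component likelihoods.

## 2. The behavioural cost and the C-DAC solver

A search costs $c$ per observation, $c_s$ per fixation switch and 1 per
wrong declaration (the unit error cost is a normalization; $c$ and $c_s$
are therefore expressed in error-cost units). The optimal policy is
stationary in the belief, so the package uses the incremental form of the
stopping cost ($1 - p_i$); time and switch costs already incurred are sunk
and do not affect the argmin.

`solve_cdac()` runs value iteration on the uniform composition lattice of
the simplex (resolution $n = 200$, i.e. 201 points per edge, `belief_grid()`),
initialized at the stopping cost. Because the Bellman operator is monotone
and the initial guess is an upper bound, sweeps are pointwise non-increasing;
iteration stops when the sup-norm change drops below `tol` ($10^{-6}$ by
default, typically 15–150 sweeps depending on $c$). The expectation over the
binary (or 8-outcome peripheral) observation alphabet is exact; only the
evaluation of $V$ at off-grid posteriors is approximate.

**Interpolation.** Posteriors of grid points fall off-grid, so $V$ is
evaluated by barycentric interpolation. The triangulation is the
Freudenthal/Kuhn triangulation applied in *cumulative* coordinates
$v_j = \sum_{i \ge j} p_i$ — the classical fixed-grid construction for
belief-MDPs — because in raw coordinates the Kuhn cells cross the simplex
boundary, whereas in cumulative coordinates every cell vertex maps back to a
valid lattice composition. The scheme reproduces affine functions exactly
(tested to $10^{-10}$), keeps interpolated values inside the cell's vertex
range, and was preferred to nearest-neighbour lookup because the value
function is smooth and concave between policy boundaries; the residual
$O(h^2)$ error is what the two-location oracle test bounds (the $k=2$
grid solution agrees with an exact, grid-free finite-horizon recursion to
$2 \times 10^{-4}$). Since each grid point's posterior under each
(fixation, outcome) pair is fixed, the interpolation weights are assembled
once into sparse matrices and every sweep reduces to a handful of sparse
mat-vecs.

**Declaration rules.** The Bellman recursion as written allows declaring
*any* location (`declare_rule = "any"`); the human task, in which the
response selects the last-viewed patch, corresponds to declaring only the
fixated location (`"current"`). Both are implemented; solver-level
properties are stated under `"any"` (the literal recursion) and the
behavioural simulations of the human task use `"current"`. The peripheral
task always uses `"any"`, because intermediate fixations cannot themselves
be targets.

**Tie-breaking** in the policy argmin is deterministic and documented:
declaring beats fixating at equal value; among declarations the lowest
index wins; among fixations the current location wins, then the lowest
index. One consequence worth knowing: the solved *values* are
permutation-equivariant to machine precision, but the lowest-index
convention makes a small fraction of boundary *actions* (~2% of grid
points) non-equivariant by construction.

**Stopping bound.** For the foveal task the package provides the closed-form
threshold $p^*$, the larger root in $(0,1)$ of
$(2\beta-1)p^2 - (2\beta-1)(1-c)p + c(1-\beta) = 0$: declaring $i$ is
optimal wherever $p_i > p^*$. It is verified by substitution to $10^{-10}$
and, on the solved grids, $\{p_i > p^*\}$ is contained in the computed
stopping region.

## 3. Comparator policies

**Infomax** fixates to minimize expected cumulative future posterior
entropy. It prescribes no stopping, so the package augments it with a
threshold on the maximum belief, defaulting to $p^*(\beta, c)$. Two
formulations of the entropy recursion were possible because the horizon of
the cumulative sum and its interaction with stopping are underdetermined:
the package's default treats thresholded beliefs as absorbing with zero
future entropy and iterates to convergence; a finite-horizon variant
(`horizon = <int>`) exists for sensitivity checks and agrees with the
converged solution once the horizon exceeds typical absorption times. The
Infomax value and policy are independent of the current fixation by
construction, which the tests assert bit-exactly.

**Myopic C-DAC** evaluates the one-step value literally, with the
minimum over post-continuation declarations taken *outside* the outcome
expectation, exactly as the formula is written. By the martingale this makes
the expected posterior equal the current belief, with two consequences the
tests pin down: continuing at the current location is never chosen, and
under `declare_rule = "any"` the literal policy stops everywhere (immediate
stopping dominates every continuation). The non-degenerate myopic policy is
the `"current"`-rule one, which matches the asymmetric policy maps of the
full solver in attenuated form: its stopping boundary sits at
$\max_j p_j - p_{\text{cur}} = c + c_s$, so a switch-cost change moves far
fewer of its actions than C-DAC's (the package quantifies "boundary shift"
as the count of grid points whose action changes between $c_s = 0$ and
$c_s = 0.1$, because the stopping-region symmetric difference alone is
dominated by the exact $c_s$-width band the myopic boundary sweeps).

**Random baseline** fixates uniformly until the maximum belief crosses a
threshold. It stands in for greedy probability-of-detection policies, which
on this task are close to random.

**Accuracy matching.** `calibrate_threshold()` bisects a policy's stopping
threshold until its simulated accuracy matches a target (each evaluation
re-simulates with the same master seed, making the accuracy curve
deterministic and approximately monotone). Used to compare policies at
matched accuracy in the peripheral task.

## 4. Value-function approximations

Both approximate solvers follow the same sweep scheme: initialize values at
the stopping cost on $m$ random (uniform-Dirichlet) belief points, fit a
surrogate, then repeatedly resample $m$ fresh points, back them up through
the current surrogate, and refit. Surrogate evaluations are clipped to
$[0,1]$ — values are error probabilities plus bounded continuation terms —
and clip events are counted in the returned object.

* **RBF**: 49 Gaussian bases, $\sigma^2 = 0.05$, $m = 200$, centred on a
  uniform $7\times 7$ lattice over the first two belief coordinates
  (embedded in the simplex plane; no coordinates for the lattice are
  canonical, and covering the bounding box keeps edge coverage uniform).
  The fit is ridge-regularized least squares computed through the SVD
  (ridge $10^{-8}$), because the overlapping Gaussians make the basis
  numerically rank-deficient and normal equations would square the
  condition number. A finite Gaussian lattice cannot represent even a
  constant exactly — the unregularized least-squares residual of a constant
  is already $\sim 7\times10^{-3}$ from boundary ripple — so fit quality is
  asserted relative to the exact least-squares optimum, not to zero.
* **GPR**: squared-exponential Gaussian-process posterior mean with an
  empirical constant mean function; length scale 1, signal variance 1,
  noise variance 0.1, $N = 200$ points; Cholesky factorization with jitter
  escalation. With `ard = TRUE` the per-dimension length scales and both
  variances are re-learned each sweep by marginal-likelihood maximization
  (Nelder–Mead on log-parameters); on the reference task ARD shortens the
  length scales to $\sim 0.15$ and visibly sharpens the policy.

**Convergence.** The natural criterion — a small relative change of the
fitted weight vector — turns out to be ill-posed under this scheme: with
condition number $\sim 10^{11}$ the weights are not identifiable, and they
change by $O(0.1\!-\!2)$ between refits of the *same* function on fresh
random designs. Even in function space, per-sweep resampling imposes a
noise floor of roughly 0.3–1% relative change. Convergence is therefore
declared when the relative $\ell_2$ change of the surrogate's predictions
on a fixed probe sample (500 points drawn once per run) falls below
`tol = 0.02`, a level chosen to sit above that measured floor. Under this
criterion both approximations converge in well under 10 sweeps across
seeds. Sweep trajectories are bit-reproducible given the configuration
seed.

A known limitation, quantified in the test suite: at the printed GPR
hyperparameters the squared-exponential kernel with unit length scale keeps
correlations above 0.37 across the whole simplex, so the surrogate cannot
track the policy boundaries sharply; its grid-policy agreement with the
exact solver plateaus near 0.85 even when fitted directly to the exact
value function, whereas the RBF surrogate reaches ~0.93 and ARD ~0.91.

## 5. The trial simulator

`simulate_trial()` rolls a policy out: observe at the current fixation,
update the belief, consult the policy, and either switch/extend fixation or
declare. Policy lookups during simulation use the *nearest* grid point —
actions are categorical, so interpolating them is meaningless and the grid
is fine (201 per edge). The policy is consulted only after at least one
observation, matching a task in which a response requires having looked. A
safeguard cap (default $10^4$ steps) truncates pathological runs and counts
them as errors. One model time step is one observation; no conversion to
physical time is attempted, and durations are reported in steps.

`run_experiment()` draws i.i.d. targets from a condition distribution
(uniform 1:1:1 or biased 1:3:9 with mass $9/13$ on the labelled patch),
derives one sub-seed per trial from the master seed (so per-trial results
are order-independent), and logs one CSV row per trial with the realized
cost decomposition $c\cdot\text{steps} + c_s\cdot\text{switches} +
\mathbf 1\{\text{error}\}$ enforced as an invariant.

**Initial fixations.** For the confirmation-bias analysis the simulator
forces the first fixation uniformly across the three stimulus locations and
the analysis then conditions on it, mirroring an analysis of trials that
began at each labelled patch; left to the policy, a biased prior would
all but always attract the first fixation to the "9" patch and empty the
other cells. For behavioural-prediction comparisons the initial fixation is
policy-chosen (the value-minimizing location, lowest index on ties), and in
the peripheral task it is the centre $l_{123}$ with a uniform prior.

**What the simulator does not emulate**: covert attention, saccade
kinematics and physical durations, block-order effects and across-trial
prior learning (the prior is given per condition), and eye-tracker noise.
Passing the behavioural tests therefore shows that the *policies* generate
the qualitative signatures under the stated conditions, not that the
generator reproduces human data quantitatively.

**Scoring.** The experiment's incentive scheme is available as
`score_trial()`: $100 - 12.5\,\text{s} - 25\cdot\text{switches} \pm 50$.

## 6. Analysis layer

`summarize()` reports accuracy, mean steps, switches and cost with standard
errors, enforcing the cost-decomposition identity. `confirmation_bias_table()`
conditions on the first fixation, pools the "1" and "3" patches (few trials
begin there), computes hit and false-alarm rates of declaring the
first-fixated patch, and mean first-fixation dwell separately for
target-present and distractor first fixations on correct trials; cells
below a minimum count are flagged `NA` rather than estimated.
`compare_policies()` simulates policy × environment cells under one master
seed, so comparisons are paired; each ordinal claim is reported
individually at a 3-standard-error margin rather than through an omnibus
test, because the claims are per-panel. Problem sizes used throughout the
package's own checks: grid resolution 200, $10^4$ trials for behavioural
contrasts, $1.5\!-\!2\times10^3$ for quick unit-level contrasts.

## 7. Known limitations

* Exact solving is exponential in $k$ (the grid has $O(n^{k-1})$ points);
  $k \le 4$ is practical, matching the approximation modules' purpose.
* The GPR surrogate at the standard hyperparameters is systematically too
  smooth (see §4); use ARD or the RBF variant when policy fidelity matters.
* The myopic policy is only meaningful under the declare-current rule; its
  declare-any form degenerates to immediate stopping.
* Infomax's stopping threshold is extrinsic; all its context sensitivity
  enters through that single scalar, which is exactly why it cannot adapt
  to switch costs.
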