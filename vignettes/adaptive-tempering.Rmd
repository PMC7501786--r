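---
title: "Adaptive Metropolis-coupled MCMC: model, tuning rule and testbed"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adaptive Metropolis-coupled MCMC: model, tuning rule and testbed}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Posterior distributions in Bayesian phylogenetics are frequently multimodal:
sets of tree topologies with high posterior probability ("tree islands") are
separated by intermediates so unfavourable that a Metropolis–Hastings chain
essentially never crosses between them. Replicate MCMC analyses then
disagree — each stuck on the island its starting point happened to reach.
Metropolis-coupled MCMC (MC³, parallel tempering) addresses this by running
$n$ chains, all but one *heated*: chain $i$ raises the posterior ratio in
its acceptance probability to a power $\beta_i \le 1$, flattening the
target so that hot chains cross probability valleys freely. Occasionally
two chains are proposed for a *swap*; the one cold chain ($\beta_1 = 1$)
remains a valid sampler of the posterior while benefiting from states that
heated chains carried across barriers.

The practical difficulty is choosing the temperatures. This package
implements an adaptive scheme in which the entire ladder is generated from
one scalar spacing parameter that is tuned *during the run* toward a target
swap-acceptance probability, so that setting up a tempered analysis
requires no more tuning knowledge than a plain MCMC run.

## Acceptance rules

All kernels work in log space (`mh_log_accept()`, `heated_log_accept()`,
`swap_log_accept()`). With posterior $\pi$, proposal density $g$ and
temperature $\beta_i$:

* within-chain move $x \to x'$:
  $R_\mathrm{heated} = \min\left[1,
  \left(\frac{\pi(x')}{\pi(x)}\right)^{\beta_i}
  \frac{g(x\mid x')}{g(x'\mid x)}\right]$.
  The whole posterior (likelihood and prior) is tempered; the Hastings
  factor is not. An option to heat only the likelihood is deliberately not
  provided.
* swap of chains $i, j$:
  $R_{ij} = \min\left[1,
  \frac{\pi(x_i)^{\beta_j}\pi(x_j)^{\beta_i}}
       {\pi(x_i)^{\beta_i}\pi(x_j)^{\beta_j}}\right]
  = \min\left[1, e^{(\beta_i-\beta_j)(\log\pi(x_j)-\log\pi(x_i))}\right]$,
  symmetric in the pair labelling.

Proposals whose log posterior is $-\infty$ are rejected rather than raising
an error; chains must be *initialized* in the support.

## Temperature ladders

Two schemes generate $\beta_1 = 1 > \beta_2 > \dots > \beta_n$ from a
single spacing scalar:

* **incremental**: $\beta_i = 1/(1 + (i-1)\,\Delta t)$;
* **beta-quantile**: $\beta_i = 1 - F\!\left(\frac{i-1}{n}\right)$ with $F$
  the Beta($1, b$) distribution function, i.e. $\beta_i = (1-(i-1)/n)^b$
  in closed form (exact for $\alpha = 1$, so no special-function code is
  involved). The argument divides by $n$, not $n-1$, so the hottest chain
  keeps $\beta_n > 0$.

Keeping a single tunable scalar under both schemes means the adaptation
machinery is scheme-agnostic. Per-pair independent temperatures would adapt
$n-1$ parameters and is out of scope by design.

## The adaptive tuning rule

Let `#exchanges` be the number of swap proposals since the start of the
run, $p_\mathrm{global}$ the accepted fraction over all of them, and
$p_\mathrm{target}$ the desired acceptance (default 0.234, the classic
optimal-scaling value; datasets with severe intermediate-state barriers
warrant lower targets, i.e. hotter ladders). After every proposed exchange
the spacing is updated as

$$\Delta t_\mathrm{new} = \max\left[0,\; \Delta t_\mathrm{current} +
  \frac{p_\mathrm{global} - p_\mathrm{target}}{\#\mathrm{exchanges}}\right]$$

subject to three safeguards, all on by default:

* **clamp**: a single update never moves the spacing by more than 0.001
  (`max_step`), protecting against over-adaptation early on when
  `#exchanges` is small and heated chains lag behind their new equilibria;
* **burn-in**: no updates during the first 100 proposed exchanges;
* **locally aware gate**: the update fires only when $p_\mathrm{global}$
  and $p_\mathrm{local}$ — the accepted fraction of the last 100 proposed
  exchanges — lie strictly on the same side of the target. Exact ties do
  not update (the rule is stated with strict inequalities); fewer than 100
  recorded outcomes use however many exist.

Because the step size is $O(1/\#\mathrm{exchanges})$, the ladder becomes
asymptotically constant and the (non-Markovian) adaptive sampler is
ergodic. The rule is self-correcting: acceptance above target grows the
spacing, which lowers future acceptance, and vice versa. The boundary
$\Delta t = 0$ is not absorbing: an all-cold ladder accepts every swap,
pushing $p_\mathrm{global}$ to 1 and the spacing back up.

The same update (and sign convention) is applied to the beta-quantile
parameter $b$: larger $b$ means a hotter ladder and lower acceptance.

### Convergence horizon of the global acceptance

A consequence of the clamp, the 100-exchange local window and the
$O(1/\#\mathrm{exchanges})$ step worth stating explicitly: when the
equilibrium spacing is far from the initial value (notably for *low*
targets, which need hot ladders), the spacing first climbs at the clamp
rate, passes the equilibrium by roughly (clamp × window-lag) before the
gate closes, and the cumulative $p_\mathrm{global}$ then needs many
exchanges to forget the transient — the correction per exchange is
$|p_\mathrm{global}-p_\mathrm{target}|/\#\mathrm{exchanges}$. At
$10^4$ proposed exchanges (a $10^6$-iteration run with swaps every 100)
the default and doubled targets are reached to within about $\pm 0.02$,
but the *halved* target (0.117) systematically undershoots by 0.03–0.05
when started from spacings at or below 0.01; the corresponding acceptance
checks in `tests/testthat/test-acceptance.R` show exactly this. The
$O(1/n)$ argument implies the gap closes at the $10^5$-exchange scale. We
report the measured values as they come out rather than re-scaling the
protocol.

## Engine mechanics

`run_mc3()` advances every chain `swap_interval` within-chain steps between
swap proposals (default 100 iterations; a `random_offset` option draws the
first swap time uniformly within one interval). On an accepted swap the two
chains exchange *temperature labels* — together with operator-tuning state
and logger binding — rather than their states: exchanging labels is
equivalent and O(1) regardless of state size. Each trace log therefore
follows a temperature, not a chain, and the rank-1 log is the posterior
sample. The new spacing after an update is applied to all chains
simultaneously, not only the swapped pair. Heated-chain logging is off by
default; `heated_logging = TRUE` enables it for the replicate-convergence
workflow (checking that heated traces agree across replicates helps detect
islands that even the hot end of the ladder fails to leave).

Randomness: one master seed spawns one L'Ecuyer stream per chain plus a
scheduler stream (pair choice, first-swap offset) and a swap-decision
stream. Chains therefore consume randomness independently of one another
and of the swap machinery; execution order between swap points cannot
affect results, a single-chain coupled run is bit-identical to plain MCMC
(`run_mcmc()`), and a checkpointed run (`write_checkpoint()` /
`resume_mc3()`) continues bit-for-bit — checkpoints serialize every double
at 17 significant digits, which round-trips IEEE doubles exactly.

## The phylogenetic testbed

The testbed posterior is deliberately minimal — its job is to exercise the
tempering machinery on a real tree space, not to cover substitution-model
breadth:

* **likelihood**: Jukes–Cantor (JC69) on a rooted ultrametric tree with a
  strict clock fixed at rate 1, computed by Felsenstein pruning over
  unique site patterns. With rate 1, node heights are in expected
  substitutions per site and coalescent units coincide. No per-node
  rescaling is performed: site partials are bounded below by roughly
  $0.25^{\,n}$, far from underflow at testbed sizes (tens of taxa); a
  zero site likelihood returns $-\infty$ and is rejected.
* **prior**: constant-size Kingman coalescent on the genealogy — interval
  contributions $-k(k-1)\tau/(2N_e)$ and $-\log N_e$ per coalescence —
  with a log-normal(0, 1) prior on $N_e$ unless it is fixed.
* **proposals**: nearest-neighbour interchange (its own inverse, zero
  Hastings), a uniform node-height move, and Uniform$(sf, 1/sf)$ scale
  moves on all internal heights and on $N_e$, whose Hastings–Jacobian
  correction is $(k-2)\log m$ for $k$ scaled dimensions.
* **simulators**: `simulate_coalescent_tree()` (standard Kingman) and
  `simulate_jc69_alignment()` (root drawn uniformly, states evolved down
  branches).

Validation follows the sample-under-the-prior logic: a prior-only run (zero
sites) must reproduce the prior. For four taxa the coalescent topology law
is known exactly — uniform over *ranked* histories, hence 1/18 per
caterpillar topology and 1/9 per balanced topology — and the suite checks
the sampled topology frequencies against it (chi-squared), along with a KS
test of the sampled $N_e$ against its log-normal prior. A recovery check
simulates six taxa × 1000 sites and requires the posterior median $N_e$
within [0.5, 2] of the true value 1.

What the generator does *not* emulate: among-site rate variation, unequal
base frequencies or exchangeabilities (no HKY/GTR), alignment gaps or
ambiguity codes, recombination, serially sampled tips, and non-constant
demography. Passing tests therefore demonstrate that the tempering engine
samples this well-specified testbed correctly — not that JC69 fits any real
alignment.

## Built-in toy targets

* `target_normal(dim = 400)`: an isotropic standard normal. The default
  dimension is chosen so the cold-chain log-posterior fluctuations
  ($\mathrm{sd} = \sqrt{d/2} \approx 14$) resemble a moderately sized real
  posterior; the equilibrium spacing for the default 0.234 target then
  falls near 0.08, inside the $[10^{-4}, 0.1]$ range of initial spacings
  the adaptation experiments start from. With only a handful of dimensions
  the log-posterior spread is so small that swap acceptance stays near 1
  until the ladder is implausibly hot, which is not the regime an adaptive
  spacing rule is meant to operate in.
* `make_island_target(n_islands, barrier_depth = 25, sd = 0.05)`: a 1-D
  mixture of equally weighted narrow modes at unit spacing whose
  inter-mode log-density valley is floored exactly `barrier_depth` below
  the peaks — a desk-scale analogue of tree islands with known mode masses
  ($1/n$ each, up to an $e^{-\mathrm{barrier}}$ remainder). A cold chain
  with the default proposal (window 0.35) is a within-mode sampler; the
  island experiments run three replicates started in different modes and
  require each replicate's occupancy within 0.1 of uniform.

Both run their within-chain updates in compiled code with a
uniform-window random-walk proposal (one uniform deviate per coordinate —
a deliberate choice over a Gaussian walk, whose deviates cost ~2.5
uniforms each at these dimensions) of matched variance
(window $= \sqrt{3}\,\sigma_\mathrm{step}$), and the window is inflated by
$1/\sqrt{\beta_i}$ per temperature so each chain's step stays proportional
to the width of the target it actually samples.

## Diagnostics

* `effective_sample_size()`: $N / (1 + 2\sum_k \rho_k)$ with the
  autocorrelation sum truncated by Geyer's initial-positive-sequence rule
  (stop before the first adjacent-lag pair with non-positive sum), clipped
  to $(0, N]$; constant traces return the documented `NA` sentinel. This
  truncation differs in dialect from fixed-maximum-lag trace analysers, so
  small numeric differences against those tools are expected.
* `ks_distance()`: exact sup-norm distance between two empirical CDFs.
* `clade_frequencies()` / `max_clade_support_difference()`: clades are
  descendant taxon sets of rooted trees; replicate runs are compared
  against a reference built by concatenating runs, with a leave-self-out
  option so a run is not compared against a reference containing itself.
* `diagnose_runs()` / the `diagnose` CLI verb apply a default burn-in of
  10% of each trace — a documented package default; the upstream
  experiments it mirrors do not state one.

## Problem sizes used by the test suite

Chosen as desk-scale versions of the experiments the engine is meant for:
acceptance-convergence runs use 4 chains × $10^6$ iterations (swaps every
100) per target/initial-spacing combination; the replicate-stationarity
check uses 20 adaptive runs of $10^5$ iterations; the island comparison
uses $10^5$-step plain chains against 4-chain × $2\times 10^6$-iteration
tempered runs; correctness KS checks thin $2\times 10^5$–$4\times 10^5$
iteration runs to near-independence. Exact stationary-distribution oracles
(enumerable targets, eigenvector comparisons at $10^{-10}$) and
closed-form/brute-force unit oracles cover the pieces that admit exact
answers.

## Known limitations

* The adaptation rule tunes one scalar; ladders whose optimal shape is not
  well approximated by either scheme would need per-pair temperatures,
  which is explicitly out of scope.
* Low target acceptances reached from cold initial spacings converge on
  the $10^5$-exchange horizon, not the $10^4$ one (see above).
* The engine runs chains serially; the contract is seed-determinism and
  serial-equivalence, and no parallel backend is provided.
* The testbed likelihood recomputes all site patterns per evaluation (no
  partial-likelihood caching); adequate at testbed sizes, not tuned for
  large alignments.
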