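---
title: "Methods: measuring the tempo of lineage diversification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: measuring the tempo of lineage diversification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

divtempo asks a classic macroevolutionary question of a time-calibrated
phylogeny: did a clade accumulate lineages at a constant rate, or did it
diversify in bursts? The motivating setting is a hyper-diverse clade (think
of a beetle subfamily with ~20,000 species) whose chronogram samples only a
few hundred tips, compared against a species-poor sister clade. This
vignette explains the statistical machinery, the modelling conventions the
package commits to, and what its simulation-based tests do and do not
establish.

## The data and their reduction

Every statistic operates on a *chronogram*: a rooted, binary, ultrametric
tree whose branch lengths are in millions of years (My). Validation
(`as_chronogram()`) enforces binarity, unique tip labels and ultrametricity
within a relative tolerance of `1e-6` of tree height — dating software
emits rounded branch lengths, so exact ultrametricity would be too strict,
while a looser default would let genuinely non-clocklike trees slip
through. A `coerce_ultrametric` option extends terminal branches to the
deepest tip depth, and polytomies can be resolved deterministically into
zero-length binary splits; both transformations are reported. Any root edge
is dropped, because every likelihood below is conditioned on the crown.

A chronogram is reduced (`branching_times()`) to its node ages
$x_2 \ge x_3 \ge \dots \ge x_n$ (time before present; $x_2$ is the crown
age), internode durations $g_k = x_k - x_{k+1}$ during which exactly $k$
reconstructed lineages existed, and the total lineage-time
$T = \sum_{k=2}^n k\,g_k$, which satisfies the algebraic cross-check
$T = 2x_2 + \sum_{i \ge 3} x_i$ (asserted to $10^{-9}$ relative in the test
suite). Tied ages from zero-length branches are carried and flagged; they
contribute $g_k = 0$ and leave every statistic defined.

## Point statistics on richness

Two clades descending from one speciation event are the same age, so their
relative extant richness is itself evidence about diversification.
`slowinski_guyer(r, s)` computes the equal-rates-Markov tail probability:
under the null that every lineage is equally likely to split, all ordered
divisions of $n = r+s$ species between two labelled sisters are equally
probable, so the chance that the named clade holds at most $s$ is
$s/(n-1)$. The one-tailed convention is the default: for richness 19,811
against 655 it gives $655/20465 = 0.032$, and the test suite checks this
against explicit enumeration of splits. The two-tailed version doubles it,
capped at 1.

`ms_rate()` converts richness plus age into a net diversification rate
$r = \lambda - \mu$ under an assumed extinction fraction
$\varepsilon = \mu/\lambda$, using the stem and crown method-of-moments
estimators of Magallón & Sanderson (2001). The crown form reduces to
$(\ln n - \ln 2)/t$ at $\varepsilon = 0$; a "2:1 speciation:extinction"
assumption is $\varepsilon = 0.5$ and always lowers the estimate. Both
modes are provided because published rates frequently do not state which
age was used; for $n = 19{,}811$ and a 98.5 My crown the two forms bracket
[0.093, 0.100] per My.

The relative cladogenesis test (`rc_test()`) localises shifts: for each
branch, with $k$ lineages alive at its origin and $r$ of the $n$ tips
descending from it, the broken-stick tail probability is
$\binom{n-r}{k-1}/\binom{n-1}{k-1}$, Bonferroni-corrected by the number of
branches tested. Two caveats are built in. First, nested clades share
descendants, so an unusually diverse subclade drags all its ancestors
toward significance; the `sig_descendant` column supports the conservative
"shallowest significant branch" reading. Second, on a subsampled tree the
test sees only the sampled tips, and a caveat is emitted. The tail formula
is verified in the tests against brute-force enumeration of all
compositions for $n \le 12$.

## Whole-tree tempo: gamma, CR and MCCR

The gamma statistic standardises where a tree's nodes sit in time:

$$\gamma = \frac{\frac{1}{n-2}\sum_{i=2}^{n-1} T_i \;-\; T/2}
{T\sqrt{1/(12(n-2))}}, \qquad T_i = \sum_{k=2}^{i} k\,g_k .$$

Under a completely sampled constant-rate pure-birth process, $\gamma$ is
asymptotically standard normal; nodes clustered toward the root (an early
burst, later slowdown) push it negative. The CR test compares $\gamma$
with the normal null; the package defaults to the lower tail (reject a
constant rate when $\gamma < -1.645$ at $\alpha = 0.05$) because slowdowns
are the hypothesis of interest, and exposes the upper tail — results
record which orientation was used, since a positive observed gamma is only
interpretable against the upper tail. $\gamma$ is exactly invariant to
rescaling all branch lengths, a property the tests assert and the MCCR
implementation exploits.

Incomplete random sampling biases $\gamma$ negative: deep nodes are likely
to survive subsampling while shallow ones are not, so a constant-rate tree
sampled at 1% looks like a slowdown. The MCCR test (`mccr_test()`)
rebuilds the null: simulate the clade at its *true* richness under a
pure-birth process (unit rate, justified by scale invariance), subsample
to the observed tip count, and take the gamma distribution of those trees
as the reference. The package reports both the add-one estimator
$p = (1 + \#\{\gamma_{null} \le \gamma_{obs}\})/(R+1)$, which cannot be
exactly zero, and the plain proportion. The suite verifies that with
$N = 2000$ sampled to $m = 100$ the corrected 5% critical value falls far
below $-1.645$ and that the corrected test has its nominal size, while
the naive CR test over-rejects grossly on the same trees.

LTT curves (`ltt()`) and envelopes (`ltt_envelope()`) visualise the same
signal: envelopes are averaged on a relative-time grid (0 = crown,
1 = present, 256 points) because trees of different crown ages cannot be
averaged in absolute time; absolute My remain the unit everywhere else.

## Six likelihood models and their shared conditioning

`fit_all()` compares six reconstructed-process models by AIC
($-2\ln L + 2k$): pure birth ($k=1$), constant birth–death ($k=2$),
declining speciation SPVAR ($\lambda(t) = \lambda_0 e^{-kt}$, constant
$\mu$; $k=3$), rising extinction EXVAR ($\mu(t) = \mu_0(1-e^{-zt})$,
constant $\lambda$; $k=3$), and piecewise pure-birth models with one
(yule2rate, $k=3$) or two (yule3rate, $k=5$) abrupt shifts.

All six likelihoods are conditioned identically: the process starts with
two lineages at the crown, both survive to the present, and the
model-independent constant $\sum_{k=2}^{n-1}\ln k$ is retained — without a
single conditioning convention, AIC differences across models would be
meaningless. The time-varying likelihoods use the survival function of the
inhomogeneous birth–death process; writing $\rho(u) = \int_0^u
(\lambda - \mu)$ in backward time, a lineage alive at age $u$ leaves
descendants with probability $1/(1 + e^{-\rho(u)} I(u))$ where
$I(u) = \int_0^u \mu(s) e^{\rho(s)} ds$. This integral has no elementary
form for SPVAR/EXVAR and is evaluated by composite 15-point Gauss–Legendre
quadrature with panels anchored at the branching times and bisected until
successive estimates agree to $10^{-9}$ relative, accumulated in log space
to avoid overflow. The scheme is validated in the tests against
`stats::integrate` and, more stringently, by the analytic limit
identities: BD at $a=0$ equals pure birth (to $10^{-9}$), SPVAR at
$k=0$ equals BD (to $10^{-6}$), EXVAR at $\mu_0=0$ equals pure birth and
at $z \to \infty$ equals BD (to $10^{-4}$). Rate functions are specified
forward from the crown (the natural direction for "declining speciation")
and converted internally to the backward convention used everywhere else.

For the piecewise models, rates given the shifts are closed form
($\hat\lambda_j = B_j/L_j$: events over lineage-time per segment), so
fitting reduces to an exhaustive search over shift candidates: the union
of a 1-My grid and the observed branching times. An event exactly on a
boundary belongs to the older segment; candidates leaving any segment
without an event are rejected outright rather than fitted with a zero
rate, because $\lambda > 0$ is part of the model; likelihood ties go to
the older shift. The closed-form profile is checked against a generic
numeric optimiser to $10^{-5}$ relative log-likelihood.

**A caveat the package insists on.** The exhaustive shift search maximises
over a couple of hundred candidates, and that selection alone gains
several log-likelihood units even on constant-rate data — more than the
AIC penalty of the extra parameters. Raw AIC therefore tends to prefer
yule3rate even when the truth is a pure birth process. Conclusions about
abrupt shifts should rest on effect size (the fitted rates and shift
times, which *are* recovered accurately when shifts are real: the suite
shows the median fitted shift of a 0.08→0.02 drop at 41 My, sampled at
193 tips, lands within ±3 My) and on simulation-calibrated comparisons,
not on a raw ΔAIC of a few units. Likelihood-ratio tests for the nested
pairs are reported alongside. A second caveat: these likelihoods take the
sampled chronogram at face value — no sampling-fraction correction is
applied, matching the analysis design the package emulates, so on
subsampled trees fitted slowdowns partly reflect the sampling artifact
quantified by the MCCR machinery.

The birth–death model is optimised in $(r, a)$ — net rate and extinction
fraction, $r \in (10^{-8}, 10]$, $a \in [0, 1)$ — because that keeps the
frequently attained boundary $\hat a = 0$ reachable; the implied
$\hat\lambda$ and $\hat\mu = \hat\lambda \hat a$ are reported. SPVAR and
EXVAR use five documented deterministic starts seeded from the pure-birth
rate; optimiser failures raise after all starts fail, and a failed model
leaves a gap row in `fit_all()` rather than aborting the table.

## Simulators: what the synthetic data emulate

The package generates its own test beds; no external data are required.

* `simulate_yule(n, lam)` builds the conditioned pure-birth process
  forward: waits are $\mathrm{Exp}(k\lambda)$ while $k$ lineages exist,
  and after the $n$-th lineage the time to the present is a full
  $\mathrm{Exp}(n\lambda)$ waiting time (the time to the never-realised
  next event) rather than stopping at a birth — stopping at a birth would
  bias the final internode short. Topologies are equal-rates-Markov.
* `simulate_piecewise_yule()` takes shift times *before present*, so a
  forward simulation would be circular (the present is unknown until the
  end). It therefore samples inter-event times backward from the present
  with hazard $k\lambda(\tau)$; for constant rates this is exactly the
  forward construction (the $g_k$ are the same independent exponentials),
  and it anchors the segments where the fitted models expect them.
* `simulate_bd()` and `simulate_time_varying()` run the full forward
  process with extinction (the latter by thinning against a supplied or
  grid-estimated rate bound), stop when the extant count first reaches
  `n`, append the waiting time to the next event, prune extinct lineages,
  and retry (capped) if the process dies. First-passage conditioning is a
  simplification — the true process conditioned on $N(T) = n$ may cross
  $n$ and return — and is the reason parameter-recovery checks use
  generous (25–35%) bands on medians rather than exact distributional
  claims.
* `subsample_tips()` samples uniformly, as the MCCR null assumes. Real
  supraspecific sampling oversamples deep lineages, so a `depth_bias`
  option weights tips by their pendant edge length raised to a chosen
  exponent for sensitivity analysis; it is off by default.
* `harpaline_fixture()` packages a deterministic worked example shaped
  like the motivating study: a 19,811-species clade generated with rate
  drops 0.149 → 0.02 at 41 My and → 0.004 at 12 My (chosen so expected
  richness reaches ~19,800 at a crown age near 100 My), sampled to 193
  tips, and a 655-species constant-rate sister (λ = 0.080) sampled to 10,
  with the associated richness table.

Internally all simulators use flat parent/age arrays (no recursion), so
the 19,811-tip fixture builds in well under a second, and the MCCR fast
path computes subsampled branching times without materialising trees.

What passing these simulation tests shows — and what it does not: the
machinery is calibrated (gamma mean ≈ 0, variance ≈ 1, 5% rejection at
−1.645 on complete Yule trees; MCCR nominal size under random
subsampling) and has power where claimed. It does not show that real
chronograms satisfy the assumptions: non-random taxon sampling,
dating error, and among-lineage rate variation are all outside the null
models here and must be weighed when interpreting real data.

## Problem sizes used by the automated checks

The test suite uses 1,000 complete Yule trees of 100 tips for gamma
calibration; a 2,000-replicate MCCR null and 500 observed trees at
$N = 2000 \to m = 100$ for the size check; exhaustive-enumeration oracles
to $n = 20$ (splits) and $n = 12$ (compositions); 50 random trees for the
likelihood limit identities; and 100 replicates at 193 tips for the
shift-recovery and model-selection power checks. These sizes keep every
Monte Carlo standard error a few times smaller than the tolerance it is
checked against.

## An end-to-end run

`run_full_analysis()` sequences the whole study design over a
configuration (`analysis_config()`): per clade it computes the sister
test, MS rates at $\varepsilon = 0$ and $0.5$, gamma/CR/MCCR, the RC
table, the LTT curve with envelope, and the six-model table, records
every seed and setting in a manifest, writes optional TSV outputs with
metadata headers, and keeps completed stages when a stage fails.

```{r, eval = FALSE}
library(divtempo)
fx <- harpaline_fixture()
cfg <- analysis_config(
  clades = list(Harpalinae = fx$harpaline, Brachininae = fx$brachinine),
  richness = fx$richness,
  sister_pairs = list(c("Harpalinae", "Brachininae")),
  mccr_reps = 1000, envelope_reps = 1000, seed = 1)
res <- run_full_analysis(cfg)
res
```

## Known limitations

* No sampling-fraction-corrected likelihoods, diversity-dependent or
  trait-dependent models; the model set is deliberately the classic
  six-model comparison.
* First-passage conditioning in the extinction simulators (above).
* The RC test, by construction, cannot reject at cohort size $k = 2$
  after Bonferroni correction; imbalance evidence at the root is the
  sister-clade test's job.
* NEXUS dialects, node annotations and unrooted trees are out of scope
  for I/O; trees come in and out as plain Newick.
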