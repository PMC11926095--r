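---
title: "Cognitive profiles and classroom sociograms: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cognitive profiles and classroom sociograms: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(socioblocks)
```

## The model

`socioblocks` analyzes two joined data structures from school classrooms:
quintile scores of students on cognitive tasks, and directed peer-nomination
networks ("sociograms") with five layers — preferred and non-preferred
workmates, preferred and non-preferred playmates, and friends, each child
naming up to three classmates per question.

The scores are modeled as a bipartite graph between $U$ students and $T$
tasks. Each student $u$ carries a membership vector $\theta_u$ on the
$K$-simplex (their *cognitive profile*), each task $t$ a membership vector
$\eta_t$ on the $L$-simplex (its *cognitive demands*), and each latent group
pair $(k, l)$ a distribution $p_{kl}(s)$ over the five quintile scores. The
probability of observing score $s$ on link $(u, t)$ is

$$\Pr[s_{ut} = s] = \sum_{k,l} \theta_{uk}\,\eta_{tl}\,p_{kl}(s),$$

and observed links are independent given the parameters. This is a
mixed-membership stochastic block model for ordinal bipartite data: group
structure is inferred jointly for both node types, and nodes may belong to
mixtures of groups. With three student groups the fitted profiles order
along a single achievement axis (high / average / low), the network
analogue of the psychometric *g*-factor.

### Fitting

`fit_em()` maximizes the log-likelihood by expectation-maximization on a
variational lower bound. The E-step computes per-link responsibilities

$$\omega_{ut}(k, l) \propto \theta_{uk}\,\eta_{tl}\,p_{kl}(s_{ut}),$$

normalized over $(k, l)$; the M-step re-estimates $\theta_u$ by averaging
the task-side-summed responsibilities over the student's links (dividing by
the student degree $d_u$), $\eta_t$ symmetrically on the task side, and
$p_{kl}(s)$ as the share of cell $(k,l)$ responsibility carried by links
with score $s$. Each step can only increase the likelihood, which the test
suite asserts along whole trajectories.

Numerical choices, all overridable:

* **Initialization**: strictly positive flat-Dirichlet rows. Zeros are
  absorbing under the multiplicative updates, so the initializer never
  produces them.
* **Convergence**: maximum absolute parameter change $< 10^{-6}$, capped at
  500 iterations, 10 random restarts by default (5 restarts in the recovery
  experiments, 3 in the holdout experiments; restart seeds are derived from
  the top-level seed). The restart with the highest final log-likelihood is
  returned.
* **Degenerate inputs**: students or tasks with no observed links receive
  uniform memberships and are flagged; group pairs with zero total
  responsibility receive a uniform score distribution and are flagged; a
  link whose responsibility normalizer is exactly zero raises an error
  rather than silently renormalizing.
* **Label switching**: the model is identifiable only up to permuting
  student groups and task groups. `align_labels()` minimizes the total L1
  distance between score tensors, exhaustively for $K, L \le 5$.
* **Prediction ties**: the modal predicted score breaks ties toward the
  lower score, deterministically.
* Students assessed in two school years are treated as distinct user
  records per wave, preserving the one-link-per-(student, task) invariant.

### Model selection

`select_dimensions()` evaluates every $(K, L)$ on a grid by mean exact
holdout accuracy (40% of links hidden) and picks the smallest $K + L$ whose
accuracy is within one standard error of the grid maximum. A plain grid
with a one-standard-error parsimony rule replaces fancier hyperparameter
searches: the space is a small two-dimensional integer grid, so the
optimizer's identity is incidental while the parsimony intent is preserved.

## The synthetic-data generator

Because classroom-level school data cannot be redistributed, the package
ships a generator whose planted truth emulates the statistical structure of
such a study, and every estimator is validated by recovery against that
truth.

**Profiles.** Student memberships follow the empirically observed pattern:
one third of students are purely low-achieving (group II), one third mix
low and average (II–III simplex edge), one third mix average and high
(I–III edge), with the mixing weight uniform; high and low achievement
never mix directly.

**Score tensor.** Score distributions decay exponentially away from a peak
quintile, with peaks ordered high > average > low within every task group
and peak triples differing across task groups ((5,1,3), (4,1,2), (5,2,4)),
so task groups both are identifiable and carry predictive value. The decay
scale is deliberately small (0.15): with only ~10 observed tasks per
student, a student's position on a simplex edge is recoverable only if
individual scores essentially identify the emitting group. The information
floor makes this precise: with perfectly separated components the
minimax-ish error of the mixing weight $w$ from $T$ observations is that of
a binomial proportion, and averaging $2\,E|{\hat w} - w|$ over a uniform
weight gives a mean row-L1 error of $\approx 0.20$ for edge students
($\approx 0.13$ over the whole population) at $T = 10$. Recovery tolerances
tighter than that are unattainable for *any* estimator, and weakly
separated components push the floor far higher — the generator therefore
plants strongly separated components, mirroring the sharply defined
achievement groups this model family is designed to expose. A caveat
follows: passing recovery tests on these conditions demonstrates estimator
correctness, not that real score data are this clean.

**Sociograms.** Each student draws a nomination count uniformly from
{1, 2, 3} and selects distinct classmates without replacement with weight

$$w(u \to v) \propto \exp\!\big(-\lambda\, d(\theta_u, \theta_v)
  + \gamma\, \mathbf{1}[\text{same gender}] + \beta\, \theta_{v,\text{high}}\big),$$

a softmax form chosen as the simplest monotone link between planted effect
sizes and the downstream estimands. Negative layers ("would *not* work/play
with") flip the signs of $\lambda$ and $\beta$, making them cognitively
disassortative with an aversion to high achievers. The `play+` layer copies
each `work+` nomination with probability `overlap_copy` before drawing its
remaining nominations, planting a controllable work/play edge overlap.

Default effect sizes were fixed once, by design analysis rather than by the
phenomena they later produce: $\gamma = 1.3$ reproduces a same-gender edge
fraction near 70–75% under a realistic gender composition (46% boys, 40%
girls, 13% undisclosed, 1% other); $\lambda = 2$ and $\beta = 4.5$ are the
smallest round values whose planted effects a 25-student classroom detects
beyond two null standard deviations in at least nine classrooms of ten —
effects weaker than that are not usable as planted truths at this classroom
size, since single-classroom Spearman correlations need
$|\rho| \gtrsim 2/\sqrt{n-1} \approx 0.4$ to clear the band. The default
age series spans ages 6–15 with classroom sizes uniform on 20–30 and a
planted work/play overlap declining from 0.6 to 0.4.

What the generator does *not* emulate: longitudinal within-child dynamics,
task content, reciprocity and transitivity in nominations beyond what the
weights induce, and classroom-level heterogeneity in effect sizes.

## Sociogram statistics and their nulls

* **Edge overlap** between two layers is the Jaccard index of their
  directed edge sets. Nominations are directed and analyzed in their
  original form, so edges are compared as ordered pairs throughout; the
  overlap of two empty layers is defined as 0. Its null rewires each layer
  independently by directed double-edge swaps (default 10 × |edges|
  attempts), which preserve every student's in- and out-degree exactly;
  swaps creating self-loops or duplicate edges are rejected, and layers
  with no feasible swap are returned unchanged and flagged.
* **Cognitive assortativity** of a layer is
  $\log(d_{\text{connected}} / d_{\text{all}})$, where $d_{\text{connected}}$
  averages the profile distance over directed edges and $d_{\text{all}}$
  over all unordered within-class pairs (connected ones included). Negative
  values mean connected students are cognitively closer than chance. The
  distance is Euclidean on the membership simplex by default (L1 and cosine
  are available); the metric choice is an open design point, exposed as a
  parameter. The null permutes profile vectors among the classroom's
  students, keeping edges fixed. Zero mean distances (profile-identical
  classrooms, or edges only between identical profiles) make the log-ratio
  undefined; such classrooms are flagged and excluded from age averages,
  with exclusions counted.
* **Status** is PageRank on the directed nomination graph, oriented
  nominator → nominee so that receiving nominations raises status, with
  damping 0.85 (the conventional default; unstated in the source analyses)
  over the full roster — isolated students receive teleport mass. The
  association with achievement is the Spearman correlation between PageRank
  and the membership in the high (or low) group, computed per classroom and
  then averaged within age, never pooled across classrooms. Its null
  permutes membership vectors among students. Constant PageRank or
  constant memberships make the correlation undefined; flagged as above.
* **Gender homophily** is the same-gender fraction of edges whose endpoints
  both disclosed a binary gender; undisclosed ("no-answer"/"other")
  endpoints are excluded from numerator and denominator, since same-gender
  is undefined for them. The null shuffles gender labels within the
  classroom.
* **Age aggregation** averages per-classroom statistics within age
  (SEM $= s/\sqrt{n}$, undefined for a single classroom); per-age null
  means average the per-classroom null means, and the per-age null sd is
  that of the age average under independent classroom nulls,
  $\sqrt{\sum_c \sigma_c^2}/n$.

## Hypothesis-testing toolkit

Dependent variables are gated through a Shapiro–Wilk normality test at
$\alpha = 0.05$ (constant samples are non-normal by convention); the
pipeline then uses two-sided Mann–Whitney U tests for categorical
predictors and Spearman correlations (average ranks on ties) for continuous
ones. Effect sizes are Hodges–Lehmann estimates — the median of all
pairwise differences — with the classical distribution-free confidence
interval from the order statistics of the pairwise-difference set at the
Mann–Whitney critical value; that CI construction is the standard companion
of the estimator, chosen here because no method was specified for the
reported intervals. No multiple-testing correction is applied anywhere:
all p-values are per-comparison, which the output columns state plainly.

## Reproducibility and problem sizes

Every stochastic stage takes its stream from a single top-level seed fanned
out by hashing stage names, so whole runs are bit-reproducible while stages
remain independent. The validation experiments use a planted population of
500 students × 10 tasks at full coverage (recovery, grid selection over
1..5 × 1..5, 20 holdout splits at 40% hidden), 100–200 simulated classrooms
of 25 students for null calibration and power, and 200–300 rewiring or
permutation samples per null; these sizes give Monte-Carlo error comfortably
inside the tolerances asserted and keep a full run in the minutes range on
one core.

## Quintile construction

Raw task performances are converted per task to percentile ranks over the
full sample (ties receive average ranks) and binned at 20/40/60/80 into
quintiles 1–5. Values exactly on a boundary go to the lower quintile — the
rule is arbitrary but fixed and tested; tasks with fewer than five distinct
values are flagged as degenerate.

## Known limitations

* The EM fit finds local optima; restarts mitigate but do not eliminate
  this, and the number of restarts used in the original analyses of this
  kind is typically unstated.
* The planted generator's nomination model is an artifact of this package:
  real sociometric choice processes are unobserved, so planted-effect
  recovery validates the estimators, not any behavioral theory.
* The discrepancy profile's threshold ("high discrepancy" at ≥ 2 quintiles)
  is a stand-in for an unpublished definition and is exposed as a
  parameter.
* Classrooms are treated as independent; school-level clustering is not
  modeled.
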