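# socioblocks

Tools for studying how children's cognitive profiles relate to their social
relationships at school. The package is aimed at quantitative researchers in
education and network science who have (or want to simulate) two linked data
sets from the same classrooms: quintile scores of students on cognitive
tasks, and multilayer peer-nomination sociograms (preferred / non-preferred
workmates and playmates, and friends, each child naming up to three
classmates).

## What it computes

**Cognitive profiles.** Scores are modeled as a bipartite graph between
students and tasks with a mixed-membership stochastic block model (MMSBM):
student *u* has a membership vector θ<sub>u</sub> on the K-simplex, task *t*
a vector η<sub>t</sub> on the L-simplex, and each group pair (k, l) a score
distribution p<sub>kl</sub>(s) over the quintiles 1–5, with

&nbsp;&nbsp;&nbsp;&nbsp;Pr[s<sub>ut</sub> = s] = Σ<sub>k,l</sub> θ<sub>uk</sub> η<sub>tl</sub> p<sub>kl</sub>(s).

The model is fitted by variational expectation-maximization with restarts
(`fit_em()`), the numbers of groups are chosen by a holdout-accuracy grid
search with a one-standard-error parsimony rule (`select_dimensions()`),
and predictive quality is measured by exact and one-off (within one
quintile) holdout accuracy against a per-task mode baseline.

**Sociogram structure.** Layer overlap is the Jaccard index of directed
edge sets against a degree-preserving rewiring null (`jaccard_overlap()`,
`null_overlap()`, `overlap_by_age()`); gender homophily is the same-gender
edge fraction against a label-shuffling null.

**Profile–network interplay.** Cognitive assortativity of a layer is
log(d<sub>connected</sub>/d<sub>all</sub>) — the mean profile distance over
connected pairs relative to all within-class pairs, negative meaning
assortative — against a profile-shuffling null (`assortativity_log_ratio()`,
`assortativity_null()`). Social status is PageRank on the directed
nomination graph, rank-correlated with high/low-achievement membership
against a membership-shuffling null (`pagerank_status()`, `status_null()`).

**Statistics toolkit.** Two-sided Mann–Whitney U tests, Spearman
correlations, Shapiro–Wilk normality gatekeeping, and Hodges–Lehmann shift
estimates with distribution-free 95% confidence intervals. No
multiple-testing correction is applied; p-values are per-comparison.

A synthetic-data module (`make_planted_params()`, `sample_ratings()`,
`make_age_series()`) generates classrooms with planted cognitive profiles
and nomination layers with tunable cognitive homophily, gender homophily
and preference for high achievers, so the whole pipeline is testable
without access to school data.

## Worked example

```r
library(socioblocks)

# a planted population: 200 students, 10 tasks, three achievement groups
pop <- make_planted_params(n_students = 200, n_tasks = 10,
                           pattern = "paper", seed = 42)
ratings <- sample_ratings(pop, coverage = 0.9, seed = 43)
ratings
#> ratings_table: 1778 links, 200 users, 10 tasks

fit <- fit_em(ratings, K = 3, L = 3, seed = 44, n_restarts = 3)
fit
#> mmsbm_fit: K=3, L=3, 281 iterations (converged),
#>   log-likelihood -638.9641 (best of 3 restarts)

# recovery of the planted score tensor, after aligning group labels
aligned <- align_labels(
  mmsbm_params(pop$theta_true, pop$eta_true, pop$p_true), fit$params)
mean(abs(aligned$p - pop$p_true))
#> score-tensor mean abs error: 0.005
```

The fitted `fit$params$theta` rows are the students' cognitive profiles:
memberships in the high-, low- and average-achievement groups. A mean
absolute error of 0.005 on the 3×3×5 score tensor means the achievement
structure was recovered essentially exactly from ~1800 observed scores.

Sociogram side, on a generated age series:

```r
series <- make_age_series(default_age_config(ages = c(6, 10, 15),
                                             n_classrooms = 3), seed = 45)
overlap_by_age(series, c("work+", "play+"), n_samples = 100, seed = 46)
#>  age n_classrooms  mean     sem null_mean null_sd
#>    6            3 0.370 0.05229    0.0742  0.0139
#>   10            3 0.315 0.00937    0.0557  0.0128
#>   15            3 0.285 0.04403    0.0552  0.0115
```

Observed work/play overlap (`mean`) declines with age and sits far above
the degree-preserving null (`null_mean`), matching the planted
configuration (`overlap_copy` declining from 0.6 to 0.4).

```r
el <- series[[1]]
assortativity_log_ratio(el$sociogram$layers[["friend"]], el$thetas)
nl <- assortativity_null(el$sociogram$layers[["friend"]], el$thetas,
                         n_shuffles = 500, seed = 47)
#> friend-layer assortativity log-ratio: -0.585 (null -0.001 +/- 0.080)
```

A log-ratio of −0.59, more than seven null standard deviations below the
shuffle null, says friends in this classroom are cognitively much more
similar than random pairs — the planted homophily, recovered.

There is also a command-line interface (`exec/socioblocks`) with
subcommands `simulate`, `fit`, `evaluate`, `select`, `overlap`,
`assortativity`, `status` and `report`; see `?cli`.

## Documentation

The methods vignette
(`vignettes/cognitive-profiles-and-sociograms.Rmd`) documents the model and
its assumptions, the generator's design (including why its planted score
distributions are sharply separated), every null model, and the package's
numerical conventions.
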