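---
title: "Esteem dynamics and emergent status hierarchies: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Esteem dynamics and emergent status hierarchies: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

`leviathan` simulates a population of `N` agents, each carrying a full vector
of esteems: `a[i, j]` is how highly agent `i` regards agent `j`, and the
diagonal `a[i, i]` is self-esteem. All esteems start at exactly zero — nobody
begins with a reputation — and stay clipped to a bounded scale, `[-1, 1]` by
default.

Agents meet in random pairs. In an encounter between listener `i` and
speaker `j`, the listener absorbs three kinds of (noisy) information, each
at a weight `p` given by the logistic *influence function*

$$p_{ij} = \frac{1}{1 + e^{-(a_{ij} - a_{ii})/\sigma_i}},$$

the credibility `i` assigns to `j` given the perceived status difference
between them:

* **self-relevant influence** — `a[i, i]` moves toward what `j` says about
  `i` (`a[j, i]` plus noise);
* **speaker-relevant influence** — `a[i, j]` moves toward `j`'s self-esteem
  (`a[j, j]` plus noise);
* **gossip** — for `k` independently drawn third parties `z` (excluding `i`
  and `j`, repeats allowed), `a[i, z]` moves toward `a[j, z]` plus noise.

Every communicated value is perturbed by an independent uniform draw on
`(-delta, +delta)`, modelling imperfect transmission. The parameter
`sigma_i` is the listener's *open-mindedness*: at small `sigma` credibility
switches sharply around status parity (people "above" me are believed,
people "below" me are ignored), at large `sigma` everyone is about equally
credible.

The population is split into an S-group with small `sigma_small` and an
L-group with larger `sigma_large`. That is the *only* difference between the
groups: partner choice, the update rule, the noise and the gossip process
are identical for everyone, and partners are drawn from the own group with a
fixed probability of 0.5 regardless of group sizes. One *iteration* is
`floor(N/2)` encounters — focal agents drawn uniformly with replacement, so
each agent interacts once on average per iteration.

## Parameters

| Parameter | Meaning | Default |
|---|---|---|
| `n_agents` | population size N | 40 |
| `n_small`, `n_large` | group sizes (sum to N) | 20 / 20 |
| `sigma_small`, `sigma_large` | open-mindedness per group (dimensionless logistic slope) | 0.1 / 0.15 |
| `noise_half_width` | half-width delta of the uniform communication noise | 0.2 |
| `gossip_count` | third parties k discussed per directed encounter | 3 |
| `same_group_prob` | probability the partner comes from the focal agent's group | 0.5 |
| `esteem_bounds` | clipping bounds of the esteem scale | (-1, 1) |
| `n_iterations` | horizon in iterations | 500,000 |
| `measure_every` | snapshot cadence in iterations | 10,000 |

Two coupling rules tie the group sigmas together in the sweep designs:
`f1` with `sigma_large = 1.5 * sigma_small` and `f2` with
`sigma_large = sigma_small + 0.1` (they agree exactly at
`sigma_small = 0.2`). The default horizon grows as `sigma_small` shrinks —
`max(500000, round(50000 / sigma_small))` — because smaller `sigma` slows
convergence to the stable regime; there is no closed-form rule for this, so
the formula is a package choice, overridable in `sweep_config()`.

## Indicators

*Reputation* of an agent is the mean esteem accorded by all *other* agents
(self-esteem excluded). *Social rank* orders agents 1..N by descending
reputation; exact ties (measure-zero under continuous noise) break by
ascending agent index, which keeps the noiseless degenerate case
deterministic. From pooled stationary snapshots the package derives:

* per-group mean reputation and mean self-esteem;
* *variation coefficients*: population SD divided by |group mean|. The
  absolute value matters and is deliberate: group mean self-esteems are
  typically negative here, and a signed coefficient would invert the
  between-group ordering. Both the self-esteem CV and the reputation CV are
  emitted as separate columns, since either may be wanted as the
  intra-group inequality measure;
* *consensual stratification*: population SD of a group's reputations;
* rank *occupancy* probabilities per (rank, group), *advancement*
  probabilities `P(rank(t+1) <= rank(t) | group, rank(t))` where `t+1` is
  the next measurement point, the *glass-ceiling rank* (best rank any
  L-group agent ever attains over the pooled stationary window), and
* extreme-rank *Z-scores*: with `q = N_L / N`, `n` pooled top-5 (or
  bottom-5) slots and `X` of them held by L agents,
  `Z = (X - n q) / sqrt(n q (1 - q))`. The binomial null with independence
  across pooled slots is an implementation decision; consecutive snapshots
  are autocorrelated, so `|Z|` magnitudes are anti-conservative and should
  be read as descriptive effect sizes, while their *signs* are the robust
  content.

Population (not sample) standard deviations are used throughout: these are
descriptive statistics over a whole group of at most 40 agents, not
estimates for a super-population.

## Numerical and design choices

* **Sequential encounter updates.** The four sub-steps of an encounter —
  influence on `i`, influence on `j`, gossip to `i`, gossip to `j` — are
  applied in that order, each reading the state left by the previous one;
  within each directed call the credibility and the difference terms are
  computed from the values at call time. A fully synchronous variant (all
  four sub-steps reading the pre-encounter state) was implemented and
  compared during development; it leaves every qualitative ordering
  unchanged and was not adopted, since the sequential form keeps each
  directed call a self-contained, hand-checkable operation.
* **Clipping.** Esteems are clipped to the bounds after every update.
  Unbounded esteems were also explored and produce runaway leaders whose
  esteem scale drifts without limit, which destroys the interpretability of
  reputations as positions on a fixed scale; bounds remain configurable.
* **Credibility reuse in gossip.** `p` is computed once per directed gossip
  call and reused for all `k` updates — it is indexed by the pair, not by
  the gossip target.
* **With-replacement sampling.** Focal agents are drawn with replacement
  within an iteration, and gossip targets with replacement within a call;
  "once on average" semantics, not a permutation schedule.
* **Degenerate pools.** If the same-group coin points at a pool that cannot
  supply a partner (the focal agent is its group's only member, or a group
  is empty as in single-group baselines), the other pool is used; a partner
  `j != i` always exists for `N >= 2`. Odd `N` runs `floor(N/2)` encounters
  per iteration.
* **Stationary window.** Time-averaged indicators use the trailing 50% of
  snapshots by default (configurable via `stationary_window`); the stable
  regime is reached gradually and no sharper criterion is imposed.
* **Randomness.** One seeded stream per replica; replica `r` uses
  `seed + r`, and sweep cells derive seeds by fixed offsets, so any
  execution order gives identical results. The compiled engine draws from
  R's own generator with the same rejection loop `runif()` uses, which is
  why `engine = "reference"` (a naive R loop kept deliberately simple)
  reproduces the compiled engine bit for bit — the basis of the
  oracle-equivalence test.

## What the simulations emulate — and what they do not

The generator's default conditions are the study design the package
targets: N = 40 split 20/20, `delta = 0.2`, `k = 3`, mixing 0.5,
`sigma_small` swept over 0.03–3 with `f1`/`f2` coupling, 500,000-iteration
horizons measured every 10,000, 50 replicas for the sigma sweep and 30 for
the size sweep. The test suite and the acceptance script run reduced
versions chosen once: 10 replicas at 100,000 iterations with 1,000-iteration
cadence for occupancy/ceiling statistics, 10 replicas at the full 500,000
iterations for the stationary directional comparisons, and a size sweep over
`N_L/N` in {0.25, 0.5, 0.75} with `k` in {1, 3}, 5 replicas and 50,000
iterations.

These are simulations of a deliberately minimal mechanism. Passing tests
show that the mechanism — a single between-group difference in
open-mindedness under group-blind pairwise influence — is sufficient to
generate stable, consensual status inequality with glass-ceiling-like rank
dynamics *in the model*. They say nothing about real populations: there is
no contact-network structure (mixing is uniform), no agent heterogeneity
beyond the two sigma values, no roles, resources, or sanctions, and the
esteem scale is an abstraction.

## Known limitations

* The very top of the hierarchy churns: pooled over enough stationary
  snapshots, L-group agents occasionally occupy even rank 1, so the
  glass-ceiling *minimum* statistic degrades as more observations are
  pooled (it is monotone non-increasing in the data by construction). The
  occupancy *curve* — L-group probability declining steadily toward the
  best ranks — is the stable description of the ceiling; the strict minimum
  is kept because it is the defined indicator, but it should be read
  together with the occupancy profile.
* The fixed 0.5 same-group mixing makes members of a smaller group interact
  more often per capita (the larger group directs half of its encounters
  into the smaller one). With markedly unequal groups this exposure
  asymmetry interacts with the negative drift that gossip imparts to
  esteems, and size-dependent effects appear at long horizons; conclusions
  drawn at equal group sizes do not automatically transfer to strongly
  unequal ones.
* Z-score magnitudes inherit temporal autocorrelation (see above); only
  signs and relative magnitudes are interpreted.

## A minimal session

```{r, eval = FALSE}
library(leviathan)

params <- model_params(n_agents = 40, n_small = 20,
                       sigma_small = 0.1, sigma_large = 0.15,
                       n_iterations = 100000, measure_every = 1000,
                       seed = 1)
runs <- run_replicas(params, 10)

ranks <- rank_records(runs, stationary = TRUE)
occupancy_probability(ranks)     # who holds which rung
glass_ceiling_rank(ranks)        # best rank the L-group ever reaches
advancement_probability(ranks)   # chances of not losing ground
group_summary(runs, stationary = TRUE)
```
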