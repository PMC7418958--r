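# leviathan

Agent-based simulation of how a stable, consensual status hierarchy — with
group inequality and glass-ceiling-like rank dynamics — can emerge in a
population whose two groups differ in exactly one behavioural trait:
*open-mindedness*, the sensitivity of credibility judgements to perceived
relative status. The package is for computational social scientists studying
status construction, opinion dynamics and group inequality: there is no
prejudice, no stereotyping, no discrimination and no group-aware behaviour
anywhere in the mechanism, which makes it a minimal existence proof that
pairwise influence alone can stratify a society along group lines.

## The model

Each of `N` agents holds an esteem `a[i, j] ∈ [-1, 1]` about every agent
(the diagonal `a[i, i]` is self-esteem); everything starts at 0. Agents meet
in random pairs — partner from the own group with probability 0.5,
regardless of group sizes — and each listener `i` absorbs the speaker `j`'s
(noisy) claims at a weight given by the logistic influence function

```
p_ij = 1 / (1 + exp(-(a_ij - a_ii) / sigma_i))
```

Within an encounter the listener updates, in order:

```
a_ii <- a_ii + p_ij (a_ji - a_ii + U(-delta, delta))     # what j says about i
a_ij <- a_ij + p_ij (a_jj - a_ij + U(-delta, delta))     # j's self-presentation
a_iz <- a_iz + p_ij (a_jz - a_iz + U(-delta, delta))     # gossip, k targets z
```

(clipped to the bounds), and symmetrically for `j` listening to `i`. One
iteration is `N/2` encounters. The S-group has small `sigma` (status-
sensitive listeners), the L-group a larger one (more open-minded listeners);
that single difference is the entire experimental manipulation. Derived
indicators: reputation (mean esteem received from all others), social ranks
1..N, per-group means/variation coefficients/stratification, rank occupancy
and advancement probabilities, the glass-ceiling rank, and binomial Z-scores
of the L-group's presence in the extreme ranks.

## Worked example

Ten replicas of the equal-group design (N = 40, sigma_S = 0.1,
sigma_L = 0.15, delta = 0.2, k = 3), 100,000 iterations each, snapshots
every 1,000, indicators over the trailing half of the snapshots:

```r
library(leviathan)
params <- model_params(n_agents = 40, n_small = 20,
                       sigma_small = 0.1, sigma_large = 0.15,
                       n_iterations = 100000, measure_every = 1000, seed = 1)
runs  <- run_replicas(params, 10)
gs    <- group_summary(runs, stationary = TRUE)
aggregate(cbind(mean_reputation, mean_self_esteem, sd_reputation) ~ group,
          data = gs, FUN = mean)
#>   group mean_reputation mean_self_esteem sd_reputation
#> 1     L         -0.2387          -0.2271         0.387
#> 2     S          0.0199           0.0351         0.466
```

The less open-minded S-group ends up with higher reputation and self-esteem
and a more strongly stratified internal hierarchy, purely from the dynamics.
The rank structure shows the ceiling:

```r
ranks <- rank_records(runs, stationary = TRUE)
occ   <- occupancy_probability(ranks)
occ[occ$group == "L" & occ$rank %in% c(1, 5, 10, 20, 30, 40), ]
#>    rank group probability n_obs
#>       1     L       0.047   510
#>       5     L       0.280   510
#>      10     L       0.443   510
#>      20     L       0.584   510
#>      30     L       0.565   510
#>      40     L       0.708   510
mean(occ[occ$group == "L" & occ$rank > 20, ]$probability)
#> [1] 0.603
```

The probability that a rank is held by an L-group agent falls steadily
toward the top (4.7% at rank 1) and the bottom half of the hierarchy is
about 60% L — the more open-minded group populates the low rungs and is
progressively filtered out of the high ones. `glass_ceiling_rank(ranks)`
gives the single best rank any L agent ever attained in the pooled window,
and `advancement_probability(ranks)` the per-rank chances of not losing
ground, which at good ranks are systematically lower for L than for S.

Two analytic anchors of the influence function, for orientation: a
near-indifferent listener (`sigma = 3`) gives credibility
`credibility(0.1, 0, 3) = 0.5083 ≈ 0.5` to a speaker perceived 0.1 above
itself, while a status-sensitive one (`sigma = 0.05`) gives
`credibility(-0.1, 0, 0.05) = 0.1192 ≈ 0.1` to a speaker perceived 0.1
below itself.

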