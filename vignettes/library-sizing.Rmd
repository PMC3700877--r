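---
title: "Statistical library sizing for saturation mutagenesis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Statistical library sizing for saturation mutagenesis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(satmut)
```

## The problem

Saturation mutagenesis randomizes the codons at M preselected positions of a
protein-coding gene and screens a library of L clones for improved variants.
Screening is the expensive step, so the central design question is how large
L must be.  Classical answers are purely combinatorial — demand a 0.95
probability that every possible variant appears in the library, or a target
expected coverage — and ignore what the experimenter actually cares about:
the *fitness* of the best variant that the screen will discover.  This
package implements both the combinatorial metrics and the fitness-aware
analysis: it simulates generative models of the sequence–fitness landscape
and tracks the expected fitness of the best variant discovered,
`E[F(v*)]`, as a function of L.

## From codons to variant-space probabilities

A randomization scheme is a set of codons with weights.  The named schemes
NNN, NNK, NNS and NNB (N = A/C/G/T, K = G/T, S = C/G, B = C/G/T) expand to
equal-weight codon sets of size 64, 32, 32 and 48; `uniform20` is the
idealized scheme with probability 1/20 per amino acid and no stop codons.
Translating through the genetic code gives, per randomized position, the
probability `Q[a, i]` of each amino acid and the stop probability
`Q[stp, i]` (under NNK, for example, leucine, arginine and serine each have
3 of the 32 codons, twelve amino acids have 1, and TAG is the single stop).

Assuming independent randomizations, a variant `v = (a_1, ..., a_M)` is
sampled with probability `p_v = prod_i Q[a_i, i]`, and a clone carries at
least one nonsense codon with probability
`p_stp = 1 - prod_i (1 - Q[stp, i])`.  A library of size L is then a
multinomial draw over the n variants and the stop class; L counts *all*
screened clones, including nonsense ones.  For equal-weight codon sets all
probabilities are exact rationals, carried as integer codon counts so that
the coverage combinatorics below are free of rounding drift.  Variants are
enumerated lexicographically (positions 1..M, amino acids alphabetical) so
indices are reproducible, and variants of equal probability are grouped
into *classes* — with two NNK positions the 400 variants collapse into six
classes — which is what makes exact coverage computations feasible.

## Coverage metrics

Three metrics are implemented, all nondecreasing in L:

* **Expected coverage** `E(|V|/n) = (1/n) sum_v (1 - (1 - p_v)^L)`.
* **Probability of full coverage** `P(|V| = n)`, by inclusion–exclusion over
  the "variant missing" events organized by probability classes.  The
  `exact` method enumerates every class composition and is used whenever
  the term count is small; the `truncated` method sums Bonferroni levels
  `B_j` until they fall below 1e-12 — the alternating partial sums bracket
  the exact value, so the reported error bound is rigorous; the
  `independent` approximation `prod_v (1 - (1 - p_v)^L)` is smooth and
  monotone and differs from the truncated value by well under a percent at
  the library sizes where full coverage becomes likely.
* **Top-k discovery probability** `P(T_k)`: assuming the fitness ranking of
  the n variants is uniform over all n! orderings, the probability that the
  library contains at least one of the k fittest variants is
  `1 - mean over k-subsets of (1 - sum_{v in K} p_v)^L`, computed exactly by
  enumerating per-class selection counts with hypergeometric weights
  (k up to 5; Monte-Carlo subset sampling with a reported standard error
  beyond that).

`min_library_size()` inverts any of these by exponential bracketing and
integer bisection.  For full coverage on large spaces the bracketing runs on
the independence approximation and the crossing is refined with the
truncated method, which converges in a handful of levels exactly where
`P(full coverage)` is near practical targets such as 0.95; the Bonferroni
series diverges at small L, where the answer is not needed (and is exactly 0
for L < n).

## Landscape models

### Gaussian random-effects model

On a transformed fitness scale with the wild type fixed at 0, a mutation
replacing the wild-type amino acid at position i with amino acid a
contributes `f[i, a] ~ Normal(mu_i, var_aa)`, where the position means
`mu_i ~ Normal(m, var_pos)` are themselves random effects; a variant's
fitness is the sum of its mutation contributions plus an independent
`Normal(0, var_nonadd)` residual.  The three ingredients encode the three
empirical regularities this model family was built around: a negative drift
m captures wild-type dominance (most mutations hurt), the shared position
means capture clustering (a position that tolerates one substitution tends
to tolerate others), and the additive sum captures approximate additivity
on the transformed scale.  The implied moments are
`E F_v = m d(v)`, `Var F_v = d (var_pos + var_aa) + var_nonadd` and, for
distinct variants, `Cov(F_v, F_v') = b var_pos + c var_aa`, with d the
Hamming distance to the wild type, b the number of positions where both
variants differ from the wild type, and c the number where they carry the
identical mutation.  `novwein_moments()` exposes these closed forms and the
test suite verifies the sampler against them by simulation.

Raw assay measurements map to the model scale with
`transform_fitness()`: the default is `log(x / wt_raw)`, with the Box–Cox
power family (lambda in (0, 1]) available as a less concave alternative.
The synthetic-data generator follows the same protocol in reverse — it
simulates a landscape on the transformed scale and exponentiates — so
fitted pipelines must log-transform, exactly as with experimental data.

### NK model

Each of N sequence positions contributes a fresh `Uniform(0, 1)` fitness
value that depends on the amino acids at the position itself and its K
nearest flanking positions; total fitness is the average contribution.
The neighborhoods are symmetric windows on a circular sequence (3 left +
3 right for K = 6); circularity removes edge effects and makes the number
of positions influenced by both randomized sites a pure function of their
separation, `max(0, K + 1 - separation)`.  Only the contributions whose
influence set contains a randomized site vary across the variant space —
with the counts (overlap, K+1−overlap, K+1−overlap) these determine the
landscape distribution completely, so the contribution tables are keyed
only by the randomized-site amino acids, never by the full `20^(K+1)`
state space.  The fixed background positions contribute a per-landscape
constant that cancels in every gap-based quantity.

### Rough Mount Fuji model

Fitness is an additive part plus `Normal(0, rho^2)` noise per variant.  The
additive contribution of an amino acid at a randomized position is a ladder
value `eps * i / 10` for rank `i = 0..19`, with `eps < 0` the mean penalty
of a non-optimal residue; `|eps| / rho` indexes landscape smoothness.  The
model itself does not say which amino acid occupies which rung.  A fixed
assignment would permanently couple the ladder to particular degenerate-
codon multiplicities — if the rank-0 amino acid happens to be encoded by a
single NNK codon, the optimum is systematically rare, and the required
library sizes inflate dramatically (our probes span roughly a factor of
five across assignments).  The package therefore draws a fresh uniform
random rank assignment per position per landscape replication, which
marginalizes over this arbitrary labeling; it is the main reason
rough-Mount-Fuji results from different implementations of this model
should only be compared with the assignment convention in hand.
Non-randomized positions are taken to carry their rank-0 residue, so the
background contributes zero (any other fixed background is an additive
constant and cancels in gap-based quantities).

## The screening curve and L*95

For a *fixed* landscape, the expectation of the best discovered fitness has
a closed form: sorting variants by fitness (stable index tie-break) and
writing `S_j` for the cumulative probability of the top j variants, the
best-present rank distribution telescopes into
`P(rank j) = (1 - S_{j-1})^L - (1 - S_j)^L`.  `screening_curve()` therefore
runs a Monte Carlo only over landscape replications and evaluates the inner
library expectation exactly — one simulation layer fewer than sampling
libraries, which is what makes 5000-replication runs take seconds and the
reported standard errors purely between-landscape.

A library can consist entirely of nonsense clones (probability `p_stp^L`),
in which case "best discovered fitness" is undefined; all expectations are
therefore conditional on at least one functional clone, with the
conditioning probability reported per L.  The effect is of order `p_stp`
at L = 1 and vanishes rapidly; conditioning is also the only convention
that stays well defined for landscapes with negative fitness values.

`find_lstar95()` extracts the headline number: the minimal L at which the
curve reaches 95% of the gap between its value at L = 1 (a single
randomized clone) and the expected global optimum `E[max_v F_v]`.  The
crossing is bracketed on a geometric grid (25 points per decade, extended
automatically) and then refined to the exact minimal integer by
re-evaluating the per-landscape expectation (integer bisection), so grid
resolution does not bias the result; being defined through a gap, it is
invariant to additive shifts of the fitness scale.  A bootstrap over
landscape replications supplies a confidence interval.

## The loss distribution

The percent fitness loss `Lambda = 100 (1 - raw(v*) / raw(v**))` compares
the best discovered to the best possible variant on the raw fitness scale
(for log-scale models the ratio is `exp(F(v*) - F(v**))`); this is the only
scale convention on which the loss provably lies in [0, 100], and it is the
default.  A transformed-scale ratio `100 (F** - F*) / F**` is available
for summary reporting but is only meaningful when `F** > 0`.  Unlike the
expected-best curve, the loss is a *distribution* over both landscape and
library randomness, so each replication samples one landscape and one
multinomial library; replications whose library contains no functional
clone are flagged rather than dropped.  `exceedance_probabilities()`
summarizes the tail `P(Lambda >= t)` with binomial standard errors.

## Maximum-likelihood fitting

Given a table of variants and transformed fitness values, the Gaussian
model's exact multivariate-normal log-likelihood is assembled from the
moment structure above (`Sigma = var_pos B + var_aa C + var_nonadd I`).
Wild-type rows, which have zero mean and variance by construction, are
excluded with a warning.  Variances are log-parameterized so the
optimization is unconstrained, with a 1e-8 floor standing in for the
boundary at zero, and the optimizer is multistarted (Nelder–Mead from
data-driven dispersed points — drift from a least-squares regression of
fitness on mutation count, total variance from its residuals split
randomly across the three components — followed by a BFGS polish).

One identifiability fact shapes the parameter-recovery study shipped with
the tests: with M = 2 randomized positions the drift m is informed by only
*two* realized position effects, so no sample size can push the standard
error of the drift estimate below `sqrt(var_pos / 2)`.  A meaningful
recovery benchmark therefore uses a generating configuration whose
position-variance share is small (m = −0.3, var_pos = 0.002,
var_aa = 0.04, var_nonadd = 0.01 at 200 observations); with a large
position variance the drift is unidentifiable from a single landscape at
any N, which is a property of the model, not of the optimizer.

## Synthetic data, problem sizes, and what the tests do and do not show

All validation runs on synthetic data, by design: the fixture generator
(`simulate_fitness_table()`) draws one landscape realization, exponentiates
it, and emits a variant/raw-fitness table, so every stage — transformation,
likelihood, optimization — is exercised end to end offline.  What the
generator does *not* emulate are the realities of assay data: replicate
measurement noise, batch effects, sampling bias from picking clones by
observed activity, and model misspecification.  Green tests therefore
demonstrate internal correctness (samplers match their closed-form
moments, analytic expectations match brute-force enumeration and naive
resampling, estimators recover generating parameters), not field accuracy
on any particular protein.

Headline simulations use 5000 landscape replications (NK and rough Mount
Fuji scenarios); model-contrast checks use 2000; moment-matching checks
use 20 000 draws on a reduced 16-variant space; the recovery study fits 50
independent 200-observation tables.  These sizes are the package's own
accuracy choices: at 5000 replications the bootstrap CI of a 95%-of-gap
size is a few percent wide, comparable to the run-to-run variation of any
implementation of these models.

## Known limitations

* Coverage metrics describe multinomial sampling of an ideal library;
  transformation efficiency, clone redundancy and other physical biases
  are out of scope.
* The top-k metric's uniform-ranking assumption is exactly that — under a
  concrete landscape model the ranking is not uniform, and the package
  deliberately computes the two metrics separately rather than assuming
  the sometimes-claimed equivalence between full coverage and the k = 1
  metric.
* The NK and rough-Mount-Fuji simulators support exactly two randomized
  sites (the Gaussian model supports any M up to the variant-space cap).
* Rough-Mount-Fuji results depend on the rank-assignment convention
  discussed above; comparisons across implementations require it.
* The sampling-bias corrections used in empirical applications of the
  Gaussian model are not implemented; fitted parameters assume the
  observed variants were measured without selection on their activity.
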