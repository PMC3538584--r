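---
title: "Systematic bias versus stochastic noise in distance-based phylogenetics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Systematic bias versus stochastic noise in distance-based phylogenetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(devadd)
```

## The problem

Distance-based reconstruction first turns pairwise sequence comparisons into
evolutionary distances through a *substitution-rate (SR) function*, then fits
a tree to the resulting dissimilarity matrix.  If the SR function is additive
for the generating substitution model — the distance of a two-edge path is
the sum of the two edge distances — then with enough data robust algorithms
such as neighbor joining recover the true topology.  In practice the model is
unknown, and a deliberately oversimplified SR function is often *less noisy*
than the model-matched one.  This package provides the machinery for making
that trade-off quantitative in homogeneous Kimura two-parameter (K2P)
sub-models: a non-additive SR function contributes a *systematic* error that
can be measured in time units and compared against edge lengths, while every
SR function contributes *stochastic* error that shrinks as $1/\sqrt{k}$ with
the sequence length $k$.

## The model

A homogeneous K2P sub-model is indexed by the transition–transversion ratio
$R = \alpha/(2\beta) \ge 1/2$, with unit rates normalised so that
$\alpha + 2\beta = 1$ and evolutionary time $t$ counts expected substitutions
per site.  After time $t$ the per-site probability of a transition-type
difference and of each transversion-type difference are

$$p_\alpha = \tfrac14\left(1 + e^{-4\beta t} - 2e^{-2(\alpha+\beta)t}\right),
\qquad p_\beta = \tfrac14\left(1 - e^{-4\beta t}\right).$$

Note the per-target convention: `estimate_pair_stats()` divides the
transversion count by $2k$, so that the classical inversion formulas apply
verbatim (many texts instead work with the total transversion proportion
$Q = 2p_\beta$).  The package implements four SR functions of these
statistics — `delta_k2p()` (always additive: it returns $t$ exactly on exact
statistics), `delta_jc()` (additive only at $R = 1/2$), `delta_tv()`
(transversions only, an affine rescaling of $t$), and `delta_r_ml()` (ML
inversion at a fixed, assumed $R$) — plus `delta_logdet()` on joint count
matrices.

## Deviation from additivity

Within a homogeneous sub-model every SR function reduces to a univariate
function $\Delta(t)$, and it is affine-additive precisely when
$\Delta(t) = at + b$ with $a > 0$.  The deviation from additivity over an
interval $[t_0, t_1]$ of inter-leaf times is the slope-normalised minimax
distance to the nearest affine function:

$$\mathrm{dev}(\Delta, [t_0,t_1]) \;=\;
\inf_{a>0,\,b}\; \frac{1}{a}\max_{t \in [t_0,t_1]} |\Delta(t) - at - b|.$$

Dividing by $a$ puts the measure in time units, so it can be compared
directly with edge lengths: if $\mathrm{dev} < t_{\min}/2$, where $t_{\min}$
is the minimal edge time, the induced dissimilarity map is *near-additive*
and robust distance methods are guaranteed to reconstruct the topology
(`consistency_check()`).  Two structural facts make the measure practical:

* If $\Delta$ does not cross its chord (in particular if it is concave or
  convex, as the JC distance is under $R > 1/2$), the optimal slope is the
  interpolation slope $A$, the optimal intercept is $B + X/2$ with $X$ the
  maximal gap to the chord, and $\mathrm{dev} = X/(2A)$.
* In general $\mathrm{dev} \le (t_1-t_0)^2 F / (16A)$ with
  $F = \max |\Delta''|$ (`deviation_bound()`), by the standard bound on
  linear interpolation error.

For the JC distance under K2P, writing $\rho = (2R-1)/(R+1)$,

$$\Delta_{JC}(R, t) = \frac{3t}{2(R+1)}
  - \frac34 \ln\!\Big(\frac{1 + 2e^{-\rho t}}{3}\Big),$$

with $\Delta''_{JC} = -\tfrac32 \rho^2 e^{-\rho t} (1+2e^{-\rho t})^{-2} < 0$,
minimised at $t = \ln(2)/\rho$ where it equals $-\tfrac{3}{16}\rho^2$
(`delta_jc_time()`, `delta_jc_derivative()`).

### Numerical choices

`deviation_from_additivity()` detects one-sided curvature by the sign of
second differences on a 512-point grid and then applies the closed form,
locating $X$ by golden-section refinement around the grid maximum.  For
functions that do cross their chord it falls back to a nested minimax: for
fixed slope the optimal intercept is the Chebyshev centre of the residuals
(evaluated on a 2001-point grid with local refinement), and the outer
minimisation of $\psi(a)/a$ runs over $a \in [A/10, 10A]$ to an absolute
tolerance of $10^{-8}$, cross-checked against a dense slope scan because the
objective is typically kinked at its minimiser.  Degenerate inputs —
non-monotone $\Delta$, empty intervals — are rejected rather than guessed
at.  The tests validate the solver against an independent brute-force grid
minimax on randomised cases to $10^{-4}$ relative error.

## Stochastic noise

The per-site mismatch class is trinomial, which gives the delta-method
standard deviations implemented in `sigma_k2p()` and `sigma_jc()`:

$$\sigma(\Delta_{K2P}) \approx \sqrt{\frac{(e^{4t/(R+1)}-1)
  + 4(e^{2t/(R+1)}-1) + 2\big(e^{4Rt/(R+1)}(e^{2t/(R+1)}+1)-2\big)}{16k}},$$

$$\sigma(\Delta_{JC}) \approx \sqrt{\frac{p(1-p)}{k(1-\tfrac43 p)^2}},
\qquad p = p_\alpha + 2p_\beta.$$

The grouping of the $\sigma(\Delta_{K2P})$ numerator was re-derived from the
trinomial covariance of the mismatch counts and is validated against the
Monte-Carlo oracle `empirical_sigma()` (which simulates actual two-leaf
alignments, drops saturated replicates, and reports their count); the suite
requires agreement within 5% at $k = 10^4$ across
$(R, t) \in \{0.5, 2, 5, 10\} \times \{0.2, 0.5, 1, 1.5\}$.  Both formulas
scale exactly as $1/\sqrt{k}$, and $\sigma(\Delta_{JC}) < \sigma(\Delta_{K2P})$
whenever $R > 1/2$: the JC estimator tracks a single pooled statistic, the
K2P estimator two.

The closest affine surrogate $\Delta^* = \Delta_{int} + X/2$ is estimated
through the additive machinery, so $\sigma(\Delta^*) = A\,\sigma(\Delta_{K2P})$
(`sigma_affine()`).  In the wide-interval setting ($R = 10$, $t \in [0.8,2]$,
500 bp) the JC margins are narrower than the $\Delta^*$ margins from
$t \approx 1.12$ onward and increasingly so with $t$ — the concrete sense in
which JC distances are *more likely to be near-additive* than K2P distances
despite their bias.

## Quartets and the Fisher criterion

The four-point method (`four_point_method()`) resolves a quartet by the
minimal of the three pairwise-distance sums; exact ties are broken uniformly
at random (seeded) so the accuracy estimate is unbiased, and tie frequencies
are reported by the drivers.  Two asymmetric prototypes bound the behaviour
(`quartet_model()`): in type A (Farris zone) both short external edges lie on
one side of the split and concavity *widens* the margin; in type B
(Felsenstein zone) each side carries a short and a long edge, concavity
*shrinks* the margin by about twice the deviation from additivity, and once
the deviation exceeds $t_i/2$ the wrong split $(13|24)$ attains the minimal
sum even on exact distances — the sense in which the $t_{\min}/2$ condition
is tight.

`fisher_criterion()` predicts which SR function resolves a quartet series
better: for the true-split sum versus a competing sum it computes
$FC = |\mu_1 - \mu_2| / \sqrt{\sigma_1^2 + \sigma_2^2}$, with the means
taken from the SR function on exact path times and each sum's variance taken
as the sum of the two delta-method variances.  Correlation between sums
through shared external edges is deliberately ignored (the usual independent
approximation), and the sums are not actually normal, so FC is a comparative
heuristic rather than an exact error probability.  The ratio decomposition
$FC(\Delta_1)/FC(\Delta_2) = \big(SEP_1/SEP_2\big)\big/\big(NOISE_1/NOISE_2\big)$
(`sep_noise_ratios()`) separates the bias effect from the noise effect.
Because both noises scale as $1/\sqrt{k}$, FC *crossings* between two SR
functions do not depend on $k$.

```{r fc}
q <- quartet_model("B", t_i = 0.2, t_s = 0.25, t_l = 1, R = 5)
fisher_criterion(q, "jc", k = 1000)
fisher_criterion(q, "k2p", k = 1000)
sep_noise_ratios(q, "jc", "k2p", k = 1000)
```

On the balanced type-B series ($R = 5$, $t_i = 0.2$, $t_l = 1$, $t_s$
varied), the FC curves of JC and K2P cross near $t_l/t_s \approx 3.5$, and
the simulated four-point accuracy curves cross at a matching location; on
the unbalanced series ($t_s = 0.2$ fixed, $t_l$ varied) FC predicts K2P
overtaking JC near $t_l/t_s \approx 4.3$.  Both numbers are recomputed from
scratch by `scripts/acceptance.R` and asserted (with tolerances) in the test
suite.

## Simulation drivers and their scope

`simulate_alignment()` evolves i.i.d. sites along a tree: the sequence at an
arbitrary internal node is uniform over the four bases and each edge applies
the exact K2P transition matrix.  Because the model is time-reversible with
uniform stationary distribution, the leaf joint law does not depend on the
root placement (tested by re-rooting).  The generator deliberately matches
the analysis assumptions — no across-site rate variation, no indels, uniform
base frequencies, a single $R$ for the whole tree.  Passing tests therefore
demonstrate the internal consistency of the framework under its own model;
they do not show robustness to rate heterogeneity, compositional bias or
alignment error in real data.

`run_quartet_series()` and `run_tree_series()` drive the two experiment
families.  The study conditions are fixed by the experimental design:
quartet series use 1,000 bp alignments at $R = 5$ with the internal edge at
0.2; the tree series uses the semi-symmetric 7-taxon caterpillar
($t_{ext} = 5\,t_{int}$), $R = 2$, 500 bp, diameters spanning $[0.1, 2]$.
Replicate counts are configurable; the acceptance script uses 20,000
replicates per quartet grid point (on a 0.05-step $t_s$ grid) and 2,000 per
diameter (0.1-step grid), which keeps the full recomputation within desk
scale while holding the Monte-Carlo standard error of each accuracy value
near $3\times10^{-3}$.  On the caterpillar, JC beats the transversion-only
distance only at the smaller diameters (the two error curves cross between
diameters 1 and 1.3 at these replicate counts); the saturation-robust
$\Delta_{tv}$ wins at larger scales.

Saturation policy is split deliberately: library functions raise a typed
condition (`is_saturation_error()`), while the drivers replace a saturated
entry by twice the largest finite distance of the same replicate's matrix
(5.0 if none is finite) and count the events.  Capping inside
`empirical_sigma()` would bias an SD estimate, so there saturated replicates
are dropped and counted instead.

Neighbor joining is implemented in the package (Q-criterion joins,
smallest-index tie-break, negative branch lengths retained) so that its
affine-invariance and determinism contracts are testable; `ape::nj` and
`phangorn::RF.dist` serve as independent cross-checks in the tests, never as
the implementation.  Robinson–Foulds distances are computed on canonical
bipartition sets and normalised by $2(n-3)$.

## Limitations

* The tractability of the deviation measure rests on homogeneity; for
  mixtures of rate matrices no univariate reduction exists and the measure
  is not defined here.
* FC ignores the covariance between competing sums and normality is only
  approximate, so its *absolute* values should not be read as error rates —
  only comparisons between SR functions are meaningful.
* The LogDet implementation uses the symmetric (doubly-normalised)
  divergence determinant; distance-matrix packages differ in normalisation
  details, which shifts absolute values but not monotonicity.
* The fixed-ratio ML distance returns the search bound (default 20) on
  saturated input rather than a typed error, mirroring its use inside
  capped distance matrices.
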