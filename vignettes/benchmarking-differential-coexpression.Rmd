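---
title: "Benchmarking differential co-expression inference with a steady-state regulatory simulator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking differential co-expression inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dcbench)
```

## Why simulate

Differential co-expression (DC) analysis asks which gene pairs change
their *association* between conditions — the signature left behind when a
condition disables one member of a set of co-regulators. Because no real
dataset comes with a certified list of condition-specific regulatory
interactions, DC methods can only be benchmarked against simulations in
which the generative network, the perturbation and the propagation of its
effects are all known. `dcbench` provides that generative model, a
principled definition of the "true" differential network at three levels
of causal strictness, implementations of network-based DC statistics, and
the evaluation glue.

## The gene-regulation model

Every regulatory edge A→B carries a normalised-Hill activation function

$$ f(A) = \frac{\beta A^{n}}{K^{n} + A^{n}}, \qquad
   \beta = \frac{E - 1}{2E - 1},\; K^{n} = \beta - 1,\; E = \mathrm{EC50}^{n}, $$

normalised so that $f(0)=0$, $f(\mathrm{EC50})=\tfrac12$ and $f(1)=1$ on
the relative-abundance scale $[0,1]$. Two numerical points are worth
stating explicitly:

* $K$ itself is never computed. When $E > \tfrac12$, $\beta - 1 < 0$ and
  $K = (\beta-1)^{1/n}$ is not real; only $K^n = \beta - 1$ enters $f$, so
  the implementation stores that quantity directly.
* At $E = \tfrac12$ the expression for $\beta$ has a pole, but the
  function itself converges to the limit $f(A) = A^{n}$. When
  $|2E - 1| < 10^{-9}$ the implementation switches to that exact limit.

EC50 is sampled uniformly from $[0.4, 0.6]$ and $n$ from $[1.01, 1.70]$,
restricting the model to *linear-like* activation: steep, switch-like
regulation is deliberately excluded, both because it is rarely observed
and because it would make correlation-based inference trivially easy or
impossible depending on the operating point. Repression contributes
$1 - f$; several regulators combine multiplicatively (a logical AND
gate), which is commutative and associative, so regulator order never
matters. Each non-input gene obeys $dB/dt = g(\text{parents}) - B$, so
its steady state is simply $g(\text{parents})$: on an acyclic network the
whole system is solved exactly by one pass in topological order. A damped
fixed-point solver is kept alongside as an independent oracle (the two
agree to below $10^{-8}$ in the test suite) and as the escape hatch for
cyclic extensions; simulation rejects cyclic inputs with an error rather
than silently breaking cycles.

## Input genes, knockdowns and noise

Genes without regulators ("input genes") are not solved but sampled.
Their joint distribution is a truncated multivariate normal on $[0,1]$:

* wildtype means $\mu \sim \mathrm{Beta}(10,10)$ (centred at 0.5),
  knockdown means $\mu^{kd} \sim \mathrm{Beta}(10,100)$ (centred near
  0.09 — abrogated but nonzero expression);
* per-gene spread $\sigma = b\,\min(\mu, 1-\mu)/3$ with
  $b \sim \mathrm{Beta}(15,15)$, the three-sigma rule that keeps each
  marginal's effective support inside $[0,1]$;
* correlations between non-knockdown inputs come from a C-vine random
  correlation matrix with partial correlations $2\,\mathrm{Beta}(5,5)-1$
  — weakly dependent inputs, as in real sample populations; knockdown
  inputs are sampled independently of everything so the differential
  signal is not confounded.

The truncated sampler draws whole vectors by rejection (with the spreads
above, acceptance is nearly certain) and falls back to univariate
inverse-CDF truncated resampling of out-of-range coordinates after a
capped number of batches, so termination is guaranteed.

A knockdown design selects 2–8 input genes (uniformly; the design is
configurable), assigns each a proportion $\rho \sim U(0.2, 0.8)$ and sets
each sample's condition bit independently with probability $\rho$;
degenerate designs (a state with no samples) are redrawn. Two noise terms
complete the generative model: each activation-function value is
multiplied by an independent lognormal variable (meanlog 0, sdlog 0.05)
per edge and sample before solving, and Gaussian noise (sd 0.05) is added
to every entry of the final matrix. Post-noise values are *not* clamped
to $[0,1]$; clamping would distort correlations near the boundaries.

The standard run simulates 500 profiles of a 150-gene network; all
stages fan out child seeds deterministically from one global seed, so a
dataset is a pure function of (network, seed, configuration).

## Source networks and subnetwork sampling

Benchmark networks are sampled from a larger source network. The built-in
synthetic source generator produces an acyclic, weakly connected, signed
network at the scale of a curated yeast transcriptional network (690
genes, 1094 edges, ~25% repression) with a heavy-tailed out-degree from
preferential attachment. Its input layer defaults to 5% of the genes:
top-level regulators are scarce in curated networks, and input-gene
richness is the single strongest driver of benchmark difficulty, so this
default was fixed once to make 150-gene samples carry on the order of
10–25 input genes (samples gain extra inputs at the boundary, where a
gene's regulators fall outside the sample).

Subnetworks are grown by seeded greedy neighbour expansion: with
probability $k$ (default 0.25) the next gene is a uniformly random
neighbour of the current set, otherwise the neighbour with the most
connections into the set. The grown set is connected by construction;
samples with fewer than 10 input genes are rejected and redrawn. The
exact sampling algorithm behind published module-sampling tools differs
in detail; only the stated constraints (size, connectivity, minimum
inputs, stochasticity) are guaranteed here.

## Truth networks from perturbation sensitivity

The evaluation hinges on knowing which pairs *should* show DC. The system
is treated as deterministic and noise-free; every input gene's mean is
reduced by 25% in turn (knockdown inputs use their wildtype mean — the
perturbation analysis characterises the intact system), and each gene's
*perturbation sensitivity* is its relative steady-state change divided by
0.25. Base abundances below 0.001 are zeroed first to avoid ratio blowups
on numerically dead genes. With linear-like activation the measure is
insensitive to the perturbation size (exactly so for strictly linear $f$;
with Hill coefficients up to 1.7 the test suite bounds the median
deviation between 25% and 10% perturbations at 10%).

Thresholding |sensitivity| at 0.01 gives a binary gene × input dependency
matrix, from which three nested truth networks are derived per knockdown
gene $k$:

* **association** — for every other input $i$ sharing a sensitive target
  $t$ with $k$, the pair $(i, t)$; plus $(p, t)$ for every *proxy* $p$
  solely sensitive to $i$ (such genes track $i$ deterministically);
* **influence** — the subset where the putative regulator has a directed
  path to $t$;
* **direct** — the subset where regulator→$t$ is a network edge.

Three conventions are deliberate design choices, documented rather than
asserted as the original procedure: pairs incident to the knockdown gene
itself are excluded (its state *is* the condition); genes solely
sensitive to the knockdown gene are excluded everywhere (they are
filtered before inference as near-copies of the condition variable); and
target–target pairs that merely share ancestry are *not* added to the
association level — only input/proxy-to-target pairs are.

## Inference statistics

All methods score every unordered gene pair within each knockdown
condition and go through Benjamini–Hochberg adjustment per condition with
an FDR cut-off of 0.1:

* **z-score** — Fisher-transformed correlation difference scaled by the
  pooled standard error $\sqrt{1/(n_1-3) + 1/(n_2-3)}$, two-sided normal
  test. The Spearman variant reuses the same variance after rank
  transformation — an approximation, adopted deliberately. Correlations
  are clamped to $\pm(1 - 10^{-12})$ before `atanh`.
* **DiffCoEx-style** — $(|\,\mathrm{sign}(r_1)r_1^2 -
  \mathrm{sign}(r_2)r_2^2|/2)^{\beta/2}$ with soft power 6, permutation
  p-values.
* **FTGI-style** — interaction linear model $x_j \sim x_i + c + x_i c$,
  squared Wald statistic of the interaction term against $\chi^2_1$,
  undirected score = max over the two fit directions. The max makes the
  pair-level null rate land between $\alpha$ and $2\alpha$; BH absorbs
  that at the thresholding step. Fits are batched per regressor through
  one QR decomposition.
* **MINDy-style** — difference in mutual information (equal-frequency
  binning, 8 bins, in bits) between condition states, symmetric by
  construction, permutation p-values.
* **Baselines** — WGCNA-flavour ($|r|^6 > 0.05$) and Prill-flavour
  ($\mathrm{atanh}(r)\sqrt{n-3}$, BH, FDR 0.1) co-expression networks
  built per state, differenced symmetrically.

Permutation p-values pool the null scores of *all* pairs across the five
label permutations, with add-one smoothing, so even five permutations
give a usable null resolution of roughly $1/(5P+1)$ for $P$ pairs.

## Evaluation

Before inference, the sole targets of the knocked-down gene are removed
from the matrix. The knockdown gene itself stays: its significant pairs
count as false positives, mirroring the truth conventions above.
Confusion counts are pooled over a simulation's knockdown conditions
(conditions with empty truth sets are excluded), then precision, recall
and $F_1 = 2PR/(P+R)$ are computed per truth level, with $F_1 = 0$ when
$P + R = 0$. Pooling (rather than per-knockdown averaging) is the
default; the alternative is available via the per-knockdown predictions.
Degree-by-role summaries use natural-log degrees; the qualitative claim —
hubs of differential association networks are differentially regulated
*targets*, not regulators — is what the test suite asserts.

## Problem sizes and what the tests show

The package's own acceptance checks run at desk scale, chosen as the
smallest sizes at which the measured quantities stabilise: the three-gene
demonstration uses 20 replicate simulations of 500 profiles; the method
sweep uses 60 simulations of 150-gene networks (the 90th percentile of a
per-simulation F1 distribution is noisy below roughly 50 simulations);
truth-nesting and solver-equivalence properties run on 100 and 150-gene
networks respectively. Passing these checks shows that the generative
model, truth derivation and statistics interlock as designed. It does
not show that any method performs comparably on real transcriptomic
data: the simulator makes no attempt to model counts, library-size or
batch effects, binding events, translation, feedback loops (the model is
feedback-free by construction) or condition confounding, and its noise
levels are mild. Conclusions about method *rankings* transfer only to the
extent that real regulatory propagation resembles this model.

## Known limitations

* Cyclic networks are rejected rather than solved, matching the
  feedback-depleted source networks the benchmark targets; the
  fixed-point solver exists but convergence on cyclic systems is not
  characterised.
* The knockdown-selection rule reuses a configurable uniform 2–8 count;
  the original description is ambiguous on this point.
* Only two-condition (binary knockdown) designs are supported; the truth
  derivation has no multi-condition extension here.
* The FTGI and MINDy formulations are reconstructions from their
  published descriptions (interaction linear model; conditional mutual
  information with a binary modulator), not ports of reference code.
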