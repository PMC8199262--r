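---
title: "Reconstructing single-cell 3D chromosome structures with scLJfold"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing single-cell 3D chromosome structures with scLJfold}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scLJfold)
```

## The problem

A single-cell Hi-C experiment yields, for one chromosome of one cell, a few
hundred locus pairs that were spatially proximate at the moment of fixation.
Binned at 500 kb, a chromosome of a few hundred beads has tens of thousands
of bead pairs, of which only a few hundred carry a contact: the binary
contact matrix is overwhelmingly zero. Classical reconstruction methods that
convert contact counts into target distances break down here, because a zero
count would map to an infinite distance, and almost everything is zero.

scLJfold takes a different route. A pair's observed contact is treated not as
a distance measurement but as a *binding confidence*: the deeper the
potential well between two beads, the harder their in-contact arrangement is
to break during stochastic optimisation. Pairs without support are left
entirely unconstrained — they are never pushed apart, their well depth is
simply zero.

## The model

**Imputation.** The binary contact matrix $C \in \{0,1\}^{l \times l}$ is
densified with a 2D Gaussian kernel. Each observed contact at matrix
position $(x_p, y_p)$ contributes

$$\exp\!\left(-\frac{(x_p-i)^2 + (y_p-j)^2}{\mu^2}\right)$$

to every pair $(i,j)$ within Chebyshev distance $d_0$ of it; contributions
are summed and clipped at 1, giving confidences $\theta_{ij} \in [0,1]$ with
$\theta_{ij} = 1$ exactly at observed contacts. The intuition: if beads $i$
and $j$ touch, their sequential neighbours $i \pm 1$, $j \pm 1$ cannot be
far apart either.

**Loss.** Each pair contributes a confidence-weighted Lennard-Jones term

$$E_{ij} = \beta\,\theta_{ij}^{\,n}\left[\left(\frac{r_m}{d_{ij}}\right)^{12}
  - 2\left(\frac{r_m}{d_{ij}}\right)^{6}\right],$$

truncated to zero for $d_{ij}$ beyond the cutoff. The well bottom sits at
$d = r_m$ with depth $\beta\,\theta^n$; the potential crosses zero at
$\sigma = r_m / 2^{1/6}$ and becomes steeply repulsive below it. The well
depth — not a target distance — encodes the data: $\theta = 1$ pairs get the
full depth $\beta$, imputed neighbours shallower wells, and $\theta = 0$
pairs none. The exponent $n$ controls how fast confidence decay translates
into well-depth decay.

**Optimisation.** The chromosome is a string of beads on an integer cubic
lattice of side $5l$. Starting from a random chain, Metropolis–Hastings
moves displace one bead at a time to one of its 26 adjacent cells; a move is
accepted when it lowers the loss, or with probability $e^{-\Delta/T_c}$
otherwise. The temperature follows $T_c = T_0 \cdot 0.9^{\,p}$ and each level
runs until $100\,l$ attempts or $10\,l$ accepted moves. Replicate runs with
distinct seeds produce an ensemble; the replicate with the highest mean
TM-score against the others is the consensus output. A coarse 500 kb model
can then be refined to 50 kb: nine beads are inserted between each pair of
consecutive coarse beads and only $5\,l$ attempts at a constant temperature
of 0.1 relax them, preserving the coarse topology.

## Parameters and defaults

| Parameter | Default | Units | Meaning |
|---|---|---|---|
| `sigma` / `rm` | 8 / 8.98 | lattice | zero-crossing / well position; `rm = 8` also supported |
| `n` | 2 | — | well-depth exponent on $\theta$ |
| `beta` | 10 | — | overall well-depth scale |
| `cutoff` | 16 | lattice | truncation distance (zero loss beyond) |
| `mu2` | 4 | beads² | Gaussian spread of imputation |
| `d0` | 3 | beads | imputation influence radius |
| `t0`, `cool_factor` | 10, 0.9 | — | annealing schedule |
| `t_min` | 0.01 | — | stopping temperature |
| `n_models` | 50 | — | ensemble size for consensus selection |

`beta`, `n`, `cutoff`, the two `rm` modes, the cooling schedule, the
per-level caps, the ensemble size and the refinement settings are the
method's published operating points. `mu2 = 4` and `d0 = 3` are this
package's choices (the original values are not recorded anywhere we could
consult): with `mu2 = 4` the kernel decays to about 0.11 at the edge of the
`d0 = 3` window, so the influence region and the truncation radius agree.
Both are exposed everywhere.

Two further choices were genuinely open:

* **Chain connectivity** (`connect_chain`, default `TRUE`). The model as
  published states no backbone term, yet its outputs are drawn as connected
  strings. We pin $\theta_{i,i+1} = 1$ after imputation, which gives every
  adjacent pair a full-depth well at $r_m$ — a soft bond that keeps the
  chain coherent without a hard constraint. Setting the flag `FALSE` gives
  the literal no-backbone reading.
* **Initialization spacing.** The published description of random
  initialization asks each new bead to sit at a distance in $[2, 10]$ of
  existing beads, but enforcing that against *all* beads caps the chain
  diameter at 10 and is infeasible beyond a handful of beads. The default
  enforces $[2, 10]$ against the sequential predecessor and $\geq 2$
  against everything else; `constraint = "all"` keeps the literal variant
  for short chains.
* **Clipping vs maximum.** The summed Gaussian can exceed 1 near clustered
  contacts while confidences are defined on $(0, 1]$; we clip at 1
  (`combine = "sum"`), with `combine = "max"` as the alternative that never
  sums.
* **Refinement anchors.** Whether coarse beads stay frozen during 50 kb
  refinement is unstated; they remain movable here, since only $5l$
  low-temperature attempts are allowed and drift is bounded anyway.

## Numerical choices

Distances are Euclidean on integer lattice coordinates, in floating point,
with no periodic boundary. The loss is maintained incrementally from
single-bead deltas during sampling and recomputed in full once per
temperature level, which removes accumulation drift from the reported trace.
The truncation introduces a discontinuity at the cutoff; this is accepted
because the sampler compares losses and never needs forces. Proposals that
leave the lattice or land on an occupied site count toward the per-level
attempt budget but can never be accepted, keeping the per-level workload as
specified. TM-score maximization is seeded from the full chain and sliding
fragments, with iterative refitting on well-superposed subsets; $d_0(L) =
1.24\,(L-15)^{1/3} - 1.8$ is floored at 0.5 so short test chains remain
scoreable. All randomness flows from one master seed; replicate $m$ uses
`seed + m - 1`, so ensembles are reproducible bead-for-bead.

## What the synthetic generator does and does not emulate

`synthetic_scenario()` grows a self-avoiding lattice chain — optionally
confined to a ball of radius $\propto l^{1/3}$ to mimic territory
compaction — and samples a few hundred non-adjacent bead pairs uniformly
among those closer than the contact threshold, writing them in the standard
four-column contact-list dialect. The defaults (333 beads, 438 contacts)
reproduce the sparsity regime of a real single-cell X-chromosome dataset.
What it does *not* emulate: distance-dependent ligation propensity, trans
ligations, duplicates, mappability gaps, or diploid ambiguity. Passing
recovery tests on this generator therefore demonstrates that the estimator
inverts its own forward model under realistic sparsity — not that it is
robust to every artefact of real Hi-C libraries.

## A worked recovery experiment

```{r recovery, eval = FALSE}
sc  <- synthetic_scenario(l = 100, n_contacts = 150, seed = 11)
rec <- recovery_experiment(sc, config = anneal_config(seed = 11,
                                                      n_models = 5,
                                                      attempts_factor = 30))
rec$pearson$r        # confidence-distance correlation (negative is good)
rec$spearman_true    # agreement with the generating structure
```

At this scale (100 beads, 150 contacts, 5 replicates with a reduced
attempt budget of `30 * l` per level) the run takes a few seconds and
recovers a clearly negative confidence–distance correlation and a clearly
positive true-structure correlation; the same quantities are recomputed from
scratch by `scripts/acceptance.R`. Full-scale runs (333 beads, 50
replicates, `100 * l` attempts) use the same code path.

## Limitations

* Absolute scale is arbitrary: lattice units do not map to nanometres, so
  radii of gyration are comparable only within a common normalization (we
  report the raw value and a max-pairwise-distance-normalized one).
* The correlation between confidence and distance is evaluated on all
  pairs, most of which have $\theta = 0$ and are unconstrained; the
  magnitude of that correlation is therefore structurally modest even for
  good fits.
* Only intra-chromosomal, haploid reconstruction is supported; no
  inter-chromosomal modelling, no diploid phasing, no TAD or compartment
  calling.
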