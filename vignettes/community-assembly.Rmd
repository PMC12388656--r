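---
title: "Inferring community assembly processes in depth-stratified soil microbiomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring community assembly processes in depth-stratified soil microbiomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

assemblyscape asks a single ecological question at several scales: when soil
bacterial communities differ from place to place and from topsoil to subsoil,
how much of that turnover is driven by deterministic niche selection, and how
much by the stochastic trio of dispersal, immigration, and drift? The package
bundles the standard inferential machinery for that question — phylogenetic
null models, a probabilistic community null, Sloan's neutral model,
correlation networks, distance-decay regression, and variance attribution —
behind a tabular, pipe-friendly interface, together with a synthetic-data
generator that produces communities whose true assembly process is known.

## The null-model core

The central statistic is the between-community mean nearest taxon distance.
For samples $k$ and $l$ with relative abundances $f$ and patristic distance
$d$ on a rooted, branch-lengthed phylogeny,

$$\beta\mathrm{MNTD}(k,l) = \tfrac12\Big[\sum_{i\in k} f_{ik}\,\min_{j\in l} d(i,j)
 + \sum_{j\in l} f_{jl}\,\min_{i\in k} d(j,i)\Big].$$

Taxa shared by both samples have a nearest neighbour at distance zero, so the
statistic measures how far the *unshared* portion of one community sits from
the other community's tips. Whether an observed value is small or large is
judged against a null that shuffles taxon labels across the tree's tips —
keeping the tree shape, the abundance matrix, and each sample's richness
fixed — and the standardized effect size is the beta nearest taxon index,

$$\beta\mathrm{NTI} = \frac{\beta\mathrm{MNTD}_{obs} - \overline{\beta\mathrm{MNTD}}_{null}}{\mathrm{sd}(\beta\mathrm{MNTD}_{null})}.$$

Values below $-2$ indicate phylogenetically *clustered* turnover (homogeneous
selection: the same filter acting everywhere), values above $+2$ indicate
*overdispersed* turnover (variable selection: different filters in different
places).

One configuration choice deserves emphasis. `beta_nti()` shuffles across the
table's **full taxon roster** — every column that is a tree tip, including
taxa with zero counts in the supplied samples — not merely the union of
observed taxa. When selection is homogeneous, every sample draws from the
same clade; a null restricted to the observed union would then reshuffle
*within* the filtered clade and, by construction, see no clustering at all.
The roster (in practice, all taxa observed anywhere in the study, sitting on
the study-wide tree) is what defines "the regional pool" against which
clustering is measured. `rc_bray()`, by contrast, drops zero-count taxa:
a taxon with zero regional occupancy can never be drawn into a null
community and contributes nothing.

Pairs that selection cannot explain ($|\beta\mathrm{NTI}| < 2$) are resolved
by the Bray–Curtis-based Raup–Crick metric. Each null community preserves
the sample's observed richness and read total; taxa are drawn without
replacement with probability proportional to regional occupancy, receive one
read each, and the remaining reads are allocated in proportion to regional
relative abundance. The observed Bray–Curtis dissimilarity is ranked in its
null distribution (ties at half weight) and rescaled to $[-1, 1]$. The
five-way classification is then a pure threshold function: $\beta$NTI $< -2$
homogeneous selection; $> 2$ variable selection; otherwise RC $< -0.95$
homogeneous dispersal, RC $> 0.95$ dispersal limitation, and $|RC| \le 0.95$
drift. Boundary values fall to the stochastic side, matching the strict
inequalities of the framework; $\beta$NTI is undefined (reported `NaN`, with
a count) when the null has zero variance, as on a star tree.

Null-model defaults: 999 iterations for both nulls (a flag on every
function), abundance-weighted $\beta$MNTD (presence-only via
`weighted = FALSE`), and within depth-layer × grassland-type groups in
`assembly_analysis()`, which is how per-group process fractions are usually
reported; an all-pairs mode exists for unstratified designs.

## The neutral model

`fit_ncm()` fits Sloan's neutral community model: with $N$ reads per sample
(the mean sample total after rarefaction, overridable), detection limit
$d = 1/N$, and migration rate $m$, a taxon at mean relative abundance $p$
should occur in a fraction

$$f_{pred}(p) = 1 - \mathrm{Beta}(d;\, Nmp,\; Nm(1-p))$$

of samples. $m$ is estimated by least squares on the occurrence frequencies;
because the SSE profile in $m$ can be flat near the boundaries, the
optimiser scans a log-spaced grid of 80 candidate values and refines the
bracketing interval with `optimize()`, which is deterministic and has never
failed to converge in our testing. The 95% band is a Wilson binomial
interval on $f_{pred}$ at the number of samples — the paper-standard way to
flag taxa above (greener-than-neutral) or below the neutral expectation.
$R^2 = 1 - SSE/SST$ may be negative for strongly non-neutral data; that is
informative, not an error.

## Networks, decay, attribution

Co-occurrence networks are built at genus level after two abundance filters:
phyla above 1% mean relative abundance, then the 200 most abundant genera
(summed counts; ties at the cap broken lexicographically and logged — mean
relative abundance is an alternative ranking the cap flag accepts). Edges
require Spearman $|\rho| > 0.8$ *and* $p < 0.05$ (taxon–taxon) or $p < 0.01$
(taxon–environment), on the t-approximation with tie-corrected ranks. No
multiple-testing correction is applied by default because the thresholds are
deliberately raw in the construction this package emulates; a
Benjamini–Hochberg flag exists and is off by default. Topology summaries:
average degree $2E/N$, mean local clustering over nodes of degree $\ge 2$,
average path length on the largest connected component (disconnected
networks are the norm), greedy modularity on the unsigned graph, and the
positive-edge fraction.

Distance-decay fits $\ln C = \alpha + \beta \ln(E/G)$ over sample pairs,
where $C$ is community dissimilarity and $E/G$ environmental or geographic
(haversine, sphere radius 6371.0088 km) distance. Pairs with a zero on
either side are excluded — a pseudo-count would manufacture slope — and
counted in the fit object. Because pairs sharing a sample are dependent, the
slope's significance comes from a Mantel-style permutation of one matrix's
labels, never from shuffling pairs independently. A similarity mode
($1 - C$) is provided since decay is conventionally phrased on similarity;
dissimilarity is the default here.

Attribution decomposes $\beta$NTI turnover. `mrm()` regresses the
vectorized lower triangle on predictor distance matrices (environmental
Euclidean on z-scored variables, geographic, biotic), with significance by
jointly permuting the response's row/column labels. The biotic "taxa
association" distance is deliberately configurable because its construction
is genuinely open: the default is the Euclidean distance between rows of
$S = P A$, where $P$ is the genus relative-abundance matrix and $A$ the
genus–genus Spearman correlation matrix — each sample described by its
abundances weighted through the association structure. `pls_pm()` estimates
a path model (mode A outer estimation, centroid inner scheme, convergence at
$10^{-6}$, 300-iteration cap) over latent blocks such as climate, soil,
space, biotic association, and $\beta$NTI, with indirect effects as products
along directed paths, $\mathrm{GOF} = \sqrt{\overline{\mathrm{communality}}
\times \overline{R^2}}$, and bootstrap percentile intervals. Latent
orientation is fixed by positive correlation with each block's first
indicator, so path signs are invariant to jointly flipping a block's
indicators.

## What the generator emulates

`simulate_dataset()` produces the whole input bundle — community table,
ultrametric Yule phylogeny (unit depth), environment table, and a truth
record — under a named regime. Its defaults mirror the study design the
package targets: 66 soil profiles on a ~400 km south–north gradient, three
depth layers (T/M/S), a few thousand taxa, reads per sample at the 16,611
rarefaction depth, precipitation declining northwards, and
SOC/TN/TP stocks scaled by 1/0.6/0.35 from topsoil to subsoil (a
qualitative depth decline, not a fit to any measured profile).

* **Niches** evolve by Brownian motion (rate `phylo_signal`, root 0) on the
  tree, so close relatives prefer similar environments — the conservatism
  that gives $\beta$NTI something to detect.
* **Selection regimes** weight the lognormal($0, 1.5$) metacommunity pool by
  a Gaussian kernel $\exp(-(o_i - E)^2 / 2\sigma^2)$ and draw reads
  multinomially. Homogeneous selection fixes one filter environment
  everywhere; variable selection spreads filters across the realized niche
  range along the latitude/precipitation gradient. Default niche breadth
  $\sigma = 0.3$ (tip-trait sd is 1) is strong filtering; each sample's
  weights also receive lognormal noise (sd 0.5), the microscale
  heterogeneity that gives samples realistic turnover (within-regime
  Bray–Curtis around 0.4–0.55) while leaving expected composition
  proportional to pool × kernel.
* **Neutral drift** draws reads through a sequential Pólya urn: a read is an
  immigrant from the pool or a copy of a uniformly chosen earlier read, with
  the immigration probability declining as $A/(A + t)$ for prior mass
  $A = Nm$. That schedule makes the final composition exactly
  Dirichlet-multinomial with concentration $Nm$ — the stationary family the
  Sloan fit asserts — so the fitted migration rate estimates the
  generator's $m$. (A constant per-read immigration probability, the other
  natural urn, is *not* Sloan-equivalent: its effective concentration decays
  with community size, and the fitted $m$ underestimates severely.) At
  $m = 1$ every read is an immigrant and samples are iid multinomials.
* **Dispersal limitation** is the same urn with small $m$ (default 0.01)
  whose starting composition is seeded from spatially autocorrelated local
  pools (per-taxon exponential-covariance random fields over the site map),
  so nearby sites resemble each other.
* **Mixed**, the default, applies strong selection in the topsoil, doubled
  niche breadth in the middle layer, and neutral drift in the subsoil —
  the depth-weakening of determinism the field repeatedly reports, available
  as a single dataset.

The generator is deliberately simple in ways worth keeping in mind:
multinomial read sampling has no overdispersion beyond the urn's, taxonomy
is carved from tree clades rather than a real classifier, the environment
table's covariance structure is stylised, and there is no sequence-level
error. Passing tests on synthetic data therefore demonstrate that the
*inference machinery* is correct and calibrated — not that any particular
field system obeys these models.

## Numerical choices and degenerate inputs

* Rarefaction subsamples without replacement (hypergeometric), drawing on
  taxon ids in sorted order so taxon-column order cannot change results.
* Shannon diversity is in nats; Chao1 is the bias-corrected form, defined
  when doubletons are absent; Good's coverage uses singletons over reads.
* Weighted UniFrac is the normalized variant (branch-sum denominator),
  bounded in $[0, 1]$.
* NMDS (Kruskal stress-1, monotone regression) takes a seed and a
  start count; permutation tests include the observed statistic in the null
  (so $p \ge 1/(n_{perm}+1)$) and require a seed.
* ANOSIM returns $R = 0$ with a warning when every distance is tied;
  singleton groups contribute no within-group pairs and are warned about.
* RC-bray ties use the half-weight convention — on tiny toy tables ties are
  the norm, and the convention makes the exact-enumeration oracle meet the
  Monte-Carlo estimate.
* The pipeline fans one master seed into named child seeds per stage, so any
  stage can be reproduced in isolation and reruns are bit-identical.

## Problem sizes used in the shipped checks

The test suite and `scripts/acceptance.R` exercise every claim above at
sizes chosen for a single CPU: 50 brute-force $\beta$MNTD instances (≤ 6
taxa); 50 null-calibration datasets of 20 samples × 100 taxa at 999 nulls;
regime-recovery datasets of 2,000 taxa × 8 sites at 501 nulls; 10
neutral-model recovery replicates of 100 samples × 50 taxa; 1,000 null
networks of 30 samples × 15 genera; 200 slope-coverage replicates at 66
sites; and 800 replicates per permutation-test calibration. The full-scale
defaults (66 profiles × 3 layers, thousands of taxa, 999 nulls) run in the
same code paths; only the sizes differ.
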