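---
title: "Local gradient maps as functional fingerprints: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Local gradient maps as functional fingerprints: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lgmprint)
```

## The model

Functional connectivity (FC) patterns of the cortex are individually
distinctive, but during infancy the connectome changes so quickly that
region-pair FC vectors identify individuals poorly across sessions. The
local gradient map (LGM) sidesteps the atlas entirely: it is a per-vertex
map of how often a vertex sits on a *boundary* of the connectivity
landscape, and those boundary configurations are far more stable within a
subject than the connectivity values themselves.

For one scan on a mesh with $V$ vertices the pipeline is:

1. **RSFC**: the $V \times V$ Pearson correlation matrix of the vertex BOLD
   time series (`computeRsfc`).
2. **Fisher z**: each correlation is mapped through
   $z = \tfrac12 \log\frac{1+r}{1-r}$ (`fisherZ`), variance-stabilizing the
   rows before comparing them. $|r|$ is clipped at $1 - 10^{-7}$ so the
   unit diagonal stays finite.
3. **Second-order correlation** (`secondOrderCorr`): the correlation
   between every pair of z-transformed connectivity rows. Connectivity maps
   drift gradually along the surface; their pairwise similarity drops
   sharply at functional area borders, which is the signal the next two
   steps extract. Rows enter whole, including their self-correlation
   entries — excluding the two diagonal entries of each pair changes the
   correlations by $O(1/V)$ and no observable result in our tests.
4. **Surface gradient** (`surfaceGradient`): for each second-order row,
   the magnitude of its spatial derivative on the mesh (below).
5. **Watershed** (`watershedBoundaries`): each gradient map is flooded from
   its local minima; vertices where two basins meet form that row's binary
   boundary map.
6. **LGM**: the mean of the $V$ binary boundary maps — the fraction of
   vertex-seeded connectivity maps for which each vertex is a boundary.
   Values lie in $[0, 1]$.

When a session has both anterior–posterior and posterior–anterior
acquisitions, their LGMs are averaged vertex-wise (`averageSessionLgm`);
the two phase-encoding directions distort differently, and averaging
cancels much of that noise.

### The mesh

All maps live on icosahedral unit-sphere meshes (`makeIcosphere`):
midpoint subdivision of the icosahedron, $10 \cdot 4^L + 2$ vertices at
level $L$, exactly 12 five-neighbour vertices at every level. Subdivision
keeps parent vertices first and appends edge midpoints in sorted-edge
order, so level $L-1$ is always the index prefix of level $L$ — "uniformly
sampled vertices" means a prefix (`uniformSubsample`), and the standard
levels 4/5/6 give the 2,562 / 10,242 / 40,962-vertex grids used in
cortical surface work. One mesh carries one map; hemispheres are processed
as independent meshes.

### The gradient operator

We use the root-mean-square of the chord-normalized finite differences
over the 1-ring, scaled by $\sqrt{2}$:
$$ |\nabla f|(v) \approx \sqrt{\; 2 \cdot \underset{u \in N(v)}{\mathrm{mean}}
   \left( \frac{f(u) - f(v)}{\lVert x_u - x_v \rVert} \right)^{\!2} \;}. $$
Each finite difference estimates the directional derivative along its
edge; for ring directions spread evenly in the tangent plane the mean
squared projection onto the gradient direction is $\tfrac12$, and the
$\sqrt 2$ factor undoes that. On $f = z$ (the height function, analytic
tangential gradient $\sqrt{1 - z^2}$) the operator is accurate to ~6%
away from the poles at level 4. The watershed only consumes the *ordering*
of gradient values, so this calibration does not affect boundaries; it
matters when gradient maps are inspected directly.

### The watershed

A Meyer-style priority flood, implemented in C++ for speed:

* a vertex is a local minimum if no neighbour is strictly lower;
  plateau-connected minima (equal values, adjacent) merge into one seed;
* vertices flood in increasing gradient order, ties broken by vertex
  index;
* a vertex whose already-labeled neighbours carry two or more distinct
  basin labels at flood time becomes a boundary vertex, excluded from
  every basin. A constant map yields one basin and no boundary.

Every rule is deterministic, and the implementation is checked
test-by-test against an exhaustive pure-R priority-flood oracle.

### Memory

At 40k vertices the $V \times V$ matrices reach ~13 GB. Above a
configurable vertex threshold (default 8,192) `computeLgm` never
materializes the second-order matrix: rows are computed in blocks from the
centred z matrix and consumed immediately. The z-RSFC matrix itself is
still held — any second-order row needs all z rows, so that is the true
memory floor of the method.

## Fingerprinting

Given a target LGM $G^t_i$ and base LGM $G^b_j$, the local correlation map
(LCM) at centre $v$ is the Pearson correlation of the two $r$-ring patch
vectors, $C_{ij}(v) = \mathrm{Corr}(P^t_i(v), P^b_j(v))$ (`computeLcm`).
Patch radius $r \in \{1..7\}$ and the sampled-centre count (all vertices,
or a nested prefix) are the two resolution knobs; identification is most
accurate with all centres and $r = 1$, so those are the defaults. A
constant patch on either side makes the correlation undefined: such
centres get value 0 and a flag, keeping centre sets aligned across pairs.

**Deformable strategy** (`deformableLcm`, $r = 1$): to absorb residual
registration misalignment, the base patch is additionally rotated by one
ring step in each direction (60° at hexagons, 72° at the 12 pentagons —
the nearest realizable rotation there) and slid to each of the centre's
ring neighbours (6 directions at hexagons, 5 at pentagons); the final
value is the maximum over the vanilla candidate and the up-to-8 deformed
candidates, hence never below the vanilla value. The target patch stays
fixed and only the base patch deforms; deforming the target instead is
symmetric and gives the same identification decisions in our tests. When a
translation pairs a hexagonal patch with a pentagonal one, both are
truncated to the shorter length (7 → 6 values) before correlating; this
affects only translations onto or off the 12 pentagons.

**Identification** (`identifyVertexwise`): each sampled centre votes for
the base subject with the highest local correlation; per-centre ties split
the vote equally; the modal vote is the prediction, with global ties
resolved to the lowest subject index and flagged. The average-based
alternative (`identifyAverage`) reduces each LCM to its mean first — it
discards the spatial pattern of similarity and is reliably worse on
synthetic cohorts, which is the point of the comparison. Rates are
percentages rounded half-up to one decimal (`identificationRate`), the
convention used when printing counts like 101/103 → 98.1.

The **connectome baseline** (`connectomeVector`, `identifyConnectome`) is
the classic approach: ROI-mean time series, ROI × ROI correlation, strict
upper triangle flattened row-major, nearest base vector by Pearson
correlation. Any label file is accepted; no specific atlas is assumed.

## Vertex contributions

With both sessions of $n$ subjects, the paired tensor holds
$C_{ij}(v)$ for all ordered subject pairs.

**Uniqueness** regresses inter-individual variability on intra-individual
variability across centres by OLS,
$$ U(v) = (1 - C_{\mathrm{inter}}(v)) - \alpha (1 - C_{\mathrm{intra}}(v)) - \beta, $$
with $C_{\mathrm{intra}}$ the mean of the $n$ self-pair maps and
$C_{\mathrm{inter}}$ the mean of the $n(n-1)$ cross-pair maps. $U$ is high
where subjects differ from each other while agreeing with themselves.

**Differential power** counts, per subject and centre, how often a
cross-subject correlation beats the self-correlation in either direction
($c_1$: $C_{ii}(v) < C_{ij}(v)$; $c_2$: $C_{ii}(v) < C_{ji}(v)$, $j \ne i$):
$$ DP_i(v) = -\ln \frac{c_1 + c_2}{2(N-1)}, \qquad DP(v) = \sum_i DP_i(v). $$
Strict inequality is taken literally (equal values are not violations). A
zero count is replaced by 0.5 before dividing, capping $DP_i$ at
$-\ln(0.5 / (2(N-1)))$ instead of producing infinity at perfectly
separating vertices. DP depends only on the within-centre ordering of
correlations, so it is invariant under strictly increasing transforms — a
property the tests exercise directly.

## Cognitive score prediction

Boundary features summarize an LGM against a reference parcellation
(`buildBoundaryAtlas`): for every adjacent region pair, the interface
vertices dilated three times (robustness to parcellation/individual
misalignment), and the feature is the mean LGM over the mask
(`boundaryFeatures`). Per cross-validation fold, boundaries whose feature
correlates with the training scores at $p < 0.01$ (two-sided t test on
Pearson r, $n-2$ df, no multiple-testing correction) are split by
correlation sign; the per-scan sums of the two sets form a two-dimensional
feature (`twoDimFeature`) fed to a regression random forest (20 trees,
minimum 5 observations per leaf, both features available at every split).
Ten iterations of 10-fold cross-validation are run; the per-scan
prediction is the mean over iterations and accuracy is the Pearson r
against the observed scores (`rfCvPredict`). A master seed spawns
per-iteration shuffle seeds and per-fold forest seeds, making the whole
procedure bit-reproducible.

When a training fold selects no boundary at all, its held-out scans
receive the training-mean score. This keeps every scan predicted in every
iteration, but it has a visible statistical signature: under a null
(scores permuted against features) almost every fold falls back, and
leave-one-fold-out training means *anticorrelate* with held-out scores, so
the null r is systematically negative (≈ −0.5 in our simulations) rather
than zero. The pipeline therefore never fabricates positive signal from
noise; the conservative bias is the price of the fallback and is asserted
in the tests.

**Network bookkeeping**: a boundary between regions of two networks counts
for both when computing contributions (`networkContribution`), and each
network's count is normalized by its total boundary-mask vertex count.
`leaveOneNetworkOut` removes every boundary touching one network and
reruns the cross-validation; a lower resulting r marks a more important
network.

## The synthetic cohort generator

`simulateLgmCohort` emulates exactly the structure the identification and
contribution analyses rely on:

* **individuality** — subjects share a group Voronoi parcellation whose
  seed vertices are jittered per subject within a hop radius (default 2),
  so parcel borders differ between subjects but not within;
* **session stability + noise** — a subject's LGM template is the
  smoothed indicator of its parcel borders (two passes of 1-ring mean
  filtering, rescaled to $[0,1]$; enough smoothing to make 1-ring patches
  informative), and each session observes the template plus Gaussian noise
  (default sd 0.1, i.e. 10% of template amplitude), clipped to $[0,1]$;
* **phase encoding** — optionally an extra per-acquisition noise draw
  produces AP/PA map pairs whose average is closer to the template than
  either, mirroring why AP/PA averaging helps;
* **BOLD** — parcel-driven time series (shared latent per parcel plus
  vertex noise at sd $1/\mathrm{snr}$) feed the full `computeLgm` pipeline
  and the connectome baseline; defaults T = 200, snr = 5 keep within- vs
  between-parcel correlations clearly separated without being degenerate;
* **misregistration** — `rotateLgmMap` resamples a map under a small
  global rotation (nearest vertex); at about one edge length (~8° at
  level 3) every vertex lands near a ring neighbour, which is precisely
  the displacement the deformable strategy is built to absorb.

`simulatePredictionStudy` adds the prediction layer: 70 subjects × 2
sessions = 140 scans, an 18-region group parcellation at level 3 (chosen
to match the region density of a fine-grained 864-region atlas on a 32k
mesh — about 36 vertices per region), networks 2–10 dealt round-robin and
network 1 built from two disjoint adjacent region pairs with maximally
separated dilated masks. One pair drives the score positively, the other
negatively, with Gaussian noise calibrated so the causal signal explains
36% of score variance. Exactly one network carries signal, so
leave-one-network-out has a known correct answer.

What the generator does **not** emulate: hemodynamics, temporal
autocorrelation, motion or distortion artifacts beyond the global-rotation
proxy, spatially correlated session noise, hemispheric asymmetry, or
development between sessions. Passing tests therefore demonstrate that the
algorithms recover the structures they claim to recover — not that real
infant data will reach any particular identification rate.

## Numerical choices and degenerate inputs

* Fisher z clips $|r|$ at $1 - 10^{-7}$ (z ≈ 8.1 at the diagonal).
* Zero-variance BOLD rows / constant connectivity rows: correlations set
  to 0, row indices flagged in the returned attributes and in the LGM's
  provenance record; the matrix shape never changes.
* Constant patches in LCMs: value 0 plus a flag (never dropped).
* Watershed ties: vertex index; plateau minima merge; constant maps give
  one basin, empty boundary.
* Per-centre vote ties split fractionally; global ties pick the lowest
  subject index and raise a flag.
* Rates round half-up to one decimal; no other quantity is rounded.
* Problem sizes in the test-suite and acceptance runs: meshes at levels
  2–3 (levels up to 6 for connectivity checks), cohorts of 10–20 subjects,
  T = 100–200 timepoints, 140-scan prediction studies — small enough to
  re-run everywhere, large enough that every recovery property is
  non-trivial.

## Known limitations

* Hop distance stands in for geodesic distance everywhere (ring
  neighbourhoods, dilation, Voronoi growth); on an icosphere the
  distortion is mild and uniform.
* The ±60° rotation is ±72° at the 12 pentagonal vertices, and
  translations there offer five directions, not six.
* The cross-validated r of the prediction pipeline has a sampling sd of
  roughly 0.065 at 140 scans; single-seed r values scatter accordingly
  around their expectation (~0.47 under the default study conditions).
* The uniqueness regression is fit per cohort and averaged across cohorts
  when several are supplied (`averageMaps`); pooling centres across
  cohorts before fitting would weight cohorts by centre count instead.
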