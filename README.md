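# microclonality

Spatial clonality analysis of multicolor (Confetti) fate-mapped microglia
around amyloid plaques.

In amyloid-model mouse cortex, microglia occupy two spatial states:
plaque-associated microglia (**PAM**, cell body in contact with or within
30 µm of an amyloid deposit) and non-plaque-associated microglia
(**non-PAM**). With a stochastic four-color lineage reporter (nGFP, YFP,
RFP, mCFP — one inherited color per recombined founder), clonal expansion
shows up as an excess of *same-colored* neighbors close to plaques,
relative to what random sparse labeling of the same cell positions would
produce. This package quantifies that signal from tables of segmented
centroids — no image files required — for researchers doing lineage
tracing and spatial analysis in neurodegeneration models.

## What it computes

**PAM / non-PAM classification.** Plaques are modeled as spheres of
equivalent volume, radius $r_p = (3V/4\pi)^{1/3}$; a cell is PAM iff its
body lies within 30 µm (inclusive) of the nearest plaque surface, or an
upstream mask-derived contact flag is set.

**Monte Carlo ring-density clonality test.** For every Confetti⁺ origin
cell, same-colored neighbors are counted in annuli of xy-distance
$(0,10], (10,30], \dots, (270,290]$ µm spanning the full image depth
$L_z$; the density of annulus $(r_1, r_2]$ is the per-origin mean count
divided by $\pi(r_2^2-r_1^2)L_z$. Densities are averaged image →
replicate → group and given a 98% Student-t interval across replicate
means. The null shuffles Confetti labels uniformly over the Pu.1⁺ cell
positions of each image (10,000 shuffles by default) and recomputes the
full group statistic per shuffle; per-annulus empirical 1%/99% quantiles
form the null envelope. Non-overlap of the two intervals rejects random
recombination at that distance with *P* < 0.02.

**Voronoi clone calling.** All cell and plaque centroids are z-projected
and tessellated in 2D (clipped to the image box); a clone is a connected
component of same-color adjacency among Confetti⁺ cells. Clones get a
territory (summed polygon area), plaque contacts (shared tessellation
edges), and per-group summaries including the fraction of plaques touched
by two or more clones.

**Clone-size regression.** Each (clone, contacted plaque) pair contributes
one point: x = plaque volume (µm³), y = clone cell count; ordinary least
squares with Pearson R and its t-test on n−2 df, stratified at 1,000 µm³.

**Synthetic tissue.** A generator produces cell/plaque tables with the
assumed statistical structure — Poisson background microglia, lognormal
plaque volumes, plaque-seeded clones whose expected size scales with
plaque volume, sparse clonal 4-color labeling, and the image → replicate →
group hierarchy — plus a scrambled-label mode that is the exact null of
the clonality test. Every analysis stage is validated against it.

## Worked example

```r
library(microclonality)

cfg <- sim_config(seed = 42)          # defaults: 3 animals x 3 tile scans
tissue <- simulate_group(cfg)
cells <- classify_cells(tissue$cells, tissue$plaques)
table(cells$state)
#> nonPAM    PAM
#>   6788  28048

rt <- ring_clonality_test(cells, make_ring_bins(290), tissue$meta,
                          n_shuffles = 2000, seed = 42)
rt
#> Ring clonality test (subset all, 2000 shuffles, 98% level)
#>   (0,10] um: excess (obs mean 0.0001, null [3.39e-06, 5.34e-06])
#>   (10,30] um: excess (obs mean 3.58e-05, null [2.01e-06, 2.57e-06])
```

The planted clones are detected exactly where they live: the observed
same-color density within 30 µm of an origin cell is ~20–30× the top of
the shuffled-label envelope, and no farther annulus departs from the
null. Clone calling and the regression on one image:

```r
img  <- cells[cells$image_id == "group1_r1_i1", ]
plq  <- tissue$plaques[tissue$plaques$image_id == "group1_r1_i1", ]
tess <- build_tessellation(img, plq, tissue$meta)
clones <- call_clones(tess, img)
clones
#> 139 Confetti clone(s) over 323 labeled cells (3723 unlabeled cells)
#> size
#>   1   2   3   4   5   6   7   8   9  10  11  13  14  16  19
#> 109   5   3   1   3   4   4   2   1   1   1   1   1   2   1

pairs <- contact_pairs(clone_plaque_contacts(clones), clones$clones, plq)
regress_strata(pairs)
#>   stratum n_pairs pearson_r p_value    slope intercept insufficient_n
#> 1     all      74    0.3694  0.0012 0.006086      1.04          FALSE
#> 2   small      63    0.1855  0.1455 0.003603      2.27          FALSE
#> 3   large      11    0.0178  0.9585 0.000628      8.80          FALSE
```

Most clones are singletons (unexpanded lineages and sparse background
labeling); the multi-cell clones sit at plaques, and clone size correlates
with contacted plaque volume. Labeled singletons that merely border a
plaque polygon enter the pair set with y = 1, which attenuates the
observational slope below the generative rate — see the methods vignette
(`vignettes/microglial-clonality.Rmd`) for why, and for how parameter
recovery is validated against the generator's founder lineages instead.

## The analysis workflow

`analysis/01_simulate_tissue.R` … `05_regression.R` run the whole study
on synthetic data — an amyloid-bearing group against a scrambled-label
control — writing each stage's tables under `results/`: simulation,
classification, the ring test for all/PAM/non-PAM subsets, Voronoi clone
calling with contacts, and the stratified regressions. Run them in order
from the repository root. `run_pipeline()` does the same end to end from
a single config and writes a manifest with file digests; reruns with the
same config and seed are byte-identical.

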