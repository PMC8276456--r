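# stormtad

Quantitative analysis of where sub-diffraction foci sit inside individual
chromatin domains imaged by single-molecule localization microscopy (STORM).

Topologically associating domains (TADs) appear in STORM as localization
clouds with radii of gyration around 200 nm; replication origins,
initiation sites and many nuclear protein assemblies appear as ~30 nm foci
inside them. The scientific question this package serves is *radial*:
are those foci at the periphery of their domain, at its center, or placed
as if at random? `stormtad` provides the full chain needed to answer it
reproducibly — a synthetic-data generator with ground truth, localization
from raw frames, drift/channel registration, two cluster-segmentation
engines, and the spatial statistics with their analytic random-placement
nulls — for analysts working with localization tables (native or
ThunderSTORM-style CSV) rather than proprietary microscope formats.

## The statistics at the core

Every localization is a point of unit mass, so for a cluster with members
$r_i$ ($i = 1..N$):

- **Barycenter** $\bar r = \frac1N \sum_i r_i$.
- **Radius of gyration** $R_g^2 = \frac1N \sum_i (r_i - \bar r)^2$.
- **Normalized barycenter distance** of a focus in a TAD:
  $d = |\bar r_\mathrm{focus} - \bar r_\mathrm{TAD}| / R$, where the
  normalizer $R$ is half the TAD's major axis (the sampling radius; default)
  or, alternatively, the TAD's $R_g$. A focus is assigned to its nearest
  TAD only when the raw distance is strictly under half the TAD major axis.
- **Random-placement nulls**: for foci uniform in a ball of radius $R$, the
  expected in-plane (projected) distance is $\frac{3\pi}{16}R \approx 0.589R$;
  the 3D mean is $\frac34 R$; for a disk, mean $\frac23 R$ and median
  $\sqrt{1/2}\,R$; the 3D median is $2^{-1/3} R$. All are verified against
  Monte Carlo within the package.
- **Radial density distribution (RDD)**: the median (or mean) distance of
  the focus localizations from the TAD barycenter, normalized by $R_g$ —
  larger means more peripheral.

Segmentation is by either a **two-radius DBSCAN** variant (core points have
$\ge N$ neighbors within $r$; cores closer than $r_\mathrm{ref}$ connect;
border points attach within $r_\mathrm{ref}$) or **Voronoi-density
segmentation** (select localizations whose inverse Voronoi-cell area
exceeds a density factor times the field's mean density — 3 for domains,
20 for origin-scale foci, 3.5 for protein clusters — then merge adjacent
selected cells).

## Worked example

```r
library(stormtad)

cfg  <- analysis_config(simulate = list(n_cells = 16), seed = 1)
res  <- run_experiment(cfg)
tapply(res$cells$mean_bary_dist, res$cells$preset, mean)
#>     g1_uniform g1s_peripheral       interior
#>     0.67847843     0.99126126     0.07906156
res$null$value
#> [1] 0.6666667
subset(res$tests, group1 == "g1_uniform" & group2 == "g1s_peripheral",
       c(mean1, mean2, p, tier))
#>       mean1     mean2            p tier
#> 2 0.6784784 0.9912613 1.752273e-12 ****
```

Sixteen synthetic cells per condition: foci planted uniformly in the domain
average a normalized distance of 0.678, statistically indistinguishable
from the analytic random null (2/3 for the disk geometry of the scene);
peripherally planted foci average 0.991 (≈ 1, the domain boundary), and
the difference carries the top significance tier. Interior foci (planted
at 0.2 of the radius) fall far below the null.

The same analysis, staged as a readable workflow with persisted
intermediates (localization CSVs, cluster tables, pair statistics, figures
under `results/`):

```sh
Rscript analysis/01_simulate.R --seed 1
Rscript analysis/02_segment.R
Rscript analysis/03_spatial_stats.R
Rscript analysis/04_report.R
Rscript analysis/05_robustness.R --seed 1
```

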