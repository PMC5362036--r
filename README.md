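# memloc

Single-cell scoring of membrane-versus-cytosol protein localization in
rod-shaped bacteria.

In *Caulobacter crescentus*, several regulatory proteins shuttle between
the cytoplasmic membrane and the cytosol in response to the second
messenger c-di-GMP — the acetyltransferase HfsK, a holdfast biogenesis
factor, is membrane-associated through most of the cell cycle and
disperses into the cytosol when c-di-GMP peaks. Deciding, cell by cell,
whether a fluorescent fusion sits at the membrane or in the cytosol is
the quantification this package implements, together with a
physics-based synthetic microscopy generator used to validate it end to
end.

## The statistic

For each cell outline (a closed polygon, e.g. from a phase-contrast
segmentation tool), the intracellular pixels are split into two
compartments:

- **membrane ring** — the first *w* intracellular pixels flanking the
  outline (default *w* = 4), formalized as Chebyshev distance ≤ *w* to
  the nearest exterior pixel, i.e. *w* successive 8-connected erosions;
- **cytosol** — the remaining intracellular pixels.

The per-cell statistic is the ratio of mean fluorescence intensities

&nbsp;&nbsp;&nbsp;&nbsp;*r* = ⟨I⟩<sub>membrane</sub> / ⟨I⟩<sub>cytosol</sub>

and the cell is classified **membrane-associated** if *r* > 0.7 and
**cytosolic** if *r* ≤ 0.7. The threshold is calibratable from control
populations (a soluble fluorophore such as free eGFP, and a membrane
dye such as FM4-64); at 0.7 both simulated control populations classify
perfectly. Because a fluorophore distributed through the cell volume
projects to a chord-depth profile that is dimmer near the cell edge
than at the axis, while a membrane label projects to an edge-peaked
shell profile, the ratio separates the two cases cleanly.

On top of the per-cell measurement the package provides cohort
summaries (membrane-associated fraction), threshold calibration and
misclassification rates, ratio-versus-cell-length tables, time-lapse
dispersal-episode detection (a maximal run of ≥ 2 consecutive
cytosolic-classified frames), and a reproducible
simulate → segment/outline → quantify → report pipeline.

## Worked example

Simulate a 40-cell cohort in which each cell is membrane-mode with
probability 0.5, quantify it with the ground-truth outlines, and
summarize:

```r
library(memloc)

cfg <- simConfig(nCells = 40L, canvasShape = c(640L, 640L),
                 populationMembraneProb = 0.5, seed = 42)
cohort <- simulateCohort(cfg)

params <- compartmentParams(backgroundMode = "constant",
                            backgroundValue = 100)
cells <- measureCells(cohort$image, cohort$outlines, params)
head(cells[, c("cell_id", "length_um", "ratio", "class")], 4)
#>    cell_id length_um     ratio     class
#> 1 cell_001  2.308992 0.6080726 cytosolic
#> 2 cell_002  2.713846 1.1558479  membrane
#> 3 cell_003  2.127495 1.1286023  membrane
#> 4 cell_004  2.779732 1.1540172  membrane

summarizePopulation(cells, threshold = 0.7)
#> PopulationSummary
#>   n=40 (membrane 19, cytosolic 21, excluded 0)
#>   fraction membrane-associated: 0.475 at threshold 0.70

table(pipeline = cells$class, truth = cohort$truth$mode)
#>            truth
#> pipeline    cytosolic membrane
#>   cytosolic        21        0
#>   membrane          0       19
```

Each row of `cells` is one cell: its Feret length in micrometres, the
mean ring and interior intensities after background subtraction, their
ratio, and the class at the 0.7 threshold. Here every cell lands on the
correct side of the threshold, so the estimated membrane-associated
fraction (0.475) equals the planted one.

A shell front end wrapping the same functions is installed at
`exec/memloc` inside the package library:

```sh
memloc simulate --config sim.yaml --out cohort/
memloc quantify --image cohort/image.tif --outlines cohort/outlines.json \
                --out cells.csv --background constant:100
memloc report --cells cells.csv --out summary.json
```

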