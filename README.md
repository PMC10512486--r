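# astromorph

Single-cell astrocyte morphometry from high-content fluorescence images,
the expression statistics that surround a differential-expression analysis,
and a simplified weighted-NNLS estimator of bulk cell-type composition —
with a synthetic-data generator providing pixel-level ground truth, so the
whole pipeline is testable without access-restricted raw data.

## Who this is for

Groups phenotyping iPSC-derived astrocyte cultures (e.g. comparing
differentiation protocols) typically quantify, per field of view:

* the fraction of GFAP⁺ cells, called from GFAP intensity in the
  **perinuclear zone** of each cell;
* mean Vimentin intensity inside the segmented cell mask (an immature
  astrocyte marker — the GFAP:Vimentin balance tracks maturation);
* the shape of the GFAP⁺ subpopulation via **summed-ratio morphometrics**
  after splitting each cell into soma and processes:

  $$\frac{\Sigma\,\text{soma area}}{\Sigma\,\text{cell area}},\qquad
    \frac{\Sigma\,\text{process area}}{\Sigma\,\text{soma area}},\qquad
    \frac{\Sigma\,\text{process area}}{\Sigma\,\text{cell area}},\qquad
    \frac{\Sigma\,\text{process perimeter}}{\Sigma\,\text{cell area}}.$$

Mature (stellate) astrocytes have small somata and long thin processes;
fibroblast-like (serum-exposed) cells have large somata and few thick
processes — the ratios separate the phenotypes. Around the imaging readouts
the package covers the standard expression-side steps (CPM-based
low-expression filtering, Benjamini–Hochberg adjustment, row Z-scores,
marker-panel scores, ΔΔCt qPCR relative expression, balanced two-way ANOVA)
and bulk deconvolution: given a cell-type signature matrix $S$ built from a
labelled multi-subject single-cell reference, composition is estimated by

$$\min_{x \ge 0}\ \lVert W^{1/2}(Sx - b)\rVert^2,\qquad
  w_g = \frac{1}{\sum_k V_{gk} x_k^2 + r_g^2 + \varepsilon},$$

iteratively reweighted NNLS with cross-subject variance $V$ and residuals
$r$ (the unweighted estimator sets $W = I$). Proportions are $x$
renormalised to sum to 1.

## Worked example

Generate a synthetic field of 12 stellate astrocytes (75% GFAP⁺, 5% channel
noise), segment it and measure every cell:

```r
library(astromorph)

lay   <- random_field_specs(12, "stellate", seed = 42,
                            gfap_positive_fraction = 0.75)
field <- generate_field(lay$specs, shape = lay$shape, noise_sd = 250,
                        background = 100, seed = 42)

nuclei_params <- segmentation_params(0, "fixed", 4050)
cell_params   <- segmentation_params(0, "fixed", 1050)
records <- segment_and_measure(field$channels, nuclei_params, cell_params)
records <- classify_gfap_positive(records, "fixed", 2550)

head(records[, c("cell_id", "cell_area_px", "soma_area_px",
                 "process_area_px", "perinuclear_gfap_mean",
                 "gfap_positive")], 4)
#>  cell_id cell_area_px soma_area_px process_area_px perinuclear_gfap_mean gfap_positive
#>        1          491          201             290             4987.6532          TRUE
#>        2          538          198             340             5035.3755          TRUE
#>        3          503          173             330             4975.4534          TRUE
#>        4          484          169             315              168.8235         FALSE

summarize_field(records)
#>  n_cells gfap_positive_fraction soma_to_cell process_to_soma process_to_cell process_perimeter_to_cell
#>       12                   0.75     0.325457        2.072603        0.674543                 0.8399465
```

The GFAP⁺ fraction is recovered exactly (9 of 12 cells were generated
positive; the negative cell's perinuclear GFAP sits at the background level
~170 vs ~5000 for positive cells), and the summed ratios show the stellate
phenotype: soma only ~33% of cell area, process/soma ratio ~2.1. A `flat`
field under the same settings gives soma_to_cell ≈ 0.89 and
process_to_soma ≈ 0.13.

The same analysis is available as config-driven workflows with manifests
and checksums:

```r
run_workflow(list(workflow = "synth", seed = 7, output_dir = "out",
                  synth = list(classes = list(stellate = 50), fields = 5,
                               gfap_positive_fraction = 0.8,
                               noise_sd = 250)))
```

(`validate_run_config()` checks a config without running it; a thin CLI
wrapper with the same two entry points is in `inst/cli/astromorph`.)

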