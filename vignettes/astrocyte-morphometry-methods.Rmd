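---
title: "Methods: synthetic astrocyte morphometry, expression statistics and bulk deconvolution"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: synthetic astrocyte morphometry, expression statistics and bulk deconvolution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope and rationale

`astromorph` re-implements, as reusable and tested code, the computational
core of a high-content comparison of astrocyte differentiation protocols:
per-cell morphometry from multi-channel fluorescence fields (nuclei/Hoechst,
GFAP, Vimentin), the expression-side statistics that surround a standard
differential-expression run, and a simplified cross-subject weighted-NNLS
estimator of bulk cell-type composition. Because raw high-content images and
human RNA-seq of this kind are typically access-restricted, the package ships
a synthetic-data generator that emulates the relevant structure of both data
types with known ground truth; every downstream stage is validated against
that truth and against independent brute-force oracles.

# The synthetic field generator

Each synthetic astrocyte is an elliptical soma with semi-axes $(a, b)$, a
nuclear disk of radius $0.6\,\min(a,b)$ at the cell centre, and $k$ straight
processes of length $L$ and width $w$ radiating from the soma boundary at
jittered regular angles. Two morphology classes are built in:

* **stellate** (mature phenotype): $(a,b) = (7,6)\cdot U(1,1.25)$ px, $k=6$,
  $L = 24\cdot U(0.9,1.15)$ px, $w = 2$ px — small soma, many long thin
  processes;
* **flat** (fibroblast-like, serum-exposed phenotype):
  $(a,b) = (16,13)\cdot U(1,1.25)$ px, $k=2$, $L = 12\cdot U(0.9,1.15)$ px,
  $w = 5$ px — large soma, few short thick processes.

Process count and width are fixed per class so the qualitative ordering
between classes holds for every draw; soma size, process length and
orientation carry bounded uniform jitter. Channel intensities are uniform
class levels on a 16-bit-like scale — background 100, nucleus 8000, GFAP
5000, Vimentin 2000 — with additive Gaussian noise clipped at zero ("5%
noise" means sd 250, 5% of the GFAP foreground). GFAP-positive cells carry
GFAP over soma plus processes; GFAP-negative cells stay at background in
that channel; Vimentin is rendered over the whole cell for every cell, since
it marks immature and mature astrocytes alike. There is no point-spread
blur, texture, or illumination gradient: the pipeline under test is
threshold-based, and a flat intensity model keeps pixel-level ground truth
exact. That choice bounds what passing tests demonstrate — recovery under
the stated noise model, not robustness to optical blur or shading, which
real acquisitions would add.

`random_field_specs()` places cells on a jittered grid with spacing derived
from the maximal cell reach, so fields are collision-free by construction;
`generate_field()` still verifies non-overlap and rejects colliding or
out-of-bounds specs. All randomness (jitter, process angles, noise, the
GFAP-positive subset) flows from the explicit seed; identical calls are
byte-identical, which the tests verify at the TIFF-file level. Bit depth and
pixel size are not properties the analysis depends on; outputs are 16-bit
TIFFs and all features are reported in pixels (a `pixel_size_um` slot exists
but no preset value is claimed).

Bulk expression is simulated as noisy mixtures: sample $=$ signature
$\times$ proportions, multiplied elementwise by lognormal noise
($\mathrm{sd}$ of the log given by `noise_sd_log`), the standard
multiplicative error model for expression data.

# Segmentation

Nuclei: Gaussian smoothing (sigma configurable), Otsu or fixed threshold,
then a watershed on the Euclidean distance transform to split touching
nuclei; components below `min_nucleus_area_px` (default 30) are removed.
Cells: foreground is the smoothed cytoplasmic marker above threshold
unioned with the nucleus supports, partitioned among nuclei by seeded
propagation on the smoothed marker — each cell inherits its nucleus label,
foreground components without a nucleus are discarded, and cells below
`min_cell_area_px` (default 100) are dropped together with their nucleus so
the nucleus/cell label sets stay in bijection. 8-connectivity is used
everywhere, and every disk structuring element contains the offsets with
squared distance at most $r^2 + 1$ — the slack of one makes the radius-1
disk the full 8-neighbourhood, keeping the dilation and connectivity
conventions consistent.

Defaults for real images are Otsu on a sigma-2-smoothed image. For the
synthetic recovery analyses the package uses `smoothing_sigma_px = 0` with
fixed thresholds halfway between background and the known foreground levels
(nuclei 4050, cells 1050, GFAP calling 2550): the generator renders no PSF,
so smoothing only erodes 2-px-wide processes, and with foreground/background
separated by roughly 10 noise standard deviations a midpoint threshold
recovers supports essentially exactly. This is a statement about the image
model, and it is the documented default of the config-driven workflows.

The perinuclear zone of a cell is its nucleus dilated by
`ring_width_px` (default 5) minus the nucleus, clipped to the cell support;
per-cell GFAP is quantified as the mean over this ring, and GFAP-positive
calling thresholds those pooled per-cell means — either at a fixed value or
by exhaustive Otsu (minimising within-class sum of squares over all midpoint
candidates), computed once per analysis batch rather than per field so the
call is consistent across fields of a condition.

Cell territory is segmented on the Vimentin channel when present (config
`cell_marker`), falling back to GFAP. GFAP-negative cells have no GFAP
signal above background; a GFAP-derived mask would collapse them to their
nuclei, empty their perinuclear rings and bias the GFAP-positive fraction
upward. Vimentin marks all astrocytes, so it defines territory while GFAP
remains the quantity measured and classified.

# Morphometry

The soma is the morphological opening of the cell mask with a disk of
radius `opening_radius_px`, restricted to the connected component containing
(or nearest to) the nucleus centroid; the processes are the remainder, so
soma and process areas are an exact partition of the cell. If the opening is
empty — a cell thinner than the disk everywhere — the fallback soma is the
nucleus dilated by 2 px, so the decomposition never degenerates to an empty
soma. The default radius is 4 px: the disk must be wider than the thickest
process (5 px for flat cells, so diameter 9 removes it) and narrower than
the smallest soma (stellate minor semi-axis 6 px survives erosion by 4).
A larger radius such as 8 px would erode the entire stellate soma and force
the fallback on every mature cell at these scales; the radius scales with
`opening_radius_px` if you generate larger cells.

The process perimeter is the exposed 4-neighbour pixel-edge count (a solid
10×10 square has perimeter 40) — an exact integer convention, chosen over
contour-length estimators so oracle tests can assert equality rather than
approximation. Field-level readouts are **summed** ratios —
$\Sigma$soma/$\Sigma$cell, $\Sigma$process/$\Sigma$soma,
$\Sigma$process/$\Sigma$cell, $\Sigma$perimeter/$\Sigma$cell — not means of
per-cell ratios, and by default the morphology sums run over GFAP-positive
cells only (the mature subpopulation of interest); the GFAP-positive
fraction always uses all cells. Skeleton-based branch counts and Sholl
profiles are deliberate extension points, not implemented.

# Expression statistics

* **Low-expression filter**: keep a gene iff CPM $\ge$ cutoff (default 1) in
  at least $k$ samples, $k$ defaulting to the smallest line-by-protocol
  group size. This is an explicit, documented approximation of the usual
  count-filter defaults, chosen so the rule is exactly testable.
* **BH adjustment**: the classical step-up map, delegated to
  `stats::p.adjust` and certified against a literal step-up oracle in the
  tests. Note the step-up map is not idempotent in general — reapplying it
  multiplies each order statistic by $m/i$ again — so only monotonicity is
  asserted as an invariant.
* **Row Z-scores** for heatmaps: centre by the row mean, scale by the
  $n-1$ standard deviation, constant rows mapping to zeros (conventions
  stated because heatmap practice varies).
* **Marker panels**: per-sample score = mean of row Z-scores over matched
  panel genes, down-direction genes sign-flipped; missing genes are
  reported, not fatal, unless none match.
* **Two-way ANOVA**: `stats::aov` on balanced complete designs only, with
  at least two observations per cell. Restricting to balanced designs
  removes the type-I/II/III sums-of-squares ambiguity — the grouped
  comparisons this is used for are balanced by construction. Post-hoc
  pairwise tests behind figure asterisks are out of scope.
* **qPCR**: $\Delta C_t = C_t^{\text{target}} - \tfrac12(C_t^{ACTB} +
  C_t^{L27})$, $\Delta\Delta C_t$ against the reference-group mean, and
  $RQ = 2^{-\Delta\Delta C_t}$, i.e. 100% amplification efficiency and the
  geometric mean of the housekeeping pair in linear space. A standard-curve
  method would need efficiencies that are not part of the inputs.

# Bulk deconvolution

`build_signature()` normalises each reference cell to relative abundance,
averages gene-wise per (subject, cell type), then takes the across-subject
mean (renormalised to column sum 1) and across-subject variance ($n-1$;
zero for types observed in one subject). `estimate_proportions_nnls()`
solves $\min_{x \ge 0} \lVert Sx - b \rVert^2$ on the shared gene set
(at least 50 genes by default), with both sides normalised to relative
abundance, and renormalises $x$ to proportions — hence the estimate is
invariant to bulk scaling and equivariant under cell-type permutation.
`estimate_proportions_weighted()` adds iteratively reweighted least squares
with gene weights

$$w_g = \frac{1}{\sum_k V_{gk} x_k^2 + r_g^2 + \varepsilon},$$

$V$ the cross-subject variance, $r$ the current residual,
$\varepsilon = 10^{-8}$; iterations stop when the maximum proportion change
drops below $10^{-6}$ or after 50 iterations (a non-convergence *flag*, not
an error — under heavy noise the IRLS tail-off can be slower than the
tolerance without affecting the estimate materially). With zero variance
and an exact fit the weights are constant and the estimator reduces to the
unweighted solution in two iterations.

This is deliberately a simplified estimator, not a clone of the full
multi-subject method: there is no multi-subject bulk model and no
tree-guided recursive estimation, and no claim to reproduce published
heatmaps that depend on restricted data. Validation is synthetic recovery:
noiseless mixtures to machine precision, Dirichlet mixtures at lognormal
noise 0.2 within 0.05 mean absolute error, and a paired heteroscedastic
scenario (10% of genes with 25× cross-subject variance and matching heavy
noise) where the weighted estimator must not lose to the unweighted one.

# Workflows, determinism, problem sizes

Four config-driven workflows (`synth`, `imaging`, `deconv`, `stats`) bind
the stages; configs are YAML/JSON with a strict schema (unknown keys are
violations), a mandatory seed for `synth`, and every effective parameter
echoed into a `manifest.json` alongside MD5 checksums of every output file.
Re-running any workflow with the same config and seed reproduces
byte-identical outputs; the test suite asserts this at the checksum level
for all four workflows.

The recovery analyses in the tests and the acceptance script use 5 fields
× 50 cells per morphology class at 5% noise for morphometry, 4 × 50 cells
at a generated GFAP-positive fraction of 0.8 for fraction recovery, and
500-gene/4-type (or 400-gene/3-type) mixtures for deconvolution — sizes at
which the class-separation and recovery properties are comfortably
identified while a full run stays in the minutes range on one core.

# Known limitations

* The generator's flat intensity model means segmentation accuracy here does
  not transfer to blurred, vignetted or textured real acquisitions; Otsu
  mode and smoothing exist for that use, but are not validated against real
  ground truth.
* Morphology is area/perimeter-based only; branching topology is invisible
  to the four summed ratios.
* The deconvolution stage models a single bulk sample at a time and assumes
  the reference covers the mixture's cell types; missing types are absorbed
  into the nearest available profiles.
* The ANOVA is restricted to balanced designs by design; unbalanced data
  need a model-based route (e.g. mixed models) outside this package's scope.
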