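# th17traj

Tools for analyzing how IL-26-producing TH17 intermediates mature into
IL-17A-producing effector cells in inflamed (psoriatic) skin. The package
re-implements, as tested and reusable R functions, the computational core
of that analysis: pseudotime ordering of single cells from marker-defined
root cells, tracking of TCR clonotypes across pseudotime stages, spatial
transcriptomics spot gating with minimum-distance colocalization
statistics, and TGF-β signature scoring — together with a seeded
synthetic-data generator that emulates the statistical structure of such
data so every step can be validated against known ground truth.

## The methods

**Geodesic pseudotime.** Cells are embedded by PCA of log-normalized
counts (`x' = ln(1 + c/C · 10⁴)` for count `c` and library size `C`) over
highly variable genes. A union k-nearest-neighbor graph is built on the
embedding (edge weights = Euclidean distances, components joined through
their closest point pairs), root cells are defined by a marker threshold
(default CCR7 > 2.5 on the log scale), and each cell's pseudotime is its
shortest-path distance to the nearest root:

    pt(v) = min over roots r of d_G(r, v)

Cells are binned into early/intermediate/late stages at the ⅓ and ⅔
pseudotime quantiles (absolute thresholds are available), and expression
trends over pseudotime are fitted with natural cubic splines (df = 4).

**Clonotype tracking.** Cells sharing a TCR clonotype are joined to their
stages and IL26/IL17A positivity (positivity = at least one count). The
package reports which subset of stages each clone occupies (Venn counts),
early-to-late cytokine-state flows (IL26± → IL17A±, the Sankey table),
and the provenance of late IL17A⁺ clones — how many had IL26⁺ members in
the early stage.

**Spatial colocalization.** Spots are gated by boolean marker rules
(e.g. `t_il26 := (CD3D|CD3E|CD3G) & IL26`, `kc_tgfb1 := KRTDAP & TGFB1`),
assigned to epidermis/dermis by a keratin gate, and flagged as
dermo-epidermal-junction spots when adjacent (≤ 1.2 × spot pitch) to the
other compartment. Minimum Euclidean distances between spot classes are
compared with a hand-built two-sample Kolmogorov–Smirnov test:

    D = sup_x |F̂₁(x) − F̂₂(x)|,   p = 2 Σ_{j≥1} (−1)^{j−1} exp(−2 j² λ²),
    λ = √(nm/(n+m)) · D

with an optional seeded permutation p-value (recommended on tied grid
distances).

**Signature scoring.** The TGF-β-induced signature score of a cell is the
mean of per-gene z-scores of normalized expression over the signature
genes (two published presets ship; the "methods" set is the default).

## Worked example

```r
library(th17traj)

# synthetic single-cell dataset with ground truth, full pipeline
res <- run_cell_pipeline(cell_sim_config(seed = 1), "run1")
res$pseudotime
#> Geodesic pseudotime over 2000 cells
#>   roots: 297 cells with CCR7 > 2.5
#>   range: [0, 23.43]
res$stages
#> Stage assignment (quantile mode, t1 = 6.327, t2 = 14.83)
#>   early 667 | intermediate 666 | late 667
res$provenance
#> Late IL17A+ clones: 210
#>   with early-stage presence: 31/210 (0.148)
#>   with early IL26+ correspondence: 31/210 (0.148)

# spatial dataset: IL26+ T spots concentrate below the junction,
# IFNG+ spots are uniform; KS compares the two distance distributions
sp <- run_spatial_pipeline(spatial_sim_config(seed = 1), "run1_sp")
sp$ks
#> Two-sample KS test: D = 0.5789, p = 5.882e-06 (n = 38, m = 38)
#>   significant at alpha = 0.05

build_report("run1")   # venn/flow/ECDF/contact/trend tables + figures
```

The pseudotime print shows the root population (cells above the CCR7
threshold sit at pseudotime 0) and the geodesic range; the stage print
shows the tercile binning; the provenance print counts clones with an
IL17A⁺ cell in the late stage and, of those, how many had early-stage
IL26⁺ members. In the spatial run the large D and small p reflect the
designed colocalization of IL26⁺ T-cell spots with TGFB1⁺ keratinocytes.

Every pipeline stage also writes plain CSV/JSON outputs (plus a manifest
with config hash and seed) into the run directory; reruns with the same
config and seed are byte-identical.

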