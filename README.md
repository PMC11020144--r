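# rootpose

Landmark-based (segmentation-free) root system architecture (RSA) trait
extraction in R.

Modern root phenotyping platforms image seedlings grown in transparent gel
cylinders on a rotating stage: 72 views per plant at 5° steps, grayscale
2048 × 1088 px frames at a scale of 10.6 px/mm. Pose-estimation models detect
each root in each view as an *instance*: an ordered polyline of named
landmark nodes (r1 … rN) along the root centerline — six nodes for primary
and crown roots, three to four for lateral roots, with occluded bases or tips
encoded as missing nodes. `rootpose` turns those landmark series into a
complete, reproducible trait table per plant, for two plant architectures:

* **Dicot pipeline** (primary + lateral roots): 35 per-frame traits
  (25 scalar, 10 non-scalar), expanding to 115 per-frame and **1,035
  summarized traits per plant**.
* **Younger-monocot pipeline** (primary + crown roots, jointly the "main"
  class): 30 per-frame traits (21 scalar, 9 non-scalar), expanding to 102
  per-frame and **918 summarized traits per plant**.

The package is aimed at plant biologists running high-throughput RSA screens
(GWAS panels, mutant collections, genotype classification) who have landmark
predictions and need trait matrices, and at methods developers who need a
fully testable, data-free reference implementation of the trait suite.

## What is computed

Per root instance (polyline `p_1 … p_N`, image coordinates, y increasing
downward so the gravity vector is (0, +1)):

* length `L = Σ ‖p_{i+1} − p_i‖`, base–tip chord `d = ‖p_N − p_1‖`, and
  curve index `(L − d) / L ∈ [0, 1)`;
* gravity angles `θ = atan2(|Δx|, Δy)` (0° = straight down, 90° =
  horizontal) between the base→proximal and base→distal node vectors and
  gravity;
* base and tip coordinates, and scalar descriptors of the lateral base
  column (extent, density per primary length, count).

Per frame (whole root system):

* **root widths**: visible lateral bases are split into left/right of the
  primary polyline, each base is projected to its normalized arc-length
  position on the primary, and left/right bases are paired by minimum-cost
  linear assignment (Hungarian algorithm) on `|proj_L − proj_R|`, keeping
  pairs within a projection tolerance (default 0.02) whose connecting
  segment crosses the primary; widths are the paired base distances;
* convex hull perimeter, area, max width/height, and all vertex-pair chord
  lengths; least-squares ellipse fit (semi-axes `a ≥ b` and ratio `a/b`);
* a 50-line horizontal scanline intersection profile with first/last
  intersecting line indices;
* network length, bounding-box width/depth ratio, solidity
  (`network length / hull area`), and the length fraction in the lower 2/3
  of the bounding box.

Traits form a dependency DAG evaluated in topological order. Non-scalar
traits are summarized per frame by nine statistics (max, min, mean, median,
SD, and the 5th/25th/75th/95th percentiles), and every per-frame trait is
summarized again across the 72 frames — `{trait}_{framestat}_{plantstat}`
columns such as `lateral_tip_pt_ys_max_median`.

A parametric synthetic root-system generator with analytic ground truth
(`generate_plant`, `generate_cohort`) makes the whole pipeline testable
without any imaging data, and `zscore_differences` / `pearson_by_trait`
quantify agreement between trait tables (e.g. proofread vs automated
predictions) via absolute z-score differences `Δz = |x_ref − x_cand| / σ_ref`
and per-trait Pearson correlation.

## Worked example

```r
library(rootpose)

g <- generate_plant(plant_model(kind = "dicot", n_children = 4,
                                branch_angles = c(40, 55, 62, 70), seed = 42))
pipe <- build_pipeline("dicot")
#> <trait_pipeline 'dicot': 35 per-frame traits (25 scalar, 10 non-scalar)>
traits <- compute_plant_traits(g$series, pipe)
length(traits)
#> [1] 1035
round(traits[c("primary_length_median", "curve_index_median",
               "lateral_count_median",
               "lateral_angles_proximal_median_median",
               "chull_area_median", "network_solidity_median")], 4)
#>                 primary_length_median                    curve_index_median
#>                              899.8214                                0.0059
#>                  lateral_count_median lateral_angles_proximal_median_median
#>                                4.0000                               58.5000
#>                     chull_area_median               network_solidity_median
#>                           142933.5149                                0.0105
```

The plant was generated with a 900 px primary root bowed slightly
(curve index 0.0059); the 6-node polyline measures 899.82 px — the small
shortfall is the resampling gap of a fixed-node skeleton. `lateral_count` is
recovered exactly, and the median of the median per-frame lateral angle is
58.5°, the median of the generating angles {40, 55, 62, 70}. Hull area
(px²) and solidity (1/px) describe the explored gel area and how densely it
is filled.

Batch use mirrors real screens: `read_landmarks` reads the plain-CSV
landmark exchange format (`plant_id,frame_idx,root_class,instance_idx,
node_idx,x,y`; empty x,y = occluded node), `merge_series` combines primary
and lateral/main prediction files, and `run_batch` writes one CSV row per
plant. Thin command-line wrappers live in `inst/cli/`
(`compute-traits.R`, `generate-synthetic.R`, `compare-traits.R`).

## Scope

The package starts from landmark predictions; training or running the pose
estimation models themselves, image handling, 3D reconstruction across
views, and downstream analyses (genotype classification, outlier flagging,
embedding) are out of scope. See `vignettes/trait-extraction.Rmd` for the
methods, numerical conventions, and known limitations.
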