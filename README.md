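# graftmorph

Patient-specific CT morphometry of coracoid bone-graft resorption after the
Latarjet procedure.

## The problem

The Latarjet procedure treats recurrent anterior shoulder dislocation by
transferring the coracoid process onto the anterior glenoid rim and fixing
it with two screws. Over the following years the transferred bone block
resorbs — sometimes losing more than half its volume — and the question of
how much, and where, matters for revision decisions. 2D grading schemes
(the Zhu classification, which scores how much of each screw is exposed on
axial CT) capture severity but no volumes; direct 3D comparison needs an
early post-operative CT that usually does not exist and would cost extra
radiation.

`graftmorph` implements a registration-based alternative that needs only
the two scans that already exist: the pre-operative CT (which still
contains the intact coracoid) and the long-term follow-up CT. The
pre-operative scapula geometry `S_pre` is rigidly registered onto the
follow-up scapula `S_fu` (trimmed point-to-surface ICP, transform
`T = (R, t)`), the documented coracoid osteotomy is replayed on
`T(S_pre)` by a plane cut, and the cut fragment — the *timepoint-zero
graft* `G_0` — is placed on the glenoid using the resorption-spared
inferior region of the actual graft as the anchor. The remodelled graft
`G_f` is isolated from the follow-up scan by removing everything inside
`T(S_pre)` (native bone) and the screw metal. Resorption is then

    ΔV = V(G_0) − V(G_f),      resorption% = 100 · ΔV / V(G_0)

with both volumes measured over the same voxel domain (the fitted screw
geometry is carved out of both — the segmented graft can never contain
metal-occupied voxels). Regional loss maps
(superior/inferior, medial/lateral, superficial/deep) and a geometric
surrogate of the Zhu grade (point-sampled coverage of the screw head and
extra-osseous shaft) complete the morphometry. A validation layer provides
tie-corrected Kendall tau-b with bootstrap CIs and absolute-agreement
ICC(2,1), the statistics used to validate the technique against ordinal
grading and repeated ratings.

Because no imaging data are published with the technique, the package
ships a synthetic phantom generator with exact voxel-level ground truth
(scapula-like body, tapering coracoid, plane osteotomy, placed graft,
two screws, graded osteolysis with a known resorbed fraction, rigid
inter-scan motion, Gaussian noise) so that every stage of the chain is
testable end to end.

## Worked example

Generate a phantom pair with 30% simulated (superiorly weighted)
osteolysis and measure it:

```r
library(graftmorph)

spec <- phantom_spec(resorption_fraction = 0.3, seed = 11)
ph <- generate_phantom_pair(spec)

report <- measure_graft_pair(ph$preop, ph$followup,
                             ph$truth$osteotomy_plane,
                             axes = ph$truth$axes_followup)
report
#> graft_report
#>   V0 2109 mm^3, Vf 1567 mm^3 -> resorption 542.5 mm^3 (25.7% loss)
#>   Zhu grade: 2 (per screw: 0, 2 )
#>   registration RMS 0.147 mm (2 iterations)

100 * ph$truth$resorbed_fraction   # ground truth: 30.0
```

The measured 25.7% against a 30.0% truth is within the package's
validated recovery tolerance (five percentage points across resorption
fractions 0–0.6; see the acceptance suite). `report$regional` localizes
the loss — here concentrated superiorly, where the phantom put it — and
`report$volumes` carries both the voxel-domain volumes above and the raw
mesh volumes. `run_pipeline()` does the same from a JSON config and file
paths, writing every intermediate mesh (STL), the transform (JSON) and a
provenance report; `inst/cli/graftmorph.R` wraps the common subcommands
(`simulate`, `segment`, `register`, `measure`, `stats`, `run`) for shell
use.

The statistics layer works on plain rating tables:

```r
co <- simulate_cohort(seed = 1)          # 31 patients, grades 8/18/5
kendall_tau_b(co$zhu_grade, co$resorption_pct)
#> Kendall tau-b = 0.544 (95% CI [0.258, 0.712]), p = 0.00018, n = 31
summarize_by_grade(co)                   # per-grade volume table
```

## Package layout

- `R/volume.R`, `R/mesh.R` — CT volumes (NIfTI/MetaImage) and triangle
  meshes (STL/PLY) with explicit physical-space conventions
- `R/segmentation.R` — two-threshold bone/metal segmentation, marching-
  tetrahedra surface extraction
- `R/registration.R` — trimmed ICP with multi-start initialization
- `R/morphometry.R` — virtual osteotomy, graft placement and isolation,
  volumetry, regional maps, screw fitting, geometric Zhu grading
- `R/stats.R` — Kendall tau-b, ICC(2,1), per-grade summaries, cohort
  simulation
- `R/phantom.R` — the ground-truth phantom generator
- `R/pipeline.R` — orchestration and reporting
- `vignettes/graft-resorption-morphometry.Rmd` — the methods vignette
  (model, assumptions, parameter choices, limitations)
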