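# coxaplan

Virtual surgical planning and accuracy assessment for **bipolar
coxofemoral (hip) osteochondral allograft transplantation** — an R package
for the full computational workflow around replacing both articular
surfaces of the hip with size-matched donor grafts:

* **Osteotomy planning** — two converging ("chevron") cut planes built from
  four landmarks on the physeal scar; the two landmarks shared by both
  defining triples form the chevron ridge by construction.
* **Virtual osteotomy** — watertight plane clipping of bone surface meshes
  with volume-exact capping, graft/remainder separation, and a subchondral
  thickness check against the 8 mm graft bound (3–8 mm working band).
* **3D morphometry** — femoral neck **version** (signed transverse-plane
  angle of the neck axis against the transcondylar axis, anteversion
  positive), **inclination** (frontal-plane angle against the distal
  diaphyseal direction, ≈135° in a normal canine femur), and **neck
  length** (head centre to the neck-axis/diaphyseal-axis intersection),
  all derived from least-squares sphere and cylinder fits in a pose-
  invariant anatomic frame.
* **CT segmentation and gap volumetry** — inclusive HU thresholding (bone
  ≥ 300 HU), watertight isosurface extraction (marching tetrahedra), and
  donor–recipient interface gap segmentation at ≤ 250 HU restricted to
  components touching both bones.
* **Matching and statistics** — donor–recipient pairing under the
  "donor acetabulum 1–4 mm smaller" rule, mirror-image plans for the
  contralateral side, absolute deviation-from-plan records, and one-tailed
  paired t-tests with Shapiro–Wilk normality reporting.
* **Synthetic data** — parametric canine proximal femora and graft–bed
  scenes with recorded ground truth, rasterized to Hounsfield-unit CT
  volumes, so the entire pipeline is testable end to end without any
  imaging download.

## Worked example

Generate a synthetic femur with known anatomy, measure it through the full
pipeline, and plan its osteotomy:

```r
library(coxaplan)

fem <- generate_femur(femur_params(version = 20, inclination = 135,
                                   neck_length = 35))
mr <- measure_femur(fem$mesh, fem$landmarks$condyle_medial,
                    fem$landmarks$condyle_lateral, side = "right")
mr
#> <morphometry_result [right femur]>
#>   head centre   : (23.97, 8.72, 103.97) mm, radius 10.00 mm (rms 0.000)
#>   inclination   : 135.0 deg
#>   version       : 20.0 deg
#>   neck length   : 35.0 mm

plan <- chevron_planes(fem$landmarks, head_point = mr$head_center)
round(plan$dihedral_angle, 1)
#> [1] 68.6

head_mesh <- sphere_mesh(mr$head_center, mr$head_radius, label = "articular")
cut <- clip_mesh(head_mesh, plan)
th <- max_subchondral_thickness(cut$graft, articular_label = "articular")
round(th$thickness, 1); th$thickness_ok
#> [1] 20
#> [1] FALSE
```

The thickness check does its job here: clipping a *solid* synthetic head at
the physeal scar leaves 20 mm of bone under the articular pole, well over
the 8 mm graft bound, so the flag trips — a real plan would place the cuts
(or trim the graft) until it passes.

The measured version/inclination/neck length reproduce the generator's
parameters exactly on noiseless meshes; with 0.2 mm vertex noise they stay
within 2° / 1.5 mm across the whole tested parameter grid.

Run the synthetic five-pair guided-vs-freehand study:

```r
report <- run_pipeline(pipeline_config(n_subjects = 5, seed = 7,
                                       include_gap = FALSE))
format_study_table(report)
#>     parameter freehand_mean freehand_sd guide_mean guide_sd p_one_tailed
#> 1     version      6.152245   3.4572374   1.183726 1.068864  0.022201002
#> 2 inclination      8.869797   6.0569564   4.336605 2.608030  0.129861416
#> 3 neck_length      4.819803   0.9705652   1.244312 1.162430  0.009213435
```

The guided arm lands significantly closer to the plan for version and neck
length but not inclination — the same pattern the workflow is designed to
detect.  A thin command-line wrapper with `synth` / `segment` / `measure` /
`plan` / `gap` / `match` / `stats` / `run` subcommands ships in
`inst/cli/coxaplan.R`.

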