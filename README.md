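# carotid3d

Headless reconstruction of carotid vessel **lumen** and **wall** surfaces
from multi-sequence black-blood MRI.

Assessing atherosclerotic plaque burden from carotid MRI involves more
than measuring stenosis: radiologists outline the blood-carrying lumen
and the outer vessel wall on every slice of a black-blood acquisition
and inspect the resulting 3D geometry. A clinical protocol acquires five
sequences of the same neck — T1, post-contrast T1 (T1CE), T2, 3D
time-of-flight (TOF) and 3D MP-RAGE — with two very different slice
spacings: the spin-echo stacks use a thick inter-slice gap (about 2 mm)
while the 3D acquisitions are thin (about 0.5 mm). carotid3d provides
the complete non-interactive pipeline for this workflow:

1. **Load** — scan a study directory, classify each sub-directory by its
   DICOM *Series Description* tag (never by folder name), sort slices by
   *Slice Location* and window stored pixels to 8-bit display values.
2. **Register** — pick a primary sequence, auto-assign corresponding
   initial slices in the secondaries, and *rationalize*: decimate
   thin-gap series onto the primary grid by nearest slice location so
   that all five series end up with identical counts, identical gaps,
   and aligned slice locations.
3. **Mark** — closed lumen/wall polygons per slice (from a JSON sidecar
   file), held in a doubly-linked stack whose Z comes from the slice
   location; markings made on the primary are propagated verbatim to the
   secondaries.
4. **Smooth** — densify each marked polygon with quadratic Bezier
   curves, `B(t) = (1−t)² M₁ + 2(1−t)t C₁ + t² M₂`. The quadratic curve
   interpolates its endpoints and stays inside the convex hull of
   {M₁, C₁, M₂}, so it cannot overshoot the marked points — the reason
   it is preferred over the cubic
   `B(t) = (1−t)³ M₁ + 3(1−t)²t C₁ + 3(1−t)t² C₂ + t³ M₂`, which is
   included as a comparison utility together with the affine-combination
   identity `B_c(t) = (1−t)·B_{M₁,C₁,C₂}(t) + t·B_{C₁,C₂,M₂}(t)` used as
   a numerical cross-check.
5. **Loft** — resample each smoothed contour to N ring points by arc
   length, stitch adjacent rings with triangles, and export the mesh
   (vertices in mm, per-vertex normals, cylindrical texture
   coordinates) as Wavefront OBJ or binary STL. Closed (capped) meshes
   support volume by the divergence theorem.

A **synthetic DICOM phantom** generator produces five-sequence studies
of a tubular vessel with known lumen/wall radii plus ground-truth
contours, so the entire pipeline is testable and demonstrable without
patient data. The package includes its own minimal DICOM Part-10 codec
(explicit-VR little endian, uncompressed 16-bit monochrome) covering
exactly the tags the pipeline consumes.

## Worked example

```r
library(carotid3d)

# a five-sequence phantom: lumen r = 3 mm, wall r = 5 mm, 38 mm of
# coverage; T1/T1CE/T2 at gap 2.0 x 20 slices, MPRAGE/TOF at 0.5 x 80
dir <- tempfile("study")
generate_study(phantom_spec(seed = 42L), dir)

report <- run_pipeline(dir, file.path(dir, "truth_contours.json"),
                       pipeline_config(cap_ends = TRUE),
                       out_dir = file.path(dir, "out"))
report$registered_count   # 20     slices retained in every series
report$gap_mm             # 2      common inter-slice gap, mm
report$volumes$lumen      # 1070.97  mm^3  (analytic pi*3^2*38 = 1074.42)
report$volumes$wall       # 2974.92  mm^3  (analytic pi*5^2*38 = 2984.51)
```

The thin-gap TOF/MPRAGE series keep every 4th slice (original indices
1, 5, 9, …, 77), the recovered volumes sit within 0.4 % of the analytic
cylinder values, and `out/` contains `lumen.obj`, `wall.obj` and a JSON
report. The same stages are scriptable from a shell via the bundled CLI:

```sh
CLI=$(Rscript -e 'cat(system.file("cli","carotid3d",package="carotid3d"))')
Rscript $CLI phantom --out study --seed 42
Rscript $CLI validate study --json
Rscript $CLI pipeline study study/truth_contours.json --caps --out-dir study/out
```

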