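Package: carotid3d
Title: Carotid Lumen and Wall Reconstruction from Multi-Sequence MRI
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Headless pipeline for reconstructing 3D carotid vessel
    lumen and wall surfaces from multi-sequence black-blood MRI. Loads
    five-sequence DICOM studies (T1, post-contrast T1, T2, 3D TOF,
    3D MP-RAGE) classified by the Series Description tag, registers the
    series by Slice Location arithmetic (equal counts, equal inter-slice
    gaps, aligned locations), represents marked lumen/wall contours as
    closed per-slice polygons, densifies them with quadratic Bezier
    curves, and lofts the contour stacks into triangle meshes with
    normals and texture coordinates, exportable as Wavefront OBJ or
    binary STL. Includes a synthetic DICOM phantom generator with known
    tubular geometry so the whole pipeline is testable without patient
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: jsonlite, stats
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
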