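Package: coxaplan
Title: Virtual Osteotomy Planning and 3D Morphometry for Bipolar Hip
    Osteochondral Allograft Transplantation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for virtual surgical planning and accuracy assessment of
    bipolar coxofemoral (hip) osteochondral allograft transplantation.
    Provides landmark-derived biplanar (chevron) osteotomy planning from
    physeal-scar landmarks, least-squares sphere and cylinder fitting,
    femoral morphometry (neck version, inclination, neck length, acetabular
    diameter), donor-recipient matching by acetabular diameter, virtual
    mesh osteotomies with watertight capping, Hounsfield-unit segmentation
    of CT volumes including donor-recipient interface gap volumetry, rigid
    landmark registration, mirror-plan construction, and the paired
    one-tailed statistical comparison of deviation from plan.  A synthetic
    data module generates parametric canine proximal femora, graft-bed
    scenes and rasterized CT volumes with recorded ground truth so the
    whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    RNifti,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
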