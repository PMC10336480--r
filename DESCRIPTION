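Package: octomdm
Title: Rule-Based Decision Support and Triage for Head-and-Neck Tumor Boards
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Decision support for multidisciplinary team meetings (MDMs, tumor
    boards) in head-and-neck oncology. A guideline-style rule table maps tumor
    sublocation and stage class to candidate treatment regimens; regimens are
    filtered by per-modality feasibility, and complex cases (relapse,
    metastatic disease, no feasible option) are escalated to a face-to-face
    meeting. Includes a consensus/validation workflow for the five consultant
    roles (votes, unanimity, 15-day review deadline, internal messaging,
    reports), canonicalization of free-text decision strings, Cohen's kappa
    for automatic-versus-expert agreement, packaged reference cases, a seeded
    synthetic case generator, and JSON/CSV case I/O.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: jsonlite, utils, stats, tools
Suggests: testthat (>= 3.0.0), optparse, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
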