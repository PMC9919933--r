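Package: hostguest
Title: Phase-Solubility, Stability Constants and Trajectory Descriptors for Host-Guest Inclusion Complexes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for cyclodextrin-flavonoid inclusion-complex
    studies. Fits Beer-Lambert UV calibration lines and Higuchi-Connors
    AL-type phase-solubility isotherms and computes 1:1 stability constants;
    post-processes periodic-box molecular trajectories (mean square
    displacement and Einstein-relation diffusion, radial distribution
    functions with interaction-band classification, geometric hydrogen-bond
    detection, typing and molar concentration); computes binding energies,
    Hildebrand solubility parameters and compatibility verdicts; and ships
    seeded synthetic-data generators (noisy isotherms, Brownian and
    ideal-gas trajectories, hydrogen-bond fixtures, pairwise-additive
    two-cluster systems) so every analysis can be validated against known
    ground truth.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
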