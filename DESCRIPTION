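Package: oxyslice
Title: Oxygen Reaction-Diffusion Modeling and CMRO2 Estimation for Brain
    Slice Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Steady-state oxygen reaction-diffusion solvers for planar
    (interface-chamber brain slice) and cylindrical (Krogh perivascular)
    geometry with Michaelis-Menten consumption; inverse estimation of the
    cerebral metabolic rate of oxygen (CMRO2) from partial tissue oxygen
    pressure depth profiles, including time-resolved quasi-steady fits
    during spreading depolarization (SD); Krogh-cylinder tissue
    oxygenation maps with hypoxia-boundary extraction; Nernst conversion
    of ion-sensitive electrode voltages and extraction of per-event SD
    features (DC shift, extracellular potassium transient, decay
    landmarks); a synthetic-data generator with ground truth for every
    stage; and paired nonparametric statistics (exact Wilcoxon
    signed-rank, Bonferroni adjustment, median/IQR summaries).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    yaml
Config/testthat/edition: 3
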