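Package: oscillomark
Title: Oscillatory Brain Activity as a Biomarker of Glioma Progression
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Links magnetoencephalography-derived broadband oscillatory
    power to neuroligin-3 (NLGN3) expression and progression-free survival
    in diffuse glioma. Computes peritumor, global and non-tumor activity
    scores from region-parcellated power, tumor-mask dilation and atlas
    overlap; compares activity across NLGN3 expression tiers with exact
    Mann-Whitney and tie-corrected Kruskal-Wallis tests implemented from
    first principles; fits Cox proportional-hazards models by direct
    maximisation of the partial likelihood (Breslow and Efron ties) with
    leave-one-out and permutation validation; and ships both a 24-patient
    diffuse-glioma cohort table and a synthetic-cohort generator (atlas
    volumes, tumor masks, 1/f-plus-alpha signals, Weibull
    proportional-hazards survival) so the whole pipeline is testable end
    to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    survival,
    RNifti,
    jsonlite,
    withr
Config/testthat/edition: 3
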