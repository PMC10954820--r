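Package: dtialps
Title: Simulation and Analysis of Diffusion MRI Along the Perivascular Space
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to study the diffusion-tensor-imaging analysis along the
    perivascular space (DTI-ALPS) index of glymphatic function. Provides a
    synthetic diffusion-MRI phantom generator with known ground-truth
    perivascular diffusivity structure, cohort simulation with glycemic
    group labels (normal glucose metabolism, prediabetes, type 2 diabetes)
    and clinical covariates, ordinary-least-squares diffusion tensor
    fitting, spherical-ROI diffusivity extraction and ALPS index
    computation, and the accompanying group-comparison and
    partial-correlation statistics (general linear models with
    family-wise-error correction, Cohen's d, variance inflation factors,
    Kruskal-Wallis and Fisher's exact tests).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    RNifti,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    car,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
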