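Package: pm25emu
Title: Gaussian Process Emulation of Sectoral Emission Impacts on PM2.5 Exposure
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Trains per-grid-cell Gaussian process emulators (Yeo-Johnson input
    transforms, standardized outputs, Matern 5/2 kernel) of a chemical-transport
    simulator's monthly-mean PM2.5 response to five sectoral emission-scaling
    factors (residential, industry, land transport, agriculture, power
    generation), quantifies sectoral sensitivities by Saltelli/Sobol variance
    decomposition, and sweeps emission scenarios to compute population-weighted
    exposure against WHO and Chinese air-quality targets. Includes a
    deterministic synthetic simulator with closed-form Sobol indices, maximin
    Latin hypercube experiment designs, k-fold cross-validation with R2, RMSE,
    NMBF and NMAEF metrics, and an end-to-end reproducible pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    lhs,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    car
Config/testthat/edition: 3
RoxygenNote: 7.3.3
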