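Package: tpcdev
Title: Thermal Performance Curves and Temperature-Dependent Development of
    Maize Stemborers
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Fits nonlinear thermal performance curves (TPCs) to insect
    development-rate data observed at constant temperatures, selects among
    eleven candidate models using AIC together with biological filters on
    the critical thermal limits, simulates individual-based egg-to-imago
    development times with inter-individual variation in development rates,
    derives thermal-window metrics (T50min, T50max) against a growing-season
    deadline, and quantifies the impact of projected climate warming on
    development through the r/rmax metric computed over monthly temperature
    ensembles from global circulation models. Ships the fitted stage-level
    parameter sets for four maize stemborer species (Ostrinia nubilalis,
    Sesamia nonagrioides, Chilo partellus, Busseola fusca) and synthetic
    data generators for development-rate observations and GCM-like
    temperature ensembles.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    minpack.lm,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
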