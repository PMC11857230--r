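Package: dllmeopt
Title: Design, Optimisation and Validation of DLLME GC-MS Methods
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools for optimising dispersive liquid-liquid microextraction
    (DLLME) methods from designed GC-MS experiments. Builds exact D-optimal
    designs over mixed categorical/quantitative factor spaces by Fedorov
    exchange, fits per-analyte response-surface regressions with iterative
    backward elimination of non-significant terms, predicts extraction
    efficiency over the full factor grid and ranks conditions under total-area
    and top-3-count criteria to select a consensus optimum. Also implements
    the method-validation mathematics (internal-standard calibration, LOD/LOQ,
    quantification, recovery, intra/inter-day precision, matrix effects) and a
    synthetic peak-area generator emulating the statistical structure of
    triplicate wine-aroma measurements, so the whole pipeline is testable
    without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
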