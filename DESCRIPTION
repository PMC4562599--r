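Package: ghkselect
Title: Ion-Selectivity Inference for Ligand-Gated Channels from Dilution-Potential Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates agonist-evoked whole-cell voltage-clamp macrocurrents of a
    ligand-gated ion channel under defined ionic solutions, extracts reversal
    potentials from current-voltage relationships, and estimates relative ion
    permeabilities (P_Cl/P_Na) by fitting the Goldman-Hodgkin-Katz voltage
    equation to dilution-potential data. Includes solution accounting (salt
    recipes, ionic strength, Davies activity coefficients), GHK constant-field
    flux and reversal-potential computations, single-exponential desensitization
    fitting, replicate quality control, and bootstrap uncertainty for fitted
    permeability ratios.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    minpack.lm
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
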