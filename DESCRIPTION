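Package: osmoAP
Title: Osmotic Hypernatremia Perturbation of Human Ventricular Action Potential Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates the acute effects of hypernatremia (elevated extracellular
    NaCl) on single human ventricular cardiomyocytes. Two endocardial ionic models
    of the O'Hara-Rudy lineage are implemented as compiled ODE systems and perturbed
    by an osmotic layer that scales ion currents, elevates the extracellular milieu,
    and shrinks the osmotically active cell volume. Cells are paced to quasi-steady
    state with threshold-calibrated stimuli, and action-potential and ionic
    biomarkers (resting potential, amplitude, APD50/APD90, maximum upstroke
    velocity, threshold current, equilibrium potentials, calcium transient peak)
    are extracted, including scenario studies that scale the L-type calcium current
    or ablate shrinkage or current scaling.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
NeedsCompilation: yes
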