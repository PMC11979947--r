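Package: krebsmca
Title: Kinetic Modelling and Metabolic Control Analysis of the Mitochondrial Krebs Cycle
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tissue-specific kinetic models of the mitochondrial Krebs
    (citric acid) cycle for AS-30D hepatoma (HepM), rat liver (RLM) and rat
    heart (RHM) mitochondria. Provides reversible Michaelis-Menten and
    Monod-Wyman-Changeux rate laws, steady-state solution of the resulting
    stiff ODE system with conserved cofactor moieties, least-squares
    calibration of free activities against measured metabolite
    concentrations and fluxes, Metabolic Control Analysis (flux and
    concentration control coefficients with summation diagnostics),
    in-silico inhibitor titrations of complex I and succinate
    dehydrogenase, synthetic observation generation for parameter-recovery
    studies, and SBML Level 3 export/import.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    optparse,
    stats,
    utils,
    xml2
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
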