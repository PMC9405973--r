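Package: itcthermo
Title: Thermodynamic Analysis of Isothermal Titration Calorimetry with
    Metal-Nucleotide Linked Equilibria
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for the thermodynamic dissection of protein-ligand
    binding measured by isothermal titration calorimetry (ITC), with
    emphasis on GTPase-guanine nucleotide systems where Mg(2+) binding to
    the nucleotide couples to protein recognition. Provides unit-safe
    identities linking binding constants, free energy, enthalpy and
    entropy; van't Hoff heat-capacity estimation from the temperature
    dependence of the binding enthalpy; closed-form and iterative
    equilibrium speciation solvers (single-site, Mg-nucleotide, and the
    ternary protein/nucleotide/Mg coupled-equilibria model); a forward
    model of per-injection heats for a perfusion calorimeter cell with
    one-site and ternary nonlinear fitting; heterotropic cooperativity
    cycles and thermodynamic-cycle closure checks; deconvolution of the
    binding heat capacity and entropy into rigid-body, solvation and
    conformational contributions with surface-area, residue and
    rotatable-bond equivalents; a synthetic-experiment generator with
    known ground truth; and auxiliary Michaelis-Menten and
    ligand-depletion fluorescence fits. All user-facing functions take
    and return tidy data frames.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
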