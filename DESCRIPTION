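Package: thzprotein
Title: Protein Dielectric Permittivity Extraction from Terahertz Spectra
    via Bruggeman Effective-Medium Inversion
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for determining the complex dielectric permittivity
    spectrum of dissolved protein molecules in the terahertz range, with
    the dielectric contribution of the aqueous phase removed.  Converts
    between terahertz optical constants (refractive index, absorption
    coefficient) and complex permittivity, computes protein and
    hydration-shell volume fractions from sample metadata, and inverts
    two- and three-phase Bruggeman effective-medium mixing equations that
    link the spectra of a pure solvent and of two protein solutions at
    different concentrations to the permittivity of the protein itself.
    Provides a numerically stable reduced solver, a full quadratic solver
    with branch bookkeeping, per-frequency validity diagnostics,
    perturbation sensitivity analysis, and a synthetic-spectrum generator
    (multi-Debye relaxation models of water and hydration shells) so the
    complete inverse problem can be exercised without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    yaml,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
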