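Package: etherCDL
Title: Identification, Quantification and Biosynthesis Modelling of
    Alkyl Ether Cardiolipins from UHPLC-HRMSn Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for the annotation of mono- to tetra-alkyl-ether
    cardiolipins and their parent phospholipids (PE, PG, lyso species)
    in positive-ion high-resolution LC-MS/MS data. Provides exact
    elemental-formula and monoisotopic-mass arithmetic with electron
    correction, enumeration of ether/ester glycerophospholipid species,
    rule-based prediction of diagnostic MS2 fragment ions and neutral
    losses, ppm-tolerance annotation of MS1 features and MS2 spectra,
    relative quantification with a 13C first-isotopologue policy, and a
    discrete-convolution model that predicts cardiolipin ether-class
    distributions from measured PE and PG core compositions under
    alternative condensation scenarios. A seedable simulator generates
    ground-truth lipidomes and MGF peak lists so the whole pipeline can
    be exercised and benchmarked without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
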