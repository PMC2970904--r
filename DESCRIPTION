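Package: torsionfit
Title: Side-Chain Torsion Potential Refitting and NMR Validation for
    Amber-Convention Force Fields
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Toolkit for re-parameterizing amino-acid side-chain torsion
    potentials against quantum-mechanical dihedral scans.  Builds chi1 and
    chi1/chi2 conformational scan grids, fits replacement cosine-series
    torsion terms to QM minus MM energy gaps by Boltzmann-weighted linear
    least squares, exports the result as Amber frcmod DIHE records, and
    validates conformational ensembles through three-state rotamer
    statistics, Karplus 3J scalar couplings and residual dipolar couplings
    predicted from a fitted molecular alignment tensor.  Ships the
    published ff99SB-ILDN chi1/chi2 corrections for Ile, Leu, Asp and Asn
    as a packaged parameter set, and a synthetic-data generator that
    produces scans, rotamer trajectories and RDC datasets with known
    ground truth.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    bio3d,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
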