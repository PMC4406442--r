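Package: epifp
Title: Interface Fingerprints and Proteochemometric Models for
    Antigen-Antibody Complexes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Detects epitope and paratope residues in antigen-antibody
    complex structures from solvent-accessible surface area loss on
    binding, builds an oriented interface coordinate frame, and computes
    residue-level descriptors: an 80-bit cylinder-model structure
    fingerprint, a 30-value shell-model physicochemical fingerprint
    driven by AAindex property scales, and a 150-bit epitope-paratope
    interaction fingerprint (EPIF). Descriptor combinations feed
    support vector regression under four kernels (normalized
    polynomial, polynomial, Pearson VII, radial basis) for
    proteochemometric modelling of binding affinity, with 10-fold
    cross-validation and the standard QSAR error statistics. Peer
    descriptors (pairwise sequence identity panels, a 41-feature
    backbone geometry summary) and a synthetic complex generator with
    planted interfaces are included so the full pipeline is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    Biostrings,
    kernlab,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    seqinr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
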