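Package: chemregistry
Title: Lightweight Chemical Registration with Layered Molecular Identity
    Hashes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A lightweight chemical registration system for computational
    chemistry workflows. Molecules are assigned stable integer identifiers
    (molregnos) using a configurable, layered structural hash built from a
    molecular formula layer, canonical SMILES with and without
    stereochemistry, tautomer-invariant skeleton hashes, canonicalized
    SGroup data, and a free-text escape layer; the layers are combined into
    a single SHA-1 digest for fast duplicate detection by string equality.
    Three-dimensional conformers are deduplicated with an atom-order
    invariant, orientation-sensitive SHA-256 coordinate hash. Registration
    is preceded by an ordered, configurable standardization and filtering
    pipeline whose applied steps are recorded per molecule. Structures,
    hash layers, conformers and configuration are persisted in an embedded
    SQLite database (any DBI backend can be substituted), alongside
    UUID-keyed companion tables for experiment metadata and results.
    Molecule handling is delegated to OpenBabel; SHA digests to the
    'digest' package.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    DBI,
    RSQLite,
    digest,
    jsonlite,
    uuid,
    ChemmineR
Suggests:
    testthat (>= 3.0.0),
    openssl,
    withr
SystemRequirements: OpenBabel (the 'obabel' executable on the PATH)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'hash-layers.R'
    'standardize.R'
    'store.R'
    'registry.R'
    'cli.R'
    'conformer-hash.R'
    'expdata.R'
    'fixtures.R'
    'molblock.R'
    'obabel.R'
    'smiles-graph.R'
    'zzz.R'
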