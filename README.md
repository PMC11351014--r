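# chemregistry

A lightweight chemical registration system for computational chemistry
workflows, written in R. It answers the question every registration system
exists for — *"have I seen this compound before?"* — while letting the
user decide what *"the same compound"* means: the same tautomer, the same
stereoisomer, the same salt form, or even the same 3D conformer.

Typical uses: tracking virtual compounds considered in a project, keeping
machine-learning training/validation sets reproducible, and avoiding
duplicated expensive computations (docking, MD, QM) by registering every
structure the pipeline touches together with its results.

## The identity model

A registered molecule is identified by a **layered structural hash** of
seven text layers:

| layer | content |
|---|---|
| `FORMULA` | molecular formula, Hill order |
| `CANONICAL_SMILES` | canonical SMILES incl. stereochemistry |
| `TAUTOMER_HASH` | tautomer-invariant skeleton serialization (stereo-aware) |
| `NO_STEREO_SMILES` | canonical SMILES, stereochemistry removed |
| `NO_STEREO_TAUTOMER_HASH` | tautomer-invariant serialization, stereo-free |
| `SGROUP_DATA` | canonical JSON of selected SGroup data fields |
| `ESCAPE` | free text supplied by the caller |

The layers are combined into a single SHA-1 digest by hashing the UTF-8
serialization `LAYERNAME:value`, joined with newlines in the fixed order
above; duplicate detection is then a string-equality lookup on an indexed
column — fast in any relational database. Queries may instead select any
subset of layers: matching on `TAUTOMER_HASH` alone finds all registered
tautomers of the probe, on `NO_STEREO_SMILES` all its stereoisomers.

The tautomer-invariant layers use a constitution-based *skeleton hash*:
every heteroatom-containing fragment is collapsed to its saturated
heavy-atom skeleton (bond orders, hydrogens and heteroatom charges
removed), canonicalized, and suffixed with the total hydrogen count and
net formal charge. True tautomers — structures differing only in proton
placement and bond orders — agree on it by construction.

3D conformers are deduplicated with a separate SHA-256 **coordinate
hash**: each atom position is formatted as `x,y,z` rounded to a
configurable number of decimals (default 3), the strings are sorted
lexicographically and joined with semicolons. The hash is invariant under
atom reordering but deliberately sensitive to translation and rotation,
so prealigned poses stay distinct; `canonicalizeOrientation()` provides
opt-in rigid-motion invariance via principal axes.

Before hashing, each molecule passes a configurable, ordered
**standardization pipeline** (sanitization/valence checks, largest
fragment, neutralization, charge parent, overlap and polymer-SGroup
filters, orientation canonicalization — plus user-registered steps); the
steps applied to each molecule are stored with it, and the pipeline
itself is stored as configuration inside the database.

Everything is persisted in an embedded SQLite database (through DBI, so
other DBI backends can stand behind the same interface), together with
UUID-keyed companion tables for experiment metadata and results.

Molecule parsing, canonicalization and format conversion are delegated to
OpenBabel (the `obabel` executable must be on the PATH).

## Worked example

```r
library(chemregistry)

reg <- initRegistry(tempfile(fileext = ".sqlite"))

registerCompound(reg, "CCO")
#> RegistrationResult: registered molregno = 1
registerCompound(reg, "OCC")          # same molecule, different SMILES
#> RegistrationResult: duplicate molregno = 1 (already registered as molregno 1)

# the 2-pyridone / 2-hydroxypyridine tautomer pair
bulkRegister(reg, c("O=c1cccc[nH]1", "Oc1ccccn1"))
#> registered molregno = 2, registered molregno = 3

queryCompound(reg, "Oc1ccccn1")                            # exact identity
#> [1] 3
queryCompound(reg, "Oc1ccccn1", layers = "TAUTOMER_HASH")  # all tautomers
#> [1] 2 3

retrieveCompound(reg, 2, mode = "hashes")[["2"]]$layers
#> MolHashLayers
#>   FORMULA                  C5H5NO
#>   CANONICAL_SMILES         O=c1cccc[nH]1
#>   TAUTOMER_HASH            [O][C]1[C][C][C][C][N]1_5_0
#>   NO_STEREO_SMILES         O=c1cccc[nH]1
#>   NO_STEREO_TAUTOMER_HASH  [O][C]1[C][C][C][C][N]1_5_0
#>   SGROUP_DATA              {}
#>   ESCAPE
closeRegistry(reg)
```

The two tautomers hold distinct molregnos (their canonical SMILES
differ), yet a single-layer query on `TAUTOMER_HASH` unites them: both
share the skeleton serialization `[O][C]1[C][C][C][C][N]1_5_0` — the
saturated ring skeleton plus 5 hydrogens and zero net charge.

A command-line front end for scripting pipelines is installed at
`system.file("cli", "chemregistry", package = "chemregistry")` with
`init`, `register`, `bulk-register`, `query`, `retrieve` and `config`
subcommands (exit codes: 0 success, 1 duplicate/not found, 2
parse/filter/usage error).

## Scope

No substructure or similarity search (pair the tables with a chemical
database cartridge if needed), no InChI layers, no GUI, and no
update/delete of registered structures — the registry is append-only by
design.
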