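---
title: "Layered molecular identity hashing and registration: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Layered molecular identity hashing and registration: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chemregistry)
```

## The registration problem

Whether two structures are "the same compound" depends on context. A
medicinal chemist usually wants salt forms and tautomers merged; a
simulation scientist tracking the exact input to an MD run wants them
kept apart, and may even need two *conformers* of one molecule to carry
distinct identities. chemregistry therefore never standardizes identity
away silently. It stores, per molecule, seven orthogonal **identity
layers** and lets every query decide which layers constitute "the same":

```{r}
hashLayerNames()
```

At registration time the seven layers are combined into one SHA-1 digest
over the UTF-8 byte serialization obtained by joining `LAYERNAME:value`
items with single newlines, in the fixed order above. This serialization
is this package's own convention — digests are deliberately *not*
interchangeable with any other registration system — but it is frozen:
changing it would re-identify every molecule in a database. Duplicate
detection is then one indexed string comparison, so lookup cost is
independent of molecular size and of corpus chemistry.

## The tautomer-invariant layers

The two tautomer layers need a serialization that is *identical for
tautomers* and *stable across input forms*. OpenBabel, which this package
uses for parsing and canonicalization, offers no tautomer-invariant hash,
so the package defines one, chosen for being exactly invariant rather
than approximately clever:

1. Split the canonical SMILES into fragments. Fragments without
   N, O, S, P, Se or Te cannot tautomerize and pass through unchanged
   (retaining bond orders and, in the stereo-aware layer, stereo
   annotations — so (*E*)- and (*Z*)-2-butene remain distinct here).
2. Collapse every heteroatom-containing fragment to its **saturated
   heavy-atom skeleton**: each atom becomes a bracket atom stripped of
   hydrogens and charges, and all bond-order/aromaticity information is
   dropped. Atoms carrying a tetrahedral tag keep the tag and their
   hydrogen count in the stereo-aware variant, so chirality survives
   where it is structurally meaningful.
3. Canonicalize the skeleton and append `_<total H count>_<net formal
   charge>`.

Tautomers differ only in proton placement and bond orders, never in
heavy-atom connectivity, hydrogen total or net charge — so they can never
disagree on this serialization. The trade-off is coarseness: structures
related by hydrogen shifts that chemists would *not* call tautomers
(e.g. some allylic alcohol/carbonyl isomer pairs) also merge under this
layer. For a registration system this errs on the safe side — the layer
is used to *find candidates*, while full-layer identity still separates
them — and the behavior is documented rather than hidden.

Two versions are supported and recorded in the database configuration:
`v2` (default) includes the net-charge component; `v1` omits it, merging
an acid with its conjugate base at this layer. Databases are
self-describing: the version tag travels with the stored configuration.

## Stereochemistry, SGroup data, escape

`CANONICAL_SMILES` / `NO_STEREO_SMILES` are OpenBabel canonical isomeric
SMILES with and without stereo annotations (the stereo-free writer also
drops isotope labels). OpenBabel does not implement CXSMILES extensions,
so enhanced (AND/OR group) stereochemistry annotations are not captured —
a known backend limitation; molecules differing only in enhanced-stereo
grouping will collide.

`SGROUP_DATA` canonicalizes DAT-type SGroup records from mol block input:
records are restricted to the configured fields (default `FIELDNAME` and
`DATA`), keys are serialized in sorted order, records sorted by their
serialized content, producing order-independent compact JSON; molecules
without SGroup data always carry `"{}"` so the layer is comparable. Which
non-DAT record types should contribute data is genuinely open; this
package includes none of them, but polymer-type records (SRU/MON/COP/...)
drive the polymer rejection filter instead.

`ESCAPE` is caller-supplied free text stored verbatim. It partitions
otherwise identical structures (e.g. by batch or provenance) and
participates in queries only when selected.

## Conformer hashing

A conformer hash must be independent of atom order (the same geometry
drawn twice rarely lists atoms identically) but must *not* be invariant
to rigid motion, or docking poses and aligned ensembles would collapse.
The four-step scheme: round each coordinate to `digits` decimals
(default 3, i.e. milli-angstrom resolution — below typical force-field
reproducibility but enough to distinguish genuinely different geometries);
format each atom as `"x,y,z"`; sort the strings lexicographically (plain
byte order — this is what removes atom-order dependence); join with
semicolons and take SHA-256.

Formatting rules matter for byte stability and are fixed: fixed-point
with exactly `digits` decimals, round-half-even, values rounding to zero
normalized to `+0` (so `-0.000` never appears), no exponent notation, no
locale dependence. All atoms present in the input participate; callers
wanting heavy-atom-only hashes strip hydrogens before registering.

`canonicalizeOrientation()` gives opt-in rigid-motion invariance:
centroid to origin, rotation onto principal axes ordered by descending
eigenvalue, the sign of each of the first two axes chosen so the
largest-magnitude coordinate along it is positive, and the third axis
their cross product (right-handed). Any deterministic convention
satisfies the contract; this one was chosen because it is cheap and
stable for asymmetric conformers. It is *not* deterministic for
symmetric tops (degenerate principal moments) or when the sign rule has
a near-tie — the fixture generator for orientation tests rejection-samples
exactly those cases away, and real users with symmetric molecules should
prealign conformers themselves.

Stored coordinates are never rounded: persistence uses 17 significant
digits, which round-trips IEEE doubles exactly. Only the hash is rounded.

## Standardization pipeline

Steps are named, ordered, and of two kinds: *standardizers* may modify
(sanitize, remove_fragments, neutralize, charge_parent,
canonicalize_orientation), *filters* gate without modifying
(filter_overlapping_atoms, filter_polymer_sgroup). A pipeline stops at
the first failure; the steps actually attempted are recorded with each
registered molecule, and the configured pipeline is stored inside the
database so a registry documents its own policy. User steps register
under new names and are addressable from stored configurations.

Numerical and chemical choices:

* **sanitize** re-canonicalizes and enforces maximum valences on C, N, O
  and F (OpenBabel itself accepts a pentavalent carbon without
  complaint). Under-valent atoms (radicals) pass; elements with genuinely
  variable valence are not second-guessed.
* **neutralize** (de)protonates only simple sites: negatively charged
  O/S/N gain a proton, positively charged N/O/S with at least one
  hydrogen lose one. A site adjacent to an opposite formal charge is a
  charge-separated resonance form (nitro, N-oxide) and is left intact;
  so are charges that cannot be fixed by (de)protonation (quaternary N).
  Zwitterions whose two charges are independently fixable (glycine) are
  fully neutralized.
* **largest fragment** ranks by heavy-atom count, then total atom count,
  then lexicographically smallest canonical SMILES — fully
  deterministic. `charge_parent` restricts the competition to
  carbon-containing fragments first, falling back to all fragments for
  purely inorganic input.
* **filter_overlapping_atoms** uses a strict `< minDist` test with
  `minDist = 1e-4` angstrom by default: it flags genuinely coincident
  atoms from broken drawings without rejecting merely congested
  depictions. Structures without coordinates pass (there is nothing to
  check).

The default pipeline is `sanitize` alone — the least destructive policy,
appropriate when registered tautomers/salt forms must be preserved;
stricter policies are opt-in per database.

## Storage

The embedded backend is SQLite via DBI; all SQL is portable DBI-style,
so a client/server DBI backend can stand behind the same contract. Every
layer is stored in its own indexed column (string equality is the only
search primitive), along with the combined digest (unique index), the
V3000 standardized structure, the byte-identical raw submission, and the
applied-step record. molregnos are a monotone integer sequence from 1;
conf_ids count per molregno from 1; conformer uniqueness is enforced per
(molregno, conf_hash) — two different molecules may in principle share
coordinates — while hash search remains global. The registry is
append-only: no update or delete of registered structures.

Experiment storage follows a one-table-pair-per-type schema:
`<type>_metadata` (UUID primary key) and `<type>_data` (UUID + molregno
+ nullable conf_id). Column kinds `number`/`text` map to plain SQL
columns (compact, fast to filter); `json` columns hold arbitrary
payloads. The same logical experiment can be stored through a json-only
minimal shape or a fully columned shape and queried identically.
Experiment UUIDs are random (version 4). Result batches are validated
before a transactional insert, so referential errors write nothing.

## What the synthetic fixtures do and do not show

The generator produces: acyclic single-bonded C/N/O/S trees in two
equivalent serializations (exercising canonicalization invariance and
duplicate detection at scale — 500 molecules twice in the acceptance
suite); uniform random point-cloud conformers, optionally grid-snapped
so sub-rounding perturbation tests cannot sit on a rounding boundary
(100 conformers per property); curated
tautomer / stereoisomer / salt pairs anchoring the layer semantics; and
hand-built pathological mol blocks (coincident atoms, SRU polymer, DAT
SGroups in permuted order, a pentavalent carbon, a Kekulé benzene, a 3D
ethanol). These sizes keep the full suite under a couple of minutes on a
single CPU while leaving the statistics trivially saturated (every rate
is expected at exactly 100%).

What passing them does *not* show: behavior on ring-rich drug-like
chemistry beyond the curated pairs, on macromolecules, on organometallics
(valence checking deliberately ignores metals), on enhanced
stereochemistry (unsupported), or tautomer-layer precision on chemistry
where the constitution-based hash over-merges. Conformer fixtures are
random point clouds, not minimum-energy geometries; this is irrelevant to
the hash contract but means nothing is claimed about chemically realistic
conformer distributions.

## Known limitations

* Enhanced stereochemistry (CXSMILES stereo groups) is not represented.
* The tautomer layers are coarser than toolkit tautomer hashes built on
  explicit transform rules; see above.
* Canonicalization quality is bounded by OpenBabel's canonical SMILES.
* `canonicalizeOrientation()` is unstable for symmetric tops, by
  construction of any principal-axes method.
* Only the embedded SQLite backend ships; other DBI backends are
  supported by construction but not exercised by the test suite.
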