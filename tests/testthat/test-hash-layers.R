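# Layered molecular identity hash: layer contents, canonicalization
# invariance, subset matching, digest combination.

test_that("formula layer reports Hill-order formulas", {
  expect_identical(layerValues(computeLayers("CCO"))[["FORMULA"]], "C2H6O")
  expect_identical(layerValues(computeLayers("OCC"))[["FORMULA"]], "C2H6O")
  expect_identical(layerValues(computeLayers("c1ccccc1"))[["FORMULA"]], "C6H6")
})

test_that("equivalent serializations give byte-identical layers and digest", {
  a <- computeLayers("CCO")
  b <- computeLayers("OCC")
  expect_identical(layerValues(a), layerValues(b))
  expect_identical(combineLayers(a), combineLayers(b))
})

test_that("stereoisomer pairs split on stereo layers and agree without", {
  for (pair in stereoPairs()) {
    a <- computeLayers(pair[[1]])
    b <- computeLayers(pair[[2]])
    expect_false(identical(a@canonicalSmiles, b@canonicalSmiles),
                 info = paste(pair, collapse = " / "))
    expect_identical(a@noStereoSmiles, b@noStereoSmiles)
    expect_identical(a@noStereoTautomerHash, b@noStereoTautomerHash)
    expect_identical(a@formula, b@formula)
  }
})

test_that("tautomer pairs agree on the tautomer-invariant layers only", {
  for (pair in tautomerPairs()) {
    a <- computeLayers(pair[[1]])
    b <- computeLayers(pair[[2]])
    expect_false(identical(a@canonicalSmiles, b@canonicalSmiles),
                 info = paste(pair, collapse = " / "))
    expect_identical(a@tautomerHash, b@tautomerHash)
    expect_identical(a@noStereoTautomerHash, b@noStereoTautomerHash)
    expect_false(identical(combineLayers(a), combineLayers(b)))
  }
})

test_that("tautomer hash keeps tetrahedral stereo; v1 drops the charge term", {
  ala <- stereoPairs()$alanine
  a <- computeLayers(ala[[1]])
  b <- computeLayers(ala[[2]])
  expect_false(identical(a@tautomerHash, b@tautomerHash))
  v1 <- computeLayers("CC(=O)[O-]", options = hashOptions(tautomerHashVersion = "v1"))
  v2 <- computeLayers("CC(=O)[O-]")
  expect_false(identical(v1@tautomerHash, v2@tautomerHash))
  # v2 separates an anion from its neutral acid; v1's hash ignores charge
  acid <- computeLayers("CC(=O)O")
  expect_false(identical(v2@tautomerHash, acid@tautomerHash))
})

test_that("random fixture molecules hash deterministically across serializations", {
  mols <- randomMolecules(40, seed = 7)
  la <- lapply(mols$smiles, computeLayers)
  lb <- lapply(mols$alt, computeLayers)
  for (k in seq_len(nrow(mols))) {
    expect_identical(layerValues(la[[k]]), layerValues(lb[[k]]),
                     info = mols$label[[k]])
    expect_identical(combineLayers(la[[k]]), combineLayers(lb[[k]]))
  }
})

test_that("escape text is carried verbatim and discriminates digests", {
  plain <- computeLayers("CCO")
  tagged <- computeLayers("CCO", escape = "batch-A")
  expect_identical(tagged@escape, "batch-A")
  expect_identical(plain@escape, "")
  expect_identical(tagged@canonicalSmiles, plain@canonicalSmiles)
  expect_false(identical(combineLayers(plain), combineLayers(tagged)))
})

test_that("combined digest matches an independently computed SHA-1", {
  # all seven layers set to their own names; expected value computed with
  # an independent SHA-1 implementation on the documented serialization
  layers <- MolHashLayers(formula = "FORMULA",
                          canonicalSmiles = "CANONICAL_SMILES",
                          tautomerHash = "TAUTOMER_HASH",
                          noStereoSmiles = "NO_STEREO_SMILES",
                          noStereoTautomerHash = "NO_STEREO_TAUTOMER_HASH",
                          sgroupData = "SGROUP_DATA", escape = "ESCAPE")
  expect_identical(combineLayers(layers),
                   "c6e3d1dd0dd3452629acd34f934c260eb7cbef30")
  expect_match(combineLayers(computeLayers("CCO")), "^[0-9a-f]{40}$")
})

test_that("layer-subset matching honors the selection and flags bad names", {
  ez <- stereoPairs()$butene
  a <- computeLayers(ez[[1]])
  b <- computeLayers(ez[[2]])
  expect_true(matchLayers(a, b, "NO_STEREO_SMILES"))
  expect_false(matchLayers(a, b))                       # all seven
  expect_true(matchLayers(a, a, c("FORMULA", "ESCAPE")))
  expect_true(matchLayers(b, b))
  expect_error(matchLayers(a, b, "NOT_A_LAYER"), "unknown layer")
  expect_error(matchLayers(a, b, character(0)), "non-empty")
})

test_that("SGroup data canonicalizes to order-independent JSON", {
  blocks <- pathologicalMolblocks()
  expect_identical(canonicalizeSgroupData("CCO-not-a-molblock"), "{}")
  expect_identical(canonicalizeSgroupData(blocks$kekule_benzene), "{}")
  single <- canonicalizeSgroupData(blocks$dat_sgroup)
  expect_identical(single, '[{"DATA":"7.4","FIELDNAME":"pH"}]')
  expect_identical(canonicalizeSgroupData(blocks$dat_sgroup_pair),
                   canonicalizeSgroupData(blocks$dat_sgroup_pair_reordered))
  onlyName <- canonicalizeSgroupData(blocks$dat_sgroup, fields = "FIELDNAME")
  expect_identical(onlyName, '[{"FIELDNAME":"pH"}]')
})

test_that("SGroup layer separates molecules that differ only in data", {
  blocks <- pathologicalMolblocks()
  withData <- computeLayers(parseMolecule(blocks$dat_sgroup))
  plain <- computeLayers("CCO")
  expect_identical(withData@canonicalSmiles, plain@canonicalSmiles)
  expect_false(identical(combineLayers(withData), combineLayers(plain)))
})

test_that("unparsable structures raise parse errors", {
  expect_error(computeLayers("not-a-smiles((("), "parse")
  expect_error(parseMolecule("C1CC"), "parse")   # unclosed ring
})
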