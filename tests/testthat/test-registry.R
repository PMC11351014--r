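# The register / query / retrieve facade.

test_that("register assigns molregnos and recognizes equivalent input", {
  reg <- localRegistry()
  r1 <- registerCompound(reg, "CCO")
  expect_identical(resultStatus(r1), "registered")
  expect_identical(molregno(r1), 1L)
  r2 <- registerCompound(reg, "OCC")
  expect_identical(resultStatus(r2), "duplicate")
  expect_identical(molregno(r2), 1L)
  expect_identical(moleculeCount(reg), 1L)
})

test_that("registering the same input repeatedly stays idempotent", {
  reg <- localRegistry()
  results <- lapply(1:5, function(i) registerCompound(reg, "c1ccncc1"))
  expect_identical(vapply(results, molregno, integer(1)), rep(1L, 5))
  expect_identical(vapply(results, resultStatus, character(1)),
                   c("registered", rep("duplicate", 4)))
  expect_identical(moleculeCount(reg), 1L)
})

test_that("query right after register returns exactly that identifier", {
  reg <- localRegistry()
  inputs <- c("CCO", "c1ccccc1", unlist(stereoPairs()),
              pathologicalMolblocks()$dat_sgroup)
  for (inp in inputs) {
    res <- registerCompound(reg, inp)
    expect_identical(queryCompound(reg, inp), molregno(res), info = inp)
  }
})

test_that("layer-subset queries unite tautomers and stereoisomers", {
  reg <- localRegistry()
  for (pair in tautomerPairs()) {
    bulkRegister(reg, pair)
    hitsFull <- queryCompound(reg, pair[[1]])
    hitsTaut <- queryCompound(reg, pair[[1]], layers = "TAUTOMER_HASH")
    expect_length(hitsFull, 1L)
    expect_length(hitsTaut, 2L)
    expect_true(all(hitsFull %in% hitsTaut))
  }
})

test_that("shrinking the selected layer set never shrinks the result set", {
  reg <- localRegistry()
  bulkRegister(reg, c(unlist(stereoPairs()), unlist(tautomerPairs())))
  probes <- c(stereoPairs()$butene[[1]], tautomerPairs()$pyridone[[1]])
  nested <- list(
    hashLayerNames(),
    c("FORMULA", "NO_STEREO_SMILES", "NO_STEREO_TAUTOMER_HASH"),
    c("FORMULA", "NO_STEREO_TAUTOMER_HASH"),
    "FORMULA")
  for (probe in probes) {
    previous <- NULL
    for (layers in nested) {
      hits <- queryCompound(reg, probe, layers = layers)
      if (!is.null(previous)) expect_true(all(previous %in% hits))
      previous <- hits
    }
  }
})

test_that("escape texts partition identical structures", {
  reg <- localRegistry()
  r0 <- registerCompound(reg, "CCO")
  rA <- registerCompound(reg, "CCO", escape = "batch-A")
  rB <- registerCompound(reg, "CCO", escape = "batch-B")
  expect_identical(vapply(list(r0, rA, rB), resultStatus, character(1)),
                   rep("registered", 3))
  expect_identical(sort(c(molregno(r0), molregno(rA), molregno(rB))), 1:3)
  expect_identical(queryCompound(reg, "CCO", escape = "batch-A"),
                   molregno(rA))
  expect_identical(queryCompound(reg, "CCO"), molregno(r0))
  # the escape layer only participates when selected
  noEscape <- setdiff(hashLayerNames(), "ESCAPE")
  expect_identical(queryCompound(reg, "CCO", layers = noEscape), 1:3)
})

test_that("bulk registration is ordered, per-item durable, failure-tolerant", {
  reg <- localRegistry()
  res <- bulkRegister(reg, c("CCO", "OCC", "CCN"))
  expect_identical(vapply(res, resultStatus, character(1)),
                   c("registered", "duplicate", "registered"))
  expect_identical(vapply(res, molregno, integer(1)), c(1L, 1L, 2L))

  res2 <- bulkRegister(reg, c("CCCC", "not-a-structure(((", "CCCCC"))
  expect_identical(vapply(res2, resultStatus, character(1)),
                   c("registered", "parse_error", "registered"))
  expect_identical(molregno(res2[[3]]), 4L)
  expect_identical(moleculeCount(reg), 4L)
})

test_that("bulk registration of distinct fixtures matches the hash oracle", {
  reg <- localRegistry()
  mols <- randomMolecules(100, seed = 31)
  res <- bulkRegister(reg, mols$smiles)
  expect_identical(vapply(res, resultStatus, character(1)),
                   rep("registered", 100))
  expect_identical(vapply(res, molregno, integer(1)), 1:100)
  # independent uniqueness oracle: distinct combined digests
  digests <- vapply(mols$smiles, function(s) combineLayers(computeLayers(s)),
                    character(1))
  expect_identical(moleculeCount(reg), length(unique(digests)))
})

test_that("queries rejected by a filter warn and return empty", {
  reg <- localRegistry(registryConfig(
    standardization = c("sanitize", "filter_overlapping_atoms")))
  registerCompound(reg, "CCO")
  expect_warning(
    hits <- queryCompound(reg, pathologicalMolblocks()$overlapping_atoms),
    "rejected")
  expect_identical(hits, integer(0))
  expect_error(queryCompound(reg, "((bad"), class = "chemregistryParseError")
  expect_identical(queryCompound(reg, "c1ccsc1"), integer(0))
})

test_that("filter rejections at registration name the step", {
  reg <- localRegistry(registryConfig(
    standardization = c("sanitize", "filter_polymer_sgroup")))
  res <- registerCompound(reg, pathologicalMolblocks()$polymer_sru)
  expect_identical(resultStatus(res), "rejected")
  expect_match(res@detail, "filter_polymer_sgroup")
  expect_identical(moleculeCount(reg), 0L)
})

test_that("conformer registration returns (molregno, confId) tuples", {
  reg <- localRegistry(registryConfig(registerConformers = TRUE))
  mb <- pathologicalMolblocks()$ethanol_3d
  r1 <- registerCompound(reg, mb)
  expect_identical(resultStatus(r1), "registered")
  expect_identical(c(molregno(r1), confId(r1)), c(1L, 1L))
  r2 <- registerCompound(reg, mb)
  expect_identical(resultStatus(r2), "duplicate")
  expect_identical(c(molregno(r2), confId(r2)), c(1L, 1L))
  # molecule-only input still registers in conformer mode
  r3 <- registerCompound(reg, "c1ccccc1")
  expect_identical(resultStatus(r3), "registered")
  expect_true(is.na(confId(r3)))
  # a registered conformer re-queried from its mol block
  hit <- queryCompound(reg, mb)
  expect_identical(hit$molregno, 1L)
  expect_identical(hit$conf_id, 1L)
})

test_that("queryConformers maps every requested molregno", {
  reg <- localRegistry(registryConfig(registerConformers = TRUE))
  mb <- pathologicalMolblocks()$ethanol_3d
  registerCompound(reg, mb)
  # second conformer: shifted copy
  mol <- parseMolecule(mb)
  mol@coords <- chemregistry:::.moleculeCoords(mol) + 2
  insertConformer(reg, 1L, mol@coords)
  registerCompound(reg, "c1ccccc1")
  out <- queryConformers(reg, c(2L, 1L))
  expect_identical(names(out), c("2", "1"))
  expect_identical(out[["1"]], c(1L, 2L))
  expect_identical(out[["2"]], integer(0))
  expect_error(queryConformers(reg, 9L),
               class = "chemregistryNotRegistered")
  regPlain <- localRegistry()
  expect_error(queryConformers(regPlain, 1L), "registerConformers")
})

test_that("retrieve returns standardized blocks, raw bytes and hashes", {
  reg <- localRegistry()
  mb <- pathologicalMolblocks()$dat_sgroup
  registerCompound(reg, mb)
  registerCompound(reg, "CCN")

  raw <- retrieveCompound(reg, 1, mode = "as_registered")[["1"]]
  expect_identical(raw$text, mb)            # byte-identical round trip
  expect_identical(raw$format, "molblock")

  std <- retrieveCompound(reg, 1:2, mode = "standardized")
  expect_match(std[["1"]], "V3000")
  reparsed <- parseMolecule(std[["2"]])
  expect_identical(reparsed@smiles,
                   layerValues(getLayers(reg, 2L))[["CANONICAL_SMILES"]])

  hashes <- retrieveCompound(reg, 2, mode = "hashes")[["2"]]
  expect_identical(layerValues(hashes$layers)[["FORMULA"]], "C2H7N")
  expect_match(hashes$fullHash, "^[0-9a-f]{40}$")

  expect_error(retrieveCompound(reg, 99, mode = "standardized"),
               class = "chemregistryNotRegistered")
})

test_that("conformer retrieval embeds full-precision coordinates", {
  reg <- localRegistry(registryConfig(registerConformers = TRUE))
  mb <- pathologicalMolblocks()$ethanol_3d
  registerCompound(reg, mb)
  out <- retrieveCompound(reg, list(c(1, 1)), mode = "standardized")[["1:1"]]
  expect_match(out, "V3000")
  got <- chemregistry:::.molblockAtoms(out)
  want <- chemregistry:::.molblockAtoms(mb)
  expect_identical(got$coords, want$coords)
  expect_identical(got$elements, want$elements)
})

test_that("SD files split into registrable records", {
  dir <- withr::local_tempdir()
  writeFixtureFiles(dir)
  records <- readSdf(file.path(dir, "pathological.sdf"))
  expect_length(records, length(pathologicalMolblocks()))
  reg <- localRegistry()
  res <- bulkRegister(reg, records)
  expect_identical(resultStatus(res[[which(names(pathologicalMolblocks())
                                           == "kekule_benzene")]]),
                   "registered")
})
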