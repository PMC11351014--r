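# Experiment metadata/data companion tables.

setupAssayRegistry <- function(env = parent.frame()) {
  reg <- localRegistry(env = env)
  bulkRegister(reg, c("CCO", "CCN", "c1ccccc1"))
  reg
}

test_that("experiment types create typed table pairs exactly once", {
  reg <- setupAssayRegistry()
  defineExperimentType(reg, "generic",
                       metadataColumns = c(details = "json"),
                       dataColumns = c(payload = "json"))
  defineExperimentType(reg, "solubility",
                       metadataColumns = c(protocol = "text",
                                           temperature = "number"),
                       dataColumns = c(logS = "number", comment = "text"))
  expect_setequal(
    DBI::dbListTables(reg@con)[grepl("^(generic|solubility)",
                                     DBI::dbListTables(reg@con))],
    c("generic_metadata", "generic_data",
      "solubility_metadata", "solubility_data"))
  expect_error(defineExperimentType(reg, "generic",
                                    dataColumns = c(x = "number")),
               "already exists")
  expect_error(defineExperimentType(reg, "empty", dataColumns = c()),
               "at least one data column")
  expect_error(defineExperimentType(reg, "bad name!",
                                    dataColumns = c(x = "number")),
               "not a valid")
})

test_that("experiment types can be declared as JSON documents", {
  reg <- setupAssayRegistry()
  defineExperimentType(reg,
    '{"name":"docking","metadata":{"engine":"text"},"data":{"score":"number"}}')
  types <- experimentTypes(reg)
  expect_identical(types$docking$data$score, "number")
})

test_that("metadata rows get unique UUIDs and validate their columns", {
  reg <- setupAssayRegistry()
  defineExperimentType(reg, "assay",
                       metadataColumns = c(protocol = "json"),
                       dataColumns = c(value = "number"))
  id1 <- recordExperiment(reg, "assay", list(protocol = list(ph = 7.4)))
  id2 <- recordExperiment(reg, "assay", list(protocol = list(ph = 7.4)))
  expect_match(id1, "^[0-9a-f-]{36}$")
  expect_false(identical(id1, id2))
  expect_error(recordExperiment(reg, "assay", list()), "missing metadata")
  expect_error(recordExperiment(reg, "assay",
                                list(protocol = 1, extra = 2)),
               "undeclared")
  expect_error(recordExperiment(reg, "undefined_type", list()),
               "not defined")
})

test_that("results enforce referential integrity without partial writes", {
  reg <- setupAssayRegistry()
  defineExperimentType(reg, "assay", dataColumns = c(value = "number"))
  id <- recordExperiment(reg, "assay")
  expect_identical(
    recordResults(reg, id, list(
      list(molregno = 1, value = 1.5),
      list(molregno = 2, value = -0.25),
      list(molregno = 3, value = 0))), 3L)
  expect_error(
    recordResults(reg, id, list(list(molregno = 1, value = 1),
                                list(molregno = 99, value = 2))),
    "not registered")
  expect_error(recordResults(reg, "no-such-uuid",
                             list(list(molregno = 1, value = 1))),
               "unknown experiment")
  # the failed batch wrote nothing
  expect_identical(nrow(fetchResults(reg, "assay")), 3L)
})

test_that("conformer-linked rows validate the (molregno, conf_id) pair", {
  reg <- localRegistry(registryConfig(registerConformers = TRUE))
  registerCompound(reg, pathologicalMolblocks()$ethanol_3d)
  defineExperimentType(reg, "pose", dataColumns = c(score = "number"))
  id <- recordExperiment(reg, "pose")
  expect_identical(
    recordResults(reg, id, list(list(molregno = 1, conf_id = 1,
                                     score = -7.2))), 1L)
  expect_error(
    recordResults(reg, id, list(list(molregno = 1, conf_id = 5,
                                     score = 0))),
    "no conformer")
  df <- fetchResults(reg, "pose")
  expect_identical(df$conf_id, 1L)
})

test_that("fetch joins metadata and structures; filters match a linear scan", {
  reg <- setupAssayRegistry()
  defineExperimentType(reg, "assay",
                       metadataColumns = c(operator = "text"),
                       dataColumns = c(value = "number"))
  id <- recordExperiment(reg, "assay", list(operator = "rig-1"))
  values <- c(-1.5, 0.25, 3.75)
  recordResults(reg, id, lapply(1:3, function(k)
    list(molregno = k, value = values[[k]])))

  df <- fetchResults(reg, "assay")
  expect_identical(nrow(df), 3L)
  expect_identical(df$meta_operator, rep("rig-1", 3))
  expect_identical(df$canonical_smiles[df$molregno == 1],
                   canon("CCO"))
  expect_identical(df$value, values)   # numeric columns round-trip exactly

  cutoff <- 0.25
  filtered <- fetchResults(reg, "assay", filter = function(d)
    d$value >= cutoff)
  oracle <- df[df$value >= cutoff, , drop = FALSE]
  rownames(oracle) <- NULL
  expect_identical(filtered, oracle)

  expect_identical(nrow(fetchResults(reg, "assay", filter = function(d)
    d$value > 100)), 0L)
})

test_that("json-only and fully-columned schemas store the same experiment", {
  reg <- setupAssayRegistry()
  # minimal shape: everything in json columns
  defineExperimentType(reg, "ml_json",
                       metadataColumns = c(details = "json"),
                       dataColumns = c(payload = "json"))
  # fully modeled shape: explicit columns, no json
  defineExperimentType(reg, "ml_cols",
                       metadataColumns = c(model = "text", seed = "number"),
                       dataColumns = c(auc = "number", split = "text"))
  meta <- list(model = "rf", seed = 42)
  rows <- list(list(molregno = 1, auc = 0.91, split = "test"),
               list(molregno = 2, auc = 0.87, split = "test"))

  idJ <- recordExperiment(reg, "ml_json", list(details = meta))
  recordResults(reg, idJ, lapply(rows, function(r)
    list(molregno = r$molregno,
         payload = list(auc = r$auc, split = r$split))))
  idC <- recordExperiment(reg, "ml_cols", meta)
  recordResults(reg, idC, rows)

  dfJ <- fetchResults(reg, "ml_json")
  dfC <- fetchResults(reg, "ml_cols")
  # same logical content modulo column packaging
  unpackedJ <- lapply(dfJ$payload, jsonlite::fromJSON)
  expect_identical(vapply(unpackedJ, `[[`, numeric(1), "auc"), dfC$auc)
  expect_identical(vapply(unpackedJ, `[[`, character(1), "split"),
                   dfC$split)
  expect_identical(dfJ$molregno, dfC$molregno)
  expect_identical(dfJ$canonical_smiles, dfC$canonical_smiles)
  metaJ <- jsonlite::fromJSON(dfJ$meta_details[[1]])
  expect_identical(metaJ$model, dfC$meta_model[[1]])
  expect_equal(metaJ$seed, dfC$meta_seed[[1]], ignore_attr = TRUE)

  # json payloads round-trip structurally
  expect_identical(unpackedJ[[1]], list(auc = 0.91, split = "test"))
})
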