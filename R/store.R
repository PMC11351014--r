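#' @include AllClasses.R hash-layers.R standardize.R
NULL

# error conditions used by the store layer ----------------------------------

.duplicateError <- function(message, molregno, confId = NA_integer_) {
  stop(structure(
    class = c("chemregistryDuplicate", "error", "condition"),
    list(message = message, call = sys.call(-1L),
         molregno = as.integer(molregno), confId = as.integer(confId))))
}

.notRegisteredError <- function(message) {
  stop(structure(
    class = c("chemregistryNotRegistered", "error", "condition"),
    list(message = message, call = sys.call(-1L))))
}

.timestamp <- function() format(Sys.time(), "%Y-%m-%dT%H:%M:%OS3%z")

.layerColumns <- c(
  FORMULA = "formula",
  CANONICAL_SMILES = "canonical_smiles",
  TAUTOMER_HASH = "tautomer_hash",
  NO_STEREO_SMILES = "no_stereo_smiles",
  NO_STEREO_TAUTOMER_HASH = "no_stereo_tautomer_hash",
  SGROUP_DATA = "sgroup_data",
  ESCAPE = "escape_layer"
)

## Configuration -------------------------------------------------------------

#' Registry configuration
#'
#' The registration policy of a database: the ordered standardization
#' pipeline, whether 3D conformers are registered alongside topologies,
#' the tautomer-hash version, the SGroup fields entering the hash, and the
#' decimal precision of the conformer hash.  The configuration is stored
#' inside the database at [initRegistry()] time and reloaded verbatim by
#' [openRegistry()], so a registry is self-describing.
#'
#' @param standardization pipeline specification (see [runPipeline()]).
#' @param registerConformers logical; hash and register 3D conformers?
#' @param tautomerHashVersion `"v2"` or `"v1"`, see [hashOptions()].
#' @param sgroupFields SGroup fields entering the SGROUP_DATA layer.
#' @param conformerDigits decimal places used by the conformer hash.
#' @return a named list with class `"registryConfig"`.
#' @export
registryConfig <- function(standardization = defaultPipeline(),
                           registerConformers = FALSE,
                           tautomerHashVersion = c("v2", "v1"),
                           sgroupFields = c("FIELDNAME", "DATA"),
                           conformerDigits = 3L) {
  tautomerHashVersion <- match.arg(tautomerHashVersion)
  structure(list(
    schemaVersion = 1L,
    standardization = .normalizeSteps(standardization),
    registerConformers = isTRUE(registerConformers),
    tautomerHashVersion = tautomerHashVersion,
    sgroupFields = as.character(sgroupFields),
    conformerDigits = as.integer(conformerDigits)
  ), class = "registryConfig")
}

# canonical JSON serialization of a configuration (stored in the database;
# reserializing a loaded configuration reproduces the stored bytes)
.serializeConfig <- function(config) {
  as.character(jsonlite::toJSON(list(
    schemaVersion = config$schemaVersion,
    standardization = lapply(config$standardization, function(s)
      list(name = s$name, params = s$params)),
    registerConformers = config$registerConformers,
    tautomerHashVersion = config$tautomerHashVersion,
    sgroupFields = I(config$sgroupFields),
    conformerDigits = config$conformerDigits
  ), auto_unbox = TRUE))
}

.deserializeConfig <- function(json) {
  raw <- jsonlite::fromJSON(json, simplifyVector = TRUE,
                            simplifyDataFrame = FALSE,
                            simplifyMatrix = FALSE)
  structure(list(
    schemaVersion = as.integer(raw$schemaVersion),
    standardization = lapply(raw$standardization, function(s)
      list(name = s$name,
           params = if (length(s$params)) s$params else list())),
    registerConformers = isTRUE(raw$registerConformers),
    tautomerHashVersion = raw$tautomerHashVersion,
    sgroupFields = as.character(raw$sgroupFields),
    conformerDigits = as.integer(raw$conformerDigits)
  ), class = "registryConfig")
}

# HashOptions corresponding to a registry configuration
.configHashOptions <- function(config) {
  hashOptions(tautomerHashVersion = config$tautomerHashVersion,
              sgroupFields = config$sgroupFields)
}

## Opening and initializing --------------------------------------------------

.schemaStatements <- function() {
  path <- system.file("schema", "schema-1.sql", package = "chemregistry",
                      mustWork = TRUE)
  text <- paste(readLines(path), collapse = "\n")
  text <- gsub("--[^\n]*", "", text)
  stmts <- strsplit(text, ";", fixed = TRUE)[[1L]]
  stmts <- trimws(stmts)
  stmts[nzchar(stmts)]
}

#' Initialize a new compound registry
#'
#' Creates the registration schema in a fresh SQLite database and persists
#' the configuration inside it.  Initializing over an existing non-empty
#' database is refused unless `overwrite = TRUE`.
#'
#' @param path file path of the SQLite database (created if absent).
#' @param config a [registryConfig()] object.
#' @param overwrite replace an existing database?
#' @return an open [CompoundRegistry-class] handle.
#' @examples
#' reg <- initRegistry(tempfile(fileext = ".sqlite"))
#' registerCompound(reg, "CCO")
#' closeRegistry(reg)
#' @export
initRegistry <- function(path, config = registryConfig(), overwrite = FALSE) {
  stopifnot(inherits(config, "registryConfig"))
  if (file.exists(path) && file.size(path) > 0L) {
    if (!overwrite)
      stop("a non-empty database already exists at '", path,
           "'; use overwrite = TRUE to replace it", call. = FALSE)
    unlink(path)
  }
  con <- DBI::dbConnect(RSQLite::SQLite(), path)
  ok <- FALSE
  on.exit(if (!ok) DBI::dbDisconnect(con), add = TRUE)
  for (stmt in .schemaStatements()) DBI::dbExecute(con, stmt)
  DBI::dbExecute(con,
    "INSERT INTO registry_config (id, config) VALUES (1, ?)",
    params = list(.serializeConfig(config)))
  ok <- TRUE
  new("CompoundRegistry", con = con, path = path, config = config)
}

#' Open an existing compound registry
#'
#' @param path file path of an initialized SQLite registry database.
#' @return an open [CompoundRegistry-class] handle with the stored
#'   configuration loaded.
#' @export
openRegistry <- function(path) {
  if (!file.exists(path))
    stop("no database at '", path, "'", call. = FALSE)
  con <- DBI::dbConnect(RSQLite::SQLite(), path)
  ok <- FALSE
  on.exit(if (!ok) DBI::dbDisconnect(con), add = TRUE)
  if (!DBI::dbExistsTable(con, "registry_config"))
    stop("'", path, "' is not a chemregistry database", call. = FALSE)
  json <- DBI::dbGetQuery(con,
    "SELECT config FROM registry_config WHERE id = 1")$config
  config <- .deserializeConfig(json)
  ok <- TRUE
  new("CompoundRegistry", con = con, path = path, config = config)
}

#' Close a registry handle
#' @param registry a [CompoundRegistry-class] object.
#' @export
closeRegistry <- function(registry) {
  stopifnot(is(registry, "CompoundRegistry"))
  DBI::dbDisconnect(registry@con)
  invisible(NULL)
}

#' Load the configuration stored in a registry database
#'
#' Reads the configuration back from the database (not from the handle),
#' so it reflects exactly what was persisted at initialization.
#'
#' @param registry a [CompoundRegistry-class] object.
#' @return a `registryConfig` list.
#' @export
loadConfig <- function(registry) {
  json <- DBI::dbGetQuery(registry@con,
    "SELECT config FROM registry_config WHERE id = 1")$config
  .deserializeConfig(json)
}

setMethod("show", "CompoundRegistry", function(object) {
  nmol <- tryCatch(DBI::dbGetQuery(object@con,
    "SELECT COUNT(*) AS n FROM molecules")$n, error = function(e) NA)
  nconf <- tryCatch(DBI::dbGetQuery(object@con,
    "SELECT COUNT(*) AS n FROM conformers")$n, error = function(e) NA)
  cat("CompoundRegistry at", object@path, "\n")
  cat("  molecules:", nmol, "| conformers:", nconf, "\n")
  cat("  registerConformers:", object@config$registerConformers,
      "| tautomer hash:", object@config$tautomerHashVersion, "\n")
  cat("  pipeline:", paste(vapply(object@config$standardization, `[[`,
                                  character(1), "name"), collapse = " -> "),
      "\n")
})

## Molecule rows -------------------------------------------------------------

#' Insert a molecule row
#'
#' Low-level store operation: persists the seven layers individually (so
#' layer-subset queries can run as indexed string comparisons) together
#' with the combined digest, the standardized structure, the
#' applied-standardization record and the raw submission, and assigns the
#' next molregno.  [registerCompound()] is the high-level entry point.
#'
#' @param registry a [CompoundRegistry-class] object.
#' @param layers a [MolHashLayers-class] object.
#' @param standardizedMolblock V3000 mol block of the standardized
#'   structure.
#' @param applied character vector of applied standardization steps.
#' @param raw the submission text, stored byte-identically.
#' @param rawFormat `"smiles"` or `"molblock"`.
#' @return the assigned molregno (integer).  If a molecule with the same
#'   combined hash is present, an error of class `chemregistryDuplicate`
#'   carrying the existing molregno is raised.
#' @export
insertMolecule <- function(registry, layers, standardizedMolblock = NA_character_,
                           applied = character(0), raw = NA_character_,
                           rawFormat = NA_character_) {
  stopifnot(is(registry, "CompoundRegistry"), is(layers, "MolHashLayers"))
  con <- registry@con
  fullHash <- combineLayers(layers)
  existing <- DBI::dbGetQuery(con,
    "SELECT molregno FROM molecules WHERE full_hash = ?",
    params = list(fullHash))
  if (nrow(existing) > 0L) {
    .duplicateError(paste0("molecule already registered as molregno ",
                           existing$molregno[[1L]]),
                    existing$molregno[[1L]])
  }
  vals <- layerValues(layers)
  DBI::dbExecute(con, paste(
    "INSERT INTO molecules (formula, canonical_smiles, tautomer_hash,",
    " no_stereo_smiles, no_stereo_tautomer_hash, sgroup_data, escape_layer,",
    " full_hash, standardized_molblock, standardization_applied,",
    " registered_at) VALUES (?,?,?,?,?,?,?,?,?,?,?)"),
    params = list(vals[["FORMULA"]], vals[["CANONICAL_SMILES"]],
                  vals[["TAUTOMER_HASH"]], vals[["NO_STEREO_SMILES"]],
                  vals[["NO_STEREO_TAUTOMER_HASH"]], vals[["SGROUP_DATA"]],
                  vals[["ESCAPE"]], fullHash, standardizedMolblock,
                  as.character(jsonlite::toJSON(applied)), .timestamp()))
  mrn <- DBI::dbGetQuery(con, "SELECT last_insert_rowid() AS n")$n[[1L]]
  if (!is.na(raw)) {
    DBI::dbExecute(con,
      "INSERT INTO raw_inputs (molregno, raw, format) VALUES (?,?,?)",
      params = list(mrn, raw, rawFormat))
  }
  as.integer(mrn)
}

#' Find molecules matching a probe on selected hash layers
#'
#' @param registry a [CompoundRegistry-class] object.
#' @param probe a [MolHashLayers-class] object.
#' @param layers non-empty subset of [hashLayerNames()]; the full default
#'   is equivalent to combined-hash equality.
#' @return integer vector of matching molregnos, ascending.
#' @export
findByLayers <- function(registry, probe, layers = hashLayerNames()) {
  stopifnot(is(registry, "CompoundRegistry"), is(probe, "MolHashLayers"))
  layers <- as.character(layers)
  if (length(layers) == 0L) stop("'layers' must be non-empty", call. = FALSE)
  unknown <- setdiff(layers, names(.layerColumns))
  if (length(unknown) > 0L)
    stop("unknown layer name(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  vals <- layerValues(probe)[layers]
  where <- paste(sprintf("%s = ?", .layerColumns[layers]), collapse = " AND ")
  res <- DBI::dbGetQuery(registry@con,
    paste("SELECT molregno FROM molecules WHERE", where,
          "ORDER BY molregno"),
    params = as.list(unname(vals)))
  as.integer(res$molregno)
}

## Conformer rows ------------------------------------------------------------

#' Insert a conformer for a registered molecule
#'
#' Coordinates are stored at full precision (only the hash is rounded).
#' conf_ids form a per-molregno sequence starting at 1.
#'
#' @param registry a [CompoundRegistry-class] object.
#' @param molregno the owning molecule (must exist).
#' @param coords n x 3 coordinate matrix.
#' @param confHash precomputed hash; defaults to
#'   `conformerHash(coords, digits)` with the registry's configured
#'   digits.
#' @param molblock optional V3000 mol block embedding these coordinates,
#'   returned later by [getMolblock()].
#' @return the assigned conf_id.  A conformer with the same hash for the
#'   same molregno raises a `chemregistryDuplicate` error carrying the
#'   existing (molregno, conf_id).
#' @export
insertConformer <- function(registry, molregno, coords, confHash = NULL,
                            molblock = NA_character_) {
  stopifnot(is(registry, "CompoundRegistry"))
  con <- registry@con
  coords <- .checkCoords(coords)
  molregno <- as.integer(molregno)
  known <- DBI::dbGetQuery(con,
    "SELECT molregno FROM molecules WHERE molregno = ?",
    params = list(molregno))
  if (nrow(known) == 0L)
    .notRegisteredError(paste0("molregno ", molregno, " is not registered"))
  if (is.null(confHash))
    confHash <- conformerHash(coords, registry@config$conformerDigits)
  existing <- DBI::dbGetQuery(con,
    "SELECT conf_id FROM conformers WHERE molregno = ? AND conf_hash = ?",
    params = list(molregno, confHash))
  if (nrow(existing) > 0L) {
    .duplicateError(paste0("conformer already registered as (", molregno,
                           ", ", existing$conf_id[[1L]], ")"),
                    molregno, existing$conf_id[[1L]])
  }
  nextId <- DBI::dbGetQuery(con,
    "SELECT COALESCE(MAX(conf_id), 0) + 1 AS n FROM conformers WHERE molregno = ?",
    params = list(molregno))$n[[1L]]
  DBI::dbExecute(con, paste(
    "INSERT INTO conformers (molregno, conf_id, conf_hash, coords,",
    " molblock, registered_at) VALUES (?,?,?,?,?,?)"),
    params = list(molregno, nextId, confHash, .serializeCoords(coords),
                  molblock, .timestamp()))
  as.integer(nextId)
}

#' Find conformers by coordinate hash
#'
#' @param registry a [CompoundRegistry-class] object.
#' @param confHash a conformer hash string.
#' @return data.frame with columns `molregno`, `conf_id` (possibly empty),
#'   ordered by (molregno, conf_id).
#' @export
findConformers <- function(registry, confHash) {
  stopifnot(is(registry, "CompoundRegistry"))
  res <- DBI::dbGetQuery(registry@con,
    paste("SELECT molregno, conf_id FROM conformers WHERE conf_hash = ?",
          "ORDER BY molregno, conf_id"),
    params = list(as.character(confHash)))
  data.frame(molregno = as.integer(res$molregno),
             conf_id = as.integer(res$conf_id))
}

# Coordinates are persisted as text at 17 significant digits, which
# round-trips IEEE doubles exactly ("x,y,z" per atom, atoms joined by ";").
.serializeCoords <- function(coords) {
  paste(apply(coords, 1L, function(r)
    paste(sprintf("%.17g", r), collapse = ",")), collapse = ";")
}

.deserializeCoords <- function(text) {
  rows <- strsplit(strsplit(text, ";", fixed = TRUE)[[1L]], ",", fixed = TRUE)
  matrix(as.numeric(unlist(rows)), ncol = 3L, byrow = TRUE)
}

# full-precision coordinates of a stored conformer
.getConformerCoords <- function(registry, molregno, confId) {
  res <- DBI::dbGetQuery(registry@con,
    "SELECT coords FROM conformers WHERE molregno = ? AND conf_id = ?",
    params = list(as.integer(molregno), as.integer(confId)))
  if (nrow(res) == 0L)
    .notRegisteredError(paste0("no conformer (", molregno, ", ", confId, ")"))
  .deserializeCoords(res$coords[[1L]])
}

## Retrieval -----------------------------------------------------------------

#' Retrieve the standardized structure as a V3000 mol block
#'
#' Without `confId`, the standardized (2D) structure stored at
#' registration is returned.  With `confId`, the mol block embeds that
#' conformer's full-precision coordinates.
#'
#' @param registry a [CompoundRegistry-class] object.
#' @param molregno a registered molregno.
#' @param confId optional conformer id.
#' @return V3000 mol block text.
#' @export
getMolblock <- function(registry, molregno, confId = NULL) {
  stopifnot(is(registry, "CompoundRegistry"))
  if (!is.null(confId)) {
    res <- DBI::dbGetQuery(registry@con,
      "SELECT molblock FROM conformers WHERE molregno = ? AND conf_id = ?",
      params = list(as.integer(molregno), as.integer(confId)))
    if (nrow(res) == 0L || is.na(res$molblock[[1L]]))
      .notRegisteredError(paste0("no conformer (", molregno, ", ", confId, ")"))
    return(res$molblock[[1L]])
  }
  res <- DBI::dbGetQuery(registry@con,
    "SELECT standardized_molblock FROM molecules WHERE molregno = ?",
    params = list(as.integer(molregno)))
  if (nrow(res) == 0L)
    .notRegisteredError(paste0("molregno ", molregno, " is not registered"))
  res$standardized_molblock[[1L]]
}

#' Retrieve the as-registered submission
#'
#' @param registry a [CompoundRegistry-class] object.
#' @param molregno a registered molregno.
#' @return `list(text =, format =)`; `text` is byte-identical to the
#'   submission.
#' @export
getRaw <- function(registry, molregno) {
  stopifnot(is(registry, "CompoundRegistry"))
  res <- DBI::dbGetQuery(registry@con,
    "SELECT raw, format FROM raw_inputs WHERE molregno = ?",
    params = list(as.integer(molregno)))
  if (nrow(res) == 0L)
    .notRegisteredError(paste0("molregno ", molregno, " is not registered"))
  list(text = res$raw[[1L]], format = res$format[[1L]])
}

#' Retrieve the stored hash layers of a molecule
#'
#' @param registry a [CompoundRegistry-class] object.
#' @param molregno a registered molregno.
#' @return a [MolHashLayers-class] object.
#' @export
getLayers <- function(registry, molregno) {
  stopifnot(is(registry, "CompoundRegistry"))
  res <- DBI::dbGetQuery(registry@con,
    "SELECT * FROM molecules WHERE molregno = ?",
    params = list(as.integer(molregno)))
  if (nrow(res) == 0L)
    .notRegisteredError(paste0("molregno ", molregno, " is not registered"))
  MolHashLayers(formula = res$formula, canonicalSmiles = res$canonical_smiles,
                tautomerHash = res$tautomer_hash,
                noStereoSmiles = res$no_stereo_smiles,
                noStereoTautomerHash = res$no_stereo_tautomer_hash,
                sgroupData = res$sgroup_data, escape = res$escape_layer)
}
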