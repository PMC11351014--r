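#' @include AllClasses.R store.R
NULL

# Companion tables for experiment metadata and results.
#
# Metadata (what is needed to reproduce an experiment) and data (its
# results) live in separate per-type tables, linked by UUID keys; data
# rows additionally link back to registered structures via molregno and,
# optionally, conf_id.  Column kinds: "number" and "text" map to plain
# SQL columns for compact storage and fast filtering, "json" columns hold
# arbitrary payloads.  A type declared with json-only columns gives the
# minimal fully generic schema; a type declared with explicit
# number/text columns gives the fully modeled variant -- both shapes are
# queried identically through fetchResults().

.validIdentifier <- function(x) grepl("^[A-Za-z][A-Za-z0-9_]*$", x)

.RESERVED_COLUMNS <- c("experiment_id", "molregno", "conf_id", "created_at")

.checkColumns <- function(cols, what) {
  if (length(cols) == 0L) return(invisible(cols))
  if (is.null(names(cols)) || !all(nzchar(names(cols))))
    stop(what, " columns must be a named vector/list of kinds", call. = FALSE)
  if (!all(.validIdentifier(names(cols))))
    stop("invalid ", what, " column name(s)", call. = FALSE)
  if (any(names(cols) %in% .RESERVED_COLUMNS))
    stop(what, " columns may not use reserved names (",
         paste(.RESERVED_COLUMNS, collapse = ", "), ")", call. = FALSE)
  kinds <- unlist(cols, use.names = FALSE)
  if (!all(kinds %in% c("number", "text", "json")))
    stop(what, " column kinds must be 'number', 'text' or 'json'",
         call. = FALSE)
  invisible(cols)
}

.sqlType <- function(kind) switch(kind, number = "REAL", text = "TEXT",
                                  json = "TEXT")

#' Define an experiment type (one metadata table + one data table)
#'
#' Creates `<name>_metadata` and `<name>_data` tables with the declared
#' typed columns.  The definition can also be given as a JSON document
#' with fields `name`, `metadata` and `data` (objects mapping column
#' names to kinds).
#'
#' @param registry an open [CompoundRegistry-class].
#' @param name experiment-type name (a valid table identifier), or a JSON
#'   document describing the whole type.
#' @param metadataColumns,dataColumns named character vectors mapping
#'   column names to kinds (`"number"`, `"text"`, `"json"`).  At least
#'   one data column is required.
#' @return the type name, invisibly.
#' @examples
#' reg <- initRegistry(tempfile(fileext = ".sqlite"))
#' defineExperimentType(reg, "assay",
#'                      metadataColumns = c(protocol = "json"),
#'                      dataColumns = c(value = "number", payload = "json"))
#' closeRegistry(reg)
#' @export
defineExperimentType <- function(registry, name, metadataColumns = c(),
                                 dataColumns = c()) {
  stopifnot(is(registry, "CompoundRegistry"))
  if (length(name) == 1L && grepl("^\\s*\\{", name)) {
    doc <- jsonlite::fromJSON(name, simplifyVector = TRUE)
    name <- doc$name
    metadataColumns <- unlist(doc$metadata)
    dataColumns <- unlist(doc$data)
  }
  stopifnot(is.character(name), length(name) == 1L)
  if (!.validIdentifier(name))
    stop("'", name, "' is not a valid experiment-type name", call. = FALSE)
  .checkColumns(metadataColumns, "metadata")
  .checkColumns(dataColumns, "data")
  if (length(dataColumns) == 0L)
    stop("an experiment type needs at least one data column", call. = FALSE)
  con <- registry@con
  existing <- DBI::dbGetQuery(con,
    "SELECT name FROM experiment_types WHERE name = ?", params = list(name))
  if (nrow(existing) > 0L)
    stop("experiment type '", name, "' already exists", call. = FALSE)

  metaCols <- paste0(
    vapply(seq_along(metadataColumns), function(k)
      sprintf(", %s %s", names(metadataColumns)[[k]],
              .sqlType(metadataColumns[[k]])), character(1)),
    collapse = "")
  dataCols <- paste0(
    vapply(seq_along(dataColumns), function(k)
      sprintf(", %s %s", names(dataColumns)[[k]],
              .sqlType(dataColumns[[k]])), character(1)),
    collapse = "")
  DBI::dbExecute(con, sprintf(
    "CREATE TABLE %s_metadata (experiment_id TEXT PRIMARY KEY%s, created_at TEXT NOT NULL)",
    name, metaCols))
  DBI::dbExecute(con, sprintf(
    paste0("CREATE TABLE %s_data (experiment_id TEXT NOT NULL REFERENCES ",
           "%s_metadata(experiment_id), molregno INTEGER NOT NULL ",
           "REFERENCES molecules(molregno), conf_id INTEGER%s)"),
    name, name, dataCols))
  definition <- as.character(jsonlite::toJSON(list(
    name = name,
    metadata = as.list(metadataColumns),
    data = as.list(dataColumns)), auto_unbox = TRUE))
  DBI::dbExecute(con,
    "INSERT INTO experiment_types (name, definition) VALUES (?, ?)",
    params = list(name, definition))
  invisible(name)
}

#' List defined experiment types
#' @param registry an open [CompoundRegistry-class].
#' @return named list of type definitions (metadata/data column maps).
#' @export
experimentTypes <- function(registry) {
  res <- DBI::dbGetQuery(registry@con,
    "SELECT name, definition FROM experiment_types ORDER BY name")
  stats::setNames(
    lapply(res$definition, jsonlite::fromJSON, simplifyVector = TRUE),
    res$name)
}

.getExperimentType <- function(registry, name) {
  res <- DBI::dbGetQuery(registry@con,
    "SELECT definition FROM experiment_types WHERE name = ?",
    params = list(name))
  if (nrow(res) == 0L)
    stop("experiment type '", name, "' is not defined", call. = FALSE)
  jsonlite::fromJSON(res$definition[[1L]], simplifyVector = TRUE)
}

# encode one R value for a declared column kind
.encodeValue <- function(value, kind, column) {
  if (identical(kind, "number")) {
    if (!is.numeric(value) || length(value) != 1L)
      stop("column '", column, "' expects a single number", call. = FALSE)
    as.numeric(value)
  } else if (identical(kind, "text")) {
    if (length(value) != 1L)
      stop("column '", column, "' expects a single string", call. = FALSE)
    as.character(value)
  } else {
    as.character(jsonlite::toJSON(value, auto_unbox = TRUE, digits = NA,
                                  null = "null"))
  }
}

#' Record experiment metadata
#'
#' Persists one metadata row and returns a fresh UUID (random, version 4)
#' identifying the experiment; data rows recorded later link to it via
#' this key.
#'
#' @param registry an open [CompoundRegistry-class].
#' @param typeName a defined experiment type.
#' @param metadata named list supplying a value for every declared
#'   metadata column (json columns take arbitrary structures).
#' @return the experiment UUID (character).
#' @export
recordExperiment <- function(registry, typeName, metadata = list()) {
  stopifnot(is(registry, "CompoundRegistry"))
  type <- .getExperimentType(registry, typeName)
  declared <- names(type$metadata)
  missing <- setdiff(declared, names(metadata))
  if (length(missing) > 0L)
    stop("missing metadata column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  extra <- setdiff(names(metadata), declared)
  if (length(extra) > 0L)
    stop("undeclared metadata column(s): ", paste(extra, collapse = ", "),
         call. = FALSE)
  uuid <- uuid::UUIDgenerate(use.time = FALSE)
  vals <- lapply(declared, function(cn)
    .encodeValue(metadata[[cn]], type$metadata[[cn]], cn))
  cols <- paste(c("experiment_id", declared, "created_at"), collapse = ", ")
  marks <- paste(rep("?", length(declared) + 2L), collapse = ", ")
  DBI::dbExecute(registry@con,
    sprintf("INSERT INTO %s_metadata (%s) VALUES (%s)", typeName, cols, marks),
    params = c(list(uuid), vals, list(.timestamp())))
  DBI::dbExecute(registry@con,
    "INSERT INTO experiments (experiment_id, type_name) VALUES (?, ?)",
    params = list(uuid, typeName))
  uuid
}

#' Record experiment results
#'
#' Each row links one registered structure (molregno, optionally a
#' conformer) to result values for every declared data column.  All rows
#' are validated against the registry before anything is written, then
#' inserted in a single transaction: a referential error (unknown
#' experiment, unregistered molregno, unknown conformer) leaves the
#' database untouched.
#'
#' @param registry an open [CompoundRegistry-class].
#' @param experimentId a UUID returned by [recordExperiment()].
#' @param rows list of named lists (or a data.frame), each with
#'   `molregno`, optional `conf_id`, and the declared data columns.
#' @return the number of rows written.
#' @export
recordResults <- function(registry, experimentId, rows) {
  stopifnot(is(registry, "CompoundRegistry"))
  con <- registry@con
  lookup <- DBI::dbGetQuery(con,
    "SELECT type_name FROM experiments WHERE experiment_id = ?",
    params = list(experimentId))
  if (nrow(lookup) == 0L)
    stop("unknown experiment id '", experimentId, "'", call. = FALSE)
  typeName <- lookup$type_name[[1L]]
  type <- .getExperimentType(registry, typeName)
  declared <- names(type$data)
  if (is.data.frame(rows))
    rows <- lapply(seq_len(nrow(rows)), function(i) as.list(rows[i, ]))

  prepared <- lapply(rows, function(row) {
    if (is.null(row$molregno))
      stop("every result row needs a molregno", call. = FALSE)
    mrn <- as.integer(row$molregno)
    known <- DBI::dbGetQuery(con,
      "SELECT molregno FROM molecules WHERE molregno = ?", params = list(mrn))
    if (nrow(known) == 0L)
      stop("molregno ", mrn, " is not registered", call. = FALSE)
    cid <- if (!is.null(row$conf_id) && !is.na(row$conf_id))
      as.integer(row$conf_id) else NA_integer_
    if (!is.na(cid)) {
      kc <- DBI::dbGetQuery(con,
        "SELECT conf_id FROM conformers WHERE molregno = ? AND conf_id = ?",
        params = list(mrn, cid))
      if (nrow(kc) == 0L)
        stop("no conformer (", mrn, ", ", cid, ") registered", call. = FALSE)
    }
    missing <- setdiff(declared, names(row))
    if (length(missing) > 0L)
      stop("missing data column(s): ", paste(missing, collapse = ", "),
           call. = FALSE)
    vals <- lapply(declared, function(cn)
      .encodeValue(row[[cn]], type$data[[cn]], cn))
    c(list(experimentId, mrn, cid), vals)
  })

  cols <- paste(c("experiment_id", "molregno", "conf_id", declared),
                collapse = ", ")
  marks <- paste(rep("?", length(declared) + 3L), collapse = ", ")
  DBI::dbWithTransaction(con, {
    for (p in prepared) {
      DBI::dbExecute(con,
        sprintf("INSERT INTO %s_data (%s) VALUES (%s)", typeName, cols, marks),
        params = p)
    }
  })
  length(prepared)
}

#' Fetch experiment results joined with metadata and structures
#'
#' Returns one row per recorded datum, carrying the data columns, the
#' experiment's metadata columns (prefixed `meta_`), and the canonical
#' SMILES of the linked molecule.  `filter` is an optional predicate
#' taking the joined data.frame and returning a logical vector (use it to
#' select rows by any column).  Export to CSV with [utils::write.csv()].
#'
#' @param registry an open [CompoundRegistry-class].
#' @param typeName a defined experiment type.
#' @param filter `NULL` or `function(df) logical`.
#' @return a data.frame (possibly with zero rows).
#' @export
fetchResults <- function(registry, typeName, filter = NULL) {
  stopifnot(is(registry, "CompoundRegistry"))
  type <- .getExperimentType(registry, typeName)
  metaCols <- names(type$metadata)
  metaSel <- if (length(metaCols))
    paste0(", ", paste(sprintf("m.%s AS meta_%s", metaCols, metaCols),
                       collapse = ", "))
  else ""
  df <- DBI::dbGetQuery(registry@con, sprintf(
    paste0("SELECT d.*, mol.canonical_smiles%s FROM %s_data d ",
           "JOIN %s_metadata m ON m.experiment_id = d.experiment_id ",
           "JOIN molecules mol ON mol.molregno = d.molregno ",
           "ORDER BY d.rowid"),
    metaSel, typeName, typeName))
  if (!is.null(filter)) {
    keep <- filter(df)
    stopifnot(is.logical(keep), length(keep) == nrow(df))
    df <- df[keep & !is.na(keep), , drop = FALSE]
    rownames(df) <- NULL
  }
  df
}
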