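#' @include AllClasses.R AllGenerics.R hash-layers.R standardize.R store.R
NULL

.parseError <- function(message) {
  stop(structure(
    class = c("chemregistryParseError", "error", "condition"),
    list(message = message, call = sys.call(-1L))))
}

# Core batch registration used by both registerCompound and bulkRegister.
# Returns a list of RegistrationResult, one per input, in order.
.registerBatch <- function(registry, inputs, escapes = "") {
  config <- registry@config
  n <- length(inputs)
  escapes <- rep_len(as.character(escapes), n)
  results <- vector("list", n)

  mols <- .parseMoleculeBatch(inputs)
  parsed <- which(!vapply(mols, is.null, logical(1)))
  for (i in setdiff(seq_len(n), parsed)) {
    results[[i]] <- new("RegistrationResult", status = "parse_error",
                        detail = "could not parse input structure")
  }
  if (length(parsed) == 0L) return(results)

  std <- .runPipelineBatch(mols[parsed], config$standardization)
  for (k in seq_along(parsed)) {
    i <- parsed[[k]]
    if (is.null(std$molecules[[k]])) {
      results[[i]] <- new("RegistrationResult", status = "rejected",
                          detail = paste0("rejected by standardization step '",
                                          std$records[[k]]@rejectingStep, "'"))
    }
  }
  alive <- parsed[!vapply(std$molecules, is.null, logical(1))]
  if (length(alive) == 0L) return(results)
  aliveMols <- std$molecules[!vapply(std$molecules, is.null, logical(1))]
  aliveRecords <- std$records[!vapply(std$molecules, is.null, logical(1))]

  opts <- .configHashOptions(config)
  layersList <- .computeLayersBatch(aliveMols, escapes[alive], opts)

  # standardized structures as V3000 blocks (batch)
  stdBlocks <- .obSmilesToMolblock(
    vapply(aliveMols, function(m) m@smiles, character(1)), v3000 = TRUE)

  # conformer templates: V3000 versions of the submitted connection tables
  wantConf <- config$registerConformers &
    vapply(aliveMols, .moleculeHas3d, logical(1))
  confTemplates <- rep(NA_character_, length(aliveMols))
  withBlock <- wantConf & !vapply(aliveMols, function(m) is.na(m@molblock),
                                  logical(1))
  if (any(withBlock)) {
    confTemplates[withBlock] <- .obMolblockToV3000(
      vapply(aliveMols[withBlock], function(m) m@molblock, character(1)))
  }

  for (k in seq_along(alive)) {
    i <- alive[[k]]
    if (is.character(layersList[[k]])) {
      results[[i]] <- new("RegistrationResult", status = "parse_error",
                          detail = paste0("hashing error in layer ",
                                          layersList[[k]]))
      next
    }
    results[[i]] <- .registerOne(
      registry, layers = layersList[[k]], mol = aliveMols[[k]],
      record = aliveRecords[[k]], raw = inputs[[i]],
      stdBlock = stdBlocks[[k]], confTemplate = confTemplates[[k]],
      wantConformer = wantConf[[k]])
  }
  results
}

# insert one standardized, hashed molecule (and conformer, when asked),
# translating duplicate conditions into result statuses
.registerOne <- function(registry, layers, mol, record, raw, stdBlock,
                         confTemplate, wantConformer) {
  mrn <- NULL
  duplicateMol <- FALSE
  mrn <- tryCatch(
    insertMolecule(registry, layers, standardizedMolblock = stdBlock,
                   applied = record@applied, raw = raw,
                   rawFormat = mol@format),
    chemregistryDuplicate = function(e) {
      duplicateMol <<- TRUE
      e$molregno
    })
  if (!wantConformer) {
    status <- if (duplicateMol) "duplicate" else "registered"
    detail <- if (duplicateMol) paste0("already registered as molregno ", mrn)
              else ""
    return(new("RegistrationResult", status = status,
               molregno = as.integer(mrn), detail = detail))
  }
  coords <- .moleculeCoords(mol)
  if (is.null(coords)) {
    status <- if (duplicateMol) "duplicate" else "registered"
    return(new("RegistrationResult", status = status,
               molregno = as.integer(mrn),
               detail = "no conformer on input"))
  }
  template <- if (!is.na(confTemplate)) {
    tryCatch(.v3000WithCoords(confTemplate, coords),
             error = function(e) NA_character_)
  } else NA_character_
  duplicateConf <- FALSE
  cid <- tryCatch(
    insertConformer(registry, mrn, coords, molblock = template),
    chemregistryDuplicate = function(e) {
      duplicateConf <<- TRUE
      e$confId
    })
  status <- if (duplicateMol && duplicateConf) "duplicate" else "registered"
  detail <- if (duplicateMol && !duplicateConf)
    "new conformer of an already registered molecule"
  else if (duplicateConf)
    paste0("conformer already registered as (", mrn, ", ", cid, ")")
  else ""
  new("RegistrationResult", status = status, molregno = as.integer(mrn),
      confId = as.integer(cid), detail = detail)
}

#' Register a compound
#'
#' Parses the input, runs the registry's configured standardization
#' pipeline, computes the layered registration hash and inserts the
#' molecule.  In registerConformers mode, a 3D conformer present on the
#' input is additionally hashed and registered, and the result carries the
#' (molregno, confId) pair.  The as-submitted text and the
#' applied-standardization record are stored with the molecule.
#'
#' Duplicates are not errors: the result has status `"duplicate"` and
#' carries the existing molregno, so pipelines can always obtain the
#' identifier in one call.
#'
#' @param registry an open [CompoundRegistry-class].
#' @param input a SMILES string or mol block text.
#' @param escape free-text escape-layer discriminator.
#' @return a [RegistrationResult-class] object.
#' @examples
#' reg <- initRegistry(tempfile(fileext = ".sqlite"))
#' registerCompound(reg, "CCO")             # registered, molregno 1
#' registerCompound(reg, "OCC")             # duplicate,  molregno 1
#' closeRegistry(reg)
#' @rdname registerCompound
#' @export
setMethod("registerCompound", "CompoundRegistry",
  function(registry, input, escape = "") {
    stopifnot(length(input) == 1L)
    .registerBatch(registry, as.character(input), escape)[[1L]]
  })

#' Register many compounds at once
#'
#' One result per input, in order.  Failures (duplicates, filter
#' rejections, parse errors) do not abort the batch, and successful
#' registrations are durable even when later items fail.
#'
#' @param registry an open [CompoundRegistry-class].
#' @param inputs character vector (or list) of SMILES / mol block texts.
#' @param escape escape-layer text, recycled over the inputs.
#' @return list of [RegistrationResult-class] objects.
#' @rdname bulkRegister
#' @export
setMethod("bulkRegister", "CompoundRegistry",
  function(registry, inputs, escape = "") {
    .registerBatch(registry, unlist(as.character(inputs)), escape)
  })

#' Query the registry with a structure
#'
#' The query molecule undergoes the same standardization as registration,
#' its hash layers are computed, and the selected layers are matched
#' against the stored per-layer columns.  Selecting fewer layers widens
#' the match: e.g. `layers = "TAUTOMER_HASH"` returns all registered
#' tautomers of the query, `layers = "NO_STEREO_SMILES"` all its
#' stereoisomers.
#'
#' In registerConformers mode, a query carrying a 3D conformer is instead
#' matched by conformer hash and returns a data.frame of
#' (molregno, conf_id) pairs.
#'
#' A query molecule rejected by a standardization filter yields an empty
#' result with a warning (queries are total); unparsable input is an
#' error.
#'
#' @param registry an open [CompoundRegistry-class].
#' @param input a SMILES string or mol block text.
#' @param layers subset of [hashLayerNames()] to match on (default: all).
#' @param escape escape-layer text of the probe.
#' @return integer vector of molregnos, or a data.frame with columns
#'   `molregno`, `conf_id` for conformer queries.
#' @rdname queryCompound
#' @export
setMethod("queryCompound", "CompoundRegistry",
  function(registry, input, layers = hashLayerNames(), escape = "") {
    config <- registry@config
    mols <- .parseMoleculeBatch(list(input))
    if (is.null(mols[[1L]]))
      .parseError("could not parse query structure")
    std <- .runPipelineBatch(mols, config$standardization)
    if (is.null(std$molecules[[1L]])) {
      warning("query structure rejected by standardization step '",
              std$records[[1L]]@rejectingStep, "'; returning no matches",
              call. = FALSE)
      return(integer(0))
    }
    mol <- std$molecules[[1L]]
    if (config$registerConformers && .moleculeHas3d(mol)) {
      hash <- conformerHash(.moleculeCoords(mol), config$conformerDigits)
      return(findConformers(registry, hash))
    }
    probe <- .computeLayersBatch(list(mol), escape,
                                 .configHashOptions(config))[[1L]]
    if (is.character(probe))
      .parseError(paste0("hashing error in layer ", probe))
    findByLayers(registry, probe, layers)
  })

#' Conformer ids for a set of molregnos
#'
#' Available in registerConformers mode only.  Every requested molregno
#' appears in the result; molecules without conformers map to an empty
#' vector.
#'
#' @param registry an open [CompoundRegistry-class].
#' @param molregnos integer vector of registered molregnos.
#' @return named list mapping each molregno to an integer vector of its
#'   conf_ids.
#' @rdname queryConformers
#' @export
setMethod("queryConformers", "CompoundRegistry",
  function(registry, molregnos) {
    if (!registry@config$registerConformers)
      stop("the registry is not in registerConformers mode", call. = FALSE)
    molregnos <- as.integer(molregnos)
    out <- stats::setNames(vector("list", length(molregnos)),
                           as.character(molregnos))
    for (k in seq_along(molregnos)) {
      mrn <- molregnos[[k]]
      known <- DBI::dbGetQuery(registry@con,
        "SELECT molregno FROM molecules WHERE molregno = ?",
        params = list(mrn))
      if (nrow(known) == 0L)
        .notRegisteredError(paste0("molregno ", mrn, " is not registered"))
      res <- DBI::dbGetQuery(registry@con,
        "SELECT conf_id FROM conformers WHERE molregno = ? ORDER BY conf_id",
        params = list(mrn))
      out[[k]] <- as.integer(res$conf_id)
    }
    out
  })

# normalize retrieve ids: list of list(molregno=, confId=)
.normalizeRetrieveIds <- function(ids) {
  if (is.numeric(ids)) ids <- as.list(ids)
  lapply(ids, function(id) {
    if (is.list(id)) id <- unlist(id)
    id <- as.integer(id)
    if (length(id) == 1L) list(molregno = id, confId = NA_integer_)
    else if (length(id) == 2L) list(molregno = id[[1L]], confId = id[[2L]])
    else stop("ids must be molregnos or (molregno, confId) pairs",
              call. = FALSE)
  })
}

#' Retrieve registered structures or hashes
#'
#' @param registry an open [CompoundRegistry-class].
#' @param ids integer vector of molregnos, or a list that may also contain
#'   `c(molregno, confId)` pairs.
#' @param mode `"standardized"` (V3000 mol block; with a conformer pair,
#'   the block embeds that conformer's full-precision coordinates),
#'   `"as_registered"` (the byte-identical submission plus its format
#'   tag), or `"hashes"` (all seven layers plus the combined digest).
#' @return named list keyed by `"<molregno>"` or `"<molregno>:<confId>"`.
#'   Unknown ids raise an error identifying the offending id.
#' @rdname retrieveCompound
#' @export
setMethod("retrieveCompound", "CompoundRegistry",
  function(registry, ids,
           mode = c("standardized", "as_registered", "hashes")) {
    mode <- match.arg(mode)
    ids <- .normalizeRetrieveIds(ids)
    out <- list()
    for (id in ids) {
      key <- if (is.na(id$confId)) as.character(id$molregno)
             else paste0(id$molregno, ":", id$confId)
      out[[key]] <- switch(mode,
        standardized = if (is.na(id$confId))
          getMolblock(registry, id$molregno)
        else getMolblock(registry, id$molregno, id$confId),
        as_registered = getRaw(registry, id$molregno),
        hashes = {
          layers <- getLayers(registry, id$molregno)
          list(layers = layers, fullHash = combineLayers(layers))
        })
    }
    out
  })

#' Read the records of an SD file
#'
#' Splits an SDF into individual mol block texts (without the terminating
#' `$$$$` lines), for feeding [bulkRegister()].
#'
#' @param path path to an SD file.
#' @return character vector of mol block texts.
#' @export
readSdf <- function(path) {
  lines <- readLines(path)
  ends <- grep("^\\$\\$\\$\\$", lines)
  if (length(ends) == 0L) return(paste(lines, collapse = "\n"))
  starts <- c(1L, ends[-length(ends)] + 1L)
  out <- character(0)
  for (k in seq_along(ends)) {
    if (starts[[k]] > ends[[k]] - 1L) next
    rec <- lines[starts[[k]]:(ends[[k]] - 1L)]
    if (any(nzchar(trimws(rec)))) out <- c(out, paste(rec, collapse = "\n"))
  }
  out
}
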