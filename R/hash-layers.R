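#' @include AllClasses.R
NULL

#' Parse a molecule from SMILES or mol block text
#'
#' Input format is auto-detected (a multi-line text containing a `V2000` /
#' `V3000` tag is treated as a mol block) or can be forced.  Parsing and
#' canonicalization are delegated to OpenBabel; stereochemistry in mol
#' blocks is perceived from wedge bonds or 3D coordinates.
#'
#' @param input a single SMILES string or mol block text.
#' @param format `"auto"` (default), `"smiles"` or `"molblock"`.
#' @return a [Molecule-class] object.
#' @examples
#' parseMolecule("CCO")
#' @export
parseMolecule <- function(input, format = c("auto", "smiles", "molblock")) {
  format <- match.arg(format)
  mol <- .parseMoleculeBatch(list(input), format)[[1L]]
  if (is.null(mol)) stop("could not parse input structure", call. = FALSE)
  mol
}

# Batch molecule parsing; returns a list of Molecule objects with NULL for
# unparsable entries.  `format` is a single value applied to all inputs.
.parseMoleculeBatch <- function(inputs, format = "auto") {
  n <- length(inputs)
  if (n == 0L) return(list())
  inputs <- as.character(inputs)
  isMb <- if (format == "auto") {
    vapply(inputs, function(x) !is.na(x) && .isMolblock(x), logical(1))
  } else rep(format == "molblock", n)
  out <- vector("list", n)
  if (any(isMb)) {
    can <- .obMolblockToCan(inputs[isMb])
    idx <- which(isMb)
    for (k in seq_along(idx)) {
      if (!is.na(can[[k]]) && nzchar(can[[k]])) {
        out[[idx[[k]]]] <- new("Molecule", smiles = can[[k]],
                               molblock = inputs[[idx[[k]]]],
                               format = "molblock")
      }
    }
  }
  if (any(!isMb)) {
    can <- .obCanonical(inputs[!isMb])
    idx <- which(!isMb)
    for (k in seq_along(idx)) {
      if (!is.na(can[[k]]) && nzchar(can[[k]])) {
        out[[idx[[k]]]] <- new("Molecule", smiles = can[[k]],
                               format = "smiles")
      }
    }
  }
  out
}

#' Compute the seven registration-hash layers for a molecule
#'
#' The layers are: `FORMULA` (Hill-order molecular formula),
#' `CANONICAL_SMILES` (canonical SMILES with stereochemistry),
#' `TAUTOMER_HASH` (tautomer-invariant skeleton serialization, keeping
#' tetrahedral stereo), `NO_STEREO_SMILES` and `NO_STEREO_TAUTOMER_HASH`
#' (the stereo-free counterparts), `SGROUP_DATA` (canonical JSON of
#' selected SGroup fields; `"{}"` when none) and `ESCAPE` (the `escape`
#' argument, verbatim).
#'
#' The tautomer-invariant layers collapse every heteroatom-containing
#' fragment to its saturated heavy-atom skeleton and append the total
#' hydrogen count (and, for hash version `"v2"`, the net formal charge),
#' so true tautomers -- structures differing only in proton placement and
#' bond orders -- always agree, while constitutional isomers do not.
#'
#' @param mol a [Molecule-class], or a single SMILES / mol block string.
#' @param escape free-text discriminator included verbatim as the ESCAPE
#'   layer.
#' @param options a `HashOptions` object, see [hashOptions()].
#' @return a [MolHashLayers-class] object.
#' @examples
#' layers <- computeLayers("CCO")
#' layerValues(layers)[["FORMULA"]]   # "C2H6O"
#' @export
computeLayers <- function(mol, escape = "", options = hashOptions()) {
  if (is.character(mol)) mol <- parseMolecule(mol)
  stopifnot(is(mol, "Molecule"), is(options, "HashOptions"))
  res <- .computeLayersBatch(list(mol), escape, options)[[1L]]
  if (is.character(res)) {
    stop("hashing error in layer ", res, call. = FALSE)
  }
  res
}

# Batch layer computation.  `mols` is a list of Molecule objects;
# `escapes` recycles to length(mols).  Returns a list whose elements are
# MolHashLayers, or the name of the failing layer (character) on error.
.computeLayersBatch <- function(mols, escapes = "", options = hashOptions()) {
  n <- length(mols)
  if (n == 0L) return(list())
  escapes <- rep_len(as.character(escapes), n)
  smiles <- vapply(mols, function(m) m@smiles, character(1))

  cf <- .obCanonicalWithFormula(smiles)
  noStereo <- .obCanonical(smiles, stereo = FALSE)

  skelStereo <- rep(NA_character_, n)
  skelBare <- rep(NA_character_, n)
  okCan <- !is.na(cf$smiles)
  skels <- lapply(which(okCan), function(i) {
    tryCatch(list(
      stereo = .skeletonSmiles(cf$smiles[[i]], keepStereo = TRUE),
      bare = .skeletonSmiles(cf$smiles[[i]], keepStereo = FALSE)
    ), error = function(e) NULL)
  })
  okSkel <- !vapply(skels, is.null, logical(1))
  idx <- which(okCan)[okSkel]
  if (length(idx)) {
    skelStereo[idx] <- .obCanonical(
      vapply(skels[okSkel], `[[`, character(1), "stereo"))
    skelBare[idx] <- .obCanonical(
      vapply(skels[okSkel], `[[`, character(1), "bare"), stereo = FALSE)
  }

  out <- vector("list", n)
  for (i in seq_len(n)) {
    if (is.na(cf$smiles[[i]]) || is.na(cf$formula[[i]])) {
      out[[i]] <- "CANONICAL_SMILES"; next
    }
    if (is.na(noStereo[[i]])) { out[[i]] <- "NO_STEREO_SMILES"; next }
    if (is.na(skelStereo[[i]])) { out[[i]] <- "TAUTOMER_HASH"; next }
    if (is.na(skelBare[[i]])) { out[[i]] <- "NO_STEREO_TAUTOMER_HASH"; next }
    hTotal <- .formulaHCount(cf$formula[[i]])
    suffix <- if (identical(options@tautomerHashVersion, "v2")) {
      sprintf("_%d_%d", hTotal, .netCharge(cf$smiles[[i]]))
    } else {
      sprintf("_%d", hTotal)
    }
    sgroup <- if (!is.na(mols[[i]]@molblock)) {
      canonicalizeSgroupData(mols[[i]]@molblock, options@sgroupFields)
    } else "{}"
    out[[i]] <- MolHashLayers(
      formula = cf$formula[[i]],
      canonicalSmiles = cf$smiles[[i]],
      tautomerHash = paste0(skelStereo[[i]], suffix),
      noStereoSmiles = noStereo[[i]],
      noStereoTautomerHash = paste0(skelBare[[i]], suffix),
      sgroupData = sgroup,
      escape = escapes[[i]]
    )
  }
  out
}

#' Canonical JSON serialization of a molecule's SGroup data
#'
#' DAT-type SGroup records are read from the mol block, restricted to the
#' requested fields, and serialized as a compact JSON array with records
#' sorted by their (field name, value) content and keys in sorted order --
#' so the output is independent of the order in which the SGroups appear
#' in the file.  Molecules without SGroup data yield `"{}"`.
#'
#' @param mol a [Molecule-class] object or mol block text.  SMILES-parsed
#'   molecules carry no SGroup data and yield `"{}"`.
#' @param fields SGroup field names to keep (default: the DAT field name
#'   and its value).
#' @return single JSON string.
#' @export
canonicalizeSgroupData <- function(mol, fields = c("FIELDNAME", "DATA")) {
  molblock <- if (is(mol, "Molecule")) mol@molblock else mol
  if (is.na(molblock) || !.isMolblock(molblock)) return("{}")
  sg <- .molblockSgroups(molblock)
  sg <- Filter(function(s) identical(s$type, "DAT"), sg)
  records <- lapply(sg, function(s) {
    keep <- intersect(fields, names(s$fields))
    if (length(keep) == 0L) return(NULL)
    as.list(s$fields[sort(keep)])
  })
  records <- Filter(Negate(is.null), records)
  if (length(records) == 0L) return("{}")
  serialized <- vapply(records, function(r)
    as.character(jsonlite::toJSON(r, auto_unbox = TRUE)), character(1))
  paste0("[", paste(serialized[order(serialized)], collapse = ","), "]")
}

#' Combine the seven layers into the registration digest
#'
#' The canonical byte serialization joins `"LAYERNAME:value"` items, in
#' the fixed layer order given by [hashLayerNames()], with a single
#' newline separator, encodes the result as UTF-8, and takes its SHA-1.
#' This serialization is specific to this package: digests are not
#' interchangeable with other registration systems.
#'
#' @param layers a [MolHashLayers-class] object.
#' @return the 40-character lowercase hexadecimal SHA-1 digest.
#' @examples
#' combineLayers(computeLayers("CCO"))
#' @export
combineLayers <- function(layers) {
  stopifnot(is(layers, "MolHashLayers"))
  digest::digest(.layerPreimage(layers), algo = "sha1", serialize = FALSE)
}

# the documented serialization of the seven layers (UTF-8 text)
.layerPreimage <- function(layers) {
  vals <- layerValues(layers)
  enc2utf8(paste(paste0(names(vals), ":", vals), collapse = "\n"))
}

#' Compare two layer sets on a selected subset of layers
#'
#' @param stored,probe [MolHashLayers-class] objects.
#' @param layers non-empty subset of [hashLayerNames()].
#' @return `TRUE` iff every selected layer is byte-identical.
#' @examples
#' a <- computeLayers("C/C=C/C"); b <- computeLayers("C/C=C\\C")
#' matchLayers(a, b, "NO_STEREO_SMILES")  # TRUE
#' matchLayers(a, b)                      # FALSE
#' @export
matchLayers <- function(stored, probe, layers = hashLayerNames()) {
  stopifnot(is(stored, "MolHashLayers"), is(probe, "MolHashLayers"))
  layers <- as.character(layers)
  if (length(layers) == 0L) stop("'layers' must be non-empty", call. = FALSE)
  unknown <- setdiff(layers, .LAYER_ORDER)
  if (length(unknown) > 0L) {
    stop("unknown layer name(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  a <- layerValues(stored)[layers]
  b <- layerValues(probe)[layers]
  all(a == b)
}
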