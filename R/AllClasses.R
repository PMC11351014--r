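#' @import methods
NULL

# Fixed layer order used when combining layers into the registration
# digest.  Constant for the lifetime of a database: changing it changes
# every combined hash.
.LAYER_ORDER <- c("FORMULA", "CANONICAL_SMILES", "TAUTOMER_HASH",
                  "NO_STEREO_SMILES", "NO_STEREO_TAUTOMER_HASH",
                  "SGROUP_DATA", "ESCAPE")

#' Names of the seven registration-hash layers
#'
#' The layers jointly define 2D molecular identity: molecular formula,
#' canonical SMILES with and without stereochemistry, tautomer-invariant
#' hashes with and without stereochemistry, canonicalized SGroup data, and
#' a free-text escape layer.  The order returned here is the fixed order
#' used for digest combination.
#'
#' @return character vector of the seven layer names.
#' @examples
#' hashLayerNames()
#' @export
hashLayerNames <- function() .LAYER_ORDER

#' Layered molecular identity hash
#'
#' Holds the seven text layers computed by [computeLayers()].  All seven
#' slots are always present; `sgroupData` and `escape` may be the empty
#' serialization.  Equality of the layers (or a subset, see
#' [matchLayers()]) defines molecular identity for registration.
#'
#' @slot formula molecular formula in Hill order.
#' @slot canonicalSmiles canonical SMILES including stereochemistry.
#' @slot tautomerHash tautomer-invariant serialization (stereo-aware).
#' @slot noStereoSmiles canonical SMILES with stereochemistry removed.
#' @slot noStereoTautomerHash tautomer-invariant serialization without
#'   stereochemistry.
#' @slot sgroupData canonical JSON serialization of selected SGroup
#'   fields; `"{}"` when the molecule has none.
#' @slot escape caller-supplied free-text discriminator; `""` by default.
#' @export
setClass("MolHashLayers",
  representation(formula = "character",
                 canonicalSmiles = "character",
                 tautomerHash = "character",
                 noStereoSmiles = "character",
                 noStereoTautomerHash = "character",
                 sgroupData = "character",
                 escape = "character"),
  prototype(sgroupData = "{}", escape = ""))

setValidity("MolHashLayers", function(object) {
  for (sl in slotNames(object)) {
    v <- slot(object, sl)
    if (length(v) != 1L || is.na(v))
      return(sprintf("slot '%s' must be a single non-NA string", sl))
  }
  TRUE
})

#' Construct a MolHashLayers object
#'
#' Mostly used internally and by tests; [computeLayers()] is the normal
#' entry point.
#'
#' @param formula,canonicalSmiles,tautomerHash,noStereoSmiles,
#'   noStereoTautomerHash,sgroupData,escape single strings; see the class
#'   documentation.
#' @return a [MolHashLayers-class] object.
#' @export
MolHashLayers <- function(formula = "", canonicalSmiles = "",
                          tautomerHash = "", noStereoSmiles = "",
                          noStereoTautomerHash = "", sgroupData = "{}",
                          escape = "") {
  new("MolHashLayers", formula = formula, canonicalSmiles = canonicalSmiles,
      tautomerHash = tautomerHash, noStereoSmiles = noStereoSmiles,
      noStereoTautomerHash = noStereoTautomerHash, sgroupData = sgroupData,
      escape = escape)
}

#' Layer values as a named character vector
#'
#' @param x a [MolHashLayers-class] object.
#' @return named character vector in the fixed layer order.
#' @export
layerValues <- function(x) {
  stopifnot(is(x, "MolHashLayers"))
  c(FORMULA = x@formula,
    CANONICAL_SMILES = x@canonicalSmiles,
    TAUTOMER_HASH = x@tautomerHash,
    NO_STEREO_SMILES = x@noStereoSmiles,
    NO_STEREO_TAUTOMER_HASH = x@noStereoTautomerHash,
    SGROUP_DATA = x@sgroupData,
    ESCAPE = x@escape)
}

setMethod("show", "MolHashLayers", function(object) {
  vals <- layerValues(object)
  cat("MolHashLayers\n")
  for (nm in names(vals)) {
    v <- vals[[nm]]
    if (nchar(v) > 60L) v <- paste0(substr(v, 1L, 57L), "...")
    cat(sprintf("  %-24s %s\n", nm, v))
  }
})

#' Hashing options
#'
#' Registration policy knobs for the layered hash: which version of the
#' tautomer hash to use and which SGroup record fields enter the
#' SGROUP_DATA layer.  The layer combination order itself is fixed (see
#' [hashLayerNames()]).
#'
#' @param tautomerHashVersion `"v2"` (default; skeleton hash including the
#'   net formal charge) or `"v1"` (without the charge component).
#' @param sgroupFields ordered character vector of SGroup field names
#'   included in the SGROUP_DATA layer; the default uses the DAT-SGroup
#'   field name and value.
#' @return a `HashOptions` object.
#' @examples
#' hashOptions()
#' hashOptions(tautomerHashVersion = "v1")
#' @export
hashOptions <- function(tautomerHashVersion = c("v2", "v1"),
                        sgroupFields = c("FIELDNAME", "DATA")) {
  tautomerHashVersion <- match.arg(tautomerHashVersion)
  new("HashOptions", tautomerHashVersion = tautomerHashVersion,
      sgroupFields = as.character(sgroupFields))
}

#' @rdname hashOptions
#' @export
setClass("HashOptions",
  representation(tautomerHashVersion = "character",
                 sgroupFields = "character"),
  prototype(tautomerHashVersion = "v2",
            sgroupFields = c("FIELDNAME", "DATA")))

setValidity("HashOptions", function(object) {
  if (!object@tautomerHashVersion %in% c("v1", "v2"))
    return("tautomerHashVersion must be 'v1' or 'v2'")
  TRUE
})

#' A parsed molecule ready for standardization and hashing
#'
#' Light container produced by [parseMolecule()]: the OpenBabel canonical
#' SMILES plus, for mol-block inputs, the original block (the carrier of
#' coordinates and SGroup data).
#'
#' @slot smiles canonical SMILES.
#' @slot molblock the mol block as submitted, or `NA` for SMILES input.
#' @slot format `"smiles"` or `"molblock"`.
#' @slot coords either `NULL`, or a full-precision n x 3 coordinate matrix
#'   that supersedes the mol block's coordinates (set by
#'   coordinate-modifying standardization steps).
#' @export
setClass("Molecule",
  representation(smiles = "character",
                 molblock = "character",
                 format = "character",
                 coords = "ANY"),
  prototype(molblock = NA_character_, format = "smiles", coords = NULL))

# effective conformer coordinates of a molecule (override first, then the
# mol block's atom block); NULL when the molecule carries none
.moleculeCoords <- function(mol) {
  if (!is.null(mol@coords)) return(mol@coords)
  if (is.na(mol@molblock)) return(NULL)
  at <- .molblockAtoms(mol@molblock)
  if (is.null(at)) NULL else at$coords
}

# TRUE when the molecule carries a 3D conformer
.moleculeHas3d <- function(mol) {
  if (!is.null(mol@coords)) return(TRUE)
  if (is.na(mol@molblock)) return(FALSE)
  .molblockHas3d(mol@molblock)
}

setMethod("show", "Molecule", function(object) {
  cat("Molecule:", object@smiles,
      if (!is.na(object@molblock)) "(with mol block)" else "", "\n")
})

#' Record of the standardization steps applied to a molecule
#'
#' @slot applied ordered character vector of the step names attempted.
#' @slot outcome `"accepted"` or `"rejected"`.
#' @slot rejectingStep name of the filter/step that rejected the molecule;
#'   `NA` when accepted.
#' @export
setClass("StandardizationRecord",
  representation(applied = "character", outcome = "character",
                 rejectingStep = "character"),
  prototype(applied = character(0), outcome = "accepted",
            rejectingStep = NA_character_))

setValidity("StandardizationRecord", function(object) {
  if (!object@outcome %in% c("accepted", "rejected"))
    return("outcome must be 'accepted' or 'rejected'")
  if (identical(object@outcome, "rejected") && is.na(object@rejectingStep))
    return("a rejected record must name the rejecting step")
  if (identical(object@outcome, "accepted") && !is.na(object@rejectingStep))
    return("an accepted record cannot name a rejecting step")
  TRUE
})

setMethod("show", "StandardizationRecord", function(object) {
  cat("StandardizationRecord:", object@outcome,
      "| applied:", paste(object@applied, collapse = " -> "), "\n")
  if (!is.na(object@rejectingStep))
    cat("  rejected by:", object@rejectingStep, "\n")
})

#' A compound registry backed by a relational store
#'
#' Open handles are created by [initRegistry()] / [openRegistry()].  The
#' embedded backend is SQLite; the slot holds a DBI connection, so any
#' conforming DBI backend can stand behind the same interface.
#'
#' @slot con a `DBIConnection`.
#' @slot path the database location (file path for SQLite).
#' @slot config the registry configuration (see [registryConfig()]).
#' @export
setClass("CompoundRegistry",
  representation(con = "ANY", path = "character", config = "ANY"))

#' Result of a registration attempt
#'
#' @slot status one of `"registered"`, `"duplicate"`, `"rejected"`,
#'   `"parse_error"`.
#' @slot molregno the assigned (or already existing) molregno; `NA` for
#'   rejected/unparsable input.
#' @slot confId conformer id when a 3D conformer was registered (or found
#'   duplicated); otherwise `NA`.
#' @slot detail human-readable detail (duplicate target, rejecting filter,
#'   parse diagnostics).
#' @export
setClass("RegistrationResult",
  representation(status = "character", molregno = "integer",
                 confId = "integer", detail = "character"),
  prototype(molregno = NA_integer_, confId = NA_integer_, detail = ""))

setValidity("RegistrationResult", function(object) {
  if (!object@status %in% c("registered", "duplicate", "rejected", "parse_error"))
    return("invalid status")
  if (object@status %in% c("registered", "duplicate") && is.na(object@molregno))
    return("registered/duplicate results must carry a molregno")
  if (object@status %in% c("rejected", "parse_error") && !is.na(object@molregno))
    return("rejected/parse_error results cannot carry a molregno")
  TRUE
})

setMethod("show", "RegistrationResult", function(object) {
  cat("RegistrationResult:", object@status)
  if (!is.na(object@molregno)) cat(" molregno =", object@molregno)
  if (!is.na(object@confId)) cat(" confId =", object@confId)
  if (nzchar(object@detail)) cat(" (", object@detail, ")", sep = "")
  cat("\n")
})

#' @describeIn RegistrationResult-class status accessor
#' @param x a `RegistrationResult`.
#' @export
resultStatus <- function(x) x@status

#' @describeIn RegistrationResult-class molregno accessor
#' @export
molregno <- function(x) x@molregno

#' @describeIn RegistrationResult-class conformer-id accessor
#' @export
confId <- function(x) x@confId
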