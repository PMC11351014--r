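#' @include AllClasses.R hash-layers.R
NULL

# Registry of standardization steps.  Each entry:
#   list(name, kind ("standardizer" | "filter"),
#        batchFun(mols, params) -> list of Molecule-or-NULL)
# Filters must return their input unchanged on success; standardizers may
# return a modified molecule.  NULL signals failure/rejection.
.stepRegistry <- new.env(parent = emptyenv())

#' Register a standardization step under a name
#'
#' Extension point for institution-specific standardizers and filters.  A
#' step is a function taking a [Molecule-class] (plus an optional list of
#' parameters) and returning a molecule on success or `NULL` on failure.
#' Filters must return their input structurally unchanged.  Registered
#' steps are addressable by name in pipeline configurations.
#'
#' @param name unique step name (used in stored configurations).
#' @param kind `"standardizer"` (may modify) or `"filter"` (gate only).
#' @param fun `function(mol, params)` returning a `Molecule` or `NULL`.
#' @param overwrite replace an existing step of the same name?
#' @return the step name, invisibly.
#' @export
registerStandardizationStep <- function(name, kind = c("standardizer", "filter"),
                                        fun, overwrite = FALSE) {
  kind <- match.arg(kind)
  stopifnot(is.character(name), length(name) == 1L, nzchar(name),
            is.function(fun))
  if (!overwrite && !is.null(.stepRegistry[[name]]))
    stop("a standardization step named '", name, "' already exists",
         call. = FALSE)
  .stepRegistry[[name]] <- list(
    name = name, kind = kind,
    batchFun = function(mols, params) lapply(mols, fun, params = params)
  )
  invisible(name)
}

# internal registration with a native batch implementation
.registerBuiltinStep <- function(name, kind, batchFun) {
  .stepRegistry[[name]] <- list(name = name, kind = kind, batchFun = batchFun)
}

#' Names of all registered standardization steps
#' @return character vector of step names (built-ins plus extensions).
#' @export
standardizationSteps <- function() sort(ls(.stepRegistry))

.getStep <- function(name) {
  step <- .stepRegistry[[name]]
  if (is.null(step))
    stop("unknown standardization step '", name, "'", call. = FALSE)
  step
}

## Built-in steps ------------------------------------------------------------

# replace the working SMILES of a molecule, keeping its mol block (the
# carrier of as-submitted coordinates and SGroup data)
.withSmiles <- function(mol, smiles) {
  if (is.na(smiles) || !nzchar(smiles)) return(NULL)
  mol@smiles <- smiles
  mol
}

.batchRecanonicalize <- function(mols, newSmiles) {
  can <- .obCanonical(newSmiles)
  lapply(seq_along(mols), function(i) {
    if (is.null(mols[[i]])) NULL else .withSmiles(mols[[i]], can[[i]])
  })
}

#' Sanitize a molecule
#'
#' Validates that the structure parses, canonicalizes (aromaticity
#' perception is OpenBabel's) and passes a maximum-valence check on C, N,
#' O and F.  Chemically invalid structures (e.g. a pentavalent carbon)
#' yield `NULL`.
#'
#' @param mol a [Molecule-class] object.
#' @param params unused.
#' @return the molecule, or `NULL` when it is not registrable.
#' @export
sanitizeMolecule <- function(mol, params = list()) {
  .getStep("sanitize")$batchFun(list(mol), params)[[1L]]
}

#' Keep only the largest fragment
#'
#' Returns the largest fragment by heavy-atom count (ties broken by total
#' atom count, then lexicographically smallest canonical SMILES).
#' Single-fragment molecules pass through unchanged.
#'
#' @inheritParams sanitizeMolecule
#' @return a [Molecule-class] object.
#' @export
removeFragments <- function(mol, params = list()) {
  .getStep("remove_fragments")$batchFun(list(mol), params)[[1L]]
}

#' Neutralize simple charged sites
#'
#' Protonates negatively charged O/S/N sites and deprotonates positively
#' charged N/O/S sites carrying a hydrogen.  Sites adjacent to an opposite
#' formal charge (charge-separated resonance forms such as nitro groups or
#' N-oxides) are left intact, as are charges that cannot be removed by
#' (de)protonation.
#'
#' @inheritParams sanitizeMolecule
#' @return a [Molecule-class] object.
#' @export
neutralizeMolecule <- function(mol, params = list()) {
  .getStep("neutralize")$batchFun(list(mol), params)[[1L]]
}

#' Charge parent: largest organic fragment, neutralized
#'
#' Keeps the largest fragment that contains at least one carbon (falling
#' back to the overall largest fragment when none does) and neutralizes
#' it.
#'
#' @inheritParams sanitizeMolecule
#' @return a [Molecule-class] object.
#' @export
chargeParent <- function(mol, params = list()) {
  .getStep("charge_parent")$batchFun(list(mol), params)[[1L]]
}

#' Filter: reject molecules with overlapping atoms
#'
#' Fails when any two atoms of a coordinate-bearing molecule lie closer
#' than `minDist` (strictly); molecules without coordinates pass.  The
#' default threshold of 1e-4 Angstrom effectively flags coincident atoms
#' in badly drawn structures.
#'
#' @inheritParams sanitizeMolecule
#' @param params list; `minDist` overrides the threshold (Angstrom).
#' @return the unmodified molecule, or `NULL` on rejection.
#' @export
filterOverlappingAtoms <- function(mol, params = list()) {
  .getStep("filter_overlapping_atoms")$batchFun(list(mol), params)[[1L]]
}

#' Filter: reject polymers declared via SGroup data
#'
#' Fails when the mol block carries any SGroup record of a polymer type
#' (SRU, MON, COP, CRO, MOD, GRA, ANY); all other molecules pass
#' unchanged.
#'
#' @inheritParams sanitizeMolecule
#' @return the unmodified molecule, or `NULL` on rejection.
#' @export
filterPolymerSgroup <- function(mol, params = list()) {
  .getStep("filter_polymer_sgroup")$batchFun(list(mol), params)[[1L]]
}

.installBuiltinSteps <- function() {
  .registerBuiltinStep("sanitize", "standardizer", function(mols, params) {
    lapply(mols, function(mol) {
      if (is.null(mol)) return(NULL)
      ok <- tryCatch(.checkValences(.smilesGraph(mol@smiles)),
                     error = function(e) conditionMessage(e))
      if (isTRUE(ok)) mol else NULL
    })
  })

  .registerBuiltinStep("remove_fragments", "standardizer", function(mols, params) {
    edited <- vapply(mols, function(mol) {
      if (is.null(mol)) NA_character_
      else tryCatch(.largestFragment(mol@smiles), error = function(e) NA_character_)
    }, character(1))
    .batchRecanonicalize(mols, edited)
  })

  .registerBuiltinStep("neutralize", "standardizer", function(mols, params) {
    edited <- vapply(mols, function(mol) {
      if (is.null(mol)) NA_character_
      else tryCatch(.neutralizeSmiles(mol@smiles), error = function(e) NA_character_)
    }, character(1))
    .batchRecanonicalize(mols, edited)
  })

  .registerBuiltinStep("charge_parent", "standardizer", function(mols, params) {
    edited <- vapply(mols, function(mol) {
      if (is.null(mol)) return(NA_character_)
      tryCatch(.neutralizeSmiles(.obCanonical(.largestFragment(mol@smiles, organic = TRUE))),
               error = function(e) NA_character_)
    }, character(1))
    .batchRecanonicalize(mols, edited)
  })

  .registerBuiltinStep("filter_overlapping_atoms", "filter", function(mols, params) {
    minDist <- if (!is.null(params$minDist)) as.numeric(params$minDist) else 1e-4
    lapply(mols, function(mol) {
      if (is.null(mol)) return(NULL)
      coords <- .moleculeCoords(mol)
      if (is.null(coords) || nrow(coords) < 2L) return(mol)
      d <- stats::dist(coords)
      if (any(d < minDist)) NULL else mol
    })
  })

  .registerBuiltinStep("filter_polymer_sgroup", "filter", function(mols, params) {
    lapply(mols, function(mol) {
      if (is.null(mol)) return(NULL)
      if (!is.na(mol@molblock) && .hasPolymerSgroup(mol@molblock)) NULL else mol
    })
  })

  .registerBuiltinStep("canonicalize_orientation", "standardizer", function(mols, params) {
    lapply(mols, function(mol) {
      if (is.null(mol)) return(NULL)
      coords <- .moleculeCoords(mol)
      if (is.null(coords)) return(mol)
      mol@coords <- canonicalizeOrientation(coords)
      mol
    })
  })
}

## Pipeline ------------------------------------------------------------------

# normalize a pipeline specification to list(list(name=, params=), ...)
# accepted forms: "sanitize", c("a","b"), list("a", list(name="b", params=..))
.normalizeSteps <- function(steps) {
  if (is.character(steps)) steps <- as.list(steps)
  if (!is.list(steps) || length(steps) == 0L)
    stop("'steps' must be a non-empty list of step names", call. = FALSE)
  lapply(steps, function(s) {
    if (is.character(s) && length(s) == 1L) {
      list(name = s, params = list())
    } else if (is.list(s) && !is.null(s$name)) {
      list(name = s$name,
           params = if (is.null(s$params)) list() else s$params)
    } else stop("invalid step specification", call. = FALSE)
  })
}

#' Default standardization pipeline
#'
#' Basic sanitization only -- the minimal policy for registries that must
#' preserve submitted tautomers and salt forms.  Stricter policies are
#' composed by listing more steps, e.g.
#' `c("sanitize", "charge_parent")`.
#'
#' @return list of step specifications.
#' @export
defaultPipeline <- function() list("sanitize")

#' Run a standardization pipeline on one molecule
#'
#' Applies the steps in the given order, stopping at the first failure.
#' The returned record lists exactly the steps attempted, in order, and
#' names the rejecting step if any.
#'
#' @param mol a [Molecule-class] object.
#' @param steps pipeline specification: character vector of step names, or
#'   a list whose elements are names or `list(name=, params=)`.
#' @return `list(molecule = Molecule-or-NULL, record = StandardizationRecord)`.
#' @examples
#' res <- runPipeline(parseMolecule("CC(=O)[O-].[Na+]"),
#'                    c("sanitize", "remove_fragments", "neutralize"))
#' res$molecule
#' res$record
#' @export
runPipeline <- function(mol, steps = defaultPipeline()) {
  out <- .runPipelineBatch(list(mol), steps)
  list(molecule = out$molecules[[1L]], record = out$records[[1L]])
}

# batch pipeline: all molecules advance through the steps together so the
# built-in steps can batch their obabel calls.
# returns list(molecules = list of Molecule-or-NULL, records = list of
# StandardizationRecord)
.runPipelineBatch <- function(mols, steps = defaultPipeline()) {
  specs <- .normalizeSteps(steps)
  n <- length(mols)
  stopifnot(!any(vapply(mols, is.null, logical(1))))
  applied <- replicate(n, character(0), simplify = FALSE)
  rejectedBy <- rep(NA_character_, n)
  current <- mols
  for (spec in specs) {
    step <- .getStep(spec$name)
    alive <- which(!vapply(current, is.null, logical(1)) & is.na(rejectedBy))
    if (length(alive) == 0L) break
    res <- step$batchFun(current[alive], spec$params)
    for (k in seq_along(alive)) {
      i <- alive[[k]]
      applied[[i]] <- c(applied[[i]], spec$name)
      if (is.null(res[[k]])) {
        rejectedBy[[i]] <- spec$name
        current[i] <- list(NULL)
      } else {
        current[[i]] <- res[[k]]
      }
    }
  }
  records <- lapply(seq_len(n), function(i) {
    if (is.na(rejectedBy[[i]])) {
      new("StandardizationRecord", applied = applied[[i]],
          outcome = "accepted")
    } else {
      new("StandardizationRecord", applied = applied[[i]],
          outcome = "rejected", rejectingStep = rejectedBy[[i]])
    }
  })
  list(molecules = current, records = records)
}
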