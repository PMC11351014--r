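# Thin batch wrapper around the OpenBabel command-line converter.
#
# All molecule parsing, canonicalization and format conversion in this
# package goes through obabel.  Conversions are run in batch: every input
# is tagged with a synthetic title ("m<i>") so that results can be
# realigned after obabel silently drops molecules it cannot parse
# (invocations always pass -e, "continue after errors").

.obabelPath <- local({
  cached <- NULL
  function() {
    if (!is.null(cached)) return(cached)
    p <- Sys.which("obabel")
    if (!nzchar(p)) {
      stop("the 'obabel' executable was not found on the PATH; ",
           "OpenBabel is required", call. = FALSE)
    }
    cached <<- unname(p)
    cached
  }
})

#' @noRd
.runObabel <- function(inFile, inFormat, outFormat, extraArgs = character()) {
  args <- c(inFile, paste0("-i", inFormat), paste0("-o", outFormat),
            "-e", extraArgs)
  out <- suppressWarnings(
    system2(.obabelPath(), args, stdout = TRUE, stderr = FALSE)
  )
  status <- attr(out, "status")
  if (!is.null(status) && status > 1L) {
    stop("obabel failed with status ", status, call. = FALSE)
  }
  as.character(out)
}

## SMILES batch conversion ---------------------------------------------------

# Convert a character vector of SMILES to a line-oriented output format
# ("can", "smi", "txt", ...).  Returns a character vector aligned with
# `smiles`; entries obabel could not parse are NA.  Any user-supplied title
# after the first whitespace is dropped.  `extra` holds additional obabel
# arguments, e.g. "-xi" (strip stereo/isotopes) or c("--append", "formula").
.obSmilesTo <- function(smiles, outFormat = "can", extra = character()) {
  n <- length(smiles)
  if (n == 0L) return(character(0))
  body <- sub("[[:space:]].*$", "", smiles)
  inFile <- tempfile(fileext = ".smi")
  on.exit(unlink(inFile), add = TRUE)
  writeLines(paste(body, paste0("m", seq_len(n))), inFile)
  out <- .runObabel(inFile, "smi", outFormat, extra)
  .alignByTitle(out, n)
}

# Parse "value\ttitle[ appended...]" lines into a vector aligned on the
# m<i> titles; the appended fields (if any) are kept attached to the value
# with a tab so callers can split them off.
.alignByTitle <- function(lines, n) {
  res <- rep(NA_character_, n)
  if (length(lines) == 0L) return(res)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  for (p in parts) {
    if (length(p) < 2L) next
    title <- p[[2L]]
    m <- regmatches(title, regexec("^m([0-9]+)\\s*(.*)$", title))[[1L]]
    if (length(m) == 0L) next
    idx <- as.integer(m[[2L]])
    if (is.na(idx) || idx < 1L || idx > n) next
    val <- p[[1L]]
    if (nzchar(m[[3L]])) val <- paste(val, m[[3L]], sep = "\t")
    res[idx] <- val
  }
  res
}

#' Canonical SMILES via OpenBabel
#'
#' @param smiles character vector of SMILES strings.
#' @param stereo keep stereochemistry annotations? When `FALSE` the output
#'   also drops isotope labels (OpenBabel's `-xi` writer option).
#' @return character vector of canonical SMILES, `NA` where parsing failed.
#' @noRd
.obCanonical <- function(smiles, stereo = TRUE) {
  extra <- if (stereo) character() else "-xi"
  .obSmilesTo(smiles, "can", extra)
}

# Canonical SMILES plus Hill-order molecular formula, as a list of two
# aligned character vectors.
.obCanonicalWithFormula <- function(smiles, stereo = TRUE) {
  extra <- c(if (!stereo) "-xi", "--append", "formula")
  raw <- .obSmilesTo(smiles, "can", extra)
  parts <- strsplit(raw, "\t", fixed = TRUE)
  can <- vapply(parts, function(p) if (length(p) >= 1L) p[[1L]] else NA_character_,
                character(1))
  formula <- vapply(parts, function(p) if (length(p) >= 2L) p[[2L]] else NA_character_,
                    character(1))
  can[is.na(raw)] <- NA_character_
  formula[is.na(raw)] <- NA_character_
  list(smiles = can, formula = formula)
}

## Mol block conversion ------------------------------------------------------

# Convert mol block texts (V2000 or V3000) to canonical SMILES (stereo is
# perceived from wedges / 3D coordinates).  Returns an aligned vector with
# NA for unparsable blocks.
.obMolblockToCan <- function(molblocks, stereo = TRUE) {
  n <- length(molblocks)
  if (n == 0L) return(character(0))
  inFile <- tempfile(fileext = ".sdf")
  on.exit(unlink(inFile), add = TRUE)
  writeLines(.taggedSdf(molblocks), inFile)
  extra <- if (stereo) character() else "-xi"
  out <- .runObabel(inFile, "sdf", "can", extra)
  .alignByTitle(out, n)
}

# Stitch mol blocks into one SDF stream, replacing each title line with the
# alignment tag m<i>.
.taggedSdf <- function(molblocks) {
  pieces <- vapply(seq_along(molblocks), function(i) {
    lines <- strsplit(molblocks[[i]], "\n", fixed = TRUE)[[1L]]
    if (length(lines) < 4L) lines <- c(lines, rep("", 4L - length(lines)))
    lines[1L] <- paste0("m", i)
    paste(c(lines, "$$$$"), collapse = "\n")
  }, character(1))
  paste(pieces, collapse = "\n")
}

# SMILES -> mol block with generated 2D coordinates (wedge bonds carry the
# stereochemistry), V2000 or V3000.  Returns aligned character vector.
.obSmilesToMolblock <- function(smiles, gen2d = TRUE, v3000 = FALSE) {
  n <- length(smiles)
  if (n == 0L) return(character(0))
  body <- sub("[[:space:]].*$", "", smiles)
  inFile <- tempfile(fileext = ".smi")
  on.exit(unlink(inFile), add = TRUE)
  writeLines(paste(body, paste0("m", seq_len(n))), inFile)
  out <- .runObabel(inFile, "smi", "sdf",
                    c(if (gen2d) "--gen2d", if (v3000) "-x3"))
  .alignSdfByTitle(out, n)
}

# mol block (V2000 or V3000) -> V3000 mol block, atom order preserved
.obMolblockToV3000 <- function(molblocks) {
  n <- length(molblocks)
  if (n == 0L) return(character(0))
  inFile <- tempfile(fileext = ".sdf")
  on.exit(unlink(inFile), add = TRUE)
  writeLines(.taggedSdf(molblocks), inFile)
  out <- .runObabel(inFile, "sdf", "sdf", "-x3")
  .alignSdfByTitle(out, n)
}

# Split an SDF output stream on $$$$ records and realign on m<i> titles.
.alignSdfByTitle <- function(lines, n) {
  res <- rep(NA_character_, n)
  if (length(lines) == 0L) return(res)
  breaks <- which(lines == "$$$$")
  start <- 1L
  for (b in breaks) {
    rec <- lines[start:(b - 1L)]
    start <- b + 1L
    if (length(rec) < 4L) next
    m <- regmatches(rec[[1L]], regexec("^m([0-9]+)$", rec[[1L]]))[[1L]]
    if (length(m) == 0L) next
    idx <- as.integer(m[[2L]])
    if (is.na(idx) || idx < 1L || idx > n) next
    rec[[1L]] <- ""
    res[idx] <- paste(rec, collapse = "\n")
  }
  res
}
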