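# Mol block (MDL CTAB) helpers.
#
# OpenBabel does the actual chemistry; ChemmineR parses V2000 atom blocks.
# The code here covers only what neither exposes: SGroup records (V2000
# "M  STY/SDT/SED" lines and V3000 SGROUP blocks), detection of 3D
# conformers, full-precision coordinate extraction from V3000 input, and
# substituting full-precision coordinates back into a V3000 block on
# retrieval (the fixed-width V2000 atom block cannot hold more than four
# decimal places).

.isMolblock <- function(text) {
  grepl("\n", text, fixed = TRUE) &&
    (grepl("V2000", text, fixed = TRUE) || grepl("V3000", text, fixed = TRUE) ||
       grepl("\\$\\$\\$\\$", text))
}

.isV3000 <- function(text) grepl("V3000", text, fixed = TRUE)

#' Atom coordinates and element symbols from a mol block
#'
#' @param molblock single mol block text (V2000 or V3000).
#' @return list with `coords` (n x 3 numeric matrix), `elements`
#'   (character vector), `dim` ("2D"/"3D"/""), or NULL when the block
#'   cannot be parsed.
#' @noRd
.molblockAtoms <- function(molblock) {
  lines <- strsplit(molblock, "\n", fixed = TRUE)[[1L]]
  if (length(lines) < 4L) return(NULL)
  dimCode <- if (length(lines) >= 2L && nchar(lines[[2L]]) >= 22L)
    trimws(substr(lines[[2L]], 21L, 22L)) else ""
  if (.isV3000(molblock)) {
    res <- .v3000Atoms(lines)
  } else {
    res <- tryCatch({
      sdf <- suppressWarnings(ChemmineR::read.SDFset(c(lines, "$$$$")))
      ab <- ChemmineR::atomblock(sdf[[1L]])
      list(coords = unname(as.matrix(ab[, 1:3, drop = FALSE])),
           elements = sub("_.*$", "", rownames(ab)))
    }, error = function(e) NULL)
  }
  if (is.null(res)) return(NULL)
  res$dim <- dimCode
  res
}

.v3000Atoms <- function(lines) {
  begin <- grep("^M  V30 BEGIN ATOM", lines)
  end <- grep("^M  V30 END ATOM", lines)
  if (length(begin) != 1L || length(end) != 1L || end <= begin) return(NULL)
  atomLines <- lines[(begin + 1L):(end - 1L)]
  toks <- strsplit(sub("^M  V30 +", "", atomLines), "[[:space:]]+")
  ok <- vapply(toks, function(t) length(t) >= 5L, logical(1))
  if (!all(ok)) return(NULL)
  elements <- vapply(toks, `[[`, character(1), 2L)
  coords <- t(vapply(toks, function(t) as.numeric(t[3:5]), numeric(3)))
  if (anyNA(coords)) return(NULL)
  list(coords = coords, elements = elements)
}

# TRUE when the block carries a 3D conformer (3D dimension flag, or any
# off-plane coordinate)
.molblockHas3d <- function(molblock) {
  at <- .molblockAtoms(molblock)
  if (is.null(at)) return(FALSE)
  identical(at$dim, "3D") || any(abs(at$coords[, 3L]) > 0)
}

## SGroups -------------------------------------------------------------------

# SGroup types that mark a polymer record
.POLYMER_SGROUP_TYPES <- c("SRU", "MON", "COP", "CRO", "MOD", "GRA", "ANY")

#' Extract SGroup records from a mol block
#'
#' Supports V2000 (M STY / M SDT / M SED lines; multiple SED lines per
#' group are concatenated) and V3000 (SGROUP block with FIELDNAME= /
#' FIELDDATA= attributes).  Absence of SGroup data yields an empty list.
#'
#' @return list of records: list(type=, fields=named character vector).
#'   DAT groups expose fields FIELDNAME and DATA.
#' @noRd
.molblockSgroups <- function(molblock) {
  lines <- strsplit(molblock, "\n", fixed = TRUE)[[1L]]
  if (.isV3000(molblock)) return(.v3000Sgroups(lines))
  types <- list()
  for (ln in grep("^M  STY", lines, value = TRUE)) {
    toks <- strsplit(trimws(sub("^M  STY[ ]*[0-9]+", "", ln)),
                     "[[:space:]]+")[[1L]]
    # pairs of (sgroup index, type)
    if (length(toks) %% 2L != 0L) next
    for (k in seq(1L, length(toks), by = 2L)) {
      types[[toks[[k]]]] <- toks[[k + 1L]]
    }
  }
  if (length(types) == 0L) return(list())
  fieldnames <- list()
  for (ln in grep("^M  SDT", lines, value = TRUE)) {
    m <- regmatches(ln, regexec("^M  SDT +([0-9]+) +(\\S+)", ln))[[1L]]
    if (length(m) == 3L) fieldnames[[m[[2L]]]] <- m[[3L]]
  }
  data <- list()
  for (ln in grep("^M  SED", lines, value = TRUE)) {
    m <- regmatches(ln, regexec("^M  SED +([0-9]+) (.*)$", ln))[[1L]]
    if (length(m) == 3L) {
      idx <- m[[2L]]
      data[[idx]] <- paste0(if (is.null(data[[idx]])) "" else data[[idx]],
                            trimws(m[[3L]], which = "right"))
    }
  }
  lapply(names(types), function(idx) {
    fields <- character(0)
    if (!is.null(fieldnames[[idx]])) fields["FIELDNAME"] <- fieldnames[[idx]]
    if (!is.null(data[[idx]])) fields["DATA"] <- data[[idx]]
    list(type = types[[idx]], fields = fields)
  })
}

.v3000Sgroups <- function(lines) {
  begin <- grep("^M  V30 BEGIN SGROUP", lines)
  end <- grep("^M  V30 END SGROUP", lines)
  if (length(begin) != 1L || length(end) != 1L || end <= begin + 0L) return(list())
  if (end == begin + 1L) return(list())
  sgLines <- lines[(begin + 1L):(end - 1L)]
  lapply(sgLines, function(ln) {
    body <- sub("^M  V30 +", "", ln)
    toks <- strsplit(body, "[[:space:]]+")[[1L]]
    type <- if (length(toks) >= 2L) toks[[2L]] else ""
    fields <- character(0)
    fn <- regmatches(body, regexec("FIELDNAME=(\"[^\"]*\"|\\S+)", body))[[1L]]
    if (length(fn) == 2L) fields["FIELDNAME"] <- gsub("\"", "", fn[[2L]])
    fd <- regmatches(body, regexec("FIELDDATA=(\"[^\"]*\"|\\S+)", body))[[1L]]
    if (length(fd) == 2L) fields["DATA"] <- gsub("\"", "", fd[[2L]])
    list(type = type, fields = fields)
  })
}

# TRUE when any SGroup record is of a polymer type
.hasPolymerSgroup <- function(molblock) {
  sg <- .molblockSgroups(molblock)
  any(vapply(sg, function(s) s$type %in% .POLYMER_SGROUP_TYPES, logical(1)))
}

## V3000 coordinate substitution ---------------------------------------------

# Replace the coordinates in a V3000 mol block with full-precision values
# (used when a registered conformer is retrieved; the template block comes
# from obabel and carries only rounded coordinates).  Numbers are written
# with up to 15 significant digits, which round-trips doubles through
# read/parse exactly in practice.
.v3000WithCoords <- function(molblockV3, coords) {
  lines <- strsplit(molblockV3, "\n", fixed = TRUE)[[1L]]
  begin <- grep("^M  V30 BEGIN ATOM", lines)
  end <- grep("^M  V30 END ATOM", lines)
  if (length(begin) != 1L || length(end) != 1L)
    stop("not a V3000 mol block", call. = FALSE)
  idx <- (begin + 1L):(end - 1L)
  if (length(idx) != nrow(coords))
    stop("coordinate count does not match the atom block", call. = FALSE)
  fmt <- function(x) format(x, digits = 15L, scientific = FALSE, trim = TRUE)
  for (k in seq_along(idx)) {
    ln <- lines[[idx[[k]]]]
    toks <- strsplit(sub("^M  V30 +", "", ln), "[[:space:]]+")[[1L]]
    toks[3:5] <- vapply(coords[k, ], fmt, character(1))
    lines[[idx[[k]]]] <- paste("M  V30", paste(toks, collapse = " "))
  }
  paste(lines, collapse = "\n")
}
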