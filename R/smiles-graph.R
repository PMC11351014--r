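# A small SMILES tokenizer and molecular-graph model.
#
# This operates on OpenBabel *canonical* SMILES only, which keeps the
# grammar small and predictable.  It exists for the graph-level edits no
# installed toolkit exposes from R: building the saturated heavy-atom
# skeleton behind the tautomer-invariant hash layers, neutralizing simple
# charged sites, splitting/selecting fragments, and validating valences.
# It never replaces OpenBabel's canonicalization: every edited SMILES is
# fed back through obabel before it is used.

.ORGANIC_ATOMS <- c("Cl", "Br", "B", "C", "N", "O", "P", "S", "F", "I")
.AROMATIC_ATOMS <- c("b", "c", "n", "o", "p", "s")
.BOND_CHARS <- c("-", "=", "#", "$", ":", "/", "\\")
# heteroelements that trigger tautomer-skeleton saturation
.TAUTOMER_HETS <- c("N", "O", "S", "P", "Se", "Te")

#' Tokenize a SMILES string
#'
#' @param smi a single SMILES string (no title field).
#' @return a list of tokens, each a list with `text` and `type` in
#'   `atom`, `bond`, `ring`, `open`, `close`, `dot`.
#' @noRd
.smilesTokenize <- function(smi) {
  chars <- strsplit(smi, "", fixed = TRUE)[[1L]]
  n <- length(chars)
  tokens <- vector("list", n)
  nt <- 0L
  i <- 1L
  push <- function(text, type) {
    nt <<- nt + 1L
    tokens[[nt]] <<- list(text = text, type = type)
  }
  while (i <= n) {
    ch <- chars[[i]]
    if (ch == "[") {
      j <- i
      while (j <= n && chars[[j]] != "]") j <- j + 1L
      if (j > n) stop("unterminated bracket atom in SMILES: ", smi, call. = FALSE)
      push(paste(chars[i:j], collapse = ""), "atom")
      i <- j + 1L
    } else if (ch %in% c("C", "B") && i < n && chars[[i + 1L]] %in% c("l", "r") &&
               paste0(ch, chars[[i + 1L]]) %in% .ORGANIC_ATOMS) {
      push(paste0(ch, chars[[i + 1L]]), "atom")
      i <- i + 2L
    } else if (ch %in% .ORGANIC_ATOMS || ch %in% .AROMATIC_ATOMS) {
      push(ch, "atom")
      i <- i + 1L
    } else if (ch %in% .BOND_CHARS) {
      push(ch, "bond")
      i <- i + 1L
    } else if (ch == "%") {
      if (i + 2L > n) stop("truncated %nn ring closure in SMILES: ", smi, call. = FALSE)
      push(paste(chars[i:(i + 2L)], collapse = ""), "ring")
      i <- i + 3L
    } else if (grepl("^[0-9]$", ch)) {
      push(ch, "ring")
      i <- i + 1L
    } else if (ch == "(") {
      push(ch, "open"); i <- i + 1L
    } else if (ch == ")") {
      push(ch, "close"); i <- i + 1L
    } else if (ch == ".") {
      push(ch, "dot"); i <- i + 1L
    } else {
      stop("unexpected character '", ch, "' in SMILES: ", smi, call. = FALSE)
    }
  }
  tokens[seq_len(nt)]
}

# Decompose a bracket-atom token like "[13C@@H2+]" into its parts.
.parseBracketAtom <- function(text) {
  inner <- sub("^\\[", "", sub("\\]$", "", text))
  m <- regmatches(inner, regexec(
    "^([0-9]*)([A-Za-z][a-z]?|\\*)(@{0,2})(H[0-9]*)?([+-][0-9]*|[+-]+)?(?::([0-9]+))?$",
    inner))[[1L]]
  if (length(m) == 0L) stop("cannot parse bracket atom ", text, call. = FALSE)
  sym <- m[[3L]]
  hTok <- m[[5L]]
  hcount <- if (!nzchar(hTok)) 0L
            else if (identical(hTok, "H")) 1L
            else as.integer(substring(hTok, 2L))
  chargeTok <- m[[6L]]
  charge <- 0L
  if (nzchar(chargeTok)) {
    if (grepl("^[+-][0-9]+$", chargeTok)) {
      charge <- as.integer(paste0(substr(chargeTok, 1L, 1L), "1")) *
        as.integer(substring(chargeTok, 2L))
    } else {
      charge <- sum(ifelse(strsplit(chargeTok, "")[[1L]] == "+", 1L, -1L))
    }
  }
  list(
    isotope = if (nzchar(m[[2L]])) as.integer(m[[2L]]) else NA_integer_,
    symbol = sym,
    aromatic = sym %in% .AROMATIC_ATOMS,
    chiral = m[[4L]],
    hcount = hcount,
    charge = charge
  )
}

#' Parse a (canonical) SMILES into an editable graph
#'
#' @return a list with `tokens`, and data frame `atoms` (token, element,
#'   aromatic, isotope, chiral, hcount, charge, bracket, fragment) plus
#'   bond list `bonds` (from, to, sym).
#' @noRd
.smilesGraph <- function(smi) {
  tokens <- .smilesTokenize(smi)
  atoms <- list()
  bonds <- list()
  prev <- NA_integer_
  pendingBond <- ""
  stack <- integer(0)
  rings <- list()   # digit -> list(atom, sym)
  frag <- 1L
  for (ti in seq_along(tokens)) {
    tok <- tokens[[ti]]
    if (tok$type == "atom") {
      if (grepl("^\\[", tok$text)) {
        info <- .parseBracketAtom(tok$text)
        bracket <- TRUE
      } else {
        sym <- tok$text
        info <- list(isotope = NA_integer_, symbol = sym,
                     aromatic = sym %in% .AROMATIC_ATOMS,
                     chiral = "", hcount = NA_integer_, charge = 0L)
        bracket <- FALSE
      }
      el <- info$symbol
      substr(el, 1L, 1L) <- toupper(substr(el, 1L, 1L))
      idx <- length(atoms) + 1L
      atoms[[idx]] <- list(token = ti, element = el, aromatic = info$aromatic,
                           isotope = info$isotope, chiral = info$chiral,
                           hcount = info$hcount, charge = info$charge,
                           bracket = bracket, fragment = frag)
      if (!is.na(prev)) {
        bonds[[length(bonds) + 1L]] <- list(from = prev, to = idx,
                                            sym = pendingBond)
      }
      prev <- idx
      pendingBond <- ""
    } else if (tok$type == "bond") {
      pendingBond <- tok$text
    } else if (tok$type == "ring") {
      key <- tok$text
      open <- rings[[key]]
      if (is.null(open)) {
        rings[[key]] <- list(atom = prev, sym = pendingBond)
      } else {
        sym <- if (nzchar(pendingBond)) pendingBond else open$sym
        bonds[[length(bonds) + 1L]] <- list(from = open$atom, to = prev,
                                            sym = sym)
        rings[[key]] <- NULL
      }
      pendingBond <- ""
    } else if (tok$type == "open") {
      stack <- c(stack, prev)
    } else if (tok$type == "close") {
      prev <- stack[[length(stack)]]
      stack <- stack[-length(stack)]
    } else if (tok$type == "dot") {
      prev <- NA_integer_
      frag <- frag + 1L
    }
  }
  atomsDf <- data.frame(
    token = vapply(atoms, `[[`, integer(1), "token"),
    element = vapply(atoms, `[[`, character(1), "element"),
    aromatic = vapply(atoms, `[[`, logical(1), "aromatic"),
    isotope = vapply(atoms, `[[`, integer(1), "isotope"),
    chiral = vapply(atoms, `[[`, character(1), "chiral"),
    hcount = vapply(atoms, `[[`, integer(1), "hcount"),
    charge = vapply(atoms, `[[`, integer(1), "charge"),
    bracket = vapply(atoms, `[[`, logical(1), "bracket"),
    fragment = vapply(atoms, `[[`, integer(1), "fragment"),
    stringsAsFactors = FALSE
  )
  list(smiles = smi, tokens = tokens, atoms = atomsDf, bonds = bonds)
}

# bond order sum per atom (aromatic/unspecified-aromatic bonds counted as
# 1.5, default single as 1), used by the valence check
.bondOrderSums <- function(graph) {
  orders <- c("-" = 1, "=" = 2, "#" = 3, "$" = 4, ":" = 1.5,
              "/" = 1, "\\" = 1)
  sums <- numeric(nrow(graph$atoms))
  for (b in graph$bonds) {
    o <- if (nzchar(b$sym)) {
      orders[[b$sym]]
    } else if (graph$atoms$aromatic[[b$from]] && graph$atoms$aromatic[[b$to]]) {
      1.5
    } else 1
    sums[[b$from]] <- sums[[b$from]] + o
    sums[[b$to]] <- sums[[b$to]] + o
  }
  sums
}

#' Valence sanity check on a canonical SMILES
#'
#' OpenBabel parses hypervalent structures (e.g. a pentavalent carbon)
#' without complaint, so registration-level sanitization enforces maximum
#' valences itself.  Only C, N, O and F are checked -- for these the
#' normal-valence model is unambiguous -- and aromatic atoms are trusted to
#' OpenBabel's aromaticity perception.  Under-valent atoms (radicals) pass.
#'
#' @return TRUE, or a character string describing the violation.
#' @noRd
.checkValences <- function(graph) {
  maxval <- function(el, charge) {
    switch(el,
      C = if (charge == 0L) 4 else 3,
      N = 3 + max(charge, 0L) - max(-charge, 0L),
      O = 2 + charge,
      F = if (charge == 0L) 1 else if (charge < 0L) 0 else 2,
      Inf)
  }
  sums <- .bondOrderSums(graph)
  at <- graph$atoms
  for (i in seq_len(nrow(at))) {
    if (at$aromatic[[i]]) next
    h <- if (is.na(at$hcount[[i]])) 0L else at$hcount[[i]]
    if (!at$bracket[[i]]) next  # organic subset: obabel filled valence
    total <- sums[[i]] + h
    lim <- maxval(at$element[[i]], at$charge[[i]])
    if (total > lim + 1e-9) {
      return(sprintf("atom %d (%s, charge %+d) has valence %g > %g",
                     i, at$element[[i]], at$charge[[i]], total, lim))
    }
  }
  TRUE
}

## Fragment handling ---------------------------------------------------------

# Split a SMILES into top-level fragments (dot-disconnected components).
# Returns a character vector of fragment SMILES.  Ring-closure digits never
# span fragments in canonical OpenBabel output.
.smilesFragments <- function(smi) {
  tokens <- .smilesTokenize(smi)
  out <- character(0)
  buf <- character(0)
  depth <- 0L
  for (tok in tokens) {
    if (tok$type == "dot" && depth == 0L) {
      out <- c(out, paste(buf, collapse = ""))
      buf <- character(0)
    } else {
      if (tok$type == "open") depth <- depth + 1L
      if (tok$type == "close") depth <- depth - 1L
      buf <- c(buf, tok$text)
    }
  }
  c(out, paste(buf, collapse = ""))
}

# Heavy-atom count of a fragment SMILES (explicit [H]/[2H] atoms excluded).
.heavyAtomCount <- function(smi) {
  g <- .smilesGraph(smi)
  sum(!(g$atoms$element %in% c("H")))
}

# TRUE when the fragment contains at least one carbon
.containsCarbon <- function(smi) {
  g <- .smilesGraph(smi)
  any(g$atoms$element == "C")
}

#' Pick the largest fragment
#'
#' Tie-break: heavy atoms, then total atom count (including implicit
#' hydrogens, via the molecular formula), then the lexicographically
#' smallest canonical SMILES.  With `organic = TRUE` only carbon-containing
#' fragments compete; when there are none, all fragments do.
#'
#' @return the chosen fragment's canonical SMILES.
#' @noRd
.largestFragment <- function(smi, organic = FALSE) {
  frags <- .smilesFragments(smi)
  if (length(frags) == 1L) return(frags)
  if (organic) {
    keep <- vapply(frags, .containsCarbon, logical(1))
    if (any(keep)) frags <- frags[keep]
  }
  heavy <- vapply(frags, .heavyAtomCount, numeric(1))
  frags <- frags[heavy == max(heavy)]
  if (length(frags) == 1L) return(frags)
  cf <- .obCanonicalWithFormula(frags)
  total <- vapply(cf$formula, .formulaAtomTotal, numeric(1))
  frags <- frags[total == max(total)]
  if (length(frags) == 1L) return(frags)
  cans <- .obCanonical(frags)
  frags[[order(cans)[[1L]]]]
}

# total atom count from a Hill formula string like "C2H3O2-"
.formulaAtomTotal <- function(formula) {
  if (is.na(formula)) return(0)
  m <- gregexpr("[A-Z][a-z]?([0-9]*)", formula)
  toks <- regmatches(formula, m)[[1L]]
  sum(vapply(toks, function(t) {
    num <- sub("^[A-Z][a-z]?", "", t)
    if (nzchar(num)) as.numeric(num) else 1
  }, numeric(1)))
}

# hydrogen count from a Hill formula string
.formulaHCount <- function(formula) {
  m <- regmatches(formula, regexec("H([0-9]*)([A-Z]|[+-]|$)", formula))[[1L]]
  if (length(m) == 0L) return(0L)
  if (nzchar(m[[2L]])) as.integer(m[[2L]]) else 1L
}

## Tautomer skeleton ---------------------------------------------------------

# Rewrite one fragment's tokens into its saturated heavy-atom skeleton:
# every atom becomes a bracket atom without hydrogens or charges, and all
# bond-order/aromaticity symbols are dropped, so only element identity and
# connectivity survive.  With keepStereo = TRUE, atoms carrying a
# tetrahedral tag keep the tag (and their hydrogen count, so they remain
# 4-connected and the tag stays meaningful after recanonicalization).
.skeletonFragment <- function(fragSmi, keepStereo) {
  g <- .smilesGraph(fragSmi)
  byToken <- setNames(seq_len(nrow(g$atoms)), as.character(g$atoms$token))
  out <- character(0)
  for (ti in seq_along(g$tokens)) {
    tok <- g$tokens[[ti]]
    if (tok$type == "bond") next
    if (tok$type != "atom") {
      out <- c(out, tok$text)
      next
    }
    ai <- byToken[[as.character(ti)]]
    el <- g$atoms$element[[ai]]
    chiral <- g$atoms$chiral[[ai]]
    if (keepStereo && nzchar(chiral)) {
      h <- g$atoms$hcount[[ai]]
      if (is.na(h)) h <- 0L
      hTxt <- if (h == 1L) "H" else if (h > 1L) paste0("H", h) else ""
      out <- c(out, paste0("[", el, chiral, hTxt, "]"))
    } else {
      out <- c(out, paste0("[", el, "]"))
    }
  }
  paste(out, collapse = "")
}

# TRUE when the fragment contains an element that can take part in
# tautomeric proton shifts
.hasTautomerHet <- function(fragSmi) {
  g <- .smilesGraph(fragSmi)
  any(g$atoms$element %in% .TAUTOMER_HETS)
}

#' Tautomer-skeleton SMILES of a whole (multi-fragment) molecule
#'
#' Fragments containing N/O/S/P/Se/Te are collapsed to their saturated
#' skeletons; pure-carbon/halide fragments are left untouched (their bond
#' orders are not tautomerically mobile).  The result is NOT canonical --
#' callers must recanonicalize through obabel.
#' @noRd
.skeletonSmiles <- function(canSmi, keepStereo) {
  frags <- .smilesFragments(canSmi)
  done <- vapply(frags, function(f) {
    if (.hasTautomerHet(f)) .skeletonFragment(f, keepStereo) else f
  }, character(1))
  paste(done, collapse = ".")
}

# net formal charge of a molecule from its SMILES
.netCharge <- function(smi) {
  g <- .smilesGraph(smi)
  sum(g$atoms$charge)
}

## Neutralization ------------------------------------------------------------

# Token-level neutralization of simple charged acid/base sites:
#   [O-]/[S-]/[N-] (and their H-bearing forms) gain a proton,
#   positively charged N/O/S with at least one hydrogen lose one.
# Sites adjacent to an opposite formal charge (nitro groups, N-oxides,
# aminoxides...) are charge-separated resonance forms and are left intact.
# Returns the edited SMILES (not canonical) or the input when nothing
# applies.
.neutralizeSmiles <- function(canSmi) {
  g <- .smilesGraph(canSmi)
  at <- g$atoms
  n <- nrow(at)
  if (n == 0L || all(at$charge == 0L)) return(canSmi)
  neighborCharge <- function(i) {
    vals <- integer(0)
    for (b in g$bonds) {
      if (b$from == i) vals <- c(vals, at$charge[[b$to]])
      if (b$to == i) vals <- c(vals, at$charge[[b$from]])
    }
    vals
  }
  newTokens <- vapply(g$tokens, `[[`, character(1), "text")
  for (i in seq_len(n)) {
    q <- at$charge[[i]]
    if (q == 0L) next
    el <- at$element[[i]]
    h <- at$hcount[[i]]
    if (is.na(h)) h <- 0L
    nb <- neighborCharge(i)
    if (q < 0L && any(nb > 0L)) next
    if (q > 0L && any(nb < 0L)) next
    replacement <- NULL
    if (q == -1L && el %in% c("O", "S", "N")) {
      replacement <- .rewriteAtomToken(at, i, hDelta = +1L)
    } else if (q == 1L && el %in% c("N", "O", "S") && h >= 1L) {
      replacement <- .rewriteAtomToken(at, i, hDelta = -1L)
    }
    if (!is.null(replacement)) newTokens[[at$token[[i]]]] <- replacement
  }
  paste(newTokens, collapse = "")
}

# Rewrite atom i as an uncharged token with its hydrogen count adjusted by
# hDelta.  Plain elements drop back to the organic subset (implicit
# hydrogen filling restores the count); atoms with isotope or stereo
# annotations keep an explicit bracket H count.
.rewriteAtomToken <- function(at, i, hDelta) {
  el <- at$element[[i]]
  iso <- at$isotope[[i]]
  chiral <- at$chiral[[i]]
  arom <- at$aromatic[[i]]
  if (is.na(iso) && !nzchar(chiral)) {
    if (arom) tolower(el) else el
  } else {
    h <- at$hcount[[i]]
    if (is.na(h)) h <- 0L
    h <- max(0L, h + hDelta)
    hTxt <- if (h == 1L) "H" else if (h > 1L) paste0("H", h) else ""
    sym <- if (arom) tolower(el) else el
    paste0("[", if (!is.na(iso)) iso else "", sym, chiral, hTxt, "]")
  }
}
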