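#' @include AllClasses.R conformer-hash.R
NULL

# Deterministic fixture generators.  Everything here is a pure function of
# its seed arguments, so the whole test corpus is reproducible without any
# external data.  Random "molecules" are acyclic single-bonded C/N/O/S
# trees (valence-safe by construction); random conformers are point sets
# in a box -- the conformer-hash contract depends only on coordinates, not
# on chemical plausibility.

# evaluate expr under a temporary RNG state
.withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Curated tautomer pairs
#'
#' Pairs of SMILES that are tautomers of each other: they differ in their
#' canonical SMILES but share the tautomer-invariant hash layers.
#' Includes the classic 2-pyridone / 2-hydroxypyridine lactam-lactim
#' pair, keto-enol pairs, and an imine-enamine pair.
#'
#' @return list of length-2 character vectors.
#' @export
tautomerPairs <- function() {
  list(
    pyridone = c("O=c1cccc[nH]1", "Oc1ccccn1"),
    acetone = c("CC(C)=O", "CC(O)=C"),
    acetaldehyde = c("CC=O", "C=CO"),
    imine = c("CC(=N)C", "CC(N)=C"),
    thiopyridone = c("S=c1cccc[nH]1", "Sc1ccccn1")
  )
}

#' Curated stereoisomer pairs
#'
#' Pairs differing only in stereochemistry: distinct canonical SMILES but
#' identical stereo-free layers.
#'
#' @return list of length-2 character vectors.
#' @export
stereoPairs <- function() {
  list(
    butene = c("C/C=C/C", "C/C=C\\C"),
    dichloroethene = c("Cl/C=C/Cl", "Cl/C=C\\Cl"),
    alanine = c("C[C@H](N)C(=O)O", "C[C@@H](N)C(=O)O"),
    halomethane = c("[C@H](F)(Cl)Br", "[C@@H](F)(Cl)Br")
  )
}

#' Curated salt / neutral-parent pairs
#'
#' Each entry pairs a salt form with its charge parent (largest organic
#' fragment, neutralized): the two registers identically under a
#' `charge_parent` standardization pipeline.
#'
#' @return list of length-2 character vectors `c(salt, parent)`.
#' @export
saltForms <- function() {
  list(
    sodium_acetate = c("[Na+].CC(=O)[O-]", "CC(=O)O"),
    methylammonium_chloride = c("C[NH3+].[Cl-]", "CN"),
    potassium_phenolate = c("[K+].[O-]c1ccccc1", "Oc1ccccc1"),
    sodium_benzoate = c("[Na+].[O-]C(=O)c1ccccc1", "OC(=O)c1ccccc1")
  )
}

# emit a SMILES for a tree molecule by DFS from `root`
.treeSmiles <- function(elements, children, root) {
  emit <- function(node, parent) {
    kids <- setdiff(children[[node]], parent)
    inner <- vapply(kids, function(k) paste0("(", emit(k, node), ")"),
                    character(1))
    paste0(elements[[node]], paste(inner, collapse = ""))
  }
  emit(root, NA_integer_)
}

# one random valence-safe tree molecule; returns list(smiles, alt) -- two
# different serializations of the same structure
.randomTreeMolecule <- function() {
  maxDegree <- c(C = 4L, N = 3L, O = 2L, S = 2L)
  nAtoms <- sample(4:12, 1L)
  elements <- sample(c("C", "C", "C", "C", "N", "O", "S"), nAtoms,
                     replace = TRUE)
  degree <- integer(nAtoms)
  children <- replicate(nAtoms, integer(0), simplify = FALSE)
  adjacency <- replicate(nAtoms, integer(0), simplify = FALSE)
  for (i in seq_len(nAtoms)[-1L]) {
    open <- which(degree[seq_len(i - 1L)] <
                    maxDegree[elements[seq_len(i - 1L)]])
    if (length(open) == 0L) open <- 1L  # C root always has room in practice
    parent <- if (length(open) == 1L) open else sample(open, 1L)
    children[[parent]] <- c(children[[parent]], i)
    adjacency[[parent]] <- c(adjacency[[parent]], i)
    adjacency[[i]] <- c(adjacency[[i]], parent)
    degree[[parent]] <- degree[[parent]] + 1L
    degree[[i]] <- degree[[i]] + 1L
  }
  primary <- .treeSmiles(elements, adjacency, 1L)
  altRoot <- if (nAtoms > 1L) nAtoms else 1L
  alt <- .treeSmiles(elements, adjacency, altRoot)
  list(smiles = primary, alt = alt)
}

#' Random distinct fixture molecules
#'
#' Generates `n` structurally distinct molecules (deduplicated by
#' canonical SMILES), each provided in two different but equivalent
#' serializations: DFS traversals of the same molecular tree from two
#' different roots.
#'
#' @param n number of distinct molecules.
#' @param seed RNG seed; the output is a pure function of `(n, seed)`.
#' @return data.frame with columns `label`, `smiles`, `alt`,
#'   `canonical`.
#' @examples
#' head(randomMolecules(5, seed = 42))
#' @export
randomMolecules <- function(n, seed = 1L) {
  .withSeed(seed, {
    out <- data.frame(label = character(0), smiles = character(0),
                      alt = character(0), canonical = character(0))
    seen <- character(0)
    guard <- 0L
    while (nrow(out) < n && guard < 50L) {
      guard <- guard + 1L
      need <- n - nrow(out)
      cand <- replicate(max(2L * need, 16L), .randomTreeMolecule(),
                        simplify = FALSE)
      can <- .obCanonical(vapply(cand, `[[`, character(1), "smiles"))
      for (k in seq_along(cand)) {
        if (is.na(can[[k]]) || can[[k]] %in% seen) next
        seen <- c(seen, can[[k]])
        out <- rbind(out, data.frame(
          label = sprintf("mol%04d", length(seen)),
          smiles = cand[[k]]$smiles, alt = cand[[k]]$alt,
          canonical = can[[k]]))
        if (nrow(out) == n) break
      }
    }
    if (nrow(out) < n)
      stop("could not generate ", n, " distinct molecules", call. = FALSE)
    rownames(out) <- NULL
    out
  })
}

#' Random conformers
#'
#' Point sets drawn uniformly in a 10 Angstrom box.  With
#' `gridSafe = TRUE` every coordinate is snapped to the `digits`-decimal
#' grid and jittered by less than `0.05 * 10^-digits`, so perturbations
#' below `0.4 * 10^-digits` can never cross a rounding boundary.
#'
#' @param n number of conformers.
#' @param maxAtoms upper bound on atoms per conformer (lower bound 4).
#' @param seed RNG seed.
#' @param gridSafe place coordinates away from rounding boundaries?
#' @param digits rounding precision the safety margin refers to.
#' @return list of n x 3 coordinate matrices.
#' @export
randomConformers <- function(n, maxAtoms = 30L, seed = 1L,
                             gridSafe = FALSE, digits = 3L) {
  .withSeed(seed, {
    lapply(seq_len(n), function(i) {
      na <- sample(4:maxAtoms, 1L)
      m <- matrix(stats::runif(na * 3L, -5, 5), ncol = 3L)
      if (gridSafe) {
        m <- round(m, digits) +
          matrix(stats::runif(na * 3L, -0.05, 0.05) * 10^(-digits),
                 ncol = 3L)
      }
      m
    })
  })
}

# distance of each coordinate to its nearest rounding boundary, in units
# of the grid spacing 10^-digits
.boundaryDistance <- function(coords, digits = 3L) {
  f <- abs(coords) * 10^digits
  abs(f - floor(f) - 0.5)
}

# smallest relative gap between principal moments (0 for degenerate tops)
.principalGap <- function(coords) {
  centered <- sweep(coords, 2L, colMeans(coords))
  ev <- eigen(crossprod(centered) / nrow(centered), symmetric = TRUE,
              only.values = TRUE)$values
  if (ev[[1L]] <= 0) return(0)
  min(abs(diff(ev))) / ev[[1L]]
}

#' Random conformers safe for orientation-canonicalized hashing
#'
#' Rejection-samples conformers whose canonical orientation is
#' numerically stable: (i) clearly separated principal moments (an
#' asymmetric top, so the principal axes are well defined), (ii) a clear
#' winner in the per-axis sign rule (the two largest projection
#' magnitudes along each axis are well separated), and (iii) every
#' canonical coordinate comfortably farther from a rounding boundary
#' than the ~1e-9 Angstrom reproducibility of re-canonicalizing after a
#' rigid transform.  For such conformers,
#' `conformerHash(canonicalizeOrientation(.))` is invariant under
#' arbitrary rigid-body motion.
#'
#' @inheritParams randomConformers
#' @return list of n x 3 coordinate matrices (already canonically
#'   oriented).
#' @export
orientationSafeConformers <- function(n, maxAtoms = 12L, seed = 1L,
                                      digits = 3L) {
  .withSeed(seed, {
    out <- vector("list", 0L)
    guard <- 0L
    while (length(out) < n && guard < 500L * n) {
      guard <- guard + 1L
      na <- sample(5:maxAtoms, 1L)
      m <- matrix(stats::runif(na * 3L, -5, 5), ncol = 3L)
      canon <- canonicalizeOrientation(m)
      if (.principalGap(canon) < 0.05) next
      signSafe <- all(vapply(1:2, function(k) {
        p <- sort(abs(canon[, k]), decreasing = TRUE)
        length(p) < 2L || (p[[1L]] - p[[2L]]) > 1e-4
      }, logical(1)))
      if (!signSafe) next
      if (min(.boundaryDistance(canon, digits)) < 1e-5) next
      out[[length(out) + 1L]] <- canon
    }
    if (length(out) < n)
      stop("could not sample ", n, " orientation-safe conformers",
           call. = FALSE)
    out
  })
}

#' Random rigid-body transform of a conformer
#'
#' Applies a uniformly random proper rotation and a random translation;
#' all pairwise interatomic distances are preserved.
#'
#' @param coords n x 3 coordinate matrix.
#' @param seed RNG seed.
#' @return transformed n x 3 matrix.
#' @export
rigidTransform <- function(coords, seed = 1L) {
  coords <- .checkCoords(coords)
  .withSeed(seed, {
    qr <- qr(matrix(stats::rnorm(9L), 3L))
    rot <- qr.Q(qr)
    rot <- rot %*% diag(sign(diag(qr.R(qr))))
    if (det(rot) < 0) rot[, 1L] <- -rot[, 1L]
    shift <- stats::runif(3L, -3, 3)
    sweep(coords %*% rot, 2L, shift, `+`)
  })
}

#' Random coordinate perturbation
#'
#' Adds independent uniform noise in `(-epsilon, epsilon)` to every
#' coordinate; `epsilon = 0` returns the input unchanged.
#'
#' @param coords n x 3 coordinate matrix.
#' @param epsilon non-negative noise bound (Angstrom).
#' @param seed RNG seed.
#' @return perturbed n x 3 matrix.
#' @export
perturbCoordinates <- function(coords, epsilon, seed = 1L) {
  coords <- .checkCoords(coords)
  stopifnot(epsilon >= 0)
  if (epsilon == 0) return(coords)
  .withSeed(seed, {
    coords + matrix(stats::runif(length(coords), -epsilon, epsilon),
                    ncol = 3L) * (1 - 1e-9)
  })
}

## Hand-built mol blocks -----------------------------------------------------

# assemble a V2000 mol block from atoms/bonds/property lines
.v2000Block <- function(elements, coords, bonds = NULL, mLines = character(0),
                        title = "fixture", dim = "2D") {
  nA <- length(elements)
  nB <- if (is.null(bonds)) 0L else nrow(bonds)
  header <- c(title,
              sprintf("%-20s%2s", "  chemregistry", dim),
              "")
  counts <- sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", nA, nB)
  atomLines <- vapply(seq_len(nA), function(i) {
    sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
            coords[i, 1L], coords[i, 2L], coords[i, 3L], elements[[i]])
  }, character(1))
  bondLines <- if (nB > 0L) {
    vapply(seq_len(nB), function(i) {
      sprintf("%3d%3d%3d  0  0  0  0", bonds[i, 1L], bonds[i, 2L],
              bonds[i, 3L])
    }, character(1))
  } else character(0)
  paste(c(header, counts, atomLines, bondLines, mLines, "M  END"),
        collapse = "\n")
}

#' Pathological and special-case mol block fixtures
#'
#' Hand-built V2000 blocks exercising the standardization filters and
#' SGroup handling: a structure with two coincident atoms, an SRU polymer
#' SGroup, DAT SGroups (the same data listed in two different orders), a
#' pentavalent carbon, a Kekule-form benzene, and a small 3D ethanol
#' conformer.
#'
#' @return named list of mol block strings.
#' @export
pathologicalMolblocks <- function() {
  ethCoords2d <- matrix(c(0, 0, 0, 1, 0, 0, 1.5, 0.87, 0), ncol = 3L,
                        byrow = TRUE)
  ethBonds <- matrix(c(1L, 2L, 1L, 2L, 3L, 1L), ncol = 3L, byrow = TRUE)
  overlapping <- .v2000Block(
    c("C", "C", "O"),
    matrix(c(0, 0, 0, 0, 0, 0, 1.5, 0.87, 0), ncol = 3L, byrow = TRUE),
    ethBonds, title = "overlapping atoms")
  polymer <- .v2000Block(
    c("C", "C", "O"), ethCoords2d, ethBonds,
    mLines = c("M  STY  1   1 SRU"), title = "SRU polymer")
  datSgroup <- .v2000Block(
    c("C", "C", "O"), ethCoords2d, ethBonds,
    mLines = c("M  STY  1   1 DAT",
               "M  SDT   1 pH",
               "M  SED   1 7.4"),
    title = "DAT sgroup")
  datTwo <- .v2000Block(
    c("C", "C", "O"), ethCoords2d, ethBonds,
    mLines = c("M  STY  2   1 DAT   2 DAT",
               "M  SDT   1 pH",
               "M  SED   1 7.4",
               "M  SDT   2 temperature",
               "M  SED   2 25"),
    title = "two DAT sgroups")
  datTwoReordered <- .v2000Block(
    c("C", "C", "O"), ethCoords2d, ethBonds,
    mLines = c("M  STY  2   1 DAT   2 DAT",
               "M  SDT   1 temperature",
               "M  SED   1 25",
               "M  SDT   2 pH",
               "M  SED   2 7.4"),
    title = "two DAT sgroups, reordered")
  penta <- .v2000Block(
    c("C", "C", "C", "C", "C", "C"),
    matrix(c(0, 0, 0, 1, 0, 0, -1, 0, 0, 0, 1, 0, 0, -1, 0, 0, 0.5, 0.87),
           ncol = 3L, byrow = TRUE),
    matrix(c(1L, 2L, 1L, 1L, 3L, 1L, 1L, 4L, 1L, 1L, 5L, 1L, 1L, 6L, 1L),
           ncol = 3L, byrow = TRUE),
    title = "pentavalent carbon")
  hexagon <- t(vapply(0:5, function(k) {
    a <- pi / 3 * k
    c(cos(a), sin(a), 0)
  }, numeric(3)))
  benzene <- .v2000Block(
    rep("C", 6L), hexagon,
    matrix(c(1L, 2L, 2L, 2L, 3L, 1L, 3L, 4L, 2L, 4L, 5L, 1L,
             5L, 6L, 2L, 6L, 1L, 1L), ncol = 3L, byrow = TRUE),
    title = "kekule benzene")
  ethanol3d <- .v2000Block(
    c("C", "C", "O"),
    matrix(c(-0.8816, 0.1701, -0.0108,
             0.5850, 0.5539, 0.0011,
             1.3903, -0.6047, 0.0148), ncol = 3L, byrow = TRUE),
    ethBonds, title = "ethanol 3D", dim = "3D")
  list(overlapping_atoms = overlapping,
       polymer_sru = polymer,
       dat_sgroup = datSgroup,
       dat_sgroup_pair = datTwo,
       dat_sgroup_pair_reordered = datTwoReordered,
       pentavalent_carbon = penta,
       kekule_benzene = benzene,
       ethanol_3d = ethanol3d)
}

#' Write fixture molecules to SMILES / SDF files
#'
#' Emits the curated pairs as a SMILES file and the pathological mol
#' blocks as an SDF into a directory, for use outside R.
#'
#' @param dir output directory (created if needed).
#' @return the directory path, invisibly.
#' @export
writeFixtureFiles <- function(dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pairs <- c(tautomerPairs(), stereoPairs(), saltForms())
  lines <- unlist(lapply(names(pairs), function(nm)
    paste(pairs[[nm]], paste0(nm, c("_a", "_b")))))
  writeLines(lines, file.path(dir, "pairs.smi"))
  blocks <- pathologicalMolblocks()
  writeLines(paste(vapply(blocks, identity, character(1)), "$$$$",
                   sep = "\n", collapse = "\n"),
             file.path(dir, "pathological.sdf"))
  invisible(dir)
}
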