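# Core structural operations on the Molecule graph: accessors, conjugation
# perception, structural alerts, Bemis-Murcko scaffolds and circular
# fingerprints.

#' @rdname Molecule-class
#' @param object,x a Molecule.
#' @export
setGeneric("smiles", function(x) standardGeneric("smiles"))
#' @rdname Molecule-class
#' @export
setMethod("smiles", "Molecule", function(x) x@smiles)

#' @rdname Molecule-class
#' @export
setGeneric("molName", function(x) standardGeneric("molName"))
#' @rdname Molecule-class
#' @export
setMethod("molName", "Molecule", function(x) x@name)

#' @rdname Molecule-class
#' @export
setGeneric("atomTable", function(x) standardGeneric("atomTable"))
#' @rdname Molecule-class
#' @export
setMethod("atomTable", "Molecule", function(x) x@atoms)

#' @rdname Molecule-class
#' @export
setGeneric("bondTable", function(x) standardGeneric("bondTable"))
#' @rdname Molecule-class
#' @export
setMethod("bondTable", "Molecule", function(x) x@bonds)

setMethod("show", "Molecule", function(object) {
  nm <- if (nzchar(object@name)) paste0(" (", object@name, ")") else ""
  cat("Molecule", paste0(object@smiles, nm), "|",
      nrow(object@atoms), "atoms,", nrow(object@bonds), "bonds\n")
})

# ---- ring perception -------------------------------------------------------

# logical vector over bonds: TRUE if the bond lies on a ring (not a bridge)
.ringBonds <- function(mol) {
  b <- mol@bonds
  if (nrow(b) == 0L) return(logical(0))
  g <- igraph::graph_from_edgelist(as.matrix(b[, c("a1", "a2")]),
                                   directed = FALSE)
  br <- igraph::bridges(g)
  res <- rep(TRUE, nrow(b))
  res[as.integer(br)] <- FALSE
  res
}

.ringAtoms <- function(mol) {
  rb <- .ringBonds(mol)
  sort(unique(c(mol@bonds$a1[rb], mol@bonds$a2[rb])))
}

# ---- conjugation -----------------------------------------------------------

# pi atoms: aromatic, or carrying a double/triple bond
.piAtoms <- function(mol) {
  a <- mol@atoms; b <- mol@bonds
  pi <- a$aromatic
  if (nrow(b) > 0L) {
    multi <- b$order >= 2L & !b$aromatic
    pi[unique(c(b$a1[multi], b$a2[multi]))] <- TRUE
  }
  pi
}

# lone-pair donors: non-aromatic N/O/S/P with only single bonds, a free lone
# pair (charge <= 0, fewer than 4 connections)
.lonePairDonors <- function(mol) {
  a <- mol@atoms; b <- mol@bonds
  deg <- tabulate(c(b$a1, b$a2), nbins = nrow(a))
  multi <- rep(FALSE, nrow(a))
  if (nrow(b) > 0L) {
    m <- b$order >= 2L & !b$aromatic
    multi[unique(c(b$a1[m], b$a2[m]))] <- TRUE
  }
  a$element %in% c("N", "O", "S", "P") & !a$aromatic & !multi &
    a$charge <= 0L & deg < 4L
}

# logical over bonds: conjugated per pi-perception
.conjugatedBonds <- function(mol) {
  b <- mol@bonds
  if (nrow(b) == 0L) return(logical(0))
  pi <- .piAtoms(mol)
  lp <- .lonePairDonors(mol)
  conj <- b$aromatic | b$order >= 2L
  single <- !conj
  p1 <- pi[b$a1]; p2 <- pi[b$a2]
  l1 <- lp[b$a1]; l2 <- lp[b$a2]
  conj | (single & ((p1 & p2) | (p1 & l2) | (p2 & l1)))
}

#' Fraction of conjugated bonds
#'
#' The rigidity descriptor theta_conjugation: the number of heavy-atom bonds
#' participating in a pi-conjugated system divided by the total number of
#' heavy-atom bonds. Hydrogens are excluded from both counts. A bond counts
#' as conjugated when it is aromatic, has order >= 2, or is a single bond
#' between two pi atoms (or a pi atom and a lone-pair donor heteroatom).
#'
#' @param mol a [Molecule-class].
#' @return numeric in [0, 1]; a molecule without heavy-atom bonds returns 0.
#' @examples
#' fractionConjugated(parseSmiles("c1ccccc1"))   # 1
#' fractionConjugated(parseSmiles("CC"))         # 0
#' fractionConjugated(parseSmiles("CCc1ccccc1")) # 0.75
#' @export
setGeneric("fractionConjugated", function(mol) {
  standardGeneric("fractionConjugated")
})

#' @rdname fractionConjugated
#' @export
setMethod("fractionConjugated", "Molecule", function(mol) {
  nb <- nrow(mol@bonds)
  if (nb == 0L) {
    message("single-atom molecule: theta_conjugation defined as 0")
    return(0)
  }
  sum(.conjugatedBonds(mol)) / nb
})

# ---- structural alerts -----------------------------------------------------

#' Names of the built-in alert predicates
#'
#' Graph predicates implementing the default exclusion motifs; referenced in
#' an [AlertCatalog-class] as \code{"builtin:<name>"}.
#'
#' @return character vector of predicate keys.
#' @export
builtinAlertPredicates <- function() {
  c("carbonyl", "het_het_bond", "aliphatic_amine", "alcohol", "olefin")
}

.alertPredicate <- function(key, mol) {
  a <- mol@atoms; b <- mol@bonds
  if (nrow(b) == 0L && key != "alcohol") return(FALSE)
  deg <- tabulate(c(b$a1, b$a2), nbins = nrow(a))
  hasMulti <- rep(FALSE, nrow(a))
  if (nrow(b) > 0L) {
    m <- b$order >= 2L & !b$aromatic
    hasMulti[unique(c(b$a1[m], b$a2[m]))] <- TRUE
  }
  aromNbr <- rep(FALSE, nrow(a))
  if (nrow(b) > 0L) {
    aromNbr[b$a1[a$aromatic[b$a2]]] <- TRUE
    aromNbr[b$a2[a$aromatic[b$a1]]] <- TRUE
  }
  het <- c("N", "O", "S", "P")
  switch(key,
    carbonyl = any(b$order == 2L & !b$aromatic &
                   ((a$element[b$a1] == "C" & a$element[b$a2] == "O") |
                    (a$element[b$a1] == "O" & a$element[b$a2] == "C"))),
    het_het_bond = any(b$order <= 2L &
                       a$element[b$a1] %in% het & a$element[b$a2] %in% het),
    aliphatic_amine = any(a$element == "N" & !a$aromatic & !hasMulti &
                          a$charge == 0L & !aromNbr & deg >= 1L),
    alcohol = any(a$element == "O" & !a$aromatic & a$hcount >= 1L &
                  !hasMulti & deg == 1L &
                  a$element[.soleNeighbor(b, which(
                    a$element == "O" & !a$aromatic & a$hcount >= 1L &
                    !hasMulti & deg == 1L))] == "C"),
    olefin = any(b$order == 2L & !b$aromatic &
                 a$element[b$a1] == "C" & a$element[b$a2] == "C"),
    stop("unknown builtin alert: ", key, call. = FALSE)
  )
}

.soleNeighbor <- function(b, idx) {
  vapply(idx, function(i) {
    k <- which(b$a1 == i | b$a2 == i)[1]
    if (is.na(k)) return(NA_integer_)
    if (b$a1[k] == i) b$a2[k] else b$a1[k]
  }, integer(1))
}

#' Construct an alert catalog
#'
#' @param names character vector of unique alert names.
#' @param patterns character vector: \code{"builtin:<key>"} or SMARTS
#'   (SMARTS requires the \code{obabel} binary on PATH).
#' @return an [AlertCatalog-class].
#' @export
alertCatalog <- function(names, patterns) {
  new("AlertCatalog",
      alerts = data.frame(name = names, pattern = patterns,
                          stringsAsFactors = FALSE))
}

#' The default structural-alert catalog
#'
#' The five motifs vetoed in the exploration campaign: carbonyls (HAT-prone
#' aryl ketones among them), heteroatom-heteroatom single/double bonds,
#' aliphatic amines, alcohols, and non-aromatic olefins (ring olefins
#' included, since olefin photodecomposition is not ring-specific).
#'
#' @return an [AlertCatalog-class].
#' @export
defaultAlertCatalog <- function() {
  keys <- builtinAlertPredicates()
  alertCatalog(keys, paste0("builtin:", keys))
}

#' An empty alert catalog (no vetoes)
#' @return an [AlertCatalog-class] with zero alerts.
#' @export
emptyAlertCatalog <- function() {
  new("AlertCatalog", alerts = data.frame(name = character(0),
                                          pattern = character(0)))
}

#' Match structural alerts against a molecule
#'
#' Returns the names of every alert in the catalog with at least one
#' substructure match; an empty vector means the molecule is clean. Built-in
#' alerts are evaluated as graph predicates; SMARTS patterns are matched via
#' the OpenBabel command-line tool.
#'
#' @param mol a [Molecule-class].
#' @param catalog an [AlertCatalog-class]; default the five-motif catalog.
#' @return character vector of matched alert names.
#' @examples
#' matchAlerts(parseSmiles("O=C(c1ccccc1)c1ccccc1"))  # "carbonyl"
#' matchAlerts(parseSmiles("c1ccccc1"))               # character(0)
#' @export
setGeneric("matchAlerts", function(mol, catalog = defaultAlertCatalog()) {
  standardGeneric("matchAlerts")
})

#' @rdname matchAlerts
#' @export
setMethod("matchAlerts", "Molecule", function(mol, catalog) {
  validObject(catalog)
  al <- catalog@alerts
  hit <- vapply(seq_len(nrow(al)), function(i) {
    p <- al$pattern[i]
    if (startsWith(p, "builtin:")) {
      .alertPredicate(sub("^builtin:", "", p), mol)
    } else {
      .smartsMatch(mol@smiles, p)
    }
  }, logical(1))
  al$name[hit]
})

# SMARTS matching through the obabel CLI (used for user-supplied patterns)
.smartsMatch <- function(smi, smarts) {
  ob <- Sys.which("obabel")
  if (!nzchar(ob))
    stop("SMARTS alert patterns require the 'obabel' binary on PATH",
         call. = FALSE)
  out <- suppressWarnings(system2(
    ob, c(paste0("-:", shQuote(smi)), "-osmi", "-s", shQuote(smarts)),
    stdout = TRUE, stderr = FALSE))
  any(nzchar(trimws(out)))
}

# ---- scaffolds -------------------------------------------------------------

#' Bemis-Murcko scaffold of a molecule
#'
#' Removes side chains, keeping ring systems and the linkers between them.
#' Terminal atoms attached by a double bond to a retained atom are kept, so
#' exocyclic carbonyls (e.g. the thioxanthone ketone) stay part of the
#' scaffold. Exactly one scaffold - the maximal framework of the largest
#' fragment - is assigned per molecule.
#'
#' Modes generalize the scaffold stepwise: \code{"murcko"} keeps atom
#' identities and bond orders; \code{"generic_bonds"} sets every bond to a
#' single bond (keeping elements); \code{"fully_generic"} additionally maps
#' every atom to carbon, retaining only the framework topology.
#'
#' @param mol a [Molecule-class].
#' @param mode one of \code{"murcko"}, \code{"generic_bonds"},
#'   \code{"fully_generic"}.
#' @return canonical scaffold SMILES (character); the empty string \code{""}
#'   is the sentinel for acyclic molecules. The mode is attached as the
#'   \code{"mode"} attribute.
#' @examples
#' murckoScaffold(parseSmiles("CCc1ccccc1"))  # "c1ccccc1"
#' murckoScaffold(parseSmiles("CCCCCC"))      # "" (acyclic)
#' @export
setGeneric("murckoScaffold", function(mol, mode = "murcko") {
  standardGeneric("murckoScaffold")
})

#' @rdname murckoScaffold
#' @export
setMethod("murckoScaffold", "Molecule", function(mol, mode) {
  mode <- match.arg(mode, c("murcko", "generic_bonds", "fully_generic"))
  a <- mol@atoms; b <- mol@bonds
  if (nrow(b) == 0L) return(structure("", mode = mode))
  # largest fragment only
  if (nrow(b) > 0L || nrow(a) > 1L) {
    g <- igraph::graph_from_edgelist(as.matrix(b[, c("a1", "a2")]),
                                     directed = FALSE)
    g <- igraph::add_vertices(g, max(0L, nrow(a) - igraph::vcount(g)))
    comp <- igraph::components(g)
    keepFrag <- which(comp$membership == which.max(comp$csize))
    sel <- b$a1 %in% keepFrag & b$a2 %in% keepFrag
    idx <- match(seq_len(nrow(a)), keepFrag)
    a <- a[keepFrag, , drop = FALSE]
    b <- data.frame(a1 = idx[b$a1[sel]], a2 = idx[b$a2[sel]],
                    order = b$order[sel], aromatic = b$aromatic[sel])
  }
  sub <- new("Molecule", smiles = "", name = "", atoms = a, bonds = b)
  if (length(.ringAtoms(sub)) == 0L) {
    return(structure("", mode = mode))
  }
  # iteratively prune terminal atoms attached by a plain single bond
  repeat {
    deg <- tabulate(c(b$a1, b$a2), nbins = nrow(a))
    bondOf <- function(i) which(b$a1 == i | b$a2 == i)[1]
    drop <- which(deg == 1L &
                  vapply(seq_len(nrow(a)), function(i) {
                    if (deg[i] != 1L) return(FALSE)
                    k <- bondOf(i)
                    b$order[k] == 1L && !b$aromatic[k]
                  }, logical(1)))
    if (length(drop) == 0L) break
    keep <- setdiff(seq_len(nrow(a)), drop)
    idx <- match(seq_len(nrow(a)), keep)
    sel <- !(b$a1 %in% drop | b$a2 %in% drop)
    a <- a[keep, , drop = FALSE]
    b <- data.frame(a1 = idx[b$a1[sel]], a2 = idx[b$a2[sel]],
                    order = b$order[sel], aromatic = b$aromatic[sel])
  }
  if (mode %in% c("generic_bonds", "fully_generic")) {
    b$order <- 1L; b$aromatic <- FALSE
    a$aromatic <- FALSE; a$charge <- 0L
    if (mode == "fully_generic") a$element <- "C"
    for (i in seq_len(nrow(a)))
      a$hcount[i] <- .implicitH(a$element[i], FALSE, b, i)
  } else {
    # re-derive hydrogen counts where pruning removed substituents
    for (i in seq_len(nrow(a))) {
      if (a$element[i] %in% .ORGANIC && a$charge[i] == 0L)
        a$hcount[i] <- .implicitH(a$element[i], a$aromatic[i], b, i)
    }
  }
  s <- .writeSmilesGraph(a, b)
  can <- canonicalSmiles(s, strict = FALSE)
  if (is.na(can)) can <- s  # generic frameworks may refuse re-perception
  structure(can, mode = mode)
})

# ---- fingerprints ----------------------------------------------------------

.HASH_MOD <- 2147483647

.hashCombine <- function(h, v) ((h * 31) %% .HASH_MOD + v) %% .HASH_MOD

#' Circular (Morgan-style) fingerprint
#'
#' A deterministic ECFP-like bit vector: atom invariants (element, degree,
#' hydrogen count, charge, aromaticity) are iteratively combined with sorted
#' neighbor invariants for \code{radius} rounds, and every environment
#' identifier is folded into \code{nbits} bits. Identical molecules give
#' identical vectors on any platform.
#'
#' @param mol a [Molecule-class].
#' @param radius neighborhood radius (default 2).
#' @param nbits fingerprint length (default 2048).
#' @return logical vector of length \code{nbits}.
#' @export
setGeneric("morganFingerprint", function(mol, radius = 2L, nbits = 2048L) {
  standardGeneric("morganFingerprint")
})

#' @rdname morganFingerprint
#' @export
setMethod("morganFingerprint", "Molecule", function(mol, radius, nbits) {
  a <- mol@atoms; b <- mol@bonds
  n <- nrow(a)
  deg <- tabulate(c(b$a1, b$a2), nbins = n)
  elemCode <- match(a$element, c("C", "N", "O", "S", "P", "F", "Cl", "Br",
                                 "I", "B"), nomatch = 11L)
  inv <- (((elemCode * 8 + deg) * 8 + pmin(a$hcount, 7L)) * 8 +
            (a$charge + 4L)) * 2 + as.integer(a$aromatic)
  inv <- inv %% .HASH_MOD
  nbrList <- vector("list", n)
  if (nrow(b) > 0L) {
    code <- ifelse(b$aromatic, 4L, b$order)
    for (k in seq_len(nrow(b))) {
      nbrList[[b$a1[k]]] <- rbind(nbrList[[b$a1[k]]], c(code[k], b$a2[k]))
      nbrList[[b$a2[k]]] <- rbind(nbrList[[b$a2[k]]], c(code[k], b$a1[k]))
    }
  }
  ids <- inv
  cur <- inv
  for (r in seq_len(radius)) {
    nxt <- numeric(n)
    for (i in seq_len(n)) {
      nb <- nbrList[[i]]
      h <- .hashCombine(r, cur[i])
      if (!is.null(nb)) {
        pairs <- cbind(nb[, 1], cur[nb[, 2]])
        ord <- order(pairs[, 1], pairs[, 2])
        for (j in ord) {
          h <- .hashCombine(h, pairs[j, 1] * 1e6 + pairs[j, 2] %% 1e6)
          h <- .hashCombine(h, pairs[j, 2])
        }
      }
      nxt[i] <- h
    }
    cur <- nxt
    ids <- c(ids, cur)
  }
  bits <- rep(FALSE, nbits)
  bits[(ids %% nbits) + 1] <- TRUE
  bits
})

#' Tanimoto similarity between two fingerprints
#'
#' @param fp1,fp2 logical vectors of equal length.
#' @return numeric in [0, 1]; two all-zero vectors return 1.
#' @export
tanimotoSimilarity <- function(fp1, fp2) {
  stopifnot(length(fp1) == length(fp2))
  inter <- sum(fp1 & fp2)
  uni <- sum(fp1 | fp2)
  if (uni == 0L) return(1)
  inter / uni
}
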