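# Desk-scale pi-electronic structure: Hueckel solver and the excited-state
# proxies built on it (HOMO-LUMO overlap, singlet-triplet gap, golden-rule
# ISC rate, gap-based lambda_max).

#' Default Hueckel heteroatom parameters
#'
#' Standard Streitwieser/Van Catledge-type Coulomb shifts h_X and C-X bond
#' scalings k_CX (dimensionless, in units of beta). Types N1/O1/S1/P1 denote
#' one-pi-electron atoms (pyridine-like N, carbonyl O), N2/O2/S2/P2 the
#' two-electron lone-pair donors (pyrrole N, furan O). Bond scalings between
#' two heteroatoms are formed as k_XY = k_CX * k_CY. The Br and I entries are
#' conventional extensions of the Van Catledge set. All values can be
#' overridden via [readHuckelParameters()].
#'
#' @return data.frame with columns \code{type}, \code{h}, \code{k}.
#' @export
huckelParameters <- function() {
  data.frame(
    type = c("C", "N1", "N2", "O1", "O2", "S1", "S2", "P1", "P2",
             "F", "Cl", "Br", "I", "B"),
    h = c(0.00, 0.51, 1.37, 0.97, 2.09, 0.46, 1.11, 0.19, 0.75,
          2.71, 1.48, 1.50, 1.35, -0.45),
    k = c(1.00, 1.02, 0.89, 1.06, 0.66, 0.81, 0.69, 0.77, 0.76,
          0.52, 0.62, 0.54, 0.45, 0.73),
    stringsAsFactors = FALSE)
}

#' Read a Hueckel parameter table from YAML
#'
#' Expected layout: a list of records with fields \code{type}, \code{h},
#' \code{k}, as written by [writeHuckelParameters()].
#'
#' @param path YAML file.
#' @return data.frame with columns \code{type}, \code{h}, \code{k}.
#' @export
readHuckelParameters <- function(path) {
  rec <- yaml::read_yaml(path)
  out <- do.call(rbind, lapply(rec, function(r)
    data.frame(type = r$type, h = as.numeric(r$h), k = as.numeric(r$k),
               stringsAsFactors = FALSE)))
  if (!all(c("C") %in% out$type)) stop("parameter table must define type C")
  out
}

#' @rdname readHuckelParameters
#' @param params parameter data.frame to serialize.
#' @export
writeHuckelParameters <- function(params, path) {
  rec <- lapply(seq_len(nrow(params)), function(i)
    list(type = params$type[i], h = params$h[i], k = params$k[i]))
  yaml::write_yaml(rec, path, precision = 15)
}

# classify each pi atom: list(type=, electrons=)
.piAtomType <- function(a, idx, hasPiDouble, deg) {
  el <- a$element[idx]
  if (hasPiDouble) {
    type <- switch(el, C = "C", N = "N1", O = "O1", S = "S1", P = "P1", el)
    return(list(type = type, electrons = 1L))
  }
  if (a$aromatic[idx]) {
    base <- switch(el,
      C = 1L,
      N = if (a$hcount[idx] > 0L || deg >= 3L) 2L else 1L,
      P = if (a$hcount[idx] > 0L || deg >= 3L) 2L else 1L,
      O = 2L, S = 2L, B = 0L, 1L)
    e <- max(0L, min(2L, base - a$charge[idx]))
    type <- switch(el, C = "C", B = "B",
                   N = if (base == 2L) "N2" else "N1",
                   P = if (base == 2L) "P2" else "P1",
                   O = "O2", S = "S2", el)
    return(list(type = type, electrons = e))
  }
  # lone-pair donor entering through a conjugated single bond
  type <- switch(el, N = "N2", O = "O2", S = "S2", P = "P2",
                 F = "F", Cl = "Cl", Br = "Br", I = "I", el)
  list(type = type, electrons = 2L)
}

#' Extract the conjugated pi system of a molecule
#'
#' Collects the largest connected component of the conjugated-bond subgraph
#' (see [fractionConjugated()] for the perception rule), assigns Hueckel
#' heteroatom parameters from the table, and counts pi electrons: atoms in
#' localized double/triple bonds contribute one electron, aromatic atoms one
#' or two depending on their lone-pair situation, and sp3 lone-pair donors
#' two.
#'
#' @param mol a [Molecule-class].
#' @param params parameter table, see [huckelParameters()].
#' @param betaEV energy scale |beta| in eV (default 2.4).
#' @return a [PiSystem-class].
#' @examples
#' sys <- buildPiSystem(parseSmiles("c1ccccc1"))
#' piElectrons(sys)  # 6
#' @export
setGeneric("buildPiSystem",
  function(mol, params = huckelParameters(), betaEV = 2.4) {
    standardGeneric("buildPiSystem")
  })

#' @rdname buildPiSystem
#' @export
setMethod("buildPiSystem", "Molecule", function(mol, params, betaEV) {
  b <- mol@bonds
  conj <- .conjugatedBonds(mol)
  if (sum(conj) == 0L)
    stop("no conjugation: molecule has no pi system", call. = FALSE)
  cb <- b[conj, , drop = FALSE]
  g <- igraph::graph_from_edgelist(as.matrix(cb[, c("a1", "a2")]),
                                   directed = FALSE)
  comp <- igraph::components(g)
  members <- which(comp$membership == which.max(comp$csize))
  sel <- cb$a1 %in% members & cb$a2 %in% members
  cb <- cb[sel, , drop = FALSE]
  atomIdx <- sort(unique(c(cb$a1, cb$a2)))
  local <- match(seq_len(nrow(mol@atoms)), atomIdx)
  a <- mol@atoms
  deg <- tabulate(c(b$a1, b$a2), nbins = nrow(a))
  piDouble <- rep(FALSE, nrow(a))
  m <- cb$order >= 2L & !cb$aromatic
  piDouble[unique(c(cb$a1[m], cb$a2[m]))] <- TRUE
  types <- character(length(atomIdx))
  electrons <- integer(length(atomIdx))
  for (j in seq_along(atomIdx)) {
    i <- atomIdx[j]
    cls <- .piAtomType(a, i, piDouble[i], deg[i])
    types[j] <- cls$type
    electrons[j] <- cls$electrons
  }
  look <- function(t, col) {
    v <- params[[col]][match(t, params$type)]
    v[is.na(v)] <- if (col == "h") 0 else 1
    v
  }
  hShift <- look(types, "h")
  kAtom <- look(types, "k")
  adj <- cbind(local[cb$a1], local[cb$a2])
  bondScale <- kAtom[adj[, 1]] * kAtom[adj[, 2]]
  ne <- sum(electrons)
  if (ne %% 2L != 0L)
    stop("odd pi-electron count (", ne, "): open-shell system", call. = FALSE)
  new("PiSystem", atomIdx = as.integer(atomIdx),
      elements = a$element[atomIdx], hShift = hShift,
      adjacency = adj, bondScale = bondScale,
      nElectrons = as.integer(ne), betaEV = betaEV)
})

#' @rdname PiSystem-class
#' @param x a PiSystem.
#' @export
piElectrons <- function(x) x@nElectrons

#' @rdname PiSystem-class
#' @export
piAtomIndices <- function(x) x@atomIdx

setMethod("show", "PiSystem", function(object) {
  cat("PiSystem:", length(object@atomIdx), "atoms,",
      nrow(object@adjacency), "pi bonds,", object@nElectrons,
      "electrons | beta =", object@betaEV, "eV\n")
})

#' Solve the Hueckel eigenproblem
#'
#' Diagonalizes the dimensionless Hueckel matrix (diagonal h_X, off-diagonal
#' k_XY on pi bonds) and converts eigenvalues x to orbital energies
#' E = -x |beta| in eV (alpha = 0), ascending. Coefficient columns are
#' unit-norm eigenvectors over the pi atoms.
#'
#' @param system a [PiSystem-class].
#' @return an [OrbitalSet-class].
#' @examples
#' orb <- solveHuckel(buildPiSystem(parseSmiles("C=C")))
#' homoLumoGap(orb)  # 2 * 2.4 eV
#' @export
setGeneric("solveHuckel", function(system) standardGeneric("solveHuckel"))

#' @rdname solveHuckel
#' @export
setMethod("solveHuckel", "PiSystem", function(system) {
  n <- length(system@atomIdx)
  H <- matrix(0, n, n)
  diag(H) <- system@hShift
  for (k in seq_len(nrow(system@adjacency))) {
    i <- system@adjacency[k, 1]; j <- system@adjacency[k, 2]
    H[i, j] <- H[i, j] + system@bondScale[k]
    H[j, i] <- H[i, j]
  }
  eig <- eigen(H, symmetric = TRUE)
  # eigen() returns descending x; E = -x*beta is then ascending
  energies <- -eig$values * system@betaEV
  coeff <- eig$vectors
  nocc <- system@nElectrons %/% 2L
  if (nocc < 1L || nocc >= n)
    stop("pi system has no frontier orbital pair (", nocc, " of ", n,
         " orbitals occupied)", call. = FALSE)
  new("OrbitalSet", energies = energies, coefficients = coeff,
      homoIndex = nocc, lumoIndex = nocc + 1L,
      nElectrons = system@nElectrons)
})

#' @rdname OrbitalSet-class
#' @param x an OrbitalSet.
#' @export
orbitalEnergies <- function(x) x@energies

#' @rdname OrbitalSet-class
#' @export
orbitalCoefficients <- function(x) x@coefficients

#' @rdname OrbitalSet-class
#' @export
homoIndex <- function(x) x@homoIndex

#' @rdname OrbitalSet-class
#' @export
lumoIndex <- function(x) x@lumoIndex

#' @rdname OrbitalSet-class
#' @export
homoLumoGap <- function(x) x@energies[x@lumoIndex] - x@energies[x@homoIndex]

setMethod("show", "OrbitalSet", function(object) {
  cat("OrbitalSet:", length(object@energies), "orbitals | HOMO",
      object@homoIndex, sprintf("(%.3f eV),", object@energies[object@homoIndex]),
      "LUMO", object@lumoIndex,
      sprintf("(%.3f eV), gap %.3f eV\n", object@energies[object@lumoIndex],
              homoLumoGap(object)))
})

#' HOMO-LUMO spatial overlap O_FMO
#'
#' Atom-condensed density overlap between the frontier orbitals:
#' O_FMO = sum_a sqrt(rho_H(a) * rho_L(a)) with rho_X(a) the squared orbital
#' coefficient on atom a. Bounded in [0, 1] by Cauchy-Schwarz; 1 when the
#' LUMO density equals the HOMO density, 0 for disjoint supports. When the
#' HOMO and/or LUMO is degenerate (within \code{degeneracyTol} eV, e.g.
#' benzene), the overlap is averaged over all frontier pairs, which removes
#' the arbitrariness of eigenvectors within a degenerate block.
#'
#' @param orbitals an [OrbitalSet-class].
#' @param degeneracyTol degeneracy window in eV (default 1e-6).
#' @return numeric O_FMO in [0, 1].
#' @export
setGeneric("fmoOverlap", function(orbitals, degeneracyTol = 1e-6) {
  standardGeneric("fmoOverlap")
})

#' @rdname fmoOverlap
#' @export
setMethod("fmoOverlap", "OrbitalSet", function(orbitals, degeneracyTol) {
  e <- orbitals@energies
  h <- orbitals@homoIndex; l <- orbitals@lumoIndex
  hset <- which(seq_along(e) <= h & abs(e - e[h]) < degeneracyTol)
  lset <- which(seq_along(e) >= l & abs(e - e[l]) < degeneracyTol)
  vals <- outer(hset, lset, Vectorize(function(i, j) {
    rh <- orbitals@coefficients[, i]^2
    rl <- orbitals@coefficients[, j]^2
    sum(sqrt(rh * rl))
  }))
  min(1, mean(vals))
})

#' Singlet-triplet gap proxy from O_FMO
#'
#' Linear map Delta_E_ST = intercept + slope * O_FMO, floored at zero. The
#' exchange interaction that dominates the S1-T1 splitting shrinks with the
#' spatial HOMO-LUMO overlap, so the slope must be non-negative; the
#' calibration (slope, intercept) is configuration, not a shipped fit.
#'
#' @param o_fmo overlap in [0, 1].
#' @param slope eV per unit overlap, >= 0.
#' @param intercept eV.
#' @return Delta_E_S1-T1 in eV (>= 0).
#' @export
deltaEstProxy <- function(o_fmo, slope, intercept = 0) {
  if (slope < 0)
    stop("negative slope would invert the overlap-exchange monotonicity",
         call. = FALSE)
  pmax(0, intercept + slope * o_fmo)
}

#' Golden-rule intersystem-crossing rate proxy
#'
#' k_ISC proportional to SOC^2 / Delta_E_ST^2 with unit proportionality
#' constant. SOC is never computed from structure here; it enters as an
#' explicit input or a configured constant.
#'
#' @param soc spin-orbit coupling, arbitrary units.
#' @param delta_e_st singlet-triplet gap in eV, > 0.
#' @return rate proxy (arbitrary units, >= 0).
#' @export
kiscGoldenRule <- function(soc, delta_e_st) {
  if (any(delta_e_st <= 0))
    stop("delta_e_st must be > 0 (resonance case outside the model)",
         call. = FALSE)
  soc^2 / delta_e_st^2
}

#' Classify excited-state character from O_FMO
#'
#' Low frontier-orbital overlap indicates charge-transfer (CT) character,
#' high overlap a locally excited (LE) state. Values exactly at the
#' threshold classify as LE.
#'
#' @param o_fmo overlap in [0, 1].
#' @param threshold decision boundary in (0, 1); default 0.5 (uncalibrated).
#' @return "CT" or "LE" (vectorized).
#' @export
classifyCharacter <- function(o_fmo, threshold = 0.5) {
  stopifnot(threshold > 0, threshold < 1)
  ifelse(o_fmo < threshold, "CT", "LE")
}

#' Absorption wavelength estimate from the HOMO-LUMO gap
#'
#' Photon energy-wavelength conversion lambda = 1239.84 / gap_eV in nm,
#' applied to the Hueckel frontier gap. A desk-scale stand-in for learned or
#' semiempirical lambda_max predictors.
#'
#' @param orbitals an [OrbitalSet-class].
#' @return lambda_max in nm.
#' @export
setGeneric("lambdaMaxFromGap", function(orbitals) {
  standardGeneric("lambdaMaxFromGap")
})

#' @rdname lambdaMaxFromGap
#' @export
setMethod("lambdaMaxFromGap", "OrbitalSet", function(orbitals) {
  gap <- homoLumoGap(orbitals)
  if (gap <= 0) stop("non-positive HOMO-LUMO gap", call. = FALSE)
  1239.84 / gap
})

#' Dump an orbital set to CSV
#'
#' Long format: one row per (atom, orbital) pair with the coefficient, plus
#' the orbital energy.
#'
#' @param orbitals an [OrbitalSet-class].
#' @param path output CSV path.
#' @export
writeOrbitalCSV <- function(orbitals, path) {
  co <- orbitals@coefficients
  df <- expand.grid(atom = seq_len(nrow(co)), orbital = seq_len(ncol(co)))
  df$coefficient <- co[cbind(df$atom, df$orbital)]
  df$energy_eV <- orbitals@energies[df$orbital]
  utils::write.csv(df, path, row.names = FALSE)
}
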