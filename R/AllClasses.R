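#' @import methods
#' @importFrom stats setNames runif
#' @importFrom utils head read.table write.table read.csv write.csv
NULL

#' Molecule: a parsed molecular graph with its canonical SMILES
#'
#' The universal currency of the package. A \code{Molecule} holds the
#' OpenBabel-canonical SMILES string together with an explicit heavy-atom
#' graph: one row per atom (element, aromaticity, formal charge, attached
#' hydrogen count) and one row per bond (endpoint indices, integer order,
#' aromatic flag). Hydrogens are implicit everywhere; all structural
#' operations (alerts, scaffolds, conjugation, fingerprints, pi systems)
#' work on this graph.
#'
#' @slot smiles canonical SMILES string.
#' @slot name optional identifier ("" when absent).
#' @slot atoms data.frame with columns \code{element}, \code{aromatic},
#'   \code{charge}, \code{hcount}.
#' @slot bonds data.frame with columns \code{a1}, \code{a2}, \code{order},
#'   \code{aromatic}. Zero-row for single-atom molecules.
#'
#' @seealso [parseSmiles()], [canonicalSmiles()]
#' @export
setClass("Molecule",
  representation(smiles = "character", name = "character",
                 atoms = "data.frame", bonds = "data.frame"),
  prototype(smiles = NA_character_, name = "",
            atoms = data.frame(), bonds = data.frame()))

setValidity("Molecule", function(object) {
  msg <- character()
  if (length(object@smiles) != 1L) msg <- c(msg, "smiles must be length 1")
  need_a <- c("element", "aromatic", "charge", "hcount")
  if (!all(need_a %in% names(object@atoms)))
    msg <- c(msg, "atoms must have element/aromatic/charge/hcount")
  if (nrow(object@bonds) > 0L) {
    need_b <- c("a1", "a2", "order", "aromatic")
    if (!all(need_b %in% names(object@bonds)))
      msg <- c(msg, "bonds must have a1/a2/order/aromatic")
    else if (any(object@bonds$a1 > nrow(object@atoms)) ||
             any(object@bonds$a2 > nrow(object@atoms)))
      msg <- c(msg, "bond endpoint out of range")
  }
  if (length(msg)) msg else TRUE
})

#' Structural-alert catalog
#'
#' Named substructure alerts used as hard vetoes in reward scoring. The
#' default catalog covers the five motifs excluded from the exploration
#' campaign: carbonyl groups, single/double bonds between two heteroatoms,
#' aliphatic amines, alcohols, and non-aromatic olefins. Each alert is either
#' a built-in graph predicate (names listed by [builtinAlertPredicates()]) or
#' a SMARTS pattern matched through the OpenBabel command line tool.
#'
#' @slot alerts data.frame with columns \code{name} and \code{pattern};
#'   \code{pattern} is either \code{"builtin:<key>"} or a SMARTS string.
#' @export
setClass("AlertCatalog", representation(alerts = "data.frame"))

setValidity("AlertCatalog", function(object) {
  a <- object@alerts
  if (!all(c("name", "pattern") %in% names(a)))
    return("alerts needs columns name, pattern")
  if (anyDuplicated(a$name)) return("alert names must be unique")
  builtin <- grepl("^builtin:", a$pattern)
  bad <- a$pattern[builtin][!sub("^builtin:", "", a$pattern[builtin]) %in%
                              builtinAlertPredicates()]
  if (length(bad)) return(paste("unknown builtin alert:", bad[1]))
  TRUE
})

#' Conjugated pi system with Hueckel parameters
#'
#' The conjugated subgraph of a molecule annotated with dimensionless
#' Hueckel heteroatom parameters: Coulomb shifts h_X (diagonal, in units of
#' beta) and bond scalings k_XY (off-diagonal), plus the energy scale |beta|
#' in eV and the pi-electron count.
#'
#' @slot atomIdx integer indices into the parent molecule's atom table.
#' @slot elements element label per pi atom.
#' @slot hShift numeric Coulomb shift h_X per atom (units of beta).
#' @slot adjacency two-column integer matrix of pi bonds (local indices).
#' @slot bondScale numeric k_XY per pi bond.
#' @slot nElectrons even integer pi-electron count.
#' @slot betaEV positive numeric, |beta| in eV.
#' @export
setClass("PiSystem",
  representation(atomIdx = "integer", elements = "character",
                 hShift = "numeric", adjacency = "matrix",
                 bondScale = "numeric", nElectrons = "integer",
                 betaEV = "numeric"))

setValidity("PiSystem", function(object) {
  n <- length(object@atomIdx)
  if (length(object@hShift) != n) return("hShift length mismatch")
  if (nrow(object@adjacency) != length(object@bondScale))
    return("bondScale length mismatch")
  if (n > 0 && nrow(object@adjacency) > 0 &&
      max(object@adjacency) > n) return("adjacency index out of range")
  if (object@nElectrons %% 2L != 0L)
    return("odd pi-electron count: open-shell systems are not supported")
  if (object@betaEV <= 0) return("betaEV must be positive")
  TRUE
})

#' Solved Hueckel molecular orbitals
#'
#' Eigenvectors and eigenvalues of the Hueckel matrix. Energies are in eV on
#' the scale E = -x |beta| with the Coulomb reference alpha at zero, sorted
#' ascending; coefficient columns are unit-norm and mutually orthogonal.
#'
#' @slot energies numeric vector, eV, ascending.
#' @slot coefficients numeric matrix, one column per orbital over pi atoms.
#' @slot homoIndex,lumoIndex integer positions of the frontier orbitals.
#' @slot nElectrons integer pi-electron count used for the filling.
#' @export
setClass("OrbitalSet",
  representation(energies = "numeric", coefficients = "matrix",
                 homoIndex = "integer", lumoIndex = "integer",
                 nElectrons = "integer"))

setValidity("OrbitalSet", function(object) {
  if (is.unsorted(object@energies, strictly = FALSE))
    return("energies must be ascending")
  if (ncol(object@coefficients) != length(object@energies))
    return("one coefficient column per energy required")
  if (object@lumoIndex != object@homoIndex + 1L)
    return("lumoIndex must be homoIndex + 1 for a closed shell")
  TRUE
})

#' Property transform onto [0, 1]
#'
#' One reward component's mapping from a raw property value to a score in
#' [0, 1]: rising/falling sigmoids, a band-pass double sigmoid (product of a
#' rising sigmoid at the lower edge and a falling one at the upper edge), or
#' hard step indicators.
#'
#' @slot kind one of "sigmoid_up", "sigmoid_down", "double_sigmoid",
#'   "step_up", "step_down".
#' @slot center numeric: one center (sigmoids/steps) or band c(lo, hi).
#' @slot steepness positive numeric k, per property unit.
#' @export
setClass("Transform",
  representation(kind = "character", center = "numeric",
                 steepness = "numeric"))

setValidity("Transform", function(object) {
  kinds <- c("sigmoid_up", "sigmoid_down", "double_sigmoid",
             "step_up", "step_down")
  if (!object@kind %in% kinds)
    return(paste("kind must be one of:", paste(kinds, collapse = ", ")))
  nc <- if (object@kind == "double_sigmoid") 2L else 1L
  if (length(object@center) != nc)
    return(sprintf("kind %s needs %d center value(s)", object@kind, nc))
  if (nc == 2L && object@center[1] >= object@center[2])
    return("double_sigmoid band must satisfy c_lo < c_hi")
  if (object@steepness <= 0) return("steepness must be positive")
  TRUE
})

#' Multi-objective reward specification
#'
#' An ordered list of (property, transform, weight) components, a
#' structural-alert veto catalog, and the aggregation mode. The total score
#' of a non-vetoed molecule is the weight-normalized geometric mean
#' S = prod(s_i ^ (w_i / sum(w))) (or the raw product when
#' \code{normalizeWeights} is FALSE); any matched alert forces S = 0.
#'
#' @slot components data.frame with columns \code{property}, \code{weight}.
#' @slot transforms list of [Transform-class] objects, one per component.
#' @slot alerts an [AlertCatalog-class] (possibly empty).
#' @slot normalizeWeights logical, geometric-mean aggregation when TRUE.
#' @export
setClass("RewardSpec",
  representation(components = "data.frame", transforms = "list",
                 alerts = "AlertCatalog", normalizeWeights = "logical"))

setValidity("RewardSpec", function(object) {
  cmp <- object@components
  if (!all(c("property", "weight") %in% names(cmp)))
    return("components needs columns property, weight")
  if (nrow(cmp) == 0L) return("at least one reward component required")
  if (any(cmp$weight < 0) || sum(cmp$weight) <= 0)
    return("weights must be non-negative with positive sum")
  if (length(object@transforms) != nrow(cmp))
    return("one transform per component required")
  if (!all(vapply(object@transforms, is, TRUE, "Transform")))
    return("transforms must be Transform objects")
  TRUE
})

#' Property predictor
#'
#' A named, deterministic map from a [Molecule-class] to one photophysical
#' property value. Backends: lookup tables keyed by canonical SMILES
#' ([lookupPredictor()]), Hueckel proxies ([huckelPredictor()]), or constants
#' ([constantPredictor()]). A predictor returning \code{NA} marks a missing
#' prediction; the scoring loop maps that to score 0 while triage treats it
#' as an error.
#'
#' @slot name predictor label recorded in provenance.
#' @slot property the property this predictor supplies.
#' @slot fun function(Molecule) -> numeric(1) (NA allowed).
#' @export
setClass("Predictor",
  representation(name = "character", property = "character",
                 fun = "function"))

#' Genetic-algorithm configuration
#'
#' Run parameters of the seedable generative optimizer. All randomness in a
#' run flows from \code{seed}; two runs with the same configuration produce
#' identical trajectories.
#'
#' @slot populationSize,generations,tournamentSize,elitism integer counts.
#' @slot mutationRate,crossoverRate numeric rates in [0, 1].
#' @slot seed integer RNG seed (mandatory).
#' @slot scaffoldBucketLimit integer; max rewarded molecules per scaffold
#'   before the diversity filter zeroes further ones (Inf disables).
#' @slot scaffoldMode scaffold key mode used by the diversity filter.
#' @export
setClass("GAConfig",
  representation(populationSize = "integer", generations = "integer",
                 mutationRate = "numeric", crossoverRate = "numeric",
                 tournamentSize = "integer", elitism = "integer",
                 seed = "integer", scaffoldBucketLimit = "numeric",
                 scaffoldMode = "character"))

setValidity("GAConfig", function(object) {
  if (object@populationSize < 1L || object@generations < 1L ||
      object@tournamentSize < 1L || object@elitism < 0L)
    return("counts must be >= 1 (elitism >= 0)")
  if (object@mutationRate < 0 || object@mutationRate > 1 ||
      object@crossoverRate < 0 || object@crossoverRate > 1)
    return("rates must lie in [0, 1]")
  if (is.na(object@seed)) return("seed is mandatory")
  if (object@scaffoldBucketLimit < 1) return("scaffoldBucketLimit must be >= 1")
  if (!object@scaffoldMode %in% c("murcko", "generic_bonds", "fully_generic"))
    return("unknown scaffold mode")
  TRUE
})

#' Generation trajectory of a GA run
#'
#' Per-generation record of every evaluated molecule with its properties,
#' component scores, raw and diversity-adjusted total scores, and scaffold
#' key. Supports the score-density and cumulative-scaffold-occurrence
#' analytics of the generative campaigns.
#'
#' @slot table data.frame with one row per evaluated molecule; columns
#'   include \code{generation}, \code{smiles}, \code{score},
#'   \code{adjusted_score}, \code{scaffold}, \code{vetoes}.
#' @slot config the [GAConfig-class] that produced the run.
#' @export
setClass("GenerationTrajectory",
  representation(table = "data.frame", config = "GAConfig"))

setValidity("GenerationTrajectory", function(object) {
  need <- c("generation", "smiles", "score", "adjusted_score", "scaffold")
  if (!all(need %in% names(object@table)))
    return(paste("trajectory table needs columns:",
                 paste(need, collapse = ", ")))
  TRUE
})
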