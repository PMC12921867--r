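# Uniform property-predictor interface: the reward engine and the triage
# funnel are agnostic to whether a property comes from a lookup table, the
# Hueckel proxies, or an external adapter registered by name.

#' Canonical property names
#'
#' The photophysical quantities a PropertyVector can carry: adiabatic
#' triplet energy delta_e_t (kcal/mol), absorption maxima lambda_max and
#' lambda_max_stda (nm), conjugated-bond fraction theta_conjugation ([0,1]),
#' frontier-orbital overlap o_fmo ([0,1]), and the rates k_isc and k_f
#' (1/s or proxy units).
#'
#' @return character vector of property names.
#' @export
propertyNames <- function() {
  c("delta_e_t", "lambda_max", "lambda_max_stda", "theta_conjugation",
    "o_fmo", "k_isc", "k_f")
}

#' Construct a predictor
#'
#' @param name predictor label (recorded in provenance).
#' @param property one of [propertyNames()].
#' @param fun function(Molecule) -> numeric(1); return NA for a missing
#'   prediction.
#' @return a [Predictor-class].
#' @export
predictor <- function(name, property, fun) {
  stopifnot(property %in% propertyNames())
  new("Predictor", name = name, property = property, fun = fun)
}

setMethod("show", "Predictor", function(object) {
  cat("Predictor", object@name, "->", object@property, "\n")
})

#' Evaluate a predictor on one molecule
#'
#' @param pred a [Predictor-class].
#' @param mol a [Molecule-class].
#' @return numeric(1), NA for a missing prediction.
#' @export
predictProperty <- function(pred, mol) {
  v <- tryCatch(pred@fun(mol), error = function(e) NA_real_)
  if (length(v) != 1L || !is.numeric(v)) NA_real_ else as.numeric(v)
}

#' Lookup-table predictor
#'
#' Returns precomputed values keyed by canonical SMILES - the package's
#' stand-in for external ML property models, and the test oracle for the
#' scoring pipeline. A miss returns \code{default} (NA marks the prediction
#' missing; the triage policy turns that into a hard error, the generative
#' policy into score 0).
#'
#' @param property one of [propertyNames()].
#' @param table named numeric vector: names are SMILES (canonicalized here),
#'   values the property.
#' @param default value for a miss; \code{NA} (the default) marks the
#'   prediction as missing.
#' @param name predictor label.
#' @return a [Predictor-class].
#' @examples
#' p <- lookupPredictor("delta_e_t", c("c1ccccc1" = 84.0))
#' predictProperty(p, parseSmiles("c1ccccc1"))  # 84
#' @export
lookupPredictor <- function(property, table, default = NA_real_,
                            name = paste0("lookup:", property)) {
  keys <- canonicalSmiles(names(table), strict = TRUE)
  vals <- as.numeric(table)
  predictor(name, property, function(mol) {
    i <- match(mol@smiles, keys)
    if (is.na(i)) default else vals[i]
  })
}

#' Lookup predictors from a property CSV
#'
#' Builds one lookup predictor per property column of a CSV with a
#' \code{smiles} column (see [readMoleculeCSV()]).
#'
#' @param path CSV path.
#' @param properties which columns to use; default every recognized
#'   property column present.
#' @param default miss value, as in [lookupPredictor()].
#' @return named list of [Predictor-class] objects.
#' @export
lookupPredictorsFromCSV <- function(path, properties = NULL,
                                    default = NA_real_) {
  df <- readMoleculeCSV(path)
  if (is.null(properties))
    properties <- intersect(propertyNames(), names(df))
  out <- lapply(properties, function(p) {
    lookupPredictor(p, stats::setNames(df[[p]], df$smiles), default = default)
  })
  stats::setNames(out, properties)
}

#' Hueckel-based predictor
#'
#' Chains [buildPiSystem()] -> [solveHuckel()] -> property extraction for
#' \code{lambda_max} (gap conversion) or \code{o_fmo} (frontier overlap).
#' Molecules without a usable pi system yield the sentinel value (default
#' NA, the score-0 pathway) instead of crashing a scoring loop.
#'
#' @param property "lambda_max" or "o_fmo".
#' @param params Hueckel parameter table.
#' @param betaEV energy scale |beta| in eV.
#' @param sentinel value returned when no pi system exists (default NA).
#' @return a [Predictor-class].
#' @examples
#' p <- huckelPredictor("lambda_max")
#' predictProperty(p, parseSmiles("c1ccccc1"))  # 258.3 nm at beta = 2.4 eV
#' @export
huckelPredictor <- function(property = c("lambda_max", "o_fmo"),
                            params = huckelParameters(), betaEV = 2.4,
                            sentinel = NA_real_) {
  property <- match.arg(property)
  predictor(paste0("huckel:", property), property, function(mol) {
    orb <- tryCatch(solveHuckel(buildPiSystem(mol, params, betaEV)),
                    error = function(e) NULL)
    if (is.null(orb)) return(sentinel)
    if (property == "lambda_max") {
      tryCatch(lambdaMaxFromGap(orb), error = function(e) sentinel)
    } else {
      fmoOverlap(orb)
    }
  })
}

#' Conjugated-fraction predictor
#'
#' Wraps [fractionConjugated()] as a predictor for theta_conjugation.
#'
#' @return a [Predictor-class].
#' @export
thetaPredictor <- function() {
  predictor("chemgraph:theta", "theta_conjugation",
            function(mol) suppressMessages(fractionConjugated(mol)))
}

#' Constant predictor
#'
#' Supplies a configured constant (e.g. an assumed SOC-derived rate) for
#' every molecule.
#'
#' @param property one of [propertyNames()].
#' @param value the constant.
#' @return a [Predictor-class].
#' @export
constantPredictor <- function(property, value) {
  predictor(paste0("const:", property), property, function(mol) value)
}

#' Batch property prediction
#'
#' Evaluates a set of predictors over a list of molecules. Order-preserving;
#' per-molecule failures are recorded as NA with provenance, never raised.
#'
#' @param mols list of [Molecule-class] objects (NULL entries allowed: they
#'   produce all-NA rows flagged \code{invalid}).
#' @param predictors list of [Predictor-class] objects.
#' @return data.frame with columns \code{smiles}, \code{name}, one column
#'   per predicted property, and a \code{provenance} attribute (data.frame
#'   of predictor names per property, plus per-row \code{invalid} flags in
#'   column \code{invalid}).
#' @export
batchPredict <- function(mols, predictors) {
  props <- vapply(predictors, function(p) p@property, character(1))
  if (anyDuplicated(props))
    stop("multiple predictors registered for: ",
         paste(unique(props[duplicated(props)]), collapse = ", "),
         call. = FALSE)
  n <- length(mols)
  out <- data.frame(
    smiles = vapply(mols, function(m) if (is.null(m)) NA_character_
                    else m@smiles, character(1)),
    name = vapply(mols, function(m) if (is.null(m)) "" else m@name,
                  character(1)),
    invalid = vapply(mols, is.null, logical(1)),
    stringsAsFactors = FALSE)
  for (j in seq_along(predictors)) {
    out[[props[j]]] <- vapply(mols, function(m) {
      if (is.null(m)) NA_real_ else predictProperty(predictors[[j]], m)
    }, numeric(1))
  }
  attr(out, "provenance") <- stats::setNames(
    vapply(predictors, function(p) p@name, character(1)), props)
  out
}
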