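# The multi-objective reward: per-property transforms onto [0,1], weighted
# multiplicative aggregation, and hard structural vetoes.

#' Construct a property transform
#'
#' @param kind one of "sigmoid_up", "sigmoid_down", "double_sigmoid",
#'   "step_up", "step_down".
#' @param center threshold/midpoint in property units; for
#'   \code{double_sigmoid} a band \code{c(lo, hi)}.
#' @param steepness sigmoid steepness k per property unit. The default
#'   scales k so the sigmoid rises over about 10 percent of the center value
#'   (k = 2 ln 9 / (0.1 |center|)); steps ignore it.
#' @return a [Transform-class].
#' @examples
#' applyTransform(58, scoreTransform("sigmoid_up", 58))    # 0.5 at the midpoint
#' applyTransform(366, scoreTransform("step_up", 365))     # 1
#' @export
scoreTransform <- function(kind, center, steepness = NULL) {
  if (is.null(steepness)) {
    width <- 0.1 * max(abs(center[1]), .Machine$double.eps)
    steepness <- 2 * log(9) / width
  }
  new("Transform", kind = kind, center = as.numeric(center),
      steepness = as.numeric(steepness))
}

setMethod("show", "Transform", function(object) {
  cat("Transform", object@kind, "@",
      paste(signif(object@center, 4), collapse = ".."),
      "k =", signif(object@steepness, 3), "\n")
})

.sigmoid <- function(x, c, k) 1 / (1 + exp(-k * (x - c)))

#' Apply a transform to property values
#'
#' sigmoid_up: 1/(1+exp(-k(x-c))); sigmoid_down its mirror; double_sigmoid:
#' product of a rising sigmoid at the band's lower edge and a falling one at
#' the upper edge; step_up/step_down: strict-threshold indicators. Output is
#' always in [0, 1].
#'
#' @param x numeric property values (finite).
#' @param t a [Transform-class].
#' @return scores in [0, 1], same length as \code{x}.
#' @export
applyTransform <- function(x, t) {
  stopifnot(is(t, "Transform"))
  k <- t@steepness
  switch(t@kind,
    sigmoid_up = .sigmoid(x, t@center[1], k),
    sigmoid_down = 1 - .sigmoid(x, t@center[1], k),
    double_sigmoid = .sigmoid(x, t@center[1], k) *
                     (1 - .sigmoid(x, t@center[2], k)),
    step_up = as.numeric(x > t@center[1]),
    step_down = as.numeric(x < t@center[1]))
}

#' Aggregate component scores into a total score
#'
#' Weight-normalized geometric aggregation S = prod(s_i^(w_i/sum(w))), or the
#' raw weighted product prod(s_i^w_i) when \code{normalize} is FALSE. A veto
#' forces S = 0. The normalized form is bounded by the smallest and largest
#' component score and equals c whenever all components equal c, making
#' scores comparable across reward specs with different component counts.
#'
#' @param scores numeric vector of component scores in [0, 1].
#' @param weights non-negative weights, same length, positive sum.
#' @param vetoed logical; TRUE short-circuits to 0.
#' @param normalize use normalized exponents (default TRUE).
#' @return total score S in [0, 1].
#' @export
aggregateScores <- function(scores, weights = rep(1, length(scores)),
                            vetoed = FALSE, normalize = TRUE) {
  if (vetoed) return(0)
  if (length(scores) != length(weights))
    stop("scores and weights must have equal length", call. = FALSE)
  if (any(weights < 0) || sum(weights) <= 0)
    stop("weights must be non-negative with positive sum", call. = FALSE)
  if (any(is.na(scores)) || any(scores < 0 | scores > 1))
    stop("component scores must lie in [0, 1]", call. = FALSE)
  w <- if (normalize) weights / sum(weights) else weights
  prod(scores^w)
}

#' Construct a reward specification
#'
#' @param properties character vector of component property names
#'   (see [propertyNames()]).
#' @param transforms list of [Transform-class], one per property.
#' @param weights non-negative component weights (default all 1).
#' @param alerts an [AlertCatalog-class] of hard vetoes (default: none).
#' @param normalizeWeights geometric-mean aggregation (default TRUE).
#' @return a [RewardSpec-class].
#' @export
rewardSpec <- function(properties, transforms,
                       weights = rep(1, length(properties)),
                       alerts = emptyAlertCatalog(),
                       normalizeWeights = TRUE) {
  new("RewardSpec",
      components = data.frame(property = properties, weight = weights,
                              stringsAsFactors = FALSE),
      transforms = transforms, alerts = alerts,
      normalizeWeights = normalizeWeights)
}

setMethod("show", "RewardSpec", function(object) {
  cat("RewardSpec:", nrow(object@components), "components |",
      nrow(object@alerts@alerts), "alert(s) |",
      if (object@normalizeWeights) "geometric mean" else "raw product", "\n")
  for (i in seq_len(nrow(object@components))) {
    t <- object@transforms[[i]]
    cat(sprintf("  %-18s w=%g %s @ %s\n", object@components$property[i],
                object@components$weight[i], t@kind,
                paste(signif(t@center, 4), collapse = "..")))
  }
})

#' Named reward presets
#'
#' Threshold sets of the four campaign stages, shipped as ready-made reward
#' specs (sigmoid centers at the published thresholds, steepness rising over
#' ~10 percent of each threshold; exact weights and steepnesses are package
#' choices, the thresholds are not):
#' \describe{
#'   \item{rediscovery}{delta_e_t > 58 kcal/mol, lambda_max > 365 nm,
#'     theta_conjugation > 0.5 (step); no structural vetoes.}
#'   \item{exploration}{delta_e_t > 55, lambda_max > 330, theta > 0.5 (step),
#'     plus an O_FMO component rewarding LOW overlap (falling sigmoid at
#'     0.5); full five-alert veto catalog.}
#'   \item{global-triage}{delta_e_t > 60, lambda_max > 350,
#'     lambda_max_stda > 325 (steps); no vetoes (post-generation filter).}
#'   \item{local-lead}{delta_e_t > 57, lambda_max > 290 (steps); no vetoes.}
#' }
#'
#' @param name preset name.
#' @return a [RewardSpec-class].
#' @export
rewardPreset <- function(name = c("rediscovery", "exploration",
                                  "global-triage", "local-lead")) {
  name <- match.arg(name)
  switch(name,
    rediscovery = rewardSpec(
      c("delta_e_t", "lambda_max", "theta_conjugation"),
      list(scoreTransform("sigmoid_up", 58), scoreTransform("sigmoid_up", 365),
           scoreTransform("step_up", 0.5))),
    exploration = rewardSpec(
      c("delta_e_t", "lambda_max", "theta_conjugation", "o_fmo"),
      list(scoreTransform("sigmoid_up", 55), scoreTransform("sigmoid_up", 330),
           scoreTransform("step_up", 0.5), scoreTransform("sigmoid_down", 0.5)),
      alerts = defaultAlertCatalog()),
    `global-triage` = rewardSpec(
      c("delta_e_t", "lambda_max", "lambda_max_stda"),
      list(scoreTransform("step_up", 60), scoreTransform("step_up", 350),
           scoreTransform("step_up", 325))),
    `local-lead` = rewardSpec(
      c("delta_e_t", "lambda_max"),
      list(scoreTransform("step_up", 57), scoreTransform("step_up", 290))))
}

#' Score one molecule under a reward spec
#'
#' Alerts run first: any match short-circuits to score 0 with the matched
#' alert names as veto flags and predictors skipped. Otherwise every
#' component property is predicted, transformed and aggregated. A missing
#' prediction (NA) vetoes with flag \code{"missing:<property>"}; an
#' unparsable molecule scores 0 with flag \code{"invalid"}.
#'
#' @param mol a [Molecule-class], or a SMILES string (parsed here; parse
#'   failure gives the invalid pathway instead of an error).
#' @param spec a [RewardSpec-class].
#' @param predictors named list of [Predictor-class] covering the reward
#'   specification's component properties (names are the property names).
#' @return list with elements \code{molecule}, \code{properties} (named
#'   numeric), \code{componentScores} (named numeric), \code{score},
#'   \code{vetoes} (character).
#' @export
scoreMolecule <- function(mol, spec, predictors) {
  validObject(spec)
  if (is.character(mol)) {
    mol <- tryCatch(parseSmiles(mol), error = function(e) NULL)
  }
  props <- spec@components$property
  empty <- stats::setNames(rep(NA_real_, length(props)), props)
  if (is.null(mol)) {
    return(list(molecule = NULL, properties = empty,
                componentScores = empty, score = 0, vetoes = "invalid"))
  }
  hits <- matchAlerts(mol, spec@alerts)
  if (length(hits) > 0L) {
    return(list(molecule = mol, properties = empty,
                componentScores = empty, score = 0, vetoes = hits))
  }
  need <- setdiff(props, names(predictors))
  if (length(need) > 0L)
    stop("no predictor registered for: ", paste(need, collapse = ", "),
         call. = FALSE)
  vals <- vapply(props, function(p) predictProperty(predictors[[p]], mol),
                 numeric(1))
  if (anyNA(vals)) {
    return(list(molecule = mol, properties = vals, componentScores = empty,
                score = 0,
                vetoes = paste0("missing:", props[is.na(vals)])))
  }
  s <- vapply(seq_along(props), function(i)
    applyTransform(vals[i], spec@transforms[[i]]), numeric(1))
  names(s) <- props
  total <- aggregateScores(s, spec@components$weight, vetoed = FALSE,
                           normalize = spec@normalizeWeights)
  list(molecule = mol, properties = vals, componentScores = s,
       score = total, vetoes = character(0))
}

#' Score a list of molecules into a table
#'
#' @param mols list of [Molecule-class] objects or character SMILES.
#' @param spec a [RewardSpec-class].
#' @param predictors named list of predictors, as in [scoreMolecule()].
#' @return data.frame: smiles, name, one column per property, one
#'   \code{s_<property>} column per component score, \code{score},
#'   \code{vetoes} (comma-joined).
#' @export
scoreMolecules <- function(mols, spec, predictors) {
  if (is.character(mols)) mols <- as.list(mols)
  rows <- lapply(mols, function(m) {
    r <- scoreMolecule(m, spec, predictors)
    props <- r$properties
    cs <- stats::setNames(as.list(r$componentScores),
                          paste0("s_", names(r$componentScores)))
    c(list(smiles = if (is.null(r$molecule)) NA_character_
             else r$molecule@smiles,
           name = if (is.null(r$molecule)) "" else r$molecule@name),
      as.list(props), cs,
      list(score = r$score, vetoes = paste(r$vetoes, collapse = ",")))
  })
  do.call(rbind, lapply(rows, function(r)
    as.data.frame(r, stringsAsFactors = FALSE)))
}

# ---- YAML round trip -------------------------------------------------------

#' Serialize a reward spec to YAML
#'
#' @param spec a [RewardSpec-class].
#' @param path output YAML path.
#' @export
writeRewardSpec <- function(spec, path) {
  obj <- list(
    normalize_weights = spec@normalizeWeights,
    components = lapply(seq_len(nrow(spec@components)), function(i) {
      t <- spec@transforms[[i]]
      list(property = spec@components$property[i],
           weight = spec@components$weight[i],
           transform = list(kind = t@kind, center = as.list(t@center),
                            steepness = t@steepness))
    }),
    alerts = lapply(seq_len(nrow(spec@alerts@alerts)), function(i)
      list(name = spec@alerts@alerts$name[i],
           pattern = spec@alerts@alerts$pattern[i])))
  yaml::write_yaml(obj, path, precision = 15)
}

#' Read a reward spec from YAML
#'
#' @param path YAML file written by [writeRewardSpec()] (or hand-authored
#'   with the same schema).
#' @return a [RewardSpec-class].
#' @export
readRewardSpec <- function(path) {
  obj <- yaml::read_yaml(path)
  comps <- obj$components
  transforms <- lapply(comps, function(cm)
    scoreTransform(cm$transform$kind, unlist(cm$transform$center),
              cm$transform$steepness))
  alerts <- if (length(obj$alerts) == 0L) emptyAlertCatalog() else
    alertCatalog(vapply(obj$alerts, `[[`, "", "name"),
                 vapply(obj$alerts, `[[`, "", "pattern"))
  rewardSpec(vapply(comps, `[[`, "", "property"), transforms,
             weights = vapply(comps, `[[`, 1, "weight"),
             alerts = alerts,
             normalizeWeights = isTRUE(obj$normalize_weights))
}
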