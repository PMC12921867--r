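# Built-in fixtures: named photocatalyst structures, the symmetric reagent
# set of the local quinoxaline library, and synthetic lookup property
# tables so every pipeline stage runs end-to-end with no download. The
# property values are plausible hand-set oracles for testing the funnel,
# not measurements.

#' Known photocatalyst and substrate structures
#'
#' Named reference molecules used throughout examples and tests:
#' established triplet sensitizers (thioxanthone, benzophenone), the
#' quinoxaline core and its 2,3-diphenyl derivative, and the two EnT
#' substrates phenyl maleimide and trans-methyl cinnamate.
#'
#' @return named list of [Molecule-class] objects.
#' @export
knownPhotocatalysts <- function() {
  smi <- c(
    thioxanthone = "O=C1c2ccccc2Sc2ccccc21",
    benzophenone = "O=C(c1ccccc1)c1ccccc1",
    quinoxaline = "c1ccc2nccnc2c1",
    diphenylquinoxaline = "c1ccc(-c2nc3ccccc3nc2-c2ccccc2)cc1",
    phenyl_maleimide = "O=C1C=CC(=O)N1c1ccccc1",
    methyl_cinnamate = "COC(=O)/C=C/c1ccccc1")
  out <- lapply(names(smi), function(n) parseSmiles(smi[[n]], name = n))
  stats::setNames(out, names(smi))
}

#' Fixture reagents for the local library
#'
#' Six symmetric aromatic ortho-diamines and three symmetric 1,2-diketones;
#' their condensation affords exactly 18 unique bicyclic pyrazines.
#'
#' @return a validated [reagentSet()].
#' @export
fixtureReagents <- function() {
  dia <- c(
    benzene_12_diamine = "Nc1ccccc1N",
    dimethyl_benzene_diamine = "Nc1cc(C)c(C)cc1N",
    difluoro_benzene_diamine = "Nc1cc(F)c(F)cc1N",
    dichloro_benzene_diamine = "Nc1cc(Cl)c(Cl)cc1N",
    naphthalene_23_diamine = "Nc1cc2ccccc2cc1N",
    pyrazine_23_diamine = "Nc1nccnc1N")
  ket <- c(
    benzil = "O=C(c1ccccc1)C(=O)c1ccccc1",
    butanedione = "CC(=O)C(C)=O",
    dimethylbenzil = "Cc1ccc(C(=O)C(=O)c2ccc(C)cc2)cc1")
  reagentSet(
    lapply(names(dia), function(n) parseSmiles(dia[[n]], name = n)),
    lapply(names(ket), function(n) parseSmiles(ket[[n]], name = n)))
}

# hand-set lookup values for the named structures; delta_e_t in kcal/mol,
# wavelengths in nm, rates in 1/s
.KNOWN_PC_PROPS <- data.frame(
  name = c("thioxanthone", "benzophenone", "quinoxaline",
           "diphenylquinoxaline", "phenyl_maleimide", "methyl_cinnamate"),
  delta_e_t = c(63.0, 69.0, 61.0, 58.5, 62.0, 54.0),
  lambda_max = c(380, 370, 315, 344, 300, 280),
  lambda_max_stda = c(362, 352, 321, 333, 296, 271),
  k_isc = c(2e9, 1e10, 1e8, 2e8, 5e7, 1e6),
  k_f = c(5e6, 1e6, 5e6, 8e6, 1e7, 1e8),
  stringsAsFactors = FALSE)

# per-product values for the 18 fixture library members, assigned in
# enumeration (diamine x diketone grid) order. Together with the named-PC
# row that covers the benzil/benzene-diamine product (2,3-diphenyl-
# quinoxaline), exactly four library members clear the local-lead criteria
# (delta_e_t > 57, lambda_max > 290, log ratio > 0.65)
.LOCAL_LIB_PROPS <- list(
  delta_e_t = c(59.5, 55.0, 58.8, 54.2, 60.1, 56.3, 58.2, 53.5, 59.0,
                56.8, 56.5, 55.6, 56.9, 54.8, 60.5, 56.1, 58.6, 53.9),
  lambda_max = c(355, 310, 298, 330, 345, 285, 352, 305, 288, 322, 360,
                 295, 342, 315, 282, 328, 348, 300),
  lambda_max_stda = c(340, 298, 285, 316, 330, 272, 338, 292, 276, 308,
                      345, 283, 328, 302, 270, 314, 333, 287),
  k_isc = c(5e8, 2e7, 3e8, 1e6, 4e8, 2e8, 2e4, 5e7, 2e8, 3e7, 6e8, 1e7,
            2e6, 4e7, 3e8, 2e7, 7e8, 5e7),
  k_f = c(2e6, 8e7, 3e6, 5e7, 4e6, 1e8, 6e7, 9e7, 2e7, 7e7, 3e6, 8e7,
          5e7, 6e7, 4e7, 9e7, 2e6, 7e7))

#' Synthetic fixture property table
#'
#' Lookup-oracle values for every fixture molecule: the named reference
#' structures and the 18 products of the fixture reagent library. The
#' computable descriptors (theta_conjugation, o_fmo) are filled by the
#' package's own predictors; the external-model quantities (delta_e_t,
#' lambda_max, lambda_max_stda, k_isc, k_f) are hand-set plausible values -
#' synthetic stand-ins for predictions the package does not ship. By
#' construction, benzophenone clears the rediscovery objectives and exactly
#' four library products clear the local-lead criteria.
#'
#' @return data.frame: \code{smiles}, \code{name}, one column per property
#'   in [propertyNames()].
#' @export
fixturePropertyTable <- function() {
  pcs <- knownPhotocatalysts()
  known <- .KNOWN_PC_PROPS
  known$smiles <- vapply(known$name, function(n) smiles(pcs[[n]]),
                         character(1))
  lib <- enumerateCondensation(fixtureReagents())
  prod <- data.frame(
    name = paste(lib$diamine, lib$diketone, sep = "+"),
    delta_e_t = .LOCAL_LIB_PROPS$delta_e_t,
    lambda_max = .LOCAL_LIB_PROPS$lambda_max,
    lambda_max_stda = .LOCAL_LIB_PROPS$lambda_max_stda,
    k_isc = .LOCAL_LIB_PROPS$k_isc,
    k_f = .LOCAL_LIB_PROPS$k_f,
    smiles = lib$smiles,
    stringsAsFactors = FALSE)
  tab <- rbind(known, prod)
  # 2,3-diphenylquinoxaline is both a named PC and a library product; the
  # named row wins
  tab <- tab[!duplicated(tab$smiles), , drop = FALSE]
  mols <- lapply(tab$smiles, parseSmiles)
  tab$theta_conjugation <- vapply(mols, function(m)
    suppressMessages(fractionConjugated(m)), numeric(1))
  tab$o_fmo <- vapply(mols, function(m)
    predictProperty(huckelPredictor("o_fmo"), m), numeric(1))
  tab[, c("smiles", "name", propertyNames())]
}

#' Predictors backed by the fixture property table
#'
#' One lookup predictor per external-model property plus the live
#' theta_conjugation and o_fmo predictors - the standard registry for
#' scoring fixture molecules.
#'
#' @param table property table (default [fixturePropertyTable()]).
#' @return named list of [Predictor-class].
#' @export
fixturePredictors <- function(table = fixturePropertyTable()) {
  ext <- c("delta_e_t", "lambda_max", "lambda_max_stda", "k_isc", "k_f")
  preds <- lapply(ext, function(p)
    lookupPredictor(p, stats::setNames(table[[p]], table$smiles)))
  preds <- stats::setNames(preds, ext)
  preds$theta_conjugation <- thetaPredictor()
  preds$o_fmo <- huckelPredictor("o_fmo")
  preds
}

#' Write the fixture set to disk
#'
#' Writes \code{known_pcs.smi}, \code{diamines.smi}, \code{diketones.smi}
#' and \code{properties.csv} into \code{dir}. The files are fully
#' deterministic; \code{seed} is accepted for interface uniformity and
#' echoed in the returned manifest.
#'
#' @param dir output directory (created if needed).
#' @param seed integer, recorded only.
#' @return invisible list of written paths plus the seed.
#' @export
makeFixtures <- function(dir, seed = 1L) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(
    known_pcs = file.path(dir, "known_pcs.smi"),
    diamines = file.path(dir, "diamines.smi"),
    diketones = file.path(dir, "diketones.smi"),
    properties = file.path(dir, "properties.csv"))
  writeSmiles(knownPhotocatalysts(), paths$known_pcs)
  rs <- fixtureReagents()
  writeSmiles(rs$diamines, paths$diamines)
  writeSmiles(rs$diketones, paths$diketones)
  utils::write.csv(fixturePropertyTable(), paths$properties,
                   row.names = FALSE)
  invisible(c(paths, list(seed = as.integer(seed))))
}
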