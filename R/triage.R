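# The post-generation funnel: threshold filtering, diversity-aware
# representative selection by fingerprint clustering, the rate-ratio
# refinement criterion, and local combinatorial library enumeration with
# lead screening.

#' Construct a criteria table
#'
#' @param property character vector of property names (see
#'   [propertyNames()]; \code{"rate_ratio"} is also allowed and derived
#'   from k_isc/k_f when absent).
#' @param comparator one of ">", ">=", "<", "<=" per criterion.
#' @param threshold finite numeric thresholds.
#' @return data.frame of class criteria with one row per criterion.
#' @export
criteria <- function(property, comparator, threshold) {
  stopifnot(all(comparator %in% c(">", ">=", "<", "<=")),
            all(is.finite(threshold)))
  data.frame(property = property, comparator = comparator,
             threshold = threshold, stringsAsFactors = FALSE)
}

#' Named triage criteria presets
#'
#' Published threshold sets of the screening funnel, all with strict
#' inequalities:
#' \describe{
#'   \item{global-triage}{delta_e_t > 60 kcal/mol, lambda_max > 350 nm,
#'     lambda_max_stda > 325 nm - the post-generation candidate filter.}
#'   \item{refined}{delta_e_t > 55 kcal/mol, lambda_max > 250 nm,
#'     log10(k_isc)/log10(k_f) > 0.75 - the refinement of the
#'     quantum-chemistry screening results.}
#'   \item{local-lead}{delta_e_t > 57 kcal/mol, lambda_max > 290 nm,
#'     log10(k_isc)/log10(k_f) > 0.65 - lead selection from the local
#'     library.}
#' }
#'
#' @param name preset name.
#' @return a criteria data.frame.
#' @export
criteriaPreset <- function(name = c("global-triage", "refined",
                                    "local-lead")) {
  name <- match.arg(name)
  switch(name,
    `global-triage` = criteria(
      c("delta_e_t", "lambda_max", "lambda_max_stda"),
      rep(">", 3), c(60, 350, 325)),
    refined = criteria(
      c("delta_e_t", "lambda_max", "rate_ratio"),
      rep(">", 3), c(55, 250, 0.75)),
    `local-lead` = criteria(
      c("delta_e_t", "lambda_max", "rate_ratio"),
      rep(">", 3), c(57, 290, 0.65)))
}

#' Filter a candidate pool by property criteria
#'
#' Applies every criterion with its exact comparator (strict thresholds stay
#' strict: a row at exactly the threshold fails ">"). Row order is
#' preserved. Any required property missing from a row is a hard error
#' naming the molecule and property - the triage policy, where silent
#' defaults would corrupt the funnel. \code{rate_ratio} is derived from the
#' \code{k_isc} and \code{k_f} columns when not itself present (undefined
#' ratios fail every criterion on it).
#'
#' @param pool data.frame with a \code{smiles} column and one column per
#'   required property.
#' @param crit criteria data.frame from [criteria()]/[criteriaPreset()].
#' @return list with \code{survivors} (sub-data.frame) and \code{report}
#'   (pool plus one logical \code{pass_<property>} column per criterion and
#'   a \code{pass} column).
#' @export
filterByCriteria <- function(pool, crit) {
  if (nrow(crit) == 0L)
    return(list(survivors = pool,
                report = cbind(pool, pass = rep(TRUE, nrow(pool)))))
  if ("rate_ratio" %in% crit$property && !"rate_ratio" %in% names(pool)) {
    if (!all(c("k_isc", "k_f") %in% names(pool)))
      stop("rate_ratio criterion needs a rate_ratio column or k_isc and k_f",
           call. = FALSE)
    rr <- rateRatio(pool$k_isc, pool$k_f)
    pool$rate_ratio <- ifelse(rr$defined, rr$ratio, NA_real_)
    pool$rate_ratio_defined <- rr$defined
  }
  report <- pool
  pass <- rep(TRUE, nrow(pool))
  for (i in seq_len(nrow(crit))) {
    p <- crit$property[i]
    if (!p %in% names(pool))
      stop("missing property column: ", p, call. = FALSE)
    v <- pool[[p]]
    bad <- is.na(v) & !(p == "rate_ratio" &
                        isTRUE(any(names(pool) == "rate_ratio_defined")))
    if (p == "rate_ratio" && "rate_ratio_defined" %in% names(pool))
      bad <- is.na(v) & pool$rate_ratio_defined
    if (any(bad)) {
      who <- if ("smiles" %in% names(pool)) pool$smiles[bad][1] else
        paste("row", which(bad)[1])
      stop("missing value for property '", p, "' on molecule ", who,
           call. = FALSE)
    }
    ok <- switch(crit$comparator[i],
                 ">" = v > crit$threshold[i],
                 ">=" = v >= crit$threshold[i],
                 "<" = v < crit$threshold[i],
                 "<=" = v <= crit$threshold[i])
    ok[is.na(ok)] <- FALSE  # undefined rate ratios fail
    report[[paste0("pass_", p)]] <- ok
    pass <- pass & ok
  }
  report$pass <- pass
  list(survivors = pool[pass, , drop = FALSE], report = report)
}

#' Rate ratio log10(k_ISC) / log10(k_f)
#'
#' The refinement statistic comparing intersystem crossing against the
#' competing fluorescence. Defined only when both rates exceed 1/s (both
#' logs positive); other inputs are flagged undefined. Strictly increasing
#' in k_isc and strictly decreasing in k_f on the defined domain.
#'
#' @param k_isc,k_f positive rates in 1/s (vectorized).
#' @return data.frame: \code{k_isc}, \code{k_f}, \code{ratio},
#'   \code{defined}.
#' @examples
#' rateRatio(1e8, 1e6)$ratio  # 8/6 = 1.333...
#' @export
rateRatio <- function(k_isc, k_f) {
  if (any(k_isc <= 0) || any(k_f <= 0))
    stop("rates must be positive", call. = FALSE)
  li <- log10(k_isc); lf <- log10(k_f)
  defined <- li > 0 & lf > 0
  ratio <- ifelse(defined, li / lf, NA_real_)
  data.frame(k_isc = k_isc, k_f = k_f, ratio = ratio, defined = defined)
}

# ---- fingerprint clustering ------------------------------------------------

#' Butina leader clustering on Tanimoto distance
#'
#' Sphere-exclusion clustering: molecules are ranked by neighbor count at
#' the distance cutoff (ties by canonical SMILES order); each still-free
#' molecule with the most free neighbors becomes a cluster leader and
#' absorbs its free neighbors. Every member lies within the cutoff of its
#' leader and leaders are pairwise farther apart than the cutoff.
#'
#' @param fps list of fingerprint vectors ([morganFingerprint()]).
#' @param cutoff Tanimoto distance cutoff (1 - similarity); default 0.35,
#'   i.e. similarity 0.65.
#' @param labels character labels used for deterministic tie-breaks
#'   (canonical SMILES).
#' @return list: \code{assignment} (integer cluster per molecule),
#'   \code{leaders} (molecule index per cluster).
#' @export
butinaCluster <- function(fps, cutoff = 0.35, labels = NULL) {
  n <- length(fps)
  if (is.null(labels)) labels <- as.character(seq_len(n))
  if (n == 0L) return(list(assignment = integer(0), leaders = integer(0)))
  sim <- matrix(1, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (j > i) {
      sim[i, j] <- sim[j, i] <- tanimotoSimilarity(fps[[i]], fps[[j]])
    }
  }
  nbr <- lapply(seq_len(n), function(i)
    setdiff(which(1 - sim[i, ] <= cutoff), i))
  counts <- lengths(nbr)
  ordIdx <- order(-counts, labels, method = "radix")
  assignment <- rep(NA_integer_, n)
  leaders <- integer(0)
  cl <- 0L
  for (i in ordIdx) {
    if (!is.na(assignment[i])) next
    cl <- cl + 1L
    leaders[cl] <- i
    members <- c(i, nbr[[i]][is.na(assignment[nbr[[i]]])])
    assignment[members] <- cl
  }
  list(assignment = assignment, leaders = leaders)
}

#' Diversity-aware representative selection
#'
#' The candidate-selection step between threshold filtering and expensive
#' validation: cluster the pool on circular-fingerprint Tanimoto distance
#' (Butina leader clustering), pick one representative per cluster - the
#' member maximizing the objective column, ties broken by canonical SMILES
#' order - then rank clusters by their representative's objective and keep
#' the best \code{nMax}.
#'
#' @param pool data.frame with a \code{smiles} column and the objective
#'   column.
#' @param objective name of the numeric column to maximize (e.g. a score or
#'   predicted property).
#' @param cutoff Tanimoto distance cutoff (default 0.35).
#' @param nMax maximum number of representatives (default Inf).
#' @param radius,nbits fingerprint parameters (defaults 2, 2048).
#' @return the pool with added columns \code{cluster}, \code{leader},
#'   \code{representative}, \code{selected}; attribute \code{"selected"}
#'   holds the representative sub-data.frame in rank order.
#' @export
clusterSelect <- function(pool, objective, cutoff = 0.35, nMax = Inf,
                          radius = 2L, nbits = 2048L) {
  if (nrow(pool) == 0L) stop("empty candidate pool", call. = FALSE)
  if (!objective %in% names(pool))
    stop("objective column not in pool: ", objective, call. = FALSE)
  mols <- lapply(pool$smiles, parseSmiles)
  can <- vapply(mols, smiles, character(1))
  fps <- lapply(mols, morganFingerprint, radius = radius, nbits = nbits)
  bc <- butinaCluster(fps, cutoff = cutoff, labels = can)
  pool$cluster <- bc$assignment
  pool$leader <- seq_len(nrow(pool)) %in% bc$leaders
  obj <- pool[[objective]]
  reps <- vapply(seq_along(bc$leaders), function(cl) {
    members <- which(bc$assignment == cl)
    members[order(-obj[members], can[members], method = "radix")][1]
  }, integer(1))
  pool$representative <- seq_len(nrow(pool)) %in% reps
  rank <- order(-obj[reps], can[reps], method = "radix")
  keep <- reps[rank][seq_len(min(nMax, length(reps)))]
  pool$selected <- seq_len(nrow(pool)) %in% keep
  attr(pool, "selected") <- pool[match(keep, seq_len(nrow(pool))), ,
                                 drop = FALSE]
  pool
}

# ---- local library enumeration ---------------------------------------------

#' Reagents for the local quinoxaline library
#'
#' Validates that every diamine contains an aromatic ortho-diamine motif
#' (two adjacent aromatic carbons each bearing a primary amine) and every
#' diketone a 1,2-diketone motif (two adjacent non-aromatic carbonyl
#' carbons, each with one further substituent). A reagent failing its motif
#' is an error at construction, before any enumeration.
#'
#' @param diamines,diketones lists of [Molecule-class] (or character
#'   SMILES).
#' @return list with validated \code{diamines} and \code{diketones}.
#' @export
reagentSet <- function(diamines, diketones) {
  asMols <- function(x) lapply(x, function(m)
    if (is.character(m)) parseSmiles(m) else m)
  diamines <- asMols(diamines); diketones <- asMols(diketones)
  for (m in diamines) {
    if (length(.orthoDiamineSites(m)) == 0L)
      stop("not an aromatic ortho-diamine: ", m@smiles, call. = FALSE)
  }
  for (m in diketones) {
    if (length(.diketoneSites(m)) == 0L)
      stop("not a 1,2-diketone: ", m@smiles, call. = FALSE)
  }
  list(diamines = diamines, diketones = diketones)
}

# adjacent aromatic C pair each bearing a primary sp3 NH2
.orthoDiamineSites <- function(mol) {
  a <- mol@atoms; b <- mol@bonds
  deg <- tabulate(c(b$a1, b$a2), nbins = nrow(a))
  isNH2 <- a$element == "N" & !a$aromatic & a$hcount >= 2L & deg == 1L &
    a$charge == 0L
  amineOn <- function(i) {
    ks <- which((b$a1 == i & isNH2[b$a2]) | (b$a2 == i & isNH2[b$a1]))
    ks <- ks[b$order[ks] == 1L & !b$aromatic[ks]]
    if (!length(ks)) return(NA_integer_)
    k <- ks[1]
    if (b$a1[k] == i) b$a2[k] else b$a1[k]
  }
  sites <- list()
  for (k in which(b$aromatic)) {
    i <- b$a1[k]; j <- b$a2[k]
    if (a$element[i] != "C" || a$element[j] != "C") next
    n1 <- amineOn(i); n2 <- amineOn(j)
    if (!is.na(n1) && !is.na(n2) && n1 != n2)
      sites[[length(sites) + 1L]] <- c(c1 = i, c2 = j, n1 = n1, n2 = n2)
  }
  sites
}

# adjacent non-aromatic carbonyl carbons, each with one extra substituent
.diketoneSites <- function(mol) {
  a <- mol@atoms; b <- mol@bonds
  carbonylO <- function(i) {
    ks <- which(((b$a1 == i & a$element[b$a2] == "O") |
                 (b$a2 == i & a$element[b$a1] == "O")) &
                b$order == 2L & !b$aromatic)
    if (!length(ks)) return(NA_integer_)
    k <- ks[1]
    if (b$a1[k] == i) b$a2[k] else b$a1[k]
  }
  sites <- list()
  for (k in which(!b$aromatic & b$order == 1L)) {
    i <- b$a1[k]; j <- b$a2[k]
    if (a$element[i] != "C" || a$element[j] != "C") next
    if (a$aromatic[i] || a$aromatic[j]) next
    oi <- carbonylO(i); oj <- carbonylO(j)
    if (!is.na(oi) && !is.na(oj))
      sites[[length(sites) + 1L]] <- c(cA = i, cB = j, oA = oi, oB = oj)
  }
  sites
}

# condense one diamine with one diketone in a given orientation; NULL on
# failed re-perception
.condenseOnce <- function(diamine, diketone, flip = FALSE) {
  sa <- .orthoDiamineSites(diamine)[[1]]
  sk <- .diketoneSites(diketone)[[1]]
  a1 <- diamine@atoms; b1 <- diamine@bonds
  # amine N atoms become aromatic ring N (lose both hydrogens)
  for (n in c(sa["n1"], sa["n2"])) {
    a1$element[n] <- "N"; a1$aromatic[n] <- TRUE; a1$hcount[n] <- 0L
  }
  a2 <- diketone@atoms; b2 <- diketone@bonds
  dropO <- c(sk[["oA"]], sk[["oB"]])
  keep <- setdiff(seq_len(nrow(a2)), dropO)
  idx <- match(seq_len(nrow(a2)), keep)
  sel <- !(b2$a1 %in% dropO | b2$a2 %in% dropO)
  a2 <- a2[keep, , drop = FALSE]
  b2 <- data.frame(a1 = idx[b2$a1[sel]], a2 = idx[b2$a2[sel]],
                   order = b2$order[sel], aromatic = b2$aromatic[sel])
  cA <- idx[sk[["cA"]]]; cB <- idx[sk[["cB"]]]
  a2$aromatic[c(cA, cB)] <- TRUE
  # the former C-C single bond becomes part of the aromatic pyrazine ring
  kcc <- which((b2$a1 == cA & b2$a2 == cB) | (b2$a1 == cB & b2$a2 == cA))
  b2$order[kcc] <- 1L; b2$aromatic[kcc] <- TRUE
  off <- nrow(a1)
  b2$a1 <- b2$a1 + off; b2$a2 <- b2$a2 + off
  ends <- if (flip) c(cB, cA) else c(cA, cB)
  bonds <- rbind(b1, b2, data.frame(
    a1 = c(sa[["n1"]], sa[["n2"]]),
    a2 = ends + off,
    order = 1L, aromatic = TRUE))
  .moleculeFromGraph(rbind(a1, a2), bonds)
}

#' Enumerate the condensation library
#'
#' Applies the quinoxaline-forming condensation template - aromatic
#' ortho-diamine plus 1,2-diketone giving a fused pyrazine with loss of two
#' waters - to every reagent pair. Both orientations are generated for
#' unsymmetric partners; products are canonicalized and deduplicated, so a
#' fully symmetric reagent set yields exactly one product per pair.
#'
#' @param reagents a validated [reagentSet()].
#' @return data.frame: \code{smiles} (canonical product), \code{diamine},
#'   \code{diketone} (parent SMILES, with names when present).
#' @examples \dontrun{
#' rs <- reagentSet(list("Nc1ccccc1N"),
#'                  list("O=C(c1ccccc1)C(=O)c1ccccc1"))
#' enumerateCondensation(rs)$smiles  # 2,3-diphenylquinoxaline
#' }
#' @export
enumerateCondensation <- function(reagents) {
  rows <- list()
  for (da in reagents$diamines) {
    for (dk in reagents$diketones) {
      for (flip in c(FALSE, TRUE)) {
        m <- .condenseOnce(da, dk, flip)
        if (is.null(m))
          stop("condensation failed for ", da@smiles, " + ", dk@smiles,
               call. = FALSE)
        rows[[length(rows) + 1L]] <- data.frame(
          smiles = m@smiles,
          diamine = if (nzchar(da@name)) da@name else da@smiles,
          diketone = if (nzchar(dk@name)) dk@name else dk@smiles,
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  out <- out[!duplicated(out$smiles), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Does a molecule contain a fused pyrazine ring?
#'
#' TRUE when an aromatic six-membered ring with exactly two nitrogens in
#' 1,4-relationship shares at least two atoms with another ring - the
#' quinoxaline/bicyclic-pyrazine core produced by the condensation.
#'
#' @param mol a [Molecule-class].
#' @return logical.
#' @export
containsFusedPyrazine <- function(mol) {
  rings <- .aromaticSixRings(mol)
  if (!length(rings)) return(FALSE)
  b <- mol@bonds
  rb <- .ringBonds(mol)
  ringDeg <- tabulate(c(b$a1[rb], b$a2[rb]), nbins = nrow(mol@atoms))
  for (r in rings) {
    els <- mol@atoms$element[r]
    nIdx <- which(els == "N")
    if (length(nIdx) != 2L) next
    sep <- abs(nIdx[1] - nIdx[2])
    if (min(sep, 6L - sep) != 3L) next      # para (1,4) nitrogens
    if (sum(ringDeg[r] >= 3L) >= 2L) return(TRUE)
  }
  FALSE
}

# all aromatic six-membered rings as ordered atom cycles
.aromaticSixRings <- function(mol) {
  b <- mol@bonds
  ar <- which(b$aromatic)
  if (!length(ar)) return(list())
  adj <- vector("list", nrow(mol@atoms))
  for (k in ar) {
    adj[[b$a1[k]]] <- c(adj[[b$a1[k]]], b$a2[k])
    adj[[b$a2[k]]] <- c(adj[[b$a2[k]]], b$a1[k])
  }
  found <- list()
  seen <- character(0)
  walk <- function(path) {
    last <- path[length(path)]
    for (nx in adj[[last]]) {
      if (length(path) == 6L) {
        if (nx == path[1]) {
          key <- paste(sort(path), collapse = "-")
          if (!key %in% seen) {
            seen <<- c(seen, key)
            found[[length(found) + 1L]] <<- path
          }
        }
      } else if (!nx %in% path && nx > path[1]) {
        walk(c(path, nx))
      }
    }
  }
  for (s in seq_along(adj)) {
    if (!is.null(adj[[s]])) walk(s)
  }
  found
}

#' Screen a local library for lead candidates
#'
#' Predicts the criteria properties for every product ([batchPredict()]) and
#' applies the lead criteria ([filterByCriteria()]); the full screening
#' report is retained.
#'
#' @param products data.frame from [enumerateCondensation()] (needs a
#'   \code{smiles} column).
#' @param predictors named predictor list covering the criteria properties.
#' @param leadCriteria criteria data.frame; default the local-lead preset.
#' @return list: \code{leads} (surviving rows), \code{report} (all rows
#'   with properties and per-criterion pass flags).
#' @export
screenLocal <- function(products, predictors,
                        leadCriteria = criteriaPreset("local-lead")) {
  if (nrow(products) == 0L)
    return(list(leads = products, report = products))
  mols <- lapply(products$smiles, parseSmiles)
  props <- batchPredict(mols, predictors)
  pool <- cbind(products[, setdiff(names(products), "smiles"), drop = FALSE],
                props)
  pool <- pool[, c("smiles", setdiff(names(pool), "smiles")), drop = FALSE]
  res <- filterByCriteria(pool, leadCriteria)
  list(leads = res$survivors, report = res$report)
}
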