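# Seedable generative optimization: a genetic algorithm over molecular
# graphs honoring the reward contract, with a scaffold-bucket diversity
# filter and the trajectory analytics (top-k score series, cumulative
# scaffold occurrence).

#' Construct a GA configuration
#'
#' @param populationSize molecules per generation (default 50).
#' @param generations number of generations (default 10).
#' @param mutationRate per-offspring mutation probability (default 0.9).
#' @param crossoverRate per-offspring crossover probability (default 0.6).
#' @param tournamentSize selection tournament size (default 3).
#' @param elitism number of best molecules copied unchanged (default 2).
#' @param seed integer RNG seed (mandatory; every source of randomness in
#'   the run flows from it).
#' @param scaffoldBucketLimit max rewarded molecules per scaffold before
#'   further ones score 0 (default 25; \code{Inf} disables the filter).
#' @param scaffoldMode scaffold key mode for the filter (default "murcko").
#' @return a [GAConfig-class].
#' @export
gaConfig <- function(populationSize = 50L, generations = 10L,
                     mutationRate = 0.9, crossoverRate = 0.6,
                     tournamentSize = 3L, elitism = 2L, seed,
                     scaffoldBucketLimit = 25, scaffoldMode = "murcko") {
  new("GAConfig", populationSize = as.integer(populationSize),
      generations = as.integer(generations),
      mutationRate = mutationRate, crossoverRate = crossoverRate,
      tournamentSize = as.integer(tournamentSize),
      elitism = as.integer(elitism), seed = as.integer(seed),
      scaffoldBucketLimit = as.numeric(scaffoldBucketLimit),
      scaffoldMode = scaffoldMode)
}

setMethod("show", "GAConfig", function(object) {
  cat("GAConfig: pop", object@populationSize, "x", object@generations,
      "generations | mut", object@mutationRate, "xover",
      object@crossoverRate, "| seed", object@seed, "| bucket limit",
      object@scaffoldBucketLimit, paste0("(", object@scaffoldMode, ")\n"))
})

# run expr under a private RNG stream derived from seed; the global RNG
# state is restored afterwards
.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# ---- graph edit helpers ----------------------------------------------------

.FRAGMENTS <- list(
  methyl = list(atoms = data.frame(element = "C", aromatic = FALSE,
                                   charge = 0L, hcount = 3L),
                bonds = data.frame(a1 = integer(0), a2 = integer(0),
                                   order = integer(0), aromatic = logical(0)),
                attach = 1L),
  fluoro = list(atoms = data.frame(element = "F", aromatic = FALSE,
                                   charge = 0L, hcount = 0L),
                bonds = data.frame(a1 = integer(0), a2 = integer(0),
                                   order = integer(0), aromatic = logical(0)),
                attach = 1L),
  cyano = list(atoms = data.frame(element = c("C", "N"),
                                  aromatic = FALSE, charge = 0L,
                                  hcount = 0L),
               bonds = data.frame(a1 = 1L, a2 = 2L, order = 3L,
                                  aromatic = FALSE),
               attach = 1L),
  phenyl = list(atoms = data.frame(element = "C", aromatic = TRUE,
                                   charge = 0L,
                                   hcount = c(0L, 1L, 1L, 1L, 1L, 1L)),
                bonds = data.frame(a1 = c(1L, 2L, 3L, 4L, 5L, 6L),
                                   a2 = c(2L, 3L, 4L, 5L, 6L, 1L),
                                   order = 1L, aromatic = TRUE),
                attach = 1L))

.appendFragment <- function(a, b, host, frag) {
  off <- nrow(a)
  a2 <- rbind(a, frag$atoms)
  a2$hcount[host] <- a2$hcount[host] - 1L
  fb <- frag$bonds
  if (nrow(fb) > 0L) { fb$a1 <- fb$a1 + off; fb$a2 <- fb$a2 + off }
  b2 <- rbind(b, fb,
              data.frame(a1 = host, a2 = frag$attach + off, order = 1L,
                         aromatic = FALSE))
  list(atoms = a2, bonds = b2)
}

# the mutation operator menu, biased toward aromatic/heteroaromatic edits
# (the target space is aryl-substituted fused heterocycles). Each entry
# returns an edited graph or NULL when inapplicable.
.mutationOps <- function(mol) {
  a <- mol@atoms; b <- mol@bonds
  deg <- tabulate(c(b$a1, b$a2), nbins = nrow(a))
  ring <- .ringBonds(mol)
  list(
    c_to_n = function() {
      cand <- which(a$aromatic & a$element == "C" & a$hcount >= 1L &
                    a$charge == 0L)
      if (!length(cand)) return(NULL)
      i <- cand[sample.int(length(cand), 1L)]
      a$element[i] <- "N"; a$hcount[i] <- 0L
      list(atoms = a, bonds = b)
    },
    n_to_c = function() {
      cand <- which(a$aromatic & a$element == "N" & a$hcount == 0L &
                    deg == 2L & a$charge == 0L)
      if (!length(cand)) return(NULL)
      i <- cand[sample.int(length(cand), 1L)]
      a$element[i] <- "C"; a$hcount[i] <- 1L
      list(atoms = a, bonds = b)
    },
    append_substituent = function() {
      cand <- which(a$hcount >= 1L & a$charge == 0L)
      if (!length(cand)) return(NULL)
      i <- cand[sample.int(length(cand), 1L)]
      frag <- .FRAGMENTS[[sample.int(length(.FRAGMENTS), 1L)]]
      .appendFragment(a, b, i, frag)
    },
    remove_substituent = function() {
      cand <- which(deg == 1L)
      cand <- cand[vapply(cand, function(i) {
        k <- which(b$a1 == i | b$a2 == i)[1]
        b$order[k] == 1L && !b$aromatic[k]
      }, logical(1))]
      if (!length(cand)) return(NULL)
      i <- cand[sample.int(length(cand), 1L)]
      k <- which(b$a1 == i | b$a2 == i)[1]
      nb <- if (b$a1[k] == i) b$a2[k] else b$a1[k]
      a$hcount[nb] <- a$hcount[nb] + 1L
      keep <- setdiff(seq_len(nrow(a)), i)
      idx <- match(seq_len(nrow(a)), keep)
      sel <- seq_len(nrow(b)) != k
      list(atoms = a[keep, , drop = FALSE],
           bonds = data.frame(a1 = idx[b$a1[sel]], a2 = idx[b$a2[sel]],
                              order = b$order[sel],
                              aromatic = b$aromatic[sel]))
    },
    fuse_benzo = function() {
      cand <- which(ring & b$aromatic &
                    a$hcount[b$a1] >= 1L & a$hcount[b$a2] >= 1L)
      if (!length(cand)) return(NULL)
      k <- cand[sample.int(length(cand), 1L)]
      i <- b$a1[k]; j <- b$a2[k]
      off <- nrow(a)
      a2 <- rbind(a, data.frame(element = "C", aromatic = TRUE, charge = 0L,
                                hcount = c(1L, 1L, 1L, 1L)))
      a2$hcount[c(i, j)] <- a2$hcount[c(i, j)] - 1L
      b2 <- rbind(b, data.frame(
        a1 = c(i, off + 1L, off + 2L, off + 3L, off + 4L),
        a2 = c(off + 1L, off + 2L, off + 3L, off + 4L, j),
        order = 1L, aromatic = TRUE))
      list(atoms = a2, bonds = b2)
    },
    toggle_bond_order = function() {
      up <- which(!ring & !b$aromatic & b$order == 1L &
                  a$element[b$a1] == "C" & a$element[b$a2] == "C" &
                  a$hcount[b$a1] >= 1L & a$hcount[b$a2] >= 1L)
      down <- which(!b$aromatic & b$order == 2L &
                    a$element[b$a1] == "C" & a$element[b$a2] == "C")
      cand <- c(up, down)
      if (!length(cand)) return(NULL)
      k <- cand[sample.int(length(cand), 1L)]
      if (b$order[k] == 1L) {
        b$order[k] <- 2L
        a$hcount[c(b$a1[k], b$a2[k])] <- a$hcount[c(b$a1[k], b$a2[k])] - 1L
      } else {
        b$order[k] <- 1L
        a$hcount[c(b$a1[k], b$a2[k])] <- a$hcount[c(b$a1[k], b$a2[k])] + 1L
      }
      list(atoms = a, bonds = b)
    })
}

#' Mutate a molecule
#'
#' Applies one randomly chosen graph edit: aromatic C<->N swap, append or
#' remove a small substituent (methyl, fluoro, cyano, phenyl), fuse a benzo
#' ring onto an aromatic CH-CH edge, or toggle an acyclic C-C bond order.
#' Proposals whose rewritten SMILES fail OpenBabel re-perception (valence or
#' aromaticity violations) are rejected and retried; after \code{maxTries}
#' failures the parent is returned unchanged, so the operator is total.
#' Randomness comes from the ambient R RNG (seeded by [runGA()]).
#'
#' @param mol a [Molecule-class].
#' @param maxTries rejection-sampling bound (default 8).
#' @param ops optional character subset of operator names (for forcing a
#'   specific edit, mainly in examples/tests).
#' @return a valid, canonical [Molecule-class].
#' @export
mutateMolecule <- function(mol, maxTries = 8L, ops = NULL) {
  menu <- .mutationOps(mol)
  if (!is.null(ops)) menu <- menu[ops]
  for (t in seq_len(maxTries)) {
    f <- menu[[sample.int(length(menu), 1L)]]
    g <- f()
    if (is.null(g)) next
    m <- .moleculeFromGraph(g$atoms, g$bonds, name = "")
    if (!is.null(m)) return(m)
  }
  mol
}

#' Crossover two molecules
#'
#' Cuts each parent at a randomly chosen acyclic, non-aromatic single bond
#' and joins one fragment of each. When both parents are the same structure
#' the same bond is cut in both, so self-crossover returns the parent.
#' Parents without a cuttable bond, or invalid offspring, fall back to
#' \code{fallback} (by convention the higher-scoring parent).
#'
#' @param molA,molB parent [Molecule-class] objects.
#' @param fallback molecule returned when crossover is impossible (default
#'   \code{molA}).
#' @return a valid [Molecule-class].
#' @export
crossoverMolecules <- function(molA, molB, fallback = molA) {
  cutBonds <- function(m) {
    rb <- .ringBonds(m)
    which(!rb & !m@bonds$aromatic & m@bonds$order == 1L)
  }
  ka <- cutBonds(molA); kb <- cutBonds(molB)
  if (!length(ka) || !length(kb)) return(fallback)
  i <- ka[sample.int(length(ka), 1L)]
  same <- identical(molA@smiles, molB@smiles)
  j <- if (same) i else kb[sample.int(length(kb), 1L)]
  sideA <- .splitAt(molA, i)
  sideB <- .splitAt(molB, j)
  fragA <- if (same || stats::runif(1) < 0.5) sideA$left else sideA$right
  fragB <- if (same || stats::runif(1) < 0.5) sideB$right else sideB$left
  g <- .joinFragments(fragA, fragB)
  m <- .moleculeFromGraph(g$atoms, g$bonds, name = "")
  if (is.null(m)) fallback else m
}

# split molecule at bond k; returns left = fragment of a1 (attachment atom
# first), right = fragment of a2
.splitAt <- function(mol, k) {
  a <- mol@atoms; b <- mol@bonds
  i <- b$a1[k]; j <- b$a2[k]
  b2 <- b[-k, , drop = FALSE]
  g <- igraph::graph_from_edgelist(as.matrix(b2[, c("a1", "a2")]),
                                   directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, nrow(a) - igraph::vcount(g)))
  memb <- igraph::components(g)$membership
  frag <- function(root) {
    keep <- which(memb == memb[root])
    keep <- c(root, setdiff(keep, root))  # attachment atom first
    idx <- match(seq_len(nrow(a)), keep)
    sel <- b2$a1 %in% keep & b2$a2 %in% keep
    list(atoms = a[keep, , drop = FALSE],
         bonds = data.frame(a1 = idx[b2$a1[sel]], a2 = idx[b2$a2[sel]],
                            order = b2$order[sel],
                            aromatic = b2$aromatic[sel]))
  }
  list(left = frag(i), right = frag(j))
}

.joinFragments <- function(f1, f2) {
  off <- nrow(f1$atoms)
  a <- rbind(f1$atoms, f2$atoms)
  b2 <- f2$bonds
  if (nrow(b2) > 0L) { b2$a1 <- b2$a1 + off; b2$a2 <- b2$a2 + off }
  b <- rbind(f1$bonds, b2,
             data.frame(a1 = 1L, a2 = off + 1L, order = 1L,
                        aromatic = FALSE))
  list(atoms = a, bonds = b)
}

# ---- diversity filter ------------------------------------------------------

#' Create a scaffold tracker
#'
#' Mutable bucket counts of rewarded molecules per scaffold key, used by the
#' diversity filter across a generative run.
#'
#' @return an environment with a named numeric \code{counts}.
#' @export
scaffoldTracker <- function() {
  e <- new.env(parent = emptyenv())
  e$counts <- stats::setNames(numeric(0), character(0))
  e
}

#' Scaffold-similarity diversity filter
#'
#' If the molecule's scaffold bucket already holds \code{limit} or more
#' rewarded molecules, the adjusted score is 0; otherwise the raw score is
#' returned unchanged. Buckets are filled only by molecules with raw score
#' greater than zero, so vetoed or worthless molecules never consume bucket
#' capacity. Repeatedly rewarding one scaffold therefore saturates it and
#' pushes the optimizer toward new frameworks.
#'
#' @param score raw reward score.
#' @param scaffold scaffold key (from [murckoScaffold()]).
#' @param tracker a [scaffoldTracker()] (mutated in place).
#' @param limit bucket capacity, >= 1 (Inf disables).
#' @return adjusted score.
#' @export
diversityFilter <- function(score, scaffold, tracker, limit) {
  stopifnot(limit >= 1)
  # acyclic molecules share the sentinel scaffold; give it a usable key
  key <- if (nzchar(scaffold)) as.character(scaffold) else "<acyclic>"
  i <- match(key, names(tracker$counts))
  n <- if (is.na(i)) 0 else tracker$counts[[i]]
  adjusted <- if (n >= limit) 0 else score
  if (score > 0) tracker$counts[key] <- n + 1
  adjusted
}

# ---- the GA loop -----------------------------------------------------------

#' Run the generative optimizer
#'
#' Generate -> score -> select, with elitism and the scaffold diversity
#' filter standing in for the agent's policy update. Every evaluated
#' molecule is recorded; identical configuration and seed give bit-identical
#' trajectories. Selection pressure acts on the diversity-adjusted score;
#' elitism ranks by raw score, so the best-so-far raw score is
#' non-decreasing across generations.
#'
#' @param config a [GAConfig-class].
#' @param spec a [RewardSpec-class].
#' @param predictors named predictor list, as in [scoreMolecule()].
#' @param seedPopulation non-empty list of [Molecule-class] (or character
#'   SMILES) used to initialize the population.
#' @return a [GenerationTrajectory-class].
#' @export
runGA <- function(config, spec, predictors, seedPopulation) {
  validObject(config)
  if (length(seedPopulation) == 0L)
    stop("seed population must be non-empty", call. = FALSE)
  if (is.character(seedPopulation)) seedPopulation <- as.list(seedPopulation)
  seedPopulation <- lapply(seedPopulation, function(m)
    if (is.character(m)) parseSmiles(m) else m)
  .withSeed(config@seed, {
    pop <- seedPopulation
    while (length(pop) < config@populationSize) {
      pop[[length(pop) + 1L]] <-
        mutateMolecule(pop[[sample.int(length(seedPopulation), 1L)]])
    }
    pop <- pop[seq_len(config@populationSize)]
    tracker <- scaffoldTracker()
    cache <- new.env(parent = emptyenv())
    evalOne <- function(mol) {
      key <- mol@smiles
      if (!is.null(cache[[key]])) return(cache[[key]])
      r <- scoreMolecule(mol, spec, predictors)
      scaf <- as.character(murckoScaffold(mol, config@scaffoldMode))
      res <- list(score = r$score, scaffold = scaf,
                  vetoes = paste(r$vetoes, collapse = ","))
      cache[[key]] <- res
      res
    }
    rows <- list()
    for (g in seq_len(config@generations)) {
      evals <- lapply(pop, evalOne)
      raw <- vapply(evals, `[[`, 0, "score")
      scafs <- vapply(evals, `[[`, "", "scaffold")
      adj <- vapply(seq_along(pop), function(i) {
        if (is.finite(config@scaffoldBucketLimit))
          diversityFilter(raw[i], scafs[i], tracker,
                          config@scaffoldBucketLimit)
        else raw[i]
      }, numeric(1))
      rows[[g]] <- data.frame(
        generation = g,
        smiles = vapply(pop, function(m) m@smiles, character(1)),
        score = raw, adjusted_score = adj, scaffold = scafs,
        vetoes = vapply(evals, `[[`, "", "vetoes"),
        stringsAsFactors = FALSE)
      if (g == config@generations) break
      # deterministic ranking: score desc, canonical SMILES as tie-break
      smi <- rows[[g]]$smiles
      eliteIdx <- head(order(-raw, smi, method = "radix"), config@elitism)
      tournament <- function() {
        cand <- sample.int(length(pop), config@tournamentSize,
                           replace = TRUE)
        best <- cand[order(-adj[cand], smi[cand], method = "radix")][1]
        pop[[best]]
      }
      nxt <- pop[eliteIdx]
      while (length(nxt) < config@populationSize) {
        child <- if (stats::runif(1) < config@crossoverRate) {
          p1 <- tournament(); p2 <- tournament()
          crossoverMolecules(p1, p2, fallback = p1)
        } else tournament()
        if (stats::runif(1) < config@mutationRate)
          child <- mutateMolecule(child)
        nxt[[length(nxt) + 1L]] <- child
      }
      pop <- nxt
    }
    new("GenerationTrajectory", table = do.call(rbind, rows),
        config = config)
  })
}

#' @rdname GenerationTrajectory-class
#' @param x a GenerationTrajectory.
#' @export
trajectoryTable <- function(x) x@table

#' @rdname GenerationTrajectory-class
#' @export
trajectoryConfig <- function(x) x@config

setMethod("show", "GenerationTrajectory", function(object) {
  t <- object@table
  cat("GenerationTrajectory:", max(t$generation), "generations,",
      nrow(t), "evaluations,", length(unique(t$smiles)),
      "unique molecules | best score", signif(max(t$score), 4), "\n")
})

#' Cumulative scaffold occurrence over generations
#'
#' For each scaffold key, the cumulative number of generated molecules
#' carrying it up to each generation (one scaffold - the maximal framework -
#' per molecule). The per-scaffold series are non-decreasing and their sum
#' at each generation equals the number of molecules evaluated so far.
#'
#' @param traj a [GenerationTrajectory-class].
#' @param mode optional scaffold mode; when it differs from the run's
#'   tracked mode the scaffolds are recomputed from the stored SMILES.
#' @return data.frame: \code{scaffold}, \code{generation},
#'   \code{cumulative}.
#' @export
scaffoldOccurrence <- function(traj, mode = NULL) {
  t <- traj@table
  if (nrow(t) == 0L) stop("empty trajectory", call. = FALSE)
  scaf <- t$scaffold
  if (!is.null(mode) && !identical(mode, traj@config@scaffoldMode)) {
    scaf <- vapply(t$smiles, function(s)
      as.character(murckoScaffold(parseSmiles(s), mode)), character(1))
  }
  gens <- sort(unique(t$generation))
  keys <- sort(unique(scaf), method = "radix")
  counts <- table(factor(scaf, levels = keys),
                  factor(t$generation, levels = gens))
  cum <- t(apply(counts, 1, cumsum))
  if (length(gens) == 1L) cum <- matrix(counts, ncol = 1L)
  df <- expand.grid(scaffold = keys, generation = gens,
                    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  df$cumulative <- as.vector(cum[cbind(match(df$scaffold, keys),
                                       match(df$generation, gens))])
  df[order(df$scaffold, df$generation, method = "radix"), , drop = FALSE]
}

#' Top-k scores per generation
#'
#' The k best raw scores of each generation, descending, ties broken by
#' canonical SMILES order. Generations smaller than k return all their
#' scores and are flagged in the \code{truncated} attribute.
#'
#' @param traj a [GenerationTrajectory-class].
#' @param k how many scores per generation (default 10).
#' @return data.frame: \code{generation}, \code{rank}, \code{score},
#'   \code{smiles}.
#' @export
topKScores <- function(traj, k = 10L) {
  stopifnot(k >= 1L)
  t <- traj@table
  out <- lapply(sort(unique(t$generation)), function(g) {
    sub <- t[t$generation == g, , drop = FALSE]
    sub <- sub[order(-sub$score, sub$smiles, method = "radix"), , drop = FALSE]
    sub <- head(sub, k)
    data.frame(generation = g, rank = seq_len(nrow(sub)),
               score = sub$score, smiles = sub$smiles,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  short <- vapply(split(t$generation, t$generation), length, 0L) < k
  attr(res, "truncated") <- as.integer(names(short)[short])
  res
}

#' Persist a trajectory as CSV plus a JSON run manifest
#'
#' @param traj a [GenerationTrajectory-class].
#' @param csvPath trajectory CSV path.
#' @param manifestPath optional JSON manifest path (config echo).
#' @param preset optional preset name recorded in the manifest.
#' @export
writeTrajectory <- function(traj, csvPath, manifestPath = NULL,
                            preset = NA_character_) {
  utils::write.csv(traj@table, csvPath, row.names = FALSE)
  if (!is.null(manifestPath)) {
    cfg <- traj@config
    manifest <- list(
      preset = preset, seed = cfg@seed,
      population_size = cfg@populationSize, generations = cfg@generations,
      mutation_rate = cfg@mutationRate, crossover_rate = cfg@crossoverRate,
      tournament_size = cfg@tournamentSize, elitism = cfg@elitism,
      scaffold_bucket_limit = cfg@scaffoldBucketLimit,
      scaffold_mode = cfg@scaffoldMode,
      package_version = as.character(utils::packageVersion("photoforge")))
    jsonlite::write_json(manifest, manifestPath, auto_unbox = TRUE,
                         pretty = TRUE)
  }
  invisible(csvPath)
}
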