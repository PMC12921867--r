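# Triage funnel: criteria semantics, rate ratio, Butina clustering,
# condensation enumeration, lead screening.

test_that("criteria filtering honors strict comparators and row order", {
  pool <- data.frame(
    smiles = c("a", "b", "c"),
    delta_e_t = c(60.0, 61.0, 65.0),
    lambda_max = c(351, 351, 349),
    lambda_max_stda = c(326, 326, 326))
  res <- filterByCriteria(pool, criteriaPreset("global-triage"))
  expect_identical(res$survivors$smiles, "b")     # 60.0 fails "> 60"
  expect_identical(res$report$pass, c(FALSE, TRUE, FALSE))
  # empty criteria = identity
  res0 <- filterByCriteria(pool, criteria(character(0), character(0),
                                          numeric(0)))
  expect_identical(res0$survivors, pool)
  # row independence: filter(A U B) = filter(A) U filter(B)
  a <- pool[1:2, ]; b <- pool[3, ]
  fa <- filterByCriteria(a, criteriaPreset("global-triage"))$survivors
  fb <- filterByCriteria(b, criteriaPreset("global-triage"))$survivors
  fab <- filterByCriteria(rbind(a, b),
                          criteriaPreset("global-triage"))$survivors
  expect_identical(fab$smiles, c(fa$smiles, fb$smiles))
  # missing property is a hard error naming molecule and property
  expect_error(filterByCriteria(pool[, 1:3],
                                criteriaPreset("global-triage")),
               "lambda_max_stda")
  pool$delta_e_t[2] <- NA
  expect_error(filterByCriteria(pool, criteriaPreset("global-triage")),
               "delta_e_t.*b")
})

test_that("rate ratio arithmetic, domain flagging and monotonicity", {
  expect_equal(rateRatio(1e8, 1e6)$ratio, 8 / 6)
  expect_equal(rateRatio(1e6, 1e6)$ratio, 1)
  r <- rateRatio(1e6, 0.5)
  expect_false(r$defined)
  expect_true(is.na(r$ratio))
  expect_error(rateRatio(-1, 1e6), "positive")
  k <- 10^seq(2, 9)
  expect_true(all(diff(rateRatio(k, rep(1e6, 8))$ratio) > 0))
  expect_true(all(diff(rateRatio(rep(1e8, 8), k)$ratio) < 0))
})

test_that("butina clustering matches a brute-force leader oracle", {
  pool <- diverseSmiles()[1:30]
  mols <- lapply(pool, parseSmiles)
  can <- vapply(mols, smiles, character(1))
  fps <- lapply(mols, morganFingerprint)
  cutoff <- 0.6
  got <- butinaCluster(fps, cutoff = cutoff, labels = can)
  # independent O(n^2) re-implementation
  n <- length(fps)
  d <- matrix(0, n, n)
  for (i in 1:n) for (j in 1:n)
    d[i, j] <- 1 - tanimotoSimilarity(fps[[i]], fps[[j]])
  nbr <- lapply(1:n, function(i) setdiff(which(d[i, ] <= cutoff), i))
  # leaders in order of (static) neighbor count, ties by canonical SMILES
  free <- rep(TRUE, n)
  oracleAssign <- rep(NA_integer_, n); oracleLeaders <- integer(0)
  cl <- 0L
  for (lead in order(-lengths(nbr), can, method = "radix")) {
    if (!free[lead]) next
    cl <- cl + 1L
    oracleLeaders[cl] <- lead
    members <- c(lead, nbr[[lead]][free[nbr[[lead]]]])
    oracleAssign[members] <- cl
    free[members] <- FALSE
  }
  expect_identical(got$leaders, oracleLeaders)
  expect_identical(got$assignment, oracleAssign)
  # every member within cutoff of its leader; leaders pairwise beyond it
  for (i in 1:n)
    expect_lte(d[i, got$leaders[got$assignment[i]]], cutoff)
  L <- got$leaders
  if (length(L) > 1) {
    for (i in seq_along(L)) for (j in seq_along(L)) {
      if (i < j) expect_gt(d[L[i], L[j]], cutoff)
    }
  }
})

test_that("cluster selection picks objective maximizers per cluster", {
  pool <- data.frame(
    smiles = c("c1ccccc1", "Cc1ccccc1", "CCc1ccccc1", "C1CCCCC1",
               "CC1CCCCC1"),
    delta_e_t = c(60, 65, 63, 70, 59))
  out <- clusterSelect(pool, "delta_e_t", cutoff = 0.55)
  expect_true(all(tapply(seq_len(nrow(out)), out$cluster, function(ix) {
    rep <- ix[out$representative[ix]]
    out$delta_e_t[rep] == max(out$delta_e_t[ix])
  })))
  # degenerate pools
  same <- data.frame(smiles = rep("c1ccccc1", 4), delta_e_t = 1:4)
  outSame <- clusterSelect(same, "delta_e_t", cutoff = 0.3)
  expect_equal(max(outSame$cluster), 1)
  expect_equal(sum(outSame$representative), 1)
  apart <- data.frame(smiles = c("c1ccccc1", "CCCCCC", "ClC(Cl)(Cl)Cl"),
                      delta_e_t = c(1, 2, 3))
  outApart <- clusterSelect(apart, "delta_e_t", cutoff = 0.05)
  expect_equal(max(outApart$cluster), 3)
  # nMax truncates by representative objective
  out1 <- clusterSelect(apart, "delta_e_t", cutoff = 0.05, nMax = 1)
  sel <- attr(out1, "selected")
  expect_equal(nrow(sel), 1)
  expect_equal(sel$delta_e_t, 3)
  expect_error(clusterSelect(apart[0, ], "delta_e_t"), "empty")
})

test_that("condensation reproduces the known quinoxaline product", {
  rs <- reagentSet(list("Nc1ccccc1N"),
                   list("O=C(c1ccccc1)C(=O)c1ccccc1"))
  out <- enumerateCondensation(rs)
  expect_equal(nrow(out), 1)
  expect_identical(out$smiles,
                   canonicalSmiles("c1ccc(-c2nc3ccccc3nc2-c2ccccc2)cc1"))
  expect_true(containsFusedPyrazine(parseSmiles(out$smiles)))
})

test_that("reagent motifs are validated at construction", {
  expect_error(reagentSet(list("Nc1ccccc1"), list("CC(=O)C(C)=O")),
               "ortho-diamine")
  expect_error(reagentSet(list("Nc1ccccc1N"), list("CC(=O)C")),
               "1,2-diketone")
})

test_that("unsymmetric reagents give at most two regiochemical products", {
  # unsymmetric diamine x unsymmetric diketone: both orientations distinct
  rs <- reagentSet(list("Nc1ccc(C)cc1N"), list("CC(=O)C(=O)c1ccccc1"))
  out <- enumerateCondensation(rs)
  expect_equal(nrow(out), 2)
  expect_lte(nrow(out), 2 * 1 * 1)
  # symmetric partner collapses the orientations
  rs2 <- reagentSet(list("Nc1ccccc1N"), list("CC(=O)C(=O)c1ccccc1"))
  expect_equal(nrow(enumerateCondensation(rs2)), 1)
})

test_that("local screening applies the lead criteria to the full library", {
  lib <- enumerateCondensation(fixtureReagents())
  expect_equal(nrow(lib), 18)
  preds <- fixturePredictors()
  res <- screenLocal(lib, preds)
  expect_equal(nrow(res$report), 18)
  # brute-force hand filter over the fixture table
  tab <- fixturePropertyTable()
  tab <- tab[match(lib$smiles, tab$smiles), ]
  rr <- log10(tab$k_isc) / log10(tab$k_f)
  manual <- tab$delta_e_t > 57 & tab$lambda_max > 290 & rr > 0.65
  expect_equal(sort(res$leads$smiles), sort(tab$smiles[manual]))
  expect_equal(nrow(res$leads), 4)
  # impossible thresholds give zero leads without error
  none <- screenLocal(lib, preds,
                      criteria("delta_e_t", ">", 1000))
  expect_equal(nrow(none$leads), 0)
  empty <- screenLocal(lib[0, ], preds)
  expect_equal(nrow(empty$leads), 0)
})
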