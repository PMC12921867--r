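# Molecular graph core: canonicalization, alerts, conjugation descriptor,
# scaffolds, fingerprints.

test_that("canonicalization maps equivalent spellings to one idempotent form", {
  expect_identical(canonicalSmiles("C1=CC=CC=C1"), canonicalSmiles("c1ccccc1"))
  pool <- mutatedPool(60)
  for (m in pool) {
    can <- smiles(m)
    expect_identical(canonicalSmiles(can), can)
  }
})

test_that("parsing builds the expected graph and errors on junk", {
  bp <- parseSmiles("O=C(c1ccccc1)c1ccccc1", name = "benzophenone")
  expect_s4_class(bp, "Molecule")
  expect_equal(nrow(atomTable(bp)), 14)
  expect_equal(nrow(bondTable(bp)), 15)
  expect_identical(molName(bp), "benzophenone")
  expect_error(parseSmiles("not_a_smiles"), "unparsable SMILES")
})

test_that("default alerts match the excluded motifs", {
  expect_identical(matchAlerts(parseSmiles("O=C(c1ccccc1)c1ccccc1")),
                   "carbonyl")
  expect_length(matchAlerts(parseSmiles("c1ccccc1")), 0)
  expect_setequal(matchAlerts(parseSmiles("NNc1ccccc1")),
                  c("het_het_bond", "aliphatic_amine"))
  expect_identical(matchAlerts(parseSmiles("OCc1ccccc1")), "alcohol")
  expect_identical(matchAlerts(parseSmiles("C=Cc1ccccc1")), "olefin")
  # ring olefins count as olefins (photodecomposition is not ring-specific)
  expect_identical(matchAlerts(parseSmiles("C1=CCCCC1")), "olefin")
  expect_length(matchAlerts(parseSmiles("Nc1ccccc1")), 0)  # anilines pass
})

test_that("alert matching agrees with a brute-force enumeration oracle", {
  mols <- lapply(diverseSmiles(), parseSmiles)
  # naive per-atom / per-bond oracle, written independently of the
  # vectorized predicates
  oracle <- function(m) {
    a <- atomTable(m); b <- bondTable(m)
    hits <- character(0)
    het <- c("N", "O", "S", "P")
    multi <- function(i) {
      any(vapply(seq_len(nrow(b)), function(k)
        (b$a1[k] == i || b$a2[k] == i) && !b$aromatic[k] && b$order[k] >= 2,
        logical(1)))
    }
    for (k in seq_len(nrow(b))) {
      e1 <- a$element[b$a1[k]]; e2 <- a$element[b$a2[k]]
      if (!b$aromatic[k] && b$order[k] == 2 &&
          setequal(c(e1, e2), c("C", "O")))
        hits <- c(hits, "carbonyl")
      if (b$order[k] <= 2 && e1 %in% het && e2 %in% het)
        hits <- c(hits, "het_het_bond")
      if (!b$aromatic[k] && b$order[k] == 2 && e1 == "C" && e2 == "C")
        hits <- c(hits, "olefin")
    }
    for (i in seq_len(nrow(a))) {
      nbrs <- unique(c(b$a2[b$a1 == i], b$a1[b$a2 == i]))
      if (a$element[i] == "N" && !a$aromatic[i] && a$charge[i] == 0 &&
          !multi(i) && length(nbrs) >= 1 && !any(a$aromatic[nbrs]))
        hits <- c(hits, "aliphatic_amine")
      if (a$element[i] == "O" && !a$aromatic[i] && a$hcount[i] >= 1 &&
          !multi(i) && length(nbrs) == 1 && a$element[nbrs] == "C")
        hits <- c(hits, "alcohol")
    }
    sort(unique(hits))
  }
  for (m in mols) {
    expect_identical(sort(matchAlerts(m)), oracle(m), label = smiles(m))
  }
})

test_that("SMARTS-expressible alerts agree with the OpenBabel matcher", {
  skip_if_not(obabelAvailable())
  patterns <- c(carbonyl = "[#6]=[OX1]",
                olefin = "[C;!c]=[C;!c]",
                het_het_bond = "[#7,#8,#16,#15]~[#7,#8,#16,#15]")
  for (s in diverseSmiles()) {
    m <- parseSmiles(s)
    hits <- matchAlerts(m)
    for (nm in names(patterns)) {
      expect_identical(nm %in% hits, obabelMatches(smiles(m), patterns[[nm]]),
                       label = paste(s, nm))
    }
  }
})

test_that("custom SMARTS alert patterns are honored", {
  skip_if_not(obabelAvailable())
  cat <- alertCatalog("nitro", "[N+](=O)[O-]")
  expect_identical(matchAlerts(parseSmiles("O=[N+]([O-])c1ccccc1"), cat),
                   "nitro")
  expect_length(matchAlerts(parseSmiles("c1ccccc1"), cat), 0)
})

test_that("conjugated fraction matches hand counts and stays in range", {
  expect_equal(fractionConjugated(parseSmiles("c1ccccc1")), 1)
  expect_equal(fractionConjugated(parseSmiles("CC")), 0)
  expect_equal(fractionConjugated(parseSmiles("CCc1ccccc1")), 0.75)
  # every fused aromatic hydrocarbon is fully conjugated
  for (s in c("c1ccc2ccccc2c1", "c1ccc2cc3ccccc3cc2c1",
              "c1ccc2c(c1)ccc1ccccc12")) {
    expect_equal(fractionConjugated(parseSmiles(s)), 1)
  }
  pool <- mutatedPool(40)
  th <- vapply(pool, quietTheta, numeric(1))
  expect_true(all(th >= 0 & th <= 1))
  # appending sp3 substituents never increases theta
  chains <- list(c("c1ccccc1", "Cc1ccccc1", "CCc1ccccc1", "CCCc1ccccc1"),
                 c("c1ccncc1", "Cc1ccncc1"),
                 c("c1ccc2ccccc2c1", "Cc1ccc2ccccc2c1"))
  for (ch in chains) {
    th2 <- vapply(lapply(ch, parseSmiles), quietTheta, numeric(1))
    expect_true(all(diff(th2) <= 1e-12), label = ch[1])
  }
})

test_that("scaffolds prune side chains, keep exocyclic carbonyls, idempotent", {
  expect_identical(as.character(murckoScaffold(parseSmiles("CCc1ccccc1"))),
                   "c1ccccc1")
  expect_identical(as.character(murckoScaffold(parseSmiles("CCCCCC"))), "")
  tx <- parseSmiles("O=C1c2ccccc2Sc2ccccc21")
  expect_identical(as.character(murckoScaffold(tx)), smiles(tx))
  dpq <- parseSmiles("CCc1ccc(-c2nc3ccccc3nc2-c2ccccc2)cc1")
  for (mode in c("murcko", "generic_bonds", "fully_generic")) {
    k1 <- murckoScaffold(dpq, mode)
    k2 <- murckoScaffold(parseSmiles(as.character(k1)), mode)
    expect_identical(as.character(k2), as.character(k1), label = mode)
  }
  # fully generic keys still distinguish different ring-atom counts
  pyrido <- parseSmiles("c1ccc(-c2nc3ncccc3nc2-c2ccccc2)cc1")
  expect_false(identical(
    as.character(murckoScaffold(dpq, "fully_generic")),
    as.character(murckoScaffold(parseSmiles("c1ccc2ccccc2c1"),
                                "fully_generic"))))
  # heteroatom-only differences collapse under fully_generic...
  expect_identical(
    as.character(murckoScaffold(parseSmiles("c1ccncc1"), "fully_generic")),
    as.character(murckoScaffold(parseSmiles("c1ccccc1"), "fully_generic")))
  # ...but are kept by the default atom-typed mode
  expect_false(identical(
    as.character(murckoScaffold(parseSmiles("c1ccncc1"))),
    as.character(murckoScaffold(parseSmiles("c1ccccc1")))))
  expect_identical(as.character(murckoScaffold(pyrido)),
                   smiles(pyrido))
})

test_that("equal murcko keys imply equal fully generic keys (coarsening)", {
  pool <- c(lapply(diverseSmiles(), parseSmiles), mutatedPool(30))
  mk <- vapply(pool, function(m) as.character(murckoScaffold(m)),
               character(1))
  fg <- vapply(pool, function(m)
    as.character(murckoScaffold(m, "fully_generic")), character(1))
  for (key in unique(mk[nzchar(mk)])) {
    expect_length(unique(fg[mk == key]), 1)
  }
})

test_that("fingerprints are deterministic and structure-sensitive", {
  f1 <- morganFingerprint(parseSmiles("C1=CC=CC=C1"))
  f2 <- morganFingerprint(parseSmiles("c1ccccc1"))
  expect_identical(f1, f2)
  f3 <- morganFingerprint(parseSmiles("c1ccncc1"))
  expect_lt(tanimotoSimilarity(f1, f3), 1)
  expect_equal(tanimotoSimilarity(f1, f1), 1)
  expect_length(f1, 2048)
  f4 <- morganFingerprint(parseSmiles("c1ccccc1"), radius = 3, nbits = 512)
  expect_length(f4, 512)
})

test_that("smi and CSV round trips preserve molecules", {
  pcs <- knownPhotocatalysts()
  p <- withr::local_tempfile(fileext = ".smi")
  writeSmiles(pcs, p)
  back <- readSmiles(p)
  expect_identical(vapply(back, smiles, character(1)),
                   unname(vapply(pcs, smiles, character(1))))
  expect_identical(vapply(back, molName, character(1)),
                   unname(vapply(pcs, molName, character(1))))
  csv <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(smiles = "C1=CC=CC=C1", delta_e_t = 84), csv,
            row.names = FALSE)
  df <- readMoleculeCSV(csv)
  expect_identical(df$smiles, "c1ccccc1")
  noSmiles <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(x = 1), noSmiles, row.names = FALSE)
  expect_error(readMoleculeCSV(noSmiles), "smiles")
})
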