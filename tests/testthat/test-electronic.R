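# Hueckel engine: closed-form spectra, pairing theorem, frontier overlap,
# proxy algebra.

betaEV <- 2.4

chainSmiles <- function(n) {
  # linear polyene with n pi carbons (n even): C=CC=C...
  paste(rep("C=C", n / 2), collapse = "")
}

ringSmiles <- function(n) {
  # cyclic polyene ring of n carbons written kekulized
  inner <- paste(rep("C=C", (n - 2) / 2), collapse = "")
  paste0("C1=C", inner, "1")
}

test_that("chain spectra match the closed form 2 cos(k pi / (n+1))", {
  for (n in c(2, 4, 6, 8, 10, 12)) {
    orb <- solveHuckel(buildPiSystem(parseSmiles(chainSmiles(n)),
                                     betaEV = betaEV))
    x <- sort(-orbitalEnergies(orb) / betaEV, decreasing = TRUE)
    expected <- sort(2 * cos(seq_len(n) * pi / (n + 1)), decreasing = TRUE)
    expect_equal(x, expected, tolerance = 1e-10, label = paste("chain", n))
  }
})

test_that("ring spectra match the closed form 2 cos(2 pi k / n)", {
  for (n in c(4, 6, 8, 10, 12)) {
    smi <- if (n == 6) "c1ccccc1" else ringSmiles(n)
    orb <- solveHuckel(buildPiSystem(parseSmiles(smi), betaEV = betaEV))
    x <- sort(-orbitalEnergies(orb) / betaEV, decreasing = TRUE)
    expected <- sort(2 * cos(2 * pi * seq(0, n - 1) / n), decreasing = TRUE)
    expect_equal(x, expected, tolerance = 1e-10, label = paste("ring", n))
  }
})

test_that("named systems reproduce the textbook energies", {
  orb <- solveHuckel(buildPiSystem(parseSmiles("C=C"), betaEV = betaEV))
  expect_equal(orbitalEnergies(orb), c(-betaEV, betaEV), tolerance = 1e-10)
  expect_equal(homoLumoGap(orb), 2 * betaEV, tolerance = 1e-10)
  orb <- solveHuckel(buildPiSystem(parseSmiles("C=CC=C"), betaEV = betaEV))
  phi <- (1 + sqrt(5)) / 2
  expect_equal(sort(-orbitalEnergies(orb) / betaEV, decreasing = TRUE),
               c(phi, phi - 1, 1 - phi, -phi), tolerance = 1e-10)
  orb <- solveHuckel(buildPiSystem(parseSmiles("c1ccccc1"), betaEV = betaEV))
  expect_equal(homoLumoGap(orb), 2 * betaEV, tolerance = 1e-10)
  expect_equal(lambdaMaxFromGap(orb), 1239.84 / 4.8, tolerance = 1e-10)
})

test_that("alternant hydrocarbons obey the pairing theorem", {
  for (smi in c("C=CC=C", "C=CC=CC=C", "c1ccccc1", "c1ccc2ccccc2c1",
                "C=Cc1ccccc1")) {
    orb <- solveHuckel(buildPiSystem(parseSmiles(smi)))
    e <- orbitalEnergies(orb)
    expect_equal(e, -rev(e), tolerance = 1e-8, label = smi)
  }
})

test_that("orbitals are orthonormal", {
  for (smi in c("c1ccncc1", "O=C(c1ccccc1)c1ccccc1", "c1ccc2nccnc2c1")) {
    orb <- solveHuckel(buildPiSystem(parseSmiles(smi)))
    co <- orbitalCoefficients(orb)
    gram <- crossprod(co)
    expect_equal(gram, diag(ncol(co)), tolerance = 1e-8, label = smi)
  }
})

test_that("pi systems assign heteroatom parameters and electron counts", {
  ps <- buildPiSystem(parseSmiles("c1ccncc1"))
  expect_equal(piElectrons(ps), 6)
  expect_equal(sum(ps@hShift > 0), 1)  # the pyridine N
  ps <- buildPiSystem(parseSmiles("c1cc[nH]c1"))
  expect_equal(piElectrons(ps), 6)     # pyrrole N donates two
  ps <- buildPiSystem(parseSmiles("Nc1ccccc1"))
  expect_equal(piElectrons(ps), 8)     # aniline N lone pair joins
  expect_length(piAtomIndices(ps), 7)
  expect_error(buildPiSystem(parseSmiles("CC")), "no conjugation")
})

test_that("frontier overlap is bounded, symmetric cases exact", {
  orb <- solveHuckel(buildPiSystem(parseSmiles("C=C")))
  expect_equal(fmoOverlap(orb), 1, tolerance = 1e-12)
  # disjoint frontier densities give zero overlap
  disjoint <- new("OrbitalSet",
                  energies = c(-1, -0.5, 0.5, 1),
                  coefficients = cbind(
                    c(1, 0, 0, 0),
                    c(0, 1, 0, 0) / 1,
                    c(0, 0, 1, 0),
                    c(0, 0, 0, 1)),
                  homoIndex = 2L, lumoIndex = 3L, nElectrons = 4L)
  expect_equal(fmoOverlap(disjoint), 0)
  # permutation of atom labels leaves the overlap unchanged
  orb <- solveHuckel(buildPiSystem(parseSmiles("O=C(c1ccccc1)c1ccccc1")))
  perm <- sample(nrow(orbitalCoefficients(orb)))
  shuffled <- new("OrbitalSet", energies = orbitalEnergies(orb),
                  coefficients = orbitalCoefficients(orb)[perm, ],
                  homoIndex = homoIndex(orb), lumoIndex = lumoIndex(orb),
                  nElectrons = orb@nElectrons)
  expect_equal(fmoOverlap(shuffled), fmoOverlap(orb), tolerance = 1e-12)
})

test_that("overlap stays in [0,1] over random pi systems", {
  set.seed(11)
  for (rep in seq_len(200)) {
    n <- sample(3:10, 1)
    # random connected graph: spanning tree plus extra edges
    edges <- cbind(2:n, vapply(2:n, function(i) sample(i - 1, 1), 1L))
    extra <- sample(0:2, 1)
    if (extra > 0) {
      more <- t(replicate(extra, sort(sample(n, 2))))
      edges <- rbind(edges, more)
    }
    edges <- unique(edges)
    sys <- new("PiSystem", atomIdx = seq_len(n),
               elements = rep("C", n),
               hShift = runif(n, -0.5, 2),
               adjacency = edges,
               bondScale = runif(nrow(edges), 0.5, 1.2),
               nElectrons = as.integer(2 * sample(1:(n - 1), 1)),
               betaEV = 2.4)
    o <- fmoOverlap(solveHuckel(sys))
    expect_gte(o, 0)
    expect_lte(o, 1)
  }
})

test_that("proxy algebra behaves as specified", {
  expect_equal(deltaEstProxy(0, slope = 1, intercept = 0), 0)
  expect_equal(deltaEstProxy(0.5, slope = 1, intercept = 0), 0.5)
  expect_error(deltaEstProxy(0.5, slope = -1), "slope")
  o <- sort(runif(20))
  d <- deltaEstProxy(o, slope = 0.8, intercept = 0.1)
  expect_true(all(diff(d) >= 0))
  expect_equal(kiscGoldenRule(1, 1), 1)
  expect_equal(kiscGoldenRule(2, 1), 4)
  expect_equal(kiscGoldenRule(1, 2), 0.25)
  expect_error(kiscGoldenRule(1, 0), "delta_e_st")
  # exact homogeneity: soc x s, gap x d scales the proxy by s^2/d^2
  set.seed(3)
  soc <- runif(10, 0.1, 2); gap <- runif(10, 0.1, 1)
  s <- 3.7; d <- 1.9
  expect_equal(kiscGoldenRule(s * soc, d * gap),
               kiscGoldenRule(soc, gap) * s^2 / d^2)
  expect_identical(classifyCharacter(c(0.05, 0.95, 0.5)),
                   c("CT", "LE", "LE"))
  expect_error(lambdaMaxFromGap(disjointGap <- new("OrbitalSet",
    energies = c(-1, -1), coefficients = diag(2),
    homoIndex = 1L, lumoIndex = 2L, nElectrons = 2L)), "gap")
})

test_that("parameter tables round-trip through YAML", {
  p <- withr::local_tempfile(fileext = ".yaml")
  writeHuckelParameters(huckelParameters(), p)
  back <- readHuckelParameters(p)
  expect_equal(back, huckelParameters())
  shipped <- system.file("extdata", "huckel_params.yaml",
                         package = "photoforge")
  expect_true(nzchar(shipped))
  expect_equal(readHuckelParameters(shipped), huckelParameters())
})
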