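# Reward algebra: transforms, aggregation, vetoes, preset behavior.

test_that("transform families hit their anchor values", {
  expect_equal(applyTransform(58, scoreTransform("sigmoid_up", 58)), 0.5)
  expect_equal(applyTransform(58, scoreTransform("sigmoid_down", 58)), 0.5)
  expect_equal(applyTransform(366, scoreTransform("step_up", 365)), 1)
  expect_equal(applyTransform(364, scoreTransform("step_up", 365)), 0)
  expect_equal(applyTransform(365, scoreTransform("step_up", 365)), 0)
  expect_equal(applyTransform(364, scoreTransform("step_down", 365)), 1)
  ds <- scoreTransform("double_sigmoid", c(55, 80), steepness = 1)
  lo <- applyTransform(55, ds); mid <- applyTransform(67.5, ds)
  hi <- applyTransform(80, ds)
  expect_gte(mid, lo); expect_gte(mid, hi)
  expect_equal(lo, 0.5, tolerance = 1e-6)  # edge: 0.5 x (almost 1)
  expect_equal(hi, lo, tolerance = 1e-10)  # symmetric band
})

test_that("transform outputs stay in [0,1] under fuzzing", {
  set.seed(23)
  kinds <- c("sigmoid_up", "sigmoid_down", "double_sigmoid", "step_up",
             "step_down")
  for (i in seq_len(1000)) {
    kind <- sample(kinds, 1)
    center <- if (kind == "double_sigmoid")
      sort(runif(2, -100, 100)) + c(0, 1e-6) else runif(1, -100, 100)
    t <- scoreTransform(kind, center, steepness = runif(1, 1e-3, 10))
    x <- runif(1, -1e4, 1e4)
    s <- applyTransform(x, t)
    expect_gte(s, 0); expect_lte(s, 1)
  }
})

test_that("sigmoid monotonicity holds in the rewarded direction", {
  xs <- seq(20, 120, length.out = 41)
  up <- applyTransform(xs, scoreTransform("sigmoid_up", 58))
  dn <- applyTransform(xs, scoreTransform("sigmoid_down", 58))
  expect_true(all(diff(up) >= 0))
  expect_true(all(diff(dn) <= 0))
})

test_that("aggregation is a bounded weighted geometric mean", {
  expect_equal(aggregateScores(c(1, 1, 1)), 1)
  expect_equal(aggregateScores(c(0.9, 0, 0.8)), 0)
  expect_equal(aggregateScores(c(0.25, 1)), 0.5)
  expect_equal(aggregateScores(c(0.3, 0.9), vetoed = TRUE), 0)
  set.seed(5)
  for (i in seq_len(200)) {
    n <- sample(1:6, 1)
    s <- runif(n); w <- runif(n, 0.1, 3)
    S <- aggregateScores(s, w)
    expect_gte(S, min(s) - 1e-12)
    expect_lte(S, max(s) + 1e-12)
    # all-equal components give back the common value for any weights
    expect_equal(aggregateScores(rep(s[1], n), w), s[1])
  }
  expect_error(aggregateScores(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_error(aggregateScores(c(0.5), numeric(0)), "length")
  expect_error(aggregateScores(c(0.5, 0.5), c(0, 0)), "weights")
  # raw-product mode multiplies without normalization
  expect_equal(aggregateScores(c(0.5, 0.5), normalize = FALSE), 0.25)
})

test_that("improving a rewarded property never decreases the total score", {
  spec <- rewardSpec(c("delta_e_t", "lambda_max", "o_fmo"),
                     list(scoreTransform("sigmoid_up", 58),
                          scoreTransform("sigmoid_up", 365),
                          scoreTransform("sigmoid_down", 0.5)))
  base <- c(delta_e_t = 60, lambda_max = 370, o_fmo = 0.4)
  total <- function(v) {
    s <- vapply(seq_along(spec@components$property), function(i)
      applyTransform(v[[spec@components$property[i]]],
                     spec@transforms[[i]]), numeric(1))
    aggregateScores(s, spec@components$weight)
  }
  for (d in c(0.5, 2, 10)) {
    up <- base; up["delta_e_t"] <- base["delta_e_t"] + d
    expect_gte(total(up), total(base))
    up <- base; up["o_fmo"] <- base["o_fmo"] - d / 100
    expect_gte(total(up), total(base))
  }
})

test_that("scoring runs vetoes first and handles missing/invalid input", {
  preds <- fixturePredictors()
  bp <- "O=C(c1ccccc1)c1ccccc1"
  r <- scoreMolecule(bp, rewardPreset("exploration"), preds)
  expect_equal(r$score, 0)
  expect_true("carbonyl" %in% r$vetoes)
  expect_true(all(is.na(r$properties)))  # predictors skipped on veto
  r <- scoreMolecule(bp, rewardPreset("rediscovery"), preds)
  expect_gt(r$score, 0)
  expect_length(r$vetoes, 0)
  r <- scoreMolecule("not_a_smiles", rewardPreset("rediscovery"), preds)
  expect_equal(r$score, 0)
  expect_identical(r$vetoes, "invalid")
  # molecule outside every lookup table: missing prediction scores 0
  r <- scoreMolecule("Brc1ccsc1", rewardPreset("rediscovery"), preds)
  expect_equal(r$score, 0)
  expect_true(any(grepl("^missing:", r$vetoes)))
  spec1 <- rewardSpec("theta_conjugation",
                      list(scoreTransform("step_up", 0.5)))
  expect_equal(scoreMolecule("c1ccccc1", spec1, preds)$score, 1)
  expect_error(scoreMolecule("c1ccccc1", rewardPreset("rediscovery"),
                             preds["delta_e_t"]),
               "no predictor")
})

test_that("adding a matched alert to any spec forces the score to zero", {
  preds <- fixturePredictors()
  base <- rewardSpec(c("delta_e_t", "lambda_max"),
                     list(scoreTransform("sigmoid_up", 58),
                          scoreTransform("sigmoid_up", 300)))
  mols <- c("O=C(c1ccccc1)c1ccccc1", "O=C1c2ccccc2Sc2ccccc21")
  for (smi in mols) {
    r0 <- scoreMolecule(smi, base, preds)
    expect_gt(r0$score, 0)
    vetoed <- rewardSpec(c("delta_e_t", "lambda_max"),
                         list(scoreTransform("sigmoid_up", 58),
                              scoreTransform("sigmoid_up", 300)),
                         alerts = defaultAlertCatalog())
    r1 <- scoreMolecule(smi, vetoed, preds)
    expect_identical(r1$score, 0)
  }
})

test_that("reward specs round-trip through YAML", {
  for (name in c("rediscovery", "exploration", "global-triage",
                 "local-lead")) {
    spec <- rewardPreset(name)
    p <- withr::local_tempfile(fileext = ".yaml")
    writeRewardSpec(spec, p)
    back <- readRewardSpec(p)
    expect_equal(back@components, spec@components, label = name)
    expect_equal(back@alerts@alerts, spec@alerts@alerts, label = name)
    expect_equal(length(back@transforms), length(spec@transforms))
    for (i in seq_along(spec@transforms)) {
      expect_equal(back@transforms[[i]]@kind, spec@transforms[[i]]@kind)
      expect_equal(back@transforms[[i]]@center,
                   spec@transforms[[i]]@center)
      expect_equal(back@transforms[[i]]@steepness,
                   spec@transforms[[i]]@steepness)
    }
  }
})

test_that("scored tables carry properties, component scores and flags", {
  preds <- fixturePredictors()
  df <- scoreMolecules(c("c1ccccc1", "O=C(c1ccccc1)c1ccccc1", "xxx"),
                       rewardPreset("exploration"), preds)
  expect_equal(nrow(df), 3)
  expect_true(all(c("smiles", "score", "vetoes", "s_delta_e_t") %in%
                  names(df)))
  expect_equal(df$score[2], 0)
  expect_identical(df$vetoes[3], "invalid")
})
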