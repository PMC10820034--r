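test_that("fragment weights follow the log-scaled m/z-weighted form", {
  expect_identical(fragmentWeight(100, 0), 0)
  expect_equal(fragmentWeight(100, 1), 100 * log(101), tolerance = 1e-12)
  expect_equal(fragmentWeight(200, 0.5), 200 * log(51), tolerance = 1e-12)
  # strictly monotone in both arguments
  expect_gt(fragmentWeight(200, 0.5), fragmentWeight(100, 0.5))
  expect_gt(fragmentWeight(100, 0.8), fragmentWeight(100, 0.2))
  expect_error(fragmentWeight(100, 1.2))
})

# a hand-built fragment chain with a genuinely mass-ambiguous mid-mass ion:
# the C4H8S radical cation (88.03412) also enumerates as C3H8OSi at ~2.6 ppm
chainGroup <- function(withAnchor = TRUE) {
  mzS <- formulaMass(parseFormula("C4H8S"), "cation_generic")
  rows <- data.frame(
    feature_id = c("anchor", "amb", "a2"),
    mz = c(formulaMass(parseFormula("C4H8"), "cation_generic"),
           mzS, mzS + 1.99580),
    rt = 10,
    intensity = c(5e5, 1e6, 4.5e4),
    group_id = "g", isotope_flag = "none", stringsAsFactors = FALSE)
  if (!withAnchor) rows <- rows[-1, ]
  rows
}

test_that("the chain resolves ambiguity through resolved smaller fragments", {
  asg <- assignFragmentFormulas(flagIsotopePeaks(
    FeatureTable(chainGroup(), "fragment_run"))@features,
    ElementConstraints(), ppm = 3)
  # the A+2 companion is isotope-flagged away, leaving two fragments
  expect_length(asg, 2L)
  expect_true(asg[[1]]$resolved)
  expect_equal(formulaToString(asg[[1]]$formulas[[1]]), "C4H8")
  # C4H8 is a subformula of C4H8S but not of the C3H8OSi twin
  expect_true(asg[[2]]$resolved)
  expect_equal(formulaToString(asg[[2]]$formulas[[1]]), "C4H8S")

  # cross-check against exhaustive scoring of every candidate of the
  # ambiguous ion: the assigned formula must carry the maximal support
  w1 <- asg[[1]]$weight
  cand <- goldenRulesFilter(enumerateFormulas(
    chainGroup()$mz[2], 3, ElementConstraints(), "cation_generic"))
  support <- vapply(cand, function(f)
    if (isSubformula(asg[[1]]$formulas[[1]], f)) w1 else 0, numeric(1))
  expect_equal(formulaToString(cand[[which.max(support)]]),
               formulaToString(asg[[2]]$formulas[[1]]))
})

test_that("unsupported ambiguity retains all formulas; noise yields none", {
  # without the anchor no smaller resolved fragment exists: all retained
  asg <- assignFragmentFormulas(flagIsotopePeaks(
    FeatureTable(chainGroup(withAnchor = FALSE), "fragment_run"))@features,
    ElementConstraints(), ppm = 3)
  amb <- asg[[1]]
  expect_false(amb$resolved)
  expect_setequal(vapply(amb$formulas, formulaToString, ""),
                  c("C4H8S", "C3H8OSi"))

  # a mass admitting no formula at all stays unresolved with an empty set
  g <- data.frame(feature_id = "n", mz = 65.512, rt = 10, intensity = 1e4,
                  group_id = "g", isotope_flag = "none")
  asgN <- assignFragmentFormulas(g, ElementConstraints(), ppm = 3)
  expect_false(asgN[[1]]$resolved)
  expect_length(asgN[[1]]$formulas, 0L)
})

test_that("relative intensities are normalized to the unflagged base peak", {
  g <- chainGroup()
  asg <- assignFragmentFormulas(flagIsotopePeaks(
    FeatureTable(g, "fragment_run"))@features, ElementConstraints(), 3)
  expect_equal(vapply(asg, `[[`, numeric(1), "rel_intensity"),
               c(0.5, 1))
  expect_equal(asg[[2]]$weight, fragmentWeight(g$mz[2], 1))
})

mkAssignment <- function(formula, weight, resolved = TRUE) {
  list(feature_id = "x", mz = 100, rel_intensity = 0.5, weight = weight,
       formulas = if (is.null(formula)) list() else list(formula),
       resolved = resolved)
}
mkCandidates <- function(mz) {
  data.frame(feature_id = sprintf("c%d", seq_along(mz)), mz = mz, rt = 10,
             intensity = 1, source_group_id = "g", adduct_evidence = "",
             evidence_source = "deconvoluted", stringsAsFactors = FALSE)
}

test_that("probability scores are supported-weight fractions of resolved evidence", {
  asg <- list(mkAssignment(parseFormula("C2H4O"), 120),
              mkAssignment(parseFormula("C4H8S"), 300))
  # A explains both fragments, B neither, C has no surviving formula
  ranked <- scoreCandidates(asg, mkCandidates(c(117.073, 138.034, 300)),
    list(list(parseFormula("C6H12OS")), list(parseFormula("C10H3N")),
         list()))
  expect_equal(ranked$probability_score, c(100, 0, 0))
  expect_equal(ranked$candidate_mz, c(117.073, 138.034, 300))
  expect_equal(ranked$rank, 1:3)
  expect_equal(ranked$n_supporting_fragments, c(2L, 0L, 0L))
  expect_equal(ranked$assigned_formula, c("C6H12OS", "C10H3N", ""))

  # partial support: 100 * w1 / (w1 + w2)
  ranked2 <- scoreCandidates(asg, mkCandidates(200),
                             list(list(parseFormula("C8H16O4"))))
  expect_equal(ranked2$probability_score, 100 * 120 / 420)
  expect_equal(ranked2$n_supporting_fragments, 1L)

  # agreement with the independent naive scorer
  expect_equal(ranked2$probability_score,
               oracleScore(list(parseFormula("C2H4O"),
                                parseFormula("C4H8S")),
                           c(120, 300), parseFormula("C8H16O4")))

  # D = 0 (nothing resolved) gives score 0, not NaN
  ranked3 <- scoreCandidates(list(mkAssignment(NULL, 50, resolved = FALSE)),
                             mkCandidates(200),
                             list(list(parseFormula("C8H16O4"))))
  expect_equal(ranked3$probability_score, 0)
})

test_that("scores stay in [0,100] and shared support preserves order", {
  set.seed(31)
  pool <- list(parseFormula("CH2O"), parseFormula("C2H4"),
               parseFormula("C2H4O"), parseFormula("C3H6O2"),
               parseFormula("C4H8"), parseFormula("C2H5N"))
  for (trial in 1:20) {
    asg <- lapply(sample(pool, sample(2:5, 1)), function(f)
      mkAssignment(f, runif(1, 10, 500)))
    cands <- mkCandidates(runif(3, 150, 400))
    cf <- list(list(parseFormula("C9H18O4")), list(parseFormula("C10H21N")),
               list(parseFormula("C12H24O2")))
    r1 <- scoreCandidates(asg, cands, cf)
    expect_true(all(r1$probability_score >= 0 &
                    r1$probability_score <= 100))
    # add a fragment that supports every candidate (subformula of all)
    asg2 <- c(asg, list(mkAssignment(parseFormula("CH2"), runif(1, 10, 500))))
    r2 <- scoreCandidates(asg2, cands, cf)
    expect_equal(r2$candidate_mz, r1$candidate_mz)
  }
})

test_that("ranking is empty without candidates and deduplicates across groups", {
  ei <- flagIsotopePeaks(makeFeatureTable(
    c(56.06205, 88.03412), c(5e5, 1e6), rt = 10, group = "e1"))
  # CI spectrum without satellites: no molecular ion is found
  ciNone <- FeatureTable(data.frame(
    feature_id = "c1", mz = 117.07325, rt = 10, intensity = 1e6,
    group_id = "g1"), "molion_run")
  pair <- matchSpectra(ei, flagIsotopePeaks(ciNone), 0.05)[[1]]
  out <- rankMolecularIons(pair, ei, flagIsotopePeaks(ciNone))
  expect_equal(nrow(out), 0L)

  # the same ion seen in two matched CI groups is reported once, keeping
  # the more intense record
  b <- 117.07325
  mk <- function(gid, int) data.frame(
    feature_id = paste0(gid, letters[1:3]), mz = c(b, b + 28.03130,
                                                   b + 40.03130),
    rt = 10, intensity = c(int, int / 10, int / 20), group_id = gid,
    stringsAsFactors = FALSE)
  ci2 <- flagIsotopePeaks(FeatureTable(rbind(mk("g1", 1e6), mk("g2", 3e6)),
                                       "molion_run"))
  pair2 <- matchSpectra(ei, ci2, 0.05)[[1]]
  out2 <- rankMolecularIons(pair2, ei, ci2)
  expect_equal(sum(abs(out2$candidate_mz - b) < 1e-3), 1L)
})

test_that("feature order never changes assignments or ranking", {
  cps <- generateCompoundSet(5, seed = 9)
  ds <- renderDatasets(cps, seed = 9, noiseRate = 0.1)
  r1 <- rankFixture(ds, useRaw = FALSE)
  set.seed(99)
  shuf <- function(ft) FeatureTable(
    features(ft)[sample(nrow(features(ft))), ], runLabel(ft))
  ds2 <- list(ei = shuf(ds$ei), ci = shuf(ds$ci))
  r2 <- rankFixture(ds2, useRaw = FALSE)
  o1 <- r1[order(r1$ei_group_id, r1$rank), ]
  o2 <- r2[order(r2$ei_group_id, r2$rank), ]
  rownames(o1) <- rownames(o2) <- NULL
  expect_equal(o1, o2)
})
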