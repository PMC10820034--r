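test_that("formula masses follow the stated ion conventions", {
  expect_equal(formulaMass(c(C = 2L, H = 4L)), 28.03130, tolerance = 1e-7)
  expect_equal(formulaMass(parseFormula("C6H12O6"), "protonated_molecule"),
               181.07066, tolerance = 5e-6)
  # cation convention subtracts exactly one electron mass
  expect_equal(formulaMass(c(C = 2L, H = 4L), "cation_generic"),
               28.03130013 - electronMass(), tolerance = 1e-9)
  expect_error(formulaMass(c(Xx = 1L)), "unknown element")
})

test_that("formula strings parse and serialize in Hill order", {
  expect_equal(parseFormula("C6H12O6"), c(C = 6L, H = 12L, O = 6L))
  expect_equal(formulaToString(c(O = 6L, H = 12L, C = 6L)), "C6H12O6")
  expect_equal(formulaToString(c(Cl = 1L, C = 6L, H = 5L)), "C6H5Cl")
  # no carbon: fully alphabetical
  expect_equal(formulaToString(c(N = 1L, H = 3L)), "H3N")
  expect_equal(parseFormula("CH4"), c(C = 1L, H = 4L))
  expect_equal(formulaToString(parseFormula("C2H6SiO")), "C2H6OSi")
})

test_that("enumeration returns exactly the in-window formulas", {
  con <- ElementConstraints(c("C", "H", "N", "O"))
  # C2H4 radical cation is the only hit at 3 ppm; CH2N sits ~92 ppm away
  got <- enumerateFormulas(28.03075, 3, con, "cation_generic")
  expect_equal(vapply(got, formulaToString, ""), "C2H4")

  # protonated glucose is found under the full default constraints
  got2 <- enumerateFormulas(181.07066, 3, ElementConstraints(),
                            "protonated_molecule")
  expect_true("C6H12O6" %in% vapply(got2, formulaToString, ""))

  # below the lightest admissible composition: empty
  expect_length(enumerateFormulas(5.0, 3, con, "cation_generic"), 0L)

  # every returned formula re-computes within the tolerance, sorted by error
  errs <- abs(vapply(got2, function(f)
    (formulaMass(f, "protonated_molecule") - 181.07066) / 181.07066 * 1e6,
    numeric(1)))
  expect_true(all(errs <= 3))
  expect_equal(errs, sort(errs))
  expect_equal(errs, abs(vapply(got2, attr, numeric(1), "dppm")),
               tolerance = 1e-9)
})

test_that("enumeration agrees with the exhaustive oracle on random instances", {
  set.seed(101)
  els <- c("C", "H", "N", "O", "S", "Cl")
  for (i in 1:40) {
    pick <- sample(els, sample(2:4, 1))
    if (!"C" %in% pick) pick[1] <- "C"
    caps <- setNames(sample(5:20, length(pick), replace = TRUE), pick)
    con <- ElementConstraints(as.list(lapply(caps, function(m) c(0L, m))))
    mz <- runif(1, 20, 350)
    ppm <- runif(1, 1, 10)
    got <- sort(vapply(enumerateFormulas(mz, ppm, con, "cation_generic"),
                       formulaToString, ""))
    want <- sort(oracleEnumerate(mz, ppm, setNames(rep(0L, length(caps)),
                                                   names(caps)), caps,
                                 adjust = -electronMass()))
    expect_equal(got, unname(want))
  }
})

test_that("the visit cap turns pathological windows into a resource error", {
  wide <- ElementConstraints(c("C", "H", "N", "O", "S", "Si", "P"),
                             max = 50L)
  expect_error(enumerateFormulas(400, 3, wide, cap = 100),
               "cap exceeded.*constraints")
})

test_that("element-ratio heuristics keep plausible formulas only", {
  keep <- goldenRulesFilter(list(parseFormula("C6H12O6"),
                                 c(C = 1L, H = 50L),
                                 c(H = 3L, N = 1L)))
  expect_equal(vapply(keep, formulaToString, ""), c("C6H12O6", "H3N"))
  expect_equal(rdbe(parseFormula("C6H12O6")), 1)
  expect_equal(rdbe(c(H = 3L, N = 1L)), 0)
  expect_equal(rdbe(parseFormula("C6H5Cl")), 4)
  # RDBE floor rejects over-saturated compositions
  expect_length(goldenRulesFilter(list(c(C = 2L, H = 8L))), 0L)
  # pure filter: output is an order-preserving subset
  fl <- list(parseFormula("C2H4"), parseFormula("CH4"), parseFormula("C2H6"))
  expect_equal(goldenRulesFilter(fl), fl)
})

test_that("missing diagnostic isotope peaks veto S/Cl/Br formulas", {
  f <- parseFormula("C6H5Cl")
  base <- formulaMass(f, "cation_generic")
  # companion present in raw at the exact Cl offset -> pass
  rawYes <- makeRawRun(c(base, base + 1.99705), rt = 10)
  expect_true(isotopePatternCheck(f, base, 10, raw = rawYes, ppm = 3))
  # companion absent -> veto
  rawNo <- makeRawRun(base, rt = 10)
  expect_false(isotopePatternCheck(f, base, 10, raw = rawNo, ppm = 3))
  # no S/Cl/Br -> exempt, passes against anything
  expect_true(isotopePatternCheck(parseFormula("C6H12O6"), 181.07, 10,
                                  raw = rawNo, ppm = 3))
  # sulfur companion at 4.5% relative intensity counts (presence-only)
  fs <- parseFormula("C2H6S")
  bs <- formulaMass(fs, "cation_generic")
  rawS <- RawRun(10, list(cbind(c(bs, bs + 1.99580), c(1e6, 4.5e4))))
  expect_true(isotopePatternCheck(fs, bs, 10, raw = rawS, ppm = 3))
  # without raw data the pseudospectrum's features serve as evidence
  grp <- data.frame(mz = c(base, base + 1.99705))
  expect_true(isotopePatternCheck(f, base, 10, groupFeatures = grp, ppm = 3))
  expect_false(isotopePatternCheck(f, base, 10,
                                   groupFeatures = grp[1, , drop = FALSE],
                                   ppm = 3))
})

test_that("the subformula relation is a partial order", {
  expect_true(isSubformula(parseFormula("C2H4O"), parseFormula("C6H12O6")))
  expect_false(isSubformula(c(C = 2L, H = 4L, N = 1L),
                            parseFormula("C6H12O6")))
  set.seed(5)
  rand <- replicate(25, {
    n <- sample(1:4, 1)
    setNames(as.integer(sample(0:6, n, replace = TRUE)),
             sample(c("C", "H", "N", "O", "S"), n))
  }, simplify = FALSE)
  for (f in rand) {
    expect_true(isSubformula(f, f))  # reflexive
    for (g in rand) {
      if (isSubformula(f, g) && isSubformula(g, f))
        expect_equal(formulaToString(f), formulaToString(g))  # antisymmetric
      for (h in rand)
        if (isSubformula(f, g) && isSubformula(g, h))
          expect_true(isSubformula(f, h))  # transitive
    }
  }
})
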