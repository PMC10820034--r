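# independent oracles, kept deliberately naive

# exhaustive-loop formula enumeration over small element caps
oracleEnumerate <- function(mz, ppm, cmin, cmax, adjust = 0) {
  masses <- elementMasses()[names(cmax)]
  grid <- do.call(expand.grid, Map(seq, cmin, cmax))
  ionMz <- as.matrix(grid) %*% masses + adjust
  hit <- abs(ionMz - mz) <= mz * ppm * 1e-6 & rowSums(grid) > 0
  if (!any(hit)) return(character(0))
  unname(apply(grid[hit, , drop = FALSE], 1, function(counts) {
    formulaToString(setNames(as.integer(counts), names(cmax)))
  }))
}

# naive re-implementation of the candidate probability score
oracleScore <- function(resolvedFormulas, resolvedWeights, neutralFormula) {
  ion <- formulaAdd(neutralFormula, c(H = 1L))
  num <- 0
  for (i in seq_along(resolvedFormulas)) {
    f <- resolvedFormulas[[i]]
    sub <- TRUE
    for (el in names(f)) {
      big <- if (el %in% names(ion)) ion[[el]] else 0L
      if (f[[el]] > big) { sub <- FALSE; break }
    }
    if (sub) num <- num + resolvedWeights[i]
  }
  d <- sum(resolvedWeights)
  if (d == 0) 0 else 100 * num / d
}

# invert the piecewise-linear shift model by bisection: find t_ei with
# t_ei + shift(t_ei) = t_ci, shift linear through the standards on the
# fragment axis and constant outside
oracleCorrectRt <- function(tCi, rtFragment, rtMolion) {
  shift <- function(tEi) {
    s <- rtMolion - rtFragment
    if (length(s) == 1 || tEi <= rtFragment[1]) return(s[1])
    n <- length(s)
    if (tEi >= rtFragment[n]) return(s[n])
    approx(rtFragment, s, xout = tEi)$y
  }
  lo <- tCi - 10; hi <- tCi + 10
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (mid + shift(mid) < tCi) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}
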