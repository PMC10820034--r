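# shared fixture builders; everything is generated in code at test time

# a tiny hand-built pseudospectrum: glucose-like [M+H]+ with two satellites
miniCiGroup <- function() {
  data.frame(
    feature_id = c("a", "b", "c"),
    mz = c(181.07066, 209.10196, 221.10196),
    rt = 10.00, intensity = c(1e6, 1e5, 5e4),
    group_id = "g1", isotope_flag = "none",
    stringsAsFactors = FALSE
  )
}

makeFeatureTable <- function(mz, intensity, rt = 10, group = "g1",
                             run = "fragment_run") {
  FeatureTable(data.frame(
    feature_id = sprintf("f%02d", seq_along(mz)), mz = mz, rt = rt,
    intensity = intensity, group_id = group, stringsAsFactors = FALSE
  ), run)
}

# one-peak raw run: a single m/z observed across a few scans
makeRawRun <- function(mz, rt, intensity = 1e4) {
  RawRun(scanTimes = rt + c(-0.01, 0, 0.01),
         scanPeaks = replicate(3, cbind(mz = mz,
                                        intensity = rep(intensity,
                                                        length(mz))),
                               simplify = FALSE))
}

# the standard end-to-end fixture (cached per test run; building it takes a
# few seconds)
standardFixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cps <- generateCompoundSet(50, seed = 42, ambiguityRate = 0.2)
      cache <<- list(compounds = cps,
                     data = renderDatasets(cps, seed = 42, noiseRate = 0.05))
    }
    cache
  }
})

# run preprocess + ranking over a rendered dataset, return merged results
rankFixture <- function(ds, rule = AdductRule(),
                        constraints = ElementConstraints(), useRaw = TRUE,
                        topXMode = "by_mz") {
  ei <- flagIsotopePeaks(ds$ei)
  ci <- flagIsotopePeaks(ds$ci)
  pairs <- matchSpectra(ei, ci, 0.05)
  do.call(rbind, lapply(pairs, function(p)
    rankMolecularIons(p, ei, ci, rule, constraints, 3, topXMode = topXMode,
                      eiRaw = if (useRaw) ds$eiRaw,
                      ciRaw = if (useRaw) ds$ciRaw)))
}

# rank of the true molecular ion per EI pseudospectrum (NA when absent)
trueRanks <- function(results, truth) {
  vapply(seq_len(nrow(truth)), function(i) {
    block <- results[results$ei_group_id == truth$ei_group_id[i], ]
    hit <- which(abs(block$candidate_mz - truth$mz_mh[i]) <=
                   truth$mz_mh[i] * 3e-6)
    if (length(hit)) block$rank[hit[1]] else NA_integer_
  }, integer(1))
}
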