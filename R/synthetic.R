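C13_SPACING <- 1.0033548

# neutral losses used to carve fragments out of the precursor composition
.LOSS_POOL <- list(
  c(H = 2L), c(H = 2L, O = 1L), c(C = 1L, H = 4L), c(C = 1L, H = 2L),
  c(C = 2L, H = 4L), c(C = 1L, O = 1L), c(C = 1L, H = 2L, O = 1L),
  c(N = 1L, H = 3L), c(C = 2L, H = 2L), c(C = 1L, H = 3L),
  c(C = 2L, H = 5L), c(C = 1L, H = 1L, O = 1L)
)

.fSub <- function(f, loss) {
  el <- union(names(f), names(loss))
  out <- stats::setNames(integer(length(el)), el)
  out[names(f)] <- out[names(f)] + f
  out[names(loss)] <- out[names(loss)] - loss
  if (any(out < 0L)) return(NULL)
  out[out > 0L]
}

.randomNeutral <- function(pool) {
  repeat {
    C <- sample(8:20, 1)
    N <- if ("N" %in% pool) sample(0:2, 1, prob = c(0.6, 0.3, 0.1)) else 0L
    O <- if ("O" %in% pool) sample(0:6, 1) else 0L
    S <- if ("S" %in% pool && stats::runif(1) < 0.15) 1L else 0L
    Cl <- if ("Cl" %in% pool && stats::runif(1) < 0.5) sample(1:2, 1) else 0L
    rd <- sample(1:6, 1)
    H <- 2L * C + 2L + N - Cl - 2L * rd
    if (H < 4L || H > 2L * C + 2L) next
    f <- c(C = C, H = H, N = N, O = O, S = S, Cl = Cl)
    f <- f[f > 0L]
    m <- formulaMass(f)
    if (m >= 120 && m <= 450) return(f)
  }
}

#' Generate a reproducible set of ground-truth compounds
#'
#' Draws \code{n} plausible neutral molecules (element pool, carbon counts
#' 8--20, RDBE 1--6, mass 120--450 u) together with a fragment set carved
#' from each [M+H]+ composition by chains of common neutral losses (H2,
#' H2O, CH4, CO, ...), so that every fragment is by construction a strict
#' subformula of the precursor composition. Fragment cation masses stay
#' above 55 Th (the EI scan range floor).
#'
#' A fraction \code{ambiguityRate} of the compounds carries at least one
#' deliberately mass-ambiguous fragment, i.e. one whose cation m/z admits
#' two or more formulas within \code{ppm} under the full downstream
#' \code{constraints} -- these exercise the bottom-up chain resolver. All
#' other fragments are verified by enumeration to have a unique formula at
#' \code{ppm} within the generator's element pool. A fraction
#' \code{omissionRate} of the compounds emits no adduct/neutral-loss
#' satellites at all, emulating compounds whose gas-phase chemistry does not
#' produce the expected pattern.
#'
#' @param n number of compounds.
#' @param seed RNG seed (integer).
#' @param elementPool elements molecules may contain.
#' @param ambiguityRate fraction of compounds given an ambiguous fragment.
#' @param omissionRate fraction of compounds emitting no satellites.
#' @param deltas satellite m/z differences emitted by non-omitted compounds.
#' @param constraints \linkS4class{ElementConstraints} used for the
#'   ambiguity check (the downstream enumeration window).
#' @param ppm tolerance for the uniqueness/ambiguity checks.
#' @param nFragments length-2 range of fragments per compound.
#' @return List of compounds: \code{formula} (neutral counts), \code{rt}
#'   (minutes), \code{fragments} (list of \code{formula}, \code{rel}),
#'   \code{satellites} (numeric deltas, possibly empty), \code{scale}
#'   (abundance), \code{ambiguous} (logical).
#' @export
generateCompoundSet <- function(n, seed = 42L,
                                elementPool = c("C", "H", "N", "O", "S"),
                                ambiguityRate = 0, omissionRate = 0,
                                deltas = c(28.03130, 40.03130, -16.03130),
                                constraints = ElementConstraints(),
                                ppm = 3, nFragments = c(12L, 16L)) {
  stopifnot(n >= 1)
  if (!all(c("C", "H") %in% elementPool))
    stop("element pool must contain at least C and H")
  set.seed(seed)
  poolCon <- ElementConstraints(elementPool)
  nAmb <- round(ambiguityRate * n)
  nOmit <- round(omissionRate * n)
  ambIdx <- if (nAmb) sample(n, nAmb) else integer(0)
  omitIdx <- if (nOmit) sample(n, nOmit) else integer(0)

  lapply(seq_len(n), function(i) {
    wantAmb <- i %in% ambIdx
    for (attempt in 1:50) {
      M <- .randomNeutral(elementPool)
      ionComp <- formulaAdd(M, c(H = 1L))
      # carve candidate fragments by random loss chains
      seen <- list()
      for (try in 1:250) {
        f <- ionComp
        for (step in 1:sample(2:7, 1)) {
          g <- .fSub(f, .LOSS_POOL[[sample(length(.LOSS_POOL), 1)]])
          if (is.null(g) || .countOf(g, "C") < 1 || .countOf(g, "H") < 1)
            break
          f <- g
          key <- formulaToString(f)
          m <- formulaMass(f, "cation_generic")
          if (m >= 55 && m <= formulaMass(ionComp) - 5 &&
              is.null(seen[[key]]))
            seen[[key]] <- f
        }
        if (length(seen) >= 40) break
      }
      if (length(seen) < nFragments[1]) next
      frs <- unname(seen)
      mzs <- vapply(frs, formulaMass, numeric(1), "cation_generic")
      nPool <- vapply(mzs, function(m)
        length(enumerateFormulas(m, ppm, poolCon, "cation_generic")),
        integer(1) + 0)
      uniq <- frs[nPool == 1]
      amb <- NULL
      if (wantAmb) {
        nFull <- vapply(mzs, function(m)
          length(enumerateFormulas(m, ppm, constraints, "cation_generic")),
          integer(1) + 0)
        ambPool <- frs[nFull >= 2]
        if (!length(ambPool)) next
        amb <- ambPool[[which.max(vapply(ambPool, formulaMass, numeric(1)))]]
        uniq <- Filter(function(f)
          formulaToString(f) != formulaToString(amb), uniq)
      }
      k <- sample(nFragments[1]:nFragments[2], 1) - !is.null(amb)
      if (length(uniq) < k) next
      # prefer a mass-spread selection: always keep lightest and heaviest
      o <- order(vapply(uniq, formulaMass, numeric(1)))
      pick <- uniq[o[unique(round(seq(1, length(o), length.out = k)))]]
      frags <- c(pick, if (!is.null(amb)) list(amb))
      rel <- stats::runif(length(frags), 0.05, 0.9)
      rel[sample(length(rel), 1)] <- 1
      return(list(
        formula = M,
        rt = 4 + 0.35 * i + stats::runif(1, -0.02, 0.02),
        fragments = Map(function(f, r) list(formula = f, rel = r),
                        frags, rel),
        satellites = if (i %in% omitIdx) numeric(0) else deltas,
        scale = 10^stats::runif(1, 5, 7),
        ambiguous = wantAmb
      ))
    }
    stop("could not build compound ", i, ": element pool too small or ",
         "constraints too tight")
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# draw a noise m/z that cannot fake adduct evidence against existing peaks:
# reject values sitting within 10 ppm of (existing + delta) in either role
.noiseMz <- function(existing, deltas, lo = 55, hi = 600) {
  for (i in 1:100) {
    m <- stats::runif(1, lo, hi)
    tol <- 10e-6 * m
    asSatellite <- abs(m - c(outer(existing, deltas, `+`))) > tol
    asSeed <- vapply(deltas, function(d)
      all(abs(existing - (m + d)) > tol), logical(1))
    if (all(asSatellite) && all(asSeed)) return(m)
  }
  stats::runif(1, lo, hi)
}

#' Render paired EI/CI datasets from ground-truth compounds
#'
#' Produces deconvoluted-style feature tables for both runs, matching
#' in-memory raw runs, and a truth table, from the output of
#' \code{\link{generateCompoundSet}}.
#'
#' Each EI pseudospectrum holds the fragment cations, M+1 isotopologue peaks
#' for the intense carbon-rich fragments, and noise. Each CI pseudospectrum
#' holds [M+H]+, its satellites at the compound's configured deltas, M+1
#' (and the exact-offset A+2 companion for S/Cl compounds), and noise. All
#' pseudospectra are padded with weak noise features to \code{minFeatures}
#' (busy deconvolution outputs are the norm, and the size filter must not
#' remove fixture groups); noise m/z values are rejected when they could
#' fake adduct evidence. CI retention times are distorted by
#' \code{rtShift = c(slope, intercept)} (fragment-run rt * slope +
#' intercept). Raw runs contain the same ions as centroids over a few scans
#' with a Gaussian elution profile, plus the A+2 companions.
#'
#' @param compounds output of \code{\link{generateCompoundSet}}.
#' @param seed RNG seed for intensities/noise placement.
#' @param rtShift numeric c(slope, intercept) applied to CI times.
#' @param noiseRate expected extra noise features per real feature
#'   (Poisson).
#' @param minFeatures pad every pseudospectrum to at least this many
#'   features.
#' @param coelutionRate fraction of compounds that receive a co-eluting
#'   heavier companion in the CI run (companion = compound + C4H8O), the
#'   classic failure mode in which a heavier co-eluting molecular ion
#'   outranks the true one.
#' @param satellitesInPeaklist when FALSE, satellites appear only in the CI
#'   raw run, never in the CI peak list (exercises the raw-data search).
#' @return list(ei, ci: \linkS4class{FeatureTable}s; eiRaw, ciRaw:
#'   \linkS4class{RawRun}s; truth: data.frame with \code{ei_group_id},
#'   \code{ci_group_id}, \code{neutral_formula}, \code{mz_mh},
#'   \code{rt_true}, \code{has_satellites}, \code{coeluted}).
#' @export
renderDatasets <- function(compounds, seed = 42L, rtShift = c(1, 0.02),
                           noiseRate = 0, minFeatures = 20L,
                           coelutionRate = 0, satellitesInPeaklist = TRUE) {
  set.seed(seed + 1L)
  nC <- length(compounds)
  nCo <- round(coelutionRate * nC)
  coIdx <- if (nCo) sample(nC, nCo) else integer(0)
  allDeltas <- unique(unlist(lapply(compounds, `[[`, "satellites")))
  if (!length(allDeltas)) allDeltas <- c(28.03130, 40.03130)

  eiRows <- list(); ciRows <- list(); truth <- list()
  eiScans <- list(); ciScans <- list()
  fid <- 0L
  nextId <- function() { fid <<- fid + 1L; sprintf("S%05d", fid) }

  addGroup <- function(rows, mzs, ints, rt, gid) {
    jitter <- stats::runif(length(mzs), -0.002, 0.002)
    rbind(rows, data.frame(
      feature_id = vapply(mzs, function(x) nextId(), character(1)),
      mz = mzs, rt = rt + jitter, intensity = ints, group_id = gid,
      stringsAsFactors = FALSE))
  }
  padNoise <- function(mzs, ints, target, rate) {
    nReal <- length(mzs)
    want <- max(target - nReal, 0L) + stats::rpois(1, rate * max(nReal, 1))
    base <- max(ints)
    for (i in seq_len(want)) {
      m <- .noiseMz(mzs, allDeltas)
      mzs <- c(mzs, m)
      ints <- c(ints, base * stats::runif(1, 0.001, 0.02))
    }
    list(mz = mzs, int = ints)
  }
  gaussScans <- function(mzs, ints, rtCenter, extraMz = numeric(0),
                         extraInt = numeric(0)) {
    lapply(-3:3, function(s) {
      fac <- exp(-((s * 0.005) / 0.008)^2)
      list(rt = rtCenter + s * 0.005,
           peaks = cbind(mz = c(mzs, extraMz),
                         intensity = c(ints, extraInt) * fac))
    })
  }

  renderCI <- function(M, satellites, scale, rtCi, gid, peaklist = TRUE) {
    b <- formulaMass(M, "protonated_molecule")
    bInt <- scale
    mzs <- b; ints <- bInt
    satMz <- numeric(0); satInt <- numeric(0)
    if (length(satellites)) {
      satMz <- b + satellites
      satInt <- bInt * stats::runif(length(satellites), 0.03, 0.2)
    }
    # isotopologues of the molecular ion
    isoMz <- b + C13_SPACING
    isoInt <- bInt * 0.011 * .countOf(M, "C")
    if (.countOf(M, "S") > 0) {
      isoMz <- c(isoMz, b + .A2_OFFSETS[["S"]])
      isoInt <- c(isoInt, bInt * 0.0445 * .countOf(M, "S"))
    }
    if (.countOf(M, "Cl") > 0) {
      isoMz <- c(isoMz, b + .A2_OFFSETS[["Cl"]])
      isoInt <- c(isoInt, bInt * 0.32 * .countOf(M, "Cl"))
    }
    plMz <- c(mzs, if (peaklist) satMz, isoMz)
    plInt <- c(ints, if (peaklist) satInt, isoInt)
    padded <- padNoise(plMz, plInt, minFeatures, noiseRate)
    ciRows <<- list(addGroup(ciRows[[1]], padded$mz, padded$int, rtCi, gid))
    ciScans <<- c(ciScans, gaussScans(padded$mz, padded$int, rtCi,
                                      extraMz = if (!peaklist) satMz,
                                      extraInt = if (!peaklist) satInt))
  }

  eiRows <- list(data.frame())
  ciRows <- list(data.frame())
  for (i in seq_len(nC)) {
    cp <- compounds[[i]]
    eiGid <- sprintf("EI_%03d", i)
    ciGid <- sprintf("CI_%03d", i)
    rtCi <- rtShift[1] * cp$rt + rtShift[2]

    fr <- cp$fragments
    fMz <- vapply(fr, function(f) formulaMass(f$formula, "cation_generic"),
                  numeric(1))
    fInt <- vapply(fr, `[[`, numeric(1), "rel") * cp$scale
    # M+1 peaks of intense, C-rich fragments
    big <- which(fInt / max(fInt) >= 0.3)
    isoMz <- fMz[big] + C13_SPACING
    isoInt <- fInt[big] * 0.011 *
      vapply(fr[big], function(f) .countOf(f$formula, "C"), numeric(1))
    padded <- padNoise(c(fMz, isoMz), c(fInt, isoInt), minFeatures,
                       noiseRate)
    eiRows[[1]] <- addGroup(eiRows[[1]], padded$mz, padded$int, cp$rt, eiGid)
    eiScans <- c(eiScans, gaussScans(padded$mz, padded$int, cp$rt))

    renderCI(cp$formula, cp$satellites, cp$scale * stats::runif(1, 0.5, 2),
             rtCi, ciGid, peaklist = satellitesInPeaklist)
    coeluted <- i %in% coIdx
    if (coeluted) {
      companion <- formulaAdd(cp$formula, c(C = 4L, H = 8L, O = 1L))
      renderCI(companion, cp$satellites,
               cp$scale * stats::runif(1, 0.3, 1),
               rtCi + stats::runif(1, -0.02, 0.02),
               paste0(ciGid, "x"), peaklist = satellitesInPeaklist)
    }
    truth[[i]] <- data.frame(
      ei_group_id = eiGid, ci_group_id = ciGid,
      neutral_formula = formulaToString(cp$formula),
      mz_mh = formulaMass(cp$formula, "protonated_molecule"),
      rt_true = cp$rt, has_satellites = length(cp$satellites) > 0,
      coeluted = coeluted, stringsAsFactors = FALSE)
  }

  toRaw <- function(scans) {
    RawRun(scanTimes = vapply(scans, `[[`, numeric(1), "rt"),
           scanPeaks = lapply(scans, `[[`, "peaks"))
  }
  list(ei = FeatureTable(eiRows[[1]], "fragment_run"),
       ci = FeatureTable(ciRows[[1]], "molion_run"),
       eiRaw = toRaw(eiScans), ciRaw = toRaw(ciScans),
       truth = do.call(rbind, truth))
}

#' Write a fixture dataset to files
#'
#' Convenience wrapper: generates compounds, renders the datasets, and
#' writes the EI/CI peak lists (CSV), truth table (CSV) and, optionally, the
#' raw runs (mzML) into \code{dir}.
#'
#' @param dir output directory (created if needed).
#' @param n,seed,... forwarded to \code{\link{generateCompoundSet}} /
#'   \code{\link{renderDatasets}} (use \code{render = list(...)} for render
#'   arguments).
#' @param render named list of \code{\link{renderDatasets}} arguments.
#' @param writeRaw also write ei.mzML / ci.mzML.
#' @return Named list of the written paths plus the in-memory dataset.
#' @export
makeFixtureDataset <- function(dir, n = 50L, seed = 42L, render = list(),
                               writeRaw = FALSE, ...) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  compounds <- generateCompoundSet(n, seed, ...)
  ds <- do.call(renderDatasets, c(list(compounds = compounds, seed = seed),
                                  render))
  paths <- list(ei_peaks = file.path(dir, "ei_peaks.csv"),
                ci_peaks = file.path(dir, "ci_peaks.csv"),
                truth = file.path(dir, "truth.csv"))
  utils::write.csv(features(ds$ei)[, 1:5], paths$ei_peaks, row.names = FALSE)
  utils::write.csv(features(ds$ci)[, 1:5], paths$ci_peaks, row.names = FALSE)
  utils::write.csv(ds$truth, paths$truth, row.names = FALSE)
  if (writeRaw) {
    paths$ei_raw <- file.path(dir, "ei.mzML")
    paths$ci_raw <- file.path(dir, "ci.mzML")
    writeMzML(ds$eiRaw, paths$ei_raw)
    writeMzML(ds$ciRaw, paths$ci_raw)
  }
  c(paths, list(data = ds))
}

#' Serialize a RawRun to mzML
#'
#' Thin wrapper over \code{mzR::writeMSData}; centroid MS1 scans only.
#'
#' @param raw a \linkS4class{RawRun}.
#' @param path output mzML path.
#' @return \code{path}, invisibly.
#' @export
writeMzML <- function(raw, path) {
  n <- nScans(raw)
  if (!n) stop("cannot write an empty RawRun")
  pk <- lapply(raw@scanPeaks, function(p) {
    p <- p[order(p[, 1L]), , drop = FALSE]
    storage.mode(p) <- "double"
    p
  })
  hd <- data.frame(
    seqNum = seq_len(n), acquisitionNum = seq_len(n), msLevel = 1L,
    polarity = 1L, peaksCount = vapply(pk, nrow, integer(1)),
    totIonCurrent = vapply(pk, function(p) sum(p[, 2L]), numeric(1)),
    retentionTime = raw@scanTimes * 60,
    basePeakMZ = vapply(pk, function(p)
      if (nrow(p)) p[which.max(p[, 2L]), 1L] else 0, numeric(1)),
    basePeakIntensity = vapply(pk, function(p)
      if (nrow(p)) max(p[, 2L]) else 0, numeric(1)),
    collisionEnergy = 0, ionisationEnergy = 0,
    lowMZ = vapply(pk, function(p) if (nrow(p)) min(p[, 1L]) else 0,
                   numeric(1)),
    highMZ = vapply(pk, function(p) if (nrow(p)) max(p[, 1L]) else 0,
                    numeric(1)),
    precursorScanNum = 0L, precursorMZ = 0, precursorCharge = 0L,
    precursorIntensity = 0, mergedScan = 0L, mergedResultScanNum = 0L,
    mergedResultStartScanNum = 0L, mergedResultEndScanNum = 0L,
    injectionTime = 0, filterString = NA_character_,
    spectrumId = paste0("scan=", seq_len(n)), centroided = TRUE,
    ionMobilityDriftTime = NA_real_,
    isolationWindowTargetMZ = NA_real_,
    isolationWindowLowerOffset = NA_real_,
    isolationWindowUpperOffset = NA_real_,
    scanWindowLowerLimit = 50, scanWindowUpperLimit = 1200,
    stringsAsFactors = FALSE)
  mzR::writeMSData(pk, file = path, header = hd)
  invisible(path)
}
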