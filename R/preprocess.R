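#' Remove undersized pseudospectra
#'
#' Pseudospectra with fewer than \code{minFeatures} features carry too little
#' fragment information for formula-based ranking and are dropped outright.
#' Counting happens on the raw feature list, before isotope flagging.
#'
#' @param table a \linkS4class{FeatureTable}.
#' @param minFeatures minimum number of features a pseudospectrum must
#'   contain to be kept (inclusive).
#' @return The filtered \linkS4class{FeatureTable}.
#' @export
filterPseudospectra <- function(table, minFeatures = 20L) {
  stopifnot(minFeatures >= 1L)
  f <- features(table)
  n <- table(f$group_id)
  keep <- names(n)[n >= minFeatures]
  FeatureTable(f[f$group_id %in% keep, , drop = FALSE], runLabel(table))
}

# Da windows below a feature within which a strictly more intense parent
# marks it as an isotopologue. They cover 13C, 15N, 18O, 34S and 37Cl
# spacings at the resolution of the flagging step.
.M1_WINDOW <- c(0.9970, 1.0100)
.M2_WINDOW <- c(1.9940, 2.0100)

#' Flag M+1 / M+2 isotopologue peaks
#'
#' Within each pseudospectrum, a feature is flagged \code{M_plus_1}
#' (\code{M_plus_2}) when a strictly more intense feature of the same group
#' sits 0.9970--1.0100 (1.9940--2.0100) u below it. Flagged features are
#' excluded from formula calculation and from candidate seeding downstream
#' but are retained, so they still serve as isotope-pattern evidence when no
#' raw file is available.
#'
#' @param table a \linkS4class{FeatureTable}.
#' @return The same table with \code{isotope_flag} filled in.
#' @export
flagIsotopePeaks <- function(table) {
  f <- features(table)
  if (!nrow(f)) return(table)
  flag <- rep("none", nrow(f))
  for (g in unique(f$group_id)) {
    idx <- which(f$group_id == g)
    mz <- f$mz[idx]; int <- f$intensity[idx]
    for (j in seq_along(idx)) {
      d <- mz[j] - mz            # positive where j sits above a parent
      parent1 <- d >= .M1_WINDOW[1] & d <= .M1_WINDOW[2] & int > int[j]
      parent2 <- d >= .M2_WINDOW[1] & d <= .M2_WINDOW[2] & int > int[j]
      if (any(parent1)) flag[idx[j]] <- "M_plus_1"
      else if (any(parent2)) flag[idx[j]] <- "M_plus_2"
    }
  }
  f$isotope_flag <- flag
  FeatureTable(f, runLabel(table))
}

#' Map molecular-ion-run retention times onto the fragment-run axis
#'
#' The retention-time shift between the two runs is modelled as a piecewise
#' linear function through the standard pairs; equivalently, corrected times
#' are obtained by linear interpolation through the pairs on the
#' molecular-ion-run axis, which makes the correction exact at every
#' standard. Beyond the outermost standards the boundary shift is held
#' constant; a single standard pair gives a constant shift everywhere.
#'
#' @param table the molecular-ion run's \linkS4class{FeatureTable}.
#' @param standards an \linkS4class{RtStandards}.
#' @return The table with \code{rt} replaced by corrected (fragment-run axis)
#'   times.
#' @export
correctRt <- function(table, standards) {
  f <- features(table)
  if (!nrow(f)) return(table)
  p <- rtPairs(standards)
  f$rt <- correctRtValues(f$rt, p$rt_fragment_run, p$rt_molion_run)
  FeatureTable(f, runLabel(table))
}

#' @rdname correctRt
#' @param rt numeric molecular-ion-run times (minutes).
#' @param rtFragment,rtMolion the standards' times in the two runs.
#' @export
correctRtValues <- function(rt, rtFragment, rtMolion) {
  n <- length(rtFragment)
  out <- numeric(length(rt))
  lo <- rt <= rtMolion[1]
  hi <- rt >= rtMolion[n]
  out[lo] <- rt[lo] - (rtMolion[1] - rtFragment[1])
  out[hi] <- rt[hi] - (rtMolion[n] - rtFragment[n])
  mid <- !lo & !hi
  if (any(mid))
    out[mid] <- stats::approx(rtMolion, rtFragment, xout = rt[mid])$y
  out
}

#' Retention time of a pseudospectrum
#'
#' Intensity-weighted mean retention time of the group's unflagged features
#' (all features if every one is isotope-flagged). Weighting damps the
#' influence of weak noise features on the group position.
#'
#' @param group data.frame of one pseudospectrum's features.
#' @return Retention time in minutes.
#' @export
pseudospectrumRt <- function(group) {
  use <- group$isotope_flag == "none"
  if (!any(use)) use <- rep(TRUE, nrow(group))
  stats::weighted.mean(group$rt[use], group$intensity[use])
}

#' Pair fragment pseudospectra with molecular-ion pseudospectra
#'
#' Each fragment (EI) pseudospectrum is assigned every molecular-ion
#' (CI/APCI) pseudospectrum whose retention time lies within
#' \code{rtTolerance} (inclusive) of its own. Fragment spectra without any
#' partner are kept in the output with an empty partner list so that they can
#' be reported as unassignable.
#'
#' @param eiTable the fragment run (isotope-flagged).
#' @param ciTable the molecular-ion run (isotope-flagged, RT-corrected).
#' @param rtTolerance matching half-window in minutes.
#' @return A list of spectrum pairs: \code{ei_group_id}, \code{rt_ei},
#'   \code{ci_group_ids}, \code{rt_ci}.
#' @export
matchSpectra <- function(eiTable, ciTable, rtTolerance = 0.05) {
  ei <- features(eiTable); ci <- features(ciTable)
  ciGroups <- unique(ci$group_id)
  ciRt <- vapply(ciGroups, function(g)
    pseudospectrumRt(ci[ci$group_id == g, , drop = FALSE]), numeric(1))
  lapply(unique(ei$group_id), function(g) {
    rtEi <- pseudospectrumRt(ei[ei$group_id == g, , drop = FALSE])
    # tiny epsilon so printed settings like 10.05 vs tolerance 0.05 behave
    # inclusively despite binary rounding
    hit <- which(abs(ciRt - rtEi) <= rtTolerance + 1e-9)
    list(ei_group_id = g, rt_ei = rtEi,
         ci_group_ids = ciGroups[hit], rt_ci = unname(ciRt[hit]))
  })
}
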