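#' Search a raw run for a peak
#'
#' Looks for a centroid within \code{ppm} of \code{targetMz} in any scan
#' whose retention time lies within \code{rtWindow} (inclusive) of
#' \code{rtCenter}. Any centroid with intensity above \code{minIntensity}
#' counts; the default floor of 0 deliberately suppresses nothing, because
#' adduct ions can be far too weak for the deconvolution tool yet clearly
#' present in raw scans.
#'
#' @param raw a \linkS4class{RawRun}.
#' @param rtCenter,rtWindow search window centre and half-width (minutes).
#' @param targetMz m/z to look for (Th).
#' @param ppm mass tolerance.
#' @param minIntensity absolute intensity floor (exclusive).
#' @return list(found = logical, intensity = max matching intensity or 0).
#' @export
searchRawPeak <- function(raw, rtCenter, rtWindow, targetMz, ppm,
                          minIntensity = 0) {
  hit <- which(abs(scanTimes(raw) - rtCenter) <= rtWindow)
  best <- 0
  tol <- targetMz * ppm * 1e-6
  for (i in hit) {
    p <- raw@scanPeaks[[i]]
    if (!nrow(p)) next
    j <- which(abs(p[, 1L] - targetMz) <= tol & p[, 2L] > minIntensity)
    if (length(j)) best <- max(best, p[j, 2L])
  }
  list(found = best > 0, intensity = best)
}

#' Find molecular-ion candidates in one pseudospectrum
#'
#' An unflagged feature X becomes a molecular-ion candidate when, for at
#' least \code{minFound} of the rule's signed m/z differences d, an ion is
#' present at X.mz + d within the ppm tolerance (applied to the satellite's
#' absolute m/z, consistent with instrument accuracy being relative). Each
#' difference is looked up first among the pseudospectrum's own features;
#' when absent there and a \linkS4class{RawRun} is supplied, it is searched
#' in raw scans within \code{rtWindow} of the group's retention time.
#'
#' @param group data.frame of one molecular-ion pseudospectrum's features
#'   (isotope-flagged rows are never seeds but do serve as satellite
#'   evidence).
#' @param rule an \linkS4class{AdductRule}.
#' @param raw optional \linkS4class{RawRun} of the molecular-ion acquisition.
#' @param rtWindow raw-search half-window (minutes).
#' @return data.frame of candidates: \code{feature_id}, \code{mz}, \code{rt},
#'   \code{intensity}, \code{source_group_id}, \code{adduct_evidence}
#'   (";"-joined signed deltas found), \code{evidence_source}
#'   (\code{"deconvoluted"} or \code{"raw"} when any delta needed raw data).
#' @export
findCandidates <- function(group, rule, raw = NULL, rtWindow = 0.05) {
  stopifnot(nrow(group) > 0)
  groupRt <- pseudospectrumRt(group)
  seeds <- which(group$isotope_flag == "none")
  rows <- lapply(seeds, function(i) {
    x <- group$mz[i]
    foundDelta <- character(0)
    usedRaw <- FALSE
    for (d in rule@deltas) {
      target <- x + d
      if (target <= 0) next
      tol <- target * rule@ppm * 1e-6
      inGroup <- any(abs(group$mz - target) <= tol)
      inRaw <- FALSE
      if (!inGroup && !is.null(raw))
        inRaw <- searchRawPeak(raw, groupRt, rtWindow, target, rule@ppm)$found
      if (inGroup || inRaw) {
        foundDelta <- c(foundDelta, sprintf("%+.5f", d))
        usedRaw <- usedRaw || inRaw
      }
    }
    if (length(foundDelta) < rule@minFound) return(NULL)
    data.frame(
      feature_id = group$feature_id[i], mz = x, rt = group$rt[i],
      intensity = group$intensity[i], source_group_id = group$group_id[i],
      adduct_evidence = paste(foundDelta, collapse = ";"),
      evidence_source = if (usedRaw) "raw" else "deconvoluted",
      stringsAsFactors = FALSE
    )
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows))
    return(data.frame(feature_id = character(), mz = numeric(),
                      rt = numeric(), intensity = numeric(),
                      source_group_id = character(),
                      adduct_evidence = character(),
                      evidence_source = character(),
                      stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

#' Keep only the most plausible candidates
#'
#' Signals with the highest m/z are the most likely molecular ions (soft
#' ionization puts the molecular species at the top of the spectrum), so the
#' candidate pool of one fragment pseudospectrum is cut to the \code{topX}
#' largest keys. With APCI data, where molecular ions dominate intensity,
#' \code{mode = "by_intensity"} ranks by intensity instead. Candidates tied
#' exactly at the cutoff key are all retained; \code{mode = "off"} disables
#' the cut.
#'
#' @param candidates pooled candidate data.frame of one fragment
#'   pseudospectrum (across all its matched molecular-ion pseudospectra).
#' @param topX number of candidates to keep.
#' @param mode ranking key.
#' @return The filtered data.frame, sorted by descending key.
#' @export
filterTopCandidates <- function(candidates, topX = 10L,
                                mode = c("by_mz", "by_intensity", "off")) {
  mode <- match.arg(mode)
  if (mode == "off" || !nrow(candidates)) return(candidates)
  stopifnot(topX >= 1L)
  key <- if (mode == "by_mz") candidates$mz else candidates$intensity
  o <- order(key, decreasing = TRUE)
  candidates <- candidates[o, , drop = FALSE]
  key <- key[o]
  if (nrow(candidates) > topX)
    candidates <- candidates[key >= key[topX], , drop = FALSE]
  rownames(candidates) <- NULL
  candidates
}
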