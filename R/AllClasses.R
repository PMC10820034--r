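.ISOTOPE_LEVELS <- c("none", "M_plus_1", "M_plus_2")
.RUN_LABELS <- c("fragment_run", "molion_run")

#' FeatureTable: a deconvoluted peak list
#'
#' Holds the deconvoluted features of one GC-HRMS run. Each feature carries
#' its accurate m/z, retention time (minutes), integrated intensity and the
#' pseudospectrum (co-eluting peak group) it was assigned to by the upstream
#' deconvolution pipeline. The \code{isotope_flag} column is \code{"none"} on
#' ingest and is set by \code{\link{flagIsotopePeaks}}.
#'
#' @slot features data.frame with columns \code{feature_id}, \code{mz},
#'   \code{rt}, \code{intensity}, \code{group_id}, \code{isotope_flag}.
#' @slot runLabel either \code{"fragment_run"} (EI) or \code{"molion_run"}
#'   (CI/APCI).
#' @export
setClass("FeatureTable",
  slots = c(features = "data.frame", runLabel = "character"),
  prototype = prototype(
    features = data.frame(
      feature_id = character(), mz = numeric(), rt = numeric(),
      intensity = numeric(), group_id = character(),
      isotope_flag = character(), stringsAsFactors = FALSE
    ),
    runLabel = "fragment_run"
  )
)

setValidity("FeatureTable", function(object) {
  f <- object@features
  need <- c("feature_id", "mz", "rt", "intensity", "group_id", "isotope_flag")
  miss <- setdiff(need, names(f))
  if (length(miss))
    return(paste("missing feature columns:", paste(miss, collapse = ", ")))
  if (length(object@runLabel) != 1L || !object@runLabel %in% .RUN_LABELS)
    return("runLabel must be 'fragment_run' or 'molion_run'")
  if (nrow(f)) {
    if (any(!is.finite(f$mz)) || any(f$mz <= 0)) return("mz must be positive")
    if (any(!is.finite(f$intensity)) || any(f$intensity <= 0))
      return("intensity must be positive")
    if (any(!is.finite(f$rt)) || any(f$rt < 0)) return("rt must be nonnegative")
    if (any(!f$isotope_flag %in% .ISOTOPE_LEVELS))
      return("isotope_flag must be one of none, M_plus_1, M_plus_2")
  }
  TRUE
})

#' Construct a FeatureTable
#'
#' @param features data.frame with columns \code{feature_id}, \code{mz},
#'   \code{rt}, \code{intensity}, \code{group_id} (an \code{isotope_flag}
#'   column is added as \code{"none"} if absent).
#' @param runLabel \code{"fragment_run"} or \code{"molion_run"}.
#' @return A \linkS4class{FeatureTable}.
#' @examples
#' ft <- FeatureTable(data.frame(
#'   feature_id = "f1", mz = 181.07066, rt = 10, intensity = 1e6,
#'   group_id = "g1"), "fragment_run")
#' @export
FeatureTable <- function(features, runLabel = c("fragment_run", "molion_run")) {
  runLabel <- match.arg(runLabel)
  if (is.null(features$isotope_flag)) features$isotope_flag <- "none"
  features$feature_id <- as.character(features$feature_id)
  features$group_id <- as.character(features$group_id)
  rownames(features) <- NULL
  methods::new("FeatureTable", features = features, runLabel = runLabel)
}

#' RtStandards: matched retention times of standards in both runs
#'
#' Retention times (minutes) at which the same reference compounds elute in
#' the fragment (EI) run and in the molecular-ion (CI/APCI) run; used to map
#' the molecular-ion run's time axis onto the fragment run's.
#'
#' @slot pairs data.frame with numeric columns \code{rt_fragment_run} and
#'   \code{rt_molion_run}, sorted by \code{rt_fragment_run}, both strictly
#'   increasing (elution order must be preserved between runs).
#' @export
setClass("RtStandards", slots = c(pairs = "data.frame"))

setValidity("RtStandards", function(object) {
  p <- object@pairs
  if (!all(c("rt_fragment_run", "rt_molion_run") %in% names(p)))
    return("pairs needs columns rt_fragment_run, rt_molion_run")
  if (nrow(p) < 1L) return("need at least one standard pair")
  if (is.unsorted(p$rt_fragment_run, strictly = TRUE))
    return("rt_fragment_run must be strictly increasing")
  if (is.unsorted(p$rt_molion_run, strictly = TRUE))
    return("rt_molion_run must be strictly increasing (crossing standards)")
  TRUE
})

#' Construct an RtStandards table
#'
#' @param rt_fragment_run,rt_molion_run numeric vectors of equal length:
#'   retention times (minutes) of the same standards in the two runs.
#' @return An \linkS4class{RtStandards}.
#' @examples
#' RtStandards(c(5, 10), c(5.02, 10.06))
#' @export
RtStandards <- function(rt_fragment_run, rt_molion_run) {
  stopifnot(length(rt_fragment_run) == length(rt_molion_run))
  o <- order(rt_fragment_run)
  methods::new("RtStandards", pairs = data.frame(
    rt_fragment_run = as.numeric(rt_fragment_run)[o],
    rt_molion_run = as.numeric(rt_molion_run)[o]
  ))
}

#' RawRun: centroided scans of one raw acquisition
#'
#' In-memory representation of an mzML/mzXML run: scan retention times in
#' minutes (ascending) and, per scan, a two-column peak matrix (m/z,
#' intensity) sorted by m/z. Profile-mode scans are reduced to centroids at
#' local maxima on ingest.
#'
#' @slot scanTimes numeric, minutes, ascending.
#' @slot scanPeaks list of numeric matrices with columns \code{mz},
#'   \code{intensity}.
#' @export
setClass("RawRun", slots = c(scanTimes = "numeric", scanPeaks = "list"))

setValidity("RawRun", function(object) {
  if (length(object@scanTimes) != length(object@scanPeaks))
    return("scanTimes and scanPeaks lengths differ")
  if (is.unsorted(object@scanTimes)) return("scans must be rt-sorted")
  ok <- vapply(object@scanPeaks, function(p)
    is.matrix(p) && ncol(p) == 2L && !is.unsorted(p[, 1L]), logical(1))
  if (!all(ok)) return("each scan needs an mz-sorted 2-column peak matrix")
  TRUE
})

#' Construct a RawRun
#'
#' @param scanTimes numeric scan retention times in minutes.
#' @param scanPeaks list of 2-column matrices (mz, intensity), one per scan.
#' @return A \linkS4class{RawRun}. Scans are sorted by retention time and
#'   peaks by m/z.
#' @export
RawRun <- function(scanTimes = numeric(), scanPeaks = list()) {
  o <- order(scanTimes)
  scanPeaks <- lapply(scanPeaks[o], function(p) {
    p <- as.matrix(p)
    colnames(p) <- c("mz", "intensity")
    p[order(p[, 1L]), , drop = FALSE]
  })
  methods::new("RawRun", scanTimes = as.numeric(scanTimes)[o],
               scanPeaks = scanPeaks)
}

#' AdductRule: the m/z-difference pattern expected of molecular ions
#'
#' A molecular-ion candidate must display at least \code{minFound} of the
#' listed signed m/z differences (adducts or neutral losses) within a ppm
#' tolerance. The methane-CI defaults are +28.03130 ([M+C2H5]+ relative to
#' [M+H]+), +40.03130 ([M+C3H5]+) and -16.03130 (loss of CH4).
#'
#' @slot deltas signed m/z differences in u.
#' @slot minFound how many distinct differences must be detected.
#' @slot ppm relative mass tolerance for each difference.
#' @export
setClass("AdductRule",
  slots = c(deltas = "numeric", minFound = "integer", ppm = "numeric"))

setValidity("AdductRule", function(object) {
  if (!length(object@deltas)) return("deltas must be non-empty")
  if (object@minFound < 1L || object@minFound > length(object@deltas))
    return("minFound must be between 1 and length(deltas)")
  if (object@ppm <= 0) return("ppm must be positive")
  TRUE
})

#' Construct an AdductRule
#'
#' @param deltas signed m/z differences (u); defaults to the methane-CI
#'   pattern.
#' @param minFound number of distinct differences required.
#' @param ppm mass tolerance (parts per million).
#' @return An \linkS4class{AdductRule}.
#' @examples
#' AdductRule()  # methane CI defaults
#' @export
AdductRule <- function(deltas = c(28.03130, 40.03130, -16.03130),
                       minFound = 2L, ppm = 3) {
  methods::new("AdductRule", deltas = as.numeric(deltas),
               minFound = as.integer(minFound), ppm = as.numeric(ppm))
}

#' ElementConstraints: per-element count windows for formula enumeration
#'
#' @slot minCounts,maxCounts named integer vectors over a subset of the
#'   supported elements (see \code{\link{elementMasses}}).
#' @export
setClass("ElementConstraints",
  slots = c(minCounts = "integer", maxCounts = "integer"))

setValidity("ElementConstraints", function(object) {
  if (!identical(names(object@minCounts), names(object@maxCounts)))
    return("minCounts and maxCounts must share names")
  bad <- setdiff(names(object@minCounts), names(.ELEMENT_MASSES))
  if (length(bad))
    return(paste("unknown element symbol:", paste(bad, collapse = ", ")))
  if (any(object@minCounts < 0L)) return("min counts must be nonnegative")
  if (any(object@minCounts > object@maxCounts))
    return("min count exceeds max count")
  TRUE
})

#' Construct ElementConstraints
#'
#' @param elements character vector of element symbols, or a named list/
#'   vector of \code{c(min, max)} pairs, or a string like
#'   \code{"C:0-50,H:0-50"}.
#' @param min,max default count window applied to plain element symbols.
#' @return An \linkS4class{ElementConstraints}.
#' @examples
#' ElementConstraints(c("C", "H", "N", "O", "S", "Si", "P"))
#' ElementConstraints("C:0-30,H:0-60,Cl:0-3")
#' @export
ElementConstraints <- function(elements = c("C", "H", "N", "O", "S", "Si", "P"),
                               min = 0L, max = 50L) {
  if (is.character(elements) && length(elements) == 1L &&
      grepl(":", elements, fixed = TRUE)) {
    parts <- strsplit(strsplit(elements, ",", fixed = TRUE)[[1]], "[:-]")
    elements <- stats::setNames(
      lapply(parts, function(p) as.integer(p[2:3])),
      vapply(parts, `[`, character(1), 1L)
    )
  }
  if (is.list(elements)) {
    lo <- vapply(elements, function(x) as.integer(x[1]), integer(1))
    hi <- vapply(elements, function(x) as.integer(x[length(x)]), integer(1))
  } else {
    lo <- stats::setNames(rep(as.integer(min), length(elements)), elements)
    hi <- stats::setNames(rep(as.integer(max), length(elements)), elements)
  }
  methods::new("ElementConstraints", minCounts = lo, maxCounts = hi)
}
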