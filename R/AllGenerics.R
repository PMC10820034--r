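#' @name accessors
#' @title Accessors for ionlink classes
#' @param object an ionlink S4 object.
#' @return \code{features}: the feature data.frame; \code{runLabel}: the run
#'   label; \code{groupIds}: unique pseudospectrum identifiers; \code{nScans}:
#'   the number of scans; \code{scanTimes}: scan retention times (minutes);
#'   \code{rtPairs}: the standards data.frame.
NULL

#' @rdname accessors
#' @export
setGeneric("features", function(object) standardGeneric("features"))
#' @rdname accessors
#' @export
setMethod("features", "FeatureTable", function(object) object@features)

#' @rdname accessors
#' @export
setGeneric("runLabel", function(object) standardGeneric("runLabel"))
#' @rdname accessors
#' @export
setMethod("runLabel", "FeatureTable", function(object) object@runLabel)

#' @rdname accessors
#' @export
setGeneric("groupIds", function(object) standardGeneric("groupIds"))
#' @rdname accessors
#' @export
setMethod("groupIds", "FeatureTable",
          function(object) unique(object@features$group_id))

#' @rdname accessors
#' @export
setGeneric("nScans", function(object) standardGeneric("nScans"))
#' @rdname accessors
#' @export
setMethod("nScans", "RawRun", function(object) length(object@scanTimes))

#' @rdname accessors
#' @export
setGeneric("scanTimes", function(object) standardGeneric("scanTimes"))
#' @rdname accessors
#' @export
setMethod("scanTimes", "RawRun", function(object) object@scanTimes)

#' @rdname accessors
#' @export
setGeneric("scanPeaks", function(object) standardGeneric("scanPeaks"))
#' @rdname accessors
#' @export
setMethod("scanPeaks", "RawRun", function(object) object@scanPeaks)

#' @rdname accessors
#' @export
setGeneric("rtPairs", function(object) standardGeneric("rtPairs"))
#' @rdname accessors
#' @export
setMethod("rtPairs", "RtStandards", function(object) object@pairs)

setMethod("show", "FeatureTable", function(object) {
  f <- object@features
  cat("FeatureTable (", object@runLabel, "): ", nrow(f), " features in ",
      length(unique(f$group_id)), " pseudospectra\n", sep = "")
  if (nrow(f))
    cat("  m/z ", round(min(f$mz), 4), "-", round(max(f$mz), 4),
        ", rt ", round(min(f$rt), 2), "-", round(max(f$rt), 2), " min, ",
        sum(f$isotope_flag != "none"), " isotope-flagged\n", sep = "")
})

setMethod("show", "RawRun", function(object) {
  n <- length(object@scanTimes)
  cat("RawRun: ", n, " scans", sep = "")
  if (n) cat(", rt ", round(min(object@scanTimes), 2), "-",
             round(max(object@scanTimes), 2), " min", sep = "")
  cat("\n")
})

setMethod("show", "RtStandards", function(object) {
  cat("RtStandards:", nrow(object@pairs), "pairs\n")
})

setMethod("show", "AdductRule", function(object) {
  cat("AdductRule: deltas {", paste(sprintf("%+.5f", object@deltas),
      collapse = ", "), "}, minFound ", object@minFound, ", ",
      object@ppm, " ppm\n", sep = "")
})

setMethod("show", "ElementConstraints", function(object) {
  cat("ElementConstraints:", paste0(names(object@minCounts), ":",
      object@minCounts, "-", object@maxCounts, collapse = ","), "\n")
})
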