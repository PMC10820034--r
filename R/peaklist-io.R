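#' Read a deconvoluted peak list
#'
#' Reads a delimited text export of any deconvolution pipeline (XCMS/CAMERA,
#' vendor tools, ...) into a \linkS4class{FeatureTable}. The canonical header
#' is \code{feature_id,mz,rt,intensity,group_id}; other layouts are mapped
#' through \code{columnMap}. Retention times must be minutes. Rows whose m/z
#' or intensity is non-numeric or non-positive are dropped with a warning
#' reporting the count; deconvolution exports routinely contain such
#' artifacts and a single bad row should not abort a run.
#'
#' @param path path to a CSV (comma) or TSV (tab) file; the delimiter is
#'   chosen by extension (\code{.tsv}/\code{.txt} means tab).
#' @param runLabel \code{"fragment_run"} (EI) or \code{"molion_run"}
#'   (CI/APCI).
#' @param columnMap named character vector mapping canonical names to the
#'   file's column names, e.g. \code{c(rt = "rt_min")}. Only \code{mz},
#'   \code{rt}, \code{intensity} and \code{group_id} are required;
#'   \code{feature_id} is generated when absent.
#' @return A \linkS4class{FeatureTable}.
#' @export
readPeaklist <- function(path, runLabel = c("fragment_run", "molion_run"),
                         columnMap = NULL) {
  runLabel <- match.arg(runLabel)
  if (!file.exists(path)) stop("peak list not found: ", path)
  sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, dec = ".",
                           comment.char = "", check.names = FALSE)
  if (!nrow(raw)) stop("empty peak list: ", path)

  canon <- c("feature_id", "mz", "rt", "intensity", "group_id")
  map <- stats::setNames(canon, canon)
  if (!is.null(columnMap)) map[names(columnMap)] <- columnMap
  required <- c("mz", "rt", "intensity", "group_id")
  miss <- required[!map[required] %in% names(raw)]
  if (length(miss))
    stop("required column(s) not found in ", path, ": ",
         paste(map[miss], collapse = ", "),
         " (use columnMap to point at your header)")

  df <- data.frame(
    feature_id = if (map[["feature_id"]] %in% names(raw))
      as.character(raw[[map[["feature_id"]]]]) else
      sprintf("F%04d", seq_len(nrow(raw))),
    mz = suppressWarnings(as.numeric(raw[[map[["mz"]]]])),
    rt = suppressWarnings(as.numeric(raw[[map[["rt"]]]])),
    intensity = suppressWarnings(as.numeric(raw[[map[["intensity"]]]])),
    group_id = as.character(raw[[map[["group_id"]]]]),
    stringsAsFactors = FALSE
  )
  bad <- !is.finite(df$mz) | df$mz <= 0 | !is.finite(df$intensity) |
    df$intensity <= 0 | !is.finite(df$rt) | df$rt < 0
  if (any(bad))
    warning(sum(bad), " malformed row(s) dropped from ", basename(path))
  FeatureTable(df[!bad, , drop = FALSE], runLabel)
}

#' Read a retention-time standards table
#'
#' Two numeric columns: retention time (minutes) of each standard in the
#' fragment (EI) run, then in the molecular-ion (CI/APCI) run. Pairs are
#' sorted by the fragment-run time; standards whose elution order differs
#' between runs (crossing) are rejected.
#'
#' @param path CSV file with two numeric columns (header optional).
#' @return An \linkS4class{RtStandards}.
#' @export
readRtStandards <- function(path) {
  if (!file.exists(path)) stop("RT standards file not found: ", path)
  raw <- utils::read.csv(path, header = FALSE, stringsAsFactors = FALSE)
  # tolerate a header line
  if (!all(vapply(raw[1, 1:2], function(x)
    is.finite(suppressWarnings(as.numeric(x))), logical(1))))
    raw <- raw[-1, , drop = FALSE]
  if (!nrow(raw)) stop("RT standards table is empty: ", path)
  a <- as.numeric(raw[[1]]); b <- as.numeric(raw[[2]])
  if (any(!is.finite(a)) || any(!is.finite(b)))
    stop("RT standards table must contain two numeric columns")
  RtStandards(a, b)
}

#' Read a raw run (mzML/mzXML)
#'
#' Loads scans through \pkg{mzR}, converts retention times to minutes and
#' reduces profile-mode scans to centroids by local-maximum picking (no
#' smoothing). Scans are returned sorted by retention time.
#'
#' @param path an mzML or mzXML file.
#' @return A \linkS4class{RawRun}.
#' @export
readRawRun <- function(path) {
  if (!file.exists(path)) stop("raw file not found: ", path)
  handle <- tryCatch(mzR::openMSfile(path),
    error = function(e) stop("cannot read '", path,
      "' as mzML/mzXML: ", conditionMessage(e)))
  on.exit(mzR::close(handle))
  hd <- mzR::header(handle)
  if (!nrow(hd)) return(RawRun())
  pk <- mzR::peaks(handle)
  if (is.matrix(pk)) pk <- list(pk)
  centroided <- hd$centroided
  centroided[is.na(centroided)] <- TRUE
  pk <- lapply(seq_along(pk), function(i) {
    p <- pk[[i]]
    if (!centroided[i]) p <- centroidScan(p)
    p
  })
  RawRun(scanTimes = hd$retentionTime / 60, scanPeaks = pk)
}

#' Centroid one profile-mode scan
#'
#' Local-maximum picking: a profile point becomes a centroid when its
#' intensity is positive, not smaller than either neighbour, and strictly
#' larger than at least one of them (flat-topped plateaus keep their first
#' point).
#'
#' @param peaks 2-column matrix (mz, intensity), mz-sorted.
#' @return 2-column centroid matrix.
#' @export
centroidScan <- function(peaks) {
  n <- nrow(peaks)
  if (n <= 1L) return(peaks[peaks[, 2L] > 0, , drop = FALSE])
  y <- peaks[, 2L]
  left <- c(0, y[-n]); right <- c(y[-1L], 0)
  keep <- y > 0 & y >= left & y >= right & (y > left | y > right)
  peaks[keep, , drop = FALSE]
}

#' Write the ranked molecular-ion assignments
#'
#' One CSV row per (EI pseudospectrum, rank). Rows are ordered by
#' \code{ei_group_id} then \code{rank}; formulas are serialized in Hill
#' order. Byte-identical output for identical input.
#'
#' @param results data.frame as returned by \code{\link{runPipeline}} /
#'   \code{\link{rankMolecularIons}} with columns \code{ei_group_id},
#'   \code{rank}, \code{candidate_mz}, \code{candidate_rt},
#'   \code{assigned_formula}, \code{probability_score},
#'   \code{n_supporting_fragments}, \code{adduct_evidence}.
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
writeResults <- function(results, path) {
  cols <- c("ei_group_id", "rank", "candidate_mz", "candidate_rt",
            "assigned_formula", "probability_score",
            "n_supporting_fragments", "adduct_evidence")
  if (!nrow(results)) {
    results <- as.data.frame(stats::setNames(
      rep(list(character(0)), length(cols)), cols))
  } else {
    miss <- setdiff(cols, names(results))
    if (length(miss)) stop("results missing columns: ",
                           paste(miss, collapse = ", "))
    results <- results[order(results$ei_group_id, results$rank), cols]
  }
  ok <- tryCatch({
    utils::write.csv(format(results, digits = 15, trim = TRUE,
                            scientific = FALSE),
                     path, row.names = FALSE, quote = FALSE)
    TRUE
  }, error = function(e) stop("cannot write results to '", path, "': ",
                              conditionMessage(e)))
  invisible(path)
}
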