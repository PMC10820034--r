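#' Build a run configuration
#'
#' Collects every tunable of the pipeline with the standard methane-CI
#' defaults: 3 ppm mass accuracy, minimum 20 m/z values per pseudospectrum
#' in both runs, m/z differences +28.03130/+40.03130/-16.03130 of which 2
#' must be found, top 10 candidates by m/z, 0.05 min retention-time
#' tolerance, element constraints C/H/N/O/S/Si/P 0--50, raw-data search
#' enabled whenever a raw file is given.
#'
#' @param ei_peaks,ci_peaks paths to the fragment-run and molecular-ion-run
#'   peak lists.
#' @param out output CSV path.
#' @param ei_raw,ci_raw optional mzML/mzXML paths.
#' @param rt_standards optional RT-standards CSV path.
#' @param ppm mass accuracy (parts per million).
#' @param min_features_ei,min_features_ci minimum pseudospectrum sizes.
#' @param deltas signed m/z differences of the adduct/neutral-loss pattern.
#' @param min_found how many differences must be found.
#' @param top_x candidate cut size.
#' @param top_x_mode \code{"by_mz"}, \code{"by_intensity"} or \code{"off"}.
#' @param rt_tolerance matching tolerance (minutes).
#' @param elements constraint string like \code{"C:0-50,H:0-50"} or an
#'   \linkS4class{ElementConstraints}.
#' @param use_raw_search logical; NULL means "when a raw path is set".
#' @return A validated config list of class \code{ionlinkConfig}.
#' @export
runConfig <- function(ei_peaks = NULL, ci_peaks = NULL, out = NULL,
                      ei_raw = NULL, ci_raw = NULL, rt_standards = NULL,
                      ppm = 3, min_features_ei = 20L, min_features_ci = 20L,
                      deltas = c(28.03130, 40.03130, -16.03130),
                      min_found = 2L, top_x = 10L, top_x_mode = "by_mz",
                      rt_tolerance = 0.05,
                      elements = "C:0-50,H:0-50,N:0-50,O:0-50,S:0-50,Si:0-50,P:0-50",
                      use_raw_search = NULL) {
  usageStop <- function(...) stop(errorCondition(paste0(...),
    class = c("ionlink_usage_error", "error")))
  if (ppm <= 0) usageStop("ppm must be positive")
  if (min_features_ei < 1 || min_features_ci < 1)
    usageStop("min_features must be >= 1")
  if (min_found < 1 || min_found > length(deltas))
    usageStop("min_found must lie between 1 and the number of deltas (",
              length(deltas), ")")
  if (top_x < 1) usageStop("top_x must be >= 1")
  if (!top_x_mode %in% c("by_mz", "by_intensity", "off"))
    usageStop("top_x_mode must be by_mz, by_intensity or off")
  if (rt_tolerance <= 0) usageStop("rt_tolerance must be positive")
  if (is.character(elements)) elements <- ElementConstraints(elements)
  if (is.null(use_raw_search))
    use_raw_search <- !is.null(ei_raw) || !is.null(ci_raw)
  structure(list(
    ei_peaks = ei_peaks, ci_peaks = ci_peaks, out = out, ei_raw = ei_raw,
    ci_raw = ci_raw, rt_standards = rt_standards, ppm = ppm,
    min_features_ei = as.integer(min_features_ei),
    min_features_ci = as.integer(min_features_ci), deltas = deltas,
    min_found = as.integer(min_found), top_x = as.integer(top_x),
    top_x_mode = top_x_mode, rt_tolerance = rt_tolerance,
    elements = elements, use_raw_search = isTRUE(use_raw_search)
  ), class = "ionlinkConfig")
}

#' Merge a YAML config file and command-line style overrides
#'
#' Values from the file override the built-in defaults and are themselves
#' overridden by entries of \code{overrides}. \code{deltas} may be a
#' comma-separated string; \code{elements} a constraint string.
#'
#' @param configFile optional YAML file of config keys.
#' @param overrides named list of config values (e.g. parsed CLI flags).
#' @return A validated \code{ionlinkConfig}.
#' @export
parseConfig <- function(configFile = NULL, overrides = list()) {
  vals <- list()
  if (!is.null(configFile)) {
    if (!file.exists(configFile)) stop("config file not found: ", configFile)
    vals <- yaml::read_yaml(configFile)
  }
  overrides <- overrides[!vapply(overrides, is.null, logical(1))]
  vals[names(overrides)] <- overrides
  bad <- setdiff(names(vals), names(formals(runConfig)))
  if (length(bad))
    stop(errorCondition(paste("unknown config key(s):",
      paste(bad, collapse = ", ")),
      class = c("ionlink_usage_error", "error")))
  if (is.character(vals$deltas))
    vals$deltas <- as.numeric(strsplit(vals$deltas, ",")[[1]])
  do.call(runConfig, vals)
}

#' Run the whole pipeline
#'
#' Reads the two peak lists, removes undersized pseudospectra, flags
#' isotopologue peaks, corrects the molecular-ion run's retention times when
#' standards are given, pairs pseudospectra by retention time, ranks
#' molecular-ion candidates for every fragment pseudospectrum and writes the
#' result CSV. Per-stage counts are reported through \code{message()} so a
#' run log documents how many spectra and candidates survived each step.
#'
#' @param config an \code{ionlinkConfig} (see \code{\link{runConfig}}).
#' @return The result data.frame, invisibly. Fragment pseudospectra without
#'   any candidate are absent from the rows (reported in the log as
#'   unassigned).
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "ionlinkConfig"))
  if (is.null(config$ei_peaks) || is.null(config$ci_peaks))
    stop(errorCondition("ei_peaks and ci_peaks are required",
                        class = c("ionlink_usage_error", "error")))
  ei <- readPeaklist(config$ei_peaks, "fragment_run")
  ci <- readPeaklist(config$ci_peaks, "molion_run")
  message("read: ", nrow(features(ei)), " EI features in ",
          length(groupIds(ei)), " pseudospectra; ", nrow(features(ci)),
          " CI features in ", length(groupIds(ci)), " pseudospectra")

  ei <- filterPseudospectra(ei, config$min_features_ei)
  ci <- filterPseudospectra(ci, config$min_features_ci)
  message("size filter (>=", config$min_features_ei, "/",
          config$min_features_ci, " features): ", length(groupIds(ei)),
          " EI and ", length(groupIds(ci)), " CI pseudospectra kept")
  ei <- flagIsotopePeaks(ei)
  ci <- flagIsotopePeaks(ci)

  if (!is.null(config$rt_standards)) {
    std <- readRtStandards(config$rt_standards)
    ci <- correctRt(ci, std)
    message("RT correction through ", nrow(rtPairs(std)), " standard pairs")
  }

  eiRaw <- ciRaw <- NULL
  if (config$use_raw_search) {
    if (!is.null(config$ei_raw)) eiRaw <- readRawRun(config$ei_raw)
    if (!is.null(config$ci_raw)) ciRaw <- readRawRun(config$ci_raw)
  }

  pairs <- matchSpectra(ei, ci, config$rt_tolerance)
  matched <- sum(vapply(pairs, function(p)
    length(p$ci_group_ids) > 0, logical(1)))
  message("RT matching (±", config$rt_tolerance, " min): ", matched, " of ",
          length(pairs), " EI pseudospectra have CI partners")

  rule <- AdductRule(config$deltas, config$min_found, config$ppm)
  blocks <- lapply(pairs, function(p)
    rankMolecularIons(p, ei, ci, rule, config$elements, config$ppm,
                      config$top_x, config$top_x_mode, config$rt_tolerance,
                      eiRaw = eiRaw, ciRaw = ciRaw))
  results <- do.call(rbind, blocks)
  if (is.null(results))
    results <- data.frame(
      ei_group_id = character(), rank = integer(), candidate_mz = numeric(),
      candidate_rt = numeric(), assigned_formula = character(),
      probability_score = numeric(), n_supporting_fragments = integer(),
      adduct_evidence = character(), stringsAsFactors = FALSE)
  assigned <- length(unique(results$ei_group_id))
  message("ranking: ", assigned, " EI pseudospectra assigned candidates, ",
          length(pairs) - assigned, " without molecular ion")
  if (!assigned && length(pairs))
    warning("no molecular ion candidate found for any fragment pseudospectrum")
  if (!is.null(config$out)) {
    writeResults(results, config$out)
    message("results written to ", config$out)
  }
  invisible(results)
}
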