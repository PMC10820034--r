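#' Weight of a fragment's evidence
#'
#' Each fragment contributes m/z-weighted, log-scaled intensity evidence:
#' \code{mz * ln(relIntensity * 100 + 1)} with \code{relIntensity} the
#' fragment's intensity relative to the pseudospectrum's base peak. The log
#' damps the dominance of the base peak; the m/z factor rewards heavy
#' fragments, which constrain the molecular composition far more than light
#' ones even when they are weak.
#'
#' @param mz fragment m/z (Th).
#' @param relIntensity relative intensity in [0, 1].
#' @return Nonnegative weight; vectorized over both arguments.
#' @examples
#' fragmentWeight(100, 1)    # 100 * log(101)
#' fragmentWeight(100, 0)    # 0
#' @export
fragmentWeight <- function(mz, relIntensity) {
  stopifnot(all(mz > 0), all(relIntensity >= 0), all(relIntensity <= 1))
  mz * log(relIntensity * 100 + 1)
}

#' Bottom-up chained formula assignment for one fragment pseudospectrum
#'
#' Fragments are processed in ascending m/z, exploiting that absolute mass
#' uncertainty grows with m/z: small ions usually admit a single formula,
#' and each resolved small ion then helps disambiguate the larger ones.
#' Per fragment the pipeline is: enumerate formulas (cation convention)
#' within ppm, drop implausible element ratios, veto formulas whose
#' diagnostic S/Cl/Br isotope peaks are missing. A fragment with exactly one
#' surviving formula is resolved outright. With several, each is scored by
#' the summed weights of previously resolved smaller fragments whose formula
#' is a subformula of it, and the best-supported one is assigned; when no
#' candidate formula receives any support (noise, or a fragment whose
#' elements differ from everything below it) all formulas are retained and
#' the fragment stays unresolved. Unresolved fragments contribute to no
#' score downstream.
#'
#' @param group data.frame of one fragment pseudospectrum's features.
#' @param constraints an \linkS4class{ElementConstraints}.
#' @param ppm mass tolerance.
#' @param raw optional fragment-run \linkS4class{RawRun} for the isotope
#'   check.
#' @param rtWindow raw-search half-window (minutes).
#' @param cap enumeration visit cap.
#' @return List of assignments, one per unflagged fragment in ascending m/z:
#'   \code{feature_id}, \code{mz}, \code{rel_intensity}, \code{weight},
#'   \code{formulas} (list of count vectors), \code{resolved}.
#' @export
assignFragmentFormulas <- function(group, constraints = ElementConstraints(),
                                   ppm = 3, raw = NULL, rtWindow = 0.05,
                                   cap = 1e7) {
  use <- group[group$isotope_flag == "none", , drop = FALSE]
  if (!nrow(use)) return(list())
  use <- use[order(use$mz), , drop = FALSE]
  base <- max(use$intensity)
  out <- vector("list", nrow(use))
  resolvedF <- list(); resolvedW <- numeric(0)
  for (i in seq_len(nrow(use))) {
    rel <- use$intensity[i] / base
    w <- fragmentWeight(use$mz[i], rel)
    cand <- enumerateFormulas(use$mz[i], ppm, constraints, "cation_generic",
                              cap = cap)
    cand <- goldenRulesFilter(cand)
    cand <- Filter(function(f) isotopePatternCheck(
      f, use$mz[i], use$rt[i], raw = raw, groupFeatures = group,
      ppm = ppm, rtWindow = rtWindow), cand)
    resolved <- FALSE
    if (length(cand) == 1L) {
      resolved <- TRUE
    } else if (length(cand) > 1L) {
      support <- vapply(cand, function(f) {
        if (!length(resolvedF)) return(0)
        sum(resolvedW[vapply(resolvedF, isSubformula, logical(1), big = f)])
      }, numeric(1))
      if (max(support) > 0) {
        cand <- cand[which.max(support)]   # first max: smallest |dppm|
        resolved <- TRUE
      }
    }
    if (resolved) {
      resolvedF <- c(resolvedF, cand[1])
      resolvedW <- c(resolvedW, w)
    }
    out[[i]] <- list(feature_id = use$feature_id[i], mz = use$mz[i],
                     rel_intensity = rel, weight = w, formulas = cand,
                     resolved = resolved)
  }
  out
}

#' Score and rank molecular-ion candidates against fragment evidence
#'
#' The probability score of a candidate is the percentage of resolved
#' fragment evidence that its composition explains: with D the summed
#' weights of all resolved fragments, a candidate formula F (tested as its
#' [M+H]+ composition, i.e. neutral + 1 H) scores
#' 100 * (sum of weights of resolved fragments whose assigned formula is a
#' subformula of F+H) / D. A candidate with several surviving formulas is
#' ranked by its best one. Ties are broken towards higher m/z, then towards
#' the smaller mass error of the formula; candidates with no surviving
#' formula are ranked last with score 0.
#'
#' @param assignments output of \code{\link{assignFragmentFormulas}}.
#' @param candidates candidate data.frame (see \code{\link{findCandidates}}).
#' @param candidateFormulas list (parallel to candidate rows) of lists of
#'   neutral count vectors.
#' @return data.frame with one row per candidate: \code{rank},
#'   \code{candidate_mz}, \code{candidate_rt}, \code{assigned_formula}
#'   (Hill string, "" when none), \code{probability_score},
#'   \code{n_supporting_fragments}, \code{adduct_evidence}.
#' @export
scoreCandidates <- function(assignments, candidates, candidateFormulas) {
  res <- vapply(assignments, `[[`, logical(1), "resolved")
  rw <- vapply(assignments[res], `[[`, numeric(1), "weight")
  rf <- lapply(assignments[res], function(a) a$formulas[[1]])
  D <- sum(rw)
  n <- nrow(candidates)
  score <- numeric(n); nsupp <- integer(n)
  fstr <- character(n); dppm <- rep(Inf, n)
  for (i in seq_len(n)) {
    fl <- candidateFormulas[[i]]
    if (!length(fl)) next
    best <- -1; bestJ <- 1L
    for (j in seq_along(fl)) {
      ionComp <- formulaAdd(fl[[j]], c(H = 1L))
      supp <- if (length(rf))
        vapply(rf, isSubformula, logical(1), big = ionComp) else logical(0)
      num <- sum(rw[supp])
      dp <- abs(attr(fl[[j]], "dppm") %||% 0)
      better <- num > best || (num == best && dp < dppm[i])
      if (better) {
        best <- num; bestJ <- j
        score[i] <- if (D > 0) 100 * num / D else 0
        nsupp[i] <- sum(supp)
        dppm[i] <- dp
      }
    }
    fstr[i] <- formulaToString(fl[[bestJ]])
  }
  hasF <- nzchar(fstr)
  o <- order(-score, -hasF, -candidates$mz, dppm)
  data.frame(
    rank = seq_len(n),
    candidate_mz = candidates$mz[o],
    candidate_rt = candidates$rt[o],
    assigned_formula = fstr[o],
    probability_score = score[o],
    n_supporting_fragments = nsupp[o],
    adduct_evidence = candidates$adduct_evidence[o],
    stringsAsFactors = FALSE
  )
}

#' Rank molecular-ion candidates for one fragment pseudospectrum
#'
#' End-to-end ranking for one retention-time-matched spectrum pair:
#' candidates are collected from every matched molecular-ion pseudospectrum
#' (adduct/neutral-loss pattern, optionally confirmed in raw data),
#' deduplicated across pseudospectra (same m/z within ppm and retention time
#' within tolerance keeps the more intense record), cut to the top
#' candidates, given enumerated + filtered neutral formulas, and finally
#' scored against the chained fragment-formula assignment of the fragment
#' pseudospectrum. Deterministic for identical inputs and parameters.
#'
#' @param pair one element of \code{\link{matchSpectra}}'s output.
#' @param eiTable,ciTable preprocessed \linkS4class{FeatureTable}s.
#' @param rule an \linkS4class{AdductRule}.
#' @param constraints an \linkS4class{ElementConstraints}.
#' @param ppm mass tolerance.
#' @param topX,topXMode candidate cut, see \code{\link{filterTopCandidates}}.
#' @param rtTolerance minutes; also the raw-search half-window.
#' @param eiRaw,ciRaw optional \linkS4class{RawRun}s.
#' @param cap enumeration visit cap.
#' @return data.frame in the result-row layout (may have zero rows when no
#'   molecular ion is found, e.g. missing adduct/neutral-loss pattern).
#' @export
rankMolecularIons <- function(pair, eiTable, ciTable, rule = AdductRule(),
                              constraints = ElementConstraints(), ppm = 3,
                              topX = 10L, topXMode = "by_mz",
                              rtTolerance = 0.05, eiRaw = NULL, ciRaw = NULL,
                              cap = 1e7) {
  empty <- data.frame(
    ei_group_id = character(), rank = integer(), candidate_mz = numeric(),
    candidate_rt = numeric(), assigned_formula = character(),
    probability_score = numeric(), n_supporting_fragments = integer(),
    adduct_evidence = character(), stringsAsFactors = FALSE)
  ci <- features(ciTable)
  cands <- lapply(pair$ci_group_ids, function(g)
    findCandidates(ci[ci$group_id == g, , drop = FALSE], rule,
                   raw = ciRaw, rtWindow = rtTolerance))
  cands <- if (length(cands)) do.call(rbind, cands) else NULL
  if (is.null(cands) || !nrow(cands)) return(empty)

  # dedup across matched pseudospectra: same ion seen twice keeps the more
  # intense record
  o <- order(-cands$intensity, cands$mz, cands$rt, cands$feature_id)
  cands <- cands[o, , drop = FALSE]
  keep <- logical(nrow(cands))
  for (i in seq_len(nrow(cands))) {
    dup <- keep & abs(cands$mz - cands$mz[i]) <= cands$mz[i] * ppm * 1e-6 &
      abs(cands$rt - cands$rt[i]) <= rtTolerance
    keep[i] <- !any(dup)
  }
  cands <- cands[keep, , drop = FALSE]
  cands <- filterTopCandidates(cands, topX, topXMode)
  if (!nrow(cands)) return(empty)

  candFormulas <- lapply(seq_len(nrow(cands)), function(i) {
    fl <- enumerateFormulas(cands$mz[i], ppm, constraints,
                            "protonated_molecule", cap = cap)
    fl <- goldenRulesFilter(fl)
    grp <- ci[ci$group_id == cands$source_group_id[i], , drop = FALSE]
    Filter(function(f) isotopePatternCheck(
      f, cands$mz[i], cands$rt[i], raw = ciRaw, groupFeatures = grp,
      ppm = ppm, rtWindow = rtTolerance), fl)
  })

  ei <- features(eiTable)
  assignments <- assignFragmentFormulas(
    ei[ei$group_id == pair$ei_group_id, , drop = FALSE],
    constraints, ppm, raw = eiRaw, rtWindow = rtTolerance, cap = cap)

  ranked <- scoreCandidates(assignments, cands, candFormulas)
  cbind(data.frame(ei_group_id = pair$ei_group_id,
                   stringsAsFactors = FALSE), ranked)
}
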