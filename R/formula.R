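#' Elemental formulas
#'
#' A formula is a named integer vector of element counts, e.g.
#' \code{c(C = 6L, H = 12L, O = 6L)}. \code{parseFormula} reads the usual
#' string form, \code{formulaToString} serializes in Hill order (C first,
#' then H, then the remaining elements alphabetically; fully alphabetical
#' when no carbon is present), and \code{formulaAdd} sums counts.
#'
#' @param x a formula string like \code{"C6H12O6"}.
#' @param f,g named integer vectors of element counts.
#' @return \code{parseFormula}: named integer vector; \code{formulaToString}:
#'   character; \code{formulaAdd}: named integer vector.
#' @examples
#' parseFormula("C6H12O6")
#' formulaToString(c(O = 6L, C = 6L, H = 12L))
#' @export
parseFormula <- function(x) {
  parts <- regmatches(x, gregexpr("[A-Z][a-z]?[0-9]*", x))[[1]]
  parts <- parts[nzchar(parts)]
  sym <- sub("[0-9]*$", "", parts)
  cnt <- sub("^[A-Za-z]+", "", parts)
  cnt <- ifelse(cnt == "", 1L, as.integer(cnt))
  bad <- setdiff(sym, names(.ELEMENT_MASSES))
  if (length(bad)) stop("unknown element symbol: ", paste(bad, collapse = ", "))
  out <- tapply(cnt, sym, sum)
  stats::setNames(as.integer(out), names(out))
}

#' @rdname parseFormula
#' @export
formulaToString <- function(f) {
  f <- f[f > 0]
  if (!length(f)) return("")
  sym <- names(f)
  if ("C" %in% sym) {
    ord <- c(intersect(c("C", "H"), sym), sort(setdiff(sym, c("C", "H"))))
  } else {
    ord <- sort(sym)
  }
  f <- f[ord]
  paste0(names(f), ifelse(f == 1L, "", f), collapse = "")
}

#' @rdname parseFormula
#' @export
formulaAdd <- function(f, g) {
  el <- union(names(f), names(g))
  out <- stats::setNames(integer(length(el)), el)
  out[names(f)] <- out[names(f)] + f
  out[names(g)] <- out[names(g)] + g
  out
}

.countOf <- function(f, el) if (el %in% names(f)) as.numeric(f[[el]]) else 0

#' Ion or neutral mass of a formula
#'
#' Computes the monoisotopic mass of an element-count vector under one of
#' three conventions: \code{"neutral"} (plain sum of element masses),
#' \code{"protonated_molecule"} (neutral plus one proton: + H mass
#' - electron mass, the [M+H]+ species of soft ionization), or
#' \code{"cation_generic"} (the composition itself carrying the +1 charge:
#' - electron mass, the convention for EI fragment cations). Charge is
#' assumed +1 throughout, so the result is directly an m/z in Th.
#'
#' @param f named integer vector of element counts.
#' @param ion mass convention, see above.
#' @return Mass (neutral) or m/z (ion species) as a double.
#' @examples
#' formulaMass(c(C = 2L, H = 4L))                         # 28.03130
#' formulaMass(parseFormula("C6H12O6"), "protonated_molecule")  # 181.07066
#' @export
formulaMass <- function(f, ion = c("neutral", "protonated_molecule",
                                   "cation_generic")) {
  ion <- match.arg(ion)
  bad <- setdiff(names(f), names(.ELEMENT_MASSES))
  if (length(bad)) stop("unknown element symbol: ", paste(bad, collapse = ", "))
  m <- sum(.ELEMENT_MASSES[names(f)] * f)
  switch(ion,
    neutral = m,
    protonated_molecule = m + .ELEMENT_MASSES[["H"]] - .ELECTRON_MASS,
    cation_generic = m - .ELECTRON_MASS)
}

#' Enumerate elemental formulas matching an observed m/z
#'
#' Finds every element-count vector within the constraint windows whose ion
#' m/z (under \code{ion}) lies within \code{ppm} of the observed value. The
#' search is a bounded nested descent with the heaviest element outermost and
#' mass-based pruning at every level; a visit cap (default 1e7 count
#' assignments) turns pathological constraint windows into an error rather
#' than an unbounded run.
#'
#' For \code{ion = "protonated_molecule"} the returned formulas are the
#' neutral molecules M (the proton is handled by the mass convention); for
#' \code{"cation_generic"} they are the charged composition itself.
#'
#' @param mz observed m/z (Th), charge +1.
#' @param ppm relative tolerance.
#' @param constraints an \linkS4class{ElementConstraints}.
#' @param ion mass convention, see \code{\link{formulaMass}}.
#' @param cap maximum number of count assignments to visit.
#' @return List of formulas (named integer vectors), sorted by increasing
#'   absolute ppm error; each carries the signed error in attribute
#'   \code{"dppm"}. The empty composition is never returned.
#' @export
enumerateFormulas <- function(mz, ppm, constraints = ElementConstraints(),
                              ion = c("cation_generic", "protonated_molecule",
                                      "neutral"),
                              cap = 1e7) {
  ion <- match.arg(ion)
  stopifnot(mz > 0, ppm > 0)
  adj <- switch(ion, neutral = 0,
    protonated_molecule = .ELEMENT_MASSES[["H"]] - .ELECTRON_MASS,
    cation_generic = -.ELECTRON_MASS)
  # composition-mass window equivalent to the ion-m/z window
  lo <- mz * (1 - ppm * 1e-6) - adj
  hi <- mz * (1 + ppm * 1e-6) - adj
  el <- names(constraints@minCounts)
  masses <- .ELEMENT_MASSES[el]
  ord <- order(masses, decreasing = TRUE)
  counts <- .enumerateCpp(unname(masses[ord]),
                          unname(constraints@minCounts[ord]),
                          unname(constraints@maxCounts[ord]),
                          lo, hi, cap)
  if (!nrow(counts)) return(list())
  colnames(counts) <- el[ord]
  keep <- rowSums(counts) > 0L
  counts <- counts[keep, , drop = FALSE]
  if (!nrow(counts)) return(list())
  ionMz <- as.vector(counts %*% masses[ord]) + adj
  dppm <- (ionMz - mz) / mz * 1e6
  o <- order(abs(dppm))
  lapply(o, function(i) {
    f <- counts[i, ]
    f <- f[f > 0L]
    attr(f, "dppm") <- dppm[i]
    f
  })
}

# default element-ratio windows; common-range heuristics for small molecules
.GOLDEN_DEFAULTS <- list(
  hc = c(0.1, 6.0), nc = 4, oc = 3, pc = 2, sc = 3, sic = 1, clc = 2,
  minRdbe = -0.5
)

#' Ring-and-double-bond equivalents
#'
#' RDBE = C - (H + Cl + Br)/2 + N/2 + P/2 + Si + 1, the valence-based
#' unsaturation count with silicon tetravalent like carbon and the halogens
#' monovalent like hydrogen.
#'
#' @param f named integer vector of element counts.
#' @return RDBE (possibly half-integral, possibly negative).
#' @export
rdbe <- function(f) {
  .countOf(f, "C") - (.countOf(f, "H") + .countOf(f, "Cl") +
    .countOf(f, "Br")) / 2 +
    .countOf(f, "N") / 2 + .countOf(f, "P") / 2 + .countOf(f, "Si") + 1
}

#' Heuristic element-ratio filter
#'
#' Removes formulas whose element ratios fall outside common-range bounds
#' (H/C in [0.1, 6]; N/C <= 4; O/C <= 3; P/C <= 2; S/C <= 3; Si/C <= 1;
#' Cl/C <= 2) or whose RDBE is below \code{minRdbe}. Ratio bounds apply only
#' when carbon is present; carbon-free formulas face only the RDBE bound.
#' The default RDBE floor of -0.5 admits both odd- and even-electron cations.
#' Order is preserved; the output is always a subset of the input.
#'
#' @param formulas list of named integer count vectors.
#' @param hc length-2 H/C window.
#' @param nc,oc,pc,sc,sic,clc upper ratio bounds relative to carbon.
#' @param minRdbe RDBE floor.
#' @return Filtered list.
#' @export
goldenRulesFilter <- function(formulas,
                              hc = .GOLDEN_DEFAULTS$hc,
                              nc = .GOLDEN_DEFAULTS$nc,
                              oc = .GOLDEN_DEFAULTS$oc,
                              pc = .GOLDEN_DEFAULTS$pc,
                              sc = .GOLDEN_DEFAULTS$sc,
                              sic = .GOLDEN_DEFAULTS$sic,
                              clc = .GOLDEN_DEFAULTS$clc,
                              minRdbe = .GOLDEN_DEFAULTS$minRdbe) {
  ok <- vapply(formulas, function(f) {
    C <- .countOf(f, "C")
    if (C > 0) {
      if (.countOf(f, "H") / C < hc[1] || .countOf(f, "H") / C > hc[2])
        return(FALSE)
      if (.countOf(f, "N") / C > nc) return(FALSE)
      if (.countOf(f, "O") / C > oc) return(FALSE)
      if (.countOf(f, "P") / C > pc) return(FALSE)
      if (.countOf(f, "S") / C > sc) return(FALSE)
      if (.countOf(f, "Si") / C > sic) return(FALSE)
      if (.countOf(f, "Cl") / C > clc) return(FALSE)
    }
    rdbe(f) >= minRdbe
  }, logical(1))
  formulas[ok]
}

#' Veto formulas whose diagnostic isotope peaks are missing
#'
#' S, Cl and Br have intense, well-separated A+2 isotopologues (offsets
#' 1.99580, 1.99705 and 1.99796 u); a formula containing any of them is only
#' plausible when the corresponding A+2 companion of the observed peak is
#' actually present. The companion is searched in raw data around the
#' feature's retention time when a \linkS4class{RawRun} is given (preferred:
#' deconvolution may have dropped weak isotope peaks), otherwise among the
#' pseudospectrum's features. Formulas without S/Cl/Br always pass; the A+2
#' signal of C/H/N/O is too weak to be diagnostic. Presence-only: no
#' abundance-ratio fit is attempted, so elements are never ruled out by a
#' poor intensity estimate.
#'
#' @param f named integer count vector.
#' @param baseMz observed monoisotopic m/z of the ion.
#' @param rt retention time (minutes) of the ion.
#' @param raw optional \linkS4class{RawRun}.
#' @param groupFeatures data.frame of the ion's pseudospectrum features
#'   (used when \code{raw} is NULL; isotope-flagged features count as
#'   evidence here).
#' @param ppm mass tolerance for locating the companion.
#' @param rtWindow raw-search half-window in minutes.
#' @return TRUE if the formula survives, FALSE if vetoed.
#' @export
isotopePatternCheck <- function(f, baseMz, rt, raw = NULL,
                                groupFeatures = NULL, ppm = 3,
                                rtWindow = 0.05) {
  need <- intersect(names(.A2_OFFSETS), names(f[f > 0]))
  if (!length(need)) return(TRUE)
  for (el in need) {
    target <- baseMz + .A2_OFFSETS[[el]]
    found <- if (!is.null(raw)) {
      searchRawPeak(raw, rt, rtWindow, target, ppm)$found
    } else if (!is.null(groupFeatures) && nrow(groupFeatures)) {
      any(abs(groupFeatures$mz - target) <= target * ppm * 1e-6)
    } else FALSE
    if (!found) return(FALSE)
  }
  TRUE
}

#' Subformula relation
#'
#' TRUE iff every element count of \code{small} is at most the corresponding
#' count of \code{big}. This is the partial order under which all fragments
#' of a molecular ion must sit below the ion's composition.
#'
#' @param small,big named integer count vectors.
#' @return Logical scalar.
#' @examples
#' isSubformula(parseFormula("C2H4O"), parseFormula("C6H12O6"))
#' @export
isSubformula <- function(small, big) {
  small <- small[small > 0]
  if (!length(small)) return(TRUE)
  bigAt <- stats::setNames(rep(0L, length(small)), names(small))
  hit <- intersect(names(small), names(big))
  bigAt[hit] <- big[hit]
  all(small <= bigAt)
}
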