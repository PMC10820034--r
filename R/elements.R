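#' Monoisotopic element masses
#'
#' Monoisotopic masses (u) of the elements supported by the formula engine,
#' plus the electron mass used for ion mass arithmetic. Values follow the
#' standard IUPAC/CODATA monoisotopic masses with carbon fixed at exactly 12.
#'
#' @return Named numeric vector of monoisotopic masses.
#' @examples
#' elementMasses()[["C"]]
#' @export
elementMasses <- function() .ELEMENT_MASSES

.ELEMENT_MASSES <- c(
  C  = 12,
  H  = 1.00782503207,
  N  = 14.0030740048,
  O  = 15.9949146196,
  P  = 30.97376163,
  S  = 31.97207100,
  Si = 27.97692653,
  Cl = 34.96885268,
  Br = 78.9183371
)

.ELECTRON_MASS <- 0.00054857991

#' Mass of the electron
#'
#' @return Electron rest mass in u.
#' @export
electronMass <- function() .ELECTRON_MASS

# A+2 isotopologue spacings (u) diagnostic for S, Cl, Br:
# 34S-32S, 37Cl-35Cl, 81Br-79Br.
.A2_OFFSETS <- c(S = 1.99580, Cl = 1.99705, Br = 1.99796)

#' Diagnostic A+2 isotope spacings
#'
#' The m/z offsets of the A+2 isotopologue peak relative to the monoisotopic
#' peak for the elements whose isotope pattern is diagnostic at high
#' resolution (34S, 37Cl, 81Br).
#'
#' @return Named numeric vector of offsets in u.
#' @export
isotopeA2Offsets <- function() .A2_OFFSETS
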