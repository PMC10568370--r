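# Chemical formula handling: Hill-notation parsing and molecular weights.

# IUPAC 2021 standard atomic weights, g/mol (conventional values for the
# interval elements). Covers the elements occurring in curated metabolic
# model formulas.
.ATOMIC_MASSES <- c(
  H = 1.008, He = 4.002602, Li = 6.94, Be = 9.0121831, B = 10.81,
  C = 12.011, N = 14.007, O = 15.999, F = 18.998403163, Ne = 20.1797,
  Na = 22.98976928, Mg = 24.305, Al = 26.9815384, Si = 28.085,
  P = 30.973761998, S = 32.06, Cl = 35.45, K = 39.0983, Ar = 39.95,
  Ca = 40.078, Cr = 51.9961, Mn = 54.938043, Fe = 55.845, Co = 58.933194,
  Ni = 58.6934, Cu = 63.546, Zn = 65.38, As = 74.921595, Se = 78.971,
  Br = 79.904, Mo = 95.95, Ag = 107.8682, Cd = 112.414, Sn = 118.71,
  I = 126.90447, W = 183.84, Hg = 200.592
)

#' Parse a chemical formula in Hill notation
#'
#' Accepts plain element-symbol/count notation such as \code{"C6H12O6"}.
#' Counts default to 1. Groups in parentheses, polymer repeats
#' (\code{"(C2H4)n"}) and generic side chains (\code{"R"}, \code{"X"})
#' are rejected: such species have no defined molecular weight.
#'
#' @param formula character(1), e.g. \code{"C10H12N5O13P3"}.
#' @return named integer vector mapping element symbols to positive counts.
#' @examples
#' parseFormula("C6H12O6")
#' @export
parseFormula <- function(formula) {
  if (length(formula) != 1L || is.na(formula) || !nzchar(formula))
    stop("empty formula")
  if (grepl("[()\\[\\]*.]", formula, perl = TRUE))
    stop(sprintf("formula '%s' contains groups or repeats; only plain Hill notation is supported",
                 formula))
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", formula, perl = TRUE)[[1]]
  tokens <- regmatches(formula, gregexpr("([A-Z][a-z]?)([0-9]*)", formula, perl = TRUE))[[1]]
  if (sum(attr(m, "match.length")) != nchar(formula) || length(tokens) == 0L)
    stop(sprintf("cannot parse formula '%s'", formula))
  syms <- sub("[0-9]*$", "", tokens)
  cnts <- sub("^[A-Z][a-z]?", "", tokens)
  cnts <- ifelse(cnts == "", 1L, suppressWarnings(as.integer(cnts)))
  bad <- setdiff(syms, names(.ATOMIC_MASSES))
  if (length(bad))
    stop(sprintf("unknown element symbol(s) in '%s': %s",
                 formula, paste(bad, collapse = ", ")))
  if (any(is.na(cnts) | cnts <= 0L))
    stop(sprintf("invalid element count in '%s'", formula))
  out <- tapply(cnts, syms, sum)
  structure(as.integer(out), names = names(out))
}

#' Molecular weight of a composition
#'
#' Sums standard atomic masses over an element-count mapping and returns the
#' weight in g/mmol (g/mol divided by 1000), the unit in which biomass
#' coefficients (mmol/gDW) times weights yield grams per gDW.
#'
#' @param composition named numeric/integer vector as returned by
#'   \code{\link{parseFormula}}.
#' @return numeric(1), molecular weight in g/mmol.
#' @examples
#' molecularWeight(parseFormula("H2O"))   # 0.018015
#' @export
molecularWeight <- function(composition) {
  if (length(composition) == 0L)
    stop("empty composition has no molecular weight")
  el <- names(composition)
  bad <- setdiff(el, names(.ATOMIC_MASSES))
  if (length(bad))
    stop(sprintf("no atomic mass for element(s): %s", paste(bad, collapse = ", ")))
  sum(.ATOMIC_MASSES[el] * as.numeric(composition)) / 1000
}

# Molecular weight of a metabolite: explicit mw wins, else the formula.
# Returns NA when neither is available.
.metaboliteMw <- function(model, id) {
  met <- model@metabolites[model@metabolites$id == id, , drop = FALSE]
  if (nrow(met) == 0L) return(NA_real_)
  if (!is.na(met$mw)) return(met$mw)
  if (!is.na(met$formula) && nzchar(met$formula))
    return(molecularWeight(parseFormula(met$formula)))
  NA_real_
}
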