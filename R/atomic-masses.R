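# Elemental compositions are named integer vectors over the element set
# used by the lipid classes covered here (C, H, N, O, P, Na).

.ELEMENTS <- c("C", "H", "N", "O", "P", "Na")

# CODATA/IUPAC 2021 monoisotopic atomic masses (u); electron mass included
# so that ion m/z values carry the correct electron correction.
.ATOMIC_MASS <- c(
  C  = 12.0,
  H  = 1.0078250319,
  N  = 14.0030740052,
  O  = 15.9949146221,
  P  = 30.97376151,
  Na = 22.98976928
)
.ELECTRON_MASS <- 0.00054857990
.D_MINUS_H <- 2.0141017781 - 1.0078250319  # deuterium label mass shift
.PROTON <- .ATOMIC_MASS[["H"]] - .ELECTRON_MASS

#' Build an elemental composition
#'
#' A composition is a named numeric vector of element counts over
#' C, H, N, O, P, Na. Compositions add element-wise; subtraction must not
#' produce negative counts.
#'
#' @param C,H,N,O,P,Na Non-negative integer element counts.
#' @return Named numeric vector of length 6.
#' @examples
#' composition(C = 3, H = 8, O = 3)  # glycerol
#' @export
composition <- function(C = 0, H = 0, N = 0, O = 0, P = 0, Na = 0) {
  x <- c(C = C, H = H, N = N, O = O, P = P, Na = Na)
  if (any(x < 0)) stop("element counts must be non-negative")
  x
}

comp_add <- function(a, b) a + b

comp_subtract <- function(a, b) {
  out <- a - b
  if (any(out < -1e-9)) {
    bad <- .ELEMENTS[out < -1e-9]
    stop("composition subtraction yields negative count for: ",
         paste(bad, collapse = ", "))
  }
  out
}

#' Monoisotopic mass of an elemental composition
#'
#' @param comp Composition from [composition()].
#' @param charge Signed integer charge; the mass of `charge` electrons is
#'   subtracted so charged compositions give ion m/z directly.
#' @return Monoisotopic mass (or m/z for |charge| = 1) in u.
#' @export
comp_mass <- function(comp, charge = 0) {
  sum(comp * .ATOMIC_MASS[names(comp)]) - charge * .ELECTRON_MASS
}

#' Molecular formula string (Hill order) of a composition
#' @param comp Composition vector.
#' @return Character scalar, e.g. `"C16H32O2"`.
#' @export
comp_formula <- function(comp) {
  ord <- c("C", "H", "N", "O", "P", "Na")
  comp <- comp[ord]
  comp <- comp[comp > 0]
  paste0(names(comp), ifelse(comp == 1, "", comp), collapse = "")
}

.WATER <- c(C = 0, H = 2, N = 0, O = 1, P = 0, Na = 0)
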