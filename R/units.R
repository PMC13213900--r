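# Internal unit system: angstrom for length, kcal/mol/e for ESP,
# e/bohr^3 for electron density.  Every file reader converts on input and
# every writer converts back on output, so no other module touches units.

#' Physical constants used for unit conversion
#'
#' The package works in a single internal unit system: angstrom (A) for
#' lengths, kcal mol^-1 e^-1 for electrostatic potential and e bohr^-3 for
#' electron density.  Cube files (bohr, hartree) are converted on read and
#' write with the constants below.
#'
#' @format A named numeric vector with elements
#' \describe{
#'   \item{bohr_to_angstrom}{0.52917721 A per bohr}
#'   \item{hartree_to_kcalmol}{627.5095 kcal/mol per hartree}
#'   \item{coulomb_kcal}{332.0637 kcal A mol^-1 e^-2, the Coulomb constant
#'     giving V = k q / r in kcal/mol/e for q in e and r in A}
#' }
#' @export
esphole_constants <- c(
  bohr_to_angstrom   = 0.52917721,
  hartree_to_kcalmol = 627.5095,
  coulomb_kcal       = 332.0637
)

.BOHR <- 0.52917721
.HARTREE_KCAL <- 627.5095
.KCOUL <- 332.0637

#' Convert lengths between angstrom and bohr
#'
#' @param x numeric vector of lengths.
#' @return Converted numeric vector.
#' @examples
#' bohr_to_ang(0.25)        # the default grid spacing in A
#' ang_to_bohr(bohr_to_ang(1))  # exactly 1
#' @export
bohr_to_ang <- function(x) x * .BOHR

#' @rdname bohr_to_ang
#' @export
ang_to_bohr <- function(x) x / .BOHR

# atomic numbers for the elements this package can meet; cube files store Z
.ELEMENTS <- c(
  H = 1, He = 2, Li = 3, Be = 4, B = 5, C = 6, N = 7, O = 8, F = 9,
  Ne = 10, Na = 11, Mg = 12, Al = 13, Si = 14, P = 15, S = 16, Cl = 17,
  Ar = 18, K = 19, Ca = 20, Sc = 21, Ti = 22, V = 23, Cr = 24, Mn = 25,
  Fe = 26, Co = 27, Ni = 28, Cu = 29, Zn = 30, Ga = 31, Ge = 32, As = 33,
  Se = 34, Br = 35, Kr = 36
)

.element_number <- function(sym) {
  z <- .ELEMENTS[sym]
  if (anyNA(z)) {
    stop("unknown element symbol(s): ",
         paste(unique(sym[is.na(z)]), collapse = ", "), call. = FALSE)
  }
  unname(z)
}

.element_symbol <- function(z) {
  sym <- names(.ELEMENTS)[match(z, .ELEMENTS)]
  if (anyNA(sym)) {
    stop("unknown atomic number(s): ",
         paste(unique(z[is.na(sym)]), collapse = ", "), call. = FALSE)
  }
  sym
}
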