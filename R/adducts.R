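# Adduct specifications and ionic m/z.
#
# An adduct is a named mass/charge transformation of the neutral molecule M:
# a delta formula (atoms gained, atoms lost) and a signed charge.  Ionic m/z
# includes the electron-count correction: each positive charge removes one
# electron mass, each negative charge adds one.

.ADDUCT_REGISTRY <- list(
  "[M+H]+"      = list(gain = c(H = 1L),               lose = NULL,        charge = +1L),
  "[M+NH4]+"    = list(gain = c(N = 1L, H = 4L),       lose = NULL,        charge = +1L),
  "[M+Na]+"     = list(gain = c(Na = 1L),              lose = NULL,        charge = +1L),
  "[M+H-H2O]+"  = list(gain = c(H = 1L),               lose = c(H = 2L, O = 1L), charge = +1L),
  "[M-H]-"      = list(gain = NULL,                    lose = c(H = 1L),   charge = -1L),
  "[M+2H]2+"    = list(gain = c(H = 2L),               lose = NULL,        charge = +2L)
)

#' Look up an adduct specification
#'
#' @param name Adduct name, one of `"[M+H]+"`, `"[M+NH4]+"`, `"[M+Na]+"`,
#'   `"[M+H-H2O]+"`, `"[M-H]-"`, `"[M+2H]2+"`.  The ASCII hyphen is used for
#'   losses.
#' @return An object of class `adduct_spec` with fields `name`, `gain`,
#'   `lose` (element-count vectors) and `charge`.
#' @export
adduct_spec <- function(name) {
  if (inherits(name, "adduct_spec")) return(name)
  spec <- .ADDUCT_REGISTRY[[name]]
  if (is.null(spec)) {
    stop("unknown adduct '", name, "'; supported adducts: ",
         paste(names(.ADDUCT_REGISTRY), collapse = ", "), call. = FALSE)
  }
  out <- list(
    name = name,
    gain = if (is.null(spec$gain)) element_count() else element_count(spec$gain),
    lose = if (is.null(spec$lose)) element_count() else element_count(spec$lose),
    charge = spec$charge
  )
  class(out) <- "adduct_spec"
  out
}

#' Supported adduct names
#' @return Character vector of adduct names understood by [adduct_spec()].
#' @export
known_adducts <- function() names(.ADDUCT_REGISTRY)

#' @export
print.adduct_spec <- function(x, ...) {
  cat("<adduct> ", x$name, "  (z = ", sprintf("%+d", x$charge),
      ", shift = ", sprintf("%+.6f", adduct_mass_shift(x)), " Da)\n", sep = "")
  invisible(x)
}

#' Mass shift of an adduct, electron-corrected
#'
#' Mass added to the neutral molecule on ionization: atoms gained minus atoms
#' lost, minus `charge` electron masses.
#'
#' @param adduct An `adduct_spec` or adduct name.
#' @return Mass shift in Da (for the whole ion, before division by |z|).
#' @export
adduct_mass_shift <- function(adduct) {
  adduct <- adduct_spec(adduct)
  monoisotopic_mass(adduct$gain) - monoisotopic_mass(adduct$lose) -
    adduct$charge * ELECTRON_MASS
}

#' Ionic m/z of a formula under an adduct
#'
#' `(monoisotopic_mass(M) + mass shift) / |charge|`, with the electron-count
#' correction included in the shift.  Values are exact; rounding is left to
#' presentation (the conventional printout keeps four decimals).
#'
#' @param formula Neutral molecule as an `element_count` or formula string.
#' @param adduct An `adduct_spec` or adduct name.
#' @return m/z in Th.
#' @examples
#' adduct_mz("C28H55O8Cl", "[M+H]+")    # 555.3658...
#' adduct_mz("C46H89O9Cl", "[M+NH4]+")  # 838.6533...
#' @export
adduct_mz <- function(formula, adduct) {
  adduct <- adduct_spec(adduct)
  stopifnot(abs(adduct$charge) >= 1L)
  (monoisotopic_mass(formula) + adduct_mass_shift(adduct)) / abs(adduct$charge)
}
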