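# Physical constants and the embedded isotope table.
#
# One fixed table of isotopic masses (Da) and natural abundances for the
# element set C, H, D, N, O, S, Cl, Na is shipped as a plain-text file under
# inst/extdata/ and cached at first use.  "D" is deuterium treated as a
# distinct element so that label atoms can be counted separately from natural
# hydrogen.  The table version string is echoed into pipeline provenance
# blocks so that any "calcd." m/z value can be traced to its constants.

ISOTOPE_TABLE_VERSION <- "halomet-isotopes-1.0 (CODATA-2018/AME-2020 rounded)"

# Electron and proton rest masses in Da.  The electron mass matters: ionic
# m/z values in the 4th decimal are only reproduced when the charge carrier
# is electron-corrected (a proton is 1.007276 Da, not 1.007825 Da).
ELECTRON_MASS <- 0.00054857990907
PROTON_MASS <- 1.00727646688

.halomet_env <- new.env(parent = emptyenv())

#' Isotope constants table
#'
#' Returns the embedded table of isotopic masses and natural abundances used
#' by all mass and envelope computations, one row per isotope.
#'
#' @return A data.frame with columns `element`, `nominal` (nominal mass
#'   number), `mass` (Da) and `abundance` (mole fraction, summing to 1 within
#'   each element).
#' @export
isotope_table <- function() {
  if (is.null(.halomet_env$isotopes)) {
    path <- system.file("extdata", "isotope_table.tsv", package = "halomet")
    if (path == "") {
      path <- file.path("inst", "extdata", "isotope_table.tsv")
    }
    tab <- utils::read.delim(path, stringsAsFactors = FALSE)
    .halomet_env$isotopes <- tab
  }
  .halomet_env$isotopes
}

#' Supported element symbols
#' @return Character vector of element symbols known to the constants table.
#' @export
known_elements <- function() unique(isotope_table()$element)

# Monoisotopic (lightest-isotope) mass of a single element symbol.
.element_monoisotopic <- function(element) {
  tab <- isotope_table()
  rows <- tab[tab$element == element, , drop = FALSE]
  if (nrow(rows) == 0L) stop("unknown element symbol: ", element, call. = FALSE)
  min(rows$mass)
}
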