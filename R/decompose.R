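# Exact-mass molecular formula decomposition.
#
# Bounded exhaustive enumeration over the configurable element set with a
# ring-plus-double-bond-equivalent (RDBE) plausibility filter, as is standard
# for assigning formulae to accurate Q-TOF masses at the 5-20 ppm level.

#' Default element count bounds for formula decomposition
#'
#' Covers lipid-scale metabolites up to ~1000 Da: C 0-60, H 0-120, N 0-5,
#' O 0-15, S 0-3, Cl 0-3, Na 0-1.
#' @return Named list of integer length-2 ranges.
#' @export
default_element_bounds <- function() {
  list(C = c(0L, 60L), H = c(0L, 120L), N = c(0L, 5L), O = c(0L, 15L),
       S = c(0L, 3L), Cl = c(0L, 3L), Na = c(0L, 1L))
}

# RDBE of a neutral formula; monovalent elements (H, D, Cl, Na) all count in
# the monovalent term.
.rdbe <- function(C, H, N, monovalent_extra = 0L) {
  C - (H + monovalent_extra) / 2 + N / 2 + 1
}

#' Decompose an observed m/z into candidate molecular formulae
#'
#' Exhaustively enumerates formulae within per-element bounds whose ionic
#' m/z under one of the given adducts falls within `tol_ppm` of the observed
#' value.  Candidates must pass an RDBE filter (integral RDBE in
#' `rdbe_range`, appropriate for even-electron adduct ions) and any
#' `require` constraints (e.g. at least one Cl when the chlorine flag from
#' the MS1 envelope is set).
#'
#' @param mz Observed m/z in Th.
#' @param adducts Character vector of adduct names (or list of
#'   `adduct_spec`) to consider; default `"[M+H]+"`.
#' @param tol_ppm Mass tolerance in ppm (> 0).
#' @param bounds Named list of integer `c(min, max)` count ranges; see
#'   [default_element_bounds()].
#' @param require Named list of minimum counts, e.g. `list(Cl = 1)`.
#' @param rdbe_range Admissible RDBE interval (default `c(-0.5, 40)`).
#' @return A data.frame of candidates with columns `formula`, `adduct`,
#'   `mz_calc`, `ppm`, `rdbe`, `heteroatoms`, sorted by `|ppm|` ascending,
#'   ties broken by fewer heteroatoms.  Zero rows when nothing matches.
#' @examples
#' decompose_mass(555.3658, tol_ppm = 5, require = list(Cl = 1))
#' @export
decompose_mass <- function(mz, adducts = "[M+H]+", tol_ppm = 10,
                           bounds = default_element_bounds(),
                           require = list(), rdbe_range = c(-0.5, 40)) {
  stopifnot(is.numeric(mz), length(mz) == 1L, tol_ppm > 0)
  if (length(bounds) == 0L) stop("empty element bounds", call. = FALSE)
  bad <- setdiff(names(bounds), known_elements())
  if (length(bad)) stop("bounds name unknown elements: ",
                        paste(bad, collapse = ", "), call. = FALSE)
  for (s in names(require)) {
    lo <- max(bounds[[s]][1] %||% 0L, as.integer(require[[s]]))
    hi <- if (is.null(bounds[[s]])) lo else bounds[[s]][2]
    if (hi < lo) return(.empty_candidates())
    bounds[[s]] <- c(lo, hi)
  }

  masses <- vapply(known_elements(), .element_monoisotopic, numeric(1))
  getb <- function(s) if (is.null(bounds[[s]])) c(0L, 0L) else as.integer(bounds[[s]])
  bC <- getb("C"); bH <- getb("H"); bN <- getb("N"); bO <- getb("O")
  bS <- getb("S"); bCl <- getb("Cl"); bNa <- getb("Na")

  out <- list()
  for (ad_name in adducts) {
    ad <- adduct_spec(ad_name)
    target <- mz * abs(ad$charge) - adduct_mass_shift(ad)  # neutral mass
    tol_da <- mz * tol_ppm * 1e-6 * abs(ad$charge)
    if (target <= 0) next
    for (nN in bN[1]:bN[2]) for (nO in bO[1]:bO[2]) for (nS in bS[1]:bS[2]) {
      for (nCl in bCl[1]:bCl[2]) for (nNa in bNa[1]:bNa[2]) {
        m_het <- nN * masses[["N"]] + nO * masses[["O"]] +
          nS * masses[["S"]] + nCl * masses[["Cl"]] + nNa * masses[["Na"]]
        if (m_het > target + tol_da) next
        nC_vec <- bC[1]:bC[2]
        rem <- target - m_het - nC_vec * masses[["C"]]
        # admissible H counts for each C: rem/massH within +-tol
        nH_lo <- ceiling((rem - tol_da) / masses[["H"]])
        nH_hi <- floor((rem + tol_da) / masses[["H"]])
        for (i in seq_along(nC_vec)) {
          if (nH_hi[i] < bH[1] || nH_lo[i] > bH[2]) next
          for (nH in max(nH_lo[i], bH[1]):min(nH_hi[i], bH[2])) {
            m <- m_het + nC_vec[i] * masses[["C"]] + nH * masses[["H"]]
            err_da <- m - target
            if (abs(err_da) > tol_da) next
            rdbe <- .rdbe(nC_vec[i], nH, nN, nCl + nNa)
            if (rdbe < rdbe_range[1] || rdbe > rdbe_range[2]) next
            if (abs(rdbe - round(rdbe)) > 1e-9) next  # even-electron ions
            cnt <- c(C = nC_vec[i], H = nH, N = nN, O = nO, S = nS,
                     Cl = nCl, Na = nNa)
            cnt <- cnt[cnt > 0L]
            f <- element_count(cnt)
            mz_calc <- adduct_mz(f, ad)
            out[[length(out) + 1L]] <- data.frame(
              formula = format(f), adduct = ad$name, mz_calc = mz_calc,
              ppm = (mz_calc - mz) / mz * 1e6, rdbe = rdbe,
              heteroatoms = nN + nO + nS + nCl + nNa,
              stringsAsFactors = FALSE)
          }
        }
      }
    }
  }
  if (length(out) == 0L) return(.empty_candidates())
  res <- do.call(rbind, out)
  res <- res[order(abs(res$ppm), res$heteroatoms), , drop = FALSE]
  rownames(res) <- NULL
  res
}

.empty_candidates <- function() {
  data.frame(formula = character(0), adduct = character(0),
             mz_calc = numeric(0), ppm = numeric(0), rdbe = numeric(0),
             heteroatoms = integer(0), stringsAsFactors = FALSE)
}
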