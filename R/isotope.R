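# Isotope envelope simulation and chlorine detection.
#
# Envelopes are centroided by integer nominal-mass offset (M+0, M+1, ...):
# within one offset the m/z is the abundance-weighted mean of all contributing
# isotopologues, so fine structure (e.g. 13C2 vs 37Cl at M+2) is deliberately
# not resolved, matching centroided Q-TOF MS1 data.  Convolution is carried in
# (abundance, abundance*mass) pairs so centroids stay exact under aggregation.

# Internal envelope: list(A = abundance by offset 0..K, AM = abundance-weighted
# mass sum by offset).  Index i corresponds to offset i-1.
.conv_env <- function(x, y, kmax) {
  nx <- length(x$A); ny <- length(y$A)
  n <- min(nx + ny - 1L, kmax + 1L)
  A <- numeric(n); AM <- numeric(n)
  for (i in seq_len(nx)) {
    jmax <- min(ny, n - i + 1L)
    if (jmax < 1L) break
    j <- seq_len(jmax)
    k <- i + j - 1L
    A[k] <- A[k] + x$A[i] * y$A[j]
    AM[k] <- AM[k] + x$AM[i] * y$A[j] + x$A[i] * y$AM[j]
  }
  list(A = A, AM = AM)
}

# Single-atom envelope for one element (optionally with overridden isotope
# distribution, used for partially pure labels).
.atom_env <- function(element, kmax) {
  tab <- isotope_table()
  rows <- tab[tab$element == element, , drop = FALSE]
  if (nrow(rows) == 0L) stop("unknown element symbol: ", element, call. = FALSE)
  rows <- rows[order(rows$mass), , drop = FALSE]
  off <- round(rows$mass - rows$mass[1])
  n <- min(max(off) + 1L, kmax + 1L)
  A <- numeric(n); AM <- numeric(n)
  keep <- off <= (n - 1L)
  A[off[keep] + 1L] <- rows$abundance[keep]
  AM[off[keep] + 1L] <- rows$abundance[keep] * rows$mass[keep]
  list(A = A, AM = AM)
}

# n-atom envelope by binary exponentiation of the single-atom envelope.
.element_env <- function(element, n, kmax) {
  base <- .atom_env(element, kmax)
  result <- NULL
  while (n > 0L) {
    if (n %% 2L == 1L) {
      result <- if (is.null(result)) base else .conv_env(result, base, kmax)
    }
    n <- n %/% 2L
    if (n > 0L) base <- .conv_env(base, base, kmax)
  }
  if (is.null(result)) list(A = 1.0, AM = 0.0) else result
}

#' Simulate the isotope envelope of a formula
#'
#' Convolves the per-element natural isotope distributions and aggregates
#' isotopologues by integer nominal-mass offset.  The centroid m/z of each
#' offset is the abundance-weighted mean mass; abundances are normalized so
#' the most abundant peak equals 1.
#'
#' @param formula An `element_count` or formula string (neutral molecule).
#' @param max_offsets Number of offsets retained beyond M+0 (default 8, i.e.
#'   M+0..M+8).
#' @param prune Abundances below this fraction of the base peak are dropped
#'   (default `1e-4`).  Use 0 to keep the full (truncated-at-`max_offsets`)
#'   distribution.
#' @param charge Optional signed charge: when non-zero, centroid masses are
#'   converted to ionic m/z, `(mass - charge * electron mass) / |charge|`.
#' @return An `isotope_pattern`: a data.frame with columns `offset`, `mz`
#'   (Da for neutral, Th when `charge != 0`) and `abundance`, plus attribute
#'   `base_offset` (offset of the most abundant peak).
#' @examples
#' isotope_pattern("Cl")          # M+2/M+0 = 0.32
#' isotope_pattern("C28H55O8Cl")
#' @export
isotope_pattern <- function(formula, max_offsets = 8L, prune = 1e-4,
                            charge = 0L) {
  stopifnot(max_offsets >= 1L, prune >= 0)
  formula <- as_element_count(formula)
  kmax <- as.integer(max_offsets)
  env <- list(A = 1.0, AM = 0.0)
  for (s in names(formula)) {
    env <- .conv_env(env, .element_env(s, formula[[s]], kmax), kmax)
  }
  A <- env$A
  M <- ifelse(A > 0, env$AM / A, NA_real_)
  keep <- A > 0
  off <- which(keep) - 1L
  A <- A[keep]; M <- M[keep]
  rel <- A / max(A)
  sel <- rel >= prune | rel == max(rel)
  off <- off[sel]; A <- A[sel]; M <- M[sel]; rel <- rel[sel]
  mz <- M
  if (charge != 0L) mz <- (M - charge * ELECTRON_MASS) / abs(charge)
  out <- data.frame(offset = off, mz = mz, abundance = rel / max(rel))
  attr(out, "base_offset") <- off[which.max(out$abundance)]
  attr(out, "isotope_table_version") <- ISOTOPE_TABLE_VERSION
  class(out) <- c("isotope_pattern", "data.frame")
  out
}

#' Build an isotope pattern from a centroided peak list
#'
#' Assigns each observed MS1 peak to an integer nominal-mass offset relative
#' to the lightest (or supplied) monoisotopic peak; peaks not matching any
#' integer offset within `mz_tol` are treated as absent.
#'
#' @param mz,abundance Numeric vectors of observed centroid m/z and
#'   intensity.
#' @param mono_mz m/z of the M+0 peak (default: smallest `mz`).
#' @param mz_tol Matching tolerance in Th (default 0.01).
#' @return An `isotope_pattern` normalized to base peak 1.
#' @export
isotope_pattern_from_peaks <- function(mz, abundance, mono_mz = min(mz),
                                       mz_tol = 0.01) {
  stopifnot(length(mz) == length(abundance))
  if (length(mz) == 0L) stop("empty peak list", call. = FALSE)
  spacing <- 1.00335  # mean nominal-offset spacing, Da
  off <- round((mz - mono_mz) / spacing)
  ok <- off >= 0 & abs(mz - mono_mz - off * spacing) <= mz_tol
  off <- off[ok]; mz <- mz[ok]; abundance <- abundance[ok]
  if (length(off) == 0L) stop("no peaks align to integer isotopologue offsets",
                              call. = FALSE)
  agg_ab <- vapply(split(abundance, off), sum, numeric(1))
  agg_mz <- vapply(split(seq_along(off), off),
                   function(i) sum(mz[i] * abundance[i]) / sum(abundance[i]),
                   numeric(1))
  o <- as.integer(names(agg_ab))
  ord <- order(o)
  out <- data.frame(offset = o[ord], mz = agg_mz[ord],
                    abundance = agg_ab[ord] / max(agg_ab))
  attr(out, "base_offset") <- out$offset[which.max(out$abundance)]
  class(out) <- c("isotope_pattern", "data.frame")
  out
}

#' @export
print.isotope_pattern <- function(x, ...) {
  cat("<isotope pattern> ", nrow(x), " offsets (base at M+",
      attr(x, "base_offset") %||% x$offset[which.max(x$abundance)], ")\n",
      sep = "")
  print.data.frame(format(as.data.frame(x), digits = 6), row.names = FALSE)
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Score an MS1 envelope for chlorination
#'
#' Classifies an observed isotope envelope as chlorinated from the intensity
#' of the M+2 isotopologue relative to M+0.  A single chlorine contributes an
#' M+2/M+0 ratio of 0.32 (37Cl/35Cl = 0.2424/0.7576); carbon and oxygen add a
#' smaller, mass-dependent amount.  The default acceptance windows are
#' 0.20-0.50 for one chlorine and 0.50-0.85 for two, applied only when the
#' M+1/M+0 ratio is consistent with a plausible carbon count (M+1/M+0 <= 0.6,
#' which also rejects overlapping double envelopes).
#'
#' @param observed An `isotope_pattern` containing an M+0 peak (offset 0).
#' @param window_1cl,window_2cl Numeric length-2 acceptance windows on the
#'   M+2/M+0 ratio for one and two chlorines.
#' @param max_m1_ratio Maximum admissible M+1/M+0 ratio.
#' @return A list with `is_chlorinated` (logical), `ratio` (M+2/M+0, 0 when
#'   M+2 is absent), `n_cl_estimate` (0, 1 or 2) and `m1_ratio`.
#' @export
chlorine_score <- function(observed,
                           window_1cl = c(0.20, 0.50),
                           window_2cl = c(0.50, 0.85),
                           max_m1_ratio = 0.6) {
  if (!inherits(observed, "isotope_pattern") || nrow(observed) == 0L) {
    stop("'observed' must be a non-empty isotope_pattern", call. = FALSE)
  }
  a0 <- observed$abundance[observed$offset == 0L]
  if (length(a0) != 1L || a0 <= 0) {
    stop("observed pattern has no M+0 peak", call. = FALSE)
  }
  a1 <- observed$abundance[observed$offset == 1L]
  a2 <- observed$abundance[observed$offset == 2L]
  m1 <- if (length(a1) == 1L) a1 / a0 else 0.0
  ratio <- if (length(a2) == 1L) a2 / a0 else 0.0
  n_cl <- 0L
  if (m1 <= max_m1_ratio) {
    if (ratio >= window_1cl[1] && ratio <= window_1cl[2]) {
      n_cl <- 1L
    } else if (ratio > window_2cl[1] && ratio <= window_2cl[2]) {
      n_cl <- 2L
    }
  }
  list(is_chlorinated = n_cl >= 1L, ratio = ratio, n_cl_estimate = n_cl,
       m1_ratio = m1)
}
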