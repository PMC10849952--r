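# Stable-isotope feeding analysis.
#
# A feeding experiment with a deuterated precursor yields an MS1 envelope
# that is a mixture of the unlabeled metabolite and one or more labeled
# species (the precursor's D atoms, minus any lost during biosynthesis, e.g.
# one deuterium displaced by chlorination).  The observed envelope is fitted
# as a non-negative mixture of theoretical envelopes; competing
# label-retention hypotheses are ranked by residual.

#' Construct a labeled species from a parent formula
#'
#' Replaces `n_label - n_lost` hydrogens of the unlabeled parent with
#' deuterium and simulates its isotope envelope.  Label atoms are modeled at
#' `purity` isotopic enrichment (commercial labels are typically 98-99
#' atom-% D); the remainder behaves as natural hydrogen.
#'
#' @param parent Unlabeled parent formula (`element_count` or string).
#' @param n_label Number of label atoms fed on the precursor.
#' @param n_lost Number of label atoms lost during incorporation
#'   (`0 <= n_lost <= n_label`).
#' @param purity Isotopic purity of the label (default 0.99; use 1 for an
#'   ideal label).
#' @param max_offsets,prune Passed to [isotope_pattern()].
#' @return A `label_species`: list with `name`, `formula`, `n_d` (retained
#'   label atoms), `mass_offset` (Da relative to the unlabeled parent) and
#'   `pattern`.
#' @export
labeled_species <- function(parent, n_label, n_lost = 0L, purity = 0.99,
                            max_offsets = 8L, prune = 1e-4) {
  parent <- as_element_count(parent)
  n_label <- as.integer(n_label); n_lost <- as.integer(n_lost)
  if (n_lost < 0L || n_label < 0L || n_lost > n_label) {
    stop("need 0 <= n_lost <= n_label", call. = FALSE)
  }
  n_d <- n_label - n_lost
  n_h <- formula_count(parent, "H")
  if (n_d > n_h) stop("more label atoms than parent hydrogens", call. = FALSE)
  f <- parent
  if (n_d > 0L) {
    f <- formula_subtract(parent, element_count(c(H = n_d)))
    f <- formula_add(f, element_count(c(D = n_d)))
  }
  pat <- .labeled_pattern(f, purity, max_offsets, prune)
  out <- list(
    name = if (n_d == 0L) "unlabeled" else paste0("d", n_d),
    formula = f, n_d = n_d,
    mass_offset = monoisotopic_mass(f) - monoisotopic_mass(parent),
    nominal_shift = as.integer(round(monoisotopic_mass(f) -
                                       monoisotopic_mass(parent))),
    pattern = pat)
  class(out) <- "label_species"
  out
}

# Envelope of a formula whose D atoms are only `purity` enriched: each D is
# D with probability `purity` and H otherwise, folded in as an extra
# two-isotope pseudo-element via direct convolution.
.labeled_pattern <- function(formula, purity, max_offsets, prune) {
  n_d <- formula_count(formula, "D")
  if (n_d == 0L || purity >= 1) {
    return(isotope_pattern(formula, max_offsets = max_offsets, prune = prune))
  }
  rest <- formula_subtract(formula, element_count(c(D = n_d)))
  base <- isotope_pattern(rest, max_offsets = max_offsets, prune = 0)
  # two-state atom: H (offset relative to D monoisotopic = -1) or D.
  # Work on an offset grid anchored at the all-D species minus n_d (worst
  # case all H), then trim.
  tab <- isotope_table()
  mh <- tab$mass[tab$element == "H"][1]
  md <- tab$mass[tab$element == "D"][1]
  env <- list(A = 1.0, AM = 0.0)
  atom <- list(A = c(1 - purity, purity),
               AM = c((1 - purity) * mh, purity * md))
  kmax <- max_offsets + n_d + 2L
  for (k in seq_len(n_d)) env <- .conv_env(env, atom, kmax)
  base_env <- list(A = numeric(max(base$offset) + 1L),
                   AM = numeric(max(base$offset) + 1L))
  base_env$A[base$offset + 1L] <- base$abundance
  base_env$AM[base$offset + 1L] <- base$abundance * base$mz
  full <- .conv_env(base_env, env, kmax)
  A <- full$A
  keep <- A > 0
  off <- which(keep) - 1L
  M <- full$AM[keep] / A[keep]
  rel <- A[keep] / max(A[keep])
  # re-anchor offsets to the most-retained-label monoisotopic peak:
  # offset 0 = lightest peak present after pruning
  sel <- rel >= prune | rel == max(rel)
  off <- off[sel]; M <- M[sel]; rel <- rel[sel]
  off <- off - min(off) + as.integer(round(min(M) - monoisotopic_mass(formula)))
  out <- data.frame(offset = off, mz = M, abundance = rel / max(rel))
  attr(out, "base_offset") <- out$offset[which.max(out$abundance)]
  class(out) <- c("isotope_pattern", "data.frame")
  out
}

#' @export
print.label_species <- function(x, ...) {
  cat("<label species> ", x$name, " (", format(x$formula), "), +",
      sprintf("%.4f", x$mass_offset), " Da vs parent\n", sep = "")
  invisible(x)
}

#' Fit an observed envelope as a mixture of labeled/unlabeled species
#'
#' The observed envelope and each theoretical species envelope are placed on
#' a common nominal-offset grid (offset 0 = unlabeled monoisotopic peak;
#' labeled species are shifted by their nominal mass shift).  Species
#' columns are normalized to unit total abundance so fractions are molar
#' shares; the fit is non-negative least squares followed by sum-to-one
#' renormalization.  Deterministic.
#'
#' @param observed An `isotope_pattern` (offsets relative to the unlabeled
#'   monoisotopic peak) or a data.frame with `offset` and `abundance`.
#' @param species List of `label_species` (>= 2, typically unlabeled plus
#'   labeled hypotheses).
#' @param offsets Integer offsets used in the fit (default `0:5` extended to
#'   cover every species envelope).
#' @return A `mixture_fit`: `fractions` (named, summing to 1), `residual`
#'   (sum of squared abundance differences on the normalized scale),
#'   `covered_offsets`, `fitted` and `observed` vectors.
#' @export
fit_label_mixture <- function(observed, species, offsets = NULL) {
  stopifnot(length(species) >= 2L)
  obs <- as.data.frame(observed)[, c("offset", "abundance")]
  if (nrow(obs) == 0L) stop("empty observed pattern", call. = FALSE)
  shifts <- vapply(species, function(s) s$nominal_shift, integer(1))
  if (is.null(offsets)) {
    offsets <- 0:max(5L, max(shifts) + 3L)
  }
  offsets <- sort(unique(as.integer(offsets)))
  # observed normalized to M+0 = 1 (the reporting convention for feeding
  # spectra); when M+0 carries no signal (complete incorporation) the base
  # peak is used instead -- the fitted fractions are scale invariant
  a0 <- obs$abundance[obs$offset == 0L]
  scale <- if (length(a0) == 1L && a0 > 0) a0 else max(obs$abundance)
  if (scale <= 0) stop("observed pattern has no signal", call. = FALSE)
  y <- stats::setNames(numeric(length(offsets)), offsets)
  hit <- obs$offset %in% offsets
  y[as.character(obs$offset[hit])] <- obs$abundance[hit] / scale

  A <- matrix(0, nrow = length(offsets), ncol = length(species))
  colnames(A) <- vapply(species, function(s) s$name, character(1))
  for (k in seq_along(species)) {
    pat <- species[[k]]$pattern
    ab <- pat$abundance / sum(pat$abundance)
    pos <- match(pat$offset + shifts[k], offsets)
    ok <- !is.na(pos)
    A[pos[ok], k] <- ab[ok]
  }
  if (anyDuplicated(t(round(A, 12))) > 0) {
    warning("species with identical envelopes: fit is rank-deficient; ",
            "their fractions are identifiable only as a sum", call. = FALSE)
  }
  nn <- pracma::lsqnonneg(A, as.numeric(y))
  coefs <- nn$x
  total <- sum(coefs)
  fractions <- if (total > 0) coefs / total else rep(1 / length(coefs),
                                                     length(coefs))
  names(fractions) <- colnames(A)
  fitted <- as.numeric(A %*% coefs)
  out <- list(fractions = fractions, residual = sum((y - fitted)^2),
              covered_offsets = offsets, fitted = fitted,
              observed = as.numeric(y), design = A)
  class(out) <- "mixture_fit"
  out
}

#' @export
print.mixture_fit <- function(x, ...) {
  cat("<label mixture fit> residual ", format(x$residual, digits = 4), "\n",
      sep = "")
  print(round(x$fractions, 4))
  invisible(x)
}

#' @export
coef.mixture_fit <- function(object, ...) object$fractions

#' @export
fitted.mixture_fit <- function(object, ...) object$fitted

#' @export
residuals.mixture_fit <- function(object, ...) object$observed - object$fitted

#' Rank label-retention hypotheses for a feeding experiment
#'
#' Fits one two-species mixture (unlabeled + labeled with `n_lost = k`) per
#' hypothesis `k = 0, 1, ..., max_lost` and ranks hypotheses by fit
#' residual.  When the best fit assigns essentially no labeled fraction the
#' ranking carries no information and the result is flagged inconclusive.
#'
#' @param observed Observed envelope (offsets relative to unlabeled M+0).
#' @param parent Unlabeled parent formula.
#' @param n_label Label atoms on the fed precursor (>= 1).
#' @param max_lost Largest loss hypothesis (default `min(n_label - 1, 2)`;
#'   losing every label atom is indistinguishable from no incorporation, so
#'   that case is not a separate hypothesis).
#' @param purity Label isotopic purity.
#' @param min_labeled_fraction Below this fitted labeled fraction the
#'   ranking is flagged inconclusive (default 0.02).
#' @return A `retention_test`: data.frame of hypotheses (`n_lost`,
#'   `labeled_fraction`, `residual`, `rank`) sorted by residual, with
#'   attributes `best` and `inconclusive`.
#' @export
retention_model_test <- function(observed, parent, n_label,
                                 max_lost = min(n_label - 1L, 2L), purity = 0.99,
                                 min_labeled_fraction = 0.02) {
  stopifnot(n_label >= 1L)
  unlab <- labeled_species(parent, n_label, n_label, purity = purity)
  rows <- lapply(0:max_lost, function(k) {
    lab <- labeled_species(parent, n_label, k, purity = purity)
    fit <- fit_label_mixture(observed, list(unlab, lab))
    data.frame(n_lost = k, labeled_fraction = unname(fit$fractions[2]),
               residual = fit$residual)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$residual), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  attr(out, "best") <- out$n_lost[1]
  attr(out, "inconclusive") <- out$labeled_fraction[1] < min_labeled_fraction
  class(out) <- c("retention_test", "data.frame")
  out
}

#' @export
print.retention_test <- function(x, ...) {
  if (attr(x, "inconclusive")) {
    cat("<label retention test> inconclusive (no labeled fraction fitted)\n")
  } else {
    cat("<label retention test> best hypothesis: ", attr(x, "best"),
        " label atom(s) lost\n", sep = "")
  }
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}
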