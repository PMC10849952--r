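# Independent oracles and fixture generators used across the suite.

# --- multinomial brute-force isotope envelope -------------------------------
# Enumerates every isotope assignment of every atom (feasible for <= 6
# atoms), sums masses, multiplies abundances, aggregates by nominal-mass
# offset.  Entirely independent of the package's convolution engine.
oracle_envelope <- function(formula) {
  f <- halomet::as_element_count(formula)
  tab <- halomet::isotope_table()
  atoms <- rep(names(f), unclass(f))
  stopifnot(length(atoms) <= 6)
  per_atom <- lapply(atoms, function(el) {
    rows <- tab[tab$element == el, , drop = FALSE]
    rows <- rows[order(rows$mass), , drop = FALSE]
    rows
  })
  grid <- expand.grid(lapply(per_atom, function(r) seq_len(nrow(r))))
  mass <- numeric(nrow(grid)); prob <- numeric(nrow(grid))
  for (g in seq_len(nrow(grid))) {
    m <- 0; p <- 1
    for (a in seq_along(per_atom)) {
      r <- per_atom[[a]][grid[g, a], ]
      m <- m + r$mass; p <- p * r$abundance
    }
    mass[g] <- m; prob[g] <- p
  }
  mono <- sum(vapply(per_atom, function(r) r$mass[1], numeric(1)))
  off <- round(mass - mono)
  ab <- vapply(split(prob, off), sum, numeric(1))
  data.frame(offset = as.integer(names(ab)), abundance = unname(ab))
}

# --- exhaustive modified-cosine matching ------------------------------------
# Maximizes the score over all one-to-one matchings of candidate pairs
# (fragment or neutral-loss matched), by recursion.  Feasible for <= 8
# peaks per spectrum.
oracle_modified_cosine <- function(a, b, frag_tol = 0.02) {
  wa <- sqrt(a$peaks$intensity); wa <- wa / sqrt(sum(wa^2))
  wb <- sqrt(b$peaks$intensity); wb <- wb / sqrt(sum(wb^2))
  shift <- a$precursor_mz - b$precursor_mz
  dmz <- outer(a$peaks$mz, b$peaks$mz, "-")
  cand <- which(abs(dmz) <= frag_tol | abs(dmz - shift) <= frag_tol,
                arr.ind = TRUE)
  best <- list(score = 0, n = 0L)
  rec <- function(k, usedA, usedB, score, n) {
    if (k > nrow(cand)) {
      if (score > best$score + 1e-15 ||
          (abs(score - best$score) <= 1e-15 && n > best$n)) {
        best <<- list(score = score, n = n)
      }
      return(invisible())
    }
    i <- cand[k, 1]; j <- cand[k, 2]
    if (!usedA[i] && !usedB[j]) {
      usedA[i] <- TRUE; usedB[j] <- TRUE
      rec(k + 1L, usedA, usedB, score + wa[i] * wb[j], n + 1L)
      usedA[i] <- FALSE; usedB[j] <- FALSE
    }
    rec(k + 1L, usedA, usedB, score, n)
  }
  if (nrow(cand) > 0) rec(1L, logical(length(wa)), logical(length(wb)), 0, 0L)
  best
}

# Random centroided spectrum with peaks spaced >= 0.5 Th (realistic for
# centroided QTOF data; spacing far above the 0.02 Th match tolerance).
rand_spectrum <- function(id, n = 8L) {
  prec <- stats::runif(1, 300, 900)
  base <- sort(sample(seq(60, 280, by = 0.5), n))
  halomet::msms_spectrum(id, prec,
                         data.frame(mz = base + stats::runif(n, -0.005, 0.005),
                                    intensity = stats::runif(n, 10, 1000)))
}

# Random pair sharing k fragment peaks and kl neutral losses.
rand_spectrum_pair <- function(n = NULL) {
  if (is.null(n)) n <- sample(4:8, 1)
  a <- rand_spectrum("a", n)
  b <- rand_spectrum("b", n)
  k <- sample(1:3, 1)
  b$peaks$mz[1:k] <- a$peaks$mz[1:k] + stats::runif(k, -0.01, 0.01)
  kl <- min(sample(0:2, 1), n - k)
  if (kl > 0) {
    idx <- (k + 1):(k + kl)
    b$peaks$mz[idx] <- b$precursor_mz -
      (a$precursor_mz - a$peaks$mz[idx]) + stats::runif(kl, -0.01, 0.01)
  }
  b$peaks <- b$peaks[order(b$peaks$mz), ]
  rownames(b$peaks) <- NULL
  list(a = a, b = b)
}

# --- random plausible formulas for the chlorine classifier ------------------
rand_formula <- function(with_cl, mass_range = c(300, 900)) {
  mass <- stats::runif(1, mass_range[1], mass_range[2])
  nC <- max(10L, round(mass * stats::runif(1, 0.55, 0.72) / 12))
  nO <- sample(2:10, 1)
  nN <- sample(0:2, 1)
  nS <- stats::rbinom(1, 1, 0.2)
  nCl <- if (with_cl) sample(1:2, 1, prob = c(0.85, 0.15)) else 0L
  rem <- mass - nC * 12 - nO * 15.995 - nN * 14.003 - nS * 31.972 -
    nCl * 34.969
  nH <- max(nC %/% 2, round(rem / 1.008))
  cnt <- c(C = nC, H = nH, N = nN, O = nO, S = nS, Cl = nCl)
  halomet::element_count(cnt[cnt > 0])
}

# Simulated observed MS1 envelope of a formula with multiplicative noise.
noisy_envelope <- function(formula, noise = 0.02, max_offsets = 5L) {
  pat <- halomet::isotope_pattern(formula, max_offsets = max_offsets)
  pat$abundance <- pmax(pat$abundance *
                          (1 + stats::rnorm(nrow(pat), 0, noise)), 1e-6)
  pat$abundance <- pat$abundance / max(pat$abundance)
  pat
}

# Small two-condition intensity matrix helper for diffmet tests.
make_table <- function(replete, depleted, mz = 500, rt = 10) {
  stopifnot(is.matrix(replete), is.matrix(depleted))
  n1 <- ncol(replete); n2 <- ncol(depleted)
  mat <- cbind(replete, depleted)
  colnames(mat) <- c(sprintf("replete_%d", seq_len(n1)),
                     sprintf("depleted_%d", seq_len(n2)))
  nf <- nrow(mat)
  feats <- data.frame(feature_id = sprintf("F%04d", seq_len(nf)),
                      mz = rep_len(mz, nf), rt = rep_len(rt, nf))
  rownames(mat) <- feats$feature_id
  out <- list(features = feats, matrix = mat,
              design = stats::setNames(rep(c("replete", "depleted"),
                                           c(n1, n2)), colnames(mat)),
              gap_filled = matrix(FALSE, nf, n1 + n2,
                                  dimnames = dimnames(mat)))
  class(out) <- "feature_table"
  out
}
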