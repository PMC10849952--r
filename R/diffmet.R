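# Cross-run feature alignment, noise-floor gap filling, fold-change +
# two-tailed Student's t-test statistics, and co-eluting adduct/in-source
# artifact grouping.
#
# The comparison design is halide-replete vs halide-depleted cultures with
# three biological replicates each; fold changes are stored as a magnitude
# >= 1 plus a direction ("depleted_without_halide" marks the halogenation-
# dependent candidates of interest), with a signed export available.

#' Read per-run feature lists from CSV
#'
#' Expected columns: `run_id`, `condition` (`replete`/`depleted`), `mz`,
#' `rt` (minutes), `intensity` (counts).  One file may hold several runs.
#'
#' @param path CSV path (UTF-8, '.' decimal, header required).
#' @return A data.frame of run features.
#' @export
read_feature_runs <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("run_id", "condition", "mz", "rt", "intensity")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("feature CSV missing column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  if (any(df$intensity < 0) || any(df$mz <= 0) || any(df$rt < 0)) {
    stop("invalid feature values (need intensity >= 0, mz > 0, rt >= 0)",
         call. = FALSE)
  }
  df
}

#' m/z joining tolerance
#'
#' The joining rule uses an absolute tolerance of 0.01 Th or 20 ppm,
#' whichever is larger at the given m/z.
#'
#' @param mz m/z values in Th.
#' @param mz_abs Absolute component in Th (default 0.01).
#' @param mz_ppm Relative component in ppm (default 20).
#' @return Tolerances in Th, same length as `mz`.
#' @export
mz_tolerance <- function(mz, mz_abs = 0.01, mz_ppm = 20) {
  pmax(mz_abs, mz * mz_ppm * 1e-6)
}

#' Join features across runs into an aligned feature table
#'
#' Greedy agglomerative join: all run features are sorted by intensity
#' descending; each feature either lands on an existing consensus row (the
#' nearest row within both tolerances whose column for that run is still
#' empty, m/z distance prioritized over rt distance) or opens a new row.
#' Consensus m/z and rt are those of the seeding (most intense) member, so
#' every member lies within the joining tolerances of the consensus.
#'
#' @param runs Data.frame of run features (see [read_feature_runs()]), or a
#'   list of such data.frames.
#' @param mz_abs,mz_ppm m/z tolerance components (see [mz_tolerance()]).
#' @param rt_tol Retention-time tolerance in minutes (default 0.2).
#' @return A `feature_table`: list with `features` (data.frame `feature_id`,
#'   `mz`, `rt`), `matrix` (features x samples intensities, 0 = not
#'   detected), `design` (named condition vector by sample) and `gap_filled`
#'   (logical matrix, all `FALSE` until [gap_fill_floor()]).
#' @export
join_features <- function(runs, mz_abs = 0.01, mz_ppm = 20, rt_tol = 0.2) {
  if (is.data.frame(runs)) df <- runs else df <- do.call(rbind, runs)
  stopifnot(nrow(df) >= 1L, rt_tol > 0, mz_abs > 0 || mz_ppm > 0)
  run_cond <- unique(df[, c("run_id", "condition")])
  if (anyDuplicated(run_cond$run_id)) {
    stop("duplicate run_id with conflicting condition labels", call. = FALSE)
  }
  run_ids <- run_cond$run_id
  ord <- order(-df$intensity)
  df <- df[ord, , drop = FALSE]

  seed_mz <- numeric(0)
  seed_rt <- numeric(0)
  members <- list()          # per row: named intensity vector by run
  for (i in seq_len(nrow(df))) {
    mzi <- df$mz[i]; rti <- df$rt[i]; run <- df$run_id[i]
    tol <- mz_tolerance(mzi, mz_abs, mz_ppm)
    cand <- which(abs(seed_mz - mzi) <= tol & abs(seed_rt - rti) <= rt_tol)
    cand <- cand[vapply(cand, function(k) !(run %in% names(members[[k]])),
                        logical(1))]
    if (length(cand) > 0L) {
      k <- cand[order(abs(seed_mz[cand] - mzi), abs(seed_rt[cand] - rti))][1]
      members[[k]][run] <- df$intensity[i]
    } else {
      seed_mz <- c(seed_mz, mzi)
      seed_rt <- c(seed_rt, rti)
      members[[length(members) + 1L]] <- stats::setNames(df$intensity[i], run)
    }
  }

  o <- order(seed_mz, seed_rt)
  mat <- matrix(0, nrow = length(members), ncol = length(run_ids),
                dimnames = list(NULL, run_ids))
  for (r in seq_along(o)) {
    mem <- members[[o[r]]]
    mat[r, names(mem)] <- mem
  }
  features <- data.frame(
    feature_id = sprintf("F%04d", seq_along(o)),
    mz = seed_mz[o], rt = seed_rt[o], stringsAsFactors = FALSE)
  rownames(mat) <- features$feature_id
  design <- stats::setNames(run_cond$condition, run_cond$run_id)
  out <- list(features = features, matrix = mat, design = design,
              gap_filled = matrix(FALSE, nrow(mat), ncol(mat),
                                  dimnames = dimnames(mat)))
  class(out) <- "feature_table"
  out
}

#' @export
print.feature_table <- function(x, ...) {
  cat("<feature table> ", nrow(x$matrix), " features x ", ncol(x$matrix),
      " runs (", sum(x$design == "replete"), " replete / ",
      sum(x$design == "depleted"), " depleted); ",
      sum(x$gap_filled), " gap-filled cells\n", sep = "")
  invisible(x)
}

#' Apply the noise-floor pseudocount to a feature table
#'
#' Every intensity below the noise floor (missing cells included) is replaced
#' by the floor value and flagged, so that fold changes against undetected
#' features are bounded by the floor rather than infinite.  Idempotent.
#'
#' @param table A `feature_table`.
#' @param noise Noise floor in counts (default 100).
#' @return The gap-filled `feature_table`.
#' @export
gap_fill_floor <- function(table, noise = 100) {
  stopifnot(inherits(table, "feature_table"), noise > 0)
  low <- table$matrix < noise
  table$gap_filled <- table$gap_filled | low
  table$matrix[low] <- noise
  attr(table, "noise_floor") <- noise
  table
}

#' Per-feature differential statistics between conditions
#'
#' For each feature: the fold change is the ratio of arithmetic condition
#' means, stored as a magnitude `max(m_r/m_d, m_d/m_r) >= 1` with a
#' `direction` enum (`depleted_without_halide` when the depleted-condition
#' mean is lower); the P value comes from a two-tailed two-sample Student's
#' t-test on raw intensities (pooled variance by default, Welch optional),
#' df = n_r + n_d - 2.  Features with zero variance in both groups and equal
#' means are degenerate: t = 0, p = 1, direction `unchanged`.
#'
#' @param table A gap-filled `feature_table` with >= 2 samples per condition.
#' @param welch Use the Welch (unequal-variance) t-test instead of pooled.
#' @return A `diff_result` data.frame: `feature_id`, `mz`, `rt`,
#'   `mean_replete`, `mean_depleted`, `fold_change`, `direction`, `t_stat`,
#'   `p_value`, `df`, `degenerate`, `n_gap_filled`.
#' @export
differential_stats <- function(table, welch = FALSE) {
  stopifnot(inherits(table, "feature_table"))
  rep_idx <- which(table$design == "replete")
  dep_idx <- which(table$design == "depleted")
  if (length(rep_idx) < 2L || length(dep_idx) < 2L) {
    stop("each condition needs at least 2 samples", call. = FALSE)
  }
  X <- table$matrix
  xr <- X[, rep_idx, drop = FALSE]
  xd <- X[, dep_idx, drop = FALSE]
  n1 <- ncol(xr); n2 <- ncol(xd)
  m1 <- rowMeans(xr); m2 <- rowMeans(xd)
  v1 <- apply(xr, 1, stats::var); v2 <- apply(xd, 1, stats::var)

  if (welch) {
    se2 <- v1 / n1 + v2 / n2
    tt <- (m1 - m2) / sqrt(se2)
    df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  } else {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    tt <- (m1 - m2) / sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- rep(n1 + n2 - 2, nrow(X))
  }
  degenerate <- (v1 + v2) == 0
  tt[degenerate & m1 == m2] <- 0
  # zero pooled variance with unequal means: infinite t, p -> 0
  tt[!is.finite(tt) & m1 != m2] <- sign(m1 - m2)[!is.finite(tt) & m1 != m2] * Inf
  p <- 2 * stats::pt(-abs(tt), df)
  p[degenerate & m1 == m2] <- 1

  fc <- pmax(m1 / m2, m2 / m1)
  direction <- ifelse(m1 == m2, "unchanged",
                      ifelse(m1 > m2, "depleted_without_halide",
                             "enriched_without_halide"))
  direction[degenerate & m1 == m2] <- "unchanged"

  out <- data.frame(
    feature_id = table$features$feature_id,
    mz = table$features$mz, rt = table$features$rt,
    mean_replete = m1, mean_depleted = m2,
    fold_change = fc, direction = direction,
    t_stat = tt, p_value = p, df = df,
    degenerate = degenerate & m1 == m2,
    n_gap_filled = rowSums(table$gap_filled),
    stringsAsFactors = FALSE, row.names = NULL)
  class(out) <- c("diff_result", "data.frame")
  attr(out, "test") <- if (welch) "welch" else "pooled"
  out
}

#' Signed fold-change export
#'
#' Supplementary-table convention: negative values mark features depleted
#' without halide, positive values features enriched without halide,
#' magnitude as in `fold_change`.
#'
#' @param diff A `diff_result`.
#' @return Numeric vector of signed fold changes.
#' @export
signed_fold_change <- function(diff) {
  s <- ifelse(diff$direction == "depleted_without_halide", -1, 1)
  s * diff$fold_change
}

#' @export
print.diff_result <- function(x, ...) {
  cat("<differential result> ", nrow(x), " features; ",
      sum(x$direction == "depleted_without_halide" & x$p_value < 0.05),
      " depleted-without-halide at p < 0.05 (raw, ",
      attr(x, "test") %||% "pooled", " t-test)\n", sep = "")
  invisible(x)
}

#' Volcano plot of differential results
#'
#' Signed log10 fold change against -log10 P, the tabular twin of the
#' classic halide-depletion volcano.
#'
#' @param x A `diff_result`.
#' @param highlight Optional character vector of feature ids drawn filled.
#' @param ... Passed to [plot()].
#' @export
plot.diff_result <- function(x, highlight = NULL, ...) {
  sfc <- log10(x$fold_change) *
    ifelse(x$direction == "depleted_without_halide", -1, 1)
  col <- ifelse(x$feature_id %in% highlight, "purple", "grey50")
  pch <- ifelse(x$feature_id %in% highlight, 18, 1)
  plot(sfc, -log10(pmax(x$p_value, 1e-300)), col = col, pch = pch,
       xlab = "signed log10 fold change (negative = depleted without halide)",
       ylab = "-log10 P", ...)
  invisible(x)
}

#' Group co-eluting adduct and in-source artifact features
#'
#' Features co-eluting within `rt_window` whose pairwise m/z differences
#' match a known mass shift (within the MS1 tolerance) are grouped by
#' transitive closure; each group designates a parent: the member
#' interpretable as `[M+H]+` (i.e. having a partner at +17.02655 or
#' +21.98194 Th), else the most intense member.
#'
#' @param table A `feature_table`.
#' @param rt_window Co-elution window in minutes (default 0.05).
#' @param deltas Named numeric vector of mass shifts in Da; the default
#'   covers `[M+H]+`/`[M+NH4]+` (17.02655), `[M+H]+`/`[M+Na]+` (21.98194),
#'   `[M+NH4]+`/`[M+Na]+` (4.95540) and water loss (18.01056).
#' @param mz_abs,mz_ppm MS1 tolerance components.
#' @return A data.frame `feature_id`, `group_id`, `is_parent`.
#' @export
artifact_group <- function(table, rt_window = 0.05,
                           deltas = c(NH4_vs_H = 17.02654910,
                                      Na_vs_H = 21.98194425,
                                      Na_vs_NH4 = 4.95539515,
                                      H2O_loss = 18.01056468),
                           mz_abs = 0.01, mz_ppm = 20) {
  stopifnot(inherits(table, "feature_table"))
  feats <- table$features
  n <- nrow(feats)
  if (n == 0L) {
    return(data.frame(feature_id = character(0), group_id = character(0),
                      is_parent = logical(0)))
  }
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i] <<- parent[parent[i]]; i }
  union_ <- function(i, j) { ri <- find(i); rj <- find(j); if (ri != rj) parent[rj] <<- ri }

  ord <- order(feats$rt)
  adduct_partner_above <- logical(n)   # has a +NH4/+Na partner => [M+H]+ candidate
  for (a in seq_len(n - 1L)) {
    i <- ord[a]
    for (b in (a + 1):n) {
      j <- ord[b]
      if (feats$rt[j] - feats$rt[i] > rt_window) break
      dmz <- abs(feats$mz[i] - feats$mz[j])
      tol <- mz_tolerance(max(feats$mz[i], feats$mz[j]), mz_abs, mz_ppm)
      if (any(abs(dmz - deltas) <= tol)) {
        union_(i, j)
        lo <- if (feats$mz[i] < feats$mz[j]) i else j
        d_adduct <- abs(dmz - deltas[c("NH4_vs_H", "Na_vs_H")])
        if (any(d_adduct <= tol, na.rm = TRUE)) adduct_partner_above[lo] <- TRUE
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  gid <- match(roots, unique(roots))
  intensity <- rowSums(table$matrix)
  is_parent <- logical(n)
  for (g in unique(gid)) {
    idx <- which(gid == g)
    cand <- idx[adduct_partner_above[idx]]
    if (length(cand) == 0L) cand <- idx
    is_parent[cand[which.max(intensity[cand])]] <- TRUE
  }
  data.frame(feature_id = feats$feature_id,
             group_id = sprintf("G%04d", gid),
             is_parent = is_parent, stringsAsFactors = FALSE)
}
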