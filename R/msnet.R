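# MS/MS spectral preprocessing and modified-cosine molecular networking.
#
# Two spectra are connected in the network when their modified cosine score
# is at least 0.60 with at least four matching fragments or neutral losses.
# Peak filtering before scoring removes the +-17 Th exclusion zone around the
# precursor (precursor and its isotope artifacts) and keeps each peak only if
# it ranks among the 6 most intense within the +-50 Th window centred on it.

#' Construct an MS/MS spectrum
#'
#' @param spectrum_id Unique id (links the spectrum to a feature).
#' @param precursor_mz Precursor m/z in Th (> 0).
#' @param peaks Two-column matrix or data.frame (`mz`, `intensity`);
#'   intensities must be positive.  Stored sorted by m/z.
#' @param charge Precursor charge (default 1).
#' @param rt Retention time in minutes (optional).
#' @param collision_energy Collision energy in volts (metadata; the
#'   acquisition convention is `10 + 0.02 * precursor_mz`).
#' @return An `msms_spectrum` object.
#' @export
msms_spectrum <- function(spectrum_id, precursor_mz, peaks, charge = 1L,
                          rt = NA_real_, collision_energy = NA_real_) {
  peaks <- as.data.frame(peaks)
  names(peaks)[1:2] <- c("mz", "intensity")
  stopifnot(precursor_mz > 0, all(peaks$intensity > 0))
  peaks <- peaks[order(peaks$mz), , drop = FALSE]
  rownames(peaks) <- NULL
  out <- list(spectrum_id = as.character(spectrum_id),
              precursor_mz = precursor_mz, charge = as.integer(charge),
              rt = rt, collision_energy = collision_energy, peaks = peaks)
  class(out) <- "msms_spectrum"
  out
}

#' @export
print.msms_spectrum <- function(x, ...) {
  cat("<MS/MS spectrum> ", x$spectrum_id, ": precursor ",
      sprintf("%.4f", x$precursor_mz), " Th (z=", x$charge, "), ",
      nrow(x$peaks), " peaks\n", sep = "")
  invisible(x)
}

#' Standard collision energy for a precursor
#'
#' The acquisition convention used throughout: CE (volts) =
#' `10 + 0.02 * m/z`.
#' @param mz Precursor m/z in Th.
#' @return Collision energy in volts.
#' @export
collision_energy <- function(mz) 10 + 0.02 * mz

#' Filter MS/MS peaks before networking
#'
#' Two rules, applied in order: (i) remove peaks within `precursor_window`
#' (17 Th) of the precursor m/z; (ii) keep a peak only if it is among the
#' `top_k` (6) most intense peaks within the `window` (+-50 Th) centred on
#' itself.  Deterministic (intensity ties broken by lower m/z) and
#' idempotent.
#'
#' @param s An `msms_spectrum`.
#' @param precursor_window Exclusion half-window around the precursor in Th.
#' @param top_k Rank cut within the sliding window.
#' @param window Half-width of the rank window in Th.
#' @return The filtered `msms_spectrum`.
#' @export
filter_peaks <- function(s, precursor_window = 17, top_k = 6L, window = 50) {
  stopifnot(inherits(s, "msms_spectrum"))
  p <- s$peaks
  if (nrow(p) > 0L) {
    p <- p[abs(p$mz - s$precursor_mz) > precursor_window, , drop = FALSE]
  }
  if (nrow(p) > 0L) {
    keep <- logical(nrow(p))
    for (i in seq_len(nrow(p))) {
      inwin <- which(abs(p$mz - p$mz[i]) <= window)
      # rank by intensity desc, ties by m/z asc
      stronger <- sum(p$intensity[inwin] > p$intensity[i] |
                        (p$intensity[inwin] == p$intensity[i] &
                           p$mz[inwin] < p$mz[i]))
      keep[i] <- stronger < top_k
    }
    p <- p[keep, , drop = FALSE]
  }
  rownames(p) <- NULL
  s$peaks <- p
  s
}

#' Modified cosine similarity between two MS/MS spectra
#'
#' Peaks `i` in `a` and `j` in `b` are matchable either directly
#' (`|mz_i - mz_j| <= frag_tol`) or as neutral losses
#' (`|(prec_a - mz_i) - (prec_b - mz_j)| <= frag_tol`).  Intensities are
#' square-root transformed and each spectrum's weight vector scaled to unit
#' L2 norm; a greedy one-to-one matching (candidate pairs sorted by weight
#' product descending, each peak used at most once, a pair counted once even
#' if it matches both ways) accumulates the score.
#'
#' @param a,b `msms_spectrum` objects, already filtered.
#' @param frag_tol Fragment tolerance in Th (default 0.02).
#' @param weighting `"sqrt"` (default) or `"raw"` intensity weighting.
#' @return A list `score` (in `[0, 1]`) and `n_matched` (pairs in the
#'   matching).
#' @export
modified_cosine <- function(a, b, frag_tol = 0.02, weighting = c("sqrt", "raw")) {
  stopifnot(inherits(a, "msms_spectrum"), inherits(b, "msms_spectrum"))
  weighting <- match.arg(weighting)
  wa <- .peak_weights(a$peaks$intensity, weighting)
  wb <- .peak_weights(b$peaks$intensity, weighting)
  na <- nrow(a$peaks); nb <- nrow(b$peaks)
  if (na == 0L || nb == 0L) return(list(score = 0.0, n_matched = 0L))

  mza <- a$peaks$mz; mzb <- b$peaks$mz
  shift <- a$precursor_mz - b$precursor_mz
  # candidate pairs: direct fragment match or neutral-loss match
  dd <- abs(outer(mza, mzb, "-"))
  dl <- abs(outer(mza, mzb, "-") - shift)
  cand <- which(dd <= frag_tol | dl <= frag_tol, arr.ind = TRUE)
  if (nrow(cand) == 0L) return(list(score = 0.0, n_matched = 0L))
  wprod <- wa[cand[, 1]] * wb[cand[, 2]]
  ord <- order(-wprod, cand[, 1], cand[, 2])
  used_a <- logical(na); used_b <- logical(nb)
  score <- 0.0; n_matched <- 0L
  for (k in ord) {
    i <- cand[k, 1]; j <- cand[k, 2]
    if (used_a[i] || used_b[j]) next
    used_a[i] <- TRUE; used_b[j] <- TRUE
    score <- score + wprod[k]
    n_matched <- n_matched + 1L
  }
  list(score = min(score, 1.0), n_matched = n_matched)
}

.peak_weights <- function(intensity, weighting = "sqrt") {
  if (length(intensity) == 0L) return(numeric(0))
  w <- if (weighting == "sqrt") sqrt(intensity) else intensity
  w / sqrt(sum(w^2))
}

#' Build a molecular network from MS/MS spectra
#'
#' Scores all spectrum pairs with [modified_cosine()] and adds an undirected
#' edge whenever the score is at least `min_cosine` and the matching holds at
#' least `min_matched` fragment or neutral-loss pairs.  Node annotations
#' (fold change, direction, P value, chlorine flag, formula) are joined from
#' a `diff_result` and auxiliary tables by feature id.
#'
#' @param spectra List of (already filtered) `msms_spectrum` objects with
#'   unique ids.
#' @param min_cosine Edge score threshold (default 0.60).
#' @param min_matched Minimum matched fragments or neutral losses (default 4).
#' @param frag_tol Fragment tolerance in Th (default 0.02).
#' @param annotations Optional data.frame keyed by `feature_id` with any of
#'   `fold_change`, `direction`, `p_value`, `chlorinated`, `formula`, `mz`,
#'   `rt`.
#' @return A `molecular_network`: list with `graph` (igraph), `edges`
#'   data.frame (`a`, `b`, `cosine`, `n_matched`) and `nodes` data.frame.
#' @export
build_network <- function(spectra, min_cosine = 0.60, min_matched = 4L,
                          frag_tol = 0.02, annotations = NULL) {
  ids <- vapply(spectra, function(s) s$spectrum_id, character(1))
  if (anyDuplicated(ids)) stop("duplicate spectrum ids", call. = FALSE)
  n <- length(spectra)
  ea <- character(0); eb <- character(0); ec <- numeric(0); em <- integer(0)
  if (n >= 2L) {
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
      mc <- modified_cosine(spectra[[i]], spectra[[j]], frag_tol = frag_tol)
      if (mc$score >= min_cosine && mc$n_matched >= min_matched) {
        ea <- c(ea, ids[i]); eb <- c(eb, ids[j])
        ec <- c(ec, mc$score); em <- c(em, mc$n_matched)
      }
    }
  }
  nodes <- data.frame(feature_id = ids,
                      precursor_mz = vapply(spectra, function(s) s$precursor_mz,
                                            numeric(1)),
                      rt = vapply(spectra, function(s) s$rt, numeric(1)),
                      stringsAsFactors = FALSE)
  if (!is.null(annotations)) {
    keep <- setdiff(intersect(names(annotations),
                              c("feature_id", "fold_change", "direction",
                                "p_value", "chlorinated", "formula", "mz", "rt")),
                    c("mz", "rt"))
    nodes <- merge(nodes, annotations[, keep, drop = FALSE],
                   by = "feature_id", all.x = TRUE, sort = FALSE)
    nodes <- nodes[match(ids, nodes$feature_id), , drop = FALSE]
    rownames(nodes) <- NULL
  }
  edges <- data.frame(a = ea, b = eb, cosine = ec, n_matched = em,
                      stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(
    if (nrow(edges)) edges else data.frame(a = character(0), b = character(0)),
    directed = FALSE, vertices = nodes)
  out <- list(graph = g, nodes = nodes, edges = edges,
              params = list(min_cosine = min_cosine, min_matched = min_matched,
                            frag_tol = frag_tol))
  class(out) <- "molecular_network"
  out
}

#' @export
print.molecular_network <- function(x, ...) {
  comp <- igraph::components(x$graph)
  cat("<molecular network> ", nrow(x$nodes), " nodes, ", nrow(x$edges),
      " edges, ", comp$no, " components (largest ", max(comp$csize), ")\n",
      sep = "")
  invisible(x)
}

#' Per-component summary of a molecular network
#'
#' For each connected component: member count, how many members are
#' depleted-without-halide (at `p_cut`), how many are chlorine-flagged, the
#' member m/z list, and the largest depletion fold change.  Components are
#' ranked by that largest depletion fold change, mirroring a discovery
#' read-out where the strongest halide-responsive cluster comes first.
#'
#' @param net A `molecular_network` with annotated nodes.
#' @param p_cut P-value cut used when counting depleted members (default
#'   0.05).
#' @return A data.frame, one row per component, ordered by rank.
#' @export
component_report <- function(net, p_cut = 0.05) {
  stopifnot(inherits(net, "molecular_network"))
  if (nrow(net$nodes) == 0L) {
    return(data.frame(component = integer(0), n_members = integer(0),
                      n_depleted = integer(0), n_chlorinated = integer(0),
                      max_depletion_fold = numeric(0), members = character(0),
                      mz_list = character(0)))
  }
  comp <- igraph::components(net$graph)
  member_of <- comp$membership[net$nodes$feature_id]
  nd <- net$nodes
  has <- function(col) col %in% names(nd)
  rows <- lapply(sort(unique(member_of)), function(ci) {
    idx <- which(member_of == ci)
    depl <- if (has("direction") && has("p_value")) {
      sum(nd$direction[idx] == "depleted_without_halide" &
            nd$p_value[idx] < p_cut, na.rm = TRUE)
    } else NA_integer_
    ncl <- if (has("chlorinated")) sum(nd$chlorinated[idx], na.rm = TRUE)
           else NA_integer_
    maxfold <- if (has("direction") && has("fold_change")) {
      f <- nd$fold_change[idx][nd$direction[idx] == "depleted_without_halide"]
      if (length(f) && any(is.finite(f))) max(f, na.rm = TRUE) else 0
    } else NA_real_
    data.frame(component = ci, n_members = length(idx), n_depleted = depl,
               n_chlorinated = ncl, max_depletion_fold = maxfold,
               members = paste(nd$feature_id[idx], collapse = ";"),
               mz_list = paste(sprintf("%.4f", nd$precursor_mz[idx]),
                               collapse = ";"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$max_depletion_fold, -out$n_members), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Export a molecular network to GraphML
#'
#' Node attributes (m/z, rt, fold change, direction, P value, chlorine flag,
#' formula when present) and edge attributes (cosine, n_matched) are carried
#' into the GraphML file for downstream visualization.
#'
#' @param net A `molecular_network`.
#' @param path Output file path.
#' @export
write_graphml <- function(net, path) {
  stopifnot(inherits(net, "molecular_network"))
  g <- net$graph
  for (col in setdiff(names(net$nodes), "feature_id")) {
    v <- net$nodes[[col]]
    if (is.logical(v)) v <- as.integer(v)
    g <- igraph::set_vertex_attr(g, col, value = v)
  }
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
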