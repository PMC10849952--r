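# End-to-end discovery pipeline: join -> gap fill -> differential stats ->
# artifact grouping -> chlorine scan -> formula assignment -> molecular
# networking -> component report -> ranked candidate list.
#
# Every report embeds the full effective configuration and the constants-
# table version, so a result can be traced to its parameters.

#' Default pipeline configuration
#'
#' Stage parameters default to the workflow's stated values where stated
#' (m/z join tolerance 0.01 Th or 20 ppm, noise floor 100 counts, fragment
#' tolerance 0.02 Th, edge rule cosine >= 0.60 with >= 4 matches, +-17 Th
#' precursor exclusion, top-6-in-+-50-Th rank filter) and to documented
#' package defaults elsewhere.
#'
#' @param ... Overrides of any configuration key.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    mz_abs = 0.01, mz_ppm = 20, rt_tol = 0.2,
    noise_floor = 100, welch = FALSE,
    artifact_rt_window = 0.05,
    min_cosine = 0.60, min_matched = 4L, frag_tol = 0.02,
    precursor_window = 17, top_k = 6L, rank_window = 50,
    chlorine_window_1cl = c(0.20, 0.50), chlorine_window_2cl = c(0.50, 0.85),
    max_m1_ratio = 0.6,
    formula_tol_ppm = 10, formula_max_candidates = 3L,
    n_formula_features = 25L,
    spectrum_match_rt = 0.3,
    rank_by = "fold",            # or "p"
    p_cut = 0.05)
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "),
                        call. = FALSE)
  cfg[names(over)] <- over
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a plain-text key=value pipeline configuration
#'
#' Lines of the form `key=value` (comma-separated values become numeric
#' vectors); `#` comments and blank lines ignored.
#'
#' @param path File path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[lines != "" & !startsWith(lines, "#")]
  over <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2L) stop("bad config line: ", ln, call. = FALSE)
    val <- trimws(strsplit(kv[2], ",", fixed = TRUE)[[1]])
    num <- suppressWarnings(as.numeric(val))
    if (!anyNA(num)) val <- num
    if (identical(val, "TRUE") || identical(val, "FALSE")) {
      val <- as.logical(val)
    }
    over[[trimws(kv[1])]] <- val
  }
  do.call(pipeline_config, over)
}

#' Match MS/MS spectra to feature-table rows
#'
#' Each feature gets at most one representative spectrum: the spectrum whose
#' precursor is closest in m/z within the MS1 tolerance and within
#' `rt_window`, tie-broken by highest total ion intensity.
#'
#' @param table A `feature_table`.
#' @param spectra List of `msms_spectrum`.
#' @param mz_abs,mz_ppm MS1 tolerance components.
#' @param rt_window rt matching window in minutes (`Inf` to ignore rt).
#' @return Named character vector: feature_id -> spectrum_id (unmatched
#'   features absent).
#' @export
match_spectra_to_features <- function(table, spectra, mz_abs = 0.01,
                                      mz_ppm = 20, rt_window = 0.3) {
  feats <- table$features
  smz <- vapply(spectra, function(s) s$precursor_mz, numeric(1))
  srt <- vapply(spectra, function(s) s$rt, numeric(1))
  stic <- vapply(spectra, function(s) sum(s$peaks$intensity), numeric(1))
  sid <- vapply(spectra, function(s) s$spectrum_id, character(1))
  out <- character(0)
  for (i in seq_len(nrow(feats))) {
    tol <- mz_tolerance(feats$mz[i], mz_abs, mz_ppm)
    ok <- abs(smz - feats$mz[i]) <= tol &
      (is.na(srt) | abs(srt - feats$rt[i]) <= rt_window)
    if (!any(ok)) next
    cand <- which(ok)
    cand <- cand[order(abs(smz[cand] - feats$mz[i]), -stic[cand])]
    out[feats$feature_id[i]] <- sid[cand[1]]
  }
  out
}

#' Chlorine scan over per-feature MS1 envelopes
#'
#' Applies [chlorine_score()] to each feature's envelope (matched by
#' `feature_key` -> spectrum/feature mapping or by m/z and rt).
#'
#' @param table A `feature_table`.
#' @param envelopes Envelope data.frame with columns `precursor_mz`, `rt`,
#'   `offset`, `abundance` (as produced by [simulate_experiment()] or read
#'   from an envelope CSV).
#' @param config A `pipeline_config`.
#' @return data.frame `feature_id`, `chlorinated`, `m2_ratio`,
#'   `n_cl_estimate`.
#' @export
chlorine_scan <- function(table, envelopes, config = pipeline_config()) {
  feats <- table$features
  out <- data.frame(feature_id = feats$feature_id, chlorinated = FALSE,
                    m2_ratio = NA_real_, n_cl_estimate = NA_integer_,
                    stringsAsFactors = FALSE)
  if (is.null(envelopes) || nrow(envelopes) == 0L) return(out)
  env_keys <- unique(envelopes[, c("feature_key", "precursor_mz", "rt")])
  for (i in seq_len(nrow(feats))) {
    tol <- mz_tolerance(feats$mz[i], config$mz_abs, config$mz_ppm)
    hit <- which(abs(env_keys$precursor_mz - feats$mz[i]) <= tol &
                   abs(env_keys$rt - feats$rt[i]) <= config$spectrum_match_rt)
    if (length(hit) == 0L) next
    hit <- hit[which.min(abs(env_keys$precursor_mz[hit] - feats$mz[i]))]
    e <- envelopes[envelopes$feature_key == env_keys$feature_key[hit], ,
                   drop = FALSE]
    pat <- data.frame(offset = e$offset, mz = e$mz,
                      abundance = e$abundance / max(e$abundance))
    class(pat) <- c("isotope_pattern", "data.frame")
    sc <- chlorine_score(pat, window_1cl = config$chlorine_window_1cl,
                         window_2cl = config$chlorine_window_2cl,
                         max_m1_ratio = config$max_m1_ratio)
    out$chlorinated[i] <- sc$is_chlorinated
    out$m2_ratio[i] <- sc$ratio
    out$n_cl_estimate[i] <- sc$n_cl_estimate
  }
  out
}

#' Run the full discovery pipeline
#'
#' Executes join -> gap fill -> stats -> artifact grouping -> chlorine scan
#' -> formula assignment -> networking -> component report on an experiment
#' (simulated or loaded from files) and assembles the discovery report:
#' volcano table, molecular network, per-component summary and the ranked
#' candidate list (depleted-without-halide features sorted by fold-change
#' magnitude, ties by P ascending; configurable to P-first).
#'
#' @param runs Per-run feature data.frame (see [read_feature_runs()]).
#' @param spectra List of `msms_spectrum` (optional; `NULL` skips
#'   networking).
#' @param envelopes Envelope data.frame (optional; `NULL` skips the
#'   chlorine scan).
#' @param config A [pipeline_config()].
#' @param out_dir Optional output directory for `volcano.csv`,
#'   `network.graphml`, `components.csv`, `candidates.csv` and
#'   `report.txt`.
#' @param verbose Print per-stage record counts.
#' @return A `discovery_report` list: `table`, `diff`, `groups`,
#'   `chlorine`, `formulas`, `network`, `components`, `candidates`, `config`
#'   and a `log` of stage record counts.
#' @export
run_pipeline <- function(runs, spectra = NULL, envelopes = NULL,
                         config = pipeline_config(), out_dir = NULL,
                         verbose = FALSE) {
  log <- list()
  note <- function(stage, n) {
    log[[stage]] <<- n
    if (verbose) message(sprintf("[%s] %d records", stage, n))
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  note("input_run_features", nrow(runs))
  table <- stage("join", join_features(runs, mz_abs = config$mz_abs,
                                       mz_ppm = config$mz_ppm,
                                       rt_tol = config$rt_tol))
  note("joined_features", nrow(table$matrix))
  table <- stage("gap_fill", gap_fill_floor(table, noise = config$noise_floor))
  note("gap_filled_cells", sum(table$gap_filled))
  diff <- stage("stats", differential_stats(table, welch = config$welch))
  note("tested_features", nrow(diff))
  groups <- stage("artifact_group",
                  artifact_group(table, rt_window = config$artifact_rt_window,
                                 mz_abs = config$mz_abs,
                                 mz_ppm = config$mz_ppm))
  note("artifact_groups", length(unique(groups$group_id)))
  chlor <- stage("chlorine_scan", chlorine_scan(table, envelopes, config))
  note("chlorinated_features", sum(chlor$chlorinated))

  ann <- merge(diff, chlor, by = "feature_id", sort = FALSE)
  ann <- merge(ann, groups, by = "feature_id", sort = FALSE)

  # formula assignment: chlorine-flagged features plus the top depleted
  # parents, up to n_formula_features
  ann$formula <- NA_character_
  sel <- which(ann$chlorinated)
  top <- order(ann$direction != "depleted_without_halide", -ann$fold_change)
  sel <- union(sel, top[seq_len(min(config$n_formula_features, nrow(ann)))])
  sel <- sel[ann$is_parent[sel]]
  for (i in sel) {
    req <- if (isTRUE(ann$chlorinated[i])) list(Cl = 1) else list()
    cand <- stage("formulas",
                  decompose_mass(ann$mz[i], adducts = c("[M+H]+", "[M+NH4]+",
                                                        "[M+Na]+"),
                                 tol_ppm = config$formula_tol_ppm,
                                 require = req))
    if (nrow(cand)) {
      keep <- utils::head(cand, config$formula_max_candidates)
      ann$formula[i] <- paste(paste0(keep$formula, " (", keep$adduct, ")"),
                              collapse = "; ")
    }
  }
  note("formula_assigned", sum(!is.na(ann$formula)))

  network <- NULL; components <- NULL
  if (!is.null(spectra) && length(spectra) > 0L) {
    filt <- stage("filter_peaks",
                  lapply(spectra, filter_peaks,
                         precursor_window = config$precursor_window,
                         top_k = config$top_k, window = config$rank_window))
    spec_map <- match_spectra_to_features(table, filt,
                                          mz_abs = config$mz_abs,
                                          mz_ppm = config$mz_ppm,
                                          rt_window = config$spectrum_match_rt)
    # one representative spectrum per feature; annotate spectra nodes by
    # their matched feature
    used <- filt[match(unique(spec_map), vapply(filt, function(s) s$spectrum_id,
                                                character(1)))]
    node_ann <- ann[match(names(spec_map), ann$feature_id),
                    c("feature_id", "fold_change", "direction", "p_value",
                      "chlorinated", "formula")]
    node_ann$feature_id <- unname(spec_map)
    network <- stage("network",
                     build_network(used, min_cosine = config$min_cosine,
                                   min_matched = config$min_matched,
                                   frag_tol = config$frag_tol,
                                   annotations = node_ann))
    note("network_edges", nrow(network$edges))
    components <- component_report(network, p_cut = config$p_cut)
    note("network_components", nrow(components))
  }

  cand <- ann[ann$direction == "depleted_without_halide" & ann$is_parent, ,
              drop = FALSE]
  if (identical(config$rank_by, "p")) {
    cand <- cand[order(cand$p_value, -cand$fold_change), , drop = FALSE]
  } else {
    cand <- cand[order(-cand$fold_change, cand$p_value), , drop = FALSE]
  }
  rownames(cand) <- NULL
  note("ranked_candidates", nrow(cand))

  report <- list(table = table, diff = ann, groups = groups, chlorine = chlor,
                 network = network, components = components,
                 candidates = cand, config = config, log = log,
                 isotope_table_version = ISOTOPE_TABLE_VERSION)
  class(report) <- "discovery_report"
  if (!is.null(out_dir)) write_discovery_report(report, out_dir)
  report
}

#' @export
print.discovery_report <- function(x, ...) {
  cat("<discovery report>\n")
  for (k in names(x$log)) cat(sprintf("  %-22s %d\n", k, x$log[[k]]))
  if (nrow(x$candidates)) {
    cat("top candidates (depleted without halide):\n")
    top <- utils::head(x$candidates[, c("feature_id", "mz", "rt",
                                        "fold_change", "p_value",
                                        "chlorinated", "formula")], 5)
    print(format(top, digits = 4), row.names = FALSE)
  }
  invisible(x)
}

#' Write the discovery report to files
#'
#' Emits `volcano.csv` (the tabular differential result), `candidates.csv`
#' (ranked list), `components.csv` and `network.graphml` when networking
#' ran, and `report.txt` with stage accounting and the full effective
#' configuration.
#'
#' @param report A `discovery_report`.
#' @param out_dir Output directory (created if needed).
#' @export
write_discovery_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  volcano <- report$diff
  volcano$signed_fold_change <- signed_fold_change(report$diff)
  utils::write.csv(volcano, file.path(out_dir, "volcano.csv"),
                   row.names = FALSE)
  utils::write.csv(report$candidates, file.path(out_dir, "candidates.csv"),
                   row.names = FALSE)
  if (!is.null(report$network)) {
    write_graphml(report$network, file.path(out_dir, "network.graphml"))
    utils::write.csv(report$components, file.path(out_dir, "components.csv"),
                     row.names = FALSE)
  }
  cfg <- report$config
  cfg_lines <- vapply(names(cfg), function(k) {
    paste0(k, "=", paste(cfg[[k]], collapse = ","))
  }, character(1))
  writeLines(c("# discovery report",
               paste0("isotope_table_version=", report$isotope_table_version),
               "", "# stage record counts",
               vapply(names(report$log),
                      function(k) paste0(k, "=", report$log[[k]]),
                      character(1)),
               "", "# effective configuration", cfg_lines,
               "", "# note: t-tests computed on raw (untransformed) intensities"),
             file.path(out_dir, "report.txt"))
  invisible(out_dir)
}
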