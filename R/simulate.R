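# Seeded generator of ground-truth two-condition metabolomics experiments.
#
# Emulates the structure of a halide-depletion study: halide-replete vs
# halide-depleted cultures, three biological replicates each, with planted
# compound families whose abundance drops by a known fold in the depleted
# condition, chlorinated vs non-chlorinated MS1 envelopes, co-eluting adduct
# artifacts, families sharing MS/MS fragments and neutral losses (so they
# network), hard censoring below the detection limit, and deuterated-feeding
# envelopes.  Everything is derived from one seed; regenerating with the
# same manifest is byte-identical.

#' Define a ground-truth compound
#'
#' @param compound_id Unique id.
#' @param formula Neutral formula (string or `element_count`).
#' @param rt Retention time in minutes.
#' @param base_abundance Mean replete-condition intensity (counts).
#' @param halide_fold Planted fold change (>= 1; 1 = halide-independent).
#' @param family_id Family label (`NA` for singletons).
#' @param adduct Primary adduct name.
#' @param secondary_adduct Optional co-eluting artifact adduct, emitted at
#'   `secondary_ratio` of the primary intensity.
#' @param secondary_ratio Relative intensity of the secondary adduct.
#' @param fragments data.frame (`mz`, `intensity`) of template fragment
#'   peaks, or `NULL` for no MS/MS.
#' @param losses data.frame (`loss`, `intensity`) of template neutral
#'   losses (realized at `precursor - loss`).
#' @return A `truth_compound` list.
#' @export
truth_compound <- function(compound_id, formula, rt, base_abundance,
                           halide_fold = 1, family_id = NA_character_,
                           adduct = "[M+H]+", secondary_adduct = NULL,
                           secondary_ratio = 0.3, fragments = NULL,
                           losses = NULL) {
  stopifnot(halide_fold >= 1, base_abundance > 0, rt >= 0)
  out <- list(compound_id = compound_id, formula = as_element_count(formula),
              rt = rt, base_abundance = base_abundance,
              halide_fold = halide_fold, family_id = family_id,
              adduct = adduct, secondary_adduct = secondary_adduct,
              secondary_ratio = secondary_ratio,
              fragments = fragments, losses = losses)
  class(out) <- "truth_compound"
  out
}

# Shared MS/MS template for one compound family.  Members share
# `n_shared_fragments` fragment m/z values and `n_shared_losses` neutral
# losses (>= 5 shared template entries in total guarantees networkability
# under the cosine >= 0.60 / >= 4 matches edge rule), plus 2 unique
# fragments each.
.family_template <- function(n_shared_fragments = 5L, n_shared_losses = 2L) {
  # sugar-like low-mass fragments and sugar-like neutral losses
  frag_mz <- c(89.0597, 127.0390, 163.0601, 203.0529, 245.1020,
               287.1482, 325.2010)[seq_len(n_shared_fragments)]
  frag_int <- c(80, 100, 60, 90, 70, 55, 45)[seq_len(n_shared_fragments)]
  loss_da <- c(180.0634, 198.0740, 342.1162)[seq_len(n_shared_losses)]
  loss_int <- c(50, 40, 30)[seq_len(n_shared_losses)]
  list(fragments = data.frame(mz = frag_mz, intensity = frag_int),
       losses = data.frame(loss = loss_da, intensity = loss_int))
}

#' Build an experiment manifest
#'
#' @param compounds List of [truth_compound()] objects.
#' @param seed Integer seed controlling every random draw.
#' @param n_replicates Replicates per condition (default 3).
#' @param cv Replicate coefficient of variation of the log-normal intensity
#'   noise (default 0.2).
#' @param noise_floor Gap-fill pseudocount (default 100 counts).
#' @param detection_limit Intensities below this are censored to "not
#'   detected" (default 500 counts).
#' @param envelope_noise Multiplicative noise SD on MS1 envelope abundances
#'   (default 0.02).
#' @param mz_jitter,rt_jitter Per-run SD of feature m/z (Th) and rt (min).
#' @param ms2_mz_jitter MS/MS fragment m/z jitter SD in Th (default 0.005).
#' @param ms2_int_jitter MS/MS relative intensity jitter SD (default 0.10).
#' @return An `experiment_manifest` list.
#' @export
experiment_manifest <- function(compounds, seed = 1L, n_replicates = 3L,
                                cv = 0.2, noise_floor = 100,
                                detection_limit = 500,
                                envelope_noise = 0.02,
                                mz_jitter = 0.002, rt_jitter = 0.02,
                                ms2_mz_jitter = 0.005, ms2_int_jitter = 0.10) {
  ids <- vapply(compounds, function(x) x$compound_id, character(1))
  fail <- character(0)
  if (anyDuplicated(ids)) fail <- c(fail, "duplicate compound ids")
  if (n_replicates < 2L) fail <- c(fail, "need >= 2 replicates per condition")
  if (cv < 0) fail <- c(fail, "cv must be >= 0")
  if (length(fail)) {
    stop("invalid manifest: ", paste(fail, collapse = "; "), call. = FALSE)
  }
  out <- list(compounds = compounds, seed = as.integer(seed),
              n_replicates = as.integer(n_replicates), cv = cv,
              noise_floor = noise_floor, detection_limit = detection_limit,
              envelope_noise = envelope_noise, mz_jitter = mz_jitter,
              rt_jitter = rt_jitter, ms2_mz_jitter = ms2_mz_jitter,
              ms2_int_jitter = ms2_int_jitter)
  class(out) <- "experiment_manifest"
  out
}

#' The default demonstration manifest
#'
#' One 8-member chlorinated halide-dependent glycolipid family with planted
#' fold changes (87.5, 421.1 and 607.0 among them, echoing depletion folds
#' typical of halogenation-dependent metabolites), one 5-member
#' halide-independent (non-chlorinated) family, and background features with
#' no condition effect.  Family members share 5 fragment peaks and 2
#' sugar-like neutral losses; three members also emit a co-eluting secondary
#' adduct artifact.
#'
#' @param seed Seed for the manifest (background feature placement) and the
#'   simulation.
#' @param n_background Number of background features (default 200).
#' @param n_family_null Members of the chlorinated family planted with
#'   `halide_fold = 1` (default 0; set 2 to emulate a family whose
#'   halide-independent members reveal cryptic precursor flux).
#' @param ... Passed on to [experiment_manifest()].
#' @return An `experiment_manifest`.
#' @export
demo_manifest <- function(seed = 1L, n_background = 200L,
                          n_family_null = 0L, ...) {
  set.seed(seed)
  tmpl <- .family_template()
  fam_formulas <- c("C28H55O8Cl", "C28H53O8Cl", "C46H89O9Cl", "C44H85O9Cl",
                    "C46H87O9Cl", "C48H93O9Cl", "C42H81O9Cl", "C44H83O9Cl")
  fam_folds <- c(87.5, 421.1, 607.0, 120, 250, 380, 500, 95)
  if (n_family_null > 0L) {
    fam_folds[seq(length(fam_folds), by = -1,
                  length.out = min(n_family_null, 8L))] <- 1
  }
  fam_adduct <- c("[M+H]+", "[M+H]+", rep("[M+NH4]+", 6))
  fam_secondary <- list("[M+NH4]+", NULL, "[M+Na]+", NULL, "[M+Na]+",
                        NULL, NULL, NULL)
  fam_rt <- c(12.4, 12.9, 18.2, 17.1, 17.8, 19.0, 16.3, 16.8)
  compounds <- list()
  for (i in seq_along(fam_formulas)) {
    uniq <- data.frame(mz = sort(stats::runif(2, 300, 520)),
                       intensity = c(30, 25))
    compounds[[length(compounds) + 1L]] <- truth_compound(
      compound_id = sprintf("NGL%02d", i), formula = fam_formulas[i],
      rt = fam_rt[i], base_abundance = 2e7, halide_fold = fam_folds[i],
      family_id = "ngl", adduct = fam_adduct[i],
      secondary_adduct = fam_secondary[[i]],
      fragments = rbind(tmpl$fragments, uniq), losses = tmpl$losses)
  }
  # halide-independent glycolipid family (no chlorine, fold 1); its own
  # shared template so it forms a separate component
  tmpl2 <- list(
    fragments = data.frame(mz = c(97.0284, 141.0546, 185.0808, 229.1071,
                                  271.1540),
                           intensity = c(90, 70, 100, 60, 50)),
    losses = data.frame(loss = c(162.0528, 132.0423), intensity = c(45, 35)))
  hex_formulas <- c("C28H56O8", "C28H54O8", "C30H58O9", "C30H60O9", "C32H62O9")
  hex_rt <- c(13.6, 14.0, 15.2, 15.6, 16.0)
  for (i in seq_along(hex_formulas)) {
    uniq <- data.frame(mz = sort(stats::runif(2, 300, 500)),
                       intensity = c(28, 22))
    compounds[[length(compounds) + 1L]] <- truth_compound(
      compound_id = sprintf("HGL%02d", i), formula = hex_formulas[i],
      rt = hex_rt[i], base_abundance = 1e6, halide_fold = 1,
      family_id = "hgl", adduct = "[M+H]+",
      fragments = rbind(tmpl2$fragments, uniq), losses = tmpl2$losses)
  }
  # background: no condition effect, spaced > 0.2 Th so the join ground
  # truth is unambiguous
  taken <- vapply(compounds, function(x) adduct_mz(x$formula, x$adduct),
                  numeric(1))
  mzs <- numeric(0)
  while (length(mzs) < n_background) {
    cand <- stats::runif(n_background, 150, 900)
    for (m in cand) {
      if (length(mzs) >= n_background) break
      if (all(abs(c(taken, mzs) - m) > 0.2)) mzs <- c(mzs, m)
    }
  }
  base <- 10^stats::runif(n_background, log10(600), 6)
  rts <- stats::runif(n_background, 0.5, 25)
  for (i in seq_len(n_background)) {
    compounds[[length(compounds) + 1L]] <- truth_compound(
      compound_id = sprintf("BG%04d", i), formula = "H2O",  # placeholder
      rt = rts[i], base_abundance = base[i], halide_fold = 1)
    # background features are raw (mz, rt, intensity) entities without a
    # meaningful formula; mark them so simulation uses the literal mz
    compounds[[length(compounds)]]$raw_mz <- mzs[i]
  }
  experiment_manifest(compounds, seed = seed, ...)
}

#' A planted-null manifest
#'
#' Background features only (no condition effect anywhere), on an m/z grid
#' so cross-run joining is unambiguous.  Used to check the type-I error of
#' the differential test.
#'
#' @param n_features Number of null features (default 2000).
#' @param seed Seed.
#' @param base_range Log10 range of base abundances (default `c(4, 6)`,
#'   i.e. well above the detection limit so censoring does not truncate the
#'   null).
#' @param ... Passed to [experiment_manifest()].
#' @return An `experiment_manifest`.
#' @export
null_manifest <- function(n_features = 2000L, seed = 1L,
                          base_range = c(4, 6), ...) {
  set.seed(seed)
  mzs <- 150 + seq_len(n_features) * 0.35 +
    stats::runif(n_features, -0.05, 0.05)
  base <- 10^stats::runif(n_features, base_range[1], base_range[2])
  rts <- stats::runif(n_features, 0.5, 25)
  compounds <- vector("list", n_features)
  for (i in seq_len(n_features)) {
    compounds[[i]] <- truth_compound(
      compound_id = sprintf("NULL%05d", i), formula = "H2O",
      rt = rts[i], base_abundance = base[i], halide_fold = 1)
    compounds[[i]]$raw_mz <- mzs[i]
  }
  experiment_manifest(compounds, seed = seed, ...)
}

#' @export
print.experiment_manifest <- function(x, ...) {
  fams <- table(vapply(x$compounds,
                       function(c) c$family_id %||% NA_character_,
                       character(1)), useNA = "ifany")
  cat("<experiment manifest> ", length(x$compounds), " compounds, ",
      x$n_replicates, " vs ", x$n_replicates, " replicates, CV ", x$cv,
      ", floor ", x$noise_floor, ", detection limit ", x$detection_limit,
      ", seed ", x$seed, "\n", sep = "")
  invisible(x)
}

# log-normal draw with arithmetic mean `mean` and CV `cv`
.rlnorm_mean <- function(n, mean, cv) {
  if (cv <= 0) return(rep(mean, n))
  sigma <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = log(mean) - sigma^2 / 2, sdlog = sigma)
}

#' Simulate a two-condition LC-MS experiment
#'
#' Realizes the manifest into per-run feature lists, MS/MS spectra, MS1
#' isotope envelopes and a ground-truth table.  Replicate intensities are
#' log-normal around the condition mean (base abundance, divided by the
#' planted fold in the depleted condition); intensities below the detection
#' limit are censored (feature absent from that run).  Envelopes come from
#' [isotope_pattern()] with multiplicative abundance noise; MS/MS spectra
#' are realized from the fragment templates with m/z and intensity jitter
#' and carry the standard collision energy `10 + 0.02 * m/z`.  Co-eluting
#' secondary-adduct artifacts are emitted at the same rt.
#'
#' @param manifest An [experiment_manifest()].
#' @param out_dir Optional directory: when given, writes `runs.csv`,
#'   `msms.mgf`, `envelopes.csv`, `truth_features.csv` and `manifest.txt`.
#' @return Invisibly (and visibly) a list: `runs` (tall per-run feature
#'   data.frame), `spectra` (list of `msms_spectrum`), `envelopes`
#'   (data.frame `feature_key`, `precursor_mz`, `rt`, `offset`, `mz`,
#'   `abundance`), `truth` (per planted feature: ids, m/z, rt, condition
#'   means, fold, family, chlorinated flag) and the `manifest`.
#' @export
simulate_experiment <- function(manifest, out_dir = NULL) {
  stopifnot(inherits(manifest, "experiment_manifest"))
  set.seed(manifest$seed)
  nrep <- manifest$n_replicates
  run_ids <- c(sprintf("replete_%d", seq_len(nrep)),
               sprintf("depleted_%d", seq_len(nrep)))
  conditions <- rep(c("replete", "depleted"), each = nrep)

  truth <- list(); runs <- list(); spectra <- list(); envelopes <- list()
  for (cmp in manifest$compounds) {
    is_raw <- !is.null(cmp$raw_mz)
    ions <- list(list(adduct = cmp$adduct, ratio = 1, role = "parent"))
    if (!is.null(cmp$secondary_adduct)) {
      ions[[2]] <- list(adduct = cmp$secondary_adduct,
                        ratio = cmp$secondary_ratio, role = "artifact")
    }
    for (ion in ions) {
      mz0 <- if (is_raw) cmp$raw_mz else adduct_mz(cmp$formula, ion$adduct)
      key <- if (ion$role == "parent") cmp$compound_id else
        paste0(cmp$compound_id, "_", gsub("[^A-Za-z0-9]", "", ion$adduct))
      mean_rep <- cmp$base_abundance * ion$ratio
      mean_dep <- mean_rep / cmp$halide_fold
      vals <- c(.rlnorm_mean(nrep, mean_rep, manifest$cv),
                .rlnorm_mean(nrep, mean_dep, manifest$cv))
      detected <- vals >= manifest$detection_limit
      mzs <- mz0 + stats::rnorm(2 * nrep, 0, manifest$mz_jitter)
      rts <- cmp$rt + stats::rnorm(2 * nrep, 0, manifest$rt_jitter)
      for (k in which(detected)) {
        runs[[length(runs) + 1L]] <- data.frame(
          run_id = run_ids[k], condition = conditions[k],
          mz = mzs[k], rt = rts[k], intensity = vals[k],
          stringsAsFactors = FALSE)
      }
      n_cl <- if (is_raw) 0L else formula_count(cmp$formula, "Cl")
      truth[[length(truth) + 1L]] <- data.frame(
        feature_key = key, compound_id = cmp$compound_id,
        adduct = if (is_raw) NA_character_ else ion$adduct, role = ion$role,
        formula = if (is_raw) NA_character_ else format(cmp$formula),
        mz = mz0, rt = cmp$rt, mean_replete = mean_rep,
        mean_depleted = mean_dep, halide_fold = cmp$halide_fold,
        family_id = cmp$family_id %||% NA_character_,
        chlorinated = n_cl > 0L, n_detected = sum(detected),
        stringsAsFactors = FALSE)
      # MS1 envelope for the parent ion of formula-bearing compounds
      if (!is_raw && ion$role == "parent") {
        pat <- isotope_pattern(cmp$formula, max_offsets = 5L, prune = 1e-4,
                               charge = if (grepl("-$", ion$adduct)) -1L else 1L)
        # envelope centered on the adduct m/z, abundances with noise
        ab <- pat$abundance *
          (1 + stats::rnorm(nrow(pat), 0, manifest$envelope_noise))
        ab <- pmax(ab, 1e-6)
        envelopes[[length(envelopes) + 1L]] <- data.frame(
          feature_key = key, precursor_mz = mz0, rt = cmp$rt,
          offset = pat$offset, mz = mz0 + pat$offset * 1.00335,
          abundance = ab / max(ab), stringsAsFactors = FALSE)
      }
      # MS/MS spectrum for the parent ion
      if (ion$role == "parent" && !is.null(cmp$fragments)) {
        fr <- cmp$fragments
        lo <- cmp$losses
        pk_mz <- c(fr$mz, if (!is.null(lo)) mz0 - lo$loss)
        pk_int <- c(fr$intensity, if (!is.null(lo)) lo$intensity)
        keep <- pk_mz > 50 & pk_mz < mz0 - 1
        pk_mz <- pk_mz[keep]; pk_int <- pk_int[keep]
        pk_mz <- pk_mz + stats::rnorm(length(pk_mz), 0, manifest$ms2_mz_jitter)
        pk_int <- pk_int *
          pmax(1 + stats::rnorm(length(pk_int), 0, manifest$ms2_int_jitter), 0.05)
        spectra[[length(spectra) + 1L]] <- msms_spectrum(
          spectrum_id = key, precursor_mz = mz0,
          peaks = data.frame(mz = pk_mz, intensity = pk_int),
          charge = 1L, rt = cmp$rt,
          collision_energy = collision_energy(mz0))
      }
    }
  }
  runs <- do.call(rbind, runs)
  truth <- do.call(rbind, truth)
  envelopes <- if (length(envelopes)) do.call(rbind, envelopes) else NULL
  out <- list(runs = runs, spectra = spectra, envelopes = envelopes,
              truth = truth, manifest = manifest)
  class(out) <- "halide_experiment"
  if (!is.null(out_dir)) .write_experiment(out, out_dir)
  out
}

#' @export
print.halide_experiment <- function(x, ...) {
  cat("<simulated experiment> ", nrow(x$truth), " planted features, ",
      nrow(x$runs), " run-feature observations, ", length(x$spectra),
      " MS/MS spectra (seed ", x$manifest$seed, ")\n", sep = "")
  invisible(x)
}

.write_experiment <- function(x, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  fmt <- function(df, cols, digits) {
    for (i in seq_along(cols)) df[[cols[i]]] <- sprintf(paste0("%.", digits[i], "f"),
                                                        df[[cols[i]]])
    df
  }
  utils::write.csv(fmt(x$runs, c("mz", "rt", "intensity"), c(5, 3, 1)),
                   file.path(out_dir, "runs.csv"), row.names = FALSE,
                   quote = FALSE)
  write_mgf(x$spectra, file.path(out_dir, "msms.mgf"))
  if (!is.null(x$envelopes)) {
    utils::write.csv(fmt(x$envelopes, c("precursor_mz", "rt", "mz", "abundance"),
                         c(5, 3, 5, 6)),
                     file.path(out_dir, "envelopes.csv"), row.names = FALSE,
                     quote = FALSE)
  }
  utils::write.csv(fmt(x$truth, c("mz", "rt", "mean_replete", "mean_depleted"),
                       c(5, 3, 2, 2)),
                   file.path(out_dir, "truth_features.csv"), row.names = FALSE,
                   quote = FALSE)
  m <- x$manifest
  keys <- c(seed = m$seed, n_replicates = m$n_replicates, cv = m$cv,
            noise_floor = m$noise_floor, detection_limit = m$detection_limit,
            envelope_noise = m$envelope_noise, mz_jitter = m$mz_jitter,
            rt_jitter = m$rt_jitter, ms2_mz_jitter = m$ms2_mz_jitter,
            ms2_int_jitter = m$ms2_int_jitter,
            n_compounds = length(m$compounds))
  writeLines(c(paste0("isotope_table_version=", ISOTOPE_TABLE_VERSION),
               paste0(names(keys), "=", keys)),
             file.path(out_dir, "manifest.txt"))
  invisible(out_dir)
}

#' Simulate a stable-isotope feeding observation
#'
#' Mixture envelope of the unlabeled metabolite and a labeled species
#' (`n_label` label atoms fed, `n_lost` lost during incorporation) at the
#' stated incorporation fraction, with multiplicative abundance noise, on
#' the nominal-offset grid of the unlabeled parent.
#'
#' @param parent Unlabeled parent formula.
#' @param n_label,n_lost Label atoms fed / lost (see [labeled_species()]).
#' @param incorporation_fraction Molar fraction of the labeled species in
#'   `[0, 1]`.
#' @param noise Multiplicative abundance noise SD (default 0.02; 0 for a
#'   noiseless envelope).
#' @param purity Label isotopic purity.
#' @param seed Optional seed.
#' @param max_offset Highest offset reported (default covers the labeled
#'   envelope).
#' @return A list: `observed` (data.frame `offset`, `abundance`, normalized
#'   to M+0 = 1) and `truth` (all generating parameters).
#' @export
simulate_feeding <- function(parent, n_label, n_lost = 0L,
                             incorporation_fraction = 0.3, noise = 0.02,
                             purity = 0.99, seed = NULL, max_offset = NULL) {
  stopifnot(incorporation_fraction >= 0, incorporation_fraction <= 1)
  if (!is.null(seed)) set.seed(seed)
  unlab <- labeled_species(parent, n_label, n_label, purity = purity)
  lab <- labeled_species(parent, n_label, n_lost, purity = purity)
  if (is.null(max_offset)) max_offset <- lab$nominal_shift + 4L
  offsets <- 0:max_offset
  mix <- numeric(length(offsets))
  for (sp in list(list(s = unlab, f = 1 - incorporation_fraction),
                  list(s = lab, f = incorporation_fraction))) {
    pat <- sp$s$pattern
    ab <- pat$abundance / sum(pat$abundance)
    pos <- match(pat$offset + sp$s$nominal_shift, offsets)
    ok <- !is.na(pos)
    mix[pos[ok]] <- mix[pos[ok]] + sp$f * ab[ok]
  }
  if (noise > 0) {
    mix <- pmax(mix * (1 + stats::rnorm(length(mix), 0, noise)), 0)
  }
  scale <- if (mix[1] > 0) mix[1] else max(mix)  # M+0-normalized when possible
  list(observed = data.frame(offset = offsets, abundance = mix / scale),
       truth = list(parent = format(as_element_count(parent)),
                    n_label = n_label, n_lost = n_lost,
                    incorporation_fraction = incorporation_fraction,
                    noise = noise, purity = purity))
}
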