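# Mascot Generic Format (MGF) reading and writing.
#
# Line-oriented BEGIN IONS / END IONS blocks with PEPMASS, CHARGE,
# TITLE=<feature id>, RTINSECONDS and optional COLLISIONENERGY headers,
# followed by "mz intensity" peak lines.

#' Read MS/MS spectra from an MGF file
#'
#' Honors `TITLE` (used as the spectrum/feature id), `PEPMASS` (first token),
#' `CHARGE` (e.g. `1+`), `RTINSECONDS` (converted to minutes) and
#' `COLLISIONENERGY`.
#'
#' @param path MGF file path.
#' @return A list of [msms_spectrum()] objects.
#' @export
read_mgf <- function(path) {
  if (!file.exists(path)) stop("MGF file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  spectra <- list()
  i <- 1L
  while (i <= length(lines)) {
    if (trimws(lines[i]) == "BEGIN IONS") {
      title <- NA_character_; pepmass <- NA_real_; charge <- 1L
      rt <- NA_real_; ce <- NA_real_
      mzs <- numeric(0); ints <- numeric(0)
      i <- i + 1L
      while (i <= length(lines) && trimws(lines[i]) != "END IONS") {
        ln <- trimws(lines[i])
        if (grepl("^TITLE=", ln)) {
          title <- sub("^TITLE=", "", ln)
        } else if (grepl("^PEPMASS=", ln)) {
          pepmass <- as.numeric(strsplit(sub("^PEPMASS=", "", ln), "[ \t]+")[[1]][1])
        } else if (grepl("^CHARGE=", ln)) {
          ch <- sub("^CHARGE=", "", ln)
          sgn <- if (grepl("-", ch)) -1L else 1L
          charge <- sgn * as.integer(gsub("[^0-9]", "", ch))
        } else if (grepl("^RTINSECONDS=", ln)) {
          rt <- as.numeric(sub("^RTINSECONDS=", "", ln)) / 60
        } else if (grepl("^COLLISIONENERGY=", ln)) {
          ce <- as.numeric(sub("^COLLISIONENERGY=", "", ln))
        } else if (grepl("^[0-9]", ln)) {
          tok <- strsplit(ln, "[ \t]+")[[1]]
          mzs <- c(mzs, as.numeric(tok[1]))
          ints <- c(ints, as.numeric(tok[2]))
        }
        i <- i + 1L
      }
      if (is.na(pepmass)) stop("MGF block without PEPMASS in ", path,
                               call. = FALSE)
      if (is.na(title)) title <- paste0("spectrum_", length(spectra) + 1L)
      spectra[[length(spectra) + 1L]] <- msms_spectrum(
        spectrum_id = title, precursor_mz = pepmass,
        peaks = data.frame(mz = mzs, intensity = ints),
        charge = charge, rt = rt, collision_energy = ce)
    }
    i <- i + 1L
  }
  spectra
}

#' Write MS/MS spectra to an MGF file
#'
#' @param spectra List of `msms_spectrum` objects.
#' @param path Output path.
#' @export
write_mgf <- function(spectra, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (s in spectra) {
    writeLines("BEGIN IONS", con)
    writeLines(paste0("TITLE=", s$spectrum_id), con)
    writeLines(sprintf("PEPMASS=%.5f", s$precursor_mz), con)
    writeLines(sprintf("CHARGE=%d%s", abs(s$charge),
                       if (s$charge < 0) "-" else "+"), con)
    if (!is.na(s$rt)) writeLines(sprintf("RTINSECONDS=%.3f", s$rt * 60), con)
    if (!is.na(s$collision_energy)) {
      writeLines(sprintf("COLLISIONENERGY=%.3f", s$collision_energy), con)
    }
    if (nrow(s$peaks)) {
      writeLines(sprintf("%.5f %.3f", s$peaks$mz, s$peaks$intensity), con)
    }
    writeLines("END IONS", con)
    writeLines("", con)
  }
  invisible(path)
}
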