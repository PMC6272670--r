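#' Write spectra to a Mascot generic format (MGF) file
#'
#' Each spectrum becomes a `BEGIN IONS`/`END IONS` block with `PEPMASS`,
#' `CHARGE=1+`, an optional `TITLE` (the compound label) and an `ADDUCT`
#' key-value line, followed by `m/z intensity` peak lines.
#'
#' @param spectra An `ms2_spectrum` or a list of them.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_mgf <- function(spectra, path) {
  if (inherits(spectra, "ms2_spectrum")) spectra <- list(spectra)
  lines <- character(0)
  for (s in spectra) {
    stopifnot(inherits(s, "ms2_spectrum"))
    block <- c(
      "BEGIN IONS",
      if (!is.na(s$label)) paste0("TITLE=compound_", s$label),
      sprintf("PEPMASS=%.6f", s$precursor_mz),
      "CHARGE=1+",
      if (!is.na(s$adduct)) paste0("ADDUCT=", s$adduct),
      sprintf("%.6f %.4f", s$peaks$mz, s$peaks$intensity),
      "END IONS", ""
    )
    lines <- c(lines, block)
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read spectra from an MGF file
#'
#' Parses `BEGIN IONS` blocks with `PEPMASS`, optional `CHARGE`, `TITLE`
#' (`compound_<id>` titles recover the label) and `ADDUCT` headers.
#'
#' @param path MGF file path.
#' @return A list of `ms2_spectrum` objects.
#' @export
read_mgf <- function(path) {
  lines <- trimws(readLines(path))
  spectra <- list()
  i <- 1L
  while (i <= length(lines)) {
    if (lines[i] != "BEGIN IONS") { i <- i + 1L; next }
    precursor <- NA_real_; adduct <- NA_character_; label <- NA_integer_
    mz <- numeric(0); intensity <- numeric(0)
    i <- i + 1L
    while (i <= length(lines) && lines[i] != "END IONS") {
      ln <- lines[i]
      if (grepl("^PEPMASS=", ln)) {
        precursor <- as.numeric(strsplit(sub("^PEPMASS=", "", ln),
                                         "[ \t]+")[[1]][1])
      } else if (grepl("^ADDUCT=", ln)) {
        adduct <- sub("^ADDUCT=", "", ln)
      } else if (grepl("^TITLE=", ln)) {
        m <- regmatches(ln, regexpr("compound_[0-9]+", ln))
        if (length(m)) label <- as.integer(sub("compound_", "", m))
      } else if (grepl("^[0-9]", ln)) {
        parts <- as.numeric(strsplit(ln, "[ \t]+")[[1]])
        mz <- c(mz, parts[1])
        intensity <- c(intensity, if (length(parts) > 1) parts[2] else 1)
      }
      i <- i + 1L
    }
    if (is.na(precursor)) stop("MGF block without PEPMASS")
    spectra[[length(spectra) + 1L]] <-
      ms2_spectrum(precursor, mz, intensity, adduct = adduct, label = label)
    i <- i + 1L
  }
  spectra
}

#' Read a two-column peak-list CSV as a spectrum
#'
#' The CSV must have columns `mz` and `intensity`; precursor metadata is
#' supplied by the caller (as when exporting a single MS/MS scan).
#'
#' @param path CSV file path.
#' @param precursor_mz Precursor ion m/z.
#' @param adduct Adduct hypothesis or `NA`.
#' @param label Optional compound id.
#' @return An `ms2_spectrum`.
#' @export
read_spectrum_csv <- function(path, precursor_mz, adduct = NA_character_,
                              label = NA_integer_) {
  df <- utils::read.csv(path)
  stopifnot(all(c("mz", "intensity") %in% names(df)))
  ms2_spectrum(precursor_mz, df$mz, df$intensity, adduct = adduct,
               label = label)
}

#' Write a spectrum peak list as CSV
#'
#' @param spectrum An `ms2_spectrum`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_spectrum_csv <- function(spectrum, path) {
  stopifnot(inherits(spectrum, "ms2_spectrum"))
  utils::write.csv(spectrum$peaks, path, row.names = FALSE)
  invisible(path)
}

#' Reference tables transcribed from the source study
#'
#' Printed data tables shipped with the package as plain CSV: the
#' calibration/validation parameters, the spike-recovery data, the 14-batch
#' content table, the diagnostic-fragment measured/calculated pairs of the
#' two lignan subclasses, and the precursor table of the additionally
#' detected constituents.
#'
#' @param name One of `"calibration"`, `"recovery"`, `"content"`,
#'   `"fragments"`, `"precursors"`.
#' @return A data frame.
#' @examples
#' head(reference_table("calibration"))
#' @export
reference_table <- function(name = c("calibration", "recovery", "content",
                                     "fragments", "precursors")) {
  name <- match.arg(name)
  path <- system.file("extdata", paste0("reference_", name, ".csv"),
                      package = "lignantools", mustWork = TRUE)
  utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
}
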