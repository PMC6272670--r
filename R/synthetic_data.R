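#' Simulation configuration
#'
#' Parameters of the instrument emulator. Fragment mass error is absolute
#' (mDa), matching the annotator's tolerance model and the flat mDa-scale
#' deviations of real QTOF fragment tables (which reach ~6 mDa); the default
#' sigma of 2 mDa brackets typical behaviour. Peak-area noise is relative
#' (1% by default). Intensities are decorative: the annotator ignores them.
#'
#' @param seed Integer RNG seed; identical configurations give identical
#'   outputs.
#' @param sigma_mass_mda SD of fragment/precursor mass error in mDa (>= 0).
#' @param sigma_area Relative SD of peak-area noise (>= 0).
#' @param intensity_model `"lognormal"` (default, realistic-looking) or
#'   `"uniform"`.
#' @param dropout_p Probability that any expected ion is absent (default 0).
#' @return A `sim_config` object.
#' @export
sim_config <- function(seed = 1L, sigma_mass_mda = 2, sigma_area = 0.01,
                       intensity_model = c("lognormal", "uniform"),
                       dropout_p = 0) {
  intensity_model <- match.arg(intensity_model)
  stopifnot(sigma_mass_mda >= 0, sigma_area >= 0,
            dropout_p >= 0, dropout_p <= 1)
  structure(list(seed = as.integer(seed),
                 sigma_mass_mda = sigma_mass_mda,
                 sigma_area = sigma_area,
                 intensity_model = intensity_model,
                 dropout_p = dropout_p),
            class = "sim_config")
}

sim_intensity <- function(n, model) {
  switch(model,
         lognormal = stats::rlnorm(n, meanlog = log(1e4), sdlog = 1),
         uniform = stats::runif(n, 1e2, 1e5))
}

#' Simulate an MS/MS spectrum of a library compound
#'
#' Applies the diagnostic fragmentation rules forward: every expected ion of
#' the compound under the chosen adduct becomes a peak with i.i.d. Gaussian
#' mass error of SD `sigma_mass_mda`, retained with probability
#' `1 - dropout_p`; the precursor receives the same error model. At zero
#' noise the peak list equals the rule table exactly.
#'
#' @param record A `compound_record` from [build_library()].
#' @param adduct Precursor adduct (default `"[M+Na]+"`, the dominant species
#'   for these lignans in positive ESI).
#' @param cfg A [sim_config()].
#' @return An `ms2_spectrum` with `label` set to the compound id.
#' @examples
#' lib <- build_library()
#' simulate_spectrum(lib[[12]], "[M+H]+", sim_config(seed = 7))
#' @export
simulate_spectrum <- function(record, adduct = "[M+Na]+",
                              cfg = sim_config()) {
  stopifnot(inherits(record, "compound_record"), inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  expected <- diagnostic_fragments(record, adduct)
  # one physical peak per distinct m/z (e.g. [A]+ and [A']+ coincide for
  # compounds with two guaiacyl rings)
  expected <- expected[!duplicated(round_half_up(expected$mz, 4)), ,
                       drop = FALSE]
  keep <- stats::runif(nrow(expected)) >= cfg$dropout_p
  mz <- expected$mz[keep] +
    stats::rnorm(sum(keep), 0, cfg$sigma_mass_mda) / 1000
  precursor <- ion_mz(record$formula, adduct) +
    stats::rnorm(1, 0, cfg$sigma_mass_mda) / 1000
  ms2_spectrum(precursor, mz,
               intensity = sim_intensity(length(mz), cfg$intensity_model),
               adduct = adduct, label = record$id)
}

#' Simulate an HPLC-UV quantification dataset
#'
#' Generates peak-area tables with the structure the quantification workflow
#' assumes: for each batch and compound the true content (mg/g) is converted
#' to an on-column amount, pushed through the compound's calibration line
#' `area = slope * ng + intercept`, and perturbed with Gaussian noise of SD
#' `sigma_area * slope * ng`. A calibration series at the standard nine
#' injection volumes (1, 2, 3, 5, 10, 15, 20, 25, 35 uL, i.e. multiples of
#' the lowest calibrated amount) is generated with the same noise model.
#' Amounts outside the calibrated range are generated but flagged.
#'
#' @param curves Data frame with columns `compound`, `slope`, `intercept`,
#'   `range_low_ng`, `range_high_ng` (the layout of
#'   `reference_table("calibration")`).
#' @param true_contents Numeric matrix/data frame of true contents (mg/g),
#'   rows = batches, columns = compounds (column order follows `curves`).
#' @param cfg A [sim_config()].
#' @param sample_mg,extract_ml,inject_ul Sample-preparation constants, as in
#'   [content_mg_per_g()].
#' @return List with `sample_areas` (data frame `batch`, `compound`, `area`,
#'   `true_ng`, `in_range`), `calibration` (data frame `compound`, `ng`,
#'   `area`) and `truth` (the input content matrix).
#' @export
simulate_quant_dataset <- function(curves, true_contents, cfg = sim_config(),
                                   sample_mg = 400, extract_ml = 20,
                                   inject_ul = 20) {
  stopifnot(inherits(cfg, "sim_config"),
            all(c("compound", "slope", "intercept") %in% names(curves)))
  set.seed(cfg$seed)
  m <- as.matrix(true_contents)
  storage.mode(m) <- "numeric"
  if (ncol(m) != nrow(curves)) {
    stop("true_contents must have one column per calibration curve")
  }
  factor_ng <- (extract_ml * 1000 / inject_ul) / (sample_mg * 1000)
  batches <- if (is.null(rownames(m))) {
    paste0("B", seq_len(nrow(m)))
  } else rownames(m)

  noisy_area <- function(slope, intercept, ng) {
    mu <- slope * ng + intercept
    mu + stats::rnorm(length(ng), 0, cfg$sigma_area * abs(slope * ng))
  }

  rows <- list()
  for (j in seq_len(nrow(curves))) {
    ng <- m[, j] / factor_ng
    in_range <- if (all(c("range_low_ng", "range_high_ng") %in%
                        names(curves))) {
      ng >= curves$range_low_ng[j] & ng <= curves$range_high_ng[j]
    } else rep(TRUE, length(ng))
    rows[[j]] <- data.frame(
      batch = batches, compound = curves$compound[j],
      area = noisy_area(curves$slope[j], curves$intercept[j], ng),
      true_ng = ng, in_range = in_range, stringsAsFactors = FALSE
    )
  }
  sample_areas <- do.call(rbind, rows)

  vols <- c(1, 2, 3, 5, 10, 15, 20, 25, 35)
  cal <- list()
  for (j in seq_len(nrow(curves))) {
    base <- if ("range_low_ng" %in% names(curves)) {
      curves$range_low_ng[j]
    } else 10
    ng <- vols * base
    cal[[j]] <- data.frame(
      compound = curves$compound[j], ng = ng,
      area = noisy_area(curves$slope[j], curves$intercept[j], ng),
      stringsAsFactors = FALSE
    )
  }
  list(sample_areas = sample_areas, calibration = do.call(rbind, cal),
       truth = m)
}
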