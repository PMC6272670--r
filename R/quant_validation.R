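#' Fit an external-standard calibration line
#'
#' Ordinary least-squares fit of peak area against on-column amount (ng),
#' `area = a * ng + b`, with r^2 the squared Pearson correlation. Unweighted
#' OLS is appropriate here: the calibration spans about a 35-fold range with
#' near-unit slopes, so weighting is immaterial.
#'
#' @param ng On-column amounts (ng); at least 3 distinct levels.
#' @param area Peak areas (same length).
#' @param compound_id Optional compound identifier carried in the result.
#' @return A `calibration_curve`: list with `compound_id`, `slope`,
#'   `intercept`, `r2`, `range_ng`.
#' @examples
#' fit_calibration(c(10, 20, 40), 0.9845 * c(10, 20, 40) - 3.0467)
#' @export
fit_calibration <- function(ng, area, compound_id = NA) {
  stopifnot(length(ng) == length(area))
  if (length(unique(ng)) < 3) {
    stop("calibration needs at least 3 distinct amount levels")
  }
  if (stats::sd(ng) == 0) stop("zero variance in amounts")
  fit <- stats::lm(area ~ ng)
  r2 <- if (stats::sd(area) == 0) 0 else stats::cor(ng, area)^2
  structure(
    list(compound_id = compound_id,
         slope = unname(stats::coef(fit)[2]),
         intercept = unname(stats::coef(fit)[1]),
         r2 = r2,
         range_ng = range(ng)),
    class = "calibration_curve"
  )
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf("<calibration_curve%s> y = %.4fx %s %.4f, r2 = %.4f, range %.2f-%.2f ng\n",
              if (is.na(x$compound_id)) "" else paste0(" ", x$compound_id),
              x$slope, if (x$intercept < 0) "-" else "+", abs(x$intercept),
              x$r2, x$range_ng[1], x$range_ng[2]))
  invisible(x)
}

#' Back-calculate amount from peak area
#'
#' Inverts the calibration line: `ng = (area - intercept) / slope`. Warns
#' when the result falls outside the calibrated range (the value is still
#' returned).
#'
#' @param area Peak area(s).
#' @param curve A `calibration_curve`.
#' @return Amount(s) in ng.
#' @export
quantify <- function(area, curve) {
  stopifnot(inherits(curve, "calibration_curve"))
  if (abs(curve$slope) < 1e-12) {
    stop("calibration slope is zero; cannot invert")
  }
  ng <- (area - curve$intercept) / curve$slope
  out_of_range <- ng < curve$range_ng[1] - 1e-9 |
    ng > curve$range_ng[2] + 1e-9
  if (any(out_of_range)) {
    warning(sum(out_of_range),
            " value(s) outside the calibrated range ",
            sprintf("%.2f-%.2f ng", curve$range_ng[1], curve$range_ng[2]))
  }
  ng
}

#' Convert on-column amount to sample content
#'
#' `mg/g = ng * (extract_ml * 1000 / inject_ul) / (sample_mg * 1000)`:
#' the injected aliquot is scaled to the whole extract and normalised by the
#' sample mass. At the study defaults (400 mg of powder extracted in 20 mL,
#' 20 uL injected) the factor is 0.0025 mg/g per ng.
#'
#' @param ng On-column amount(s) in ng.
#' @param sample_mg Sample mass in mg (default 400).
#' @param extract_ml Extraction volume in mL (default 20).
#' @param inject_ul Injection volume in uL (default 20).
#' @return Content(s) in mg per g of sample.
#' @export
content_mg_per_g <- function(ng, sample_mg = 400, extract_ml = 20,
                             inject_ul = 20) {
  stopifnot(sample_mg > 0, extract_ml > 0, inject_ul > 0)
  ng * (extract_ml * 1000 / inject_ul) / (sample_mg * 1000)
}

#' Limits of detection and quantification from a dilution series
#'
#' LOD is the smallest amount whose signal-to-noise ratio reaches 3; LOQ the
#' smallest reaching 10. The series must be sorted by increasing amount. A
#' threshold never reached gives `NA` (absent), not 0.
#'
#' @param series Data frame with columns `ng`, `signal`, `noise`.
#' @return A list with `lod_ng` and `loq_ng`.
#' @export
lod_loq <- function(series) {
  stopifnot(all(c("ng", "signal", "noise") %in% names(series)))
  if (is.unsorted(series$ng)) {
    stop("dilution series must be sorted ascending in ng")
  }
  sn <- series$signal / series$noise
  lod <- series$ng[sn >= 3][1]
  loq <- series$ng[sn >= 10][1]
  list(lod_ng = if (is.na(lod)) NA_real_ else lod,
       loq_ng = if (is.na(loq)) NA_real_ else loq)
}

#' Relative standard deviation
#'
#' Sample standard deviation (n-1 denominator) over the mean, in percent,
#' rounded half-up to `digits` decimals.
#'
#' @param values Numeric vector, length >= 2, non-zero mean.
#' @param digits Decimals to round to (default 2); `NULL` for unrounded.
#' @return RSD in percent.
#' @examples
#' rsd(c(98, 100, 102))
#' @export
rsd <- function(values, digits = 2) {
  if (length(values) < 2) stop("RSD needs at least 2 values")
  m <- mean(values)
  if (m == 0) stop("RSD undefined for zero mean")
  out <- stats::sd(values) / m * 100
  if (is.null(digits)) out else round_half_up(out, digits)
}

#' Spike recovery
#'
#' `recovery (%) = (observed - original) / spiked * 100`, rounded half-up to
#' 2 decimals. Vectorised: given per-replicate triples it returns
#' per-replicate recoveries, which are conventionally averaged.
#'
#' @param original_ug Amount in the unspiked sample (ug).
#' @param spiked_ug Amount added (ug), positive.
#' @param observed_ug Amount found in the spiked sample (ug).
#' @param digits Decimals to round to (default 2); `NULL` for unrounded.
#' @return Recovery in percent.
#' @examples
#' recovery(163.01, 164.02, 329.03)  # 101.22
#' @export
recovery <- function(original_ug, spiked_ug, observed_ug, digits = 2) {
  if (any(spiked_ug <= 0)) stop("spiked amount must be positive")
  out <- (observed_ug - original_ug) / spiked_ug * 100
  if (is.null(digits)) out else round_half_up(out, digits)
}

#' Summarise a batch-by-compound content table
#'
#' Computes the derived rows of a content matrix: per-batch totals, per-
#' compound means and RSDs, and the grand mean of the batch totals. If a
#' `declared_total` (a previously reported grand mean) is supplied and
#' disagrees with the recomputed value by more than 0.001 mg/g, the
#' discrepancy is flagged rather than reconciled.
#'
#' @param contents Numeric matrix or data frame, rows = batches, columns =
#'   compounds, values in mg/g.
#' @param declared_total Optional reported average total content to check.
#' @return A `content_summary`: list with `batch_sum` (named vector),
#'   `compound_average`, `compound_rsd`, `grand_mean`, `flags` (character).
#' @export
summarize_batches <- function(contents, declared_total = NULL) {
  m <- as.matrix(contents)
  if (!nrow(m) || !ncol(m)) stop("empty content table")
  storage.mode(m) <- "numeric"
  batch_sum <- rowSums(m)
  compound_average <- colMeans(m)
  compound_rsd <- if (nrow(m) >= 2) {
    apply(m, 2, rsd)
  } else {
    setNames(rep(NA_real_, ncol(m)), colnames(m))
  }
  grand_mean <- mean(batch_sum)
  flags <- character(0)
  if (!is.null(declared_total) &&
      abs(grand_mean - declared_total) > 0.001) {
    flags <- sprintf(paste0("declared average total %.3f mg/g disagrees ",
                            "with recomputed %.3f mg/g"),
                     declared_total, grand_mean)
  }
  structure(list(batch_sum = batch_sum,
                 compound_average = compound_average,
                 compound_rsd = compound_rsd,
                 grand_mean = grand_mean,
                 flags = flags),
            class = "content_summary")
}

#' @export
print.content_summary <- function(x, ...) {
  cat("<content_summary>\n")
  df <- data.frame(average = round_half_up(x$compound_average, 3),
                   rsd_pct = x$compound_rsd)
  print(df)
  cat(sprintf("grand mean of batch totals: %.3f mg/g\n", x$grand_mean))
  for (f in x$flags) cat("FLAG:", f, "\n")
  invisible(x)
}

#' Assemble a per-compound method-validation report
#'
#' Combines the individual validation computations into one table. Each
#' input is optional; missing inputs give `NA` columns.
#'
#' @param dilution Data frame `compound`, `ng`, `signal`, `noise` (for
#'   LOD/LOQ).
#' @param intraday,interday,repeatability,stability Data frames `compound`,
#'   `value` of replicate measurements (peak areas or contents); summarised
#'   as RSDs.
#' @param recovery_data Data frame `compound`, `original_ug`, `spiked_ug`,
#'   `observed_ug`, one row per replicate (or one row of means).
#' @return Data frame with one row per compound: `compound`, `lod_ng`,
#'   `loq_ng`, `intraday_rsd`, `interday_rsd`, `repeatability_rsd`,
#'   `stability_rsd`, `recovery_mean`, `recovery_rsd`.
#' @export
validation_report <- function(dilution = NULL, intraday = NULL,
                              interday = NULL, repeatability = NULL,
                              stability = NULL, recovery_data = NULL) {
  ids <- sort(unique(c(
    if (!is.null(dilution)) dilution$compound,
    if (!is.null(intraday)) intraday$compound,
    if (!is.null(interday)) interday$compound,
    if (!is.null(repeatability)) repeatability$compound,
    if (!is.null(stability)) stability$compound,
    if (!is.null(recovery_data)) recovery_data$compound
  )))
  if (!length(ids)) stop("no validation inputs supplied")

  rsd_of <- function(df, id) {
    if (is.null(df)) return(NA_real_)
    v <- df$value[df$compound == id]
    if (length(v) < 2) NA_real_ else rsd(v)
  }
  rows <- lapply(ids, function(id) {
    lod <- loq <- NA_real_
    if (!is.null(dilution)) {
      d <- dilution[dilution$compound == id, , drop = FALSE]
      d <- d[order(d$ng), , drop = FALSE]
      if (nrow(d)) {
        ll <- lod_loq(d)
        lod <- ll$lod_ng; loq <- ll$loq_ng
      }
    }
    rec_mean <- rec_rsd <- NA_real_
    if (!is.null(recovery_data)) {
      r <- recovery_data[recovery_data$compound == id, , drop = FALSE]
      if (nrow(r)) {
        recs <- recovery(r$original_ug, r$spiked_ug, r$observed_ug,
                         digits = NULL)
        rec_mean <- round_half_up(mean(recs), 2)
        rec_rsd <- if (length(recs) >= 2) rsd(recs) else NA_real_
      }
    }
    data.frame(compound = id, lod_ng = lod, loq_ng = loq,
               intraday_rsd = rsd_of(intraday, id),
               interday_rsd = rsd_of(interday, id),
               repeatability_rsd = rsd_of(repeatability, id),
               stability_rsd = rsd_of(stability, id),
               recovery_mean = rec_mean, recovery_rsd = rec_rsd)
  })
  out <- do.call(rbind, rows)
  row.names(out) <- NULL
  out
}
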