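# Calibration: log10-linear transfer function between inverted-gray mean
# pixel intensity and iron concentration, plus the assay's figures of merit
# (working range, LOD, sensitivity) and inverse prediction of samples.

#' Build a calibration standards table
#'
#' Standards are stored long: one row per replicate spot, with the known
#' concentration (ug Fe/mL) and the measured mean pixel intensity
#' (inverted-gray units, 0-255). Zero-concentration rows are legal — they
#' are excluded from the log-linear fit but are the blanks used for the
#' limit of detection.
#'
#' @param concentration numeric vector of concentrations, ug Fe/mL, >= 0.
#' @param intensity numeric vector of replicate mean intensities, same
#'   length, each in `[0, 255]`.
#' @return A `data.frame` with columns `concentration` and `intensity`.
#' @export
calibration_standards <- function(concentration, intensity) {
  if (length(concentration) != length(intensity))
    fp_stop("`concentration` and `intensity` must have equal length",
            "fp_invalid_input")
  if (any(!is.finite(concentration)) || any(concentration < 0))
    fp_stop("concentrations must be finite and >= 0", "fp_invalid_input")
  if (any(!is.finite(intensity)))
    fp_stop("intensities must be finite", "fp_invalid_input")
  data.frame(concentration = as.numeric(concentration),
             intensity = as.numeric(intensity))
}

new_calibration_curve <- function(slope, intercept, r_squared,
                                  log_base = 10, n = NA_integer_,
                                  range_low = NA_real_, range_high = NA_real_,
                                  lod = NA_real_,
                                  grayscale_method = NA_character_) {
  structure(list(slope = slope, intercept = intercept,
                 r_squared = r_squared, log_base = log_base, n = n,
                 range_low = range_low, range_high = range_high, lod = lod,
                 grayscale_method = grayscale_method),
            class = "calibration_curve")
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf("Calibration: intensity = %.4g * log%g(conc) + %.4g  (R2 = %.4f, n = %s)\n",
              x$slope, x$log_base, x$intercept, x$r_squared,
              ifelse(is.na(x$n), "?", x$n)))
  if (!is.na(x$range_low))
    cat(sprintf("  working range: %g - %g ug/mL\n", x$range_low, x$range_high))
  if (!is.na(x$lod))
    cat(sprintf("  LOD: %.4g ug/mL\n", x$lod))
  invisible(x)
}

curve_usable <- function(curve) is.finite(curve$slope) && curve$slope > 0

#' Fit the log-linear calibration curve
#'
#' Ordinary least squares of mean pixel intensity on the log10 of the
#' standard concentration, over all replicate rows. Zero-concentration
#' standards are excluded (their log is undefined); keep them in the table
#' for [compute_lod()].
#'
#' @param standards a standards table from [calibration_standards()] or
#'   [read_standards_csv()].
#' @param log_base logarithm base for the concentration axis; base 10 is the
#'   analytical-chemistry convention and the default.
#' @param grayscale_method optional label recorded in the curve so a
#'   quantification is reproducible from the serialized curve alone.
#' @return A `calibration_curve` with `slope`, `intercept` (intensity at
#'   1 ug/mL), `r_squared`, `log_base` and `n`. A non-positive slope yields
#'   a warning: the curve cannot be inverted.
#' @export
fit_calibration <- function(standards, log_base = 10,
                            grayscale_method = NA_character_) {
  st <- standards[standards$concentration > 0, , drop = FALSE]
  if (length(unique(st$concentration)) < 3L)
    fp_stop("need >= 3 distinct nonzero concentration levels",
            "fp_insufficient_data")
  x <- log(st$concentration, base = log_base)
  fit <- lm(st$intensity ~ x)
  # noiseless synthetic standards fit exactly; the perfect-fit warning from
  # summary.lm is expected there, not informative
  r2 <- suppressWarnings(summary(fit)$r.squared)
  curve <- new_calibration_curve(
    slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
    r_squared = r2, log_base = log_base, n = nrow(st),
    grayscale_method = grayscale_method
  )
  if (!curve_usable(curve))
    warning("fitted slope is not positive; curve is unusable for ",
            "quantification", call. = FALSE)
  curve
}

#' Determine the assay's working range
#'
#' The working range is the widest contiguous run of standard levels over
#' which intensity is linear against log concentration: the OLS fit on the
#' replicates of those levels must have R^2 above `r2_threshold` (default
#' 0.95) and a positive slope. Ties between equally wide runs are broken
#' toward the run with more levels, then toward the lower starting level.
#'
#' @inheritParams fit_calibration
#' @param r2_threshold minimum coefficient of determination for a run to
#'   qualify.
#' @param min_levels minimum number of contiguous levels in a run.
#' @return Named numeric vector `c(range_low, range_high)` in ug/mL.
#' @export
determine_working_range <- function(standards, r2_threshold = 0.95,
                                    min_levels = 3L, log_base = 10) {
  st <- standards[standards$concentration > 0, , drop = FALSE]
  levels <- sort(unique(st$concentration))
  if (length(levels) < min_levels)
    fp_stop("need >= 3 distinct nonzero concentration levels",
            "fp_insufficient_data")
  best <- NULL
  for (i in seq_along(levels)) {
    if (i + min_levels - 1L > length(levels)) break
    for (j in seq(i + min_levels - 1L, length(levels))) {
      run <- levels[i:j]
      rows <- st[st$concentration %in% run, ]
      fit <- lm(rows$intensity ~ log(rows$concentration, base = log_base))
      r2 <- suppressWarnings(summary(fit)$r.squared)
      slope <- unname(coef(fit)[2])
      if (!is.finite(r2) || r2 <= r2_threshold || !is.finite(slope) ||
          slope <= 0) next
      cand <- list(low = run[1], high = run[length(run)],
                   span = run[length(run)] - run[1], nlev = length(run))
      if (is.null(best) ||
          cand$span > best$span ||
          (cand$span == best$span && cand$nlev > best$nlev) ||
          (cand$span == best$span && cand$nlev == best$nlev &&
           cand$low < best$low))
        best <- cand
    }
  }
  if (is.null(best))
    fp_stop("no contiguous run of levels is linear at the required R^2",
            "fp_no_working_range")
  c(range_low = best$low, range_high = best$high)
}

#' Limit of detection from blank replicates
#'
#' The intensity threshold is the blank mean plus three blank standard
#' deviations; the LOD is that threshold mapped back through the calibration
#' curve to a concentration.
#'
#' @param blank_intensities numeric vector of blank (reagents-only) mean
#'   pixel intensities, n >= 2.
#' @param curve a usable `calibration_curve`.
#' @return LOD in ug Fe/mL.
#' @export
compute_lod <- function(blank_intensities, curve) {
  if (length(blank_intensities) < 2L)
    fp_stop("need >= 2 blank replicates for an SD", "fp_insufficient_data")
  if (!curve_usable(curve))
    fp_stop("curve slope must be positive", "fp_unusable_curve")
  threshold <- mean(blank_intensities) + 3 * sd(blank_intensities)
  curve$log_base^((threshold - curve$intercept) / curve$slope)
}

#' Detectable iron mass in a deposited aliquot
#'
#' Converts an LOD concentration into the iron mass contained in the dried
#' sample aliquot (1 ug/mL x 1 uL = 1 ng), rounded to 3 significant figures.
#'
#' @param lod_concentration LOD in ug Fe/mL.
#' @param deposition_volume_ul deposited aliquot volume in uL.
#' @return Mass in ng, 3 significant figures.
#' @examples
#' lod_mass(3.691, 5) # 18.5 ng
#' @export
lod_mass <- function(lod_concentration, deposition_volume_ul) {
  if (lod_concentration <= 0 || deposition_volume_ul <= 0)
    fp_stop("concentration and volume must be positive", "fp_invalid_input")
  signif(lod_concentration * deposition_volume_ul, 3)
}

#' Assay sensitivity over the working range
#'
#' Change in output response per unit change in concentration between the
#' working-range endpoints, computed from the observed level means:
#' `(mean intensity at range_high - mean intensity at range_low) /
#' (range_high - range_low)`.
#'
#' @inheritParams fit_calibration
#' @param range numeric length-2, the working range endpoints (ug/mL); both
#'   must be standard levels present in `standards`.
#' @return Sensitivity in intensity units per (ug/mL).
#' @export
sensitivity <- function(standards, range) {
  lo <- range[[1]]; hi <- range[[2]]
  m_lo <- standards$intensity[standards$concentration == lo]
  m_hi <- standards$intensity[standards$concentration == hi]
  if (length(m_lo) == 0L || length(m_hi) == 0L)
    fp_stop("range endpoints not present among the standards",
            "fp_invalid_input")
  (mean(m_hi) - mean(m_lo)) / (hi - lo)
}

#' Invert the calibration curve
#'
#' Maps intensity back to concentration:
#' `conc = base^((intensity - intercept) / slope)`. When the curve carries a
#' working range, intensities mapping outside it trigger a warning (the
#' sample should be re-assayed at a different dilution); the value is still
#' returned.
#'
#' @param curve a usable `calibration_curve`.
#' @param intensity numeric vector of mean pixel intensities.
#' @return Concentration(s) in ug Fe/mL.
#' @export
inverse_predict <- function(curve, intensity) {
  if (!curve_usable(curve))
    fp_stop("curve slope must be positive", "fp_unusable_curve")
  conc <- curve$log_base^((intensity - curve$intercept) / curve$slope)
  if (!is.na(curve$range_low) &&
      any(conc < curve$range_low | conc > curve$range_high))
    warning("prediction outside the working range [",
            curve$range_low, ", ", curve$range_high, "] ug/mL",
            call. = FALSE)
  conc
}

#' Sample preparation parameters
#'
#' Records how the food extract was prepared, so extract concentrations
#' (ug Fe/mL) can be converted to food concentrations (ug Fe/g):
#' `food = extract * (extraction_volume / sample_mass) * extra_dilution`.
#'
#' @param sample_mass_g mass of food extracted, g.
#' @param extraction_volume_ml volume of acid extractant, mL.
#' @param extra_dilution additional dilution factor applied to the extract
#'   before deposition (>= 1; 1 = none).
#' @param deposition_volume_ul aliquot deposited on the paper, uL.
#' @return An object of class `sample_prep`.
#' @examples
#' sample_prep(2.5, 10)  # 2.5 g in 10 mL: 10 ug/mL extract -> 40 ug/g food
#' @export
sample_prep <- function(sample_mass_g, extraction_volume_ml,
                        extra_dilution = 1, deposition_volume_ul = 5) {
  vals <- c(sample_mass_g, extraction_volume_ml, extra_dilution,
            deposition_volume_ul)
  if (any(!is.finite(vals)) || any(vals <= 0))
    fp_stop("all sample-prep quantities must be positive",
            "fp_invalid_input")
  if (extra_dilution < 1)
    fp_stop("`extra_dilution` must be >= 1", "fp_invalid_input")
  structure(list(sample_mass_g = sample_mass_g,
                 extraction_volume_ml = extraction_volume_ml,
                 extra_dilution = extra_dilution,
                 deposition_volume_ul = deposition_volume_ul),
            class = "sample_prep")
}

#' Quantify a sample from replicate spot intensities
#'
#' Each replicate intensity is inverted through the calibration curve; the
#' replicate concentrations are averaged (averaging in concentration space
#' is the default; intensity-space averaging is available), and the mean
#' extract concentration is converted to the food concentration using the
#' sample-prep dilution factors.
#'
#' @param curve a usable `calibration_curve`.
#' @param measurements replicate measurements: a numeric vector of mean
#'   intensities, or a list of `intensity_measurement` objects from
#'   [mean_roi_intensity()].
#' @param prep a [sample_prep()].
#' @param average `"concentration"` (default) to average replicate
#'   concentrations, or `"intensity"` to average intensities before a single
#'   inverse prediction.
#' @return A list of class `quant_result`: `extract_concentration` (ug/mL),
#'   `food_concentration` (ug/g), `replicate_concentrations`, `cv_percent`
#'   (over replicate concentrations), `in_range` (TRUE iff every replicate
#'   falls inside the curve's working range; NA when the curve has none).
#' @export
quantify_sample <- function(curve, measurements, prep,
                            average = c("concentration", "intensity")) {
  average <- match.arg(average)
  if (is.list(measurements))
    measurements <- vapply(measurements, function(m) m$mean_intensity, 0)
  if (length(measurements) < 1L)
    fp_stop("need >= 1 replicate measurement", "fp_invalid_input")
  if (!inherits(prep, "sample_prep"))
    fp_stop("`prep` must be a sample_prep", "fp_invalid_input")
  conc <- suppressWarnings(inverse_predict(curve, measurements))
  extract <- if (average == "concentration") mean(conc) else
    suppressWarnings(inverse_predict(curve, mean(measurements)))
  food <- extract * (prep$extraction_volume_ml / prep$sample_mass_g) *
    prep$extra_dilution
  cv <- if (length(conc) > 1L) 100 * sd(conc) / mean(conc) else 0
  in_range <- if (is.na(curve$range_low)) NA else
    all(conc >= curve$range_low & conc <= curve$range_high)
  structure(list(extract_concentration = extract,
                 food_concentration = food,
                 replicate_concentrations = conc,
                 cv_percent = cv, in_range = in_range),
            class = "quant_result")
}

#' @export
print.quant_result <- function(x, ...) {
  cat(sprintf("extract %.4g ug Fe/mL -> food %.4g ug Fe/g (CV %.1f%%, n = %d%s)\n",
              x$extract_concentration, x$food_concentration, x$cv_percent,
              length(x$replicate_concentrations),
              if (isTRUE(x$in_range)) "" else
                if (isFALSE(x$in_range)) ", OUT OF RANGE" else ""))
  invisible(x)
}

#' Serialize a calibration curve to JSON
#'
#' The JSON records slope, intercept, R^2, log base, working range, LOD and
#' the grayscale method, so a quantification is reproducible from the file
#' alone.
#'
#' @param curve a `calibration_curve`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_calibration_json <- function(curve, path) {
  jsonlite::write_json(
    list(slope = curve$slope, intercept = curve$intercept,
         r_squared = curve$r_squared, log_base = curve$log_base,
         n = curve$n, range_low = curve$range_low,
         range_high = curve$range_high, lod = curve$lod,
         grayscale_method = curve$grayscale_method),
    path, auto_unbox = TRUE, digits = NA, null = "null", na = "null")
  invisible(path)
}

#' Read a calibration curve from JSON
#'
#' @param path path to a file written by [write_calibration_json()].
#' @return A `calibration_curve`.
#' @export
read_calibration_json <- function(path) {
  if (!file.exists(path))
    fp_stop(paste0("curve file not found: ", path), "fp_io_error")
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  num <- function(v) if (is.null(v) || length(v) == 0) NA_real_ else as.numeric(v)
  new_calibration_curve(
    slope = num(j$slope), intercept = num(j$intercept),
    r_squared = num(j$r_squared),
    log_base = if (is.null(j$log_base)) 10 else j$log_base,
    n = if (is.null(j$n)) NA_integer_ else as.integer(j$n),
    range_low = num(j$range_low), range_high = num(j$range_high),
    lod = num(j$lod),
    grayscale_method = if (is.null(j$grayscale_method)) NA_character_
                       else j$grayscale_method)
}

parse_roi_string <- function(s) {
  v <- suppressWarnings(as.numeric(strsplit(trimws(s), ",")[[1]]))
  if (length(v) != 3L || anyNA(v))
    fp_stop("ROI must be 'row,col,radius'", "fp_invalid_input")
  circular_roi(v[1], v[2], v[3])
}

#' Read a calibration standards CSV
#'
#' Two schemas are accepted. Tabulated intensities:
#' `concentration_ug_per_ml, intensity` (one row per replicate). Image
#' references: `concentration_ug_per_ml, image, roi` where `roi` is
#' `"row,col,radius"` (0-based pixel coordinates) or `"auto"` for spot
#' detection; each image is processed through grayscale conversion and
#' inversion before the ROI mean is taken.
#'
#' @param path CSV path.
#' @param grayscale_method passed to [to_grayscale()] for the image schema.
#' @param base_dir directory against which relative image paths are
#'   resolved; defaults to the CSV's directory.
#' @return A standards table (columns `concentration`, `intensity`).
#' @export
read_standards_csv <- function(path, grayscale_method = "unweighted_mean",
                               base_dir = dirname(path)) {
  if (!file.exists(path))
    fp_stop(paste0("standards file not found: ", path), "fp_io_error")
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!"concentration_ug_per_ml" %in% names(df))
    fp_stop("standards CSV needs a `concentration_ug_per_ml` column",
            "fp_schema_error")
  if ("intensity" %in% names(df)) {
    if (!is.numeric(df$intensity) ||
        !is.numeric(df$concentration_ug_per_ml) || anyNA(df$intensity) ||
        anyNA(df$concentration_ug_per_ml))
      fp_stop("standards CSV columns must be numeric and complete",
              "fp_schema_error")
    return(calibration_standards(df$concentration_ug_per_ml, df$intensity))
  }
  if (!all(c("image", "roi") %in% names(df)))
    fp_stop("standards CSV needs `intensity` or `image` + `roi` columns",
            "fp_schema_error")
  intensity <- vapply(seq_len(nrow(df)), function(i) {
    img_path <- df$image[i]
    if (!file.exists(img_path))
      img_path <- file.path(base_dir, df$image[i])
    g <- invert_gray(to_grayscale(read_assay_image(img_path),
                                  grayscale_method))
    roi <- if (identical(trimws(df$roi[i]), "auto")) detect_spot(g)
           else parse_roi_string(df$roi[i])
    mean_roi_intensity(g, roi)$mean_intensity
  }, 0)
  calibration_standards(df$concentration_ug_per_ml, intensity)
}

#' Read sample-prep parameters from YAML
#'
#' Expected keys: `sample_mass_g`, `extraction_volume_ml`, and optionally
#' `extra_dilution` (default 1) and `deposition_volume_ul` (default 5).
#'
#' @param path YAML path.
#' @return A [sample_prep()].
#' @export
read_prep_yaml <- function(path) {
  if (!file.exists(path))
    fp_stop(paste0("prep file not found: ", path), "fp_io_error")
  y <- yaml::read_yaml(path)
  if (is.null(y$sample_mass_g) || is.null(y$extraction_volume_ml))
    fp_stop("prep YAML needs `sample_mass_g` and `extraction_volume_ml`",
            "fp_schema_error")
  sample_prep(y$sample_mass_g, y$extraction_volume_ml,
              extra_dilution = if (is.null(y$extra_dilution)) 1
                               else y$extra_dilution,
              deposition_volume_ul = if (is.null(y$deposition_volume_ul)) 5
                                     else y$deposition_volume_ul)
}
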