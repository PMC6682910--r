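# Validation: figures of merit and error analysis for the assay —
# apparent spike recovery, interference bias, within-day random error, and
# method comparison against a gold-standard (AES) reference.
#
# Sample standard deviations (n - 1 denominator) are used throughout,
# matching spreadsheet defaults.

#' Apparent recovery of a spike
#'
#' `R_A = (original_plus_spike - original) / spike`: the fraction of a known
#' iron spike the assay recovers. Scale-invariant: multiplying all three
#' inputs by the same nonzero factor leaves it unchanged.
#'
#' @param original_plus_spike assay output of the spiked sample.
#' @param original assay output of the unspiked sample.
#' @param spike known added amount (same units as the outputs), nonzero.
#' @param spike_level optional label for the spike level (for reports).
#' @return A list of class `recovery_result` with `r_a` (fraction),
#'   `percent` and `spike_level`.
#' @examples
#' apparent_recovery(33.66, 10, 20)$percent # 118.3
#' @export
apparent_recovery <- function(original_plus_spike, original, spike,
                              spike_level = NA) {
  if (!is.finite(spike) || spike == 0)
    fp_stop("`spike` must be nonzero", "fp_invalid_input")
  r_a <- (original_plus_spike - original) / spike
  structure(list(r_a = r_a, percent = 100 * r_a, spike_level = spike_level),
            class = "recovery_result")
}

#' @export
print.recovery_result <- function(x, ...) {
  cat(sprintf("apparent recovery: %.1f%%\n", x$percent))
  invisible(x)
}

#' Interference bias of a co-occurring mineral
#'
#' Difference between the mean measured iron with an interferent present and
#' the mean without it, on identically fortified matrix. Antisymmetric:
#' swapping the argument roles negates the difference.
#'
#' @param with_interferent replicate measurements (ug Fe/g) with the
#'   interferent present.
#' @param without_interferent replicate measurements (ug Fe/g) of the
#'   interferent-free baseline.
#' @param interferent optional label (e.g. `"Zn"`).
#' @param amount_ug_per_g optional amount of interferent added, ug/g.
#' @return A list of class `interference_result` with `mean_with`,
#'   `mean_without`, `difference` (ug Fe/g) and `difference_2dp` (the value
#'   rounded to 2 decimals for report tables).
#' @export
interference_bias <- function(with_interferent, without_interferent,
                              interferent = NA_character_,
                              amount_ug_per_g = NA_real_) {
  if (length(with_interferent) < 1L || length(without_interferent) < 1L)
    fp_stop("need >= 1 replicate in each group", "fp_invalid_input")
  m_w <- mean(with_interferent)
  m_wo <- mean(without_interferent)
  structure(list(interferent = interferent,
                 amount_ug_per_g = amount_ug_per_g,
                 mean_with = m_w, mean_without = m_wo,
                 difference = m_w - m_wo,
                 difference_2dp = round(m_w - m_wo, 2)),
            class = "interference_result")
}

#' @export
print.interference_result <- function(x, ...) {
  cat(sprintf("%s: %.2f ug Fe/g (with %.2f, without %.2f)\n",
              ifelse(is.na(x$interferent), "interferent", x$interferent),
              x$difference, x$mean_with, x$mean_without))
  invisible(x)
}

#' Average interference over a panel of interferents
#'
#' Arithmetic mean of the per-interferent mean differences — the overall
#' systematic error attributable to naturally co-occurring minerals.
#'
#' @param results a list of `interference_result` objects from
#'   [interference_bias()], or a numeric vector of differences.
#' @return Mean interference in ug Fe/g.
#' @export
average_interference <- function(results) {
  if (is.list(results) && !is.numeric(results))
    results <- vapply(results, function(r) r$difference, 0)
  if (length(results) < 1L)
    fp_stop("need >= 1 interference result", "fp_invalid_input")
  mean(results)
}

#' Within-day replication (random error)
#'
#' Random error of the assay expressed as the coefficient of variation of
#' within-day replicate measurements of one sample:
#' `%CV = (SD / mean) * 100` with the sample SD.
#'
#' @param values replicate measurements (ug Fe/g), n >= 2.
#' @return A list of class `replication_result` with `mean`, `sd`,
#'   `cv_percent` and `n`.
#' @export
within_day_replication <- function(values) {
  if (length(values) < 2L)
    fp_stop("need >= 2 replicates for a CV", "fp_insufficient_data")
  m <- mean(values)
  s <- sd(values)
  structure(list(mean = m, sd = s, cv_percent = 100 * s / m,
                 n = length(values)),
            class = "replication_result")
}

#' @export
print.replication_result <- function(x, ...) {
  cat(sprintf("%.4g +/- %.4g ug/g (CV %.1f%%, n = %d)\n",
              x$mean, x$sd, x$cv_percent, x$n))
  invisible(x)
}

#' Method comparison against a reference method
#'
#' Compares paired measurements of the same samples by the candidate
#' (paper-based) and reference (e.g. atomic emission spectroscopy) methods:
#' Pearson correlation, mean-difference bias (systematic error), SD of the
#' differences, Bland-Altman limits of agreement `bias +/- loa_k * sd_diff`,
#' and a two-sided paired t-test.
#'
#' When the differences have zero variance the t statistic is defined by
#' continuity: 0 (p = 1) for zero bias, signed infinity (p = 0) otherwise.
#'
#' @param test_values candidate-method measurements (ug Fe/g).
#' @param reference_values reference-method measurements, same order/length.
#' @param loa_k limits-of-agreement multiplier; default 2, with 1.96
#'   available for the conventional 95% normal limits.
#' @return A list of class `method_comparison_result` with `pearson_r`,
#'   `bias`, `sd_diff`, `loa_low`, `loa_high`, `t_statistic`, `p_value`,
#'   `n`, `loa_k`, and the `differences` and `pair_means` used (for
#'   Bland-Altman plotting).
#' @export
method_comparison <- function(test_values, reference_values, loa_k = 2) {
  if (length(test_values) != length(reference_values))
    fp_stop("paired vectors must have equal length", "fp_invalid_input")
  n <- length(test_values)
  if (n < 3L)
    fp_stop("need >= 3 pairs", "fp_insufficient_data")
  if (sd(test_values) == 0 || sd(reference_values) == 0)
    fp_stop("zero variance in one method: correlation undefined",
            "fp_degenerate_data")
  d <- test_values - reference_values
  bias <- mean(d)
  sd_diff <- sd(d)
  r <- cor(test_values, reference_values)
  tt <- if (sd_diff > 0)
    tryCatch(t.test(test_values, reference_values, paired = TRUE),
             error = function(e) NULL)  # near-constant differences
  else NULL
  if (!is.null(tt)) {
    t_stat <- unname(tt$statistic)
    p <- tt$p.value
  } else {
    t_stat <- if (bias == 0) 0 else sign(bias) * Inf
    p <- if (bias == 0) 1 else 0
  }
  structure(list(pearson_r = r, bias = bias, sd_diff = sd_diff,
                 loa_low = bias - loa_k * sd_diff,
                 loa_high = bias + loa_k * sd_diff,
                 t_statistic = t_stat, p_value = p, n = n, loa_k = loa_k,
                 differences = d,
                 pair_means = (test_values + reference_values) / 2),
            class = "method_comparison_result")
}

#' @export
print.method_comparison_result <- function(x, ...) {
  cat(sprintf("bias %+.4g +/- %.4g ug/g; r = %.3f; LoA [%.4g, %.4g] (k = %g); paired t = %.3g, p = %.3g, n = %d\n",
              x$bias, x$sd_diff, x$pearson_r, x$loa_low, x$loa_high,
              x$loa_k, x$t_statistic, x$p_value, x$n))
  invisible(x)
}

#' Bland-Altman plot of a method comparison
#'
#' Differences against pair means with the bias line and limits of
#' agreement.
#'
#' @param comparison a `method_comparison_result`.
#' @param ... passed to [plot()].
#' @return The comparison, invisibly.
#' @export
plot_bland_altman <- function(comparison, ...) {
  plot(comparison$pair_means, comparison$differences,
       xlab = "mean of methods (ug Fe/g)",
       ylab = "difference, test - reference (ug Fe/g)", ...)
  graphics::abline(h = comparison$bias, lty = 1)
  graphics::abline(h = c(comparison$loa_low, comparison$loa_high), lty = 2)
  invisible(comparison)
}

#' Read a method-comparison CSV
#'
#' Schema: `sample_id, paper_ug_per_g, reference_ug_per_g`.
#'
#' @param path CSV path.
#' @return A data.frame with those columns.
#' @export
read_method_comparison_csv <- function(path) {
  if (!file.exists(path))
    fp_stop(paste0("file not found: ", path), "fp_io_error")
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "paper_ug_per_g", "reference_ug_per_g")
  if (!all(need %in% names(df)))
    fp_stop(paste("method-comparison CSV needs columns:",
                  paste(need, collapse = ", ")), "fp_schema_error")
  if (!is.numeric(df$paper_ug_per_g) || !is.numeric(df$reference_ug_per_g) ||
      anyNA(df$paper_ug_per_g) || anyNA(df$reference_ug_per_g))
    fp_stop("measurement columns must be numeric and complete",
            "fp_schema_error")
  df
}

#' Read an interference CSV
#'
#' Schema: `interferent, amount_ug_per_g, measurement_ug_per_g`, with the
#' baseline group labelled `none`.
#'
#' @param path CSV path.
#' @return A data.frame with those columns.
#' @export
read_interference_csv <- function(path) {
  if (!file.exists(path))
    fp_stop(paste0("file not found: ", path), "fp_io_error")
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("interferent", "amount_ug_per_g", "measurement_ug_per_g")
  if (!all(need %in% names(df)))
    fp_stop(paste("interference CSV needs columns:",
                  paste(need, collapse = ", ")), "fp_schema_error")
  if (!any(df$interferent == "none"))
    fp_stop("interference CSV needs a `none` baseline group",
            "fp_schema_error")
  if (!is.numeric(df$measurement_ug_per_g) || anyNA(df$measurement_ug_per_g))
    fp_stop("`measurement_ug_per_g` must be numeric and complete",
            "fp_schema_error")
  df
}

#' Interference study from a grouped table
#'
#' Applies [interference_bias()] to every interferent group against the
#' `none` baseline and appends the [average_interference()].
#'
#' @param df a data.frame as returned by [read_interference_csv()].
#' @return A list with `results` (list of `interference_result`, in first
#'   appearance order) and `average` (ug Fe/g).
#' @export
interference_study <- function(df) {
  base <- df$measurement_ug_per_g[df$interferent == "none"]
  groups <- unique(df$interferent[df$interferent != "none"])
  if (length(groups) == 0L)
    fp_stop("no interferent groups beside the baseline", "fp_invalid_input")
  results <- lapply(groups, function(g) {
    rows <- df[df$interferent == g, ]
    interference_bias(rows$measurement_ug_per_g, base, interferent = g,
                      amount_ug_per_g = rows$amount_ug_per_g[1])
  })
  list(results = results, average = average_interference(results))
}
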