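# Synthetic fixtures: rendered assay-spot images and tabular datasets with
# the statistical structure the assay assumes, so every pipeline stage is
# testable without a real photograph.

# Evaluate expr under a temporary RNG state; NULL seed leaves the RNG alone.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Describe a synthetic assay-spot scene
#'
#' A scene fixes everything needed to render a paper-spot photograph whose
#' *inverted* unweighted-mean grayscale intensity inside the spot has
#' expectation `slope * log10(true_concentration) + intercept`, plus iid
#' Gaussian pixel noise. The `streaky` heterogeneity adds a low-frequency
#' multiplicative field across the spot, emulating the uneven colour
#' development seen on plain cellulose filter papers (capillary streaking),
#' as opposed to the near-uniform spots on hydrophobic silicone-treated
#' paper.
#'
#' @param true_concentration iron concentration the spot represents,
#'   ug Fe/mL (> 0).
#' @param slope,intercept generating transfer function (inverted-gray
#'   intensity per log10 ug/mL, and intensity at 1 ug/mL).
#' @param canvas_height,canvas_width canvas size in pixels.
#' @param spot_center 0-based (row, col) of the spot centre.
#' @param spot_radius spot radius in pixels; the disc must fit the canvas.
#' @param background_intensity inverted-gray background level (paper is
#'   near-white, so near 0 on the inverted scale).
#' @param noise_sd per-pixel Gaussian noise SD, intensity units, >= 0.
#' @param heterogeneity `"uniform"` or `"streaky"`.
#' @param streak_amplitude relative amplitude of the streak field (only used
#'   when `heterogeneity = "streaky"`).
#' @param seed integer seed making the rendering reproducible; `NULL` uses
#'   the current RNG state.
#' @return An object of class `spot_scene`.
#' @export
spot_scene <- function(true_concentration, slope = 47.01, intercept = 126.18,
                       canvas_height = 160, canvas_width = 160,
                       spot_center = c(80, 80), spot_radius = 40,
                       background_intensity = 20, noise_sd = 0,
                       heterogeneity = c("uniform", "streaky"),
                       streak_amplitude = 0.15, seed = NULL) {
  heterogeneity <- match.arg(heterogeneity)
  if (!is.finite(true_concentration) || true_concentration <= 0)
    fp_stop("`true_concentration` must be > 0", "fp_invalid_input")
  if (noise_sd < 0)
    fp_stop("`noise_sd` must be >= 0", "fp_invalid_input")
  if (spot_center[1] - spot_radius < 0 ||
      spot_center[1] + spot_radius > canvas_height - 1 ||
      spot_center[2] - spot_radius < 0 ||
      spot_center[2] + spot_radius > canvas_width - 1)
    fp_stop("spot disc must lie inside the canvas", "fp_invalid_input")
  structure(list(true_concentration = true_concentration, slope = slope,
                 intercept = intercept, canvas_height = canvas_height,
                 canvas_width = canvas_width, spot_center = spot_center,
                 spot_radius = spot_radius,
                 background_intensity = background_intensity,
                 noise_sd = noise_sd, heterogeneity = heterogeneity,
                 streak_amplitude = streak_amplitude, seed = seed),
            class = "spot_scene")
}

#' Render a synthetic assay-spot photograph
#'
#' Draws a magenta disc on a pale background. The disc's colour is chosen so
#' that converting the image with the unweighted-mean grayscale and
#' inverting recovers the per-pixel inverted-gray target exactly (channel
#' sums are constructed to be exactly `3 * (255 - target)`); the only error
#' left in the pipeline is the half-unit quantisation of the target itself.
#'
#' @param scene a [spot_scene()].
#' @return An [rgb_image()].
#' @export
render_spot <- function(scene) {
  if (!inherits(scene, "spot_scene"))
    fp_stop("`scene` must be a spot_scene", "fp_invalid_input")
  target <- scene$slope * log10(scene$true_concentration) + scene$intercept
  if (target < 0 || target > 255)
    fp_stop(sprintf("spot target intensity %.1f outside [0, 255]: scene not representable",
                    target), "fp_unrepresentable_scene")
  if (scene$background_intensity < 0 || scene$background_intensity > 255)
    fp_stop("background intensity outside [0, 255]",
            "fp_unrepresentable_scene")
  h <- scene$canvas_height; w <- scene$canvas_width
  rows <- matrix(seq_len(h) - 1L, h, w)
  cols <- matrix(seq_len(w) - 1L, h, w, byrow = TRUE)
  in_disc <- (rows - scene$spot_center[1])^2 +
    (cols - scene$spot_center[2])^2 <= scene$spot_radius^2
  g_target <- matrix(scene$background_intensity, h, w)
  g_target[in_disc] <- target
  with_seed(scene$seed, {
    if (scene$heterogeneity == "streaky") {
      theta <- runif(1, 0, pi)
      phase <- runif(1, 0, 2 * pi)
      wavelength <- 2 * scene$spot_radius  # one streak cycle across the spot
      field <- 1 + scene$streak_amplitude *
        sin(2 * pi * (cos(theta) * rows + sin(theta) * cols) / wavelength +
            phase)
      g_target[in_disc] <- g_target[in_disc] * field[in_disc]
    }
    if (scene$noise_sd > 0)
      g_target <- g_target + rnorm(h * w, 0, scene$noise_sd)
  })
  g_int <- as.integer(round_half_up(pmin(pmax(g_target, 0), 255)))
  total <- 765L - 3L * g_int
  r <- as.integer(round_half_up(255 - 0.95 * g_int))
  g <- total - 2L * r
  low <- g < 0L
  if (any(low)) {            # very dark spots: fold the deficit into R and B
    g[low] <- 0L
    r[low] <- as.integer(ceiling(total[low] / 2))
  }
  high <- g > 255L           # near-white: cap green, pad R and B
  if (any(high)) {
    g[high] <- 255L
    r[high] <- as.integer(ceiling((total[high] - 255L) / 2))
  }
  b <- total - r - g
  px <- array(0L, dim = c(h, w, 3L))
  px[, , 1] <- r; px[, , 2] <- g; px[, , 3] <- b
  rgb_image(px)
}

#' Generate a synthetic calibration dataset
#'
#' Draws replicate mean intensities around the generating line
#' `slope * log10(c) + intercept` with Gaussian noise. Zero-concentration
#' levels are generated around `blank_intensity` (the flat response of
#' reagents alone); an optional `response_floor` flattens the low end of the
#' curve, emulating levels below the assay's useful range.
#'
#' @param levels concentration levels, ug Fe/mL (0 allowed).
#' @param reps replicates per level, >= 1.
#' @param slope,intercept generating transfer function.
#' @param noise_sd intensity noise SD, >= 0.
#' @param blank_intensity expected intensity at concentration 0.
#' @param response_floor optional lower bound applied to the generating line
#'   (`NA` for none).
#' @param flat_below optional concentration (ug/mL) below which the response
#'   plateaus at `blank_intensity`, emulating levels under the assay's
#'   working range (`NA` for none).
#' @param seed integer seed; `NULL` uses the current RNG state.
#' @return A standards table (columns `concentration`, `intensity`).
#' @export
generate_calibration_dataset <- function(levels, reps, slope = 47.01,
                                         intercept = 126.18, noise_sd = 0,
                                         blank_intensity = 100,
                                         response_floor = NA,
                                         flat_below = NA, seed = NULL) {
  if (reps < 1L) fp_stop("`reps` must be >= 1", "fp_invalid_input")
  conc <- rep(levels, each = reps)
  target <- ifelse(conc == 0, blank_intensity,
                   slope * log10(pmax(conc, .Machine$double.xmin)) + intercept)
  if (!is.na(response_floor)) target <- pmax(target, response_floor)
  if (!is.na(flat_below)) target[conc < flat_below] <- blank_intensity
  intensity <- with_seed(seed,
                         target + rnorm(length(target), 0, noise_sd))
  calibration_standards(conc, intensity)
}

#' Generate a synthetic paired method-comparison dataset
#'
#' Reference-method values are drawn uniformly over a concentration range
#' and perturbed by the reference method's own relative error
#' (`reference_cv`); candidate-method values are the reference plus a
#' Normal(bias, sd_diff) error, so the generating systematic error and
#' difference SD are exactly `bias` and `sd_diff`.
#'
#' @param n number of paired samples, >= 3.
#' @param concentration_range length-2, ug Fe/g. The default spans
#'   unfortified through highly fortified foods (10-110 ug/g), whose
#'   dispersion, combined with the default error structure, yields a
#'   test-reference correlation in the high-0.8s typical of such studies.
#' @param bias generating systematic error, ug Fe/g.
#' @param sd_diff generating SD of the paired differences, ug Fe/g.
#' @param reference_cv relative error of the reference method, percent.
#' @param seed integer seed; `NULL` uses the current RNG state.
#' @return A data.frame with columns `sample_id`, `paper_ug_per_g`,
#'   `reference_ug_per_g`.
#' @export
generate_method_comparison_dataset <- function(n, concentration_range = c(10, 110),
                                               bias = 8.65, sd_diff = 18,
                                               reference_cv = 4.24,
                                               seed = NULL) {
  if (n < 3L) fp_stop("`n` must be >= 3", "fp_invalid_input")
  with_seed(seed, {
    true <- runif(n, concentration_range[1], concentration_range[2])
    reference <- true * (1 + rnorm(n, 0, reference_cv / 100))
    test <- reference + rnorm(n, bias, sd_diff)
    data.frame(sample_id = sprintf("S%03d", seq_len(n)),
               paper_ug_per_g = test, reference_ug_per_g = reference)
  })
}

#' Render a batch of spot images to disk
#'
#' Writes one PNG per concentration/replicate plus a `manifest.csv`
#' (`path, concentration_ug_per_ml, roi`) that [read_standards_csv()] can
#' consume directly (rename the columns or pass the manifest's `image`
#' schema). Used by the CLI `simulate` subcommand.
#'
#' @param dir output directory (created if missing).
#' @param concentrations vector of ug Fe/mL values, one spot batch each.
#' @param reps replicates per concentration.
#' @param noise_sd,heterogeneity,seed passed to [spot_scene()]; each image
#'   gets a distinct sub-seed derived from `seed`.
#' @param ... further arguments to [spot_scene()].
#' @return Path to the manifest CSV, invisibly.
#' @export
simulate_spot_images <- function(dir, concentrations, reps = 3,
                                 noise_sd = 2, heterogeneity = "uniform",
                                 seed = 1, ...) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- list()
  k <- 0L
  for (conc in concentrations) {
    for (r in seq_len(reps)) {
      k <- k + 1L
      scene <- spot_scene(conc, noise_sd = noise_sd,
                          heterogeneity = heterogeneity,
                          seed = seed + k, ...)
      img <- render_spot(scene)
      fname <- sprintf("spot_c%g_r%d.png", conc, r)
      png::writePNG(img$pixels / 255, file.path(dir, fname))
      rows[[k]] <- data.frame(
        image = fname, concentration_ug_per_ml = conc,
        roi = sprintf("%g,%g,%g", scene$spot_center[1],
                      scene$spot_center[2], scene$spot_radius))
    }
  }
  manifest <- do.call(rbind, rows)
  out <- file.path(dir, "manifest.csv")
  write.csv(manifest, out, row.names = FALSE)
  invisible(out)
}
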