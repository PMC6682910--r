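# Independent oracles and shared fixtures.

# Exhaustive per-pixel ROI membership oracle: loops over every pixel and
# keeps those whose 0-based centre is within Euclidean distance <= radius.
roi_oracle <- function(pixels, center_row, center_col, radius) {
  vals <- c()
  for (r in seq_len(nrow(pixels))) {
    for (cl in seq_len(ncol(pixels))) {
      if (sqrt((r - 1 - center_row)^2 + (cl - 1 - center_col)^2) <= radius)
        vals <- c(vals, pixels[r, cl])
    }
  }
  vals
}

# Closed-form simple-OLS oracle, independent of lm().
ols_oracle <- function(x, y) {
  sxx <- sum((x - mean(x))^2)
  slope <- sum((x - mean(x)) * (y - mean(y))) / sxx
  intercept <- mean(y) - slope * mean(x)
  fitted <- intercept + slope * x
  r2 <- 1 - sum((y - fitted)^2) / sum((y - mean(y))^2)
  list(slope = slope, intercept = intercept, r_squared = r2)
}

# The published transfer function, recovered exactly from noiseless
# generator output (so the curve object is produced by the package itself).
paper_curve <- function() {
  st <- generate_calibration_dataset(c(5, 10, 25, 50, 100), 2, noise_sd = 0)
  suppressWarnings(fit_calibration(st))
}

# Uniform-colour single-pixel image.
px1 <- function(r, g, b) rgb_image(array(c(r, g, b), dim = c(1, 1, 3)))

# Random 8-bit grayscale image (values drawn uniformly).
random_gray <- function(h, w, inverted = TRUE) {
  gray_image(matrix(sample(0:255, h * w, replace = TRUE), h, w),
             inverted = inverted)
}
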