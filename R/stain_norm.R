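#' Reference color statistics for stain normalization
#'
#' Per-channel target mean and SD in CIELAB space, toward which
#' [normalize_color()] remaps every image. The packaged constant is derived
#' once from a canonical undegraded phantom (640 x 480, default palette,
#' abnormal fraction 0.2, seed 20140723) and versioned; downstream
#' segmentation thresholds are calibrated against it.
#'
#' @return List with `mean` and `sd` (length-3, L/a/b order) and `version`.
#' @seealso [derive_reference_stats()], [normalize_color()]
#' @export
he_reference_stats <- function() {
  # frozen output of derive_reference_stats(generate_phantom(
  #   phantom_config(seed = 20140723))$image); see data-raw/calibrate.R
  list(
    mean = c(L = 72.590926, a = 23.344829, b = -4.134520),
    sd = c(L = 13.470186, a = 10.714251, b = 14.248827),
    version = "1.0"
  )
}

#' Derive reference color statistics from an image
#'
#' @param image rows x cols x 3 numeric array, 0..255.
#' @return List with CIELAB channel `mean`, `sd` and `version`, usable as the
#'   `ref` argument of [normalize_color()].
#' @export
derive_reference_stats <- function(image) {
  lab <- rgb_to_lab(image)
  list(
    mean = c(L = mean(lab[, , 1]), a = mean(lab[, , 2]), b = mean(lab[, , 3])),
    sd = c(L = stats::sd(lab[, , 1]), a = stats::sd(lab[, , 2]),
           b = stats::sd(lab[, , 3])),
    version = "custom"
  )
}

#' Normalize color and illumination of an H&E image
#'
#' First pipeline step. Removes the slide-to-slide staining and illumination
#' variability that would otherwise destabilize the downstream color
#' thresholds: (1) the luminance channel is divided by a heavily smoothed
#' copy of itself (Gaussian scale equal to the image width, so the estimate
#' is insensitive to tissue-scale structure), rescaled to preserve the
#' global mean, which flattens illumination gradients;
#' (2) each CIELAB channel is linearly remapped so its mean and SD equal the
#' reference (Reinhard-style statistics transfer). Computation is in floating
#' point; clipping happens only at the final sRGB conversion.
#'
#' A constant-color channel (zero SD) cannot be rescaled; it degenerates to a
#' mean shift and is flagged in the `pq_norm_meta` attribute of the result
#' rather than raising an error.
#'
#' @param image rows x cols x 3 numeric array, 0..255.
#' @param ref Reference statistics, by default [he_reference_stats()].
#' @return Normalized image array (0..255) with attribute `pq_norm_meta`
#'   (list: `degenerate_channels`, logical length 3).
#' @export
normalize_color <- function(image, ref = he_reference_stats()) {
  stopifnot(length(dim(image)) == 3, dim(image)[3] == 3,
            dim(image)[1] > 0, dim(image)[2] > 0,
            all(ref$sd > 0))
  lab <- rgb_to_lab(image)

  # illumination flattening on L; the field is estimated at coarse scale on
  # a downsampled copy (equivalent and much cheaper for large sigma)
  L <- lab[, , 1]
  smooth <- coarse_blur(L, sigma = ncol(L))
  flat <- L / pmax(smooth, 1e-6)
  mf <- mean(flat)
  if (mf > 1e-8) flat <- flat * (mean(L) / mf)
  lab[, , 1] <- flat

  # channel statistics matching in Lab
  degenerate <- logical(3)
  for (ch in 1:3) {
    x <- lab[, , ch]
    m <- mean(x); s <- stats::sd(x)
    if (is.na(s) || s < 1e-8) {
      degenerate[ch] <- TRUE
      lab[, , ch] <- x - m + ref$mean[ch]
    } else {
      lab[, , ch] <- (x - m) / s * ref$sd[ch] + ref$mean[ch]
    }
  }
  out <- lab_to_rgb(lab)
  attr(out, "pq_norm_meta") <- list(degenerate_channels = degenerate)
  out
}
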