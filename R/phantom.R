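#' Configuration for a synthetic H&E pulley-tissue phantom
#'
#' Describes one synthetic microscopy tile emulating an H&E-stained A1-pulley
#' section: eosinophilic pink collagen with elongated spindle nuclei (normal
#' tissue) next to basophilic blue-purple chondromyxoid patches with rounded
#' nuclei (abnormal tissue), on a near-white slide background. The phantom
#' carries exact per-pixel and per-nucleus ground truth, so every downstream
#' pipeline stage can be scored without patient data.
#'
#' @param width_px,height_px Canvas size in pixels. The default 640 x 480 is a
#'   desk-scale stand-in for full-resolution 2560 x 1920 slide tiles; all
#'   geometry is expressed in pixels so rescaling is a configuration change.
#' @param abnormal_fraction_target Target fraction of tissue pixels labeled
#'   abnormal, in `[0, 1]`. The realized fraction is exact up to pixel
#'   rounding (within 0.02).
#' @param nucleus_density Nuclei per 10^4 tissue pixels (> 0).
#' @param nucleus_area_px Nominal area of one nucleus in pixels; all nuclei
#'   share this area so that class differs by shape, not size.
#' @param normal_axis_ratio_range Range of major/minor axis ratios for
#'   spindle (normal) nuclei.
#' @param abnormal_axis_ratio_range Range of axis ratios for round (abnormal)
#'   nuclei.
#' @param abnormal_nucleus_fraction_target Optional fraction of nuclei placed
#'   in abnormal regions. `NULL` (default) allocates nuclei proportionally to
#'   class area; a number decouples the nucleus ratio from the area ratio,
#'   emulating the clustering of round cartilaginous cells in chondroid
#'   metaplasia.
#' @param background_fraction_target Fraction of pixels that are empty slide
#'   background, in `[0, 0.5]`.
#' @param stain_palette Named list of reference RGB triples (0..255):
#'   `background`, `eosinophilic`, `basophilic`, `nuclear`.
#' @param illumination_gradient_amplitude Amplitude of a linear illumination
#'   ramp as a fraction of the dynamic range, in `[0, 0.3]`. 0 = flat.
#' @param stain_shift Length-3 multiplicative per-channel perturbation, each
#'   in `[0.7, 1.3]`. `c(1, 1, 1)` = no shift.
#' @param noise_sd Gaussian pixel noise SD in intensity units (0..255 scale).
#' @param seed Integer seed; identical config + seed gives a bit-identical
#'   phantom.
#'
#' @return An object of class `pq_phantom_config` (a validated list).
#' @seealso [generate_phantom()]
#' @export
phantom_config <- function(width_px = 640, height_px = 480,
                           abnormal_fraction_target = 0.2,
                           nucleus_density = 10,
                           nucleus_area_px = 36,
                           normal_axis_ratio_range = c(3, 6),
                           abnormal_axis_ratio_range = c(1, 1.4),
                           abnormal_nucleus_fraction_target = NULL,
                           background_fraction_target = 0.15,
                           stain_palette = default_stain_palette(),
                           illumination_gradient_amplitude = 0,
                           stain_shift = c(1, 1, 1),
                           noise_sd = 2,
                           seed = 1L) {
  stopifnot(
    width_px >= 32, height_px >= 32,
    abnormal_fraction_target >= 0, abnormal_fraction_target <= 1,
    nucleus_density > 0, nucleus_area_px >= 10,
    length(normal_axis_ratio_range) == 2,
    length(abnormal_axis_ratio_range) == 2,
    min(normal_axis_ratio_range) >= 1,
    min(abnormal_axis_ratio_range) >= 1,
    background_fraction_target >= 0, background_fraction_target <= 0.5,
    illumination_gradient_amplitude >= 0, illumination_gradient_amplitude <= 0.3,
    length(stain_shift) == 3, all(stain_shift >= 0.7), all(stain_shift <= 1.3),
    noise_sd >= 0
  )
  if (!is.null(abnormal_nucleus_fraction_target)) {
    stopifnot(abnormal_nucleus_fraction_target >= 0,
              abnormal_nucleus_fraction_target <= 1)
  }
  stopifnot(all(c("background", "eosinophilic", "basophilic", "nuclear") %in%
                  names(stain_palette)))
  structure(list(
    width_px = as.integer(width_px), height_px = as.integer(height_px),
    abnormal_fraction_target = abnormal_fraction_target,
    nucleus_density = nucleus_density,
    nucleus_area_px = nucleus_area_px,
    normal_axis_ratio_range = normal_axis_ratio_range,
    abnormal_axis_ratio_range = abnormal_axis_ratio_range,
    abnormal_nucleus_fraction_target = abnormal_nucleus_fraction_target,
    background_fraction_target = background_fraction_target,
    stain_palette = stain_palette,
    illumination_gradient_amplitude = illumination_gradient_amplitude,
    stain_shift = stain_shift,
    noise_sd = noise_sd,
    seed = as.integer(seed)
  ), class = "pq_phantom_config")
}

#' Default H&E stain palette for phantom rendering
#'
#' RGB triples (0..255) for the four rendered materials: near-white slide
#' background, eosinophilic pink collagen, basophilic blue-purple
#' chondromyxoid matrix, and dark-purple nuclear stain.
#'
#' @return Named list of length-3 numeric vectors.
#' @export
default_stain_palette <- function() {
  list(
    background   = c(246, 244, 241),
    eosinophilic = c(231, 157, 173),
    basophilic   = c(148, 138, 205),
    nuclear      = c(72, 48, 110)
  )
}

#' Generate a synthetic H&E phantom with exact ground truth
#'
#' Renders one tile per the configuration: abnormal regions are smoothed
#' random blobs thresholded to hit the target area fraction; nuclei are
#' non-overlapping ellipses placed by rejection sampling, spindle-shaped in
#' normal tissue and round in abnormal tissue. Ground truth (label mask,
#' nucleus list, realized ratios) is recorded before degradation; stain
#' shift, illumination gradient and pixel noise are applied last.
#'
#' @param config A [phantom_config()].
#' @return A `pq_phantom`: list with `image` (rows x cols x 3 array, 0..255),
#'   `ground_truth` (list: `label_mask` integer matrix with codes 0/1/2;
#'   `nuclei` tibble with centroid, axes, orientation and `true_class`;
#'   `realized_abn_sr`; `realized_abn_nr`) and `config`.
#' @examples
#' ph <- generate_phantom(phantom_config(width_px = 96, height_px = 96,
#'                                       seed = 1))
#' ph$ground_truth$realized_abn_sr
#' @export
generate_phantom <- function(config) {
  stopifnot(inherits(config, "pq_phantom_config"))
  with_seed(config$seed, generate_phantom_impl(config))
}

generate_phantom_impl <- function(config) {
  h <- config$height_px; w <- config$width_px
  npx <- h * w

  # -- geometry: background and abnormal blobs by quantile thresholding of
  #    smoothed noise fields (realized fractions exact up to rounding)
  label <- matrix(1L, h, w)
  n_bg <- round(config$background_fraction_target * npx)
  if (n_bg > 0) {
    f_bg <- gauss_blur(matrix(stats::rnorm(npx), h, w), sigma = min(h, w) / 5)
    label[order(f_bg, decreasing = TRUE)[seq_len(n_bg)]] <- 0L
  }
  tissue_idx <- which(label == 1L)
  n_tissue <- length(tissue_idx)
  if (n_tissue == 0L) {
    stop_pq("phantom has no tissue pixels; lower background_fraction_target",
            "pq_generation_failure")
  }
  n_ab <- round(config$abnormal_fraction_target * n_tissue)
  if (n_ab > 0) {
    f_ab <- gauss_blur(matrix(stats::rnorm(npx), h, w), sigma = min(h, w) / 4)
    ord <- tissue_idx[order(f_ab[tissue_idx], decreasing = TRUE)]
    label[ord[seq_len(n_ab)]] <- 2L
  }
  realized_abn_sr <- n_ab / n_tissue

  # -- nucleus placement
  n_total <- round(config$nucleus_density * n_tissue / 1e4)
  fr_ab <- config$abnormal_nucleus_fraction_target %||% (n_ab / n_tissue)
  n_nuc_ab <- round(n_total * fr_ab)
  n_nuc_no <- n_total - n_nuc_ab
  if (n_ab == 0 && n_nuc_ab > 0) {
    stop_pq("abnormal nuclei requested but no abnormal region exists",
            "pq_generation_failure")
  }
  if (n_ab == n_tissue && n_nuc_no > 0) {
    stop_pq("normal nuclei requested but no normal region exists",
            "pq_generation_failure")
  }
  occupied <- matrix(FALSE, h, w)
  nuclei <- place_nuclei(
    label, occupied,
    counts = c(normal = n_nuc_no, abnormal = n_nuc_ab),
    area = config$nucleus_area_px,
    ratio_ranges = list(normal = config$normal_axis_ratio_range,
                        abnormal = config$abnormal_axis_ratio_range)
  )
  realized_abn_nr <- if (n_total > 0) n_nuc_ab / n_total else NA_real_

  # -- rendering
  img <- render_phantom(label, nuclei$pixel_sets, config)

  # -- degradation (ground truth fixed above)
  img <- degrade_staining(img, config$stain_shift,
                          config$illumination_gradient_amplitude)
  if (config$noise_sd > 0) {
    img <- img + array(stats::rnorm(npx * 3, sd = config$noise_sd), dim = dim(img))
  }
  img <- clip255(img)

  structure(list(
    image = img,
    ground_truth = list(
      label_mask = label,
      nuclei = nuclei$records,
      realized_abn_sr = realized_abn_sr,
      realized_abn_nr = realized_abn_nr
    ),
    config = config
  ), class = "pq_phantom")
}

# Place non-overlapping ellipses wholly inside their tissue class. Each
# nucleus walks a freshly shuffled list of candidate centres, so placement
# succeeds whenever a legal spot exists; the scan budget bounds worst-case
# work on nearly-jammed regions.
place_nuclei <- function(label, occupied, counts, area, ratio_ranges,
                         scan_budget = 4000L) {
  h <- nrow(label); w <- ncol(label)
  recs <- list(); sets <- list(); id <- 0L
  for (cls in c("normal", "abnormal")) {
    code <- if (cls == "normal") 1L else 2L
    n_want <- counts[[cls]]
    if (n_want == 0) next
    class_idx <- which(label == code)
    rng <- ratio_ranges[[cls]]
    for (k in seq_len(n_want)) {
      placed <- FALSE
      for (draw in 1:5) {  # fresh shape/orientation if this one cannot fit
      ratio <- stats::runif(1, rng[1], rng[2])
      a <- sqrt(area * ratio / pi)
      b <- sqrt(area / (pi * ratio))
      th <- stats::runif(1, 0, pi)
      cand <- class_idx[sample.int(length(class_idx))]
      if (length(cand) > scan_budget) cand <- cand[seq_len(scan_budget)]
      for (ctr in cand) {
        r0 <- ((ctr - 1L) %% h) + 1L
        c0 <- ((ctr - 1L) %/% h) + 1L
        px <- ellipse_pixels(r0, c0, a, b, th, h, w)
        if (is.null(px)) next
        if (!all(label[px] == code) || any(occupied[px])) next
        # dilated footprint must clear existing nuclei, so pixel sets never
        # touch orthogonally (labeling is 4-connected)
        moat <- ellipse_pixels(r0, c0, a + 1, b + 1, th, h, w)
        if (is.null(moat) || any(occupied[moat])) next
        occupied[px] <- TRUE
        id <- id + 1L
        recs[[id]] <- tibble::tibble(
          id = id, centroid_row = r0, centroid_col = c0,
          major_axis = 2 * a, minor_axis = 2 * b, orientation = th,
          true_class = cls
        )
        sets[[id]] <- px
        placed <- TRUE
        break
      }
      if (placed) break
      }
      if (!placed) {
        stop_pq(paste0("could not place ", cls, " nucleus ", k, " of ",
                       n_want, " within the scan budget; lower ",
                       "nucleus_density or enlarge the region"),
                "pq_generation_failure")
      }
    }
  }
  records <- if (id > 0) dplyr::bind_rows(recs) else tibble::tibble(
    id = integer(), centroid_row = integer(), centroid_col = integer(),
    major_axis = numeric(), minor_axis = numeric(), orientation = numeric(),
    true_class = character()
  )
  list(records = records, pixel_sets = sets)
}

render_phantom <- function(label, nucleus_pixel_sets, config) {
  h <- nrow(label); w <- ncol(label)
  pal <- config$stain_palette
  img <- array(0, dim = c(h, w, 3))

  # collagen stripe texture along one global fibre orientation
  th <- stats::runif(1, 0, pi)
  period <- stats::runif(1, 7, 11)
  rows <- matrix(seq_len(h), h, w)
  cols <- matrix(seq_len(w), h, w, byrow = TRUE)
  stripe <- sin(2 * pi * (rows * sin(th) + cols * cos(th)) / period)
  # gentle mottle for the chondromyxoid matrix
  mottle <- gauss_blur(matrix(stats::rnorm(h * w), h, w), sigma = 4)
  mottle <- mottle / max(stats::sd(mottle), 1e-8)

  for (ch in 1:3) {
    plane <- matrix(pal$background[ch], h, w)
    plane[label == 1L] <- pal$eosinophilic[ch] * (1 + 0.06 * stripe[label == 1L])
    plane[label == 2L] <- pal$basophilic[ch] * (1 + 0.04 * mottle[label == 2L])
    img[, , ch] <- plane
  }
  plane_off <- as.integer(h) * as.integer(w)
  for (px in nucleus_pixel_sets) {
    jit <- stats::runif(1, -0.05, 0.05)
    lin <- (px[, "col"] - 1L) * h + px[, "row"]
    for (ch in 1:3) {
      img[lin + (ch - 1L) * plane_off] <- pal$nuclear[ch] * (1 + jit)
    }
  }
  clip255(img)
}

#' Apply stain and illumination degradation to an image
#'
#' Emulates the staining and imaging variability across microscope slides: a
#' per-channel multiplicative stain shift and a linear illumination ramp
#' across the field of view. Ground truth of a phantom is never touched. With
#' the identity shift `c(1, 1, 1)` and zero gradient the image is returned
#' unchanged.
#'
#' @param image rows x cols x 3 numeric array, 0..255.
#' @param stain_shift Length-3 multiplicative factors in `[0.7, 1.3]`.
#' @param illumination_gradient_amplitude Ramp amplitude as a fraction of the
#'   dynamic range, in `[0, 0.3]`; the ramp direction is drawn from the RNG.
#' @param seed Optional integer seed; `NULL` uses the current RNG stream.
#' @return Degraded image array, clipped to 0..255.
#' @export
degrade_staining <- function(image, stain_shift = c(1, 1, 1),
                             illumination_gradient_amplitude = 0,
                             seed = NULL) {
  stopifnot(length(dim(image)) == 3, dim(image)[3] == 3,
            length(stain_shift) == 3,
            all(stain_shift >= 0.7), all(stain_shift <= 1.3),
            illumination_gradient_amplitude >= 0,
            illumination_gradient_amplitude <= 0.3)
  run <- function() {
    out <- image
    if (illumination_gradient_amplitude > 0) {
      h <- dim(image)[1]; w <- dim(image)[2]
      phi <- stats::runif(1, 0, 2 * pi)
      rows <- matrix(seq_len(h), h, w)
      cols <- matrix(seq_len(w), h, w, byrow = TRUE)
      t <- rows * sin(phi) + cols * cos(phi)
      t <- (t - min(t)) / max(max(t) - min(t), 1e-8)
      ramp <- 1 + illumination_gradient_amplitude * (t - 0.5)
      for (ch in 1:3) out[, , ch] <- out[, , ch] * ramp
    }
    if (!all(stain_shift == 1)) {
      for (ch in 1:3) out[, , ch] <- out[, , ch] * stain_shift[ch]
    }
    clip255(out)
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

#' @export
print.pq_phantom <- function(x, ...) {
  gt <- x$ground_truth
  cat(sprintf(
    "<pq_phantom> %d x %d px | Abn-SR %.3f | %d nuclei (Abn-NR %s) | seed %d\n",
    x$config$height_px, x$config$width_px, gt$realized_abn_sr,
    nrow(gt$nuclei),
    ifelse(is.na(gt$realized_abn_nr), "NA", sprintf("%.3f", gt$realized_abn_nr)),
    x$config$seed
  ))
  invisible(x)
}
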