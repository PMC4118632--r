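#' Segmentation parameters
#'
#' Thresholds for the three-step color segmentation, calibrated on
#' color-normalized phantoms (see the methods vignette).
#'
#' @param lum_background Luminance (0..255) above which a low-saturation
#'   pixel is empty slide background.
#' @param sat_background Saturation (0..1) below which a bright pixel is
#'   background.
#' @param t_basophilia Threshold on the basophilia index (blue minus red,
#'   intensity units) separating basophilic abnormal matrix (above) from
#'   eosinophilic normal matrix (below).
#' @param t_dark Luminance below which a tissue pixel is nuclear stain; such
#'   pixels inherit the tissue class of their surroundings.
#' @param min_region_px Connected tissue components smaller than this are
#'   flipped to the other tissue class.
#' @param brush_size Diameter of the disc structuring element used for
#'   morphological smoothing (odd integer).
#' @return A `pq_seg_params` list.
#' @export
seg_params <- function(lum_background = 215, sat_background = 0.12,
                       t_basophilia = 0, t_dark = 110,
                       min_region_px = 64, brush_size = 3) {
  stopifnot(lum_background > 0, lum_background < 256,
            sat_background >= 0, sat_background <= 1,
            t_dark > 0, t_dark < lum_background,
            min_region_px >= 0, brush_size >= 1, brush_size %% 2 == 1)
  structure(list(
    lum_background = lum_background, sat_background = sat_background,
    t_basophilia = t_basophilia, t_dark = t_dark,
    min_region_px = min_region_px, brush_size = brush_size
  ), class = "pq_seg_params")
}

#' Three-class tissue segmentation
#'
#' Second pipeline step: assigns every pixel of a color-normalized image to
#' background (0), normal eosinophilic tissue (1), or abnormal basophilic
#' tissue (2), in three steps. Step 1 removes empty slide background (bright
#' and unsaturated pixels). Step 2 scores the remaining pixels by a
#' basophilia index, blue minus red: positive for the blue-purple
#' chondromyxoid matrix, negative for eosin pink. Dark nuclear-stain pixels
#' carry no matrix color, so they inherit the class of the nearest stained
#' tissue pixel (nuclei are counted with their surrounding tissue for area
#' purposes). Step 3 thresholds the index and cleans up: morphological
#' opening/closing with a small disc, then connected components smaller than
#' `min_region_px` are merged into the opposing tissue class. Fully
#' deterministic.
#'
#' @param image Color-normalized rows x cols x 3 array, 0..255.
#' @param params A [seg_params()].
#' @return Integer matrix of codes 0/1/2, same dimensions as the image.
#' @export
segment_tissue <- function(image, params = seg_params()) {
  stopifnot(inherits(params, "pq_seg_params"),
            length(dim(image)) == 3, dim(image)[3] == 3)
  lum <- luminance(image)
  sat <- pixel_saturation(image)
  bg <- lum > params$lum_background & sat < params$sat_background
  tissue <- !bg
  dark <- tissue & lum < params$t_dark
  stained <- tissue & !dark

  bindex <- image[, , 3] - image[, , 1]
  abn <- stained & bindex > params$t_basophilia
  nor <- stained & !abn

  # nuclear-stain pixels take the class of the nearest stained pixel
  # (exact Euclidean distance transform; ties resolve to normal)
  if (any(dark)) {
    if (any(abn)) {
      d_abn <- EBImage::distmap(1 - abn)
    } else {
      d_abn <- matrix(Inf, nrow(lum), ncol(lum))
    }
    if (any(nor)) {
      d_nor <- EBImage::distmap(1 - nor)
    } else {
      d_nor <- matrix(Inf, nrow(lum), ncol(lum))
    }
    take_abn <- dark & (d_abn < d_nor)
    abn <- abn | take_abn
  }
  abn_in_tissue <- tissue & abn

  # morphological smoothing of the abnormal class within tissue
  brush <- EBImage::makeBrush(params$brush_size, shape = "disc")
  m2 <- EBImage::closing(EBImage::opening(abn_in_tissue * 1, brush), brush) > 0.5
  m2 <- m2 & tissue

  label <- matrix(0L, nrow(lum), ncol(lum))
  label[tissue] <- 1L
  label[m2] <- 2L

  # flip connected tissue components smaller than min_region_px
  if (params$min_region_px > 0) {
    for (code in c(2L, 1L)) {
      comp <- EBImage::bwlabel(label == code)
      if (max(comp) == 0) next
      sizes <- tabulate(comp[comp > 0])
      small <- which(sizes < params$min_region_px)
      if (length(small)) {
        label[comp %in% small] <- if (code == 2L) 1L else 2L
      }
    }
  }
  label
}

#' Image suitability proxy
#'
#' The acquisition protocol discards tiles dominated by empty background or
#' containing too few nuclei to witness pulley tissue. This quantitative
#' proxy replaces that screening: a tile is suitable when its tissue
#' fraction and nucleus count both clear their thresholds; the tissue
#' fraction serves as a ranking score.
#'
#' @param mask Tissue label mask from [segment_tissue()].
#' @param nucleus_count Number of detected nuclei in the same image.
#' @param min_tissue_frac Minimum fraction of non-background pixels
#'   (default 0.5).
#' @param min_nuclei Minimum nucleus count (default 30).
#' @return One-row tibble: `score` (tissue fraction), `is_suitable`.
#' @export
suitability_score <- function(mask, nucleus_count,
                              min_tissue_frac = 0.5, min_nuclei = 30) {
  frac <- mean(mask > 0)
  tibble::tibble(
    score = frac,
    is_suitable = frac >= min_tissue_frac && nucleus_count >= min_nuclei
  )
}
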