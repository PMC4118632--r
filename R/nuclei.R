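#' Nucleus detection and classification parameters
#'
#' @param t_dark Luminance (0..255) below which a tissue pixel is a
#'   nuclear-stain candidate; shared with the segmentation default.
#' @param min_nucleus_area,max_nucleus_area Area bounds in pixels for a
#'   retained component; components above the maximum are split by
#'   distance-transform watershed.
#' @param t_low,t_high Circularity hysteresis thresholds of the double
#'   thresholding scheme: at or above `t_high` a nucleus is round (abnormal),
#'   at or below `t_low` it is spindle (normal); between them the axis ratio
#'   decides.
#' @param band_axis_ratio In the ambiguous circularity band, nuclei with
#'   major/minor axis ratio at or below this value are called abnormal.
#' @return A `pq_nucleus_params` list.
#' @export
nucleus_params <- function(t_dark = 110, min_nucleus_area = 12,
                           max_nucleus_area = 120,
                           t_low = 0.55, t_high = 0.75,
                           band_axis_ratio = 2.0) {
  stopifnot(t_dark > 0, min_nucleus_area >= 1,
            max_nucleus_area > min_nucleus_area,
            t_low < t_high, t_low > 0, band_axis_ratio >= 1)
  structure(list(
    t_dark = t_dark, min_nucleus_area = min_nucleus_area,
    max_nucleus_area = max_nucleus_area,
    t_low = t_low, t_high = t_high, band_axis_ratio = band_axis_ratio
  ), class = "pq_nucleus_params")
}

#' Detect nuclei in a normalized image
#'
#' Third pipeline step (detection half). Nuclear-stain candidates are tissue
#' pixels darker than `t_dark`; 4-connected components within the area
#' bounds are kept, oversized components are split by watershed on the
#' distance transform, and shape descriptors are computed per component:
#' area, perimeter (4-neighbor boundary edge count corrected by pi/4),
#' major/minor axis from second moments, axis ratio, and circularity
#' 4*pi*area/perimeter^2. Deterministic; the tissue mask only restricts the
#' search region.
#'
#' @param image Color-normalized rows x cols x 3 array, 0..255.
#' @param mask Tissue label mask from [segment_tissue()].
#' @param params A [nucleus_params()].
#' @return Tibble with one row per nucleus: `id`, `centroid_row`,
#'   `centroid_col`, `area`, `perimeter`, `major_axis`, `minor_axis`,
#'   `axis_ratio`, `circularity`. Empty tibble when nothing is detected.
#' @export
detect_nuclei <- function(image, mask, params = nucleus_params()) {
  stopifnot(inherits(params, "pq_nucleus_params"),
            all(dim(mask) == dim(image)[1:2]))
  lum <- luminance(image)
  cand <- mask > 0 & lum < params$t_dark
  empty <- tibble::tibble(
    id = integer(), centroid_row = numeric(), centroid_col = numeric(),
    area = numeric(), perimeter = numeric(), major_axis = numeric(),
    minor_axis = numeric(), axis_ratio = numeric(), circularity = numeric()
  )
  if (!any(cand)) return(empty)

  comp <- EBImage::bwlabel(cand)
  sizes <- tabulate(comp[comp > 0])

  # split oversized components (touching nuclei) by watershed on distmap
  big <- which(sizes > params$max_nucleus_area)
  if (length(big)) {
    sel <- comp %in% big
    dm <- EBImage::distmap(sel * 1)
    ws <- EBImage::watershed(dm)
    nxt <- max(comp)
    comp[sel] <- ifelse(ws[sel] > 0, nxt + as.integer(ws[sel]), 0L)
    # compact labels
    comp <- matrix(match(comp, sort(unique(comp[comp > 0]))), nrow(comp),
                   ncol(comp))
    comp[is.na(comp)] <- 0L
    sizes <- tabulate(comp[comp > 0])
  }

  keep <- which(sizes >= params$min_nucleus_area &
                  sizes <= params$max_nucleus_area)
  if (!length(keep)) return(empty)
  comp[!(comp %in% keep)] <- 0L
  comp <- matrix(match(comp, sort(unique(comp[comp > 0]))), nrow(comp),
                 ncol(comp))
  comp[is.na(comp)] <- 0L

  mom <- EBImage::computeFeatures.moment(comp)
  if (is.null(dim(mom))) mom <- matrix(mom, nrow = 1,
                                       dimnames = list(NULL, names(mom)))
  area <- tabulate(comp[comp > 0])
  per <- region_perimeter(comp)
  major <- mom[, "m.majoraxis"]
  minor <- major * sqrt(pmax(1 - mom[, "m.eccentricity"]^2, 1e-6))
  tibble::tibble(
    id = seq_along(area),
    centroid_row = as.numeric(mom[, "m.cx"]),
    centroid_col = as.numeric(mom[, "m.cy"]),
    area = as.numeric(area),
    perimeter = per,
    major_axis = as.numeric(major),
    minor_axis = as.numeric(minor),
    axis_ratio = as.numeric(major / pmax(minor, 1e-6)),
    circularity = as.numeric(4 * pi * area / pmax(per, 1e-6)^2)
  )
}

# Digital perimeter per labeled region: number of 4-neighbor object/non-object
# boundary edges, multiplied by pi/4 (the standard correction that makes a
# digital disc's perimeter match 2*pi*r in expectation).
region_perimeter <- function(comp) {
  h <- nrow(comp); w <- ncol(comp)
  pad <- matrix(0L, h + 2, w + 2)
  pad[2:(h + 1), 2:(w + 1)] <- comp
  counts <- numeric(max(comp))
  for (sh in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
    nb <- pad[(2:(h + 1)) + sh[1], (2:(w + 1)) + sh[2]]
    edge <- comp > 0 & nb != comp
    if (any(edge)) {
      t <- tabulate(comp[edge], nbins = max(comp))
      counts <- counts + t
    }
  }
  counts * pi / 4
}

#' Classify nuclei as normal (spindle) or abnormal (round)
#'
#' Third pipeline step (classification half): a double-thresholding scheme
#' on shape. Circularity at or above `t_high` forces abnormal (round);
#' at or below `t_low` forces normal (elongated); in the ambiguous band the
#' major/minor axis ratio decides (at or below `band_axis_ratio` is
#' abnormal). The rule is a deterministic function of each record's shape
#' descriptors, so record order is irrelevant.
#'
#' @param nuclei Tibble from [detect_nuclei()].
#' @param params A [nucleus_params()] supplying `t_low`, `t_high` and
#'   `band_axis_ratio`.
#' @return The input tibble with `class` (`"normal"`/`"abnormal"`) and
#'   `resolved_by` (`"low_threshold"`/`"high_threshold"`/`"band_rule"`)
#'   columns appended.
#' @export
classify_nuclei <- function(nuclei, params = nucleus_params()) {
  stopifnot(inherits(params, "pq_nucleus_params"))
  if (nrow(nuclei) == 0) {
    return(dplyr::mutate(nuclei, class = character(),
                         resolved_by = character()))
  }
  dplyr::mutate(
    nuclei,
    resolved_by = dplyr::case_when(
      .data$circularity >= params$t_high ~ "high_threshold",
      .data$circularity <= params$t_low ~ "low_threshold",
      TRUE ~ "band_rule"
    ),
    class = dplyr::case_when(
      .data$circularity >= params$t_high ~ "abnormal",
      .data$circularity <= params$t_low ~ "normal",
      .data$axis_ratio <= params$band_axis_ratio ~ "abnormal",
      TRUE ~ "normal"
    )
  )
}
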