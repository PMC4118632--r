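#' Abnormal tissue size ratio (Abn-SR)
#'
#' Fourth pipeline step, parameter 1: the area of abnormal tissue divided by
#' the total tissue area (normal plus abnormal). Background pixels are
#' excluded from the denominator. An image with no tissue pixels has no
#' defined ratio and yields `NA`, never 0.
#'
#' @param mask Tissue label mask (codes 0/1/2).
#' @return Numeric in `[0, 1]`, or `NA_real_` when the mask holds no tissue.
#' @export
compute_abn_sr <- function(mask) {
  tissue <- sum(mask > 0)
  if (tissue == 0) return(NA_real_)
  sum(mask == 2L) / tissue
}

#' Abnormal nucleus number ratio (Abn-NR)
#'
#' Fourth pipeline step, parameter 2: the number of abnormal (round) nuclei
#' divided by the total nucleus count. An empty nucleus table yields `NA`.
#'
#' @param nuclei Classified nucleus tibble from [classify_nuclei()].
#' @return Numeric in `[0, 1]`, or `NA_real_` when no nuclei were detected.
#' @export
compute_abn_nr <- function(nuclei) {
  if (nrow(nuclei) == 0) return(NA_real_)
  mean(nuclei$class == "abnormal")
}

#' Pipeline parameters for per-image analysis
#'
#' Bundles the stage parameters used by [analyze_image()] and the study
#' driver.
#'
#' @param ref Normalization reference, default [he_reference_stats()].
#' @param seg A [seg_params()].
#' @param nuc A [nucleus_params()].
#' @param min_tissue_frac,min_nuclei Suitability thresholds, see
#'   [suitability_score()].
#' @return A `pq_pipeline_params` list.
#' @export
pipeline_params <- function(ref = he_reference_stats(), seg = seg_params(),
                            nuc = nucleus_params(),
                            min_tissue_frac = 0.5, min_nuclei = 30) {
  structure(list(ref = ref, seg = seg, nuc = nuc,
                 min_tissue_frac = min_tissue_frac, min_nuclei = min_nuclei),
            class = "pq_pipeline_params")
}

#' Run the full image pipeline on one image
#'
#' Normalize, segment, detect and classify nuclei, and compute both severity
#' parameters plus the suitability proxy for one RGB image.
#'
#' @param image rows x cols x 3 numeric array, 0..255 (raw, not yet
#'   normalized).
#' @param image_id Identifier recorded in the result row.
#' @param params A [pipeline_params()].
#' @return One-row tibble (an ImageResult): `image_id`, `abn_sr`, `abn_nr`,
#'   `tissue_px`, `abnormal_px`, `n_nuclei_normal`, `n_nuclei_abnormal`,
#'   `suitability`, `suitable`.
#' @export
analyze_image <- function(image, image_id = "img", params = pipeline_params()) {
  stopifnot(inherits(params, "pq_pipeline_params"))
  norm <- normalize_color(image, params$ref)
  mask <- segment_tissue(norm, params$seg)
  nuc <- classify_nuclei(detect_nuclei(norm, mask, params$nuc), params$nuc)
  suit <- suitability_score(mask, nrow(nuc),
                            min_tissue_frac = params$min_tissue_frac,
                            min_nuclei = params$min_nuclei)
  tibble::tibble(
    image_id = image_id,
    abn_sr = compute_abn_sr(mask),
    abn_nr = compute_abn_nr(nuc),
    tissue_px = sum(mask > 0),
    abnormal_px = sum(mask == 2L),
    n_nuclei_normal = sum(nuc$class == "normal"),
    n_nuclei_abnormal = sum(nuc$class == "abnormal"),
    suitability = suit$score,
    suitable = suit$is_suitable
  )
}

#' Select images for quantification
#'
#' Mirrors the acquisition protocol: unsuitable images are discarded first,
#' then `k` images are drawn uniformly without replacement from the suitable
#' ones with a seeded generator. When fewer than `k` suitable images remain,
#' all of them are returned and a warning is recorded on the result
#' (attribute `short_selection`).
#'
#' @param candidates Tibble of image results with at least `image_id` and
#'   `suitable` columns (see [analyze_image()]).
#' @param k Number of images to select (default 10).
#' @param seed Integer seed controlling the draw.
#' @return Character/whatever vector of selected `image_id`s, deterministic
#'   per seed.
#' @export
select_images <- function(candidates, k = 10, seed = 1L) {
  stopifnot(k >= 1, all(c("image_id", "suitable") %in% names(candidates)))
  pool <- candidates$image_id[candidates$suitable]
  if (length(pool) == 0) {
    stop_pq("no suitable images to select from", "pq_no_suitable_images")
  }
  short <- length(pool) < k
  ids <- if (length(pool) <= k) {
    pool
  } else {
    with_seed(seed, pool[sample.int(length(pool), k)])
  }
  if (short) {
    rlang::warn(sprintf("only %d suitable images available (requested %d)",
                        length(pool), k),
                class = "pq_short_selection")
    attr(ids, "short_selection") <- TRUE
  }
  ids
}

#' Aggregate selected image results into a specimen summary
#'
#' Specimen-level Abn-SR and Abn-NR are the unweighted arithmetic means over
#' the selected images. Undefined per-image ratios (no tissue, no nuclei)
#' are excluded from the corresponding mean and counted; if every ratio of a
#' parameter is undefined the aggregation fails.
#'
#' @param results Tibble of selected image results ([analyze_image()] rows).
#' @param specimen_id Identifier for the specimen.
#' @param pathological_grade,clinical_grade Optional grade labels
#'   (`"L"/"M"/"H"` and `"I"/"II"/"III"/"IV"`).
#' @return One-row tibble (a SpecimenResult): ids, grades, `n_images`,
#'   `mean_abn_sr`, `mean_abn_nr`, `n_undefined_sr`, `n_undefined_nr`.
#' @export
summarize_specimen <- function(results, specimen_id = "specimen",
                               pathological_grade = NA_character_,
                               clinical_grade = NA_character_) {
  stopifnot(nrow(results) >= 1)
  sr <- results$abn_sr; nr <- results$abn_nr
  if (all(is.na(sr)) || all(is.na(nr))) {
    stop_pq(sprintf("specimen %s: all ratios undefined", specimen_id),
            "pq_all_undefined")
  }
  tibble::tibble(
    specimen_id = specimen_id,
    pathological_grade = pathological_grade,
    clinical_grade = clinical_grade,
    n_images = nrow(results),
    mean_abn_sr = mean(sr, na.rm = TRUE),
    mean_abn_nr = mean(nr, na.rm = TRUE),
    n_undefined_sr = sum(is.na(sr)),
    n_undefined_nr = sum(is.na(nr))
  )
}

#' Analyze a phantom end to end
#'
#' Convenience wrapper running [analyze_image()] on a phantom's rendered
#' image and attaching the generator's ground truth for scoring.
#'
#' @param phantom A `pq_phantom` from [generate_phantom()].
#' @param image_id Identifier for the result row.
#' @param params A [pipeline_params()].
#' @return One-row tibble: the [analyze_image()] columns plus `true_abn_sr`
#'   and `true_abn_nr` from the ground truth.
#' @export
analyze_phantom <- function(phantom, image_id = "phantom",
                            params = pipeline_params()) {
  stopifnot(inherits(phantom, "pq_phantom"))
  res <- analyze_image(phantom$image, image_id, params)
  res$true_abn_sr <- phantom$ground_truth$realized_abn_sr
  res$true_abn_nr <- phantom$ground_truth$realized_abn_nr
  res
}
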