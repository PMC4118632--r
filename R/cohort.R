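#' Per-grade calibration and design of a simulated cohort
#'
#' Defines the generative conditions of a whole simulated study: per
#' pathological grade (L/M/H) the mean and SD of specimen-level Abn-SR and
#' Abn-NR, the number of specimens, the conditional distribution of the
#' clinical (Froimson II-IV) grade given the pathological grade, and the
#' image acquisition design (candidate tiles per specimen, number selected,
#' fraction unsuitable, within-specimen jitter).
#'
#' The defaults calibrate the specimen-level parameter distributions to the
#' published per-grade means and SDs (L: SR 0.14 +- 0.03, NR 0.57 +- 0.07;
#' M: 0.20 +- 0.01 / 0.64 +- 0.04; H: 0.26 +- 0.01 / 0.74 +- 0.05) with
#' 5/8/8 specimens, and the clinical assignment to the empirical grade
#' confusion (L always II; M grade II with probability 3/8 else III; H grade
#' III with probability 1/8 else IV). Grade-I specimens are representable in
#' the label vocabulary but never generated: mild trigger fingers are
#' treated conservatively and yield no surgical specimens.
#'
#' @param grade_params Tibble with columns `grade`, `sr_mean`, `sr_sd`,
#'   `nr_mean`, `nr_sd`.
#' @param subjects_per_grade Named integer vector over grades L/M/H.
#' @param clinical_assignment 3 x 3 row-stochastic matrix, rows L/M/H,
#'   columns II/III/IV: conditional probability of each clinical grade.
#' @param clinical_mode `"probabilistic"` (sample from
#'   `clinical_assignment`) or `"exact"` (assign deterministically the
#'   integer counts `round(p * n)` per grade, reproducing the target
#'   contingency table exactly).
#' @param images_per_specimen Candidate tiles acquired per specimen
#'   (default 49).
#' @param images_selected Tiles randomly selected for quantification
#'   (default 10).
#' @param unsuitable_fraction Fraction of candidate tiles flagged unsuitable
#'   by construction (default 0.2).
#' @param image_jitter_sd SD of the Gaussian jitter of per-image targets
#'   around the specimen-level parameter (default 0.02).
#' @param phantom Template [phantom_config()] for rendered tiles; per-image
#'   targets and seeds override its fraction fields. The default study
#'   canvas is 256 x 192.
#' @param seed Integer seed for the whole cohort.
#' @return A `pq_cohort_config` list.
#' @export
cohort_config <- function(grade_params = default_grade_params(),
                          subjects_per_grade = c(L = 5L, M = 8L, H = 8L),
                          clinical_assignment = default_clinical_assignment(),
                          clinical_mode = c("probabilistic", "exact"),
                          images_per_specimen = 49L,
                          images_selected = 10L,
                          unsuitable_fraction = 0.2,
                          image_jitter_sd = 0.02,
                          phantom = phantom_config(width_px = 256,
                                                   height_px = 192),
                          seed = 1L) {
  clinical_mode <- match.arg(clinical_mode)
  stopifnot(
    all(c("grade", "sr_mean", "sr_sd", "nr_mean", "nr_sd") %in%
          names(grade_params)),
    all(grade_params$sr_sd >= 0), all(grade_params$nr_sd >= 0),
    all(names(subjects_per_grade) == c("L", "M", "H")),
    all(subjects_per_grade >= 0),
    nrow(clinical_assignment) == 3, ncol(clinical_assignment) == 3,
    all(abs(rowSums(clinical_assignment) - 1) < 1e-9),
    all(clinical_assignment >= 0),
    images_per_specimen >= 1, images_selected >= 1,
    unsuitable_fraction >= 0, unsuitable_fraction < 1,
    image_jitter_sd >= 0,
    inherits(phantom, "pq_phantom_config")
  )
  structure(list(
    grade_params = grade_params,
    subjects_per_grade = subjects_per_grade,
    clinical_assignment = clinical_assignment,
    clinical_mode = clinical_mode,
    images_per_specimen = as.integer(images_per_specimen),
    images_selected = as.integer(images_selected),
    unsuitable_fraction = unsuitable_fraction,
    image_jitter_sd = image_jitter_sd,
    phantom = phantom,
    seed = as.integer(seed)
  ), class = "pq_cohort_config")
}

#' @rdname cohort_config
#' @export
default_grade_params <- function() {
  tibble::tibble(
    grade = c("L", "M", "H"),
    sr_mean = c(0.14, 0.20, 0.26), sr_sd = c(0.03, 0.01, 0.01),
    nr_mean = c(0.57, 0.64, 0.74), nr_sd = c(0.07, 0.04, 0.05)
  )
}

#' @rdname cohort_config
#' @export
default_clinical_assignment <- function() {
  m <- matrix(c(
    1, 0, 0,
    3 / 8, 5 / 8, 0,
    0, 1 / 8, 7 / 8
  ), nrow = 3, byrow = TRUE,
  dimnames = list(c("L", "M", "H"), c("II", "III", "IV")))
  m
}

#' Generate a simulated cohort
#'
#' Draws the specimen-level true parameters per grade from normal
#' distributions truncated to `[0, 1]`, assigns clinical grades per the
#' configured conditional distribution (or deterministically in exact-counts
#' mode), and lays out per-specimen candidate images: each carries jittered
#' per-image targets, a suitability flag by construction, and its own
#' phantom seed. Candidate pixels are rendered lazily by
#' [render_candidate()] so that a whole 21 x 49 design stays cheap while
#' every selected image can be materialized exactly.
#'
#' @param config A [cohort_config()].
#' @return A `pq_cohort`: list with `specimens` (tibble: `specimen_id`,
#'   `pathological_grade`, `clinical_grade`, `true_abn_sr`, `true_abn_nr`),
#'   `candidates` (tibble: `specimen_id`, `image_id`, `target_abn_sr`,
#'   `target_abn_nr`, `suitable`, `phantom_seed`) and `config`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "pq_cohort_config"))
  with_seed(config$seed, generate_cohort_impl(config))
}

generate_cohort_impl <- function(config) {
  gp <- config$grade_params
  spg <- config$subjects_per_grade
  ca <- config$clinical_assignment
  clin_lv <- colnames(ca) %||% c("II", "III", "IV")

  specimens <- purrr::map_dfr(c("L", "M", "H"), function(g) {
    n <- spg[[g]]
    if (n == 0) return(NULL)
    row <- gp[gp$grade == g, ]
    clinical <- if (config$clinical_mode == "exact") {
      counts <- round(ca[g, ] * n)
      if (sum(counts) != n) {
        stop_pq(sprintf(
          "exact-counts mode: probabilities for grade %s do not yield integer counts",
          g), "pq_invalid_exact_counts")
      }
      rep(clin_lv, times = counts)
    } else {
      clin_lv[apply(stats::rmultinom(n, 1, ca[g, ]) == 1, 2, which)]
    }
    tibble::tibble(
      specimen_id = sprintf("%s%02d", g, seq_len(n)),
      pathological_grade = g,
      clinical_grade = clinical,
      true_abn_sr = rtrunc_norm(n, row$sr_mean, row$sr_sd),
      true_abn_nr = rtrunc_norm(n, row$nr_mean, row$nr_sd)
    )
  })

  n_img <- config$images_per_specimen
  n_bad <- round(config$unsuitable_fraction * n_img)
  candidates <- purrr::map_dfr(seq_len(nrow(specimens)), function(i) {
    sp <- specimens[i, ]
    bad <- rep(FALSE, n_img)
    if (n_bad > 0) bad[sample.int(n_img, n_bad)] <- TRUE
    tibble::tibble(
      specimen_id = sp$specimen_id,
      image_id = sprintf("%s_img%02d", sp$specimen_id, seq_len(n_img)),
      target_abn_sr = pmin(pmax(
        sp$true_abn_sr + stats::rnorm(n_img, 0, config$image_jitter_sd),
        0.02), 0.98),
      target_abn_nr = pmin(pmax(
        sp$true_abn_nr + stats::rnorm(n_img, 0, config$image_jitter_sd),
        0.02), 0.98),
      suitable = !bad,
      phantom_seed = sample.int(2^30, n_img)
    )
  })

  structure(list(specimens = specimens, candidates = candidates,
                 config = config), class = "pq_cohort")
}

# Truncated-normal draws on [0,1] by rejection with a bounded budget.
rtrunc_norm <- function(n, mean, sd, budget = 10000L) {
  if (sd == 0) {
    if (mean < 0 || mean > 1) {
      stop_pq("degenerate truncated normal outside [0,1]", "pq_generation_failure")
    }
    return(rep(mean, n))
  }
  out <- numeric(0)
  for (i in seq_len(budget)) {
    draw <- stats::rnorm(n, mean, sd)
    out <- c(out, draw[draw >= 0 & draw <= 1])
    if (length(out) >= n) return(out[seq_len(n)])
  }
  stop_pq("truncated-normal rejection budget exceeded", "pq_generation_failure")
}

#' Render one candidate image of a simulated cohort
#'
#' Materializes the phantom for a candidate row: suitable tiles use the
#' cohort's template canvas with the candidate's jittered targets;
#' unsuitable tiles emulate the discarded acquisitions (mostly empty
#' background, few nuclei).
#'
#' @param cohort A `pq_cohort`.
#' @param image_id One of `cohort$candidates$image_id`.
#' @return A `pq_phantom`.
#' @export
render_candidate <- function(cohort, image_id) {
  stopifnot(inherits(cohort, "pq_cohort"))
  cand <- cohort$candidates[cohort$candidates$image_id == image_id, ]
  if (nrow(cand) != 1) {
    stop_pq(sprintf("unknown image_id %s", image_id), "pq_unknown_image")
  }
  tpl <- cohort$config$phantom
  cfg <- if (cand$suitable) {
    phantom_config(
      width_px = tpl$width_px, height_px = tpl$height_px,
      abnormal_fraction_target = cand$target_abn_sr,
      nucleus_density = tpl$nucleus_density,
      nucleus_area_px = tpl$nucleus_area_px,
      normal_axis_ratio_range = tpl$normal_axis_ratio_range,
      abnormal_axis_ratio_range = tpl$abnormal_axis_ratio_range,
      abnormal_nucleus_fraction_target = cand$target_abn_nr,
      background_fraction_target = tpl$background_fraction_target,
      stain_palette = tpl$stain_palette,
      illumination_gradient_amplitude = tpl$illumination_gradient_amplitude,
      stain_shift = tpl$stain_shift,
      noise_sd = tpl$noise_sd,
      seed = cand$phantom_seed
    )
  } else {
    # discarded-acquisition look: mostly background, sparse nuclei
    phantom_config(
      width_px = tpl$width_px, height_px = tpl$height_px,
      abnormal_fraction_target = cand$target_abn_sr,
      nucleus_density = tpl$nucleus_density / 4,
      nucleus_area_px = tpl$nucleus_area_px,
      normal_axis_ratio_range = tpl$normal_axis_ratio_range,
      abnormal_axis_ratio_range = tpl$abnormal_axis_ratio_range,
      abnormal_nucleus_fraction_target = cand$target_abn_nr,
      background_fraction_target = 0.5,
      stain_palette = tpl$stain_palette,
      illumination_gradient_amplitude = tpl$illumination_gradient_amplitude,
      stain_shift = tpl$stain_shift,
      noise_sd = tpl$noise_sd,
      seed = cand$phantom_seed
    )
  }
  generate_phantom(cfg)
}

#' Cross-tabulate the two grading systems of a cohort
#'
#' @param specimens Tibble with `pathological_grade` and `clinical_grade`
#'   columns (e.g. `cohort$specimens` or a study's per-specimen table).
#' @return 3 x 3 integer matrix, rows L/M/H, columns II/III/IV.
#' @export
grade_contingency <- function(specimens) {
  tab <- table(
    factor(specimens$pathological_grade, levels = c("L", "M", "H")),
    factor(specimens$clinical_grade, levels = c("II", "III", "IV"))
  )
  m <- matrix(as.integer(tab), nrow = 3,
              dimnames = list(c("L", "M", "H"), c("II", "III", "IV")))
  m
}

#' @export
print.pq_cohort <- function(x, ...) {
  cat(sprintf("<pq_cohort> %d specimens (%s), %d candidate images each\n",
              nrow(x$specimens),
              paste(x$config$subjects_per_grade, collapse = "/"),
              x$config$images_per_specimen))
  invisible(x)
}
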