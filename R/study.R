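#' Study configuration
#'
#' One object holding everything [run_study()] needs: either a simulated
#' cohort design or a directory of images with a labels table, plus the
#' image-pipeline parameters, the selection size, and the seeds. All
#' randomness is explicit here, so identical configurations reproduce every
#' output byte for byte.
#'
#' @param mode `"simulate"` (generate a cohort of phantoms) or
#'   `"directory"` (read PNG images and a labels CSV).
#' @param cohort A [cohort_config()] (simulate mode).
#' @param images_dir Directory of `<specimen_id>_<image>.png` files
#'   (directory mode).
#' @param labels Data frame with columns `specimen_id`,
#'   `pathological_grade`, `clinical_grade` (directory mode), or a path to
#'   such a CSV.
#' @param pipeline A [pipeline_params()].
#' @param k Images selected per specimen (default 10).
#' @param seed Integer seed for image selection.
#' @param out_dir Optional output directory; when given, all result tables
#'   are written as CSV plus a JSON manifest.
#' @return A `pq_study_config` list.
#' @export
study_config <- function(mode = c("simulate", "directory"),
                         cohort = cohort_config(),
                         images_dir = NULL, labels = NULL,
                         pipeline = pipeline_params(),
                         k = 10L, seed = 1L, out_dir = NULL) {
  mode <- match.arg(mode)
  if (mode == "directory") {
    stopifnot(!is.null(images_dir), !is.null(labels))
  }
  structure(list(mode = mode, cohort = cohort, images_dir = images_dir,
                 labels = labels, pipeline = pipeline, k = as.integer(k),
                 seed = as.integer(seed), out_dir = out_dir),
            class = "pq_study_config")
}

#' Run the full severity-quantification study
#'
#' Orchestrates the whole analysis: obtain a cohort (simulated phantoms or a
#' directory of images), run the image pipeline on every candidate of each
#' specimen, discard unsuitable tiles and randomly select `k`, aggregate to
#' specimen level, and compute the study statistics — grade-wise means and
#' SDs of both parameters under both grading systems, one-way ANOVA with LSD
#' post-hoc comparisons per parameter per grading system, the pathological x
#' clinical contingency table with Cohen's kappa, an agreement ICC, and
#' boxplot summaries. Deterministic given the configuration.
#'
#' Per-specimen failures (no suitable images, unreadable files) are recorded
#' in `errors` and skipped; the run fails only if every specimen fails.
#' ANOVA/LSD for a grouping is skipped with an explicit note when fewer than
#' two groups have at least two specimens.
#'
#' @param config A [study_config()].
#' @return A `pq_study` list: `per_image`, `per_specimen`, `grade_summary`,
#'   `anova`, `lsd`, `contingency`, `kappa`, `icc`, `boxplots`, `errors`,
#'   `notes`, `manifest`.
#' @export
run_study <- function(config) {
  stopifnot(inherits(config, "pq_study_config"))

  cohort <- NULL
  if (config$mode == "simulate") {
    cohort <- generate_cohort(config$cohort)
    specimens <- cohort$specimens
  } else {
    labels <- config$labels
    if (is.character(labels)) {
      labels <- utils::read.csv(labels, stringsAsFactors = FALSE)
    }
    stopifnot(all(c("specimen_id", "pathological_grade", "clinical_grade")
                  %in% names(labels)))
    validate_grades(labels)
    specimens <- tibble::as_tibble(labels)
  }

  per_image <- list(); per_specimen <- list(); errors <- list()
  for (i in seq_len(nrow(specimens))) {
    sp <- specimens[i, ]
    sid <- sp$specimen_id
    res <- tryCatch({
      if (config$mode == "simulate") {
        # screening precedes quantification: unsuitable candidates are
        # discarded on their construction flags, the k survivors selected
        # by seed, and only those are rendered and quantified
        cand <- cohort$candidates[cohort$candidates$specimen_id == sid, ]
        sel <- withCallingHandlers(
          select_images(cand, k = config$k, seed = config$seed + i),
          pq_short_selection = function(w) invokeRestart("muffleWarning")
        )
        img_res <- purrr::map_dfr(sel, function(id) {
          analyze_image(render_candidate(cohort, id)$image, id,
                        config$pipeline)
        })
        img_res$selected <- TRUE
      } else {
        files <- sort(list.files(config$images_dir,
                                 pattern = paste0("^", sid, "_.*\\.png$"),
                                 full.names = TRUE))
        if (length(files) == 0) {
          stop_pq(sprintf("specimen %s: no images found", sid),
                  "pq_no_images")
        }
        img_res <- purrr::map_dfr(files, function(f) {
          analyze_image(read_image_png(f), sub("\\.png$", "", basename(f)),
                        config$pipeline)
        })
        sel <- withCallingHandlers(
          select_images(img_res, k = config$k, seed = config$seed + i),
          pq_short_selection = function(w) invokeRestart("muffleWarning")
        )
        img_res$selected <- img_res$image_id %in% sel
      }
      spec_res <- summarize_specimen(
        img_res[img_res$selected, ], sid,
        pathological_grade = sp$pathological_grade,
        clinical_grade = sp$clinical_grade
      )
      list(images = dplyr::mutate(img_res, specimen_id = sid,
                                  .before = 1),
           specimen = spec_res)
    }, pulleyquant_error = function(e) e)
    if (inherits(res, "error")) {
      errors[[sid]] <- conditionMessage(res)
    } else {
      per_image[[sid]] <- res$images
      per_specimen[[sid]] <- res$specimen
    }
  }
  if (length(per_specimen) == 0) {
    stop_pq("every specimen failed", "pq_study_failure")
  }
  per_image <- dplyr::bind_rows(per_image)
  per_specimen <- dplyr::bind_rows(per_specimen)

  stats_out <- study_statistics(per_specimen)

  manifest <- list(
    package_version = as.character(utils::packageVersion("pulleyquant")),
    mode = config$mode,
    seed = config$seed,
    k = config$k,
    cohort_seed = if (config$mode == "simulate") config$cohort$seed else NULL,
    n_specimens = nrow(per_specimen),
    errors = errors,
    notes = stats_out$notes
  )

  study <- structure(c(
    list(per_image = per_image, per_specimen = per_specimen),
    stats_out[c("grade_summary", "anova", "lsd", "contingency", "kappa",
                "icc", "boxplots")],
    list(errors = errors, notes = stats_out$notes, manifest = manifest)
  ), class = "pq_study")

  if (!is.null(config$out_dir)) write_study(study, config$out_dir)
  study
}

validate_grades <- function(labels) {
  ok_p <- labels$pathological_grade %in% c("L", "M", "H")
  ok_c <- labels$clinical_grade %in% c("I", "II", "III", "IV")
  if (!all(ok_p) || !all(ok_c)) {
    stop_pq("grade labels outside {L,M,H} / {I,II,III,IV}",
            "pq_invalid_labels")
  }
}

# Statistics layer over the per-specimen table: summaries, ANOVA + LSD per
# parameter per grading system, contingency + kappa, agreement ICC,
# boxplot summaries. Grade-I specimens are described but excluded from the
# II-IV comparisons, matching the study population.
study_statistics <- function(per_specimen) {
  notes <- character(0)
  params <- c(abn_sr = "mean_abn_sr", abn_nr = "mean_abn_nr")
  groupings <- c(pathological = "pathological_grade",
                 clinical = "clinical_grade")
  comparison <- per_specimen[
    is.na(per_specimen$clinical_grade) |
      per_specimen$clinical_grade != "I", , drop = FALSE]
  if (nrow(comparison) < nrow(per_specimen)) {
    notes <- c(notes, sprintf(
      "%d grade-I specimen(s) reported descriptively, excluded from comparisons",
      nrow(per_specimen) - nrow(comparison)))
  }

  grade_summary <- list(); anova <- list(); lsd <- list(); boxplots <- list()
  for (gname in names(groupings)) {
    gcol <- groupings[[gname]]
    for (pname in names(params)) {
      pcol <- params[[pname]]
      gs <- group_summary(comparison, pcol, gcol)
      grade_summary[[paste(pname, gname, sep = "_")]] <-
        dplyr::mutate(gs, parameter = pname, grouping = gname, .before = 1)
      usable <- gs[gs$n >= 2, ]
      key <- paste(pname, gname, sep = "_")
      if (nrow(usable) >= 2) {
        an <- anova_from_summary(usable)
        anova[[key]] <- an
        lsd[[key]] <- lsd_pairwise(an$groups, an$mse, an$df_within)
      } else {
        notes <- c(notes, sprintf(
          "insufficient groups for ANOVA: %s by %s", pname, gname))
      }
      boxplots[[key]] <- purrr::map_dfr(unique(gs$label), function(lv) {
        vals <- comparison[[pcol]][comparison[[gcol]] == lv]
        dplyr::mutate(boxplot_summary(vals), parameter = pname,
                      grouping = gname, label = lv, .before = 1)
      })
    }
  }

  cont <- grade_contingency(comparison)
  kappa <- tryCatch(cohens_kappa(cont), pulleyquant_error = function(e) {
    notes <<- c(notes, paste("kappa unavailable:", conditionMessage(e)))
    NULL
  })
  icc <- tryCatch({
    enc <- cbind(
      pathological = match(comparison$pathological_grade, c("L", "M", "H")),
      clinical = match(comparison$clinical_grade, c("II", "III", "IV"))
    )
    icc_inter_rater(enc)
  }, error = function(e) {
    notes <<- c(notes, paste("ICC unavailable:", conditionMessage(e)))
    NULL
  })

  list(
    grade_summary = dplyr::bind_rows(grade_summary),
    anova = anova, lsd = lsd,
    contingency = cont, kappa = kappa, icc = icc,
    boxplots = dplyr::bind_rows(boxplots),
    notes = notes
  )
}

# Serialize every result table of a study deterministically.
write_study <- function(study, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wcsv <- function(df, name) {
    utils::write.csv(df, file.path(out_dir, name), row.names = FALSE)
  }
  wcsv(study$per_image, "per_image.csv")
  wcsv(study$per_specimen, "per_specimen.csv")
  wcsv(study$grade_summary, "grade_summary.csv")
  if (length(study$anova)) {
    wcsv(purrr::map_dfr(names(study$anova), function(k) {
      dplyr::mutate(glance(study$anova[[k]]), analysis = k, .before = 1)
    }), "anova.csv")
    wcsv(purrr::map_dfr(names(study$lsd), function(k) {
      dplyr::mutate(study$lsd[[k]], analysis = k, .before = 1)
    }), "lsd_pairwise.csv")
  }
  cont_df <- as.data.frame(study$contingency)
  cont_df <- cbind(pathological_grade = rownames(study$contingency), cont_df)
  wcsv(cont_df, "contingency.csv")
  wcsv(dplyr::select(study$boxplots, -"outliers"), "boxplots.csv")
  report <- list(
    kappa = if (!is.null(study$kappa)) tidy(study$kappa),
    icc = if (!is.null(study$icc)) tidy(study$icc),
    manifest = study$manifest
  )
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' @export
print.pq_study <- function(x, ...) {
  cat(sprintf("<pq_study> %d specimens, %d images analyzed\n",
              nrow(x$per_specimen), nrow(x$per_image)))
  if (!is.null(x$kappa)) print(x$kappa)
  for (k in names(x$anova)) {
    cat(sprintf("  %s: p = %s\n", k,
                format.pval(x$anova[[k]]$p_value, digits = 3)))
  }
  if (length(x$notes)) cat("notes:", paste(x$notes, collapse = "; "), "\n")
  invisible(x)
}
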