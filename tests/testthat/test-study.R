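small_study_config <- function(out_dir = NULL, seed = 1L) {
  study_config(
    cohort = cohort_config(
      subjects_per_grade = c(L = 2L, M = 2L, H = 2L),
      images_per_specimen = 6L,
      phantom = phantom_config(width_px = 160, height_px = 120),
      clinical_mode = "exact", seed = 42
    ),
    k = 3L, seed = seed, out_dir = out_dir
  )
}

test_that("a small simulated study is internally consistent", {
  st <- cached("small_study", run_study(small_study_config()))
  expect_s3_class(st, "pq_study")
  expect_identical(nrow(st$per_specimen), 6L)
  expect_identical(nrow(st$per_image), 18L)
  expect_length(st$errors, 0)

  # grade-wise summary equals the group means of the per-specimen table
  gs <- st$grade_summary
  row <- gs[gs$parameter == "abn_sr" & gs$grouping == "pathological" &
              gs$label == "H", ]
  manual <- mean(st$per_specimen$mean_abn_sr[
    st$per_specimen$pathological_grade == "H"])
  expect_equal(row$mean, manual)

  # contingency counts specimens
  expect_identical(sum(st$contingency), 6L)
  expect_s3_class(st$kappa, "pq_kappa")
  expect_s3_class(st$icc, "pq_icc")
  expect_true(all(vapply(st$anova, inherits, TRUE, "pq_anova")))
})

test_that("identical configurations byte-reproduce every output file", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  run_study(small_study_config(out_dir = d1))
  run_study(small_study_config(out_dir = d2))
  files <- list.files(d1)
  expect_true(length(files) >= 6)
  for (f in files) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }
})

test_that("directory mode handles a single specimen with an explicit note", {
  dir <- withr::local_tempdir()
  coh <- generate_cohort(cohort_config(
    subjects_per_grade = c(L = 0L, M = 1L, H = 0L),
    images_per_specimen = 4L, unsuitable_fraction = 0,
    phantom = phantom_config(width_px = 160, height_px = 120), seed = 77
  ))
  for (id in coh$candidates$image_id) {
    write_image_png(render_candidate(coh, id)$image,
                    file.path(dir, paste0(id, ".png")))
  }
  labels <- data.frame(specimen_id = coh$specimens$specimen_id,
                       pathological_grade = "M", clinical_grade = "III")
  # the desk-scale canvas carries ~16 nuclei per tile, so the suitability
  # count threshold is lowered accordingly
  st <- run_study(study_config(mode = "directory", images_dir = dir,
                               labels = labels,
                               pipeline = pipeline_params(min_nuclei = 10),
                               k = 3L, seed = 2))
  expect_identical(nrow(st$per_specimen), 1L)
  expect_true(st$per_specimen$mean_abn_sr >= 0 &&
                st$per_specimen$mean_abn_sr <= 1)
  expect_length(st$anova, 0)
  expect_true(any(grepl("insufficient groups", st$notes)))
})

test_that("grade vocabularies are validated in directory mode", {
  labels <- data.frame(specimen_id = "x", pathological_grade = "Q",
                       clinical_grade = "II")
  expect_error(
    run_study(study_config(mode = "directory", images_dir = tempdir(),
                           labels = labels)),
    class = "pq_invalid_labels"
  )
})

test_that("masks and images survive a PNG round trip", {
  ph <- generate_phantom(phantom_config(width_px = 64, height_px = 48,
                                        seed = 31))
  dir <- withr::local_tempdir()
  ip <- file.path(dir, "img.png"); mp <- file.path(dir, "mask.png")
  write_image_png(ph$image, ip)
  back <- read_image_png(ip)
  expect_lte(max(abs(back - ph$image)), 1)  # 8-bit quantization only
  write_mask_png(ph$ground_truth$label_mask, mp)
  expect_identical(read_mask_png(mp), ph$ground_truth$label_mask)
})

test_that("plot builders return ggplot objects", {
  ph <- generate_phantom(phantom_config(width_px = 64, height_px = 48,
                                        seed = 31))
  expect_s3_class(autoplot(ph), "ggplot")
  expect_s3_class(plot_mask(ph$ground_truth$label_mask), "ggplot")
  st <- cached("small_study", run_study(small_study_config()))
  expect_s3_class(autoplot(st), "ggplot")
})
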