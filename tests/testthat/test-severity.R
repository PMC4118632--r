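test_that("Abn-SR is the abnormal share of tissue, background excluded", {
  mask <- matrix(0L, 40, 50)          # 2000 px
  mask[1:14, ] <- 1L                  # 700 normal
  mask[15:20, ] <- 2L                 # 300 abnormal
  expect_equal(compute_abn_sr(mask), 0.3)
  expect_equal(compute_abn_sr(matrix(1L, 5, 5)), 0)
  expect_identical(compute_abn_sr(matrix(0L, 5, 5)), NA_real_)
})

test_that("Abn-NR is the abnormal share of nuclei", {
  nuc <- tibble::tibble(class = rep(c("abnormal", "normal"), c(74, 26)))
  expect_equal(compute_abn_nr(nuc), 0.74)
  expect_equal(compute_abn_nr(tibble::tibble(class = rep("normal", 10))), 0)
  expect_identical(compute_abn_nr(tibble::tibble(class = character())),
                   NA_real_)
})

test_that("image selection discards unsuitable, is seeded and uniform", {
  cand <- tibble::tibble(
    image_id = sprintf("img%02d", 1:49),
    suitable = c(rep(TRUE, 10), rep(FALSE, 39))
  )
  # forced selection: exactly the 10 suitable regardless of seed
  expect_setequal(select_images(cand, k = 10, seed = 1),
                  cand$image_id[1:10])
  expect_setequal(select_images(cand, k = 10, seed = 99),
                  cand$image_id[1:10])

  all_ok <- tibble::tibble(image_id = sprintf("img%02d", 1:49),
                           suitable = TRUE)
  expect_identical(select_images(all_ok, k = 10, seed = 7),
                   select_images(all_ok, k = 10, seed = 7))

  none <- tibble::tibble(image_id = "a", suitable = FALSE)
  expect_error(select_images(none, k = 1), class = "pq_no_suitable_images")

  short <- tibble::tibble(image_id = c("a", "b"), suitable = TRUE)
  expect_warning(select_images(short, k = 5), class = "pq_short_selection")

  # uniformity: 20 suitable candidates, k = 10, selection frequency 1/2
  pool <- tibble::tibble(image_id = sprintf("c%02d", 1:20), suitable = TRUE)
  hits <- integer(20); names(hits) <- pool$image_id
  for (s in 1:10000) {
    sel <- select_images(pool, k = 10, seed = s)
    hits[sel] <- hits[sel] + 1L
  }
  freq <- hits / 10000
  expect_true(all(abs(freq - 0.5) <= 0.02))
})

test_that("specimen aggregation is the unweighted mean over defined ratios", {
  res <- tibble::tibble(image_id = c("a", "b"), abn_sr = c(0.2, 0.3),
                        abn_nr = c(0.5, 0.7))
  s <- summarize_specimen(res, "sp1", "L", "II")
  expect_equal(s$mean_abn_sr, 0.25)
  expect_equal(s$mean_abn_nr, 0.6)

  one <- summarize_specimen(res[1, ], "sp1")
  expect_equal(one$mean_abn_sr, 0.2)

  with_na <- tibble::tibble(image_id = c("a", "b", "c"),
                            abn_sr = c(0.2, NA, 0.4),
                            abn_nr = c(0.5, 0.5, NA))
  s2 <- summarize_specimen(with_na, "sp2")
  expect_equal(s2$mean_abn_sr, 0.3)
  expect_identical(s2$n_undefined_sr, 1L)

  all_na <- tibble::tibble(image_id = "a", abn_sr = NA_real_,
                           abn_nr = NA_real_)
  expect_error(summarize_specimen(all_na, "sp3"), class = "pq_all_undefined")
})

test_that("10-image specimen means concentrate around the true parameter", {
  # within-specimen jitter SD 0.02: the mean of 10 images is within 0.02 of
  # the specimen parameter in well over 95% of replicates
  set.seed(101)
  truth <- 0.2
  cover <- vapply(1:1000, function(i) {
    res <- tibble::tibble(
      image_id = as.character(1:10),
      abn_sr = truth + rnorm(10, 0, 0.02),
      abn_nr = 0.6 + rnorm(10, 0, 0.02)
    )
    abs(summarize_specimen(res, "s")$mean_abn_sr - truth) <= 0.02
  }, TRUE)
  expect_gte(mean(cover), 0.95)
})

test_that("pipeline estimates track phantom ground truth", {
  for (s in c(21, 22)) {
    ph <- test_phantom(seed = s, abnormal_fraction_target = 0.2,
                       abnormal_nucleus_fraction_target = 0.64)
    res <- analyze_phantom(ph)
    expect_lte(abs(res$abn_sr - res$true_abn_sr), 0.05)
    expect_lte(abs(res$abn_nr - res$true_abn_nr), 0.07)
    expect_true(res$abn_sr >= 0 && res$abn_sr <= 1)
    expect_true(res$abn_nr >= 0 && res$abn_nr <= 1)
  }
})
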