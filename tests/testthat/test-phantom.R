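test_that("degenerate abnormal fractions give exact ratios and pure classes", {
  p0 <- generate_phantom(phantom_config(width_px = 128, height_px = 96,
                                        seed = 2,
                                        abnormal_fraction_target = 0))
  expect_identical(sum(p0$ground_truth$label_mask == 2L), 0L)
  expect_identical(p0$ground_truth$realized_abn_sr, 0)
  expect_true(all(p0$ground_truth$nuclei$true_class == "normal"))

  p1 <- generate_phantom(phantom_config(width_px = 128, height_px = 96,
                                        seed = 2,
                                        abnormal_fraction_target = 1))
  expect_identical(p1$ground_truth$realized_abn_sr, 1)
  expect_true(all(p1$ground_truth$nuclei$true_class == "abnormal"))
})

test_that("ground truth is self-consistent over random configs", {
  set.seed(42)
  for (i in 1:12) {
    cfg <- phantom_config(
      width_px = 128, height_px = 96,
      abnormal_fraction_target = runif(1, 0.05, 0.6),
      background_fraction_target = runif(1, 0, 0.3),
      nucleus_density = runif(1, 5, 12),
      seed = sample.int(1e6, 1)
    )
    ph <- generate_phantom(cfg)
    gt <- ph$ground_truth
    lm <- gt$label_mask
    # ratios recompute exactly from the mask / nucleus list
    expect_identical(gt$realized_abn_sr, sum(lm == 2L) / sum(lm > 0L))
    expect_identical(gt$realized_abn_nr,
                     mean(gt$nuclei$true_class == "abnormal"))
    expect_gte(gt$realized_abn_sr, 0); expect_lte(gt$realized_abn_sr, 1)
    # every centroid sits inside its own tissue class
    codes <- lm[cbind(gt$nuclei$centroid_row, gt$nuclei$centroid_col)]
    expect_identical(codes,
                     ifelse(gt$nuclei$true_class == "abnormal", 2L, 1L))
    # shape separation between the classes
    ratio <- gt$nuclei$major_axis / gt$nuclei$minor_axis
    norm <- gt$nuclei$true_class == "normal"
    if (any(norm)) {
      expect_true(all(ratio[norm] >= min(cfg$normal_axis_ratio_range)))
    }
    if (any(!norm)) {
      expect_true(all(ratio[!norm] <= max(cfg$abnormal_axis_ratio_range)))
    }
  }
})

test_that("phantoms are deterministic, on-target, and monotone in the target", {
  ph <- generate_phantom(test_phantom_config(
    seed = 7, abnormal_fraction_target = 0.26))
  expect_gte(ph$ground_truth$realized_abn_sr, 0.24)
  expect_lte(ph$ground_truth$realized_abn_sr, 0.28)
  ph2 <- generate_phantom(test_phantom_config(
    seed = 7, abnormal_fraction_target = 0.26))
  expect_identical(ph, ph2)

  srs <- vapply(c(0.1, 0.3, 0.5, 0.7, 0.9), function(f) {
    generate_phantom(phantom_config(
      width_px = 128, height_px = 96, seed = 3,
      abnormal_fraction_target = f))$ground_truth$realized_abn_sr
  }, 1)
  expect_true(all(diff(srs) > 0))
  expect_true(all(abs(srs - c(0.1, 0.3, 0.5, 0.7, 0.9)) <= 0.02))
})

test_that("degrade_staining: identity, determinism, and channel scaling", {
  ph <- test_phantom(seed = 4)
  expect_identical(degrade_staining(ph$image, c(1, 1, 1), 0), ph$image)

  d1 <- degrade_staining(ph$image, c(1.1, 0.9, 1.0), 0.2, seed = 9)
  d2 <- degrade_staining(ph$image, c(1.1, 0.9, 1.0), 0.2, seed = 9)
  expect_identical(d1, d2)

  # unclipped mid-gray: channel means scale exactly with the shift
  gray <- array(100, dim = c(20, 30, 3))
  out <- degrade_staining(gray, c(1.2, 0.9, 1.0), 0)
  expect_equal(apply(out, 3, mean), c(120, 90, 100))
})

test_that("impossible nucleus geometry fails loudly, not silently", {
  cfg <- phantom_config(width_px = 96, height_px = 96,
                        abnormal_fraction_target = 0.04,
                        abnormal_nucleus_fraction_target = 0.9,
                        nucleus_density = 60, seed = 1)
  expect_error(generate_phantom(cfg), class = "pq_generation_failure")
})
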