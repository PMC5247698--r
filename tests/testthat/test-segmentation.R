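test_that("a vacuole-free field measures zero fat", {
  g <- generate_field(small_field_spec(fat = 0, seed = 6))
  s <- segment_fat(g$field)
  expect_equal(s$fat_area_um2, 0)
  expect_gt(s$parenchyma_area_um2, 0)
})

test_that("measured fraction tracks ground truth within one percentage point", {
  for (fat in c(0.05, 0.15)) {
    g <- generate_field(small_field_spec(fat = fat, seed = 21))
    s <- segment_fat(g$field)
    expect_lt(abs(100 * s$fraction - 100 * g$truth$true_fat_fraction), 1.0)
  }
})

test_that("segmentation masks satisfy their set invariants", {
  g <- generate_field(small_field_spec(fat = 0.1, seed = 13, artifact_density = 2))
  s <- segment_fat(g$field)
  expect_true(all(s$parenchyma_mask[s$fat_mask]))          # fat inside parenchyma
  expect_false(any(s$exclusion_mask & s$fat_mask))
  expect_false(any(s$exclusion_mask & s$parenchyma_mask))
  expect_equal(s$fat_area_um2, sum(s$fat_mask) * 0.5^2)
  expect_equal(s$parenchyma_area_um2, sum(s$parenchyma_mask) * 0.5^2)
})

test_that("an elongated sinusoid ribbon is excluded, not measured as fat", {
  g <- generate_field(small_field_spec(fat = 0, seed = 17, artifact_density = 2,
                                       artifact_kinds = "sinusoid"))
  expect_gt(sum(g$truth$artifact_mask), 0)
  s <- segment_fat(g$field)
  expect_equal(s$fat_area_um2, 0)
  expect_true(all(s$exclusion_mask[g$truth$artifact_mask]))
})

test_that("manual exclusion pixels never count as fat or parenchyma", {
  g <- generate_field(small_field_spec(fat = 0.1, seed = 19))
  manual <- matrix(FALSE, 256, 256)
  manual[1:64, 1:64] <- TRUE
  s <- segment_fat(g$field, manual_exclusion = manual)
  expect_false(any(s$fat_mask[manual]))
  expect_false(any(s$parenchyma_mask[manual]))
  expect_true(all(s$exclusion_mask[manual]))
})

test_that("mFPA is scale-invariant under resampling of the same scene", {
  g <- generate_field(field_spec(target_fat_fraction = 0.1, seed = 23))
  s1 <- segment_fat(g$field)
  half <- g$field$pixels[seq(1, 512, 2), seq(1, 512, 2), , drop = FALSE]
  s2 <- segment_fat(rgb_field(half, um_per_px = 1.0, field_id = "half"))
  expect_lt(abs(100 * s1$fraction - 100 * s2$fraction), 0.5)
})

test_that("uncalibrated or degenerate fields are refused", {
  g <- generate_field(small_field_spec(fat = 0.05, seed = 3))
  bad <- g$field; bad$um_per_px <- -1
  expect_error(segment_fat(bad), "calibrated")
  white <- rgb_field(array(255L, dim = c(64, 64, 3)), um_per_px = 0.5)
  expect_error(segment_fat(white), "no tissue")
  expect_error(segment_fat(g$field, manual_exclusion = matrix(FALSE, 3, 3)),
               "dimensions")
})

test_that("aggregation pools areas rather than averaging percentages", {
  r1 <- fake_seg_result(10, 100, "f1")
  r2 <- fake_seg_result(30, 100, "f2")
  expect_equal(aggregate_mfpa(list(r1, r2))$mfpa_pct, 20.0)
  expect_equal(aggregate_mfpa(list(fake_seg_result(50, 50)))$mfpa_pct, 100.0)
  # unequal parenchyma: pooled ratio, not mean of ratios
  r3 <- fake_seg_result(10, 40, "f3")   # 25%
  r4 <- fake_seg_result(10, 160, "f4")  # 6.25%
  expect_equal(aggregate_mfpa(list(r3, r4))$mfpa_pct, 100 * 20 / 200)
  # equal parenchyma: pooled equals the mean of per-field fractions exactly
  fr <- c(0.1, 0.25, 0.4)
  rs <- lapply(fr, function(f) fake_seg_result(f * 100, 100))
  expect_equal(aggregate_mfpa(rs)$mfpa_pct, 100 * mean(fr))
})

test_that("aggregation rejects empty input and zero-parenchyma fields by name", {
  expect_error(aggregate_mfpa(list()), "no field results")
  expect_error(aggregate_mfpa(list(fake_seg_result(0, 0, "empty_field"))),
               "empty_field")
})

test_that("field sampling is uniform, without replacement, and seeded", {
  cand <- as.list(1:100)
  s1 <- sample_fields(cand, 21, seed = 7)
  s2 <- sample_fields(cand, 21, seed = 7)
  expect_identical(s1, s2)
  expect_equal(length(unique(unlist(s1))), 21)
  expect_identical(sort(unlist(sample_fields(as.list(1:21), 21, seed = 1))), 1:21)
  expect_error(sample_fields(as.list(1:10), 21), "candidate")
  # binomial uniformity: each candidate picked with frequency ~ 21/100
  hits <- integer(100)
  for (seed in 1:1000) {
    idx <- unlist(sample_fields(cand, 21, seed = seed))
    hits[idx] <- hits[idx] + 1L
  }
  freq <- hits / 1000
  expect_true(all(abs(freq - 0.21) <= 0.04))
})

test_that("adequacy check flags stable and unstable running estimates", {
  expect_true(adequacy_check(rep(0.1, 10)))
  expect_false(adequacy_check(rep(c(0, 0.30), 5)))
  expect_error(adequacy_check(rep(0.1, 3), window = 5), "at least 5")
  expect_error(adequacy_check(rep(0.1, 10), window = 1), "window")
  # converges once enough stable fields accumulate after an early swing
  expect_true(adequacy_check(c(0.3, rep(0.1, 30))))
})
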