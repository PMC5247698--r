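test_that("zero fat fraction yields an empty fat mask", {
  g <- generate_field(small_field_spec(fat = 0, seed = 3))
  expect_equal(g$truth$true_fat_fraction, 0)
  expect_false(any(g$truth$fat_mask))
  expect_equal(nrow(g$truth$vacuoles), 0)
})

test_that("rendered fat fraction hits the target within rasterisation slack", {
  for (seed in 1:3) {
    g <- generate_field(field_spec(target_fat_fraction = 0.10, seed = seed))
    expect_gte(g$truth$true_fat_fraction, 0.095)
    expect_lte(g$truth$true_fat_fraction, 0.105)
    # ground truth consistent with its own mask
    expect_equal(g$truth$true_fat_fraction,
                 sum(g$truth$fat_mask) / length(g$truth$fat_mask))
  }
})

test_that("identical seeds give bit-identical fields", {
  s <- small_field_spec(fat = 0.08, seed = 42, artifact_density = 2)
  g1 <- generate_field(s)
  g2 <- generate_field(s)
  expect_identical(g1$field$pixels, g2$field$pixels)
  expect_identical(g1$truth$fat_mask, g2$truth$fat_mask)
  expect_identical(g1$truth$artifact_mask, g2$truth$artifact_mask)
})

test_that("fat and artifact ground-truth masks are disjoint", {
  for (seed in 1:5) {
    g <- generate_field(small_field_spec(fat = 0.1, seed = seed,
                                         artifact_density = 3))
    expect_false(any(g$truth$fat_mask & g$truth$artifact_mask))
  }
})

test_that("artifact-free ground truth equals the rendered white pixels", {
  g <- generate_field(small_field_spec(fat = 0.12, seed = 9))
  white <- g$field$pixels[, , 1] >= 200 & g$field$pixels[, , 2] >= 200 &
           g$field$pixels[, , 3] >= 200
  expect_identical(unname(which(white)), which(g$truth$fat_mask))
})

test_that("vacuoles never overlap and stay inside the field", {
  g <- generate_field(small_field_spec(fat = 0.25, seed = 5))
  v <- g$truth$vacuoles
  expect_true(all(v$x - v$r >= 1 & v$x + v$r <= 256))
  expect_true(all(v$y - v$r >= 1 & v$y + v$r <= 256))
  if (nrow(v) > 1) {
    d <- as.matrix(dist(cbind(v$x, v$y)))
    rsum <- outer(v$r, v$r, `+`)
    diag(d) <- Inf
    expect_true(all(d > rsum))
  }
})

test_that("infeasible packing fails loudly, naming the achieved fraction", {
  expect_error(field_spec(target_fat_fraction = 0.7), "packing")
  expect_error(
    generate_field(small_field_spec(fat = 0.55, seed = 1), max_retries = 50L),
    "achieved fat fraction")
})

test_that("spec validation rejects bad geometry and calibration", {
  expect_error(field_spec(width_px = 32), "width_px")
  expect_error(field_spec(um_per_px = 0), "um_per_px")
  expect_error(field_spec(vacuole_diameter_um = c(80, 10)), "vacuole_diameter_um")
  expect_error(field_spec(target_fat_fraction = -0.1), "target_fat_fraction")
})

test_that("field round-trips through PNG and TIFF with sidecar calibration", {
  g <- generate_field(small_field_spec(fat = 0.05, seed = 2))
  for (ext in c("png", "tiff")) {
    path <- file.path(withr::local_tempdir(), paste0("field.", ext))
    write_field(g$field, path, truth = g$truth)
    back <- read_field(path)
    expect_identical(back$pixels, g$field$pixels)
    expect_equal(back$um_per_px, g$field$um_per_px)
    # ground-truth sidecar retains the exact fat fraction
    sc <- jsonlite::read_json(sub(paste0("\\.", ext, "$"), ".json", path))
    expect_equal(sc$true_fat_fraction, g$truth$true_fat_fraction)
  }
})

test_that("reading an image without calibration is refused", {
  g <- generate_field(small_field_spec(fat = 0.02, seed = 8))
  path <- file.path(withr::local_tempdir(), "bare.png")
  png::writePNG(g$field$pixels / 255, path)
  expect_error(read_field(path), "calibration")
  expect_silent(read_field(path, um_per_px = 0.5))
})
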