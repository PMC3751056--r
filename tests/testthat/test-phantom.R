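test_that("phantom generation is exactly reproducible from its seed", {
  p <- phantom_params(speckle_contrast = 0.5, blob_count = 3,
                      branch_sectors = list(c(40, 25)), seed = 123)
  a <- generate_phantom(p)
  b <- generate_phantom(p)
  expect_identical(a$image, b$image)
  expect_identical(a$gold, b$gold)

  # the caller's RNG stream is not disturbed
  set.seed(99); x1 <- runif(3)
  set.seed(99); invisible(generate_phantom(p)); x2 <- runif(3)
  expect_identical(x1, x2)
})

test_that("the noise-free phantom is a clean ring with an analytic gold disk", {
  p <- phantom_params(speckle_contrast = 0, eccentricity = 0,
                      perturb_amp = 0, alignment_mark = FALSE,
                      blob_count = 0, seed = 1)
  ph <- generate_phantom(p)
  side <- p$side_px
  expect_identical(ph$gold, disk_mask(side, p$lumen_radius_mm / ph$meta$px_mm))

  # intensity equals the analytic profile at probe depths
  cc <- (side + 1) / 2
  r_b <- (p$lumen_radius_mm + 0.2) / ph$meta$px_mm   # 0.2 mm into the wall
  val <- ph$image[round(cc), round(cc + r_b)]        # east, gain = 1 at angle 0
  expect_equal(val, p$tissue_intensity * exp(-p$attenuation_per_mm * 0.2),
               tolerance = 0.05)
  # lumen interior is dark except the catheter ring
  inner <- disk_mask(side, 10)
  expect_true(all(ph$image[inner] == 0))
})

test_that("branch sectors suppress exactly the recorded polar columns", {
  p <- phantom_params(speckle_contrast = 0, alignment_mark = FALSE,
                      branch_sectors = list(c(90, 20)), seed = 4)
  ph <- generate_phantom(p)
  pol <- cartesian_to_polar(ph$image, 200, 630)
  cols <- ph$meta$branch_cols[[1]]
  expect_gt(length(cols), 25)
  # exclude the catheter ring rows and the half-pixel interpolation bleed
  # at the sector edges; interior shadow columns carry no tissue signal
  interior <- cols[3:(length(cols) - 2)]
  means_in <- colMeans(unclass(pol)[30:200, interior])
  other <- setdiff(seq_len(630), c(cols, cols + 3, cols - 3))
  means_out <- colMeans(unclass(pol)[30:200, other])
  expect_lt(max(means_in), 1e-6)
  expect_gt(min(means_out), 0.001)
  # recorded columns match the sector angles (90-110 degrees)
  expect_lte(abs(min(cols) - (floor(90 / 360 * 630) + 1)), 1)
  expect_lte(abs(max(cols) - (floor(110 / 360 * 630) + 1)), 1)
})

test_that("gold masks are simply connected and centered", {
  suite <- generate_suite(6, "hard", seed = 31)
  for (ph in suite) {
    g <- ph$gold
    expect_equal(max(label_components(g)), 1)
    expect_equal(max(label_components(!g)), 1)   # no holes
    cc <- round(ph$meta$center)
    expect_true(g[cc[1], cc[2]])
  }
})

test_that("speckle is multiplicative with unit mean", {
  base <- phantom_params(speckle_contrast = 0, eccentricity = 0,
                         perturb_amp = 0, alignment_mark = FALSE, seed = 1)
  clean <- generate_phantom(base)$image
  side <- base$side_px
  acc <- matrix(0, side, side)
  n_rep <- 40
  for (s in seq_len(n_rep)) {
    p <- phantom_params(speckle_contrast = 0.5, eccentricity = 0,
                        perturb_amp = 0, alignment_mark = FALSE, seed = 1000 + s)
    acc <- acc + generate_phantom(p)$image
  }
  avg <- acc / n_rep
  # probe a bright shallow annulus of the wall
  cc <- (side + 1) / 2
  r_px <- sqrt(outer((seq_len(side) - cc)^2, (seq_len(side) - cc)^2, "+"))
  probe <- r_px > (base$lumen_radius_mm / 0.015 + 3) &
    r_px < (base$lumen_radius_mm / 0.015 + 15)
  expect_equal(mean(avg[probe]), mean(clean[probe]), tolerance = 0.05)
})

test_that("suites are reproducible and differ across cases", {
  s1 <- generate_suite(5, "easy", seed = 9)
  s2 <- generate_suite(5, "easy", seed = 9)
  expect_identical(lapply(s1, `[[`, "image"), lapply(s2, `[[`, "image"))
  areas <- vapply(s1, function(ph) sum(ph$gold), numeric(1))
  expect_gt(length(unique(areas)), 1)
  expect_true(all(vapply(s1, function(ph)
    length(ph$params$branch_sectors) == 0, logical(1))))
  hard <- generate_suite(5, "hard", seed = 9)
  expect_true(all(vapply(hard, function(ph)
    length(ph$params$branch_sectors) >= 1, logical(1))))
})

test_that("impossible geometries are rejected", {
  expect_error(phantom_params(lumen_radius_mm = 2.5, wall_thickness_mm = 1),
               "field of view")
  expect_error(phantom_params(eccentricity = 1.1), "collapses")
  expect_error(phantom_params(branch_sectors = list(c(0, 200))), "width")
})
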