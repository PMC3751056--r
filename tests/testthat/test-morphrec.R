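test_that("disk structuring elements follow the center-in-radius rule", {
  expect_identical(disk_se(3), matrix(1L, 3, 3))
  expect_identical(disk_se(2), matrix(c(0L, 1L, 0L, 1L, 1L, 1L, 0L, 1L, 0L), 3, 3))
  expect_identical(disk_se(1), matrix(1L, 1, 1))
})

test_that("polar reconstruction cleans speckle and closes small notches", {
  n_r <- 200; n_theta <- 630
  clean <- step_mask(n_r, n_theta, 121)

  expect_identical(bare(polar_reconstruct(clean, 20)), clean)


  # isolated lumen speckles vanish under the 3-px opening
  noisy <- clean
  set.seed(3)
  spots <- cbind(sample(5:100, 10), sample(seq(10, 620, length.out = 10)))
  noisy[spots] <- TRUE
  expect_identical(bare(polar_reconstruct(noisy, 20)), clean)

  # a 2-px-deep boundary notch is closed to within one row
  notched <- clean
  notched[121:122, 300:304] <- FALSE
  rec <- polar_reconstruct(notched, 20)
  h <- height_signal(rec)
  expect_true(all(abs(as.numeric(h) - 120) <= 1))

  expect_error(polar_reconstruct(matrix(FALSE, n_r, n_theta), 20), "no tissue")
})

test_that("polar reconstruction is idempotent on its own output", {
  n_r <- 200; n_theta <- 630
  m <- step_mask(n_r, n_theta, 121)
  m[50:70, 100:140] <- TRUE
  m[130:140, 400:420] <- FALSE
  once <- polar_reconstruct(m, 20)
  twice <- polar_reconstruct(once, 20)
  expect_identical(bare(twice), bare(once))
})

test_that("the reconstructed object is bottom-attached and single", {
  n_r <- 200; n_theta <- 630
  set.seed(15)
  base <- round(120 + 15 * sin(2 * pi * seq_len(n_theta) / n_theta))
  m <- outer(seq_len(n_r), base, ">=")
  m[cbind(sample(30:80, 25, TRUE), sample(n_theta, 25))] <- TRUE
  rec <- polar_reconstruct(m, 20)
  expect_true(all(rec[n_r, ]))                       # bottom row solid
  lab <- label_components(rec, circular = TRUE)
  expect_equal(max(lab), 1)
  lab_lumen <- label_components(!rec, circular = TRUE)
  expect_equal(max(lab_lumen), 1)                    # lumen attached to top
})

test_that("height signal and rebuild invert each other", {
  n_r <- 200; n_theta <- 630
  expect_true(all(as.numeric(height_signal(matrix(TRUE, 10, 16))) == 0))
  expect_true(all(as.numeric(height_signal(step_mask(n_r, n_theta, 121))) == 120))

  m <- step_mask(n_r, n_theta, 121)
  m[, 100:140] <- FALSE
  h <- height_signal(m)
  expect_true(all(as.numeric(h)[100:140] == n_r))
  expect_true(all(as.numeric(h)[-(100:140)] == 120))

  expect_identical(rebuild_from_height(structure(rep(0L, 16), n_r = 10),
                                       c(10, 16)),
                   matrix(TRUE, 10, 16))
  expect_identical(rebuild_from_height(structure(rep(10L, 16), n_r = 10),
                                       c(10, 16)),
                   matrix(FALSE, 10, 16))

  set.seed(8)
  for (i in 1:5) {
    h0 <- sample(0:200, 630, replace = TRUE)
    mk <- outer(0:199, h0, ">=")
    expect_identical(as.numeric(height_signal(mk)),
                     as.numeric(pmin(h0, 200)))
    expect_identical(rebuild_from_height(structure(h0, n_r = 200),
                                         c(200, 630)), mk)
  }
})

test_that("gap detection recovers constructed shadow runs", {
  n <- 630
  h_const <- structure(rep(120L, n), n_r = 200, class = "height_signal")
  expect_length(detect_gaps(h_const), 0)

  # one outward run (empty columns)
  h1 <- rep(120L, n); h1[300:360] <- 200L
  g1 <- detect_gaps(structure(h1, n_r = 200, class = "height_signal"))
  expect_length(g1, 1)
  expect_lte(abs(g1[[1]]$start - 300), 2)
  expect_lte(abs(g1[[1]]$end - 360), 2)

  # two disjoint runs of 40 columns
  h2 <- rep(120L, n); h2[101:140] <- 200L; h2[401:440] <- 200L
  g2 <- detect_gaps(structure(h2, n_r = 200, class = "height_signal"))
  expect_length(g2, 2)
  starts <- sort(vapply(g2, `[[`, numeric(1), "start"))
  ends <- sort(vapply(g2, `[[`, numeric(1), "end"))
  expect_lte(max(abs(starts - c(101, 401))), 2)
  expect_lte(max(abs(ends - c(140, 440))), 2)

  # inward run (artifact-flooded columns) is found too
  h3 <- rep(120L, n); h3[201:230] <- 10L
  g3 <- detect_gaps(structure(h3, n_r = 200, class = "height_signal"))
  expect_length(g3, 1)
  expect_lte(abs(g3[[1]]$start - 201), 2)
  expect_lte(abs(g3[[1]]$end - 230), 2)
})

test_that("gap correction restores constants exactly and sinusoids closely", {
  n <- 630
  h <- structure(rep(120L, n), n_r = 200, class = "height_signal")
  expect_identical(correct_gaps(h, list()), h)

  h1 <- rep(120L, n); h1[300:360] <- 200L
  hs1 <- structure(h1, n_r = 200, class = "height_signal")
  fixed <- correct_gaps(hs1, detect_gaps(hs1))
  expect_true(all(as.numeric(fixed) == 120))

  true_h <- 120 + 10 * sin(2 * pi * seq_len(n) / n)
  h2 <- as.integer(round(true_h)); gap_cols <- 201:240
  h2[gap_cols] <- 200L
  hs2 <- structure(h2, n_r = 200, class = "height_signal")
  fixed2 <- correct_gaps(hs2, detect_gaps(hs2))
  expect_lte(max(abs(as.numeric(fixed2)[gap_cols] - true_h[gap_cols])), 3)

  # a wrap-around gap is interpolated across the seam
  h3 <- as.integer(round(true_h)); h3[c(611:630, 1:20)] <- 200L
  hs3 <- structure(h3, n_r = 200, class = "height_signal")
  fixed3 <- correct_gaps(hs3, detect_gaps(hs3))
  expect_lte(max(abs(as.numeric(fixed3)[c(611:630, 1:20)] -
                       true_h[c(611:630, 1:20)])), 3)
})

test_that("detect-correct-rebuild leaves gap-free signals unchanged", {
  n <- 630
  set.seed(21)
  for (i in 1:5) {
    smooth <- round(120 + 12 * sin(2 * pi * (1:n) / n + runif(1, 0, 6)) +
                      3 * sin(6 * pi * (1:n) / n))
    hs <- structure(as.integer(smooth), n_r = 200, class = "height_signal")
    gaps <- detect_gaps(hs)
    out <- correct_gaps(hs, gaps)
    expect_identical(as.numeric(out), as.numeric(hs))
    expect_identical(rebuild_from_height(out, c(200, n)),
                     rebuild_from_height(hs, c(200, n)))
  }
})

test_that("Cartesian reconstruction produces the analytic lumen disk", {
  side <- 400
  pol0 <- cartesian_to_polar(matrix(0, side, side), 200, 630)
  mk <- structure(step_mask(200, 630, 101),
                  r_scale_px = attr(pol0, "r_scale_px"),
                  center = attr(pol0, "center"), side_px = side)
  lum <- cartesian_reconstruct(mk)
  R <- 100 * attr(pol0, "r_scale_px")
  expect_gte(dice(lum, disk_mask(side, R)), 0.97)

  # an inward 1-column spike is removed by the adaptive opening: the
  # result stays close to the disk and carries no thin notch (a 3-px
  # closing adds almost nothing), unlike the unopened transform
  spiked <- mk
  spiked[61:200, 50] <- TRUE
  spiked <- structure(spiked, r_scale_px = attr(pol0, "r_scale_px"),
                      center = attr(pol0, "center"), side_px = side)
  lum2 <- cartesian_reconstruct(spiked)
  expect_gte(dice(lum2, disk_mask(side, R)), 0.97)
  raw <- polar_to_cartesian(structure((!spiked) * 1.0,
                                      r_scale_px = attr(pol0, "r_scale_px"),
                                      center = attr(pol0, "center"),
                                      side_px = side)) >= 0.5
  notch <- function(m) {
    cl <- EBImage::closing(m * 1, matrix(1, 3, 3))
    sum(as.numeric(cl) > 0.5 & !m)
  }
  expect_lt(notch(lum2), notch(raw) / 2)

  expect_error(cartesian_reconstruct(
    structure(matrix(TRUE, 200, 630), r_scale_px = 1, center = c(200.5, 200.5),
              side_px = side)), "lumen not found")
})

test_that("contour extraction traces closed boundaries of the right length", {
  sq <- matrix(FALSE, 30, 30); sq[11:20, 11:20] <- TRUE
  ct <- extract_contour(sq)
  expect_equal(ct[1, ], ct[nrow(ct), ], ignore_attr = TRUE)
  per <- sum(sqrt(diff(ct$x)^2 + diff(ct$y)^2))
  expect_equal(per, 40, tolerance = 0.1)

  dk <- disk_mask(201, 50)
  ctd <- extract_contour(dk)
  perd <- sum(sqrt(diff(ctd$x)^2 + diff(ctd$y)^2))
  expect_equal(perd, 2 * pi * 50, tolerance = 0.05)
  expect_gte(nrow(ctd), 8)

  expect_error(extract_contour(matrix(FALSE, 5, 5)), "empty")
})

test_that("component labeling honors 8-connectivity and the angular seam", {
  m <- matrix(FALSE, 5, 6)
  m[1, 1] <- TRUE; m[2, 2] <- TRUE          # diagonal pair
  m[5, 1] <- TRUE; m[5, 6] <- TRUE          # seam pair
  expect_equal(max(label_components(m, circular = FALSE)), 3)
  expect_equal(max(label_components(m, circular = TRUE)), 2)
  lab <- label_components(m, circular = TRUE)
  expect_equal(lab[5, 1], lab[5, 6])
  expect_equal(lab[1, 1], lab[2, 2])
})
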