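test_that("sharpness index matches the analytic blurred-edge oracle", {
  # Phi^-1(0.8) - Phi^-1(0.2) = 1.6832...: 80-20% distance of an erf edge
  ny <- 64; nx <- 96; x0 <- 48
  for (sigma_b in c(1, 2, 3, 4)) {
    img <- erf_edge_image(ny, nx, x0, sigma_b)
    ys <- seq(20, 44, length.out = 7)
    curves <- interface_curves(
      myo_points = cbind(ys, x0 + 12),    # low side
      blood_points = cbind(ys, x0 - 12),  # high side
      pixel_spacing = c(1, 1))
    got <- sharpness_index(img, curves)
    want <- 1 / (1.6832 * sigma_b)
    expect_equal(got$slice, want, tolerance = 0.03)
    expect_identical(got$n_valid, 7L)
  }
  # strictly decreasing with blur
  vals <- vapply(1:4, function(s) {
    sharpness_index(erf_edge_image(ny, nx, x0, s), interface_curves(
      cbind(seq(20, 44, length.out = 7), x0 + 12),
      cbind(seq(20, 44, length.out = 7), x0 - 12), c(1, 1)))$slice
  }, numeric(1))
  expect_true(all(diff(vals) < 0))
  # doubling the pixel spacing halves the index of the same pixel profile
  img <- erf_edge_image(ny, nx, x0, 2)
  cur1 <- interface_curves(cbind(seq(20, 44, length.out = 7), x0 + 12),
                           cbind(seq(20, 44, length.out = 7), x0 - 12), c(1, 1))
  cur2 <- interface_curves(cbind(seq(20, 44, length.out = 7), x0 + 12),
                           cbind(seq(20, 44, length.out = 7), x0 - 12), c(2, 2))
  expect_equal(sharpness_index(img, cur1)$slice,
               2 * sharpness_index(img, cur2)$slice, tolerance = 1e-10)
  # flat image: every profile excluded
  expect_error(sharpness_index(matrix(1, ny, nx), cur1), "excluded")
  expect_error(interface_curves(cbind(1:3, 1), cbind(1:3, 2), c(1, 1)),
               "at least 5")
})

test_that("noise estimate targets the averaged-image noise", {
  set.seed(31)
  ny <- 80; nx <- 80
  clean <- matrix(runif(ny * nx), ny, nx)
  roi <- matrix(FALSE, ny, nx); roi[11:70, 11:50] <- TRUE   # 2400 px
  sigma <- 0.08
  mk <- function() clean + matrix(rnorm(ny * nx, sd = sigma), ny)
  expect_equal(noise_estimate(clean, clean, roi)$Ne, 0)
  ne <- noise_estimate(mk(), mk(), roi)
  expect_equal(ne$sigma_d, sigma * sqrt(2), tolerance = 0.05)
  expect_equal(ne$Ne, sigma / sqrt(6), tolerance = 0.05)
  # against the empirical noise of a 6-average
  avg6 <- Reduce(`+`, replicate(6, mk(), simplify = FALSE)) / 6
  expect_equal(ne$Ne, sd((avg6 - clean)[roi]), tolerance = 0.1)
  expect_error(noise_estimate(clean, clean, matrix(FALSE, ny, nx)), "empty")
  expect_error(noise_estimate(clean, clean[1:10, ], roi), "match")
})

test_that("CNRe is contrast over noise", {
  img <- matrix(4, 10, 10)
  a <- matrix(FALSE, 10, 10); a[1:5, ] <- TRUE
  b <- !a
  img[a] <- 10
  expect_equal(cnre(img, a, b, 0.5), 12)
  expect_equal(cnre(img, a, a, 0.5), 0)
  expect_equal(cnre(img, b, a, 0.5), 12)               # absolute by default
  expect_equal(cnre(img, b, a, 0.5, signed = TRUE), -12)
  expect_equal(cnre(img, a, b, 1.0), cnre(img, a, b, 0.5) / 2)
  expect_error(cnre(img, a, b, 0), "Ne")
})

test_that("scar volume is exact mask arithmetic", {
  m <- matrix(FALSE, 32, 32)
  m[1:10, 1:10] <- TRUE   # 100 px
  expect_equal(scar_volume(list(m), c(1.48, 1.98), 8), 2.34432)
  expect_equal(scar_volume(list(m, m), c(1.48, 1.98), 8), 2 * 2.34432)
  expect_equal(scar_volume(array(FALSE, c(8, 8, 3)), c(1, 1), 8), 0)
  expect_error(scar_volume(list(m), c(0, 1), 8), "> 0")
})

test_that("scar area estimator is area-preserving under blur", {
  # disk of known area blurred by a Gaussian on a zero background
  ny <- nx <- 96
  yy <- matrix(1:ny, ny, nx); xx <- matrix(rep(1:nx, each = ny), ny, nx)
  disk <- (yy - 48)^2 + (xx - 48)^2 <= 14^2
  img <- smslge:::gaussian_smooth(disk * 0.34, 1.5)
  region <- matrix(TRUE, ny, nx)
  est <- scar_area_fraction(img, region)
  expect_equal(est, sum(disk), tolerance = 0.05)
  # the plain half-maximum mask is close on a clean symmetric edge
  expect_equal(sum(segment_scar_fwhm(img, region)), sum(disk),
               tolerance = 0.05)
  expect_error(scar_area_fraction(img, matrix(FALSE, ny, nx)), "empty")
})

test_that("protocol arithmetic reproduces the clinical prescription", {
  sms <- protocol_params(n_slices = 16, multiband = 2, n_reps = 8,
                         rr_per_image = 2, inplane_accel = 5,
                         phase_oversampling = 2)
  ref <- protocol_params(n_slices = 16, multiband = 1, n_reps = 8,
                         rr_per_image = 2, inplane_accel = 3,
                         phase_oversampling = 1.2)
  cs <- protocol_counts(sms)
  cr <- protocol_counts(ref)
  expect_identical(cs$heartbeats, 128L)
  expect_identical(cr$heartbeats, 256L)
  expect_equal(cs$accel_nominal_inplane, 2.5)
  expect_equal(cr$accel_nominal_inplane, 2.5)
  expect_equal(cs$accel_total, 5)
  expect_equal(cr$accel_total, 2.5)
  expect_length(cs$slice_pairs, 8)
  expect_identical(cs$slice_pairs[[1]], c(1L, 9L))
})

test_that("mask morphology shrinks and grows as expected", {
  m <- matrix(FALSE, 20, 20)
  m[5:15, 5:15] <- TRUE
  e <- erode_mask(m, 2)
  expect_identical(sum(e), 49L)          # 11x11 -> 7x7
  expect_true(all(m[e]))
  d <- smslge:::dilate_mask(m, 1)
  expect_identical(sum(d), 169L)         # 13x13
})
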