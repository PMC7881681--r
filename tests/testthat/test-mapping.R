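test_that("noiseless two-compartment map recovers truth at every fitted pixel", {
  spec <- phantom_spec(
    shape = c(24, 24),
    compartments = list(
      compartment(rect_region(c(1, 24), c(1, 12)), t1_ms = 400),
      compartment(disk_region(c(12, 18), 5), t1_ms = 1000)),
    scheme = "pre_5(3)3", seed = 1)
  ph <- generate_phantom(spec)
  for (method in c("RD", "LM")) {
    map <- compute_t1_map(ph$stack, method)
    expect_true(all(map$valid == ph$truth$tissue))
    expect_lt(max(abs(map$t1[map$valid] - ph$truth$t1[map$valid])), 0.1)
  }
})

test_that("threshold masks sub-threshold pixels and is monotone", {
  ph <- small_phantom(shape = c(16, 16))
  map0 <- compute_t1_map(ph$stack, "RD", threshold = 0)
  # air pixels are exactly zero, so threshold 0 already excludes them
  expect_equal(sum(!map0$valid), sum(!ph$truth$tissue))
  # the myocardial asymptote a + c = 150 < blood's 200: a threshold between
  # the two compartments' peak signals removes exactly the dimmer one
  peak_myo <- max(ph$stack$voxels[phantom_mask(ph, 1)])
  map1 <- compute_t1_map(ph$stack, "RD", threshold = peak_myo)
  expect_true(all(map1$valid <= map0$valid))        # valid set shrinks
  expect_true(all(!map1$valid[phantom_mask(ph, 1)]))
  expect_true(all(map1$valid[phantom_mask(ph, 2)]))
})

test_that("clamp limit invalidates rather than clips out-of-range fits", {
  ph <- small_phantom(shape = c(16, 16))   # compartments at 950 and 1500 ms
  map <- compute_t1_map(ph$stack, "RD", clamp_limit = 1200)
  expect_true(all(!map$valid[phantom_mask(ph, 2)]))  # blood 1500 ms excluded
  expect_true(all(map$valid[phantom_mask(ph, 1)]))
  expect_true(all(map$t1[map$valid] <= 1200))
  expect_true(all(is.na(map$t1[!map$valid])))
})

test_that("worker count does not change the result bit for bit", {
  ph <- small_phantom(noise_sigma = 6, seed = 3, shape = c(16, 16))
  m1 <- compute_t1_map(ph$stack, "RD", workers = 1)
  m4 <- compute_t1_map(ph$stack, "RD", workers = 4)
  expect_identical(m1$t1, m4$t1)
  expect_identical(m1$rss, m4$rss)
  expect_identical(m1$valid, m4$valid)
})

test_that("pixel report reproduces the fit and flags invalid pixels", {
  ph <- small_phantom(noise_sigma = 4, seed = 9, shape = c(16, 16))
  idx <- which(phantom_mask(ph, 1), arr.ind = TRUE)[1, ]
  rep <- fit_pixel_report(ph$stack, idx[1], idx[2], "RD")
  expect_true(rep$fit$converged)
  series <- ti_series(ph$stack$tis, ph$stack$voxels[idx[1], idx[2], ])
  signs <- sign_vector(rep$fit$flip_count, length(series$tis))
  expect_equal(rep$fit$rss, residual_cost(rep$fit$params, series, signs),
               tolerance = 1e-8)
  expect_equal(nrow(rep$curve), 200)
  expect_equal(max(rep$curve$t), max(ph$stack$tis))
  # noiseless pixel: curve passes through every sample
  ph0 <- small_phantom(shape = c(16, 16))
  idx0 <- which(phantom_mask(ph0, 2), arr.ind = TRUE)[1, ]
  rep0 <- fit_pixel_report(ph0$stack, idx0[1], idx0[2], "RD")
  expect_lt(rep0$fit$rss, 1e-6)
  # air pixel: flagged not converged
  air <- which(!ph0$truth$tissue, arr.ind = TRUE)[1, ]
  expect_false(fit_pixel_report(ph0$stack, air[1], air[2], "RD")$fit$converged)
  expect_error(fit_pixel_report(ph0$stack, 0, 1), "out of bounds")
  expect_error(fit_pixel_report(ph0$stack, 1, 17), "out of bounds")
})

test_that("stack construction validates protocol slice counts and sorts TIs", {
  vox <- array(1, c(4, 4, 8))
  expect_error(ti_image_stack(vox, c(1:7, 7)), "distinct")
  expect_error(ti_image_stack(array(1, c(4, 4, 7)), 1:7, "pre_5(3)3"),
               "8 TI images")
  shuffled <- c(5, 1, 8, 2, 7, 3, 6, 4) * 100
  st <- ti_image_stack(array(rep(shuffled, each = 16), c(4, 4, 8)), shuffled)
  expect_equal(st$tis, sort(shuffled))
  # slices follow their TIs through the sort
  expect_equal(st$voxels[1, 1, ], sort(shuffled))
})
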