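test_that("MOLLI TI schedules follow the block rule and pool sorted", {
  tis <- generate_molli_tis("pre_5(3)3", rr_ms = 1000, ti_bases = c(120, 200))
  expect_equal(tis, c(120, 200, 1120, 1200, 2120, 2200, 3120, 4120))
  post <- generate_molli_tis("post_4(1)3(1)2", 1000, c(120, 200, 280))
  expect_length(post, 9)
  expect_equal(post, sort(c(120 + 0:3 * 1000, 200 + 0:2 * 1000,
                            280 + 0:1 * 1000)))
  expect_error(generate_molli_tis("pre_5(3)3", rr_ms = 0), "positive")
  expect_error(generate_molli_tis("pre_5(3)3", 1000, c(120, 120)), "distinct")
  expect_error(generate_molli_tis("pre_5(3)3", 1000, c(120, 200, 280)),
               "2 TI bases")
  # bases 80 ms apart with rr 80 would collide
  expect_error(generate_molli_tis("pre_5(3)3", 80, c(120, 200)), "duplicate")
})

test_that("noiseless phantom pixels satisfy the model exactly with correct signs", {
  ph <- small_phantom(shape = c(16, 16))
  tis <- ph$stack$tis
  idx <- which(ph$truth$tissue, arr.ind = TRUE)
  for (i in sample(nrow(idx), 10)) {
    r <- idx[i, 1]; cl <- idx[i, 2]
    p <- relaxation_params(ph$truth$a[r, cl], ph$truth$b[r, cl],
                           ph$truth$c[r, cl])
    flips <- true_flips(p$a, p$b, p$c, tis)
    s <- ti_series(tis, ph$stack$voxels[r, cl, ], is_magnitude = TRUE)
    expect_equal(residual_cost(p, s, sign_vector(flips, length(tis))), 0,
                 tolerance = 1e-16)
  }
  # air background is exactly zero and magnitude stacks are non-negative
  expect_true(all(ph$stack$voxels[!ph$truth$tissue] == 0))
  expect_true(all(ph$stack$voxels >= 0))
})

test_that("phantom generation is seed-deterministic", {
  a <- small_phantom(noise_sigma = 6, seed = 42, shape = c(12, 12))
  b <- small_phantom(noise_sigma = 6, seed = 42, shape = c(12, 12))
  c <- small_phantom(noise_sigma = 6, seed = 43, shape = c(12, 12))
  expect_identical(a$stack$voxels, b$stack$voxels)
  expect_false(identical(a$stack$voxels, c$stack$voxels))
})

test_that("phantom generation does not disturb the caller's RNG stream", {
  set.seed(99)
  before <- .Random.seed
  invisible(small_phantom(noise_sigma = 6, seed = 1, shape = c(8, 8)))
  expect_identical(.Random.seed, before)
})

test_that("background magnitude noise has the Rayleigh mean sigma*sqrt(pi/2)", {
  sigma <- 10
  spec <- phantom_spec(shape = c(200, 100),
                       compartments = list(compartment(rect_region(c(1, 1), c(1, 1)),
                                                       t1_ms = 800)),
                       scheme = "pre_5(3)3", noise_sigma = sigma, seed = 7)
  ph <- generate_phantom(spec)
  bg <- ph$stack$voxels[ph$truth$region == 0]   # ~160k Rayleigh draws
  expect_equal(mean(bg), sigma * sqrt(pi / 2), tolerance = 0.01)
})

test_that("compartment precedence and geometry masks behave as documented", {
  spec <- phantom_spec(
    shape = c(20, 20),
    compartments = list(
      compartment(rect_region(c(1, 20), c(1, 20)), t1_ms = 400),
      compartment(disk_region(c(10, 10), 4), t1_ms = 1000)),
    scheme = "pre_5(3)3", seed = 1)
  ph <- generate_phantom(spec)
  expect_equal(ph$truth$t1[10, 10], 1000)       # disk overrides rectangle
  expect_equal(ph$truth$t1[1, 1], 400)
  expect_true(all(ph$truth$tissue))
  expect_equal(phantom_mask(ph, 2), ph$truth$region == 2)
})

test_that("imperfect inversion still yields the requested corrected T1", {
  sp <- phantom_spec(shape = c(4, 4),
                     compartments = list(compartment(rect_region(c(1, 4), c(1, 4)),
                                                     t1_ms = 900, a = 300,
                                                     c = -160)),
                     scheme = "pre_5(3)3", seed = 1, is_magnitude = FALSE)
  ph <- generate_phantom(sp)
  s <- ti_series(ph$stack$tis, ph$stack$voxels[2, 2, ], is_magnitude = FALSE)
  fit <- fit_rd(s)
  expect_equal(fit$t1_ms, 900, tolerance = 1e-3)
  # c below -a/2 emulates readout-driven saturation: apparent T1* < T1
  expect_lt(fit$t1_star_ms, 900)
})

test_that("canonical noisy phantoms round-trip with <1% ROI-mean error", {
  for (contrast in c("pre", "post")) {
    ph <- cardiac_phantom(contrast, shape = c(32, 32), noise_sigma = 6,
                          seed = 5)
    init <- if (contrast == "pre") relaxation_params(350, 0.001, -150)
            else relaxation_params(350, 0.005, -150)
    for (method in c("RD", "LM")) {
      map <- compute_t1_map(ph$stack, method, init = init)
      for (k in 1:2) {
        truth <- ph$truth$t1[phantom_mask(ph, k)][1]
        expect_equal(roi_mean(map, phantom_mask(ph, k)), truth,
                     tolerance = 0.01)
      }
    }
  }
})
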