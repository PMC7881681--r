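test_that("sign_vector builds prefix-negated vectors and checks its range", {
  expect_equal(sign_vector(0, 5), rep(1, 5))
  expect_equal(sign_vector(5, 5), rep(-1, 5))
  expect_equal(sign_vector(2, 5), c(-1, -1, 1, 1, 1))
  expect_error(sign_vector(6, 5))
  expect_error(sign_vector(-1, 5))
})

test_that("polarity candidate windows follow the documented rule", {
  s <- ti_series(c(100, 200, 300, 400, 500), c(140, 80, 30, 120, 180))
  expect_equal(restore_polarity_candidates(s, 3), c(2L, 3L, 4L))
  expect_equal(restore_polarity_candidates(s, 2), c(2L, 3L))
  expect_equal(restore_polarity_candidates(s), c(1L, 2L, 3L, 4L))
  # minimum at the last index: window clips at N
  mono <- ti_series(c(100, 200, 300, 400, 500), c(180, 120, 80, 40, 10))
  expect_equal(restore_polarity_candidates(mono, 3), c(4L, 5L))
  expect_error(restore_polarity_candidates(s, 0))
  expect_error(restore_polarity_candidates(s, 6))
  signed <- ti_series(1:5, c(-1, 0, 1, 2, 3), is_magnitude = FALSE)
  expect_error(restore_polarity_candidates(signed), "magnitude")
})

test_that("reduced cost recovers generating (a, c) exactly at the true rate", {
  f <- make_series(t1 = 800, a = 300, c = -150)
  sol <- reduced_cost(f$params$b, f$series)
  expect_equal(sol$cost, 0, tolerance = 1e-16)
  expect_equal(sol$a_opt, 300, tolerance = 1e-9)
  expect_equal(sol$c_opt, -150, tolerance = 1e-9)
})

test_that("reduced cost beats a brute-force (a, c) grid around its optimum", {
  set.seed(3)
  f <- make_series(t1 = 1100, a = 280, sigma = 5)
  for (b in c(1 / 400, 1 / 1100, 1 / 2500)) {
    sol <- reduced_cost(b, f$series)
    as <- seq(sol$a_opt - 20, sol$a_opt + 20, length.out = 50)
    cs <- seq(sol$c_opt - 20, sol$c_opt + 20, length.out = 50)
    grid_cost <- outer(as, cs, Vectorize(function(a, cc)
      residual_cost(relaxation_params(a, b, cc), f$series)))
    expect_lte(sol$cost, min(grid_cost) + 1e-9)
  }
})

test_that("reduced cost rejects an ill-conditioned rate", {
  f <- make_series(t1 = 800)
  expect_error(reduced_cost(10, f$series), "ill-conditioned")
})

test_that("both fitters recover noiseless signed series exactly", {
  # the empirical LM initialisation triple is also a recoverable target
  for (par in list(c(350, 0.001, -150), c(300, 1 / 800, -150),
                   c(350, 0.005, -150))) {
    p <- relaxation_params(par[1], par[2], par[3])
    tis <- if (par[2] > 0.003) post_tis() else pre_tis()
    s <- ti_series(tis, relaxation_signal(p, tis), is_magnitude = FALSE)
    t1_true <- look_locker_correct(p)
    flm <- fit_lm(s, init = relaxation_params(350, par[2], -150))
    frd <- fit_rd(s)
    expect_true(flm$converged)
    expect_true(frd$converged)
    expect_equal(flm$t1_ms, t1_true, tolerance = 1e-5)
    expect_equal(frd$t1_ms, t1_true, tolerance = 1e-4)
    expect_lt(flm$rss, 1e-6)
    expect_equal(flm$params$a, par[1], tolerance = 1e-4)
    expect_equal(flm$flip_count, 0L)
    expect_equal(frd$flip_count, 0L)
  }
})

test_that("magnitude fitting restores the analytically known polarity", {
  p <- relaxation_params(350, 0.001, -150)
  tis <- pre_tis()
  s_signed <- ti_series(tis, relaxation_signal(p, tis), is_magnitude = FALSE)
  s_mag <- ti_series(tis, abs(relaxation_signal(p, tis)), is_magnitude = TRUE)
  flips <- true_flips(350, 0.001, -150, tis)  # crossing at 559.6 ms -> 2
  expect_equal(flips, 2L)
  for (fit in list(fit_lm(s_mag), fit_rd(s_mag))) {
    expect_equal(fit$flip_count, flips)
    expect_equal(fit$t1_ms, 750, tolerance = 0.01)
  }
  # magnitude and signed agree
  expect_equal(fit_lm(s_mag)$t1_ms, fit_lm(s_signed)$t1_ms, tolerance = 0.01)
})

test_that("rss stored in a fit equals an independent recomputation", {
  set.seed(11)
  f <- make_series(t1 = 950, magnitude = TRUE, sigma = 6)
  for (fit in list(fit_rd(f$series), fit_lm(f$series))) {
    signs <- sign_vector(fit$flip_count, length(f$series$tis))
    expect_equal(fit$rss, residual_cost(fit$params, f$series, signs),
                 tolerance = 1e-8)
  }
})

test_that("constant series are reported as non-converged by both fitters", {
  flat <- ti_series(pre_tis(), rep(100, 8))
  expect_false(fit_lm(flat)$converged)
  expect_false(fit_rd(flat)$converged)
  expect_true(is.na(fit_rd(flat)$t1_ms))
})

test_that("sign symmetry: the fully flipped signed series fits to (-a, b, -c)", {
  f <- make_series(t1 = 800, a = 300, c = -150)
  neg <- ti_series(f$series$tis, -f$series$signals, is_magnitude = FALSE)
  for (fit in list(fit_rd(neg), fit_lm(neg))) {
    expect_true(fit$converged)
    expect_equal(fit$params$a, -300, tolerance = 1e-4)
    expect_equal(fit$params$c, 150, tolerance = 1e-4)
    expect_equal(fit$params$b, f$params$b, tolerance = 1e-6)
    expect_equal(fit$rss, 0, tolerance = 1e-10)
  }
})

test_that("noiseless LM and RD agree to within 0.01 ms across T1 values", {
  for (t1 in c(250, 500, 950, 1500, 2000)) {
    f <- make_series(t1 = t1, magnitude = TRUE)
    expect_equal(fit_lm(f$series)$t1_ms, fit_rd(f$series)$t1_ms,
                 tolerance = 0.01 / t1)
  }
})

test_that("noisy magnitude fits are accurate and the methods agree closely", {
  set.seed(29)
  n <- 120
  serr_rd <- serr_lm <- dd <- numeric(n)
  for (i in seq_len(n)) {
    t1 <- runif(1, 200, 2000)
    f <- make_series(t1 = t1, a = 300, magnitude = TRUE, sigma = 6)
    frd <- fit_rd(f$series); flm <- fit_lm(f$series)
    serr_rd[i] <- (frd$t1_ms - t1) / t1
    serr_lm[i] <- (flm$t1_ms - t1) / t1
    dd[i] <- frd$t1_ms - flm$t1_ms
  }
  # sigma/a = 2%: precision is bound by the information in 8 samples
  expect_lt(median(abs(serr_rd)), 0.04)
  expect_lt(median(abs(serr_lm)), 0.04)
  # essentially unbiased
  expect_lt(abs(median(serr_rd)), 0.015)
  expect_lt(abs(median(serr_lm)), 0.015)
  # when both methods pick the same polarity they find the same optimum
  expect_lt(median(abs(dd)), 0.01)
})

test_that("RD search matches an exhaustive fine-grid oracle", {
  set.seed(17)
  for (i in 1:25) {
    t1 <- exp(runif(1, log(150), log(2500)))
    a <- runif(1, 200, 400)
    f <- make_series(t1 = t1, a = a, c = -a / 2 * runif(1, 0.9, 1.1),
                     sigma = 4)
    fit <- fit_rd(f$series, candidates = 0L)
    oracle <- oracle_grid_min_cost(f$series$tis, f$series$signals)
    expect_lte(fit$rss, oracle * (1 + 1e-6) + 1e-9)
  }
})
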