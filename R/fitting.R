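#' Prefix sign vector for polarity restoration
#'
#' Magnitude reconstruction discards the sign of the early inversion-recovery
#' samples, which are physically negative before the zero crossing. Candidate
#' polarity restorations negate a prefix of the TI-ascending samples: the
#' vector for `flip_count = k` has its first `k` entries equal to -1 and the
#' rest +1.
#'
#' @param flip_count Number of earliest-TI samples to negate, `0..n`.
#' @param n Number of samples.
#' @return Numeric vector of +1/-1 of length `n`.
#' @export
sign_vector <- function(flip_count, n) {
  stopifnot(length(flip_count) == 1L, length(n) == 1L, n >= 0)
  if (flip_count < 0 || flip_count > n)
    stop("`flip_count` must be between 0 and n")
  c(rep(-1, flip_count), rep(1, n - flip_count))
}

#' Candidate flip counts for polarity restoration
#'
#' The classical reduced-dimension rule tries two restorations anchored at the
#' minimum-magnitude sample (index m, 0-based, TI-ascending): flip everything
#' before it, or everything up to and including it. When two TIs nearly
#' coincide, noise can swap which of them attains the minimum and the
#' two-candidate rule can miss the true zero crossing. The displacement
#' happens in both directions — near-coincident TIs sit before the crossing
#' in some pixels and after it in others — so the candidate window must reach
#' one index either side of the observed minimum: the default tries the four
#' flip counts `{m-1, m, m+1, m+2}` (clipped to `[0, N]` and deduplicated).
#' Smaller windows grow forward first: `n_candidates = 2` reproduces the
#' classical behaviour `{m, m+1}` and `n_candidates = 3` its one-sided
#' extension `{m, m+1, m+2}`. Ties in the minimum magnitude break toward the
#' smaller index.
#'
#' @param series A magnitude [ti_series].
#' @param n_candidates Number of candidates, `1..N`; default 4.
#' @return Integer vector of candidate `flip_count` values.
#' @export
restore_polarity_candidates <- function(series, n_candidates = 4L) {
  stopifnot(inherits(series, "ti_series"))
  if (!series$is_magnitude)
    stop("polarity restoration applies to magnitude data only")
  n <- length(series$signals)
  if (n < 1L) stop("empty series")
  if (n_candidates < 1L || n_candidates > n)
    stop("`n_candidates` must be in 1..N")
  m <- which.min(series$signals) - 1L   # 0-based; which.min breaks ties low
  start <- m - max(0L, (as.integer(n_candidates) - 2L) %/% 2L)
  cand <- start + seq_len(n_candidates) - 1L
  unique(pmin(pmax(cand, 0L), n))
}

#' Reduced-dimension cost: closed-form (a, c) for a fixed rate
#'
#' For a fixed relaxation rate `b` the model is linear in `(a, c)` with
#' regressor \eqn{x_i = 1 - e^{-b\,TI_i}}, so the inner minimisation is an
#' ordinary least-squares solve and the full 3-parameter problem collapses to
#' a one-dimensional search over `b`. Returns the exact OLS `(a, c)` against
#' the sign-restored samples and the objective value there.
#'
#' @param b Relaxation rate, 1/ms, `b > 0`.
#' @param series A [ti_series].
#' @param signs Sign vector (see [sign_vector()]); defaults to all +1.
#' @return List with `cost`, `a_opt`, `c_opt`.
#' @seealso [fit_rd()]
#' @export
reduced_cost <- function(b, series, signs = rep(1, length(series$tis))) {
  stopifnot(inherits(series, "ti_series"), b > 0)
  if (length(signs) != length(series$tis))
    stop("`signs` must have one entry per sample")
  x <- 1 - exp(-b * series$tis)
  if (max(x) - min(x) < 1e-12)
    stop("ill-conditioned rate: regressor 1 - exp(-b*TI) is constant across samples")
  y <- signs * series$signals
  n <- length(y)
  sx <- sum(x); sxx <- sum(x * x); sy <- sum(y); sxy <- sum(x * y)
  den <- n * sxx - sx * sx
  a <- (n * sxy - sx * sy) / den
  cc <- (sy - a * sx) / n
  r <- y - a * x - cc
  list(cost = sum(r * r), a_opt = a, c_opt = cc)
}

# Precomputed log-spaced b grid and per-b regressor sums for a fixed TI set.
# Shared across all pixels of a map so the exp() table is built once.
rd_grid <- function(tis, t1star_range = c(1, 5000), n_grid = 500L) {
  t1 <- exp(seq(log(t1star_range[1]), log(t1star_range[2]), length.out = n_grid))
  b <- sort(1 / t1)                       # ascending rates
  X <- 1 - exp(-outer(b, tis))            # n_grid x N
  sx <- rowSums(X)
  sxx <- rowSums(X * X)
  n <- length(tis)
  den <- n * sxx - sx * sx
  list(b = b, X = X, sx = sx, sxx = sxx, den = den, n = n, tis = tis)
}

# Vectorised reduced cost over the whole b grid for one sign-restored sample
# vector y. Ill-conditioned grid points get +Inf cost.
rd_grid_cost <- function(grid, y) {
  sxy <- as.vector(grid$X %*% y)
  sy <- sum(y); syy <- sum(y * y)
  a <- (grid$n * sxy - grid$sx * sy) / grid$den
  cc <- (sy - a * grid$sx) / grid$n
  cost <- syy - a * sxy - cc * sy         # RSS at the inner OLS optimum
  cost[!is.finite(cost) | grid$den < 1e-12] <- Inf
  pmax(cost, 0)
}

#' Reduced-dimension search configuration
#'
#' @param t1star_range Search range for the apparent T1* = 1/b, in ms.
#' @param n_grid Number of log-spaced grid points over `t1star_range` for the
#'   coarse search.
#' @param rel_tol Relative tolerance on `b` for the bracketed refinement.
#' @return A list of class `rd_search`.
#' @export
rd_search <- function(t1star_range = c(1, 5000), n_grid = 500L, rel_tol = 1e-6) {
  stopifnot(length(t1star_range) == 2L, all(t1star_range > 0),
            t1star_range[1] < t1star_range[2], n_grid >= 10L, rel_tol > 0)
  structure(list(t1star_range = as.numeric(t1star_range),
                 n_grid = as.integer(n_grid), rel_tol = rel_tol),
            class = "rd_search")
}

# Relative tie tolerance between polarity candidates: equal-cost ties go to
# the smaller flip_count for deterministic output.
.rd_tie_rel <- 1e-12

new_fit_result <- function(params, rss, flip_count, converged, method) {
  t1_star <- if (converged) 1 / params$b else NA_real_
  t1 <- if (converged) look_locker_correct(params) else NA_real_
  structure(list(params = params, rss = rss, flip_count = as.integer(flip_count),
                 t1_star_ms = t1_star, t1_ms = t1,
                 converged = converged, method = method),
            class = "fit_result")
}

failed_fit <- function(method) {
  structure(list(params = relaxation_params(NA_real_, NA_real_, NA_real_),
                 rss = NA_real_, flip_count = NA_integer_,
                 t1_star_ms = NA_real_, t1_ms = NA_real_,
                 converged = FALSE, method = method),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  if (x$converged) {
    cat(sprintf(
      "fit_result [%s]: T1 = %.2f ms (T1* = %.2f ms), a = %.3g, b = %.3g, c = %.3g\n  rss = %.4g, flip_count = %d\n",
      x$method, x$t1_ms, x$t1_star_ms, x$params$a, x$params$b, x$params$c,
      x$rss, x$flip_count))
  } else {
    cat(sprintf("fit_result [%s]: did not converge\n", x$method))
  }
  invisible(x)
}

# Degenerate-series guard shared by both fitters: a constant series carries no
# information about b (any rate fits exactly with a = 0).
series_is_constant <- function(series) {
  diff(range(series$signals)) == 0
}

#' Reduced-dimension nonlinear least-squares T1 fit
#'
#' For each polarity candidate, minimises the reduced one-dimensional cost
#' over the relaxation rate `b` by a dense log-spaced grid followed by
#' bracketed refinement ([stats::optimize()]) on the interval around the best
#' grid point; `(a, c)` come from the closed-form inner solve and T1 from the
#' Look-Locker correction. The candidate with globally minimal cost wins;
#' ties (within `1e-12` relative) break toward the smaller `flip_count`.
#' The search needs no starting values, which is the method's practical
#' advantage over iterative Levenberg-Marquardt fitting.
#'
#' @param series A [ti_series].
#' @param search An [rd_search()] configuration.
#' @param candidates Integer vector of `flip_count` values to try. Default
#'   `NULL` uses [restore_polarity_candidates()] with `n_candidates` for
#'   magnitude data and the single all-positive restoration for signed data.
#'   Pass `0:N` for an exhaustive sweep.
#' @param n_candidates Passed to [restore_polarity_candidates()] when
#'   `candidates` is `NULL`; default 4.
#' @param grid Internal: a precomputed grid object for this series' TI set,
#'   used by [compute_t1_map()] to share the exponential table across pixels.
#' @return A `fit_result` with `method = "RD"`.
#' @export
fit_rd <- function(series, search = rd_search(), candidates = NULL,
                   n_candidates = 4L, grid = NULL) {
  stopifnot(inherits(series, "ti_series"), inherits(search, "rd_search"))
  if (series_is_constant(series)) return(failed_fit("RD"))
  n <- length(series$tis)
  if (is.null(candidates)) {
    candidates <- if (series$is_magnitude)
      restore_polarity_candidates(series, n_candidates) else 0L
  }
  if (any(candidates < 0L | candidates > n)) stop("candidate flip_count out of range")
  if (is.null(grid))
    grid <- rd_grid(series$tis, search$t1star_range, search$n_grid)

  best <- NULL
  for (fc in sort(as.integer(candidates))) {
    signs <- sign_vector(fc, n)
    y <- signs * series$signals
    cost_grid <- rd_grid_cost(grid, y)
    i <- which.min(cost_grid)
    if (!is.finite(cost_grid[i])) next
    lo <- grid$b[max(i - 1L, 1L)]
    hi <- grid$b[min(i + 1L, length(grid$b))]
    cand <- list(b = grid$b[i], cost = cost_grid[i])
    if (hi > lo) {
      opt <- stats::optimize(function(bb) {
        tryCatch(reduced_cost(bb, series, signs)$cost, error = function(e) Inf)
      }, interval = c(lo, hi), tol = search$rel_tol * grid$b[i])
      if (is.finite(opt$objective) && opt$objective < cand$cost)
        cand <- list(b = opt$minimum, cost = opt$objective)
    }
    if (is.null(best) ||
        cand$cost < best$cost * (1 - .rd_tie_rel) ||
        (abs(cand$cost - best$cost) <= .rd_tie_rel * max(best$cost, 1) &&
         fc < best$fc)) {
      best <- c(cand, list(fc = fc, signs = signs))
    }
  }
  if (is.null(best)) return(failed_fit("RD"))

  sol <- reduced_cost(best$b, series, best$signs)
  params <- relaxation_params(sol$a_opt, best$b, sol$c_opt)
  t1 <- tryCatch(look_locker_correct(params), error = function(e) NA_real_)
  if (!is.finite(t1) || t1 <= 0) return(failed_fit("RD"))
  new_fit_result(params, residual_cost(params, series, best$signs),
                 best$fc, TRUE, "RD")
}

#' Levenberg-Marquardt T1 fit with incremental polarity flipping
#'
#' Minimises the sum-of-squares objective iteratively with
#' [minpack.lm::nls.lm()] starting from empirical initial values. Magnitude
#' data lose the sign of the early samples, so with
#' `flip_policy = "full_sweep"` one LM minimisation is run for every
#' `flip_count` in `0..N` and the restoration with minimal residual sum of
#' squares wins; `"candidates"` restricts the sweep to the three-candidate
#' rule of [restore_polarity_candidates()]; `"none"` fits the samples as
#' given. Signed data are always fit once with all-positive signs.
#'
#' @param series A [ti_series].
#' @param init A [relaxation_params] starting point with `init$b > 0`.
#'   Defaults to `(a, b, c) = (350, 0.001, -150)`, an empirical choice suited
#'   to pre-contrast myocardial data; use `b = 0.005` for post-contrast
#'   (short-T1) series.
#' @param flip_policy One of `"full_sweep"`, `"candidates"`, `"none"`.
#' @param n_candidates Candidates for `flip_policy = "candidates"`.
#' @param max_iter Maximum LM iterations per polarity candidate.
#' @param ftol Relative reduction in the cost below which LM stops.
#' @return A `fit_result` with `method = "LM"`; `converged = FALSE` when every
#'   polarity candidate diverges or yields a non-physical fit.
#' @export
fit_lm <- function(series, init = relaxation_params(350, 0.001, -150),
                   flip_policy = c("full_sweep", "candidates", "none"),
                   n_candidates = 4L, max_iter = 200L, ftol = 1e-8) {
  stopifnot(inherits(series, "ti_series"), inherits(init, "relaxation_params"))
  flip_policy <- match.arg(flip_policy)
  if (init$b <= 0) stop("`init$b` must be positive")
  if (series_is_constant(series)) return(failed_fit("LM"))
  n <- length(series$tis)

  candidates <- if (!series$is_magnitude || flip_policy == "none") {
    0L
  } else if (flip_policy == "full_sweep") {
    0:n
  } else {
    restore_polarity_candidates(series, n_candidates)
  }

  tis <- series$tis
  best <- NULL
  for (fc in sort(as.integer(candidates))) {
    signs <- sign_vector(fc, n)
    y <- signs * series$signals
    fit <- tryCatch(
      minpack.lm::nls.lm(
        par = c(init$a, init$b, init$c),
        fn = function(p) y - (p[1] * (1 - exp(-p[2] * tis)) + p[3]),
        control = minpack.lm::nls.lm.control(maxiter = max_iter, ftol = ftol)),
      error = function(e) NULL)
    if (is.null(fit) || !fit$info %in% 1:4) next
    p <- fit$par
    if (!all(is.finite(p)) || p[2] <= 0) next
    params <- relaxation_params(p[1], p[2], p[3])
    rss <- residual_cost(params, series, signs)
    t1 <- tryCatch(look_locker_correct(params), error = function(e) NA_real_)
    if (!is.finite(t1) || t1 <= 0) next
    if (is.null(best) ||
        rss < best$rss * (1 - .rd_tie_rel) ||
        (abs(rss - best$rss) <= .rd_tie_rel * max(best$rss, 1) && fc < best$fc)) {
      best <- list(params = params, rss = rss, fc = fc)
    }
  }
  if (is.null(best)) return(failed_fit("LM"))
  new_fit_result(best$params, best$rss, best$fc, TRUE, "LM")
}
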