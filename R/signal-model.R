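#' Three-parameter inversion-recovery relaxation parameters
#'
#' Bundles the parameter triple (a, b, c) of the longitudinal relaxation model
#' \deqn{S(t) = a\,(1 - e^{-bt}) + c,}
#' where `a` is the recovery amplitude (signal units), `b` the apparent
#' relaxation rate in 1/ms (so the apparent T1 is T1* = 1/b), and `c` the
#' signal at t = 0. A physically meaningful (converged) fit has `b > 0`.
#'
#' @param a Recovery amplitude, arbitrary signal units.
#' @param b Apparent relaxation rate, 1/ms.
#' @param c Signal offset at t = 0, arbitrary signal units.
#' @return An object of class `relaxation_params`.
#' @examples
#' p <- relaxation_params(350, 0.001, -150)
#' relaxation_signal(p, c(0, 1000))
#' @export
relaxation_params <- function(a, b, c) {
  stopifnot(is.numeric(a), is.numeric(b), is.numeric(c),
            length(a) == 1L, length(b) == 1L, length(c) == 1L)
  structure(list(a = as.numeric(a), b = as.numeric(b), c = as.numeric(c)),
            class = "relaxation_params")
}

#' @export
print.relaxation_params <- function(x, ...) {
  cat(sprintf("relaxation_params: a = %g, b = %g /ms (T1* = %g ms), c = %g\n",
              x$a, x$b, if (x$b > 0) 1 / x$b else NA_real_, x$c))
  invisible(x)
}

#' One pixel's inversion-time samples
#'
#' A TI series holds the (inversion time, signal) pairs observed at one pixel,
#' sorted by ascending TI. MOLLI acquisitions pool the readouts of all
#' inversion blocks, giving N = 8 samples for the 5(3)3 pre-contrast scheme
#' and N = 9 for the 4(1)3(1)2 post-contrast scheme. `is_magnitude = TRUE`
#' marks magnitude-reconstructed data, whose early-TI samples have lost their
#' (physically negative) sign and require polarity restoration before fitting.
#'
#' @param tis Inversion times in ms, strictly increasing, length >= 4
#'   (the model has 3 unknowns; fewer samples leave no residual information).
#' @param signals Observed signals, same length as `tis`; non-negative when
#'   `is_magnitude` is `TRUE`.
#' @param is_magnitude Logical flag; `TRUE` for magnitude data.
#' @return An object of class `ti_series`.
#' @export
ti_series <- function(tis, signals, is_magnitude = TRUE) {
  tis <- as.numeric(tis); signals <- as.numeric(signals)
  if (length(tis) != length(signals))
    stop("`tis` and `signals` must have the same length")
  if (length(tis) < 4L)
    stop("a TI series needs at least 4 samples to fit 3 parameters")
  if (any(diff(tis) <= 0))
    stop("`tis` must be strictly increasing")
  if (isTRUE(is_magnitude) && any(signals < 0))
    stop("magnitude data cannot contain negative signals")
  structure(list(tis = tis, signals = signals,
                 is_magnitude = isTRUE(is_magnitude)),
            class = "ti_series")
}

#' @export
print.ti_series <- function(x, ...) {
  cat(sprintf("ti_series: N = %d (%s data), TI %g..%g ms\n",
              length(x$tis), if (x$is_magnitude) "magnitude" else "signed",
              min(x$tis), max(x$tis)))
  invisible(x)
}

#' Evaluate the relaxation model
#'
#' Returns \eqn{a (1 - e^{-bt}) + c}; vectorised over `t`.
#'
#' @param params A [relaxation_params] object.
#' @param t Time(s) in ms, `t >= 0`.
#' @return Signal value(s), same length as `t`.
#' @export
relaxation_signal <- function(params, t) {
  stopifnot(inherits(params, "relaxation_params"), all(t >= 0))
  params$a * (1 - exp(-params$b * t)) + params$c
}

#' Sum-of-squares fitting objective
#'
#' The objective minimised by both fitters:
#' \deqn{f(a,b,c) = \sum_i (s_i S(TI_i) - a(1 - e^{-b\,TI_i}) - c)^2,}
#' evaluated on the sign-restored samples \eqn{s_i S(TI_i)}. For signed data
#' pass `signs = rep(1, N)` (the default).
#'
#' @param params A [relaxation_params] object.
#' @param series A [ti_series].
#' @param signs Sign vector of +1/-1 entries, one per sample; see
#'   [sign_vector()].
#' @return A non-negative scalar; zero iff the model reproduces every
#'   sign-restored sample exactly.
#' @export
residual_cost <- function(params, series, signs = rep(1, length(series$tis))) {
  stopifnot(inherits(params, "relaxation_params"), inherits(series, "ti_series"))
  if (length(signs) != length(series$tis))
    stop("`signs` must have one entry per sample")
  if (!all(signs %in% c(-1, 1)))
    stop("`signs` entries must be +1 or -1")
  r <- signs * series$signals - relaxation_signal(params, series$tis)
  sum(r * r)
}

#' Look-Locker correction: apparent T1* to T1
#'
#' The repeated readouts of a Look-Locker style acquisition drive the observed
#' recovery faster than true longitudinal relaxation; the fitted rate `b`
#' yields the apparent T1* = 1/b. The standard correction recovers T1 from the
#' fitted triple:
#' \deqn{T1 = T1^{*}\,\left(\frac{a}{a+c} - 1\right).}
#' Under ideal inversion (a = -2c) the factor is exactly 1 and T1 = T1*.
#'
#' @param params A [relaxation_params] object with `b > 0`.
#' @param degeneracy_floor Fits with `|a + c| < degeneracy_floor * max(|a|, 1)`
#'   are treated as degenerate (the correction divides by `a + c`); such a fit
#'   signals an error and the pixel is flagged invalid by callers.
#' @return Corrected T1 in ms.
#' @export
look_locker_correct <- function(params, degeneracy_floor = 1e-6) {
  stopifnot(inherits(params, "relaxation_params"))
  if (!is.finite(params$b) || params$b <= 0)
    stop("Look-Locker correction requires a positive relaxation rate b")
  denom <- params$a + params$c
  if (!is.finite(denom) || abs(denom) < degeneracy_floor * max(abs(params$a), 1))
    stop("degenerate fit: a + c is (near) zero, T1 undefined")
  (1 / params$b) * (params$a / denom - 1)
}
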