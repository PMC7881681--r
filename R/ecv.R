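#' Pixel-wise extracellular volume fraction map
#'
#' ECV is computed from co-registered pre- and post-contrast T1 maps via the
#' standard relaxivity-ratio formula
#' \deqn{ECV = (1 - Hct)\,\frac{1/T1_{post} - 1/T1_{pre}}
#'                            {1/T1_{blood,post} - 1/T1_{blood,pre}},}
#' i.e. the myocardial change in relaxation rate (delta R1) relative to the
#' blood-pool change, scaled by the plasma volume fraction. Blood values are
#' scalars — typically ROI means over a blood-pool mask (see [roi_mean()]) —
#' because per-pixel blood references are noisy. Pixels invalid in either
#' input map are invalid in the ECV map, as are pixels whose ECV falls
#' outside the plausibility band.
#'
#' @param pre_map,post_map `parameter_map` objects on the same grid, assumed
#'   co-registered (no resampling is performed).
#' @param blood_t1_pre,blood_t1_post Blood-pool T1 values in ms.
#' @param hct Hematocrit as a fraction in (0, 1).
#' @param band Plausibility band for ECV; values outside it are flagged
#'   invalid rather than clipped.
#' @return A list of class `ecv_map` with matrix `ecv` (fraction; `NA` where
#'   invalid), logical matrix `valid`, and the inputs used.
#' @export
compute_ecv_map <- function(pre_map, post_map, blood_t1_pre, blood_t1_post,
                            hct, band = c(0, 1)) {
  stopifnot(inherits(pre_map, "parameter_map"), inherits(post_map, "parameter_map"))
  if (!identical(dim(pre_map$t1), dim(post_map$t1)))
    stop("pre and post maps must share the same grid")
  if (blood_t1_pre <= 0 || blood_t1_post <= 0)
    stop("blood T1 values must be positive")
  if (hct <= 0 || hct >= 1)
    stop("`hct` must be a fraction strictly between 0 and 1")
  blood_dr1 <- 1 / blood_t1_post - 1 / blood_t1_pre
  if (blood_dr1 == 0)
    stop("blood delta R1 is zero; pre and post blood T1 must differ")

  valid <- pre_map$valid & post_map$valid
  ecv <- matrix(NA_real_, nrow(pre_map$t1), ncol(pre_map$t1))
  dr1 <- 1 / post_map$t1[valid] - 1 / pre_map$t1[valid]
  ecv[valid] <- (1 - hct) * dr1 / blood_dr1
  out_of_band <- valid & (ecv < band[1] | ecv > band[2])
  ecv[out_of_band] <- NA_real_
  valid[out_of_band] <- FALSE

  structure(list(ecv = ecv, valid = valid, hct = hct,
                 blood_t1_pre = blood_t1_pre, blood_t1_post = blood_t1_post,
                 band = band),
            class = "ecv_map")
}

#' @export
print.ecv_map <- function(x, ...) {
  cat(sprintf("ecv_map: %d x %d, %d valid pixels (Hct = %.2f)",
              nrow(x$ecv), ncol(x$ecv), sum(x$valid), x$hct))
  if (any(x$valid))
    cat(sprintf(", ECV %.3f..%.3f", min(x$ecv[x$valid]), max(x$ecv[x$valid])))
  cat("\n")
  invisible(x)
}
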