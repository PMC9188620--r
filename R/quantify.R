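#' Perfusion-weighted map
#'
#' Per-voxel mean over pairs of (control - label) from the interleaved 4-D
#' label/control series of an acquisition.
#'
#' @param acq An `asl_acquisition`, or a 4-D array with volumes interleaved
#'   control, label, control, label, ...
#' @return 3-D array of difference signal, signal units.
#' @export
perfusion_weighted_map <- function(acq) {
  series <- if (inherits(acq, "asl_acquisition")) acq$series else acq
  if (length(dim(series)) != 4) stop("need a 4-D label/control series")
  nvol <- dim(series)[4]
  if (nvol < 2 || nvol %% 2 != 0)
    stop("mismatched pair count: series must hold complete control/label pairs")
  ctrl <- seq(1, nvol, by = 2)
  lab <- seq(2, nvol, by = 2)
  d4 <- series[, , , ctrl, drop = FALSE] - series[, , , lab, drop = FALSE]
  apply(d4, 1:3, mean)
}

#' Estimate the equilibrium magnetization of arterial blood
#'
#' Fits the saturation-recovery model `M(ti) = M0_t * (1 - exp(-ti/T1_t))`
#' to the masked median signal of the calibration control series by
#' nonlinear least squares, and scales the tissue equilibrium magnetization
#' by the blood-brain partition coefficient: `m0b = M0_t / lambda_bp`.
#'
#' @param calib_series 4-D array, one calibration volume per TI.
#' @param calib_tis Calibration inversion times, ms; >= 2 distinct values.
#' @param mask Logical 3-D array selecting the reference region (non-empty).
#' @param lambda_bp Blood-brain partition coefficient, ml/g.
#' @return `m0b`, signal units (length-1 numeric with attributes `m0_t` and
#'   `t1_t` carrying the fitted tissue parameters).
#' @export
estimate_m0_blood <- function(calib_series, calib_tis, mask, lambda_bp = 0.9) {
  if (length(dim(calib_series)) != 4) stop("calib_series must be 4-D")
  if (dim(calib_series)[4] != length(calib_tis))
    stop("calib_series volume count must match calib_tis")
  if (length(calib_tis) < 2 || length(unique(calib_tis)) < 2)
    stop("degenerate design: need >= 2 distinct calibration time points")
  if (!any(mask)) stop("empty reference-region mask")
  if (lambda_bp <= 0) stop("lambda_bp must be > 0")

  med <- vapply(seq_along(calib_tis),
                function(j) stats::median(calib_series[, , , j][mask]),
                numeric(1))
  df <- data.frame(ti = calib_tis, m = med)
  fit <- tryCatch(
    stats::nls(m ~ m0 * (1 - exp(-ti / t1)), data = df,
               start = list(m0 = max(med) * 1.05,
                            t1 = stats::median(calib_tis) / 2),
               algorithm = "port",
               lower = c(m0 = 1e-8, t1 = 1),
               control = stats::nls.control(maxiter = 200, warnOnly = FALSE)),
    error = function(e) {
      stop(errorCondition(paste0("calibration fit failed: ",
                                 conditionMessage(e)),
                          class = c("asltilab_fit_error", "error")))
    })
  est <- stats::coef(fit)
  structure(unname(est["m0"]) / lambda_bp,
            m0_t = unname(est["m0"]), t1_t = unname(est["t1"]))
}

#' Quantify absolute CBF
#'
#' Inverts the single-compartment bolus model under the full-delivery
#' assumption (standard PASL quantification):
#' \deqn{CBF = \frac{6000\,\lambda\,\Delta M\, e^{TI/T_{1b}}}
#'   {2\,\alpha\, TI_1\, M_{0b}}}
#' with `TI1` in seconds inside the formula. For voxels whose bolus was
#' fully delivered (ATT = 0 or `TI >= ATT + TI1` with no residual transit
#' effect) this is the exact algebraic inverse of [tissue_delta_m()];
#' voxels with `ATT > TI` quantify to 0 regardless of true perfusion (the
#' distal-territory underestimation mechanism), and intravascular arterial
#' signal inflates the estimate wherever the bolus still occupies the
#' arteries. Negative values arising from noise are retained, not clipped.
#'
#' @param pwi Perfusion-weighted 3-D array from [perfusion_weighted_map()].
#' @param m0b Equilibrium magnetization of arterial blood, > 0 (see
#'   [estimate_m0_blood()]).
#' @param params [acq_params()] of the acquisition.
#' @param consts [quant_constants()]; its `m0b` entry is ignored in favour
#'   of the `m0b` argument.
#' @param mask Optional logical array; voxels outside are set to `NaN`.
#' @param subject_id Identifier stored with the map.
#' @return An object of class `cbf_map`: list with `volume`
#'   (ml/min/100 g), `ti`, `constants_used`, `subject_id`.
#' @export
quantify_cbf <- function(pwi, m0b, params, consts = quant_constants(),
                         mask = NULL, subject_id = NA_character_) {
  if (!is.numeric(m0b) || length(m0b) != 1 || m0b <= 0)
    stop("m0b must be a positive scalar")
  vol <- 6000 * consts$lambda_bp * pwi * exp(params$ti / consts$t1b) /
    (2 * consts$alpha * (params$ti1 / 1000) * m0b)
  if (!is.null(mask)) vol[!mask] <- NaN
  used <- consts
  used$m0b <- as.numeric(m0b)
  structure(list(volume = vol, ti = params$ti, constants_used = used,
                 subject_id = subject_id),
            class = "cbf_map")
}

#' @export
print.cbf_map <- function(x, ...) {
  v <- x$volume[is.finite(x$volume)]
  cat(sprintf("CBF map (%s, TI %g ms): %d finite voxels, mean %.1f ml/min/100 g\n",
              x$subject_id, x$ti, length(v), mean(v)))
  invisible(x)
}

# full quantification of one acquisition: PWI, M0 calibration on the
# reference region, inversion. Used by the pipeline.
.quantify_acquisition <- function(acq, ref_mask, subject_id = acq$subject_id) {
  pwi <- perfusion_weighted_map(acq)
  m0b <- estimate_m0_blood(acq$calib, acq$params$calib_tis, ref_mask,
                           acq$consts$lambda_bp)
  quantify_cbf(pwi, m0b, acq$params, acq$consts, subject_id = subject_id)
}
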