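#' Acquisition parameters for one PASL series
#'
#' Bundles the timing and noise parameters of a single pulsed-ASL
#' (PICORE Q2TIPS style) acquisition: the inversion time `ti`, the bolus
#' duration `ti1` enforced by the QUIPSS-II saturation, the number of
#' label/control pairs, and the calibration (M0) image timings.
#'
#' @param ti Inversion time in ms (time from labeling to readout).
#' @param ti1 Bolus duration in ms; labeled blood delivery stops at
#'   `ti1` after labeling. Default 700 ms.
#' @param n_pairs Number of label/control pairs acquired. Default 8.
#' @param calib_tis Inversion times of the calibration control images, ms,
#'   strictly increasing.
#' @param calib_trs Repetition times of the calibration images, ms; same
#'   length as `calib_tis` (stored as provenance).
#' @param noise_sd Standard deviation of the additive Gaussian acquisition
#'   noise, in signal units, applied per volume.
#' @return An object of class `acq_params`.
#' @examples
#' acq_params(ti = 1500)
#' @export
acq_params <- function(ti, ti1 = 700, n_pairs = 8,
                       calib_tis = c(1000, 1990, 4000),
                       calib_trs = c(1270, 2270, 4270),
                       noise_sd = 1) {
  stopifnot(is.numeric(ti), length(ti) == 1, is.numeric(ti1), length(ti1) == 1)
  if (!(ti > ti1 && ti1 > 0))
    stop("need ti > ti1 > 0 (got ti = ", ti, ", ti1 = ", ti1, ")")
  if (n_pairs < 1) stop("n_pairs must be >= 1")
  if (length(calib_tis) != length(calib_trs))
    stop("calib_tis and calib_trs must have the same length")
  if (length(calib_tis) > 1 && any(diff(calib_tis) <= 0))
    stop("calib_tis must be strictly increasing")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  structure(list(ti = ti, ti1 = ti1, n_pairs = as.integer(n_pairs),
                 calib_tis = calib_tis, calib_trs = calib_trs,
                 noise_sd = noise_sd),
            class = "acq_params")
}

#' Quantification constants
#'
#' Physical constants entering both the forward signal model and the CBF
#' quantification formula. Defaults follow the consensus recommendation for
#' PASL at 3 T: blood-brain partition coefficient 0.9 ml/g, labeling
#' efficiency 0.98, arterial blood T1 1650 ms. `m0b` is the equilibrium
#' magnetization of arterial blood in (arbitrary) signal units; in a real
#' study it is estimated from calibration images (see
#' [estimate_m0_blood()]), in simulation it sets the signal scale.
#'
#' @param lambda_bp Blood-brain partition coefficient, ml/g.
#' @param alpha Labeling efficiency, in (0, 1].
#' @param t1b Longitudinal relaxation time of arterial blood, ms.
#' @param m0b Equilibrium magnetization of arterial blood, signal units.
#' @return An object of class `quant_constants`.
#' @export
quant_constants <- function(lambda_bp = 0.9, alpha = 0.98, t1b = 1650,
                            m0b = 1000) {
  stopifnot(lambda_bp > 0, alpha > 0, alpha <= 1, t1b > 0, m0b > 0)
  structure(list(lambda_bp = lambda_bp, alpha = alpha, t1b = t1b, m0b = m0b),
            class = "quant_constants")
}

#' Tissue difference signal of the single-compartment bolus model
#'
#' Closed-form label/control difference signal delta-M for a voxel perfused
#' at CBF `f` with arterial transit time `att`, under the plug-flow bolus
#' model with QUIPSS-II bolus truncation and T1 decay at the blood rate:
#' \deqn{\Delta M(TI) = 0, \quad TI < att}
#' \deqn{\Delta M(TI) = 2\alpha M_{0b} \frac{f}{6000\lambda}(TI-att)\,
#'   e^{-TI/T_{1b}}, \quad att \le TI < att + TI_1}
#' \deqn{\Delta M(TI) = 2\alpha M_{0b} \frac{f}{6000\lambda} TI_1\,
#'   e^{-TI/T_{1b}}, \quad TI \ge att + TI_1}
#' with durations in seconds inside the formula (f/6000 converts
#' ml/min/100 g to 1/s). The signal is continuous in TI, linear in `f`, and
#' non-increasing in `att` at fixed TI.
#'
#' @param f CBF, ml/min/100 g; vector or array, >= 0.
#' @param att Arterial transit time, ms; recycled against `f`, >= 0.
#' @param params [acq_params()].
#' @param consts [quant_constants()].
#' @return Difference signal in the units of `m0b`, same shape as
#'   `f` (after recycling).
#' @examples
#' p <- acq_params(ti = 1500)
#' k <- quant_constants()
#' tissue_delta_m(60, 0, p, k)     # full bolus delivered
#' tissue_delta_m(60, 1800, p, k)  # bolus not yet arrived: 0
#' @export
tissue_delta_m <- function(f, att, params, consts) {
  if (any(f < 0)) stop("f must be >= 0")
  if (any(att < 0)) stop("att must be >= 0")
  ti <- params$ti
  ti1 <- params$ti1
  # delivered bolus duration seen at TI, clamped to [0, ti1], in seconds
  delivered <- pmin(pmax(ti - att, 0), ti1) / 1000
  out <- 2 * consts$alpha * consts$m0b * (f / (6000 * consts$lambda_bp)) *
    delivered * exp(-ti / consts$t1b)
  if (is.array(f)) array(out, dim(f)) else out
}

#' Intravascular arterial difference signal
#'
#' Difference signal from labeled blood still inside the voxel's arteries:
#' the labeled bolus occupies the arterial compartment (fractional volume
#' `abv`) during `[att_art, att_art + ti1)` and has cleared afterwards:
#' \deqn{\Delta M_{art}(TI) = 2\alpha M_{0b}\, abv\, e^{-TI/T_{1b}}}
#' within that window and 0 outside. This is the contamination mechanism
#' that inflates short-TI CBF estimates in proximal arterial territories.
#'
#' @param abv Arterial blood volume fraction, in \[0, 0.05\].
#' @param att_art Transit time to the voxel's arterial compartment, ms.
#' @inheritParams tissue_delta_m
#' @return Difference signal, same shape as `abv` (after recycling).
#' @export
arterial_delta_m <- function(abv, att_art, params, consts) {
  if (any(abv < 0) || any(abv > 0.05))
    stop("abv must be within [0, 0.05]")
  if (any(att_art < 0)) stop("att_art must be >= 0")
  ti <- params$ti
  present <- (att_art <= ti) & (ti < att_art + params$ti1)
  out <- 2 * consts$alpha * consts$m0b * abv * exp(-ti / consts$t1b) * present
  if (is.array(abv)) array(out, dim(abv)) else out
}

#' Saturation-recovery control signal
#'
#' Signal of a non-background-suppressed control (M0 calibration) image at
#' effective recovery time `ti_eff`:
#' `M(ti_eff) = tissue_m0 * (1 - exp(-ti_eff / t1_tissue))`.
#' Strictly increasing in `ti_eff`, approaching `tissue_m0`.
#'
#' @param tissue_m0 Equilibrium tissue magnetization, signal units, > 0.
#' @param ti_eff Recovery time since saturation, ms, > 0.
#' @param t1_tissue Tissue longitudinal relaxation time, ms, > 0.
#' @return Signal, same shape as `tissue_m0` (after recycling).
#' @export
control_signal <- function(tissue_m0, ti_eff, t1_tissue) {
  if (any(t1_tissue <= 0)) stop("t1_tissue must be > 0")
  if (any(tissue_m0 <= 0) || any(ti_eff <= 0))
    stop("tissue_m0 and ti_eff must be > 0")
  tissue_m0 * (1 - exp(-ti_eff / t1_tissue))
}

# tissue T1 values (ms) used for the calibration control images, and
# relative proton densities vs the lambda-scaled blood M0
.tissue_t1 <- c(gm = 1300, wm = 900, csf = 4000)
.tissue_pd <- c(gm = 1.0, wm = 0.8, csf = 1.2)

#' Simulate a PASL acquisition from a ground-truth phantom
#'
#' Produces `n_pairs` control/label volume pairs whose per-voxel difference
#' equals [tissue_delta_m()] + [arterial_delta_m()] (the voxel's ATT serves
#' as both the tissue and arterial transit time), plus the saturation-
#' recovery calibration series, with independent zero-mean Gaussian noise of
#' sd `params$noise_sd` added to every volume. Background suppression is
#' modelled as ideal: static tissue is nulled in the label/control pairs and
#' the difference signal is split symmetrically (control = +delta-M/2,
#' label = -delta-M/2) before noise.
#'
#' @param truth A `phantom_truth` from [generate_phantom()].
#' @param params [acq_params()].
#' @param seed Integer seed; the simulation is deterministic given
#'   `(truth, params, seed)`.
#' @param consts [quant_constants()]; `m0b` sets the signal scale of both
#'   the perfusion signal and the calibration images.
#' @return An object of class `asl_acquisition`: list with `series`
#'   (4-D array, volumes interleaved control, label, control, label, ...),
#'   `calib` (4-D array, one volume per calibration TI), `params`, `consts`,
#'   `voxel_size`, `subject_id`.
#' @export
simulate_acquisition <- function(truth, params, seed, consts = quant_constants()) {
  stopifnot(inherits(truth, "phantom_truth"), inherits(params, "acq_params"))
  dm <- tissue_delta_m(truth$cbf, truth$att, params, consts) +
    arterial_delta_m(truth$abv, truth$att, params, consts)

  # equilibrium tissue magnetization map for the calibration images
  m0t <- array(0, dim = truth$grid_shape)
  t1t <- array(1, dim = truth$grid_shape)
  for (tis in c("gm", "wm", "csf")) {
    idx <- truth$tissue == .tissue_code(tis)
    m0t[idx] <- consts$lambda_bp * consts$m0b * .tissue_pd[[tis]]
    t1t[idx] <- .tissue_t1[[tis]]
  }

  nv <- prod(truth$grid_shape)
  old_seed <- .save_rng()
  on.exit(.restore_rng(old_seed), add = TRUE)
  set.seed(seed)

  series <- array(0, dim = c(truth$grid_shape, 2L * params$n_pairs))
  for (k in seq_len(params$n_pairs)) {
    series[, , , 2L * k - 1L] <- dm / 2 + rnorm(nv, sd = params$noise_sd)
    series[, , , 2L * k]      <- -dm / 2 + rnorm(nv, sd = params$noise_sd)
  }
  calib <- array(0, dim = c(truth$grid_shape, length(params$calib_tis)))
  for (j in seq_along(params$calib_tis)) {
    vol <- array(0, dim = truth$grid_shape)
    in_tissue <- truth$tissue != 0L
    vol[in_tissue] <- control_signal(m0t[in_tissue], params$calib_tis[j],
                                     t1t[in_tissue])
    calib[, , , j] <- vol + rnorm(nv, sd = params$noise_sd)
  }

  structure(list(series = series, calib = calib, params = params,
                 consts = consts, voxel_size = truth$voxel_size,
                 subject_id = truth$subject_id),
            class = "asl_acquisition")
}

#' @export
print.asl_acquisition <- function(x, ...) {
  d <- dim(x$series)
  cat(sprintf("PASL acquisition: TI %g ms, %d label/control pairs, grid %s\n",
              x$params$ti, x$params$n_pairs,
              paste(d[1:3], collapse = "x")))
  cat(sprintf("  calibration TIs: %s ms; noise sd %g\n",
              paste(x$params$calib_tis, collapse = "/"), x$params$noise_sd))
  invisible(x)
}

#' Write an acquisition to NIfTI + JSON sidecar
#'
#' Serializes the 4-D label/control series (interleaved control, label, ...)
#' and the calibration series as NIfTI files plus a JSON sidecar holding the
#' acquisition parameters and volume ordering.
#'
#' @param acq An `asl_acquisition`.
#' @param dir Output directory (created if missing).
#' @param prefix File name prefix.
#' @return Invisibly, the paths written.
#' @export
write_acquisition <- function(acq, dir, prefix = "asl") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    series = file.path(dir, paste0(prefix, "_series.nii.gz")),
    calib = file.path(dir, paste0(prefix, "_calib.nii.gz")),
    sidecar = file.path(dir, paste0(prefix, "_params.json"))
  )
  RNifti::writeNifti(.as_nifti(acq$series, acq$voxel_size), paths["series"])
  RNifti::writeNifti(.as_nifti(acq$calib, acq$voxel_size), paths["calib"])
  side <- list(ti = acq$params$ti, ti1 = acq$params$ti1,
               n_pairs = acq$params$n_pairs,
               calib_tis = acq$params$calib_tis,
               calib_trs = acq$params$calib_trs,
               noise_sd = acq$params$noise_sd,
               volume_order = "control/label interleaved, control first",
               constants = unclass(acq$consts),
               subject_id = acq$subject_id)
  jsonlite::write_json(side, paths["sidecar"], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
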