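#' VOI label scheme
#'
#' Integer labels of the parcellation used by the phantom: 7 cortical
#' volumes of interest per hemisphere (labels 1-7 left, 8-14 right), the
#' basal ganglia (15) and the supratentorial white matter (16).
#'
#' @return Named integer vector of VOI labels.
#' @export
voi_labels <- function() {
  cortical <- c("frontal", "parietal", "temporal", "occipital", "insular",
                "temporomesial", "cingulate")
  lab <- c(stats::setNames(1:7, paste0(cortical, "_L")),
           stats::setNames(8:14, paste0(cortical, "_R")),
           basal_ganglia = 15L, white_matter = 16L)
  vapply(lab, as.integer, integer(1))
}

# cortical VOI base codes whose territory is a PTA/DTA mixture
.mixed_voi_base <- c(1L, 3L, 6L, 7L)   # frontal, temporal, temporomesial, cingulate

#' Cohort configuration
#'
#' Describes a synthetic subject cohort: geometry, the territory-specific
#' arterial transit time (ATT) and CBF distributions (mean, across-subject
#' sd), the arterial blood volume of the proximal territories, acquisition
#' noise, and optional subject covariates with ATT coupling. Distributions
#' are Gaussian truncated at physical bounds.
#'
#' The proximal territories of the arteries (PTA: basal ganglia, insular
#' cortex, a perisylvian band inside the mixed VOIs) receive short ATT and
#' carry intravascular arterial signal (`abv_pta`); the distal territories
#' (DTA: parietal and occipital cortex, white matter) receive long ATT; the
#' watershed bands (the non-perisylvian part of the frontal, temporal,
#' temporomesial and cingulate VOIs) receive the longest ATT. The mixed
#' VOIs therefore contain both territories, so opposite TI biases average
#' out in their regional means.
#'
#' @param n_subjects Number of subjects, >= 1.
#' @param seed Integer seed of the cohort's deterministic random stream.
#' @param att_pta_ms,att_dta_ms,att_watershed_ms `c(mean, sd)` of the
#'   territory ATTs, ms (across-subject variation).
#' @param gm_cbf,wm_cbf `c(mean, sd)` of grey / white matter CBF,
#'   ml/min/100 g.
#' @param abv_pta Arterial blood volume fraction of PTA voxels, in
#'   \[0, 0.05\].
#' @param noise_sd Acquisition noise sd, signal units.
#' @param mixed_pta_frac Fraction of each mixed VOI occupied by the
#'   perisylvian PTA band (by voxel volume), in \[0, 1\].
#' @param att_voxel_sd,cbf_voxel_sd Within-territory voxel-level jitter sds
#'   (ms, ml/min/100 g).
#' @param grid_shape 3 positive integers, voxels.
#' @param voxel_size Voxel dimensions, mm.
#' @param subject_covariates `NULL` or a data.frame with columns `age`
#'   (years) and `sedated` (logical), one row per subject. Default: ages
#'   evenly spaced over 9.6-17.4 years, nobody sedated.
#' @param age_att_slope ATT change per year of age, ms/year (applied to all
#'   territories, centred on the cohort mean age).
#' @param sedation_att_shift ATT shift for sedated subjects, ms.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects = 12, seed = 1,
                          att_pta_ms = c(900, 50),
                          att_dta_ms = c(1800, 75),
                          att_watershed_ms = c(1900, 75),
                          gm_cbf = c(60, 6), wm_cbf = c(25, 3),
                          abv_pta = 0.01, noise_sd = 1,
                          mixed_pta_frac = 0.13,
                          att_voxel_sd = 25, cbf_voxel_sd = 5,
                          grid_shape = c(32, 32, 10),
                          voxel_size = c(7.5, 7.5, 10.5),
                          subject_covariates = NULL,
                          age_att_slope = 0, sedation_att_shift = 0) {
  n_subjects <- as.integer(n_subjects)
  stopifnot(n_subjects >= 1, length(grid_shape) == 3)
  if (any(grid_shape <= 0)) stop("grid dimensions must be positive")
  for (nm in c("att_pta_ms", "att_dta_ms", "att_watershed_ms", "gm_cbf",
               "wm_cbf")) {
    v <- get(nm)
    if (length(v) != 2 || v[2] < 0)
      stop(nm, " must be c(mean, sd) with sd >= 0")
  }
  if (att_dta_ms[1] <= att_pta_ms[1])
    stop("att_dta_ms mean must exceed att_pta_ms mean")
  if (abv_pta < 0 || abv_pta > 0.05) stop("abv_pta must be in [0, 0.05]")
  if (mixed_pta_frac < 0 || mixed_pta_frac > 1)
    stop("mixed_pta_frac must be in [0, 1]")
  if (is.null(subject_covariates)) {
    subject_covariates <- data.frame(
      age = if (n_subjects == 1) 13.5 else
        seq(9.6, 17.4, length.out = n_subjects),
      sedated = rep(FALSE, n_subjects))
  }
  stopifnot(nrow(subject_covariates) == n_subjects,
            all(c("age", "sedated") %in% names(subject_covariates)))
  structure(list(n_subjects = n_subjects, seed = as.integer(seed),
                 att_pta_ms = att_pta_ms, att_dta_ms = att_dta_ms,
                 att_watershed_ms = att_watershed_ms,
                 gm_cbf = gm_cbf, wm_cbf = wm_cbf, abv_pta = abv_pta,
                 noise_sd = noise_sd, mixed_pta_frac = mixed_pta_frac,
                 att_voxel_sd = att_voxel_sd, cbf_voxel_sd = cbf_voxel_sd,
                 grid_shape = as.integer(grid_shape),
                 voxel_size = voxel_size,
                 subject_covariates = subject_covariates,
                 age_att_slope = age_att_slope,
                 sedation_att_shift = sedation_att_shift),
            class = "cohort_config")
}

# Deterministic zoned-cylinder atlas on the given grid. Radial zones
# (scaled to the in-plane grid size): CSF core, deep nuclei, white matter,
# cortical ribbon; angular sectors parcellate the ribbon into the 7
# cortical VOIs per hemisphere (anterior = +y, left = -x). The innermost
# shell of the ribbon inside the mixed VOIs is the perisylvian PTA band,
# with width set by mixed_pta_frac; the remainder of the mixed VOIs is
# watershed. Returns tissue, voi, territory and ATT-zone label arrays.
.build_atlas <- function(grid_shape, mixed_pta_frac) {
  nx <- grid_shape[1]; ny <- grid_shape[2]; nz <- grid_shape[3]
  cx <- (nx + 1) / 2; cy <- (ny + 1) / 2
  scale <- min(nx, ny) / 32
  r_csf <- 2 * scale; r_deep <- 5 * scale
  r_rib_in <- 10.5 * scale; r_brain <- 14 * scale
  deep_slices <- seq(max(1L, ceiling(0.35 * nz)), max(1L, floor(0.7 * nz)))

  xs <- slice.index(array(0, grid_shape), 1) - cx
  ys <- slice.index(array(0, grid_shape), 2) - cy
  zs <- slice.index(array(0, grid_shape), 3)
  r <- sqrt(xs^2 + ys^2)
  # polar angle from the anterior (+y) direction, degrees in [0, 180]
  psi <- abs(atan2(xs, ys)) * 180 / pi
  right <- xs > 0

  sector_breaks <- c(0, 40, 55, 90, 120, 155, 165, 180.001)
  # sector order from anterior: frontal, cingulate, parietal, occipital,
  # temporal, temporomesial, insular -> VOI base codes
  sector_code <- c(1L, 7L, 2L, 4L, 3L, 6L, 5L)

  tissue <- array(.tissue_levels[["background"]], grid_shape)
  voi <- array(0L, grid_shape)
  zone <- array(0L, grid_shape)  # 0 none, 1 pta, 2 dta, 3 watershed

  in_brain <- r <= r_brain
  tissue[in_brain & r <= r_csf] <- .tissue_levels[["csf"]]

  deep <- in_brain & r > r_csf & r <= r_deep
  bg <- deep & (zs %in% deep_slices)
  tissue[deep] <- .tissue_levels[["wm"]]
  tissue[bg] <- .tissue_levels[["gm"]]
  voi[bg] <- 15L
  zone[bg] <- 1L

  wm <- in_brain & r > r_deep & r <= r_rib_in
  tissue[wm] <- .tissue_levels[["wm"]]
  voi[wm | (deep & !bg)] <- 16L
  zone[wm | (deep & !bg)] <- 2L

  ribbon <- in_brain & r > r_rib_in
  tissue[ribbon] <- .tissue_levels[["gm"]]
  sector <- findInterval(psi, sector_breaks, rightmost.closed = TRUE)
  base <- array(sector_code[sector], grid_shape)
  voi[ribbon] <- base[ribbon] + ifelse(right[ribbon], 7L, 0L)

  zone[ribbon & base == 5L] <- 1L                      # insular: PTA
  zone[ribbon & base %in% c(2L, 4L)] <- 2L             # parietal/occipital: DTA
  # mixed VOIs: the innermost (perisylvian) shell of each VOI is PTA, the
  # rest is watershed; ranking by radius within each VOI gives every mixed
  # VOI the configured PTA fraction exactly (up to one voxel)
  for (b in .mixed_voi_base) {
    for (hemi_right in c(FALSE, TRUE)) {
      idx <- which(ribbon & base == b & (right == hemi_right))
      if (!length(idx)) next
      k <- round(mixed_pta_frac * length(idx))
      inner <- idx[order(r[idx])][seq_len(k)]
      zone[idx] <- 3L                                  # watershed
      zone[inner] <- 1L                                # perisylvian band: PTA
    }
  }

  territory <- array(.territory_levels[["none"]], grid_shape)
  territory[zone == 1L] <- .territory_levels[["pta"]]
  territory[zone %in% c(2L, 3L)] <- .territory_levels[["dta"]]

  list(tissue = tissue, voi = voi, zone = zone, territory = territory)
}

.rtruncnorm0 <- function(n, mean, sd) pmax(stats::rnorm(n, mean, sd), 0)

#' Generate one ground-truth phantom
#'
#' Builds the digital phantom of one subject: a zoned axial stack with
#' grey/white/CSF tissue classes, the VOI parcellation of [voi_labels()],
#' PTA/DTA territory labels, and per-voxel ground-truth CBF, ATT and
#' arterial blood volume maps drawn from the configured distributions using
#' a deterministic stream derived from `(config$seed, subject_index)`.
#' Subject covariates shift ATT by `sedation_att_shift` (sedated subjects)
#' and `age_att_slope * (age - cohort mean age)`.
#'
#' @param config A [cohort_config()].
#' @param subject_index Subject number, 1-based, <= `config$n_subjects`.
#' @return An object of class `phantom_truth`: grid metadata plus 3-D
#'   arrays `cbf` (ml/min/100 g), `att` (ms), `abv` (fraction), `tissue`,
#'   `voi`, `territory` (integer labels), with the subject's covariates
#'   attached.
#' @export
generate_phantom <- function(config, subject_index) {
  stopifnot(inherits(config, "cohort_config"))
  subject_index <- as.integer(subject_index)
  if (subject_index < 1 || subject_index > config$n_subjects)
    stop("subject_index must be in 1..n_subjects")

  atlas <- .build_atlas(config$grid_shape, config$mixed_pta_frac)
  cov <- config$subject_covariates[subject_index, ]
  att_shift <- config$sedation_att_shift * as.numeric(cov$sedated) +
    config$age_att_slope * (cov$age - mean(config$subject_covariates$age))

  old_seed <- .save_rng()
  on.exit(.restore_rng(old_seed), add = TRUE)
  set.seed(.derive_seed(config$seed, subject_index, stage = 1L))

  att_mean <- c(pta = .rtruncnorm0(1, config$att_pta_ms[1], config$att_pta_ms[2]),
                dta = .rtruncnorm0(1, config$att_dta_ms[1], config$att_dta_ms[2]),
                watershed = .rtruncnorm0(1, config$att_watershed_ms[1],
                                         config$att_watershed_ms[2]))
  att_mean <- pmax(att_mean + att_shift, 0)
  gm_cbf_s <- .rtruncnorm0(1, config$gm_cbf[1], config$gm_cbf[2])
  wm_cbf_s <- .rtruncnorm0(1, config$wm_cbf[1], config$wm_cbf[2])

  nv <- prod(config$grid_shape)
  att <- array(0, config$grid_shape)
  for (z in 1:3) {
    idx <- atlas$zone == z
    if (any(idx))
      att[idx] <- .rtruncnorm0(sum(idx), att_mean[z], config$att_voxel_sd)
  }

  cbf <- array(0, config$grid_shape)
  gm <- atlas$tissue == .tissue_levels[["gm"]]
  wm <- atlas$tissue == .tissue_levels[["wm"]]
  cbf[gm] <- .rtruncnorm0(sum(gm), gm_cbf_s, config$cbf_voxel_sd)
  cbf[wm] <- .rtruncnorm0(sum(wm), wm_cbf_s, config$cbf_voxel_sd)

  abv <- array(0, config$grid_shape)
  abv[atlas$zone == 1L] <- config$abv_pta

  structure(list(grid_shape = config$grid_shape,
                 voxel_size = config$voxel_size,
                 cbf = cbf, att = att, abv = abv,
                 tissue = atlas$tissue, voi = atlas$voi,
                 territory = atlas$territory,
                 subject_id = sprintf("sub-%02d", subject_index),
                 covariates = list(age = cov$age, sedated = cov$sedated)),
            class = "phantom_truth")
}

#' Generate a cohort of phantoms
#'
#' @param config A [cohort_config()].
#' @return List of `config$n_subjects` [generate_phantom()] results,
#'   mutually independent given the seed stream.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  lapply(seq_len(config$n_subjects), function(i) generate_phantom(config, i))
}

#' @export
print.phantom_truth <- function(x, ...) {
  cat(sprintf("Phantom %s: grid %s, %d GM / %d WM voxels\n",
              x$subject_id, paste(x$grid_shape, collapse = "x"),
              sum(x$tissue == .tissue_levels[["gm"]]),
              sum(x$tissue == .tissue_levels[["wm"]])))
  cat(sprintf("  PTA median ATT %.0f ms, DTA median ATT %.0f ms\n",
              stats::median(x$att[x$territory == .territory_levels[["pta"]]]),
              stats::median(x$att[x$territory == .territory_levels[["dta"]]])))
  invisible(x)
}

#' Write a phantom to NIfTI volumes + JSON sidecar
#'
#' @param truth A `phantom_truth`.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
write_phantom <- function(truth, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  vols <- c("cbf", "att", "abv", "tissue", "voi", "territory")
  paths <- stats::setNames(
    file.path(dir, paste0(truth$subject_id, "_", vols, ".nii.gz")), vols)
  for (v in vols)
    RNifti::writeNifti(.as_nifti(truth[[v]], truth$voxel_size), paths[[v]])
  sidecar <- file.path(dir, paste0(truth$subject_id, "_truth.json"))
  jsonlite::write_json(
    list(subject_id = truth$subject_id, grid_shape = truth$grid_shape,
         voxel_size = truth$voxel_size, covariates = truth$covariates,
         voi_labels = as.list(voi_labels()),
         tissue_labels = as.list(.tissue_levels),
         territory_labels = as.list(.territory_levels)),
    sidecar, auto_unbox = TRUE, digits = NA)
  invisible(c(paths, sidecar = sidecar))
}
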