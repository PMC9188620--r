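#' Intersect a VOI mask with a tissue segmentation mask
#'
#' Logical AND of a parcellation mask with its matching tissue class
#' (cortical VOIs with grey matter, the white-matter VOI with white
#' matter), mitigating partial-volume contamination of regional means. An
#' empty intersection is signalled as a warning condition of class
#' `asltilab_empty_voi` so the caller can drop the VOI from statistics.
#'
#' @param voi_mask,tissue_mask Logical arrays on the same grid.
#' @return Logical array `voi_mask & tissue_mask`.
#' @export
intersect_voi <- function(voi_mask, tissue_mask) {
  if (!identical(dim(voi_mask), dim(tissue_mask)))
    stop("grid mismatch between VOI and tissue masks")
  out <- voi_mask & tissue_mask
  if (!any(out))
    warning(warningCondition("VOI/tissue intersection is empty; VOI dropped",
                             class = c("asltilab_empty_voi", "warning")))
  out
}

#' Regional mean CBF
#'
#' @param cbf A `cbf_map` or a numeric array.
#' @param mask Logical array, non-empty.
#' @return Arithmetic mean over in-mask voxels, ml/min/100 g.
#' @export
regional_mean <- function(cbf, mask) {
  vol <- if (inherits(cbf, "cbf_map")) cbf$volume else cbf
  if (!identical(dim(vol), dim(mask))) stop("grid mismatch")
  if (!any(mask)) stop("empty mask")
  mean(vol[mask])
}

#' Regional Z-score of a cortical VOI
#'
#' Standardizes a VOI's mean CBF against the whole cerebral cortex of the
#' same subject: `Z_VOI = (CBF_VOI - mean(cortex)) / sd(cortex)`, where the
#' reference is the set of voxel CBF values of all cortical VOIs. Reflects
#' whether a cortical region is hyper- or hypoperfused relative to the rest
#' of the cortex, the quantity a neuroradiologist reads off a perfusion
#' map.
#'
#' @param mean_cbf_voi VOI mean CBF, ml/min/100 g.
#' @param cortex_voxels Numeric vector of cortex voxel CBF values,
#'   length >= 2 with nonzero spread.
#' @param sd_type `"population"` (n denominator, default) or `"sample"`.
#' @return Unitless Z-score.
#' @export
z_voi <- function(mean_cbf_voi, cortex_voxels,
                  sd_type = c("population", "sample")) {
  if (length(cortex_voxels) < 2) stop("need >= 2 cortex voxels")
  s <- .stat_sd(cortex_voxels, sd_type)
  if (s == 0) stop("zero cortex standard deviation")
  (mean_cbf_voi - mean(cortex_voxels)) / s
}

#' Voxel-wise grey-matter Z-score map
#'
#' Per-voxel counterpart of [z_voi()]: every grey-matter voxel is
#' standardized against the subject's grey-matter mean and standard
#' deviation; voxels outside the mask are `NaN`. By construction the
#' in-mask values have mean 0 and (population) sd 1.
#'
#' @param cbf A `cbf_map` or numeric array.
#' @param gm_mask Logical array with >= 2 `TRUE` voxels.
#' @inheritParams z_voi
#' @return An object of class `z_map`: list with `volume`, `ti`,
#'   `subject_id`.
#' @export
z_map <- function(cbf, gm_mask, sd_type = c("population", "sample")) {
  vol <- if (inherits(cbf, "cbf_map")) cbf$volume else cbf
  ti <- if (inherits(cbf, "cbf_map")) cbf$ti else NA_real_
  sid <- if (inherits(cbf, "cbf_map")) cbf$subject_id else NA_character_
  if (!identical(dim(vol), dim(gm_mask))) stop("grid mismatch")
  if (sum(gm_mask) < 2) stop("need >= 2 grey-matter voxels")
  v <- vol[gm_mask]
  s <- .stat_sd(v, sd_type)
  if (s == 0) stop("zero grey-matter standard deviation")
  out <- array(NaN, dim(vol))
  out[gm_mask] <- (v - mean(v)) / s
  structure(list(volume = out, ti = ti, subject_id = sid), class = "z_map")
}

#' Voxel-wise subtraction map
#'
#' @param map_a,map_b `cbf_map`/`z_map` objects or numeric arrays on the
#'   same grid.
#' @return Numeric array `a - b` (anti-symmetric in its arguments).
#' @export
subtraction_map <- function(map_a, map_b) {
  va <- if (is.list(map_a)) map_a$volume else map_a
  vb <- if (is.list(map_b)) map_b$volume else map_b
  if (!identical(dim(va), dim(vb))) stop("grid mismatch")
  va - vb
}

#' Across-subject binarized sum map
#'
#' Binarizes each subject's difference map at strict sign (exact zeros and
#' non-finite voxels count in neither direction) and adds the binary maps:
#' the value at a voxel is the number of subjects whose difference has the
#' requested sign. Since all synthetic subjects share one grid, no
#' resampling is needed; `resample` accepts a hook (a function applied to
#' each binary map) to keep the common-space pipeline shape.
#'
#' @param diff_maps Non-empty list of numeric arrays on one grid.
#' @param sign `"positive"` or `"negative"`.
#' @param resample Optional function mapping a binary array to a binary
#'   array (identity by default).
#' @return Integer-valued count array in \[0, n_subjects\].
#' @export
across_subjects_sum <- function(diff_maps, sign = c("positive", "negative"),
                                resample = identity) {
  sign <- match.arg(sign)
  if (length(diff_maps) == 0) stop("empty list of difference maps")
  dims <- dim(diff_maps[[1]])
  acc <- array(0, dims)
  for (m in diff_maps) {
    if (!identical(dim(m), dims)) stop("grid mismatch across subjects")
    b <- if (sign == "positive") m > 0 else m < 0
    b[!is.finite(m)] <- FALSE
    acc <- acc + resample(b + 0)
  }
  acc
}

#' Per-VOI regional summary of one CBF map
#'
#' Extracts, for one subject and one TI, the mean CBF and voxel count of
#' every VOI (cortical VOIs intersected with grey matter, the white-matter
#' VOI with white matter), plus whole-cortex, white-matter and
#' basal-ganglia rows, and the cortical Z-scores of [z_voi()] against the
#' union of all cortical VOI voxels.
#'
#' @param cbf A `cbf_map`.
#' @param truth The subject's `phantom_truth` (supplies tissue and VOI
#'   labels).
#' @inheritParams z_voi
#' @return data.frame with columns `subject`, `ti`, `voi`, `hemisphere`,
#'   `n_voxels`, `mean_cbf`, `z_voi` (NA for non-cortical rows).
#' @export
regional_table <- function(cbf, truth, sd_type = c("population", "sample")) {
  stopifnot(inherits(cbf, "cbf_map"), inherits(truth, "phantom_truth"))
  sd_type <- match.arg(sd_type)
  labs <- voi_labels()
  gm <- truth$tissue == .tissue_levels[["gm"]]
  wm <- truth$tissue == .tissue_levels[["wm"]]

  cortical <- labs[labs <= 14L]
  masks <- list()
  for (nm in names(cortical))
    masks[[nm]] <- intersect_voi(truth$voi == cortical[[nm]], gm)
  cortex_mask <- Reduce(`|`, masks)
  cortex_vox <- cbf$volume[cortex_mask]

  rows <- list()
  add_row <- function(voi, hemi, mask, z) {
    rows[[length(rows) + 1]] <<- data.frame(
      subject = cbf$subject_id, ti = cbf$ti, voi = voi, hemisphere = hemi,
      n_voxels = sum(mask), mean_cbf = regional_mean(cbf, mask),
      z_voi = z, stringsAsFactors = FALSE)
  }
  add_row("cerebral_cortex", NA_character_, cortex_mask, NA_real_)
  add_row("white_matter", NA_character_,
          intersect_voi(truth$voi == labs[["white_matter"]], wm), NA_real_)
  add_row("basal_ganglia", NA_character_,
          intersect_voi(truth$voi == labs[["basal_ganglia"]], gm), NA_real_)
  for (nm in names(cortical)) {
    m <- masks[[nm]]
    if (!any(m)) next
    hemi <- sub("^.*_", "", nm)
    base <- sub("_[LR]$", "", nm)
    add_row(base, hemi, m,
            z_voi(regional_mean(cbf, m), cortex_vox, sd_type))
  }
  do.call(rbind, rows)
}
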