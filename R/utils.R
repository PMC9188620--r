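# internal helpers shared across modules

.tissue_levels <- c(background = 0L, gm = 1L, wm = 2L, csf = 3L)

.tissue_code <- function(name) .tissue_levels[[tolower(name)]]

.territory_levels <- c(none = 0L, pta = 1L, dta = 2L)

# save/restore the global RNG state so simulation calls are deterministic
# without clobbering the caller's stream
.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

.restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

# deterministic sub-seed for (seed, subject, stage); kept within 32-bit range
.derive_seed <- function(seed, subject_index = 0L, stage = 0L) {
  as.integer((abs(seed) * 48271 + subject_index * 16807 + stage * 69621) %%
               2147483587)
}

.as_nifti <- function(arr, voxel_size) {
  pix <- c(voxel_size, rep(1, max(0, length(dim(arr)) - 3)))
  RNifti::asNifti(arr, pixdim = pix)
}

.same_grid <- function(a, b) identical(dim(a)[1:3], dim(b)[1:3])

# population (n-denominator) standard deviation
.pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

.stat_sd <- function(x, sd_type = c("population", "sample")) {
  sd_type <- match.arg(sd_type)
  if (sd_type == "population") .pop_sd(x) else stats::sd(x)
}

# significance markers used in the report tables
.p_stars <- function(p) {
  ifelse(p < 1e-4, "****",
         ifelse(p < 1e-3, "***",
                ifelse(p < 1e-2, "**",
                       ifelse(p < 0.05, "*", "n.s."))))
}
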