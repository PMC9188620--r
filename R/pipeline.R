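#' Study configuration
#'
#' Bundles a cohort with the two inversion times to compare, the
#' significance level, and the analyses to run. `ti_a != ti_b` is required
#' for the TI-comparison design and `ti_a == ti_b` for scan-rescan.
#'
#' @param cohort A [cohort_config()].
#' @param ti_a,ti_b The two inversion times, ms.
#' @param alpha Significance level applied after FDR adjustment.
#' @param analyses Character subset of
#'   `c("ti_comparison", "scan_rescan", "sedation", "age")`.
#' @param output_dir Optional directory; when set, the runners write their
#'   report files there.
#' @param sd_type Standard-deviation convention for the Z-scores.
#' @return An object of class `study_config`.
#' @export
study_config <- function(cohort, ti_a = 1500, ti_b = 2020, alpha = 0.05,
                         analyses = "ti_comparison", output_dir = NULL,
                         sd_type = c("population", "sample")) {
  stopifnot(inherits(cohort, "cohort_config"))
  bad <- setdiff(analyses, c("ti_comparison", "scan_rescan", "sedation", "age"))
  if (length(bad)) stop("unknown analyses: ", paste(bad, collapse = ", "))
  if ("ti_comparison" %in% analyses && ti_a == ti_b)
    stop("ti_comparison requires ti_a != ti_b")
  if ("scan_rescan" %in% analyses && ti_a != ti_b)
    stop("scan_rescan requires ti_a == ti_b")
  structure(list(cohort = cohort, ti_a = ti_a, ti_b = ti_b, alpha = alpha,
                 analyses = analyses, output_dir = output_dir,
                 sd_type = match.arg(sd_type)),
            class = "study_config")
}

#' Reference cohort of the TI-comparison study
#'
#' Twelve subjects with proximal-territory ATT 900 +/- 50 ms, distal 1800
#' +/- 75 ms, watershed 1900 +/- 75 ms, arterial blood volume 0.01 in the
#' proximal territories, and moderate acquisition noise: the conditions
#' under which the region-dependent TI effect between 1500 and 2020 ms is
#' expressed.
#'
#' @param seed Cohort seed.
#' @param n_subjects Cohort size.
#' @param ... Overrides passed to [cohort_config()].
#' @return A [cohort_config()].
#' @export
reference_cohort_config <- function(seed = 1, n_subjects = 12, ...) {
  cohort_config(n_subjects = n_subjects, seed = seed, ...)
}

#' Scan-rescan cohort
#'
#' Five adult subjects, both acquisitions at the same TI; perfusion
#' parameters as in the reference cohort.
#'
#' @param seed Cohort seed.
#' @param n_subjects Cohort size.
#' @param ... Overrides passed to [cohort_config()].
#' @return A [cohort_config()].
#' @export
scan_rescan_cohort_config <- function(seed = 1, n_subjects = 5, ...) {
  args <- list(...)
  if (is.null(args$subject_covariates))
    args$subject_covariates <- data.frame(
      age = seq(26, 29, length.out = n_subjects),
      sedated = rep(FALSE, n_subjects))
  do.call(cohort_config, c(list(n_subjects = n_subjects, seed = seed), args))
}

#' Covariate-demo cohort (sedation and age coupling)
#'
#' Twelve pediatric subjects with transit times in the short-ATT regime
#' (proximal 820 +/- 40 ms, distal 1250 +/- 60 ms, watershed 1350 +/- 60
#' ms), three of them sedated, with ATT lengthened by sedation and
#' shortened with age. In this regime the kinetic model reproduces the
#' covariate sign pattern of the TI effect: longer ATT (younger or
#' sedated) increases the distal-territory variation and deepens the
#' proximal-territory arterial contamination at the short TI (see the
#' methods vignette for why the signs invert when baseline ATT exceeds
#' the shorter TI).
#'
#' @param seed Cohort seed.
#' @param ... Overrides passed to [cohort_config()].
#' @return A [cohort_config()].
#' @export
covariate_cohort_config <- function(seed = 1, ...) {
  args <- list(...)
  defaults <- list(
    n_subjects = 12, seed = seed,
    att_pta_ms = c(820, 40), att_dta_ms = c(1250, 60),
    att_watershed_ms = c(1350, 60),
    age_att_slope = -25, sedation_att_shift = 150,
    subject_covariates = data.frame(
      age = c(10.0, 11.5, 13.0, 9.6, 10.8, 12.4, 13.9, 15.2, 16.1, 16.8,
              17.4, 14.6),
      sedated = c(TRUE, TRUE, TRUE, rep(FALSE, 9))))
  for (nm in names(defaults))
    if (is.null(args[[nm]])) args[[nm]] <- defaults[[nm]]
  do.call(cohort_config, args)
}

.with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop(errorCondition(sprintf("[stage %s] %s", stage, conditionMessage(e)),
                        class = c("asltilab_stage_error", "error")))
  })
}

# simulate + quantify + summarize one subject at one TI
.process_subject <- function(truth, ti, cohort, seed, sd_type) {
  params <- acq_params(ti = ti, noise_sd = cohort$noise_sd)
  acq <- .with_stage("simulate", simulate_acquisition(truth, params, seed))
  gm <- truth$tissue == .tissue_levels[["gm"]]
  cbf <- .with_stage("quantify", .quantify_acquisition(acq, gm))
  cbf$subject_id <- truth$subject_id
  tab <- .with_stage("regional", regional_table(cbf, truth, sd_type))
  list(cbf = cbf, table = tab)
}

# paired Wilcoxon + BH over the rows of a two-TI regional table
.paired_battery <- function(tab, value_col, family, ti_a, ti_b, alpha) {
  keys <- unique(tab[, c("voi", "hemisphere")])
  res <- list()
  for (i in seq_len(nrow(keys))) {
    voi <- keys$voi[i]; hemi <- keys$hemisphere[i]
    sel <- tab$voi == voi &
      (is.na(hemi) & is.na(tab$hemisphere) |
         (!is.na(hemi) & !is.na(tab$hemisphere) & tab$hemisphere == hemi))
    sel[is.na(sel)] <- FALSE
    sub <- tab[sel, ]
    a <- sub[sub$ti == ti_a, ]
    b <- sub[sub$ti == ti_b, ]
    a <- a[order(a$subject), ]; b <- b[order(b$subject), ]
    if (nrow(a) == 0 || nrow(a) != nrow(b)) next
    va <- a[[value_col]]; vb <- b[[value_col]]
    if (anyNA(va) || anyNA(vb)) next
    name <- if (is.na(hemi)) voi else paste(voi, hemi, sep = "_")
    tr <- wilcoxon_signed_rank(va, vb, name = name, family = family)
    res[[name]] <- data.frame(
      family = family, name = name, statistic = tr$statistic,
      p_raw = tr$p_raw, median_diff = stats::median(vb - va),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  bh <- benjamini_hochberg(out$p_raw, alpha)
  out$p_adjusted <- bh$adjusted
  out$significant <- bh$rejected
  out$stars <- ifelse(out$significant, .p_stars(out$p_raw), "n.s.")
  rownames(out) <- NULL
  out
}

.format_table <- function(df) {
  for (nm in names(df))
    if (is.numeric(df[[nm]])) df[[nm]] <- sprintf("%.6g", df[[nm]])
  df
}

.write_tsv <- function(df, path) {
  utils::write.table(.format_table(df), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
}

.write_study_outputs <- function(result, config) {
  dir <- config$output_dir
  if (is.null(dir)) return(invisible(NULL))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  .write_tsv(result$regional_table, file.path(dir, "regional_table.tsv"))
  .write_tsv(result$stats, file.path(dir, "stats_report.tsv"))
  vs <- config$cohort$voxel_size
  if (!is.null(result$sum_pos)) {
    RNifti::writeNifti(.as_nifti(result$sum_pos, vs),
                       file.path(dir, "sum_pos.nii.gz"))
    RNifti::writeNifti(.as_nifti(result$sum_neg, vs),
                       file.path(dir, "sum_neg.nii.gz"))
  }
  if (!is.null(result$correlations))
    .write_tsv(result$correlations, file.path(dir, "corr_results.tsv"))
  log <- list(ti_a = config$ti_a, ti_b = config$ti_b, alpha = config$alpha,
              analyses = config$analyses, sd_type = config$sd_type,
              cohort = unclass(config$cohort))
  log$cohort$subject_covariates <- as.list(config$cohort$subject_covariates)
  jsonlite::write_json(log, file.path(dir, "run.log"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}

#' Run the TI-comparison study end-to-end
#'
#' For every subject of the cohort: generate the phantom, simulate PASL at
#' both TIs, quantify CBF, and summarize per VOI; then compare the two TIs
#' with paired Wilcoxon signed-rank tests (Benjamini-Hochberg adjusted,
#' one family for the CBF means and one for the cortical Z-scores) and
#' accumulate the across-subject binarized sum maps of the
#' `CBF(ti_b) - CBF(ti_a)` subtraction maps. Deterministic given the
#' cohort seed.
#'
#' @param config A [study_config()] whose analyses include
#'   `"ti_comparison"`.
#' @return An object of class `ti_comparison_result`: list with
#'   `regional_table`, `stats` (family, name, statistic, raw/adjusted p,
#'   significance, median paired difference), `sum_pos`/`sum_neg` count
#'   maps, and the config. Reports are written to `config$output_dir` when
#'   set.
#' @export
run_ti_comparison <- function(config) {
  stopifnot(inherits(config, "study_config"))
  if (!"ti_comparison" %in% config$analyses)
    stop("config$analyses does not include ti_comparison")
  cohort <- config$cohort
  tabs <- list()
  diffs <- list()
  for (i in seq_len(cohort$n_subjects)) {
    truth <- .with_stage("phantom", generate_phantom(cohort, i))
    ra <- .process_subject(truth, config$ti_a, cohort,
                           .derive_seed(cohort$seed, i, 2L), config$sd_type)
    rb <- .process_subject(truth, config$ti_b, cohort,
                           .derive_seed(cohort$seed, i, 3L), config$sd_type)
    tabs[[i]] <- rbind(ra$table, rb$table)
    diffs[[i]] <- subtraction_map(rb$cbf, ra$cbf)
  }
  regional <- do.call(rbind, tabs)
  stats_cbf <- .paired_battery(regional, "mean_cbf", "cbf_voi",
                               config$ti_a, config$ti_b, config$alpha)
  zrows <- regional[!is.na(regional$z_voi), ]
  stats_z <- .paired_battery(zrows, "z_voi", "z_voi",
                             config$ti_a, config$ti_b, config$alpha)
  result <- structure(
    list(regional_table = regional,
         stats = rbind(stats_cbf, stats_z),
         sum_pos = across_subjects_sum(diffs, "positive"),
         sum_neg = across_subjects_sum(diffs, "negative"),
         subtraction_maps = diffs,
         config = config),
    class = "ti_comparison_result")
  .write_study_outputs(result, config)
  result
}

#' @export
print.ti_comparison_result <- function(x, ...) {
  sig <- x$stats[x$stats$significant, ]
  cat(sprintf("TI comparison %g vs %g ms, %d subjects\n",
              x$config$ti_a, x$config$ti_b, x$config$cohort$n_subjects))
  cat(sprintf("  %d of %d comparisons FDR-significant\n",
              nrow(sig), nrow(x$stats)))
  invisible(x)
}

#' Run the scan-rescan study
#'
#' Two independent noisy acquisitions per subject at the same TI, followed
#' by the same regional battery as [run_ti_comparison()]; additionally
#' reports the per-voxel median scan-rescan difference in grey matter and
#' the point-biserial correlation between the net subtraction-map counts
#' and the PTA/DTA territory label (which should be near zero: scan-rescan
#' differences carry no territory structure).
#'
#' @param config A [study_config()] with `ti_a == ti_b` and analyses
#'   including `"scan_rescan"`.
#' @return An object of class `ti_comparison_result` with extra entries
#'   `gm_median_diff` and `territory_r`.
#' @export
run_scan_rescan <- function(config) {
  stopifnot(inherits(config, "study_config"))
  if (!"scan_rescan" %in% config$analyses)
    stop("config$analyses does not include scan_rescan")
  if (config$ti_a != config$ti_b) stop("scan_rescan requires ti_a == ti_b")
  cohort <- config$cohort
  tabs <- list(); diffs <- list(); med <- numeric(0)
  truth1 <- NULL
  for (i in seq_len(cohort$n_subjects)) {
    truth <- .with_stage("phantom", generate_phantom(cohort, i))
    if (i == 1) truth1 <- truth
    ra <- .process_subject(truth, config$ti_a, cohort,
                           .derive_seed(cohort$seed, i, 4L), config$sd_type)
    rb <- .process_subject(truth, config$ti_b, cohort,
                           .derive_seed(cohort$seed, i, 5L), config$sd_type)
    # tag the two scans so the paired battery can split them
    ra$table$ti <- 1; rb$table$ti <- 2
    tabs[[i]] <- rbind(ra$table, rb$table)
    d <- subtraction_map(rb$cbf, ra$cbf)
    diffs[[i]] <- d
    gm <- truth$tissue == .tissue_levels[["gm"]]
    med[i] <- stats::median(d[gm])
  }
  regional <- do.call(rbind, tabs)
  stats_cbf <- .paired_battery(regional, "mean_cbf", "scan_rescan_cbf",
                               1, 2, config$alpha)
  zrows <- regional[!is.na(regional$z_voi), ]
  stats_z <- .paired_battery(zrows, "z_voi", "scan_rescan_z", 1, 2,
                             config$alpha)
  sum_pos <- across_subjects_sum(diffs, "positive")
  sum_neg <- across_subjects_sum(diffs, "negative")
  terr <- truth1$territory
  in_terr <- terr != .territory_levels[["none"]] &
    truth1$tissue == .tissue_levels[["gm"]]
  net <- (sum_pos - sum_neg)[in_terr]
  is_pta <- (terr[in_terr] == .territory_levels[["pta"]]) + 0
  territory_r <- if (.pop_sd(net) == 0) 0 else stats::cor(net, is_pta)
  result <- structure(
    list(regional_table = regional, stats = rbind(stats_cbf, stats_z),
         sum_pos = sum_pos, sum_neg = sum_neg,
         gm_median_diff = med, territory_r = territory_r,
         config = config),
    class = "ti_comparison_result")
  .write_study_outputs(result, config)
  result
}

#' Run the sedation/age covariate analysis
#'
#' Computes the VOI-specific TI-dependent CBF variation
#' `CBF(ti_b) - CBF(ti_a)` for every subject, then (a) compares variations
#' between sedated and awake subjects with Mann-Whitney U tests
#' (Benjamini-Hochberg adjusted) and (b) correlates variations with age
#' among awake subjects only (Pearson, with regression slope, R-squared
#' and strength category).
#'
#' @param config A [study_config()] whose analyses include `"sedation"`
#'   and/or `"age"`; the cohort must carry covariates.
#' @return An object of class `covariate_result`: list with `variations`
#'   (subject x VOI data.frame), `stats` (Mann-Whitney report, if
#'   requested), `correlations` (per-VOI Pearson report, if requested).
#' @export
run_covariate_analysis <- function(config) {
  stopifnot(inherits(config, "study_config"))
  if (!any(c("sedation", "age") %in% config$analyses))
    stop("config$analyses must include sedation and/or age")
  cohort <- config$cohort
  cov <- cohort$subject_covariates
  tabs <- list()
  for (i in seq_len(cohort$n_subjects)) {
    truth <- .with_stage("phantom", generate_phantom(cohort, i))
    ra <- .process_subject(truth, config$ti_a, cohort,
                           .derive_seed(cohort$seed, i, 2L), config$sd_type)
    rb <- .process_subject(truth, config$ti_b, cohort,
                           .derive_seed(cohort$seed, i, 3L), config$sd_type)
    tabs[[i]] <- rbind(ra$table, rb$table)
  }
  regional <- do.call(rbind, tabs)
  keys <- unique(regional[, c("voi", "hemisphere")])
  subjects <- unique(regional$subject)

  vars <- list()
  for (i in seq_len(nrow(keys))) {
    voi <- keys$voi[i]; hemi <- keys$hemisphere[i]
    name <- if (is.na(hemi)) voi else paste(voi, hemi, sep = "_")
    v <- vapply(subjects, function(s)
      cbf_variation(regional, s, voi, hemi, config$ti_a, config$ti_b),
      numeric(1))
    vars[[name]] <- data.frame(
      subject = subjects, voi = name, variation = v,
      age = cov$age, sedated = cov$sedated, stringsAsFactors = FALSE)
  }
  variations <- do.call(rbind, vars)
  rownames(variations) <- NULL

  stats_mw <- NULL
  if ("sedation" %in% config$analyses) {
    if (sum(cov$sedated) < 2 || sum(!cov$sedated) < 2)
      stop("need >= 2 subjects per sedation group")
    rows <- lapply(names(vars), function(name) {
      v <- vars[[name]]
      tr <- mann_whitney_u(v$variation[v$sedated], v$variation[!v$sedated],
                           name = name, family = "sedation")
      data.frame(family = "sedation", name = name, statistic = tr$statistic,
                 p_raw = tr$p_raw,
                 median_diff = stats::median(v$variation[v$sedated]) -
                   stats::median(v$variation[!v$sedated]),
                 stringsAsFactors = FALSE)
    })
    stats_mw <- do.call(rbind, rows)
    bh <- benjamini_hochberg(stats_mw$p_raw, config$alpha)
    stats_mw$p_adjusted <- bh$adjusted
    stats_mw$significant <- bh$rejected
    stats_mw$stars <- ifelse(stats_mw$significant,
                             .p_stars(stats_mw$p_raw), "n.s.")
  }

  correlations <- NULL
  if ("age" %in% config$analyses) {
    awake <- !cov$sedated
    if (sum(awake) < 3) stop("need >= 3 awake subjects for the correlation")
    rows <- lapply(names(vars), function(name) {
      v <- vars[[name]]
      cr <- pearson_with_category(v$age[!v$sedated], v$variation[!v$sedated])
      data.frame(name = name, rho = cr$rho, slope_m = cr$slope_m,
                 r_squared = cr$r_squared, category = cr$category,
                 n = cr$n, stringsAsFactors = FALSE)
    })
    correlations <- do.call(rbind, rows)
    rownames(correlations) <- NULL
  }

  result <- structure(
    list(variations = variations, stats = stats_mw,
         correlations = correlations, regional_table = regional,
         config = config),
    class = "covariate_result")
  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
    .write_tsv(variations, file.path(config$output_dir, "variations.tsv"))
    if (!is.null(stats_mw))
      .write_tsv(stats_mw, file.path(config$output_dir, "stats_report.tsv"))
    if (!is.null(correlations))
      .write_tsv(correlations, file.path(config$output_dir,
                                         "corr_results.tsv"))
  }
  result
}

#' @export
print.covariate_result <- function(x, ...) {
  cat(sprintf("Covariate analysis (%s), %d subjects\n",
              paste(intersect(x$config$analyses, c("sedation", "age")),
                    collapse = " + "),
              x$config$cohort$n_subjects))
  if (!is.null(x$correlations)) {
    cat("  age correlations (awake subjects):\n")
    for (i in seq_len(nrow(x$correlations)))
      cat(sprintf("    %-18s rho = %+.2f (%s)\n", x$correlations$name[i],
                  x$correlations$rho[i], x$correlations$category[i]))
  }
  invisible(x)
}
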