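p1500 <- acq_params(ti = 1500)
p2020 <- acq_params(ti = 2020)
k <- quant_constants()

test_that("tissue signal is zero before bolus arrival and without perfusion", {
  expect_identical(tissue_delta_m(60, 1800, p1500, k), 0)
  expect_identical(tissue_delta_m(0, 500, p1500, k), 0)
  expect_identical(tissue_delta_m(0, 0, p2020, k), 0)
  expect_error(tissue_delta_m(-1, 0, p1500, k), "f must be")
  expect_error(tissue_delta_m(60, -5, p1500, k), "att must be")
})

test_that("closed-form tissue signal matches the numeric bolus integral", {
  for (f in c(10, 60, 100)) {
    for (att in c(0, 400, 900, 1300, 1800)) {
      for (p in list(p1500, p2020)) {
        expect_equal(tissue_delta_m(f, att, p, k),
                     oracle_tissue_dm(f, att, p$ti),
                     tolerance = 1e-8)
      }
    }
  }
})

test_that("tissue signal is continuous at the bolus knots", {
  eps <- 1e-6
  for (att in c(800, 1100)) {
    for (knot in c(att, att + 700)) {
      lo <- tissue_delta_m(60, att, acq_params(ti = knot - eps), k)
      hi <- tissue_delta_m(60, att, acq_params(ti = knot + eps), k)
      expect_equal(lo, hi, tolerance = 1e-7)
    }
  }
})

test_that("tissue signal is linear in CBF and non-increasing in ATT", {
  base <- tissue_delta_m(30, 600, p1500, k)
  for (c in c(0, 0.5, 2, 3.3))
    expect_equal(tissue_delta_m(c * 30, 600, p1500, k), c * base)
  atts <- seq(0, 2500, by = 50)
  dm <- tissue_delta_m(rep(60, length(atts)), atts, p1500, k)
  expect_true(all(diff(dm) <= 1e-12))
})

test_that("arterial signal obeys the bolus occupancy window", {
  expect_identical(arterial_delta_m(0, 200, p1500, k), 0)
  # bolus cleared: 2020 >= 200 + 700
  expect_identical(arterial_delta_m(0.01, 200, p2020, k), 0)
  expect_identical(arterial_delta_m(0.01, 200, p1500, k), 0)
  # inside the window [900, 1600)
  expect_equal(arterial_delta_m(0.01, 900, p1500, k),
               2 * 0.98 * 1000 * 0.01 * exp(-1500 / 1650))
  expect_error(arterial_delta_m(0.2, 200, p1500, k), "abv")
})

test_that("the transit-time crossover drives opposite TI preferences", {
  # distal voxel, att between the TIs: signal only at the longer TI
  expect_identical(tissue_delta_m(60, 1800, p1500, k), 0)
  expect_gt(tissue_delta_m(60, 1800, p2020, k), 0)
  # proximal voxel with arterial contamination: more total signal at short TI
  total <- function(p) tissue_delta_m(60, 0, p, k) +
    arterial_delta_m(0.01, 0, p, k)
  expect_gt(total(p1500), total(p2020))
})

test_that("control signal follows saturation recovery", {
  expect_equal(control_signal(1000, 13000, 1300), 1000,
               tolerance = 5e-5)
  expect_equal(control_signal(1000, 1300, 1300), 1000 * (1 - exp(-1)))
  expect_equal(control_signal(1000, 4000, 1300),
               1000 * (1 - exp(-4000 / 1300)))
  expect_error(control_signal(1000, 1000, -5), "t1_tissue")
})

test_that("simulated acquisitions are deterministic and unbiased", {
  cfg <- tiny_config(noise_sd = 0)
  ph <- generate_phantom(cfg, 1)
  params <- acq_params(ti = 1500, noise_sd = 0)
  a1 <- simulate_acquisition(ph, params, seed = 11)
  a2 <- simulate_acquisition(ph, params, seed = 11)
  expect_identical(a1$series, a2$series)
  expect_identical(a1$calib, a2$calib)
  dm <- tissue_delta_m(ph$cbf, ph$att, params, a1$consts) +
    arterial_delta_m(ph$abv, ph$att, params, a1$consts)
  expect_equal(perfusion_weighted_map(a1), dm, tolerance = 1e-12)
})

test_that("pair-difference noise has sd noise_sd * sqrt(2)", {
  cfg <- tiny_config()
  ph <- generate_phantom(cfg, 1)
  s <- 3
  acq <- simulate_acquisition(ph, acq_params(ti = 1500, noise_sd = s),
                              seed = 5)
  nvol <- dim(acq$series)[4]
  d <- acq$series[, , , seq(1, nvol, 2), drop = FALSE] -
    acq$series[, , , seq(2, nvol, 2), drop = FALSE]
  per_voxel_sd <- apply(d, 1:3, sd)
  # average over all voxels: tight despite only 8 pairs per voxel;
  # 0.96503 = c4(8), the small-sample bias of the sd estimator
  expect_equal(mean(per_voxel_sd), s * sqrt(2) * 0.96503, tolerance = 0.02)
})

test_that("acquisitions round-trip through NIfTI serialization", {
  cfg <- tiny_config()
  ph <- generate_phantom(cfg, 2)
  acq <- simulate_acquisition(ph, acq_params(ti = 2020), seed = 3)
  dir <- withr::local_tempdir()
  paths <- write_acquisition(acq, dir)
  back <- RNifti::readNifti(paths[["series"]])
  expect_equal(unclass(back)[seq_along(acq$series)],
               as.vector(acq$series), tolerance = 1e-6,
               ignore_attr = TRUE)
  side <- jsonlite::read_json(paths[["sidecar"]])
  expect_equal(side$ti, 2020)
  expect_equal(side$n_pairs, 8)
})
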