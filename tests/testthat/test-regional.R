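test_that("VOI/tissue intersection behaves as set intersection", {
  a <- array(c(TRUE, TRUE, FALSE, FALSE), c(2, 2, 1))
  b <- array(c(FALSE, FALSE, TRUE, TRUE), c(2, 2, 1))
  expect_warning(out <- intersect_voi(a, b), class = "asltilab_empty_voi")
  expect_false(any(out))
  sub <- array(c(TRUE, FALSE, FALSE, FALSE), c(2, 2, 1))
  sup <- array(c(TRUE, TRUE, TRUE, FALSE), c(2, 2, 1))
  expect_identical(intersect_voi(sub, sup), sub)
  set.seed(1)
  for (i in 1:10) {
    m1 <- array(runif(27) > 0.4, c(3, 3, 3))
    m2 <- array(runif(27) > 0.4, c(3, 3, 3))
    if (!any(m1 & m2)) next
    expect_equal(sum(intersect_voi(m1, m2)), sum(m1 & m2))
  }
  expect_error(intersect_voi(a, array(TRUE, c(3, 2, 1))), "grid")
})

test_that("regional means match a brute-force loop", {
  vol <- array(7, c(3, 3, 2))
  expect_equal(regional_mean(vol, array(TRUE, dim(vol))), 7)
  two <- array(0, c(2, 2, 1)); two[1, 1, 1] <- 30; two[2, 1, 1] <- 50
  mask <- array(FALSE, c(2, 2, 1)); mask[1:2, 1, 1] <- TRUE
  expect_equal(regional_mean(two, mask), 40)
  set.seed(2)
  vol <- array(rnorm(60), c(5, 4, 3))
  mask <- array(runif(60) > 0.5, c(5, 4, 3))
  acc <- 0; n <- 0
  for (i in 1:5) for (j in 1:4) for (l in 1:3)
    if (mask[i, j, l]) { acc <- acc + vol[i, j, l]; n <- n + 1 }
  expect_equal(regional_mean(vol, mask), acc / n)
  expect_error(regional_mean(vol, array(FALSE, dim(vol))), "empty")
})

test_that("regional Z-scores standardize against the cortex", {
  cortex <- c(30, 40, 50)
  expect_equal(z_voi(40, cortex), 0)
  expect_equal(z_voi(45, c(35, 45, 35, 45)), 1)
  expect_equal(z_voi(35, cortex), (35 - 40) / pop_sd_oracle(cortex))
  expect_equal(z_voi(35, cortex, sd_type = "sample"), (35 - 40) / sd(cortex))
  expect_error(z_voi(10, c(5, 5, 5)), "zero")
  expect_error(z_voi(10, 5), "cortex voxels")
})

test_that("Z maps are exactly standardized over the mask", {
  set.seed(3)
  vol <- array(rnorm(4 * 4 * 3, 50, 8), c(4, 4, 3))
  gm <- array(runif(48) > 0.3, c(4, 4, 3))
  zm <- z_map(vol, gm)
  v <- zm$volume[gm]
  expect_lt(abs(mean(v)), 1e-12)
  expect_lt(abs(pop_sd_oracle(v) - 1), 1e-12)
  expect_true(all(is.nan(zm$volume[!gm])))
  # 5-voxel toy against hand computation
  toy <- array(0, c(5, 1, 1)); toy[, 1, 1] <- c(10, 20, 30, 40, 50)
  zm5 <- z_map(toy, array(TRUE, c(5, 1, 1)))
  expect_equal(zm5$volume[, 1, 1],
               (c(10, 20, 30, 40, 50) - 30) / pop_sd_oracle(c(10, 20, 30, 40, 50)))
  expect_error(z_map(array(5, c(2, 2, 1)), array(TRUE, c(2, 2, 1))), "zero")
})

test_that("subtraction maps are elementwise and anti-symmetric", {
  a <- array(1:8, c(2, 2, 2)); b <- array(8:1, c(2, 2, 2))
  expect_true(all(subtraction_map(a, a) == 0))
  expect_equal(subtraction_map(a, b), -subtraction_map(b, a))
  expect_equal(subtraction_map(a, b)[2, 1, 1], 2 - 7)
  expect_error(subtraction_map(a, array(0, c(2, 2, 3))), "grid")
})

test_that("across-subject sum maps count strict signs", {
  ones <- array(2.5, c(2, 2, 1))
  expect_true(all(across_subjects_sum(list(ones), "positive") == 1))
  expect_true(all(across_subjects_sum(list(ones), "negative") == 0))
  m1 <- array(c(1, -1, 0, 2), c(2, 2, 1))
  m2 <- array(c(1, 1, -3, 0), c(2, 2, 1))
  m3 <- array(c(-2, 1, 5, 1), c(2, 2, 1))
  maps <- list(m1, m2, m3)
  pos <- across_subjects_sum(maps, "positive")
  neg <- across_subjects_sum(maps, "negative")
  expect_equal(as.vector(pos), c(2, 2, 1, 2))
  expect_equal(as.vector(neg), c(1, 1, 1, 0))
  # exact zeros belong to neither map
  expect_true(all(pos + neg <= 3))
  expect_error(across_subjects_sum(list()), "empty")
})

test_that("regional tables are internally consistent", {
  cfg <- tiny_config()
  ph <- generate_phantom(cfg, 1)
  acq <- simulate_acquisition(ph, acq_params(ti = 1500), seed = 4)
  gm <- ph$tissue == 1
  pwi <- perfusion_weighted_map(acq)
  m0b <- estimate_m0_blood(acq$calib, acq$params$calib_tis, gm)
  cbf <- quantify_cbf(pwi, m0b, acq$params, acq$consts,
                      subject_id = ph$subject_id)
  tab <- regional_table(cbf, ph)
  expect_true(all(tab$n_voxels > 0))
  cortical <- tab[!is.na(tab$hemisphere), ]
  expect_equal(nrow(cortical), 14)
  expect_true(all(!is.na(cortical$z_voi)))
  expect_true(all(is.na(tab$z_voi[is.na(tab$hemisphere)])))
  # weighted-mean consistency: cortical VOIs recompose the cortex row
  ctx <- tab[tab$voi == "cerebral_cortex", ]
  expect_equal(sum(cortical$n_voxels * cortical$mean_cbf),
               ctx$n_voxels * ctx$mean_cbf)
  expect_equal(sum(cortical$n_voxels), ctx$n_voxels)
})
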