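test_that("phantom generation is bit-reproducible from its seed", {
  sp <- tissue_spec("biexp", list(d_slow = 0.9e-3, d_fast = 70e-3, f_p = 0.25))
  a <- make_phantom(sp, c(10, 10, 5), snr = 40, seed = 99)
  b <- make_phantom(sp, c(10, 10, 5), snr = 40, seed = 99)
  expect_identical(a$image, b$image)
  expect_identical(a$truth, b$truth)
  c <- make_phantom(sp, c(10, 10, 5), snr = 40, seed = 100)
  expect_false(identical(a$image, c$image))
})

test_that("noiseless phantom round-trips through voxelwise fitting", {
  sp <- tissue_spec("mono", list(adc = 1.08e-3), intra_tumor_cv = 0.15)
  ph <- make_phantom(sp, c(10, 10, 5), snr = Inf, seed = 5)
  maps <- fit_volume(ph, "mono")
  fitted <- maps$maps$mono$adc[ph$mask]
  truth <- ph$truth$adc[ph$mask]
  expect_true(all(maps$converged$mono[ph$mask]))
  expect_lt(max(abs(fitted - truth) / truth), 1e-3)
  # unmasked voxels stay missing
  expect_true(all(is.na(maps$maps$mono$adc[!ph$mask])))
})

test_that("Rician noise converges to unbiased Gaussian at high SNR", {
  set.seed(7)
  s <- rep(100, 20000)
  noisy <- rician_noise(s, sigma = 100 / 200)  # SNR 200
  expect_lt(abs(mean(noisy) - 100) / 100, 0.01)
  # near zero signal the magnitude floor appears
  floor_sample <- rician_noise(rep(0, 20000), sigma = 10)
  expect_gt(mean(floor_sample), 10)  # E = sigma * sqrt(pi/2)
})

test_that("generated voxel parameters always respect validity bounds", {
  sp <- tissue_spec("stretched", list(ddc = 1.2e-3, alpha = 0.95),
                    intra_tumor_cv = 0.3)
  ph <- make_phantom(sp, c(10, 10, 5), snr = 50, seed = 3)
  expect_true(all(ph$truth$alpha[ph$mask] <= 1))
  expect_true(all(ph$truth$alpha[ph$mask] > 0))
  expect_true(all(ph$truth$ddc[ph$mask] > 0))

  spb <- tissue_spec("biexp", list(d_slow = 1e-3, d_fast = 12e-3, f_p = 0.5),
                     intra_tumor_cv = 0.5)
  phb <- make_phantom(spb, c(10, 10, 5), snr = 50, seed = 3)
  expect_true(all(phb$truth$d_fast[phb$mask] > phb$truth$d_slow[phb$mask]))
  expect_true(all(phb$truth$f_p[phb$mask] >= 0 & phb$truth$f_p[phb$mask] <= 1))
})

test_that("phantom rejects invalid requests", {
  sp <- tissue_spec("mono", list(adc = 1e-3))
  expect_error(make_phantom(sp, c(10, 10, 5), snr = 0), "snr")
  expect_error(make_phantom(sp, c(10, 10, 5), snr = -5), "snr")
  expect_error(tissue_spec("mono", list(adc = 1e-3), intra_tumor_cv = -1),
               "intra_tumor_cv")
  expect_error(tissue_spec("biexp", list(d_slow = 1e-3)), "missing")
})

test_that("phantom mask spans at least three axial slices", {
  ph <- make_phantom(tissue_spec("mono", list(adc = 1e-3)), c(10, 10, 5),
                     snr = Inf, seed = 1)
  expect_gte(sum(apply(ph$mask, 3, any)), 3)
})

test_that("cohort draws reproduce the reference group distributions", {
  big_cr <- group_spec("CR", n_patients = 10000)
  big_non <- group_spec("non-CR", n_patients = 10000)
  coh <- simulate_cohort(big_cr, big_non, seed = 8)
  non <- coh[coh$group == "non-CR", ]
  cr <- coh[coh$group == "CR", ]
  # law of large numbers against the stated means
  expect_lt(abs(mean(non$d_slow_t0) - 0.76) / 0.76, 0.01)
  expect_lt(abs(mean(cr$adc_t1) - 1.26) / 1.26, 0.01)
  # the serial correlation is tuned so change scores match their stated SD
  expect_lt(abs(sd(cr$alpha_delta) - 0.02) / 0.02, 0.10)
  expect_lt(abs(sd(non$adc_delta) - 0.17) / 0.17, 0.10)
  # validity bounds hold for every draw
  expect_true(all(coh$f_p_t0 >= 0 & coh$f_p_t0 <= 1))
  expect_true(all(coh$alpha_t0 > 0 & coh$alpha_t0 <= 1))
  expect_true(all(coh$adc_t0 > 0))
})

test_that("zero-SD group specs produce the group means exactly", {
  p <- reference_group_params("CR")
  p[c("t0_sd", "t1_sd", "delta_sd")] <- 0
  coh <- simulate_cohort(group_spec("CR", 5, p), group_spec("non-CR", 2),
                         seed = 1)
  cr <- coh[coh$group == "CR", ]
  expect_true(all(cr$adc_t1 == 1.26))
  expect_true(all(cr$d_slow_t0 == 0.93))
})

test_that("cohort simulation is reproducible and delta = T1 - T0", {
  a <- simulate_cohort(seed = 12)
  b <- simulate_cohort(seed = 12)
  expect_identical(a, b)
  expect_equal(a$ddc_delta, a$ddc_t1 - a$ddc_t0)
})

test_that("two-rater simulation supports the ICC design", {
  coh <- simulate_cohort(seed = 4)
  r0 <- simulate_two_raters(coh, rater_noise_sd = 0, seed = 1)
  expect_identical(r0$rater1, r0$rater2)

  # designed reliability: ICC = var_between/(var_between + var_noise) = 0.90
  set.seed(31)
  records <- data.frame(patient_id = sprintf("S%03d", 1:200),
                        x = rnorm(200, 0, 1))
  rr <- simulate_two_raters(records, parameters = "x",
                            rater_noise_sd = 1 / 3, seed = 32)
  est <- icc_two_rater(rr[, c("rater1", "rater2")])
  expect_lt(abs(est$icc - 0.90), 0.05)

  r1 <- simulate_two_raters(coh, rater_noise_sd = 0.05, seed = 9)
  r2 <- simulate_two_raters(coh, rater_noise_sd = 0.05, seed = 9)
  expect_identical(r1, r2)
})
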