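test_that("noiseless phantom signal follows the monoexponential model exactly", {
  cfg <- phantom_config(snr = Inf)
  ph <- generate_phantom(cfg)
  # tumor voxel at the ellipsoid centre, highest b-value: S = S0 * exp(-0.6)
  ctr <- round(cfg$center)
  s_b800 <- ph$study$volumes[ctr[1], ctr[2], ctr[3], 9]
  expect_equal(s_b800, 1000 * exp(-0.8 * 0.75), tolerance = 1e-12)
  # every b-value, every voxel
  for (bi in c(1, 5, 9)) {
    expected <- ph$truth$s0 * exp(-cfg$bvalues[bi] / 1000 * ph$truth$values)
    expect_equal(ph$study$volumes[, , , bi], expected, tolerance = 1e-12)
  }
  # ground truth is exactly two-valued inside/outside the ellipsoid
  expect_setequal(unique(as.numeric(ph$truth$values)), c(0.75, 1.40))
  expect_true(all(ph$truth$values[ph$mask$mask] == 0.75))
  expect_true(all(ph$truth$values[!ph$mask$mask] == 1.40))
})

test_that("phantom validates its geometry and supports a necrotic core", {
  expect_error(phantom_config(center = c(2, 2, 2), semi_axes = c(20, 9, 2)),
               class = "dwi_validation_error")
  expect_error(phantom_config(snr = 0), class = "dwi_validation_error")
  cfg <- phantom_config(core = list(center = c(32.5, 24.5, 3.5),
                                    semi_axes = c(4, 3, 1), adc = 2.2))
  ph <- generate_phantom(cfg)
  expect_setequal(unique(as.numeric(ph$truth$values)), c(0.75, 1.40, 2.2))
  # core lies inside the tumor mask
  expect_true(all(ph$truth$values[!ph$mask$mask] == 1.40))
})

test_that("Rician noise has the correct mean at zero and high signal", {
  x <- apply_rician_noise(array(0, c(100, 100, 100)), sigma = 1, seed = 2)
  expect_equal(mean(x), sqrt(pi / 2), tolerance = 0.005)
  y <- apply_rician_noise(array(100, c(100, 100, 100)), sigma = 1, seed = 3)
  expect_equal(mean(y), sqrt(100^2 + 1), tolerance = 0.001)
  z <- array(runif(100), c(10, 5, 2))
  expect_identical(apply_rician_noise(z, 0, seed = 1), z)
  expect_error(apply_rician_noise(z, -1, seed = 1),
               class = "dwi_validation_error")
})

test_that("phantom tumor signal at finite SNR matches the Rician mean from quadrature", {
  cfg <- phantom_config(dims = c(64, 56, 10), center = c(32.5, 28.5, 5.5),
                        semi_axes = c(26, 21, 4.5), snr = 50, seed = 9)
  ph <- generate_phantom(cfg)
  tumor_b10 <- ph$study$volumes[, , , 1][ph$mask$mask]
  expect_gt(length(tumor_b10), 1e4)
  # independent oracle: E[R] by numerical integration of the Rician density
  v <- 1000 * exp(-0.010 * 0.75)
  sigma <- 1000 / 50
  # scaled Bessel keeps the Rician density finite at high SNR
  integrand <- function(r) {
    r / sigma^2 * exp(-(r - v)^2 / (2 * sigma^2) +
                        log(besselI(r * v / sigma^2, 0, expon.scaled = TRUE)))
  }
  mean_oracle <- stats::integrate(function(r) r * integrand(r),
                                  lower = max(0, v - 10 * sigma),
                                  upper = v + 10 * sigma,
                                  rel.tol = 1e-10)$value
  expect_equal(mean(tumor_b10), mean_oracle, tolerance = 0.01)
})

test_that("phantom and cohort generation are deterministic under a fixed seed", {
  a <- generate_phantom(small_phantom_config(snr = 40, seed = 5))
  b <- generate_phantom(small_phantom_config(snr = 40, seed = 5))
  c <- generate_phantom(small_phantom_config(snr = 40, seed = 6))
  expect_identical(a$study$volumes, b$study$volumes)
  expect_false(identical(a$study$volumes, c$study$volumes))

  c1 <- generate_cohort(cohort_config(seed = 11))
  c2 <- generate_cohort(cohort_config(seed = 11))
  c3 <- generate_cohort(cohort_config(seed = 12))
  expect_identical(c1$d_adc, c2$d_adc)
  expect_false(identical(c1$d_adc, c3$d_adc))
})

test_that("degenerate cohort scales give exact configured locations", {
  cfg <- cohort_config(
    therapy = list(adc_b = c(0.76, 0), d_adc = c(0.10, 0),
                   vol_b = c(347.8, 0), d_vol_pct = c(33.30, 0), r = 0),
    control = list(adc_b = c(0.73, 0), d_adc = c(0.03, 0),
                   vol_b = c(219.7, 0), d_vol_pct = c(96.43, 0), r = 0),
    seed = 1)
  coh <- generate_cohort(cfg)
  th <- coh[coh$group == "therapy", ]
  # deltas are re-derived from the session values, so equality holds to
  # floating-point round-off
  expect_equal(th$d_adc, rep(0.10, 12), tolerance = 1e-12)
  expect_equal(median(th$d_vol_pct), 33.30, tolerance = 1e-12)
  expect_equal(unique(th$vol_b), 347.8, tolerance = 1e-12)
  expect_equal(unique(th$adc_f), 0.86, tolerance = 1e-12)
})

test_that("cohort generator recovers configured moments and correlations at large n", {
  cfg <- cohort_config(n_therapy = 5000, n_control = 5000, seed = 21)
  coh <- generate_cohort(cfg)
  th <- coh[coh$group == "therapy", ]
  co <- coh[coh$group == "control", ]
  # locations within 4 Monte-Carlo standard errors of the sample median
  se_med <- function(s, n) 1.2533 * s / sqrt(n)
  expect_equal(median(th$d_adc), 0.10, tolerance = 4 * se_med(0.11, 5000) / 0.10)
  expect_equal(median(co$d_adc), 0.03, tolerance = 4 * se_med(0.09, 5000) / 0.03)
  expect_equal(median(co$d_vol_pct), 96.43,
               tolerance = 4 * se_med(31.66, 5000) / 96.43)
  expect_equal(sd(th$d_adc), 0.11, tolerance = 0.04)
  # volume margins: log-normal with configured median and SD
  expect_equal(median(co$vol_b), 219.7, tolerance = 4 * se_med(79.5, 5000) / 219.7)
  expect_equal(sd(co$vol_b), 79.5, tolerance = 0.05)
  expect_true(all(coh$vol_f > 0))
  # copula calibration: Pearson r of the Gaussian-margin pair
  expect_equal(cor(co$d_adc, co$d_vol_pct), 0.65, tolerance = 0.03)
  expect_equal(cor(th$d_adc, th$d_vol_pct), 0.05, tolerance = 0.05)
})

test_that("cohort generator is unbiased: mean of per-seed medians hits the target", {
  meds <- vapply(1:30, function(s) {
    coh <- generate_cohort(cohort_config(n_therapy = 500, n_control = 2,
                                         seed = 100 + s))
    median(coh$d_vol_pct[coh$group == "therapy"])
  }, numeric(1))
  # SE of the mean of 30 medians at n = 500: 1.2533 * 47.3 / sqrt(500*30) ~ 0.48
  expect_equal(mean(meds), 33.30, tolerance = 3 * 0.49 / 33.30)
})

test_that("cohort configuration is validated", {
  expect_error(cohort_config(n_therapy = 1), class = "dwi_validation_error")
  bad <- list(adc_b = c(0.76, 0.09), d_adc = c(0.10, 0.11),
              vol_b = c(347.8, 449.1), d_vol_pct = c(33.3, 47.3), r = 1.2)
  expect_error(cohort_config(therapy = bad), class = "dwi_validation_error")
  bad2 <- list(adc_b = c(0.76, -0.09), d_adc = c(0.10, 0.11),
               vol_b = c(347.8, 449.1), d_vol_pct = c(33.3, 47.3), r = 0)
  expect_error(cohort_config(therapy = bad2), class = "dwi_validation_error")
})
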