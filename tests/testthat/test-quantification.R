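test_that("flip-angle calibration recovers (A, R1_pre) from noiseless series", {
  p <- default_params
  s <- ute_signal(1000, p$flip_angles, p$tr, 800)  # R1_pre = 1.25 s^-1
  fit <- fit_pre_calibration(s, p)
  expect_lt(abs(fit$A - 1000) / 1000, 1e-6)
  expect_lt(abs(fit$R1_pre - 1.25) / 1.25, 1e-6)
  expect_lt(fit$fit_residual, 1e-8)
})

test_that("two-point calibration matches the algebraic closed form", {
  p2 <- acquisition_params(flip_angles = c(5, 25), post_flip_angle = 25)
  A <- 740; t1 <- 620
  s <- ute_signal(A, p2$flip_angles, p2$tr, t1)
  # closed form: in (x, y) = (S/tan a, S/sin a) the two points fix the line
  a <- p2$flip_angles * pi / 180
  y <- s / sin(a); x <- s / tan(a)
  e1 <- (y[2] - y[1]) / (x[2] - x[1])
  A_cf <- (y[1] - e1 * x[1]) / (1 - e1)
  r1_cf <- -log(e1) / p2$tr * 1000
  fit <- fit_pre_calibration(s, p2)
  expect_equal(fit$A, A_cf, tolerance = 1e-8)
  expect_equal(fit$R1_pre, r1_cf, tolerance = 1e-8)
  expect_equal(fit$A, A, tolerance = 1e-8)
})

test_that("calibration is scale-equivariant and rejects degenerate input", {
  p <- default_params
  s <- ute_signal(1000, p$flip_angles, p$tr, 800)
  f1 <- fit_pre_calibration(s, p)
  f2 <- fit_pre_calibration(3.5 * s, p)
  expect_equal(f2$A, 3.5 * f1$A, tolerance = 1e-8)
  expect_equal(f2$R1_pre, f1$R1_pre, tolerance = 1e-8)

  pd <- acquisition_params(flip_angles = c(10, 10), post_flip_angle = 10)
  expect_error(fit_pre_calibration(c(5, 5), pd), "degenerate")
  expect_error(fit_pre_calibration(c(5, -1, 3, 2), p), "positive")
  expect_error(fit_pre_calibration(c(5, 3), p), "one mean signal per")
})

test_that("pixel-wise R1 map inverts uniform volumes exactly", {
  p <- default_params
  calib <- fit_pre_calibration(
    ute_signal(1000, p$flip_angles, p$tr, 800), p)
  s170 <- ute_signal(1000, 25, p$tr, 170)
  vol <- volume3d(array(s170, c(8, 8, 4)), c(1, 1, 1))
  m <- array(TRUE, c(8, 8, 4))
  r1 <- r1_post_map(vol, calib, p, m)
  expect_lt(max(abs(r1$volume$data - 1000 / 170)), 1e-6)
  expect_equal(r1$invalid_voxel_count, 0L)

  # voxels at or above the model ceiling are flagged, not fatal
  vol2 <- vol; vol2$data[1, 1, 1] <- 1000 * sin(25 * pi / 180) * 1.01
  r1b <- r1_post_map(vol2, calib, p, m)
  expect_equal(r1b$invalid_voxel_count, 1L)
  expect_true(is.na(r1b$volume$data[1, 1, 1]))
  expect_error(r1_post_map(vol, calib, p, m & FALSE), "empty")
})

test_that("concentration map applies the relaxivity relation", {
  p <- default_params
  # R1_pre = 0.5 s^-1 (T1 2000 ms); R1_post = 5.882 -> C = 1.794 mM
  calib <- fit_pre_calibration(
    ute_signal(1000, p$flip_angles, p$tr, 2000), p)
  s170 <- ute_signal(1000, 25, p$tr, 170)
  vol <- volume3d(array(s170, c(6, 6, 3)), c(1, 1, 1))
  r1 <- r1_post_map(vol, calib, p, array(TRUE, c(6, 6, 3)))
  conc <- concentration_map(r1, calib, p)
  expect_equal(mean(conc$concentration$data), (1000 / 170 - 0.5) / 3,
               tolerance = 1e-6)
  expect_equal(mean(conc$concentration$data), 1.794, tolerance = 1e-3)

  # R1_post == R1_pre -> zero concentration everywhere
  s2000 <- ute_signal(1000, 25, p$tr, 2000)
  r1z <- r1_post_map(volume3d(array(s2000, c(6, 6, 3)), c(1, 1, 1)),
                     calib, p, array(TRUE, c(6, 6, 3)))
  cz <- concentration_map(r1z, calib, p)
  expect_equal(max(abs(cz$concentration$data)), 0, tolerance = 1e-8)
})

test_that("noiseless phantom concentration is recovered voxel-wise", {
  ds <- small_noiseless()
  run <- run_specimen(dataset = ds)
  enh <- region_mask(ds$truth_labels, "enhanced")
  truth <- ds$truth_concentration$data[enh]
  est <- run$concentration$concentration$data[enh]
  pos <- truth > 0
  expect_lt(max(abs(est[pos] - truth[pos]) / truth[pos]), 1e-8)
  # solution-free airway cores: zero up to floating-point dust
  expect_lt(max(abs(est[!pos])), 1e-10)
})

test_that("Gd amounts integrate concentration over regions in micromoles", {
  # uniform 4.6 mM over a 31.8 mL enhanced region -> 146.3 umol
  sp <- c(1, 1, 1)  # 0.001 mL voxels; 31800 voxels = 31.8 mL
  l <- array(0L, c(60, 60, 10))
  idx <- seq_len(31800)
  l[idx] <- 2L
  cmap <- array(0, dim(l)); cmap[idx] <- 4.6
  labs <- region_labels(l)
  conc <- synth_conc(cmap, sp)
  expect_equal(gd_amount(conc, labs, sp, "enhanced"), 31.8 * 4.6,
               tolerance = 1e-10)
  expect_equal(gd_amount(conc, labs, sp, "enhanced"), 146.3,
               tolerance = 1e-3)
  expect_equal(gd_amount(synth_conc(cmap * 0, sp), labs, sp, "TLV"), 0)
  expect_error(gd_amount(conc, labs, sp, "lobe"), "unknown region")
})

test_that("amounts are additive over the disjoint PER/CER split", {
  ds <- small_snr50()
  run <- run_specimen(dataset = ds)
  sp <- ds$spec$spacing
  q_per <- gd_amount(run$concentration, ds$truth_labels, sp, "PER")
  q_cer <- gd_amount(run$concentration, ds$truth_labels, sp, "CER")
  q_enh <- gd_amount(run$concentration, ds$truth_labels, sp, "enhanced")
  expect_equal(q_per + q_cer, q_enh, tolerance = 1e-12)
})

test_that("instilled dose follows the mixture arithmetic", {
  expect_equal(instilled_gd_amount(2.7, 0.27, 500, 2.2), 100)
  expect_equal(instilled_gd_amount(2.7, 0.27, 500, 0), 0)
  # dilution symmetry: doubling both component volumes changes nothing
  expect_equal(instilled_gd_amount(5.4, 0.54, 500, 2.2),
               instilled_gd_amount(2.7, 0.27, 500, 2.2))
  expect_error(instilled_gd_amount(2.7, 0.27, 500, 10), "exceeds")
  expect_error(instilled_gd_amount(-1, 0.27, 500, 1), "positive")
})

test_that("concentration is invariant to global rescaling of pre and post", {
  ds <- small_noiseless()
  k <- 3.7
  pre_k <- lapply(ds$pre_volumes, function(v)
    volume3d(v$data * k, v$spacing, v$axes))
  post_k <- volume3d(ds$post_volume$data * k, ds$post_volume$spacing)
  r1 <- run_specimen(dataset = ds)
  r2 <- run_specimen(dataset = ds, pre_volumes = pre_k, post_volume = post_k)
  expect_equal(r2$calibration$A, k * r1$calibration$A, tolerance = 1e-8)
  enh <- region_mask(ds$truth_labels, "enhanced")
  expect_equal(r2$concentration$concentration$data[enh],
               r1$concentration$concentration$data[enh], tolerance = 1e-8)
})
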