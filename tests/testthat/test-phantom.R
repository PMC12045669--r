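test_that("phantom spec validates its targets", {
  expect_error(phantom_spec(enhanced_fraction_of_tlv = 0), "0, 100")
  expect_error(phantom_spec(peripheral_amount_fraction = 100), "0, 100")
  expect_error(phantom_spec(noise_sd = -1), "non-negative")
})

test_that("phantom generation is deterministic for a fixed seed", {
  sp <- small_phantom_spec(seed = 5)
  d1 <- build_phantom(sp, default_params)
  d2 <- build_phantom(sp, default_params)
  expect_identical(d1$truth_labels$labels, d2$truth_labels$labels)
  expect_identical(d1$post_volume$data, d2$post_volume$data)
  expect_identical(d1$pre_volumes$fa5$data, d2$pre_volumes$fa5$data)
})

test_that("changing only the seed changes noise, not the truth fields", {
  g <- build_geometry(small_phantom_spec(seed = 5))
  conc <- assign_concentration(g)
  sp2 <- small_phantom_spec(seed = 6)
  r1 <- render_mri(g, conc, small_phantom_spec(seed = 5), default_params)
  r2 <- render_mri(g, conc, sp2, default_params)
  expect_identical(r1$truth_labels$labels, r2$truth_labels$labels)
  expect_identical(r1$truth_concentration$data, r2$truth_concentration$data)
  expect_false(identical(r1$post_volume$data, r2$post_volume$data))
})

test_that("the airway tree log counts the configured generations", {
  g <- build_geometry(small_phantom_spec(noise_sd = 0))
  expect_equal(max(g$tree$gen), 4)
  expect_equal(nrow(g$tree), 1 + 2 + 4 + 8)
  g1 <- build_geometry(small_phantom_spec(n_generations = 1, noise_sd = 0))
  expect_equal(nrow(g1$tree), 1)  # a single cylinder
  expect_true(all(region_mask(g1$labels, "CER") <=
                  region_mask(g1$labels, "TLV")))
})

test_that("symmetric seeding balances peripheral voxels between lungs", {
  counts <- vapply(1:10, function(s) {
    g <- build_geometry(small_phantom_spec(right_left_asymmetry = 0.5,
                                           seed = 100 + s))
    per <- g$labels$labels == 2L
    c(right = sum(per & g$side == 1L), left = sum(per & g$side == 2L))
  }, numeric(2))
  r <- sum(counts["right", ]); l <- sum(counts["left", ])
  expect_lt(abs(r - l) / ((r + l) / 2), 0.05)
})

test_that("ground-truth concentration conserves the instilled amount", {
  ds <- small_noiseless()
  sp <- ds$spec$spacing
  total <- sum(ds$truth_concentration$data) * voxel_volume_ml(sp)
  expect_equal(total, ds$spec$total_instilled_gd_umol, tolerance = 1e-3)
  # zero outside the enhanced regions
  outside <- ds$truth_labels$labels < 2L
  expect_true(all(ds$truth_concentration$data[outside] == 0))
  # truth PDF hits the configured target
  expect_equal(ds$truth_report$pdf_percent,
               ds$spec$peripheral_amount_fraction, tolerance = 0.5)
  expect_equal(ds$truth_report$pvf_percent,
               ds$spec$enhanced_fraction_of_tlv, tolerance = 0.1)
})

test_that("total amount is conserved under grid refinement", {
  base <- small_phantom_spec(noise_sd = 0, seed = 31)
  fine <- phantom_spec(shape = c(120, 120, 95), spacing = c(0.96, 0.96, 1.2),
                       noise_sd = 0, seed = 31)
  for (s in list(base, fine)) {
    g <- build_geometry(s)
    co <- assign_concentration(g)
    tot <- sum(co$data) * voxel_volume_ml(s$spacing)
    expect_equal(tot, s$total_instilled_gd_umol, tolerance = 5e-3)
  }
})

test_that("concentration field is linear in the instilled amount and
           uniform without a gradient", {
  g <- build_geometry(small_phantom_spec(seed = 41))
  c1 <- assign_concentration(g, small_phantom_spec(seed = 41))
  c2 <- assign_concentration(
    g, small_phantom_spec(seed = 41, total_instilled_gd_umol = 200))
  expect_equal(c2$data, 2 * c1$data, tolerance = 1e-12)

  g0 <- build_geometry(small_phantom_spec(seed = 41,
                                          dependent_gradient_strength = 0))
  c0 <- assign_concentration(g0)
  per_vals <- c0$data[g0$labels$labels == 2L]
  expect_lt(diff(range(per_vals)), 1e-12)
})

test_that("rendering follows the relaxivity-shortened T1 forward model", {
  ds <- small_noiseless()
  expected_t1 <- 1000 / (1000 / ds$spec$t1_pre_ms +
                         default_params$r1 * ds$truth_concentration$data)
  tissue <- ds$truth_labels$labels >= 1L
  expect_equal(ds$truth_t1_post$data[tissue], expected_t1[tissue],
               tolerance = 1e-12)
  # a voxel carrying C = 1.794 mM on T1_pre = 2000 ms tissue relaxes at
  # R1 = 0.5 + 3 * 1.794 = 5.882 s^-1, i.e. T1 = 170 ms
  expect_equal(1000 / (1000 / 2000 + 3 * 1.794), 170, tolerance = 0.01)
})

test_that("a contrast-free noiseless phantom renders post equal to pre", {
  spz <- small_phantom_spec(noise_sd = 0, total_instilled_gd_umol = 0,
                            seed = 51)
  g <- build_geometry(spz)
  co <- assign_concentration(g)
  expect_true(all(co$data == 0))
  ds <- render_mri(g, co, spz, default_params)
  expect_equal(ds$post_volume$data, ds$pre_volumes$fa25$data,
               tolerance = 1e-14)
})
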