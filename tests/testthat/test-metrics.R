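make_two_region <- function(q_per = 84, q_cer = 16) {
  # 1 mm voxels: amounts in umol equal summed concentration / 1000
  l <- array(0L, c(10, 10, 4))
  l[1:5, , 1] <- 2L
  l[6:10, , 1] <- 3L
  cmap <- array(0, dim(l))
  cmap[l == 2L] <- q_per * 1000 / sum(l == 2L)
  cmap[l == 3L] <- q_cer * 1000 / sum(l == 3L)
  list(labels = region_labels(l), conc = synth_conc(cmap, c(1, 1, 1)),
       spacing = c(1, 1, 1))
}

test_that("PDF is the peripheral share of the enhanced Gd amount", {
  x <- make_two_region(84, 16)
  expect_equal(pdf_metric(x$conc, x$labels, x$spacing), 84)
  # empty CER -> 100%
  y <- make_two_region(84, 0)
  y$labels$labels[y$labels$labels == 3L] <- 1L
  expect_equal(pdf_metric(y$conc, y$labels, y$spacing), 100)
  # zero total amount is undefined
  z <- make_two_region(0, 0)
  expect_error(pdf_metric(z$conc, z$labels, z$spacing), "undefined")
})

test_that("PDF is invariant to uniform concentration scaling", {
  ds <- small_snr50()
  run <- run_specimen(dataset = ds)
  p1 <- run$report$pdf_percent
  scaled <- run$concentration
  scaled$concentration$data <- scaled$concentration$data * 17
  expect_equal(pdf_metric(scaled, ds$truth_labels, ds$spec$spacing), p1,
               tolerance = 1e-12)
})

test_that("PVF is a pure volume ratio", {
  l <- array(0L, c(10, 10, 1))
  l[1:100] <- 1L
  l[1:33] <- 2L
  expect_equal(pvf_metric(region_labels(l)), 33)
  # PER = TLV minus an empty CER -> 100%
  l2 <- array(2L, c(5, 5, 2))
  expect_equal(pvf_metric(region_labels(l2)), 100)
  expect_error(pvf_metric(region_labels(array(0L, c(2, 2, 2)))), "empty")
  # cohort-mean volumes: PER 34.3 mL over TLV 91 mL -> 37.7%
  l3 <- array(0L, c(20, 20, 3))
  l3[seq_len(910)] <- 1L
  l3[seq_len(343)] <- 2L
  expect_equal(pvf_metric(region_labels(l3)), 100 * 34.3 / 91,
               tolerance = 1e-9)
  expect_equal(pvf_metric(region_labels(l3)), 37.7, tolerance = 1e-3)
})

test_that("quantity profiles conserve the regional Gd amounts", {
  # slab spanning two slices: two equal bins summing to the total
  l <- array(0L, c(6, 6, 6))
  l[, 3:4, ] <- 2L
  cmap <- array(0, dim(l)); cmap[l == 2L] <- 2.5
  conc <- synth_conc(cmap, c(1, 1, 1))
  labs <- region_labels(l)
  prof <- slice_profile(conc, labs, c(1, 1, 1), axis = "ventral-dorsal",
                        mode = "quantity")
  nz <- prof$PER[prof$PER > 0]
  expect_length(nz, 2)
  expect_equal(nz[1], nz[2])
  expect_equal(sum(prof$PER), gd_amount(conc, labs, c(1, 1, 1), "PER"))

  # phantom: profile sums equal region amounts along every axis
  ds <- small_snr50()
  run <- run_specimen(dataset = ds)
  sp <- ds$spec$spacing
  totals <- vapply(c("ventral-dorsal", "right-left", "cranial-caudal"),
    function(ax) {
      pr <- slice_profile(run$concentration, ds$truth_labels, sp, ax,
                          "quantity")
      sum(pr$PER) + sum(pr$CER)
    }, numeric(1))
  q <- gd_amount(run$concentration, ds$truth_labels, sp, "enhanced")
  expect_true(all(abs(totals - q) / q < 1e-10))
  expect_error(slice_profile(run$concentration, ds$truth_labels, sp,
                             "diagonal"), "unknown anatomical axis")
})

test_that("dependent (dorsal) lung regions carry more Gd than ventral ones", {
  ds <- small_noiseless()
  conc <- synth_conc(ds$truth_concentration$data, ds$spec$spacing)
  prof <- slice_profile(conc, ds$truth_labels, ds$spec$spacing,
                        "ventral-dorsal", "quantity")
  half <- floor(nrow(prof) / 2)
  ventral <- sum(prof$PER[seq_len(half)])
  dorsal <- sum(prof$PER[(half + 1):nrow(prof)])
  expect_gt(dorsal, ventral)
})

test_that("area profiles integrate to region volumes", {
  ds <- small_noiseless()
  sp <- ds$spec$spacing
  prof <- slice_profile(NULL, ds$truth_labels, sp, "ventral-dorsal", "area")
  vols <- region_volumes(ds$truth_labels, sp)
  for (r in c("CER", "PER", "TLV")) {
    # mm^2 per slice x slice thickness (mm) / 1000 = mL
    expect_equal(sum(prof[[r]]) * sp[2] / 1000, unname(vols[r]),
                 tolerance = 1e-10)
  }
})

test_that("maximum intensity projections behave as per-ray maxima", {
  v <- volume3d(array(3, c(4, 5, 6)), c(1, 1, 1))
  m <- mip_render(v, "ventral-dorsal")
  expect_true(all(m == 3))
  expect_identical(dim(m), c(4L, 6L))

  arr <- array(0, c(4, 5, 6)); arr[2, 3, 5] <- 9
  vh <- volume3d(arr, c(0.5, 1, 2))
  mh <- mip_render(vh, "ventral-dorsal")
  expect_equal(which(mh == 9, arr.ind = TRUE)[1, ], c(row = 2, col = 5))
  expect_equal(attr(mh, "spacing"), c(0.5, 2))
  for (ax in c("right-left", "ventral-dorsal", "cranial-caudal"))
    expect_equal(max(mip_render(vh, ax)), max(arr))
})

test_that("cohort summaries reproduce the reference table statistics", {
  dist_tab <- reference_cohort("distribution_fractions")
  s <- summarize_cohort(dist_tab$pdf_percent)
  expect_equal(s$mean, 84.05, tolerance = 1e-10)
  expect_equal(s$cov, 6.2355, tolerance = 1e-4)

  quant <- reference_cohort("enhanced_quantification")
  expect_equal(summarize_cohort(quant$gd_amount_umol)$mean, 93.5333,
               tolerance = 1e-4)

  lf <- reference_cohort("lung_function")
  expect_lt(abs(summarize_cohort(lf$compliance_ml_per_cmh2o)$mean - 0.133),
            5e-4)

  cs <- summarize_cohort(rep(4.2, 5))
  expect_equal(cs$sd, 0)
  expect_equal(cs$cov, 0)
  expect_error(summarize_cohort(3), "at least two")
})

test_that("specimen reports assemble the per-specimen metrics", {
  ds <- small_noiseless()
  run <- run_specimen(dataset = ds, specimen = "ph1")
  rep <- run$report
  expect_s3_class(rep, "specimen_report")
  expect_equal(rep$enhanced_volume_ml, rep$per_ml + rep$cer_ml)
  expect_true(rep$pdf_percent >= 0 && rep$pdf_percent <= 100)
  expect_true(rep$pvf_percent >= 0 && rep$pvf_percent <= 100)
  df <- reports_to_df(list(rep, rep))
  expect_equal(nrow(df), 2)
  expect_true("gd_amount_umol" %in% names(df))
})
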