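# run code with a fixed RNG seed without disturbing global RNG state
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Specification of the digital thorax phantom
#'
#' Parametric description of a synthetic two-lung thorax used as the test
#' substrate for the whole pipeline: two ellipsoidal lungs (right slightly
#' larger), a recursively bifurcating central airway tree entered through a
#' trachea (the central enhanced region), and peripheral enhanced blobs
#' seeded with a ventral-to-dorsal (dependent-region, supine) bias and a
#' right/left asymmetry. Ground-truth region labels and a ground-truth
#' concentration field are carried alongside the rendered signal volumes.
#'
#' Geometric defaults emulate an ex vivo leporine thorax: a total lung
#' volume near 91 mL, four airway generations, and about 100 micromoles of
#' instilled Gd3+ of which 84% reaches the periphery (the cohort means of
#' the motivating ex vivo study). The tissue T1 of 800 ms is a declared
#' convention for degassed ex vivo lung tissue; the background models a
#' gel-filled chamber surrounding the thorax (short T1, quarter-strength
#' proton density) so that background ROIs carry measurable noise.
#'
#' @param shape Grid dimensions, default `c(144, 144, 110)`.
#' @param spacing Voxel spacing in mm, default `c(0.78, 0.78, 1.0)`.
#' @param n_generations Number of airway generations including the trachea
#'   (default 4).
#' @param trachea_radius_mm,radius_shrink Trachea radius (mm) and
#'   per-generation radius factor.
#' @param trachea_length_mm,length_shrink Trachea length (mm) and
#'   per-generation length factor.
#' @param branch_angle_deg Bifurcation half-angle in degrees.
#' @param lung_semiaxes_mm Base ellipsoid semi-axes `c(RL, VD, CC)` in mm.
#' @param right_scale,left_scale Per-lung scale of the semi-axes (right
#'   larger by default).
#' @param t1_pre_ms Pre-administration tissue T1 in ms (default 800).
#' @param t1_background_ms Background (chamber medium) T1 in ms.
#' @param A_tissue,A_background Proton-density scale constants per tissue
#'   class (arbitrary units).
#' @param total_instilled_gd_umol Total Gd3+ amount distributed in the
#'   lungs, micromoles (default 100).
#' @param dependent_gradient_strength Linear ventral-to-dorsal weighting of
#'   the peripheral concentration (0 = uniform; default 1.5, so the most
#'   dorsal voxels carry 2.5x the ventral weight).
#' @param right_left_asymmetry Fraction of the peripheral Gd amount (and of
#'   blob seeding weight) assigned to the right lung (default 0.6).
#' @param enhanced_fraction_of_tlv Target peripheral volume fraction (PVF),
#'   percent of TLV occupied by PER (default 32.5).
#' @param peripheral_amount_fraction Target peripheral distribution
#'   fraction (PDF), percent of the Gd amount in PER (default 84).
#' @param wall_shell_mm Thickness of the enhancing inner-wall shell of the
#'   airways (default 2 mm); airway cores wider than this stay
#'   solution-free.
#' @param blob_radius_range_mm Radius range of the peripheral enhanced
#'   blobs, mm.
#' @param noise_sd Additive Gaussian noise SD in signal units; `NA`
#'   (default) derives it from `snr`.
#' @param snr Target signal-to-noise ratio, referenced to the mean
#'   noiseless post-administration signal over the peripheral enhanced
#'   region (default 50). Used only when `noise_sd` is `NA`.
#' @param seed RNG seed controlling blob placement and rendered noise.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(144, 144, 110),
                         spacing = c(0.78, 0.78, 1.0),
                         n_generations = 4,
                         trachea_radius_mm = 3.2, radius_shrink = 0.78,
                         trachea_length_mm = 34, length_shrink = 0.76,
                         branch_angle_deg = 38,
                         lung_semiaxes_mm = c(16, 21, 32),
                         right_scale = 1.05, left_scale = 0.95,
                         t1_pre_ms = 800, t1_background_ms = 300,
                         A_tissue = 100, A_background = 25,
                         total_instilled_gd_umol = 100,
                         dependent_gradient_strength = 1.5,
                         right_left_asymmetry = 0.6,
                         enhanced_fraction_of_tlv = 32.5,
                         peripheral_amount_fraction = 84,
                         wall_shell_mm = 2,
                         blob_radius_range_mm = c(2, 5),
                         noise_sd = NA_real_, snr = 50,
                         seed = 1L) {
  stopifnot(length(shape) == 3L, all(shape >= 8),
            length(spacing) == 3L, all(spacing > 0),
            n_generations >= 1, trachea_radius_mm > 0,
            radius_shrink > 0, radius_shrink <= 1,
            trachea_length_mm > 0, length_shrink > 0, length_shrink <= 1,
            all(lung_semiaxes_mm > 0), right_scale > 0, left_scale > 0,
            t1_pre_ms > 0, t1_background_ms > 0,
            A_tissue > 0, A_background >= 0,
            total_instilled_gd_umol >= 0,
            dependent_gradient_strength >= 0,
            right_left_asymmetry >= 0, right_left_asymmetry <= 1,
            wall_shell_mm > 0, length(blob_radius_range_mm) == 2L,
            all(blob_radius_range_mm > 0))
  if (enhanced_fraction_of_tlv <= 0 || enhanced_fraction_of_tlv >= 100)
    stop("target PVF must be strictly inside (0, 100) percent")
  if (peripheral_amount_fraction <= 0 || peripheral_amount_fraction >= 100)
    stop("target PDF must be strictly inside (0, 100) percent")
  if (!is.na(noise_sd) && noise_sd < 0)
    stop("`noise_sd` must be non-negative")
  spec <- as.list(environment())
  structure(spec, class = "phantom_spec")
}

# voxel-center coordinate vectors in mm
grid_coords <- function(shape, spacing) {
  lapply(1:3, function(k) (seq_len(shape[k]) - 0.5) * spacing[k])
}

# linear voxel indices inside a cylinder from p0 to p1 of radius r,
# together with the radial distance of each voxel to the axis segment
cylinder_voxels <- function(p0, p1, r, shape, spacing) {
  lo <- pmax(1L, floor((pmin(p0, p1) - r) / spacing + 0.5))
  hi <- pmin(shape, ceiling((pmax(p0, p1) + r) / spacing + 0.5))
  if (any(lo > hi)) return(list(idx = integer(0), d = numeric(0)))
  ii <- lapply(1:3, function(k) lo[k]:hi[k])
  n <- vapply(ii, length, integer(1))
  PX <- array((ii[[1]] - 0.5) * spacing[1], n)
  PY <- array(rep((ii[[2]] - 0.5) * spacing[2], each = n[1]), n)
  PZ <- array(rep((ii[[3]] - 0.5) * spacing[3], each = n[1] * n[2]), n)
  v <- p1 - p0
  L2 <- sum(v^2)
  if (L2 == 0) {
    t <- 0
  } else {
    t <- ((PX - p0[1]) * v[1] + (PY - p0[2]) * v[2] + (PZ - p0[3]) * v[3]) / L2
    t <- pmin(pmax(t, 0), 1)
  }
  d2 <- (PX - p0[1] - t * v[1])^2 + (PY - p0[2] - t * v[2])^2 +
        (PZ - p0[3] - t * v[3])^2
  inside <- d2 <= r^2
  IX <- array(ii[[1]], n)
  IY <- array(rep(ii[[2]], each = n[1]), n)
  IZ <- array(rep(ii[[3]], each = n[1] * n[2]), n)
  idx <- (IZ[inside] - 1L) * shape[1] * shape[2] +
         (IY[inside] - 1L) * shape[1] + IX[inside]
  list(idx = as.integer(idx), d = sqrt(d2[inside]))
}

normalize3 <- function(v) v / sqrt(sum(v^2))

# recursively bifurcating airway centerline tree; deterministic
build_airway_tree <- function(spec, lung_centers) {
  ext <- spec$shape * spec$spacing
  mx <- ext[1] / 2; my <- ext[2] / 2
  c_cc <- spec$lung_semiaxes_mm[3]
  cz <- lung_centers$right[3]
  z_carina <- cz - 0.65 * c_cc * spec$right_scale
  z0 <- z_carina - spec$trachea_length_mm
  if (z0 < spec$spacing[3])
    stop("airway tree does not fit the grid cranially; enlarge the grid ",
         "or shorten the trachea")
  branches <- list(list(gen = 1L, p0 = c(mx, my, z0),
                        p1 = c(mx, my, z_carina),
                        radius = spec$trachea_radius_mm, side = 0L))
  frontier <- branches
  theta <- spec$branch_angle_deg * pi / 180
  for (g in seq_len(spec$n_generations - 1L) + 1L) {
    len <- spec$trachea_length_mm * spec$length_shrink^(g - 1)
    rad <- spec$trachea_radius_mm * spec$radius_shrink^(g - 1)
    new_frontier <- list()
    for (b in frontier) {
      d <- normalize3(b$p1 - b$p0)
      # bifurcation plane alternates: lateral (RL) at even generations,
      # ventral-dorsal at odd ones
      axis <- if (g %% 2 == 0) c(1, 0, 0) else c(0, 1, 0)
      perp <- axis - sum(axis * d) * d
      if (sum(perp^2) < 1e-12) perp <- c(0, 1, 0) - d[2] * d
      perp <- normalize3(perp)
      for (s in c(-1, 1)) {
        side <- if (g == 2L) (if (s < 0) 1L else 2L) else b$side
        raw <- cos(theta) * d + s * sin(theta) * perp
        ctr <- if (side == 1L) lung_centers$right else lung_centers$left
        pull <- normalize3(ctr + c(0, 0, 0.25 * c_cc) - b$p1)
        dir <- normalize3(0.85 * raw + 0.15 * pull)
        child <- list(gen = g, p0 = b$p1, p1 = b$p1 + len * dir,
                      radius = rad, side = side)
        if (any(child$p1 < 0) || any(child$p1 > ext))
          stop("airway generation ", g, " leaves the grid; enlarge the ",
               "grid or reduce branch lengths")
        new_frontier <- c(new_frontier, list(child))
      }
    }
    branches <- c(branches, new_frontier)
    frontier <- new_frontier
  }
  branches
}

#' Build the phantom geometry: region labels and tissue structure
#'
#' Constructs the two lung ellipsoids, rasterizes the airway tree (CER,
#' with solution-free cores where the tube is wider than the wall shell),
#' and seeds the peripheral enhanced blobs (PER) with dorsal-weighted,
#' side-weighted probability until the target PVF voxel count is reached
#' exactly. Deterministic for a fixed `spec$seed`.
#'
#' @param spec A [phantom_spec()].
#' @return A list of class `phantom_geometry` with fields `labels`
#'   ([region_labels()]), `side` (0/1/2 array: none/right/left),
#'   `cer_core` (logical array: solution-free airway core), `tree` (a
#'   data.frame log of the branch construction with one row per branch),
#'   and `spec`.
#' @export
build_geometry <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  shape <- as.integer(spec$shape); spacing <- spec$spacing
  ext <- shape * spacing
  co <- grid_coords(shape, spacing)
  sa <- spec$lung_semiaxes_mm
  mx <- ext[1] / 2
  a_r <- sa[1] * spec$right_scale; a_l <- sa[1] * spec$left_scale
  gap <- 3  # mediastinal half-gap, mm
  centers <- list(
    right = c(mx - a_r - gap, ext[2] / 2, ext[3] * 0.56),
    left  = c(mx + a_l + gap, ext[2] / 2, ext[3] * 0.56)
  )
  for (side in c("right", "left")) {
    sc <- if (side == "right") spec$right_scale else spec$left_scale
    if (any(centers[[side]] - sa * sc < 0) ||
        any(centers[[side]] + sa * sc > ext))
      stop("lung ellipsoids do not fit the grid; enlarge the grid or ",
           "shrink `lung_semiaxes_mm`")
  }
  ellipsoid <- function(ctr, semi) {
    q1 <- ((co[[1]] - ctr[1]) / semi[1])^2
    q2 <- ((co[[2]] - ctr[2]) / semi[2])^2
    q3 <- ((co[[3]] - ctr[3]) / semi[3])^2
    outer(outer(q1, q2, "+"), q3, "+") <= 1
  }
  lung_r <- ellipsoid(centers$right, sa * spec$right_scale)
  lung_l <- ellipsoid(centers$left, sa * spec$left_scale)
  if (any(lung_r & lung_l)) stop("lung lobes overlap; widen the gap")

  tree <- build_airway_tree(spec, centers)
  cer <- array(FALSE, shape)
  core <- array(FALSE, shape)
  for (b in tree) {
    cv <- cylinder_voxels(b$p0, b$p1, b$radius, shape, spacing)
    cer[cv$idx] <- TRUE
    if (b$radius > spec$wall_shell_mm) {
      inner <- cv$idx[cv$d <= b$radius - spec$wall_shell_mm]
      core[inner] <- TRUE
    }
  }

  lung <- lung_r | lung_l
  tlv <- lung | cer
  side <- array(0L, shape)
  side[lung_r] <- 1L
  side[lung_l] <- 2L

  # peripheral blobs: dorsal- and side-weighted seeding up to the PVF target
  target <- round(spec$enhanced_fraction_of_tlv / 100 * sum(tlv))
  cand <- which(lung & !cer)
  if (length(cand) < target)
    stop("not enough lung voxels outside the airways to reach the target ",
         "PVF; shrink the target or enlarge the lungs")
  ar <- arrayInd(cand, shape)
  yv <- (ar[, 2] - 0.5) * spacing[2]
  yr <- range(yv)
  t_dorsal <- (yv - yr[1]) / max(yr[2] - yr[1], 1e-9)
  w <- 1 + spec$dependent_gradient_strength * t_dorsal

  cer_dil <- dilate_ball(cer, max(spacing) + 1e-6, spacing)
  cer_coords <- sweep(arrayInd(which(cer), shape) - 0.5, 2, spacing, "*")
  per <- array(FALSE, shape)

  # fill each lung to its own voxel target, so the right lung holds exactly
  # `right_left_asymmetry` of the peripheral volume (up to rounding)
  target_r <- round(spec$right_left_asymmetry * target)
  side_targets <- c(`1` = target_r, `2` = target - target_r)
  seed_side <- function(side_code, target_side) {
    sel <- side[cand] == side_code
    if (target_side == 0L || !any(sel)) {
      if (target_side > 0L)
        stop("no candidate voxels in one lung for the requested ",
             "right/left split")
      return(invisible())
    }
    cand_s <- cand[sel]; w_s <- w[sel]
    n_draw <- 512L
    draws <- sample(length(cand_s), n_draw, replace = TRUE, prob = w_s)
    radii <- runif(n_draw, spec$blob_radius_range_mm[1],
                   spec$blob_radius_range_mm[2])
    i <- 0L; total <- 0L; guard <- 0L
    while (total < target_side) {
      i <- i + 1L; guard <- guard + 1L
      if (guard > 20000L)
        stop("blob seeding failed to reach the target PVF; review the ",
             "phantom parameters")
      if (i > n_draw) {
        draws <- c(draws, sample(length(cand_s), n_draw, replace = TRUE,
                                 prob = w_s))
        radii <- c(radii, runif(n_draw, spec$blob_radius_range_mm[1],
                                spec$blob_radius_range_mm[2]))
        n_draw <- length(draws)
      }
      ctr <- (arrayInd(cand_s[draws[i]], shape) - 0.5) * spacing
      r_blob <- radii[i]
      # keep blobs clear of the airway tree so PER and CER stay separable
      dmin <- min(sqrt(colSums((t(cer_coords) - as.numeric(ctr))^2)))
      if (dmin < r_blob + 2 * max(spacing)) next
      cv <- cylinder_voxels(as.numeric(ctr), as.numeric(ctr), r_blob,
                            shape, spacing)
      new <- cv$idx[lung[cv$idx] & !cer_dil[cv$idx] & !per[cv$idx] &
                    side[cv$idx] == side_code]
      if (length(new) == 0L) next
      if (total + length(new) > target_side)
        new <- new[seq_len(target_side - total)]
      per[new] <<- TRUE  # accumulate in the enclosing scope
      total <- total + length(new)
    }
  }
  with_seed(spec$seed, {
    for (sc in c(1L, 2L)) seed_side(sc, side_targets[[as.character(sc)]])
  })

  labels <- array(0L, shape)
  labels[tlv] <- 1L
  labels[per] <- 2L
  labels[cer] <- 3L
  tree_df <- do.call(rbind, lapply(tree, function(b)
    data.frame(gen = b$gen, x0 = b$p0[1], y0 = b$p0[2], z0 = b$p0[3],
               x1 = b$p1[1], y1 = b$p1[2], z1 = b$p1[3],
               radius = b$radius, side = b$side)))
  structure(list(labels = region_labels(labels), side = side,
                 cer_core = core, tree = tree_df, spec = spec),
            class = "phantom_geometry")
}

#' Assign the ground-truth Gd3+ concentration field
#'
#' Distributes `spec$total_instilled_gd_umol` over the enhanced regions:
#' the peripheral fraction (`peripheral_amount_fraction` percent) goes to
#' PER with a linear ventral-to-dorsal weighting and the configured
#' right/left split, the remainder to the airway wall shells of CER. Each
#' region's field is rescaled so the total integrates exactly to the
#' specified amount.
#'
#' @param geom A `phantom_geometry` from [build_geometry()].
#' @param spec The [phantom_spec()] (defaults to `geom$spec`).
#' @return A [volume3d()] concentration map in mM, zero outside PER and
#'   CER.
#' @export
assign_concentration <- function(geom, spec = geom$spec) {
  stopifnot(inherits(geom, "phantom_geometry"))
  shape <- dim(geom$labels$labels)
  spacing <- spec$spacing
  vv <- voxel_volume_ml(spacing)
  f <- spec$peripheral_amount_fraction / 100
  q_total <- spec$total_instilled_gd_umol
  per <- geom$labels$labels == 2L
  shell <- (geom$labels$labels == 3L) & !geom$cer_core
  if (q_total > 0 && (!any(per) || !any(shell)))
    stop("empty PER or CER with a nonzero instilled amount; rebuild the ",
         "geometry")
  conc <- array(0, shape)

  if (q_total > 0) {
    idx <- which(per)
    ar <- arrayInd(idx, shape)
    yv <- (ar[, 2] - 0.5) * spacing[2]
    yr <- range(yv)
    w <- 1 + spec$dependent_gradient_strength *
      (yv - yr[1]) / max(yr[2] - yr[1], 1e-9)
    # the right/left amount split follows from the asymmetric blob
    # placement; per-voxel weights depend only on the dorsal position, so a
    # zero gradient gives an exactly uniform peripheral concentration
    conc[idx] <- (w / sum(w) * f * q_total) / vv  # umol per voxel -> mM
    q_cer <- (1 - f) * q_total
    conc[shell] <- q_cer / sum(shell) / vv
  }
  volume3d(conc, spacing, geom$labels$axes)
}

#' Render the phantom into multi-flip-angle UTE volumes
#'
#' The forward model: per voxel, the post-administration relaxation rate is
#' `R1_post = R1_pre + r1 * C` (the relaxivity relation inverted), and
#' signals follow the spoiled gradient-echo equation with the tissue-class
#' scale constants. Zero-mean Gaussian noise of SD `spec$noise_sd` (or
#' derived from `spec$snr`, see [phantom_spec()]) is added to the
#' magnitudes and floored at zero. The noise is drawn under `spec$seed`,
#' so the same seed gives a bit-identical dataset while different seeds
#' change only the noise for fixed geometry and concentration.
#'
#' @param geom A `phantom_geometry`.
#' @param conc A [volume3d()] concentration map (mM), e.g. from
#'   [assign_concentration()].
#' @param spec The [phantom_spec()] (defaults to `geom$spec`).
#' @param params An [acquisition_params()].
#' @return An object of class `phantom_dataset` with fields `pre_volumes`
#'   (named list of [volume3d()], one per flip angle), `post_volume`,
#'   `truth_labels`, `truth_concentration`, `truth_t1_post` (ms),
#'   `truth_report` (a [specimen_report()] computed from the truth fields),
#'   `noise_sd`, `side`, `tree`, `spec`, `params`.
#' @export
render_mri <- function(geom, conc, spec = geom$spec,
                       params = acquisition_params()) {
  stopifnot(inherits(geom, "phantom_geometry"), inherits(conc, "volume3d"),
            inherits(params, "acquisition_params"),
            identical(dim(conc$data), dim(geom$labels$labels)))
  if (!is.na(spec$noise_sd) && spec$noise_sd < 0)
    stop("`noise_sd` must be non-negative")
  shape <- dim(conc$data); spacing <- spec$spacing
  lab <- geom$labels$labels
  tissue <- lab >= 1L
  A_map <- array(spec$A_background, shape); A_map[tissue] <- spec$A_tissue
  t1_pre <- array(spec$t1_background_ms, shape)
  t1_pre[tissue] <- spec$t1_pre_ms

  r1_post <- 1000 / t1_pre + params$r1 * conc$data  # s^-1
  t1_post <- 1000 / r1_post                         # ms

  pre_clean <- lapply(params$flip_angles, function(a)
    ute_signal(A_map, a, params$tr, t1_pre))
  post_clean <- ute_signal(A_map, params$post_flip_angle, params$tr, t1_post)

  per <- lab == 2L
  sd_n <- if (is.na(spec$noise_sd)) {
    if (!is.finite(spec$snr) || spec$snr <= 0) 0
    else mean(post_clean[per]) / spec$snr
  } else spec$noise_sd

  add_noise <- function(s) {
    if (sd_n == 0) return(s)
    pmax(s + stats::rnorm(length(s), 0, sd_n), 0)
  }
  vols <- with_seed(spec$seed, {
    pre <- lapply(pre_clean, function(s)
      volume3d(array(add_noise(s), shape), spacing))
    post <- volume3d(array(add_noise(post_clean), shape), spacing)
    list(pre = pre, post = post)
  })
  names(vols$pre) <- paste0("fa", params$flip_angles)

  vv <- voxel_volume_ml(spacing)
  enh <- lab >= 2L
  vols3 <- region_volumes(geom$labels, spacing)
  q_per <- sum(conc$data[lab == 2L]) * vv
  q_cer <- sum(conc$data[lab == 3L]) * vv
  truth_report <- structure(list(
    specimen = "truth",
    enhanced_volume_ml = unname(vols3["PER"] + vols3["CER"]),
    mean_t1_post_ms = mean(t1_post[enh]),
    mean_concentration_mm = mean(conc$data[enh]),
    gd_amount_umol = q_per + q_cer,
    pdf_percent = if (q_per + q_cer > 0) 100 * q_per / (q_per + q_cer)
                  else NA_real_,
    pvf_percent = pvf_metric(geom$labels),
    tlv_ml = unname(vols3["TLV"]),
    per_ml = unname(vols3["PER"]),
    cer_ml = unname(vols3["CER"]),
    invalid_voxel_count = 0L, negative_clamped_count = 0L
  ), class = "specimen_report")

  structure(list(pre_volumes = vols$pre, post_volume = vols$post,
                 truth_labels = geom$labels,
                 truth_concentration = conc,
                 truth_t1_post = volume3d(t1_post, spacing),
                 truth_report = truth_report,
                 noise_sd = sd_n, side = geom$side, tree = geom$tree,
                 spec = spec, params = params),
            class = "phantom_dataset")
}

#' Build a complete phantom dataset in one call
#'
#' Chains [build_geometry()], [assign_concentration()] and [render_mri()].
#'
#' @param spec A [phantom_spec()].
#' @param params An [acquisition_params()].
#' @return A `phantom_dataset`.
#' @export
build_phantom <- function(spec = phantom_spec(),
                          params = acquisition_params()) {
  geom <- build_geometry(spec)
  conc <- assign_concentration(geom, spec)
  render_mri(geom, conc, spec, params)
}

#' @export
print.phantom_dataset <- function(x, ...) {
  cat("phantom_dataset", paste(dim(x$post_volume$data), collapse = " x "),
      sprintf("@ (%g, %g, %g) mm\n", x$spec$spacing[1], x$spec$spacing[2],
              x$spec$spacing[3]))
  cat(sprintf("  %d pre volumes (flip angles %s deg), noise SD %.4g\n",
              length(x$pre_volumes),
              paste(x$params$flip_angles, collapse = ", "), x$noise_sd))
  print(x$truth_report)
  invisible(x)
}
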