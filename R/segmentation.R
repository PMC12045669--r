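# ---- binary morphology on anisotropic grids --------------------------------

# integer offsets (n x 3) whose physical distance is <= radius_mm
ball_offsets <- function(radius_mm, spacing) {
  r <- ceiling(radius_mm / spacing)
  g <- expand.grid(dx = -r[1]:r[1], dy = -r[2]:r[2], dz = -r[3]:r[3])
  d2 <- (g$dx * spacing[1])^2 + (g$dy * spacing[2])^2 + (g$dz * spacing[3])^2
  as.matrix(g[d2 <= radius_mm^2 + 1e-9, , drop = FALSE])
}

# shift a 3D logical array by integer offset, padding with FALSE
shift_mask <- function(mask, off) {
  d <- dim(mask)
  out <- array(FALSE, d)
  src <- dst <- vector("list", 3)
  for (k in 1:3) {
    o <- off[k]
    if (abs(o) >= d[k]) return(out)
    if (o >= 0) { dst[[k]] <- (1 + o):d[k]; src[[k]] <- 1:(d[k] - o) }
    else        { dst[[k]] <- 1:(d[k] + o); src[[k]] <- (1 - o):d[k] }
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- mask[src[[1]], src[[2]], src[[3]]]
  out
}

erode_ball <- function(mask, radius_mm, spacing) {
  offs <- ball_offsets(radius_mm, spacing)
  acc <- array(0L, dim(mask))
  for (i in seq_len(nrow(offs))) acc <- acc + shift_mask(mask, offs[i, ])
  acc == nrow(offs)
}

dilate_ball <- function(mask, radius_mm, spacing) {
  offs <- ball_offsets(radius_mm, spacing)
  acc <- array(FALSE, dim(mask))
  for (i in seq_len(nrow(offs))) acc <- acc | shift_mask(mask, offs[i, ])
  acc
}

open_ball <- function(mask, radius_mm, spacing) {
  dilate_ball(erode_ball(mask, radius_mm, spacing), radius_mm, spacing)
}

# ---- connected components (6-connectivity) ---------------------------------

# label the 6-connected components of a logical 3D array; returns an integer
# array (0 = background) plus component sizes as attribute "sizes"
label_components <- function(mask) {
  d <- dim(mask)
  idx <- which(mask)
  lab <- array(0L, d)
  if (length(idx) == 0L) return(structure(lab, sizes = integer(0)))
  pos <- match(seq_len(prod(d)), idx)  # linear index -> vertex id (NA outside)

  edges <- integer(0)
  strides <- c(1L, d[1], d[1] * d[2])
  ar <- arrayInd(idx, d)
  for (k in 1:3) {
    ok <- ar[, k] < d[k]
    nb <- idx[ok] + strides[k]
    has <- !is.na(pos[nb])
    from <- pos[idx[ok][has]]
    to <- pos[nb[has]]
    edges <- c(edges, rbind(from, to))
  }
  g <- igraph::make_graph(edges, n = length(idx), directed = FALSE)
  comp <- igraph::components(g)
  lab[idx] <- comp$membership
  structure(lab, sizes = as.integer(comp$csize))
}

drop_small_components <- function(mask, min_voxels) {
  if (min_voxels <= 1L) return(mask)
  lab <- label_components(mask)
  sizes <- attr(lab, "sizes")
  keep <- which(sizes >= min_voxels)
  array(lab %in% keep, dim(mask))
}

# ---- fallback segmenter ----------------------------------------------------

#' Configuration of the threshold-based fallback segmenter
#'
#' The fallback segmenter is transparent plumbing for phantom-driven runs:
#' it stands where an external segmentation (manual or learned) would
#' normally supply the region masks. Its defaults are declared conventions
#' of this package, not measured protocol values.
#'
#' @param enhancement_threshold Voxel-wise signal-enhancement threshold (as
#'   a fraction; default 1.0 = 100% signal increase) above which a lung
#'   voxel counts as enhanced.
#' @param min_component_voxels Connected components of the enhanced mask
#'   smaller than this are discarded as noise (default 20).
#' @param central_radius_mm Tube-radius cutoff separating central airways
#'   from peripheral enhancement: the enhanced mask is morphologically
#'   opened by a ball of this radius before the trachea-connectivity step
#'   (default 1.0 mm).
#' @param trachea_seed `"auto"` (centroid of the most cranial enhanced
#'   slice) or an integer voxel coordinate `c(i, j, k)`.
#' @return An object of class `segmentation_config`.
#' @export
segmentation_config <- function(enhancement_threshold = 1.0,
                                min_component_voxels = 20L,
                                central_radius_mm = 1.0,
                                trachea_seed = "auto") {
  if (enhancement_threshold <= 0)
    stop("`enhancement_threshold` must be positive")
  if (central_radius_mm <= 0)
    stop("`central_radius_mm` must be positive")
  structure(list(enhancement_threshold = enhancement_threshold,
                 min_component_voxels = as.integer(min_component_voxels),
                 central_radius_mm = central_radius_mm,
                 trachea_seed = trachea_seed),
            class = "segmentation_config")
}

#' Threshold-based fallback segmentation into TLV/PER/CER
#'
#' Deterministic stand-in for an externally trained segmentation model,
#' driven by the pre/post volume pair:
#' * enhanced voxels: lung voxels whose voxel-wise signal enhancement
#'   `(post - pre)/pre` exceeds the configured threshold, after removal of
#'   small connected components;
#' * CER: the part of the enhanced set reachable from the trachea seed
#'   through tubes of local radius at least `central_radius_mm`
#'   (morphological opening by a ball of that radius, then 6-connectivity
#'   from the seed);
#' * PER: the remaining enhanced voxels;
#' * TLV: the supplied lung mask.
#'
#' @param pre,post Congruent [volume3d()] volumes at the same flip angle,
#'   before and after contrast administration.
#' @param cfg A [segmentation_config()].
#' @param tlv_mask Logical lung mask (airways included); the enhancement
#'   search is restricted to it.
#' @return A [region_labels()] object.
#' @export
fallback_segment <- function(pre, post, cfg, tlv_mask) {
  stopifnot(inherits(pre, "volume3d"), inherits(post, "volume3d"),
            inherits(cfg, "segmentation_config"),
            identical(dim(pre$data), dim(post$data)),
            identical(dim(tlv_mask), dim(pre$data)))
  if (any(abs(pre$spacing - post$spacing) > 1e-3))
    stop("pre and post volumes have different spacing")

  se <- array(NA_real_, dim(pre$data))
  ok <- tlv_mask & is.finite(pre$data) & pre$data > 0
  se[ok] <- (post$data[ok] - pre$data[ok]) / pre$data[ok]
  enhanced <- !is.na(se) & se > cfg$enhancement_threshold
  enhanced <- drop_small_components(enhanced, cfg$min_component_voxels)
  if (!any(enhanced))
    stop("no voxels exceed the enhancement threshold (",
         cfg$enhancement_threshold, "); review the threshold or the inputs")

  opened <- open_ball(enhanced, cfg$central_radius_mm, pre$spacing)
  seed <- resolve_trachea_seed(cfg$trachea_seed, enhanced, pre$axes)
  cer <- seeded_component(opened, seed)
  cer <- cer & enhanced
  per <- enhanced & !cer
  l <- array(0L, dim(pre$data))
  l[tlv_mask] <- 1L
  l[cer] <- 3L
  l[per] <- 2L
  region_labels(l, axes = pre$axes)
}

# centroid of the most cranial slice containing enhancement, or a user voxel
resolve_trachea_seed <- function(seed, enhanced, axes) {
  if (is.numeric(seed)) {
    if (length(seed) != 3L) stop("`trachea_seed` voxel must have 3 indices")
    return(as.integer(round(seed)))
  }
  cc <- axis_index(axes, "CC")
  ar <- arrayInd(which(enhanced), dim(enhanced))
  k0 <- min(ar[, cc])
  top <- ar[ar[, cc] == k0, , drop = FALSE]
  as.integer(round(colMeans(top)))
}

# 6-connected component of `mask` containing (or nearest to) the seed voxel
seeded_component <- function(mask, seed) {
  d <- dim(mask)
  lab <- label_components(mask)
  seed <- pmin(pmax(seed, 1L), d)
  id <- lab[seed[1], seed[2], seed[3]]
  if (id == 0L) {
    # seed fell just outside the opened mask: snap to the nearest mask voxel
    idx <- which(mask)
    if (length(idx) == 0L) return(array(FALSE, d))
    ar <- arrayInd(idx, d)
    d2 <- (ar[, 1] - seed[1])^2 + (ar[, 2] - seed[2])^2 + (ar[, 3] - seed[3])^2
    id <- lab[idx[which.min(d2)]]
  }
  array(lab == id, d)
}

#' Dice overlap coefficient between two masks
#'
#' @param a,b Logical arrays of identical shape.
#' @return `2|a & b| / (|a| + |b|)`; 1 for identical non-empty masks.
#' @export
dice_coefficient <- function(a, b) {
  stopifnot(identical(dim(a), dim(b)))
  denom <- sum(a) + sum(b)
  if (denom == 0) return(NA_real_)
  2 * sum(a & b) / denom
}
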