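#' @importFrom stats rnorm runif sd coef lm
#' @importFrom utils read.csv
NULL

# canonical anatomical axis codes, in the package's internal storage order:
# array axis 1 = right -> left, axis 2 = ventral -> dorsal,
# axis 3 = cranial -> caudal
.anat_axes <- c("RL", "VD", "CC")

.anat_aliases <- c(
  "RL" = "RL", "right-left" = "RL", "right_left" = "RL",
  "VD" = "VD", "ventral-dorsal" = "VD", "ventral_dorsal" = "VD",
  "anterior-posterior" = "VD",
  "CC" = "CC", "cranial-caudal" = "CC", "cranial_caudal" = "CC",
  "superior-inferior" = "CC"
)

# resolve an anatomical direction name to the array dimension of `axes`
axis_index <- function(axes, direction) {
  code <- .anat_aliases[as.character(direction)]
  if (is.na(code))
    stop("unknown anatomical axis '", direction, "'; expected one of: ",
         paste(unique(names(.anat_aliases)), collapse = ", "))
  match(code, axes)
}

#' 3D scalar volume with physical spacing and anatomical axis convention
#'
#' The carrier type for signal, relaxation-rate and concentration maps.
#' `axes` records which anatomical direction each array axis runs along, so
#' profile and projection operations can be addressed by anatomy
#' ("ventral-dorsal") rather than by raw array axis. The canonical order is
#' `c("RL", "VD", "CC")`: axis 1 right to left, axis 2 ventral to dorsal,
#' axis 3 cranial to caudal (a supine subject, head first).
#'
#' @param data A 3D numeric array. NaN values are rejected; represent
#'   excluded voxels as NA explicitly.
#' @param spacing Voxel spacing `c(dx, dy, dz)` in mm, all strictly positive.
#' @param axes Character vector of length 3: a permutation of
#'   `c("RL", "VD", "CC")` naming the anatomical direction of each array
#'   axis.
#' @return An object of class `volume3d` with fields `data`, `spacing`,
#'   `axes`.
#' @examples
#' v <- volume3d(array(0, c(4, 4, 2)), spacing = c(0.78, 0.78, 1))
#' voxel_volume_ml(v$spacing)
#' @export
volume3d <- function(data, spacing, axes = .anat_axes) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3D array; got ",
         if (is.array(data)) length(dim(data)) else "non-array", " dimensions")
  if (any(is.nan(data)))
    stop("`data` contains NaN; mask excluded voxels as NA explicitly")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be three strictly positive values in mm")
  if (length(axes) != 3L || !setequal(axes, .anat_axes))
    stop("`axes` must be a permutation of ",
         paste(.anat_axes, collapse = ", "))
  structure(list(data = data, spacing = spacing, axes = as.character(axes)),
            class = "volume3d")
}

#' @export
print.volume3d <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("volume3d %d x %d x %d @ (%g, %g, %g) mm, axes %s\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3],
              paste(x$axes, collapse = "-")))
  rng <- range(x$data, na.rm = TRUE)
  cat(sprintf("  range [%.4g, %.4g], %d NA voxels\n", rng[1], rng[2],
              sum(is.na(x$data))))
  invisible(x)
}

#' Volume of one voxel in mL
#'
#' @param spacing Voxel spacing `c(dx, dy, dz)` in mm.
#' @return Voxel volume in mL (`dx*dy*dz / 1000`).
#' @export
voxel_volume_ml <- function(spacing) prod(spacing) / 1000

#' Read a 3D volume from a NIfTI file
#'
#' Spacing is taken from the header `pixdim`. NIfTI orientation codes are
#' not interpreted: the array axes are assumed to follow the package's
#' canonical anatomical order unless an explicit `axes` override is given.
#'
#' @param path Path to a `.nii` or `.nii.gz` file containing a 3D volume.
#' @param axes Anatomical axis mapping of the stored array (see
#'   [volume3d()]); override when the file was written in another
#'   convention.
#' @return A [volume3d()] object.
#' @export
read_volume <- function(path, axes = .anat_axes) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3L)
    stop("expected a 3D volume, but '", path, "' has ", length(d),
         " dimensions")
  sp <- RNifti::pixdim(img)[seq_len(3)]
  if (any(!is.finite(sp)) || any(sp <= 0))
    stop("degenerate voxel spacing in '", path, "': (",
         paste(sp, collapse = ", "), ") mm")
  volume3d(array(as.numeric(img), dim = d), spacing = sp, axes = axes)
}

#' Write a 3D volume to a NIfTI file
#'
#' Written as float64 so the round trip through [read_volume()] is lossless
#' for double-precision data.
#'
#' @param vol A [volume3d()] object.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @param datatype NIfTI storage type; `"double"` (default) is lossless,
#'   `"int16"` suits label volumes.
#' @return Invisibly, `path`.
#' @export
write_volume <- function(vol, path, datatype = "double") {
  stopifnot(inherits(vol, "volume3d"))
  dat <- vol$data
  dat[is.na(dat)] <- NA_real_
  img <- RNifti::asNifti(dat)
  RNifti::pixdim(img) <- vol$spacing
  tryCatch(
    RNifti::writeNifti(img, path, datatype = datatype),
    error = function(e) stop("failed to write '", path, "': ",
                             conditionMessage(e))
  )
  invisible(path)
}

# ---- region labels ---------------------------------------------------------

.label_codes <- c(background = 0L, TLV_only = 1L, PER = 2L, CER = 3L)

#' Voxel-wise three-region lung partition
#'
#' Encodes the partition of the grid into background (0), lung tissue with
#' no enhancement ("TLV-only", 1), the peripheral enhanced region (PER, 2)
#' and the central enhanced region (CER, 3). One integer label per voxel
#' makes PER and CER disjoint by construction; the total lung volume (TLV)
#' is defined as the union of labels 1, 2 and 3, so PER and CER are always
#' subsets of TLV.
#'
#' @param labels A 3D integer array with values in `{0, 1, 2, 3}`.
#' @param axes Anatomical axis mapping, as for [volume3d()].
#' @return An object of class `region_labels`.
#' @export
region_labels <- function(labels, axes = .anat_axes) {
  if (!is.array(labels) || length(dim(labels)) != 3L)
    stop("`labels` must be a 3D array")
  vals <- unique(as.vector(labels))
  bad <- setdiff(vals, .label_codes)
  if (length(bad) > 0)
    stop("unknown label values: {", paste(sort(bad), collapse = ", "),
         "}; expected 0 (background), 1 (TLV-only), 2 (PER), 3 (CER)")
  storage.mode(labels) <- "integer"
  structure(list(labels = labels, axes = as.character(axes)),
            class = "region_labels")
}

#' @export
print.region_labels <- function(x, ...) {
  tab <- table(factor(x$labels, levels = .label_codes,
                      labels = names(.label_codes)))
  cat("region_labels", paste(dim(x$labels), collapse = " x "), "\n")
  print(tab)
  invisible(x)
}

#' Binary mask for a named region
#'
#' @param labels A [region_labels()] object.
#' @param region One of `"TLV"`, `"PER"`, `"CER"`, `"enhanced"`
#'   (= PER union CER), `"TLV_only"`, `"background"`.
#' @return A logical 3D array.
#' @export
region_mask <- function(labels, region) {
  stopifnot(inherits(labels, "region_labels"))
  l <- labels$labels
  switch(region,
    TLV = l >= 1L,
    PER = l == 2L,
    CER = l == 3L,
    enhanced = l >= 2L,
    TLV_only = l == 1L,
    background = l == 0L,
    stop("unknown region '", region,
         "'; expected TLV, PER, CER, enhanced, TLV_only or background")
  )
}

#' Region volumes in mL
#'
#' Volume of each region as voxel count times voxel volume. TLV includes
#' both enhanced regions and un-enhanced lung, so `TLV >= max(PER, CER)`
#' always, while `TLV >= PER + CER` holds whenever TLV-only voxels exist.
#'
#' @param labels A [region_labels()] object.
#' @param spacing Voxel spacing `c(dx, dy, dz)` in mm.
#' @return Named numeric vector with elements `TLV`, `PER`, `CER` (mL).
#' @export
region_volumes <- function(labels, spacing) {
  stopifnot(inherits(labels, "region_labels"))
  vv <- voxel_volume_ml(spacing)
  l <- labels$labels
  c(TLV = sum(l >= 1L) * vv,
    PER = sum(l == 2L) * vv,
    CER = sum(l == 3L) * vv)
}

#' Read a label volume from a NIfTI file, validated against a grid
#'
#' The externally produced partition (e.g. from manual delineation or a
#' trained segmentation network) is a first-class input. The label volume
#' must be congruent with the reference grid: same array shape, and spacing
#' equal within 1e-3 mm.
#'
#' @param path Path to an integer NIfTI label volume with values 0-3.
#' @param grid A [volume3d()] providing the reference geometry.
#' @return A [region_labels()] object.
#' @export
ingest_labels <- function(path, grid) {
  stopifnot(inherits(grid, "volume3d"))
  lab <- read_volume(path, axes = grid$axes)
  if (!identical(dim(lab$data), dim(grid$data)))
    stop("label volume shape (", paste(dim(lab$data), collapse = "x"),
         ") does not match grid (", paste(dim(grid$data), collapse = "x"), ")")
  if (any(abs(lab$spacing - grid$spacing) > 1e-3))
    stop("label spacing (", paste(lab$spacing, collapse = ", "),
         ") mm does not match grid (", paste(grid$spacing, collapse = ", "),
         ") mm")
  region_labels(array(as.integer(round(lab$data)), dim = dim(lab$data)),
                axes = grid$axes)
}

#' Build a three-region partition from binary masks
#'
#' When the inputs are a lung mask plus an enhanced mask and a PER mask
#' (the peripheral region), the central enhanced region is constructed as
#' the complement of PER within the enhanced set.
#'
#' @param tlv Logical 3D array: all lung voxels (airways included).
#' @param enhanced Logical 3D array: all contrast-enhanced voxels; must be a
#'   subset of `tlv`.
#' @param per Logical 3D array: peripheral enhanced voxels; must be a subset
#'   of `enhanced`.
#' @param axes Anatomical axis mapping.
#' @return A [region_labels()] object with `CER = enhanced & !per`.
#' @export
region_labels_from_masks <- function(tlv, enhanced, per, axes = .anat_axes) {
  stopifnot(identical(dim(tlv), dim(enhanced)),
            identical(dim(tlv), dim(per)))
  if (any(enhanced & !tlv))
    stop("`enhanced` must be a subset of `tlv`")
  if (any(per & !enhanced))
    stop("`per` must be a subset of `enhanced`")
  l <- array(0L, dim = dim(tlv))
  l[tlv] <- 1L
  l[enhanced & !per] <- 3L  # CER as the complement of PER within enhanced
  l[per] <- 2L
  region_labels(l, axes = axes)
}
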