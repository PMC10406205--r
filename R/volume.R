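#' 3D image volume
#'
#' Container for a 3D scalar MR image on a regular voxel grid. Axis order is
#' (sagittal, coronal, axial); the axial direction is the third array axis.
#'
#' @param data 3D numeric array.
#' @param spacing Per-axis voxel size in mm (length 3, all positive).
#' @param space Coordinate-space tag, `"native"` or `"template"`. The tag
#'   documents whether the volume has been registered to a template grid; it
#'   is carried through operations but not enforced.
#' @param header Optional NIfTI header (from [RNifti::niftiHeader()]) used to
#'   propagate the affine unchanged on save.
#' @return An object of class `ll_volume`.
#' @export
volume <- function(data, spacing = c(1, 1, 1), space = "native", header = NULL) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stopf("expected 3D array, got %d dimension(s)", length(dim(data)))
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stopf("spacing must be 3 positive values")
  if (!space %in% c("native", "template"))
    stopf("space must be 'native' or 'template'")
  nbad <- sum(!is.finite(data))
  if (nbad > 0L)
    stopf("volume contains %d non-finite voxel(s)", nbad)
  structure(list(data = data, spacing = spacing, space = space, header = header),
            class = "ll_volume")
}

#' Binary lesion mask
#'
#' @param data 3D array with values in \{0, 1\} (anything else is an error;
#'   use [load_mask()] to binarize probabilistic files).
#' @param spacing Per-axis voxel size in mm.
#' @return An object of class `ll_mask`.
#' @export
lesion_mask <- function(data, spacing = c(1, 1, 1)) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stopf("expected 3D array, got %d dimension(s)", length(dim(data)))
  if (!all(data %in% c(0, 1)))
    stopf("mask values must be 0 or 1")
  storage.mode(data) <- "double"
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(spacing <= 0))
    stopf("spacing must be 3 positive values")
  structure(list(data = data, spacing = spacing), class = "ll_mask")
}

#' @export
print.ll_volume <- function(x, ...) {
  cat(sprintf("<ll_volume %s, spacing %s mm, space=%s, range [%.4g, %.4g]>\n",
              paste(dim(x$data), collapse = "x"),
              paste(signif(x$spacing, 4), collapse = "x"),
              x$space, min(x$data), max(x$data)))
  invisible(x)
}

#' @export
print.ll_mask <- function(x, ...) {
  cat(sprintf("<ll_mask %s, spacing %s mm, %d positive voxel(s)>\n",
              paste(dim(x$data), collapse = "x"),
              paste(signif(x$spacing, 4), collapse = "x"), sum(x$data)))
  invisible(x)
}

#' Voxel volume in cubic millimetres
#' @param x An `ll_volume` or `ll_mask`.
#' @return Scalar voxel volume (product of spacings), mm^3.
#' @export
voxel_volume <- function(x) prod(x$spacing)

same_grid <- function(a, b, tol = 1e-3) {
  identical(dim(a$data), dim(b$data)) && all(abs(a$spacing - b$spacing) <= tol)
}

#' Load a NIfTI volume
#'
#' @param path Path to a `.nii` or `.nii.gz` file containing a 3D image.
#' @param space Space tag to attach (`"native"` default).
#' @return An [volume()] object; spacing comes from the file header and the
#'   full header is retained so the affine round-trips unchanged.
#' @export
load_volume <- function(path, space = "native") {
  if (!file.exists(path)) stopf("file not found: %s", path)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3L)
    stopf("expected 3D image, got %dD: %s", length(d), path)
  hdr <- RNifti::niftiHeader(img)
  data <- array(as.numeric(img), dim = d)
  nbad <- sum(!is.finite(data))
  if (nbad > 0L)
    stopf("volume contains %d non-finite voxel(s): %s", nbad, path)
  volume(data, spacing = RNifti::pixdim(img)[1:3], space = space, header = hdr)
}

#' Save a volume as NIfTI (float32)
#'
#' @param vol An `ll_volume`.
#' @param path Output `.nii` or `.nii.gz` path.
#' @return `path`, invisibly.
#' @export
save_volume <- function(vol, path) {
  img <- if (!is.null(vol$header)) RNifti::asNifti(vol$data, reference = vol$header)
         else RNifti::asNifti(vol$data)
  RNifti::pixdim(img) <- vol$spacing
  RNifti::writeNifti(img, path, datatype = "float")
  invisible(path)
}

#' Load a lesion mask and check it against a reference grid
#'
#' Values are binarized at 0.5, so probabilistic maps load as hard masks.
#'
#' @param path NIfTI file path.
#' @param reference `ll_volume` defining the expected grid.
#' @param tol Spacing agreement tolerance in mm.
#' @return An [lesion_mask()].
#' @export
load_mask <- function(path, reference, tol = 1e-3) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3L) stopf("expected 3D mask, got %dD: %s", length(d), path)
  sp <- RNifti::pixdim(img)[1:3]
  if (!identical(as.integer(d), as.integer(dim(reference$data))))
    stopf("mask grid %s does not match reference %s",
          paste(d, collapse = "x"), paste(dim(reference$data), collapse = "x"))
  if (any(abs(sp - reference$spacing) > tol))
    stopf("mask spacing (%s) does not match reference (%s) within %g mm",
          paste(signif(sp, 6), collapse = ","),
          paste(signif(reference$spacing, 6), collapse = ","), tol)
  data <- array(as.numeric(as.numeric(img) > 0.5), dim = d)
  lesion_mask(data, spacing = sp)
}

#' Save a mask as NIfTI (uint8)
#' @param mask An `ll_mask`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_mask <- function(mask, path) {
  img <- RNifti::asNifti(mask$data)
  RNifti::pixdim(img) <- mask$spacing
  RNifti::writeNifti(img, path, datatype = "uint8")
  invisible(path)
}

#' Patch specification
#'
#' Patches are half-open boxes `[center - floor(size/2), center -
#' floor(size/2) + size)` in 0-based voxel coordinates.
#'
#' @param center Integer voxel coordinate triple (0-based).
#' @param size Edge lengths in voxels (length 1 or 3, each >= 1).
#' @return An object of class `ll_patch_spec`.
#' @export
patch_spec <- function(center, size) {
  center <- as.integer(round(center))
  if (length(center) != 3L) stopf("center must have length 3")
  if (length(size) == 1L) size <- rep(size, 3L)
  size <- as.integer(size)
  if (length(size) != 3L || any(size < 1L)) stopf("size components must be >= 1")
  structure(list(center = center, size = size), class = "ll_patch_spec")
}

patch_bounds <- function(spec) {
  lo <- spec$center - spec$size %/% 2L   # 0-based inclusive start
  list(lo = lo, hi = lo + spec$size)     # half-open [lo, hi)
}

#' Extract a 3D patch (out-of-bounds regions padded)
#'
#' @param vol An `ll_volume` (or `ll_mask`).
#' @param spec A [patch_spec()].
#' @param pad_value Fill value for voxels outside the source grid.
#' @return An `ll_volume` with shape `spec$size` and the source spacing.
#' @export
extract_patch <- function(vol, spec, pad_value = 0) {
  d <- dim(vol$data)
  b <- patch_bounds(spec)
  out <- array(pad_value, dim = spec$size)
  src_lo <- pmax(b$lo, 0L); src_hi <- pmin(b$hi, d)
  if (all(src_hi > src_lo)) {
    dst_lo <- src_lo - b$lo
    out[(dst_lo[1] + 1):(dst_lo[1] + src_hi[1] - src_lo[1]),
        (dst_lo[2] + 1):(dst_lo[2] + src_hi[2] - src_lo[2]),
        (dst_lo[3] + 1):(dst_lo[3] + src_hi[3] - src_lo[3])] <-
      vol$data[(src_lo[1] + 1):src_hi[1],
               (src_lo[2] + 1):src_hi[2],
               (src_lo[3] + 1):src_hi[3]]
  }
  volume(out, spacing = vol$spacing, space = vol$space %||% "native")
}

#' Reinsert a patch into a volume
#'
#' Inverse of [extract_patch()] on the interior region: voxels of the patch
#' that fall inside the target grid overwrite the target.
#'
#' @param vol Target `ll_volume`.
#' @param patch Patch volume of shape `spec$size`.
#' @param spec The [patch_spec()] used at extraction.
#' @return The modified `ll_volume`.
#' @export
insert_patch <- function(vol, patch, spec) {
  d <- dim(vol$data)
  if (!identical(dim(patch$data), as.integer(spec$size)))
    stopf("patch shape does not match spec size")
  b <- patch_bounds(spec)
  src_lo <- pmax(b$lo, 0L); src_hi <- pmin(b$hi, d)
  if (all(src_hi > src_lo)) {
    dst_lo <- src_lo - b$lo
    vol$data[(src_lo[1] + 1):src_hi[1],
             (src_lo[2] + 1):src_hi[2],
             (src_lo[3] + 1):src_hi[3]] <-
      patch$data[(dst_lo[1] + 1):(dst_lo[1] + src_hi[1] - src_lo[1]),
                 (dst_lo[2] + 1):(dst_lo[2] + src_hi[2] - src_lo[2]),
                 (dst_lo[3] + 1):(dst_lo[3] + src_hi[3] - src_lo[3])]
  }
  vol
}
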