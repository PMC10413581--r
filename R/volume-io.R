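#' 3D image volumes and label masks
#'
#' `image_volume()` wraps a 3D numeric array together with its voxel spacing
#' (mm per axis, depth/height/width order) and origin. `label_mask()` is the
#' binary counterpart used for WMH annotations; its values must be exactly 0
#' or 1 and its grid must match the paired image.
#'
#' @param data 3D numeric array (depth x height x width).
#' @param spacing numeric length-3, mm per voxel along each axis; all > 0.
#'   The default (2, 2, 2) mm matches a 256 mm FOV on a 128 matrix with 2 mm
#'   slices, giving 8 mm3 voxels.
#' @param origin numeric length-3, mm offset of the first voxel.
#' @return An object of class `wmh_volume` (or `wmh_mask`, which inherits
#'   from it).
#' @export
image_volume <- function(data, spacing = c(2, 2, 2), origin = c(0, 0, 0)) {
  data <- as.array(data)
  if (length(dim(data)) != 3L)
    stop_wmh("image_volume expects a 3D array, got ", length(dim(data)),
             " dimensions", class = "wmh_dim_error")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop_wmh("spacing must be 3 positive finite values",
             class = "wmh_spacing_error")
  n_bad <- sum(!is.finite(data))
  if (n_bad > 0)
    stop_wmh("volume contains ", n_bad, " non-finite voxel(s)",
             class = "wmh_validation_error")
  structure(list(data = data, spacing = spacing,
                 origin = as.numeric(origin)),
            class = "wmh_volume")
}

#' @rdname image_volume
#' @export
label_mask <- function(data, spacing = c(2, 2, 2), origin = c(0, 0, 0)) {
  vol <- image_volume(data, spacing, origin)
  if (!all(vol$data %in% c(0, 1)))
    stop_wmh("label mask values must be exactly 0 or 1",
             class = "wmh_validation_error")
  storage.mode(vol$data) <- "double"
  class(vol) <- c("wmh_mask", "wmh_volume")
  vol
}

#' @export
print.wmh_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<%s> %d x %d x %d voxels, spacing %.3g x %.3g x %.3g mm\n",
              class(x)[1], d[1], d[2], d[3],
              x$spacing[1], x$spacing[2], x$spacing[3]))
  cat(sprintf("  intensity range [%.4g, %.4g]\n",
              min(x$data), max(x$data)))
  invisible(x)
}

#' @export
dim.wmh_volume <- function(x) dim(x$data)

#' Read and write NIfTI volumes
#'
#' Thin wrappers over RNifti keeping the package's (depth, height, width)
#' array convention and carrying voxel spacing from/to the NIfTI header.
#' Masks are written as unsigned 8-bit with values 0/1.
#'
#' @param path a `.nii` or `.nii.gz` file.
#' @param mask logical; validate and return a binary `wmh_mask`.
#' @return `read_volume()` returns a `wmh_volume` (or `wmh_mask`).
#' @export
read_volume <- function(path, mask = FALSE) {
  if (!file.exists(path))
    stop_wmh("file not found: ", path, class = "wmh_io_error")
  img <- RNifti::readNifti(path)
  arr <- array(as.numeric(img), dim(img))
  if (length(dim(arr)) != 3L)
    stop_wmh("expected a 3D image, got ", length(dim(arr)),
             "D in ", path, class = "wmh_dim_error")
  spacing <- RNifti::pixdim(img)[seq_len(3)]
  if (mask) label_mask(arr, spacing = spacing)
  else image_volume(arr, spacing = spacing)
}

#' @rdname read_volume
#' @param vol a `wmh_volume` or `wmh_mask`.
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "wmh_volume"))
  datatype <- if (inherits(vol, "wmh_mask")) "uint8" else "double"
  img <- structure(vol$data, pixdim = vol$spacing)
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}

#' Per-volume z-score normalization
#'
#' Standardizes intensities over all voxels to mean 0, SD 1 (denominator n).
#' Applied to every FLAIR volume before it enters the network.
#'
#' @param vol a `wmh_volume`.
#' @return a `wmh_volume` with standardized intensities.
#' @export
zscore_normalize <- function(vol) {
  stopifnot(inherits(vol, "wmh_volume"))
  x <- vol$data
  m <- mean(x)
  s <- sqrt(mean((x - m)^2))
  if (s == 0)
    stop_wmh("cannot z-score a constant volume", class = "wmh_degenerate_error")
  image_volume((x - m) / s, spacing = vol$spacing, origin = vol$origin)
}

#' Cut a volume into overlapping cubic patches
#'
#' Patch offsets step by `stride` per axis; the volume is zero-padded at the
#' high end of each axis so the patch grid covers every voxel. Padding happens
#' in normalized intensity space where background is approximately 0.
#'
#' @param vol a `wmh_volume`.
#' @param patch_size cubic patch edge length in voxels.
#' @param stride step between patch corners in voxels; must be in
#'   `[1, patch_size]` or the union of patches could not cover the volume.
#' @return list with `offsets` (matrix of 0-based corners), `patch_size`,
#'   `stride`, `padded_dim`, and `patches` (list of 3D arrays).
#' @export
extract_patches <- function(vol, patch_size, stride = patch_size) {
  stopifnot(inherits(vol, "wmh_volume"))
  p <- as.integer(patch_size); s <- as.integer(stride)
  if (s < 1L) stop_wmh("stride must be >= 1", class = "wmh_config_error")
  if (s > p)
    stop_wmh("stride ", s, " exceeds patch size ", p,
             ": patches would leave gaps", class = "wmh_gap_error")
  d <- dim(vol$data)
  axis_offsets <- function(n) {
    if (n <= p) return(0L)
    last <- s * ceiling((n - p) / s)
    seq.int(0L, last, by = s)
  }
  offs <- lapply(d, function(n) as.integer(axis_offsets(n)))
  padded <- vapply(seq_len(3), function(a) max(offs[[a]]) + p, integer(1))
  xp <- array(0, padded)
  xp[seq_len(d[1]), seq_len(d[2]), seq_len(d[3])] <- vol$data
  grid <- as.matrix(expand.grid(offs[[1]], offs[[2]], offs[[3]]))
  colnames(grid) <- c("d", "h", "w")
  patches <- lapply(seq_len(nrow(grid)), function(i) {
    o <- grid[i, ]
    xp[o[1] + seq_len(p), o[2] + seq_len(p), o[3] + seq_len(p)]
  })
  list(offsets = grid, patch_size = p, stride = s,
       padded_dim = padded, dim = d, patches = patches)
}

#' Reassemble patches into a volume
#'
#' Overlapping voxels are averaged; the high-end zero padding added by
#' [extract_patches()] is cropped away. Reassembling untouched patches
#' reproduces the source volume exactly.
#'
#' @param grid result of [extract_patches()] (its `patches` may be replaced,
#'   e.g. by per-patch predictions of the same shape).
#' @param spacing voxel spacing for the rebuilt volume.
#' @return a `wmh_volume`.
#' @export
reassemble_patches <- function(grid, spacing = c(2, 2, 2)) {
  p <- grid$patch_size
  acc <- array(0, grid$padded_dim)
  cnt <- array(0, grid$padded_dim)
  for (i in seq_len(nrow(grid$offsets))) {
    o <- grid$offsets[i, ]
    id <- o[1] + seq_len(p); ih <- o[2] + seq_len(p); iw <- o[3] + seq_len(p)
    acc[id, ih, iw] <- acc[id, ih, iw] + grid$patches[[i]]
    cnt[id, ih, iw] <- cnt[id, ih, iw] + 1
  }
  out <- acc / cnt
  d <- grid$dim
  image_volume(out[seq_len(d[1]), seq_len(d[2]), seq_len(d[3])],
               spacing = spacing)
}
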