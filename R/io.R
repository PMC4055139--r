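# Volume and mask I/O. Internal orientation: a slice is a numeric matrix
# with rows = image rows; volumes are ordered slice lists. For NIfTI the
# slice index is the last axis; for stack directories, files sort
# lexicographically.

.is_image_file <- function(f) grepl("\\.(png|tif|tiff)$", f,
                                    ignore.case = TRUE)

.read_slice_file <- function(path) {
  img <- EBImage::readImage(path)
  a <- as.array(img)
  if (length(dim(a)) == 3L) {
    # RGB(A): luma conversion
    a <- 0.2126 * a[, , 1] + 0.7152 * a[, , 2] + 0.0722 * a[, , 3]
  }
  t(a)
}

#' Read an image volume
#'
#' Accepts a NIfTI file (`.nii` / `.nii.gz`; slice index = last axis), a
#' directory of 2-D grayscale PNG/TIFF slices (lexicographic filename
#' order), or an `.rds` file holding a 3-D array or list of matrices. RGB
#' inputs are converted to grayscale by luma weighting.
#'
#' @param path File or directory path.
#' @return List with `slices` (list of matrices), `shape`, `format` and,
#'   for stacks, `filenames`.
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("no such file or directory: ", path,
                               call. = FALSE)
  if (dir.exists(path)) {
    files <- sort(list.files(path, full.names = TRUE))
    files <- files[.is_image_file(files)]
    if (length(files) == 0L) stop("no PNG/TIFF slices in ", path,
                                  call. = FALSE)
    slices <- lapply(files, .read_slice_file)
    shp <- dim(slices[[1L]])
    for (i in seq_along(slices)) {
      if (!identical(dim(slices[[i]]), shp)) {
        stop("mixed slice shapes in ", path, " (", basename(files[i]), ")",
             call. = FALSE)
      }
    }
    return(list(slices = slices, shape = shp, format = "stack",
                filenames = basename(files)))
  }
  if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) {
    vol <- RNifti::readNifti(path)
    a <- as.array(vol)
    if (length(dim(a)) == 2L) a <- array(a, c(dim(a), 1L))
    if (length(dim(a)) != 3L) stop("expected a 2-D or 3-D NIfTI volume",
                                   call. = FALSE)
    slices <- lapply(seq_len(dim(a)[3L]), function(z) a[, , z])
    return(list(slices = slices, shape = dim(a)[1:2], format = "nifti"))
  }
  if (grepl("\\.rds$", path, ignore.case = TRUE)) {
    obj <- readRDS(path)
    slices <- .as_slices(obj)
    return(list(slices = slices, shape = dim(slices[[1L]]),
                format = "array"))
  }
  stop("unrecognized volume format: ", path, call. = FALSE)
}

#' Read a binary mask
#'
#' PNG/TIFF (any nonzero pixel is foreground) or `.rds` matrix.
#'
#' @param path File path.
#' @return Binary 0/1 matrix.
#' @export
read_mask <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (.is_image_file(path)) {
    return(.as_binary(.read_slice_file(path)))
  }
  if (grepl("\\.rds$", path, ignore.case = TRUE)) {
    return(.as_binary(readRDS(path)))
  }
  stop("unrecognized mask format: ", path, call. = FALSE)
}

#' Write a mask, or a sequence of masks, as PNG
#'
#' Masks are written single-channel, foreground 255, background 0;
#' [read_mask()] restores them exactly.
#'
#' @param mask Binary matrix.
#' @param path Output PNG path.
#' @export
write_mask <- function(mask, path) {
  EBImage::writeImage(t(.as_binary(mask)), path)
  invisible(path)
}

#' @param masks Named (by slice index) or unnamed list of binary masks.
#' @param dir Output directory (created if missing).
#' @param prefix Filename prefix; files are `<prefix>_<index>.png` with
#'   zero-padded indices.
#' @rdname write_mask
#' @export
write_masks <- function(masks, dir, prefix = "mask") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  nm <- names(masks)
  if (is.null(nm)) nm <- as.character(seq_along(masks))
  paths <- character(length(masks))
  for (i in seq_along(masks)) {
    paths[i] <- file.path(dir, sprintf("%s_%04d.png", prefix,
                                       as.integer(nm[i])))
    write_mask(masks[[i]], paths[i])
  }
  invisible(paths)
}

#' Write a volume
#'
#' NIfTI (`.nii` / `.nii.gz`, lossless for float data) or a PNG stack
#' directory (intensities clipped to [0, 255] and quantized to 16 bits).
#'
#' @param volume List of slice matrices or 3-D array.
#' @param path `.nii`/`.nii.gz` file, or a directory for a PNG stack.
#' @export
write_volume <- function(volume, path) {
  slices <- .as_slices(volume)
  if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) {
    a <- array(unlist(slices), c(dim(slices[[1L]]), length(slices)))
    RNifti::writeNifti(RNifti::asNifti(a), path)
  } else {
    if (!dir.exists(path)) dir.create(path, recursive = TRUE)
    for (z in seq_along(slices)) {
      m <- pmin(pmax(slices[[z]], 0), 255) / 255
      EBImage::writeImage(t(m), file.path(path, sprintf("slice_%04d.png", z)),
                          bits.per.sample = 16L)
    }
  }
  invisible(path)
}

#' Overlay a mask contour on a slice
#'
#' Quick base-graphics rendering of a slice with the mask boundary (and
#' optionally the ground truth) drawn as contour lines.
#'
#' @param image Numeric matrix, the slice.
#' @param mask Binary matrix, the segmentation.
#' @param truth Optional binary matrix, the gold standard.
#' @param main Plot title.
#' @export
plot_segmentation <- function(image, mask, truth = NULL, main = "") {
  h <- nrow(image); w <- ncol(image)
  graphics::image(seq_len(w), seq_len(h), t(image[h:1, ]),
                  col = grDevices::gray.colors(256, 0, 1), asp = 1,
                  xlab = "", ylab = "", axes = FALSE, main = main)
  graphics::contour(seq_len(w), seq_len(h), t(mask[h:1, ]), levels = 0.5,
                    add = TRUE, drawlabels = FALSE, col = "red", lwd = 2)
  if (!is.null(truth)) {
    graphics::contour(seq_len(w), seq_len(h), t(truth[h:1, ]), levels = 0.5,
                      add = TRUE, drawlabels = FALSE, col = "yellow",
                      lty = 2)
  }
  invisible(NULL)
}
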