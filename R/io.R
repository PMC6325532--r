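#' Image stacks
#'
#' A 3D grid of intensities with its pixel size: the common currency of
#' the pipeline. Data are stored `[row, column, slice]` with illumination
#' along image rows (left/right edges are the sheet entry sides).
#'
#' @param data numeric 3D array (or matrix, treated as one slice).
#' @param pixel_size pixel pitch (um).
#' @return object of class `image_stack`.
#' @export
image_stack <- function(data, pixel_size) {
  if (is.matrix(data)) data <- array(data, dim = c(dim(data), 1L))
  stopifnot(length(dim(data)) == 3, pixel_size > 0)
  structure(list(data = data, pixel_size = pixel_size),
            class = "image_stack")
}

#' @export
dim.image_stack <- function(x) dim(x$data)

# TIFF files store values scaled into [0, 1]; this is the count value
# that maps to 1.0, recorded in dataset manifests.
STACK_SCALE <- 65535

#' Read a single-channel TIFF stack
#'
#' Reads an 8/16-bit integer or 32-bit float grayscale multi-page TIFF
#' into an [image_stack()]. Pixel values are rescaled by `scale` (so
#' stacks written by [write_stack()] round-trip to counts). The pixel
#' size is taken from the file's x-resolution tag when present (assumed
#' pixels per cm), otherwise `pixel_size` must be given.
#'
#' @param path TIFF file.
#' @param pixel_size pixel pitch (um); required when the file carries no
#'   resolution tag.
#' @param scale count value mapping to 1.0 in the file.
#' @return an [image_stack()].
#' @export
read_stack <- function(path, pixel_size = NULL, scale = STACK_SCALE) {
  pages <- tiff::readTIFF(path, all = TRUE, info = TRUE)
  if (!length(pages)) stop("empty TIFF: ", path)
  first <- pages[[1]]
  if (length(dim(first)) == 3 && dim(first)[3] > 1) {
    stop("multi-channel TIFF not supported (", dim(first)[3],
         " samples per pixel): split channels into separate files: ", path)
  }
  bits <- attr(first, "bits.per.sample")
  if (!is.null(bits) && !bits %in% c(8L, 16L, 32L)) {
    stop("unsupported bit depth ", bits, " in ", path)
  }
  if (is.null(pixel_size)) {
    xres <- attr(first, "x.resolution")
    if (is.null(xres) || !is.finite(xres) || xres <= 0) {
      stop("missing field 'pixel_size': ", path,
           " carries no resolution tag; pass pixel_size explicitly")
    }
    pixel_size <- 1e4 / xres  # pixels per cm -> um per pixel
  }
  arr <- array(0, dim = c(dim(first)[1], dim(first)[2], length(pages)))
  for (k in seq_along(pages)) arr[, , k] <- pages[[k]]
  image_stack(arr * scale, pixel_size)
}

#' Write an [image_stack()] as a multi-page TIFF
#'
#' Counts are divided by `scale`, clipped to `[0, 1]`, and stored at the
#' requested bit depth (16-bit integer by default, so integer counts in
#' `[0, scale]` round-trip exactly).
#'
#' @param stack an [image_stack()] or 3D array.
#' @param path output file.
#' @param bits bits per sample (8, 16 or 32).
#' @param scale count value mapping to 1.0.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path, bits = 16L, scale = STACK_SCALE) {
  data <- if (inherits(stack, "image_stack")) stack$data else stack
  if (is.matrix(data)) data <- array(data, dim = c(dim(data), 1L))
  pages <- lapply(seq_len(dim(data)[3]), function(k) {
    clamp(data[, , k] / scale, 0, 1)
  })
  ok <- try(tiff::writeTIFF(pages, path, bits.per.sample = bits,
                            compression = "none"), silent = TRUE)
  if (inherits(ok, "try-error")) {
    stop("failed to write TIFF '", path, "': ", attr(ok, "condition")$message)
  }
  invisible(path)
}

# write a logical stack as 8-bit 0/255 TIFF
write_mask_stack <- function(mask, path) {
  data <- array(as.numeric(mask), dim = dim(mask))
  if (is.matrix(data)) data <- array(data, dim = c(dim(data), 1L))
  write_stack(data * 255, path, bits = 8L, scale = 255)
}

# read an 8-bit mask TIFF back to logical
read_mask_stack <- function(path) {
  s <- read_stack(path, pixel_size = 1, scale = 255)
  s$data > 127
}
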