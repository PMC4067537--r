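#' Multi-channel 3-D image field
#'
#' The unit of acquisition: one field of view holding one 3-D intensity
#' array per channel (dimensions z, y, x) plus voxel geometry and free-form
#' provenance metadata. All channels must share the same shape and hold
#' finite non-negative intensities.
#'
#' @param channels named list of 3-D numeric arrays (z, y, x).
#' @param voxel_size numeric `c(z=, xy=)` voxel pitch in nm.
#' @param metadata named list of provenance entries (source files, simulation
#'   config hash, session key, ...).
#' @return An `image_field` object.
#' @export
image_field <- function(channels, voxel_size = c(z = 200, xy = 65),
                        metadata = list()) {
  if (!length(channels) || is.null(names(channels)) ||
      any(!nzchar(names(channels))))
    stop("channels must be a non-empty named list")
  dims <- lapply(channels, dim)
  if (any(vapply(dims, length, 0L) != 3L))
    stop("each channel must be a 3-D array (z, y, x)")
  if (!all(vapply(dims, identical, TRUE, dims[[1]])))
    stop("all channels must share the same shape")
  for (nm in names(channels)) {
    ch <- channels[[nm]]
    if (!all(is.finite(ch))) stop("channel ", nm, " has non-finite values")
    if (min(ch) < 0) stop("channel ", nm, " has negative intensities")
  }
  structure(list(channels = channels,
                 voxel_size = unname_pair(voxel_size),
                 metadata = metadata),
            class = "image_field")
}

#' @export
print.image_field <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat(sprintf("image_field: %d channel(s) [%s], %d x %d x %d (z,y,x)\n",
              length(x$channels), paste(names(x$channels), collapse = ", "),
              d[1], d[2], d[3]))
  invisible(x)
}

field_dim <- function(field) dim(field$channels[[1]])

get_channel <- function(field, channel) {
  if (!channel %in% names(field$channels))
    stop("no channel '", channel, "' in field")
  field$channels[[channel]]
}

#' Read a multi-channel field from single-channel TIFF stacks
#'
#' Each path is a multi-page TIFF holding one channel's z-stack; pages
#' become z-planes. Pixel data are widened to double without rescaling
#' (integer grey levels are preserved exactly).
#'
#' @param paths character vector of TIFF files, one per channel.
#' @param channel_names names for the channels, same length as `paths`.
#' @param voxel_size,metadata passed to [image_field()].
#' @return An [image_field()].
#' @export
read_field <- function(paths, channel_names,
                       voxel_size = c(z = 200, xy = 65), metadata = list()) {
  stopifnot(length(paths) == length(channel_names), length(paths) >= 1L)
  chans <- setNames(vector("list", length(paths)), channel_names)
  for (i in seq_along(paths)) {
    if (!file.exists(paths[i])) stop("file not found: ", paths[i])
    pages <- tryCatch(tiff::readTIFF(paths[i], all = TRUE, as.is = TRUE),
                      error = function(e) stop("not a readable TIFF: ",
                                               paths[i]))
    if (!is.list(pages)) pages <- list(pages)
    shp <- dim(pages[[1]])
    if (any(!vapply(pages, function(p) identical(dim(p), shp), TRUE)))
      stop("mismatched page shapes in ", paths[i])
    arr <- array(0, dim = c(length(pages), shp))
    for (z in seq_along(pages)) arr[z, , ] <- as.numeric(pages[[z]])
    chans[[i]] <- arr
  }
  metadata$source_files <- paths
  image_field(chans, voxel_size, metadata)
}

#' Write a field as one multi-page TIFF per channel
#'
#' Writes 16-bit (or `bits`-bit) unsigned little-endian TIFFs named
#' `<channel>.tif`; values are rounded to integer grey levels and must fit
#' the bit depth. Lossless for integer-valued data within range.
#'
#' @param field an [image_field()].
#' @param out_dir output directory (created if needed).
#' @param bits bits per sample (8 or 16).
#' @return Named character vector of written paths, invisibly.
#' @export
write_field <- function(field, out_dir, bits = 16) {
  stopifnot(inherits(field, "image_field"))
  if (!length(field$channels)) stop("field has no channels")
  if (!bits %in% c(8L, 16L)) stop("bits must be 8 or 16")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  maxval <- 2^bits - 1
  paths <- character(0)
  for (nm in names(field$channels)) {
    arr <- round(field$channels[[nm]])
    if (max(arr) > maxval)
      stop("channel ", nm, " exceeds ", bits, "-bit range")
    pages <- lapply(seq_len(dim(arr)[1]),
                    function(z) arr[z, , ] / maxval)
    p <- file.path(out_dir, paste0(nm, ".tif"))
    tiff::writeTIFF(pages, p, bits.per.sample = bits)
    paths[nm] <- p
  }
  meta <- file.path(out_dir, "field_metadata.txt")
  writeLines(c(sprintf("voxel_z_nm = %g", field$voxel_size["z"]),
               sprintf("voxel_xy_nm = %g", field$voxel_size["xy"]),
               sprintf("channels = %s",
                       paste(names(field$channels), collapse = ","))),
             meta)
  invisible(paths)
}

#' Planar image with projection provenance
#'
#' A 2-D pixel array tagged with how it was derived (`single-plane`,
#' `sum-projection` or `max-projection`). Quantification operations accept
#' only single planes and sum projections; max projections are for display
#' and QC and are refused by the measurement path.
#'
#' @param pixels 2-D numeric matrix (y, x).
#' @param kind one of "single-plane", "sum-projection", "max-projection".
#' @param channel source channel name.
#' @param z_range integer (lo, hi) plane range (1-based) or single plane.
#' @return A `plane_image`.
#' @export
plane_image <- function(pixels, kind, channel = NA_character_,
                        z_range = NULL) {
  kind <- match.arg(kind,
                    c("single-plane", "sum-projection", "max-projection"))
  stopifnot(is.matrix(pixels))
  structure(list(pixels = pixels, kind = kind, channel = channel,
                 z_range = z_range),
            class = "plane_image")
}

#' @export
print.plane_image <- function(x, ...) {
  cat(sprintf("plane_image [%s] %s, %d x %d px, z %s\n", x$kind,
              x$channel, nrow(x$pixels), ncol(x$pixels),
              paste(x$z_range, collapse = "-")))
  invisible(x)
}

check_z_range <- function(field, z_range) {
  nz <- field_dim(field)[1]
  if (is.null(z_range)) z_range <- c(1L, nz)
  z_range <- as.integer(round(z_range))
  if (length(z_range) == 1L) z_range <- c(z_range, z_range)
  if (z_range[1] > z_range[2] || z_range[1] < 1L || z_range[2] > nz)
    stop("invalid z_range")
  z_range
}

#' Sum projection of a channel over a z-range
#'
#' Pixel-wise sum over the given planes ("sum-quick" projection). Total
#' intensity is conserved exactly: the sum over the projected image equals
#' the sum over the projected voxels.
#'
#' @param field an [image_field()].
#' @param channel channel name.
#' @param z_range integer (lo, hi), 1-based inclusive; NULL for the full
#'   stack.
#' @return A [plane_image()] of kind "sum-projection".
#' @export
sum_project <- function(field, channel, z_range = NULL) {
  z_range <- check_z_range(field, z_range)
  arr <- get_channel(field, channel)
  px <- colSums(arr[z_range[1]:z_range[2], , , drop = FALSE], dims = 1)
  plane_image(px, "sum-projection", channel, z_range)
}

#' Maximum projection of a channel over a z-range
#'
#' Pixel-wise maximum; display/QC only. The quantification path refuses
#' max projections.
#'
#' @inheritParams sum_project
#' @return A [plane_image()] of kind "max-projection".
#' @export
max_project <- function(field, channel, z_range = NULL) {
  z_range <- check_z_range(field, z_range)
  arr <- get_channel(field, channel)
  px <- Reduce(pmax, lapply(z_range[1]:z_range[2], function(z) arr[z, , ]))
  plane_image(px, "max-projection", channel, z_range)
}

#' Extract a single plane
#'
#' @param field an [image_field()].
#' @param channel channel name.
#' @param z plane index (1-based).
#' @return A [plane_image()] of kind "single-plane".
#' @export
single_plane <- function(field, channel, z) {
  z <- check_z_range(field, c(z, z))
  arr <- get_channel(field, channel)
  plane_image(arr[z[1], , ], "single-plane", channel, z)
}
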