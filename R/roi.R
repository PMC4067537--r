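#' Region of interest on a plane
#'
#' A 2-D boolean pixel mask tied to the plane geometry it was drawn on.
#' Must be non-empty and fully inside the plane (by construction the mask
#' matrix has the plane's dimensions).
#'
#' @param mask logical matrix (y, x); TRUE pixels belong to the ROI.
#' @return A `roi` object (logical matrix with class attribute).
#' @export
roi <- function(mask) {
  stopifnot(is.matrix(mask), is.logical(mask))
  if (!any(mask)) stop("ROI is empty")
  structure(mask, class = c("roi", "matrix"))
}

#' Disc-shaped ROI
#'
#' @param center numeric (y, x), 0-based pixel coordinates of the centre.
#' @param radius radius in pixels.
#' @param dim integer (ny, nx) plane dimensions.
#' @return A [roi()].
#' @export
roi_from_disc <- function(center, radius, dim) {
  yy <- matrix(0:(dim[1] - 1L), dim[1], dim[2])
  xx <- matrix(0:(dim[2] - 1L), dim[1], dim[2], byrow = TRUE)
  roi((yy - center[1])^2 + (xx - center[2])^2 <= radius^2)
}

roi_area <- function(r) sum(r)

roi_centroid <- function(r) {
  idx <- which(unclass(r), arr.ind = TRUE)
  c(y = mean(idx[, 1]) - 1, x = mean(idx[, 2]) - 1)  # 0-based
}

#' Run-length encode / decode an ROI mask
#'
#' Compact text form used in tabular outputs: `"ny,nx:start-length,..."`
#' over the column-major linearised mask.
#'
#' @param r a [roi()].
#' @param code a string produced by `roi_encode`.
#' @return `roi_encode`: a character scalar; `roi_decode`: a [roi()].
#' @export
roi_encode <- function(r) {
  v <- as.vector(unclass(r))
  rl <- rle(v)
  ends <- cumsum(rl$lengths)
  starts <- ends - rl$lengths + 1L
  keep <- rl$values
  paste0(nrow(r), ",", ncol(r), ":",
         paste(sprintf("%d-%d", starts[keep], rl$lengths[keep]),
               collapse = ","))
}

#' @rdname roi_encode
#' @export
roi_decode <- function(code) {
  parts <- strsplit(code, ":", fixed = TRUE)[[1]]
  dm <- as.integer(strsplit(parts[1], ",")[[1]])
  m <- matrix(FALSE, dm[1], dm[2])
  if (length(parts) > 1L && nzchar(parts[2])) {
    for (seg in strsplit(parts[2], ",")[[1]]) {
      sl <- as.integer(strsplit(seg, "-")[[1]])
      m[sl[1]:(sl[1] + sl[2] - 1L)] <- TRUE
    }
  }
  roi(m)
}

#' Import externally drawn ROIs from a label-mask TIFF
#'
#' Reads a single-page TIFF whose integer pixel values label regions
#' (0 = background, 1..k = ROIs) — the interchange format written by most
#' interactive ROI tools — and returns one [roi()] per label.
#'
#' @param path TIFF file with integer labels.
#' @return Named list of [roi()]s ("roi1", "roi2", ...); labels absent from
#'   the image are skipped.
#' @export
read_roi_labels <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lab <- tiff::readTIFF(path, as.is = TRUE)
  if (length(dim(lab)) > 2L) stop("label mask must be single-channel")
  out <- list()
  for (id in sort(unique(lab[lab > 0]))) {
    out[[paste0("roi", id)]] <- roi(lab == id)
  }
  out
}

check_plane_roi <- function(plane, r, op = "quantification") {
  stopifnot(inherits(plane, "plane_image"))
  if (plane$kind == "max-projection")
    stop(op, " on a max projection is not supported; use a single plane ",
         "or sum projection")
  if (!identical(dim(unclass(r)), dim(plane$pixels)))
    stop("ROI does not match plane dimensions")
  invisible(TRUE)
}

#' Sum intensity inside an ROI
#'
#' @param plane a [plane_image()] of kind single-plane or sum-projection.
#' @param r a [roi()] on that plane.
#' @return The sum of pixel intensities under the mask.
#' @export
sum_intensity <- function(plane, r) {
  check_plane_roi(plane, r)
  sum(plane$pixels[unclass(r)])
}

# compass directions in deterministic tie-break order
DIRECTIONS <- list(N = c(-1, 0), NE = c(-1, 1), E = c(0, 1), SE = c(1, 1),
                   S = c(1, 0), SW = c(1, -1), W = c(0, -1), NW = c(-1, -1))

direction_offset <- function(dir, shift_px) {
  u <- DIRECTIONS[[dir]]
  round(shift_px * u / sqrt(sum(u^2)))
}

shift_roi_idx <- function(r, offset) {
  idx <- which(unclass(r), arr.ind = TRUE)
  idx[, 1] <- idx[, 1] + offset[1]
  idx[, 2] <- idx[, 2] + offset[2]
  if (any(idx[, 1] < 1L) || any(idx[, 1] > nrow(r)) ||
      any(idx[, 2] < 1L) || any(idx[, 2] > ncol(r))) return(NULL)
  idx
}

#' Shifted-ROI background measurement
#'
#' Implements the manual background protocol: the same ROI is translated by
#' `shift_px` pixels and its sum intensity is taken as background. The
#' translated ROI is evaluated in the 8 compass directions (diagonal
#' offsets are scaled so the translation magnitude stays ~`shift_px`);
#' candidates pushed off the plane are discarded. Among the rest the
#' candidate overlapping the fewest `forbidden` pixels wins; ties go to the
#' lowest sum, then to the fixed direction order N, NE, E, SE, S, SW, W,
#' NW. If the chosen candidate still touches a forbidden mask the
#' measurement is flagged `background-overlap`.
#'
#' @param plane a [plane_image()].
#' @param r a [roi()].
#' @param shift_px integer translation in pixels; the protocol allows 5-10.
#' @param forbidden optional list of logical masks (foreground of other
#'   objects) the background ROI should avoid.
#' @return A list: `value` (background sum), `shift_used` (dy, dx),
#'   `direction`, `flags` (character vector), and `candidates` (a data
#'   frame of all evaluated positions, for QC).
#' @export
background_intensity <- function(plane, r, shift_px = 10, forbidden = NULL) {
  check_plane_roi(plane, r, "background measurement")
  if (shift_px < 5 || shift_px > 10)
    stop("shift_px must be between 5 and 10 pixels")
  forb <- if (is.null(forbidden)) NULL else
    Reduce(`|`, lapply(forbidden, unclass))
  cand <- data.frame(direction = names(DIRECTIONS), dy = NA_integer_,
                     dx = NA_integer_, value = NA_real_,
                     overlap = NA_integer_, stringsAsFactors = FALSE)
  for (k in seq_along(DIRECTIONS)) {
    off <- direction_offset(cand$direction[k], shift_px)
    idx <- shift_roi_idx(r, off)
    if (is.null(idx)) next
    cand$dy[k] <- off[1]; cand$dx[k] <- off[2]
    cand$value[k] <- sum(plane$pixels[idx])
    cand$overlap[k] <- if (is.null(forb)) 0L else sum(forb[idx])
  }
  valid <- which(!is.na(cand$value))
  if (!length(valid)) stop("no valid background position")
  ord <- valid[order(cand$overlap[valid], cand$value[valid], valid)]
  best <- ord[1]
  flags <- character(0)
  if (cand$overlap[best] > 0L) flags <- "background-overlap"
  list(value = cand$value[best],
       shift_used = c(dy = cand$dy[best], dx = cand$dx[best]),
       direction = cand$direction[best],
       flags = flags, candidates = cand)
}

#' Net (background-subtracted) ROI intensity
#'
#' Combines [sum_intensity()] and [background_intensity()]:
#' `net = sum_value - background_value`, exactly. Negative nets are
#' preserved (not clamped) and flagged `negative-net` so cohort statistics
#' stay unbiased.
#'
#' @inheritParams background_intensity
#' @return An `intensity_measurement`: list(sum_value, background_value,
#'   net, shift_used, direction, flags).
#' @export
net_intensity <- function(plane, r, shift_px = 10, forbidden = NULL) {
  s <- sum_intensity(plane, r)
  b <- background_intensity(plane, r, shift_px, forbidden)
  flags <- b$flags
  net <- s - b$value
  if (net < 0) flags <- c(flags, "negative-net")
  structure(list(sum_value = s, background_value = b$value, net = net,
                 shift_used = b$shift_used, direction = b$direction,
                 flags = flags),
            class = "intensity_measurement")
}

#' @export
print.intensity_measurement <- function(x, ...) {
  cat(sprintf("sum %.4g - background %.4g = net %.4g (%s%s)\n",
              x$sum_value, x$background_value, x$net, x$direction,
              if (length(x$flags)) paste0("; ", paste(x$flags,
                                                      collapse = ",")) else ""))
  invisible(x)
}

#' Intensity line profile
#'
#' Samples each plane by bilinear interpolation along the segment from `p0`
#' to `p1` at unit-pixel spacing; the series has `ceiling(|p1 - p0|) + 1`
#' points.
#'
#' @param planes a [plane_image()] or named list of them (one per channel).
#' @param p0,p1 numeric (y, x) endpoints, 0-based pixel coordinates.
#' @return A data frame with `distance` and one intensity column per plane.
#' @export
line_profile <- function(planes, p0, p1) {
  if (inherits(planes, "plane_image")) planes <- list(intensity = planes)
  len <- sqrt(sum((p1 - p0)^2))
  n <- as.integer(ceiling(len)) + 1L
  t <- if (n == 1L) 0 else seq(0, 1, length.out = n)
  ys <- p0[1] + t * (p1[1] - p0[1])
  xs <- p0[2] + t * (p1[2] - p0[2])
  out <- data.frame(distance = t * len)
  for (nm in names(planes)) {
    px <- planes[[nm]]$pixels
    if (any(ys < 0 | ys > nrow(px) - 1 | xs < 0 | xs > ncol(px) - 1))
      stop("profile endpoints outside plane")
    out[[nm]] <- bilinear_sample(px, ys, xs)
  }
  out
}

# bilinear interpolation at 0-based fractional (y, x)
bilinear_sample <- function(px, ys, xs) {
  ny <- nrow(px); nx <- ncol(px)
  i0 <- pmin(floor(ys), ny - 2); i0 <- pmax(i0, 0)
  j0 <- pmin(floor(xs), nx - 2); j0 <- pmax(j0, 0)
  fy <- ys - i0; fx <- xs - j0
  v00 <- px[cbind(i0 + 1, j0 + 1)]
  v01 <- px[cbind(i0 + 1, j0 + 2)]
  v10 <- px[cbind(i0 + 2, j0 + 1)]
  v11 <- px[cbind(i0 + 2, j0 + 2)]
  (1 - fy) * ((1 - fx) * v00 + fx * v01) + fy * ((1 - fx) * v10 + fx * v11)
}
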