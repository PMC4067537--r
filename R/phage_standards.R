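PHAGE_KB <- c(lambda = 48, P1 = 90, T4 = 168)

#' Select the in-focus plane for a region
#'
#' The measurement plane for a spot is the z-plane maximising the total
#' intensity inside the candidate region; ties break to the lower index.
#'
#' @param field an [image_field()].
#' @param channel channel name.
#' @param region a [roi()] mask (plane-sized) delimiting the candidate area.
#' @return 1-based plane index.
#' @export
select_focus_plane <- function(field, channel, region) {
  arr <- get_channel(field, channel)
  m <- unclass(region)
  stopifnot(any(m))
  idx <- which(m, arr.ind = TRUE)
  rows <- range(idx[, 1]); cols <- range(idx[, 2])
  sub <- arr[, rows[1]:rows[2], cols[1]:cols[2], drop = FALSE]
  msub <- m[rows[1]:rows[2], cols[1]:cols[2], drop = FALSE]
  sums <- vapply(seq_len(dim(sub)[1]),
                 function(z) sum(sub[z, , ][msub]), 0)
  which.max(sums)  # first maximum -> lower index on ties
}

#' Detect spot ROIs on a plane
#'
#' Automates the hand-drawn "ROI covering the spot area": the plane is
#' thresholded at `background median + k_mad * MAD`, with a floor of
#' `floor_frac * (max - median)` so the rule stays meaningful on noise-free
#' synthetic planes; connected components within the area bounds are kept,
#' components touching the plane border are dropped with a QC note, and
#' each surviving component is dilated by `dilate_px` to form its ROI.
#'
#' @param plane a [plane_image()] (not a max projection).
#' @param k_mad MAD multiplier of the threshold (default 5).
#' @param min_area,max_area component area bounds in pixels.
#' @param dilate_px morphological dilation radius applied to components.
#' @param floor_frac threshold floor as a fraction of (plane max - median).
#' @return A list of [roi()] objects sorted by centroid (y, then x), each
#'   with attributes `centroid` (0-based y, x), `area` (pre-dilation) and
#'   `component` (undilated mask). Attribute `qc` on the list records
#'   dropped border components. Empty list when nothing is found.
#' @export
detect_spots <- function(plane, k_mad = 5, min_area = 4, max_area = 400,
                         dilate_px = 2, floor_frac = 0.02) {
  check_plane_roi_free(plane)
  px <- plane$pixels
  if (min(px) < 0) stop("plane must be non-negative")
  bg <- median(px)
  thr <- bg + max(k_mad * mad(px), floor_frac * (max(px) - bg))
  bw <- matrix(as.numeric(px > thr), nrow(px), ncol(px))
  lab <- EBImage::bwlabel(bw)
  nlab <- max(lab)
  if (nlab == 0) return(structure(list(), qc = character(0)))
  qc <- character(0)
  out <- list()
  brush <- EBImage::makeBrush(2L * as.integer(dilate_px) + 1L, "disc")
  for (id in seq_len(nlab)) {
    comp <- lab == id
    idx <- which(comp, arr.ind = TRUE)
    if (any(idx[, 1] %in% c(1L, nrow(px))) ||
        any(idx[, 2] %in% c(1L, ncol(px)))) {
      qc <- c(qc, sprintf("component %d touches border; dropped", id))
      next
    }
    area <- nrow(idx)
    if (area < min_area || area > max_area) next
    mask <- if (dilate_px > 0) {
      # dilate on a padded bounding box, not the whole plane
      pad <- as.integer(dilate_px) + 1L
      rlo <- max(1L, min(idx[, 1]) - pad); rhi <- min(nrow(px), max(idx[, 1]) + pad)
      clo <- max(1L, min(idx[, 2]) - pad); chi <- min(ncol(px), max(idx[, 2]) + pad)
      sub <- matrix(0, rhi - rlo + 1L, chi - clo + 1L)
      sub[cbind(idx[, 1] - rlo + 1L, idx[, 2] - clo + 1L)] <- 1
      subd <- EBImage::dilate(sub, brush) > 0
      m <- matrix(FALSE, nrow(px), ncol(px))
      m[rlo:rhi, clo:chi] <- subd
      m
    } else comp
    r <- roi(mask)
    attr(r, "centroid") <- c(y = mean(idx[, 1]) - 1, x = mean(idx[, 2]) - 1)
    attr(r, "area") <- area
    attr(r, "component") <- comp
    out[[length(out) + 1L]] <- r
  }
  if (length(out)) {
    cents <- t(vapply(out, attr, c(y = 0, x = 0), "centroid"))
    out <- out[order(cents[, "y"], cents[, "x"])]
  }
  structure(out, qc = qc)
}

check_plane_roi_free <- function(plane) {
  stopifnot(inherits(plane, "plane_image"))
  if (plane$kind == "max-projection")
    stop("detection for quantification runs on single planes or sum ",
         "projections, not max projections")
  invisible(TRUE)
}

#' Detect and measure phage standard spots in a field
#'
#' Runs spot detection on the full-stack DAPI sum projection, drops
#' GFP-positive detections (kinetochores are not standards) and any
#' component outside the area bounds (chromatin masses), records each
#' spot's focus plane, and measures its net DAPI intensity with the
#' shifted-ROI background protocol, using every other detection as a
#' forbidden region for background placement.
#'
#' By default spots are measured on the sum projection so that the
#' measured net equals the object's whole integrated intensity, the same
#' quantity the kinetochore envelope measurement integrates; this keeps the
#' standard curve transferable. `measure_on = "focus-plane"` instead
#' measures each spot on its single in-focus plane, mirroring the manual
#' protocol literally (the recovered slope then depends on each spot's
#' sub-plane z-position).
#'
#' @param field an [image_field()] with DAPI and GFP channels.
#' @param dapi,gfp channel names.
#' @param shift_px background translation in pixels (5-10).
#' @param measure_on "projection" (default) or "focus-plane".
#' @param detect_params named list overriding [detect_spots()] defaults.
#' @return A list with `spots` (data frame: spot_id, z, y, x, area, sum,
#'   background, net, flags), `rois` (list of [roi()]s), and `qc` notes.
#' @export
measure_standards <- function(field, dapi = "DAPI", gfp = "GFP",
                              shift_px = 10,
                              measure_on = c("projection", "focus-plane"),
                              detect_params = list()) {
  measure_on <- match.arg(measure_on)
  proj <- sum_project(field, dapi)
  spots <- do.call(detect_spots, c(list(plane = proj), detect_params))
  qc <- attr(spots, "qc")

  gfp_mask <- NULL
  if (gfp %in% names(field$channels)) {
    gproj <- sum_project(field, gfp)
    gspots <- detect_spots(gproj, max_area = 5000)
    if (length(gspots))
      gfp_mask <- Reduce(`|`, lapply(gspots, unclass))
  }

  keep <- rep(TRUE, length(spots))
  for (i in seq_along(spots)) {
    if (!is.null(gfp_mask) && any(gfp_mask & unclass(spots[[i]]))) {
      keep[i] <- FALSE
      qc <- c(qc, sprintf("spot at (%.0f,%.0f) is GFP-positive; excluded",
                          attr(spots[[i]], "centroid")["y"],
                          attr(spots[[i]], "centroid")["x"]))
    }
  }
  spots <- spots[keep]
  n <- length(spots)
  if (n == 0)
    return(list(spots = empty_spot_table(), rois = list(), qc = qc))

  rows <- vector("list", n)
  for (i in seq_len(n)) {
    r <- spots[[i]]
    z <- select_focus_plane(field, dapi, r)
    plane <- if (measure_on == "projection") proj else
      single_plane(field, dapi, z)
    forbidden <- c(lapply(spots[-i], unclass),
                   if (!is.null(gfp_mask)) list(gfp_mask))
    m <- net_intensity(plane, r, shift_px = shift_px, forbidden = forbidden)
    cent <- attr(r, "centroid")
    rows[[i]] <- data.frame(
      spot_id = sprintf("spot%02d", i), z = z,
      y = cent[["y"]], x = cent[["x"]], area = attr(r, "area"),
      sum = m$sum_value, background = m$background_value, net = m$net,
      flags = paste(m$flags, collapse = ";"), stringsAsFactors = FALSE)
  }
  list(spots = do.call(rbind, rows), rois = spots, qc = qc)
}

empty_spot_table <- function() {
  data.frame(spot_id = character(0), z = integer(0), y = numeric(0),
             x = numeric(0), area = numeric(0), sum = numeric(0),
             background = numeric(0), net = numeric(0),
             flags = character(0), stringsAsFactors = FALSE)
}

#' Assign phage spots to the lambda / P1 / T4 classes
#'
#' Clusters net intensities with 1-D k-means (k = 3, deterministic
#' initialisation at the 1/6, 3/6 and 5/6 quantiles, Lloyd iterations);
#' clusters ordered by ascending mean become lambda, P1, T4. A QC check
#' requires the pairwise cluster-mean ratios to match the genome-size
#' ratios 48:90:168 within `ratio_tol`; spots in offending clusters are
#' flagged unassigned. With a ground-truth manifest
#' (`manifest` argument) assignment instead matches each spot to the
#' nearest manifest object (known-identity mode, used in recovery tests).
#'
#' @param spots spot data frame from [measure_standards()].
#' @param ratio_tol relative tolerance on cluster-mean ratios (default
#'   0.25).
#' @param manifest optional simulator manifest for known-identity mode.
#' @param max_match_dist maximum centroid-to-truth distance (px) in
#'   known-identity mode.
#' @return The spot data frame with an `assigned_class` column (one of
#'   lambda, P1, T4, unassigned).
#' @export
assign_classes <- function(spots, ratio_tol = 0.25, manifest = NULL,
                           max_match_dist = 5) {
  if (!is.null(manifest)) {
    ph <- manifest[manifest$class %in% names(PHAGE_KB), ]
    spots$assigned_class <- "unassigned"
    for (i in seq_len(nrow(spots))) {
      d <- sqrt((ph$y - spots$y[i])^2 + (ph$x - spots$x[i])^2)
      if (length(d) && min(d) <= max_match_dist)
        spots$assigned_class[i] <- ph$class[which.min(d)]
    }
    return(spots)
  }
  pos <- spots$net > 0
  if (sum(pos) < 3)
    stop("underdetermined: need at least 3 spots with positive net intensity")
  net <- spots$net[pos]
  centers <- quantile(net, c(1, 3, 5) / 6, names = FALSE)
  km <- tryCatch(
    kmeans(net, centers = matrix(centers, ncol = 1), iter.max = 100,
           algorithm = "Lloyd"),
    error = function(e) NULL)
  if (is.null(km) || length(unique(km$cluster)) < 3)
    stop("incomplete standard set: could not resolve three phage classes")
  ord <- order(km$centers)
  rank_of <- match(km$cluster, ord)      # 1 = dimmest cluster
  means <- sort(as.vector(km$centers))
  # pairwise ratio QC against 48:90:168
  expect <- c(PHAGE_KB[["P1"]] / PHAGE_KB[["lambda"]],
              PHAGE_KB[["T4"]] / PHAGE_KB[["lambda"]],
              PHAGE_KB[["T4"]] / PHAGE_KB[["P1"]])
  got <- c(means[2] / means[1], means[3] / means[1], means[3] / means[2])
  pairs <- list(c(1, 2), c(1, 3), c(2, 3))
  bad <- rep(FALSE, 3)
  for (k in 1:3) {
    if (abs(got[k] / expect[k] - 1) > ratio_tol)
      bad[pairs[[k]]] <- TRUE
  }
  cls <- names(PHAGE_KB)[rank_of]
  cls[bad[rank_of]] <- "unassigned"
  spots$assigned_class <- "unassigned"
  spots$assigned_class[pos] <- cls
  if (!all(names(PHAGE_KB) %in% spots$assigned_class))
    stop("incomplete standard set: not all three phage classes represented")
  spots
}

#' Build standard points from assigned spots
#'
#' Maps assigned classes to genome sizes (lambda 48, P1 90, T4 168 kb);
#' unassigned spots are excluded with a QC note.
#'
#' @param spots spot data frame with an `assigned_class` column.
#' @return A data frame of standard points: genome_kb, net_intensity,
#'   spot_id; attribute `qc` lists exclusions.
#' @export
make_standard_points <- function(spots) {
  if (!nrow(spots))
    return(structure(data.frame(genome_kb = numeric(0),
                                net_intensity = numeric(0),
                                spot_id = character(0)), qc = character(0)))
  if (is.null(spots$assigned_class)) stop("spots are not assigned")
  keep <- spots$assigned_class %in% names(PHAGE_KB)
  qc <- if (any(!keep))
    sprintf("%d unassigned spot(s) excluded from the standard set",
            sum(!keep)) else character(0)
  structure(data.frame(genome_kb = unname(PHAGE_KB[spots$assigned_class[keep]]),
                       net_intensity = spots$net[keep],
                       spot_id = spots$spot_id[keep],
                       stringsAsFactors = FALSE),
            qc = qc)
}
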