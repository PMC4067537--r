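#' Segment a kinetochore's GFP envelope
#'
#' Reproduces "a ROI covering the area of the pulled centromere, selected
#' on the GFP image": a window (default 31 x 31 px, full z) is cropped
#' around the seed, the GFP sum projection of the window is thresholded at
#' `threshold_frac` of (local max - local background median), the connected
#' component containing the seed is kept and dilated by `dilate_px`, and
#' the z-range is the contiguous run of planes (around the brightest) where
#' the component's GFP exceeds the plane-wise local background.
#'
#' @param field an [image_field()].
#' @param seed_point numeric (y, x) or (z, y, x), 0-based voxel coordinates
#'   near the kinetochore centre.
#' @param gfp_channel GFP channel name.
#' @param window odd window edge length in px.
#' @param threshold_frac fraction of the background-corrected local peak
#'   (default 0.5, i.e. half-max).
#' @param dilate_px dilation applied to the component (default 1).
#' @param voxel_mask also build a voxel-level 3-D envelope (GFP voxels
#'   above the half-max threshold inside the component prism); downstream
#'   measurement then integrates DAPI over that mask instead of the
#'   projected ROI. Sensitivity-analysis mode; the 2-D projected envelope
#'   remains the default measured quantity.
#' @return An `envelope` object: `roi` (plane-sized [roi()]), `z_range`
#'   (lo, hi), `centroid` (0-based y, x), `window` (row/col 1-based
#'   ranges), `flags` ("envelope-truncated" if the component touches the
#'   window border), and with `voxel_mask = TRUE` a `mask3d` logical array
#'   (z within z_range, window rows, window cols).
#' @export
segment_envelope <- function(field, seed_point, gfp_channel = "GFP",
                             window = 31, threshold_frac = 0.5,
                             dilate_px = 1, voxel_mask = FALSE) {
  arr <- get_channel(field, gfp_channel)
  d <- dim(arr)
  sp <- as.numeric(seed_point)
  if (length(sp) == 3L) sp <- sp[2:3]
  sy <- as.integer(round(sp[1])) + 1L  # 1-based row
  sx <- as.integer(round(sp[2])) + 1L
  if (sy < 1L || sy > d[2] || sx < 1L || sx > d[3])
    stop("seed_point outside field")
  half <- (as.integer(window) - 1L) %/% 2L
  rlo <- max(1L, sy - half); rhi <- min(d[2], sy + half)
  clo <- max(1L, sx - half); chi <- min(d[3], sx + half)
  crop <- arr[, rlo:rhi, clo:chi, drop = FALSE]
  projw <- colSums(crop, dims = 1)

  bg_med <- median(projw)
  pk <- max(projw)
  if (pk <= bg_med) stop("no GFP signal at seed point")
  thr <- bg_med + threshold_frac * (pk - bg_med)
  bw <- matrix(as.numeric(projw > thr), nrow(projw), ncol(projw))
  lab <- EBImage::bwlabel(bw)
  sid <- lab[sy - rlo + 1L, sx - clo + 1L]
  if (sid == 0) stop("no GFP signal at seed point")
  comp <- lab == sid
  flags <- character(0)
  cidx <- which(comp, arr.ind = TRUE)
  if (any(cidx[, 1] %in% c(1L, nrow(comp))) ||
      any(cidx[, 2] %in% c(1L, ncol(comp))))
    flags <- "envelope-truncated"

  mask_w <- if (dilate_px > 0) {
    brush <- EBImage::makeBrush(2L * as.integer(dilate_px) + 1L, "disc")
    EBImage::dilate(matrix(as.numeric(comp), nrow(comp), ncol(comp)),
                    brush) > 0
  } else comp

  # plane-wise z support of the component, contiguous around the maximum
  area <- sum(comp)
  s_z <- vapply(seq_len(d[1]), function(z) sum(crop[z, , ][comp]), 0)
  b_z <- vapply(seq_len(d[1]),
                function(z) median(crop[z, , ][!mask_w]) * area, 0)
  above <- s_z > b_z
  zmax <- which.max(s_z)
  zlo <- zmax
  while (zlo > 1L && above[zlo - 1L]) zlo <- zlo - 1L
  zhi <- zmax
  while (zhi < d[1] && above[zhi + 1L]) zhi <- zhi + 1L

  mask <- matrix(FALSE, d[2], d[3])
  mask[rlo:rhi, clo:chi] <- mask_w
  cent <- c(y = mean(cidx[, 1]) + rlo - 2, x = mean(cidx[, 2]) + clo - 2)

  mask3d <- NULL
  if (voxel_mask) {
    # voxel threshold at threshold_frac of the background-corrected peak
    # voxel, restricted to the dilated component prism and the z-range
    bg_vox <- median(crop)
    thr3 <- bg_vox + threshold_frac * (max(crop) - bg_vox)
    mask3d <- array(FALSE, dim = c(zhi - zlo + 1L, nrow(mask_w),
                                   ncol(mask_w)))
    for (z in zlo:zhi)
      mask3d[z - zlo + 1L, , ] <- (crop[z, , ] > thr3) & mask_w
    if (!any(mask3d)) mask3d <- NULL
  }

  structure(list(roi = roi(mask), z_range = c(zlo, zhi), centroid = cent,
                 window = list(rows = c(rlo, rhi), cols = c(clo, chi)),
                 seed = sp, flags = flags, mask3d = mask3d),
            class = "envelope")
}

#' @export
print.envelope <- function(x, ...) {
  cat(sprintf("envelope: %d px at (%.1f, %.1f), z %d-%d%s\n",
              roi_area(x$roi), x$centroid["y"], x$centroid["x"],
              x$z_range[1], x$z_range[2],
              if (length(x$flags)) paste0(" [", paste(x$flags,
                                                      collapse = ","), "]")
              else ""))
  invisible(x)
}

# local GFP total by window photometry on the full-z projection:
# inner box sum minus (inner area x median of an outer frame)
gfp_total_local <- function(field, gfp_channel, centroid,
                            inner_half = 16L, outer_half = 20L) {
  gproj <- sum_project(field, gfp_channel)
  px <- gproj$pixels
  cy <- as.integer(round(centroid[["y"]])) + 1L
  cx <- as.integer(round(centroid[["x"]])) + 1L
  ri <- c(max(1L, cy - inner_half), min(nrow(px), cy + inner_half))
  ci <- c(max(1L, cx - inner_half), min(ncol(px), cx + inner_half))
  ro <- c(max(1L, cy - outer_half), min(nrow(px), cy + outer_half))
  co <- c(max(1L, cx - outer_half), min(ncol(px), cx + outer_half))
  inner <- px[ri[1]:ri[2], ci[1]:ci[2]]
  outer <- px[ro[1]:ro[2], co[1]:co[2]]
  frame <- outer
  frame[(ri[1] - ro[1] + 1):(ri[2] - ro[1] + 1),
        (ci[1] - co[1] + 1):(ci[2] - co[1] + 1)] <- NA
  bg_px <- median(frame, na.rm = TRUE)
  sum(inner) - length(inner) * bg_px
}

#' Measure one kinetochore and convert to kilobases
#'
#' The envelope ROI is applied to the DAPI sum projection over the
#' envelope's z-range; net intensity uses the shifted-ROI background
#' protocol with `forbidden` masks (other objects, chromatin) steering the
#' background placement. The net is then divided by the envelope
#' completeness factor and converted to kb by inverse prediction from the
#' session's standard curve.
#'
#' The completeness factor is the fraction of the kinetochore's total GFP
#' captured by the very same measurement (same envelope, same z-range, same
#' background shift) relative to the local GFP total. Because the DAPI and
#' GFP signals of one kinetochore share the same spatial profile, this
#' factor cancels both the envelope's truncation of the blob and the
#' contamination of the nearby background ROI by the blob's own tail,
#' making the measurement comparable with the near-complete apertures used
#' for the point-like phage standards. `completeness = FALSE` reverts to
#' the raw protocol.
#'
#' @param field an [image_field()].
#' @param envelope an `envelope` from [segment_envelope()].
#' @param fit the session's `calibration_fit`.
#' @param shift_px background translation (5-10 px).
#' @param forbidden optional list of logical masks to keep the background
#'   ROI away from.
#' @param completeness apply the GFP completeness correction (default TRUE).
#' @param level,interval interval options passed to [predict_dna()].
#' @param dapi,gfp channel names.
#' @return A `kinetochore_record`: measurement (an intensity_measurement),
#'   net_corrected, completeness, estimate (one-row data frame from
#'   [predict_dna()]), z_range, envelope, flags.
#' @export
measure_kinetochore <- function(field, envelope, fit, shift_px = 10,
                                forbidden = NULL, completeness = TRUE,
                                level = 0.95, interval = "delta",
                                dapi = "DAPI", gfp = "GFP") {
  stopifnot(inherits(envelope, "envelope"),
            inherits(fit, "calibration_fit"))
  zr <- envelope$z_range

  # work on a local crop: every ingredient (ROI, shifted background, local
  # GFP photometry window) lives within the envelope window plus a margin
  d <- field_dim(field)
  margin <- as.integer(ceiling(shift_px)) + 30L
  rlo <- max(1L, envelope$window$rows[1] - margin)
  rhi <- min(d[2], envelope$window$rows[2] + margin)
  clo <- max(1L, envelope$window$cols[1] - margin)
  chi <- min(d[3], envelope$window$cols[2] + margin)
  subfield <- image_field(
    lapply(field$channels, function(a) a[, rlo:rhi, clo:chi, drop = FALSE]),
    voxel_size = field$voxel_size, metadata = field$metadata)
  sub_roi <- roi(unclass(envelope$roi)[rlo:rhi, clo:chi, drop = FALSE])
  sub_forbidden <- if (is.null(forbidden)) NULL else
    lapply(forbidden, function(mk) mk[rlo:rhi, clo:chi, drop = FALSE])
  sub_centroid <- c(y = envelope$centroid[["y"]] - (rlo - 1),
                    x = envelope$centroid[["x"]] - (clo - 1))

  dproj <- sum_project(subfield, dapi, zr)
  m <- net_intensity(dproj, sub_roi, shift_px = shift_px,
                     forbidden = sub_forbidden)

  sub_dim <- dim(subfield$channels[[dapi]])
  wr <- (envelope$window$rows[1]:envelope$window$rows[2]) - rlo + 1L
  wc <- (envelope$window$cols[1]:envelope$window$cols[2]) - clo + 1L
  vox_ok <- !is.null(envelope$mask3d) &&
    min(wr) + m$shift_used[["dy"]] >= 1L &&
    max(wr) + m$shift_used[["dy"]] <= sub_dim[2] &&
    min(wc) + m$shift_used[["dx"]] >= 1L &&
    max(wc) + m$shift_used[["dx"]] <= sub_dim[3]
  if (!is.null(envelope$mask3d) && !vox_ok)
    m$flags <- c(m$flags, "voxel-mask-unavailable")
  if (vox_ok) {
    # voxel-envelope mode: integrate over the 3-D GFP mask instead of the
    # projected ROI, with the background mask translated in-plane by the
    # same offset the projected measurement chose
    M <- array(FALSE, dim = sub_dim)
    M[zr[1]:zr[2], wr, wc] <- envelope$mask3d
    Ms <- array(FALSE, dim = dim(M))
    Ms[, wr + m$shift_used[["dy"]], wc + m$shift_used[["dx"]]] <-
      M[, wr, wc]
    vox_net <- function(ch) {
      a <- subfield$channels[[ch]]
      sum(a[M]) - sum(a[Ms])
    }
    s3 <- sum(subfield$channels[[dapi]][M])
    b3 <- sum(subfield$channels[[dapi]][Ms])
    m$sum_value <- s3
    m$background_value <- b3
    m$net <- s3 - b3
    m$flags <- setdiff(m$flags, "negative-net")
    if (m$net < 0) m$flags <- c(m$flags, "negative-net")
  }

  flags <- union(envelope$flags, m$flags)
  f <- 1
  if (completeness) {
    if (vox_ok) {
      g_net <- vox_net(gfp)
    } else {
      gproj <- sum_project(subfield, gfp, zr)
      g_sum <- sum_intensity(gproj, sub_roi)
      sh_idx <- shift_roi_idx(sub_roi, m$shift_used)
      g_bg <- sum(gproj$pixels[sh_idx])
      g_net <- g_sum - g_bg
    }
    g_total <- gfp_total_local(subfield, gfp, sub_centroid)
    f <- g_net / g_total
    if (!is.finite(f) || f <= 0.05 || f > 1.5) {
      flags <- union(flags, "completeness-failed")
      f <- 1
    }
  }
  net_corr <- m$net / f
  est <- predict_dna(fit, net_corr, level = level, interval = interval)
  if (nzchar(est$flags)) flags <- union(flags, strsplit(est$flags, ";")[[1]])
  structure(list(measurement = m, net_corrected = net_corr,
                 completeness = f, estimate = est, z_range = zr,
                 envelope = envelope, flags = flags),
            class = "kinetochore_record")
}

#' @export
print.kinetochore_record <- function(x, ...) {
  cat(sprintf(
    "kinetochore: net %.4g (completeness %.3f) -> %.1f kb [%.1f, %.1f]%s\n",
    x$measurement$net, x$completeness, x$estimate$kb, x$estimate$ci_low,
    x$estimate$ci_high,
    if (length(x$flags)) paste0(" flags: ", paste(x$flags, collapse = ","))
    else ""))
  invisible(x)
}

#' Quantify every kinetochore in a field
#'
#' Finds kinetochore seeds on the GFP sum projection (or takes them from
#' `seeds`), segments each envelope, and measures each kinetochore with
#' every other detected object (other envelopes, phages, chromatin, all
#' detected on the DAPI projection) as forbidden territory for its
#' background ROI.
#'
#' @param field an [image_field()].
#' @param fit the session's `calibration_fit`.
#' @param seeds "auto" or a matrix / data frame with columns y, x (0-based).
#' @param shift_px,completeness,level,interval passed to
#'   [measure_kinetochore()].
#' @param segment_params named list overriding [segment_envelope()]
#'   defaults.
#' @return A list: `records` (data frame, one row per kinetochore:
#'   record_id, session, y, x, z_lo, z_hi, area_px, sum, background, net,
#'   completeness, kb, ci_low, ci_high, flags, roi_rle), `details` (list of
#'   `kinetochore_record`s).
#' @export
quantify_kinetochores <- function(field, fit, seeds = "auto", shift_px = 10,
                                  completeness = TRUE, level = 0.95,
                                  interval = "delta",
                                  segment_params = list()) {
  if (identical(seeds, "auto")) {
    gproj <- sum_project(field, "GFP")
    gspots <- detect_spots(gproj, max_area = 5000)
    seeds <- do.call(rbind, lapply(gspots, function(r)
      attr(r, "centroid")))
  } else {
    seeds <- as.matrix(as.data.frame(seeds))
    colnames(seeds) <- c("y", "x")[seq_len(ncol(seeds))]
  }
  if (is.null(seeds) || nrow(seeds) == 0)
    return(list(records = empty_record_table(), details = list()))

  envs <- lapply(seq_len(nrow(seeds)), function(i)
    do.call(segment_envelope,
            c(list(field = field, seed_point = seeds[i, c("y", "x")]),
              segment_params)))

  # all DAPI-detected foreground (phages, chromatin, kinetochore blobs)
  dproj <- sum_project(field, "DAPI")
  dspots <- detect_spots(dproj, max_area = Inf)
  dmasks <- lapply(dspots, unclass)

  session <- field$metadata$session
  details <- vector("list", length(envs))
  rows <- vector("list", length(envs))
  for (i in seq_along(envs)) {
    env <- envs[[i]]
    own <- unclass(env$roi)
    keep_masks <- Filter(function(mk) !any(mk & own), dmasks)
    forbidden <- c(lapply(envs[-i], function(e) unclass(e$roi)), keep_masks)
    rec <- measure_kinetochore(field, env, fit, shift_px = shift_px,
                               forbidden = forbidden,
                               completeness = completeness,
                               level = level, interval = interval)
    details[[i]] <- rec
    rows[[i]] <- data.frame(
      record_id = sprintf("kin%02d", i),
      session = if (is.null(session)) NA_character_ else session,
      y = env$centroid[["y"]], x = env$centroid[["x"]],
      z_lo = rec$z_range[1], z_hi = rec$z_range[2],
      area_px = roi_area(env$roi),
      sum = rec$measurement$sum_value,
      background = rec$measurement$background_value,
      net = rec$measurement$net,
      completeness = rec$completeness,
      kb = rec$estimate$kb, ci_low = rec$estimate$ci_low,
      ci_high = rec$estimate$ci_high,
      flags = paste(rec$flags, collapse = ";"),
      roi_rle = roi_encode(env$roi),
      stringsAsFactors = FALSE)
  }
  list(records = do.call(rbind, rows), details = details)
}

empty_record_table <- function() {
  data.frame(record_id = character(0), session = character(0),
             y = numeric(0), x = numeric(0), z_lo = integer(0),
             z_hi = integer(0), area_px = numeric(0), sum = numeric(0),
             background = numeric(0), net = numeric(0),
             completeness = numeric(0), kb = numeric(0),
             ci_low = numeric(0), ci_high = numeric(0),
             flags = character(0), roi_rle = character(0),
             stringsAsFactors = FALSE)
}

#' Summarize a cohort of kinetochore measurements
#'
#' Arithmetic mean, sample SD (n - 1), minimum, maximum and count of the kb
#' estimates, pooled and per marker (e.g. CENP-A-GFP vs CENP-H-GFP).
#' Flagged records (negative net, truncated envelope, background overlap,
#' ...) are excluded from the headline numbers by default but remain in the
#' records table.
#'
#' @param records records data frame from [quantify_kinetochores()]; a
#'   `marker` column, when present, drives the per-marker breakdown.
#' @param include_flagged include flagged records (default FALSE).
#' @return A `cohort_summary`: n, mean_kb, sd_kb, min_kb, max_kb, and
#'   `by_marker` (data frame with the same statistics per marker).
#' @export
summarize_cohort <- function(records, include_flagged = FALSE) {
  if (!nrow(records)) stop("empty cohort")
  keep <- if (include_flagged) rep(TRUE, nrow(records)) else
    !nzchar(records$flags)
  rec <- records[keep, , drop = FALSE]
  if (!nrow(rec)) stop("empty cohort: all records flagged")
  stat <- function(kb) {
    data.frame(n = length(kb), mean_kb = mean(kb),
               sd_kb = if (length(kb) > 1) sd(kb) else NA_real_,
               min_kb = min(kb), max_kb = max(kb))
  }
  pooled <- stat(rec$kb)
  by_marker <- NULL
  if (!is.null(rec$marker) && any(!is.na(rec$marker))) {
    by_marker <- do.call(rbind, lapply(split(rec, rec$marker), function(g) {
      cbind(data.frame(marker = g$marker[1]), stat(g$kb))
    }))
    rownames(by_marker) <- NULL
  }
  structure(c(as.list(pooled), list(by_marker = by_marker,
                                    n_excluded = sum(!keep))),
            class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("cohort: n = %d, %.1f +/- %s kb (range %.1f-%.1f)%s\n",
              x$n, x$mean_kb,
              if (is.na(x$sd_kb)) "NA" else sprintf("%.1f", x$sd_kb),
              x$min_kb, x$max_kb,
              if (x$n_excluded) sprintf(" [%d flagged record(s) excluded]",
                                        x$n_excluded) else ""))
  if (!is.null(x$by_marker)) {
    for (i in seq_len(nrow(x$by_marker)))
      cat(sprintf("  %s: n = %d, %.1f +/- %s kb\n",
                  x$by_marker$marker[i], x$by_marker$n[i],
                  x$by_marker$mean_kb[i],
                  if (is.na(x$by_marker$sd_kb[i])) "NA" else
                    sprintf("%.1f", x$by_marker$sd_kb[i])))
  }
  invisible(x)
}

#' Plot the cohort's DNA-content distribution
#'
#' Histogram of per-kinetochore kb estimates with a per-marker rug and the
#' cohort mean, the usual at-a-glance view of a quantification run.
#'
#' @param records records data frame from [quantify_kinetochores()].
#' @param include_flagged include flagged records (default FALSE).
#' @param ... passed to [graphics::hist()].
#' @return The histogram object, invisibly.
#' @export
plot_cohort <- function(records, include_flagged = FALSE, ...) {
  keep <- if (include_flagged) rep(TRUE, nrow(records)) else
    !nzchar(records$flags)
  kb <- records$kb[keep]
  if (!length(kb)) stop("empty cohort")
  h <- graphics::hist(kb, main = "Kinetochore DNA content",
                      xlab = "DNA (kb)", col = "grey85", border = "grey40",
                      ...)
  graphics::abline(v = mean(kb), lwd = 2, col = "firebrick")
  if (!is.null(records$marker)) {
    mk <- records$marker[keep]
    cols <- setNames(c("dodgerblue3", "darkorange2", "forestgreen",
                       "purple")[seq_along(unique(stats::na.omit(mk)))],
                     unique(stats::na.omit(mk)))
    for (mm in names(cols))
      graphics::rug(kb[!is.na(mk) & mk == mm], col = cols[mm], lwd = 1.5)
    graphics::legend("topright", bty = "n", lty = 1, col = cols,
                     legend = names(cols))
  }
  invisible(h)
}

#' Attach ground truth to kinetochore records
#'
#' Matches each record to the nearest manifest kinetochore by in-plane
#' centroid distance and copies its marker and true kb; used by recovery
#' tests and simulator-based validation.
#'
#' @param records records data frame from [quantify_kinetochores()].
#' @param manifest simulator manifest.
#' @param max_dist maximum match distance in px.
#' @return `records` with `marker`, `true_kb` and `match_dist` columns.
#' @export
match_manifest <- function(records, manifest, max_dist = 8) {
  kin <- manifest[manifest$class == "kinetochore", ]
  records$marker <- NA_character_
  records$true_kb <- NA_real_
  records$match_dist <- NA_real_
  for (i in seq_len(nrow(records))) {
    d <- sqrt((kin$y - records$y[i])^2 + (kin$x - records$x[i])^2)
    if (length(d) && min(d) <= max_dist) {
      j <- which.min(d)
      records$marker[i] <- kin$marker[j]
      records$true_kb[i] <- kin$true_kb[j]
      records$match_dist[i] <- d[j]
    }
  }
  records
}

#' Run the full pipeline on one field
#'
#' simulate/load -> detect and measure standards -> assign classes -> fit
#' the session's standard curve -> segment and measure every kinetochore ->
#' summarize the cohort. The single-field equivalent of the study's
#' per-experiment analysis.
#'
#' @param x a `sim_result` from [simulate_field()] / [read_simulation()],
#'   or an [image_field()].
#' @param manifest optional manifest (taken from `x` when it is a
#'   `sim_result`); used to attach ground truth to records and, with
#'   `known_identity = TRUE`, to bypass intensity clustering when assigning
#'   phage classes.
#' @param known_identity use manifest positions for class assignment.
#' @param shift_px,measure_on,completeness,interval,detect_params,segment_params
#'   forwarded to the component steps.
#' @return A list: spots, points, fit, records, details, summary.
#' @export
analyze_field <- function(x, manifest = NULL, known_identity = FALSE,
                          shift_px = 10, measure_on = "projection",
                          completeness = TRUE, interval = "delta",
                          detect_params = list(), segment_params = list()) {
  if (inherits(x, "sim_result")) {
    if (is.null(manifest)) manifest <- x$manifest
    field <- x$field
  } else field <- x
  std <- measure_standards(field, shift_px = shift_px,
                           measure_on = measure_on,
                           detect_params = detect_params)
  spots <- assign_classes(std$spots,
                          manifest = if (known_identity) manifest else NULL)
  points <- make_standard_points(spots)
  fit <- fit_standard_curve(points, session = field$metadata$session)
  kq <- quantify_kinetochores(field, fit, shift_px = shift_px,
                              completeness = completeness,
                              interval = interval,
                              segment_params = segment_params)
  records <- kq$records
  if (!is.null(manifest) && nrow(records))
    records <- match_manifest(records, manifest)
  summary <- if (nrow(records)) summarize_cohort(records) else NULL
  list(spots = spots, points = points, fit = fit, records = records,
       details = kq$details, summary = summary)
}

#' Write kinetochore records and summary to text files
#'
#' @param records records data frame.
#' @param summary a `cohort_summary` (optional).
#' @param out_dir output directory.
#' @return `out_dir`, invisibly.
#' @export
write_records <- function(records, summary = NULL, out_dir = ".") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(records, file.path(out_dir, "kinetochore_records.csv"),
            row.names = FALSE)
  if (!is.null(summary)) {
    writeLines(c(sprintf("n = %d", summary$n),
                 sprintf("mean_kb = %.6g", summary$mean_kb),
                 sprintf("sd_kb = %.6g", summary$sd_kb),
                 sprintf("min_kb = %.6g", summary$min_kb),
                 sprintf("max_kb = %.6g", summary$max_kb)),
               file.path(out_dir, "cohort_summary.txt"))
  }
  invisible(out_dir)
}
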