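#' Simulate a two-channel field with phage standards and kinetochores
#'
#' Generates one field of view as acquired in the calibration experiments:
#' a DAPI channel containing every DNA-carrying object (three bacteriophage
#' classes of 48, 90 and 168 kb rendered as PSF-limited point sources,
#' kinetochores and an optional chromatin mass rendered as Gaussian blobs)
#' and a GFP channel containing only the kinetochore marker signal. Expected
#' integrated DAPI photons are `brightness_per_kb * true_kb * at_bias`,
#' exactly, before noise. Noise model: Poisson on (signal + background),
#' then additive Gaussian read noise, then clipping to the camera range and
#' rounding to integer grey levels (noiseless simulations stay unrounded so
#' conservation is exact). With a fixed config + seed the output is
#' bit-reproducible.
#'
#' Objects are auto-placed uniformly at random, keeping `2 * 3 sigma_xy`
#' from the field borders, at least `min_separation_px` (and the two
#' objects' 3-sigma supports) apart in-plane, and the chromatin mass at
#' least `chromatin_min_dist_nm` from every kinetochore. Placement failure
#' after bounded retries raises "field too crowded". An object whose
#' expected signal would saturate more than 1% of its voxels raises
#' "saturation risk".
#'
#' @param config a [sim_config()].
#' @param seed RNG seed; defaults to `config$seed`.
#' @return A list of class `sim_result` with elements `field` (an
#'   [image_field()]), `manifest` (the ground-truth data frame: id, class,
#'   marker, z, y, x in 0-based voxel coordinates, true_kb, expected_dapi,
#'   expected_gfp, truncation_flag) and `config`.
#' @export
#' @examples
#' sim <- simulate_field(sim_config(field_shape = c(9, 96, 96),
#'                                  n_phage_per_class = 1, n_kinetochores = 1,
#'                                  min_separation_px = 25, seed = 3))
#' sim$manifest[, c("class", "true_kb")]
simulate_field <- function(config, seed = config$seed) {
  validate_sim_config(config)
  set.seed(seed)
  shape <- config$field_shape
  psf <- sigma_vox(config$psf_sigma, config$voxel_size)
  ksig <- sigma_vox(config$kinetochore_sigma, config$voxel_size)

  objects <- data.frame(
    class = c(rep(c("lambda", "P1", "T4"), each = config$n_phage_per_class),
              rep("kinetochore", config$n_kinetochores)),
    true_kb = c(rep(c(48, 90, 168), each = config$n_phage_per_class),
                if (config$n_kinetochores > 0)
                  runif(config$n_kinetochores,
                        config$kinetochore_kb_range[1],
                        config$kinetochore_kb_range[2]) else numeric(0)),
    stringsAsFactors = FALSE
  )
  if (!is.null(config$chromatin_mass))
    objects <- rbind(objects,
                     data.frame(class = "chromatin",
                                true_kb = config$chromatin_mass$total_kb))
  n_obj <- nrow(objects)
  objects$marker <- rep(NA_character_, n_obj)
  kin <- objects$class == "kinetochore"
  if (any(kin))
    objects$marker[kin] <- rep_len(config$markers, sum(kin))

  obj_sigma <- function(cls) {
    switch(cls,
           kinetochore = ksig,
           chromatin = sigma_vox(config$chromatin_mass$sigma,
                                 config$voxel_size),
           psf)
  }

  # --- placement -----------------------------------------------------------
  pos <- matrix(NA_real_, n_obj, 3)  # 0-based (z, y, x)
  sig_xy <- vapply(objects$class, function(cl) obj_sigma(cl)[["xy"]], 0)
  sig_z <- vapply(objects$class, function(cl) obj_sigma(cl)[["z"]], 0)
  chrom_min_px <- config$chromatin_min_dist_nm / config$voxel_size[["xy"]]
  max_tries <- 5000L
  for (i in seq_len(n_obj)) {
    m_xy <- 2 * 3 * sig_xy[i]
    m_z <- min(4 * sig_z[i], (shape[1] - 1) / 2)
    if (shape[2] - 1 - 2 * m_xy <= 0 || shape[3] - 1 - 2 * m_xy <= 0)
      stop("field too crowded")
    placed <- FALSE
    for (try in seq_len(max_tries)) {
      cand <- c(runif(1, m_z, shape[1] - 1 - m_z),
                runif(1, m_xy, shape[2] - 1 - m_xy),
                runif(1, m_xy, shape[3] - 1 - m_xy))
      ok <- TRUE
      for (j in seq_len(i - 1L)) {
        d <- sqrt(sum((cand[2:3] - pos[j, 2:3])^2))
        lim <- max(config$min_separation_px, 3 * (sig_xy[i] + sig_xy[j]))
        pair <- c(objects$class[i], objects$class[j])
        if ("chromatin" %in% pair && "kinetochore" %in% pair)
          lim <- max(lim, chrom_min_px)
        if (d < lim) { ok <- FALSE; break }
      }
      if (ok) { pos[i, ] <- cand; placed <- TRUE; break }
    }
    if (!placed) stop("field too crowded")
  }
  if (!is.null(config$chromatin_mass) &&
      !is.null(config$chromatin_mass$position)) {
    pos[objects$class == "chromatin", ] <- config$chromatin_mass$position
  }

  # --- expected intensities ------------------------------------------------
  bias <- config$at_bias[objects$class]
  objects$expected_dapi <- config$brightness_per_kb * objects$true_kb * bias
  objects$expected_gfp <- ifelse(kin, config$gfp_brightness, 0)

  # --- render --------------------------------------------------------------
  maxval <- 2^config$camera_bit_depth - 1
  dapi <- array(0, dim = shape)
  gfp <- array(0, dim = shape)
  trunc_flag <- logical(n_obj)
  for (i in seq_len(n_obj)) {
    sg <- obj_sigma(objects$class[i])
    p <- render_patch(pos[i, ], objects$expected_dapi[i], sg, shape)
    trunc_flag[i] <- p$captured < 0.99
    sat <- p$values + config$background_dapi > maxval
    support <- p$values > 1e-3 * max(p$values)
    if (sum(sat & support) > 0.01 * sum(support))
      stop("saturation risk")
    dapi <- add_patch(dapi, p)
    if (objects$expected_gfp[i] > 0) {
      pg <- render_patch(pos[i, ], objects$expected_gfp[i], sg, shape)
      satg <- pg$values + config$background_gfp > maxval
      supg <- pg$values > 1e-3 * max(pg$values)
      if (sum(satg & supg) > 0.01 * sum(supg))
        stop("saturation risk")
      gfp <- add_patch(gfp, pg)
    }
  }

  # --- noise ---------------------------------------------------------------
  apply_noise <- function(arr, bg) {
    arr <- arr + bg
    n <- length(arr)
    if (config$poisson_noise) {
      v <- rpois(n, as.vector(arr))
      dim(v) <- dim(arr)
      arr <- v
    }
    if (config$read_noise_sd > 0)
      arr <- arr + array(rnorm(n, 0, config$read_noise_sd), dim = dim(arr))
    arr <- pmin(pmax(arr, 0), maxval)
    if (config$poisson_noise || config$read_noise_sd > 0) arr <- round(arr)
    arr
  }
  dapi <- apply_noise(dapi, config$background_dapi)
  gfp <- apply_noise(gfp, config$background_gfp)

  manifest <- data.frame(
    id = sprintf("obj%02d", seq_len(n_obj)),
    class = objects$class,
    marker = objects$marker,
    z = pos[, 1], y = pos[, 2], x = pos[, 3],
    true_kb = objects$true_kb,
    expected_dapi = objects$expected_dapi,
    expected_gfp = objects$expected_gfp,
    truncation_flag = trunc_flag,
    stringsAsFactors = FALSE
  )

  field <- image_field(
    list(DAPI = dapi, GFP = gfp),
    voxel_size = config$voxel_size,
    metadata = list(session = sprintf("sim-seed%d", seed),
                    simulated = TRUE, seed = seed)
  )
  structure(list(field = field, manifest = manifest, config = config),
            class = "sim_result")
}

#' @export
print.sim_result <- function(x, ...) {
  print(x$field)
  cat(sprintf("manifest: %d objects (%s)\n", nrow(x$manifest),
              paste(sprintf("%s:%d", names(table(x$manifest$class)),
                            table(x$manifest$class)), collapse = ", ")))
  invisible(x)
}

#' Write simulator output to a directory
#'
#' Writes one 16-bit multi-page TIFF per channel, the ground-truth manifest
#' as `manifest.csv`, and the echoed configuration as `config.txt`.
#'
#' @param sim a `sim_result` from [simulate_field()].
#' @param out_dir output directory.
#' @return `out_dir`, invisibly.
#' @export
write_simulation <- function(sim, out_dir) {
  stopifnot(inherits(sim, "sim_result"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_field(sim$field, out_dir, bits = sim$config$camera_bit_depth)
  write.csv(sim$manifest, file.path(out_dir, "manifest.csv"),
            row.names = FALSE)
  write_sim_config(sim$config, file.path(out_dir, "config.txt"))
  invisible(out_dir)
}

#' Read simulator output written by [write_simulation()]
#'
#' @param dir directory holding `DAPI.tif`, `GFP.tif`, `manifest.csv`,
#'   `config.txt`.
#' @return A `sim_result` list (field, manifest, config).
#' @export
read_simulation <- function(dir) {
  cfg <- read_sim_config(file.path(dir, "config.txt"))
  field <- read_field(file.path(dir, c("DAPI.tif", "GFP.tif")),
                      c("DAPI", "GFP"), voxel_size = cfg$voxel_size,
                      metadata = list(session = sprintf("sim-seed%d",
                                                        cfg$seed)))
  manifest <- read.csv(file.path(dir, "manifest.csv"),
                       stringsAsFactors = FALSE)
  structure(list(field = field, manifest = manifest, config = cfg),
            class = "sim_result")
}
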