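#' Simulation configuration
#'
#' Builds and validates the parameter set for [simulate_field()]. Defaults
#' reproduce the acquisition geometry of the study the package models:
#' 1,024 x 1,024 px planes in z-stacks with a 200 nm step, a 100x/1.4 NA
#' objective sampled at 65 nm in xy, and an as-if-deconvolved Gaussian PSF.
#' Objects are three bacteriophage standards (lambda 48 kb, P1 90 kb,
#' T4 168 kb) rendered as diffraction-limited point sources, plus stretched
#' kinetochores rendered as wider Gaussian blobs carrying both DAPI
#' (proportional to their true kb) and GFP (marker) signal.
#'
#' @param field_shape integer (z, y, x) stack dimensions in voxels.
#' @param voxel_size numeric (z, xy) voxel pitch in nm.
#' @param psf_sigma numeric (z, xy) PSF Gaussian sigma in nm; models the
#'   compact effective PSF of deconvolved data.
#' @param brightness_per_kb expected integrated DAPI photons emitted per
#'   kilobase of DNA (the quantity the calibration recovers).
#' @param gfp_brightness expected integrated GFP photons per kinetochore.
#' @param background_dapi,background_gfp mean background photons per voxel
#'   in each channel.
#' @param read_noise_sd detector read noise (Gaussian sd, photons).
#' @param n_phage_per_class number of phage particles per class.
#' @param n_kinetochores number of kinetochores.
#' @param kinetochore_kb_range (min, max) kb; true kinetochore DNA content is
#'   drawn uniformly on this range. Default 28-147 kb, the observed spread
#'   of stretched-kinetochore measurements the simulator emulates.
#' @param kinetochore_sigma numeric (z, xy) Gaussian extent of a kinetochore
#'   blob in nm.
#' @param markers character labels cycled over kinetochores (GFP fusion
#'   identity, e.g. CENP-A vs CENP-H); metadata only, no optical effect.
#' @param chromatin_mass optional list(total_kb, sigma = c(z, xy) nm,
#'   position = NULL) describing a bright DAPI-only chromatin mass; NULL
#'   (default) omits it. When auto-placed it is kept at least
#'   `chromatin_min_dist_nm` from every kinetochore, emulating condensin-
#'   depleted "excursions" that isolate kinetochores from the chromosome.
#' @param chromatin_min_dist_nm minimum chromatin-to-kinetochore distance.
#' @param at_bias named numeric multipliers on expected DAPI photons per
#'   object class (lambda, P1, T4, kinetochore, chromatin), all 1 by
#'   default. Models the AT-richness preference of DAPI: a class whose DNA
#'   the dye underreports gets a factor < 1. The bias is simulated, never
#'   corrected downstream.
#' @param camera_bit_depth camera bit depth; intensities clip at
#'   `2^camera_bit_depth - 1` grey levels (gain 1 photon/level).
#' @param poisson_noise logical; apply Poisson shot noise.
#' @param min_separation_px minimum in-plane distance between object
#'   centres, so detection ROIs and shifted background ROIs stay clear of
#'   neighbours.
#' @param seed integer RNG seed; with the same config + seed the simulated
#'   field is bit-reproducible.
#' @return A validated `sim_config` object (a named list).
#' @export
#' @examples
#' cfg <- sim_config(field_shape = c(9, 128, 128), n_phage_per_class = 1,
#'                   n_kinetochores = 1, seed = 7)
#' cfg$brightness_per_kb
sim_config <- function(field_shape = c(21, 1024, 1024),
                       voxel_size = c(z = 200, xy = 65),
                       psf_sigma = c(z = 300, xy = 100),
                       brightness_per_kb = 100,
                       gfp_brightness = 5e4,
                       background_dapi = 5,
                       background_gfp = 2,
                       read_noise_sd = 2,
                       n_phage_per_class = 3,
                       n_kinetochores = 5,
                       kinetochore_kb_range = c(28, 147),
                       kinetochore_sigma = c(z = 300, xy = 250),
                       markers = c("CENP-A", "CENP-H"),
                       chromatin_mass = NULL,
                       chromatin_min_dist_nm = 1500,
                       at_bias = c(lambda = 1, P1 = 1, T4 = 1,
                                   kinetochore = 1, chromatin = 1),
                       camera_bit_depth = 16,
                       poisson_noise = TRUE,
                       min_separation_px = 40,
                       seed = 1L) {
  cfg <- list(
    field_shape = as.integer(field_shape),
    voxel_size = unname_pair(voxel_size),
    psf_sigma = unname_pair(psf_sigma),
    brightness_per_kb = brightness_per_kb,
    gfp_brightness = gfp_brightness,
    background_dapi = background_dapi,
    background_gfp = background_gfp,
    read_noise_sd = read_noise_sd,
    n_phage_per_class = as.integer(n_phage_per_class),
    n_kinetochores = as.integer(n_kinetochores),
    kinetochore_kb_range = as.numeric(kinetochore_kb_range),
    kinetochore_sigma = unname_pair(kinetochore_sigma),
    markers = as.character(markers),
    chromatin_mass = chromatin_mass,
    chromatin_min_dist_nm = chromatin_min_dist_nm,
    at_bias = at_bias,
    camera_bit_depth = as.integer(camera_bit_depth),
    poisson_noise = isTRUE(poisson_noise),
    min_separation_px = min_separation_px,
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

# store (z, xy) pairs as named numeric of length 2
unname_pair <- function(x) {
  x <- as.numeric(x)
  stopifnot(length(x) == 2L)
  names(x) <- c("z", "xy")
  x
}

validate_sim_config <- function(cfg) {
  stopifnot(length(cfg$field_shape) == 3L)
  if (any(cfg$field_shape < 1L)) stop("field_shape must be positive")
  if (any(cfg$voxel_size <= 0) || any(cfg$psf_sigma <= 0) ||
      any(cfg$kinetochore_sigma <= 0))
    stop("voxel sizes and sigmas must be > 0")
  if (cfg$brightness_per_kb <= 0) stop("brightness_per_kb must be > 0")
  if (cfg$n_phage_per_class < 0L || cfg$n_kinetochores < 0L)
    stop("object counts must be >= 0")
  if (cfg$background_dapi < 0 || cfg$background_gfp < 0 ||
      cfg$read_noise_sd < 0)
    stop("background and read noise must be >= 0")
  if (diff(cfg$kinetochore_kb_range) < 0 || any(cfg$kinetochore_kb_range <= 0))
    stop("kinetochore_kb_range must be positive and ordered")
  need <- c("lambda", "P1", "T4", "kinetochore", "chromatin")
  if (!all(need %in% names(cfg$at_bias)))
    stop("at_bias must name factors for: ", paste(need, collapse = ", "))
  if (any(cfg$at_bias < 0)) stop("at_bias factors must be >= 0")
  if (!is.null(cfg$chromatin_mass)) {
    cm <- cfg$chromatin_mass
    if (is.null(cm$total_kb) || cm$total_kb <= 0)
      stop("chromatin_mass$total_kb must be > 0")
    if (is.null(cm$sigma) || any(cm$sigma <= 0))
      stop("chromatin_mass$sigma must be > 0")
  }
  if (cfg$camera_bit_depth < 1L || cfg$camera_bit_depth > 32L)
    stop("camera_bit_depth out of range")
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Simulation config:",
      sprintf("%d x %d x %d (z,y,x) voxels, %g/%g nm (z/xy)",
              x$field_shape[1], x$field_shape[2], x$field_shape[3],
              x$voxel_size["z"], x$voxel_size["xy"]), "\n")
  cat(sprintf("  %d phage/class, %d kinetochores (%g-%g kb), %g photons/kb\n",
              x$n_phage_per_class, x$n_kinetochores,
              x$kinetochore_kb_range[1], x$kinetochore_kb_range[2],
              x$brightness_per_kb))
  cat(sprintf("  noise: poisson=%s, bg DAPI/GFP %g/%g, read sd %g, seed %d\n",
              x$poisson_noise, x$background_dapi, x$background_gfp,
              x$read_noise_sd, x$seed))
  invisible(x)
}

# sigma in voxel units, (z, xy)
sigma_vox <- function(sigma_nm, voxel_size) {
  c(z = unname(sigma_nm["z"] / voxel_size["z"]),
    xy = unname(sigma_nm["xy"] / voxel_size["xy"]))
}

#' Write / read a simulation config as a key-value text file
#'
#' Flat `key = value` serialization used as the sidecar of simulator output
#' directories; complex entries (at_bias, chromatin_mass) are stored as
#' comma-separated `name:value` pairs.
#'
#' @param cfg a `sim_config`.
#' @param path file path.
#' @return `write_sim_config` returns `path` invisibly; `read_sim_config`
#'   returns the reconstructed `sim_config`.
#' @export
write_sim_config <- function(cfg, path) {
  kv <- c(
    field_shape = paste(cfg$field_shape, collapse = ","),
    voxel_size = paste(cfg$voxel_size, collapse = ","),
    psf_sigma = paste(cfg$psf_sigma, collapse = ","),
    brightness_per_kb = cfg$brightness_per_kb,
    gfp_brightness = cfg$gfp_brightness,
    background_dapi = cfg$background_dapi,
    background_gfp = cfg$background_gfp,
    read_noise_sd = cfg$read_noise_sd,
    n_phage_per_class = cfg$n_phage_per_class,
    n_kinetochores = cfg$n_kinetochores,
    kinetochore_kb_range = paste(cfg$kinetochore_kb_range, collapse = ","),
    kinetochore_sigma = paste(cfg$kinetochore_sigma, collapse = ","),
    markers = paste(cfg$markers, collapse = ","),
    chromatin_mass = if (is.null(cfg$chromatin_mass)) "none" else
      paste(c(cfg$chromatin_mass$total_kb, cfg$chromatin_mass$sigma),
            collapse = ","),
    chromatin_min_dist_nm = cfg$chromatin_min_dist_nm,
    at_bias = paste(sprintf("%s:%g", names(cfg$at_bias), cfg$at_bias),
                    collapse = ","),
    camera_bit_depth = cfg$camera_bit_depth,
    poisson_noise = cfg$poisson_noise,
    min_separation_px = cfg$min_separation_px,
    seed = cfg$seed
  )
  writeLines(sprintf("%s = %s", names(kv), kv), path)
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  ln <- readLines(path)
  kv <- strsplit(ln, " = ", fixed = TRUE)
  vals <- setNames(vapply(kv, `[`, "", 2L), vapply(kv, `[`, "", 1L))
  num <- function(k) as.numeric(strsplit(vals[[k]], ",")[[1]])
  bias <- strsplit(strsplit(vals[["at_bias"]], ",")[[1]], ":")
  cm <- if (identical(vals[["chromatin_mass"]], "none")) NULL else {
    v <- num("chromatin_mass")
    list(total_kb = v[1], sigma = c(z = v[2], xy = v[3]))
  }
  sim_config(
    field_shape = num("field_shape"),
    voxel_size = num("voxel_size"),
    psf_sigma = num("psf_sigma"),
    brightness_per_kb = num("brightness_per_kb"),
    gfp_brightness = num("gfp_brightness"),
    background_dapi = num("background_dapi"),
    background_gfp = num("background_gfp"),
    read_noise_sd = num("read_noise_sd"),
    n_phage_per_class = num("n_phage_per_class"),
    n_kinetochores = num("n_kinetochores"),
    kinetochore_kb_range = num("kinetochore_kb_range"),
    kinetochore_sigma = num("kinetochore_sigma"),
    markers = strsplit(vals[["markers"]], ",")[[1]],
    chromatin_mass = cm,
    chromatin_min_dist_nm = num("chromatin_min_dist_nm"),
    at_bias = setNames(as.numeric(vapply(bias, `[`, "", 2L)),
                       vapply(bias, `[`, "", 1L)),
    camera_bit_depth = num("camera_bit_depth"),
    poisson_noise = identical(vals[["poisson_noise"]], "TRUE"),
    min_separation_px = num("min_separation_px"),
    seed = num("seed")
  )
}
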