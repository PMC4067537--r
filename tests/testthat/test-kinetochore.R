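# exact calibration at the simulator's default brightness (100 photons/kb)
perfect_fit <- function(b = 100) {
  fit_standard_curve(data.frame(genome_kb = c(48, 90, 168),
                                net_intensity = b * c(48, 90, 168)))
}

test_that("the GFP envelope captures the kinetochore and nothing else", {
  cfg <- quiet_config(field_shape = c(13, 200, 200), n_phage_per_class = 0,
                      n_kinetochores = 1, seed = 61)
  sim <- simulate_field(cfg)
  kin <- sim$manifest[1, ]
  env <- segment_envelope(sim$field, c(kin$y, kin$x))
  expect_s3_class(env, "envelope")
  expect_true(unclass(env$roi)[round(kin$y) + 1, round(kin$x) + 1])
  expect_lt(sqrt(sum((env$centroid - c(kin$y, kin$x))^2)), 1.5)
  # half-max envelope holds at least half the GFP signal
  gproj <- sum_project(sim$field, "GFP")
  expect_gt(sum_intensity(gproj, env$roi) / sum(gproj$pixels), 0.5)
  # z-range covers the blob's rendered support
  expect_lte(env$z_range[1], floor(kin$z))
  expect_gte(env$z_range[2], ceiling(kin$z))
})

test_that("seeding on empty background raises 'no GFP signal'", {
  cfg <- quiet_config(field_shape = c(13, 128, 128), n_phage_per_class = 0,
                      n_kinetochores = 1, seed = 62)
  sim <- simulate_field(cfg)
  kin <- sim$manifest[1, ]
  far <- c((kin$y + 64) %% 120, (kin$x + 64) %% 120)
  expect_error(segment_envelope(sim$field, far), "no GFP signal")
})

test_that("well-separated kinetochores get disjoint envelopes", {
  # two kinetochores 3 um apart (46 px at 65 nm)
  shape <- c(13L, 160L, 160L)
  g <- render_blob(c(6, 80, 56), 5e4, kin_vox, shape) +
    render_blob(c(6, 80, 102.2), 5e4, kin_vox, shape)
  d <- render_blob(c(6, 80, 56), 9000, kin_vox, shape) +
    render_blob(c(6, 80, 102.2), 9000, kin_vox, shape)
  f <- image_field(list(DAPI = unclass(d), GFP = unclass(g)))
  env <- segment_envelope(f, c(80, 56))
  sig3 <- roi_from_disc(c(80, 102.2), 3 * kin_vox[["xy"]], shape[2:3])
  expect_equal(sum(unclass(env$roi) & unclass(sig3)), 0)
})

test_that("a noiseless kinetochore measures within 2% of its true kb", {
  cfg <- quiet_config(field_shape = c(13, 200, 200), n_phage_per_class = 0,
                      n_kinetochores = 1, kinetochore_kb_range = c(90, 90),
                      seed = 63)
  sim <- simulate_field(cfg)
  kin <- sim$manifest[1, ]
  env <- segment_envelope(sim$field, c(kin$y, kin$x))
  rec <- measure_kinetochore(sim$field, env, perfect_fit())
  expect_lt(abs(rec$estimate$kb - 90) / 90, 0.02)
  expect_equal(rec$measurement$net,
               rec$measurement$sum_value - rec$measurement$background_value)
  # the raw (uncorrected) protocol undershoots: the half-max envelope truncates
  raw <- measure_kinetochore(sim$field, env, perfect_fit(),
                             completeness = FALSE)
  expect_lt(raw$estimate$kb, 0.8 * 90)
})

test_that("zero DAPI signal maps to the calibration's zero point", {
  shape <- c(9L, 96L, 96L)
  g <- render_blob(c(4, 48, 48), 5e4, kin_vox, shape)
  f <- image_field(list(DAPI = array(0, shape), GFP = unclass(g)))
  env <- segment_envelope(f, c(48, 48))
  fit <- fit_standard_curve(data.frame(genome_kb = c(48, 90, 168),
                                       net_intensity = c(530, 950, 1730)))
  rec <- measure_kinetochore(f, env, fit, completeness = FALSE)
  expect_equal(rec$estimate$kb, -fit$intercept / fit$slope, tolerance = 1e-9)
  if (fit$intercept > 0) expect_true("negative-kb" %in% rec$flags)
})

test_that("doubling exposure everywhere leaves kb estimates unchanged", {
  cfg <- quiet_config(field_shape = c(13, 200, 200), n_phage_per_class = 1,
                      n_kinetochores = 1, seed = 64)
  sim <- simulate_field(cfg)
  res1 <- analyze_field(sim)
  f2 <- image_field(lapply(sim$field$channels, function(a) 2 * a),
                    voxel_size = sim$field$voxel_size,
                    metadata = sim$field$metadata)
  res2 <- analyze_field(f2, manifest = sim$manifest)
  expect_equal(res2$fit$slope, 2 * res1$fit$slope, tolerance = 1e-6)
  expect_equal(res2$records$kb, res1$records$kb, tolerance = 1e-6)
})

test_that("cohort summaries report mean, sd and range correctly", {
  one <- data.frame(record_id = "k1", kb = 58, flags = "")
  s1 <- summarize_cohort(one)
  expect_equal(s1$mean_kb, 58)
  expect_true(is.na(s1$sd_kb))
  expect_equal(c(s1$min_kb, s1$max_kb), c(58, 58))

  three <- data.frame(record_id = c("a", "b", "c"), kb = c(40, 60, 80),
                      flags = c("", "", ""),
                      marker = c("CENP-A", "CENP-H", "CENP-A"))
  s3 <- summarize_cohort(three)
  expect_equal(s3$mean_kb, 60)
  expect_equal(s3$sd_kb, 20)
  expect_equal(c(s3$min_kb, s3$max_kb), c(40, 80))
  expect_equal(sort(s3$by_marker$marker), c("CENP-A", "CENP-H"))

  flagged <- three; flagged$flags[2] <- "negative-net"
  sf <- summarize_cohort(flagged)
  expect_equal(sf$n, 2)
  expect_equal(sf$mean_kb, 60)
  expect_equal(summarize_cohort(flagged, include_flagged = TRUE)$n, 3)
  expect_error(summarize_cohort(three[0, ]), "empty cohort")
  allbad <- three; allbad$flags <- "negative-net"
  expect_error(summarize_cohort(allbad), "empty cohort")
})

test_that("marker labels do not shift cohort means", {
  # same true-kb distribution under both GFP markers; permutation check
  recs <- list()
  for (s in 1:3) {
    cfg <- noisy_config(field_shape = c(13, 512, 512), n_phage_per_class = 3,
                        n_kinetochores = 8, seed = 700 + s)
    res <- analyze_field(simulate_field(cfg))
    recs[[s]] <- res$records
  }
  rec <- do.call(rbind, recs)
  rec <- rec[!nzchar(rec$flags) & !is.na(rec$marker), ]
  a <- rec$kb[rec$marker == "CENP-A"]; b <- rec$kb[rec$marker == "CENP-H"]
  obs <- abs(mean(a) - mean(b))
  set.seed(99)
  pooled <- c(a, b)
  perm <- replicate(999, {
    idx <- sample(length(pooled), length(a))
    abs(mean(pooled[idx]) - mean(pooled[-idx]))
  })
  p <- (1 + sum(perm >= obs)) / 1000
  expect_gt(p, 0.01)
})

test_that("the pipeline recovers truth on a noiseless mixed field", {
  cfg <- quiet_config(field_shape = c(13, 300, 300), n_phage_per_class = 1,
                      n_kinetochores = 2, seed = 66)
  res <- analyze_field(simulate_field(cfg))
  expect_equal(nrow(res$records), 2)
  err <- abs(res$records$kb - res$records$true_kb) / res$records$true_kb
  expect_lt(max(err), 0.02)
  expect_s3_class(res$summary, "cohort_summary")
  # every emitted record satisfies the exact net identity
  expect_equal(res$records$net, res$records$sum - res$records$background)
  expect_equal(res$spots$net, res$spots$sum - res$spots$background)
})

test_that("the voxel-envelope mode also recovers truth after correction", {
  cfg <- quiet_config(field_shape = c(13, 200, 200), n_phage_per_class = 0,
                      n_kinetochores = 1, kinetochore_kb_range = c(90, 90),
                      seed = 67)
  sim <- simulate_field(cfg)
  kin <- sim$manifest[1, ]
  env <- segment_envelope(sim$field, c(kin$y, kin$x), voxel_mask = TRUE)
  expect_false(is.null(env$mask3d))
  rec <- measure_kinetochore(sim$field, env, perfect_fit())
  expect_lt(abs(rec$estimate$kb - 90) / 90, 0.03)
  # the voxel mask is strictly tighter than the projected prism, so its
  # raw (uncorrected) net is smaller
  rec2d <- measure_kinetochore(sim$field,
                               segment_envelope(sim$field, c(kin$y, kin$x)),
                               perfect_fit(), completeness = FALSE)
  raw3d <- measure_kinetochore(sim$field, env, perfect_fit(),
                               completeness = FALSE)
  expect_lt(raw3d$measurement$net, rec2d$measurement$net)
})

test_that("label-mask TIFFs import as ROIs", {
  lab <- matrix(0L, 16, 16)
  lab[3:5, 3:5] <- 1L
  lab[10:12, 8:9] <- 2L
  path <- withr::local_tempfile(fileext = ".tif")
  tiff::writeTIFF(lab / 255, path, bits.per.sample = 8)
  rois <- read_roi_labels(path)
  expect_length(rois, 2)
  expect_equal(sum(rois$roi1), 9)
  expect_equal(sum(rois$roi2), 6)
  expect_true(all(unclass(rois$roi1)[3:5, 3:5]))
})

test_that("cohort plots render without error", {
  rec <- data.frame(record_id = sprintf("k%d", 1:6),
                    kb = c(40, 55, 61, 70, 88, 120),
                    flags = c("", "", "", "negative-net", "", ""),
                    marker = rep(c("CENP-A", "CENP-H"), 3))
  path <- withr::local_tempfile(fileext = ".png")
  grDevices::png(path)
  h <- plot_cohort(rec)
  grDevices::dev.off()
  expect_s3_class(h, "histogram")
  expect_true(file.exists(path))
})

test_that("records and summaries serialize to delimited text", {
  rec <- data.frame(record_id = c("k1", "k2"), kb = c(50, 70),
                    flags = c("", ""), marker = c("CENP-A", "CENP-H"))
  dir <- withr::local_tempdir()
  write_records(rec, summarize_cohort(rec), dir)
  back <- read.csv(file.path(dir, "kinetochore_records.csv"))
  expect_equal(back$kb, rec$kb)
  expect_true(file.exists(file.path(dir, "cohort_summary.txt")))
})
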