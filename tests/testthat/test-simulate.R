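test_that("a noiseless lambda phage integrates to brightness x 48 kb", {
  cfg <- quiet_config(n_phage_per_class = 1, n_kinetochores = 0)
  # one phage per class; isolate lambda by summing a box around it
  sim <- simulate_field(cfg)
  lam <- sim$manifest[sim$manifest$class == "lambda", ]
  expect_equal(lam$expected_dapi, 48 * cfg$brightness_per_kb)

  one <- sim_config(field_shape = c(13, 96, 96), n_phage_per_class = 0,
                    n_kinetochores = 1, kinetochore_kb_range = c(48, 48),
                    kinetochore_sigma = c(z = 300, xy = 100),
                    background_dapi = 0, background_gfp = 0,
                    read_noise_sd = 0, poisson_noise = FALSE, seed = 5)
  s1 <- simulate_field(one)
  expect_lt(abs(sum(s1$field$channels$DAPI) - 4800) / 4800, 0.001)
})

test_that("equal DNA content gives equal integrated DAPI signal", {
  cfg <- quiet_config(field_shape = c(13, 200, 200), n_phage_per_class = 1,
                      n_kinetochores = 1,
                      kinetochore_kb_range = c(90, 90), seed = 42)
  sim <- simulate_field(cfg)
  dapi <- sim$field$channels$DAPI
  boxsum <- function(row) {
    z <- row$z; y <- row$y; x <- row$x
    r <- 18
    sum(dapi[, max(1, round(y) - r):min(dim(dapi)[2], round(y) + r + 2),
             max(1, round(x) - r):min(dim(dapi)[3], round(x) + r + 2)])
  }
  p1 <- boxsum(sim$manifest[sim$manifest$class == "P1", ])
  kin <- boxsum(sim$manifest[sim$manifest$class == "kinetochore", ])
  expect_lt(abs(p1 - kin) / kin, 0.005)
})

test_that("noiseless fields equal the sum of their manifest objects", {
  cfg <- quiet_config(field_shape = c(13, 160, 160), n_phage_per_class = 1,
                      n_kinetochores = 2, seed = 9)
  sim <- simulate_field(cfg)
  shape <- cfg$field_shape
  recon <- array(0, dim = shape)
  for (i in seq_len(nrow(sim$manifest))) {
    row <- sim$manifest[i, ]
    sg <- if (row$class == "kinetochore") kin_vox else psf_vox
    recon <- recon + render_point_source(c(row$z, row$y, row$x),
                                         row$expected_dapi, sg, shape)
  }
  expect_equal(max(abs(recon - sim$field$channels$DAPI)), 0)
})

test_that("simulation is bit-reproducible under a fixed config and seed", {
  cfg <- noisy_config(field_shape = c(9, 128, 128), seed = 77)
  a <- simulate_field(cfg)
  b <- simulate_field(cfg)
  expect_identical(a$field$channels, b$field$channels)
  expect_identical(a$manifest, b$manifest)
  c2 <- simulate_field(cfg, seed = 78)
  expect_false(identical(a$field$channels$DAPI, c2$field$channels$DAPI))
})

test_that("Poisson-sweep net signal of a T4 phage matches its 16,800-photon truth", {
  # Monte-Carlo oracle: empirical mean/variance of whole-field sums over a
  # seed sweep; background-free so the field sum is the object's signal
  cfg <- sim_config(field_shape = c(9, 64, 64), n_phage_per_class = 0,
                    n_kinetochores = 1, kinetochore_kb_range = c(168, 168),
                    kinetochore_sigma = c(z = 300, xy = 100),
                    background_dapi = 0, background_gfp = 0,
                    read_noise_sd = 0, poisson_noise = TRUE, seed = 1)
  sums <- vapply(1:60, function(s)
    sum(simulate_field(cfg, seed = s)$field$channels$DAPI), 0)
  expect_lt(abs(mean(sums) - 16800), 4 * sqrt(16800 / 60))
  expect_gt(var(sums) / 16800, 0.6)   # Poisson: variance ~ mean
  expect_lt(var(sums) / 16800, 1.5)
})

test_that("per-voxel variance equals the mean under Poisson noise", {
  cfg <- sim_config(field_shape = c(3, 20, 20), n_phage_per_class = 0,
                    n_kinetochores = 0, background_dapi = 6,
                    background_gfp = 0, read_noise_sd = 0,
                    poisson_noise = TRUE, seed = 1)
  reps <- vapply(1:120, function(s)
    simulate_field(cfg, seed = s)$field$channels$DAPI, array(0, c(3, 20, 20)))
  m <- apply(reps, 1:3, mean)
  v <- apply(reps, 1:3, var)
  expect_equal(mean(v) / mean(m), 1, tolerance = 0.05)
})

test_that("manifest bookkeeping follows the config exactly", {
  cfg <- noisy_config(field_shape = c(13, 256, 256), n_phage_per_class = 2,
                      n_kinetochores = 3,
                      at_bias = c(lambda = 1, P1 = 1, T4 = 1,
                                  kinetochore = 0.8, chromatin = 1),
                      seed = 15)
  sim <- simulate_field(cfg)
  mf <- sim$manifest
  expect_setequal(unique(mf$class), c("lambda", "P1", "T4", "kinetochore"))
  expect_true(all(mf$true_kb[mf$class == "lambda"] == 48))
  expect_true(all(mf$true_kb[mf$class == "P1"] == 90))
  expect_true(all(mf$true_kb[mf$class == "T4"] == 168))
  kin <- mf$class == "kinetochore"
  expect_true(all(mf$true_kb[kin] >= 28 & mf$true_kb[kin] <= 147))
  expect_equal(mf$expected_dapi,
               cfg$brightness_per_kb * mf$true_kb *
                 ifelse(kin, 0.8, 1))
  expect_equal(mf$expected_gfp, ifelse(kin, cfg$gfp_brightness, 0))
  expect_setequal(unique(mf$marker[kin]), c("CENP-A", "CENP-H"))

  # placement respects borders and separation
  sig_xy <- ifelse(kin, kin_vox[["xy"]], psf_vox[["xy"]])
  m_xy <- 2 * 3 * sig_xy
  expect_true(all(mf$y >= m_xy & mf$y <= 255 - m_xy))
  expect_true(all(mf$x >= m_xy & mf$x <= 255 - m_xy))
  d <- as.matrix(dist(mf[, c("y", "x")]))
  diag(d) <- Inf
  expect_gte(min(d), cfg$min_separation_px)
})

test_that("crowded fields and saturating objects are refused", {
  expect_error(simulate_field(quiet_config(field_shape = c(9, 64, 64),
                                           n_phage_per_class = 6,
                                           n_kinetochores = 6)),
               "field too crowded")
  expect_error(simulate_field(quiet_config(field_shape = c(13, 128, 128),
                                           n_phage_per_class = 1,
                                           n_kinetochores = 0,
                                           brightness_per_kb = 1e7)),
               "saturation risk")
})
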