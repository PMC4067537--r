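# Shared fixtures: compact noiseless / noisy study fields built in code.

# default sigmas in voxel units for the standard geometry
psf_vox <- c(z = 300 / 200, xy = 100 / 65)
kin_vox <- c(z = 300 / 200, xy = 250 / 65)

# small noiseless configuration (fast; exact photon bookkeeping)
quiet_config <- function(field_shape = c(13, 256, 256),
                         n_phage_per_class = 1, n_kinetochores = 1,
                         seed = 101, ...) {
  sim_config(field_shape = field_shape,
             n_phage_per_class = n_phage_per_class,
             n_kinetochores = n_kinetochores,
             background_dapi = 0, background_gfp = 0,
             read_noise_sd = 0, poisson_noise = FALSE,
             min_separation_px = 40, seed = seed, ...)
}

# noisy configuration at the default (high) SNR
noisy_config <- function(field_shape = c(13, 256, 256),
                         n_phage_per_class = 1, n_kinetochores = 1,
                         seed = 202, ...) {
  sim_config(field_shape = field_shape,
             n_phage_per_class = n_phage_per_class,
             n_kinetochores = n_kinetochores,
             min_separation_px = 40, seed = seed, ...)
}

# plane with one voxel-integrated 2-D gaussian spot (0-based center)
gauss_plane <- function(dim_yx, center, sigma, total) {
  wy <- pnorm(0:(dim_yx[1] - 1) + 0.5, center[1], sigma) -
    pnorm(0:(dim_yx[1] - 1) - 0.5, center[1], sigma)
  wx <- pnorm(0:(dim_yx[2] - 1) + 0.5, center[2], sigma) -
    pnorm(0:(dim_yx[2] - 1) - 0.5, center[2], sigma)
  total * outer(wy, wx)
}

# textbook OLS of y on x via the normal equations, kept independent of the
# package's fitting path
ols_oracle <- function(x, y) {
  n <- length(x)
  xbar <- mean(x); ybar <- mean(y)
  sxx <- sum((x - xbar)^2)
  b1 <- sum((x - xbar) * (y - ybar)) / sxx
  b0 <- ybar - b1 * xbar
  res <- y - b0 - b1 * x
  s2 <- sum(res^2) / (n - 2)
  V <- s2 * matrix(c(1 / n + xbar^2 / sxx, -xbar / sxx,
                     -xbar / sxx, 1 / sxx), 2, 2)
  list(slope = b1, intercept = b0, residual_sd = sqrt(s2), vcov = V,
       r_squared = 1 - sum(res^2) / sum((y - ybar)^2))
}

rel_err <- function(a, b) abs(a - b) / abs(b)
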