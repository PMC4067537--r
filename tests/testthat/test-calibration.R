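exact_pts <- data.frame(genome_kb = c(48, 90, 168),
                        net_intensity = c(480, 900, 1680))

test_that("a proportional standard set fits slope 10 through the origin", {
  fit <- fit_standard_curve(exact_pts)
  expect_equal(fit$slope, 10, tolerance = 1e-12)
  expect_equal(fit$intercept, 0, tolerance = 1e-9)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  expect_equal(fit$residual_sd, 0, tolerance = 1e-9)
})

test_that("fit matches the closed-form normal equations on random instances", {
  set.seed(14)
  for (rep in 1:25) {
    n_per <- sample(1:4, 1)
    kb <- rep(c(48, 90, 168), each = n_per)
    y <- 12 * kb + rnorm(length(kb), 50, 120)
    pts <- data.frame(genome_kb = kb, net_intensity = y)
    fit <- fit_standard_curve(pts)
    o <- ols_oracle(kb, y)
    expect_lt(rel_err(fit$slope, o$slope), 1e-9)
    expect_lt(abs(fit$intercept - o$intercept) /
                max(1, abs(o$intercept)), 1e-9)
    expect_lt(rel_err(fit$residual_sd, o$residual_sd), 1e-9)
    expect_lt(max(abs(fit$param_covariance - o$vcov)) /
                max(abs(o$vcov)), 1e-9)
    expect_equal(fit$r_squared, o$r_squared, tolerance = 1e-9)
  }
})

test_that("duplicating noiseless points leaves the fit unchanged", {
  fit1 <- fit_standard_curve(exact_pts)
  fit2 <- fit_standard_curve(rbind(exact_pts, exact_pts))
  expect_equal(fit2$slope, fit1$slope, tolerance = 1e-12)
  expect_equal(fit2$intercept, fit1$intercept, tolerance = 1e-9)
})

test_that("degenerate standard sets are refused", {
  expect_error(fit_standard_curve(exact_pts[1:2, ]), "at least 3")
  three_same <- data.frame(genome_kb = c(48, 48, 90),
                           net_intensity = c(480, 500, 900))
  expect_error(fit_standard_curve(three_same), "incomplete standard set")
  neg <- data.frame(genome_kb = c(48, 90, 168),
                    net_intensity = c(1680, 900, 480))
  expect_error(fit_standard_curve(neg), "non-positive calibration slope")
})

test_that("inverse prediction inverts the forward line", {
  set.seed(31)
  pts <- data.frame(genome_kb = rep(c(48, 90, 168), 2),
                    net_intensity = 11 * rep(c(48, 90, 168), 2) + 30 +
                      rnorm(6, 0, 40))
  fit <- fit_standard_curve(pts)
  for (x in c(1, 48, 90, 168, 500)) {
    est <- predict_dna(fit, fit$intercept + fit$slope * x)
    expect_lt(rel_err(est$kb, x), 1e-9)
    expect_true(est$ci_low <= est$kb && est$kb <= est$ci_high)
  }
  expect_equal(predict_dna(fit_standard_curve(exact_pts), 900)$kb, 90,
               tolerance = 1e-12)
})

test_that("predicted kb is strictly increasing in net intensity", {
  fit <- fit_standard_curve(exact_pts)
  kb <- predict_dna(fit, seq(-200, 3000, by = 50))$kb
  expect_true(all(diff(kb) > 0))
  expect_true(grepl("negative-kb", predict_dna(fit, -100)$flags))
})

test_that("intensity rescaling leaves every predicted kb unchanged", {
  set.seed(7)
  pts <- data.frame(genome_kb = rep(c(48, 90, 168), 3),
                    net_intensity = 9 * rep(c(48, 90, 168), 3) +
                      rnorm(9, 0, 60))
  fit1 <- fit_standard_curve(pts)
  for (cst in c(0.25, 3, 117)) {
    pts2 <- pts; pts2$net_intensity <- pts2$net_intensity * cst
    fit2 <- fit_standard_curve(pts2)
    expect_equal(fit2$slope, cst * fit1$slope, tolerance = 1e-9)
    expect_equal(fit2$intercept, cst * fit1$intercept, tolerance = 1e-9)
    expect_equal(fit2$residual_sd, cst * fit1$residual_sd, tolerance = 1e-9)
    y <- c(500, 1200, 2500)
    expect_equal(predict_dna(fit2, cst * y)$kb, predict_dna(fit1, y)$kb,
                 tolerance = 1e-9)
  }
})

test_that("delta and Fieller intervals agree for a strong calibration", {
  set.seed(18)
  pts <- data.frame(genome_kb = rep(c(48, 90, 168), 3),
                    net_intensity = 10 * rep(c(48, 90, 168), 3) +
                      rnorm(9, 0, 50))
  fit <- fit_standard_curve(pts)
  d <- predict_dna(fit, 900, interval = "delta")
  f <- predict_dna(fit, 900, interval = "fieller")
  expect_equal(d$kb, f$kb, tolerance = 1e-12)
  expect_lt(abs(d$ci_low - f$ci_low) / (d$ci_high - d$ci_low), 0.1)
  expect_lt(abs(d$ci_high - f$ci_high) / (d$ci_high - d$ci_low), 0.1)
})

test_that("inverse-prediction intervals hold near-nominal coverage", {
  set.seed(71)
  cover <- 0; n_rep <- 300
  for (r in 1:n_rep) {
    kb <- rep(c(48, 90, 168), each = 3)
    pts <- data.frame(genome_kb = kb,
                      net_intensity = 10 * kb + rnorm(9, 0, 45))
    fit <- tryCatch(fit_standard_curve(pts), error = function(e) NULL)
    if (is.null(fit)) next
    y0 <- 10 * 90 + rnorm(1, 0, 45)  # new on-curve observation at 90 kb
    est <- predict_dna(fit, y0)
    if (est$ci_low <= 90 && 90 <= est$ci_high) cover <- cover + 1
  }
  expect_gt(cover / n_rep, 0.90)
  expect_lt(cover / n_rep, 0.99)
})

test_that("diagnostics expose residual structure and outliers", {
  perfect <- fit_diagnostics(fit_standard_curve(exact_pts))
  expect_true(all(abs(perfect$residual) < 1e-9))

  set.seed(5)
  kb <- rep(c(48, 90, 168), each = 8)
  y <- 10 * kb + rnorm(24, 0, 20)
  y[5] <- y[5] + 900  # gross outlier
  diag <- fit_diagnostics(fit_standard_curve(data.frame(genome_kb = kb,
                                                        net_intensity = y)))
  expect_true(diag$outlier[5])
  expect_equal(sum(diag$outlier), 1)
  expect_lt(abs(sum(diag$residual)), 1e-9)  # OLS residuals sum to zero
})

test_that("calibration fits round trip through key-value text", {
  set.seed(2)
  pts <- data.frame(genome_kb = c(48, 90, 168),
                    net_intensity = c(500, 930, 1700))
  fit <- fit_standard_curve(pts, session = "exp1")
  path <- withr::local_tempfile(fileext = ".txt")
  write_calibration(fit, path)
  back <- read_calibration(path)
  expect_equal(back$slope, fit$slope)
  expect_equal(back$intercept, fit$intercept)
  expect_equal(back$param_covariance, fit$param_covariance)
  expect_identical(back$session, "exp1")
  expect_equal(predict_dna(back, 1000)$kb, predict_dna(fit, 1000)$kb)
})
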