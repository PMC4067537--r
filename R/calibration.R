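#' Fit the intensity-versus-DNA standard curve
#'
#' Ordinary least squares of net intensity (response) on genome size in kb
#' (predictor), with a free intercept, matching the orientation of the
#' plotted standard curve (intensity on y, DNA on x). Unknowns are later
#' converted by inverse prediction, not by regressing kb on intensity.
#' The intercept is estimated rather than forced through the origin since
#' background subtraction can leave a small offset.
#'
#' @param points data frame of standard points with columns `genome_kb` and
#'   `net_intensity` (from [make_standard_points()]); all three genome
#'   sizes (48, 90, 168 kb) must be represented and n >= 3.
#' @param session optional experiment/session key; standards and unknowns
#'   must share a session, so the key is carried on the fit and checked at
#'   prediction time inside the pipeline.
#' @return A `calibration_fit`: slope (intensity/kb), intercept, r_squared,
#'   residual_sd (n - 2 df), param_covariance (2 x 2, intercept first),
#'   n_points, points, session.
#' @export
#' @examples
#' pts <- data.frame(genome_kb = c(48, 90, 168),
#'                   net_intensity = c(480, 900, 1680))
#' fit <- fit_standard_curve(pts)
#' fit$slope      # 10
#' fit$intercept  # ~0
fit_standard_curve <- function(points, session = NULL) {
  if (is.null(points$genome_kb) || is.null(points$net_intensity))
    stop("points must have genome_kb and net_intensity")
  n <- nrow(points)
  if (n < 3) stop("underdetermined: need at least 3 standard points")
  if (!all(PHAGE_KB %in% points$genome_kb))
    stop("incomplete standard set: all three genome sizes ",
         "(48, 90, 168 kb) must be represented")
  fit <- lm(net_intensity ~ genome_kb, data = points)
  cf <- coef(fit)
  slope <- unname(cf["genome_kb"])
  if (!is.finite(slope) || slope <= 0)
    stop("non-positive calibration slope")
  res <- points$net_intensity - fitted(fit)
  sst <- sum((points$net_intensity - mean(points$net_intensity))^2)
  r2 <- if (sst > 0) 1 - sum(res^2) / sst else 1
  s <- sqrt(sum(res^2) / (n - 2))
  # parameter covariance from the closed form (vcov(lm) routes through
  # summary.lm, which warns on the exact fits the simulator produces)
  x <- points$genome_kb
  sxx <- sum((x - mean(x))^2)
  V <- s^2 * matrix(c(1 / n + mean(x)^2 / sxx, -mean(x) / sxx,
                      -mean(x) / sxx, 1 / sxx), 2, 2)
  structure(list(slope = slope,
                 intercept = unname(cf["(Intercept)"]),
                 r_squared = r2,
                 residual_sd = s,
                 param_covariance = V,
                 n_points = n,
                 points = points,
                 session = session),
            class = "calibration_fit")
}

#' @export
print.calibration_fit <- function(x, ...) {
  cat(sprintf(
    "Standard curve: net = %.4g + %.4g * kb  (n = %d, r^2 = %.4f, s = %.3g)\n",
    x$intercept, x$slope, x$n_points, x$r_squared, x$residual_sd))
  if (!is.null(x$session)) cat("  session:", x$session, "\n")
  invisible(x)
}

#' Convert net intensity to DNA amount by inverse prediction
#'
#' `kb = (net - intercept) / slope`, with a 95% single-observation
#' inverse-prediction interval. The default interval propagates the
#' residual variance of a new observation plus the parameter covariance
#' through the inverse transform (delta method, t quantile on n - 2 df);
#' `interval = "fieller"` solves the Fieller quadratic instead, which stays
#' valid for weak slopes (an unbounded interval is reported as infinite and
#' flagged).
#'
#' @param fit a `calibration_fit`.
#' @param net_intensity numeric vector of background-subtracted intensities.
#' @param level confidence level (default 0.95).
#' @param interval "delta" (default) or "fieller".
#' @return A data frame: net_intensity, kb, ci_low, ci_high, method, flags.
#'   Negative kb estimates are allowed and flagged `negative-kb`.
#' @export
#' @examples
#' fit <- fit_standard_curve(data.frame(genome_kb = c(48, 90, 168),
#'                                      net_intensity = c(480, 900, 1680)))
#' predict_dna(fit, 900)$kb  # 90
predict_dna <- function(fit, net_intensity, level = 0.95,
                        interval = c("delta", "fieller")) {
  stopifnot(inherits(fit, "calibration_fit"))
  interval <- match.arg(interval)
  b0 <- fit$intercept; b1 <- fit$slope
  V <- fit$param_covariance; s2 <- fit$residual_sd^2
  tq <- qt(1 - (1 - level) / 2, df = fit$n_points - 2)
  kb <- (net_intensity - b0) / b1
  if (interval == "delta") {
    varg <- (s2 + V[1, 1] + 2 * kb * V[1, 2] + kb^2 * V[2, 2]) / b1^2
    half <- tq * sqrt(pmax(varg, 0))
    lo <- kb - half; hi <- kb + half
  } else {
    lo <- hi <- numeric(length(kb))
    for (i in seq_along(kb)) {
      d <- net_intensity[i] - b0
      A <- b1^2 - tq^2 * V[2, 2]
      B <- -2 * (b1 * d + tq^2 * V[1, 2])
      C <- d^2 - tq^2 * (s2 + V[1, 1])
      disc <- B^2 - 4 * A * C
      if (A > 0 && disc >= 0) {
        rt <- sort(c((-B - sqrt(disc)) / (2 * A), (-B + sqrt(disc)) / (2 * A)))
        lo[i] <- rt[1]; hi[i] <- rt[2]
      } else {
        lo[i] <- -Inf; hi[i] <- Inf
      }
    }
  }
  flags <- ifelse(kb < 0, "negative-kb", "")
  flags <- ifelse(is.infinite(lo) | is.infinite(hi),
                  paste0(flags, ifelse(nzchar(flags), ";", ""),
                         "unbounded-interval"), flags)
  data.frame(net_intensity = net_intensity, kb = kb, ci_low = lo,
             ci_high = hi, method = interval, flags = flags,
             stringsAsFactors = FALSE)
}

#' Residual and leverage diagnostics for a standard curve
#'
#' Per-point residuals, leverages and standardized residuals of the fitted
#' line; points with |standardized residual| > 3 are flagged as outliers,
#' the usual QC before accepting a per-session calibration.
#'
#' @param fit a `calibration_fit`.
#' @return A data frame: genome_kb, net_intensity, fitted, residual,
#'   leverage, std_residual, outlier.
#' @export
fit_diagnostics <- function(fit) {
  stopifnot(inherits(fit, "calibration_fit"))
  x <- fit$points$genome_kb; y <- fit$points$net_intensity
  yhat <- fit$intercept + fit$slope * x
  res <- y - yhat
  sxx <- sum((x - mean(x))^2)
  h <- 1 / length(x) + (x - mean(x))^2 / sxx
  denom <- fit$residual_sd * sqrt(pmax(1 - h, .Machine$double.eps))
  std <- if (fit$residual_sd > 0) res / denom else rep(0, length(res))
  data.frame(genome_kb = x, net_intensity = y, fitted = yhat,
             residual = res, leverage = h, std_residual = std,
             outlier = abs(std) > 3)
}

#' Serialize / deserialize a calibration fit as key-value text
#'
#' @param fit a `calibration_fit`.
#' @param path file path.
#' @return `write_calibration` returns `path` invisibly; `read_calibration`
#'   the reconstructed fit (without the original points).
#' @export
write_calibration <- function(fit, path) {
  V <- fit$param_covariance
  writeLines(c(
    sprintf("slope = %.17g", fit$slope),
    sprintf("intercept = %.17g", fit$intercept),
    sprintf("r_squared = %.17g", fit$r_squared),
    sprintf("residual_sd = %.17g", fit$residual_sd),
    sprintf("cov_00 = %.17g", V[1, 1]),
    sprintf("cov_01 = %.17g", V[1, 2]),
    sprintf("cov_11 = %.17g", V[2, 2]),
    sprintf("n_points = %d", fit$n_points),
    sprintf("session = %s", if (is.null(fit$session)) "NA" else fit$session)
  ), path)
  invisible(path)
}

#' @rdname write_calibration
#' @export
read_calibration <- function(path) {
  kv <- strsplit(readLines(path), " = ", fixed = TRUE)
  vals <- setNames(vapply(kv, `[`, "", 2L), vapply(kv, `[`, "", 1L))
  V <- matrix(c(as.numeric(vals["cov_00"]), as.numeric(vals["cov_01"]),
                as.numeric(vals["cov_01"]), as.numeric(vals["cov_11"])), 2, 2)
  structure(list(slope = as.numeric(vals["slope"]),
                 intercept = as.numeric(vals["intercept"]),
                 r_squared = as.numeric(vals["r_squared"]),
                 residual_sd = as.numeric(vals["residual_sd"]),
                 param_covariance = V,
                 n_points = as.integer(vals["n_points"]),
                 points = NULL,
                 session = if (identical(vals[["session"]], "NA")) NULL else
                   vals[["session"]]),
            class = "calibration_fit")
}
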