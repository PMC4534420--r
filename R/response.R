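#' Normalized t-value histograms as a function of NSA
#'
#' For each subject and each NSA grid value, histograms the masked
#' voxels' t-values over the fixed range \[-10, +50\] (values outside
#' the range are clipped into the extreme bins so the unit-area
#' normalization is preserved) and normalizes each histogram to unit
#' area.  The group-mean density is the arithmetic mean of the
#' per-subject densities, bin by bin.
#'
#' @param curve_sets A single [t_curves()] result or a list of them
#'   (one per subject); all must share the same NSA grid.
#' @param bins Number of bins over \[-10, 50\]; default 60 (width 1).
#' @param range Fixed t-value range, default `c(-10, 50)`.
#' @return A list of class `t_histogram_set`: `breaks`, `mids`,
#'   `nsa_grid`, `density` (list over subjects of bins x NSA matrices),
#'   `group_mean` (bins x NSA matrix).
#' @examples
#' tc <- t_curves(matrix(rnorm(4000), 10, 400), c(100, 400))
#' h <- t_histograms(tc)
#' colSums(h$group_mean) * diff(h$breaks)[1]  # unit areas
#' @export
t_histograms <- function(curve_sets, bins = 60, range = c(-10, 50)) {
  if (inherits(curve_sets, "t_curve_set")) curve_sets <- list(curve_sets)
  stopifnot(length(curve_sets) >= 1,
            all(vapply(curve_sets, inherits, TRUE, "t_curve_set")))
  grid <- curve_sets[[1]]$nsa_grid
  for (cs in curve_sets)
    if (!identical(cs$nsa_grid, grid))
      stop("all subjects must share one NSA grid", call. = FALSE)
  breaks <- seq(range[1], range[2], length.out = bins + 1)
  width <- diff(breaks)[1]
  dens <- lapply(curve_sets, function(cs) {
    if (nrow(cs$t) == 0) stop("empty mask", call. = FALSE)
    out <- matrix(0, bins, length(grid))
    for (j in seq_along(grid)) {
      tv <- cs$t[, j]
      tv <- pmin(pmax(tv, range[1]), range[2])  # clip into end bins
      h <- hist(tv, breaks = breaks, plot = FALSE, include.lowest = TRUE)
      out[, j] <- h$counts / (sum(h$counts) * width)
    }
    out
  })
  gm <- Reduce(`+`, dens) / length(dens)
  structure(list(breaks = breaks, mids = (breaks[-1] + breaks[-length(
    breaks)]) / 2, nsa_grid = grid, density = dens, group_mean = gm),
    class = "t_histogram_set")
}

#' Adjusted Fisher-Pearson sample skewness
#'
#' `g1 * sqrt(n (n-1)) / (n - 2)` with `g1 = m3 / m2^(3/2)` the moment
#' coefficient of skewness.  Used to quantify the growing upper tail
#' of the WM t-value distribution as averaging proceeds.
#'
#' @param x Numeric vector, length at least 3, nonzero variance.
#' @return Scalar skewness.
#' @export
skewness <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 3) stop("skewness needs at least 3 values", call. = FALSE)
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 == 0) stop("skewness undefined for zero-variance sample",
                    call. = FALSE)
  g1 <- mean((x - m)^3) / m2^1.5
  g1 * sqrt(n * (n - 1)) / (n - 2)
}

fit_ci <- function(est, se, df) {
  hw <- qt(0.975, df) * se
  cbind(lower = est - hw, upper = est + hw)
}

fit_one_nls <- function(x, y, formula, start, lower) {
  fit <- try(minpack.lm::nlsLM(formula, data = data.frame(x = x, y = y),
                               start = start, lower = lower,
                               control = minpack.lm::nls.lm.control(
                                 maxiter = 200)), silent = TRUE)
  if (inherits(fit, "try-error")) return(NULL)
  est <- coef(fit)
  sm <- summary(fit)
  list(params = est, residual_error = sum(residuals(fit)^2),
       ci = fit_ci(est, sm$coefficients[, "Std. Error"], sm$df[2]),
       converged = TRUE)
}

#' Fit asymptotic response models to a percent-significant curve
#'
#' Fits three candidate models of percent significant voxels (y)
#' against NSA (x) — exponential recovery `y = a (1 - exp(-b x))`,
#' logarithmic `y = a log(x)`, and the fractional (Michaelis-Menten
#' form) recovery `y = a x / (b + x)` whose asymptote `a` is the
#' ceiling fraction of reachable voxels — and selects the model with
#' the smallest residual sum of squares among those that converged.
#' 95% parameter confidence intervals are asymptotic (linearized
#' covariance at the optimum).
#'
#' @param nsa Numeric vector of NSA values (positive).
#' @param percent Percent of significant voxels at each NSA.
#' @return A list of class `response_fit`: `best` (name of selected
#'   model), `fits` (per model: `params`, `residual_error`, `ci`,
#'   `converged`).
#' @examples
#' x <- seq(10, 400, by = 10)
#' f <- fit_response_curve(x, 94 * x / (10 + x))
#' f$best; f$fits$fractional$params
#' @export
fit_response_curve <- function(nsa, percent) {
  x <- as.numeric(nsa); y <- as.numeric(percent)
  if (length(x) < 4) stop("need at least 4 points", call. = FALSE)
  if (any(x <= 0)) stop("NSA values must be positive", call. = FALSE)

  fits <- list()
  # documented, fixed starts for reproducibility
  fits$exp_recovery <- fit_one_nls(
    x, y, y ~ a * (1 - exp(-b * x)),
    start = list(a = max(y), b = 1 / median(x)), lower = c(0, 0))
  # y = a log(x): linear least squares, no intercept
  lx <- log(x)
  lfit <- lm(y ~ 0 + lx)
  est <- c(a = unname(coef(lfit)))
  fits$logarithmic <- list(
    params = est, residual_error = sum(residuals(lfit)^2),
    ci = fit_ci(est, suppressWarnings(
      summary(lfit)$coefficients[, "Std. Error"]), lfit$df.residual),
    converged = TRUE)
  fits$fractional <- fit_one_nls(
    x, y, y ~ a * x / (b + x),
    start = list(a = max(y), b = median(x)), lower = c(0, 0))

  ok <- !vapply(fits, is.null, TRUE)
  fits[!ok] <- lapply(names(fits)[!ok], function(nm)
    list(params = NULL, residual_error = Inf, ci = NULL,
         converged = FALSE))
  rss <- vapply(fits, `[[`, 0, "residual_error")
  if (all(!is.finite(rss)))
    stop("no candidate model converged", call. = FALSE)
  structure(list(best = names(fits)[which.min(rss)], fits = fits),
            class = "response_fit")
}

#' @export
print.response_fit <- function(x, ...) {
  cat("response_fit: best model =", x$best, "\n")
  for (nm in names(x$fits)) {
    f <- x$fits[[nm]]
    if (!f$converged) { cat(sprintf("  %-13s did not converge\n", nm));
      next }
    cat(sprintf("  %-13s RSS %.4g  params: %s\n", nm, f$residual_error,
                paste(sprintf("%s=%.4g", names(f$params), f$params),
                      collapse = ", ")))
  }
  invisible(x)
}

#' Fit the square-root-of-N law to mean t-values
#'
#' Least-squares slope of mean t against `sqrt(NSA)` through the
#' origin (`y = K sqrt(NSA)`); the origin constraint follows from the
#' t-score definition `t = u sqrt(N) / sd`, which vanishes at N = 0.
#'
#' @param nsa NSA values.
#' @param mean_t Mean t-value at each NSA.
#' @return A list of class `sqrt_fit`: `K`, `residual_error`, `ci`.
#' @examples
#' fit_sqrt_law(c(4, 16, 64), 2 * sqrt(c(4, 16, 64)))$K  # 2
#' @export
fit_sqrt_law <- function(nsa, mean_t) {
  x <- sqrt(as.numeric(nsa)); y <- as.numeric(mean_t)
  if (length(x) < 2) stop("need at least 2 points", call. = FALSE)
  if (all(x == 0)) stop("all-zero predictor", call. = FALSE)
  fit <- lm(y ~ 0 + x)
  K <- unname(coef(fit))
  se <- suppressWarnings(summary(fit)$coefficients[, "Std. Error"])
  structure(list(K = K, residual_error = sum(residuals(fit)^2),
                 ci = fit_ci(c(K = K), se, fit$df.residual)),
            class = "sqrt_fit")
}
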