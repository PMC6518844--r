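# Semivariogram estimation and model fitting. The empirical semivariogram is
# the classical Matheron estimator gamma(h) = (1/2N(h)) * sum (v_i - v_j)^2
# over point pairs binned by separation distance; a parametric model
# (spherical, exponential or gaussian) is fitted by Cressie-weighted least
# squares, and its effective range is the reported range of spatial
# autocorrelation.

#' Empirical (Matheron) semivariogram
#'
#' Bins all point pairs with separation `<= max_lag` into `n_bins` equal-width
#' lag classes and computes the classical semivariance estimate per bin.
#'
#' @param centroids `region_set` or 2-column matrix of planar coordinates
#'   (metres).
#' @param values Numeric values at the points (must not be constant).
#' @param n_bins Number of lag bins.
#' @param max_lag Maximum lag in metres; defaults to half the maximum pairwise
#'   distance.
#' @return An `empirical_variogram` data frame: `lag` (bin centre),
#'   `lag_lower`, `lag_upper`, `n_pairs`, `gamma`, `empty`.
#' @export
empirical_variogram <- function(centroids, values, n_bins = 12, max_lag = NULL) {
  cc <- resolve_centroids(centroids)
  if (nrow(cc$xy) < 3L) stop("at least 3 points are required")
  if (nrow(cc$xy) < 10L) {
    warning("fewer than 10 points: the empirical semivariogram will be unstable")
  }
  if (length(values) != nrow(cc$xy)) stop("one value per point is required")
  stop_if_constant(values)
  d <- as.vector(stats::dist(cc$xy))
  dmax <- max(d)
  max_lag <- max_lag %||% (dmax / 2)
  if (max_lag > dmax) stop("max_lag exceeds the maximum pairwise distance")
  g2 <- as.vector(stats::dist(values))^2
  sel <- d <= max_lag
  width <- max_lag / n_bins
  bin <- pmin(pmax(ceiling(d[sel] / width), 1L), n_bins)
  np <- tabulate(bin, nbins = n_bins)
  ssq <- vapply(seq_len(n_bins), function(b) sum(g2[sel][bin == b]), numeric(1))
  gamma <- ifelse(np > 0, ssq / (2 * np), NA_real_)
  out <- data.frame(
    lag = (seq_len(n_bins) - 0.5) * width,
    lag_lower = (seq_len(n_bins) - 1) * width,
    lag_upper = seq_len(n_bins) * width,
    n_pairs = np, gamma = gamma, empty = np == 0L
  )
  attr(out, "max_lag") <- max_lag
  attr(out, "n_points") <- nrow(cc$xy)
  class(out) <- c("empirical_variogram", "data.frame")
  out
}

#' Parametric semivariogram families
#'
#' Semivariance at lag `h` for the spherical, exponential or gaussian model
#' with nugget `c0`, partial sill `c` and range parameter `a`:
#' spherical `c0 + c*(1.5 h/a - 0.5 (h/a)^3)` for `h <= a` and `c0 + c`
#' beyond; exponential `c0 + c*(1 - exp(-h/a))`; gaussian
#' `c0 + c*(1 - exp(-(h/a)^2))`. By convention `gamma(0) = 0`, the nugget
#' attaching only for `h > 0`.
#'
#' @param h Lag distance(s), `>= 0`.
#' @param family `"spherical"`, `"exponential"` or `"gaussian"`.
#' @param nugget,psill,range_par Model parameters (`c0 >= 0`, `c >= 0`,
#'   `a > 0`).
#' @return Semivariance at each `h`.
#' @export
variogram_gamma <- function(h, family, nugget, psill, range_par) {
  if (any(h < 0)) stop("lag distances must be >= 0")
  family <- match.arg(family, c("spherical", "exponential", "gaussian"))
  s <- switch(family,
    spherical = ifelse(h >= range_par, 1,
                       1.5 * h / range_par - 0.5 * (h / range_par)^3),
    exponential = 1 - exp(-h / range_par),
    gaussian = 1 - exp(-(h / range_par)^2)
  )
  ifelse(h == 0, 0, nugget + psill * s)
}

#' Effective range of a variogram model
#'
#' The distance at which the model effectively reaches its sill: `a` for the
#' spherical family (exact), `3a` for the exponential and `sqrt(3) a` for the
#' gaussian (95% of the sill).
#'
#' @param family Model family.
#' @param range_par Range parameter `a`.
#' @return Effective range in the units of `a`.
#' @export
effective_range <- function(family, range_par) {
  switch(match.arg(family, c("spherical", "exponential", "gaussian")),
         spherical = range_par,
         exponential = 3 * range_par,
         gaussian = sqrt(3) * range_par)
}

#' @noRd
.fit_failure <- function(reason) {
  structure(list(reason = reason), class = "variogram_fit_failure")
}

#' Test for a variogram fit failure
#' @param x Object returned by [fit_variogram_model()].
#' @return `TRUE` if the fit failed (no range of spatial autocorrelation could
#'   be defined).
#' @export
is_fit_failure <- function(x) inherits(x, "variogram_fit_failure")

#' Fit a semivariogram model by weighted least squares
#'
#' Fits each candidate family to the non-empty bins of an empirical
#' semivariogram by Cressie-weighted least squares (weights
#' `N(h) / gamma_model(h)^2`, which stabilise small-count bins) with
#' multi-start Levenberg-Marquardt optimisation, and keeps the family with the
#' smallest weighted SSE. The fit is declared a failure - the "unable to
#' define a range of spatial autocorrelation" outcome - when fewer than 4
#' usable bins exist, the optimiser fails, the fitted effective range exceeds
#' the maximum lag, the structured fraction `c/(c0+c)` falls below 0.05, or
#' the effective range falls at or below the first lag centre (a flat, pure-nugget
#' variogram is equally well fitted by any nugget/sill split with a tiny
#' range, so ranges below the lag resolution are not identifiable).
#'
#' @param emp An [empirical_variogram()].
#' @param families Candidate families to try.
#' @return A `variogram_model` (family, `nugget`, `psill`, `range`, `sill`,
#'   `effective_range`, `wsse`) or a `variogram_fit_failure` with a reason;
#'   test with [is_fit_failure()].
#' @export
fit_variogram_model <- function(emp, families = c("spherical", "exponential",
                                                  "gaussian")) {
  use <- !emp$empty & emp$n_pairs > 0 & !is.na(emp$gamma)
  if (sum(use) < 4L) return(.fit_failure("fewer than 4 usable lag bins"))
  h <- emp$lag[use]; g <- emp$gamma[use]; np <- emp$n_pairs[use]
  max_lag <- attr(emp, "max_lag") %||% max(emp$lag_upper)
  gm <- mean(g)
  if (gm <= 0) return(.fit_failure("degenerate empirical semivariogram"))
  eps <- 1e-8 * gm

  resid_fun <- function(par, fam) {
    mhat <- variogram_gamma(h, fam, par[1], par[2], par[3])
    sqrt(np) * (g - mhat) / pmax(mhat, eps)
  }
  best <- NULL
  for (fam in families) {
    a_eff_starts <- c(0.25, 0.5, 0.75) * max(h)
    a_starts <- vapply(a_eff_starts, function(ae) {
      switch(fam, spherical = ae, exponential = ae / 3, gaussian = ae / sqrt(3))
    }, numeric(1))
    for (a0 in a_starts) {
      for (c00 in c(0, 0.2 * gm)) {
        start <- c(c00, max(max(g) - c00, 0.1 * gm), a0)
        fit <- tryCatch(
          minpack.lm::nls.lm(par = start, fn = resid_fun, fam = fam,
                             lower = c(0, 0, 1e-6 * max(h)),
                             upper = c(5 * max(g), 10 * max(g), 20 * max(h)),
                             control = minpack.lm::nls.lm.control(maxiter = 200)),
          error = function(e) NULL)
        if (is.null(fit)) next
        wsse <- sum(resid_fun(fit$par, fam)^2)
        if (!is.finite(wsse)) next
        if (is.null(best) || wsse < best$wsse) {
          best <- list(family = fam, par = fit$par, wsse = wsse)
        }
      }
    }
  }
  if (is.null(best)) return(.fit_failure("optimiser failed for all families"))
  c0 <- best$par[1]; cc <- best$par[2]; a <- best$par[3]
  eff <- effective_range(best$family, a)
  if (eff > max_lag) {
    return(.fit_failure("fitted effective range exceeds the maximum lag"))
  }
  if (cc / (c0 + cc) < 0.05) {
    return(.fit_failure("structured fraction c/(c0+c) below 0.05"))
  }
  if (eff <= min(h)) {
    return(.fit_failure("fitted effective range below the lag resolution"))
  }
  structure(list(family = best$family, nugget = c0, psill = cc, range = a,
                 sill = c0 + cc, effective_range = eff, wsse = best$wsse,
                 empirical = emp),
            class = "variogram_model")
}

#' @rdname fit_variogram_model
#' @param object A fitted `variogram_model`.
#' @param h Lags at which to evaluate the fitted semivariance.
#' @param ... Unused.
#' @export
predict.variogram_model <- function(object, h, ...) {
  variogram_gamma(h, object$family, object$nugget, object$psill, object$range)
}

#' @export
print.variogram_model <- function(x, ...) {
  cat(sprintf("Semivariogram model (%s)\n", x$family))
  cat(sprintf("  nugget c0: %.4g   partial sill c: %.4g   sill: %.4g\n",
              x$nugget, x$psill, x$sill))
  cat(sprintf("  range parameter a: %.1f m   effective range: %.1f m\n",
              x$range, x$effective_range))
  cat(sprintf("  weighted SSE: %.4g\n", x$wsse))
  invisible(x)
}

#' @export
print.variogram_fit_failure <- function(x, ...) {
  cat("Semivariogram fit failure: no range of spatial autocorrelation defined\n")
  cat(sprintf("  reason: %s\n", x$reason))
  invisible(x)
}

#' @export
plot.variogram_model <- function(x, ...) {
  emp <- x$empirical
  plot(emp$lag, emp$gamma, pch = 16, xlab = "lag (m)",
       ylab = expression(hat(gamma)(h)), ...)
  hh <- seq(0, max(emp$lag_upper), length.out = 200)
  graphics::lines(hh, predict(x, hh), col = "steelblue", lwd = 2)
  graphics::abline(v = x$effective_range, lty = 2, col = "grey40")
  invisible(x)
}

#' @export
plot.empirical_variogram <- function(x, ...) {
  plot(x$lag, x$gamma, pch = 16, xlab = "lag (m)",
       ylab = expression(hat(gamma)(h)), ...)
  invisible(x)
}
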