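# Directional (axial) statistics for fiber and curvelet orientations.
#
# Fiber orientations are undirected, so all statistics are computed on
# doubled angles (the standard treatment of axial data): an angle theta in
# [0, 180) degrees is mapped to 2*theta on the full circle, circular moments
# are taken there, and angular results are folded back to [0, 180).

.weights_or_default <- function(angles, weights) {
  if (is.null(weights)) weights <- rep(1, length(angles))
  if (length(weights) != length(angles)) {
    stop("weights must have the same length as angles")
  }
  if (any(weights < 0)) stop("weights must be nonnegative")
  weights
}

# First trigonometric moment of the doubled angles. Returns the resultant
# length R in [0,1] and mean direction (on the doubled circle, radians).
.axial_moment <- function(angles_deg, weights, p = 1) {
  th <- 2 * p * angles_deg * pi / 180
  w <- weights / sum(weights)
  C <- sum(w * cos(th))
  S <- sum(w * sin(th))
  list(R = sqrt(C^2 + S^2), mu = atan2(S, C))
}

#' Weighted axial circular mean
#'
#' Mean orientation of a sample of axial angles, computed on doubled angles
#' and folded back to `[0, 180)`. Undefined (returns `NA`) when the resultant
#' vector is numerically zero, e.g. for the sample \{0, 90\}.
#'
#' @param angles_deg axial angles in degrees.
#' @param weights optional nonnegative weights (default all 1).
#' @return mean angle in degrees in `[0, 180)`, or `NA_real_` if undefined.
#' @export
axial_mean <- function(angles_deg, weights = NULL) {
  if (length(angles_deg) == 0) return(NA_real_)
  weights <- .weights_or_default(angles_deg, weights)
  if (sum(weights) == 0) return(NA_real_)
  m <- .axial_moment(angles_deg, weights)
  if (m$R < 1e-12) return(NA_real_)
  fold_axial(m$mu / 2 * 180 / pi)
}

#' Alignment coefficient (resultant vector length of axial angles)
#'
#' The resultant vector length of the doubled angles: a unitless number
#' between 0 and 1, where 0 means the orientations are completely dispersed
#' (e.g. \{0, 90\} or a uniform sample) and 1 means all orientations are
#' identical modulo 180.
#'
#' @inheritParams axial_mean
#' @return alignment in `[0, 1]`, or `NA_real_` for an empty sample.
#' @export
alignment <- function(angles_deg, weights = NULL) {
  if (length(angles_deg) == 0) return(NA_real_)
  weights <- .weights_or_default(angles_deg, weights)
  if (sum(weights) == 0) return(NA_real_)
  .axial_moment(angles_deg, weights)$R
}

#' Weighted axial circular median
#'
#' The sample angle minimizing the weighted mean axial deviation (the axial
#' distance is at most 90 degrees). Ties are broken toward the smallest
#' angle.
#'
#' @inheritParams axial_mean
#' @return median angle in degrees, or `NA_real_` for an empty sample.
#' @export
axial_median <- function(angles_deg, weights = NULL) {
  if (length(angles_deg) == 0) return(NA_real_)
  weights <- .weights_or_default(angles_deg, weights)
  if (sum(weights) == 0) return(NA_real_)
  cand <- sort(unique(fold_axial(angles_deg)))
  dev <- vapply(cand, function(a) {
    sum(weights * axial_diff_deg(a, angles_deg))
  }, numeric(1))
  cand[which.min(dev)]  # which.min returns the first (smallest) minimizer
}

#' Circular summary statistics of axial angles
#'
#' Computes the standard circular summary of a sample of axial orientations:
#' mean, median, circular variance (1 - R), circular standard deviation
#' (sqrt(-2 log R), converted back to axial degrees), skewness and kurtosis
#' (Fisher's circular definitions based on the second trigonometric moment),
#' the alignment coefficient, and the sample size. All moments are taken on
#' doubled angles.
#'
#' An empty or zero-weight sample yields a summary with `undefined = TRUE`
#' and `NA` statistics rather than an error, so that batch runs are robust
#' to blank images.
#'
#' @inheritParams axial_mean
#' @return an object of class `circ_summary`: a list with fields `n`,
#'   `mean_deg`, `median_deg`, `variance`, `std_deg`, `skewness`,
#'   `kurtosis`, `alignment`, `undefined`.
#' @export
circular_summary <- function(angles_deg, weights = NULL) {
  n <- length(angles_deg)
  if (n == 0 || sum(.weights_or_default(angles_deg, weights)) == 0) {
    out <- list(n = n, mean_deg = NA_real_, median_deg = NA_real_,
                variance = NA_real_, std_deg = NA_real_,
                skewness = NA_real_, kurtosis = NA_real_,
                alignment = NA_real_, undefined = TRUE)
    class(out) <- "circ_summary"
    return(out)
  }
  weights <- .weights_or_default(angles_deg, weights)
  m1 <- .axial_moment(angles_deg, weights, p = 1)
  m2 <- .axial_moment(angles_deg, weights, p = 2)
  R <- m1$R
  V <- 1 - R
  # circular std on the doubled scale, folded back to axial degrees
  std_deg <- if (R > 0) sqrt(-2 * log(R)) / 2 * 180 / pi else Inf
  skew <- if (V > 1e-12) m2$R * sin(m2$mu - 2 * m1$mu) / V^1.5 else 0
  kurt <- if (V > 1e-12) (m2$R * cos(m2$mu - 2 * m1$mu) - R^4) / V^2 else 0
  out <- list(
    n = n,
    mean_deg = axial_mean(angles_deg, weights),
    median_deg = axial_median(angles_deg, weights),
    variance = V,
    std_deg = std_deg,
    skewness = skew,
    kurtosis = kurt,
    alignment = R,
    undefined = FALSE
  )
  class(out) <- "circ_summary"
  out
}

#' @export
print.circ_summary <- function(x, ...) {
  if (x$undefined) {
    cat("Axial summary: undefined (empty sample)\n")
    return(invisible(x))
  }
  cat(sprintf(
    "Axial summary (n = %d): mean %.2f deg, median %.2f deg, alignment %.3f\n",
    x$n, x$mean_deg, x$median_deg, x$alignment))
  cat(sprintf("  variance %.3f, std %.2f deg, skewness %.3f, kurtosis %.3f\n",
              x$variance, x$std_deg, x$skewness, x$kurtosis))
  invisible(x)
}

#' @export
as.data.frame.circ_summary <- function(x, ...) {
  data.frame(n = x$n, mean_deg = x$mean_deg, median_deg = x$median_deg,
             variance = x$variance, std_deg = x$std_deg,
             skewness = x$skewness, kurtosis = x$kurtosis,
             alignment = x$alignment, undefined = x$undefined)
}

# --- von Mises machinery (used by the synthetic generator and tests) -----

#' Expected resultant length of a von Mises distribution
#'
#' The Bessel-function ratio A1(kappa) = I1(kappa) / I0(kappa), which is the
#' expected resultant vector length of a von Mises sample with concentration
#' `kappa`.
#'
#' @param kappa concentration parameter (>= 0).
#' @return expected resultant length in `[0, 1)`.
#' @export
vm_mean_resultant <- function(kappa) {
  ifelse(kappa <= 0, 0,
         besselI(kappa, 1, expon.scaled = TRUE) /
           besselI(kappa, 0, expon.scaled = TRUE))
}

#' Concentration parameter for a target resultant length
#'
#' Numerically inverts A1(kappa) = rho.
#'
#' @param rho target mean resultant length in `[0, 1)`.
#' @return concentration `kappa >= 0`.
#' @export
vm_concentration <- function(rho) {
  if (rho < 0 || rho >= 1) stop("rho must lie in [0, 1)")
  if (rho < 1e-8) return(0)
  # A1 is strictly increasing; bracket generously.
  f <- function(k) vm_mean_resultant(k) - rho
  upper <- 2
  while (f(upper) < 0) upper <- upper * 2
  stats::uniroot(f, c(1e-8, upper), tol = 1e-10)$root
}

#' Sample from a von Mises distribution
#'
#' Best-Fisher rejection sampler. Angles are returned in radians on the full
#' circle. Uses the current RNG state, so results are reproducible under
#' `set.seed()`.
#'
#' @param n number of draws.
#' @param mu mean direction in radians.
#' @param kappa concentration (>= 0); 0 gives the uniform distribution.
#' @return numeric vector of angles in `[0, 2*pi)`.
#' @export
rvonmises <- function(n, mu, kappa) {
  if (kappa < 1e-10) return(stats::runif(n, 0, 2 * pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 1L
  while (i <= n) {
    u <- stats::runif(3)
    z <- cos(pi * u[1])
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    if (cc * (2 - cc) - u[2] > 0 || log(cc / u[2]) + 1 - cc >= 0) {
      out[i] <- (mu + sign(u[3] - 0.5) * acos(clamp(f, -1, 1))) %% (2 * pi)
      i <- i + 1L
    }
  }
  out
}
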