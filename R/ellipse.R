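#' Fit an ellipse to 2D points by direct constrained conic least squares
#'
#' Direct least-squares ellipse fitting (Halir-Flusser formulation of the
#' Fitzgibbon method): the conic \eqn{ax^2 + bxy + cy^2 + dx + ey + f = 0} is
#' fit subject to the ellipse constraint \eqn{4ac - b^2 = 1}, which guarantees
#' an elliptical solution and is exact on noiseless samples of an ellipse.
#' Points are centered and scaled before the fit for numerical conditioning.
#' If the constrained solve fails to produce an ellipse (pathological
#' configurations), the fit falls back to second-moment (covariance) axes and
#' flags the result.
#'
#' @param points numeric matrix (n x 2), n >= 5, in micrometers.
#' @return object of class `onh_ellipse`: list with `center` (length-2, um),
#'   `semi_major_um`, `semi_minor_um`, `axis_angle_deg` (major-axis
#'   orientation in \eqn{[0, 180)} degrees counterclockwise from the
#'   temporal horizontal), and `method` ("conic" or "moments").
#' @examples
#' th <- seq(0, 2 * pi, length.out = 49)[-49]
#' e <- fit_ellipse_2d(cbind(1000 * cos(th), 850 * sin(th)))
#' c(e$semi_major_um, e$semi_minor_um)
#' @export
fit_ellipse_2d <- function(points) {
  points <- as.matrix(points)
  if (!is.numeric(points) || ncol(points) != 2L) {
    stop_validation("`points` must be a numeric matrix with 2 columns")
  }
  if (nrow(points) < 5L) {
    stop_onhmorph("ellipse fit needs at least 5 points", class = "onhmorph_fit_error")
  }
  if (any(!is.finite(points))) {
    stop_validation("ellipse fit: points contain non-finite coordinates")
  }
  ctr <- colMeans(points)
  sc <- sqrt(mean(rowSums(sweep(points, 2L, ctr)^2)))
  if (sc < 1e-12) {
    stop_onhmorph("ellipse fit: points are coincident", class = "onhmorph_fit_error")
  }
  x <- (points[, 1] - ctr[1]) / sc
  y <- (points[, 2] - ctr[2]) / sc

  ell <- tryCatch(fit_conic_halir(x, y), error = function(e) NULL)
  if (is.null(ell)) {
    ell <- fit_moments_axes(x, y)
    method <- "moments"
  } else {
    method <- "conic"
  }

  structure(list(
    center = ell$center * sc + ctr,
    semi_major_um = ell$a * sc,
    semi_minor_um = ell$b * sc,
    axis_angle_deg = ell$angle %% 180,
    method = method
  ), class = "onh_ellipse")
}

# Halir & Flusser numerically stable partitioned solve of the
# Fitzgibbon direct ellipse fit.
fit_conic_halir <- function(x, y) {
  D1 <- cbind(x^2, x * y, y^2)
  D2 <- cbind(x, y, 1)
  S1 <- crossprod(D1)
  S2 <- crossprod(D1, D2)
  S3 <- crossprod(D2)
  Tm <- -solve(S3, t(S2))
  M <- S1 + S2 %*% Tm
  # premultiply by inv(C1) for constraint 4ac - b^2 = 1
  M2 <- rbind(M[3, ] / 2, -M[2, ], M[1, ] / 2)
  ev <- eigen(M2)
  vec <- Re(ev$vectors)
  ok <- abs(Im(ev$values)) < 1e-8
  cond <- 4 * vec[1, ] * vec[3, ] - vec[2, ]^2
  pick <- which(ok & cond > 0)
  if (length(pick) == 0L) stop("no elliptical solution")
  a1 <- vec[, pick[1]]
  a2 <- as.numeric(Tm %*% a1)
  conic_to_ellipse(c(a1, a2))
}

# Geometric parameters from conic coefficients (A, B, C, D, E, F).
conic_to_ellipse <- function(k) {
  A <- k[1]; B <- k[2]; C <- k[3]; D <- k[4]; E <- k[5]; F <- k[6]
  den <- 4 * A * C - B^2
  if (den <= 0) stop("conic is not an ellipse")
  x0 <- (B * E - 2 * C * D) / den
  y0 <- (B * D - 2 * A * E) / den
  mu <- A * x0^2 + B * x0 * y0 + C * y0^2 + D * x0 + E * y0 + F
  Q <- matrix(c(A, B / 2, B / 2, C), 2, 2)
  eq <- eigen(Q, symmetric = TRUE)
  lam <- eq$values
  if (-mu / lam[1] <= 0 || -mu / lam[2] <= 0) stop("conic is not a real ellipse")
  # semi-axis along eigenvector v_i has length sqrt(-mu / lambda_i); the
  # conic coefficients carry an arbitrary overall sign, so pick the major
  # axis by length, not by eigenvalue order
  r <- sqrt(-mu / lam)
  major <- which.max(r)
  v <- eq$vectors[, major]
  list(center = c(x0, y0), a = max(r), b = min(r),
       angle = atan2(v[2], v[1]) * RAD2DEG)
}

# Second-moment fallback: principal axes of the point covariance; axis
# lengths scaled for uniform-angle ellipse samples (var of a*cos t = a^2/2).
fit_moments_axes <- function(x, y) {
  V <- stats::cov(cbind(x, y))
  eg <- eigen(V, symmetric = TRUE)
  if (eg$values[2] <= 0) {
    stop_onhmorph("ellipse fit failed: points are collinear",
                  class = "onhmorph_fit_error")
  }
  list(center = c(mean(x), mean(y)),
       a = sqrt(2 * eg$values[1]), b = sqrt(2 * eg$values[2]),
       angle = atan2(eg$vectors[2, 1], eg$vectors[1, 1]) * RAD2DEG)
}

#' Ovality index of a fitted ellipse
#'
#' Ratio of the minor to the major axis, in \eqn{(0, 1]}; 1 is a circle and
#' smaller values indicate a more oval opening.
#'
#' @param e an `onh_ellipse`.
#' @return dimensionless ratio.
#' @export
compute_ovality <- function(e) {
  if (!inherits(e, "onh_ellipse")) stop_validation("`e` must be an `onh_ellipse`")
  e$semi_minor_um / e$semi_major_um
}

#' Rotation angle of the BMO ellipse
#'
#' Angle between the (undirected) semimajor axis and the temporal horizontal
#' axis of the en-face image, individualized by subtracting the FoBMO-center
#' angle and folded into \eqn{[0, 90]} degrees. When the ellipse is nearly
#' circular (ovality > `circular_tol`) the major-axis orientation is
#' numerically meaningless; the function then returns 0 with attribute
#' `circular = TRUE`.
#'
#' @param e an `onh_ellipse` (fit in the laterality-normalized frame).
#' @param fobmo_deg fovea-to-BMO-center axis angle, degrees.
#' @param circular_tol ovality above which orientation is treated as undefined.
#' @return rotation angle in degrees, \eqn{[0, 90]}.
#' @export
compute_rotation_angle <- function(e, fobmo_deg = 0, circular_tol = 0.99) {
  if (!inherits(e, "onh_ellipse")) stop_validation("`e` must be an `onh_ellipse`")
  check_number(fobmo_deg, "fobmo_deg")
  if (compute_ovality(e) > circular_tol) {
    return(structure(0, circular = TRUE))
  }
  structure(fold_axis_angle(e$axis_angle_deg - fobmo_deg), circular = FALSE)
}

#' BMO area of a fitted ellipse
#'
#' \eqn{\pi a b}, converted from square micrometers to square millimeters.
#'
#' @param e an `onh_ellipse`.
#' @return area in mm^2.
#' @export
compute_bmo_area <- function(e) {
  if (!inherits(e, "onh_ellipse")) stop_validation("`e` must be an `onh_ellipse`")
  pi * e$semi_major_um * e$semi_minor_um / 1e6
}

#' @exportS3Method base::print
print.onh_ellipse <- function(x, ...) {
  cat(sprintf(
    "Ellipse: center (%.1f, %.1f) um, semi-axes %.1f x %.1f um, axis %.1f deg (%s fit)\n",
    x$center[1], x$center[2], x$semi_major_um, x$semi_minor_um,
    x$axis_angle_deg, x$method))
  invisible(x)
}
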