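#' Fit a plane to 3D points by orthogonal (total) least squares
#'
#' Fits the plane minimizing the sum of squared orthogonal distances to the
#' points, via the eigen-decomposition of the centered scatter matrix. The
#' plane normal is the eigenvector of the smallest eigenvalue; its sign is
#' fixed so the z-component is positive (ties broken towards positive x, then
#' positive y), which makes the orientation convention reproducible. An
#' orthogonal fit (rather than a regression of z on x, y) keeps the result
#' invariant to the device coordinate frame, so the tilt angle derived from
#' two such planes does not depend on how the scan volume happened to be
#' oriented.
#'
#' @param points numeric matrix with >= 3 rows and columns x, y, z (micrometers).
#' @return an object of class `onh_plane`: list with `centroid` (length-3) and
#'   `normal` (unit length-3 vector).
#' @examples
#' p <- fit_plane(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(1, 1, 0)))
#' p$normal  # (0, 0, 1)
#' @export
fit_plane <- function(points) {
  points <- as.matrix(points)
  if (!is.numeric(points) || ncol(points) != 3L) {
    stop_validation("`points` must be a numeric matrix with 3 columns (x, y, z)")
  }
  if (nrow(points) < 3L) {
    stop_validation("plane fit needs at least 3 points")
  }
  if (any(!is.finite(points))) {
    stop_validation("plane fit: points contain non-finite coordinates")
  }
  centroid <- colMeans(points)
  centered <- sweep(points, 2L, centroid)
  scatter <- crossprod(centered)
  eig <- eigen(scatter, symmetric = TRUE)
  # eigenvalues descending; collinear points leave only one non-trivial
  # direction, making the plane orientation about the line arbitrary
  if (eig$values[2] <= max(eig$values[1], 1) * 1e-12) {
    stop_onhmorph("degenerate geometry: points are collinear, plane fit is not unique",
                  class = "onhmorph_degenerate_error")
  }
  normal <- eig$vectors[, 3L]
  normal <- orient_normal(normal)
  structure(list(centroid = centroid, normal = normal / sqrt(sum(normal^2))),
            class = "onh_plane")
}

# Sign convention: positive z-component; if z ~ 0, positive x, then y.
orient_normal <- function(n, tol = 1e-12) {
  s <- if (abs(n[3]) > tol) sign(n[3]) else if (abs(n[1]) > tol) sign(n[1]) else sign(n[2])
  if (s == 0) s <- 1
  n * s
}

#' Angle between two planes
#'
#' Returns the acute angle between the plane normals in degrees, in
#' \eqn{[0, 90]}. Antiparallel normals describe the same plane orientation, so
#' the absolute dot product is used and the result is symmetric in its
#' arguments. This is the BMO tilt angle when applied to the fitted BMO and
#' Bruch's-membrane-boundary planes.
#'
#' @param a,b `onh_plane` objects (or lists with a unit `normal`).
#' @return angle in degrees.
#' @export
angle_between_planes <- function(a, b) {
  na <- unit(a$normal)
  nb <- unit(b$normal)
  acos(clamp(abs(sum(na * nb)), 0, 1)) * RAD2DEG
}

#' Project 3D points orthogonally onto a plane
#'
#' Projects points onto `ref` and expresses them in an in-plane orthonormal
#' basis \eqn{(e_1, e_2)}, where \eqn{e_1} is the unit projection of the
#' en-face temporal axis (the +x axis of the laterality-normalized frame) onto
#' the plane and \eqn{e_2 = n \times e_1}. In-plane distances are preserved,
#' and the basis ties the in-plane angular origin to the temporal horizontal,
#' which is what the rotation-angle convention requires.
#'
#' @param points numeric matrix (n x 3).
#' @param ref an `onh_plane`.
#' @return n x 2 matrix of in-plane coordinates (micrometers).
#' @export
project_to_plane <- function(points, ref) {
  points <- as.matrix(points)
  if (ncol(points) != 3L) stop_validation("`points` must have 3 columns")
  n <- unit(ref$normal)
  t_axis <- c(1, 0, 0)
  e1 <- t_axis - sum(t_axis * n) * n
  if (sqrt(sum(e1^2)) < 1e-9) {
    stop_onhmorph("degenerate basis: temporal axis is parallel to the plane normal",
                  class = "onhmorph_degenerate_error")
  }
  e1 <- unit(e1)
  e2 <- cross3(n, e1)
  # coordinates along the in-plane basis; a point already in the plane z = 0
  # keeps its (x, y), and in-plane distances are preserved in general
  cbind(points %*% e1, points %*% e2)
}

#' @exportS3Method base::print
print.onh_plane <- function(x, ...) {
  cat("Plane: centroid (", paste(signif(x$centroid, 6), collapse = ", "),
      ") um, normal (", paste(signif(x$normal, 6), collapse = ", "), ")\n",
      sep = "")
  invisible(x)
}
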