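#' @keywords internal
"_PACKAGE"

#' @importFrom stats coef dist median nlminb optim prcomp quantile rnorm sd setNames
#' @importFrom utils read.table write.table head tail
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

vnorm <- function(v) sqrt(sum(v^2))

unitize <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("cannot normalize a (near-)zero vector")
  v / n
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

## Deterministic right-handed orthonormal basis (e1, e2) for the plane
## perpendicular to unit vector u.
plane_basis <- function(u) {
  u <- unitize(u)
  ref <- if (abs(u[1]) <= abs(u[2]) && abs(u[1]) <= abs(u[3])) {
    c(1, 0, 0)
  } else if (abs(u[2]) <= abs(u[3])) c(0, 1, 0) else c(0, 0, 1)
  e1 <- unitize(cross3(u, ref))
  e2 <- cross3(u, e1)
  cbind(e1, e2)
}

#' Rotation matrix about an axis (Rodrigues form)
#' @param u length-3 axis (normalized internally).
#' @param angle rotation angle in radians.
#' @return 3x3 proper rotation matrix.
#' @export
rotation_about_axis <- function(u, angle) {
  u <- unitize(u)
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

#' Angle between two axes
#'
#' Undirected: `u` and `-u` are the same axis, so the result lies in
#' \[0, 90\] degrees.
#' @param u,v length-3 direction vectors.
#' @return angle in degrees.
#' @export
axis_angle_deg <- function(u, v) {
  u <- unitize(u); v <- unitize(v)
  rad2deg(acos(pmin(1, abs(sum(u * v)))))
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

## Expand a list/matrix of residue intervals c(start, end) into a vector.
expand_intervals <- function(intervals) {
  if (is.numeric(intervals) && is.null(dim(intervals))) {
    if (length(intervals) == 2L && intervals[1] <= intervals[2]) {
      intervals <- list(intervals)
    } else {
      return(as.integer(intervals))
    }
  }
  if (is.matrix(intervals)) intervals <- asplit(intervals, 1)
  unlist(lapply(intervals, function(iv) seq.int(iv[1], iv[2])), use.names = FALSE)
}
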