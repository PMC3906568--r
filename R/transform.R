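#' 3D affine transforms
#'
#' Transforms are 4x4 homogeneous matrices in the column-vector convention:
#' a point \code{p = c(x, y, z)} maps to \code{(M %*% c(p, 1))[1:3]}.
#' Composition is matrix product, applied left-of-vector, so
#' \code{tf_compose(A, B)} applies \code{B} first, then \code{A}.
#' Translations are in meters.
#'
#' @param offset length-3 numeric translation (m).
#' @param scale length-1 or length-3 numeric scale factors.
#' @param angle_deg rotation about the z axis, degrees, counter-clockwise.
#' @return A 4x4 numeric matrix of class \code{"transform3d"}.
#' @examples
#' tf <- tf_compose(tf_translate(c(1e-4, 0, 0)), tf_scale(2e-6))
#' tf_apply(tf, c(10, 10, 0))
#' @name transform3d
NULL

new_transform <- function(m) {
  stopifnot(is.matrix(m), all(dim(m) == c(4L, 4L)))
  structure(m, class = "transform3d")
}

#' @rdname transform3d
#' @export
tf_identity <- function() new_transform(diag(4))

#' @rdname transform3d
#' @export
tf_translate <- function(offset) {
  offset <- rep_len(as.numeric(offset), 3L)
  m <- diag(4)
  m[1:3, 4] <- offset
  new_transform(m)
}

#' @rdname transform3d
#' @export
tf_scale <- function(scale) {
  scale <- as.numeric(scale)
  if (length(scale) == 1L) scale <- rep(scale, 3L)
  if (length(scale) == 2L) scale <- c(scale, 1)
  m <- diag(c(scale, 1))
  new_transform(m)
}

#' @rdname transform3d
#' @export
tf_rotate_z <- function(angle_deg) {
  a <- angle_deg * pi / 180
  m <- diag(4)
  m[1:2, 1:2] <- matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2L, 2L)
  new_transform(m)
}

#' Compose transforms (rightmost applied first)
#' @param ... transforms.
#' @export
tf_compose <- function(...) {
  ts <- list(...)
  new_transform(Reduce(`%*%`, lapply(ts, unclass)))
}

#' Invert a transform
#' @param tf a \code{transform3d}.
#' @export
tf_invert <- function(tf) {
  if (abs(det(unclass(tf)[1:3, 1:3])) <= 1e-12)
    stop("transform is singular (|det| <= 1e-12)")
  new_transform(solve(unclass(tf)))
}

#' Apply a transform to points
#'
#' @param tf a \code{transform3d}.
#' @param points length-3 vector or n x 3 matrix of points (m).
#' @return Same shape as the input.
#' @export
tf_apply <- function(tf, points) {
  vec <- !is.matrix(points)
  p <- if (vec) matrix(as.numeric(points), 1L) else points
  if (ncol(p) == 2L) p <- cbind(p, 0)
  stopifnot(ncol(p) == 3L)
  if (!all(is.finite(p))) stop("non-finite coordinates")
  out <- t(unclass(tf) %*% rbind(t(p), 1))[, 1:3, drop = FALSE]
  if (vec) as.numeric(out) else out
}

#' Build a transform from offset / scale / rotation blocks
#'
#' The convention is translate(offset) o rotate_z(angle) o scale(scale):
#' offsets are expressed in the parent frame (post-scale).
#' @param offset,scale,angle_deg see \code{\link{transform3d}}.
#' @export
tf_from_parts <- function(offset = c(0, 0, 0), scale = c(1, 1, 1),
                          angle_deg = 0) {
  tf_compose(tf_translate(offset), tf_rotate_z(angle_deg), tf_scale(scale))
}

#' @export
print.transform3d <- function(x, ...) {
  cat("<transform3d>\n")
  print(unclass(x))
  invisible(x)
}
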