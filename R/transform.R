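#' Rigid-body transform
#'
#' A proper rigid-body transform: a 3x3 rotation matrix (orthonormal,
#' determinant +1) plus a 3-vector translation in Angstrom. Transforms act on
#' row-vector coordinates as `x %*% t(R) + t`, i.e. rotation first, then
#' translation.
#'
#' @param rotation 3x3 orthonormal matrix with determinant +1.
#' @param translation numeric length-3 translation (Angstrom).
#' @return An object of class `rigid_transform` with elements `R` and `t`.
#' @examples
#' rt <- rigid_transform(rot_z(90), c(0, 0, 27.57))
#' rt_apply(rt, c(1, 0, 0))
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  translation <- as.numeric(translation)
  if (!identical(dim(rotation), c(3L, 3L)))
    stop("'rotation' must be a 3x3 matrix")
  if (length(translation) != 3L)
    stop("'translation' must have length 3")
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-9)
    stop("'rotation' is not orthonormal (tolerance 1e-9)")
  if (abs(det(rotation) - 1) > 1e-9)
    stop("'rotation' must be proper (det = +1); reflections are not allowed")
  structure(list(R = rotation, t = translation), class = "rigid_transform")
}

#' @rdname rigid_transform
#' @export
rt_identity <- function() rigid_transform()

#' Compose two rigid transforms
#'
#' Returns the transform equivalent to applying `b` first, then `a`
#' (function composition `a o b`).
#'
#' @param a,b `rigid_transform` objects.
#' @return A `rigid_transform`.
#' @export
rt_compose <- function(a, b) {
  stopifnot(inherits(a, "rigid_transform"), inherits(b, "rigid_transform"))
  structure(list(R = a$R %*% b$R, t = as.numeric(a$R %*% b$t) + a$t),
            class = "rigid_transform")
}

#' Invert a rigid transform
#'
#' @param a A `rigid_transform`.
#' @return The inverse `rigid_transform`, satisfying
#'   `rt_compose(a, rt_inverse(a)) == rt_identity()` to within 1e-9.
#' @export
rt_inverse <- function(a) {
  stopifnot(inherits(a, "rigid_transform"))
  Rt <- t(a$R)
  structure(list(R = Rt, t = as.numeric(-Rt %*% a$t)), class = "rigid_transform")
}

#' Apply a rigid transform to coordinates
#'
#' @param a A `rigid_transform`.
#' @param xyz Numeric vector of length 3 or an n x 3 matrix of coordinates
#'   (Angstrom).
#' @return Transformed coordinates with the same shape as the input.
#' @export
rt_apply <- function(a, xyz) {
  stopifnot(inherits(a, "rigid_transform"))
  if (is.null(dim(xyz))) {
    if (length(xyz) != 3L) stop("'xyz' must be length 3 or an n x 3 matrix")
    return(as.numeric(a$R %*% xyz) + a$t)
  }
  xyz <- as.matrix(xyz)
  if (ncol(xyz) != 3L) stop("'xyz' must be length 3 or an n x 3 matrix")
  sweep(xyz %*% t(a$R), 2L, -a$t)
}

#' Rotation about the z axis
#'
#' @param deg Angle in degrees (counter-clockwise looking down +z).
#' @return A 3x3 rotation matrix.
#' @export
rot_z <- function(deg) {
  th <- deg * pi / 180
  c1 <- cos(th); s1 <- sin(th)
  matrix(c(c1, s1, 0, -s1, c1, 0, 0, 0, 1), nrow = 3)
}

#' Rotation about the x axis
#'
#' @param deg Angle in degrees.
#' @return A 3x3 rotation matrix.
#' @export
rot_x <- function(deg) {
  th <- deg * pi / 180
  c1 <- cos(th); s1 <- sin(th)
  matrix(c(1, 0, 0, 0, c1, s1, 0, -s1, c1), nrow = 3)
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat("rigid transform\n  rotation:\n")
  print(round(x$R, 6))
  cat("  translation (A):", paste(signif(x$t, 7), collapse = ", "), "\n")
  invisible(x)
}

# minimal circular distance between angle a and b on a circle of the given
# period (degrees); vectorized over a and b
circ_dist <- function(a, b = 0, period = 360) {
  d <- (a - b) %% period
  pmin(d, period - d)
}
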