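#' Rigid-body transforms
#'
#' A rigid transform is a proper rotation `R` (3x3, orthonormal, det +1) and
#' a translation `t` (length 3, Angstrom); it maps a coordinate row `x` to
#' `R x + t`.  Throughout the package, transforms superimpose structure 2
#' onto structure 1.
#'
#' @param rotation 3x3 proper rotation matrix.
#' @param translation numeric length-3 translation vector.
#' @return An object of class `rigid_transform`.
#' @examples
#' tr <- rigid_transform(diag(3), c(1, 0, 0))
#' apply_transform(tr, matrix(0, 1, 3))
#' @export
rigid_transform <- function(rotation, translation = c(0, 0, 0)) {
  rotation <- unname(as.matrix(rotation))
  translation <- unname(as.numeric(translation))
  if (!all(dim(rotation) == c(3L, 3L)) || length(translation) != 3L) {
    abort("rotation must be 3x3 and translation length 3",
          class = "castalign_error_bad_rotation")
  }
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-6 ||
      abs(det(rotation) - 1) > 1e-6) {
    abort("rotation is not a proper rotation (orthonormal, det +1)",
          class = "castalign_error_bad_rotation")
  }
  structure(list(rotation = rotation, translation = translation),
            class = "rigid_transform")
}

#' @rdname rigid_transform
#' @export
identity_transform <- function() rigid_transform(diag(3), c(0, 0, 0))

#' @rdname rigid_transform
#' @param transform A `rigid_transform`.
#' @param coords n x 3 coordinate matrix (rows are points).
#' @export
apply_transform <- function(transform, coords) {
  coords <- as.matrix(coords)
  sweep(coords %*% t(transform$rotation), 2L, -transform$translation)
}

#' @rdname rigid_transform
#' @export
invert_transform <- function(transform) {
  Rt <- t(transform$rotation)
  rigid_transform(Rt, -drop(Rt %*% transform$translation))
}

#' @rdname rigid_transform
#' @param a,b Two `rigid_transform`s; `compose_transform(a, b)` applies `b`
#'   first, then `a`.
#' @export
compose_transform <- function(a, b) {
  rigid_transform(a$rotation %*% b$rotation,
                  drop(a$rotation %*% b$translation) + a$translation)
}

#' Angular distance between two rotations, in degrees
#'
#' The geodesic angle of the relative rotation `R1 R2^T`; zero iff the
#' rotations are equal.
#'
#' @param r1,r2 3x3 rotation matrices or `rigid_transform`s.
#' @return Angle in degrees, in `[0, 180]`.
#' @export
rotation_angle <- function(r1, r2 = diag(3)) {
  if (inherits(r1, "rigid_transform")) r1 <- r1$rotation
  if (inherits(r2, "rigid_transform")) r2 <- r2$rotation
  ctheta <- (sum(diag(r1 %*% t(r2))) - 1) / 2
  acos(min(1, max(-1, ctheta))) * 180 / pi
}

#' Uniform random rotation matrix
#'
#' Quaternion method; draws from the current RNG stream (wrap in
#' [withr::with_seed()] or `set.seed()` for reproducibility).
#'
#' @return A 3x3 proper rotation matrix.
#' @export
random_rotation <- function() {
  q <- rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), 3L, 3L, byrow = TRUE)
}

#' Deterministic random rigid transform
#'
#' A uniformly random proper rotation plus a uniform translation in
#' `[-t_max, t_max]^3`, reproducible for a given seed.
#'
#' @param seed Integer seed.
#' @param t_max Half-width of the translation cube (Angstrom).
#' @return A `rigid_transform`.
#' @export
random_rigid_transform <- function(seed, t_max = 20) {
  withr::with_seed(as.integer(seed), {
    rigid_transform(random_rotation(), runif(3, -t_max, t_max))
  })
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat("<rigid_transform>\n rotation:\n")
  print(round(x$rotation, 6))
  cat(" translation:", paste(sprintf("%.6f", x$translation), collapse = " "), "\n")
  invisible(x)
}
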