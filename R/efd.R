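#' Ellipsoidal fibril distributions (EFDs)
#'
#' An EFD encodes a collagen fibril orientation distribution as a 3x3 symmetric
#' positive-definite (SPD) structure tensor. Its eigenvalues are the
#' semiprincipal radii of the distribution ellipsoid and its eigenvectors the
#' corresponding axes, so an EFD with radii `(5, 1, 1)` describes fibrils
#' strongly aligned along the leading eigenvector.
#'
#' `efd()` validates (and symmetrizes) a 3x3 matrix; `efd_from_axes()` builds
#' the tensor from its spectral form, radii and an orthonormal axis matrix.
#'
#' @param tensor A 3x3 numeric matrix. It is symmetrized as `(P + t(P))/2`;
#'   matrices that are not SPD after symmetrization are rejected.
#' @param radii Numeric vector of three strictly positive semiprincipal radii.
#' @param rotation 3x3 orthonormal matrix whose columns are the semiprincipal
#'   axes associated with `radii`.
#' @return An object of class `"efd"`: the SPD tensor with the class attribute.
#' @examples
#' efd_from_axes(c(5, 1, 1))                  # diag(5, 1, 1)
#' efd(diag(3))                               # isotropic
#' @export
efd <- function(tensor) {
  if (!is.matrix(tensor) || !identical(dim(tensor), c(3L, 3L)) ||
      !is.numeric(tensor)) {
    stop("EFD tensor must be a 3x3 numeric matrix")
  }
  scale <- max(abs(tensor), 1e-300)
  if (max(abs(tensor - t(tensor))) > 1e-12 * scale) {
    stop("EFD tensor must be symmetric (relative tolerance 1e-12)")
  }
  P <- (tensor + t(tensor)) / 2
  ev <- eigen(P, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev <= 0)) {
    stop("EFD tensor must be positive-definite; eigenvalues: ",
         paste(signif(ev, 6), collapse = ", "))
  }
  structure(P, class = "efd")
}

#' @rdname efd
#' @export
efd_from_axes <- function(radii, rotation = diag(3)) {
  radii <- as.numeric(radii)
  if (length(radii) != 3 || any(!is.finite(radii)) || any(radii <= 0)) {
    stop("radii must be three strictly positive numbers")
  }
  if (!is.matrix(rotation) || !identical(dim(rotation), c(3L, 3L)) ||
      max(abs(crossprod(rotation) - diag(3))) > 1e-10) {
    stop("rotation must be a 3x3 orthonormal matrix (RtR = I to 1e-10)")
  }
  P <- rotation %*% diag(radii) %*% t(rotation)
  structure((P + t(P)) / 2, class = "efd")
}

#' Spectral decomposition of an EFD
#'
#' Extracts the semiprincipal radii (eigenvalues, sorted descending) and the
#' orthonormal axes (eigenvector columns, in matching order) of an EFD. For
#' degenerate spectra any orthonormal completion of the eigenspace may be
#' returned; all downstream operations are invariant to that choice.
#'
#' @param x An `"efd"` object or a 3x3 SPD matrix.
#' @return A list with `radii` (descending) and `axes` (3x3 orthonormal,
#'   columns matching `radii`).
#' @export
spectral_axes <- function(x) {
  P <- as_efd(x)
  e <- eigen(P, symmetric = TRUE)
  list(radii = e$values, axes = e$vectors)
}

as_efd <- function(x) {
  if (inherits(x, "efd")) return(x)
  efd(x)
}

#' Fractional anisotropy of an EFD
#'
#' FA measures how far the semiprincipal radii deviate from equality,
#' \deqn{FA = \frac{1}{\sqrt 2}\,
#'   \frac{\sqrt{(\beta_1-\beta_2)^2 + (\beta_2-\beta_3)^2 +
#'   (\beta_3-\beta_1)^2}}{\sqrt{\beta_1^2+\beta_2^2+\beta_3^2}},}
#' ranging from 0 (isotropic) to 1 (uniaxial limit). FA is invariant under
#' rotation of the EFD and under uniform scaling of the radii.
#'
#' @param x An `"efd"` object, a 3x3 SPD matrix, or a numeric vector of three
#'   positive radii.
#' @return FA in `[0, 1]`.
#' @examples
#' fractional_anisotropy(c(1, 1, 1))   # 0
#' fractional_anisotropy(c(5, 1, 1))   # 4 / sqrt(27)
#' @export
fractional_anisotropy <- function(x) {
  if (is.numeric(x) && is.null(dim(x)) && length(x) == 3) {
    if (any(x <= 0)) stop("radii must be strictly positive")
    b <- x
  } else {
    b <- spectral_axes(x)$radii
  }
  fa <- sqrt(((b[1] - b[2])^2 + (b[2] - b[3])^2 + (b[3] - b[1])^2) /
               (2 * sum(b^2)))
  min(max(fa, 0), 1)
}

#' Elementary rotation matrices
#'
#' Right-handed rotations about the coordinate axes, in degrees.
#'
#' @param deg Rotation angle in degrees.
#' @return A 3x3 rotation matrix.
#' @export
rot_x <- function(deg) {
  t <- deg * pi / 180
  matrix(c(1, 0, 0, 0, cos(t), sin(t), 0, -sin(t), cos(t)), 3, 3)
}

#' @rdname rot_x
#' @export
rot_y <- function(deg) {
  t <- deg * pi / 180
  matrix(c(cos(t), 0, -sin(t), 0, 1, 0, sin(t), 0, cos(t)), 3, 3)
}

#' @rdname rot_x
#' @export
rot_z <- function(deg) {
  t <- deg * pi / 180
  matrix(c(cos(t), sin(t), 0, -sin(t), cos(t), 0, 0, 0, 1), 3, 3)
}

#' @export
print.efd <- function(x, ...) {
  s <- spectral_axes(x)
  cat("EFD structure tensor\n")
  print(unclass(x), ...)
  cat("radii:", paste(signif(s$radii, 6), collapse = ", "),
      " FA:", signif(fractional_anisotropy(x), 4), "\n")
  invisible(x)
}

# 6-component packing (xx, yy, zz, xy, xz, yz) used for tensor field storage
sym3_to_vec6 <- function(P) {
  c(P[1, 1], P[2, 2], P[3, 3], P[1, 2], P[1, 3], P[2, 3])
}

vec6_to_sym3 <- function(v) {
  matrix(c(v[1], v[4], v[5], v[4], v[2], v[6], v[5], v[6], v[3]), 3, 3)
}

# matrix log / exp on the SPD cone via eigendecomposition
logm_spd <- function(P) {
  e <- eigen(P, symmetric = TRUE)
  e$vectors %*% (log(e$values) * t(e$vectors))
}

expm_sym <- function(S) {
  e <- eigen(S, symmetric = TRUE)
  e$vectors %*% (exp(e$values) * t(e$vectors))
}
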