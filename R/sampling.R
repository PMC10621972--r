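#' Monte-Carlo sampling of fibril directions from an EFD
#'
#' Emulates filopodial probing of the matrix: a candidate point `r` is drawn
#' uniformly in the cube bounding the distribution ellipsoid in its principal
#' frame (each component in `[-max(beta), max(beta)]`), accepted if
#' `r1^2/beta1^2 + r2^2/beta2^2 + r3^2/beta3^2 < 1`, normalized to a unit
#' vector, and rotated into the global frame by the EFD eigenvector basis.
#' Uniform-in-volume sampling followed by normalization yields a directional
#' density proportional to the cube of the ellipsoid radius function, i.e. a
#' sharper distribution than the radius function itself; this sampler is the
#' definition of fibril probing used throughout the package.
#'
#' Samples consume the R random number stream, so runs are reproducible under
#' `set.seed()`.
#'
#' @param efd An `"efd"` object (or 3x3 SPD matrix).
#' @param n Number of directions to draw.
#' @param max_iter Cap on total candidate draws (diagnostic guard; the
#'   rejection loop terminates with probability 1).
#' @return If `n == 1`, a length-3 unit vector; otherwise an `n` x 3 matrix of
#'   unit row vectors with attribute `"acceptance"`, the empirical rejection
#'   acceptance rate (which estimates the ellipsoid-to-bounding-cube volume
#'   ratio).
#' @export
sample_direction <- function(efd, n = 1, max_iter = 1e6) {
  s <- spectral_axes(efd)
  b <- s$radii
  Q <- s$axes
  rmax <- b[1]
  # acceptance probability = ellipsoid volume / bounding cube volume
  acc <- (4 / 3) * pi * prod(b) / (2 * rmax)^3
  out <- matrix(NA_real_, n, 3)
  got <- 0L
  n_cand <- 0
  n_acc <- 0
  while (got < n) {
    m <- min(ceiling((n - got) / acc * 1.2) + 16, 5e5)
    if (n_cand + m > max_iter) {
      stop("sample_direction: rejection iteration cap exceeded (acceptance ",
           signif(acc, 3), ")")
    }
    r <- matrix(stats::runif(3 * m, -rmax, rmax), m, 3)
    n_cand <- n_cand + m
    keep <- (r[, 1] / b[1])^2 + (r[, 2] / b[2])^2 + (r[, 3] / b[3])^2 < 1
    # drop the (measure-zero) origin to avoid 0/0 on normalization
    keep <- keep & (rowSums(r^2) > 0)
    n_acc <- n_acc + sum(keep)
    r <- r[keep, , drop = FALSE]
    if (nrow(r) > 0) {
      take <- min(nrow(r), n - got)
      r <- r[seq_len(take), , drop = FALSE] / sqrt(rowSums(r[seq_len(take), ,
                                                             drop = FALSE]^2))
      out[got + seq_len(take), ] <- r %*% t(Q)
      got <- got + take
    }
  }
  if (n == 1) {
    as.numeric(out)
  } else {
    attr(out, "acceptance") <- n_acc / n_cand
    out
  }
}

#' Natural (reference) coordinates in a hexahedral cell
#'
#' Inverse of the trilinear map for an axis-aligned hexahedral cell: returns
#' coordinates in `[-1, 1]^3` such that the trilinear interpolation of the
#' corner positions reproduces `position`.
#'
#' @param cell_bounds 2x3 matrix: row 1 the lower corner, row 2 the upper
#'   corner (mm).
#' @param position Length-3 position (mm), inside the cell to within 1e-9 mm.
#' @return Length-3 natural coordinates in `[-1, 1]^3`.
#' @export
natural_coordinates <- function(cell_bounds, position) {
  lo <- cell_bounds[1, ]
  hi <- cell_bounds[2, ]
  if (any(position < lo - 1e-9) || any(position > hi + 1e-9)) {
    stop("position is outside the cell")
  }
  xi <- 2 * (position - lo) / (hi - lo) - 1
  pmin(pmax(xi, -1), 1)
}

# corner sign table, FE hex8 ordering:
# (-,-,-) (+,-,-) (+,+,-) (-,+,-) (-,-,+) (+,-,+) (+,+,+) (-,+,+)
hex8_signs <- matrix(c(
  -1, -1, -1,   1, -1, -1,   1, 1, -1,  -1, 1, -1,
  -1, -1,  1,   1, -1,  1,   1, 1,  1,  -1, 1,  1
), ncol = 3, byrow = TRUE)

#' Trilinear interpolation weights
#'
#' Standard hexahedral shape functions
#' `N_i(xi) = (1/8) (1 + s_i1 xi_1)(1 + s_i2 xi_2)(1 + s_i3 xi_3)` evaluated at
#' natural coordinates `xi`; the eight weights are non-negative and sum to 1.
#' Corner ordering is the finite-element hex8 convention (bottom face
#' counter-clockwise from the lower corner, then the top face).
#'
#' @param natural_coords Length-3 vector in `[-1, 1]^3`.
#' @return Numeric vector of 8 weights.
#' @export
interpolation_weights <- function(natural_coords) {
  xi <- as.numeric(natural_coords)
  if (length(xi) != 3 || any(abs(xi) > 1 + 1e-12)) {
    stop("natural coordinates must lie in [-1, 1]^3")
  }
  w <- (1 + hex8_signs[, 1] * xi[1]) *
    (1 + hex8_signs[, 2] * xi[2]) *
    (1 + hex8_signs[, 3] * xi[3]) / 8
  pmax(w, 0)
}

#' Geodesic (Log-Euclidean) interpolation of EFDs
#'
#' Weighted mean of SPD tensors on the SPD cone. The default Log-Euclidean
#' mean `exp(sum(w_i log(P_i)))` preserves symmetry and positive-definiteness
#' for any convex weights; the affine-invariant (Karcher) mean is available
#' for sensitivity checks and is computed by fixed-point iteration.
#'
#' @param efds List of `"efd"` objects (or SPD matrices).
#' @param weights Non-negative weights summing to 1, one per tensor.
#' @param method `"log_euclidean"` (default) or `"affine_invariant"`.
#' @return The interpolated `"efd"`.
#' @export
geodesic_interpolate <- function(efds, weights,
                                 method = c("log_euclidean",
                                            "affine_invariant")) {
  method <- match.arg(method)
  if (length(efds) != length(weights)) {
    stop("one weight per tensor is required")
  }
  if (any(weights < -1e-12) || abs(sum(weights) - 1) > 1e-9) {
    stop("weights must be non-negative and sum to 1")
  }
  weights <- pmax(weights, 0)
  Ps <- lapply(efds, function(p) unclass(as_efd(p)))
  if (method == "log_euclidean") {
    S <- Reduce(`+`, Map(function(P, w) w * logm_spd(P), Ps, weights))
    return(structure(expm_sym((S + t(S)) / 2), class = "efd"))
  }
  # affine-invariant Karcher mean by fixed-point iteration
  M <- Reduce(`+`, Map(`*`, Ps, weights))
  for (it in 1:50) {
    e <- eigen(M, symmetric = TRUE)
    Mh <- e$vectors %*% (sqrt(e$values) * t(e$vectors))
    Mih <- e$vectors %*% ((1 / sqrt(e$values)) * t(e$vectors))
    S <- Reduce(`+`, Map(function(P, w) {
      w * logm_spd(Mih %*% P %*% Mih)
    }, Ps, weights))
    S <- (S + t(S)) / 2
    if (max(abs(S)) < 1e-12) break
    M <- Mh %*% expm_sym(S) %*% Mh
    M <- (M + t(M)) / 2
  }
  structure(M, class = "efd")
}

#' Linear interpolation of orientation vectors (legacy mode)
#'
#' Normalized weighted arithmetic sum of unit vectors, the interpolation rule
#' of the legacy vector-field representation of collagen orientation. If the
#' weighted sum cancels to (numerically) zero, the input with the highest
#' weight is returned and the event is signalled as a warning.
#'
#' @param vectors n x 3 matrix of unit row vectors.
#' @param weights Non-negative weights summing to 1.
#' @return A unit length-3 vector.
#' @export
vector_interpolate <- function(vectors, weights) {
  if (is.null(dim(vectors))) vectors <- matrix(vectors, ncol = 3)
  if (nrow(vectors) != length(weights)) {
    stop("one weight per vector is required")
  }
  if (any(weights < -1e-12) || abs(sum(weights) - 1) > 1e-9) {
    stop("weights must be non-negative and sum to 1")
  }
  v <- colSums(vectors * weights)
  nv <- sqrt(sum(v^2))
  if (nv < 1e-12) {
    warning("vector interpolation cancelled; falling back to the ",
            "highest-weight vector")
    v <- vectors[which.max(weights), ]
    nv <- sqrt(sum(v^2))
  }
  v / nv
}
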