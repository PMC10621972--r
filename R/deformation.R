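#' Deformation gradients and canonical load cases
#'
#' A deformation gradient is a 3x3 matrix `F` with positive determinant
#' describing the local affine mapping of material. `deformation_gradient()`
#' validates a matrix; the `def_*()` constructors build the canonical
#' homogeneous load cases used by the verification harness:
#' uniaxial `F = diag(lambda, 1, 1)`, equibiaxial `F = diag(lambda, lambda, 1)`,
#' simple shear `F = I + kappa e1 (x) e2`, and pure shear
#' `F = diag(1 + kappa, 1/(1 + kappa), 1)`.
#'
#' @param F A 3x3 numeric matrix with `det(F) > 0`.
#' @param lambda Stretch ratio (1 is the undeformed state).
#' @param kappa Shear ratio (0 is the undeformed state).
#' @return A `"defgrad"` 3x3 matrix.
#' @export
deformation_gradient <- function(F) {
  if (!is.matrix(F) || !identical(dim(F), c(3L, 3L)) || !is.numeric(F)) {
    stop("deformation gradient must be a 3x3 numeric matrix")
  }
  if (det(F) <= 0) stop("deformation gradient must have det(F) > 0")
  structure(F, class = "defgrad")
}

#' @rdname deformation_gradient
#' @export
def_uniaxial <- function(lambda) deformation_gradient(diag(c(lambda, 1, 1)))

#' @rdname deformation_gradient
#' @export
def_biaxial <- function(lambda) deformation_gradient(diag(c(lambda, lambda, 1)))

#' @rdname deformation_gradient
#' @export
def_simple_shear <- function(kappa) {
  F <- diag(3)
  F[1, 2] <- kappa
  deformation_gradient(F)
}

#' @rdname deformation_gradient
#' @export
def_pure_shear <- function(kappa) {
  deformation_gradient(diag(c(1 + kappa, 1 / (1 + kappa), 1)))
}

#' Net mapping from the unit sphere to the deformed distribution
#'
#' The composition `Fn = F %*% P0` maps unit-sphere directions first onto the
#' undeformed distribution ellipsoid (via the structure tensor `P0`) and then
#' through the material deformation `F`. `Fn` is generally non-symmetric.
#'
#' @param P0 Initial EFD.
#' @param F Deformation gradient.
#' @return The 3x3 net mapping matrix.
#' @export
net_mapping <- function(P0, F) {
  unclass(F) %*% unclass(as_efd(P0))
}

#' Pseudo-deformation of an EFD
#'
#' The deformed distribution mapping `Fn = F %*% P0` is generally not
#' symmetric, so the deformed distribution is not ellipsoidal. The
#' pseudo-deformed EFD is the SPD left-stretch factor `Vn` of the polar
#' decomposition `Fn = Vn %*% Rn`, i.e. the rotation `Rn` is replaced by the
#' identity. `Vn` is computed from the singular value decomposition
#' `Fn = U S t(W)` as `Vn = U S t(U)`, which is numerically robust for
#' near-singular mappings. When `F` is itself SPD and commutes with `P0` the
#' result equals `F %*% P0` exactly (affine-exact regime).
#'
#' @param P0 Initial EFD.
#' @param F Deformation gradient.
#' @return The pseudo-deformed EFD (`"efd"`).
#' @export
pseudo_deform <- function(P0, F) {
  Fn <- net_mapping(P0, F)
  scale <- max(abs(Fn))
  if (max(abs(Fn - t(Fn))) <= 1e-13 * scale) {
    # already symmetric: the polar factor of an SPD matrix is itself, so
    # return it bit-exactly (zero-strain and axis-aligned affine cases)
    S <- (Fn + t(Fn)) / 2
    if (all(eigen(S, symmetric = TRUE, only.values = TRUE)$values > 0)) {
      return(structure(S, class = "efd"))
    }
  }
  s <- svd(Fn)
  if (min(s$d) <= 1e-12 * max(s$d)) {
    stop(sprintf(
      "net mapping is numerically singular (condition number %.3g)",
      max(s$d) / max(min(s$d), .Machine$double.xmin)
    ))
  }
  V <- s$u %*% (s$d * t(s$u))
  structure((V + t(V)) / 2, class = "efd")
}

#' Squared-stretch diagnostic tensor
#'
#' The prior-art comparator `Bhat = Fn %*% t(Fn)`: an analogue of the left
#' Cauchy-Green tensor acting from the unit sphere. Its eigenvalues are the
#' squares of the pseudo-deformed radii (the eigenvalues of `Vn`), so using it
#' directly as an EFD overstates stretch; it is provided for diagnostics only.
#'
#' @inheritParams pseudo_deform
#' @return A 3x3 SPD matrix.
#' @export
b_hat_diagnostic <- function(P0, F) {
  Fn <- net_mapping(P0, F)
  tcrossprod(Fn)
}

# map sphere points through a linear mapping and renormalize
map_directions <- function(Fmap, points) {
  s <- points %*% t(Fmap)
  s / sqrt(rowSums(s^2))
}

#' ODF density of a linearly mapped uniform sphere
#'
#' Closed-form probability density at unit directions of the pushforward of
#' the uniform sphere measure under `u -> M u / |M u|` -- the angular central
#' Gaussian with parameter `A = M t(M)`:
#' `f(u) = (4 pi sqrt(det A))^-1 (u' A^-1 u)^-3/2`. This is the continuous
#' ODF that the point-mapped histograms estimate; evaluating it at mesh nodes
#' gives a smooth set of ODF values for generalized fractional anisotropy.
#'
#' @param Fmap 3x3 mapping matrix (e.g. a net mapping or pseudo-deformation).
#' @param points n x 3 matrix of unit directions.
#' @return Numeric vector of density values (units 1/steradian).
#' @export
mapped_density <- function(Fmap, points) {
  A <- tcrossprod(Fmap)
  Ai <- solve(A)
  q <- rowSums((points %*% Ai) * points)
  (4 * pi * sqrt(det(A)))^-1 * q^-1.5
}

#' True and pseudo-deformed ODF histograms
#'
#' `true_deform_odf()` maps every vertex of `mesh` through the net mapping
#' `Fn = F %*% P0`, renormalizes to the unit sphere, and bins the mapped
#' directions to facets. `pseudo_deform_odf()` does the same with the
#' pseudo-deformation `Fp = Vn` in place of `Fn`. The binning mesh defaults to
#' the mapping mesh but may be coarser: with n mapped points and m facets the
#' facet masses are multinomial-like estimates whose noise scales as
#' `sqrt(m/n)`, so a coarser `bins` mesh gives a statistically meaningful
#' histogram from a fixed point budget.
#'
#' @param P0 Initial EFD.
#' @param F Deformation gradient.
#' @param mesh `"sphere_mesh"` whose vertices are mapped.
#' @param bins `"sphere_mesh"` defining the facet partition (default `mesh`).
#' @return An `"odf_histogram"` on `bins`.
#' @export
true_deform_odf <- function(P0, F, mesh, bins = mesh) {
  Fn <- net_mapping(P0, F)
  histogram_from_directions(map_directions(Fn, mesh$vertices), bins)
}

#' @rdname true_deform_odf
#' @export
pseudo_deform_odf <- function(P0, F, mesh, bins = mesh) {
  Fp <- pseudo_deform(P0, F)
  histogram_from_directions(map_directions(Fp, mesh$vertices), bins)
}

#' Canonical verification load cases
#'
#' Builds the default case table for the pseudo-deformation verification
#' study: three initial EFD families (uniform `I`, uniaxial `diag(5,1,1)`,
#' planar `diag(3,3,1)`) pre-rotated by 45 degrees about the X, Y and Z axes
#' (extrinsic composition `Rz(45) Ry(45) Rx(45)`, so no load acts along an EFD
#' principal direction), crossed with four load modes. Uniaxial and biaxial
#' sweeps span stretch ratios `lambda` in `[0.5, 1.5]`; shear sweeps span
#' `kappa` in `[0, 0.5]`; each sampled at `n_sweep` evenly spaced points.
#'
#' @param families Character subset of `c("uniform", "uniaxial", "planar")`.
#' @param modes Character subset of
#'   `c("uniaxial", "biaxial", "simple_shear", "pure_shear")`.
#' @param n_sweep Number of sweep points per mode.
#' @param family_radii Named list of radii for the three EFD families.
#' @param pre_rotation 3x3 rotation applied to every family EFD.
#' @return A data.frame of cases with columns `family`, `mode`, `parameter`.
#' @export
verification_cases <- function(families = c("uniform", "uniaxial", "planar"),
                               modes = c("uniaxial", "biaxial",
                                         "simple_shear", "pure_shear"),
                               n_sweep = 11,
                               family_radii = list(uniform = c(1, 1, 1),
                                                   uniaxial = c(5, 1, 1),
                                                   planar = c(3, 3, 1)),
                               pre_rotation = rot_z(45) %*% rot_y(45) %*%
                                 rot_x(45)) {
  families <- match.arg(families, several.ok = TRUE)
  modes <- match.arg(modes, several.ok = TRUE)
  sweep_of <- function(mode) {
    if (mode %in% c("uniaxial", "biaxial")) seq(0.5, 1.5, length.out = n_sweep)
    else seq(0, 0.5, length.out = n_sweep)
  }
  cases <- do.call(rbind, lapply(modes, function(mo) {
    expand.grid(family = families, mode = mo, parameter = sweep_of(mo),
                stringsAsFactors = FALSE)
  }))
  attr(cases, "family_radii") <- family_radii
  attr(cases, "pre_rotation") <- pre_rotation
  cases[order(cases$family, cases$mode, cases$parameter), ]
}

load_case_defgrad <- function(mode, parameter) {
  switch(mode,
    uniaxial = def_uniaxial(parameter),
    biaxial = def_biaxial(parameter),
    simple_shear = def_simple_shear(parameter),
    pure_shear = def_pure_shear(parameter),
    stop("unknown load mode: ", mode)
  )
}

#' Run the pseudo-deformation verification suite
#'
#' For each load case the suite maps the `mesh` vertices through the true net
#' mapping `Fn` and through the pseudo-deformation `Fp = Vn`, and compares the
#' resulting orientation distributions two ways:
#' \itemize{
#'   \item `gfa_true`, `gfa_pseudo`, `delta_gfa`: generalized fractional
#'     anisotropy evaluated on the ODF probability-density values at the mesh
#'     nodes (the closed-form density of the point mapping). Because
#'     `Fn t(Fn) = Vn^2`, the two continuous densities coincide and
#'     `delta_gfa` quantifies pure numerical error.
#'   \item `delta_gfa_hist` and `fisher_rao`: the same comparison on the
#'     count-based facet histograms, whose differences are dominated by the
#'     finite point sample (the two mapped point sets differ by the removed
#'     rotation `Rn`). The Fisher-Rao distance in degrees is the
#'     discretization-level dissimilarity of the two mapped node sets.
#' }
#'
#' @param cases Case table from [verification_cases()].
#' @param mesh Mapping mesh (default level 5, 10,242 nodes).
#' @param bins Binning mesh for histograms (default level 2, 320 facets, about
#'   32 points per facet).
#' @return A data.frame with one row per case and the columns described above;
#'   attribute `"maxima"` holds per-mode maxima of `delta_gfa`,
#'   `delta_gfa_hist` and `fisher_rao`.
#' @export
run_verification_suite <- function(cases = verification_cases(),
                                   mesh = build_icosphere(5),
                                   bins = build_icosphere(2)) {
  if (nrow(cases) == 0) stop("cases must be non-empty")
  radii <- attr(cases, "family_radii")
  R <- attr(cases, "pre_rotation")
  fam_efd <- lapply(radii, efd_from_axes, rotation = R)
  out <- cases
  out$gfa_true <- out$gfa_pseudo <- out$delta_gfa <- NA_real_
  out$delta_gfa_hist <- out$fisher_rao <- NA_real_
  for (i in seq_len(nrow(cases))) {
    P0 <- fam_efd[[cases$family[i]]]
    F <- load_case_defgrad(cases$mode[i], cases$parameter[i])
    Fn <- net_mapping(P0, F)
    Fp <- unclass(pseudo_deform(P0, F))
    gt <- gfa(mapped_density(Fn, mesh$vertices))
    gp <- gfa(mapped_density(Fp, mesh$vertices))
    ht <- histogram_from_directions(map_directions(Fn, mesh$vertices), bins)
    hp <- histogram_from_directions(map_directions(Fp, mesh$vertices), bins)
    out$gfa_true[i] <- gt
    out$gfa_pseudo[i] <- gp
    out$delta_gfa[i] <- abs(gt - gp)
    out$delta_gfa_hist[i] <- abs(gfa(ht) - gfa(hp))
    out$fisher_rao[i] <- fisher_rao_distance(ht, hp)
  }
  maxima <- do.call(rbind, lapply(split(out, out$mode), function(d) {
    data.frame(mode = d$mode[1],
               max_delta_gfa = max(d$delta_gfa),
               max_delta_gfa_hist = max(d$delta_gfa_hist),
               max_fisher_rao = max(d$fisher_rao))
  }))
  rownames(maxima) <- NULL
  attr(out, "maxima") <- maxima
  out
}

#' Restrict verification results to the moderate-strain regime
#'
#' Keeps sweep points with stretch ratios in `[0.5, 1.5]` (up to 50 percent
#' tension or compression) and shear ratios up to 0.45 (45 percent shear), the
#' regime over which pseudo-deformation is reported accurate.
#'
#' @param results Output of [run_verification_suite()].
#' @return The filtered data.frame.
#' @export
restrict_moderate_strain <- function(results) {
  keep <- ifelse(results$mode %in% c("simple_shear", "pure_shear"),
                 results$parameter <= 0.45 + 1e-12,
                 results$parameter >= 0.5 - 1e-12 &
                   results$parameter <= 1.5 + 1e-12)
  results[keep, ]
}
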