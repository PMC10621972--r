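#' Subdivided icosahedral sphere meshes
#'
#' Builds a geodesic sphere by recursive midpoint subdivision of a regular
#' icosahedron, projecting new vertices onto the unit sphere. Level `k` has
#' `10 * 4^k + 2` vertices and `20 * 4^k` triangular facets; level 5 gives the
#' 10,242-node mesh used for orientation-distribution verification.
#'
#' @param level Non-negative integer subdivision level.
#' @return An object of class `"sphere_mesh"`: a list with `vertices`
#'   (n x 3 unit vectors), `facets` (m x 3 vertex indices), `centroids`
#'   (m x 3 unit facet centroids) and `level`.
#' @examples
#' m <- build_icosphere(2)
#' nrow(m$vertices)  # 162
#' nrow(m$facets)    # 320
#' @export
build_icosphere <- function(level) {
  if (length(level) != 1 || is.na(level) || level < 0 || level != round(level)) {
    stop("subdivision level must be a non-negative integer")
  }
  level <- as.integer(level)
  phi <- (1 + sqrt(5)) / 2
  v <- matrix(c(
    -1,  phi, 0,   1,  phi, 0,  -1, -phi, 0,   1, -phi, 0,
     0, -1,  phi,  0,  1,  phi,  0, -1, -phi,  0,  1, -phi,
     phi, 0, -1,   phi, 0,  1,  -phi, 0, -1,  -phi, 0,  1
  ), ncol = 3, byrow = TRUE)
  v <- v / sqrt(rowSums(v^2))
  f <- matrix(c(
    1, 12, 6,  1, 6, 2,   1, 2, 8,   1, 8, 11,  1, 11, 12,
    2, 6, 10,  6, 12, 5,  12, 11, 3, 11, 8, 7,  8, 2, 9,
    4, 10, 5,  4, 5, 3,   4, 3, 7,   4, 7, 9,   4, 9, 10,
    5, 10, 6,  3, 5, 12,  7, 3, 11,  9, 7, 8,   10, 9, 2
  ), ncol = 3, byrow = TRUE)

  if (level > 0) {
    for (i in seq_len(level)) {
      nv <- nrow(v)
      # unique undirected edges
      e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
      e <- t(apply(e, 1, sort))
      key <- e[, 1] * (nv + 1) + e[, 2]
      uk <- !duplicated(key)
      ue <- e[uk, , drop = FALSE]
      mid_index <- integer(max(key))
      mid_index[key[uk]] <- nv + seq_len(nrow(ue))
      mids <- (v[ue[, 1], ] + v[ue[, 2], ]) / 2
      mids <- mids / sqrt(rowSums(mids^2))
      v <- rbind(v, mids)
      mid_of <- function(a, b) mid_index[pmin(a, b) * (nv + 1) + pmax(a, b)]
      ab <- mid_of(f[, 1], f[, 2])
      bc <- mid_of(f[, 2], f[, 3])
      ca <- mid_of(f[, 3], f[, 1])
      f <- rbind(
        cbind(f[, 1], ab, ca),
        cbind(f[, 2], bc, ab),
        cbind(f[, 3], ca, bc),
        cbind(ab, bc, ca)
      )
    }
  }
  cen <- (v[f[, 1], ] + v[f[, 2], ] + v[f[, 3], ]) / 3
  cen <- cen / sqrt(rowSums(cen^2))
  structure(list(vertices = v, facets = f, centroids = cen, level = level),
            class = "sphere_mesh")
}

#' @export
print.sphere_mesh <- function(x, ...) {
  cat("Icosphere mesh, level", x$level, ":", nrow(x$vertices), "vertices,",
      nrow(x$facets), "facets\n")
  invisible(x)
}

same_mesh <- function(a, b) {
  inherits(a, "sphere_mesh") && inherits(b, "sphere_mesh") &&
    a$level == b$level && nrow(a$facets) == nrow(b$facets)
}

#' Assign unit vectors to icosphere facets
#'
#' Each direction is assigned to the facet whose unit centroid has the maximum
#' dot product with it; ties (a measure-zero event) are broken by the lowest
#' facet index. Assignment is chunked so that large direction sets do not
#' materialize an oversized dot-product matrix.
#'
#' @param directions n x 3 matrix of unit vectors (a length-3 vector is
#'   treated as a single direction).
#' @param mesh A `"sphere_mesh"`.
#' @return Integer vector of facet indices.
#' @export
assign_facets <- function(directions, mesh) {
  if (is.null(dim(directions))) directions <- matrix(directions, ncol = 3)
  n <- nrow(directions)
  out <- integer(n)
  ctr <- t(mesh$centroids)
  chunk <- max(1L, as.integer(2e7 / nrow(mesh$facets)))
  i <- 1L
  while (i <= n) {
    j <- min(n, i + chunk - 1L)
    out[i:j] <- max.col(directions[i:j, , drop = FALSE] %*% ctr,
                        ties.method = "first")
    i <- j + 1L
  }
  out
}

# facet index of the antipodal facet (icosphere meshes are centrosymmetric)
antipode_map <- function(mesh) {
  assign_facets(-mesh$centroids, mesh)
}

#' Directional histograms on an icosphere
#'
#' Bins unit vectors to the facets of an icosphere (nearest facet centroid) and
#' normalizes the per-facet mass to a probability mass function, the discrete
#' analogue of an orientation distribution function integrating to one. With
#' `symmetrize = TRUE` mass is averaged between antipodal facets, appropriate
#' for axial data (fibrils, vessel segments) where `u` and `-u` are the same
#' observation.
#'
#' @param directions n x 3 matrix of unit vectors.
#' @param mesh A `"sphere_mesh"` defining the facet partition.
#' @param symmetrize Average mass between antipodal facets.
#' @param weights Optional non-negative per-direction weights (e.g. segment
#'   lengths); default 1.
#' @return An object of class `"odf_histogram"`: list with `mesh` and `mass`
#'   (one non-negative value per facet, summing to 1).
#' @export
histogram_from_directions <- function(directions, mesh, symmetrize = FALSE,
                                      weights = NULL) {
  if (is.null(dim(directions))) directions <- matrix(directions, ncol = 3)
  if (nrow(directions) == 0) stop("directions must be non-empty")
  idx <- assign_facets(directions, mesh)
  nf <- nrow(mesh$facets)
  if (is.null(weights)) {
    mass <- tabulate(idx, nbins = nf)
  } else {
    if (length(weights) != nrow(directions) || any(weights < 0)) {
      stop("weights must be non-negative, one per direction")
    }
    mass <- numeric(nf)
    agg <- rowsum(as.numeric(weights), idx)
    mass[as.integer(rownames(agg))] <- agg
  }
  mass <- mass / sum(mass)
  if (symmetrize) {
    ap <- antipode_map(mesh)
    mass <- (mass + mass[ap]) / 2
  }
  structure(list(mesh = mesh, mass = mass), class = "odf_histogram")
}

#' @export
print.odf_histogram <- function(x, ...) {
  cat("ODF histogram on level-", x$mesh$level, " icosphere (",
      length(x$mass), " facets), GFA = ", signif(gfa(x), 4), "\n", sep = "")
  invisible(x)
}

#' Generalized fractional anisotropy
#'
#' GFA is the population standard deviation of the ODF values divided by their
#' root-mean-square. It is 0 for a perfectly uniform distribution and
#' approaches 1 as all mass concentrates in a single bin. For a histogram the
#' ODF values are the facet masses; for a numeric vector the values are used
#' directly (e.g. density values evaluated at sphere nodes).
#'
#' @param x An `"odf_histogram"` or a numeric vector of non-negative ODF
#'   values (not all zero).
#' @return GFA in `[0, 1]`.
#' @export
gfa <- function(x) UseMethod("gfa")

#' @export
gfa.odf_histogram <- function(x) gfa(x$mass)

#' @export
gfa.default <- function(x) {
  x <- as.numeric(x)
  if (length(x) == 0 || any(!is.finite(x)) || all(x == 0)) {
    stop("GFA requires a non-empty set of finite ODF values, not all zero")
  }
  n <- length(x)
  m <- mean(x)
  sqrt(max(0, mean((x - m)^2)) / mean(x^2))
}

#' Fisher-Rao distance between directional histograms
#'
#' Computed as the arccosine of the Bhattacharyya coefficient,
#' `d = acos(sum(sqrt(p * q)))`, reported in degrees: 0 deg for identical
#' distributions, 90 deg for distributions with disjoint support. This is the
#' unique form matching that 0-90 degree range for probability mass functions.
#'
#' @param p,q `"odf_histogram"` objects on the same mesh.
#' @return Distance in degrees, in `[0, 90]`.
#' @export
fisher_rao_distance <- function(p, q) {
  if (!inherits(p, "odf_histogram") || !inherits(q, "odf_histogram")) {
    stop("p and q must be odf_histogram objects")
  }
  if (!same_mesh(p$mesh, q$mesh)) stop("histograms are on different meshes")
  bc <- sum(sqrt(p$mass * q$mass))
  acos(min(1, max(-1, bc))) * 180 / pi
}

#' Area-corrected ODF density (glyph rendering helper)
#'
#' Facet masses divided by spherical facet area, so that the values estimate
#' the continuous ODF density rather than the per-facet probability. Intended
#' for visualization; all metrics in the package are count-based.
#'
#' @param odf An `"odf_histogram"`.
#' @return Numeric vector of per-facet densities (integrating to 1 over the
#'   sphere).
#' @export
odf_density <- function(odf) {
  m <- odf$mesh
  a <- spherical_facet_areas(m)
  odf$mass / a
}

spherical_facet_areas <- function(mesh) {
  v1 <- mesh$vertices[mesh$facets[, 1], ]
  v2 <- mesh$vertices[mesh$facets[, 2], ]
  v3 <- mesh$vertices[mesh$facets[, 3], ]
  # L'Huilier via the planar triangle solid angle (Van Oosterom & Strackee)
  num <- rowSums(v1 * cross3(v2, v3))
  den <- 1 + rowSums(v1 * v2) + rowSums(v2 * v3) + rowSums(v1 * v3)
  2 * atan2(abs(num), den)
}

cross3 <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

#' Read and write ODF histograms as plain-text tables
#'
#' Two-column tab-separated tables (facet index, mass). The mesh is not
#' serialized; supply a mesh with the matching facet count when reading.
#'
#' @param odf An `"odf_histogram"`.
#' @param path File path.
#' @param mesh Mesh to attach when reading.
#' @export
write_odf <- function(odf, path) {
  utils::write.table(
    data.frame(facet = seq_along(odf$mass), mass = odf$mass),
    path, sep = "\t", row.names = FALSE, quote = FALSE
  )
  invisible(path)
}

#' @rdname write_odf
#' @export
read_odf <- function(path, mesh) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t")
  if (nrow(tab) != nrow(mesh$facets)) {
    stop("facet count in file does not match the supplied mesh")
  }
  mass <- tab$mass[order(tab$facet)]
  structure(list(mesh = mesh, mass = mass / sum(mass)),
            class = "odf_histogram")
}

#' Export a sphere mesh as legacy VTK polydata
#'
#' Optionally scales vertices by per-vertex values (e.g. an ODF density) to
#' produce glyph surfaces.
#'
#' @param mesh A `"sphere_mesh"`.
#' @param path Output file.
#' @param radius Optional per-vertex radius scaling.
#' @export
write_vtk_sphere <- function(mesh, path, radius = NULL) {
  v <- mesh$vertices
  if (!is.null(radius)) v <- v * radius
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0", "icosphere", "ASCII",
               "DATASET POLYDATA", paste("POINTS", nrow(v), "float")), con)
  utils::write.table(format(v, scientific = FALSE), con, row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  f <- mesh$facets - 1L
  writeLines(paste("POLYGONS", nrow(f), 4 * nrow(f)), con)
  utils::write.table(cbind(3L, f), con, row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
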