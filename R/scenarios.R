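#' Rectilinear simulation domains carrying fibril fields
#'
#' A domain grid is a union of axis-aligned rectilinear blocks of hexahedral
#' cells. Every cell carries eight Gauss integration points (at natural
#' coordinates `+/- 1/sqrt(3)`), and every integration point stores a collagen
#' EFD (with its matrix logarithm precomputed for Log-Euclidean
#' interpolation), a collagen density in mg/mL and, in legacy vector mode, a
#' unit orientation vector. Cells belong to exactly one named region
#' (axis-aligned box).
#'
#' `domain_grid()` is the low-level constructor used by the scenario
#' builders: `blocks` is a list of `list(lo, hi, n)` (bounds in mm, cell
#' counts per axis) and `regions` a named list of `list(lo, hi)` boxes that
#' tile the domain.
#'
#' @param blocks List of block definitions.
#' @param regions Named list of region boxes.
#' @return A `"domain_grid"` (fields unset until [set_grid_field()]).
#' @export
domain_grid <- function(blocks, regions) {
  cell_lo <- cell_hi <- NULL
  cell_block <- integer()
  block_meta <- vector("list", length(blocks))
  offset <- 0L
  for (b in seq_along(blocks)) {
    bl <- blocks[[b]]
    n <- as.integer(bl$n)
    d <- (bl$hi - bl$lo) / n
    ijk <- as.matrix(expand.grid(i = seq_len(n[1]) - 1L,
                                 j = seq_len(n[2]) - 1L,
                                 k = seq_len(n[3]) - 1L))
    lo <- sweep(sweep(ijk, 2, d, `*`), 2, bl$lo, `+`)
    hi <- sweep(lo, 2, d, `+`)
    cell_lo <- rbind(cell_lo, lo)
    cell_hi <- rbind(cell_hi, hi)
    cell_block <- c(cell_block, rep.int(b, nrow(ijk)))
    block_meta[[b]] <- list(lo = bl$lo, hi = bl$hi, n = n, d = d,
                            offset = offset)
    offset <- offset + nrow(ijk)
  }
  n_cells <- nrow(cell_lo)
  centers <- (cell_lo + cell_hi) / 2
  region_id <- rep(NA_integer_, n_cells)
  for (r in seq_along(regions)) {
    rb <- regions[[r]]
    inside <- centers[, 1] >= rb$lo[1] & centers[, 1] <= rb$hi[1] &
      centers[, 2] >= rb$lo[2] & centers[, 2] <= rb$hi[2] &
      centers[, 3] >= rb$lo[3] & centers[, 3] <= rb$hi[3]
    if (any(!is.na(region_id[inside]))) {
      stop("regions overlap: every cell must belong to exactly one region")
    }
    region_id[inside] <- r
  }
  if (anyNA(region_id)) stop("regions do not cover the domain")
  # Gauss point positions: cell center +/- half-edge / sqrt(3)
  g <- hex8_signs / sqrt(3)
  half <- (cell_hi - cell_lo) / 2
  idx <- rep(seq_len(n_cells), each = 8L)
  corner <- rep(1:8, times = n_cells)
  ip_xyz <- centers[idx, , drop = FALSE] +
    half[idx, , drop = FALSE] * g[corner, , drop = FALSE]
  cell_lo <- unname(as.matrix(cell_lo))
  cell_hi <- unname(as.matrix(cell_hi))
  ip_xyz <- unname(ip_xyz)
  lo_all <- unname(apply(cell_lo, 2, min))
  hi_all <- unname(apply(cell_hi, 2, max))
  structure(list(
    blocks = block_meta,
    regions = regions,
    n_cells = n_cells,
    cell_lo = cell_lo,
    cell_hi = cell_hi,
    cell_block = cell_block,
    cell_region = region_id,
    cell_volume = apply(cell_hi - cell_lo, 1, prod),
    ip_xyz = ip_xyz,
    lo = lo_all, hi = hi_all,
    efd6 = NULL, logefd6 = NULL, density = NULL, vectors = NULL,
    mode = "efd"
  ), class = "domain_grid")
}

#' @export
print.domain_grid <- function(x, ...) {
  cat("Domain grid:", x$n_cells, "cells in", length(x$blocks), "block(s),",
      "extent", paste(signif(x$hi - x$lo, 4), collapse = " x "), "mm,",
      "regions:", paste(names(x$regions), collapse = ", "), "\n")
  invisible(x)
}

#' Locate the cell containing a position
#'
#' @param grid A `"domain_grid"`.
#' @param position Length-3 position in mm.
#' @return Integer cell index, or `NA` if the position lies outside the
#'   domain.
#' @export
grid_locate <- function(grid, position) {
  for (b in grid$blocks) {
    if (all(position >= b$lo - 1e-12) && all(position <= b$hi + 1e-12)) {
      ijk <- pmin(pmax(floor((position - b$lo) / b$d), 0), b$n - 1)
      return(b$offset + 1L +
               as.integer(ijk[1] + b$n[1] * (ijk[2] + b$n[2] * ijk[3])))
    }
  }
  NA_integer_
}

#' Assign the fibril field of a grid
#'
#' Evaluates an EFD-valued function and a density-valued function at every
#' integration point and stores the tensors (plus their matrix logarithms)
#' and densities. In `"vector"` mode one unit orientation vector is
#' additionally sampled from each integration point's EFD, exactly once
#' (legacy vector-field representation); the EFDs are retained so that the
#' velocity scale sees the same density/anisotropy field in both modes.
#'
#' @param grid A `"domain_grid"`.
#' @param efd_fn Function of a length-3 position returning an EFD (or 3x3 SPD
#'   matrix).
#' @param density_fn Function of a length-3 position returning density in
#'   mg/mL, or a single number.
#' @param mode `"efd"` or `"vector"`. Vector sampling consumes the R random
#'   number stream.
#' @return The grid with populated fields.
#' @export
set_grid_field <- function(grid, efd_fn, density_fn, mode = c("efd",
                                                              "vector")) {
  mode <- match.arg(mode)
  n_ip <- nrow(grid$ip_xyz)
  efd6 <- logefd6 <- matrix(NA_real_, n_ip, 6)
  density <- numeric(n_ip)
  dens_const <- is.numeric(density_fn)
  # cache field evaluation per cell when the functions are cell-wise constant
  for (i in seq_len(n_ip)) {
    pos <- grid$ip_xyz[i, ]
    P <- unclass(as_efd(efd_fn(pos)))
    efd6[i, ] <- sym3_to_vec6(P)
    logefd6[i, ] <- sym3_to_vec6(logm_spd(P))
    density[i] <- if (dens_const) density_fn else density_fn(pos)
  }
  if (any(density <= 0)) stop("density must be positive everywhere")
  grid$efd6 <- efd6
  grid$logefd6 <- logefd6
  grid$density <- density
  grid$mode <- mode
  if (mode == "vector") {
    vec <- matrix(NA_real_, n_ip, 3)
    for (i in seq_len(n_ip)) {
      vec[i, ] <- sample_direction(vec6_to_sym3(efd6[i, ]))
    }
    grid$vectors <- vec
  }
  grid
}

#' Interpolate the fibril field at a position
#'
#' Log-Euclidean interpolation of the cell's eight Gauss-point EFDs with
#' trilinear weights (natural coordinates rescaled by `sqrt(3)` and clamped,
#' treating the Gauss points as a shrunken virtual hexahedron), plus the
#' linearly interpolated density.
#'
#' @param grid A `"domain_grid"` with fields set.
#' @param position Length-3 position in mm.
#' @return List with `efd`, `density`, `fa` and `cell`.
#' @export
interpolate_field <- function(grid, position) {
  cell <- grid_locate(grid, position)
  if (is.na(cell)) stop("position is outside the domain")
  lo <- grid$cell_lo[cell, ]
  hi <- grid$cell_hi[cell, ]
  xi <- pmin(pmax(sqrt(3) * (2 * (position - lo) / (hi - lo) - 1), -1), 1)
  w <- interpolation_weights(xi)
  ips <- (cell - 1L) * 8L + 1:8
  Svec <- as.numeric(w %*% grid$logefd6[ips, , drop = FALSE])
  P <- structure(expm_sym(vec6_to_sym3(Svec)), class = "efd")
  list(efd = P, density = sum(w * grid$density[ips]),
       fa = fractional_anisotropy(P), cell = cell)
}

aligned_efd <- function(radii, axis = c("x", "y", "z")) {
  axis <- match.arg(axis)
  R <- switch(axis, x = diag(3), y = rot_z(90), z = rot_y(-90))
  efd_from_axes(radii, R)
}

#' Uniform-anisotropy culture domain
#'
#' A cube of edge `extent` mm tiled with cubic cells, carrying a homogeneous
#' EFD whose major axis lies along X and a homogeneous collagen density.
#' Anisotropy levels set the major-to-second radius ratio `beta1/beta2` to
#' 1.3 (low), 2.5 (med) or 5.0 (high) with `beta2 = 1`, `beta3 = 0.5`,
#' anchoring the low/high levels to the gradient-study endpoints.
#'
#' @param anisotropy `"low"`, `"med"` or `"high"`.
#' @param density Collagen density in mg/mL (3 = low, 4 = high).
#' @param extent Cube edge in mm.
#' @param cell_size Cell edge in mm.
#' @param mode `"efd"` or `"vector"`.
#' @param level_radii Named list giving the EFD radii per anisotropy level.
#' @return A populated `"domain_grid"` with a single region `"culture"`.
#' @export
build_uniform_culture <- function(anisotropy = c("low", "med", "high"),
                                  density = 3, extent = 1, cell_size = 0.1,
                                  mode = c("efd", "vector"),
                                  level_radii = list(low = c(1.3, 1, 0.5),
                                                     med = c(2.5, 1, 0.5),
                                                     high = c(5, 1, 0.5))) {
  anisotropy <- match.arg(anisotropy)
  mode <- match.arg(mode)
  n <- max(1L, round(extent / cell_size))
  g <- domain_grid(
    blocks = list(list(lo = c(0, 0, 0), hi = rep(extent, 3), n = rep(n, 3))),
    regions = list(culture = list(lo = c(0, 0, 0), hi = rep(extent, 3)))
  )
  P <- aligned_efd(level_radii[[anisotropy]], "x")
  set_grid_field(g, function(pos) P, density, mode = mode)
}

#' Anisotropy-gradient healing domain
#'
#' Three regions along X: proximal and distal flanks (0.4 mm wide) and a
#' middle region (1.0 mm wide), `width` mm in Y and `thickness` mm in Z, with
#' 0.1 mm cells. In the gradient cases the X-direction radius `beta1` ramps
#' linearly across the middle region between 1.3 and 5.0 (increasing for
#' `"positive"`, decreasing for `"negative"`) with `beta2 = 1.0` and
#' `beta3 = 0.5` fixed; each flank takes the adjacent ramp end value. The
#' `"baseline"` case carries a near-isotropic field `(1.05, 1, 0.95)`
#' (exact degeneracy avoided so spectral axes stay well defined).
#'
#' @param direction `"baseline"`, `"positive"` or `"negative"`.
#' @param width Domain width in Y (mm).
#' @param thickness Domain thickness in Z (mm).
#' @param density Collagen density in mg/mL.
#' @param cell_size Cell edge in mm.
#' @param mode `"efd"` or `"vector"`.
#' @return A populated `"domain_grid"` with regions `proximal`, `middle`,
#'   `distal`.
#' @export
build_gradient <- function(direction = c("baseline", "positive", "negative"),
                           width = 2.0, thickness = 0.5, density = 3,
                           cell_size = 0.1, mode = c("efd", "vector")) {
  direction <- match.arg(direction)
  mode <- match.arg(mode)
  x1 <- 0.4
  x2 <- 1.4
  x3 <- 1.8
  n <- function(len) max(1L, round(len / cell_size))
  g <- domain_grid(
    blocks = list(list(lo = c(0, 0, 0), hi = c(x3, width, thickness),
                       n = c(n(x3), n(width), n(thickness)))),
    regions = list(
      proximal = list(lo = c(0, 0, 0), hi = c(x1, width, thickness)),
      middle = list(lo = c(x1, 0, 0), hi = c(x2, width, thickness)),
      distal = list(lo = c(x2, 0, 0), hi = c(x3, width, thickness))
    )
  )
  efd_fn <- if (direction == "baseline") {
    P <- aligned_efd(c(1.05, 1, 0.95), "x")
    function(pos) P
  } else {
    b1_lo <- 1.3
    b1_hi <- 5.0
    function(pos) {
      frac <- min(max((pos[1] - x1) / (x2 - x1), 0), 1)
      b1 <- if (direction == "positive") {
        b1_lo + frac * (b1_hi - b1_lo)
      } else {
        b1_hi - frac * (b1_hi - b1_lo)
      }
      efd_from_axes(c(b1, 1.0, 0.5))
    }
  }
  set_grid_field(g, efd_fn, density, mode = mode)
}

#' Tumor-interface (TACS) domain
#'
#' Three regions stacked along Y: the peritumoral stroma (`periphery`,
#' `x_width` x 0.8 x 0.6 mm), an 80 um thick `interface`
#' (`x_width` x 0.08 x 0.6 mm, refined 0.1 x 0.04 x 0.01 mm cells) and the
#' `tumor` (`x_width` x 0.8 x 0.6 mm). The interface structure encodes
#' tumor-associated collagen signatures: TACS-1 raises interface density to
#' 5 mg/mL (3 mg/mL elsewhere), TACS-2 aligns interface fibrils in-plane
#' along the interface (X), TACS-3 aligns them across the interface towards
#' the tumor (Y); combined cases compose. The baseline case is structurally
#' uniform.
#'
#' @param case One of `"baseline"`, `"tacs1"`, `"tacs2"`, `"tacs3"`,
#'   `"tacs1_2"`, `"tacs1_3"`.
#' @param x_width Domain width in X (mm).
#' @param mode `"efd"` or `"vector"`.
#' @param aligned_radii EFD radii used for aligned interface fibrils.
#' @return A populated `"domain_grid"`.
#' @export
build_tacs <- function(case = c("baseline", "tacs1", "tacs2", "tacs3",
                                "tacs1_2", "tacs1_3"),
                       x_width = 1.0, mode = c("efd", "vector"),
                       aligned_radii = c(5, 1, 1)) {
  case <- match.arg(case)
  mode <- match.arg(mode)
  y1 <- 0.8
  y2 <- 0.88
  y3 <- 1.68
  z <- 0.6
  nx <- max(1L, round(x_width / 0.1))
  g <- domain_grid(
    blocks = list(
      list(lo = c(0, 0, 0), hi = c(x_width, y1, z),
           n = c(nx, round(y1 / 0.1), round(z / 0.1))),
      list(lo = c(0, y1, 0), hi = c(x_width, y2, z),
           n = c(nx, 2L, round(z / 0.01))),
      list(lo = c(0, y2, 0), hi = c(x_width, y3, z),
           n = c(nx, round((y3 - y2) / 0.1), round(z / 0.1)))
    ),
    regions = list(
      periphery = list(lo = c(0, 0, 0), hi = c(x_width, y1, z)),
      interface = list(lo = c(0, y1, 0), hi = c(x_width, y2, z)),
      tumor = list(lo = c(0, y2, 0), hi = c(x_width, y3, z))
    )
  )
  base_efd <- aligned_efd(c(1.05, 1, 0.95), "x")
  iface_efd <- switch(case,
    tacs2 = , tacs1_2 = aligned_efd(aligned_radii, "x"),
    tacs3 = , tacs1_3 = aligned_efd(aligned_radii, "y"),
    base_efd
  )
  iface_rho <- if (case %in% c("tacs1", "tacs1_2", "tacs1_3")) 5 else 3
  in_iface <- function(pos) pos[2] >= y1 && pos[2] <= y2
  g <- set_grid_field(
    g,
    function(pos) if (in_iface(pos)) iface_efd else base_efd,
    function(pos) if (in_iface(pos)) iface_rho else 3,
    mode = mode
  )
  g
}

#' Seed parent microvessel fragments
#'
#' Places straight parent fragments uniformly at random inside a seeding
#' region. Initial lengths are drawn from a log-normal distribution (a
#' stand-in for the image-derived initial-length distribution; any sampler
#' can be supplied via `length_fn`). Orientations are sampled from the
#' seeding EFD `diag(1, 1, beta3)`, isotropic in the XY plane and flattened
#' towards it for `beta3 < 1`, then nudged once towards the local fibril
#' field with the initialization fibril weight. Both fragment ends become
#' active tips. Fragments extending outside the domain are re-positioned (up
#' to 100 tries) and finally trimmed.
#'
#' @param grid A populated `"domain_grid"`.
#' @param config A `"growth_config"` (seeding block used for defaults).
#' @param n Number of fragments; default `round(per_mm3 * region volume)`.
#' @param region Region name to seed into (default: the whole domain).
#' @param length_fn Optional function(n) returning n fragment lengths in mm.
#' @return A `"vessel_network"` of parent fragments with two active tips
#'   each.
#' @export
seed_fragments <- function(grid, config, n = NULL, region = NULL,
                           length_fn = NULL) {
  sd_cfg <- config$seeding
  box <- if (is.null(region)) {
    list(lo = grid$lo, hi = grid$hi)
  } else {
    grid$regions[[region]]
  }
  if (is.null(box)) stop("unknown seeding region: ", region)
  vol <- prod(box$hi - box$lo)
  if (is.null(n)) n <- round(sd_cfg$per_mm3 * vol)
  nw <- new_network(grid, n_seg_guess = max(16L, 2L * n),
                    n_tip_guess = max(16L, 4L * n))
  if (n == 0) return(nw)
  if (is.null(length_fn)) {
    length_fn <- function(m) {
      stats::rlnorm(m, meanlog = log(sd_cfg$length_median),
                    sdlog = sd_cfg$length_sdlog)
    }
  }
  seed_efd <- efd_from_axes(c(1, 1, sd_cfg$z_polarization),
                            diag(3))  # beta3 along z
  lens <- length_fn(n)
  for (i in seq_len(n)) {
    placed <- FALSE
    for (try in 1:100) {
      ctr <- box$lo + stats::runif(3) * (box$hi - box$lo)
      dir <- sample_direction(seed_efd)
      if (config$init_fibril_weight > 0) {
        fld <- interpolate_field(grid, ctr)
        theta <- sample_direction(fld$efd)
        if (sum(theta * dir) < 0) theta <- -theta
        dir <- growth_direction(dir, theta, config$init_fibril_weight)
      }
      p0 <- ctr - 0.5 * lens[i] * dir
      p1 <- ctr + 0.5 * lens[i] * dir
      if (all(p0 >= grid$lo) && all(p0 <= grid$hi) &&
          all(p1 >= grid$lo) && all(p1 <= grid$hi)) {
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      # trim the fragment to the domain box
      clip <- function(p, q) {
        tt <- 1
        d <- q - p
        for (k in 1:3) {
          if (d[k] > 0 && q[k] > grid$hi[k]) {
            tt <- min(tt, (grid$hi[k] - p[k]) / d[k])
          }
          if (d[k] < 0 && q[k] < grid$lo[k]) {
            tt <- min(tt, (grid$lo[k] - p[k]) / d[k])
          }
        }
        p + max(tt, 0) * d
      }
      ctr <- pmin(pmax(ctr, grid$lo), grid$hi)
      p0 <- clip(ctr, ctr - 0.5 * lens[i] * dir)
      p1 <- clip(ctr, ctr + 0.5 * lens[i] * dir)
    }
    nw <- nw_add_segment(nw, p0, p1, 0, 0)
    seg_id <- nw$n_seg
    # seeded length counts toward the local vessel volume fraction
    ccell <- grid_locate(grid, (p0 + p1) / 2)
    if (!is.na(ccell)) {
      nw$cell_length[ccell] <- nw$cell_length[ccell] +
        sqrt(sum((p1 - p0)^2))
    }
    nw$n_lineage <- nw$n_lineage + 2L
    thr <- if (isTRUE(config$branching$enabled)) {
      stats::rexp(2, 1 / config$branching$mean_threshold)
    } else {
      c(Inf, Inf)
    }
    nw <- nw_add_tip(nw, p1, dir, thr[1], nw$n_lineage - 1L, seg_id)
    nw <- nw_add_tip(nw, p0, -dir, thr[2], nw$n_lineage, seg_id)
  }
  nw
}

#' Pseudo-deform the EFD field of a grid
#'
#' Replaces every stored EFD by its pseudo-deformation under a prescribed
#' deformation-gradient field (one `F` per cell or per integration point);
#' densities are unchanged. Used to impose tissue-level strains on a domain
#' without a mechanics solver.
#'
#' @param grid A populated `"domain_grid"`.
#' @param F_field A single 3x3 matrix, a function(position) returning one, or
#'   a list with one matrix per cell.
#' @return The grid with deformed EFDs.
#' @export
apply_deformation_field <- function(grid, F_field) {
  n_ip <- nrow(grid$ip_xyz)
  get_F <- if (is.function(F_field)) {
    function(i) F_field(grid$ip_xyz[i, ])
  } else if (is.list(F_field)) {
    function(i) F_field[[(i - 1L) %/% 8L + 1L]]
  } else {
    function(i) F_field
  }
  for (i in seq_len(n_ip)) {
    F <- get_F(i)
    if (det(F) <= 0) {
      stop(sprintf("deformation gradient in cell %d has det(F) <= 0",
                   (i - 1L) %/% 8L + 1L))
    }
    P <- pseudo_deform(vec6_to_sym3(grid$efd6[i, ]), F)
    grid$efd6[i, ] <- sym3_to_vec6(P)
    grid$logefd6[i, ] <- sym3_to_vec6(logm_spd(P))
  }
  grid
}

#' Simulate microvessel growth on a grid
#'
#' Seeds parent fragments and advances the network through `days / dt` growth
#' (and optional branching) steps. All randomness flows through the R random
#' number stream: `set.seed(seed)` is called at entry, so a given
#' (grid-builder, config, seed) triple reproduces an identical segment table.
#'
#' @param build_grid Function returning a populated `"domain_grid"` (called
#'   after seeding the RNG so legacy vector fields are reproducible), or a
#'   grid object for deterministic fields.
#' @param config A `"growth_config"`.
#' @param days Simulated duration in days.
#' @param seed Random engine seed.
#' @param seed_region Region name to seed fragments into (default whole
#'   domain).
#' @param n_fragments Optional fragment count override.
#' @return List with `network` and `grid`.
#' @export
simulate_growth <- function(build_grid, config, days, seed,
                            seed_region = NULL, n_fragments = NULL) {
  set.seed(seed)
  grid <- if (is.function(build_grid)) build_grid() else build_grid
  nw <- seed_fragments(grid, config, n = n_fragments, region = seed_region)
  steps <- floor(days / config$dt + 1e-9)
  t <- 0
  for (s in seq_len(steps)) {
    nw <- grow_step(nw, grid, config, t)
    nw <- branch_step(nw, grid, config, t)
    t <- t + config$dt
  }
  list(network = nw, grid = grid)
}
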