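#' Growth configuration
#'
#' Collects every tunable parameter of the microvessel growth engine. Defaults
#' describe microvessel fragments cultured in collagen hydrogels; all values
#' are exposed so that scenario studies can override them.
#'
#' @param alpha Fibril weight in `[0, 1]`: 0 grows purely along the vessel's
#'   current orientation (persistence), 1 purely along the sampled fibril
#'   direction (contact guidance).
#' @param dt Time step in days.
#' @param mode `"efd"` (tensor field, sampled every step) or `"vector"`
#'   (legacy vector field, sampled once at initialization).
#' @param rate_mode `"sigmoid"` (culture-style growth burst) or `"linear"`
#'   (ramp to a constant rate with volume-fraction arrest).
#' @param sigmoid List: `amplitude` (total tip path length, mm), `midpoint`
#'   (day of peak rate), `tau` (time constant, days).
#' @param linear List: `rate` (mm/day plateau), `ramp_days` (initial ramp).
#' @param nu Lorentzian velocity-scale coefficients: `b` (mg/mL width in
#'   density), `c` (width in FA), `rho0` (mg/mL center, below the physiologic
#'   range so growth decreases with density), `fa0` (FA center, above 1 so
#'   growth increases with anisotropy), `d` (non-negative floor), `rho_ref`
#'   and `fa_ref` (calibration point, defaults 3 mg/mL unaligned). The
#'   amplitude `a` is rescaled at construction so that
#'   `velocity_scale(rho_ref, fa_ref) == 1`.
#' @param max_step Cap on the tip step length per time step, in mm. Default
#'   half the standard 0.1 mm cell edge -- the spatial scale at which EFDs
#'   approximate collagen ODFs -- so steps stay local with respect to the
#'   field discretization even in geometrically refined cells.
#' @param w_thresh Local vessel volume fraction above which tip extension
#'   arrests (linear rate mode).
#' @param vessel_radius Vessel radius in mm used for the volume fraction.
#' @param branching List: `enabled`, `mean_threshold` (mm of lineage growth
#'   between branches, exponential), `zenith_mean`/`zenith_sd` (degrees,
#'   truncated normal on `(0, 90]`).
#' @param init_fibril_weight Fibril weight applied once to each seeded
#'   fragment orientation during initialization.
#' @param seeding List: `per_mm3` (parent fragments per mm^3),
#'   `length_median` (mm) and `length_sdlog` (log-normal initial lengths),
#'   `z_polarization` (seeding-distribution vertical radius `beta3` in
#'   `(0, 1]`; X and Y radii are fixed at 1 so fragments are isotropic in the
#'   XY plane).
#' @return A `"growth_config"` list with the calibrated `nu$a`.
#' @export
growth_config <- function(alpha = 0.5,
                          dt = 0.125,
                          mode = c("efd", "vector"),
                          rate_mode = c("sigmoid", "linear"),
                          sigmoid = list(amplitude = 1.5, midpoint = 5,
                                         tau = 1.5),
                          linear = list(rate = 0.25, ramp_days = 2),
                          nu = list(b = 1.5, c = 1.0, rho0 = 2, fa0 = 1.2,
                                    d = 0.05, rho_ref = 3, fa_ref = 0),
                          max_step = 0.05,
                          w_thresh = 0.02,
                          vessel_radius = 0.005,
                          branching = list(enabled = TRUE,
                                           mean_threshold = 0.5,
                                           zenith_mean = 60, zenith_sd = 15),
                          init_fibril_weight = 0.3,
                          seeding = list(per_mm3 = 150, length_median = 0.06,
                                         length_sdlog = 0.5,
                                         z_polarization = 0.3)) {
  mode <- match.arg(mode)
  rate_mode <- match.arg(rate_mode)
  if (alpha < 0 || alpha > 1) stop("alpha must be in [0, 1]")
  if (dt <= 0) stop("dt must be positive")
  if (nu$d < 0) stop("nu$d must be non-negative")
  if (w_thresh <= 0 || w_thresh > 1) stop("w_thresh must be in (0, 1]")
  if (seeding$z_polarization <= 0 || seeding$z_polarization > 1) {
    stop("seeding z_polarization must be in (0, 1]")
  }
  # calibrate the Lorentzian amplitude: velocity_scale(rho_ref, fa_ref) == 1
  nu$a <- (1 - nu$d) *
    (1 + ((nu$rho_ref - nu$rho0) / nu$b)^2) *
    (1 + ((nu$fa_ref - nu$fa0) / nu$c)^2)
  if (max_step <= 0) stop("max_step must be positive")
  structure(list(alpha = alpha, dt = dt, mode = mode, rate_mode = rate_mode,
                 sigmoid = sigmoid, linear = linear, nu = nu,
                 max_step = max_step,
                 w_thresh = w_thresh, vessel_radius = vessel_radius,
                 branching = branching,
                 init_fibril_weight = init_fibril_weight,
                 seeding = seeding),
            class = "growth_config")
}

#' Contact-guidance growth direction
#'
#' Partially rotates the current vessel orientation `psi` towards the sampled
#' fibril direction `theta` about their shared orthogonal axis
#' `u = psi x theta / |psi x theta|`, by the fraction `alpha` of the full
#' angle: `alpha = 0` returns `psi` unchanged, `alpha = 1` returns `theta`.
#' `theta` is expected sign-aligned with `psi` (axial convention,
#' `psi . theta >= 0`); if the two are numerically parallel `psi` is returned.
#'
#' @param psi Current orientation (unit 3-vector).
#' @param theta Sampled fibril direction (unit 3-vector).
#' @param alpha Fibril weight in `[0, 1]`.
#' @return Unit 3-vector coplanar with `psi` and `theta`.
#' @export
growth_direction <- function(psi, theta, alpha) {
  if (alpha < 0 || alpha > 1) stop("alpha must be in [0, 1]")
  u <- c(psi[2] * theta[3] - psi[3] * theta[2],
         psi[3] * theta[1] - psi[1] * theta[3],
         psi[1] * theta[2] - psi[2] * theta[1])
  nu_ <- sqrt(sum(u^2))
  if (nu_ < 1e-12) return(psi)
  if (alpha == 1) return(theta / sqrt(sum(theta^2)))
  u <- u / nu_
  ang <- alpha * acos(min(1, max(-1, sum(psi * theta))))
  # u is orthogonal to psi, so Rodrigues reduces to a planar rotation
  ups <- c(u[2] * psi[3] - u[3] * psi[2],
           u[3] * psi[1] - u[1] * psi[3],
           u[1] * psi[2] - u[2] * psi[1])
  out <- psi * cos(ang) + ups * sin(ang)
  out / sqrt(sum(out^2))
}

#' Density- and anisotropy-dependent velocity scale
#'
#' A three-dimensional Lorentzian in collagen density `rho` (mg/mL) and
#' fractional anisotropy `FA`,
#' \deqn{\nu(\rho, FA) = \frac{a_\nu}{\left(1 + \left(\frac{\rho -
#'   \rho_0}{b_\nu}\right)^2\right)\left(1 + \left(\frac{FA -
#'   FA_0}{c_\nu}\right)^2\right)} + d_\nu,}
#' normalized so that unaligned 3 mg/mL collagen gives `nu = 1`. With the
#' default centers (`rho0` below and `fa0` above the physiologic range) the
#' scale decreases with density over `[3, 5]` mg/mL and increases with
#' anisotropy over `[0, 1]`; the floor `d` sustains minimal non-negative
#' growth everywhere.
#'
#' @param rho Collagen density in mg/mL (positive).
#' @param fa Fractional anisotropy in `[0, 1]`.
#' @param config A `"growth_config"`.
#' @return The dimensionless velocity scale (`>= config$nu$d`).
#' @export
velocity_scale <- function(rho, fa, config) {
  if (any(rho <= 0)) stop("density must be positive")
  nu <- config$nu
  nu$a / ((1 + ((rho - nu$rho0) / nu$b)^2) *
            (1 + ((fa - nu$fa0) / nu$c)^2)) + nu$d
}

#' Time-dependent extension rates
#'
#' `sigmoid_rate()` is the time derivative of a logistic total-length curve
#' `L(t) = A * plogis((t - midpoint)/tau)`: non-negative, unimodal with its
#' maximum at the midpoint day, integrating to the sigmoid's total length
#' increment. `linear_rate_with_arrest()` ramps linearly to a constant rate
#' over the first `ramp_days` and returns 0 once the local vessel volume
#' fraction exceeds `w_thresh`.
#'
#' @param t Time in days.
#' @param config A `"growth_config"`.
#' @param local_volume_fraction Vessel volume fraction in the tip's cell.
#' @return Extension rate in mm/day.
#' @export
sigmoid_rate <- function(t, config) {
  s <- config$sigmoid
  p <- stats::plogis((t - s$midpoint) / s$tau)
  s$amplitude * p * (1 - p) / s$tau
}

#' @rdname sigmoid_rate
#' @export
linear_rate_with_arrest <- function(t, local_volume_fraction, config) {
  if (local_volume_fraction > config$w_thresh) return(0)
  config$linear$rate * min(1, t / config$linear$ramp_days)
}

# --- network container ---------------------------------------------------

new_network <- function(grid, n_seg_guess = 256L, n_tip_guess = 64L) {
  structure(list(
    seg = matrix(NA_real_, n_seg_guess, 8,
                 dimnames = list(NULL, c("x0", "y0", "z0", "x1", "y1", "z1",
                                         "birth", "parent"))),
    n_seg = 0L,
    tip = matrix(NA_real_, n_tip_guess, 12,
                 dimnames = list(NULL, c("x", "y", "z", "px", "py", "pz",
                                         "active", "accum", "thresh",
                                         "lineage", "last_seg", "cell"))),
    n_tip = 0L,
    n_lineage = 0L,
    cell_length = numeric(if (is.null(grid)) 0 else grid$n_cells)
  ), class = "vessel_network")
}

grow_matrix <- function(m, need) {
  while (nrow(m) < need) {
    m <- rbind(m, matrix(NA_real_, nrow(m), ncol(m)))
  }
  m
}

nw_add_segment <- function(nw, p0, p1, birth, parent) {
  nw$n_seg <- nw$n_seg + 1L
  if (nw$n_seg > nrow(nw$seg)) nw$seg <- grow_matrix(nw$seg, nw$n_seg)
  nw$seg[nw$n_seg, ] <- c(p0, p1, birth, parent)
  nw
}

nw_add_tip <- function(nw, pos, psi, thresh, lineage, last_seg, cell = NA) {
  nw$n_tip <- nw$n_tip + 1L
  if (nw$n_tip > nrow(nw$tip)) nw$tip <- grow_matrix(nw$tip, nw$n_tip)
  nw$tip[nw$n_tip, ] <- c(pos, psi, 1, 0, thresh, lineage, last_seg, cell)
  nw
}

#' Segment table of a vessel network
#'
#' @param network A `"vessel_network"`.
#' @return A data.frame with one row per segment: endpoints (mm), birth time
#'   (days), parent segment id and segment id.
#' @export
network_segments <- function(network) {
  if (network$n_seg == 0) {
    return(data.frame(id = integer(), x0 = numeric(), y0 = numeric(),
                      z0 = numeric(), x1 = numeric(), y1 = numeric(),
                      z1 = numeric(), birth = numeric(), parent = integer()))
  }
  s <- as.data.frame(network$seg[seq_len(network$n_seg), , drop = FALSE])
  cbind(id = seq_len(network$n_seg), s)
}

#' Total network length
#'
#' @param network A `"vessel_network"`.
#' @return Total segment length in mm.
#' @export
network_length <- function(network) {
  if (network$n_seg == 0) return(0)
  s <- network$seg[seq_len(network$n_seg), , drop = FALSE]
  sum(sqrt((s[, 4] - s[, 1])^2 + (s[, 5] - s[, 2])^2 + (s[, 6] - s[, 3])^2))
}

#' @export
print.vessel_network <- function(x, ...) {
  cat("Vessel network:", x$n_seg, "segments,",
      sum(x$tip[seq_len(x$n_tip), "active"] == 1), "active tips, total length",
      signif(network_length(x), 5), "mm\n")
  invisible(x)
}

# rejection sampler working from a precomputed spectral decomposition
sample_direction_spectral <- function(radii, axes) {
  rmax <- radii[1]
  acc <- (4 / 3) * pi * prod(radii) / (2 * rmax)^3
  batch <- min(max(16, ceiling(2 / acc)), 4096)
  for (it in 1:64) {
    r <- matrix(stats::runif(3 * batch, -rmax, rmax), batch, 3)
    ok <- which((r[, 1] / radii[1])^2 + (r[, 2] / radii[2])^2 +
                  (r[, 3] / radii[3])^2 < 1 & rowSums(r^2) > 0)
    if (length(ok) > 0) {
      v <- r[ok[1], ]
      v <- v / sqrt(sum(v^2))
      return(as.numeric(axes %*% v))
    }
  }
  stop("sample_direction: rejection iteration cap exceeded")
}

#' Advance all active vessel tips by one time step
#'
#' For each active tip: the local fibril field is interpolated to the tip
#' position (Log-Euclidean over the cell's eight integration points, with
#' natural coordinates rescaled by `sqrt(3)` and clamped so that trilinear
#' weights apply to Gauss-point data), a contact-guidance direction `theta` is
#' sampled from the interpolated EFD (or interpolated from the legacy vector
#' field), sign-aligned into the hemisphere of the current orientation, and
#' the tip is rotated by [growth_direction()] and extended by
#' `rate(t) * velocity_scale(rho, FA) * dt` (capped at `config$max_step`).
#' Tips leaving the domain are trimmed to the boundary and deactivated.
#'
#' @param network A `"vessel_network"`.
#' @param grid A `"domain_grid"`.
#' @param config A `"growth_config"`.
#' @param t Simulation time at the start of the step (days).
#' @return The updated network.
#' @export
grow_step <- function(network, grid, config, t) {
  if (network$n_tip == 0L) return(network)
  dt <- config$dt
  tip <- network$tip
  act <- which(tip[seq_len(network$n_tip), "active"] == 1)
  for (i in act) {
    pos <- tip[i, 1:3]
    cell <- grid_locate(grid, pos)
    if (is.na(cell)) {
      tip[i, "active"] <- 0
      next
    }
    lo <- grid$cell_lo[cell, ]
    hi <- grid$cell_hi[cell, ]
    xi <- 2 * (pos - lo) / (hi - lo) - 1
    xi <- pmin(pmax(sqrt(3) * xi, -1), 1)
    w <- (1 + hex8_signs[, 1] * xi[1]) * (1 + hex8_signs[, 2] * xi[2]) *
      (1 + hex8_signs[, 3] * xi[3]) / 8
    ips <- (cell - 1L) * 8L + 1:8
    rho <- sum(w * grid$density[ips])
    Svec <- as.numeric(w %*% grid$logefd6[ips, , drop = FALSE])
    e <- eigen(vec6_to_sym3(Svec), symmetric = TRUE)
    radii <- exp(e$values)
    fa <- fractional_anisotropy(radii)
    psi <- tip[i, 4:6]
    theta <- if (config$mode == "efd") {
      sample_direction_spectral(radii, e$vectors)
    } else {
      suppressWarnings(
        vector_interpolate(grid$vectors[ips, , drop = FALSE], w)
      )
    }
    if (sum(theta * psi) < 0) theta <- -theta
    psi_new <- growth_direction(psi, theta, config$alpha)
    base <- if (config$rate_mode == "sigmoid") {
      sigmoid_rate(t, config)
    } else {
      vf <- network$cell_length[cell] * pi * config$vessel_radius^2 /
        grid$cell_volume[cell]
      linear_rate_with_arrest(t, vf, config)
    }
    len <- base * velocity_scale(rho, fa, config) * dt
    len <- min(len, config$max_step)
    if (len <= 0) next
    newpos <- pos + len * psi_new
    outside <- any(newpos < grid$lo) || any(newpos > grid$hi)
    if (outside) {
      # trim to the domain boundary and deactivate
      tt <- 1
      for (k in 1:3) {
        if (psi_new[k] > 0 && newpos[k] > grid$hi[k]) {
          tt <- min(tt, (grid$hi[k] - pos[k]) / (len * psi_new[k]))
        }
        if (psi_new[k] < 0 && newpos[k] < grid$lo[k]) {
          tt <- min(tt, (grid$lo[k] - pos[k]) / (len * psi_new[k]))
        }
      }
      tt <- max(tt, 0)
      len <- len * tt
      newpos <- pos + len * psi_new
      tip[i, "active"] <- 0
    }
    if (len > 0) {
      network$tip <- tip
      network <- nw_add_segment(network, pos, newpos, t + dt,
                                tip[i, "last_seg"])
      tip <- network$tip
      tip[i, 1:3] <- newpos
      tip[i, 4:6] <- psi_new
      tip[i, "accum"] <- tip[i, "accum"] + len
      tip[i, "last_seg"] <- network$n_seg
      tip[i, "cell"] <- cell
      network$cell_length[cell] <- network$cell_length[cell] + len
    }
  }
  network$tip <- tip
  network
}

# truncated normal on (lo, hi] by rejection
rtrunc_norm <- function(mean, sd, lo, hi) {
  for (it in 1:200) {
    x <- stats::rnorm(1, mean, sd)
    if (x > lo && x <= hi) return(x)
  }
  min(max(mean, lo + 1e-6), hi)
}

#' Stochastic branching along recently grown segments
#'
#' A lineage branches once its accumulated growth since the last branch
#' exceeds its threshold (drawn from an exponential distribution with mean
#' `branching$mean_threshold`). The branch emerges from a uniformly random
#' point on the lineage's most recent segment; its direction is the parent
#' orientation rotated by a zenith angle (truncated normal, degrees) about an
#' axis set by an azimuth angle uniform on `[0, 2 pi)` around the parent axis.
#'
#' @inheritParams grow_step
#' @return The updated network (possibly with new active tips).
#' @export
branch_step <- function(network, grid, config, t) {
  br <- config$branching
  if (!isTRUE(br$enabled) || network$n_tip == 0L) return(network)
  nt <- network$n_tip
  candidates <- which(network$tip[seq_len(nt), "active"] == 1 &
                        network$tip[seq_len(nt), "accum"] >
                          network$tip[seq_len(nt), "thresh"])
  for (i in candidates) {
    seg_id <- network$tip[i, "last_seg"]
    if (is.na(seg_id) || seg_id < 1) next
    s <- network$seg[seg_id, ]
    u <- stats::runif(1)
    bp <- c(s[1] + u * (s[4] - s[1]), s[2] + u * (s[5] - s[2]),
            s[3] + u * (s[6] - s[3]))
    psi <- network$tip[i, 4:6]
    zen <- rtrunc_norm(br$zenith_mean, br$zenith_sd, 0, 90) * pi / 180
    az <- stats::runif(1, 0, 2 * pi)
    # orthonormal frame around the parent axis
    a <- if (abs(psi[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    u1 <- a - sum(a * psi) * psi
    u1 <- u1 / sqrt(sum(u1^2))
    u2 <- c(psi[2] * u1[3] - psi[3] * u1[2],
            psi[3] * u1[1] - psi[1] * u1[3],
            psi[1] * u1[2] - psi[2] * u1[1])
    dir <- cos(zen) * psi + sin(zen) * (cos(az) * u1 + sin(az) * u2)
    dir <- dir / sqrt(sum(dir^2))
    network$n_lineage <- network$n_lineage + 1L
    network <- nw_add_tip(network, bp, dir,
                          thresh = stats::rexp(1, 1 / br$mean_threshold),
                          lineage = network$n_lineage, last_seg = seg_id)
    network$tip[i, "accum"] <- 0
    network$tip[i, "thresh"] <- stats::rexp(1, 1 / br$mean_threshold)
  }
  network
}
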