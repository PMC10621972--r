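test_that("uniform culture grids have the stated geometry and fields", {
  g <- build_uniform_culture("low", 3)
  expect_equal(g$n_cells, 1000)
  expect_equal(g$hi - g$lo, rep(1, 3))
  expect_equal(unique(g$density), 3)
  fld <- interpolate_field(g, c(0.55, 0.31, 0.77))
  expect_equal(fld$fa, fractional_anisotropy(c(1.3, 1, 0.5)),
               tolerance = 1e-9)
  g4 <- build_uniform_culture("high", 4, extent = 0.5, cell_size = 0.1)
  expect_equal(g4$n_cells, 125)
  expect_equal(unique(g4$density), 4)
  s <- spectral_axes(interpolate_field(g4, c(0.25, 0.25, 0.25))$efd)
  expect_equal(s$radii, c(5, 1, 0.5), tolerance = 1e-9)
  expect_equal(abs(s$axes[, 1]), c(1, 0, 0), tolerance = 1e-9)
})

test_that("gradient domains ramp beta1 across the middle region", {
  g <- build_gradient("positive")
  expect_equal(g$hi - g$lo, c(1.8, 2.0, 0.5))
  expect_equal(g$n_cells, 18 * 20 * 5)
  fa_left <- interpolate_field(g, c(0.45, 1, 0.25))$fa
  fa_right <- interpolate_field(g, c(1.35, 1, 0.25))$fa
  expect_gt(fa_right, fa_left)
  # flanks take the adjacent end values
  s_prox <- spectral_axes(interpolate_field(g, c(0.05, 1, 0.25))$efd)
  expect_equal(s_prox$radii, c(1.3, 1, 0.5), tolerance = 1e-6)
  s_dist <- spectral_axes(interpolate_field(g, c(1.75, 1, 0.25))$efd)
  expect_equal(s_dist$radii, c(5, 1, 0.5), tolerance = 1e-6)
  # beta2 and beta3 fixed along the ramp
  s_mid <- spectral_axes(interpolate_field(g, c(0.9, 1, 0.25))$efd)
  expect_equal(s_mid$radii[2:3], c(1, 0.5), tolerance = 1e-6)

  gneg <- build_gradient("negative")
  expect_gt(interpolate_field(gneg, c(0.45, 1, 0.25))$fa,
            interpolate_field(gneg, c(1.35, 1, 0.25))$fa)

  gb <- build_gradient("baseline")
  expect_lt(interpolate_field(gb, c(0.9, 1, 0.25))$fa, 0.05)
})

test_that("TACS domains encode interface density and alignment", {
  gb <- build_tacs("baseline", x_width = 0.4)
  expect_equal(unique(gb$density), 3)
  in_iface <- c(0.2, 0.84, 0.3)
  in_tumor <- c(0.2, 1.2, 0.3)
  expect_equal(interpolate_field(gb, in_iface)$fa,
               interpolate_field(gb, in_tumor)$fa, tolerance = 1e-9)

  g1 <- build_tacs("tacs1", x_width = 0.4)
  expect_equal(interpolate_field(g1, in_iface)$density, 5)
  expect_equal(interpolate_field(g1, in_tumor)$density, 3)

  g2 <- build_tacs("tacs2", x_width = 0.4)
  a2 <- spectral_axes(interpolate_field(g2, in_iface)$efd)
  expect_equal(abs(a2$axes[, 1]), c(1, 0, 0), tolerance = 1e-6)

  g3 <- build_tacs("tacs3", x_width = 0.4)
  a3 <- spectral_axes(interpolate_field(g3, in_iface)$efd)
  expect_equal(abs(a3$axes[, 1]), c(0, 1, 0), tolerance = 1e-6)

  g13 <- build_tacs("tacs1_3", x_width = 0.4)
  expect_equal(interpolate_field(g13, in_iface)$density, 5)
  a13 <- spectral_axes(interpolate_field(g13, in_iface)$efd)
  expect_equal(abs(a13$axes[, 1]), c(0, 1, 0), tolerance = 1e-6)
})

test_that("region bookkeeping tiles the domain exactly", {
  for (g in list(build_gradient("positive"), build_tacs("tacs2",
                                                        x_width = 0.4))) {
    expect_false(anyNA(g$cell_region))
    vol_regions <- sum(vapply(g$regions, function(b) prod(b$hi - b$lo),
                              numeric(1)))
    expect_equal(vol_regions, prod(g$hi - g$lo), tolerance = 1e-9)
    expect_equal(sum(g$cell_volume), prod(g$hi - g$lo), tolerance = 1e-9)
  }
})

test_that("grid_locate agrees with cell bounds, including refined blocks", {
  g <- build_tacs("baseline", x_width = 0.4)
  set.seed(34)
  for (i in 1:50) {
    p <- g$lo + runif(3) * (g$hi - g$lo)
    cell <- grid_locate(g, p)
    expect_false(is.na(cell))
    expect_true(all(p >= g$cell_lo[cell, ] - 1e-9) &&
                  all(p <= g$cell_hi[cell, ] + 1e-9))
  }
  expect_true(is.na(grid_locate(g, g$hi + 1)))
})

test_that("fragment seeding: counts, isotropy and length distribution", {
  g <- build_uniform_culture("low", 3)
  cfg <- fast_config()
  cfg$init_fibril_weight <- 0

  set.seed(35)
  nw0 <- seed_fragments(g, cfg, n = 0)
  expect_equal(nw0$n_seg, 0)

  # z_polarization = 1: isotropic orientations, XY axis ratio -> 1
  cfg1 <- cfg
  cfg1$seeding$z_polarization <- 1
  set.seed(36)
  nw1 <- seed_fragments(g, cfg1, n = 4000)
  expect_equal(nw1$n_seg, 4000)
  r1 <- fit_axis_ratio(network_odf(nw1, "xy"))
  expect_lt(r1, 1.06)

  # z_polarization < 1: flattened towards XY, still isotropic within XY
  set.seed(37)
  nw3 <- seed_fragments(g, cfg, n = 4000)
  expect_lt(fit_axis_ratio(network_odf(nw3, "xy")), 1.06)
  expect_gt(fit_axis_ratio(network_odf(nw3, "xz")), 1.3)

  # Kolmogorov-Smirnov non-rejection against the configured length law
  segs <- network_segments(nw3)
  lens <- sqrt((segs$x1 - segs$x0)^2 + (segs$y1 - segs$y0)^2 +
                 (segs$z1 - segs$z0)^2)
  ks <- suppressWarnings(
    stats::ks.test(lens, stats::plnorm,
                   meanlog = log(cfg$seeding$length_median),
                   sdlog = cfg$seeding$length_sdlog)
  )
  expect_gt(ks$p.value, 0.01)

  # default count follows the per-volume density
  set.seed(38)
  nwd <- seed_fragments(g, cfg)
  expect_equal(nwd$n_seg, round(cfg$seeding$per_mm3 * 1))
  # region-restricted seeding stays inside the region
  gg <- build_gradient("baseline")
  set.seed(39)
  nwr <- seed_fragments(gg, cfg, region = "proximal")
  segs <- network_segments(nwr)
  ctrs <- cbind((segs$x0 + segs$x1) / 2)
  expect_true(all(ctrs <= 0.4 + 1e-9))
})

test_that("vector mode samples each integration point exactly once", {
  set.seed(40)
  g <- build_uniform_culture("high", 3, extent = 0.3, mode = "vector")
  expect_equal(dim(g$vectors), c(g$n_cells * 8, 3))
  expect_equal(rowSums(g$vectors^2), rep(1, nrow(g$vectors)),
               tolerance = 1e-12)
  v1 <- g$vectors
  # interpolating fields later never mutates the stored vectors
  fld <- interpolate_field(g, c(0.15, 0.15, 0.15))
  expect_identical(g$vectors, v1)
})

test_that("prescribed deformation fields pseudo-deform the stored EFDs", {
  g <- build_uniform_culture("low", 3, extent = 0.3)
  gI <- apply_deformation_field(g, diag(3))
  expect_equal(gI$efd6, g$efd6, tolerance = 1e-12)

  R <- rot_z(30)
  gR <- apply_deformation_field(g, R)
  s0 <- spectral_axes(efdangio:::vec6_to_sym3(g$efd6[1, ]))
  sR <- spectral_axes(efdangio:::vec6_to_sym3(gR$efd6[1, ]))
  expect_equal(sR$radii, s0$radii, tolerance = 1e-9)

  giso <- build_uniform_culture("low", 3, extent = 0.3,
                                level_radii = list(low = c(1, 1, 1),
                                                   med = c(1, 1, 1),
                                                   high = c(1, 1, 1)))
  g2 <- apply_deformation_field(giso, diag(c(2, 1, 1)))
  s2 <- spectral_axes(efdangio:::vec6_to_sym3(g2$efd6[5, ]))
  expect_equal(s2$radii, c(2, 1, 1), tolerance = 1e-9)
  expect_equal(g2$density, giso$density)

  expect_error(apply_deformation_field(g, diag(c(-1, 1, 1))), "det")
})
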