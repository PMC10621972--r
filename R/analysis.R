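#' Orientation distribution of a vessel network
#'
#' Segment orientations are treated as axial data (a segment and its reversal
#' are the same observation) and weighted by segment length. For planar
#' projections (`"xy"`, `"xz"`) orientations are projected and binned into
#' 180 one-degree axial bins; for `"none"` the 3D orientations are binned on
#' an icosphere with antipodal symmetrization.
#'
#' @param network A `"vessel_network"` with at least one segment.
#' @param projection `"xy"`, `"xz"` or `"none"`.
#' @param mesh Icosphere used when `projection = "none"` (default level 3).
#' @return For projections, a `"planar_odf"`: list with `angle` (bin centers,
#'   degrees in `[0, 180)`) and `mass` (summing to 1). Otherwise an
#'   `"odf_histogram"`.
#' @export
network_odf <- function(network, projection = c("xy", "xz", "none"),
                        mesh = NULL) {
  projection <- match.arg(projection)
  if (network$n_seg == 0) stop("network has no segments")
  s <- network$seg[seq_len(network$n_seg), , drop = FALSE]
  d <- s[, 4:6, drop = FALSE] - s[, 1:3, drop = FALSE]
  len <- sqrt(rowSums(d^2))
  keep <- len > 0
  d <- d[keep, , drop = FALSE]
  len <- len[keep]
  if (length(len) == 0) stop("network has no segments of positive length")
  if (projection == "none") {
    if (is.null(mesh)) mesh <- build_icosphere(3)
    return(histogram_from_directions(d / len, mesh, symmetrize = TRUE,
                                     weights = len))
  }
  cols <- if (projection == "xy") c(1, 2) else c(1, 3)
  u <- d[, cols[1]]
  v <- d[, cols[2]]
  plen <- sqrt(u^2 + v^2)
  ok <- plen > 1e-12
  ang <- (atan2(v[ok], u[ok]) * 180 / pi) %% 180
  bin <- pmin(floor(ang) + 1L, 180L)
  mass <- numeric(180)
  agg <- rowsum(len[ok], bin)
  mass[as.integer(rownames(agg))] <- agg
  mass <- mass / sum(mass)
  structure(list(angle = seq(0.5, 179.5, by = 1), mass = mass),
            class = "planar_odf")
}

#' Major/minor axis ratio of a planar ODF
#'
#' Fits the axial second-moment (structure) tensor of the planar orientation
#' histogram, `M = sum_b m_b u_b u_b'` with `u_b` the bin-center axis, and
#' returns the square root of its eigenvalue ratio -- the semiprincipal axis
#' ratio of the best-fitting orientation ellipse. A perfectly uniform
#' histogram gives exactly 1; a single-axis histogram is degenerate and is
#' reported as `cap` with a warning.
#'
#' @param odf A `"planar_odf"`.
#' @param cap Upper bound on the reported ratio.
#' @return Axis ratio `>= 1`.
#' @export
fit_axis_ratio <- function(odf, cap = 50) {
  if (!inherits(odf, "planar_odf")) stop("odf must be a planar_odf")
  phi <- odf$angle * pi / 180
  m <- odf$mass
  M <- matrix(c(sum(m * cos(phi)^2), sum(m * cos(phi) * sin(phi)),
                sum(m * cos(phi) * sin(phi)), sum(m * sin(phi)^2)), 2, 2)
  ev <- eigen(M, symmetric = TRUE, only.values = TRUE)$values
  if (ev[2] <= ev[1] / cap^2) {
    warning("degenerate planar ODF; axis ratio capped at ", cap)
    return(cap)
  }
  min(sqrt(ev[1] / ev[2]), cap)
}

#' Per-region vessel lengths and vascularity
#'
#' Clips every segment exactly against each region's axis-aligned box and
#' accredits the clipped length, so the per-region lengths sum to the total
#' network length. Vascularity is length per region volume (mm / mm^3).
#'
#' @param network A `"vessel_network"`.
#' @param grid A `"domain_grid"` with named regions.
#' @return A `"network_metrics"` list: `total_length`, `region_length`
#'   (named), `vascularity` (named), `region_volume` (named).
#' @export
regional_lengths <- function(network, grid) {
  regions <- grid$regions
  rl <- stats::setNames(numeric(length(regions)), names(regions))
  total <- 0
  if (network$n_seg > 0) {
    s <- network$seg[seq_len(network$n_seg), , drop = FALSE]
    p0 <- s[, 1:3, drop = FALSE]
    d <- s[, 4:6, drop = FALSE] - p0
    len <- sqrt(rowSums(d^2))
    total <- sum(len)
    for (r in seq_along(regions)) {
      lo <- regions[[r]]$lo
      hi <- regions[[r]]$hi
      t0 <- rep(0, nrow(s))
      t1 <- rep(1, nrow(s))
      for (k in 1:3) {
        dk <- d[, k]
        a <- (lo[k] - p0[, k]) / dk
        b <- (hi[k] - p0[, k]) / dk
        tlo <- pmin(a, b)
        thi <- pmax(a, b)
        par <- abs(dk) < 1e-300
        inside <- p0[, k] >= lo[k] & p0[, k] <= hi[k]
        tlo[par] <- ifelse(inside[par], -Inf, Inf)
        thi[par] <- ifelse(inside[par], Inf, -Inf)
        t0 <- pmax(t0, tlo)
        t1 <- pmin(t1, thi)
      }
      rl[r] <- sum(pmax(t1 - t0, 0) * len)
    }
  }
  vols <- vapply(regions, function(b) prod(b$hi - b$lo), numeric(1))
  structure(list(total_length = total, region_length = rl,
                 vascularity = rl / vols, region_volume = vols),
            class = "network_metrics")
}

#' @export
print.network_metrics <- function(x, ...) {
  cat("Network metrics: total length", signif(x$total_length, 5), "mm\n")
  print(data.frame(region = names(x$region_length),
                   length_mm = signif(x$region_length, 5),
                   vascularity = signif(x$vascularity, 5)))
  invisible(x)
}

#' Standard per-run morphometry
#'
#' Total and per-region lengths plus fitted XY and XZ axis ratios for one
#' simulated network.
#'
#' @param network A `"vessel_network"`.
#' @param grid A `"domain_grid"`.
#' @return A one-row data.frame.
#' @export
network_metrics_row <- function(network, grid) {
  rl <- regional_lengths(network, grid)
  ratios <- c(xy = NA_real_, xz = NA_real_)
  if (network$n_seg > 0) {
    ratios["xy"] <- fit_axis_ratio(network_odf(network, "xy"))
    ratios["xz"] <- fit_axis_ratio(network_odf(network, "xz"))
  }
  out <- data.frame(total_length = rl$total_length,
                    axis_ratio_xy = ratios[["xy"]],
                    axis_ratio_xz = ratios[["xz"]])
  for (r in names(rl$region_length)) {
    out[[paste0("length_", r)]] <- rl$region_length[[r]]
  }
  out
}

#' Scenario specification
#'
#' Bundles a scenario family, its builder options and the replicate seeds.
#' Families: `"uniform_culture"` ([build_uniform_culture()]), `"gradient"`
#' ([build_gradient()]), `"tacs"` ([build_tacs()]).
#'
#' @param family Scenario family name.
#' @param options Named list of builder arguments.
#' @param seeds Integer vector of replicate seeds (default `1:10`).
#' @param days Simulated duration in days.
#' @param seed_region Region to seed fragments into; defaults to the family's
#'   convention (whole domain for cultures, `proximal` for gradients,
#'   `periphery` for tumor interfaces).
#' @return A `"scenario_spec"`.
#' @export
scenario_spec <- function(family = c("uniform_culture", "gradient", "tacs"),
                          options = list(), seeds = 1:10, days = 10,
                          seed_region = NULL) {
  family <- match.arg(family)
  if (length(seeds) < 1) stop("at least one seed is required")
  if (is.null(seed_region)) {
    seed_region <- switch(family, uniform_culture = NULL,
                          gradient = "proximal", tacs = "periphery")
  }
  structure(list(family = family, options = options, seeds = seeds,
                 days = days, seed_region = seed_region),
            class = "scenario_spec")
}

scenario_builder <- function(spec) {
  fn <- switch(spec$family,
    uniform_culture = build_uniform_culture,
    gradient = build_gradient,
    tacs = build_tacs
  )
  function() do.call(fn, spec$options)
}

#' Run replicate simulations of a scenario
#'
#' Runs the full pipeline once per seed and collects per-seed morphometry,
#' mean and standard deviation summaries, and a reproducibility manifest
#' (configuration hash, seeds, package version). A replicate that fails is
#' marked in the report and the remaining seeds proceed.
#'
#' @param spec A `"scenario_spec"`.
#' @param config A `"growth_config"`.
#' @return A `"replicate_report"`: list with `per_seed` (data.frame),
#'   `summary` (mean/sd per metric), `failed` (seeds) and `manifest`.
#' @export
run_replicates <- function(spec, config) {
  builder <- scenario_builder(spec)
  rows <- list()
  failed <- integer()
  for (sd in spec$seeds) {
    res <- tryCatch({
      sim <- simulate_growth(builder, config, days = spec$days, seed = sd,
                             seed_region = spec$seed_region)
      cbind(seed = sd, network_metrics_row(sim$network, sim$grid))
    }, error = function(e) {
      warning("replicate seed ", sd, " failed: ", conditionMessage(e))
      NULL
    })
    if (is.null(res)) failed <- c(failed, sd) else rows[[length(rows) + 1]] <- res
  }
  per_seed <- do.call(rbind, rows)
  num <- per_seed[, setdiff(names(per_seed), "seed"), drop = FALSE]
  summary <- data.frame(metric = names(num),
                        mean = vapply(num, mean, numeric(1)),
                        sd = vapply(num, stats::sd, numeric(1)),
                        row.names = NULL)
  manifest <- list(
    family = spec$family,
    options = spec$options,
    days = spec$days,
    seeds = spec$seeds,
    failed = failed,
    config_hash = config_hash(config),
    package_version = as.character(utils::packageVersion("efdangio")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  structure(list(per_seed = per_seed, summary = summary, failed = failed,
                 manifest = manifest), class = "replicate_report")
}

config_hash <- function(config) {
  js <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = NA)
  # small stable checksum without external dependencies
  bytes <- as.integer(charToRaw(as.character(js)))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Write and read vessel segment tables
#'
#' Plain CSV with one row per segment (id, parent, birth time, endpoints).
#'
#' @param network A `"vessel_network"`.
#' @param path File path.
#' @export
write_segments_csv <- function(network, path) {
  utils::write.csv(network_segments(network), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_segments_csv
#' @export
read_segments_csv <- function(path) {
  df <- utils::read.csv(path)
  nw <- new_network(NULL, n_seg_guess = max(1L, nrow(df)))
  for (i in seq_len(nrow(df))) {
    nw <- nw_add_segment(nw, c(df$x0[i], df$y0[i], df$z0[i]),
                         c(df$x1[i], df$y1[i], df$z1[i]),
                         df$birth[i], df$parent[i])
  }
  nw
}

#' Export a network as legacy VTK polylines
#'
#' @param network A `"vessel_network"`.
#' @param path Output file.
#' @export
write_vtk_network <- function(network, path) {
  n <- network$n_seg
  s <- network$seg[seq_len(n), , drop = FALSE]
  pts <- rbind(s[, 1:3, drop = FALSE], s[, 4:6, drop = FALSE])
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0", "vessel network", "ASCII",
               "DATASET POLYDATA", paste("POINTS", 2 * n, "float")), con)
  utils::write.table(format(pts, scientific = FALSE), con,
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  writeLines(paste("LINES", n, 3 * n), con)
  utils::write.table(cbind(2L, seq_len(n) - 1L, seq_len(n) - 1L + n), con,
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}
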