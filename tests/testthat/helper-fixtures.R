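# shared fixtures: meshes are expensive to rebuild per test
mesh_l2 <- build_icosphere(2)
mesh_l1 <- build_icosphere(1)

random_rotation <- function() {
  # QR of a Gaussian matrix, sign-fixed to det +1
  q <- qr.Q(qr(matrix(stats::rnorm(9), 3, 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

random_spd <- function(cond = 10) {
  efd_from_axes(stats::runif(3, 1 / sqrt(cond), sqrt(cond)),
                random_rotation())
}

random_defgrad <- function() {
  repeat {
    F <- matrix(stats::rnorm(9, sd = 0.5), 3, 3) + diag(3)
    if (det(F) > 0.05) return(deformation_gradient(F))
  }
}

unit <- function(v) v / sqrt(sum(v^2))

# tiny culture config used by growth tests
fast_config <- function(...) {
  growth_config(branching = list(enabled = FALSE), ...)
}

unit_rows <- function(m) m / sqrt(rowSums(m^2))

# a synthetic network of n parents all oriented along +x, each primed to
# branch on the next branch_step
new_network_for_test <- function(grid, n) {
  nw <- efdangio:::new_network(grid, n_seg_guess = 2 * n, n_tip_guess = 4 * n)
  ctr <- (grid$lo + grid$hi) / 2
  for (i in seq_len(n)) {
    p0 <- ctr - c(0.05, 0, 0)
    p1 <- ctr + c(0.05, 0, 0)
    nw <- efdangio:::nw_add_segment(nw, p0, p1, 0, 0)
    nw <- efdangio:::nw_add_tip(nw, p1, c(1, 0, 0), thresh = 0.01,
                                lineage = i, last_seg = nw$n_seg)
    nw$tip[nw$n_tip, "accum"] <- 1
  }
  nw
}
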