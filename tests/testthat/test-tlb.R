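test_that("the D3Q27 lattice satisfies the weight and moment identities", {
  lat <- lattice_d3q27()
  expect_equal(sum(lat$w), 1, tolerance = 1e-15)
  expect_equal(colSums(lat$w * lat$xi), c(0, 0, 0))
  second <- t(lat$xi) %*% (lat$w * lat$xi)
  expect_equal(second, diag(3) * lat$cs2, tolerance = 1e-15)
  expect_equal(lat$xi[lat$opp, ], -lat$xi)
})

test_that("equilibria reproduce their defining moments and a scalar
          oracle value", {
  lat <- lattice_d3q27()
  set.seed(2)
  for (k in 1:20) {
    rho <- runif(1, 0.9, 1.1)
    v <- runif(3, -0.05, 0.05)
    Fi <- equilibrium_f(rho, v)
    expect_equal(sum(Fi), rho, tolerance = 1e-14)
    expect_equal(as.numeric(t(lat$xi) %*% Fi), rho * v, tolerance = 1e-14)
    R <- lat$cs2 / 303.15
    temp <- runif(1, 280, 320)
    Hi <- equilibrium_h(rho, v, temp, R)
    E <- 1.5 * R * temp + 0.5 * sum(v^2)
    expect_equal(sum(Hi), rho * E, tolerance = 1e-12)
  }
  # single-direction scalar arithmetic: direction (1,0,0), rho=1, v=(0.03,0,0)
  v <- c(0.03, 0, 0)
  i <- which(lat$xi[, 1] == 1 & lat$xi[, 2] == 0 & lat$xi[, 3] == 0)
  manual <- 1 * (2 / 27) * (1 + 3 * 0.03 + 4.5 * 0.03^2 - 1.5 * 0.03^2)
  expect_equal(equilibrium_f(1, v)[i], manual, tolerance = 1e-15)
  # rest state
  expect_equal(equilibrium_f(1.2, c(0, 0, 0)), 1.2 * lat$w)
  # H first moment vanishes at rest
  H0 <- equilibrium_h(1, c(0, 0, 0), 300, 1e-3)
  expect_equal(as.numeric(t(lat$xi) %*% H0), c(0, 0, 0), tolerance = 1e-15)
})

test_that("macroscopic recovery inverts the equilibria and is linear", {
  R <- (1 / 3) / 303.15
  Fi <- equilibrium_f(1.05, c(0.02, -0.01, 0.04))
  Hi <- equilibrium_h(1.05, c(0.02, -0.01, 0.04), 305, R)
  mac <- macroscopic(Fi, Hi, R)
  expect_equal(mac$rho, 1.05, tolerance = 1e-14)
  expect_equal(mac$v, c(0.02, -0.01, 0.04), tolerance = 1e-14)
  expect_equal(mac$T, 305, tolerance = 1e-10)
  expect_equal(mac$p, 1.05 / 3, tolerance = 1e-14)
  # brute-force 27-term sums on a random state
  set.seed(5)
  f <- runif(27, 0.01, 0.1)
  mac2 <- macroscopic(f)
  expect_equal(mac2$rho, sum(f))
  lat <- lattice_d3q27()
  expect_equal(mac2$v, colSums(f * lat$xi) / sum(f))
  # linearity of moments
  f2 <- runif(27, 0.01, 0.1)
  expect_equal(macroscopic(f + f2)$rho,
               macroscopic(f)$rho + macroscopic(f2)$rho)
  expect_error(macroscopic(-f), "density")
})

test_that("the nostril density relation has the stagnation limit, the
          low-speed expansion, and matches direct arithmetic", {
  expect_equal(svw_density(1, 0), 1)
  # Taylor: rho ~ 1 - (3/2) v^2 for gamma = 1.4, to fourth order
  for (v in c(1e-2, 5e-3)) {
    dev <- abs(svw_density(1, v) - (1 - 1.5 * v^2))
    expect_lt(dev, 10 * v^4)
  }
  # direct evaluation oracle at rho = 1, v = 0.05
  g <- 1.4
  manual <- (1 - (g - 1) / (2 * g) * 3 * 0.05^2)^(g / (g - 1))
  expect_equal(svw_density(1, 0.05), manual, tolerance = 1e-15)
  expect_error(svw_density(1, 2), "supersonic")
})

periodic_box <- function(nx = 4, ny = 16, nz = 1) {
  cellid <- array(seq_len(nx * ny * nz), c(nx, ny, nz))
  nb <- rhinoflow:::grid_neighbor_table(cellid, periodic = rep(TRUE, 3))
  ij <- which(cellid > 0, arr.ind = TRUE)
  list(nb = nb, ij = ij[order(cellid[cellid > 0]), , drop = FALSE])
}

test_that("a uniform equilibrium is a fixed point and mass is conserved
          to round-off in a periodic box", {
  box <- periodic_box(4, 8, 2)
  f0 <- matrix(rep(equilibrium_f(1, c(0.02, -0.01, 0.03)),
                   each = nrow(box$nb)), nrow(box$nb))
  res <- lbm_run(box$nb, f0 = f0, omega = 1.6, n_iter = 1000,
                 monitor_every = 100)
  expect_lt(max(abs(res$f - f0)), 1e-12)
  mass <- res$monitors$mass
  expect_lt(max(abs(mass - mass[1])) / mass[1], 1e-12)
})

test_that("a shear wave decays at the analytic viscous rate", {
  N <- 32
  box <- periodic_box(4, N, 1)
  A <- 0.01; k <- 2 * pi / N
  f0 <- t(vapply(seq_len(nrow(box$nb)), function(c)
    equilibrium_f(1, c(A * sin(k * (box$ij[c, 2] - 1)), 0, 0)),
    numeric(27)))
  omega <- 1.5
  nu <- (1 / omega - 0.5) / 3
  nsteps <- 800
  res <- lbm_run(box$nb, f0 = f0, omega = omega, n_iter = nsteps)
  amp <- 2 * mean(res$v[, 1] * sin(k * (box$ij[, 2] - 1)))
  expect_equal(amp, A * exp(-nu * k^2 * nsteps), tolerance = 0.01)
})

test_that("steady conduction between isothermal plates is linear and the
          total-energy moment identity holds", {
  cd <- run_conduction_slab(W = 16, n_iter = 8000)
  expect_lt(cd$max_rel_dev, 0.01)
  # sum(h) equals rho((DR/2)T + v^2/2) by construction of the moments
  res <- cd$result
  R <- (1 / 3) / ((309.15 + 293.15) / 2)
  E <- rowSums(res$h) / res$rho
  Tm <- (E - 0.5 * rowSums(res$v^2)) / (1.5 * R)
  expect_equal(Tm, res$T, tolerance = 1e-10)
})

test_that("pressure-driven channel flow reproduces the Poiseuille
          profile with little wall slip", {
  ch <- run_channel_poiseuille(W = 16, len = 16, dp = 2e-4, omega = 1.6,
                               n_iter = 9000)
  expect_false(ch$result$diverged)
  expect_lt(ch$l2_error, 0.015)
  # wall slip: quadratic extrapolation of the profile to the wall
  # position stays far below the centerline velocity
  y <- ch$y; u <- ch$profile
  co <- solve(cbind(1, y[1:3], y[1:3]^2), u[1:3])
  u_wall <- co[1]
  expect_lt(abs(u_wall) / max(u), 1e-2)
})

test_that("halfway bounce-back is the q = 1/2 case of the Bouzidi scheme", {
  # identical channels with default (NA -> 1/2) and explicit q = 1/2
  a <- run_channel_poiseuille(W = 8, len = 8, dp = 1e-4, omega = 1.5,
                              n_iter = 1500, q_wall = 0.5)
  cellid <- array(seq_len(8 * 8), c(8, 8, 1))
  nb <- rhinoflow:::grid_neighbor_table(cellid, periodic = c(FALSE, FALSE, TRUE))
  # NA q defaults to the halfway scheme
  otype <- integer(64); onormal <- integer(64)
  ij <- which(cellid > 0, arr.ind = TRUE)
  ij <- ij[order(cellid[cellid > 0]), , drop = FALSE]
  otype[ij[, 1] == 1] <- 1L; otype[ij[, 1] == 8] <- 2L
  onormal[otype == 1L] <- rhinoflow:::dir_index(c(1, 0, 0)) - 1L
  onormal[otype == 2L] <- rhinoflow:::dir_index(c(-1, 0, 0)) - 1L
  res <- lbm_run(nb, q = NULL, otype, onormal,
                 list(list(mode = 1L, dp = 1e-4), list(mode = 1L, dp = 0)),
                 omega = 1.5, n_iter = 1500)
  mid <- which(ij[, 1] == 4)
  expect_equal(res$v[mid, 1][order(ij[mid, 2])],
               a$result$v[mid, 1][order(ij[mid, 2])], tolerance = 1e-12)
})

test_that("the pharynx flux controller converges to the target Reynolds
          number in a straight duct", {
  d <- make_duct(width = 10, height = 10, length = 40)
  g <- mesh_to_grid(generate_mesh(d, l_uniform = 5))
  props <- fluid_properties(nu_lat = 0.02)
  bcs <- boundary_spec(pharynx = list(mode = "volume_flux", vdot = 4,
                                      gain = 5e-7))
  sim <- run_simulation(g, props, bcs, n_iter = 12000, avg_iter = 0,
                        patch_normals = attr(d, "patch_normals"),
                        thermal = FALSE, monitor_every = 100)
  expect_false(sim$lbm$diverged)
  gm <- sim$lbm$group_monitors[[which(sim$open_names == "pharynx")]]
  H_P <- length(sim$boundary_cells$pharynx)
  A_P <- H_P * (g$dx * 1e-3)^2
  re_target <- (4e-6 / A_P) * sqrt(4 * A_P / pi) / props$nu
  expect_equal(tail(gm$re, 1), re_target, tolerance = 0.01)
  # steady-state flux balance: the mass flux through developed interior
  # cross sections is z-independent to better than 1e-3 (the open-cell
  # layers themselves carry a first-order entrance artifact)
  flux_z <- vapply(sort(unique(sim$grid$cells$iz)), function(k) {
    sel <- sim$grid$cells$iz == k
    sum(sim$lbm$rho[sel] * sim$lbm$v[sel, 3])
  }, numeric(1))
  interior <- flux_z[5:(length(flux_z) - 4)]
  expect_lt((max(interior) - min(interior)) / abs(mean(interior)), 1e-3)
})

test_that("lattice/physical unit bridge reproduces collision frequencies
          and scales", {
  props <- fluid_properties(nu = 1.63e-5, nu_lat = 0.05)
  u <- lattice_units(1e-4, props)
  expect_equal(u$dt_s, 0.05 * 1e-8 / 1.63e-5)
  expect_equal(u$omega, 1 / (3 * 0.05 + 0.5))
  expect_equal((1 / u$omega - 0.5) / 3 * 1e-4^2 / u$dt_s, props$nu,
               tolerance = 1e-12)
  expect_equal(u$R_lat * props$T_avg, 1 / 3)
  expect_error(fluid_properties(nu_lat = 0.5), "nu_lat")
})

test_that("simulations are deterministic", {
  ch1 <- run_channel_poiseuille(W = 8, len = 8, dp = 1e-4, n_iter = 500)
  ch2 <- run_channel_poiseuille(W = 8, len = 8, dp = 1e-4, n_iter = 500)
  expect_identical(ch1$result$f, ch2$result$f)
})
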