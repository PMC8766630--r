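#' The D3Q27 lattice model
#'
#' 27 discrete molecule velocities (all combinations of \{-1,0,1\}^3),
#' the standard weights 8/27, 2/27, 1/54, 1/216 by velocity magnitude,
#' and the isothermal speed of sound `c_s^2 = 1/3`. Direction `i` and
#' `28-i` are opposite (R indexing).
#'
#' @return A list with `xi` (27 x 3 integer velocity matrix), weights
#'   `w`, `cs2`, `opp` (opposite direction index) and `D = 3`.
#' @export
lattice_d3q27 <- function() {
  i <- 0:26
  xi <- cbind(i %% 3 - 1, (i %/% 3) %% 3 - 1, i %/% 9 - 1)
  list(xi = xi, w = d3q27_weights_cpp(), cs2 = 1 / 3, opp = 27:1,
       D = 3L)
}

#' Maxwell equilibrium distribution (second order, low Mach)
#'
#' `F_i = rho t_p (1 + xi.v/cs2 + (v v / 2 cs2)(xi xi / cs2 - delta))`.
#'
#' @param rho density (lattice units).
#' @param v velocity 3-vector (lattice units), `|v| << c_s`.
#' @return Numeric vector of 27 equilibrium values.
#' @export
equilibrium_f <- function(rho, v) {
  lat <- lattice_d3q27()
  ev <- as.numeric(lat$xi %*% v)
  v2 <- sum(v^2)
  rho * lat$w * (1 + ev / lat$cs2 + ev^2 / (2 * lat$cs2^2) - v2 / (2 * lat$cs2))
}

#' Total-energy equilibrium distribution
#'
#' The D3Q27 equilibrium of the total energy distribution function, with
#' total energy `E = (D/2) R T + v^2/2`.
#'
#' @param rho density; @param v velocity 3-vector; @param temp
#'   temperature (K); @param R_gas specific gas constant (lattice units).
#' @return Numeric vector of 27 values.
#' @export
equilibrium_h <- function(rho, v, temp, R_gas) {
  lat <- lattice_d3q27()
  ev <- as.numeric(lat$xi %*% v)
  xi2 <- rowSums(lat$xi^2)
  v2 <- sum(v^2)
  E <- 1.5 * R_gas * temp + 0.5 * v2
  Fi <- equilibrium_f(rho, v)
  rho * lat$w * (ev + ev^2 / lat$cs2 - v2 + 0.5 * (xi2 - 3 * lat$cs2)) +
    E * Fi
}

#' Macroscopic fields from distribution moments
#'
#' `rho = sum f_i`, `rho v = sum xi_i f_i`,
#' `rho((D R/2) T + v^2/2) = sum h_i`, and the ideal-gas pressure
#' `p = rho cs2`.
#'
#' @param f 27-vector (or n x 27 matrix) of particle distributions.
#' @param h optional matching total-energy distributions.
#' @param R_gas specific gas constant (needed with `h`).
#' @return A list with `rho`, `v`, and (given `h`) `T`, `E`, plus `p`.
#' @export
macroscopic <- function(f, h = NULL, R_gas = NULL) {
  lat <- lattice_d3q27()
  if (is.null(dim(f))) f <- matrix(f, 1)
  rho <- rowSums(f)
  if (any(rho <= 0)) stop("non-positive density")
  v <- (f %*% lat$xi) / rho
  out <- list(rho = drop(rho), v = drop(v), p = drop(rho * lat$cs2))
  if (!is.null(h)) {
    if (is.null(R_gas)) stop("R_gas required to recover temperature")
    if (is.null(dim(h))) h <- matrix(h, 1)
    E <- rowSums(h) / rho
    v2 <- rowSums((v)^2)
    out$E <- drop(E)
    out$T <- drop((E - 0.5 * v2) / (1.5 * R_gas))
  }
  out
}

#' Saint-Venant/Wantzel density update for the nostril boundary
#'
#' `rho = (1 - (gamma-1)/(2 gamma) * (3/rho_prev^2) * (rho_prev
#' v_prev)^2)^(gamma/(gamma-1))`, evaluated in lattice units with the
#' ambient density normalized to 1; the factor 3 is `1/c_s^2`.
#'
#' @param rho_prev previous-step density extrapolated from inner cells.
#' @param v_prev previous-step speed (magnitude) likewise.
#' @param gamma isentropic exponent (1.4 for air).
#' @return The updated boundary density.
#' @export
svw_density <- function(rho_prev, v_prev, gamma = 1.4) {
  mom2 <- (rho_prev * v_prev)^2
  bracket <- 1 - (gamma - 1) / (2 * gamma) * (3 / rho_prev^2) * mom2
  if (any(bracket <= 0)) stop("supersonic state at nostril boundary")
  bracket^(gamma / (gamma - 1))
}

#' Fluid and boundary properties of the respiration simulations
#'
#' Defaults match respiration at rest: kinematic viscosity of air
#' `1.63e-5 m^2/s` at the average temperature 303.15 K, body (wall)
#' temperature 309.15 K, ambient (nostril) temperature 293.15 K,
#' isentropic exponent 1.4, Prandtl number 0.72.
#'
#' @param nu kinematic viscosity, m^2/s.
#' @param Pr Prandtl number (sets the thermal collision frequency via
#'   the diffusivity `alpha = nu/Pr`).
#' @param rho0 reference density, kg/m^3.
#' @param gamma isentropic exponent.
#' @param T_B,T_N,T_avg body, ambient, and average temperature in K.
#' @param nu_lat lattice viscosity (fixes the time step via the
#'   diffusive unit bridge).
#' @return An object of class `fluid_props`.
#' @export
fluid_properties <- function(nu = 1.63e-5, Pr = 0.72, rho0 = 1.177,
                             gamma = 1.4, T_B = 309.15, T_N = 293.15,
                             T_avg = 303.15, nu_lat = 0.05) {
  stopifnot(nu > 0, Pr > 0, rho0 > 0, nu_lat > 0, nu_lat < 1 / 6)
  structure(list(nu = nu, Pr = Pr, rho0 = rho0, gamma = gamma,
                 T_B = T_B, T_N = T_N, T_avg = T_avg, nu_lat = nu_lat),
            class = "fluid_props")
}

#' Physical/lattice unit bridge
#'
#' Diffusive scaling: the time step follows from matching the lattice
#' viscosity to the physical one, `dt = nu_lat dx^2 / nu`. The lattice
#' gas constant is fixed so the ideal-gas relation holds at the ambient
#' temperature, `R_lat T_avg = c_s^2`.
#'
#' @param dx_m cell size in meters.
#' @param props a [fluid_properties()].
#' @return A list with `dt_s`, scale factors `u_scale` (m/s per lattice
#'   unit), `p_scale` (Pa per lattice unit), `R_lat`, and collision
#'   frequencies `omega`, `omega_t`.
#' @export
lattice_units <- function(dx_m, props) {
  dt <- props$nu_lat * dx_m^2 / props$nu
  u_scale <- dx_m / dt
  cs2 <- 1 / 3
  alpha_lat <- props$nu_lat / props$Pr
  list(dt_s = dt, u_scale = u_scale,
       p_scale = props$rho0 * u_scale^2,
       R_lat = cs2 / props$T_avg,
       omega = 1 / (props$nu_lat / cs2 + 0.5),
       omega_t = 1 / (alpha_lat / cs2 + 0.5))
}

# --- neighbor table construction ---------------------------------------

# 0-based neighbor table (ncell x 27) from an occupancy/cellid array;
# periodic per axis. Absent neighbors are -1.
grid_neighbor_table <- function(cellid, periodic = c(FALSE, FALSE, FALSE)) {
  d <- dim(cellid)
  cells <- which(cellid > 0, arr.ind = TRUE)
  ord <- order(cellid[cellid > 0])
  cells <- cells[ord, , drop = FALSE]
  nc <- nrow(cells)
  lat <- lattice_d3q27()
  nb <- matrix(-1L, nc, 27)
  for (i in 1:27) {
    if (i == 14) { nb[, i] <- seq_len(nc) - 1L; next }
    tgt <- cells + matrix(lat$xi[i, ], nc, 3, byrow = TRUE)
    for (a in 1:3) {
      if (periodic[a]) {
        tgt[, a] <- ((tgt[, a] - 1L) %% d[a]) + 1L
      }
    }
    ok <- tgt[, 1] >= 1 & tgt[, 1] <= d[1] & tgt[, 2] >= 1 &
      tgt[, 2] <= d[2] & tgt[, 3] >= 1 & tgt[, 3] <= d[3]
    ids <- rep(0L, nc)
    ids[ok] <- cellid[tgt[ok, , drop = FALSE]]
    nb[, i] <- ids - 1L
  }
  nb
}

# direction index (1-based) of an axis unit vector
dir_index <- function(v) {
  v <- sign(v)
  (v[1] + 1) + 3 * (v[2] + 1) + 9 * (v[3] + 1) + 1
}

#' Run the thermal lattice-Boltzmann solver on a prepared lattice
#'
#' Low-level driver around the C++ stepper: BGK collision of `f` toward
#' the Maxwell equilibrium, relaxation of `h` toward the total-energy
#' equilibrium with the `(omega_t - omega_f)` coupling term, streaming,
#' Bouzidi interpolated bounce-back at walls, and the open-boundary
#' updates. Deterministic: identical inputs give bitwise identical
#' results.
#'
#' @param nb 0-based neighbor table (ncell x 27), -1 marking wall links.
#' @param q wall distance fractions (ncell x 27), `NA` defaulting to 1/2.
#' @param otype per-cell open-boundary group id (0 = none).
#' @param onormal per-cell 0-based direction index toward the interior.
#' @param groups list of open-boundary groups (`mode` 1 = fixed
#'   pressure `dp`, 2 = Saint-Venant/Wantzel, 3 = flux controller with
#'   `re_target`, `d_h`, `gain`, `sign`; optional fixed `T`).
#' @param omega,omega_t collision frequencies (0 < omega < 2).
#' @param thermal solve the total-energy distributions as well.
#' @param R_lat lattice gas constant; @param T0 initial temperature;
#'   @param T_wall wall temperature(s), scalar or per cell.
#' @param gamma isentropic exponent for the nostril update.
#' @param f0,h0 optional initial distributions (ncell x 27).
#' @param n_iter simulation iterations; @param avg_iter additional
#'   iterations over which results are time-averaged.
#' @param monitor_every monitor sampling interval (0 = off).
#' @return The C++ result list (fields, averages, monitors,
#'   `diverged`).
#' @export
lbm_run <- function(nb, q = NULL, otype = NULL, onormal = NULL,
                    groups = list(), omega = 1.7, omega_t = omega,
                    thermal = FALSE, R_lat = 1 / 3 / 303.15, T0 = 293.15,
                    T_wall = 309.15, gamma = 1.4, f0 = NULL, h0 = NULL,
                    n_iter = 1000, avg_iter = 0, monitor_every = 0) {
  nc <- nrow(nb)
  if (is.null(q)) q <- matrix(NA_real_, nc, 27)
  if (is.null(otype)) otype <- integer(nc)
  if (is.null(onormal)) onormal <- integer(nc)
  if (length(T_wall) == 1L) T_wall <- rep(T_wall, nc)
  stopifnot(omega > 0, omega < 2, omega_t > 0, omega_t < 2)
  res <- lbm_run_cpp(nb, q, as.integer(otype), as.integer(onormal), groups,
                     f0, h0, omega, omega_t, thermal, R_lat, T0, T_wall,
                     gamma, as.integer(n_iter), as.integer(avg_iter),
                     as.integer(monitor_every))
  if (isTRUE(res$diverged))
    warning("lattice-Boltzmann run diverged (negative or non-finite density)")
  res
}

#' Boundary conditions for a respiration simulation
#'
#' @param pharynx list: either `mode = "volume_flux"` with `vdot` in
#'   ml/s (a proportional controller adapts the pharynx pressure each
#'   step until the target Reynolds number is met) plus optional `gain`,
#'   or `mode = "pressure"` with `dp` in Pa relative to ambient.
#' @param direction `"inspiration"` (flow in at the nostrils, suction at
#'   the pharynx) or `"expiration"`.
#' @param T_B wall (body) temperature, K.
#' @param T_N ambient temperature imposed at the nostrils, K.
#' @return An object of class `boundary_spec`.
#' @export
boundary_spec <- function(pharynx = list(mode = "volume_flux", vdot = 250),
                          direction = c("inspiration", "expiration"),
                          T_B = 309.15, T_N = 293.15) {
  direction <- match.arg(direction)
  stopifnot(pharynx$mode %in% c("volume_flux", "pressure"))
  structure(list(pharynx = pharynx, direction = direction,
                 T_B = T_B, T_N = T_N),
            class = "boundary_spec")
}

#' Run a respiratory flow simulation on a solver grid
#'
#' Initializes the lattice at rest at ambient density and temperature,
#' runs `n_iter` iterations and then accumulates time averages over
#' another `avg_iter` iterations. Walls are treated with the Bouzidi
#' interpolated bounce-back (isothermal at `T_B`); the pharynx is driven
#' by a prescribed volume flux (Reynolds-number controller) or a fixed
#' pressure; the nostrils follow the Saint-Venant/Wantzel density
#' relation at the ambient temperature `T_N`.
#'
#' @param grid a `solver_grid` from [mesh_to_grid()], with boundary
#'   patches `pharynx`, `nostril_left`, `nostril_right` on the capped
#'   surface openings.
#' @param props a [fluid_properties()].
#' @param bcs a [boundary_spec()].
#' @param n_iter,avg_iter iteration counts.
#' @param patch_normals named list of inward normal axis vectors per
#'   open patch (e.g. `list(pharynx = c(0,0,-1))`).
#' @param thermal include the temperature field.
#' @param monitor_every monitor interval in iterations.
#' @return An object of class `simulation_result` with per-cell final
#'   and averaged fields, boundary cell sets, monitors and the unit
#'   bridge.
#' @export
run_simulation <- function(grid, props, bcs, n_iter, avg_iter = 0,
                           patch_normals, thermal = TRUE,
                           monitor_every = 200) {
  stopifnot(inherits(grid, "solver_grid"), inherits(props, "fluid_props"),
            inherits(bcs, "boundary_spec"))
  units <- lattice_units(grid$dx * 1e-3, props)
  nb <- grid_neighbor_table(grid$cellid)
  nc <- nrow(nb)
  open_names <- intersect(c("nostril_left", "nostril_right", "pharynx"),
                          stats::na.omit(unique(grid$patch)))
  if (!all(c("pharynx") %in% open_names))
    stop("grid has no pharynx boundary cells")
  otype <- integer(nc)
  onormal <- integer(nc)
  groups <- list()
  insp <- bcs$direction == "inspiration"
  for (gi in seq_along(open_names)) {
    nm <- open_names[gi]
    sel <- which(!is.na(grid$patch) & grid$patch == nm)
    otype[sel] <- gi
    ndir <- dir_index(patch_normals[[nm]])
    onormal[sel] <- ndir - 1L
    if (nm == "pharynx") {
      H_P <- length(sel)
      A_P <- H_P * (grid$dx * 1e-3)^2
      d_P <- sqrt(4 * A_P / pi)
      if (bcs$pharynx$mode == "volume_flux") {
        vdot_m3s <- bcs$pharynx$vdot * 1e-6
        re_target <- (vdot_m3s / A_P) * d_P / props$nu
        groups[[gi]] <- list(mode = 3L, re_target = re_target,
                             d_h = d_P / (grid$dx * 1e-3),
                             gain = bcs$pharynx$gain %||% 1e-6,
                             sign = if (insp) -1 else 1)
      } else {
        groups[[gi]] <- list(mode = 1L,
                             dp = bcs$pharynx$dp / units$p_scale)
      }
    } else {
      groups[[gi]] <- list(mode = 2L, T = bcs$T_N)
    }
  }
  res <- lbm_run(nb, grid$q, otype, onormal, groups,
                 omega = units$omega, omega_t = units$omega_t,
                 thermal = thermal, R_lat = units$R_lat, T0 = bcs$T_N,
                 T_wall = bcs$T_B, gamma = props$gamma,
                 n_iter = n_iter, avg_iter = avg_iter,
                 monitor_every = monitor_every)
  boundary_cells <- stats::setNames(
    lapply(seq_along(open_names), function(gi) which(otype == gi)),
    open_names)
  structure(list(lbm = res, grid = grid, units = units, props = props,
                 bcs = bcs, boundary_cells = boundary_cells,
                 open_names = open_names, patch_normals = patch_normals,
                 n_iter = n_iter, avg_iter = avg_iter),
            class = "simulation_result")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.simulation_result <- function(x, ...) {
  cat(sprintf("<simulation_result> %d cells, %d+%d iterations%s\n",
              nrow(x$lbm$f), x$n_iter, x$avg_iter,
              if (isTRUE(x$lbm$diverged)) " [DIVERGED]" else ""))
  invisible(x)
}

# --- benchmark lattices -------------------------------------------------

#' Plane Poiseuille channel benchmark
#'
#' A pressure-driven channel: width `W` cells between two no-slip walls
#' (wall offset `q_wall` in units of the cell size), length `len` cells
#' with fixed-pressure open boundaries (`dp` at the inlet, 0 at the
#' outlet), one periodic cell in the third direction. Returns the steady
#' velocity profile at mid-length and the analytic parabolic solution.
#'
#' @param W channel width in cells.
#' @param len channel length in cells.
#' @param dp inlet/outlet lattice pressure difference.
#' @param omega collision frequency.
#' @param n_iter iterations.
#' @param q_wall wall distance fraction on the wall links.
#' @return A list with the simulated and analytic profiles and their
#'   relative L2 error.
#' @export
run_channel_poiseuille <- function(W = 32, len = 24, dp = 1e-4,
                                   omega = 1.6, n_iter = 20000,
                                   q_wall = 0.5) {
  cellid <- array(0L, c(len, W, 1))
  cellid[] <- seq_len(len * W)
  nb <- grid_neighbor_table(cellid, periodic = c(FALSE, FALSE, TRUE))
  nc <- nrow(nb)
  q <- matrix(NA_real_, nc, 27)
  lat <- lattice_d3q27()
  # wall links (missing neighbors in y) get offset q_wall
  wall_links <- which(nb < 0, arr.ind = TRUE)
  q[wall_links] <- q_wall
  ij <- which(cellid > 0, arr.ind = TRUE)
  ij <- ij[order(cellid[cellid > 0]), , drop = FALSE]
  otype <- integer(nc); onormal <- integer(nc)
  otype[ij[, 1] == 1] <- 1L
  otype[ij[, 1] == len] <- 2L
  onormal[otype == 1L] <- dir_index(c(1, 0, 0)) - 1L
  onormal[otype == 2L] <- dir_index(c(-1, 0, 0)) - 1L
  groups <- list(list(mode = 1L, dp = dp), list(mode = 1L, dp = 0))
  res <- lbm_run(nb, q, otype, onormal, groups, omega = omega,
                 thermal = FALSE, n_iter = n_iter, monitor_every = 0)
  mid <- which(ij[, 1] == ceiling(len / 2))
  prof <- res$v[mid, 1][order(ij[mid, 2])]
  nu <- (1 / omega - 0.5) / 3
  G <- dp / (len - 1)           # pressure gradient between the BC cells
  Wphys <- (W - 1) + 2 * q_wall # wall-to-wall distance
  y <- seq_len(W) - 1 + q_wall  # distance of cell centers from the wall
  ana <- G / (2 * nu) * y * (Wphys - y)
  list(profile = prof, analytic = ana, y = y,
       l2_error = sqrt(sum((prof - ana)^2) / sum(ana^2)),
       result = res)
}

#' Steady conduction between two isothermal plates
#'
#' A quiescent slab of `W` cells between plates at `T_hot` and `T_cold`
#' (periodic in the other directions); the steady temperature profile of
#' the thermal lattice-Boltzmann solver is compared against the linear
#' conduction solution.
#'
#' @param W slab thickness in cells; @param T_hot,T_cold plate
#'   temperatures in K; @param omega,omega_t collision frequencies;
#'   @param n_iter iterations.
#' @return A list with the simulated and analytic profiles and the
#'   maximum relative deviation.
#' @export
run_conduction_slab <- function(W = 24, T_hot = 309.15, T_cold = 293.15,
                                omega = 1.2, omega_t = 1.2,
                                n_iter = 20000) {
  cellid <- array(0L, c(1, W, 1))
  cellid[] <- seq_len(W)
  nb <- grid_neighbor_table(cellid, periodic = c(TRUE, FALSE, TRUE))
  nc <- nrow(nb)
  Tw <- rep(NA_real_, nc)
  Tw[1] <- T_cold; Tw[W] <- T_hot
  Tw[is.na(Tw)] <- (T_hot + T_cold) / 2  # unused (interior cells)
  R_lat <- (1 / 3) / ((T_hot + T_cold) / 2)
  res <- lbm_run(nb, otype = NULL, groups = list(), omega = omega,
                 omega_t = omega_t, thermal = TRUE, R_lat = R_lat,
                 T0 = (T_hot + T_cold) / 2, T_wall = Tw,
                 n_iter = n_iter, monitor_every = 0)
  y <- seq_len(W) - 0.5
  ana <- T_cold + (T_hot - T_cold) * y / W
  list(profile = res$T, analytic = ana, y = y,
       max_rel_dev = max(abs(res$T - ana) / (T_hot - T_cold)),
       result = res)
}
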