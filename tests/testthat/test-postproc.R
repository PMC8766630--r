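duct_grid <- function(nx = 6, ny = 6, nz = 20, dx = 1, origin = c(0, 0, 0)) {
  cellid <- array(0L, c(nx, ny, nz))
  cellid[] <- seq_len(nx * ny * nz)
  structure(list(dim = c(nx, ny, nz), cellid = cellid, dx = dx,
                 origin = origin),
            class = "solver_grid")
}

test_that("moving average matches an explicit windowed mean with
          truncated, renormalized edges", {
  s <- c(5, 5, 5, 5, 5)
  expect_equal(moving_average(s, 2), s)
  ramp <- 1:20
  ma <- moving_average(ramp, 4)
  expect_equal(ma[3:18], as.numeric(ramp[3:18]))  # symmetric window
  set.seed(8)
  r <- rnorm(30)
  ma4 <- moving_average(r, 4)
  for (t in c(1, 2, 15, 30)) {
    lo <- max(1, t - 2); hi <- min(30, t + 2)
    expect_equal(ma4[t], mean(r[lo:hi]))
  }
  expect_error(moving_average(r, 3), "even")
  expect_error(moving_average(r[1:3], 4), "shorter")
})

test_that("cross sections equal the slab/connected-component oracle on a
          duct and exclude disconnected passages", {
  g <- duct_grid()
  cs <- cross_section_cells(g, point = c(3, 3, 10.2), normal = c(0, 0, 1))
  oracle <- slab_component_oracle(g$cellid, g$dx, g$origin,
                                  c(3, 3, 10.2), c(0, 0, 1))
  expect_equal(sort(cs$cells), oracle)
  # axis-aligned slab of sqrt(3) dx covers 1-2 layers of 36 cells
  expect_true(cs$H_cs %in% c(36, 72))
  # two parallel disjoint ducts: the second passage contributes nothing
  g2 <- duct_grid(nx = 14)
  g2$cellid[7:8, , ] <- 0L
  g2$cellid[g2$cellid > 0] <- seq_len(sum(g2$cellid > 0))
  csA <- cross_section_cells(g2, point = c(3, 3, 10), normal = c(0, 0, 1))
  idsA <- which(g2$cellid > 0, arr.ind = TRUE)
  idsA <- idsA[order(g2$cellid[g2$cellid > 0]), ]
  expect_true(all(idsA[csA$cells, 1] <= 6))
  expect_equal(sort(csA$cells),
               slab_component_oracle(g2$cellid, 1, c(0, 0, 0),
                                     c(3, 3, 10), c(0, 0, 1)))
  expect_error(cross_section_cells(g2, point = c(7.5, 3, 10),
                                   normal = c(0, 0, 1)), "outside the mesh")
})

test_that("cross sections on oblique stations of a Y junction match the
          oracle for random stations", {
  # Y phantom: two branches joining into one trunk
  g <- duct_grid(nx = 20, ny = 6, nz = 24)
  mask <- array(FALSE, c(20, 6, 24))
  for (z in 1:10) {  # trunk
    mask[9:12, , z] <- TRUE
  }
  for (z in 11:24) { # two branches drifting apart
    off <- round((z - 10) * 0.5)
    mask[pmax(1, 5 - off):(8 - off), , z] <- TRUE
    mask[(13 + off):pmin(20, 16 + off), , z] <- TRUE
  }
  g$cellid <- array(0L, dim(mask))
  g$cellid[mask] <- seq_len(sum(mask))
  set.seed(31)
  n_checked <- 0
  for (k in 1:12) {
    ids <- which(g$cellid > 0, arr.ind = TRUE)
    pick <- ids[sample(nrow(ids), 1), ]
    pt <- (pick - 0.5) * g$dx + g$origin
    nrm <- rnorm(3); nrm <- nrm / sqrt(sum(nrm^2))
    cs <- tryCatch(cross_section_cells(g, pt, nrm), error = function(e) NULL)
    if (is.null(cs)) next
    expect_equal(sort(cs$cells),
                 slab_component_oracle(g$cellid, g$dx, g$origin, pt, nrm))
    n_checked <- n_checked + 1
  }
  expect_gt(n_checked, 5)
})

test_that("section averages are arithmetic means", {
  g <- duct_grid()
  cs <- cross_section_cells(g, point = c(3, 3, 10.2), normal = c(0, 0, 1))
  field <- rep(7.5, max(g$cellid))
  expect_equal(section_average(cs, field), 7.5)
  field2 <- seq_len(max(g$cellid))
  expect_equal(section_average(cs, field2), mean(field2[cs$cells]))
})

test_that("centerlines validate, interpolate, and round-trip as CSV", {
  pts <- cbind(0, 0, seq(0, 30, by = 2))
  cl <- centerline(pts, side = "left")
  expect_equal(max(cl$arclength), 30)
  expect_true(all(abs(rowSums(cl$tangents^2) - 1) < 1e-12))
  expect_error(centerline(rbind(c(0, 0, 0), c(0, 0, 0))), "distinct")
  at <- rhinoflow:::centerline_at(cl, 15.5)
  expect_equal(at$point, c(0, 0, 15.5))
  f <- tempfile(fileext = ".csv")
  write_centerline_csv(cl, f)
  cl2 <- read_centerline_csv(f, side = "left")
  expect_equal(cl2$points, cl$points)
})

test_that("flow summary obeys total-pressure additivity and matches an
          explicit summation oracle on synthetic fields", {
  # hand-built simulation_result with 10-cell boundary sets
  set.seed(13)
  nc <- 30
  rho <- runif(nc, 0.95, 1.05)
  v <- matrix(runif(nc * 3, -0.05, 0.05), nc, 3)
  temp <- runif(nc, 295, 309)
  fake <- structure(list(
    lbm = list(rho = rho, v = v, T = temp, n_avg = 0),
    grid = list(dx = 1),
    units = list(p_scale = 2.5, u_scale = 3),
    props = fluid_properties(),
    bcs = boundary_spec(),
    patch_normals = list(pharynx = c(0, 0, -1), nostril_left = c(0, 0, 1)),
    boundary_cells = list(pharynx = 1:10, nostril_left = 11:20)),
    class = "simulation_result")
  fs <- boundary_summary(fake)
  dyn <- function(i) mean(0.5 * rho[i] * rowSums(v[i, ]^2))
  expect_equal(fs$dp_dyn_left, (dyn(1:10) - dyn(11:20)) * 2.5)
  expect_equal(fs$dp_stat_left,
               (mean(rho[1:10] / 3) - mean(rho[11:20] / 3)) * 2.5)
  expect_identical(fs$dp_tot_left, fs$dp_dyn_left + fs$dp_stat_left)
  expect_equal(fs$dT, mean(temp[1:10]) - 309.15)
  expect_equal(fs$mdot_pharynx,
               sum(-v[1:10, 3]) * 3 * 1.177 * (1e-3)^2 * 1000)
  expect_equal(fs$H_P, 10)
  # uniform fields: all pressure differences vanish
  fake2 <- fake
  fake2$lbm$rho <- rep(1, nc)
  fake2$lbm$v <- matrix(0.03, nc, 3)
  fs2 <- boundary_summary(fake2)
  expect_equal(fs2$dp_dyn_left, 0)
  expect_equal(fs2$dp_stat_left, 0)
})

test_that("naive centerlines recover phantom axes and mask medial paths", {
  d <- make_duct(width = 10, height = 10, length = 50)
  cls <- naive_centerline(d)
  expect_equal(cls[[1]]$points[, 1], rep(0, nrow(cls[[1]]$points)))
  expect_equal(max(cls[[1]]$arclength), 50)
  # L-bend voxel mask: ridge path stays near the medial axis
  mask <- array(FALSE, c(24, 10, 24))
  mask[4:7, 4:7, 1:20] <- TRUE   # vertical arm, axis x ~ 5.5
  mask[4:20, 4:7, 17:20] <- TRUE # horizontal arm, axis z ~ 18.5
  cl <- naive_centerline(mask, from = c(5, 5, 2), to = c(19, 5, 18))
  expect_gt(nrow(cl$points), 10)
  # all path points at least 1 voxel from the wall, near arm axes
  on_vert <- cl$points[, 3] < 14
  expect_true(all(abs(cl$points[on_vert, 1] - 4.5) <= 1.5))
  on_horz <- cl$points[, 1] > 10
  expect_true(all(abs(cl$points[on_horz, 3] - 17.5) <= 1.5))
  expect_error(naive_centerline(mask, from = c(1, 1, 1), to = c(19, 5, 18)),
               "not inside")
})

test_that("centerline profiles are linear for linear fields and respect
          station counts", {
  g <- duct_grid(nx = 6, ny = 6, nz = 20)
  nc <- max(g$cellid)
  ids <- which(g$cellid > 0, arr.ind = TRUE)
  ids <- ids[order(g$cellid[g$cellid > 0]), ]
  # linear static pressure in z, at rest: p_tot ~ a + b z
  rho <- 1 + 0.01 * (20 - ids[, 3])
  fake <- structure(list(
    lbm = list(rho = rho, v = matrix(0, nc, 3), T = rep(300, nc), n_avg = 0),
    grid = g, units = list(p_scale = 1, u_scale = 1),
    props = fluid_properties(), bcs = boundary_spec(),
    patch_normals = list(), boundary_cells = list()),
    class = "simulation_result")
  cl <- centerline(cbind(3, 3, seq(1, 19, length.out = 10)))
  prof <- centerline_profiles(fake, cl, n_stations = 10)
  expect_lte(nrow(prof), 10)
  expect_gt(abs(cor(prof$p_tot_pa, prof$arc_pct)), 0.9999)
  expect_true(all(prof$temperature_k == 300))
  expect_true(all(prof$arc_pct >= 0 & prof$arc_pct <= 100))
})
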