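# Synthetic phantoms: every input the pipeline needs (flow geometries,
# labeled CT-like volumes, respiration waveforms) with known ground truth.

box_corners <- function(lo, hi) {
  rbind(c(lo[1], lo[2], lo[3]), c(hi[1], lo[2], lo[3]),
        c(lo[1], hi[2], lo[3]), c(hi[1], hi[2], lo[3]),
        c(lo[1], lo[2], hi[3]), c(hi[1], lo[2], hi[3]),
        c(lo[1], hi[2], hi[3]), c(hi[1], hi[2], hi[3]))
}

# outward-oriented triangulated box; face patches named by side
box_mesh <- function(lo, hi, patch_names = c(zlo = "wall", zhi = "wall",
                                             ylo = "wall", yhi = "wall",
                                             xlo = "wall", xhi = "wall")) {
  v <- box_corners(lo, hi)
  f <- rbind(c(1, 3, 4), c(1, 4, 2),   # z = lo
             c(5, 6, 8), c(5, 8, 7),   # z = hi
             c(1, 2, 6), c(1, 6, 5),   # y = lo
             c(3, 7, 8), c(3, 8, 4),   # y = hi
             c(1, 5, 7), c(1, 7, 3),   # x = lo
             c(2, 4, 8), c(2, 8, 6))   # x = hi
  patch <- rep(patch_names[c("zlo", "zhi", "ylo", "yhi", "xlo", "xhi")],
               each = 2)
  triangle_mesh(v, f, patch = patch)
}

#' Rectangular duct phantom with analytic Poiseuille reference
#'
#' A watertight box duct oriented along z, walls on the four sides and
#' labeled caps on the two open ends. The attached analytic record
#' provides the laminar (Poiseuille) velocity profile and the pressure
#' gradient that produces a prescribed volume flux (series solution of
#' the rectangular-duct flow).
#'
#' @param width,height cross-section dimensions (x, y), mm.
#' @param length duct length (z), mm.
#' @param inlet_patch,outlet_patch patch names of the z = 0 and z =
#'   `length` caps.
#' @return A [triangle_mesh()] with attributes `watertight`, `analytic`
#'   (see Details), `centerlines` and `patch_normals`.
#' @export
make_duct <- function(width = 10, height = 10, length = 100,
                      inlet_patch = "nostril_left",
                      outlet_patch = "pharynx") {
  if (width <= 0 || height <= 0 || length <= 0)
    stop("degenerate duct dimensions")
  mesh <- box_mesh(lo = c(-width / 2, -height / 2, 0),
                   hi = c(width / 2, height / 2, length),
                   patch_names = c(zlo = inlet_patch, zhi = outlet_patch,
                                   ylo = "wall", yhi = "wall",
                                   xlo = "wall", xhi = "wall"))
  attr(mesh, "watertight") <- is_watertight(mesh)
  attr(mesh, "analytic") <- duct_analytic(width, height)
  cl <- centerline(cbind(0, 0, seq(0, length, length.out = 32)),
                   side = "total")
  attr(mesh, "centerlines") <- list(cl)
  attr(mesh, "patch_normals") <-
    stats::setNames(list(c(0, 0, 1), c(0, 0, -1)),
                    c(inlet_patch, outlet_patch))
  attr(mesh, "spec") <- list(kind = "duct", width = width, height = height,
                             length = length)
  mesh
}

# series solution of laminar flow in a rectangular duct
# (half-widths a = width/2 along x, b = height/2 along y)
duct_analytic <- function(width, height, n_terms = 51) {
  a <- width / 2; b <- height / 2
  ns <- seq(1, n_terms, by = 2)
  profile <- function(x, y, G, mu) {
    # u(x,y) for dp/dz = -G (flow in +z)
    u <- (G / (2 * mu)) * (a^2 - x^2)
    for (n in ns) {
      lam <- n * pi / (2 * a)
      u <- u - (G / mu) * (4 * (2 * a)^2 / (pi^3 * n^3)) *
        (-1)^((n - 1) / 2) * cosh(lam * y) / cosh(lam * b) * cos(lam * x)
    }
    u
  }
  flux_of_G <- function(G, mu) {
    s <- sum(tanh(ns * pi * b / (2 * a)) / ns^5)
    (4 * b * a^3 * G / (3 * mu)) * (1 - (192 * a / (pi^5 * b)) * s)
  }
  G_for_flux <- function(flux, mu) flux / flux_of_G(1, mu)
  list(profile = profile, flux_of_G = flux_of_G, G_for_flux = G_for_flux,
       a = a, b = b)
}

#' Sphere phantom
#'
#' Implicit sphere extracted at high resolution; guaranteed watertight.
#'
#' @param radius mm; @param center mm; @param resolution samples across
#'   the diameter.
#' @return A [triangle_mesh()] with attribute `watertight`.
#' @export
make_sphere <- function(radius = 10, center = c(0, 0, 0), resolution = 40) {
  n <- resolution + 4
  h <- 2.4 * radius / (n - 1)
  org <- center - 1.2 * radius
  gx <- org[1] + (0:(n - 1)) * h
  gy <- org[2] + (0:(n - 1)) * h
  gz <- org[3] + (0:(n - 1)) * h
  fld <- array(0, c(n, n, n))
  for (k in seq_len(n)) {
    r2 <- outer((gx - center[1])^2, (gy - center[2])^2, "+") +
      (gz[k] - center[3])^2
    fld[, , k] <- radius - sqrt(r2)
  }
  res <- marching_tets(as.numeric(fld), dim(fld), 0, org, rep(h, 3))
  mesh <- triangle_mesh(res$vertices, res$faces)
  attr(mesh, "watertight") <- is_watertight(mesh)
  attr(mesh, "spec") <- list(kind = "sphere", radius = radius,
                             center = center, resolution = resolution)
  mesh
}

# smoothstep in [0,1]
sstep <- function(t) {
  t <- pmin(pmax(t, 0), 1)
  t * t * (3 - 2 * t)
}

#' Two-passage airway phantom
#'
#' Two curved passages ("left" and "right") start at separate nostril
#' openings, run parallel, then merge into a single outlet tube (the
#' "pharynx"). Optional spherical side pockets ("sinuses") connect to
#' each passage through narrow ostia. An asymmetry factor `a < 1`
#' scales the narrowed (left) passage's cross-section area to `a` times
#' the other side's, emulating unilateral obstruction. The surface is
#' extracted from an implicit function, hence watertight; analytic
#' centerlines for both sides are attached.
#'
#' @param passage_radius radius of each passage, mm.
#' @param separation center-to-center distance of the passages, mm.
#' @param merge_start,merge_length z where the passages begin to merge
#'   and the length of the transition, mm.
#' @param outlet_length length of the common outlet tube, mm.
#' @param outlet_radius radius of the common tube, mm.
#' @param asymmetry area factor of the left passage (1 = symmetric).
#' @param sinus_radius radius of the side pockets (0 = none), mm.
#' @param resolution grid samples per mm for the implicit extraction.
#' @return A [triangle_mesh()] with attributes `watertight`,
#'   `centerlines` (left/right), `patch_normals` and `spec`.
#' @export
make_two_passage_airway <- function(passage_radius = 3, separation = 10,
                                    merge_start = 18, merge_length = 10,
                                    outlet_length = 10, outlet_radius = 4.2,
                                    asymmetry = 1, sinus_radius = 0,
                                    resolution = 1.2) {
  r_left <- passage_radius * sqrt(asymmetry)
  r_right <- passage_radius
  z_end <- merge_start + merge_length + outlet_length
  xc <- function(z, side) {
    s <- sstep((z - merge_start) / merge_length)
    side * (separation / 2) * (1 - s)
  }
  rad <- function(z, r_side) {
    s <- sstep((z - merge_start) / merge_length)
    (1 - s) * r_side + s * outlet_radius
  }
  margin <- 2
  lo <- c(-(separation / 2 + passage_radius + margin),
          -(max(passage_radius, outlet_radius, sinus_radius * 2) + margin),
          -margin)
  hi <- c(separation / 2 + passage_radius + margin,
          max(passage_radius, outlet_radius, sinus_radius * 2) + margin +
            if (sinus_radius > 0) 2 * sinus_radius else 0,
          z_end + margin)
  h <- 1 / resolution
  nx <- ceiling((hi[1] - lo[1]) / h) + 1
  ny <- ceiling((hi[2] - lo[2]) / h) + 1
  nz <- ceiling((hi[3] - lo[3]) / h) + 1
  gx <- lo[1] + (0:(nx - 1)) * h
  gy <- lo[2] + (0:(ny - 1)) * h
  gz <- lo[3] + (0:(nz - 1)) * h
  fld <- array(Inf, c(nx, ny, nz))
  sin_z <- merge_start * 0.5
  for (k in seq_len(nz)) {
    z <- gz[k]
    fl <- sqrt(outer((gx - xc(z, -1))^2, gy^2, "+")) - rad(z, r_left)
    fr <- sqrt(outer((gx - xc(z, +1))^2, gy^2, "+")) - rad(z, r_right)
    f <- pmin(fl, fr)
    if (sinus_radius > 0) {
      # one spherical pocket per side, connected by a narrow ostium
      for (side in c(-1, 1)) {
        cx <- side * separation / 2
        cy <- r_right + sinus_radius * 1.1
        pocket <- sqrt(outer((gx - cx)^2, (gy - cy)^2, "+") +
                         (z - sin_z)^2) - sinus_radius
        # ostium: thin cylinder along y from passage to pocket
        ost <- sqrt(outer((gx - cx)^2, rep(0, ny), "+") + (z - sin_z)^2) -
          sinus_radius * 0.35
        ost[, gy < 0 | gy > cy] <- Inf
        f <- pmin(f, pocket, ost)
      }
    }
    # clip to the slab 0 <= z <= z_end (caps close the surface)
    f <- pmax(f, z - z_end, -z)
    fld[, , k] <- f
  }
  res <- marching_tets(as.numeric(-fld), c(nx, ny, nz), 0, lo, rep(h, 3))
  mesh <- triangle_mesh(res$vertices, res$faces)
  # patch labels from face centroid position
  cen <- (mesh$vertices[mesh$faces[, 1], , drop = FALSE] +
            mesh$vertices[mesh$faces[, 2], , drop = FALSE] +
            mesh$vertices[mesh$faces[, 3], , drop = FALSE]) / 3
  patch <- rep("wall", nrow(mesh$faces))
  patch[cen[, 3] < 0.51 * h] <-
    ifelse(cen[cen[, 3] < 0.51 * h, 1] < 0, "nostril_left", "nostril_right")
  patch[cen[, 3] > z_end - 0.51 * h] <- "pharynx"
  mesh$patch <- factor(patch)
  attr(mesh, "watertight") <- is_watertight(mesh)
  zs <- seq(0.5, z_end - 0.5, length.out = 48)
  attr(mesh, "centerlines") <- list(
    centerline(cbind(vapply(zs, xc, numeric(1), side = -1), 0, zs),
               side = "left"),
    centerline(cbind(vapply(zs, xc, numeric(1), side = +1), 0, zs),
               side = "right"))
  attr(mesh, "patch_normals") <- list(nostril_left = c(0, 0, 1),
                                      nostril_right = c(0, 0, 1),
                                      pharynx = c(0, 0, -1))
  attr(mesh, "spec") <- list(kind = "two_passage_airway",
                             passage_radius = passage_radius,
                             separation = separation,
                             asymmetry = asymmetry,
                             outlet_radius = outlet_radius,
                             z_end = z_end, sinus_radius = sinus_radius)
  mesh
}

#' Labeled head phantom: CT-like intensity volume plus ground truth
#'
#' An ellipsoidal "head" of soft tissue wrapped in a bone shell inside
#' outside air, containing seven air spaces laid out anatomically: a
#' central nasal/oral cavity column and the left/right frontal,
#' combined maxillary and left/right sphenoid sinus pockets. Intensities
#' are drawn per class from nominal Hounsfield values (air -1000, tissue
#' +40, bone +700) with Gaussian noise, then rescaled to \[0,1\]. The
#' sinus classes together stay well below 5% of the pixels, reproducing
#' the severe class imbalance of clinical data.
#'
#' @param dims volume dimensions (x, y, z).
#' @param noise_sd intensity noise standard deviation in HU.
#' @param spacing voxel spacing, mm.
#' @param seed RNG seed (recorded in the output metadata).
#' @return A list with `intensity` (array in \[0,1\]), `labels`
#'   (a [label_volume()]), `hu` (noise-free HU values per class) and
#'   `seed`.
#' @export
make_labeled_head <- function(dims = c(64, 64, 16), noise_sd = 30,
                              spacing = c(1, 1, 1), seed = 1L) {
  set.seed(seed)
  tab <- head_class_table()
  nx <- dims[1]; ny <- dims[2]; nz <- dims[3]
  lab <- array(tab[["air_outside"]], dims)
  cx <- (nx + 1) / 2; cy <- (ny + 1) / 2; cz <- (nz + 1) / 2
  X <- slice.index(lab, 1); Y <- slice.index(lab, 2); Z <- slice.index(lab, 3)
  ell <- function(x0, y0, z0, rx, ry, rz)
    ((X - x0) / rx)^2 + ((Y - y0) / ry)^2 + ((Z - z0) / rz)^2 <= 1
  rx <- 0.44 * nx; ry <- 0.46 * ny; rz <- max(cz - 1, nz)
  head_out <- ell(cx, cy, cz, rx, ry, rz * 2)
  head_in <- ell(cx, cy, cz, rx - 0.05 * nx, ry - 0.05 * ny, rz * 2)
  lab[head_out] <- tab[["bone"]]
  lab[head_in] <- tab[["tissue"]]
  # air spaces (fractions of the head size)
  lab[ell(cx, cy * 0.95, cz, 0.07 * nx, 0.26 * ny, rz)] <-
    tab[["nasal_oral_cavity"]]
  # sinuses occupy different axial ranges (frontal superior, maxillary
  # mid, sphenoid posterior-inferior), as in real anatomy; this is what
  # makes per-slice class combinations differ and the balancer effective
  sx <- 0.17 * nx
  lab[ell(cx - sx, cy * 0.55, cz * 1.62, 0.07 * nx, 0.07 * ny, 0.2 * nz)] <-
    tab[["frontal_sinus_left"]]
  lab[ell(cx + sx, cy * 0.55, cz * 1.62, 0.07 * nx, 0.07 * ny, 0.2 * nz)] <-
    tab[["frontal_sinus_right"]]
  lab[ell(cx - 0.23 * nx, cy * 1.05, cz, 0.075 * nx, 0.095 * ny, 0.17 * nz)] <-
    tab[["maxillary_sinuses"]]
  lab[ell(cx + 0.23 * nx, cy * 1.05, cz, 0.075 * nx, 0.095 * ny, 0.17 * nz)] <-
    tab[["maxillary_sinuses"]]
  lab[ell(cx - 0.08 * nx, cy * 1.42, cz * 0.42, 0.06 * nx, 0.075 * ny,
          0.17 * nz)] <- tab[["sphenoid_sinus_left"]]
  lab[ell(cx + 0.08 * nx, cy * 1.42, cz * 0.42, 0.06 * nx, 0.075 * ny,
          0.17 * nz)] <- tab[["sphenoid_sinus_right"]]
  hu <- c(frontal_sinus_left = -1000, frontal_sinus_right = -1000,
          maxillary_sinuses = -1000, sphenoid_sinus_left = -1000,
          sphenoid_sinus_right = -1000, nasal_oral_cavity = -1000,
          air_outside = -1000, bone = 700, tissue = 40)
  intens <- array(hu[match(lab, tab)], dims)
  if (noise_sd > 0) intens <- intens + stats::rnorm(length(intens), 0, noise_sd)
  intens <- pmin(pmax((intens + 1000) / 2000, 0), 1)
  list(intensity = intens,
       labels = label_volume(lab, spacing = spacing, class_names = tab),
       hu = hu, seed = seed)
}

#' Synthetic 4-phase rhinomanometry waveform with known resistance
#'
#' A sinusoidal respiration cycle with prescribed effective resistance:
#' under the `rms` convention `delta_p = r_true * vdot` (so the
#' RMS-ratio resistance recovers `r_true` exactly); under the
#' `printed` convention `delta_p = r_true^2 * vdot`, matching the
#' integral-form definition `sqrt(mean(delta_p/vdot))`. Optional
#' Gaussian pressure noise (fraction of the peak pressure).
#'
#' @param r_true target effective resistance, Pa*s/cm^3.
#' @param cycle_s duration of the respiration cycle, s.
#' @param peak_flux peak volume flux, cm^3/s.
#' @param n samples over the cycle.
#' @param noise noise standard deviation as a fraction of the peak
#'   pressure.
#' @param seed RNG seed.
#' @param convention `"rms"` or `"printed"` (see above).
#' @param side nasal side label.
#' @return A list with the full-cycle recording (`cycle`), the
#'   single-phase recordings `inspiration` and `expiration`, `r_true`,
#'   `convention` and `seed`.
#' @export
make_4pr_waveform <- function(r_true, cycle_s = 4, peak_flux = 400,
                              n = 256, noise = 0, seed = 1L,
                              convention = c("rms", "printed"),
                              side = "left") {
  stopifnot(r_true > 0)
  convention <- match.arg(convention)
  set.seed(seed)
  t <- seq(0, cycle_s, length.out = n)
  vdot <- peak_flux * sin(2 * pi * t / cycle_s)
  dp <- if (convention == "rms") r_true * vdot else r_true^2 * vdot
  if (noise > 0) dp <- dp + stats::rnorm(n, 0, noise * max(abs(dp)))
  cyc <- four_phase_recording(t, dp, vdot, side = side)
  insp <- vdot >= 0 & t <= cycle_s / 2
  expn <- vdot <= 0 & t >= cycle_s / 2
  list(cycle = cyc,
       inspiration = four_phase_recording(t[insp], dp[insp], vdot[insp],
                                          side = side),
       expiration = four_phase_recording(t[expn], dp[expn], vdot[expn],
                                         side = side),
       r_true = r_true, convention = convention, seed = seed)
}
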