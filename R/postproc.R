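#' Boundary-integrated flow summary
#'
#' Reduces a simulation to the diagnostic quantities reported per nasal
#' side: unweighted boundary-cell means of the dynamic pressure
#' `(1/H_P) sum 1/2 rho v^2` and static pressure `(1/H) sum rho cs^2`
#' at the pharynx minus the corresponding nostril mean, their sum (total
#' pressure loss, additive by construction), the mean pharynx
#' temperature relative to the body temperature, and the mass flux
#' `sum (rho_0 v_n)` per open surface (positive into the domain).
#' Time-averaged fields are used when the run accumulated averages.
#'
#' @param result a `simulation_result` from [run_simulation()].
#' @return An object of class `flow_summary`: pressures in Pa,
#'   temperatures in K, mass fluxes in g/s, plus boundary cell counts.
#' @export
boundary_summary <- function(result) {
  stopifnot(inherits(result, "simulation_result"))
  lat <- lattice_d3q27()
  use_avg <- result$lbm$n_avg > 0
  rho <- if (use_avg) result$lbm$avg_rho else result$lbm$rho
  v <- if (use_avg) result$lbm$avg_v else result$lbm$v
  temp <- if (use_avg) result$lbm$avg_T else result$lbm$T
  ps <- result$units$p_scale
  bc <- result$boundary_cells
  if (!length(bc$pharynx)) stop("empty pharynx boundary set")
  dyn <- function(cells) mean(0.5 * rho[cells] * rowSums(v[cells, , drop = FALSE]^2))
  stat <- function(cells) mean(rho[cells] * lat$cs2)
  dx_m <- result$grid$dx * 1e-3
  mdot <- function(cells, nm) {
    ndir <- result$patch_normals[[nm]]
    ndir <- ndir / sqrt(sum(ndir^2))
    vn <- v[cells, , drop = FALSE] %*% ndir
    sum(vn) * result$units$u_scale * result$props$rho0 * dx_m^2 * 1000
  }
  sides <- intersect(c("nostril_left", "nostril_right"), names(bc))
  out <- list(H_P = length(bc$pharynx))
  for (s in sides) {
    side <- sub("nostril_", "", s)
    dpd <- (dyn(bc$pharynx) - dyn(bc[[s]])) * ps
    dps <- (stat(bc$pharynx) - stat(bc[[s]])) * ps
    out[[paste0("dp_dyn_", side)]] <- dpd
    out[[paste0("dp_stat_", side)]] <- dps
    out[[paste0("dp_tot_", side)]] <- dpd + dps
    out[[paste0("H_N_", side)]] <- length(bc[[s]])
    out[[paste0("mdot_nostril_", side)]] <- mdot(bc[[s]], s)
  }
  if (length(temp) && any(temp != 0))
    out$dT <- mean(temp[bc$pharynx]) - result$bcs$T_B
  out$mdot_pharynx <- mdot(bc$pharynx, "pharynx")
  structure(out, class = "flow_summary")
}

#' @export
print.flow_summary <- function(x, ...) {
  cat("<flow_summary>\n")
  for (nm in names(x)) cat(sprintf("  %-18s %.6g\n", nm, x[[nm]]))
  invisible(x)
}

#' Moving temporal average
#'
#' Centered window mean `a_bar_t = 1/(dt+1) sum_{k=-dt/2}^{dt/2}
#' a_{t+k}`; at the series edges the window is truncated to the
#' available samples and the count renormalized.
#'
#' @param series numeric vector.
#' @param dt averaging interval; must be even so the window is
#'   symmetric (`dt + 1` samples).
#' @return Numeric vector of the same length.
#' @export
moving_average <- function(series, dt) {
  if (dt %% 2 != 0)
    stop(sprintf("dt must be even for a symmetric window; try %d or %d",
                 dt - 1, dt + 1))
  if (length(series) <= dt) stop("series shorter than the window")
  half <- dt / 2
  n <- length(series)
  vapply(seq_len(n), function(t) {
    lo <- max(1, t - half); hi <- min(n, t + half)
    mean(series[lo:hi])
  }, numeric(1))
}

#' Cells of a centerline cross section by region growing
#'
#' Starting from the cell containing the station point, neighbor cells
#' (26-connectivity) are recursively marked if their centers lie inside
#' the cuboid slab of thickness `sqrt(3) dx` centered on the plane
#' through the station with the given normal:
#' `|(x - C_cl) . n_cl| < sqrt(3)/2 dx`. Only cells connected to the
#' seed are returned, which separates the two nasal sides and excludes
#' sinus cells not connected to the main cavity within the slab.
#'
#' @param grid a `solver_grid`.
#' @param point station point on the centerline, mm.
#' @param normal centerline tangent (slab normal), any length > 0.
#' @return An object of class `cross_section`: cell ids, count `H_cs`,
#'   and the station geometry.
#' @export
cross_section_cells <- function(grid, point, normal) {
  stopifnot(inherits(grid, "solver_grid"))
  n <- normal / sqrt(sum(normal^2))
  dx <- grid$dx
  d <- grid$dim
  idx <- floor((point - grid$origin) / dx) + 1
  if (any(idx < 1) || any(idx > d) ||
      grid$cellid[idx[1], idx[2], idx[3]] == 0)
    stop("seed point is outside the mesh")
  centers <- function(ijk)
    sweep((ijk - 0.5) * dx, 2, grid$origin, "+")
  in_slab <- function(ijk) {
    x <- centers(ijk)
    abs((x - matrix(point, nrow(ijk), 3, byrow = TRUE)) %*% n) <
      sqrt(3) / 2 * dx
  }
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, ]
  seen <- new.env(hash = TRUE)
  key <- function(v) paste(v, collapse = ",")
  if (!in_slab(matrix(idx, 1)))
    stop("seed cell center is outside the slab; station ill-posed")
  queue <- list(idx)
  assign(key(idx), TRUE, envir = seen)
  members <- matrix(idx, 1)
  while (length(queue)) {
    cur <- queue[[1]]; queue <- queue[-1]
    cand <- sweep(offs, 2, cur, "+")
    ok <- cand[, 1] >= 1 & cand[, 1] <= d[1] & cand[, 2] >= 1 &
      cand[, 2] <= d[2] & cand[, 3] >= 1 & cand[, 3] <= d[3]
    cand <- cand[ok, , drop = FALSE]
    for (r in seq_len(nrow(cand))) {
      v <- cand[r, ]
      k <- key(v)
      if (exists(k, envir = seen, inherits = FALSE)) next
      assign(k, TRUE, envir = seen)
      if (grid$cellid[v[1], v[2], v[3]] == 0) next
      if (!in_slab(matrix(v, 1))) next
      members <- rbind(members, v)
      queue[[length(queue) + 1]] <- v
    }
  }
  ids <- grid$cellid[members]
  structure(list(cells = ids, ijk = members, H_cs = length(ids),
                 point = point, normal = n, dx = dx),
            class = "cross_section")
}

#' Spatial average over a cross section
#'
#' `a_bar = (1/H_cs) sum a_i`, the arithmetic mean over member cells.
#'
#' @param cs a `cross_section`.
#' @param field per-cell field vector (indexed by solver cell id).
#' @return The mean value.
#' @export
section_average <- function(cs, field) {
  stopifnot(inherits(cs, "cross_section"))
  if (cs$H_cs < 1) stop("empty cross section")
  mean(field[cs$cells])
}

#' Construct a centerline
#'
#' @param points ordered polyline points (n x 3), mm.
#' @param side label (`left`, `right`, `total`).
#' @return An object of class `centerline` with unit tangents and
#'   arclength.
#' @export
centerline <- function(points, side = "total") {
  points <- as.matrix(points)
  stopifnot(ncol(points) == 3, nrow(points) >= 2)
  seg <- diff(points)
  len <- sqrt(rowSums(seg^2))
  if (any(len == 0)) stop("consecutive centerline points must be distinct")
  tang <- seg / len
  tang <- rbind(tang, tang[nrow(tang), ])
  structure(list(points = points, tangents = tang,
                 arclength = c(0, cumsum(len)), side = side),
            class = "centerline")
}

#' Read / write centerline polylines as CSV
#'
#' Columns `x_mm, y_mm, z_mm` (header mandatory).
#'
#' @param path CSV path; @param cl a [centerline()]; @param side label.
#' @return A [centerline()] / the path.
#' @export
read_centerline_csv <- function(path, side = "total") {
  df <- utils::read.csv(path)
  centerline(unname(as.matrix(df[, c("x_mm", "y_mm", "z_mm")])), side = side)
}

#' @rdname read_centerline_csv
#' @export
write_centerline_csv <- function(cl, path) {
  utils::write.csv(data.frame(x_mm = cl$points[, 1], y_mm = cl$points[, 2],
                              z_mm = cl$points[, 3]), path, row.names = FALSE)
  invisible(path)
}

# interpolate a centerline at arclength s
centerline_at <- function(cl, s) {
  s <- min(max(s, 0), max(cl$arclength))
  i <- findInterval(s, cl$arclength, rightmost.closed = TRUE)
  i <- min(i, nrow(cl$points) - 1)
  t0 <- cl$arclength[i]; t1 <- cl$arclength[i + 1]
  w <- if (t1 > t0) (s - t0) / (t1 - t0) else 0
  list(point = (1 - w) * cl$points[i, ] + w * cl$points[i + 1, ],
       tangent = cl$tangents[i, ])
}

#' Pressure and temperature profiles along centerlines
#'
#' Places `n_stations` equidistant stations along each centerline's
#' arclength, grows the cross section at each station and averages the
#' total pressure and temperature over its cells. Stations whose seed
#' point falls outside the mesh are skipped with a warning. Arclength is
#' reported as percent of the total centerline length (from the
#' nostril).
#'
#' @param result a `simulation_result`.
#' @param centerlines a [centerline()] or list of them.
#' @param n_stations stations per centerline.
#' @return A data.frame with `side`, `station`, `arc_pct`, `p_tot_pa`,
#'   `temperature_k`, `n_cells`.
#' @export
centerline_profiles <- function(result, centerlines, n_stations = 20) {
  stopifnot(inherits(result, "simulation_result"))
  if (inherits(centerlines, "centerline")) centerlines <- list(centerlines)
  lat <- lattice_d3q27()
  use_avg <- result$lbm$n_avg > 0
  rho <- if (use_avg) result$lbm$avg_rho else result$lbm$rho
  v <- if (use_avg) result$lbm$avg_v else result$lbm$v
  temp <- if (use_avg) result$lbm$avg_T else result$lbm$T
  ptot <- (0.5 * rho * rowSums(v^2) + rho * lat$cs2) * result$units$p_scale
  out <- NULL
  for (cl in centerlines) {
    total_len <- max(cl$arclength)
    ss <- seq(0, total_len, length.out = n_stations)
    for (k in seq_along(ss)) {
      st <- centerline_at(cl, ss[k])
      cs <- tryCatch(cross_section_cells(result$grid, st$point, st$tangent),
                     error = function(e) NULL)
      if (is.null(cs)) {
        warning(sprintf("station %d of side %s outside mesh; skipped",
                        k, cl$side))
        next
      }
      out <- rbind(out, data.frame(
        side = cl$side, station = k, arc_pct = 100 * ss[k] / total_len,
        p_tot_pa = section_average(cs, ptot),
        temperature_k = if (length(temp)) section_average(cs, temp) else NA_real_,
        n_cells = cs$H_cs))
    }
  }
  out
}

#' Geometric centerline for phantoms and voxel masks
#'
#' Generated phantom geometries carry their analytic axis; for those the
#' exact polyline is returned. For a voxel mask, a medial path is
#' extracted as the minimum-cost voxel path between two endpoints,
#' where the step cost penalizes proximity to the wall
#' (`1/dist_to_wall^2`), i.e. a distance-transform ridge path.
#'
#' @param x a phantom geometry with a `centerlines` attribute, or a
#'   logical 3-D mask array.
#' @param from,to endpoints in voxel index coordinates (mask input).
#' @param spacing,origin voxel geometry (mask input), mm.
#' @param side label for the resulting [centerline()].
#' @return A [centerline()] (or list of them for phantom input).
#' @export
naive_centerline <- function(x, from = NULL, to = NULL,
                             spacing = c(1, 1, 1), origin = c(0, 0, 0),
                             side = "total") {
  cls <- attr(x, "centerlines")
  if (!is.null(cls)) return(cls)
  mask <- x
  stopifnot(is.array(mask), length(dim(mask)) == 3)
  if (is.null(from) || is.null(to)) stop("endpoints required for mask input")
  d <- dim(mask)
  lin <- function(v) (v[3] - 1) * d[1] * d[2] + (v[2] - 1) * d[1] + v[1]
  if (!mask[from[1], from[2], from[3]] || !mask[to[1], to[2], to[3]])
    stop("endpoints not inside the mask")
  # multi-source BFS distance to the wall (6-connectivity)
  dist <- array(Inf, d)
  idx <- which(mask)
  co <- arrayInd(idx, d)
  offs6 <- rbind(c(1,0,0), c(-1,0,0), c(0,1,0), c(0,-1,0), c(0,0,1), c(0,0,-1))
  boundary <- rep(FALSE, length(idx))
  for (r in seq_len(6)) {
    nbco <- sweep(co, 2, offs6[r, ], "+")
    outside <- nbco[, 1] < 1 | nbco[, 1] > d[1] | nbco[, 2] < 1 |
      nbco[, 2] > d[2] | nbco[, 3] < 1 | nbco[, 3] > d[3]
    inside <- !outside
    val <- rep(FALSE, length(idx))
    val[inside] <- !mask[nbco[inside, , drop = FALSE]]
    boundary <- boundary | outside | val
  }
  dist[idx[boundary]] <- 1
  frontier <- idx[boundary]
  lvl <- 1
  while (length(frontier)) {
    lvl <- lvl + 1
    fco <- arrayInd(frontier, d)
    nxt <- integer(0)
    for (r in seq_len(6)) {
      nbco <- sweep(fco, 2, offs6[r, ], "+")
      ok <- nbco[, 1] >= 1 & nbco[, 1] <= d[1] & nbco[, 2] >= 1 &
        nbco[, 2] <= d[2] & nbco[, 3] >= 1 & nbco[, 3] <= d[3]
      nbl <- nbco[ok, , drop = FALSE]
      li <- (nbl[, 3] - 1) * d[1] * d[2] + (nbl[, 2] - 1) * d[1] + nbl[, 1]
      sel <- mask[li] & !is.finite(dist[li])
      if (any(sel)) {
        dist[li[sel]] <- lvl
        nxt <- c(nxt, li[sel])
      }
    }
    frontier <- unique(nxt)
  }
  # graph over mask voxels, 26-connectivity, cost ~ 1/dist^2
  vmap <- integer(prod(d))
  vmap[idx] <- seq_along(idx)
  offs26 <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs26 <- offs26[rowSums(abs(offs26)) > 0, ]
  ed <- NULL; wt <- NULL
  for (r in seq_len(nrow(offs26))) {
    nbco <- sweep(co, 2, offs26[r, ], "+")
    ok <- nbco[, 1] >= 1 & nbco[, 1] <= d[1] & nbco[, 2] >= 1 &
      nbco[, 2] <= d[2] & nbco[, 3] >= 1 & nbco[, 3] <= d[3]
    nbl <- (nbco[ok, 3] - 1) * d[1] * d[2] + (nbco[ok, 2] - 1) * d[1] +
      nbco[ok, 1]
    sel <- mask[nbl]
    a <- vmap[idx[ok]][sel]; b <- vmap[nbl[sel]]
    keep <- a < b
    step_len <- sqrt(sum(offs26[r, ]^2))
    cost <- step_len * (1 / dist[idx[ok]][sel]^2 + 1 / dist[nbl[sel]]^2) / 2
    ed <- rbind(ed, cbind(a[keep], b[keep]))
    wt <- c(wt, cost[keep])
  }
  g <- igraph::graph_from_edgelist(ed, directed = FALSE)
  igraph::E(g)$weight <- wt
  sp <- igraph::shortest_paths(g, from = vmap[lin(from)],
                               to = vmap[lin(to)])$vpath[[1]]
  path_co <- co[as.integer(sp), , drop = FALSE]
  pts <- sweep((path_co - 0.5) * matrix(spacing, nrow(path_co), 3,
                                        byrow = TRUE), 2, origin, "+")
  centerline(pts, side = side)
}
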