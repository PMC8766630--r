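#' Generate a hierarchical Cartesian (octree) mesh from a surface
#'
#' Starting from an initial cube enclosing the geometry (its bounding box
#' inflated by 5% and cubified), all cells of the current level are
#' subdivided into 8 children and children located outside the geometry
#' are deleted, until `l_uniform` is reached. Beyond that, cells cut by
#' the boundary (`boundary_refine = TRUE`) and/or cells inside refinement
#' patches are subdivided further until `l_final`. Cut cells store the
#' wall distance fraction `q` of the link length along each of the 26
#' lattice directions (for the interpolated bounce-back scheme) and the
#' boundary patch of their nearest surface triangle. A 2:1 level balance
#' across neighbors is enforced.
#'
#' @param geom a watertight [triangle_mesh()] (see [read_surface()]).
#' @param l_uniform uniform refinement level (>= 1).
#' @param l_final final level (>= `l_uniform`).
#' @param patches optional refinement boxes, a matrix with rows
#'   `(xmin, ymin, zmin, xmax, ymax, zmax)` in mm.
#' @param boundary_refine refine cells cut by the surface up to
#'   `l_final`.
#' @return An object of class `cartesian_mesh`.
#' @export
generate_mesh <- function(geom, l_uniform, l_final = l_uniform,
                          patches = NULL, boundary_refine = FALSE) {
  stopifnot(inherits(geom, "triangle_mesh"))
  wt <- attr(geom, "watertight")
  if (is.null(wt)) wt <- is_watertight(geom)
  if (!wt) stop("mesh generation requires a watertight geometry")
  if (l_uniform < 1 || l_final < l_uniform)
    stop("need l_final >= l_uniform >= 1")
  bb <- apply(geom$vertices, 2, range)
  center <- colMeans(bb)
  edge <- max(bb[2, ] - bb[1, ]) * 1.05
  origin <- center - edge / 2
  res <- octree_generate_cpp(geom$vertices, geom$faces, origin, edge,
                             as.integer(l_uniform), as.integer(l_final),
                             boundary_refine,
                             if (is.null(patches)) NULL else as.matrix(patches))
  cells <- data.frame(level = res$level, ix = res$ix, iy = res$iy,
                      iz = res$iz, parent = res$parent, cx = res$cx,
                      cy = res$cy, cz = res$cz, dx = res$dx,
                      cut = res$cut, leaf = res$leaf)
  patch <- NULL
  if (!is.null(geom$patch)) {
    patch <- rep(NA_character_, length(res$cut_leaf))
    hit <- res$nearest_tri
    patch[hit > 0] <- as.character(geom$patch[hit[hit > 0]])
  }
  structure(list(cells = cells, origin = origin, root_edge = edge,
                 l_uniform = as.integer(l_uniform),
                 l_final = as.integer(l_final),
                 cut_leaf = res$cut_leaf, q = res$q, cut_patch = patch,
                 geometry = geom),
            class = "cartesian_mesh")
}

#' @export
print.cartesian_mesh <- function(x, ...) {
  lf <- x$cells[x$cells$leaf, ]
  cat(sprintf("<cartesian_mesh> %d cells (%d leaves, %d cut), levels %d..%d, dx(final)=%.4g mm\n",
              nrow(x$cells), nrow(lf), sum(lf$cut), x$l_uniform, x$l_final,
              x$root_edge / 2^x$l_final))
  invisible(x)
}

#' Leaf cells of a Cartesian mesh
#' @param mesh a `cartesian_mesh`.
#' @param level optional level filter.
#' @return The leaf rows of the cell table.
#' @export
mesh_leaves <- function(mesh, level = NULL) {
  lf <- mesh$cells[mesh$cells$leaf, ]
  if (!is.null(level)) lf <- lf[lf$level == level, ]
  lf
}

#' Check the 2:1 level balance of the leaves
#'
#' Every pair of face/edge/corner-adjacent leaves may differ by at most
#' one refinement level.
#'
#' @param mesh a `cartesian_mesh`.
#' @return `TRUE` if balanced.
#' @export
is_balanced <- function(mesh) {
  lf <- mesh_leaves(mesh)
  if (length(unique(lf$level)) <= 2 &&
      diff(range(lf$level)) <= 1) return(TRUE)
  lv <- sort(unique(lf$level))
  keys <- lapply(lv, function(l) {
    sel <- lf$level == l
    paste(lf$ix[sel], lf$iy[sel], lf$iz[sel])
  })
  names(keys) <- as.character(lv)
  for (l in lv) {
    deeper <- lv[lv > l + 1]
    if (!length(deeper)) next
    sel <- lf$level == l
    for (ld in deeper) {
      f <- 2^(ld - l)
      # any leaf at ld whose ancestor box touches a leaf at l?
      selD <- lf$level == ld
      ax <- lf$ix[selD] %/% f; ay <- lf$iy[selD] %/% f; az <- lf$iz[selD] %/% f
      coarse <- paste(lf$ix[sel], lf$iy[sel], lf$iz[sel])
      for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
        if (any(paste(ax + dx, ay + dy, az + dz) %in% coarse)) return(FALSE)
      }
    }
  }
  TRUE
}

#' Map a uniformly refined mesh to a dense solver grid
#'
#' The flow solver operates on the leaves of the finest uniform level as
#' a dense Cartesian grid. Cut leaves whose center lies outside the
#' geometry are excluded from the lattice (the surface is represented
#' link-wise from the inside cells). For every remaining cell with a
#' missing neighbor, the wall distance fraction `q` along each cut link
#' is recomputed by ray casting, and cells whose closest axis-direction
#' hit belongs to an open surface patch (`pharynx`, `nostril_*`) are
#' labeled as open boundary cells of that patch.
#'
#' @param mesh a `cartesian_mesh` with all leaves on one level.
#' @return A list of class `solver_grid` with the occupancy array,
#'   cell index array, cell table, spacing and boundary metadata.
#' @export
mesh_to_grid <- function(mesh) {
  lf <- mesh_leaves(mesh)
  lev <- unique(lf$level)
  if (length(lev) != 1)
    stop("solver grid requires a uniformly refined mesh (one leaf level)")
  geom <- mesh$geometry
  # drop cut leaves whose center is outside the geometry
  if (any(lf$cut)) {
    ins <- rep(TRUE, nrow(lf))
    ins[lf$cut] <- point_inside(
      geom, as.matrix(lf[lf$cut, c("cx", "cy", "cz")]))
    lf <- lf[ins, , drop = FALSE]
  }
  n <- 2^lev
  dx <- mesh$root_edge / n
  occ <- array(FALSE, c(n, n, n))
  occ[cbind(lf$ix + 1L, lf$iy + 1L, lf$iz + 1L)] <- TRUE
  cellid <- array(0L, c(n, n, n))
  cellid[cbind(lf$ix + 1L, lf$iy + 1L, lf$iz + 1L)] <- seq_len(nrow(lf))
  # cells with at least one missing neighbor need link data
  nb <- grid_neighbor_table(cellid)
  bnd <- which(rowSums(nb < 0) > 1)  # rest direction never missing
  qm <- matrix(NA_real_, nrow(lf), 27)
  patch <- rep(NA_character_, nrow(lf))
  if (length(bnd)) {
    scan <- link_scan_cpp(as.matrix(lf[bnd, c("cx", "cy", "cz")]), dx,
                          geom$vertices, geom$faces)
    qm[bnd, ] <- scan$q
    if (!is.null(geom$patch)) {
      axis_dirs <- which(rowSums(abs(lattice_d3q27()$xi)) == 1)
      pl <- as.character(geom$patch)
      open_names <- setdiff(unique(pl), "wall")
      for (k in seq_along(bnd)) {
        cellrow <- bnd[k]
        miss <- which(nb[cellrow, ] < 0)
        dirs <- intersect(miss, axis_dirs)
        hits <- scan$tri[k, dirs]
        qs <- scan$q[k, dirs]
        ok <- hits > 0 & !is.na(qs)
        if (!any(ok)) next
        pp <- pl[hits[ok]]
        qq <- qs[ok]
        open <- pp %in% open_names
        if (any(open)) {
          best <- which(open)[which.min(qq[open])]
          patch[cellrow] <- pp[best]
        }
      }
      patch[setdiff(bnd, which(!is.na(patch)))] <- "wall"
    } else {
      patch[bnd] <- "wall"
    }
  }
  structure(list(dim = c(n, n, n), occ = occ, cellid = cellid,
                 cells = lf, q = qm, patch = patch,
                 dx = dx, origin = mesh$origin,
                 level = lev),
            class = "solver_grid")
}

#' Export mesh leaves as legacy VTK unstructured grid (text)
#'
#' One hexahedral cell per leaf, with the refinement level and cut flag
#' as cell data; loadable in ParaView for inspection.
#'
#' @param mesh a `cartesian_mesh`.
#' @param path output `.vtk` path.
#' @return `path`, invisibly.
#' @export
write_mesh_vtk <- function(mesh, path) {
  lf <- mesh_leaves(mesh)
  nc <- nrow(lf)
  h <- lf$dx / 2
  corners <- expand.grid(x = c(-1, 1), y = c(-1, 1), z = c(-1, 1))
  pts <- matrix(0, nc * 8, 3)
  for (k in 1:8) {
    idx <- seq(k, by = 8, length.out = nc)
    pts[idx, ] <- cbind(lf$cx + corners$x[k] * h,
                        lf$cy + corners$y[k] * h,
                        lf$cz + corners$z[k] * h)
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0", "rhinoflow mesh", "ASCII",
               "DATASET UNSTRUCTURED_GRID",
               sprintf("POINTS %d float", nc * 8)), con)
  writeLines(sprintf("%.9g %.9g %.9g", pts[, 1], pts[, 2], pts[, 3]), con)
  writeLines(sprintf("CELLS %d %d", nc, nc * 9), con)
  base <- (seq_len(nc) - 1L) * 8L
  writeLines(sprintf("8 %d %d %d %d %d %d %d %d",
                     base, base + 1L, base + 2L, base + 3L,
                     base + 4L, base + 5L, base + 6L, base + 7L), con)
  writeLines(sprintf("CELL_TYPES %d", nc), con)
  writeLines(rep("11", nc), con)  # VTK_VOXEL
  writeLines(c(sprintf("CELL_DATA %d", nc), "SCALARS level int 1",
               "LOOKUP_TABLE default"), con)
  writeLines(sprintf("%d", lf$level), con)
  writeLines(c("SCALARS cut int 1", "LOOKUP_TABLE default"), con)
  writeLines(sprintf("%d", as.integer(lf$cut)), con)
  invisible(path)
}

#' Persist / restore a Cartesian mesh
#'
#' @param mesh a `cartesian_mesh`.
#' @param path container path (`.rds`).
#' @return `path` invisibly, or the restored mesh.
#' @export
save_mesh <- function(mesh, path) {
  saveRDS(mesh, path)
  invisible(path)
}

#' @rdname save_mesh
#' @export
load_mesh <- function(path) readRDS(path)
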