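#' Construct a triangle surface mesh
#'
#' @param vertices numeric matrix (n x 3), coordinates in mm.
#' @param faces integer matrix (m x 3) of 1-based vertex indices.
#' @param patch optional integer or character vector (length m) labeling
#'   faces with named boundary patches (e.g. `wall`, `nostril_left`,
#'   `pharynx`); used to attribute open boundaries in the flow solver.
#' @return An object of class `triangle_mesh`.
#' @export
triangle_mesh <- function(vertices, faces, patch = NULL) {
  vertices <- as.matrix(vertices)
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  stopifnot(ncol(vertices) == 3, ncol(faces) == 3)
  if (nrow(faces) && (min(faces) < 1L || max(faces) > nrow(vertices)))
    stop("face indices out of range")
  if (!is.null(patch)) {
    patch <- as.factor(patch)
    stopifnot(length(patch) == nrow(faces))
  }
  structure(list(vertices = vertices, faces = faces, patch = patch),
            class = "triangle_mesh")
}

#' @export
print.triangle_mesh <- function(x, ...) {
  cat(sprintf("<triangle_mesh> %d vertices, %d faces%s, watertight: %s\n",
              nrow(x$vertices), nrow(x$faces),
              if (!is.null(x$patch))
                sprintf(" (%d patches)", nlevels(x$patch)) else "",
              is_watertight(x)))
  invisible(x)
}

#' Edge-manifold (watertightness) test
#'
#' A closed, manifold surface has every undirected edge shared by exactly
#' two faces.
#'
#' @param mesh a [triangle_mesh()].
#' @return `TRUE` if every edge is used by exactly 2 faces.
#' @export
is_watertight <- function(mesh) {
  f <- mesh$faces
  if (!nrow(f)) return(FALSE)
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  all(table(key) == 2L)
}

#' Signed volume enclosed by a surface mesh
#'
#' Divergence-theorem sum of signed tetrahedron volumes; positive for
#' outward-oriented watertight surfaces.
#'
#' @param mesh a [triangle_mesh()].
#' @return Volume in mm^3.
#' @export
mesh_volume <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  c_ <- v[f[, 3], , drop = FALSE]
  cr <- cbind(b[, 2] * c_[, 3] - b[, 3] * c_[, 2],
              b[, 3] * c_[, 1] - b[, 1] * c_[, 3],
              b[, 1] * c_[, 2] - b[, 2] * c_[, 1])
  sum(rowSums(a * cr)) / 6
}

#' Write a triangle mesh as STL
#'
#' ASCII by default; `binary = TRUE` writes the 80-byte-header binary
#' layout. Patch labels, if present, are written as separate `solid`
#' blocks in ASCII mode so they survive a round trip.
#'
#' @param mesh a [triangle_mesh()].
#' @param path output path.
#' @param binary write binary STL instead of ASCII.
#' @return `path`, invisibly.
#' @export
write_stl <- function(mesh, path, binary = FALSE) {
  v <- mesh$vertices; f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  c_ <- v[f[, 3], , drop = FALSE]
  e1 <- b - a; e2 <- c_ - a
  n <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
             e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
             e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  len <- sqrt(rowSums(n^2)); len[len == 0] <- 1
  n <- n / len
  if (binary) {
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(raw(80), con)
    writeBin(as.integer(nrow(f)), con, size = 4, endian = "little")
    for (i in seq_len(nrow(f))) {
      writeBin(as.numeric(c(n[i, ], a[i, ], b[i, ], c_[i, ])), con,
               size = 4, endian = "little")
      writeBin(as.integer(0), con, size = 2, endian = "little")
    }
    return(invisible(path))
  }
  grp <- if (is.null(mesh$patch)) factor(rep("surface", nrow(f)))
         else mesh$patch
  con <- file(path, "w")
  on.exit(close(con))
  fmt <- function(x) sprintf("%.9g", x)
  for (g in levels(grp)) {
    idx <- which(grp == g)
    writeLines(paste0("solid ", g), con)
    for (i in idx) {
      writeLines(c(
        sprintf("  facet normal %s %s %s", fmt(n[i,1]), fmt(n[i,2]), fmt(n[i,3])),
        "    outer loop",
        sprintf("      vertex %s %s %s", fmt(a[i,1]), fmt(a[i,2]), fmt(a[i,3])),
        sprintf("      vertex %s %s %s", fmt(b[i,1]), fmt(b[i,2]), fmt(b[i,3])),
        sprintf("      vertex %s %s %s", fmt(c_[i,1]), fmt(c_[i,2]), fmt(c_[i,3])),
        "    endloop",
        "  endfacet"), con)
    }
    writeLines(paste0("endsolid ", g), con)
  }
  invisible(path)
}

#' Read an STL file (ASCII or binary)
#'
#' Vertices are merged exactly (identical coordinates), so watertight
#' meshes written by [write_stl()] read back watertight.
#'
#' @param path STL path.
#' @return A [triangle_mesh()]; ASCII `solid` names become patch labels.
#' @export
read_stl <- function(path) {
  head5 <- readBin(path, "raw", n = 5)
  is_ascii <- identical(rawToChar(head5), "solid") && {
    # binary files may also start with "solid": check facet keyword
    txt <- readBin(path, "raw", n = 512)
    grepl("facet", rawToChar(txt[txt != as.raw(0)]), fixed = TRUE)
  }
  if (is_ascii) {
    lines <- readLines(path, warn = FALSE)
    lines <- trimws(lines)
    solid_idx <- grepl("^solid", lines)
    vert_idx <- grepl("^vertex", lines)
    solid_name <- sub("^solid\\s*", "", lines[solid_idx])
    if (!length(solid_name)) stop("malformed STL: no solid")
    grp <- cumsum(solid_idx)[vert_idx]
    vv <- do.call(rbind, lapply(strsplit(lines[vert_idx], "\\s+"),
                                function(p) as.numeric(p[2:4])))
    if (nrow(vv) %% 3 != 0) stop("malformed STL: vertex count not divisible by 3")
    patch <- solid_name[grp[seq(1, nrow(vv), by = 3)]]
  } else {
    con <- file(path, "rb")
    on.exit(close(con))
    readBin(con, "raw", n = 80)
    nf <- readBin(con, "integer", size = 4, endian = "little")
    rec <- matrix(NA_real_, nf, 9)
    for (i in seq_len(nf)) {
      vals <- readBin(con, "numeric", n = 12, size = 4, endian = "little")
      readBin(con, "integer", n = 1, size = 2, endian = "little")
      rec[i, ] <- vals[4:12]
    }
    vv <- matrix(t(rec), ncol = 3, byrow = TRUE)
    patch <- NULL
  }
  key <- paste(vv[, 1], vv[, 2], vv[, 3])
  uid <- match(key, unique(key))
  verts <- vv[!duplicated(key), , drop = FALSE]
  faces <- matrix(uid, ncol = 3, byrow = TRUE)
  if (!is.null(patch) && length(unique(patch)) == 1L) patch <- NULL
  triangle_mesh(verts, faces, patch = patch)
}

#' Write a triangle mesh as ASCII PLY
#'
#' @param mesh a [triangle_mesh()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ply <- function(mesh, path) {
  v <- mesh$vertices; f <- mesh$faces
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               sprintf("element vertex %d", nrow(v)),
               "property float x", "property float y", "property float z",
               sprintf("element face %d", nrow(f)),
               "property list uchar int vertex_indices", "end_header"), con)
  writeLines(sprintf("%.9g %.9g %.9g", v[, 1], v[, 2], v[, 3]), con)
  writeLines(sprintf("3 %d %d %d", f[, 1] - 1L, f[, 2] - 1L, f[, 3] - 1L), con)
  invisible(path)
}

#' Read a surface file (STL or PLY by extension)
#'
#' The result carries a `watertight` attribute from the edge-manifold
#' test; inside/outside queries refuse non-watertight geometry.
#'
#' @param path surface path (`.stl` or `.ply`).
#' @return A [triangle_mesh()] with attribute `watertight`.
#' @export
read_surface <- function(path) {
  ext <- tolower(tools::file_ext(path))
  mesh <- if (ext == "ply") read_ply(path) else read_stl(path)
  attr(mesh, "watertight") <- is_watertight(mesh)
  mesh
}

read_ply <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr_end <- which(lines == "end_header")[1]
  nv <- as.integer(sub("element vertex ", "",
                       grep("^element vertex", lines, value = TRUE)[1]))
  nf <- as.integer(sub("element face ", "",
                       grep("^element face", lines, value = TRUE)[1]))
  vl <- lines[(hdr_end + 1):(hdr_end + nv)]
  fl <- lines[(hdr_end + nv + 1):(hdr_end + nv + nf)]
  verts <- do.call(rbind, lapply(strsplit(vl, "\\s+"),
                                 function(p) as.numeric(p[1:3])))
  faces <- do.call(rbind, lapply(strsplit(fl, "\\s+"),
                                 function(p) as.integer(p[2:4]) + 1L))
  triangle_mesh(verts, faces)
}

#' Write a surface file (STL or PLY by extension)
#' @param mesh a [triangle_mesh()].
#' @param path output path ending in `.stl` or `.ply`.
#' @return `path`, invisibly.
#' @export
write_surface <- function(mesh, path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "ply") write_ply(mesh, path) else write_stl(mesh, path)
}

#' Point-in-geometry test for watertight surfaces
#'
#' Ray-casting parity test against all triangles.
#'
#' @param geom a watertight [triangle_mesh()].
#' @param p numeric vector (single point) or n x 3 matrix, mm.
#' @return Logical vector.
#' @export
point_inside <- function(geom, p) {
  if (is.null(dim(p))) p <- matrix(p, ncol = 3)
  wt <- attr(geom, "watertight")
  if (is.null(wt)) wt <- is_watertight(geom)
  if (!wt) stop("inside test refused: geometry is not watertight")
  inside_points(as.matrix(p), geom$vertices, geom$faces)
}

#' Laplacian smoothing of a triangle mesh
#'
#' Moves every vertex a fraction `lambda` toward the mean of its
#' one-ring neighbors; repeated `passes` times. Connectivity (and hence
#' watertightness) is unchanged; volumes shrink slightly.
#'
#' @param mesh a [triangle_mesh()].
#' @param passes number of smoothing passes.
#' @param lambda relaxation factor in (0, 1].
#' @return The smoothed [triangle_mesh()].
#' @export
smooth_mesh <- function(mesh, passes = 1, lambda = 0.5) {
  if (passes < 1) return(mesh)
  v <- mesh$vertices; f <- mesh$faces
  ei <- c(f[, 1], f[, 2], f[, 3], f[, 2], f[, 3], f[, 1])
  ej <- c(f[, 2], f[, 3], f[, 1], f[, 1], f[, 2], f[, 3])
  deg <- tabulate(ei, nbins = nrow(v))
  for (p in seq_len(passes)) {
    mx <- rowsum(v[ej, 1], ei, reorder = TRUE)
    my <- rowsum(v[ej, 2], ei, reorder = TRUE)
    mz <- rowsum(v[ej, 3], ei, reorder = TRUE)
    mean_nb <- cbind(mx, my, mz) / deg
    v <- v + lambda * (mean_nb - v)
  }
  triangle_mesh(v, f, patch = mesh$patch)
}
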