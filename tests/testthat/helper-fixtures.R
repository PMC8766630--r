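# Shared in-code fixtures for the test suite.

# dense-quadrature oracle for the RMS-ratio resistance on an analytic
# waveform (sum of harmonics), independent of the package's trapezoids
riemann_rms_ratio <- function(dp_fun, vd_fun, T, n = 2e5) {
  t <- seq(0, T, length.out = n)
  sqrt(mean(dp_fun(t)^2) / mean(vd_fun(t)^2))
}

# brute-force 3-D connected component labeling (BFS, 26-connectivity)
bfs_components <- function(mask) {
  d <- dim(mask)
  lab <- array(0L, d)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, ]
  cur <- 0L
  for (s in which(mask)) {
    if (lab[s] != 0L) next
    cur <- cur + 1L
    queue <- list(arrayInd(s, d)[1, ])
    lab[s] <- cur
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      for (r in seq_len(nrow(offs))) {
        q <- p + offs[r, ]
        if (any(q < 1) || any(q > d)) next
        if (mask[q[1], q[2], q[3]] && lab[q[1], q[2], q[3]] == 0L) {
          lab[q[1], q[2], q[3]] <- cur
          queue[[length(queue) + 1]] <- q
        }
      }
    }
  }
  attr(lab, "n") <- cur
  lab
}

# generalized winding number (sum of signed solid angles, van Oosterom)
winding_inside <- function(mesh, pts) {
  v <- mesh$vertices; f <- mesh$faces
  apply(pts, 1, function(p) {
    a <- t(v[f[, 1], , drop = FALSE]) - p
    b <- t(v[f[, 2], , drop = FALSE]) - p
    c_ <- t(v[f[, 3], , drop = FALSE]) - p
    la <- sqrt(colSums(a^2)); lb <- sqrt(colSums(b^2)); lc <- sqrt(colSums(c_^2))
    num <- a[1, ] * (b[2, ] * c_[3, ] - b[3, ] * c_[2, ]) -
      a[2, ] * (b[1, ] * c_[3, ] - b[3, ] * c_[1, ]) +
      a[3, ] * (b[1, ] * c_[2, ] - b[2, ] * c_[1, ])
    den <- la * lb * lc + colSums(a * b) * lc + colSums(a * c_) * lb +
      colSums(b * c_) * la
    omega <- 2 * atan2(num, den)
    abs(sum(omega) / (4 * pi)) > 0.5
  })
}

# slab-and-connectivity oracle for cross sections: all occupied cells in
# the slab, intersected with the seed's connected component (igraph)
slab_component_oracle <- function(cellid, dx, origin, point, normal) {
  n <- normal / sqrt(sum(normal^2))
  ids <- which(cellid > 0, arr.ind = TRUE)
  ids <- ids[order(cellid[cellid > 0]), , drop = FALSE]
  centers <- sweep((ids - 0.5) * dx, 2, origin, "+")
  inslab <- abs((centers - matrix(point, nrow(ids), 3, byrow = TRUE)) %*% n) <
    sqrt(3) / 2 * dx
  slab_cells <- which(inslab)
  if (!length(slab_cells)) return(integer(0))
  # seed cell
  sidx <- floor((point - origin) / dx) + 1
  seed <- cellid[sidx[1], sidx[2], sidx[3]]
  if (!(seed %in% slab_cells)) return(integer(0))
  # 26-neighbor graph over slab cells
  key <- function(m) paste(m[, 1], m[, 2], m[, 3])
  kmap <- stats::setNames(slab_cells, key(ids[slab_cells, , drop = FALSE]))
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, ]
  edges <- NULL
  for (r in seq_len(nrow(offs))) {
    nbk <- key(sweep(ids[slab_cells, , drop = FALSE], 2, -offs[r, ], "-"))
    hit <- !is.na(kmap[nbk])
    if (any(hit))
      edges <- rbind(edges, cbind(slab_cells[hit], unname(kmap[nbk[hit]])))
  }
  n_v <- length(slab_cells)
  if (is.null(edges)) {
    g <- igraph::make_empty_graph(n = n_v, directed = FALSE)
  } else {
    g <- igraph::graph_from_edgelist(
      matrix(match(edges, slab_cells), ncol = 2), directed = FALSE)
    if (igraph::vcount(g) < n_v)
      g <- igraph::add_vertices(g, n_v - igraph::vcount(g))
  }
  comp <- igraph::components(g)
  seed_pos <- match(seed, slab_cells)
  sort(slab_cells[comp$membership == comp$membership[seed_pos]])
}

# tiny toy label volume: two blocks of class 1 in a class-0 background
toy_label_volume <- function() {
  vox <- array(0L, c(8, 8, 4))
  vox[2:3, 2:3, 2:3] <- 1L
  vox[6:7, 6:7, 2:3] <- 1L
  label_volume(vox, class_names = c(bg = 0L, fg = 1L))
}
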