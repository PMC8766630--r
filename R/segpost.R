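#' Default 9-class anatomical label table
#'
#' Class ids 0..8 for the segmentation of axial CT slices: the paranasal
#' sinus air spaces (left/right frontal, combined maxillary, left/right
#' sphenoid), the combined nasal and oral cavity, air outside the head
#' (incl. mastoid air cells), bone, and soft tissue. Splitting the
#' maxillary class yields the 10-class table.
#'
#' @param split_maxillary return the 10-class table with separate
#'   left/right maxillary sinuses.
#' @return Named integer vector (names are anatomical labels, values ids).
#' @export
head_class_table <- function(split_maxillary = FALSE) {
  base <- c(frontal_sinus_left = 0L, frontal_sinus_right = 1L,
            maxillary_sinuses = 2L, sphenoid_sinus_left = 3L,
            sphenoid_sinus_right = 4L, nasal_oral_cavity = 5L,
            air_outside = 6L, bone = 7L, tissue = 8L)
  if (!split_maxillary) return(base)
  c(base[setdiff(names(base), "maxillary_sinuses")],
    maxillary_sinus_left = 2L, maxillary_sinus_right = 9L)[
      c("frontal_sinus_left", "frontal_sinus_right", "maxillary_sinus_left",
        "sphenoid_sinus_left", "sphenoid_sinus_right", "nasal_oral_cavity",
        "air_outside", "bone", "tissue", "maxillary_sinus_right")]
}

#' Construct a label volume
#'
#' @param voxels 3-D integer array of class ids `0..n_classes-1` (axial
#'   slices along the third dimension).
#' @param spacing voxel spacing per axis, mm.
#' @param origin position of the first voxel center, mm.
#' @param class_names named integer vector mapping names to ids.
#' @return An object of class `label_volume`.
#' @export
label_volume <- function(voxels, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                         class_names = head_class_table()) {
  voxels <- as.array(voxels)
  storage.mode(voxels) <- "integer"
  stopifnot(length(dim(voxels)) == 3, all(spacing > 0))
  if (any(voxels < 0) || any(!unique(as.vector(voxels)) %in% class_names))
    stop("voxel values must be ids present in class_names")
  structure(list(voxels = voxels, spacing = as.numeric(spacing),
                 origin = as.numeric(origin), class_names = class_names),
            class = "label_volume")
}

#' @export
print.label_volume <- function(x, ...) {
  cat(sprintf("<label_volume> %s voxels, %d classes, spacing %s mm\n",
              paste(dim(x$voxels), collapse = "x"), length(x$class_names),
              paste(signif(x$spacing, 3), collapse = "x")))
  invisible(x)
}

#' Label connected components of a mask
#'
#' 26-connectivity in 3-D, 8-connectivity in 2-D (defaults); 6/18 and 4
#' are available.
#'
#' @param mask logical array (2-D or 3-D).
#' @param connectivity neighborhood definition.
#' @return Integer array of component labels (0 = background) with
#'   attribute `n` (component count).
#' @export
connected_components <- function(mask, connectivity = NULL) {
  d <- dim(mask)
  if (is.null(connectivity)) connectivity <- if (length(d) == 3) 26 else 8
  cc_label(as.logical(mask), as.integer(d), as.integer(connectivity))
}

#' Split the combined maxillary sinus class into left and right
#'
#' Connected components of the combined class are assigned to the left or
#' right side by the position of their centroid relative to the
#' mid-sagittal plane (the volume x-midplane unless `mid_x` is given;
#' patient left is the +x half). The class table grows to 10 classes.
#'
#' @param lv a [label_volume()].
#' @param combined_id id of the combined maxillary class (default 2).
#' @param mid_x optional x index of the mid-sagittal plane.
#' @return The relabeled [label_volume()] with 10 classes.
#' @export
split_maxillary <- function(lv, combined_id = 2L, mid_x = NULL) {
  stopifnot(inherits(lv, "label_volume"))
  tab <- head_class_table(split_maxillary = TRUE)
  mask <- lv$voxels == combined_id
  left_id <- tab[["maxillary_sinus_left"]]
  right_id <- tab[["maxillary_sinus_right"]]
  if (!any(mask)) {
    lv$class_names <- tab
    return(lv)
  }
  if (is.null(mid_x)) mid_x <- (dim(lv$voxels)[1] + 1) / 2
  comp <- connected_components(mask)
  ncomp <- attr(comp, "n")
  if (ncomp > 2) warning(sprintf(
    "maxillary class has %d components; assigning each by centroid side", ncomp))
  xs <- slice.index(lv$voxels, 1)
  for (k in seq_len(ncomp)) {
    sel <- comp == k
    side_left <- mean(xs[sel]) > mid_x
    lv$voxels[sel] <- if (side_left) left_id else right_id
  }
  lv$class_names <- tab
  lv
}

#' Dissolve small connected components into their surroundings
#'
#' For every class, 26-connected components with fewer than `min_voxels`
#' voxels are removed voxel by voxel: each voxel receives the dominant
#' (mode) label of its 3x3x3 neighborhood, its own current label excluded
#' from the count. Ties break to the smallest class id. All target labels
#' are computed from a snapshot before any reassignment.
#'
#' @param lv a [label_volume()].
#' @param min_voxels strict threshold; components with exactly
#'   `min_voxels` voxels are kept.
#' @return The cleaned [label_volume()].
#' @export
dissolve_small_components <- function(lv, min_voxels = 10L) {
  stopifnot(inherits(lv, "label_volume"))
  vox <- lv$voxels
  nclass <- max(lv$class_names) + 1L
  small <- integer(0)
  for (cid in sort(unique(as.vector(vox)))) {
    comp <- connected_components(vox == cid)
    if (attr(comp, "n") == 0) next
    sizes <- tabulate(comp[comp > 0], nbins = attr(comp, "n"))
    bad <- which(sizes < min_voxels)
    if (length(bad)) small <- c(small, which(comp %in% bad))
  }
  if (!length(small)) return(lv)
  new_lab <- neighborhood_mode(as.vector(vox), dim(vox),
                               as.integer(small - 1L), nclass)
  lv$voxels[small] <- new_lab
  lv
}

#' Reassign anatomically implausible sinus components
#'
#' For a geometry deemed healthy, each sinus cavity is a single connected
#' component. Per sinus class, only the largest component keeps its
#' label; any smaller component whose centroid falls inside another sinus
#' cavity's bounding region is recolored to that cavity's class, and
#' remaining strays take the dominant label of their neighborhood.
#'
#' @param lv a [label_volume()].
#' @param healthy logical; if `FALSE` the volume is returned unchanged
#'   (with a message), since the single-component assumption only holds
#'   for healthy geometries.
#' @param sinus_ids ids of the sinus classes to check. The default covers
#'   the paired frontal/sphenoid sinuses; the combined maxillary class is
#'   legitimately two components, so include maxillary ids only after
#'   [split_maxillary()].
#' @return The corrected [label_volume()].
#' @export
enforce_plausibility <- function(lv, healthy = TRUE,
                                 sinus_ids = c(0L, 1L, 3L, 4L)) {
  stopifnot(inherits(lv, "label_volume"))
  if (!isTRUE(healthy)) {
    message("geometry not marked healthy; plausibility step skipped")
    return(lv)
  }
  sinus_ids <- intersect(sinus_ids, unique(as.vector(lv$voxels)))
  comp_of <- list(); main_bbox <- list()
  dims <- dim(lv$voxels)
  idx_arrays <- lapply(1:3, function(a) slice.index(lv$voxels, a))
  for (cid in sinus_ids) {
    comp <- connected_components(lv$voxels == cid)
    n <- attr(comp, "n")
    if (n == 0) next
    sizes <- tabulate(comp[comp > 0], nbins = n)
    main <- which.max(sizes)
    sel <- comp == main
    bb <- vapply(1:3, function(a) range(idx_arrays[[a]][sel]), numeric(2))
    bb[1, ] <- bb[1, ] - 1; bb[2, ] <- bb[2, ] + 1  # one-voxel margin
    main_bbox[[as.character(cid)]] <- bb
    comp_of[[as.character(cid)]] <- list(comp = comp, main = main, n = n)
  }
  nclass <- max(lv$class_names) + 1L
  for (cid in names(comp_of)) {
    info <- comp_of[[cid]]
    for (k in seq_len(info$n)) {
      if (k == info$main) next
      sel <- which(info$comp == k)
      cen <- vapply(1:3, function(a) mean(idx_arrays[[a]][sel]), numeric(1))
      target <- NA_integer_
      for (other in names(main_bbox)) {
        if (other == cid) next
        bb <- main_bbox[[other]]
        if (all(cen >= bb[1, ] & cen <= bb[2, ])) {
          target <- as.integer(other)
          break
        }
      }
      if (is.na(target)) {
        lv$voxels[sel] <- neighborhood_mode(as.vector(lv$voxels), dims,
                                            as.integer(sel - 1L), nclass)
      } else {
        lv$voxels[sel] <- target
      }
    }
  }
  lv
}

#' Segmentation quality metrics
#'
#' Compares a predicted label volume against a reference:
#' * `accuracy` — percentage of voxels with equal labels;
#' * `jaccard` — per axial slice and class, intersection over union
#'   (100% when the class is absent from both), averaged over classes
#'   then slices;
#' * `segment_match` — per slice, the percentage of classes whose
#'   presence/absence agrees, averaged over slices;
#' * `component_match` — per slice and class, `100/(1+|dC|)` where `dC`
#'   is the difference in 8-connected component count, averaged.
#'
#' @param pred,truth [label_volume()] objects of identical shape and
#'   class table.
#' @return A list of the four percentages.
#' @export
segmentation_metrics <- function(pred, truth) {
  stopifnot(inherits(pred, "label_volume"), inherits(truth, "label_volume"))
  if (!identical(dim(pred$voxels), dim(truth$voxels)))
    stop("shape mismatch between prediction and truth")
  ids <- sort(unique(as.integer(truth$class_names)))
  nz <- dim(pred$voxels)[3]
  acc <- 100 * mean(pred$voxels == truth$voxels)
  jac <- s_match <- c_match <- numeric(nz)
  for (z in seq_len(nz)) {
    p <- pred$voxels[, , z]; t_ <- truth$voxels[, , z]
    jz <- sz <- cz <- numeric(length(ids))
    for (k in seq_along(ids)) {
      pm <- p == ids[k]; tm <- t_ == ids[k]
      un <- sum(pm | tm)
      jz[k] <- if (un == 0) 100 else 100 * sum(pm & tm) / un
      sz[k] <- 100 * (any(pm) == any(tm))
      ncp <- attr(connected_components(pm), "n")
      nct <- attr(connected_components(tm), "n")
      cz[k] <- 100 / (1 + abs(ncp - nct))
    }
    jac[z] <- mean(jz); s_match[z] <- mean(sz); c_match[z] <- mean(cz)
  }
  list(accuracy = acc, jaccard = mean(jac), segment_match = mean(s_match),
       component_match = mean(c_match))
}

#' Extract a surface mesh from label-volume classes
#'
#' Isosurface of the binary mask of the selected classes at level 0.5
#' (tetrahedral marching-cubes variant), with vertices in mm via the
#' volume's spacing and origin. The mask is padded by one background
#' voxel so closed regions yield watertight surfaces.
#'
#' @param lv a [label_volume()].
#' @param class_ids ids forming the region of interest.
#' @param smoothing optional number of Laplacian smoothing passes.
#' @return A [triangle_mesh()] with attribute `watertight`.
#' @export
extract_surface <- function(lv, class_ids, smoothing = 0) {
  stopifnot(inherits(lv, "label_volume"))
  mask <- array(lv$voxels %in% class_ids, dim(lv$voxels))
  if (!any(mask)) stop("selected classes form an empty region")
  d <- dim(mask)
  field <- array(0, d + 2L)
  field[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- mask
  res <- marching_tets(as.numeric(field), dim(field), 0.5,
                       lv$origin - lv$spacing, lv$spacing)
  mesh <- triangle_mesh(res$vertices, res$faces)
  if (smoothing > 0) mesh <- smooth_mesh(mesh, passes = smoothing)
  attr(mesh, "watertight") <- is_watertight(mesh)
  mesh
}
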