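test_that("connected component labeling agrees with a brute-force BFS", {
  set.seed(3)
  mask <- array(runif(8 * 8 * 6) < 0.35, c(8, 8, 6))
  lab <- connected_components(mask)
  ref <- bfs_components(mask)
  expect_equal(attr(lab, "n")[1], attr(ref, "n"))
  # same partition up to label permutation
  key <- paste(as.vector(lab), as.vector(ref))
  expect_equal(length(unique(key[mask])), attr(ref, "n"))
  expect_true(all(lab[!mask] == 0))
})

test_that("maxillary split assigns components by centroid side", {
  vox <- array(8L, c(10, 10, 4))
  vox[2:3, 4:6, 2:3] <- 2L   # low x: right of the mid-sagittal plane
  vox[8:9, 4:6, 2:3] <- 2L   # high x: left
  vox[6, 2, 1] <- 2L         # third small component, high x
  lv <- label_volume(vox)
  expect_warning(lv10 <- split_maxillary(lv), "3 components")
  tab <- head_class_table(split_maxillary = TRUE)
  expect_equal(length(lv10$class_names), 10L)
  expect_true(all(lv10$voxels[8:9, 4:6, 2:3] ==
                    tab[["maxillary_sinus_left"]]))
  expect_true(all(lv10$voxels[2:3, 4:6, 2:3] ==
                    tab[["maxillary_sinus_right"]]))
  expect_equal(lv10$voxels[6, 2, 1], tab[["maxillary_sinus_left"]])
  # empty maxillary class: voxels unchanged, table extended
  lv_empty <- label_volume(array(8L, c(4, 4, 4)))
  out <- split_maxillary(lv_empty)
  expect_equal(out$voxels, lv_empty$voxels)
  expect_equal(length(out$class_names), 10L)
})

test_that("small components dissolve into the neighborhood mode,
          with a strict size threshold", {
  vox <- array(8L, c(12, 12, 6))
  vox[6, 6, 3] <- 0L                      # 1-voxel island
  lv <- dissolve_small_components(label_volume(vox))
  expect_equal(lv$voxels[6, 6, 3], 8L)
  # a component of exactly min_voxels survives
  vox2 <- array(8L, c(12, 12, 6))
  vox2[2:6, 2, 2] <- 0L; vox2[2:6, 3, 2] <- 0L  # 10 voxels
  lv2 <- dissolve_small_components(label_volume(vox2), min_voxels = 10L)
  expect_equal(sum(lv2$voxels == 0L), 10L)
  # random speckle: equals the brute-force neighborhood-mode oracle
  set.seed(11)
  vox3 <- array(8L, c(9, 9, 5))
  vox3[sample(length(vox3), 25)] <- sample(c(0L, 1L, 7L), 25, replace = TRUE)
  lv3 <- label_volume(vox3)
  out <- dissolve_small_components(lv3, min_voxels = 10L)
  # oracle: every voxel of a small component takes the 3^3 mode (own
  # label excluded), computed from the original volume
  ref <- vox3
  d <- dim(vox3)
  for (cid in unique(as.vector(vox3))) {
    comp <- bfs_components(vox3 == cid)
    sizes <- tabulate(comp[comp > 0], nbins = attr(comp, "n"))
    for (k in which(sizes < 10)) {
      for (j in which(comp == k)) {
        co <- arrayInd(j, d)
        xs <- max(1, co[1] - 1):min(d[1], co[1] + 1)
        ys <- max(1, co[2] - 1):min(d[2], co[2] + 1)
        zs <- max(1, co[3] - 1):min(d[3], co[3] + 1)
        nbh <- as.vector(vox3[xs, ys, zs])
        nbh <- nbh[nbh != vox3[j]]
        if (length(nbh)) {
          tb <- table(nbh)
          best <- as.integer(names(tb)[tb == max(tb)])
          ref[j] <- min(best)
        }
      }
    }
  }
  expect_equal(out$voxels, ref)
  # idempotence at fixpoint
  out2 <- dissolve_small_components(out, min_voxels = 10L)
  out3 <- dissolve_small_components(out2, min_voxels = 10L)
  expect_equal(out3$voxels, out2$voxels)
})

test_that("plausibility enforcement recolors stray sinus components", {
  head <- make_labeled_head(dims = c(48, 48, 10), noise_sd = 0, seed = 5)
  lv <- head$labels
  expect_equal(enforce_plausibility(lv, healthy = TRUE)$voxels, lv$voxels)
  # stray sphenoid-labeled blob inside the right frontal sinus
  lv2 <- lv
  sel <- which(lv$voxels == 1L)[1:4]
  lv2$voxels[sel] <- 3L
  fixed <- enforce_plausibility(lv2, healthy = TRUE)
  expect_true(all(fixed$voxels[sel] == 1L))
  expect_message(out <- enforce_plausibility(lv2, healthy = FALSE),
                 "skipped")
  expect_equal(out$voxels, lv2$voxels)
  # largest-component rule: the main component keeps its label
  main <- which(fixed$voxels == 3L)
  expect_gt(length(main), 0)
})

test_that("segmentation metrics match set arithmetic on a toy pair and
          are symmetric", {
  p <- array(0L, c(8, 8, 1)); t_ <- array(0L, c(8, 8, 1))
  p[2:4, 2:4, 1] <- 1L        # 9 px
  t_[3:5, 3:5, 1] <- 1L       # 9 px, overlap 4
  cn <- c(bg = 0L, fg = 1L)
  pred <- label_volume(p, class_names = cn)
  truth <- label_volume(t_, class_names = cn)
  m <- segmentation_metrics(pred, truth)
  inter_fg <- 4; union_fg <- 14
  inter_bg <- 64 - union_fg; union_bg <- 64 - inter_fg
  expect_equal(m$accuracy, 100 * (64 - 10) / 64)
  expect_equal(m$jaccard,
               100 * mean(c(inter_fg / union_fg, inter_bg / union_bg)))
  expect_equal(m$segment_match, 100)
  expect_equal(m$component_match, 100)  # one component each
  # symmetry
  m2 <- segmentation_metrics(truth, pred)
  expect_equal(m$jaccard, m2$jaccard)
  expect_equal(m$accuracy, m2$accuracy)
  # identity and disjoint cases
  mi <- segmentation_metrics(pred, pred)
  expect_equal(unlist(mi), c(accuracy = 100, jaccard = 100,
                             segment_match = 100, component_match = 100))
  q <- array(0L, c(8, 8, 1)); q[6:8, 6:8, 1] <- 1L
  md <- segmentation_metrics(label_volume(q, class_names = cn), truth)
  # disjoint foreground: J = 0 for that class
  expect_equal(md$jaccard, 100 * mean(c(0, (64 - 18) / (64 - 0))))
  expect_error(segmentation_metrics(pred,
                                    label_volume(array(0L, c(4, 4, 1)),
                                                 class_names = cn)),
               "shape mismatch")
})

test_that("surface extraction is watertight with voxel-accurate volume", {
  # single interior voxel: closed surface of roughly one voxel volume
  vox <- array(0L, c(5, 5, 5)); vox[3, 3, 3] <- 1L
  lv <- label_volume(vox, class_names = c(bg = 0L, fg = 1L))
  s1 <- extract_surface(lv, 1L)
  expect_true(attr(s1, "watertight"))
  expect_gt(mesh_volume(s1), 0.1)
  expect_lt(mesh_volume(s1), 1.5)
  # solid sphere mask, radius 10 voxels
  d <- c(25, 25, 25)
  co <- arrayInd(seq_len(prod(d)), d)
  r2 <- rowSums(sweep(co, 2, c(13, 13, 13))^2)
  vox2 <- array(as.integer(r2 <= 100), d)
  lv2 <- label_volume(vox2, class_names = c(bg = 0L, fg = 1L))
  s2 <- extract_surface(lv2, 1L)
  expect_true(attr(s2, "watertight"))
  expect_lt(abs(mesh_volume(s2) - 4 / 3 * pi * 1000) / (4 / 3 * pi * 1000),
            0.05)
  # empty region errors
  expect_error(extract_surface(lv, 5L), "empty region")
  # smoothing preserves watertightness
  s3 <- extract_surface(lv2, 1L, smoothing = 2)
  expect_true(is_watertight(s3))
})

test_that("voxelizing an extracted surface recovers the mask", {
  d <- c(20, 20, 20)
  co <- arrayInd(seq_len(prod(d)), d)
  r2 <- rowSums(sweep(co, 2, c(10.5, 10.5, 10.5))^2)
  vox <- array(as.integer(r2 <= 49), d)
  lv <- label_volume(vox, class_names = c(bg = 0L, fg = 1L))
  surf <- extract_surface(lv, 1L)
  centers <- (co - 1) * 1  # voxel centers: origin + (i-1) * spacing
  ins <- point_inside(surf, centers)
  overlap <- sum(ins & vox == 1L) / sum(vox == 1L)
  expect_gt(overlap, 0.95)
})
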