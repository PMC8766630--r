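test_that("phantom generators are seed-deterministic", {
  a <- make_labeled_head(dims = c(24, 24, 8), seed = 5)
  b <- make_labeled_head(dims = c(24, 24, 8), seed = 5)
  expect_identical(a$intensity, b$intensity)
  expect_identical(a$labels$voxels, b$labels$voxels)
  w1 <- make_4pr_waveform(0.4, noise = 0.1, seed = 3)
  w2 <- make_4pr_waveform(0.4, noise = 0.1, seed = 3)
  expect_identical(w1$cycle$delta_p, w2$cycle$delta_p)
  s1 <- make_two_passage_airway(resolution = 0.8)
  s2 <- make_two_passage_airway(resolution = 0.8)
  expect_identical(s1$vertices, s2$vertices)
})

test_that("duct phantom is watertight with exact volume and a
          self-consistent laminar reference", {
  d <- make_duct(width = 8, height = 12, length = 80)
  expect_true(attr(d, "watertight"))
  expect_equal(mesh_volume(d), 8 * 12 * 80)
  expect_setequal(levels(d$patch),
                  c("wall", "nostril_left", "pharynx"))
  expect_error(make_duct(width = 0), "degenerate")
  ana <- attr(d, "analytic")
  mu <- 1.9e-5
  G <- ana$G_for_flux(2.5e5, mu)
  # closed-form flux equals the prescribed flux
  expect_equal(ana$flux_of_G(G, mu), 2.5e5, tolerance = 1e-10)
  # numeric integration of the profile recovers the same flux
  xs <- seq(-4, 4, length.out = 101)
  ys <- seq(-6, 6, length.out = 151)
  u <- outer(xs, ys, function(x, y) ana$profile(x, y, G, mu))
  q_num <- sum(u) * diff(xs)[1] * diff(ys)[1]
  expect_equal(q_num, 2.5e5, tolerance = 1e-3)
  # no-slip at the walls
  expect_lt(max(abs(ana$profile(c(-4, 4), 0, G, mu))) / max(u), 1e-12)
})

test_that("two-passage airway phantom has the designed topology,
          symmetry, and asymmetry scaling", {
  aw <- make_two_passage_airway(resolution = 1.0)
  expect_true(attr(aw, "watertight"))
  expect_setequal(levels(aw$patch),
                  c("wall", "nostril_left", "nostril_right", "pharynx"))
  # Euler characteristic: two capped passages merging into one outlet
  # are simply connected (a "pair of pants" solid, genus 0):
  # chi = V - E + F = V - F/2 = 2
  chi <- nrow(aw$vertices) - nrow(aw$faces) / 2
  expect_equal(chi, 2)
  # left/right symmetry of the passage volumes via inside sampling
  set.seed(6)
  pts <- cbind(runif(4000, -12, 12), runif(4000, -6, 6), runif(4000, 0, 16))
  ins <- point_inside(aw, pts)
  vl <- sum(ins & pts[, 1] < 0); vr <- sum(ins & pts[, 1] > 0)
  expect_lt(abs(vl - vr) / vr, 0.1)
  # asymmetry halves the narrowed side's cross-section area
  aw5 <- make_two_passage_airway(asymmetry = 0.5, resolution = 1.2)
  grid_xy <- as.matrix(expand.grid(x = seq(-10, 10, by = 0.15),
                                   y = seq(-6, 6, by = 0.15)))
  at_z <- cbind(grid_xy, 8)
  ins5 <- point_inside(aw5, at_z)
  aL <- sum(ins5 & at_z[, 1] < 0); aR <- sum(ins5 & at_z[, 1] > 0)
  expect_equal(aL / aR, 0.5, tolerance = 0.12)
  # sinus pockets raise the genus and stay watertight
  aws <- make_two_passage_airway(sinus_radius = 2.5, resolution = 1.2)
  expect_true(attr(aws, "watertight"))
})

test_that("labeled head phantom is thresholdable at zero noise, severely
          imbalanced, and one-hot valid", {
  head <- make_labeled_head(dims = c(48, 48, 12), noise_sd = 0, seed = 9)
  # intensity thresholding at the air/tissue midpoint recovers air exactly
  air_ids <- 0:6
  air_true <- head$labels$voxels %in% air_ids
  thr <- ((head$hu[["tissue"]] - 1000) / 2 + 1000) / 2000  # air/tissue midpoint
  expect_identical(as.vector(head$intensity < thr), air_true)
  # sinus classes are a small minority (class imbalance regime)
  shares <- table(factor(head$labels$voxels, levels = 0:8)) /
    length(head$labels$voxels)
  expect_lt(sum(shares[as.character(0:4)]), 0.05)
  expect_gt(sum(shares[as.character(6:8)]), 0.85)
  # labels convert to a valid one-hot dataset
  ds <- slice_dataset(lapply(1:12, function(z) head$intensity[, , z]),
                      lapply(1:12, function(z) head$labels$voxels[, , z]),
                      n_classes = 9L)
  expect_equal(ds$N, 12L)
  # heavy noise degrades thresholding but intensities stay in [0, 1]
  noisy <- make_labeled_head(dims = c(48, 48, 12), noise_sd = 250, seed = 9)
  expect_true(all(noisy$intensity >= 0 & noisy$intensity <= 1))
  expect_gt(mean((noisy$intensity < thr) == air_true), 0.9)
  expect_lt(mean((noisy$intensity < thr) == air_true), 1)
})

test_that("synthetic waveforms encode the target resistance under both
          conventions and survive noise", {
  wf <- make_4pr_waveform(0.37, seed = 2)
  expect_equal(effective_resistance(wf$cycle), 0.37, tolerance = 1e-12)
  wfp <- make_4pr_waveform(0.37, convention = "printed", seed = 2)
  expect_equal(effective_resistance(wfp$cycle, "printed_integral"), 0.37,
               tolerance = 1e-3)
  # inspiration/expiration split carries the phases
  expect_true(all(wf$inspiration$vdot >= 0))
  expect_true(all(wf$expiration$vdot <= 0))
  # noisy recovery across seeds: small error and bias
  errs <- vapply(1:100, function(s)
    effective_resistance(make_4pr_waveform(0.4, noise = 0.05,
                                           seed = s)$cycle) / 0.4 - 1,
    numeric(1))
  expect_lt(max(abs(errs)), 0.02)
  expect_lt(abs(mean(errs)), 0.005)
  # classification of the recovered value matches the true class away
  # from the class boundaries
  bounds <- resistance_class_bounds("one")
  set.seed(77)
  for (r_true in c(0.05, 0.2, 0.9, 2.0, 4.0)) {
    lr_true <- log_effective_resistance(r_true)
    if (min(abs(lr_true - bounds)) < 0.05) next
    r_hat <- effective_resistance(
      make_4pr_waveform(r_true, noise = 0.05, seed = sample.int(1e4, 1))$cycle)
    expect_equal(classify_resistance(log_effective_resistance(r_hat))$class,
                 classify_resistance(lr_true)$class)
  }
})
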