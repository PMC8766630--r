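test_that("recordings validate and round-trip through CSV", {
  rec <- four_phase_recording(0:3, c(1, 2, 1, -1), c(10, 20, 10, -10))
  expect_equal(rec$T, 3)
  expect_error(four_phase_recording(c(0, 1, 1, 2), rep(1, 4), rep(1, 4)),
               "non-monotone time")
  expect_error(four_phase_recording(0:2, 1:3, 1:3), "at least 4")

  f <- tempfile(fileext = ".csv")
  wf <- make_4pr_waveform(0.42, seed = 11)
  write_recording(wf$cycle, f)
  back <- load_recording(f, side = "left")
  expect_equal(back$t, wf$cycle$t)
  expect_equal(back$delta_p, wf$cycle$delta_p)
  expect_equal(back$vdot, wf$cycle$vdot)
  expect_equal(back$T, wf$cycle$T)

  bad <- tempfile(fileext = ".csv")
  write.csv(data.frame(time_s = 0:3, delta_p_pa = 1:4), bad, row.names = FALSE)
  expect_error(load_recording(bad), "missing column")
})

test_that("effective resistance: constant-ratio and proportional waveforms", {
  t <- seq(0, 4, length.out = 200)
  vd <- 300 * sin(2 * pi * t / 4)
  rec <- four_phase_recording(t, 2 * vd, vd)
  expect_equal(effective_resistance(rec, "rms_ratio"), 2, tolerance = 1e-12)
  expect_equal(effective_resistance(rec, "printed_integral"), sqrt(2),
               tolerance = 1e-6)
  rec2 <- four_phase_recording(t, 3 * sin(2 * pi * t / 4),
                               1.5 * sin(2 * pi * t / 4))
  expect_equal(effective_resistance(rec2), 2, tolerance = 1e-12)
  # the two printed forms expose the definitional ambiguity: c vs sqrt(c)
  expect_equal(effective_resistance(rec, "printed_integral")^2,
               effective_resistance(rec, "rms_ratio"), tolerance = 1e-6)
})

test_that("effective resistance matches a dense Riemann-sum oracle", {
  T <- 4
  dp_fun <- function(t) 8 * sin(2 * pi * t / T) + 2 * sin(4 * pi * t / T + 0.7)
  vd_fun <- function(t) 300 * sin(2 * pi * t / T) + 40 * sin(6 * pi * t / T)
  t <- seq(0, T, length.out = 4096)
  rec <- four_phase_recording(t, dp_fun(t), vd_fun(t))
  oracle <- riemann_rms_ratio(dp_fun, vd_fun, T)
  expect_equal(effective_resistance(rec), oracle, tolerance = 1e-6)
})

test_that("effective resistance rejects degenerate recordings and is
          invariant under sign flip and re-sampling", {
  t <- seq(0, 4, length.out = 64)
  rec0 <- four_phase_recording(t, rep(0, 64), rep(0, 64))
  expect_error(effective_resistance(rec0), "degenerate")
  dp_fun <- function(t) 6 * sin(2 * pi * t / 4)
  vd_fun <- function(t) 250 * sin(2 * pi * t / 4)
  r1 <- effective_resistance(four_phase_recording(t, dp_fun(t), vd_fun(t)))
  r2 <- effective_resistance(four_phase_recording(t, -dp_fun(t), -vd_fun(t)))
  expect_equal(r1, r2)
  t2 <- seq(0, 4, length.out = 257)
  r3 <- effective_resistance(four_phase_recording(t2, dp_fun(t2), vd_fun(t2)))
  expect_equal(r1, r3, tolerance = 1e-4)
})

test_that("vertex resistance picks the peak of each phase", {
  t <- seq(0, 4, length.out = 200)
  vd <- 300 * sin(2 * pi * t / 4)
  rec <- four_phase_recording(t, 2 * vd, vd)
  expect_equal(vertex_resistance(rec, "inspiration"), 2)
  expect_equal(vertex_resistance(rec, "expiration"), 2)
  # triangular single peak: dp = 8 Pa at vdot = 200
  tt <- c(0, 1, 2, 3, 4)
  rec2 <- four_phase_recording(tt, c(0, 4, 8, 4, 0), c(0, 100, 200, 100, 0))
  expect_equal(vertex_resistance(rec2, "inspiration"), 0.04)
  expect_error(vertex_resistance(rec2, "expiration"), "absent")
  # asymmetric cycle vs explicit argmax scan
  set.seed(4)
  vd3 <- 250 * sin(2 * pi * t / 4) + 60 * sin(4 * pi * t / 4)
  dp3 <- 0.02 * vd3 * abs(vd3) / 100 + 0.5 * sin(2 * pi * t / 4)
  rec3 <- four_phase_recording(t, dp3, vd3)
  for (ph in c("inspiration", "expiration")) {
    sel <- if (ph == "inspiration") vd3 > 0 else vd3 < 0
    i <- which(sel)[which.max(abs(vd3[sel]))]
    expect_equal(vertex_resistance(rec3, ph), dp3[i] / vd3[i])
  }
})

test_that("log resistance transforms follow the base-10 convention", {
  expect_equal(log_effective_resistance(0.1), 0)
  expect_equal(log_effective_resistance(1), 1)
  expect_equal(log_effective_resistance(0.5689), log10(5.689))
  expect_error(log_effective_resistance(0), "positive")
  # equal sides combine like parallel resistors: 5r on the linear scale
  expect_equal(combined_log_resistance(0.2, 0.2), log10(10 * 0.1))
  expect_equal(combined_log_resistance(0.3, 0.7),
               log10(10 * 0.3 * 0.7 / (0.3 + 0.7)))
  # one side fully blocked: the combination tends to the open side
  expect_equal(combined_log_resistance(1e9, 0.4),
               log_effective_resistance(0.4), tolerance = 1e-8)
  # exact parallel identity: LR2(r, r) = LR1(r) - log10(2)
  expect_equal(combined_log_resistance(0.5, 0.5),
               log_effective_resistance(0.5) - log10(2))
})

test_that("resistance classification uses ordered bounds with
          lower-class tie-breaking and is monotone", {
  expect_equal(classify_resistance(0.5, "one")$class, 1L)
  expect_equal(classify_resistance(0.5, "one")$label, "very low")
  expect_equal(classify_resistance(1.40, "one")$class, 5L)
  expect_equal(classify_resistance(1.40, "one")$label, "very high")
  # 0.93 lies in the printed class-2/class-3 overlap; lower class wins
  expect_equal(classify_resistance(0.93, "one")$class, 2L)
  # boundary values belong to the lower class
  for (b in resistance_class_bounds("one"))
    expect_equal(classify_resistance(b, "one")$class,
                 classify_resistance(b - 1e-12, "one")$class)
  # monotone, total
  x <- seq(-1, 3, length.out = 400)
  cl <- classify_resistance(x, "one")$class
  expect_true(all(diff(cl) >= 0))
  expect_true(all(cl %in% 1:5))
  cl2 <- classify_resistance(x, "two")$class
  expect_true(all(diff(cl2) >= 0))
  expect_error(classify_resistance(NaN, "one"), "finite")
})

test_that("full analysis and JSON export work for two sides", {
  wl <- make_4pr_waveform(0.3, seed = 1)
  wr <- make_4pr_waveform(0.6, seed = 2)
  res <- analyze_4pr(left = wl$cycle, right = wr$cycle)
  expect_equal(res$left$r_eff, 0.3, tolerance = 1e-10)
  expect_equal(res$right$r_eff, 0.6, tolerance = 1e-10)
  expect_equal(res$combined$lr_eff_2,
               combined_log_resistance(0.3, 0.6), tolerance = 1e-10)
  f <- tempfile(fileext = ".json")
  write_resistance_json(res, f)
  parsed <- jsonlite::read_json(f, simplifyVector = TRUE)
  expect_equal(parsed$left$r_eff, 0.3, tolerance = 1e-8)
})

test_that("overlay table merges measurement loops and steady points", {
  wf <- make_4pr_waveform(0.35, seed = 3)
  tab0 <- overlay_data(wf$inspiration, wf$expiration)
  expect_equal(nrow(tab0),
               length(wf$inspiration$t) + length(wf$expiration$t))
  expect_true(all(tab0$source == "measurement"))
  sim <- data.frame(delta_p = c(-2, 2), vdot = c(-180, 190))
  tab <- overlay_data(wf$inspiration, wf$expiration, sim)
  expect_equal(nrow(tab), nrow(tab0) + 2)
  expect_equal(sum(tab$source == "simulation"), 2)
  expect_true(all(tab$sr[tab$source == "simulation"] == 0))
  expect_error(overlay_data(wf$inspiration, wf$expiration,
                            data.frame(delta_p = 1, vdot = 1, sr = 0.2)),
               "Strouhal")
})
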