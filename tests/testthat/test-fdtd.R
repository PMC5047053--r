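test_that("stable time step closed form and scaling", {
  expect_equal(stable_time_step(1e-5, 3669.76, 0.95),
               0.95 * 1e-5 / (3669.76 * sqrt(2)), tolerance = 1e-12)
  expect_equal(stable_time_step(1e-5, 3669.76, 0.95) * 1e9, 1.83,
               tolerance = 0.01)
  expect_equal(stable_time_step(sqrt(2), 1, 1), 1, tolerance = 1e-12)
  expect_equal(stable_time_step(0.5e-5, 3669.76, 0.95),
               stable_time_step(1e-5, 3669.76, 0.95) / 2, tolerance = 1e-12)
  expect_error(stable_time_step(0, 1500), "positive")
  expect_error(stable_time_step(1e-5, 1500, 0), "cfl")
})

test_that("source toneburst: support, normalization, spectral peak", {
  dt <- 1e-8
  w <- make_source_waveform(1e6, 3e-6, dt, n_total = 2000)
  t <- (seq_along(w) - 1) * dt
  expect_true(all(w[t > 3e-6] == 0))
  expect_equal(max(abs(w)), 1)
  # discrete spectrum peaks at 1 MHz within 5%
  sp <- Mod(stats::fft(w))[1:1000]
  fpk <- (which.max(sp) - 1) / (length(w) * dt)
  expect_lt(abs(fpk - 1e6) / 1e6, 0.05)
  expect_error(make_source_waveform(1e6, 3e-6, 2e-7), "coarse")
  expect_error(make_source_waveform(1e6, 0.5e-6, 1e-8), "period")
})

test_that("zero source amplitude gives identically zero records", {
  mats <- mk_material("soft", 1000, 1500, 3)
  g <- rasterize_model(layer_stack("soft", 2), dx = 0.1, width = 2,
                       gap_width = 0, materials = mats, source_mm = 1)
  run <- fdtd_run(g, source_spec(amplitude = 0), duration = 2e-6,
                  pml_cells = 10)
  expect_true(all(vapply(run$records, function(r) all(r$samples == 0),
                         logical(1))))
})

test_that("homogeneous first arrival matches d/c and improves on refinement", {
  d <- 3e-3; c0 <- 1500
  t_true <- d / c0
  errs <- sapply(c(0.05, 0.025), function(dx) {
    run <- homogeneous_run(dx = dx, depth_mm = 3)
    fas <- detect_fas(run$records$P, 0.05)
    src <- make_source_waveform(1e6, 3e-6, run$dt)
    fas_src <- detect_fas(waveform_record("s", run$dt, src), 0.05)
    c(raw = fas - t_true, corrected = fas - fas_src - t_true)
  })
  # raw onset within one source period (1 us) of the analytic travel time
  expect_true(all(abs(errs["raw", ]) < 1e-6))
  # source-onset-corrected error shrinks when dx is halved
  expect_lt(abs(errs["corrected", 2]), abs(errs["corrected", 1]))
  expect_lt(abs(errs["corrected", 1]), 0.1e-6)
})

test_that("interface reflection matches the plane-wave impedance ratio", {
  mats <- soft_hard_materials()     # Z: 1.5e6 vs 5.4e6
  stk <- layer_stack(c("soft", "hard"), c(8, 4))
  g <- rasterize_model(stk, dx = 0.05, width = 1, gap_width = 0,
                       materials = mats, source_mm = 1)
  rec <- data.frame(label = "P", row = as.integer(3 / 0.05) + 1L,
                    col = g$receivers$col[1])
  run <- fdtd_run(g, source_spec(aperture_mm = "full"), duration = 12e-6,
                  pml_cells = 20, receivers = rec)
  x <- run$records$P$samples; t <- run$time
  inc <- max(abs(x[t < 5e-6]))                      # direct pass, ~2-5 us
  ref <- max(abs(x[t > 6.7e-6 & t < 11.5e-6]))      # round trip, ~8.7 us
  R_theory <- (5.4e6 - 1.5e6) / (5.4e6 + 1.5e6)
  expect_lt(abs(ref / inc - R_theory) / R_theory, 0.03)
})

test_that("closed lossless run conserves discrete energy after source cutoff", {
  mats <- mk_material("soft", 1000, 1500, 3)
  g <- rasterize_model(layer_stack("soft", 4), dx = 0.05, width = 4,
                       gap_width = 0, materials = mats, source_mm = 2)
  run <- fdtd_run(g, source_spec(aperture_mm = 2), duration = 10e-6,
                  boundary = "reflecting", record_energy = TRUE)
  e <- run$energy
  post <- e$total[e$time > 3.5e-6]      # source off after 3 us
  expect_lt((max(post) - min(post)) / max(post), 0.005)
  expect_true(all(e$kinetic[e$time > 3.5e-6] >= 0))
})

test_that("source-receiver reciprocity in a heterogeneous lossless model", {
  mats <- soft_hard_materials()
  stk <- layer_stack(c("soft", "hard", "soft"), c(2, 0.5, 2))
  g <- rasterize_model(stk, dx = 0.05, width = 5, gap_width = 0,
                       materials = mats, source_mm = 2)
  A <- c(as.integer(1.0 / 0.05) + 1L, as.integer(1.5 / 0.05) + 1L)
  B <- c(as.integer(3.5 / 0.05) + 1L, as.integer(3.5 / 0.05) + 1L)
  rA <- data.frame(label = "X", row = A[1], col = A[2])
  rB <- data.frame(label = "X", row = B[1], col = B[2])
  ab <- fdtd_run(g, source_spec(), duration = 6e-6, source_row = A[1],
                 source_cols = A[2], receivers = rB)$records$X$samples
  ba <- fdtd_run(g, source_spec(), duration = 6e-6, source_row = B[1],
                 source_cols = B[2], receivers = rA)$records$X$samples
  expect_lt(sqrt(mean((ab - ba)^2)) / sqrt(mean(ab^2)), 0.01)
})

test_that("record length covers the requested duration for all receivers", {
  run <- homogeneous_run(dx = 0.05, duration = 3e-6)
  n_expect <- round(3e-6 / run$dt)
  expect_true(all(vapply(run$records, function(r) length(r$samples),
                         integer(1)) == n_expect))
})
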