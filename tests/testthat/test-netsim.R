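test_that("build_lattice produces the full lattice edge set and honours p_frag0", {
  g <- small_geom(20, 5)
  st <- build_lattice(g, sim_params(p_frag0 = 0))
  expect_equal(nrow(st$nodes), 100)
  expect_equal(nrow(st$edges), 19 * 5 + 20 * 4)  # longitudinal + transverse
  expect_true(all(st$present))
  expect_true(all(st$tracer == 0))
  expect_true(all(st$potential == 1))
  # edges join lattice neighbours only, no self edges or duplicates
  dr <- abs(st$nodes$row[st$edges$i] - st$nodes$row[st$edges$j])
  dc <- abs(st$nodes$col[st$edges$i] - st$nodes$col[st$edges$j])
  expect_true(all(dr + dc == 1))
  expect_false(any(duplicated(st$edges[, c("i", "j")])))

  st2 <- build_lattice(g, sim_params(p_frag0 = 1 - 1e-12))
  expect_equal(sum(st2$present), 0)
})

test_that("initial edge retention matches independent binomial sampling", {
  g <- fiber_geometry(n_long = 1000, n_trans = 6)  # 10994 candidate edges
  p0 <- 0.3
  set.seed(42)
  fr <- replicate(50, {
    st <- build_lattice(g, sim_params(p_frag0 = p0))
    mean(st$present)
  })
  n_edges <- 999 * 6 + 1000 * 5
  se <- sqrt(p0 * (1 - p0) / (n_edges * 50))
  expect_lt(abs(mean(fr) - (1 - p0)), 4 * se)
})

test_that("parameter validation names the offending field", {
  expect_error(sim_params(d_intra = -1), "d_intra")
  expect_error(sim_params(k_fus = NaN), "k_fus")
  expect_error(sim_params(p_frag0 = 1), "p_frag0")
  expect_error(sim_params(depol_at_aggregate = 2), "depol_at_aggregate")
  expect_error(fiber_geometry(pixel_size = 1.2), "pixel_size")
  expect_error(fiber_geometry(n_long = 4), "n_long")
})

test_that("photoactivate marks compartments with centers inside the ROI", {
  g <- fiber_geometry()  # 72 x 9, 2.2 um pitch
  st <- build_lattice(g, sim_params(p_frag0 = 0))
  # 10 x 10 um ROI centered on the fiber: 4 full sarcomere columns
  st1 <- photoactivate(st, c(74.2, 84.2, 0, 10))
  act_cols <- unique(st1$nodes$col[st1$tracer > 0])
  expect_length(act_cols, 4)
  # 4 columns x 5 rows with centers below y = 10
  expect_equal(sum(st1$tracer), 20)
  expect_equal(st1$time, 0)

  # zero-area ROI inside the fiber: nothing activated, no error
  st0 <- photoactivate(st, c(50, 50, 5, 5))
  expect_equal(sum(st0$tracer), 0)

  # ROI covering the whole fiber: everything activated
  stf <- photoactivate(st, c(0, 200, 0, 50))
  expect_true(all(stf$tracer == 1))

  expect_error(photoactivate(st, c(500, 510, 0, 10)), "outside")
})

test_that("evolve equilibrates connected compartments and leaves isolated ones", {
  p <- sim_params(d_intra = 1, k_fus = 0, k_fis = 0)
  st <- path_state(3, c(1, 0, 0), present = c(TRUE, FALSE))
  out <- evolve(st, p, 40)
  expect_equal(out$tracer[1:2], c(0.5, 0.5), tolerance = 1e-8)
  expect_equal(out$tracer[3], 0)  # disconnected: unchanged
  expect_equal(out$time, 40)
  expect_error(evolve(out, p, 10), "t_end")
})

test_that("tracer is conserved to 1e-9 across parameter regimes", {
  g <- small_geom(16, 4)
  set.seed(11)
  for (k in 1:6) {
    p <- sim_params(d_intra = runif(1, 0, 80), k_fus = runif(1, 0, 0.1),
                    k_fis = runif(1, 0, 0.1), p_frag0 = runif(1, 0, 0.8))
    st <- build_lattice(g, p)
    st <- photoactivate(st, c(10, 20, 0, 10))
    tot0 <- sum(st$tracer)
    out <- evolve(st, p, 25)
    expect_lt(abs(sum(out$tracer) - tot0), 1e-9 * tot0)
    expect_true(all(out$tracer >= 0))
    expect_identical(out$potential, st$potential)  # v untouched by evolve
  }
})

test_that("event-driven simulation matches the master-equation oracle on a 3-node path", {
  skip_if_not_installed("Matrix")
  d <- 1; k_fis <- 0.7; k_fus <- 0.5; p0 <- 0.5; t_end <- 1
  a0 <- c(1, 0, 0)
  oracle <- master_equation_mean(3, a0, d, k_fis, k_fus, t_end, p0)
  p <- sim_params(d_intra = d, k_fus = k_fus, k_fis = k_fis)
  nrep <- 10000
  set.seed(5)
  sims <- matrix(0, nrep, 3)
  for (r in seq_len(nrep)) {
    st <- path_state(3, a0, present = runif(2) >= p0)
    sims[r, ] <- evolve(st, p, t_end)$tracer
  }
  mc_mean <- colMeans(sims)
  mc_se <- apply(sims, 2, sd) / sqrt(nrep)
  expect_true(all(abs(mc_mean - oracle) <= 3 * mc_se))
})

test_that("trajectories are bit-identical for identical (preset, seed)", {
  a <- simulate_experiment("control", seed = 7,
                           geometry = small_geom(24, 5),
                           frame_times = c(2, 4, 6))
  b <- simulate_experiment("control", seed = 7,
                           geometry = small_geom(24, 5),
                           frame_times = c(2, 4, 6))
  expect_identical(a$frames, b$frames)
  expect_identical(a$truth$curve$steps, b$truth$curve$steps)
  c2 <- simulate_experiment("control", seed = 8,
                            geometry = small_geom(24, 5),
                            frame_times = c(2, 4, 6))
  expect_false(identical(a$frames, c2$frames))
})

test_that("render paints footprints, conserves zero fields, and honours blur/noise flags", {
  g <- small_geom(12, 4)
  st <- build_lattice(g, sim_params(p_frag0 = 0))
  op0 <- optics_params(blur_sigma = 0, read_sd = 0, offset = 0, gap_px = 0)

  # all-zero tracer, no aggregates: tracer channel identically zero
  im <- render(st, g, op0, noise = FALSE)
  expect_true(all(im$tracer == 0))
  expect_true(all(im$tmre[im$tmre > 0] > 0))

  # single active compartment, zero blur/noise: nonzero only in its footprint
  st$tracer[30] <- 1
  im <- render(st, g, op0, noise = FALSE)
  nd <- st$nodes[30, ]
  on <- which(im$tracer > 0, arr.ind = TRUE)
  px <- g$pixel_size; m <- op0$margin_px
  expect_true(all(on[, "col"] > m + (nd$col - 1) * 2.2 / px &
                  on[, "col"] <= m + nd$col * 2.2 / px))
  expect_true(all(on[, "row"] > m + (nd$row - 1) * 2.2 / px &
                  on[, "row"] <= m + nd$row * 2.2 / px))

  # rendering with a seed is reproducible and does not disturb the RNG stream
  set.seed(1); r1 <- render(st, g, optics_params(), seed = 3)
  x1 <- runif(1)
  set.seed(1); r2 <- render(st, g, optics_params(), seed = 3)
  x2 <- runif(1)
  expect_identical(r1, r2)
  expect_identical(x1, x2)
})

test_that("plateau SNR follows Poisson statistics", {
  g <- small_geom(12, 4)
  st <- build_lattice(g, sim_params(p_frag0 = 0))
  st$tracer <- rep(1, nrow(st$nodes))
  scale <- 400
  op <- optics_params(blur_sigma = 0, photon_scale = scale, read_sd = 2,
                      offset = 0, gap_px = 0)
  set.seed(21)
  stack <- replicate(20, render(st, g, op, noise = TRUE)$tracer[16, 30])
  # single-pixel SNR across repeated acquisitions
  snr_obs <- scale / sd(replicate(200, render(st, g, op, noise = TRUE)$tracer[16, 30]))
  expect_lt(abs(snr_obs - sqrt(scale)) / sqrt(scale), 0.10)
  expect_equal(mean(stack), scale, tolerance = 0.05)
})

test_that("aggregates are placed at the configured density with local depolarization", {
  g <- fiber_geometry()  # 158.4 um long
  set.seed(31)
  counts <- replicate(40, {
    st <- build_lattice(g, sim_params(aggregate_density = 2.5,
                                      depol_at_aggregate = 0.5))
    expect_true(all(st$potential[st$aggregate] == 0.5))
    expect_true(all(st$potential[!st$aggregate] == 1))
    sum(st$aggregate)
  })
  lambda <- 2.5 * 158.4 / 100
  expect_lt(abs(mean(counts) - lambda), 3 * sqrt(lambda / 40))
})

test_that("condition presets encode the stated relationships", {
  md <- condition_preset("mdivi1")$params
  g9 <- condition_preset("mtSOD1G93A")$params
  # mdivi1 differs from mtSOD1G93A only in k_fis
  expect_lt(md$k_fis, g9$k_fis)
  same <- setdiff(names(unclass(md)), "k_fis")
  expect_identical(unclass(md)[same], unclass(g9)[same])
  fc <- condition_preset("fccp")$params
  expect_equal(fc$global_depol, 0.19)
  expect_lt(fc$k_fus, condition_preset("mtSOD1")$params$k_fus)
  expect_error(condition_preset("nope"))
})

test_that("g93a migrates slower than control in ground truth (20 seeds)", {
  ctl <- vapply(1:20, function(i) truth_fit("control", 4000 + i)$rate_late, 1)
  g9 <- vapply(1:20, function(i) truth_fit("g93a", 4500 + i)$rate_late, 1)
  p <- t.test(g9, ctl, alternative = "less", var.equal = TRUE)$p.value
  expect_lt(p, 0.05)
})
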