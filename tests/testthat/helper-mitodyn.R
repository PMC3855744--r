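# shared fixtures, built in code

small_geom <- function(n_long = 20, n_trans = 5)
  fiber_geometry(n_long = n_long, n_trans = n_trans)

quiet_curve <- function(series, ...) suppressWarnings(migration_curve(series, ...))

# hand-made network state for tiny topologies (path graphs), bypassing the
# lattice constructor so oracle tests can run on <= 4 nodes
path_state <- function(n, a0, present = rep(TRUE, n - 1)) {
  structure(list(
    geometry = NULL,
    nodes = data.frame(id = seq_len(n), row = 1L, col = seq_len(n),
                       x = (seq_len(n) - 0.5) * 2.2, y = 1.1),
    edges = data.frame(i = seq_len(n - 1), j = 2:n, type = "long"),
    present = present, tracer = a0, potential = rep(1, n),
    aggregate = rep(FALSE, n), time = 0), class = "mito_network")
}

# brute-force master equation for the joint (edge configuration, tracer mean)
# process on a path of n nodes: states are the 2^(n-1) edge configurations;
# the first-moment vector M_k = E[a * 1{config = k}] obeys a linear ODE whose
# generator couples mixing (graph Laplacian per configuration) with the
# fission/fusion jump process. Solved with a matrix exponential.
master_equation_mean <- function(n, a0, d, k_fis, k_fus, t, p_frag0) {
  ne <- n - 1
  configs <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), ne)))
  nc <- nrow(configs)
  lap <- function(cfg) {
    L <- matrix(0, n, n)
    for (e in seq_len(ne)) if (cfg[e]) {
      i <- e; j <- e + 1
      L[i, i] <- L[i, i] - 1; L[i, j] <- L[i, j] + 1
      L[j, j] <- L[j, j] - 1; L[j, i] <- L[j, i] + 1
    }
    L
  }
  # generator A acting on stacked M (nc blocks of length n)
  A <- matrix(0, nc * n, nc * n)
  blk <- function(k) ((k - 1) * n + 1):(k * n)
  for (k in seq_len(nc)) {
    A[blk(k), blk(k)] <- d * lap(configs[k, ])
    for (e in seq_len(ne)) {
      k2 <- k + (if (configs[k, e]) -1 else 1) * 2^(e - 1)
      rate <- if (configs[k, e]) k_fis else k_fus
      A[blk(k2), blk(k)] <- A[blk(k2), blk(k)] + rate * diag(n)
      A[blk(k), blk(k)] <- A[blk(k), blk(k)] - rate * diag(n)
    }
  }
  M0 <- numeric(nc * n)
  for (k in seq_len(nc)) {
    pk <- prod(ifelse(configs[k, ], 1 - p_frag0, p_frag0))
    M0[blk(k)] <- pk * a0
  }
  Mt <- as.numeric(Matrix::expm(A * t) %*% M0)
  rowSums(matrix(Mt, n, nc))  # sum over configurations = E[a]
}

# synthetic image series from raw matrices
make_series <- function(frames_tracer, frames_tmre = frames_tracer,
                        times = seq_along(frames_tracer) * 2,
                        roi_px, fiber_px, geometry = small_geom()) {
  frames <- lapply(seq_along(frames_tracer), function(k)
    list(time = times[k], tracer = frames_tracer[[k]],
         tmre = frames_tmre[[k]]))
  mitodyn:::new_image_series(frames, times, roi_px, fiber_px, geometry,
                             optics_params())
}

truth_fit <- function(preset, seed, ...)
  fit_two_phase(simulate_experiment(preset, seed = seed,
                                    render = "truth_only", ...)$truth$curve)
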