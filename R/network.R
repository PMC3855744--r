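#' Build the initial mitochondrial lattice network
#'
#' Creates a compartment lattice from a [fiber_geometry()], joins all
#' lattice-adjacent compartments (longitudinal and transverse neighbours),
#' removes an independent fraction `p_frag0` of those edges, places protein
#' aggregates by Poisson sampling at `aggregate_density`, and sets membrane
#' potential to 1 reduced by `global_depol` everywhere and additionally by
#' `depol_at_aggregate` at aggregate compartments. Tracer starts at zero.
#'
#' @param geometry a [fiber_geometry()].
#' @param params a [sim_params()].
#' @return An object of class `mito_network` with fields `nodes`
#'   (data.frame: id, row, col, x, y in um), `edges` (data.frame: i, j, type),
#'   `present` (logical per candidate edge), `tracer`, `potential`,
#'   `aggregate` (per node), `time` (minutes since photoactivation) and
#'   `geometry`.
#' @export
build_lattice <- function(geometry, params) {
  stopifnot(inherits(geometry, "fiber_geometry"),
            inherits(params, "sim_params"))
  if (!is.null(params$seed)) set.seed(params$seed)

  mask <- geometry$fiber_mask
  nt <- geometry$n_trans; nl <- geometry$n_long
  idx <- matrix(NA_integer_, nt, nl)
  idx[mask] <- seq_len(sum(mask))
  rows <- row(mask)[mask]; cols <- col(mask)[mask]
  s <- geometry$sarcomere_length
  nodes <- data.frame(id = idx[mask], row = rows, col = cols,
                      x = (cols - 0.5) * s, y = (rows - 0.5) * s)
  nodes <- nodes[order(nodes$id), , drop = FALSE]

  # candidate edges: longitudinal then transverse, deterministic order
  el <- cbind(as.vector(idx[, -nl, drop = FALSE]),
              as.vector(idx[, -1, drop = FALSE]))
  el <- el[stats::complete.cases(el), , drop = FALSE]
  et <- cbind(as.vector(idx[-nt, , drop = FALSE]),
              as.vector(idx[-1, , drop = FALSE]))
  et <- et[stats::complete.cases(et), , drop = FALSE]
  edges <- data.frame(i = c(el[, 1], et[, 1]), j = c(el[, 2], et[, 2]),
                      type = rep(c("long", "trans"),
                                 c(nrow(el), nrow(et))))
  o <- order(edges$i, edges$j)
  edges <- edges[o, , drop = FALSE]
  rownames(edges) <- NULL

  p0 <- effective_p_frag0(params)
  present <- runif(nrow(edges)) >= p0

  n <- nrow(nodes)
  potential <- rep(1 - params$global_depol, n)
  aggregate <- rep(FALSE, n)
  if (params$aggregate_density > 0) {
    n_agg <- rpois(1, params$aggregate_density * fiber_length_um(geometry) / 100)
    n_agg <- min(n_agg, n)
    if (n_agg > 0) {
      aggregate[sample.int(n, n_agg)] <- TRUE
      potential[aggregate] <- potential[aggregate] * (1 - params$depol_at_aggregate)
    }
  }

  structure(list(geometry = geometry, nodes = nodes, edges = edges,
                 present = present, tracer = rep(0, n),
                 potential = potential, aggregate = aggregate, time = 0),
            class = "mito_network")
}

#' @export
print.mito_network <- function(x, ...) {
  cat(sprintf(paste0("<mito_network> %d compartments, %d/%d edges present, ",
                     "%d aggregates, sum(tracer)=%.3f, t=%.2f min\n"),
              nrow(x$nodes), sum(x$present), nrow(x$edges),
              sum(x$aggregate), sum(x$tracer), x$time))
  invisible(x)
}

#' Photoactivate a rectangular region
#'
#' Sets tracer to 1 in every compartment whose center lies inside the region
#' of interest and resets the clock to zero (time is counted in minutes since
#' photoactivation).
#'
#' @param state a `mito_network`.
#' @param roi numeric `c(x0, x1, y0, y1)` in um (fiber coordinates; the fiber
#'   spans `[0, n_long * sarcomere_length] x [0, n_trans * sarcomere_length]`).
#' @return The updated `mito_network`.
#' @export
photoactivate <- function(state, roi) {
  stopifnot(inherits(state, "mito_network"))
  roi <- as_roi(roi)
  g <- state$geometry
  if (roi[2] < 0 || roi[1] > fiber_length_um(g) ||
      roi[4] < 0 || roi[3] > fiber_width_um(g))
    stop("photoactivation roi lies outside the fiber", call. = FALSE)
  inside <- state$nodes$x >= roi[1] & state$nodes$x <= roi[2] &
            state$nodes$y >= roi[3] & state$nodes$y <= roi[4]
  state$tracer <- as.numeric(inside)
  state$time <- 0
  state
}

as_roi <- function(roi) {
  if (is.list(roi)) roi <- unlist(roi[c("x0", "x1", "y0", "y1")])
  if (!is.numeric(roi) || length(roi) != 4L || any(!is.finite(roi)))
    stop("roi must be numeric c(x0, x1, y0, y1) in um", call. = FALSE)
  if (roi[1] > roi[2] || roi[3] > roi[4])
    stop("roi must satisfy x0 <= x1 and y0 <= y1", call. = FALSE)
  unname(roi)
}

#' Evolve the network by stochastic fission/fusion plus tracer mixing
#'
#' Advances the state to `t_end` by an exact event-driven scheme: edge
#' fission/fusion events occur as a continuous-time Markov process (each
#' present edge is cut at rate `k_fis`, each absent lattice-neighbour pair
#' joins at rate `k_fus`), and between events the tracer mixes
#' deterministically between connected neighbours,
#' `da_i/dt = d_intra * sum_j (a_j - a_i)`. Total tracer is conserved;
#' membrane potential is unchanged.
#'
#' @param state a `mito_network`.
#' @param params a [sim_params()].
#' @param t_end target time in minutes; must exceed `state$time`.
#' @return The updated `mito_network` at `time = t_end`.
#' @export
evolve <- function(state, params, t_end) {
  stopifnot(inherits(state, "mito_network"), inherits(params, "sim_params"))
  if (!is.numeric(t_end) || length(t_end) != 1L || !is.finite(t_end) ||
      t_end <= state$time)
    stop("'t_end' must be a finite time later than state$time", call. = FALSE)

  a0 <- state$tracer
  # RK4 stability limit is dt < 2.78 / (2 * d_intra * max_degree) ~= 0.35 / d;
  # 0.08 / d keeps a 4x margin and phase error far below the front resolution
  dt_max <- if (params$d_intra > 0) 0.08 / params$d_intra else Inf
  res <- evolve_cpp(as.integer(state$edges$i) - 1L,
                    as.integer(state$edges$j) - 1L,
                    state$present, a0, nrow(state$nodes),
                    params$d_intra, params$k_fis, params$k_fus,
                    t_end - state$time, dt_max)
  a <- res$tracer
  tot0 <- sum(a0)
  if (tot0 > 0 && abs(sum(a) - tot0) > 1e-9 * tot0)
    stop("tracer conservation violated beyond 1e-9 relative tolerance",
         call. = FALSE)
  a[a < 0] <- 0  # clamp round-off (magnitude already checked in C++)
  state$present <- res$present
  state$tracer <- a
  state$time <- t_end
  state
}

#' Connected components of the current network
#'
#' @param state a `mito_network`.
#' @return Integer vector of component membership per node.
#' @export
network_components <- function(state) {
  g <- igraph::graph_from_edgelist(
    as.matrix(state$edges[state$present, c("i", "j")]), directed = FALSE)
  g <- igraph::add_vertices(g, max(0, nrow(state$nodes) - igraph::vcount(g)))
  igraph::components(g)$membership
}
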