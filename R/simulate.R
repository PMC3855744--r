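# coordinate helpers shared by the simulator and the quantification side

# pixel column/row range (with margin offset) whose pixel centers fall inside
# a um interval [u0, u1]
um_to_px_range <- function(u0, u1, px, margin) {
  lo <- ceiling(margin + u0 / px + 0.5 - 1e-9)
  hi <- floor(margin + u1 / px + 0.5 - 1e-9)
  c(lo, hi)
}

roi_to_px <- function(roi, geometry, margin) {
  px <- geometry$pixel_size
  xs <- um_to_px_range(max(roi[1], 0), min(roi[2], fiber_length_um(geometry)),
                       px, margin)
  ys <- um_to_px_range(max(roi[3], 0), min(roi[4], fiber_width_um(geometry)),
                       px, margin)
  c(x0 = xs[1], x1 = xs[2], y0 = ys[1], y1 = ys[2])
}

fiber_px_bbox <- function(geometry, margin) {
  dims <- canvas_dims(geometry)
  c(x0 = margin + 1L, x1 = margin + as.integer(dims["w"]),
    y0 = margin + 1L, y1 = margin + as.integer(dims["h"]))
}

default_roi <- function(geometry, width_um = 10) {
  cx <- fiber_length_um(geometry) / 2
  c(cx - width_um / 2, cx + width_um / 2, 0, fiber_width_um(geometry))
}

new_image_series <- function(frames, times, roi_px, fiber_px, geometry,
                             optics, preset = NA_character_, seed = NA,
                             truth = NULL) {
  stopifnot(length(frames) == length(times))
  if (is.unsorted(times, strictly = TRUE))
    stop("frame times must be strictly increasing", call. = FALSE)
  structure(list(frames = frames, times = times, roi_px = roi_px,
                 fiber_px = fiber_px, geometry = geometry, optics = optics,
                 preset = preset, seed = seed, truth = truth),
            class = "image_series")
}

#' @export
print.image_series <- function(x, ...) {
  cat(sprintf("<image_series> %d frames (t = %s min), preset=%s, seed=%s\n",
              length(x$frames), paste(x$times, collapse = ","),
              x$preset, x$seed))
  invisible(x)
}

#' Simulate a photoactivation experiment
#'
#' Builds a fiber network for the given condition preset, photoactivates a
#' region of interest (default: a 10-um-long band spanning the fiber width,
#' centered along the fiber), evolves the network under stochastic
#' fission/fusion with tracer mixing, and renders two-channel frames at the
#' requested times. Frame times follow the experimental protocol: the first
#' frame is at 2 min after photoactivation (the time needed to reconfigure
#' the microscope) and frames continue through 20 min.
#'
#' The returned series carries ground truth: the migration curve computed
#' from the noise-free tracer field (no PSF, no noise, no puncta), the
#' parameters used, the initial absent-edge fraction, and the true aggregate
#' count.
#'
#' @param preset a [condition_preset()] or a preset name.
#' @param geometry a [fiber_geometry()].
#' @param frame_times acquisition times in minutes, strictly increasing
#'   (default `seq(2, 20, by = 2)`).
#' @param seed integer seed; the whole series is reproducible from
#'   (preset, geometry, frame_times, seed).
#' @param optics an [optics_params()].
#' @param roi photoactivation rectangle `c(x0, x1, y0, y1)` in um.
#' @param threshold_frac front threshold used for the ground-truth curve.
#' @param render one of `"full"` (render noisy frames) or `"truth_only"`
#'   (skip rendering; `frames` empty, ground truth still computed). The two
#'   modes consume different RNG streams, so trajectories are reproducible
#'   per (mode, seed).
#' @return An `image_series`.
#' @export
simulate_experiment <- function(preset, geometry = fiber_geometry(),
                                frame_times = seq(2, 20, by = 2), seed = 1,
                                optics = optics_params(), roi = NULL,
                                threshold_frac = 0.1,
                                render = c("full", "truth_only")) {
  if (is.character(preset)) preset <- condition_preset(preset)
  stopifnot(inherits(preset, "condition_preset"))
  render <- match.arg(render)
  if (length(frame_times) < 1 || is.unsorted(frame_times, strictly = TRUE))
    stop("'frame_times' must be strictly increasing", call. = FALSE)
  if (frame_times[1] <= 0)
    stop("'frame_times' must start after photoactivation (t > 0)",
         call. = FALSE)
  if (frame_times[1] < 2)
    warning("first frame before 2 min: earlier than the published protocol")
  set.seed(seed)

  params <- preset$params
  params$seed <- NULL  # the experiment seed governs everything
  state <- build_lattice(geometry, params)
  if (is.null(roi)) roi <- default_roi(geometry)
  state <- photoactivate(state, roi)

  margin <- optics$margin_px
  roi_px <- roi_to_px(roi, geometry, margin)
  fiber_px <- fiber_px_bbox(geometry, margin)

  frames <- vector("list", length(frame_times))
  truth_frames <- vector("list", length(frame_times))
  for (k in seq_along(frame_times)) {
    state <- evolve(state, params, frame_times[k])
    truth_frames[[k]] <- list(
      time = frame_times[k],
      tracer = add_margin(paint_field(state$tracer, state, geometry), margin),
      tmre = add_margin(paint_field(state$potential, state, geometry), margin))
    if (render == "full") {
      imgs <- render(state, geometry, optics, noise = TRUE)
      frames[[k]] <- list(time = frame_times[k], tracer = imgs$tracer,
                          tmre = imgs$tmre)
    }
  }

  truth_series <- new_image_series(truth_frames, frame_times, roi_px,
                                   fiber_px, geometry, optics,
                                   preset = preset$name, seed = seed)
  truth_curve <- if (length(frame_times) >= 2) suppressWarnings(
    migration_curve(truth_series, threshold_frac = threshold_frac,
                    mask_aggregates = FALSE)) else NULL
  truth <- list(curve = truth_curve, params = params,
                p_frag0 = effective_p_frag0(params),
                n_aggregates = sum(state$aggregate),
                final_state = state)

  if (render == "truth_only") frames <- truth_frames
  new_image_series(frames, frame_times, roi_px, fiber_px, geometry, optics,
                   preset = preset$name, seed = seed, truth = truth)
}
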