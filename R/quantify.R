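#' Estimate the background level of a frame
#'
#' Uses the median intensity of the declared background region: all pixels
#' outside the fiber bounding box (the rendered margin).
#'
#' @param frame image matrix.
#' @param series the `image_series` the frame belongs to (provides the fiber
#'   bounding box).
#' @return Scalar background level.
#' @export
estimate_background <- function(frame, series) {
  if (!is.matrix(frame)) stop("'frame' must be a matrix", call. = FALSE)
  if (anyNA(frame)) stop("frame contains NA/NaN pixels", call. = FALSE)
  f <- series$fiber_px
  inside <- matrix(FALSE, nrow(frame), ncol(frame))
  rs <- max(f["y0"], 1):min(f["y1"], nrow(frame))
  cs <- max(f["x0"], 1):min(f["x1"], ncol(frame))
  inside[rs, cs] <- TRUE
  bg <- frame[!inside]
  if (!length(bg)) stop("background region empty", call. = FALSE)
  median(bg)
}

direction_names <- function() c("long+", "long-", "trans+", "trans-")

# centered running median with shrinking windows at the ends; suppresses
# isolated noise excursions without displacing step edges
running_median <- function(x, w) {
  if (w <= 1 || length(x) < 2) return(x)
  h <- w %/% 2
  vapply(seq_along(x), function(i) {
    median(x[max(1, i - h):min(length(x), i + h)])
  }, numeric(1))
}

# band/axis bookkeeping for one direction; returns NULL if the ROI is flush
# with the fiber border in that direction
direction_axis <- function(series, direction) {
  r <- series$roi_px; f <- series$fiber_px
  switch(direction,
    "long+" = if (r["x1"] < f["x1"])
      list(cols = (r["x1"] + 1):f["x1"], band = r["y0"]:r["y1"],
           along = "x", edge = r["x1"]),
    "long-" = if (r["x0"] > f["x0"])
      list(cols = (r["x0"] - 1):f["x0"], band = r["y0"]:r["y1"],
           along = "x", edge = r["x0"]),
    "trans+" = if (r["y1"] < f["y1"])
      list(cols = (r["y1"] + 1):f["y1"], band = r["x0"]:r["x1"],
           along = "y", edge = r["y1"]),
    "trans-" = if (r["y0"] > f["y0"])
      list(cols = (r["y0"] - 1):f["y0"], band = r["x0"]:r["x1"],
           along = "y", edge = r["y0"]),
    stop("unknown direction: ", direction, call. = FALSE)
  )
}

#' Directional intensity profiles away from the photoactivation ROI
#'
#' For every frame, averages background-subtracted tracer intensity over the
#' band of pixels spanning the ROI, as a function of outward distance from
#' the ROI edge, normalized to the same-frame ROI plateau intensity.
#'
#' @param series an `image_series`.
#' @param direction one of `"long+"`, `"long-"`, `"trans+"`, `"trans-"`.
#' @param mask optional logical matrix of pixels to exclude (e.g. aggregate
#'   footprints, which the published protocol avoided).
#' @param smooth_px width of the running-median filter applied along the
#'   distance axis to suppress single-pixel noise excursions before
#'   thresholding; default `NULL` uses one sarcomere (rounded up to odd).
#'   Use 0 for no smoothing.
#' @return List of `directional_profile` objects (fields `direction`,
#'   `distance` (um, strictly increasing), `intensity` (normalized, clipped
#'   at 0), `time`), or `NULL` with a warning when the ROI is flush with the
#'   fiber border in that direction.
#' @export
profile_along <- function(series, direction, mask = NULL, smooth_px = NULL) {
  stopifnot(inherits(series, "image_series"))
  if (is.null(smooth_px)) {
    smooth_px <- round(series$geometry$sarcomere_length /
                         series$geometry$pixel_size)
    if (smooth_px %% 2 == 0) smooth_px <- smooth_px + 1
  }
  ax <- direction_axis(series, direction)
  if (is.null(ax)) {
    warning("ROI flush with fiber border in direction ", direction,
            "; direction dropped", call. = FALSE)
    return(NULL)
  }
  px <- series$geometry$pixel_size
  r <- series$roi_px
  lapply(series$frames, function(fr) {
    img <- fr$tracer
    bg <- estimate_background(img, series)
    sub <- pmax(img - bg, 0)
    keep <- if (is.null(mask)) NULL else !mask
    roi_block <- sub[r["y0"]:r["y1"], r["x0"]:r["x1"], drop = FALSE]
    if (!is.null(keep)) {
      kb <- keep[r["y0"]:r["y1"], r["x0"]:r["x1"], drop = FALSE]
      plateau <- if (any(kb)) mean(roi_block[kb]) else mean(roi_block)
    } else plateau <- mean(roi_block)
    vals <- vapply(ax$cols, function(k) {
      v <- if (ax$along == "x") sub[ax$band, k] else sub[k, ax$band]
      if (!is.null(keep)) {
        kk <- if (ax$along == "x") keep[ax$band, k] else keep[k, ax$band]
        if (any(kk)) v <- v[kk]
      }
      mean(v)
    }, numeric(1))
    dist_um <- (abs(ax$cols - ax$edge) - 0.5) * px
    vals <- running_median(vals, smooth_px)
    intensity <- if (plateau > 0) vals / plateau else rep(0, length(vals))
    structure(list(direction = direction, distance = dist_um,
                   intensity = pmax(intensity, 0), time = fr$time),
              class = "directional_profile")
  })
}

#' Front distance of a directional profile
#'
#' Largest outward distance at which the normalized intensity still reaches
#' `threshold_frac`, with linear interpolation between samples; 0 when the
#' profile never reaches the threshold.
#'
#' @param profile a `directional_profile` (or any list with `distance` and
#'   `intensity`).
#' @param threshold_frac fraction of the ROI plateau, in (0, 1);
#'   default 0.10.
#' @return Front distance in um.
#' @export
front_distance <- function(profile, threshold_frac = 0.1) {
  check_scalar(threshold_frac, "threshold_frac", min = 0, max = 1)
  if (threshold_frac <= 0 || threshold_frac >= 1)
    stop("'threshold_frac' must be in (0, 1)", call. = FALSE)
  d <- profile$distance; I <- profile$intensity
  if (length(d) != length(I) || length(d) == 0)
    stop("profile must have matching distance/intensity vectors",
         call. = FALSE)
  idx <- which(I >= threshold_frac)
  if (!length(idx)) return(0)
  k <- max(idx)
  if (k == length(d)) return(d[k])
  # interpolate to the crossing with the next (sub-threshold) sample
  d[k] + (I[k] - threshold_frac) / (I[k] - I[k + 1]) * (d[k + 1] - d[k])
}

#' Migration curve in m-steps
#'
#' Converts the tracer front positions of an image series into the migration
#' statistic of the assay: per frame and direction, the front distance
#' divided by the sarcomere length (2.2 um = 1 m-step), with a running
#' maximum per direction (a cumulative migration front cannot retreat; this
#' guards against noise), aggregated as the arithmetic mean of the available
#' directions.
#'
#' @param series an `image_series`.
#' @param threshold_frac front threshold, fraction of ROI plateau.
#' @param directions directions to evaluate; flush directions are dropped
#'   with a warning.
#' @param mask_aggregates detect aggregate puncta on the first frame and
#'   exclude their (dilated) footprints from the band averages, mirroring the
#'   published protocol of avoiding aggregate-bearing regions.
#' @return A `migration_curve`: fields `times`, `steps_by_direction`
#'   (matrix, one column per retained direction), `steps` (mean across
#'   directions), `msteps_unit` (um per m-step).
#' @export
migration_curve <- function(series, threshold_frac = 0.1,
                            directions = direction_names(),
                            mask_aggregates = TRUE) {
  stopifnot(inherits(series, "image_series"))
  if (length(series$frames) < 2)
    stop("migration curve needs at least 2 frames", call. = FALSE)
  mask <- NULL
  if (mask_aggregates) {
    fr1 <- series$frames[[1]]
    bg <- estimate_background(fr1$tracer, series)
    sub1 <- pmax(fr1$tracer - bg, 0)
    r <- series$roi_px
    body1 <- quantile(sub1[r["y0"]:r["y1"], r["x0"]:r["x1"]], 0.95,
                      names = FALSE)
    outside_roi <- matrix(TRUE, nrow(sub1), ncol(sub1))
    outside_roi[max(1, r["y0"] - 6):min(nrow(sub1), r["y1"] + 6),
                max(1, r["x0"] - 6):min(ncol(sub1), r["x1"] + 6)] <- FALSE
    aggs <- detect_aggregates(sub1, region = outside_roi,
                              min_intensity = 1.8 * body1)
    if (length(aggs)) mask <- aggregate_mask(aggs, dim(fr1$tracer), grow = 2)
  }
  unit <- series$geometry$sarcomere_length
  cols <- list()
  for (dir in directions) {
    profs <- profile_along(series, dir, mask = mask)
    if (is.null(profs)) next
    fronts <- vapply(profs, front_distance, numeric(1),
                     threshold_frac = threshold_frac)
    cols[[dir]] <- cummax(fronts) / unit
  }
  if (!length(cols))
    stop("all requested directions were dropped", call. = FALSE)
  steps_dir <- do.call(cbind, cols)
  structure(list(times = series$times, steps_by_direction = steps_dir,
                 steps = rowMeans(steps_dir), msteps_unit = unit,
                 threshold_frac = threshold_frac),
            class = "migration_curve")
}

#' @export
print.migration_curve <- function(x, ...) {
  cat("<migration_curve> m-steps (mean of",
      paste(colnames(x$steps_by_direction), collapse = ", "), ")\n")
  print(data.frame(time_min = x$times, steps = round(x$steps, 3)))
  invisible(x)
}

#' @export
as.data.frame.migration_curve <- function(x, ...) {
  dirs <- colnames(x$steps_by_direction)
  long <- do.call(rbind, lapply(dirs, function(d) {
    data.frame(time_min = x$times, dir = d,
               steps = x$steps_by_direction[, d])
  }))
  long$steps_mean <- rep(x$steps, length(dirs))
  rownames(long) <- NULL
  long
}
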