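#' Write an image series to a directory
#'
#' Persists each channel of each frame as a TSV matrix of pixel values plus a
#' JSON sidecar (`series.json`) with acquisition times, ROI and fiber
#' bounding boxes in pixels, pixel size, preset name, seed, and (when
#' present) the ground-truth migration curve and simulation parameters.
#' Values round-trip bit-identically through [read_series()].
#'
#' @param series an `image_series`.
#' @param path output directory (created if missing).
#' @return `path`, invisibly.
#' @export
write_series <- function(series, path) {
  stopifnot(inherits(series, "image_series"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  files <- data.frame(
    time_min = series$times,
    tracer = sprintf("frame%03d_tracer.tsv", seq_along(series$times)),
    tmre = sprintf("frame%03d_tmre.tsv", seq_along(series$times)))
  write_mat <- function(m, f) {
    # %.17g guarantees doubles survive the text round-trip bit-identically
    writeLines(apply(m, 1, function(r)
      paste(sprintf("%.17g", r), collapse = "\t")), f)
  }
  for (k in seq_along(series$frames)) {
    fr <- series$frames[[k]]
    write_mat(fr$tracer, file.path(path, files$tracer[k]))
    write_mat(fr$tmre, file.path(path, files$tmre[k]))
  }
  g <- series$geometry
  sidecar <- list(
    format = "mitodyn-series", version = as.character(packageVersion("mitodyn")),
    preset = series$preset, seed = series$seed,
    pixel_size = g$pixel_size, sarcomere_length = g$sarcomere_length,
    n_long = g$n_long, n_trans = g$n_trans,
    roi_px = as.list(series$roi_px), fiber_px = as.list(series$fiber_px),
    frames = files)
  if (!is.null(series$truth)) {
    sidecar$truth <- list(
      curve = data.frame(time_min = series$truth$curve$times,
                         steps = series$truth$curve$steps),
      p_frag0 = series$truth$p_frag0,
      n_aggregates = series$truth$n_aggregates,
      params = unclass(series$truth$params)[
        c("d_intra", "k_fus", "k_fis", "aggregate_density",
          "depol_at_aggregate", "global_depol")])
  }
  jsonlite::write_json(sidecar, file.path(path, "series.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(path)
}

#' Read an image series from a directory
#'
#' Counterpart of [write_series()]. Frames are re-sorted by timestamp if they
#' are listed out of order; duplicate timestamps, a missing sidecar, missing
#' channel files or an ROI outside the image are errors.
#'
#' @param path directory produced by [write_series()] (or real data arranged
#'   the same way).
#' @return An `image_series` (with a `truth` field when the sidecar carries
#'   ground truth).
#' @export
read_series <- function(path) {
  sc_file <- file.path(path, "series.json")
  if (!file.exists(sc_file))
    stop("sidecar series.json not found in ", path, call. = FALSE)
  sc <- jsonlite::read_json(sc_file, simplifyVector = TRUE)
  fr_tab <- sc$frames
  if (is.null(fr_tab$time_min) || is.null(fr_tab$tracer) ||
      is.null(fr_tab$tmre))
    stop("sidecar must list two channels (tracer, tmre) per frame",
         call. = FALSE)
  if (anyDuplicated(fr_tab$time_min))
    stop("non-monotone timestamps: duplicate frame times in sidecar",
         call. = FALSE)
  fr_tab <- fr_tab[order(fr_tab$time_min), , drop = FALSE]

  read_mat <- function(f) {
    fp <- file.path(path, f)
    if (!file.exists(fp)) stop("missing channel file ", f, call. = FALSE)
    as.matrix(data.table::fread(fp, sep = "\t", header = FALSE))
  }
  frames <- lapply(seq_len(nrow(fr_tab)), function(k) {
    tr <- unname(read_mat(fr_tab$tracer[k]))
    tm <- unname(read_mat(fr_tab$tmre[k]))
    if (!identical(dim(tr), dim(tm)))
      stop("channel dimensions differ in frame ", k, call. = FALSE)
    list(time = fr_tab$time_min[k], tracer = tr, tmre = tm)
  })

  geometry <- fiber_geometry(n_long = sc$n_long, n_trans = sc$n_trans,
                             sarcomere_length = sc$sarcomere_length,
                             pixel_size = sc$pixel_size)
  roi_px <- unlist(sc$roi_px)[c("x0", "x1", "y0", "y1")]
  fiber_px <- unlist(sc$fiber_px)[c("x0", "x1", "y0", "y1")]
  dims <- dim(frames[[1]]$tracer)
  if (roi_px["x0"] < 1 || roi_px["y0"] < 1 ||
      roi_px["x1"] > dims[2] || roi_px["y1"] > dims[1])
    stop("sidecar ROI lies outside the image", call. = FALSE)

  truth <- NULL
  if (!is.null(sc$truth)) {
    cv <- sc$truth$curve
    truth <- list(
      curve = structure(list(times = cv$time_min,
                             steps_by_direction = matrix(cv$steps,
                                                         dimnames = list(NULL, "stored")),
                             steps = cv$steps,
                             msteps_unit = sc$sarcomere_length),
                        class = "migration_curve"),
      p_frag0 = sc$truth$p_frag0, n_aggregates = sc$truth$n_aggregates,
      params = sc$truth$params)
  }
  new_image_series(frames, fr_tab$time_min, roi_px, fiber_px, geometry,
                   optics_params(), preset = sc$preset %||% NA_character_,
                   seed = sc$seed %||% NA, truth = truth)
}

#' Write a migration curve as CSV
#'
#' Columns `time_min`, `dir`, `steps`, `steps_mean`.
#'
#' @param curve a [migration_curve()].
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_migration_csv <- function(curve, file) {
  stopifnot(inherits(curve, "migration_curve"))
  data.table::fwrite(as.data.frame(curve), file)
  invisible(file)
}

#' Read a migration curve CSV
#'
#' @param file path written by [write_migration_csv()].
#' @return A `migration_curve`.
#' @export
read_migration_csv <- function(file) {
  df <- as.data.frame(data.table::fread(file))
  dirs <- unique(df$dir)
  times <- sort(unique(df$time_min))
  m <- sapply(dirs, function(d) {
    sub <- df[df$dir == d, ]
    sub$steps[order(sub$time_min)]
  })
  if (is.null(dim(m))) m <- matrix(m, ncol = length(dirs),
                                   dimnames = list(NULL, dirs))
  structure(list(times = times, steps_by_direction = m,
                 steps = rowMeans(m), msteps_unit = 2.2),
            class = "migration_curve")
}
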