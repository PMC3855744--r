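#' Optical parameters for confocal-like rendering
#'
#' @param blur_sigma Gaussian PSF sigma in um (default 0.25, a typical
#'   confocal lateral PSF width).
#' @param photon_scale expected photon count per pixel at unit brightness;
#'   Poisson shot noise is applied at this scale.
#' @param read_sd additive Gaussian read-noise standard deviation, counts.
#' @param offset detector baseline added to every pixel, counts. A nonzero
#'   baseline keeps pixel values non-negative while letting median background
#'   subtraction recenter the read noise at zero.
#' @param margin_px background margin rendered around the fiber, pixels.
#' @param gap_px width of the unstained gap between compartments, pixels;
#'   present edges are bridged across the gap so connected components of the
#'   TMRE image follow the network topology.
#' @param punctum_mult brightness multiplier of aggregate puncta in the
#'   tracer channel (>= 3).
#' @param punctum_px linear size of the rendered punctum, pixels.
#' @return A list of class `optics_params`.
#' @export
optics_params <- function(blur_sigma = 0.25, photon_scale = 500, read_sd = 2,
                          offset = 10, margin_px = 8, gap_px = 1,
                          punctum_mult = 3, punctum_px = 2) {
  check_scalar(blur_sigma, "blur_sigma", min = 0)
  check_scalar(photon_scale, "photon_scale", min = 0, strict_min = TRUE)
  check_scalar(read_sd, "read_sd", min = 0)
  check_scalar(offset, "offset", min = 0)
  check_scalar(margin_px, "margin_px", min = 0)
  check_scalar(gap_px, "gap_px", min = 0)
  check_scalar(punctum_mult, "punctum_mult", min = 0)
  check_scalar(punctum_px, "punctum_px", min = 1)
  structure(list(blur_sigma = blur_sigma, photon_scale = photon_scale,
                 read_sd = read_sd, offset = offset,
                 margin_px = as.integer(margin_px),
                 gap_px = as.integer(gap_px), punctum_mult = punctum_mult,
                 punctum_px = as.integer(punctum_px)),
            class = "optics_params")
}

# pixel extents of the fiber (without margin)
canvas_dims <- function(geometry) {
  c(h = ceiling(geometry$n_trans * geometry$sarcomere_length /
                  geometry$pixel_size),
    w = ceiling(geometry$n_long * geometry$sarcomere_length /
                  geometry$pixel_size))
}

# inclusive pixel index range [lo, hi] covered by cell k (1-based, no margin)
cell_px_range <- function(k, pitch_um, px) {
  lo <- floor((k - 1) * pitch_um / px + 1e-9) + 1L
  hi <- floor(k * pitch_um / px + 1e-9)
  c(lo, max(lo, hi))
}

# paint node values onto the pixel canvas (no margin); gap_px > 0 leaves an
# unstained separation on the high side of each cell, bridged where the edge
# is present
paint_field <- function(values, state, geometry, gap_px = 0,
                        bridge = (gap_px > 0), puncta = NULL) {
  dims <- canvas_dims(geometry)
  img <- matrix(0, dims["h"], dims["w"])
  s <- geometry$sarcomere_length; px <- geometry$pixel_size
  nd <- state$nodes
  rr <- lapply(seq_len(geometry$n_trans), cell_px_range, s, px)
  cc <- lapply(seq_len(geometry$n_long), cell_px_range, s, px)
  foot <- function(rg) {
    hi <- max(rg[1], rg[2] - gap_px)
    rg[1]:hi
  }
  for (k in seq_len(nrow(nd))) {
    img[foot(rr[[nd$row[k]]]), foot(cc[[nd$col[k]]])] <- values[k]
  }
  if (bridge && any(state$present)) {
    e <- state$edges[state$present, , drop = FALSE]
    for (k in seq_len(nrow(e))) {
      i <- e$i[k]; j <- e$j[k]
      v <- (values[i] + values[j]) / 2
      if (e$type[k] == "long") {
        rg <- cc[[nd$col[i]]]
        gap_cols <- (max(rg[1], rg[2] - gap_px) + 1):rg[2]
        img[foot(rr[[nd$row[i]]]), gap_cols] <- v
      } else {
        rg <- rr[[nd$row[i]]]
        gap_rows <- (max(rg[1], rg[2] - gap_px) + 1):rg[2]
        img[gap_rows, foot(cc[[nd$col[i]]])] <- v
      }
    }
  }
  if (!is.null(puncta) && any(puncta$which)) {
    half <- puncta$size %/% 2
    for (k in which(puncta$which)) {
      rc <- round(c(nd$y[k], nd$x[k]) / px)
      rows <- pmin(pmax((rc[1] - half + 1):(rc[1] - half + puncta$size), 1),
                   nrow(img))
      cols <- pmin(pmax((rc[2] - half + 1):(rc[2] - half + puncta$size), 1),
                   ncol(img))
      img[rows, cols] <- pmax(img[rows, cols], puncta$value[k])
    }
  }
  img
}

add_margin <- function(img, m) {
  if (m <= 0) return(img)
  out <- matrix(0, nrow(img) + 2 * m, ncol(img) + 2 * m)
  out[m + seq_len(nrow(img)), m + seq_len(ncol(img))] <- img
  out
}

# separable Gaussian blur with border renormalization
gauss_blur <- function(img, sigma_px) {
  if (sigma_px <= 0) return(img)
  band <- function(n) {
    d <- abs(outer(seq_len(n), seq_len(n), "-"))
    B <- exp(-d^2 / (2 * sigma_px^2))
    B[d > ceiling(4 * sigma_px)] <- 0
    B / rowSums(B)
  }
  band(nrow(img)) %*% img %*% t(band(ncol(img)))
}

#' Render a network state as a two-channel confocal-like image pair
#'
#' Each compartment is painted as its pixel footprint with brightness
#' proportional to tracer (tracer channel) and membrane potential (TMRE
#' channel); aggregate compartments carry a bright punctum in the tracer
#' channel. The field is blurred by a Gaussian PSF, scaled to expected photon
#' counts, and corrupted by Poisson shot noise plus Gaussian read noise
#' (clamped at zero).
#'
#' @param state a `mito_network`.
#' @param geometry a [fiber_geometry()]; defaults to the state's own.
#' @param optics an [optics_params()].
#' @param seed optional seed making the noise draw reproducible.
#' @param noise if `FALSE`, return the noise-free expected image
#'   (`photon_scale * blurred field`).
#' @return list with matrices `tracer` and `tmre` (photon-count units).
#' @export
render <- function(state, geometry = state$geometry,
                   optics = optics_params(), seed = NULL, noise = TRUE) {
  stopifnot(inherits(state, "mito_network"), inherits(optics, "optics_params"))
  puncta <- list(which = state$aggregate, size = optics$punctum_px,
                 value = optics$punctum_mult * pmax(state$tracer, 1))
  tracer_f <- paint_field(state$tracer, state, geometry,
                          gap_px = optics$gap_px, puncta = puncta)
  tmre_f <- paint_field(state$potential, state, geometry,
                        gap_px = optics$gap_px)
  out <- lapply(list(tracer = tracer_f, tmre = tmre_f), function(f) {
    f <- add_margin(f, optics$margin_px)
    gauss_blur(f, optics$blur_sigma / geometry$pixel_size)
  })
  if (!noise) {
    return(lapply(out, function(f) optics$photon_scale * f))
  }
  draw <- function() {
    lapply(out, function(f) {
      counts <- optics$offset +
        matrix(rpois(length(f), optics$photon_scale * pmax(f, 0)),
               nrow(f), ncol(f))
      if (optics$read_sd > 0)
        counts <- counts + matrix(rnorm(length(f), 0, optics$read_sd),
                                  nrow(f), ncol(f))
      pmax(counts, 0)
    })
  }
  if (is.null(seed)) draw() else with_preserved_seed(seed, draw())
}

# evaluate code under a temporary seed, restoring the caller's RNG stream
with_preserved_seed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    runif(1)
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(code)
}
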