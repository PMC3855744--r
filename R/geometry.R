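#' Fiber geometry for the compartment lattice
#'
#' Describes a muscle fiber as a lattice of mitochondrial compartments: one
#' compartment per sarcomere column (pitch `sarcomere_length`, the m-step
#' unit) and per transverse row (same pitch, i.e. square compartments).
#'
#' @param n_long number of sarcomere columns along the fiber axis (>= 8).
#' @param n_trans number of transverse compartment rows (>= 3).
#' @param sarcomere_length physical pitch of one sarcomere column, um
#'   (default 2.2, the average sarcomere length that defines one m-step).
#' @param pixel_size um per rendered pixel; must be at most
#'   `sarcomere_length / 4` so one sarcomere spans at least 4 pixels.
#' @param fiber_mask logical `n_trans x n_long` matrix of valid compartments;
#'   defaults to the full rectangle.
#' @return An object of class `fiber_geometry`.
#' @export
fiber_geometry <- function(n_long = 72, n_trans = 9, sarcomere_length = 2.2,
                           pixel_size = 0.55, fiber_mask = NULL) {
  check_scalar(sarcomere_length, "sarcomere_length", min = 0, strict_min = TRUE)
  check_scalar(n_long, "n_long", min = 8)
  check_scalar(n_trans, "n_trans", min = 3)
  check_scalar(pixel_size, "pixel_size", min = 0, strict_min = TRUE)
  if (pixel_size > sarcomere_length / 4 + 1e-12)
    stop("'pixel_size' must be <= sarcomere_length / 4 ",
         "(a sarcomere must span at least 4 pixels)", call. = FALSE)
  n_long <- as.integer(n_long); n_trans <- as.integer(n_trans)
  if (is.null(fiber_mask)) {
    fiber_mask <- matrix(TRUE, n_trans, n_long)
  } else {
    if (!is.logical(fiber_mask) || !identical(dim(fiber_mask),
                                              c(n_trans, n_long)))
      stop("'fiber_mask' must be a logical n_trans x n_long matrix",
           call. = FALSE)
    if (!any(fiber_mask)) stop("'fiber_mask' is empty", call. = FALSE)
  }
  structure(list(n_long = n_long, n_trans = n_trans,
                 sarcomere_length = sarcomere_length,
                 pixel_size = pixel_size, fiber_mask = fiber_mask),
            class = "fiber_geometry")
}

#' @export
print.fiber_geometry <- function(x, ...) {
  cat(sprintf("<fiber_geometry> %d x %d compartments (%.1f x %.1f um), %.3g um/px\n",
              x$n_long, x$n_trans,
              x$n_long * x$sarcomere_length, x$n_trans * x$sarcomere_length,
              x$pixel_size))
  invisible(x)
}

fiber_length_um <- function(geometry) geometry$n_long * geometry$sarcomere_length
fiber_width_um <- function(geometry) geometry$n_trans * geometry$sarcomere_length
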