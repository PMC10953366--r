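# Base-graphics displays for reconstruction results.

#' @noRd
show_mag <- function(img, main) {
  m <- Mod(img)
  graphics::image(t(m)[, rev(seq_len(nrow(m)))], col = grDevices::gray.colors(256),
                  axes = FALSE, main = main, asp = nrow(m) / ncol(m))
}

#' Display corrected and uncorrected reconstructions side by side
#'
#' @param x a \code{recon_result} from [run_grics()].
#' @param slice 1-based slice number.
#' @param ... unused.
#' @return \code{x}, invisibly.
#' @export
plot.recon_result <- function(x, slice = 1L, ...) {
  op <- graphics::par(mfrow = c(1, 2), mar = c(1, 1, 2, 1))
  on.exit(graphics::par(op))
  show_mag(slice_matrix(x$uncorrected, slice), "uncorrected")
  show_mag(slice_matrix(x$corrected, slice), "motion-corrected")
  invisible(x)
}

#' Display an image volume slice
#'
#' @param x an [image_volume()].
#' @param slice 1-based slice number.
#' @param main plot title.
#' @param ... unused.
#' @return \code{x}, invisibly.
#' @export
plot.image_volume <- function(x, slice = 1L, main = NULL, ...) {
  show_mag(slice_matrix(x, slice), main %||% "")
  invisible(x)
}

#' Quiver-style display of a motion model at a given sensor amplitude
#'
#' Draws the displacement field \code{u = alpha * s_value} as arrows on a
#' decimated grid.
#'
#' @param x an [alpha_maps()].
#' @param s_value sensor amplitude at which to evaluate the field.
#' @param every arrow decimation (one arrow per \code{every} pixels).
#' @param ... passed to [graphics::arrows()].
#' @return \code{x}, invisibly.
#' @export
plot.alpha_maps <- function(x, s_value = 1, every = 4L, ...) {
  u <- predict_displacement(x, s_value)$u
  ny <- dim(u)[2]; nx <- dim(u)[3]
  ys <- seq(1, ny, by = every); xs <- seq(1, nx, by = every)
  graphics::plot(NA, xlim = c(1, nx), ylim = c(ny, 1), asp = 1,
                 xlab = "x (px)", ylab = "y (px)")
  for (i in ys) for (j in xs) {
    if (abs(u[1, i, j]) + abs(u[2, i, j]) > 1e-3)
      graphics::arrows(j, i, j + u[2, i, j], i + u[1, i, j],
                       length = 0.03, ...)
  }
  invisible(x)
}
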