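#' Cubic periodic simulation box
#'
#' @param edge_length box edge, nm; must be positive.
#' @return An object of class `simulation_box`.
#' @export
simulation_box <- function(edge_length) {
  if (!is.numeric(edge_length) || length(edge_length) != 1 ||
      !is.finite(edge_length) || edge_length <= 0)
    stop("edge_length must be a single positive finite number (nm)")
  structure(list(edge_length = edge_length, periodic = TRUE),
            class = "simulation_box")
}

#' @export
print.simulation_box <- function(x, ...) {
  cat(sprintf("cubic periodic box, L = %.6g nm\n", x$edge_length))
  invisible(x)
}

#' Minimum-image displacement between two points
#'
#' Returns r2 - r1 shifted by integer multiples of the box length per axis so
#' that each component lies in [-L/2, L/2). Both arguments may be matrices
#' (one row per point), in which case displacements are computed row-wise.
#'
#' @param r1,r2 3-vectors (or n x 3 matrices) of coordinates, nm.
#' @param box a [simulation_box()].
#' @return displacement 3-vector (or n x 3 matrix), nm.
#' @export
minimum_image_displacement <- function(r1, r2, box) {
  stopifnot(inherits(box, "simulation_box"))
  if (!all(is.finite(r1)) || !all(is.finite(r2)))
    stop("non-finite coordinates")
  L <- box$edge_length
  d <- r2 - r1
  d - L * floor(d / L + 0.5)
}

#' Wrap coordinates into the primary box [0, L)
#' @param x coordinate vector or matrix, nm
#' @param box a [simulation_box()]
#' @return wrapped coordinates
#' @export
wrap_coordinates <- function(x, box) {
  L <- box$edge_length
  x - L * floor(x / L)
}
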