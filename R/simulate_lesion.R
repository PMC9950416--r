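# Lesion phantoms: serial-section outline stacks with known analytic volume.

#' Generate a lesion phantom slice stack
#'
#' Samples cross-sections of a solid of known closed-form volume at slice
#' centers, producing the traced-outline stack that the volumetry consumes
#' (Cavalieri estimation: sum of areas times slice thickness). Shapes:
#' \describe{
#'   \item{cylinder}{`dimensions = c(radius, length)`, axis perpendicular to
#'     the cutting plane; volume `pi r^2 L`.}
#'   \item{box}{`dimensions = c(a, b, c)` with `c` along the cutting axis;
#'     volume `a b c`.}
#'   \item{ellipsoid}{`dimensions = c(a, b, c)` semi-axes, `c` along the
#'     cutting axis; volume `4/3 pi a b c`.}
#' }
#'
#' @param shape one of "cylinder", "box", "ellipsoid".
#' @param dimensions shape dimensions, mm (see above).
#' @param slice_thickness section thickness, mm.
#' @param hemisphere hemisphere label for the generated outlines.
#' @param n_vertices polygon vertex count for curved cross-sections.
#' @return list of class `lesion_phantom`: `stack` (a `lesion_stack`, see
#'   [lesion_stack()]) and `analytic_volume` (mm^3).
#' @export
generate_lesion_stack <- function(shape = c("cylinder", "box", "ellipsoid"),
                                  dimensions, slice_thickness = 0.1,
                                  hemisphere = "left", n_vertices = 64L) {
  shape <- match.arg(shape)
  if (slice_thickness <= 0) stop("slice_thickness must be positive")
  if (any(dimensions <= 0)) stop("dimensions must be positive")

  ellipse_poly <- function(a, b) {
    th <- 2 * pi * (seq_len(n_vertices) - 1) / n_vertices
    data.frame(x = a * cos(th), y = b * sin(th))
  }
  rect_poly <- function(a, b)
    data.frame(x = c(-a, a, a, -a) / 2, y = c(-b, -b, b, b) / 2)

  axis_len <- switch(shape,
    cylinder = dimensions[2],
    box = dimensions[3],
    ellipsoid = 2 * dimensions[3])
  n_slices <- max(1L, round(axis_len / slice_thickness))
  z <- (seq_len(n_slices) - 0.5) * slice_thickness - axis_len / 2

  section <- switch(shape,
    cylinder = function(z) ellipse_poly(dimensions[1], dimensions[1]),
    box = function(z) rect_poly(dimensions[1], dimensions[2]),
    ellipsoid = function(z) {
      s <- 1 - (z / dimensions[3])^2
      if (s <= 0) return(NULL)
      ellipse_poly(dimensions[1] * sqrt(s), dimensions[2] * sqrt(s))
    })

  outlines <- list()
  for (i in seq_len(n_slices)) {
    p <- section(z[i])
    if (is.null(p)) next
    outlines[[length(outlines) + 1L]] <- data.frame(
      slice = i, hemisphere = hemisphere, kind = "lesion",
      vertex = seq_len(nrow(p)), x_mm = p$x, y_mm = p$y)
  }
  analytic <- switch(shape,
    cylinder = pi * dimensions[1]^2 * dimensions[2],
    box = prod(dimensions[1:3]),
    ellipsoid = 4 / 3 * pi * prod(dimensions[1:3]))
  list(stack = lesion_stack(do.call(rbind, outlines), slice_thickness),
       analytic_volume = analytic, shape = shape)
}
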