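# Serial-section lesion volumetry: shoelace areas x slice thickness
# (Cavalieri estimation), per hemisphere, with a size classification.

#' Area of a simple polygon
#'
#' Absolute shoelace area; independent of vertex orientation. Errors on
#' self-intersecting outlines (tracing artifacts) rather than returning a
#' misleading signed area.
#'
#' @param x,y polygon vertex coordinates, mm (or a two-column matrix /
#'   data frame as `x`).
#' @param check_simple verify the polygon is simple (non-self-intersecting).
#' @return area in mm^2.
#' @export
polygon_area <- function(x, y = NULL, check_simple = TRUE) {
  if (is.null(y)) {
    xy <- as.matrix(x)
    x <- xy[, 1]; y <- xy[, 2]
  }
  n <- length(x)
  if (n < 3L) stop("a polygon needs at least 3 vertices")
  if (check_simple && !is_simple_polygon(x, y))
    stop("polygon is self-intersecting")
  i2 <- c(2:n, 1L)
  abs(sum(x * y[i2] - x[i2] * y)) / 2
}

# proper-crossing test for every pair of non-adjacent edges (vectorized
# over the second edge)
is_simple_polygon <- function(x, y) {
  n <- length(x)
  x2 <- x[c(2:n, 1L)]; y2 <- y[c(2:n, 1L)]
  for (i in seq_len(n - 2L)) {
    j <- (i + 2L):n
    if (i == 1L) j <- j[j != n]   # edge n wraps to edge 1: adjacent
    if (!length(j)) next
    ax <- x2[i] - x[i]; ay <- y2[i] - y[i]
    d1 <- ax * (y[j] - y[i]) - ay * (x[j] - x[i])
    d2 <- ax * (y2[j] - y[i]) - ay * (x2[j] - x[i])
    bx <- x2[j] - x[j]; by <- y2[j] - y[j]
    d3 <- bx * (y[i] - y[j]) - by * (x[i] - x[j])
    d4 <- bx * (y2[i] - y[j]) - by * (x2[i] - x[j])
    if (any(d1 * d2 < 0 & d3 * d4 < 0)) return(FALSE)
  }
  TRUE
}

#' Construct a lesion outline stack
#'
#' @param outlines data frame in long vertex format: `slice`, `hemisphere`
#'   ("left"/"right"), `kind`, `vertex`, `x_mm`, `y_mm`; an optional logical
#'   `hole` column marks outlines whose area is subtracted.
#' @param slice_thickness section thickness, mm.
#' @return list of class `lesion_stack`.
#' @export
lesion_stack <- function(outlines, slice_thickness = 0.1) {
  if (slice_thickness <= 0) stop("slice_thickness must be positive")
  needed <- c("slice", "hemisphere", "kind", "vertex", "x_mm", "y_mm")
  if (!all(needed %in% names(outlines)))
    stop("outlines must have columns: ", paste(needed, collapse = ", "))
  if (is.null(outlines$hole)) outlines$hole <- FALSE
  structure(list(outlines = outlines, slice_thickness = slice_thickness),
            class = "lesion_stack")
}

#' Read lesion outlines from CSV
#'
#' Expects columns `animal` (optional), `hemisphere`, `slice`, `kind`,
#' `vertex` (or `vertex_order`), `x_mm`, `y_mm`.
#' @param path CSV file path.
#' @param slice_thickness section thickness, mm.
#' @return a [lesion_stack()].
#' @export
read_lesion_outlines <- function(path, slice_thickness = 0.1) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(d$vertex_order) && is.null(d$vertex)) d$vertex <- d$vertex_order
  lesion_stack(d, slice_thickness)
}

#' Lesion volume from a slice stack
#'
#' Per-hemisphere volume as the sum over slices of traced lesion area times
#' slice thickness. Outlines flagged as holes subtract their area.
#'
#' @param stack a [lesion_stack()].
#' @param kind which outline kind to integrate (default "lesion").
#' @return list of class `volume_report`: `left`, `right`, `total` (mm^3)
#'   and `per_slice` areas.
#' @export
stack_volume <- function(stack, kind = "lesion") {
  o <- stack$outlines[stack$outlines$kind == kind, , drop = FALSE]
  if (!nrow(o)) stop("no outlines of kind '", kind, "' in stack")
  key <- interaction(o$hemisphere, o$slice, o$hole, drop = TRUE)
  parts <- split(o, key)
  per_slice <- do.call(rbind, lapply(parts, function(p) {
    p <- p[order(p$vertex), ]
    data.frame(hemisphere = p$hemisphere[1], slice = p$slice[1],
               area = polygon_area(p$x_mm, p$y_mm) * ifelse(p$hole[1], -1, 1))
  }))
  agg <- stats::aggregate(area ~ hemisphere + slice, per_slice, sum)
  if (any(agg$area < 0)) stop("hole outlines exceed their slice's lesion area")
  vol <- function(h) sum(agg$area[agg$hemisphere == h]) * stack$slice_thickness
  left <- vol("left"); right <- vol("right")
  structure(list(left = left, right = right, total = left + right,
                 per_slice = agg), class = "volume_report")
}

#' @export
print.volume_report <- function(x, ...) {
  cat(sprintf("<volume_report> left %.3g + right %.3g = %.3g mm^3 (%s)\n",
              x$left, x$right, x$total, classify_size(x)))
  invisible(x)
}

#' Classify lesion size
#'
#' A lesion counts as "large" when its total volume strictly exceeds the
#' threshold (default 15 mm^3).
#'
#' @param report a `volume_report`, or a total volume in mm^3.
#' @param threshold size cutoff, mm^3.
#' @return "large" or "small".
#' @export
classify_size <- function(report, threshold = 15) {
  total <- if (inherits(report, "volume_report")) report$total else report
  if (total > threshold) "large" else "small"
}
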