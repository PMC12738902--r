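#' Construct a bounding box
#'
#' Boxes are axis-aligned rectangles in continuous image coordinates with
#' the origin at the top-left corner and y increasing downward (the usual
#' image convention). Sub-pixel corners are allowed.
#'
#' @param x1,y1 Top-left corner.
#' @param x2,y2 Bottom-right corner; must satisfy `x2 > x1`, `y2 > y1`.
#' @return Named numeric vector `c(x1, y1, x2, y2)`.
#' @export
#' @examples
#' bbox(0, 0, 10, 10)
bbox <- function(x1, y1, x2, y2) {
  b <- c(x1 = as.numeric(x1), y1 = as.numeric(y1),
         x2 = as.numeric(x2), y2 = as.numeric(y2))
  validate_bbox(b)
  b
}

validate_bbox <- function(b) {
  if (length(b) != 4L || anyNA(b) || !all(is.finite(b)))
    stop("bounding box must be four finite numbers (x1, y1, x2, y2)", call. = FALSE)
  if (b[[1]] >= b[[3]] || b[[2]] >= b[[4]])
    stop("degenerate bounding box: need x1 < x2 and y1 < y2", call. = FALSE)
  invisible(b)
}

#' Box center, width and height
#'
#' @param b Box as `c(x1, y1, x2, y2)`.
#' @return `box_center()`: `c(x, y)`; `box_size()`: `c(width, height)`.
#' @export
box_center <- function(b) {
  c(x = (b[[1]] + b[[3]]) / 2, y = (b[[2]] + b[[4]]) / 2)
}

#' @rdname box_center
#' @export
box_size <- function(b) {
  c(width = b[[3]] - b[[1]], height = b[[4]] - b[[2]])
}

#' Convert between corner and center/aspect/height box parameterizations
#'
#' The tracker's motion model carries boxes as
#' `(center x, center y, aspect ratio width/height, height)`; detections and
#' annotations carry corners. These two helpers convert between the
#' parameterizations and are exact inverses of each other.
#'
#' @param b Box as `c(x1, y1, x2, y2)`.
#' @param m Measurement as `c(cx, cy, a, h)` with `a = width / height`.
#' @return `box_to_cah()`: `c(cx, cy, a, h)`; `cah_to_box()`:
#'   `c(x1, y1, x2, y2)`.
#' @export
box_to_cah <- function(b) {
  w <- b[[3]] - b[[1]]
  h <- b[[4]] - b[[2]]
  c(cx = (b[[1]] + b[[3]]) / 2, cy = (b[[2]] + b[[4]]) / 2,
    a = w / h, h = h)
}

#' @rdname box_to_cah
#' @export
cah_to_box <- function(m) {
  h <- m[[4]]
  w <- m[[3]] * h
  c(x1 = m[[1]] - w / 2, y1 = m[[2]] - h / 2,
    x2 = m[[1]] + w / 2, y2 = m[[2]] + h / 2)
}

#' Intersection over union of two boxes
#'
#' Continuous-area IoU: the ratio of the overlap area to the union area.
#' Symmetric, bounded in \[0, 1\], zero for disjoint boxes and one exactly
#' when the boxes coincide.
#'
#' @param a,b Boxes as `c(x1, y1, x2, y2)`.
#' @return IoU in \[0, 1\].
#' @export
#' @examples
#' iou(c(0, 0, 10, 10), c(5, 0, 15, 10)) # 1/3
iou <- function(a, b) {
  iw <- min(a[[3]], b[[3]]) - max(a[[1]], b[[1]])
  ih <- min(a[[4]], b[[4]]) - max(a[[2]], b[[2]])
  if (iw <= 0 || ih <= 0) return(0)
  inter <- iw * ih
  area_a <- (a[[3]] - a[[1]]) * (a[[4]] - a[[2]])
  area_b <- (b[[3]] - b[[1]]) * (b[[4]] - b[[2]])
  inter / (area_a + area_b - inter)
}

# IoU of one box against each row of an n x 4 matrix; used on the
# association hot path.
iou_one_many <- function(a, B) {
  if (is.null(dim(B))) B <- matrix(B, ncol = 4L)
  iw <- pmin(a[[3]], B[, 3L]) - pmax(a[[1]], B[, 1L])
  ih <- pmin(a[[4]], B[, 4L]) - pmax(a[[2]], B[, 2L])
  inter <- pmax(iw, 0) * pmax(ih, 0)
  area_a <- (a[[3]] - a[[1]]) * (a[[4]] - a[[2]])
  area_b <- (B[, 3L] - B[, 1L]) * (B[, 4L] - B[, 2L])
  inter / (area_a + area_b - inter)
}
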