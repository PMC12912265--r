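#' Regions of interest
#'
#' ROIs are defined in pixel coordinates with `x` = column and `y` = row,
#' origin top-left (1-based, matching frame indexing). Three kinds are
#' supported: axis-aligned rectangles, simple polygons, and binary masks.
#'
#' @param x,y Top-left corner of the rectangle (column, row), 1-based.
#' @param width,height Rectangle extent in pixels (> 0).
#' @param label Free-text label.
#' @return An object of class `roi`.
#' @export
roi_rect <- function(x, y, width, height, label = "") {
  if (width <= 0 || height <= 0) {
    stop("rectangle must have positive width and height", call. = FALSE)
  }
  structure(list(kind = "rectangle", x = x, y = y, width = width,
                 height = height, label = label), class = "roi")
}

#' @rdname roi_rect
#' @param xs,ys Polygon vertex coordinates (columns, rows).
#' @export
roi_polygon <- function(xs, ys, label = "") {
  if (length(xs) != length(ys) || length(xs) < 3L) {
    stop("polygon needs >= 3 vertices with matching x/y lengths",
         call. = FALSE)
  }
  if (polygon_self_intersects(xs, ys)) {
    stop("polygon must be simple (non-self-intersecting)", call. = FALSE)
  }
  structure(list(kind = "polygon", xs = xs, ys = ys, label = label),
            class = "roi")
}

#' @rdname roi_rect
#' @param mask Logical or 0/1 matrix matching the stack's spatial shape.
#' @export
roi_mask <- function(mask, label = "") {
  if (!is.matrix(mask)) stop("mask must be a matrix", call. = FALSE)
  structure(list(kind = "mask", mask = mask != 0, label = label),
            class = "roi")
}

#' @export
print.roi <- function(x, ...) {
  desc <- switch(x$kind,
    rectangle = sprintf("%d x %d px at (%g, %g)", x$width, x$height, x$x, x$y),
    polygon = sprintf("%d vertices", length(x$xs)),
    mask = sprintf("%d px foreground", sum(x$mask))
  )
  cat(sprintf("<roi:%s> %s%s\n", x$kind, desc,
              if (nzchar(x$label)) paste0(" [", x$label, "]") else ""))
  invisible(x)
}

# segment-intersection scan; O(n^2) is fine for annotation-scale polygons
polygon_self_intersects <- function(xs, ys) {
  n <- length(xs)
  seg <- cbind(xs, ys, c(xs[-1], xs[1]), c(ys[-1], ys[1]))
  ccw <- function(ax, ay, bx, by, cx, cy) (by - ay) * (cx - ax) - (bx - ax) * (cy - ay)
  for (i in seq_len(n - 2L)) {
    for (j in seq(i + 2L, n)) {
      if (i == 1L && j == n) next  # shares the closing vertex
      d1 <- ccw(seg[i, 1], seg[i, 2], seg[i, 3], seg[i, 4], seg[j, 1], seg[j, 2])
      d2 <- ccw(seg[i, 1], seg[i, 2], seg[i, 3], seg[i, 4], seg[j, 3], seg[j, 4])
      d3 <- ccw(seg[j, 1], seg[j, 2], seg[j, 3], seg[j, 4], seg[i, 1], seg[i, 2])
      d4 <- ccw(seg[j, 1], seg[j, 2], seg[j, 3], seg[j, 4], seg[i, 3], seg[i, 4])
      if (((d1 > 0) != (d2 > 0)) && ((d3 > 0) != (d4 > 0))) return(TRUE)
    }
  }
  FALSE
}

#' Bounding box of an ROI
#' @param roi An [roi_rect()], [roi_polygon()] or [roi_mask()].
#' @return Named list `x0, y0, x1, y1` (inclusive pixel bounds).
#' @export
roi_bbox <- function(roi) {
  stopifnot(inherits(roi, "roi"))
  switch(roi$kind,
    rectangle = list(x0 = roi$x, y0 = roi$y,
                     x1 = roi$x + roi$width - 1L, y1 = roi$y + roi$height - 1L),
    polygon = list(x0 = floor(min(roi$xs)), y0 = floor(min(roi$ys)),
                   x1 = ceiling(max(roi$xs)), y1 = ceiling(max(roi$ys))),
    mask = {
      idx <- which(roi$mask, arr.ind = TRUE)
      if (nrow(idx) == 0L) stop("mask roi is empty", call. = FALSE)
      list(x0 = min(idx[, 2]), y0 = min(idx[, 1]),
           x1 = max(idx[, 2]), y1 = max(idx[, 1]))
    }
  )
}

# logical membership matrix for the pixels of a bbox-cropped region
roi_membership <- function(roi, bbox) {
  h <- bbox$y1 - bbox$y0 + 1L
  w <- bbox$x1 - bbox$x0 + 1L
  if (roi$kind == "rectangle") return(matrix(TRUE, h, w))
  if (roi$kind == "mask") {
    return(roi$mask[bbox$y0:bbox$y1, bbox$x0:bbox$x1, drop = FALSE])
  }
  px <- rep(bbox$x0:bbox$x1, each = h)
  py <- rep(bbox$y0:bbox$y1, times = w)
  inside <- mgcv::in.out(
    cbind(c(roi$xs, roi$xs[1]), c(roi$ys, roi$ys[1])),
    cbind(px, py)
  )
  matrix(inside, h, w)
}

#' Crop a stack to an ROI
#'
#' Returns the sub-stack covering the ROI's bounding box. For polygon and
#' mask ROIs, pixels outside the region are set to `fill` and the membership
#' mask is attached as the `roi_mask` attribute. Calibration is unchanged.
#'
#' @param stack A [calibrated_stack()].
#' @param roi An [roi_rect()], [roi_polygon()] or [roi_mask()].
#' @param fill Fill value for out-of-region pixels (default 0).
#' @return A [calibrated_stack()] cropped to the ROI bounding box.
#' @export
crop_roi <- function(stack, roi, fill = 0) {
  stopifnot(inherits(stack, "calibrated_stack"), inherits(roi, "roi"))
  d <- dim(stack$frames)
  if (roi$kind == "mask" && !all(dim(roi$mask) == d[2:3])) {
    stop("mask roi shape must match the stack's spatial shape", call. = FALSE)
  }
  bb <- roi_bbox(roi)
  if (bb$x0 < 1 || bb$y0 < 1 || bb$x1 > d[3] || bb$y1 > d[2]) {
    stop(sprintf("roi [%g,%g]-[%g,%g] lies outside stack bounds %d x %d",
                 bb$x0, bb$y0, bb$x1, bb$y1, d[3], d[2]), call. = FALSE)
  }
  sub <- stack$frames[, bb$y0:bb$y1, bb$x0:bb$x1, drop = FALSE]
  member <- roi_membership(roi, bb)
  if (!all(member)) {
    for (i in seq_len(d[1])) {
      fr <- sub[i, , ]
      fr[!member] <- fill
      sub[i, , ] <- fr
    }
  }
  out <- calibrated_stack(sub, stack$pixel_size, stack$frame_interval,
                          stack$channel_label)
  attr(out, "roi_mask") <- member
  attr(out, "roi_offset") <- c(x = bb$x0, y = bb$y0)
  out
}

#' Read/write ROI definitions as JSON
#' @param roi An `roi` object.
#' @param path File path.
#' @return `write_roi` returns `path` invisibly; `read_roi` returns an `roi`.
#' @export
write_roi <- function(roi, path) {
  stopifnot(inherits(roi, "roi"))
  jsonlite::write_json(unclass(roi), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_roi
#' @export
read_roi <- function(path) {
  x <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  switch(x$kind,
    rectangle = roi_rect(x$x, x$y, x$width, x$height, x$label %||% ""),
    polygon = roi_polygon(x$xs, x$ys, x$label %||% ""),
    mask = roi_mask(matrix(unlist(x$mask), nrow = length(x$mask),
                           byrow = TRUE), x$label %||% ""),
    stop("unknown roi kind: ", x$kind, call. = FALSE)
  )
}
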