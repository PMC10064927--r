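#' Read an RGB micrograph from PNG
#'
#' @param path PNG path.
#' @return Integer array `height x width x 3`, values 0..255.
#' @export
read_image_png <- function(path) {
  arr <- png::readPNG(path)
  if (length(dim(arr)) == 2L) arr <- array(rep(arr, 3), dim = c(dim(arr), 3L))
  if (dim(arr)[3] == 4L) arr <- arr[, , 1:3, drop = FALSE]
  array(as.integer(round(arr * 255)), dim = dim(arr))
}

#' Write an RGB image to PNG
#'
#' @param image Integer array `height x width x 3`, values 0..255.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_image_png <- function(image, path) {
  png::writePNG(image / 255, path)
  invisible(path)
}

#' Extract per-islet boundary pixel sets
#'
#' A pixel is a boundary pixel of its component iff it belongs to the
#' component and at least one of its 4-neighbors lies outside the component
#' (the image edge counts as outside). This is the inner boundary: a closed
#' 1-px edge drawn on the object itself, as used for contour overlays.
#'
#' @param components A `labeled_components` from [label_islets()].
#' @return A `boundary_set`: named list mapping component label (as
#'   character) to an `n x 2` integer matrix of (row, col) boundary pixels.
#' @export
extract_boundaries <- function(components) {
  stopifnot(inherits(components, "labeled_components"))
  lab <- components$labels
  nr <- nrow(lab); nc <- ncol(lab)
  pad <- matrix(0L, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- lab
  core <- pad[2:(nr + 1L), 2:(nc + 1L)]
  up    <- pad[1:nr, 2:(nc + 1L)]
  down  <- pad[3:(nr + 2L), 2:(nc + 1L)]
  left  <- pad[2:(nr + 1L), 1:nc]
  right <- pad[2:(nr + 1L), 3:(nc + 2L)]
  is_b <- core > 0L & (up != core | down != core | left != core | right != core)
  out <- list()
  if (any(is_b)) {
    idx <- which(is_b, arr.ind = TRUE)
    labs <- core[is_b]
    ord <- order(labs, idx[, 1], idx[, 2])
    idx <- idx[ord, , drop = FALSE]; labs <- labs[ord]
    sp <- split(seq_along(labs), labs)
    out <- lapply(sp, function(i) {
      m <- idx[i, , drop = FALSE]
      dimnames(m) <- list(NULL, c("row", "col"))
      m
    })
  }
  # components entirely absent from `out` can only be empty masks; every
  # nonempty component has at least one pixel touching non-component area
  structure(out, class = "boundary_set")
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# offsets of a filled disc of the given radius, for thickness dilation
disc_offsets <- function(radius) {
  r <- seq(-radius, radius)
  g <- expand.grid(dr = r, dc = r)
  g[g$dr^2 + g$dc^2 <= radius^2, , drop = FALSE]
}

#' Overlay islet boundaries on a micrograph
#'
#' Recolors exactly the boundary pixels (dilated to the requested thickness)
#' with the given color; all other pixels are untouched.
#'
#' @param image Integer RGB array from [read_image_png()] or [make_scene()].
#' @param boundaries A `boundary_set` from [extract_boundaries()].
#' @param color Length-3 integer RGB in 0..255. Default bright yellow.
#' @param thickness_px Odd-ish line thickness; pixels within radius
#'   `(thickness_px - 1) / 2` of a boundary pixel are recolored.
#' @return The recolored image array.
#' @export
render_overlay <- function(image, boundaries, color = c(255L, 255L, 0L),
                           thickness_px = 1L) {
  stopifnot(length(dim(image)) == 3L, length(color) == 3L, thickness_px >= 1L)
  nr <- dim(image)[1]; nc <- dim(image)[2]
  pts <- do.call(rbind, unname(boundaries))
  if (is.null(pts) || nrow(pts) == 0L) return(image)
  if (any(pts[, 1] < 1L | pts[, 1] > nr | pts[, 2] < 1L | pts[, 2] > nc))
    stopf("boundary pixels fall outside the image: dimension mismatch")
  radius <- (thickness_px - 1L) %/% 2L
  if (radius > 0L) {
    off <- disc_offsets(radius)
    pts <- cbind(rep(pts[, 1], each = nrow(off)) + off$dr,
                 rep(pts[, 2], each = nrow(off)) + off$dc)
    keep <- pts[, 1] >= 1L & pts[, 1] <= nr & pts[, 2] >= 1L & pts[, 2] <= nc
    pts <- pts[keep, , drop = FALSE]
  }
  for (ch in 1:3)
    image[cbind(pts[, 1], pts[, 2], ch)] <- as.integer(color[ch])
  image
}

component_bbox <- function(components, label) {
  idx <- which(components$labels == label, arr.ind = TRUE)
  if (nrow(idx) == 0L) stopf("no component with label %s", label)
  c(rmin = min(idx[, 1]), rmax = max(idx[, 1]),
    cmin = min(idx[, 2]), cmax = max(idx[, 2]))
}

#' Crop one islet out of a micrograph
#'
#' Returns the component's bounding box expanded by a margin and clipped to
#' the image bounds; used for the per-islet displays sent back to experts.
#'
#' @param image Integer RGB array.
#' @param components A `labeled_components`.
#' @param label Component label to crop.
#' @param margin_px Margin added on all four sides before clipping.
#' @return The cropped RGB array.
#' @export
crop_islet <- function(image, components, label, margin_px = 0L) {
  bb <- component_bbox(components, label)
  r1 <- clamp(bb["rmin"] - margin_px, 1L, dim(image)[1])
  r2 <- clamp(bb["rmax"] + margin_px, 1L, dim(image)[1])
  c1 <- clamp(bb["cmin"] - margin_px, 1L, dim(image)[2])
  c2 <- clamp(bb["cmax"] + margin_px, 1L, dim(image)[2])
  image[r1:r2, c1:c2, , drop = FALSE]
}

#' Draw arrow marks pointing at selected islets
#'
#' Purely presentational: a fixed-geometry arrow glyph is drawn pointing at
#' each target (by default a 40 px shaft at 45 degrees ending 6 px from the
#' target, with a small head). Deterministic: identical inputs give
#' bit-identical output.
#'
#' @param image Integer RGB array.
#' @param marks Data frame with columns `row`, `col` (targets, typically
#'   islet centroids) and optionally `per_set_id`.
#' @param length_px Shaft length. @param angle_deg Approach angle.
#' @param color RGB color, default white.
#' @return The image with arrows drawn.
#' @export
render_arrows <- function(image, marks, length_px = 40, angle_deg = 45,
                          color = c(255L, 255L, 255L)) {
  nr <- dim(image)[1]; nc <- dim(image)[2]
  if (NROW(marks) == 0L) return(image)
  if (any(marks$row < 1 | marks$row > nr | marks$col < 1 | marks$col > nc))
    stopf("arrow target outside image bounds")
  th <- angle_deg * pi / 180
  for (i in seq_len(nrow(marks))) {
    tip <- c(marks$row[i] + round(6 * sin(th)), marks$col[i] + round(6 * cos(th)))
    tail <- c(tip[1] + round(length_px * sin(th)), tip[2] + round(length_px * cos(th)))
    seg <- rbind(bresenham(tip, tail),
                 bresenham(tip, tip + c(8, 0)),   # arrow-head barbs
                 bresenham(tip, tip + c(0, 8)))
    keep <- seg[, 1] >= 1 & seg[, 1] <= nr & seg[, 2] >= 1 & seg[, 2] <= nc
    seg <- seg[keep, , drop = FALSE]
    for (ch in 1:3)
      image[cbind(seg[, 1], seg[, 2], ch)] <- as.integer(color[ch])
  }
  image
}
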