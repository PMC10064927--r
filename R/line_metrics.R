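#' Construct a polyline annotation
#'
#' Expert and template drawings are ordered point lists in (row, col) pixel
#' coordinates: open polylines are islet separation lines, closed ones are
#' full islet contours.
#'
#' @param points `n x 2` numeric matrix of (row, col) coordinates; finite.
#' @param closed Logical; closed contours need >= 3 points, open lines >= 2.
#' @param author Author id (expert id, or e.g. `"template"`).
#' @param role One of `"TEMPLATE"`, `"EXPERT"`, `"GROUND_TRUTH"`.
#' @param ref For expert lines, the id of the template line being traced
#'   (used to pair lines in [accuracy_batch()]); `NA` otherwise.
#' @return A `polyline` object.
#' @export
polyline <- function(points, closed = FALSE, author = "unknown",
                     role = c("EXPERT", "TEMPLATE", "GROUND_TRUTH"),
                     ref = NA_character_) {
  role <- match.arg(role)
  points <- as.matrix(points)
  if (ncol(points) != 2L || !all(is.finite(points)))
    stopf("points must be an n x 2 matrix of finite (row, col) coordinates")
  if (nrow(points) < ifelse(closed, 3L, 2L))
    stopf("polyline needs >= %d points", ifelse(closed, 3L, 2L))
  dimnames(points) <- list(NULL, c("row", "col"))
  structure(list(points = points, closed = isTRUE(closed),
                 author = author, role = role, ref = ref),
            class = "polyline")
}

#' @export
print.polyline <- function(x, ...) {
  cat(sprintf("<polyline> %s/%s, %d points, %s\n", x$author, x$role,
              nrow(x$points), if (x$closed) "closed" else "open"))
  invisible(x)
}

# Bresenham-style 8-connected line between two (row, col) points.
bresenham <- function(p0, p1) {
  r0 <- round(p0[1]); c0 <- round(p0[2]); r1 <- round(p1[1]); c1 <- round(p1[2])
  dr <- abs(r1 - r0); dc <- abs(c1 - c0)
  n <- max(dr, dc)
  if (n == 0) return(matrix(c(r0, c0), 1, 2, dimnames = list(NULL, c("row", "col"))))
  t <- seq(0, 1, length.out = n + 1)
  cbind(row = round(r0 + t * (r1 - r0)), col = round(c0 + t * (c1 - c0)))
}

#' Rasterize a polyline to a 1-px-wide pixel chain
#'
#' Each segment becomes an 8-connected Bresenham chain; a closed polyline
#' additionally connects its last point back to its first. Duplicate pixels
#' at segment joints are removed.
#'
#' @param line A [polyline()].
#' @return `n x 2` integer matrix of unique (row, col) pixels.
#' @export
rasterize_polyline <- function(line) {
  stopifnot(inherits(line, "polyline"))
  pts <- line$points
  segs <- cbind(seq_len(nrow(pts) - 1L), seq_len(nrow(pts) - 1L) + 1L)
  if (line$closed) segs <- rbind(segs, c(nrow(pts), 1L))
  px <- do.call(rbind, lapply(seq_len(nrow(segs)), function(i)
    bresenham(pts[segs[i, 1], ], pts[segs[i, 2], ])))
  px <- unique(px)
  dimnames(px) <- list(NULL, c("row", "col"))
  px
}

#' Trim line pixels to one islet component
#'
#' Separation lines are only meaningful within the islet mass they split, so
#' before scoring, both expert and template lines are trimmed to the pixels
#' lying inside the ground-truth component. An empty result is allowed (a
#' line drawn entirely off the islet).
#'
#' @param line_pixels `n x 2` matrix from [rasterize_polyline()].
#' @param components A `labeled_components`.
#' @param label Component label to trim to.
#' @return The subset of pixels inside the component.
#' @export
trim_to_islet <- function(line_pixels, components, label) {
  stopifnot(inherits(components, "labeled_components"))
  nr <- nrow(components$labels); nc <- ncol(components$labels)
  inb <- line_pixels[, 1] >= 1 & line_pixels[, 1] <= nr &
         line_pixels[, 2] >= 1 & line_pixels[, 2] <= nc
  keep <- inb
  keep[inb] <- components$labels[line_pixels[inb, , drop = FALSE]] == label
  line_pixels[keep, , drop = FALSE]
}

# mean over a of the Euclidean distance to the nearest pixel of b,
# vectorized over the full cross-distance matrix in row blocks.
mean_nn_dist <- function(a, b) {
  block <- max(1L, floor(4e6 / nrow(b)))
  tot <- 0
  for (s in seq(1L, nrow(a), by = block)) {
    i <- s:min(s + block - 1L, nrow(a))
    d2 <- outer(a[i, 1], b[, 1], "-")^2 + outer(a[i, 2], b[, 2], "-")^2
    tot <- tot + sum(sqrt(apply(d2, 1, min)))
  }
  tot / nrow(a)
}

#' Average distance between two rasterized lines
#'
#' The agreement measure for separation-line drawing: for each pixel of one
#' line, the Euclidean distance to the nearest pixel of the other line is
#' taken, and these nearest-neighbor distances are averaged. The symmetric
#' default averages the two directed means, so the measure is zero exactly
#' on identical sets and free of direction bias.
#'
#' @param a,b `n x 2` matrices of (row, col) pixels; both nonempty.
#' @param directed If `TRUE`, only the `a -> b` directed mean is returned.
#' @return Average distance in px.
#' @export
average_line_distance <- function(a, b, directed = FALSE) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (nrow(a) == 0L || nrow(b) == 0L)
    stopf("average_line_distance needs two nonempty pixel sets")
  ab <- mean_nn_dist(a, b)
  if (directed) return(ab)
  (ab + mean_nn_dist(b, a)) / 2
}

#' Accuracy verdict for an average line distance
#'
#' Drawing accuracy is judged good when the average distance from the
#' template stays strictly below 2 px; the boundary itself is `POOR`.
#'
#' @param avg_distance_px Average line distance(s) in px.
#' @return `"GOOD"` or `"POOR"` per element.
#' @export
accuracy_verdict <- function(avg_distance_px) {
  ifelse(avg_distance_px < 2, "GOOD", "POOR")
}

#' Score an expert line against a template line
#'
#' Both lines are rasterized, trimmed to the ground-truth islet component,
#' and compared by [average_line_distance()]; accuracy is judged good when
#' the average distance is below 2 px. If either trimmed line is empty the
#' verdict is `POOR` with an infinite distance and `empty_trim = TRUE`.
#'
#' @param expert_line,template_line [polyline()] objects.
#' @param components A `labeled_components`.
#' @param label Ground-truth component the lines belong to.
#' @return An `accuracy_result`: list with `avg_distance_px`,
#'   `template_length_px` (trimmed pixel count), `verdict` (`"GOOD"` iff
#'   distance < 2 px, else `"POOR"`) and `empty_trim`.
#' @export
score_accuracy <- function(expert_line, template_line, components, label) {
  te <- trim_to_islet(rasterize_polyline(template_line), components, label)
  ex <- trim_to_islet(rasterize_polyline(expert_line), components, label)
  if (nrow(te) == 0L || nrow(ex) == 0L) {
    res <- list(avg_distance_px = Inf, template_length_px = nrow(te),
                verdict = "POOR", empty_trim = TRUE)
  } else {
    d <- average_line_distance(ex, te)
    res <- list(avg_distance_px = d, template_length_px = nrow(te),
                verdict = accuracy_verdict(d), empty_trim = FALSE)
  }
  structure(res, class = "accuracy_result")
}

#' @export
print.accuracy_result <- function(x, ...) {
  cat(sprintf("<accuracy_result> avg distance %.3f px over %d template px -> %s\n",
              x$avg_distance_px, x$template_length_px, x$verdict))
  invisible(x)
}

# pixel centers inside a closed polygon, even-odd (crossing number) rule
polygon_fill_count <- function(pts) {
  rmin <- floor(min(pts[, 1])); rmax <- ceiling(max(pts[, 1]))
  cmin <- floor(min(pts[, 2])); cmax <- ceiling(max(pts[, 2]))
  rows <- rmin:rmax; cols <- cmin:cmax
  n <- nrow(pts)
  j <- c(n, seq_len(n - 1L))
  count <- 0L
  for (r in rows) {
    # edges crossing the horizontal line at this row
    y1 <- pts[, 1]; y2 <- pts[j, 1]
    cross <- (y1 <= r & y2 > r) | (y2 <= r & y1 > r)
    if (!any(cross)) next
    xs <- pts[cross, 2] + (r - y1[cross]) * (pts[j, 2][cross] - pts[cross, 2]) /
      (y2[cross] - y1[cross])
    count <- count + sum(rowSums(outer(cols, xs, ">")) %% 2 == 1)
  }
  count
}

#' IE volume enclosed by a drawn contour
#'
#' The contour is treated the way the analysis pipeline treats expert
#' drawings: converted to a filled binary mask (pixel centers inside the
#' polygon under the even-odd rule), whose pixel count gives the area, then
#' area -> equivalent diameter -> IE volume via the spherical model. A
#' degenerate contour enclosing no pixel yields volume 0 with a warning.
#'
#' @param contour A closed [polyline()].
#' @param pixel_size Pixel size in um/px.
#' @return Volume in IE.
#' @export
contour_volume <- function(contour, pixel_size) {
  stopifnot(inherits(contour, "polyline"))
  if (!contour$closed) stopf("contour_volume needs a closed polyline")
  area_px <- polygon_fill_count(contour$points)
  if (area_px == 0L) {
    warning("degenerate contour encloses no pixel; volume is 0 IE")
    return(0)
  }
  islet_volume_ie(equivalent_diameter(area_px, pixel_size))
}

#' Compare an expert volume with a template volume
#'
#' @param v_expert,v_template Volumes in IE; `v_template` must be positive.
#' @return List with `v_expert`, `v_template`,
#'   `relative_error = |v_expert - v_template| / v_template` and
#'   `normalized_volume = v_expert / v_template`.
#' @export
compare_volumes <- function(v_expert, v_template) {
  if (v_template <= 0) stopf("v_template must be positive")
  list(v_expert = v_expert, v_template = v_template,
       relative_error = abs(v_expert - v_template) / v_template,
       normalized_volume = v_expert / v_template)
}

#' Repeatability of replicate volume measurements
#'
#' An expert's repeatability is the coefficient of variation (sample
#' standard deviation over mean) of the volumes they obtained for the same
#' islet on repeated occasions, typically triplicates. A replicate set
#' containing a zero volume is excluded from the CV (the ratio is not a
#' meaningful repeatability there); `excluded` is flagged and `cv` is `NA`.
#'
#' @param volumes Numeric vector of >= 2 replicate volumes in IE.
#' @param sd_type `"sample"` (n-1, default) or `"population"` (n).
#' @return A `replicate_stats`: list with `volumes`, `mean`, `cv`,
#'   `excluded`.
#' @export
replicate_cv <- function(volumes, sd_type = c("sample", "population")) {
  sd_type <- match.arg(sd_type)
  if (length(volumes) < 2L) stopf("replicate_cv needs >= 2 volumes")
  if (any(volumes < 0)) stopf("volumes must be non-negative")
  excluded <- any(volumes == 0)
  m <- mean(volumes)
  s <- stats::sd(volumes)
  if (sd_type == "population")
    s <- s * sqrt((length(volumes) - 1) / length(volumes))
  structure(list(volumes = volumes, mean = m,
                 cv = if (excluded) NA_real_ else s / m,
                 excluded = excluded),
            class = "replicate_stats")
}

#' @export
print.replicate_stats <- function(x, ...) {
  cat(sprintf("<replicate_stats> n = %d, mean = %.3f IE, %s\n",
              length(x$volumes), x$mean,
              if (x$excluded) "EXCLUDED (zero replicate)"
              else sprintf("CV = %.3f", x$cv)))
  invisible(x)
}

#' Write polylines to the CSV interchange format
#'
#' One row per vertex: `author,role,closed,line_id,point_index,row,col`.
#'
#' @param lines List of [polyline()] objects; names become `line_id`s
#'   (defaults to `line1..lineN`).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_polylines <- function(lines, path) {
  if (length(lines) == 0L) {
    writeLines("author,role,closed,line_id,ref,point_index,row,col", path)
    return(invisible(path))
  }
  ids <- names(lines)
  if (is.null(ids)) ids <- paste0("line", seq_along(lines))
  rows <- do.call(rbind, lapply(seq_along(lines), function(i) {
    l <- lines[[i]]
    data.frame(author = l$author, role = l$role, closed = l$closed,
               line_id = ids[i], ref = l$ref %||% NA_character_,
               point_index = seq_len(nrow(l$points)),
               row = l$points[, 1], col = l$points[, 2])
  }))
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read polylines from the CSV interchange format
#'
#' @param path CSV written by [write_polylines()].
#' @return Named list of [polyline()] objects.
#' @export
read_polylines <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  out <- lapply(split(df, df$line_id), function(d) {
    d <- d[order(d$point_index), ]
    polyline(cbind(d$row, d$col), closed = d$closed[1],
             author = d$author[1], role = d$role[1],
             ref = if ("ref" %in% names(d)) as.character(d$ref[1]) else NA_character_)
  })
  out[unique(df$line_id)]
}

#' Score a batch of expert lines against their templates
#'
#' Pairs every expert line with the template named by its `ref` field,
#' resolves the ground-truth component each template belongs to (the modal
#' nonzero label under the template's rasterized pixels), and runs
#' [score_accuracy()] on each pair.
#'
#' @param expert_lines List of expert [polyline()]s with `ref` set.
#' @param templates Named list of template [polyline()]s.
#' @param components A `labeled_components` for the underlying mask.
#' @return Data frame with one row per expert line: `expert`, `template_id`,
#'   `avg_distance_px`, `template_length_px`, `verdict`.
#' @export
accuracy_batch <- function(expert_lines, templates, components) {
  tmpl_label <- vapply(templates, function(tl) {
    px <- rasterize_polyline(tl)
    labs <- trimmed_labels(px, components)
    if (length(labs) == 0L) stopf("template does not touch any islet component")
    as.integer(names(sort(table(labs), decreasing = TRUE))[1])
  }, integer(1))
  rows <- lapply(expert_lines, function(el) {
    if (is.na(el$ref) || !el$ref %in% names(templates))
      stopf("expert line by '%s' references unknown template '%s'",
            el$author, el$ref)
    res <- score_accuracy(el, templates[[el$ref]], components,
                          tmpl_label[[el$ref]])
    data.frame(expert = el$author, template_id = el$ref,
               avg_distance_px = res$avg_distance_px,
               template_length_px = res$template_length_px,
               verdict = res$verdict, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

trimmed_labels <- function(px, components) {
  nr <- nrow(components$labels); nc <- ncol(components$labels)
  inb <- px[, 1] >= 1 & px[, 1] <= nr & px[, 2] >= 1 & px[, 2] <= nc
  labs <- components$labels[px[inb, , drop = FALSE]]
  labs[labs > 0L]
}
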