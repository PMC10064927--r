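# Class codes used in the `classes` matrix of a label_mask.
CLASS_BACKGROUND <- 0L
CLASS_EXOCRINE <- 1L
CLASS_ISLET <- 2L

#' Default gray-level encoding of segmentation masks
#'
#' Maps 8-bit gray levels to tissue classes: 0 = background, 128 = exocrine
#' tissue, 255 = islet. The gray levels are an artifact convention (the class
#' semantics, not the levels, are fixed by the masks' provenance); any
#' three-level encoding can be supplied to [read_mask()] instead.
#'
#' @return Named integer vector mapping class name to gray level, with names
#'   `BACKGROUND`, `EXOCRINE`, `ISLET`.
#' @export
default_mask_encoding <- function() {
  c(BACKGROUND = 0L, EXOCRINE = 128L, ISLET = 255L)
}

class_names <- c("BACKGROUND", "EXOCRINE", "ISLET")

check_encoding <- function(encoding) {
  if (!is.numeric(encoding) || is.null(names(encoding)) ||
      !setequal(names(encoding), class_names))
    stopf("encoding must be a named vector with names BACKGROUND, EXOCRINE, ISLET")
  if (anyDuplicated(encoding)) stopf("encoding gray levels must be distinct")
  enc <- as.integer(encoding[class_names])
  if (any(enc < 0L | enc > 255L)) stopf("encoding gray levels must be in 0..255")
  names(enc) <- class_names
  enc
}

new_label_mask <- function(classes, encoding) {
  structure(list(classes = classes, encoding = encoding),
            class = "label_mask")
}

#' Read a class-coded segmentation mask from a grayscale PNG
#'
#' The mask distinguishes islet, exocrine-tissue and background pixels by
#' gray level. Every gray level present in the file must be covered by the
#' encoding; stray levels are an error (they usually indicate an anti-aliased
#' or re-saved mask, which would silently corrupt areas downstream).
#'
#' @param path Path to an 8-bit single-channel PNG.
#' @param encoding Named integer vector mapping `BACKGROUND`, `EXOCRINE`,
#'   `ISLET` to gray levels; see [default_mask_encoding()].
#' @return A `label_mask`: list with `classes`, an integer matrix coded
#'   0 = background, 1 = exocrine, 2 = islet, and the `encoding` used.
#' @seealso [write_mask()], [label_islets()]
#' @export
read_mask <- function(path, encoding = default_mask_encoding()) {
  enc <- check_encoding(encoding)
  arr <- png::readPNG(path)
  if (length(dim(arr)) == 3L) {
    if (dim(arr)[3] == 2L) arr <- arr[, , 1L]  # gray + alpha
    else stopf("mask '%s' is multi-channel; expected single-channel grayscale", path)
  }
  gray <- matrix(as.integer(round(arr * 255)), nrow = nrow(arr))
  gray_to_class(gray, enc)
}

gray_to_class <- function(gray, enc) {
  present <- sort(unique(as.vector(gray)))
  unmapped <- setdiff(present, enc)
  if (length(unmapped))
    stopf("mask contains gray level(s) not covered by the encoding: %s",
          paste(unmapped, collapse = ", "))
  classes <- matrix(CLASS_BACKGROUND, nrow(gray), ncol(gray))
  classes[gray == enc[["EXOCRINE"]]] <- CLASS_EXOCRINE
  classes[gray == enc[["ISLET"]]] <- CLASS_ISLET
  new_label_mask(classes, enc)
}

#' Write a label mask to an 8-bit grayscale PNG
#'
#' Inverse of [read_mask()]: the written file round-trips pixel-identically.
#'
#' @param mask A `label_mask`.
#' @param path Output PNG path.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "label_mask"))
  enc <- mask$encoding
  gray <- matrix(enc[["BACKGROUND"]], nrow(mask$classes), ncol(mask$classes))
  gray[mask$classes == CLASS_EXOCRINE] <- enc[["EXOCRINE"]]
  gray[mask$classes == CLASS_ISLET] <- enc[["ISLET"]]
  png::writePNG(gray / 255, path)
  invisible(path)
}

#' Read a per-image pixel size table
#'
#' The table accompanies an image bundle and gives the physical pixel size of
#' each micrograph in micrometres per pixel (typical dithizone micrographs
#' fall in roughly 1.4--3.8 um/px). Required header:
#' `image,pixel_size_um_per_px`.
#'
#' @param path CSV path.
#' @return Data frame with columns `image` (character) and
#'   `pixel_size_um_per_px` (positive numeric), one row per image.
#' @export
read_pixel_size_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  need <- c("image", "pixel_size_um_per_px")
  if (!all(need %in% names(df)))
    stopf("pixel size table must have columns %s", paste(need, collapse = ", "))
  ps <- suppressWarnings(as.numeric(df$pixel_size_um_per_px))
  bad <- which(is.na(ps) | ps <= 0)
  if (length(bad))
    stopf("non-positive or non-numeric pixel size at row %d ('%s')",
          bad[1], df$pixel_size_um_per_px[bad[1]])
  out_of_range <- which(ps < 0.1 | ps > 20)
  if (length(out_of_range))
    stopf("pixel size %.4g at row %d is outside the plausible range [0.1, 20] um/px",
          ps[out_of_range[1]], out_of_range[1])
  if (anyDuplicated(df$image))
    stopf("duplicate image id in pixel size table: '%s'",
          df$image[duplicated(df$image)][1])
  data.frame(image = df$image, pixel_size_um_per_px = ps,
             stringsAsFactors = FALSE)
}

#' Look up one image's pixel size
#'
#' @param table Data frame from [read_pixel_size_table()].
#' @param image Image identifier (file stem).
#' @return Pixel size in um/px.
#' @export
pixel_size_for <- function(table, image) {
  i <- match(image, table$image)
  if (is.na(i)) stopf("no pixel size recorded for image '%s'", image)
  table$pixel_size_um_per_px[i]
}

#' Label connected islet components
#'
#' Individuates islets as maximal connected sets of islet-class pixels, so
#' they can be measured, marked with arrows and referenced by per-set
#' numbers. Uses a run-based union-find pass; 8-connectivity is the default
#' because blob-like islets touching diagonally are one object.
#'
#' @param mask A `label_mask` (or a logical/0-1 matrix of islet pixels).
#' @param connectivity 4 or 8.
#' @return A `labeled_components`: list with `labels`, an integer matrix
#'   (0 = not islet, components numbered 1..n in row-major order of first
#'   appearance), `n_components` and `connectivity`.
#' @export
label_islets <- function(mask, connectivity = 8) {
  fg <- if (inherits(mask, "label_mask")) mask$classes == CLASS_ISLET
        else mask > 0
  if (!connectivity %in% c(4, 8)) stopf("connectivity must be 4 or 8")
  labels <- label_binary(fg, connectivity)
  structure(list(labels = labels, n_components = max(labels),
                 connectivity = as.integer(connectivity)),
            class = "labeled_components")
}

# Run-based two-pass labeling: decompose each row into runs of foreground,
# union runs in adjacent rows whose column spans touch (expanded by 1 for
# 8-connectivity), then relabel union-find roots to 1..n.
label_binary <- function(fg, connectivity) {
  nr <- nrow(fg); nc <- ncol(fg)
  runs_start <- list(); runs_end <- list()
  run_row <- integer(0); run_s <- integer(0); run_e <- integer(0)
  for (r in seq_len(nr)) {
    v <- fg[r, ]
    if (!any(v)) next
    d <- diff(c(FALSE, v, FALSE))
    s <- which(d == 1L); e <- which(d == -1L) - 1L
    run_row <- c(run_row, rep(r, length(s)))
    run_s <- c(run_s, s); run_e <- c(run_e, e)
  }
  n_runs <- length(run_row)
  if (n_runs == 0L) return(matrix(0L, nr, nc))
  parent <- seq_len(n_runs)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  slack <- if (connectivity == 8) 1L else 0L
  row_of <- split(seq_len(n_runs), run_row)
  rows_present <- as.integer(names(row_of))
  for (k in seq_along(rows_present)[-1]) {
    if (rows_present[k] - rows_present[k - 1] != 1L) next
    for (i in row_of[[k]]) for (j in row_of[[k - 1]]) {
      if (run_s[i] <= run_e[j] + slack && run_e[i] >= run_s[j] - slack) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
      }
    }
  }
  root <- vapply(seq_len(n_runs), find, integer(1))
  # first-appearance order: runs are already row-major
  lab_of_root <- integer(n_runs)
  nxt <- 0L
  comp <- integer(n_runs)
  for (i in seq_len(n_runs)) {
    r <- root[i]
    if (lab_of_root[r] == 0L) { nxt <- nxt + 1L; lab_of_root[r] <- nxt }
    comp[i] <- lab_of_root[r]
  }
  labels <- matrix(0L, nr, nc)
  for (i in seq_len(n_runs))
    labels[run_row[i], run_s[i]:run_e[i]] <- comp[i]
  labels
}

#' @export
print.label_mask <- function(x, ...) {
  tab <- table(factor(x$classes, levels = 0:2, labels = class_names))
  cat(sprintf("<label_mask> %d x %d px | %s\n", nrow(x$classes), ncol(x$classes),
              paste(sprintf("%s: %d", names(tab), tab), collapse = ", ")))
  invisible(x)
}

#' @export
print.labeled_components <- function(x, ...) {
  cat(sprintf("<labeled_components> %d x %d px, %d islet(s), %d-connectivity\n",
              nrow(x$labels), ncol(x$labels), x$n_components, x$connectivity))
  invisible(x)
}
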