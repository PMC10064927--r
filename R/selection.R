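#' Randomly select images for a review set
#'
#' Uniform sample without replacement. When `n_images` is at least the
#' number of candidates, all candidates are returned in their original
#' order. Draws come from R's RNG; seed at the call site (the bundled set
#' builders do this for you).
#'
#' @param image_ids Character vector of candidate image ids.
#' @param n_images Number of images to draw (>= 1).
#' @return Character vector of selected ids.
#' @export
select_images <- function(image_ids, n_images) {
  if (length(image_ids) == 0L) stopf("no candidate images")
  if (n_images < 1) stopf("n_images must be >= 1")
  if (n_images >= length(image_ids)) return(image_ids)
  image_ids[sort(sample.int(length(image_ids), n_images))]
}

#' Size-stratified random islet selection
#'
#' Only islets with equivalent diameter at or above the threshold are
#' eligible. Selection then proceeds by round-robin over the occupied 50 um
#' size categories in ascending order — one uniform draw without replacement
#' from each category in turn — until the quota is filled or eligibility is
#' exhausted. This guarantees that whenever the quota is at least the number
#' of occupied categories, every occupied category is represented, so the
#' chosen islets span the size range rather than following its (typically
#' small-islet-heavy) frequency distribution.
#'
#' @param records Morphometry data frame from [summarize_image()].
#' @param threshold_um Minimum equivalent diameter for eligibility.
#' @param quota Maximum number of islets to select (>= 1).
#' @return Integer vector of selected `islet_label`s (selection order).
#' @export
select_islets_stratified <- function(records, threshold_um = 50, quota = 7) {
  if (quota < 1) stopf("quota must be >= 1")
  elig <- records[records$eq_diameter_um >= threshold_um, , drop = FALSE]
  if (nrow(elig) == 0L) return(integer(0))
  pools <- lapply(split(elig$islet_label, elig$size_category),
                  function(x) x[sample.int(length(x))])
  pools <- pools[order(as.integer(names(pools)))]
  chosen <- integer(0)
  while (length(chosen) < quota && any(lengths(pools) > 0L)) {
    for (k in seq_along(pools)) {
      if (length(chosen) >= quota) break
      if (length(pools[[k]]) == 0L) next
      chosen <- c(chosen, pools[[k]][1L])
      pools[[k]] <- pools[[k]][-1L]
    }
  }
  chosen
}

bundle_paths <- function(bundle_dir) {
  imgs <- list.files(file.path(bundle_dir, "images"), pattern = "\\.png$",
                     full.names = TRUE)
  masks <- list.files(file.path(bundle_dir, "masks"), pattern = "\\.png$",
                      full.names = TRUE)
  stems <- tools::file_path_sans_ext(basename(imgs))
  if (anyDuplicated(stems))
    stopf("duplicate image id in bundle: '%s'", stems[duplicated(stems)][1])
  list(images = stats::setNames(imgs, stems),
       masks = stats::setNames(masks, tools::file_path_sans_ext(basename(masks))),
       pixel_sizes = read_pixel_size_table(file.path(bundle_dir, "pixel_sizes.csv")))
}

new_manifest <- function(set_name, seed, threshold_um, mode, entries) {
  structure(list(set_name = set_name, seed = seed,
                 size_threshold_um = threshold_um, mode = mode,
                 entries = entries),
            class = "selection_manifest")
}

#' Build a validation-scenario review set
#'
#' The automated upload engine: from a bundle directory containing
#' `images/`, `masks/` and `pixel_sizes.csv`, draw `n_images` random images,
#' then within each image draw up to `quota_per_image` islets stratified by
#' 50 um size category above the size threshold. Selected images and islets
#' receive per-set identification numbers (contiguous from 1). A single
#' seeded generator drives the image draw followed by the per-image islet
#' draws in image order, so the manifest is bit-reproducible.
#'
#' @param bundle_dir Bundle directory.
#' @param n_images Number of images to draw.
#' @param threshold_um Islet size threshold in um (default 50).
#' @param quota_per_image Maximum marked islets per image (default 7).
#' @param seed Integer seed.
#' @param set_name Name recorded in the manifest.
#' @param out_dir If non-NULL, [write_manifest()] and arrow-marked review
#'   PNGs are written there.
#' @param encoding Mask encoding, see [read_mask()].
#' @param connectivity Islet labeling connectivity.
#' @return A `selection_manifest`: list with `set_name`, `seed`,
#'   `size_threshold_um`, `mode = "VALIDATION"` and `entries`, a data frame
#'   with one row per marked islet (`image`, `set_image_no`, `islet_label`,
#'   `set_islet_no`, `centroid_row`, `centroid_col`, `size_category`).
#' @export
build_validation_set <- function(bundle_dir, n_images, threshold_um = 50,
                                 quota_per_image = 7, seed = 1L,
                                 set_name = "validation", out_dir = NULL,
                                 encoding = default_mask_encoding(),
                                 connectivity = 8) {
  bp <- bundle_paths(bundle_dir)
  for (id in names(bp$images)) {
    if (!id %in% names(bp$masks)) stopf("image '%s' has no mask", id)
    if (!id %in% bp$pixel_sizes$image) stopf("image '%s' has no pixel size", id)
  }
  entries <- with_seed(seed, {
    picked <- select_images(names(bp$images), n_images)
    rows <- list()
    for (i in seq_along(picked)) {
      id <- picked[i]
      comp <- label_islets(read_mask(bp$masks[[id]], encoding), connectivity)
      rec <- summarize_image(comp, pixel_size_for(bp$pixel_sizes, id))
      labs <- select_islets_stratified(rec, threshold_um, quota_per_image)
      if (length(labs) == 0L) next
      r <- rec[match(labs, rec$islet_label), ]
      rows[[length(rows) + 1L]] <- data.frame(
        image = id, set_image_no = i, islet_label = r$islet_label,
        set_islet_no = seq_along(labs),
        centroid_row = r$centroid_row, centroid_col = r$centroid_col,
        size_category = r$size_category, stringsAsFactors = FALSE)
    }
    if (length(rows)) do.call(rbind, rows)
    else data.frame(image = character(0), set_image_no = integer(0),
                    islet_label = integer(0), set_islet_no = integer(0),
                    centroid_row = numeric(0), centroid_col = numeric(0),
                    size_category = integer(0))
  })
  man <- new_manifest(set_name, as.integer(seed), threshold_um, "VALIDATION",
                      entries)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_manifest(man, file.path(out_dir, "manifest.csv"))
    for (id in unique(entries$image)) {
      img <- read_image_png(bp$images[[id]])
      e <- entries[entries$image == id, ]
      marked <- render_arrows(img, data.frame(row = round(e$centroid_row),
                                              col = round(e$centroid_col)))
      write_image_png(marked, file.path(out_dir, paste0(id, "_marked.png")))
    }
  }
  man
}

#' Build an inquiry-scenario review set from manual picks
#'
#' The inquiry scenario serves the ground-truth-generating expert in
#' collecting peer advice on a handful of hand-picked difficult objects in a
#' single image. The given labels are preserved in order and numbered 1..n.
#'
#' @param image_id Image identifier.
#' @param components The image's `labeled_components`.
#' @param islet_labels Integer labels of the marked objects (nonempty, no
#'   duplicates, all present in `components`).
#' @param pixel_size Pixel size in um/px (for size categories).
#' @param set_name Name recorded in the manifest.
#' @return A `selection_manifest` with `mode = "INQUIRY"`.
#' @export
build_inquiry_set <- function(image_id, components, islet_labels, pixel_size,
                              set_name = "inquiry") {
  if (length(islet_labels) == 0L) stopf("islet_labels must be nonempty")
  if (anyDuplicated(islet_labels))
    stopf("duplicate islet label: %d", islet_labels[duplicated(islet_labels)][1])
  rec <- summarize_image(components, pixel_size)
  miss <- setdiff(islet_labels, rec$islet_label)
  if (length(miss)) stopf("unknown islet label: %d", miss[1])
  r <- rec[match(islet_labels, rec$islet_label), ]
  entries <- data.frame(image = image_id, set_image_no = 1L,
                        islet_label = r$islet_label,
                        set_islet_no = seq_along(islet_labels),
                        centroid_row = r$centroid_row,
                        centroid_col = r$centroid_col,
                        size_category = r$size_category,
                        stringsAsFactors = FALSE)
  new_manifest(set_name, NA_integer_, NA_real_, "INQUIRY", entries)
}

#' Write a selection manifest to CSV
#'
#' Header comment lines (`#key=value`) carry the set name, seed, threshold
#' and mode; then one row per marked islet with stable column order.
#'
#' @param manifest A `selection_manifest`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("#set_name=%s", manifest$set_name),
               sprintf("#seed=%s", manifest$seed),
               sprintf("#size_threshold_um=%s", manifest$size_threshold_um),
               sprintf("#mode=%s", manifest$mode)), con)
  utils::write.csv(manifest$entries, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a selection manifest written by [write_manifest()]
#'
#' @param path Manifest CSV path.
#' @return A `selection_manifest`.
#' @export
read_manifest <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  kv <- do.call(rbind, strsplit(sub("^#", "", hdr), "=", fixed = TRUE))
  meta <- stats::setNames(kv[, 2], kv[, 1])
  entries <- utils::read.csv(text = lines[!grepl("^#", lines)],
                             stringsAsFactors = FALSE)
  entries$image <- as.character(entries$image)
  new_manifest(meta[["set_name"]],
               suppressWarnings(as.integer(meta[["seed"]])),
               suppressWarnings(as.numeric(meta[["size_threshold_um"]])),
               meta[["mode"]], entries)
}

#' @export
print.selection_manifest <- function(x, ...) {
  cat(sprintf("<selection_manifest> '%s' (%s): %d image(s), %d marked islet(s)\n",
              x$set_name, x$mode, length(unique(x$entries$image)),
              nrow(x$entries)))
  invisible(x)
}
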