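#' Specify a synthetic islet scene
#'
#' Describes one synthetic micrograph: blob-like islets of known equivalent
#' diameter on a light background, optional exocrine distractor blobs, and a
#' matching class-coded mask. Diameters span the working range of islet
#' counting (roughly 50--400 um; the generator accepts 20--500).
#'
#' @param height_px,width_px Image size in px.
#' @param pixel_size_um Pixel size in um/px.
#' @param islets Data frame with columns `center_row`, `center_col`,
#'   `eq_diameter_um`, and optionally `shape` (`"disc"` or `"blob"`),
#'   `irregularity` (relative radial harmonic amplitude, default 0.12) and
#'   `embedded` (logical: wrap the islet in an exocrine annulus).
#' @param n_exocrine_distractors Number of small exocrine-only blobs.
#' @param seed Integer seed controlling blob shapes and rendering jitter.
#' @return A `scene_spec`.
#' @export
scene_spec <- function(height_px = 512L, width_px = 512L, pixel_size_um = 2,
                       islets = NULL, n_exocrine_distractors = 0L, seed = 1L) {
  if (is.null(islets))
    islets <- data.frame(center_row = numeric(0), center_col = numeric(0),
                         eq_diameter_um = numeric(0))
  if (!all(c("center_row", "center_col", "eq_diameter_um") %in% names(islets)))
    stopf("islets needs center_row, center_col, eq_diameter_um")
  if (nrow(islets)) {
    if (is.null(islets$shape)) islets$shape <- "blob"
    if (is.null(islets$irregularity)) islets$irregularity <- 0.12
    if (is.null(islets$embedded)) islets$embedded <- FALSE
    if (any(islets$eq_diameter_um < 20 | islets$eq_diameter_um > 500))
      stopf("islet diameters must be in [20, 500] um")
    r_px <- islets$eq_diameter_um / 2 / pixel_size_um
    fit <- islets$center_row - r_px >= 1 & islets$center_row + r_px <= height_px &
           islets$center_col - r_px >= 1 & islets$center_col + r_px <= width_px
    if (!all(fit)) stopf("islet %d does not fit within the image", which(!fit)[1])
  }
  structure(list(height_px = as.integer(height_px),
                 width_px = as.integer(width_px),
                 pixel_size_um = pixel_size_um, islets = islets,
                 n_exocrine_distractors = as.integer(n_exocrine_distractors),
                 seed = as.integer(seed)),
            class = "scene_spec")
}

# radial profile of one blob: r(theta) = r0 * (1 + sum_k a_k cos(k theta + phi_k)),
# low-order harmonics k = 2..4, amplitudes scaled by `irregularity`
blob_radius_fun <- function(r0, irregularity) {
  if (irregularity <= 0) return(function(theta) rep(r0, length(theta)))
  k <- 2:4
  amp <- irregularity * r0 * stats::runif(3, 0.3, 1) / seq_along(k)
  phi <- stats::runif(3, 0, 2 * pi)
  function(theta)
    r0 + Reduce(`+`, lapply(seq_along(k),
                            function(i) amp[i] * cos(k[i] * theta + phi[i])))
}

paint_blob <- function(canvas, center, rfun, rmax, value) {
  nr <- nrow(canvas); nc <- ncol(canvas)
  r1 <- max(1L, floor(center[1] - rmax)); r2 <- min(nr, ceiling(center[1] + rmax))
  c1 <- max(1L, floor(center[2] - rmax)); c2 <- min(nc, ceiling(center[2] + rmax))
  rows <- r1:r2; cols <- c1:c2
  dr <- outer(rows - center[1], rep(1, length(cols)))
  dc <- outer(rep(1, length(rows)), cols - center[2])
  theta <- atan2(dr, dc)
  inside <- sqrt(dr^2 + dc^2) <= matrix(rfun(as.vector(theta)),
                                        length(rows), length(cols))
  sub <- canvas[rows, cols, drop = FALSE]
  clash_islet <- sum(inside & sub == CLASS_ISLET & value == CLASS_ISLET)
  sub[inside] <- value
  canvas[rows, cols] <- sub
  list(canvas = canvas, n_painted = sum(inside), clash_islet = clash_islet)
}

#' Render a synthetic scene: image, mask and true morphometry
#'
#' Islets are rasterized as discs or low-order radial-harmonic blobs
#' (star-shaped, area within a few percent of the nominal equivalent
#' diameter), painted into the mask's islet class; embedded islets receive
#' a surrounding exocrine annulus, and exocrine distractors are painted
#' into the exocrine class. The RGB image shows reddish islets and pale
#' exocrine blobs on a light background with deterministic brightness
#' jitter. Non-embedded islets may not overlap each other.
#'
#' @param spec A [scene_spec()].
#' @return List with `image` (RGB array), `mask` (a `label_mask`),
#'   `components` (a `labeled_components`), and `records`: the measured
#'   morphometry ([summarize_image()]) joined with the generating truth
#'   (`true_diameter_um`, `shape`, `embedded`).
#' @export
make_scene <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  with_seed(spec$seed, {
    classes <- matrix(0L, spec$height_px, spec$width_px)
    isl <- spec$islets
    order_ix <- seq_len(nrow(isl))
    for (i in order_ix) {
      r0 <- isl$eq_diameter_um[i] / 2 / spec$pixel_size_um
      rfun <- if (isl$shape[i] == "disc") blob_radius_fun(r0, 0)
              else blob_radius_fun(r0, isl$irregularity[i])
      if (isl$embedded[i]) {
        ann <- paint_blob(classes, c(isl$center_row[i], isl$center_col[i]),
                          function(th) rfun(th) * 1.3, r0 * 1.6, CLASS_EXOCRINE)
        classes <- ann$canvas
      }
      res <- paint_blob(classes, c(isl$center_row[i], isl$center_col[i]),
                        rfun, r0 * 1.5, CLASS_ISLET)
      if (!isl$embedded[i] && res$clash_islet > 0)
        stopf("islet %d overlaps an earlier islet", i)
      classes <- res$canvas
    }
    for (j in seq_len(spec$n_exocrine_distractors)) {
      r0 <- stats::runif(1, 5, 15)
      ctr <- c(stats::runif(1, r0 + 1, spec$height_px - r0),
               stats::runif(1, r0 + 1, spec$width_px - r0))
      rfun <- blob_radius_fun(r0, 0.2)
      res <- paint_blob(classes, ctr, rfun, r0 * 1.5, CLASS_EXOCRINE)
      # distractors must not eat islet pixels
      keep_islet <- classes == CLASS_ISLET
      canvas <- res$canvas
      canvas[keep_islet] <- CLASS_ISLET
      classes <- canvas
    }
    mask <- new_label_mask(classes, check_encoding(default_mask_encoding()))
    image <- render_scene_image(classes)
    components <- label_islets(mask)
    records <- summarize_image(components, spec$pixel_size_um)
    if (nrow(isl)) {
      ctr_lab <- components$labels[cbind(round(isl$center_row),
                                         round(isl$center_col))]
      truth <- data.frame(islet_label = ctr_lab,
                          true_diameter_um = isl$eq_diameter_um,
                          shape = isl$shape, embedded = isl$embedded)
      records <- merge(records, truth, by = "islet_label", all.x = TRUE,
                       sort = TRUE)
    }
    list(image = image, mask = mask, components = components,
         records = records)
  })
}

# cosmetic rendering: dithizone-like reddish islets on a light field
render_scene_image <- function(classes) {
  nr <- nrow(classes); nc <- ncol(classes)
  base <- list(c(235, 228, 222), c(214, 182, 170), c(176, 58, 66))
  jitter <- matrix(stats::rnorm(nr * nc, 0, 4), nr, nc)
  img <- array(0L, dim = c(nr, nc, 3L))
  for (ch in 1:3) {
    plane <- matrix(base[[1]][ch], nr, nc)
    plane[classes == CLASS_EXOCRINE] <- base[[2]][ch]
    plane[classes == CLASS_ISLET] <- base[[3]][ch]
    img[, , ch] <- pmin(255L, pmax(0L, as.integer(round(plane + jitter))))
  }
  img
}

#' Derive a template line from a ground-truth islet component
#'
#' `CONTOUR` returns the component's boundary as a closed polyline, vertices
#' ordered by angle around the centroid (the generator's blobs are
#' star-shaped, so angular ordering traces the boundary faithfully).
#' `SEPARATION` returns a random chord through the centroid, extended past
#' the component on both sides, as an open 2-point polyline.
#'
#' @param components A `labeled_components`.
#' @param label Component label.
#' @param kind `"CONTOUR"` or `"SEPARATION"`.
#' @param author Recorded author id.
#' @return A [polyline()] with role `TEMPLATE`.
#' @export
make_template_lines <- function(components, label,
                                kind = c("CONTOUR", "SEPARATION"),
                                author = "template") {
  kind <- match.arg(kind)
  idx <- which(components$labels == label, arr.ind = TRUE)
  if (nrow(idx) < 3L) stopf("component %s too small for a template", label)
  ctr <- colMeans(idx)
  if (kind == "CONTOUR") {
    bset <- extract_boundaries(components)
    b <- bset[[as.character(label)]]
    ang <- atan2(b[, 1] - ctr[1], b[, 2] - ctr[2])
    b <- b[order(ang), , drop = FALSE]
    polyline(b, closed = TRUE, author = author, role = "TEMPLATE")
  } else {
    theta <- stats::runif(1, 0, pi)
    ext <- max(max(idx[, 1]) - min(idx[, 1]), max(idx[, 2]) - min(idx[, 2]))
    d <- c(sin(theta), cos(theta)) * ext
    polyline(rbind(ctr - d, ctr + d), closed = FALSE, author = author,
             role = "TEMPLATE")
  }
}

#' An expert's simulated drawing behavior
#'
#' @param id Expert identifier.
#' @param jitter_sigma_px Marginal SD of the perpendicular tracing jitter.
#' @param p_false_call Probability of disputing a (correct) contour.
#' @param p_quality_issue Probability of down-rating an image's quality.
#' @return An `expert_profile`.
#' @export
expert_profile <- function(id, jitter_sigma_px = 1, p_false_call = 0.2,
                           p_quality_issue = 0.15) {
  stopifnot(jitter_sigma_px >= 0, p_false_call >= 0, p_false_call <= 1,
            p_quality_issue >= 0, p_quality_issue <= 1)
  structure(list(id = id, jitter_sigma_px = jitter_sigma_px,
                 p_false_call = p_false_call,
                 p_quality_issue = p_quality_issue),
            class = "expert_profile")
}

#' Simulate an expert tracing a template line
#'
#' Each vertex is displaced along the local curve normal by Gaussian jitter
#' of marginal SD `sigma`. The noise is correlated along the curve (raw
#' per-vertex draws are convolved with a Gaussian kernel, circularly for
#' closed contours, then rescaled to marginal SD `sigma`): a tracing hand
#' drifts smoothly off the target line rather than oscillating per pixel,
#' and the rescaling makes the injected noise level the realized one, not
#' an upper bound eroded by the smoothing.
#'
#' @param template A template [polyline()].
#' @param sigma Perpendicular jitter SD in px (0 returns the template's
#'   geometry unchanged).
#' @param author Expert id recorded on the returned line.
#' @param ref Template id recorded on the returned line.
#' @param correlation_px Correlation length of the jitter along the curve,
#'   as the SD (in vertices, i.e. roughly px) of the smoothing kernel; 0
#'   disables smoothing.
#' @return An expert [polyline()], closed iff the template is closed.
#' @export
simulate_expert_line <- function(template, sigma, author = "expert",
                                 ref = NA_character_, correlation_px = 8) {
  stopifnot(inherits(template, "polyline"), sigma >= 0)
  pts <- template$points
  n <- nrow(pts)
  if (sigma == 0)
    return(polyline(pts, closed = template$closed, author = author,
                    role = "EXPERT", ref = ref))
  noise <- stats::rnorm(n)
  if (correlation_px > 0 && n >= 5L) {
    half <- min(ceiling(3 * correlation_px), floor((n - 1) / 2))
    kern <- stats::dnorm(-half:half, sd = correlation_px)
    kern <- kern / sum(kern)
    idx <- function(k) if (template$closed) ((seq_len(n) - 1 + k) %% n) + 1
                       else pmin(pmax(seq_len(n) + k, 1L), n)
    sm <- rep(0, n)
    for (k in -half:half) sm <- sm + kern[k + half + 1] * noise[idx(k)]
    noise <- sm / stats::sd(sm)   # restore unit marginal SD
  }
  disp <- sigma * noise
  # local tangent by central differences; normal = tangent rotated 90 deg
  nxt <- if (template$closed) c(2:n, 1) else c(2:n, n)
  prv <- if (template$closed) c(n, 1:(n - 1)) else c(1, 1:(n - 1))
  tang <- pts[nxt, , drop = FALSE] - pts[prv, , drop = FALSE]
  len <- sqrt(rowSums(tang^2)); len[len == 0] <- 1
  normal <- cbind(-tang[, 2], tang[, 1]) / len
  polyline(pts + disp * normal, closed = template$closed, author = author,
           role = "EXPERT", ref = ref)
}

#' Simulate an opinion set for a review manifest
#'
#' Emits, per expert profile, one [image_opinion()] for every manifest
#' image (down-rated to `BORDERLINE` or `UNACCEPTABLE` with probability
#' `p_quality_issue`) and one [islet_opinion()] for every marked islet:
#' `FALSE_CONTOUR` with probability `p_false_call`, carrying a full redraw
#' of the ground-truth contour traced with the expert's jitter; otherwise
#' `TRUE_CONTOUR`.
#'
#' @param manifest A `selection_manifest`.
#' @param profiles List of [expert_profile()]s.
#' @param bundle_dir Bundle directory (masks provide the ground truth).
#' @param seed Integer seed.
#' @param encoding Mask encoding. @param connectivity Labeling connectivity.
#' @return List of opinion objects, valid against `manifest`.
#' @export
simulate_opinions <- function(manifest, profiles, bundle_dir, seed = 1L,
                              encoding = default_mask_encoding(),
                              connectivity = 8) {
  bp <- bundle_paths(bundle_dir)
  images <- unique(manifest$entries$image)
  comps <- lapply(images, function(id)
    label_islets(read_mask(bp$masks[[id]], encoding), connectivity))
  names(comps) <- images
  with_seed(seed, {
    ops <- list()
    for (p in profiles) {
      for (id in images) {
        quality <- if (stats::runif(1) < p$p_quality_issue)
          sample(c("BORDERLINE", "UNACCEPTABLE"), 1) else "GOOD"
        ops[[length(ops) + 1L]] <- image_opinion(p$id, id, quality)
        e <- manifest$entries[manifest$entries$image == id, ]
        for (k in seq_len(nrow(e))) {
          if (stats::runif(1) < p$p_false_call) {
            tmpl <- make_template_lines(comps[[id]], e$islet_label[k],
                                        "CONTOUR", author = "ground_truth")
            redraw <- simulate_expert_line(tmpl, max(p$jitter_sigma_px, 2),
                                           author = p$id)
            ops[[length(ops) + 1L]] <- islet_opinion(
              p$id, id, e$set_islet_no[k], "FALSE_CONTOUR",
              edits = list(graphical_edit("FULL_REDRAW", redraw)))
          } else {
            ops[[length(ops) + 1L]] <- islet_opinion(p$id, id,
                                                     e$set_islet_no[k],
                                                     "TRUE_CONTOUR")
          }
        }
      }
    }
    ops
  })
}

#' Write a complete synthetic review bundle
#'
#' Generates `n_images` scenes and writes the directory layout the
#' selection engine consumes: `images/*.png`, `masks/*.png` and
#' `pixel_sizes.csv`. Defaults emulate a multi-center upload: pixel sizes
#' drawn uniformly from 1.41--3.77 um/px, 4--10 blob islets per image with
#' equivalent diameters spanning 50--400 um (skewed toward small islets, as
#' real isolates are), plus a couple of exocrine distractors; roughly one
#' islet in five is embedded in an exocrine annulus.
#'
#' @param dir Output directory (created).
#' @param n_images Number of images (default 19).
#' @param seed Master seed; per-image seeds are derived from it.
#' @param height_px,width_px Scene size.
#' @param pixel_size_range um/px range to draw from.
#' @param islets_per_image Range (min, max) of islets per image.
#' @param diameter_range_um Equivalent-diameter range.
#' @param p_embedded Probability an islet is embedded.
#' @return Invisible list of the generated scenes, named by image id.
#' @export
make_fixture_bundle <- function(dir, n_images = 19L, seed = 1L,
                                height_px = 400L, width_px = 400L,
                                pixel_size_range = c(1.41, 3.77),
                                islets_per_image = c(4L, 10L),
                                diameter_range_um = c(50, 400),
                                p_embedded = 0.2) {
  dir.create(file.path(dir, "images"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "masks"), recursive = TRUE, showWarnings = FALSE)
  scenes <- with_seed(seed, {
    out <- list()
    ps_tab <- data.frame(image = character(0), pixel_size_um_per_px = numeric(0))
    for (i in seq_len(n_images)) {
      id <- sprintf("img%02d", i)
      ps <- stats::runif(1, pixel_size_range[1], pixel_size_range[2])
      n_isl <- sample(islets_per_image[1]:islets_per_image[2], 1)
      isl <- place_islets(n_isl, height_px, width_px, ps, diameter_range_um,
                          p_embedded)
      spec <- scene_spec(height_px, width_px, ps, isl,
                         n_exocrine_distractors = 2L,
                         seed = sample.int(2^30, 1))
      sc <- make_scene(spec)
      write_image_png(sc$image, file.path(dir, "images", paste0(id, ".png")))
      write_mask(sc$mask, file.path(dir, "masks", paste0(id, ".png")))
      ps_tab <- rbind(ps_tab, data.frame(image = id, pixel_size_um_per_px = ps))
      out[[id]] <- sc
    }
    utils::write.csv(format(ps_tab, digits = 6),
                     file.path(dir, "pixel_sizes.csv"),
                     row.names = FALSE, quote = FALSE)
    out
  })
  invisible(scenes)
}

# rejection-sample non-overlapping islet placements; diameters skewed small
place_islets <- function(n, height_px, width_px, pixel_size, d_range,
                         p_embedded) {
  placed <- data.frame(center_row = numeric(0), center_col = numeric(0),
                       eq_diameter_um = numeric(0))
  # largest diameter whose blob (with harmonic/annulus head-room) fits
  d_fit <- (min(height_px, width_px) / 2 - 5) / 1.35 * 2 * pixel_size
  d_hi <- min(d_range[2], d_fit)
  for (i in seq_len(n)) {
    if (d_hi <= d_range[1]) break
    d <- d_range[1] * (d_hi / d_range[1])^(stats::rbeta(1, 1, 2.5))
    r_px <- d / 2 / pixel_size * 1.35   # head-room for blob harmonics/annulus
    for (try in 1:50) {
      ctr <- c(stats::runif(1, r_px + 2, height_px - r_px - 2),
               stats::runif(1, r_px + 2, width_px - r_px - 2))
      if (nrow(placed) == 0L) break
      sep <- sqrt((placed$center_row - ctr[1])^2 + (placed$center_col - ctr[2])^2)
      min_sep <- placed$eq_diameter_um / 2 / pixel_size * 1.35 + r_px + 3
      if (all(sep > min_sep)) break
      ctr <- NULL
    }
    if (is.null(ctr)) next   # scene crowded; place fewer islets
    placed <- rbind(placed, data.frame(center_row = ctr[1], center_col = ctr[2],
                                       eq_diameter_um = d))
  }
  placed$shape <- "blob"
  placed$irregularity <- stats::runif(nrow(placed), 0.05, 0.15)
  placed$embedded <- stats::runif(nrow(placed)) < p_embedded
  placed
}

#' Simulate the line-tracing accuracy experiment
#'
#' Builds a scene with `n_templates` islets, derives one separation-line
#' template per islet, has every simulated expert trace every template with
#' their own jitter, and scores all lines with [accuracy_batch()]: the
#' protocol of a drawing-accuracy study (default 9 experts x 15 templates
#' = 135 scored lines).
#'
#' @param n_experts,n_templates Experiment size.
#' @param sigmas Per-expert jitter SDs in px, recycled to `n_experts`.
#'   Default spans accurate (0.5 px) to sloppy (2.5 px) tracers.
#' @param seed Integer seed.
#' @return List with `results` (the [accuracy_batch()] data frame),
#'   `templates`, `expert_lines` and `scene`.
#' @export
simulate_accuracy_experiment <- function(n_experts = 9L, n_templates = 15L,
                                         sigmas = seq(0.5, 2.5,
                                                      length.out = n_experts),
                                         seed = 1L) {
  with_seed(seed, {
    grid_n <- ceiling(sqrt(n_templates))
    cell <- 110
    side <- grid_n * cell + 20
    centers <- expand.grid(r = seq_len(grid_n), c = seq_len(grid_n))[
      seq_len(n_templates), ]
    isl <- data.frame(center_row = 10 + (centers$r - 0.5) * cell,
                      center_col = 10 + (centers$c - 0.5) * cell,
                      eq_diameter_um = stats::runif(n_templates, 60, 95),
                      shape = "blob", irregularity = 0.1, embedded = FALSE)
    sc <- make_scene(scene_spec(side, side, pixel_size_um = 1, islets = isl,
                                seed = sample.int(2^30, 1)))
    labs <- sort(sc$records$islet_label)[seq_len(n_templates)]
    templates <- lapply(labs, function(l)
      make_template_lines(sc$components, l, "SEPARATION"))
    names(templates) <- paste0("t", seq_along(templates))
    # densify 2-point chords so jitter acts per-pixel along the line
    templates <- lapply(templates, function(tl) {
      px <- rasterize_polyline(tl)
      polyline(px, closed = FALSE, author = tl$author, role = "TEMPLATE")
    })
    sigmas <- rep_len(sigmas, n_experts)
    expert_lines <- list()
    for (e in seq_len(n_experts)) {
      for (t in names(templates)) {
        expert_lines[[length(expert_lines) + 1L]] <-
          simulate_expert_line(templates[[t]], sigmas[e],
                               author = sprintf("expert%d", e), ref = t)
      }
    }
    list(results = accuracy_batch(expert_lines, templates, sc$components),
         templates = templates, expert_lines = expert_lines, scene = sc)
  })
}

#' Simulate the replicate contour reproducibility experiment
#'
#' One embedded islet is re-traced `n_replicates` times by each simulated
#' expert (default 9 x 3 = 27 contours); each contour is converted to an IE
#' volume and each expert's replicate CV is computed.
#'
#' @param n_experts,n_replicates Experiment size.
#' @param sigmas Per-expert jitter SDs in px, recycled.
#' @param seed Integer seed.
#' @return List with `volumes` (data frame `expert`, `replicate`,
#'   `volume_ie`), `per_expert` (data frame `expert`, `mean_ie`, `cv`,
#'   `excluded`) and `template_volume_ie`.
#' @export
simulate_replicate_experiment <- function(n_experts = 9L, n_replicates = 3L,
                                          sigmas = seq(0.5, 3,
                                                       length.out = n_experts),
                                          seed = 1L) {
  with_seed(seed, {
    isl <- data.frame(center_row = 100, center_col = 100,
                      eq_diameter_um = 120, shape = "blob",
                      irregularity = 0.12, embedded = TRUE)
    sc <- make_scene(scene_spec(200L, 200L, pixel_size_um = 1, islets = isl,
                                seed = sample.int(2^30, 1)))
    lab <- sc$records$islet_label[1]
    tmpl <- make_template_lines(sc$components, lab, "CONTOUR")
    v_tmpl <- contour_volume(tmpl, 1)
    sigmas <- rep_len(sigmas, n_experts)
    rows <- list()
    for (e in seq_len(n_experts)) for (r in seq_len(n_replicates)) {
      drawn <- simulate_expert_line(tmpl, sigmas[e],
                                    author = sprintf("expert%d", e))
      rows[[length(rows) + 1L]] <- data.frame(
        expert = sprintf("expert%d", e), replicate = r,
        volume_ie = contour_volume(drawn, 1), stringsAsFactors = FALSE)
    }
    volumes <- do.call(rbind, rows)
    per_expert <- do.call(rbind, lapply(split(volumes, volumes$expert), function(d) {
      st <- replicate_cv(d$volume_ie)
      data.frame(expert = d$expert[1], mean_ie = st$mean, cv = st$cv,
                 excluded = st$excluded, stringsAsFactors = FALSE)
    }))
    rownames(per_expert) <- NULL
    list(volumes = volumes, per_expert = per_expert,
         template_volume_ie = v_tmpl)
  })
}
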