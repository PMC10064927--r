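edit_kinds <- c("PARTIAL_DISAGREEMENT", "NOT_AN_ISLET", "SEPARATION_LINE",
                "INCLUDE_PART", "EXCLUDE_PART", "FULL_REDRAW",
                "MISSING_CONTOUR")

#' One graphical edit attached to an islet opinion
#'
#' The drawing vocabulary experts use when disputing a contour: mark a
#' disagreeing portion, declare the object a non-islet (no geometry), add a
#' separation line between adjacent islets (open polyline), include/exclude
#' a part, fully redraw the contour, or supply a missing contour (closed
#' polylines).
#'
#' @param kind One of `PARTIAL_DISAGREEMENT`, `NOT_AN_ISLET`,
#'   `SEPARATION_LINE`, `INCLUDE_PART`, `EXCLUDE_PART`, `FULL_REDRAW`,
#'   `MISSING_CONTOUR`.
#' @param geometry A [polyline()], or `NULL` for `NOT_AN_ISLET`.
#' @return A `graphical_edit`.
#' @export
graphical_edit <- function(kind, geometry = NULL) {
  kind <- match.arg(kind, edit_kinds)
  if (kind == "NOT_AN_ISLET") {
    if (!is.null(geometry)) stopf("NOT_AN_ISLET carries no geometry")
  } else {
    if (!inherits(geometry, "polyline")) stopf("%s needs polyline geometry", kind)
    if (kind == "SEPARATION_LINE" && geometry$closed)
      stopf("SEPARATION_LINE geometry must be an open polyline")
    if (kind %in% c("FULL_REDRAW", "MISSING_CONTOUR") && !geometry$closed)
      stopf("%s geometry must be a closed polyline", kind)
  }
  structure(list(kind = kind, geometry = geometry), class = "graphical_edit")
}

#' An expert's qualitative opinion on one micrograph
#'
#' @param expert,image Identifiers.
#' @param quality `"GOOD"` (usable for clinical counting without
#'   hesitation), `"BORDERLINE"` (usable with reservation) or
#'   `"UNACCEPTABLE"`.
#' @param note Optional free-text comment.
#' @return An `image_opinion`.
#' @export
image_opinion <- function(expert, image,
                          quality = c("GOOD", "BORDERLINE", "UNACCEPTABLE"),
                          note = NULL) {
  structure(list(expert = expert, image = image,
                 quality = match.arg(quality), note = note),
            class = "image_opinion")
}

#' An expert's opinion on one marked islet
#'
#' A contour judged correct is `TRUE_CONTOUR`; a disputed contour is
#' `FALSE_CONTOUR` and carries at least one [graphical_edit()]; `SKIPPED`
#' records a refusal to judge and carries none.
#'
#' @param expert,image Identifiers.
#' @param islet Per-set islet number from the manifest.
#' @param verdict `"TRUE_CONTOUR"`, `"FALSE_CONTOUR"` or `"SKIPPED"`.
#' @param edits List of [graphical_edit()]s (only for `FALSE_CONTOUR`).
#' @param note Optional free-text comment.
#' @return An `islet_opinion`.
#' @export
islet_opinion <- function(expert, image, islet,
                          verdict = c("TRUE_CONTOUR", "FALSE_CONTOUR", "SKIPPED"),
                          edits = list(), note = NULL) {
  verdict <- match.arg(verdict)
  structure(list(expert = expert, image = image, islet = as.integer(islet),
                 verdict = verdict, edits = edits, note = note),
            class = "islet_opinion")
}

#' Validate opinions against a selection manifest
#'
#' Checks that every opinion references a manifest image (and, for islet
#' opinions, a marked islet of that image), that no expert submits twice on
#' the same target, that edits appear exactly when the verdict is
#' `FALSE_CONTOUR`, and that each edit's kind/geometry contract holds
#' (enforced at construction, re-checked here).
#'
#' @param ops List of [image_opinion()] / [islet_opinion()] objects.
#' @param manifest A `selection_manifest`.
#' @return `ops` invisibly if valid; otherwise an error listing the first
#'   violations (up to 5).
#' @export
validate_opinions <- function(ops, manifest) {
  viol <- character(0)
  seen <- character(0)
  images <- unique(manifest$entries$image)
  for (i in seq_along(ops)) {
    op <- ops[[i]]
    if (inherits(op, "image_opinion")) {
      if (!op$image %in% images)
        viol <- c(viol, sprintf("opinion %d: unknown image '%s'", i, op$image))
      key <- paste0("img|", op$expert, "|", op$image)
    } else if (inherits(op, "islet_opinion")) {
      here <- manifest$entries$image == op$image
      if (!any(here))
        viol <- c(viol, sprintf("opinion %d: unknown image '%s'", i, op$image))
      else if (!op$islet %in% manifest$entries$set_islet_no[here])
        viol <- c(viol, sprintf("opinion %d: image '%s' has no marked islet %d",
                                i, op$image, op$islet))
      if (op$verdict == "FALSE_CONTOUR" && length(op$edits) == 0L)
        viol <- c(viol, sprintf("opinion %d: FALSE_CONTOUR without edits", i))
      if (op$verdict != "FALSE_CONTOUR" && length(op$edits) > 0L)
        viol <- c(viol, sprintf("opinion %d: %s must carry no edits", i, op$verdict))
      if (!all(vapply(op$edits, inherits, logical(1), "graphical_edit")))
        viol <- c(viol, sprintf("opinion %d: edits must be graphical_edit objects", i))
      key <- paste0("isl|", op$expert, "|", op$image, "|", op$islet)
    } else {
      viol <- c(viol, sprintf("opinion %d: not an opinion object", i))
      next
    }
    if (key %in% seen)
      viol <- c(viol, sprintf("opinion %d: duplicate submission (%s)", i, key))
    seen <- c(seen, key)
  }
  if (length(viol))
    stopf("invalid opinion set:\n%s",
          paste(utils::head(viol, 5), collapse = "\n"))
  invisible(ops)
}

#' Tally qualitative image classifications
#'
#' @param ops List of [image_opinion()]s.
#' @return Data frame per image: counts of `GOOD`/`BORDERLINE`/
#'   `UNACCEPTABLE`, `n_opinions`, and `unanimous` (all submitted opinions
#'   in one class).
#' @export
tally_image_classifications <- function(ops) {
  ops <- Filter(function(o) inherits(o, "image_opinion"), ops)
  df <- data.frame(image = vapply(ops, `[[`, "", "image"),
                   quality = vapply(ops, `[[`, "", "quality"),
                   stringsAsFactors = FALSE)
  tab <- table(factor(df$image, levels = unique(df$image)),
               factor(df$quality, levels = c("GOOD", "BORDERLINE", "UNACCEPTABLE")))
  out <- data.frame(image = rownames(tab), GOOD = as.integer(tab[, "GOOD"]),
                    BORDERLINE = as.integer(tab[, "BORDERLINE"]),
                    UNACCEPTABLE = as.integer(tab[, "UNACCEPTABLE"]),
                    stringsAsFactors = FALSE)
  out$n_opinions <- out$GOOD + out$BORDERLINE + out$UNACCEPTABLE
  out$unanimous <- pmax(out$GOOD, out$BORDERLINE, out$UNACCEPTABLE) == out$n_opinions
  rownames(out) <- NULL
  out
}

#' Tally islet verdicts and graphical opinions
#'
#' A "graphical opinion" is an islet opinion whose edits list is nonempty
#' (a `NOT_AN_ISLET` call counts: it is a drawing-screen act even though it
#' carries no geometry). An islet is "disputed" when it received at least
#' one graphical opinion, and "identity-disputed" when at least one expert
#' called it a non-islet.
#'
#' @param ops List of [islet_opinion()]s.
#' @return List with `per_islet` (data frame: image, islet, verdict counts,
#'   per-edit-kind counts, `n_graphical`, contributing experts) and `totals`
#'   (`n_graphical_opinions`, `n_disputed_islets`,
#'   `n_identity_disputed_islets`).
#' @export
tally_islet_opinions <- function(ops) {
  ops <- Filter(function(o) inherits(o, "islet_opinion"), ops)
  key <- vapply(ops, function(o) paste(o$image, o$islet, sep = "#"), "")
  per <- lapply(split(seq_along(ops), factor(key, levels = unique(key))), function(ix) {
    sub <- ops[ix]
    verd <- vapply(sub, `[[`, "", "verdict")
    kinds <- unlist(lapply(sub, function(o)
      vapply(o$edits, `[[`, "", "kind")))
    graphical <- vapply(sub, function(o) length(o$edits) > 0L, logical(1))
    row <- data.frame(image = sub[[1]]$image, islet = sub[[1]]$islet,
                      TRUE_CONTOUR = sum(verd == "TRUE_CONTOUR"),
                      FALSE_CONTOUR = sum(verd == "FALSE_CONTOUR"),
                      SKIPPED = sum(verd == "SKIPPED"),
                      n_graphical = sum(graphical),
                      stringsAsFactors = FALSE)
    for (k in edit_kinds) row[[k]] <- sum(kinds == k)
    row$experts <- paste(sort(unique(vapply(sub[graphical], `[[`, "", "expert"))),
                         collapse = ";")
    row
  })
  per_islet <- do.call(rbind, per)
  rownames(per_islet) <- NULL
  list(per_islet = per_islet,
       totals = list(
         n_graphical_opinions = sum(per_islet$n_graphical),
         n_disputed_islets = sum(per_islet$n_graphical > 0L),
         n_identity_disputed_islets = sum(per_islet$NOT_AN_ISLET > 0L)))
}

#' Render an anonymized consensus report
#'
#' For every disputed islet, writes a cropped image showing the
#' ground-truth boundary in one color and every expert edit overlaid in a
#' second color, with expert identities replaced by stable anonymous labels
#' `e1..eN`; plus a `consensus.csv` summary of the per-islet tallies.
#'
#' @param manifest A `selection_manifest`.
#' @param ops Validated list of opinions.
#' @param bundle_dir Bundle directory with `images/` and `masks/`.
#' @param out_dir Report directory (created).
#' @param margin_px Crop margin around each islet.
#' @param gt_color Ground-truth overlay color, default blue.
#' @param expert_color Expert overlay color, default white.
#' @param encoding Mask encoding. @param connectivity Labeling connectivity.
#' @return Invisible data frame: the consensus summary (one row per islet,
#'   `crop_file` empty where no edits exist and no crop was emitted).
#' @export
consensus_report <- function(manifest, ops, bundle_dir, out_dir,
                             margin_px = 20L,
                             gt_color = c(0L, 0L, 255L),
                             expert_color = c(255L, 255L, 255L),
                             encoding = default_mask_encoding(),
                             connectivity = 8) {
  validate_opinions(ops, manifest)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  bp <- bundle_paths(bundle_dir)
  islet_ops <- Filter(function(o) inherits(o, "islet_opinion"), ops)
  tal <- tally_islet_opinions(islet_ops)
  experts <- sort(unique(vapply(islet_ops, `[[`, "", "expert")))
  anon <- stats::setNames(paste0("e", seq_along(experts)), experts)
  summary_rows <- tal$per_islet
  summary_rows$experts <- vapply(strsplit(summary_rows$experts, ";"), function(e)
    paste(anon[e[nzchar(e)]], collapse = ";"), "")
  summary_rows$crop_file <- ""
  for (i in seq_len(nrow(summary_rows))) {
    if (summary_rows$n_graphical[i] == 0L) next
    id <- summary_rows$image[i]
    set_no <- summary_rows$islet[i]
    e <- manifest$entries[manifest$entries$image == id &
                          manifest$entries$set_islet_no == set_no, ]
    comp <- label_islets(read_mask(bp$masks[[id]], encoding), connectivity)
    img <- read_image_png(bp$images[[id]])
    bset <- extract_boundaries(comp)
    gt_b <- bset[as.character(e$islet_label)]
    img <- render_overlay(img, gt_b, color = gt_color)
    for (o in islet_ops) {
      if (o$image != id || o$islet != set_no) next
      for (ed in o$edits) {
        if (is.null(ed$geometry)) next
        px <- rasterize_polyline(ed$geometry)
        keep <- px[, 1] >= 1 & px[, 1] <= dim(img)[1] &
                px[, 2] >= 1 & px[, 2] <= dim(img)[2]
        px <- px[keep, , drop = FALSE]
        for (ch in 1:3)
          img[cbind(px[, 1], px[, 2], ch)] <- as.integer(expert_color[ch])
      }
    }
    crop <- crop_islet(img, comp, e$islet_label, margin_px)
    fn <- sprintf("%s_islet%d.png", id, set_no)
    write_image_png(crop, file.path(out_dir, fn))
    summary_rows$crop_file[i] <- fn
  }
  utils::write.csv(summary_rows, file.path(out_dir, "consensus.csv"),
                   row.names = FALSE)
  invisible(summary_rows)
}

#' Export opinions to CSV
#'
#' One row per opinion; graphical edits are serialized as a JSON array in
#' the `edits` column (kind plus polyline vertices).
#'
#' @param ops List of opinions.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_opinions <- function(ops, path) {
  rows <- lapply(ops, function(o) {
    if (inherits(o, "image_opinion"))
      data.frame(type = "image", expert = o$expert, image = o$image,
                 islet = NA_integer_, value = o$quality, edits = "",
                 note = if (is.null(o$note)) "" else o$note,
                 stringsAsFactors = FALSE)
    else
      data.frame(type = "islet", expert = o$expert, image = o$image,
                 islet = o$islet, value = o$verdict,
                 edits = as.character(jsonlite::toJSON(lapply(o$edits, function(e) {
                   rec <- list(kind = e$kind)
                   if (!is.null(e$geometry)) {
                     rec$closed <- e$geometry$closed
                     rec$points <- unname(apply(e$geometry$points, 1,
                                                as.numeric, simplify = FALSE))
                   }
                   rec
                 }), auto_unbox = TRUE, digits = NA)),
                 note = if (is.null(o$note)) "" else o$note,
                 stringsAsFactors = FALSE)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Read opinions exported by [write_opinions()]
#'
#' @param path CSV path.
#' @return List of opinion objects.
#' @export
read_opinions <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(edits = "character", note = "character",
                                       image = "character"))
  lapply(seq_len(nrow(df)), function(i) {
    r <- df[i, ]
    note <- if (nzchar(r$note)) r$note else NULL
    if (r$type == "image")
      image_opinion(r$expert, r$image, r$value, note)
    else {
      edits <- list()
      if (nzchar(r$edits) && r$edits != "[]") {
        parsed <- jsonlite::fromJSON(r$edits, simplifyVector = FALSE)
        edits <- lapply(parsed, function(e) {
          geom <- NULL
          if (length(e$points)) {
            pts <- do.call(rbind, lapply(e$points, unlist))
            geom <- polyline(pts, closed = isTRUE(e$closed), author = r$expert,
                             role = "EXPERT")
          }
          graphical_edit(e$kind, geom)
        })
      }
      islet_opinion(r$expert, r$image, r$islet, r$value, edits, note)
    }
  })
}
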