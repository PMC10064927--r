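mini_manifest <- function() {
  entries <- data.frame(image = c("a", "a", "b"), set_image_no = c(1, 1, 2),
                        islet_label = c(1, 2, 1), set_islet_no = c(1, 2, 1),
                        centroid_row = c(5, 9, 4), centroid_col = c(5, 9, 4),
                        size_category = c(50, 100, 50))
  isletscope:::new_manifest("s", 1L, 50, "VALIDATION", entries)
}

closed_tri <- function(author = "e1") {
  polyline(rbind(c(2, 2), c(2, 8), c(8, 5)), closed = TRUE, author = author)
}

test_that("edit kind/geometry contracts are enforced at construction", {
  expect_silent(graphical_edit("NOT_AN_ISLET"))
  expect_error(graphical_edit("NOT_AN_ISLET", closed_tri()), "no geometry")
  expect_error(graphical_edit("SEPARATION_LINE", closed_tri()), "open")
  expect_error(graphical_edit("FULL_REDRAW",
                              polyline(rbind(c(1, 1), c(2, 2)))), "closed")
  expect_silent(graphical_edit("FULL_REDRAW", closed_tri()))
  expect_silent(graphical_edit("SEPARATION_LINE",
                               polyline(rbind(c(1, 1), c(9, 9)))))
})

test_that("opinion validation flags unknown targets, duplicates and edit misuse", {
  man <- mini_manifest()
  good <- list(image_opinion("e1", "a", "GOOD"),
               islet_opinion("e1", "a", 1, "TRUE_CONTOUR"),
               islet_opinion("e1", "a", 2, "FALSE_CONTOUR",
                             list(graphical_edit("FULL_REDRAW", closed_tri()))))
  expect_silent(validate_opinions(good, man))

  expect_error(validate_opinions(list(image_opinion("e1", "zz", "GOOD")), man),
               "unknown image")
  expect_error(validate_opinions(list(islet_opinion("e1", "a", 9, "TRUE_CONTOUR")),
                                 man), "no marked islet")
  expect_error(validate_opinions(list(
    islet_opinion("e1", "a", 1, "TRUE_CONTOUR",
                  list(graphical_edit("NOT_AN_ISLET")))), man),
    "must carry no edits")
  expect_error(validate_opinions(list(
    islet_opinion("e1", "a", 1, "FALSE_CONTOUR")), man), "without edits")
  dup <- list(image_opinion("e1", "a", "GOOD"),
              image_opinion("e1", "a", "BORDERLINE"))
  expect_error(validate_opinions(dup, man), "duplicate")
})

test_that("image classification tallies count classes and unanimity", {
  ops <- c(lapply(1:8, function(e) image_opinion(paste0("e", e), "a", "GOOD")),
           lapply(1:7, function(e) image_opinion(paste0("e", e), "b", "GOOD")),
           list(image_opinion("e8", "b", "BORDERLINE")))
  tal <- tally_image_classifications(ops)
  expect_equal(tal$n_opinions, c(8, 8))
  expect_equal(tal$unanimous, c(TRUE, FALSE))
  expect_equal(tal$GOOD, c(8, 7))
  expect_equal(tal$BORDERLINE, c(0, 1))
})

test_that("a configured unanimity split is reproduced in the tallies", {
  images <- paste0("img", 1:8)
  contested <- images[5:8]
  ops <- list()
  for (e in paste0("e", 1:8)) for (img in images) {
    q <- if (img %in% contested && e %in% c("e1", "e2")) "UNACCEPTABLE" else "GOOD"
    ops[[length(ops) + 1L]] <- image_opinion(e, img, q)
  }
  tal <- tally_image_classifications(ops)
  expect_equal(sum(tal$unanimous), 4)
  expect_equal(sum(!tal$unanimous), 4)
  expect_equal(nrow(tal), 8)
  expect_equal(sum(tal$n_opinions), 64)
})

test_that("islet tallies count graphical opinions and disputed islets", {
  redraw <- function(e, img, isl)
    islet_opinion(e, img, isl, "FALSE_CONTOUR",
                  list(graphical_edit("FULL_REDRAW", closed_tri(e))))
  ops <- list(redraw("e1", "a", 1), redraw("e2", "a", 1),
              islet_opinion("e3", "a", 1, "TRUE_CONTOUR"),
              islet_opinion("e1", "a", 2, "TRUE_CONTOUR"),
              islet_opinion("e2", "a", 2, "SKIPPED"),
              islet_opinion("e1", "b", 1, "FALSE_CONTOUR",
                            list(graphical_edit("NOT_AN_ISLET"))))
  tal <- tally_islet_opinions(ops)
  expect_equal(tal$totals$n_graphical_opinions, 3)
  expect_equal(tal$totals$n_disputed_islets, 2)
  expect_equal(tal$totals$n_identity_disputed_islets, 1)
  per <- tal$per_islet
  expect_equal(per$n_graphical[per$image == "a" & per$islet == 1], 2)
  expect_equal(per$SKIPPED[per$image == "a" & per$islet == 2], 1)
  # conservation: per-islet graphical counts = opinions with edits
  expect_equal(sum(per$n_graphical),
               sum(vapply(ops, function(o) length(o$edits) > 0, logical(1))))
  # zero disputes when no FALSE verdicts
  tal0 <- tally_islet_opinions(list(islet_opinion("e1", "a", 1, "TRUE_CONTOUR")))
  expect_equal(tal0$totals$n_disputed_islets, 0)
})

test_that("a fixture with 69 graphical opinions over 24 of 33 islets tallies exactly", {
  set.seed(77)
  islets <- data.frame(image = rep(paste0("img", 1:8), c(5, 5, 4, 4, 4, 4, 4, 3)),
                       islet = unlist(lapply(c(5, 5, 4, 4, 4, 4, 4, 3), seq_len)))
  stopifnot(nrow(islets) == 33)
  disputed <- sample.int(33, 24)
  n_ops <- rep(0L, 33)
  n_ops[disputed] <- 1L
  extra <- sample(disputed, 69 - 24, replace = TRUE)
  for (i in extra) n_ops[i] <- n_ops[i] + 1L
  ops <- list()
  for (i in seq_len(33)) {
    for (e in seq_len(n_ops[i]))
      ops[[length(ops) + 1L]] <- islet_opinion(paste0("e", e),
                                               islets$image[i], islets$islet[i],
                                               "FALSE_CONTOUR",
                                               list(graphical_edit("FULL_REDRAW",
                                                                   closed_tri())))
    if (n_ops[i] == 0L)
      ops[[length(ops) + 1L]] <- islet_opinion("e1", islets$image[i],
                                               islets$islet[i], "TRUE_CONTOUR")
  }
  tal <- tally_islet_opinions(ops)
  expect_equal(tal$totals$n_graphical_opinions, 69)
  expect_equal(tal$totals$n_disputed_islets, 24)
  expect_equal(nrow(tal$per_islet), 33)
})

test_that("opinions round-trip through the CSV export", {
  ops <- list(image_opinion("e1", "a", "BORDERLINE", note = "dark image"),
              islet_opinion("e2", "a", 1, "FALSE_CONTOUR",
                            list(graphical_edit("SEPARATION_LINE",
                                                polyline(rbind(c(1, 1), c(9.5, 3)),
                                                         author = "e2")),
                                 graphical_edit("NOT_AN_ISLET"))),
              islet_opinion("e2", "a", 2, "SKIPPED"))
  f <- withr::local_tempfile(fileext = ".csv")
  write_opinions(ops, f)
  back <- read_opinions(f)
  expect_length(back, 3)
  expect_equal(back[[1]]$quality, "BORDERLINE")
  expect_equal(back[[1]]$note, "dark image")
  expect_equal(back[[2]]$verdict, "FALSE_CONTOUR")
  expect_length(back[[2]]$edits, 2)
  expect_equal(back[[2]]$edits[[1]]$kind, "SEPARATION_LINE")
  expect_equal(back[[2]]$edits[[1]]$geometry$points,
               ops[[2]]$edits[[1]]$geometry$points)
  expect_null(back[[2]]$edits[[2]]$geometry)
  expect_equal(back[[3]]$verdict, "SKIPPED")
})

test_that("consensus report anonymizes experts and crops disputed islets only", {
  dir <- withr::local_tempdir()
  make_fixture_bundle(dir, n_images = 2, seed = 42, height_px = 240L,
                      width_px = 240L, islets_per_image = c(3L, 4L))
  man <- build_validation_set(dir, n_images = 2, seed = 8)
  profiles <- lapply(1:3, function(i)
    expert_profile(paste0("secret_name_", i), jitter_sigma_px = 1.5,
                   p_false_call = if (i == 1) 1 else 0.5))
  ops <- simulate_opinions(man, profiles, dir, seed = 4)
  out <- withr::local_tempdir()
  summ <- consensus_report(man, ops, dir, out)
  expect_true(file.exists(file.path(out, "consensus.csv")))
  disputed <- summ[summ$n_graphical > 0, ]
  expect_true(all(nzchar(disputed$crop_file)))
  expect_true(all(file.exists(file.path(out, disputed$crop_file))))
  expect_true(all(summ$crop_file[summ$n_graphical == 0] == ""))
  # anonymization: no real expert id appears anywhere in the report csv
  txt <- readLines(file.path(out, "consensus.csv"))
  expect_false(any(grepl("secret_name", txt)))
  expect_true(any(grepl("e1", disputed$experts)))
  # determinism
  out2 <- withr::local_tempdir()
  summ2 <- consensus_report(man, ops, dir, out2)
  expect_equal(summ, summ2)
})
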