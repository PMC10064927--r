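test_that("rasterization produces 8-connected unit-width chains", {
  horiz <- polyline(rbind(c(5, 3), c(5, 13)))
  px <- rasterize_polyline(horiz)
  expect_equal(nrow(px), 11)
  expect_true(all(px[, 1] == 5))

  degenerate <- polyline(rbind(c(4, 4), c(4, 4)))
  expect_equal(nrow(rasterize_polyline(degenerate)), 1)

  tri <- polyline(rbind(c(2, 2), c(2, 20), c(15, 10)), closed = TRUE)
  px <- rasterize_polyline(tri)
  # chain is a single 8-connected cycle: flood fill from any pixel covers all
  fg <- matrix(FALSE, 20, 22)
  fg[px] <- TRUE
  expect_equal(max(flood_fill_label(fg, 8)), 1)
})

test_that("trimming keeps exactly the in-component pixels", {
  sc <- test_scene()
  lab <- sc$records$islet_label[which.max(sc$records$area_px)]
  ctr <- round(c(sc$records$centroid_row[lab], sc$records$centroid_col[lab]))
  long <- polyline(rbind(ctr - c(0, 200), ctr + c(0, 200)))
  px <- rasterize_polyline(long)
  tr <- trim_to_islet(px, sc$components, lab)
  inb <- px[, 1] >= 1 & px[, 1] <= nrow(sc$components$labels) &
         px[, 2] >= 1 & px[, 2] <= ncol(sc$components$labels)
  member <- px[inb, , drop = FALSE]
  member <- member[sc$components$labels[member] == lab, , drop = FALSE]
  expect_equal(tr, member)
  expect_lt(nrow(tr), nrow(px))

  inside <- polyline(rbind(ctr, ctr + c(0, 3)))
  pxi <- rasterize_polyline(inside)
  expect_equal(trim_to_islet(pxi, sc$components, lab), pxi)
  expect_equal(nrow(trim_to_islet(cbind(1, 1:4), sc$components, lab)), 0)
})

test_that("average line distance matches the all-pairs oracle", {
  set.seed(51)
  for (i in 1:200) {
    a <- random_pixel_set(sample(3:25, 1))
    b <- random_pixel_set(sample(3:25, 1))
    expect_equal(average_line_distance(a, b), allpairs_avg_dist(a, b),
                 tolerance = 1e-9)
  }
})

test_that("distance metric properties: symmetry, identity, translation", {
  set.seed(52)
  a <- random_pixel_set(30); b <- random_pixel_set(25)
  expect_equal(average_line_distance(a, b), average_line_distance(b, a))
  expect_equal(average_line_distance(a, a), 0)
  shift <- cbind(a[, 1] + 17, a[, 2] - 9)
  shiftb <- cbind(b[, 1] + 17, b[, 2] - 9)
  expect_equal(average_line_distance(a, b),
               average_line_distance(shift, shiftb), tolerance = 1e-12)
  expect_error(average_line_distance(a[0, ], b), "nonempty")
})

test_that("a 3 px parallel shift scores exactly 3.0 and asymmetric cases match the oracle", {
  a <- cbind(10, 1:50)
  b <- cbind(13, 1:50)
  expect_equal(average_line_distance(a, b), 3.0)
  short <- cbind(5, 11:20)
  long <- cbind(5, 1:30)
  expect_equal(average_line_distance(short, long),
               allpairs_avg_dist(short, long), tolerance = 1e-12)
  expect_equal(average_line_distance(short, long, directed = TRUE), 0)
})

test_that("the good/poor verdict boundary sits exactly at 2 px", {
  expect_equal(accuracy_verdict(c(0, 1.999, 2.0, 3)),
               c("GOOD", "GOOD", "POOR", "POOR"))
})

test_that("score_accuracy retraces, offsets and empty trims behave", {
  sc <- test_scene()
  lab <- sc$records$islet_label[which.max(sc$records$area_px)]
  ctr <- round(c(sc$records$centroid_row[lab], sc$records$centroid_col[lab]))
  tmpl <- polyline(rbind(ctr - c(0, 30), ctr + c(0, 30)), role = "TEMPLATE")
  same <- score_accuracy(tmpl, tmpl, sc$components, lab)
  expect_equal(same$avg_distance_px, 0)
  expect_equal(same$verdict, "GOOD")

  off <- polyline(rbind(ctr - c(-3, 30), ctr + c(3, 30)), role = "EXPERT")
  res <- score_accuracy(off, tmpl, sc$components, lab)
  expect_equal(res$verdict, "POOR")
  expect_gte(res$avg_distance_px, 2)

  faraway <- polyline(rbind(c(1, 1), c(1, 5)))
  res2 <- score_accuracy(faraway, tmpl, sc$components, lab)
  expect_true(res2$empty_trim)
  expect_equal(res2$verdict, "POOR")
  expect_equal(res2$avg_distance_px, Inf)
})

test_that("contour volume matches analytic discs and the shoelace cross-check", {
  theta <- seq(0, 2 * pi, length.out = 721)[-721]
  circ75 <- polyline(cbind(100 + 75 * sin(theta), 100 + 75 * cos(theta)),
                     closed = TRUE)
  expect_equal(contour_volume(circ75, 1), 1.0, tolerance = 0.02)

  sq <- polyline(rbind(c(10, 10), c(10, 110), c(110, 110), c(110, 10)),
                 closed = TRUE)
  expect_equal(contour_volume(sq, 1), (112.8379 / 150)^3, tolerance = 0.02)
  expect_equal(contour_volume(sq, 1),
               islet_volume_ie(equivalent_diameter(shoelace_area(sq$points), 1)),
               tolerance = 0.02)

  circ160 <- polyline(cbind(200 + 160 * sin(theta), 200 + 160 * cos(theta)),
                      closed = TRUE)
  expect_equal(contour_volume(circ160, 1), (320 / 150)^3, tolerance = 0.01)

  flat <- polyline(rbind(c(5, 5), c(5, 9), c(5, 12)), closed = TRUE)
  expect_warning(v <- contour_volume(flat, 1), "degenerate")
  expect_equal(v, 0)
})

test_that("volume comparison computes RE and normalized volume", {
  eq <- compare_volumes(1, 1)
  expect_equal(eq$relative_error, 0)
  expect_equal(eq$normalized_volume, 1)
  expect_equal(compare_volumes(1.05, 1)$relative_error, 0.05)
  half <- compare_volumes(0.5, 1)
  expect_equal(half$relative_error, 0.5)
  expect_equal(half$normalized_volume, 0.5)
  expect_error(compare_volumes(1, 0), "positive")
})

test_that("replicate CV uses sample sd and excludes zero replicates", {
  expect_equal(replicate_cv(c(1, 1, 1))$cv, 0)
  st <- replicate_cv(c(2, 4, 6))
  expect_equal(st$mean, 4)
  expect_equal(st$cv, 0.5)
  ex <- replicate_cv(c(0, 0.4, 0.5))
  expect_true(ex$excluded)
  expect_true(is.na(ex$cv))
  expect_error(replicate_cv(1), ">= 2")
  expect_equal(replicate_cv(c(2, 4, 6), sd_type = "population")$cv,
               sqrt(8 / 3) / 4)
})

test_that("polylines round-trip through the CSV interchange format", {
  lines <- list(t1 = polyline(rbind(c(1.5, 2), c(8, 9)), role = "TEMPLATE"),
                e1 = polyline(rbind(c(1, 2), c(3, 4), c(5, 2)), closed = TRUE,
                              author = "expert1", ref = "t1"))
  f <- withr::local_tempfile(fileext = ".csv")
  write_polylines(lines, f)
  back <- read_polylines(f)
  expect_equal(names(back), names(lines))
  expect_equal(back$t1$points, lines$t1$points)
  expect_equal(back$e1$closed, TRUE)
  expect_equal(back$e1$ref, "t1")
})
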