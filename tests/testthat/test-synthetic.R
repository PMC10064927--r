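test_that("generated masks carry islets of the requested size", {
  sc <- test_scene()
  rec <- sc$records[!is.na(sc$records$true_diameter_um), ]
  discs <- rec[rec$shape == "disc", ]
  blobs <- rec[rec$shape == "blob", ]
  expect_equal(discs$eq_diameter_um, discs$true_diameter_um, tolerance = 0.02)
  expect_equal(blobs$eq_diameter_um, blobs$true_diameter_um, tolerance = 0.10)
  # embedded islet is wrapped in exocrine tissue
  emb <- rec[rec$embedded, ]
  expect_equal(nrow(emb), 1)
  expect_gt(sum(sc$mask$classes == 1L), 0)
})

test_that("scenes are deterministic under a fixed seed", {
  spec <- scene_spec(120L, 120L, 1.5,
                     data.frame(center_row = 60, center_col = 60,
                                eq_diameter_um = 100),
                     n_exocrine_distractors = 2L, seed = 13L)
  s1 <- make_scene(spec); s2 <- make_scene(spec)
  expect_identical(s1$mask$classes, s2$mask$classes)
  expect_identical(s1$image, s2$image)
})

test_that("empty and invalid specs are handled", {
  empty <- make_scene(scene_spec(40L, 40L, 1, seed = 1L))
  expect_true(all(empty$mask$classes == 0L))
  expect_equal(nrow(empty$records), 0)
  expect_error(scene_spec(100L, 100L, 1,
                          data.frame(center_row = 5, center_col = 50,
                                     eq_diameter_um = 80)), "fit")
  expect_error(scene_spec(100L, 100L, 1,
                          data.frame(center_row = 50, center_col = 50,
                                     eq_diameter_um = 600)), "20, 500")
  overlap <- data.frame(center_row = c(50, 55), center_col = c(50, 55),
                        eq_diameter_um = c(60, 60))
  expect_error(make_scene(scene_spec(100L, 100L, 1, overlap, seed = 2L)),
               "overlaps")
})

test_that("contour templates reproduce component volume; chords cross it", {
  sc <- test_scene()
  rec <- sc$records
  lab <- rec$islet_label[which.max(rec$area_px)]
  ct <- make_template_lines(sc$components, lab, "CONTOUR")
  expect_true(ct$closed)
  v_mask <- rec$volume_ie[rec$islet_label == lab]
  expect_equal(contour_volume(ct, 1), v_mask, tolerance = 0.05)

  sep <- isletscope:::with_seed(3,
    make_template_lines(sc$components, lab, "SEPARATION"))
  expect_false(sep$closed)
  px <- rasterize_polyline(sep)
  tr <- trim_to_islet(px, sc$components, lab)
  expect_gt(nrow(tr), 0)          # interior crossing
  ends <- rbind(px[1, ], px[nrow(px), ])
  expect_equal(nrow(trim_to_islet(ends, sc$components, lab)), 0)  # ends outside
})

test_that("zero jitter reproduces the template exactly", {
  sc <- test_scene()
  ct <- make_template_lines(sc$components, 1, "CONTOUR")
  el <- simulate_expert_line(ct, 0)
  expect_equal(el$points, ct$points)
  expect_true(el$closed)
})

test_that("moderate jitter lands in a plausible accuracy range", {
  sc <- test_scene()
  lab <- sc$records$islet_label[which.max(sc$records$area_px)]
  ct <- make_template_lines(sc$components, lab, "CONTOUR")
  d <- isletscope:::with_seed(9, {
    el <- simulate_expert_line(ct, 2)
    average_line_distance(rasterize_polyline(el), rasterize_polyline(ct))
  })
  expect_gt(d, 0.5)
  expect_lt(d, 4)
})

test_that("measured distance increases with injected jitter with zero inversions", {
  sc <- test_scene()
  lab <- sc$records$islet_label[which.max(sc$records$area_px)]
  ct <- make_template_lines(sc$components, lab, "CONTOUR")
  ct_px <- rasterize_polyline(ct)
  means <- isletscope:::with_seed(1234, vapply(c(0.5, 1, 2, 4), function(s)
    mean(replicate(20, average_line_distance(
      rasterize_polyline(simulate_expert_line(ct, s)), ct_px))), numeric(1)))
  expect_true(all(diff(means) > 0))
  # at sigma >= 1 the mean tracks the folded-normal mean E|N(0,s)|
  expected <- c(0.5, 1, 2, 4) * sqrt(2 / pi)
  expect_true(all(abs(means[-1] / expected[-1] - 1) < 0.25))
})

test_that("simulated opinion sets have the right cardinalities", {
  dir <- withr::local_tempdir()
  make_fixture_bundle(dir, n_images = 3, seed = 6, height_px = 240L,
                      width_px = 240L, islets_per_image = c(3L, 5L))
  man <- build_validation_set(dir, n_images = 3, seed = 2)
  profiles <- lapply(1:4, function(i)
    expert_profile(paste0("e", i), 1, p_false_call = 0.3))
  ops <- simulate_opinions(man, profiles, dir, seed = 10)
  validate_opinions(ops, man)
  img_ops <- Filter(function(o) inherits(o, "image_opinion"), ops)
  isl_ops <- Filter(function(o) inherits(o, "islet_opinion"), ops)
  expect_length(img_ops, 4 * 3)
  expect_length(isl_ops, 4 * nrow(man$entries))
  # p_false_call = 0 gives zero graphical opinions
  quiet <- simulate_opinions(man, list(expert_profile("q", 1, 0, 0)), dir,
                             seed = 11)
  expect_equal(tally_islet_opinions(quiet)$totals$n_graphical_opinions, 0)
})

test_that("fixture bundles are complete and deterministic", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  make_fixture_bundle(d1, n_images = 2, seed = 3, height_px = 200L,
                      width_px = 200L)
  make_fixture_bundle(d2, n_images = 2, seed = 3, height_px = 200L,
                      width_px = 200L)
  expect_true(file.exists(file.path(d1, "pixel_sizes.csv")))
  expect_length(list.files(file.path(d1, "images")), 2)
  expect_length(list.files(file.path(d1, "masks")), 2)
  for (f in c("images/img01.png", "masks/img01.png", "pixel_sizes.csv"))
    expect_identical(readBin(file.path(d1, f), "raw", 1e6),
                     readBin(file.path(d2, f), "raw", 1e6))
  tab <- read_pixel_size_table(file.path(d1, "pixel_sizes.csv"))
  expect_true(all(tab$pixel_size_um_per_px >= 1.41 &
                  tab$pixel_size_um_per_px <= 3.77))
})

test_that("full pipeline runs end to end deterministically", {
  dir <- withr::local_tempdir()
  make_fixture_bundle(dir, n_images = 2, seed = 21, height_px = 220L,
                      width_px = 220L, islets_per_image = c(3L, 4L))
  man <- build_validation_set(dir, n_images = 2, seed = 22,
                              out_dir = file.path(dir, "set"))
  expect_true(file.exists(file.path(dir, "set", "manifest.csv")))
  profiles <- lapply(1:3, function(i) expert_profile(paste0("e", i), 1.5, 0.4))
  ops <- simulate_opinions(man, profiles, dir, seed = 23)
  rep1 <- consensus_report(man, ops, dir, file.path(dir, "rep1"))
  rep2 <- consensus_report(man, ops, dir, file.path(dir, "rep2"))
  expect_equal(rep1, rep2)
})
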