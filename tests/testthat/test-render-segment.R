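test_that("rendered foreground area matches the requested area within 1%", {
  for (pcs in c(10, 60, 150, 300, 400)) {
    img <- render_canopy_image(pcs, overlap_ratio = 2, n_plants = 1,
                               pixel_scale = 0.05, seed = 7)
    gt <- img$ground_truth
    expect_lt(abs(gt$projected_area_cm2 - pcs) / pcs, 0.01)
  }
  # area/pixel-area arithmetic: 100 cm^2 at 0.05 cm/px is 40,000 px
  img <- render_canopy_image(100, 1.5, n_plants = 1, pixel_scale = 0.05,
                             seed = 1)
  expect_lt(abs(img$ground_truth$foreground_px - 40000) / 40000, 0.01)
})

test_that("drawn leaf area tracks the requested overlap ratio", {
  # a dense lettuce-like rosette: 240 cm^2 projected, overlap 5
  img <- render_canopy_image(240, 5, n_plants = 1, pixel_scale = 0.05,
                             seed = 3)
  expect_lt(abs(img$ground_truth$drawn_area_cm2 - 1200) / 1200, 0.10)
  # near-disjoint leaves at overlap ~1.1
  img2 <- render_canopy_image(100, 1.1, n_plants = 1, pixel_scale = 0.05,
                              seed = 3)
  ratio <- img2$ground_truth$drawn_area_cm2 /
    img2$ground_truth$projected_area_cm2
  expect_lt(abs(ratio - 1.1) / 1.1, 0.15)
})

test_that("degenerate render requests are rejected", {
  expect_error(render_canopy_image(0), "> 0")
  expect_error(render_canopy_image(-5), "> 0")
  expect_error(render_canopy_image(100, overlap_ratio = 0.5), ">= 1")
  expect_error(render_canopy_image(100, n_plants = 9, canvas_px = c(50, 50)),
               "canvas capacity")
})

test_that("segmentation recovers the rendered mask exactly on clean images", {
  img <- render_canopy_image(50, 1.6, n_plants = 4, pixel_scale = 0.05,
                             seed = 2, noise_sd = 0)
  seg <- segment_canopy(img, min_object_px = 0, n_plants = 4)
  expect_identical(seg$foreground_pixels, img$ground_truth$foreground_px)
  expect_equal(seg$total_area_cm2,
               img$ground_truth$foreground_px * 0.05^2)
  expect_equal(seg$pcs_per_plant_cm2, seg$total_area_cm2 / 4)
  # with sensor noise the count stays within 1% of truth
  imgn <- render_canopy_image(50, 1.6, n_plants = 4, pixel_scale = 0.05,
                              seed = 2, noise_sd = 0.02)
  segn <- segment_canopy(imgn, n_plants = 4)
  expect_lt(abs(segn$foreground_pixels - imgn$ground_truth$foreground_px) /
              imgn$ground_truth$foreground_px, 0.01)
})

test_that("thresholding edge cases behave as specified", {
  blank <- canopy_image(matrix(0.3, 40, 40), pixel_scale = 0.1)
  expect_error(segment_canopy(blank, method = "otsu"), "no bimodality")
  expect_error(segment_canopy(blank, method = "fixed"), "fixed_threshold")
  # fixed threshold above every intensity: zero area, no error
  seg0 <- segment_canopy(blank, method = "fixed", fixed_threshold = 0.9)
  expect_equal(seg0$total_area_cm2, 0)

  # the threshold is strict: pixels equal to it stay background
  m <- matrix(0.2, 10, 10); m[3:8, 3:8] <- 0.8
  img <- canopy_image(m, pixel_scale = 1)
  seg <- segment_canopy(img, method = "fixed", fixed_threshold = 0.8,
                        min_object_px = 0)
  expect_equal(seg$foreground_pixels, 0L)

  # monotonicity: raising a fixed threshold never adds foreground
  img2 <- render_canopy_image(30, 1.5, n_plants = 1, pixel_scale = 0.05,
                              seed = 5)
  counts <- vapply(seq(0.1, 0.9, by = 0.1), function(th) {
    segment_canopy(img2, method = "fixed", fixed_threshold = th,
                   min_object_px = 0)$foreground_pixels
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("per-plant PCS is the group mean over n_plants", {
  m <- matrix(0, 100, 100); m[1:60, 1:60] <- 1   # 3600 px = 3600 cm^2 at 1 cm/px
  img <- canopy_image(m, pixel_scale = 1, meta = list(n_plants = 9))
  seg <- segment_canopy(img, method = "fixed", fixed_threshold = 0.5)
  expect_equal(seg$total_area_cm2, 3600)
  expect_equal(seg$pcs_per_plant_cm2, 400)
})

test_that("small-object removal uses 8-connectivity", {
  m <- matrix(0, 60, 60)
  for (i in 1:30) m[i, i] <- 1          # diagonal chain, 30 px 8-connected
  m[50, 50] <- 1                        # isolated speckle
  img <- canopy_image(m, pixel_scale = 1)
  seg <- segment_canopy(img, method = "fixed", fixed_threshold = 0.5,
                        min_object_px = 25)
  # the chain survives (4-connectivity would shatter it into 1-px pieces)
  expect_equal(seg$foreground_pixels, 30L)
  expect_false(seg$mask[50, 50])
})

test_that("images round-trip through PNG and TIFF with sidecars", {
  dir <- withr::local_tempdir()
  img <- render_canopy_image(40, 1.5, n_plants = 1, pixel_scale = 0.05,
                             seed = 9)
  img$capture_day <- 14L
  for (ext in c("png", "tif")) {
    p <- file.path(dir, paste0("plant.", ext))
    write_canopy_image(img, p)
    back <- read_canopy_image(p)
    expect_equal(back$pixel_scale, 0.05)
    expect_equal(back$capture_day, 14L)
    expect_equal(dim(back$pixels), dim(img$pixels))
    seg1 <- segment_canopy(img); seg2 <- segment_canopy(back)
    # 8-bit PNG quantisation must not move the segmentation
    expect_equal(seg2$foreground_pixels, seg1$foreground_pixels,
                 tolerance = 0.002)
  }
})

test_that("trajectory assembly groups, sorts and validates", {
  mk <- function(day, pcs) tibble::tibble(
    species = "mizuna", ppfd = 210, block = 1L, day = day,
    pcs_cm2_per_plant = pcs, threshold_used = 0.4)
  scrambled <- dplyr::bind_rows(mk(14, 120), mk(4, 5), mk(25, 300))
  out <- build_trajectories(scrambled)
  expect_equal(out$day, c(4, 14, 25))
  expect_error(build_trajectories(dplyr::bind_rows(mk(4, 5), mk(4, 6))),
               "duplicate")
})
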