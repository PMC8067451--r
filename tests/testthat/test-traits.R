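test_that("trait quotients and their guards", {
  expect_equal(compute_lue(1, 1), 1)
  expect_equal(compute_lue(6.02, 4.78), 6.02 / 4.78)
  expect_error(compute_lue(1, 0), "> 0")
  expect_error(compute_lue(-1, 1), ">= 0")

  expect_equal(compute_sla(100, 1), 100)
  expect_equal(compute_sla(0, 1), 0)
  expect_equal(compute_sla(1200, 3.85), 311.688311688, tolerance = 1e-9)
  expect_error(compute_sla(100, 0), "> 0")

  expect_equal(compute_overlap_ratio(1200, 240), 5)
  expect_equal(compute_overlap_ratio(800, 340), 800 / 340)
  expect_equal(compute_overlap_ratio(240, 240), 1)
  expect_warning(compute_overlap_ratio(100, 240), "overlap ratio < 1")
  expect_error(compute_overlap_ratio(100, 0), "> 0")
})

test_that("traits scale the way ratios must", {
  expect_equal(compute_lue(2 * 1.5, 3), 2 * compute_lue(1.5, 3))
  expect_equal(compute_sla(500, 2 * 2), compute_sla(500, 2) / 2)
  expect_equal(compute_sla(2 * 500, 2), 2 * compute_sla(500, 2))
  expect_equal(compute_overlap_ratio(2 * 500, 250),
               2 * compute_overlap_ratio(500, 250))
})

test_that("the noise-free pipeline returns every unit's LUE within 2%", {
  exp <- generate_experiment(experiment_config(noise = zero_noise(), seed = 2))
  fits <- fit_sigmoids(exp$pcs_long)
  daily <- predict_daily_all(fits)
  light <- incident_light(daily, exp$treatments)
  traits <- compute_traits(exp$harvest, light, fits)
  joined <- dplyr::inner_join(traits, exp$truth,
                              by = c("species", "ppfd", "block"))
  expect_equal(nrow(joined), 36L)
  expect_true(all(abs(joined$lue_g_mol - joined$lue_true_g_mol) /
                    joined$lue_true_g_mol < 0.02))
  # overlap ratio recovered from leaf area and the fitted harvest PCS
  expect_true(all(abs(joined$overlap_ratio - joined$overlap_ratio_true) /
                    joined$overlap_ratio_true < 0.02))
})

test_that("pcs_at_harvest can come from the fit or the last image", {
  exp <- generate_experiment(experiment_config(seed = 21))
  fits <- fit_sigmoids(exp$pcs_long)
  daily <- predict_daily_all(fits)
  light <- incident_light(daily, exp$treatments)
  t_fit <- compute_traits(exp$harvest, light, fits)
  t_img <- compute_traits(exp$harvest, light, fits, pcs_source = "image",
                          pcs_long = exp$pcs_long)
  expect_equal(nrow(t_img), 36L)
  # the two conventions agree to within the trajectory noise scale
  rel <- abs(t_fit$pcs_at_harvest_cm2 - t_img$pcs_at_harvest_cm2) /
    t_fit$pcs_at_harvest_cm2
  expect_lt(median(rel), 0.15)
  expect_error(compute_traits(exp$harvest, light, fits,
                              pcs_source = "image"), "pcs_long")
})
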