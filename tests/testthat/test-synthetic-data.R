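test_that("noise-free trajectories follow the logistic exactly", {
  sp <- default_species_params()$mizuna
  traj <- generate_pcs_trajectory(sp, 210, zero_noise(), days = c(4, 18, 25))
  a <- attr(traj, "true_params")[["a"]]
  expect_equal(a, 340)
  # midpoint is exactly a/2
  expect_equal(traj$pcs[traj$day == 18], a / 2)
  # asymptote: far beyond the midpoint the curve reaches a
  expect_equal(sigmoid(1e3, 340, 18, 3), 340)
  # frozen value computed with an independent calculator
  expect_equal(sigmoid(12, 240, 19, 3.5), 28.6087012853, tolerance = 1e-10)
})

test_that("trajectory preconditions are enforced", {
  sp <- default_species_params()$mizuna
  expect_error(generate_pcs_trajectory(sp, 210, zero_noise(), numeric(0)),
               "empty")
  expect_error(generate_pcs_trajectory(sp, 210, zero_noise(), c(7, 4)),
               "increasing")
  expect_error(generate_pcs_trajectory(sp, 210, zero_noise(), c(4, 30)),
               "harvest_day")
})

test_that("physiology records realise the printed linear responses", {
  sp <- default_species_params()
  ph <- generate_physiology(sp$mizuna, c(50, 400), zero_noise())
  # CCI rises by slope * delta-PPFD: 0.08 * 350 = 28
  expect_equal(diff(ph$cci), 28)
  phl <- generate_physiology(sp$lettuce, c(50, 400), zero_noise())
  expect_equal(diff(phl$aci), 0.004 * 350)
  # intercepts recovered by removing the slope term
  expect_equal(ph$cci - sp$mizuna$cci_slope * ph$ppfd,
               rep(sp$mizuna$cci_intercept, 2))
  # quantum yield stays within physical bounds even with heavy noise
  set.seed(99)
  noisy <- generate_physiology(
    sp$mizuna, rep(six_ppfds, 50),
    noise_model(physiology_sd = c(cci = 0, aci = 0, phipsii = 0.3, assim = 0)))
  expect_true(all(noisy$phipsii >= 0 & noisy$phipsii <= 0.85))
  expect_error(generate_physiology(sp$mizuna, 30, zero_noise()), "50, 425")
})

test_that("the default experiment has the full split-plot layout", {
  exp <- generate_experiment(experiment_config(seed = 42))
  expect_equal(nrow(exp$truth), 36L)            # 6 PPFD x 2 species x 3 blocks
  expect_equal(nrow(exp$harvest), 36L)
  expect_equal(nrow(exp$physiology), 36L)
  # twice-weekly imaging plus the pre-harvest day: 8 days per unit
  expect_equal(nrow(exp$pcs_long), 36L * 8L)
  counts <- dplyr::count(exp$pcs_long, species, ppfd, block)
  expect_true(all(counts$n >= 5L))
})

test_that("identical seeds reproduce the dataset bit-for-bit", {
  e1 <- generate_experiment(experiment_config(seed = 7))
  e2 <- generate_experiment(experiment_config(seed = 7))
  for (tab in c("pcs_long", "physiology", "harvest", "truth")) {
    expect_identical(e1[[tab]], e2[[tab]])
  }
  e3 <- generate_experiment(experiment_config(seed = 8))
  expect_false(identical(e1$pcs_long$pcs_cm2_per_plant,
                         e3$pcs_long$pcs_cm2_per_plant))
})

test_that("noise-free dry weights encode the target LUE exactly", {
  exp <- generate_experiment(experiment_config(noise = zero_noise(), seed = 3))
  joined <- dplyr::inner_join(exp$harvest, exp$truth,
                              by = c("species", "ppfd", "block"))
  expect_equal(joined$dry_weight_g / joined$total_incident_true_mol,
               joined$lue_true_g_mol, tolerance = 1e-12)
  # and leaf area encodes the overlap ratio
  expect_equal(joined$leaf_area_cm2 / joined$pcs_at_harvest_true_cm2,
               joined$overlap_ratio_true, tolerance = 1e-12)
})

test_that("invalid experiment configurations are rejected", {
  expect_error(experiment_config(images = TRUE), "out_dir")
  expect_error(experiment_config(imaging_days = c(4, 7)), "5 imaging days")
  expect_error(experiment_config(blocks = 0), ">= 1")
})
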