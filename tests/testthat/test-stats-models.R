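phys_data <- function(noise, seed = 1) {
  sp <- default_species_params()
  set.seed(seed)
  dplyr::bind_rows(purrr::map(sp, function(p) {
    dplyr::bind_rows(purrr::map(1:3, function(b) {
      dplyr::mutate(generate_physiology(p, six_ppfds, noise), block = b)
    }))
  }))
}

test_that("a shared slope with a species offset prunes the interaction", {
  d <- phys_data(zero_noise())
  fit <- fit_species_ppfd_model(d, phipsii)
  expect_true(fit$interaction_dropped)
  expect_equal(nrow(fit$coefficients), 3L)     # intercept, slope, offset
  expect_equal(fit$slopes$slope, c(-3e-4, -3e-4))
  expect_equal(fit$species_offset, 0.05)
  expect_equal(fit$r_squared, 1)
  # zero-noise p-values are undefined, reported as NA, never invented
  expect_true(all(is.na(fit$coefficients$p.value)))
})

test_that("species-specific slopes keep the interaction and are recovered", {
  d <- phys_data(zero_noise())
  fit <- fit_species_ppfd_model(d, cci)
  expect_false(fit$interaction_dropped)
  expect_equal(fit$slopes$slope[fit$slopes$species == "mizuna"], 0.08)
  expect_equal(fit$slopes$slope[fit$slopes$species == "lettuce"], 0.01)

  # at the default noise the CCI interaction is overwhelmingly significant
  fitn <- fit_species_ppfd_model(phys_data(noise_model(), seed = 5), cci)
  expect_false(fitn$interaction_dropped)
  expect_lt(fitn$interaction_p, 0.05)
  expect_equal(fitn$slopes$slope[fitn$slopes$species == "mizuna"], 0.08,
               tolerance = 0.15)
})

test_that("a constant response yields a clean degenerate fit", {
  d <- phys_data(zero_noise())
  d$flatline <- 5
  fit <- fit_species_ppfd_model(d, flatline)
  expect_true(fit$interaction_dropped)
  expect_equal(fit$r_squared, 0)
  expect_equal(fit$slopes$slope, c(0, 0))
  expect_equal(fit$species_offset, 0)
  expect_true(all(is.na(fit$coefficients$p.value)))
})

test_that("swapping the reference species only flips the offset", {
  d <- phys_data(noise_model(), seed = 11)
  f1 <- fit_species_ppfd_model(d, phipsii, reference = "lettuce")
  f2 <- fit_species_ppfd_model(d, phipsii, reference = "mizuna")
  expect_equal(f1$species_offset, -f2$species_offset)
  expect_equal(f1$interaction_dropped, f2$interaction_dropped)
  expect_equal(unname(sort(stats::fitted(f1$model))),
               unname(sort(stats::fitted(f2$model))))
  expect_equal(dplyr::arrange(f1$slopes, species),
               dplyr::arrange(f2$slopes, species))
})

test_that("regression preconditions are enforced", {
  d <- phys_data(zero_noise())
  expect_error(fit_species_ppfd_model(dplyr::filter(d, species == "mizuna"),
                                      cci), "two species")
  expect_error(fit_species_ppfd_model(d, cci, alpha = 1.2), "0, 1")
  few <- dplyr::filter(d, ppfd %in% c(53, 128))
  expect_error(fit_species_ppfd_model(few, cci), "3 PPFD")
})

test_that("response-curve forms are fitted and recovered", {
  x <- six_ppfds
  # exponential rise to maximum: exact recovery of the generating curve
  y <- 340 * (1 - exp(-0.015 * x))
  fit <- fit_response_curve(x, y, "exponential_rise")
  est <- coef(fit)
  expect_lt(abs(est[["A"]] - 340) / 340, 1e-3)
  expect_lt(abs(est[["k"]] - 0.015) / 0.015, 1e-3)
  expect_gt(fit$r_squared, 0.9999)

  # collinear points: perfect linear fit
  lin <- fit_response_curve(c(1, 2, 3), c(2, 4, 6), "linear")
  expect_equal(lin$r_squared, 1)
  expect_equal(unname(coef(lin)["slope"]), 2)

  # two published dry-weight endpoints give the published slope
  dw <- fit_response_curve(c(50, 425), c(0.11, 6.02), "linear")
  expect_equal(signif(coef(dw)[["slope"]] * 1000, 3), 15.8)

  quad <- fit_response_curve(x, 1 + 0.2 * x - 3e-4 * x^2, "quadratic")
  expect_equal(unname(coef(quad)), c(1, 0.2, -3e-4), tolerance = 1e-8)

  sig <- fit_response_curve(0:27, sigmoid(0:27, 300, 14, 4), "sigmoid")
  expect_equal(unname(coef(sig)), c(300, 14, 4), tolerance = 1e-4)

  expect_error(fit_response_curve(c(1, 2), c(1, 2), "quadratic"),
               "at least 3")
})

test_that("early-PCS correlation behaves at its extremes", {
  expect_equal(early_pcs_correlation(1:10, 2 * (1:10))$estimate, 1)
  expect_equal(early_pcs_correlation(1:10, -3 * (1:10))$estimate, -1)
  expect_error(early_pcs_correlation(rep(1, 5), 1:5), "zero variance")
  expect_error(early_pcs_correlation(1:2, 1:2), "at least 3")
})

test_that("early canopy size predicts final biomass in the generator", {
  rs <- purrr::map_dfr(1:10, function(s) {
    run_pipeline(run_config(seed = s))$early_pcs
  })
  med <- dplyr::summarise(dplyr::group_by(rs, species),
                          r = median(estimate), p = max(p.value))
  expect_true(all(med$r > 0.65))
  expect_true(all(med$p < 0.01))
  expect_equal(unique(rs$n), 18L)     # 6 PPFDs x 3 blocks per species
})
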