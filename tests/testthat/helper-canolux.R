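## shared fixtures, all built in code

six_ppfds <- c(53, 128, 210, 281, 345, 410)
imaging_days <- c(4, 7, 11, 14, 18, 21, 25)

zero_noise <- function(seed = 1L) {
  noise_model(pcs_cv = 0, dw_cv = 0,
              physiology_sd = c(cci = 0, aci = 0, phipsii = 0, assim = 0),
              seed = seed)
}

clean_trajectory <- function(a = 340, x0 = 18, b = 3, days = imaging_days) {
  data.frame(day = days, pcs = sigmoid(days, a, x0, b))
}

## independent fine-grid trapezoid oracle for the incident-light total:
## the daily sum treats each integer day as a unit-width bin, so the
## matching continuous integral runs over [-0.5, harvest + 0.5]
quadrature_total <- function(a, x0, b, dli, harvest_day, n = 1000) {
  x <- seq(-0.5, harvest_day + 0.5, length.out = n)
  y <- a / (1 + exp(-(x - x0) / b)) * 1e-4 * dli
  sum((y[-1] + y[-n]) / 2 * diff(x))
}

## noisy per-unit trajectory for fit-quality sweeps
noisy_trajectory <- function(seed, cv = 0.05, a = 340, x0 = 18, b = 3,
                             days = imaging_days) {
  params <- species_params(
    name = "mizuna",
    pcs_asymptote_by_ppfd = c(`210` = a),
    midpoint_day = x0, shape_b = b,
    overlap_ratio_by_ppfd = c(`210` = 2),
    lue_by_ppfd = c(`210` = 1.1),
    cci_slope = 0.08, cci_intercept = 3,
    aci_slope = 0.015, aci_intercept = 2.25,
    phipsii_slope = -3e-4, phipsii_intercept = 0.77,
    assim_slope = 0.044, assim_intercept = -1.2,
    harvest_day = 27
  )
  set.seed(seed)
  generate_pcs_trajectory(params, 210, noise_model(pcs_cv = cv), days)
}
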