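#' Three-parameter logistic (sigmoid) growth curve
#'
#' `f(x) = a / (1 + exp(-(x - x0) / b))`: `a` is the asymptotic projected
#' canopy size (cm² per plant), `x0` the inflection day (where `f = a/2`)
#' and `b` the shape parameter (days).
#'
#' @param x Day (numeric vector).
#' @param a Asymptote (cm²), > 0.
#' @param x0 Inflection day.
#' @param b Shape (days), > 0.
#' @return Numeric vector of canopy sizes.
#' @examples
#' sigmoid(18, a = 340, x0 = 18, b = 3) # a/2 = 170
#' @export
sigmoid <- function(x, a, x0, b) a / (1 + exp(-(x - x0) / b))

#' Fit a sigmoidal growth curve to a PCS trajectory
#'
#' Nonlinear least squares (Levenberg--Marquardt, via
#' [minpack.lm::nlsLM()]) of the three-parameter logistic to one projected
#' canopy size (PCS) time series. Starting values are analytic: `a0 = 1.05 *
#' max(pcs)`, `x0_0` the day whose PCS is nearest half of `a0`, `b0 =
#' (last_day - first_day) / 6`; on failure up to five deterministic jittered
#' restarts are tried. Parameters are bounded (`a` in (0, 10 max(pcs)], `b`
#' in [0.1, 30] days, `x0` in [-10, max(day) + 10]) to exclude flat-line and
#' step-function degenerate optima.
#'
#' @param data Data frame with one row per imaging day.
#' @param day,pcs Columns of `data` holding the day (days after seeding) and
#'   PCS (cm² per plant); tidy-evaluated, defaults `day` and `pcs`.
#' @return An object of class `sigmoid_fit` with elements `a`, `x0`, `b`,
#'   `r_squared`, `residual_sd`, `converged`, `n_points` and the underlying
#'   `nls` fit. `tidy()` and `glance()` methods are provided.
#' @section Errors:
#' Fewer than 4 distinct days, negative PCS, a flat trajectory
#' (`"no growth signal"`), or non-convergence after all restarts (the error
#' condition carries the best attempt in its `best` field) raise errors;
#' there is no silent fallback.
#' @examples
#' d <- data.frame(day = c(4, 7, 11, 14, 18, 21, 25))
#' d$pcs <- sigmoid(d$day, a = 340, x0 = 18, b = 3)
#' fit <- fit_sigmoid(d)
#' coef(fit)
#' @export
fit_sigmoid <- function(data, day = day, pcs = pcs) {
  d <- dplyr::transmute(as.data.frame(data),
                        day = {{ day }}, pcs = {{ pcs }})
  if (length(unique(d$day)) < 4L) {
    abort("need at least 4 distinct imaging days to fit 3 parameters")
  }
  if (any(!is.finite(d$pcs)) || any(d$pcs < 0)) {
    abort("PCS values must be finite and non-negative")
  }
  sst <- sum((d$pcs - mean(d$pcs))^2)
  if (sst == 0 || diff(range(d$pcs)) < 1e-9 * max(d$pcs, 1e-12)) {
    abort("no growth signal: trajectory is flat")
  }

  a0 <- 1.05 * max(d$pcs)
  x00 <- d$day[which.min(abs(d$pcs - a0 / 2))]
  b0 <- (max(d$day) - min(d$day)) / 6
  lower <- c(a = 1e-9, x0 = -10, b = 0.1)
  upper <- c(a = 10 * max(d$pcs), x0 = max(d$day) + 10, b = 30)
  ## deterministic jitter ladder: no RNG so fitting never perturbs seeds
  jit <- list(c(1, 1, 1), c(0.8, 0.9, 1.3), c(1.2, 1.1, 0.7),
              c(0.9, 1.2, 1.6), c(1.1, 0.8, 0.5), c(0.7, 1.05, 2))

  best <- NULL
  for (j in jit) {
    start <- list(a = min(max(a0 * j[1], lower["a"]), upper["a"]),
                  x0 = min(max(x00 * j[2], lower["x0"]), upper["x0"]),
                  b = min(max(b0 * j[3], lower["b"]), upper["b"]))
    res <- tryCatch(
      minpack.lm::nlsLM(pcs ~ a / (1 + exp(-(day - x0) / b)),
                        data = d, start = start,
                        lower = lower, upper = upper,
                        control = nls.control(maxiter = 200, warnOnly = FALSE)),
      error = function(e) e
    )
    if (!inherits(res, "error")) { best <- res; break }
  }
  if (is.null(best)) {
    abort("sigmoid fit did not converge after bounded restarts",
          class = "canolux_fit_error", best = res)
  }

  est <- coef(best)
  sse <- sum(stats::residuals(best)^2)
  structure(
    list(
      a = unname(est["a"]), x0 = unname(est["x0"]), b = unname(est["b"]),
      r_squared = 1 - sse / sst,
      residual_sd = sqrt(sse / max(nrow(d) - 3, 1)),
      converged = best$convInfo$isConv %||% TRUE,
      n_points = nrow(d),
      fit = best,
      data = tibble::as_tibble(d)
    ),
    class = "sigmoid_fit"
  )
}

#' @export
print.sigmoid_fit <- function(x, ...) {
  cat(sprintf(
    "<sigmoid_fit> a = %.2f cm^2, x0 = %.2f d, b = %.2f d (R^2 = %.4f, n = %d)\n",
    x$a, x$x0, x$b, x$r_squared, x$n_points))
  invisible(x)
}

#' @export
coef.sigmoid_fit <- function(object, ...) {
  c(a = object$a, x0 = object$x0, b = object$b)
}

#' @rdname fit_sigmoid
#' @param x,object A `sigmoid_fit`.
#' @param ... Unused.
#' @export
tidy.sigmoid_fit <- function(x, ...) {
  s <- summary(x$fit)$coefficients
  tibble::tibble(
    term = rownames(s),
    estimate = s[, "Estimate"],
    std.error = s[, "Std. Error"],
    statistic = s[, "t value"],
    p.value = s[, "Pr(>|t|)"]
  )
}

#' @rdname fit_sigmoid
#' @export
glance.sigmoid_fit <- function(x, ...) {
  tibble::tibble(
    r.squared = x$r_squared,
    sigma = x$residual_sd,
    nobs = x$n_points,
    converged = x$converged
  )
}

#' Daily PCS series from a fitted sigmoid
#'
#' Evaluates a converged sigmoid fit at integer days 0..`harvest_day`
#' (day 0 = seeding), the grid on which incident light is accumulated.
#'
#' @param fit A [fit_sigmoid()] result, or a named vector/list with
#'   elements `a`, `x0`, `b` (a known-truth curve).
#' @param harvest_day Last day of the series (>= 1).
#' @return Tibble with columns `day` (0..harvest_day) and `pcs` (cm²/plant).
#' @export
predict_daily <- function(fit, harvest_day) {
  stopifnot_scalar_number(harvest_day, "harvest_day")
  if (harvest_day < 1) abort("`harvest_day` must be >= 1")
  if (inherits(fit, "sigmoid_fit")) {
    if (!isTRUE(fit$converged)) abort("cannot predict from an unconverged fit")
    pars <- coef(fit)
  } else {
    pars <- unlist(fit)[c("a", "x0", "b")]
    if (any(is.na(pars))) abort("`fit` must provide a, x0 and b")
  }
  days <- 0:harvest_day
  tibble::tibble(day = days,
                 pcs = sigmoid(days, pars[["a"]], pars[["x0"]], pars[["b"]]))
}

#' Fit sigmoids to every experimental unit
#'
#' Groups a long PCS table by `species`, `ppfd` and `block` and fits one
#' sigmoid per unit (the per-replicate fits of the standard workflow).
#'
#' @param pcs_long Tibble with columns `species`, `ppfd`, `block`, `day`
#'   and `pcs_cm2_per_plant` (or `pcs`).
#' @param pooled If `TRUE`, fit one curve per `species` x `ppfd`, pooling
#'   blocks. Default `FALSE`.
#' @return Tibble with the group keys, `a`, `x0`, `b`, `r_squared`,
#'   `residual_sd`, `converged`, `n_points` and a list-column `fit`.
#' @export
fit_sigmoids <- function(pcs_long, pooled = FALSE) {
  df <- tibble::as_tibble(pcs_long)
  if (!"pcs" %in% names(df) && "pcs_cm2_per_plant" %in% names(df)) {
    df$pcs <- df$pcs_cm2_per_plant
  }
  keys <- if (pooled) c("species", "ppfd") else c("species", "ppfd", "block")
  if (!all(c(keys, "day", "pcs") %in% names(df))) {
    abort(paste("`pcs_long` must have columns",
                paste(c(keys, "day", "pcs (or pcs_cm2_per_plant)"),
                      collapse = ", ")))
  }
  tidyr::nest(df, data = -dplyr::all_of(keys)) |>
    dplyr::mutate(fit = purrr::map(data, fit_sigmoid)) |>
    dplyr::mutate(
      a = purrr::map_dbl(fit, "a"),
      x0 = purrr::map_dbl(fit, "x0"),
      b = purrr::map_dbl(fit, "b"),
      r_squared = purrr::map_dbl(fit, "r_squared"),
      residual_sd = purrr::map_dbl(fit, "residual_sd"),
      converged = purrr::map_lgl(fit, "converged"),
      n_points = purrr::map_int(fit, "n_points")
    ) |>
    dplyr::select(-data)
}

#' Daily PCS for every fitted unit
#'
#' @param fits Result of [fit_sigmoids()].
#' @param harvest_days Named vector of harvest days per species,
#'   default `c(mizuna = 27, lettuce = 28)`.
#' @return Long tibble `species`, `ppfd`, `block`, `day`, `pcs`.
#' @export
predict_daily_all <- function(fits, harvest_days = c(mizuna = 27, lettuce = 28)) {
  missing_sp <- setdiff(unique(fits$species), names(harvest_days))
  if (length(missing_sp)) {
    abort(paste("no harvest day given for species:",
                paste(missing_sp, collapse = ", ")))
  }
  keys <- intersect(c("species", "ppfd", "block"), names(fits))
  fits |>
    dplyr::mutate(daily = purrr::map2(fit, species, function(f, sp) {
      predict_daily(f, harvest_days[[sp]])
    })) |>
    dplyr::select(dplyr::all_of(keys), daily) |>
    tidyr::unnest(daily)
}
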